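# Stage orchestration: a YAML-configured run that chains
# simulate/ingest -> differential expression -> attribute weighting ->
# ensemble ranking -> PCA -> (posterior) -> (network / repurposing), plus
# the command-line dispatcher behind the `crsig` script.

#' Read and validate a YAML run configuration
#'
#' Unknown keys are rejected so typos fail fast. See [run_pipeline()] for
#' the recognized keys and their defaults.
#'
#' @param path YAML file path
#' @return named list of class `cr_run_config`
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg named list of configuration values
#' @export
validate_run_config <- function(cfg) {
  known <- c("counts", "samples", "annotation", "relations", "preset",
             "seed", "bins", "relief_k", "k_signature", "transform",
             "prefilter_fdr", "rope", "max_drugs", "n_genes", "n_spike",
             "spike_log2fc", "tissues", "n_per_group")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  defaults <- list(seed = 1, bins = 5, relief_k = 10, k_signature = 20,
                   transform = "log2cpm", max_drugs = 4)
  for (k in names(defaults))
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  class(cfg) <- "cr_run_config"
  cfg
}

# derived per-stage seeds, kept below 2^31
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 101, de = 211, weigh = 307, posterior = 401,
               relations = 503)
  (as.integer(seed) * 7919 + offsets[[stage]]) %% .Machine$integer.max
}

log_msg <- function(...) {
  message(sprintf("[crsig %s] ", format(Sys.time(), "%H:%M:%S")),
          sprintf(...))
}

#' Run the full signature-discovery pipeline
#'
#' Stages: load (or simulate) counts and samples; per-tissue NB Wald
#' differential expression; attribute weighting of all features; ensemble
#' ranking and top-k signature; PCA evaluation of the signature; and, when a
#' relation corpus is configured, network construction and greedy
#' drug-combination selection. All stage tables land in `out_dir` as TSV
#' together with a JSON run manifest recording the seed, configuration and
#' output files.
#'
#' @param cfg a `cr_run_config` (or plain list passed through
#'   [validate_run_config()])
#' @param out_dir output directory (created if missing)
#' @return invisibly, the manifest list
#' @export
run_pipeline <- function(cfg, out_dir) {
  cfg <- validate_run_config(unclass(cfg))
  if (!is.null(cfg$counts) && !file.exists(cfg$counts))
    stop("counts file not found: ", cfg$counts)
  if (!is.null(cfg$samples) && !file.exists(cfg$samples))
    stop("samples file not found: ", cfg$samples)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(name, writer, obj) {
    path <- file.path(out_dir, name)
    writer(obj, path)
    outputs <<- c(outputs, name)
    path
  }

  if (!is.null(cfg$counts)) {
    log_msg("loading counts from %s", cfg$counts)
    cm <- read_count_matrix(cfg$counts)
    st <- read_sample_table(cfg$samples)
  } else {
    log_msg("simulating counts (preset seed %d)", cfg$seed)
    args <- cfg[intersect(names(cfg),
                          c("n_genes", "n_spike", "spike_log2fc",
                            "tissues", "n_per_group"))]
    args$seed <- stage_seed(cfg$seed, "simulate")
    sim <- do.call(sim_config, args)
    gen <- simulate_counts(sim)
    cm <- gen$counts; st <- gen$samples
    emit("counts.tsv", write_count_matrix, cm)
    emit("samples.tsv", write_sample_table, st)
    emit("truth.tsv", function(x, p)
      utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE),
      gen$truth)
  }

  log_msg("differential expression per tissue")
  for (tis in levels(st$tissue)) {
    de <- nb_wald_test(cm, st, tissue = tis)
    emit(sprintf("de_%s.tsv", tis), write_de_result, de)
  }

  gene_subset <- NULL
  if (!is.null(cfg$prefilter_fdr)) {
    de_all <- nb_wald_test(cm, st)
    gene_subset <- de_all$gene_id[!is.na(de_all$fdr_q) &
                                  de_all$fdr_q < cfg$prefilter_fdr]
    log_msg("prefilter fdr < %g keeps %d genes", cfg$prefilter_fdr,
            length(gene_subset))
  }

  log_msg("attribute weighting (%d bins, relief k = %d)", cfg$bins,
          cfg$relief_k)
  ft <- build_feature_table(cm, st, transform = cfg$transform,
                            gene_subset = gene_subset)
  w <- weigh_features(ft, bins = cfg$bins, relief_k = cfg$relief_k,
                      seed = stage_seed(cfg$seed, "weigh"))
  emit("weights.tsv", write_weights, w)

  log_msg("ensemble ranking and signature (k = %d)", cfg$k_signature)
  er <- ensemble_overall_weights(w)
  emit("ranking.tsv", function(x, p)
    utils::write.table(as.data.frame(x), p, sep = "\t", quote = FALSE,
                       row.names = FALSE), er)
  ann <- if (!is.null(cfg$annotation)) read_annotation_table(cfg$annotation)
  sig <- rank_and_select(er, k = cfg$k_signature, annotation = ann)
  emit("signature.tsv", write_signature, sig)
  tir <- tissue_independence_report(er)
  log_msg("tissue attribute: W = %.3f, rank %d/%d", tir$overall_weight,
          tir$rank, tir$n_features)

  pca <- pca_correlation(ft, genes = sig$feature)
  sep <- separation_on_pc1(pca, feature_label(ft))
  emit("pca_scores.tsv", function(x, p)
    utils::write.table(data.frame(sample_id = rownames(x$scores), x$scores),
                       p, sep = "\t", quote = FALSE, row.names = FALSE), pca)
  emit("pca_loadings.tsv", function(x, p)
    utils::write.table(data.frame(gene_id = rownames(x$loadings),
                                  x$loadings),
                       p, sep = "\t", quote = FALSE, row.names = FALSE), pca)
  log_msg("PC1 variance fraction %.3f, label separation %.2f",
          pca$variance_fraction[1], sep$fraction)

  repurposing <- NULL
  if (!is.null(cfg$relations)) {
    log_msg("relation network and drug repurposing")
    rec <- load_relations(cfg$relations)
    net <- build_network(aggregate_confidence(rec))
    emit("edges.tsv", write_edge_list, net)
    emit("network.graphml", function(x, p) write_graphml(x, p), net)
    dr <- rank_drugs(net, sig$feature)
    emit("drug_ranking.tsv", function(x, p)
      utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE),
      dr)
    combo <- select_drug_combination(net, sig$feature,
                                     max_drugs = cfg$max_drugs)
    repurposing <- list(drugs = combo$drugs, covered = combo$covered,
                        uncovered = combo$uncovered)
  }

  manifest <- list(
    package = "crsig",
    version = as.character(utils::packageVersion("crsig")),
    seed = cfg$seed,
    config = unclass(cfg),
    tissue_report = tir,
    pc1_variance_fraction = unname(pca$variance_fraction[1]),
    pc1_separation = sep,
    repurposing = repurposing,
    outputs = outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "run_config.yaml"))
  log_msg("done; %d outputs in %s", length(outputs) + 2, out_dir)
  invisible(manifest)
}

#' Command-line entry point
#'
#' Dispatches `crsig <subcommand>`; see `crsig help`. Installed as
#' `inst/cli/crsig`, runnable as
#' `Rscript -e 'crsig::crsig_main()' <subcommand> ...` or via the script.
#'
#' @param args command-line arguments (default `commandArgs(trailingOnly =
#'   TRUE)`)
#' @return exit status, invisibly
#' @export
crsig_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: crsig <command> [options]",
    "commands:",
    "  run        --config run.yaml --out DIR   full pipeline",
    "  simulate   --seed N --out DIR            synthetic counts/samples/truth",
    "  de         --counts F --samples F --tissue T --out F",
    "  weigh      --counts F --samples F --bins 5 --relief-k 10 --out F",
    "  rank       --weights F --k 20 --out F    ensemble ranking + signature",
    "  posterior  --data F --out F              subject,group,outcome TSV",
    "  network    --relations F --out DIR",
    "  repurpose  --relations F --signature F --max-drugs 4",
    sep = "\n")
  if (length(args) == 0 || args[1] %in% c("help", "--help", "-h")) {
    cat(usage, "\n")
    return(invisible(0L))
  }
  cmd <- args[1]
  opts <- parse_cli_opts(args[-1])
  getopt <- function(name, default = NULL, required = FALSE) {
    v <- opts[[name]]
    if (is.null(v)) {
      if (required) stop("missing required option --", name)
      return(default)
    }
    v
  }
  switch(cmd,
    run = {
      cfg <- read_run_config(getopt("config", required = TRUE))
      run_pipeline(cfg, getopt("out", "crsig_out"))
    },
    simulate = {
      out <- getopt("out", "crsig_out")
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      cfg <- sim_config(seed = as.integer(getopt("seed", 1)),
                        duration = getopt("preset", "short"))
      gen <- simulate_counts(cfg)
      write_count_matrix(gen$counts, file.path(out, "counts.tsv"))
      write_sample_table(gen$samples, file.path(out, "samples.tsv"))
      utils::write.table(gen$truth, file.path(out, "truth.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    },
    de = {
      cm <- read_count_matrix(getopt("counts", required = TRUE))
      st <- read_sample_table(getopt("samples", required = TRUE))
      de <- nb_wald_test(cm, st, tissue = getopt("tissue"))
      write_de_result(de, getopt("out", "de.tsv"))
    },
    weigh = {
      cm <- read_count_matrix(getopt("counts", required = TRUE))
      st <- read_sample_table(getopt("samples", required = TRUE))
      ft <- build_feature_table(cm, st)
      w <- weigh_features(ft, bins = as.integer(getopt("bins", 5)),
                          relief_k = as.integer(getopt("relief-k", 10)))
      write_weights(w, getopt("out", "weights.tsv"))
    },
    rank = {
      wdf <- utils::read.table(getopt("weights", required = TRUE),
                               header = TRUE, sep = "\t",
                               check.names = FALSE)
      w <- as.matrix(wdf[, -1]); rownames(w) <- wdf[[1]]
      er <- ensemble_overall_weights(w)
      sig <- rank_and_select(er, k = as.integer(getopt("k", 20)))
      write_signature(sig, getopt("out", "signature.tsv"))
    },
    posterior = {
      df <- utils::read.table(getopt("data", required = TRUE), header = TRUE,
                              sep = "\t", stringsAsFactors = FALSE)
      draws <- fit_group_model(df$outcome, df$group,
                               seed = as.integer(getopt("seed", 1)))
      summ <- posterior_summary(draws)
      cat(format(summ), "\n")
      out <- getopt("out")
      if (!is.null(out)) writeLines(format(summ), out)
    },
    network = {
      rec <- load_relations(getopt("relations", required = TRUE))
      net <- build_network(aggregate_confidence(rec))
      out <- getopt("out", "crsig_out")
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      write_edge_list(net, file.path(out, "edges.tsv"))
      write_graphml(net, file.path(out, "network.graphml"))
    },
    repurpose = {
      rec <- load_relations(getopt("relations", required = TRUE))
      net <- build_network(aggregate_confidence(rec))
      sig <- utils::read.table(getopt("signature", required = TRUE),
                               header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
      combo <- select_drug_combination(
        net, sig$feature, max_drugs = as.numeric(getopt("max-drugs", 4)))
      cat("combination:", paste(combo$drugs, collapse = ", "), "\n")
      cat("covered:", paste(combo$covered, collapse = ", "), "\n")
      if (length(combo$uncovered) > 0)
        cat("uncovered:", paste(combo$uncovered, collapse = ", "), "\n")
    },
    stop("unknown command '", cmd, "'\n", usage)
  )
  invisible(0L)
}

# parse "--key value" pairs into a named list
parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (i == length(args) || startsWith(args[i + 1], "--")) {
      opts[[key]] <- TRUE
      i <- i + 1
    } else {
      opts[[key]] <- args[i + 1]
      i <- i + 2
    }
  }
  opts
}
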