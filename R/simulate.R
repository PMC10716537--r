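# Seeded generators reproducing the statistical structure every pipeline
# stage assumes: negative-binomial counts with tissue effects, library-size
# variation and a spiked set of treatment-responsive genes; Gaussian
# posterior draw vectors; and toy mined-relation corpora.

#' Simulation configuration for the count generator
#'
#' Defaults mirror the emulated study design: four tissues, five animals per
#' tissue and treatment group, 1000 genes with log-normal-ish baseline
#' abundance, NB dispersion drawn log-normally around 0.05, ten spiked
#' treatment-responsive genes at |log2FC| = 2 (half up, half down), modest
#' per-gene tissue effects, and library-size factors varying about 2-fold.
#'
#' @param seed RNG seed
#' @param n_genes gene count (default 1000)
#' @param tissues tissue level names (default 4 brain/endocrine tissues)
#' @param n_per_group samples per tissue per treatment (default 5)
#' @param baseline_meanlog2,baseline_sdlog2 Normal parameters of the per-gene
#'   baseline log2 mean count (default 6 and 2)
#' @param dispersion_meanlog,dispersion_sdlog log-Normal parameters of the
#'   per-gene NB dispersion (default log(0.05), 0.3)
#' @param n_spike number of treatment-responsive genes (default 10)
#' @param spike_log2fc absolute log2 fold change of spiked genes (default 2)
#' @param tissue_sd_log2 SD of per-gene per-tissue log2 offsets (default 0.5)
#' @param libsize_range range of uniform library-size factors
#'   (default c(0.7, 1.4))
#' @param duration duration label written to the sample table
#' @return list of class `cr_sim_config`
#' @export
sim_config <- function(seed = 1,
                       n_genes = 1000,
                       tissues = c("hypothalamus", "amygdala", "pituitary",
                                   "adrenal"),
                       n_per_group = 5,
                       baseline_meanlog2 = 6,
                       baseline_sdlog2 = 2,
                       dispersion_meanlog = log(0.05),
                       dispersion_sdlog = 0.3,
                       n_spike = 10,
                       spike_log2fc = 2,
                       tissue_sd_log2 = 0.5,
                       libsize_range = c(0.7, 1.4),
                       duration = "short") {
  cfg <- list(seed = seed, n_genes = n_genes, tissues = tissues,
              n_per_group = n_per_group,
              baseline_meanlog2 = baseline_meanlog2,
              baseline_sdlog2 = baseline_sdlog2,
              dispersion_meanlog = dispersion_meanlog,
              dispersion_sdlog = dispersion_sdlog,
              n_spike = n_spike, spike_log2fc = spike_log2fc,
              tissue_sd_log2 = tissue_sd_log2,
              libsize_range = libsize_range, duration = duration)
  if (cfg$n_spike > cfg$n_genes)
    stop("spike set size exceeds gene count")
  class(cfg) <- "cr_sim_config"
  cfg
}

#' Simulate a count matrix with tissue effects and spiked CR responders
#'
#' Per gene g and sample j the count is NB with mean
#' `L_j * 2^(b_g + t_tissue(j),g + delta_g * I(CR_j))` and dispersion
#' `alpha_g` (Var = mu + alpha mu^2). Spiked genes split evenly between up-
#' and down-regulation. Deterministic per seed.
#'
#' @param cfg a `cr_sim_config` (see [sim_config()])
#' @return list with `counts` (a `cr_counts`), `samples` (a `cr_samples`),
#'   and `truth` (data.frame gene_id, delta_log2fc, spiked)
#' @export
simulate_counts <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  genes <- sprintf("gene%04d", seq_len(cfg$n_genes))
  n_t <- length(cfg$tissues)
  n_samples <- n_t * 2 * cfg$n_per_group
  tissue_of <- rep(cfg$tissues, each = 2 * cfg$n_per_group)
  treat_of <- rep(rep(c("control", "CR"), each = cfg$n_per_group), n_t)
  sample_ids <- sprintf("s%03d_%s_%s", seq_len(n_samples),
                        substr(tissue_of, 1, 4), treat_of)
  b <- stats::rnorm(cfg$n_genes, cfg$baseline_meanlog2, cfg$baseline_sdlog2)
  alpha <- stats::rlnorm(cfg$n_genes, cfg$dispersion_meanlog,
                         cfg$dispersion_sdlog)
  tis_eff <- matrix(stats::rnorm(cfg$n_genes * n_t, 0, cfg$tissue_sd_log2),
                    cfg$n_genes, n_t, dimnames = list(genes, cfg$tissues))
  delta <- numeric(cfg$n_genes)
  spiked <- integer(0)
  if (cfg$n_spike > 0) {
    spiked <- sample.int(cfg$n_genes, cfg$n_spike)
    signs <- rep(c(1, -1), length.out = cfg$n_spike)
    delta[spiked] <- signs * cfg$spike_log2fc
  }
  L <- stats::runif(n_samples, cfg$libsize_range[1], cfg$libsize_range[2])
  is_cr <- as.integer(treat_of == "CR")
  tis_idx <- match(tissue_of, cfg$tissues)
  log2mu <- b + tis_eff[, tis_idx, drop = FALSE] +
    outer(delta, is_cr)
  mu <- t(t(2^log2mu) * L)
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = rep(1 / alpha,
                                                                  n_samples)),
                   cfg$n_genes, n_samples,
                   dimnames = list(genes, sample_ids))
  samples <- sample_table(data.frame(
    sample_id = sample_ids, treatment = treat_of, tissue = tissue_of,
    duration = cfg$duration, stringsAsFactors = FALSE))
  truth <- data.frame(gene_id = genes, delta_log2fc = delta,
                      spiked = seq_len(cfg$n_genes) %in% spiked,
                      stringsAsFactors = FALSE)
  list(counts = count_matrix(counts), samples = samples, truth = truth)
}

#' Simulate Gaussian posterior draws
#' @param mean,sd Normal parameters (sd = 0 gives constant draws)
#' @param S draw count
#' @param seed RNG seed
#' @return a `cr_draws` vector
#' @export
simulate_posterior <- function(mean, sd, S = 4000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  draws <- if (sd == 0) rep(mean, S) else stats::rnorm(S, mean, sd)
  structure(draws, parameter = "delta", class = "cr_draws")
}

#' Simulate a toy mined-relation corpus
#'
#' Draws random gene-concept and drug-gene edges; each edge's
#' supporting-sentence count is `1 + Poisson(lambda)`. One designated hub
#' gene receives an edge to every concept, so hub recovery is testable by
#' construction.
#'
#' @param n_genes,n_drugs,n_concepts entity counts
#' @param n_edges random edge count on top of the hub edges (default 50)
#' @param lambda Poisson rate of extra supporting sentences (default 1)
#' @param seed RNG seed
#' @param hub_gene id of the designated hub (default first gene)
#' @return a `cr_relations` data.frame (one row per sentence)
#' @export
simulate_relations <- function(n_genes = 10, n_drugs = 5, n_concepts = 6,
                               n_edges = 50, lambda = 1, seed = 1,
                               hub_gene = NULL) {
  set.seed(seed)
  genes <- sprintf("GENE%02d", seq_len(n_genes))
  drugs <- sprintf("drug%02d", seq_len(n_drugs))
  concepts <- sprintf("concept%02d", seq_len(n_concepts))
  if (is.null(hub_gene)) hub_gene <- genes[1]
  mk <- function(subject, stype, object, otype) {
    data.frame(subject = subject, subject_type = stype, object = object,
               object_type = otype,
               relation_type = sample(RELATION_TYPES, length(subject),
                                      replace = TRUE),
               sign = sample(RELATION_SIGNS, length(subject), replace = TRUE),
               stringsAsFactors = FALSE)
  }
  hub <- mk(rep(hub_gene, n_concepts), "gene", concepts, "concept")
  subs <- sample(c(genes, drugs), n_edges, replace = TRUE)
  objs <- vapply(subs, function(s) {
    pool <- if (s %in% drugs) genes else c(genes, concepts)
    sample(setdiff(pool, s), 1)
  }, character(1))
  rnd <- mk(subs, ifelse(subs %in% drugs, "drug", "gene"),
            objs, ifelse(objs %in% concepts, "concept", "gene"))
  edges <- rbind(hub, rnd)
  edges <- edges[edges$subject != edges$object, , drop = FALSE]
  ns <- 1 + stats::rpois(nrow(edges), lambda)
  rows <- edges[rep(seq_len(nrow(edges)), ns), , drop = FALSE]
  sent_idx <- unlist(lapply(ns, seq_len))
  rows$sentence <- sprintf("Mined sentence %d on %s %s of %s by %s.",
                           sent_idx, rows$sign, rows$relation_type,
                           rows$object, rows$subject)
  rownames(rows) <- NULL
  class(rows) <- c("cr_relations", "data.frame")
  rows
}

#' Write relation records as TSV
#' @param records a `cr_relations` data.frame
#' @param path output path
#' @export
write_relations <- function(records, path) {
  utils::write.table(as.data.frame(records), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
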