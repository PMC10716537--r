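# Confidence-weighted relation networks from mined literature records.
#
# Records are (subject, object, relation_type, sign, sentence) tuples; the
# confidence of an aggregated edge is the number of distinct supporting
# sentences s, classed high (s >= 3), medium (s = 2) or low (s = 1) by
# default.  Hubs are ranked by distinct-neighbor degree, and drug
# repurposing against a gene signature is formalized as greedy weighted set
# cover.

ENTITY_TYPES <- c("gene", "drug", "concept")
RELATION_TYPES <- c("regulation", "expression", "molecular_transport",
                    "genetic_change", "association")
RELATION_SIGNS <- c("positive", "negative", "unsigned")

#' Load mined relation records from TSV
#'
#' Required columns: subject, subject_type, object, object_type,
#' relation_type, sign, sentence. Duplicate identical sentences for the same
#' (pair, relation_type, sign) are de-duplicated; self-loop rows are skipped
#' with a warning.
#'
#' @param path file path
#' @param delimiter field delimiter
#' @return data.frame of relation records, class `cr_relations`
#' @export
load_relations <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  required <- c("subject", "subject_type", "object", "object_type",
                "relation_type", "sign", "sentence")
  if (nrow(df) == 0) {
    df <- data.frame(matrix(character(0), 0, length(required),
                            dimnames = list(NULL, required)),
                     stringsAsFactors = FALSE)
    class(df) <- c("cr_relations", "data.frame")
    return(df)
  }
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("missing required columns: ", paste(missing, collapse = ", "))
  bad <- which(!(df$subject_type %in% ENTITY_TYPES) |
               !(df$object_type %in% ENTITY_TYPES))
  if (length(bad) > 0)
    stop("unknown entity type in row ", bad[1], ": ",
         df$subject_type[bad[1]], "/", df$object_type[bad[1]])
  bad <- which(!(df$relation_type %in% RELATION_TYPES))
  if (length(bad) > 0)
    stop("unknown relation type in row ", bad[1], ": ",
         df$relation_type[bad[1]])
  bad <- which(!(df$sign %in% RELATION_SIGNS))
  if (length(bad) > 0)
    stop("unknown sign in row ", bad[1], ": ", df$sign[bad[1]])
  loops <- df$subject == df$object
  if (any(loops)) {
    warning("skipping ", sum(loops), " self-loop row(s)")
    df <- df[!loops, , drop = FALSE]
  }
  df <- unique(df)
  rownames(df) <- NULL
  class(df) <- c("cr_relations", "data.frame")
  df
}

#' Aggregate relation records into confidence-classed edges
#'
#' Groups records by (subject, object, relation_type, sign); the support s
#' is the distinct supporting-sentence count and the confidence class is a
#' step function of s: `s >= high_threshold` is high, `s = 2` medium,
#' `s = 1` low.
#'
#' @param records a `cr_relations` data.frame
#' @param high_threshold sentence count from which an edge is high
#'   confidence (default 3)
#' @return data.frame of class `cr_edges`: subject, subject_type, object,
#'   object_type, relation_type, sign, s, confidence_class
#' @export
aggregate_confidence <- function(records, high_threshold = 3) {
  cols <- c("subject", "subject_type", "object", "object_type",
            "relation_type", "sign")
  if (nrow(records) == 0) {
    out <- data.frame(matrix(character(0), 0, length(cols),
                             dimnames = list(NULL, cols)),
                      s = integer(0), confidence_class = character(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("cr_edges", "data.frame")
    return(out)
  }
  key <- do.call(paste, c(records[cols], sep = "\r"))
  s <- vapply(split(records$sentence, key),
              function(x) length(unique(x)), integer(1))
  first <- records[!duplicated(key), cols, drop = FALSE]
  first_key <- key[!duplicated(key)]
  out <- first
  out$s <- as.integer(s[first_key])
  out$confidence_class <- confidence_class(out$s, high_threshold)
  o <- order(out$subject, out$object, out$relation_type, out$sign)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cr_edges", "data.frame")
  out
}

#' Confidence class of a supporting-sentence count
#' @param s integer vector of sentence counts (>= 1)
#' @param high_threshold count from which class is high (default 3)
#' @return character vector in {high, medium, low}
#' @export
confidence_class <- function(s, high_threshold = 3) {
  ifelse(s >= high_threshold, "high",
         ifelse(s >= 2, "medium", "low"))
}

#' Build a typed relation network from aggregated edges
#'
#' Nodes carry entity types; parallel edges are kept per (pair,
#' relation_type, sign) so opposite-sign evidence survives; self-loops are
#' disallowed upstream.
#'
#' @param edges a `cr_edges` data.frame
#' @return list of class `cr_network` with `nodes` (id, type) and `edges`
#' @export
build_network <- function(edges) {
  nodes <- unique(rbind(
    data.frame(id = edges$subject, type = edges$subject_type,
               stringsAsFactors = FALSE),
    data.frame(id = edges$object, type = edges$object_type,
               stringsAsFactors = FALSE)))
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  conflict <- nodes$id[duplicated(nodes$id)]
  if (length(conflict) > 0)
    stop("entity with conflicting types: ", paste(conflict, collapse = ", "))
  structure(list(nodes = nodes, edges = edges), class = "cr_network")
}

#' @export
print.cr_network <- function(x, ...) {
  cat(sprintf("<cr_network> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

# distinct neighbors of a node id
node_neighbors <- function(net, id) {
  e <- net$edges
  unique(c(e$object[e$subject == id], e$subject[e$object == id]))
}

#' Rank nodes by degree (distinct neighbors)
#'
#' @param net a `cr_network`
#' @param node_type optional filter: only rank nodes of this entity type
#' @return data.frame: id, type, degree, in descending degree order with
#'   lexicographic tie-breaking
#' @export
find_hubs <- function(net, node_type = NULL) {
  nodes <- net$nodes
  if (!is.null(node_type)) nodes <- nodes[nodes$type %in% node_type, ]
  deg <- vapply(nodes$id, function(id) length(node_neighbors(net, id)),
                integer(1))
  out <- data.frame(id = nodes$id, type = nodes$type, degree = deg,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# signature genes covered by a drug: distinct signature genes sharing >= 1
# edge with it
drug_coverage <- function(net, drug, signature) {
  intersect(node_neighbors(net, drug), signature)
}

#' Rank drugs by signature coverage
#'
#' Coverage is the number of distinct signature genes a drug has at least
#' one edge with; ties are broken by total supporting-sentence count with
#' those genes, then lexicographically. Drugs with zero coverage are
#' excluded.
#'
#' @param net a `cr_network`
#' @param signature character vector of signature gene ids
#' @return data.frame: drug, coverage, total_s, genes (comma-joined)
#' @export
rank_drugs <- function(net, signature) {
  drugs <- net$nodes$id[net$nodes$type == "drug"]
  e <- net$edges
  rows <- lapply(drugs, function(d) {
    genes <- drug_coverage(net, d, signature)
    if (length(genes) == 0) return(NULL)
    sel <- (e$subject == d & e$object %in% genes) |
           (e$object == d & e$subject %in% genes)
    data.frame(drug = d, coverage = length(genes),
               total_s = sum(e$s[sel]),
               genes = paste(sort(genes), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(drug = character(0), coverage = integer(0),
                      total_s = integer(0), genes = character(0),
                      stringsAsFactors = FALSE))
  out <- out[order(-out$coverage, -out$total_s, out$drug, method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' Greedy drug-combination selection (weighted set cover)
#'
#' Repeatedly adds the drug covering the most still-uncovered signature
#' genes (ties: larger total supporting-sentence count with signature genes,
#' then lexicographic) until every coverable gene is covered or `max_drugs`
#' is reached.
#'
#' @param net a `cr_network`
#' @param signature character vector of signature gene ids
#' @param max_drugs maximum combination size (default Inf)
#' @return list of class `cr_combination`: drugs (in selection order),
#'   covered, uncovered
#' @export
select_drug_combination <- function(net, signature, max_drugs = Inf) {
  e <- net$edges
  drugs <- net$nodes$id[net$nodes$type == "drug"]
  cov <- lapply(drugs, function(d) drug_coverage(net, d, signature))
  names(cov) <- drugs
  tot_s <- vapply(drugs, function(d) {
    genes <- cov[[d]]
    sel <- (e$subject == d & e$object %in% genes) |
           (e$object == d & e$subject %in% genes)
    sum(e$s[sel])
  }, numeric(1))
  uncovered <- unique(signature)
  chosen <- character(0)
  while (length(uncovered) > 0 && length(chosen) < max_drugs) {
    gain <- vapply(drugs, function(d) length(intersect(cov[[d]], uncovered)),
                   integer(1))
    if (all(gain == 0)) break
    cand <- drugs[gain == max(gain)]
    cand <- cand[order(-tot_s[cand], cand, method = "radix")]
    pick <- cand[1]
    chosen <- c(chosen, pick)
    uncovered <- setdiff(uncovered, cov[[pick]])
    drugs <- setdiff(drugs, pick)
  }
  structure(list(drugs = chosen,
                 covered = setdiff(unique(signature), uncovered),
                 uncovered = uncovered),
            class = "cr_combination")
}

#' Write a network edge list as TSV (with sign glyphs)
#'
#' Adds a human-readable `glyph` column (positive, negative, or unsigned
#' association) alongside the machine-readable sign.
#'
#' @param net a `cr_network`
#' @param path output path
#' @export
write_edge_list <- function(net, path) {
  e <- as.data.frame(net$edges)
  e$glyph <- c(positive = "(+)", negative = "-|", unsigned = "--")[e$sign]
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a network back from an edge-list TSV written by [write_edge_list()]
#' @param path file path
#' @return a `cr_network`
#' @export
read_edge_list <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  df$glyph <- NULL
  class(df) <- c("cr_edges", "data.frame")
  build_network(df)
}

#' Export a network as GraphML
#' @param net a `cr_network`
#' @param path output path
#' @export
write_graphml <- function(net, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="type" for="node" attr.name="type" attr.type="string"/>',
    '  <key id="relation" for="edge" attr.name="relation_type" attr.type="string"/>',
    '  <key id="sign" for="edge" attr.name="sign" attr.type="string"/>',
    '  <key id="s" for="edge" attr.name="sentences" attr.type="int"/>',
    '  <key id="conf" for="edge" attr.name="confidence" attr.type="string"/>',
    '  <graph edgedefault="undirected">'), con)
  for (i in seq_len(nrow(net$nodes)))
    writeLines(sprintf('    <node id="%s"><data key="type">%s</data></node>',
                       esc(net$nodes$id[i]), esc(net$nodes$type[i])), con)
  e <- net$edges
  for (i in seq_len(nrow(e)))
    writeLines(sprintf(
      paste0('    <edge source="%s" target="%s"><data key="relation">%s</data>',
             '<data key="sign">%s</data><data key="s">%d</data>',
             '<data key="conf">%s</data></edge>'),
      esc(e$subject[i]), esc(e$object[i]), esc(e$relation_type[i]),
      esc(e$sign[i]), e$s[i], esc(e$confidence_class[i])), con)
  writeLines(c('  </graph>', '</graphml>'), con)
  invisible(path)
}
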