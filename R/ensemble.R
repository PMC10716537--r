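# Ensemble aggregation of the seven normalized weight vectors, signature
# selection, tissue-independence reporting, and PCA evaluation of a
# signature on the gene-gene correlation matrix.

#' Overall ensemble weights and ranking
#'
#' The overall weight of a feature is the plain sum of its seven normalized
#' per-algorithm weights, `W(f) = sum_a w_a(f)`, so `0 <= W <= 7`. Features
#' are ranked by descending W; ties are broken lexicographically by feature
#' id.
#'
#' @param wvs features x algorithms matrix of normalized weights (a
#'   `cr_weights` matrix), or a named list of seven per-algorithm weight
#'   vectors over identical feature sets
#' @return data.frame of class `cr_ranking`, sorted by rank: feature,
#'   overall_weight, rank, plus one column per algorithm
#' @export
ensemble_overall_weights <- function(wvs) {
  if (is.list(wvs) && !is.data.frame(wvs)) {
    feats <- names(wvs[[1]])
    wvs <- do.call(cbind, lapply(wvs, function(v) v[feats]))
    rownames(wvs) <- feats
  }
  wvs <- as.matrix(wvs)
  absent <- setdiff(WEIGHTING_ALGORITHMS, colnames(wvs))
  if (length(absent) > 0)
    stop("missing algorithm(s): ", paste(absent, collapse = ", "))
  wvs <- wvs[, WEIGHTING_ALGORITHMS, drop = FALSE]
  W <- rowSums(wvs)
  o <- order(-W, rownames(wvs), method = "radix")
  out <- data.frame(feature = rownames(wvs)[o],
                    overall_weight = W[o],
                    rank = seq_along(W),
                    unclass(wvs)[o, , drop = FALSE],
                    row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  class(out) <- c("cr_ranking", "data.frame")
  out
}

#' Select the top-k gene signature from an ensemble ranking
#'
#' The tissue feature is excluded from membership (its weight is carried in
#' the ranking); if `k` exceeds the number of genes all genes are returned
#' with a warning. Optional annotation attaches symbols and protein classes.
#'
#' @param er a `cr_ranking` data.frame
#' @param k signature size (default 20)
#' @param annotation optional annotation data.frame (gene_id, symbol,
#'   protein_class)
#' @return data.frame of class `cr_signature`: the top-k gene rows of the
#'   ranking in rank order
#' @export
rank_and_select <- function(er, k = 20, annotation = NULL) {
  genes <- er[er$feature != "tissue", , drop = FALSE]
  if (k > nrow(genes)) {
    warning("k = ", k, " exceeds number of genes (", nrow(genes),
            "); returning all genes")
    k <- nrow(genes)
  }
  sig <- genes[seq_len(k), , drop = FALSE]
  if (!is.null(annotation)) {
    idx <- match(sig$feature, annotation$gene_id)
    sig$symbol <- annotation$symbol[idx]
    sig$protein_class <- annotation$protein_class[idx]
  }
  rownames(sig) <- NULL
  class(sig) <- c("cr_signature", "data.frame")
  sig
}

#' Where does the tissue attribute sit in the ensemble ranking?
#'
#' A tissue-independent signature requires the categorical tissue feature to
#' receive a low overall weight relative to the genes. The quantile is the
#' fraction of features ranked at or above the tissue feature (1 = last).
#'
#' @param er a `cr_ranking` data.frame containing the `tissue` feature
#' @return list with overall_weight, rank, n_features, quantile
#' @export
tissue_independence_report <- function(er) {
  i <- which(er$feature == "tissue")
  if (length(i) == 0) stop("tissue feature absent from ranking")
  list(overall_weight = er$overall_weight[i],
       rank = er$rank[i],
       n_features = nrow(er),
       quantile = er$rank[i] / nrow(er))
}

#' PCA of signature genes on the correlation matrix
#'
#' Expression of the signature genes is standardized per gene and the
#' gene-gene Pearson correlation matrix eigendecomposed. Zero-variance genes
#' are dropped with a warning. Sign convention: within each component the
#' largest-magnitude loading is made positive.
#'
#' @param ft a `cr_features` table (samples x features)
#' @param genes character vector of signature gene features to use
#' @return list of class `cr_pca`: loadings (genes x PCs), variance_fraction,
#'   scores (samples x PCs), genes
#' @export
pca_correlation <- function(ft, genes = gene_features(ft)) {
  absent <- setdiff(genes, names(ft))
  if (length(absent) > 0)
    stop("genes absent from feature table: ", paste(absent, collapse = ", "))
  x <- as.matrix(as.data.frame(ft)[, genes, drop = FALSE])
  v <- apply(x, 2, stats::var)
  if (all(v == 0)) stop("all signature genes have zero variance")
  if (any(v == 0)) {
    warning("dropping zero-variance gene(s): ",
            paste(genes[v == 0], collapse = ", "))
    x <- x[, v > 0, drop = FALSE]
  }
  if (ncol(x) < 2) stop("need >= 2 non-constant genes for PCA")
  if (nrow(x) < 2) stop("need >= 2 samples for PCA")
  z <- scale(x)
  R <- stats::cor(x)
  eig <- eigen(R, symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  load <- eig$vectors
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  dimnames(load) <- list(colnames(x), paste0("PC", seq_len(ncol(load))))
  scores <- z %*% load
  rownames(scores) <- rownames(ft)
  structure(list(loadings = load,
                 variance_fraction = lam / sum(lam),
                 scores = scores,
                 genes = colnames(x)),
            class = "cr_pca")
}

#' Label separation along PC1
#'
#' Reports the standardized mean difference of PC1 scores between CR and
#' control samples (absolute difference of group means over the pooled SD)
#' and the fraction of samples correctly classified by the midpoint of the
#' two group means (samples on the CR-mean side of the midpoint are called
#' CR).
#'
#' @param pca a `cr_pca` object
#' @param labels treatment factor aligned with the score rows
#' @return list with score (standardized mean difference) and fraction
#'   (midpoint-threshold accuracy)
#' @export
separation_on_pc1 <- function(pca, labels) {
  pc1 <- pca$scores[, 1]
  y <- factor(labels)
  if (nlevels(y) != 2) stop("labels must be binary")
  g <- split(pc1, y)
  m <- vapply(g, mean, numeric(1))
  n <- vapply(g, length, numeric(1))
  v <- vapply(g, function(x) if (length(x) > 1) stats::var(x) else 0,
              numeric(1))
  pooled <- sqrt(sum((n - 1) * v) / max(sum(n) - 2, 1))
  score <- if (pooled == 0) {
    if (m[1] == m[2]) 0 else Inf
  } else {
    unname(abs(m[1] - m[2]) / pooled)
  }
  mid <- mean(m)
  if (m[1] == m[2]) {
    fraction <- 0.5
  } else {
    # side of the midpoint closer to each group's mean claims that group
    pred <- if (m[2] > m[1]) levels(y)[(pc1 > mid) + 1L]
            else levels(y)[(pc1 < mid) + 1L]
    fraction <- mean(pred == as.character(y))
  }
  list(score = score, fraction = fraction)
}

#' Write a signature table as TSV
#' @param sig a `cr_signature` data.frame
#' @param path output path
#' @export
write_signature <- function(sig, path) {
  utils::write.table(as.data.frame(sig), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
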