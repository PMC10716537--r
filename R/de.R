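# Two-group negative-binomial differential expression.
#
# Model per gene: count_ij ~ NB(mean = sf_j * exp(b0 + b1 * I(CR_j)), alpha_g)
# with Var = mu + alpha * mu^2.  b1 is estimated by maximum likelihood at
# fixed gene-wise dispersion; the Wald z = b1 / SE(b1) is referred to a
# standard normal, and p-values are Benjamini-Hochberg corrected.

#' Median-of-ratios size factors
#'
#' Library-size normalization: the reference is the per-gene geometric mean
#' over genes with all-positive counts; each sample's factor is the median of
#' its count/reference ratios, rescaled so the factors' geometric mean is 1.
#' If no gene is positive in all samples the total-count (library-size)
#' factors are used instead, with a warning.
#'
#' @param cm a `cr_counts` matrix
#' @return named positive numeric vector, one per sample
#' @export
size_factors <- function(cm) {
  m <- unclass(cm)
  if (ncol(m) == 1) return(stats::setNames(1, colnames(m)))
  allpos <- rowSums(m == 0) == 0
  if (!any(allpos)) {
    warning("no gene with positive counts in all samples; ",
            "falling back to total-count size factors")
    sf <- colSums(m)
  } else {
    ref <- exp(rowMeans(log(m[allpos, , drop = FALSE])))
    sf <- apply(m[allpos, , drop = FALSE] / ref, 2, stats::median)
  }
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(m))
}

#' Method-of-moments NB dispersion per gene
#'
#' alpha = max(0, (s^2 - mean) / mean^2) on size-factor-normalized counts,
#' floored at 1e-8 for testable genes. All-zero genes get alpha = 0 and an
#' `untestable` flag.
#'
#' @param cm a `cr_counts` matrix
#' @param factors size factors (defaults to [size_factors()])
#' @return data.frame with gene_id, alpha, untestable
#' @export
estimate_dispersion <- function(cm, factors = size_factors(cm)) {
  if (ncol(cm) < 2) stop("dispersion estimation needs >= 2 samples")
  norm <- t(t(unclass(cm)) / factors)
  mu <- rowMeans(norm)
  s2 <- apply(norm, 1, stats::var)
  untestable <- mu == 0
  alpha <- ifelse(untestable, 0, pmax((s2 - mu) / mu^2, 1e-8))
  data.frame(gene_id = rownames(cm), alpha = alpha,
             untestable = untestable, row.names = NULL,
             stringsAsFactors = FALSE)
}

# MLE of a single NB group mean m with per-sample offsets sf at fixed alpha.
# Solves the score equation sum_j (y_j - sf_j m)/(1 + alpha sf_j m) = 0 by
# Newton iteration on m.  Returns 0 for an all-zero group.
nb_group_mean <- function(y, sf, alpha) {
  if (all(y == 0)) return(0)
  m <- sum(y) / sum(sf)
  for (it in 1:100) {
    mu <- sf * m
    d <- 1 + alpha * mu
    U <- sum((y - mu) / d)
    J <- sum((-sf * d - (y - mu) * alpha * sf) / d^2)
    if (!is.finite(U) || !is.finite(J) || J == 0) break
    m2 <- m - U / J
    if (m2 <= 0) m2 <- m / 2
    if (abs(m2 - m) < 1e-12 * (m + 1e-12)) { m <- m2; break }
    m <- m2
  }
  m
}

# Wald fit for one gene: returns c(b0, b1, se, converged)
nb_wald_gene <- function(y, sf, alpha, grp) {
  m0 <- nb_group_mean(y[grp == 0], sf[grp == 0], alpha)
  m1 <- nb_group_mean(y[grp == 1], sf[grp == 1], alpha)
  if (m0 <= 0 || m1 <= 0) return(c(NA, NA, NA, 0))
  # expected Fisher information of (b0, b1) under the log link; its inverse
  # [2,2] element reduces to 1/A0 + 1/A1 with A_g = sum_g mu/(1 + alpha mu)
  mu0 <- sf[grp == 0] * m0
  mu1 <- sf[grp == 1] * m1
  A0 <- sum(mu0 / (1 + alpha * mu0))
  A1 <- sum(mu1 / (1 + alpha * mu1))
  se <- sqrt(1 / A0 + 1 / A1)
  c(log(m0), log(m1) - log(m0), se, 1)
}

#' Negative-binomial Wald differential expression, CR vs control
#'
#' For the samples of one tissue (or all samples when `tissue` is NULL) fits
#' the per-gene two-group NB model and reports log2 fold changes, Wald
#' p-values and BH-adjusted q-values. Genes with all-zero counts in one group
#' are refit after adding a 0.5 pseudo-count to every sample of the gene and
#' flagged `pseudo`. Untestable (all-zero) genes carry NA p and are excluded
#' from the BH denominator.
#'
#' @param cm a `cr_counts` matrix
#' @param st a `cr_samples` table
#' @param tissue tissue level to subset to, or NULL for all samples pooled
#' @return data.frame of class `cr_de`: gene_id, baseMean, log2FC, se,
#'   wald_p, fdr_q, dispersion, flag
#' @export
nb_wald_test <- function(cm, st, tissue = NULL) {
  st <- if (inherits(st, "cr_samples")) st else sample_table(st)
  st <- st[match(colnames(cm), st$sample_id), ]
  if (!is.null(tissue)) {
    keep <- st$tissue == tissue
    if (!any(keep)) stop("no samples with tissue '", tissue, "'")
    cm <- count_matrix(unclass(cm)[, keep, drop = FALSE])
    st <- st[keep, ]
  }
  grp <- as.integer(st$treatment == "CR")
  if (sum(grp == 0) < 2 || sum(grp == 1) < 2)
    stop("need >= 2 samples per treatment level")
  sf <- size_factors(cm)
  disp <- estimate_dispersion(cm, sf)
  m <- unclass(cm)
  norm <- t(t(m) / sf)
  n_genes <- nrow(m)
  out <- matrix(NA_real_, n_genes, 3,
                dimnames = list(NULL, c("log2FC", "se", "wald_p")))
  flag <- character(n_genes)
  for (g in seq_len(n_genes)) {
    if (disp$untestable[g]) { flag[g] <- "untestable"; next }
    y <- m[g, ]
    onegrp_zero <- all(y[grp == 0] == 0) || all(y[grp == 1] == 0)
    if (onegrp_zero) {
      fit <- nb_wald_gene(y + 0.5, sf, disp$alpha[g], grp)
      flag[g] <- "pseudo"
    } else {
      fit <- nb_wald_gene(y, sf, disp$alpha[g], grp)
    }
    if (fit[4] == 0) { flag[g] <- "nonconverged"; next }
    b1 <- fit[2]; se <- fit[3]
    out[g, ] <- c(b1 / log(2), se / log(2),
                  2 * stats::pnorm(-abs(b1 / se)))
  }
  res <- data.frame(
    gene_id = rownames(m),
    baseMean = rowMeans(norm),
    log2FC = out[, "log2FC"],
    se = out[, "se"],
    wald_p = out[, "wald_p"],
    fdr_q = bh_adjust(out[, "wald_p"]),
    dispersion = disp$alpha,
    flag = flag,
    row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("cr_de", "data.frame")
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' NA entries are excluded from the number of tests m and returned as NA;
#' order is preserved and monotonicity enforced.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA allowed)
#' @return q-values, same length and order
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m == 0) return(q)
  o <- order(pv)
  ro <- order(o)
  adj <- pmin(1, rev(cummin(rev(pv[o] * m / seq_len(m)))))
  q[ok] <- adj[ro]
  q
}

#' Write a differential-expression result table as TSV
#' @param de a `cr_de` data.frame
#' @param path output path
#' @export
write_de_result <- function(de, path) {
  utils::write.table(as.data.frame(de), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
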