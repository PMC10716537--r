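# The seven attribute-weighting (feature-selection) algorithms scored
# against a binary treatment label: information gain, gain ratio, single-rule
# accuracy, Pearson chi-squared, Gini index decrease, symmetric uncertainty,
# and Relief.  Numeric features are discretized by equal-frequency binning
# for the contingency-table weighters; Relief and Rule operate on the raw
# numeric scale.  Per-algorithm raw weights are min-max normalized to [0, 1]
# before ensemble aggregation.

WEIGHTING_ALGORITHMS <- c("info_gain", "gain_ratio", "rule", "chi_squared",
                          "gini", "uncertainty", "relief")

#' Equal-frequency discretization
#'
#' Bin edges are the `B - 1` interior quantiles (type 7); identical adjacent
#' edges are merged so the effective bin count can be below `B`. A constant
#' vector collapses to a single bin with a warning.
#'
#' @param values numeric vector, length >= 2
#' @param B requested bin count, >= 2 (default 5)
#' @return factor of bin labels with attribute `"edges"` (interior cut
#'   points after merging)
#' @export
discretize_equal_frequency <- function(values, B = 5) {
  if (B < 2) stop("B must be >= 2")
  if (length(values) < 2) stop("need >= 2 values")
  if (length(unique(values)) == 1) {
    warning("constant feature: single bin")
    f <- factor(rep("bin1", length(values)))
    attr(f, "edges") <- numeric(0)
    return(f)
  }
  probs <- seq_len(B - 1) / B
  edges <- unique(stats::quantile(values, probs, names = FALSE, type = 7))
  bins <- findInterval(values, edges, left.open = TRUE) + 1L
  # drop empty bins so labels are consecutive
  f <- factor(paste0("bin", bins), levels = paste0("bin", sort(unique(bins))))
  attr(f, "edges") <- edges
  f
}

# Coerce a feature to categorical: factors pass through, numerics are
# discretized.
as_bins <- function(f, bins = 5) {
  if (is.factor(f) || is.character(f)) return(factor(f))
  suppressWarnings(discretize_equal_frequency(f, bins))
}

entropy_bits <- function(x) {
  p <- table(x) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

cond_entropy_bits <- function(y, f) {
  tab <- table(f, y)
  pv <- rowSums(tab) / sum(tab)
  h <- apply(tab, 1, function(r) {
    if (sum(r) == 0) return(0)
    p <- r / sum(r); p <- p[p > 0]
    -sum(p * log2(p))
  })
  sum(pv * h)
}

#' Information gain of a feature for a binary label
#'
#' IG = H(y) - sum_v p(v) H(y | f = v), base-2 entropy. Numeric features are
#' discretized by equal-frequency binning first.
#'
#' @param f feature vector (numeric or factor)
#' @param y binary label factor
#' @param bins bin count for numeric features
#' @return raw weight (>= 0, bits)
#' @export
weight_info_gain <- function(f, y, bins = 5) {
  fb <- as_bins(f, bins)
  entropy_bits(y) - cond_entropy_bits(y, fb)
}

#' Information gain ratio: IG / H(f), 0 when H(f) = 0
#' @inheritParams weight_info_gain
#' @return raw weight
#' @export
weight_gain_ratio <- function(f, y, bins = 5) {
  fb <- as_bins(f, bins)
  hf <- entropy_bits(fb)
  if (hf == 0) return(0)
  (entropy_bits(y) - cond_entropy_bits(y, fb)) / hf
}

#' Symmetric uncertainty: 2 IG / (H(f) + H(y)), in \[0, 1\]
#' @inheritParams weight_info_gain
#' @return raw weight
#' @export
weight_symmetric_uncertainty <- function(f, y, bins = 5) {
  fb <- as_bins(f, bins)
  denom <- entropy_bits(fb) + entropy_bits(y)
  if (denom == 0) return(0)
  2 * (entropy_bits(y) - cond_entropy_bits(y, fb)) / denom
}

#' Pearson chi-squared statistic on the feature-bin x label table
#'
#' No continuity correction; cells in zero-marginal rows/columns contribute 0.
#'
#' @inheritParams weight_info_gain
#' @return raw weight (chi-squared statistic)
#' @export
weight_chi_squared <- function(f, y, bins = 5) {
  fb <- as_bins(f, bins)
  tab <- table(fb, y)
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (n == 0) return(0)
  expected <- outer(rs, cs) / n
  keep <- expected > 0
  sum((tab[keep] - expected[keep])^2 / expected[keep])
}

#' Gini-index decrease: gini(y) - sum_v p(v) gini(y | f = v)
#'
#' gini(x) = 1 - sum_c p_c^2.
#'
#' @inheritParams weight_info_gain
#' @return raw weight (>= 0)
#' @export
weight_gini <- function(f, y, bins = 5) {
  fb <- as_bins(f, bins)
  gini <- function(x) { p <- table(x) / length(x); 1 - sum(p^2) }
  tab <- table(fb)
  pv <- tab / length(fb)
  cond <- sum(vapply(names(tab), function(v) {
    if (tab[[v]] == 0) return(0)
    pv[[v]] * gini(y[fb == v])
  }, numeric(1)))
  gini(y) - cond
}

#' Best single-feature rule accuracy
#'
#' For a categorical feature: predict the majority label within each level
#' (ties toward the first label level). For a numeric feature: the best
#' threshold split over all midpoints between consecutive distinct sorted
#' values, both orientations, ties resolved toward the lower threshold.
#' The weight is the training accuracy of that rule.
#'
#' @param f feature vector (numeric or factor)
#' @param y binary label factor
#' @return raw weight in \[max class share limited below by 0.5, 1\]
#' @export
weight_rule <- function(f, y) {
  y <- factor(y)
  n <- length(y)
  if (is.factor(f) || is.character(f)) {
    f <- factor(f)
    correct <- 0
    for (v in levels(f)) {
      yy <- y[f == v]
      if (length(yy) == 0) next
      correct <- correct + max(table(yy))
    }
    return(correct / n)
  }
  # numeric: majority class is the fallback (the empty-split rule)
  best <- max(table(y)) / n
  vals <- sort(unique(f))
  if (length(vals) >= 2) {
    cuts <- (vals[-1] + vals[-length(vals)]) / 2
    for (thr in cuts) {
      left <- f <= thr
      acc <- (max(table(y[left])) + max(table(y[!left]))) / n
      if (acc > best) best <- acc
    }
  }
  best
}

#' Relief weights for every feature of a mixed feature table
#'
#' Deterministic full-pass Relief (m = n): for each sample, its `k` nearest
#' same-class (hit) and opposite-class (miss) neighbors are found under
#' Manhattan distance, with numeric feature differences range-normalized to
#' \[0, 1\] and categorical differences 0/1. The weight of feature f is
#' `sum(miss diffs)/(n k) - sum(hit diffs)/(n k)`, in \[-1, 1\]. `k` is
#' capped at the smaller class size minus one. Distance ties are broken by
#' sample order, so the pass is deterministic; `seed` is accepted for
#' interface compatibility and only matters if random tie-breaking is ever
#' enabled.
#'
#' @param ft a `cr_features` table (or data.frame + `label`)
#' @param k neighbor count (default 10, capped)
#' @param label binary label; defaults to `feature_label(ft)`
#' @param seed unused under deterministic tie-breaking
#' @return named numeric vector of raw Relief weights, one per feature
#' @export
weight_relief <- function(ft, k = 10, label = feature_label(ft), seed = NULL) {
  y <- factor(label)
  if (nlevels(y) != 2) stop("Relief requires a binary label")
  n <- nrow(ft)
  cls_sizes <- table(y)
  if (min(cls_sizes) < 2) stop("Relief requires >=2 per class")
  k <- max(1L, min(k, min(cls_sizes) - 1L))
  feats <- names(ft)
  # per-feature pairwise difference matrices, range-normalized
  diffs <- vector("list", length(feats))
  names(diffs) <- feats
  dist_total <- matrix(0, n, n)
  for (f in feats) {
    v <- ft[[f]]
    if (is.factor(v) || is.character(v)) {
      v <- as.character(v)
      d <- outer(v, v, FUN = "!=") * 1.0
    } else {
      rng <- diff(range(v))
      d <- if (rng == 0) matrix(0, n, n) else abs(outer(v, v, "-")) / rng
    }
    diffs[[f]] <- d
    dist_total <- dist_total + d
  }
  hit_sum <- stats::setNames(numeric(length(feats)), feats)
  miss_sum <- stats::setNames(numeric(length(feats)), feats)
  for (i in seq_len(n)) {
    same <- which(y == y[i]); same <- same[same != i]
    other <- which(y != y[i])
    hits <- same[order(dist_total[i, same])][seq_len(k)]
    misses <- other[order(dist_total[i, other])][seq_len(k)]
    for (f in feats) {
      hit_sum[f] <- hit_sum[f] + sum(diffs[[f]][i, hits])
      miss_sum[f] <- miss_sum[f] + sum(diffs[[f]][i, misses])
    }
  }
  (miss_sum - hit_sum) / (n * k)
}

#' Min-max normalize a raw weight vector to \[0, 1\]
#'
#' `(w - min) / (max - min)` per algorithm across features; a constant raw
#' vector maps to all zeros with a warning. Relief's signed raw scale is
#' normalized the same way.
#'
#' @param w named numeric vector of raw weights
#' @return normalized weights in \[0, 1\]
#' @export
normalize_weights <- function(w) {
  rng <- range(w)
  if (diff(rng) == 0) {
    warning("all raw weights equal; normalized weights set to 0")
    return(stats::setNames(rep(0, length(w)), names(w)))
  }
  (w - rng[1]) / diff(rng)
}

#' Run all seven attribute-weighting algorithms over a feature table
#'
#' Numeric gene features and the categorical tissue feature are scored
#' against the binary treatment label by each algorithm; each algorithm's
#' raw weights are then min-max normalized across features.
#'
#' @param ft a `cr_features` table
#' @param bins equal-frequency bin count for the contingency-table weighters
#' @param relief_k Relief neighbor count
#' @param seed passed to [weight_relief()]
#' @return features x 7 numeric matrix of normalized weights, class
#'   `cr_weights`; `attr(, "raw")` holds the raw weights
#' @export
weigh_features <- function(ft, bins = 5, relief_k = 10, seed = NULL) {
  y <- feature_label(ft)
  if (is.null(y) || nlevels(factor(y)) != 2)
    stop("feature table must carry a binary treatment label")
  feats <- names(ft)
  raw <- matrix(0, length(feats), length(WEIGHTING_ALGORITHMS),
                dimnames = list(feats, WEIGHTING_ALGORITHMS))
  for (f in feats) {
    v <- ft[[f]]
    fb <- as_bins(v, bins)
    tab <- table(fb, y)
    hy <- entropy_bits(y)
    hf <- entropy_bits(fb)
    ig <- hy - cond_entropy_bits(y, fb)
    raw[f, "info_gain"] <- ig
    raw[f, "gain_ratio"] <- if (hf == 0) 0 else ig / hf
    raw[f, "uncertainty"] <- if (hf + hy == 0) 0 else 2 * ig / (hf + hy)
    rs <- rowSums(tab); cs <- colSums(tab); ntot <- sum(tab)
    expd <- outer(rs, cs) / ntot
    keep <- expd > 0
    raw[f, "chi_squared"] <- sum((tab[keep] - expd[keep])^2 / expd[keep])
    gini <- function(p) 1 - sum((p / sum(p))^2)
    cond_g <- sum(apply(tab, 1, function(r)
      if (sum(r) == 0) 0 else sum(r) / ntot * gini(r)))
    raw[f, "gini"] <- gini(cs) - cond_g
    raw[f, "rule"] <- weight_rule(v, y)
  }
  raw[, "relief"] <- weight_relief(ft, k = relief_k, label = y, seed = seed)
  norm <- apply(raw, 2, function(w)
    suppressWarnings(normalize_weights(stats::setNames(w, feats))))
  dimnames(norm) <- dimnames(raw)
  structure(norm, raw = raw, class = c("cr_weights", "matrix", "array"))
}

#' Write a normalized weight matrix as TSV
#' @param w a `cr_weights` matrix (features x algorithms)
#' @param path output path
#' @export
write_weights <- function(w, path) {
  df <- data.frame(feature = rownames(w), unclass(w)[, , drop = FALSE],
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
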