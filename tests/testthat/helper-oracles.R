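# Independent brute-force oracles.  These deliberately re-derive each
# quantity from its textbook definition with naive loops so they share no
# code path with the package implementation.

oracle_entropy <- function(x) {
  x <- as.character(x)
  h <- 0
  for (v in unique(x)) {
    p <- sum(x == v) / length(x)
    h <- h - p * log2(p)
  }
  h
}

oracle_info_gain <- function(f, y) {
  f <- as.character(f)
  ig <- oracle_entropy(y)
  for (v in unique(f)) {
    sel <- f == v
    ig <- ig - sum(sel) / length(f) * oracle_entropy(y[sel])
  }
  ig
}

oracle_gain_ratio <- function(f, y) {
  hf <- oracle_entropy(f)
  if (hf == 0) 0 else oracle_info_gain(f, y) / hf
}

oracle_symmetric_uncertainty <- function(f, y) {
  denom <- oracle_entropy(f) + oracle_entropy(y)
  if (denom == 0) 0 else 2 * oracle_info_gain(f, y) / denom
}

oracle_chi_squared <- function(f, y) {
  f <- as.character(f); y <- as.character(y)
  n <- length(f)
  stat <- 0
  for (v in unique(f)) for (c in unique(y)) {
    obs <- sum(f == v & y == c)
    exp <- sum(f == v) * sum(y == c) / n
    if (exp > 0) stat <- stat + (obs - exp)^2 / exp
  }
  stat
}

oracle_gini_index <- function(f, y) {
  f <- as.character(f)
  gini <- function(x) {
    g <- 1
    for (v in unique(x)) g <- g - (sum(x == v) / length(x))^2
    g
  }
  out <- gini(y)
  for (v in unique(f)) {
    sel <- f == v
    out <- out - sum(sel) / length(f) * gini(y[sel])
  }
  out
}

# exhaustive single-feature rule accuracy (numeric: every threshold and
# orientation; categorical: per-level majority)
oracle_rule <- function(f, y) {
  y <- as.character(y)
  n <- length(y)
  majority <- function(yy) if (length(yy) == 0) 0 else max(table(yy))
  if (is.character(f) || is.factor(f)) {
    f <- as.character(f)
    correct <- 0
    for (v in unique(f)) correct <- correct + majority(y[f == v])
    return(correct / n)
  }
  best <- majority(y) / n
  for (thr in sort(unique(f))) {
    for (dir in c("le", "gt")) {
      left <- if (dir == "le") f <= thr else f > thr
      acc <- (majority(y[left]) + majority(y[!left])) / n
      if (acc > best) best <- acc
    }
  }
  best
}

# full-pass Relief over a data.frame of features with exhaustive neighbor
# search (k nearest hits/misses under Manhattan distance, numeric diffs
# range-normalized, ties by sample index)
oracle_relief <- function(df, y, k) {
  y <- as.character(y)
  n <- nrow(df)
  diffmat <- function(col) {
    v <- df[[col]]
    if (is.numeric(v)) {
      rng <- max(v) - min(v)
      m <- matrix(0, n, n)
      if (rng > 0) for (i in 1:n) for (j in 1:n) m[i, j] <- abs(v[i] - v[j]) / rng
      m
    } else {
      v <- as.character(v)
      m <- matrix(0, n, n)
      for (i in 1:n) for (j in 1:n) m[i, j] <- as.numeric(v[i] != v[j])
      m
    }
  }
  dms <- lapply(names(df), diffmat)
  names(dms) <- names(df)
  total <- Reduce("+", dms)
  w <- setNames(numeric(ncol(df)), names(df))
  for (i in 1:n) {
    hits <- setdiff(which(y == y[i]), i)
    misses <- which(y != y[i])
    hits <- hits[order(total[i, hits], hits)][1:k]
    misses <- misses[order(total[i, misses], misses)][1:k]
    for (f in names(df)) {
      w[f] <- w[f] + sum(dms[[f]][i, misses]) / (n * k) -
        sum(dms[[f]][i, hits]) / (n * k)
    }
  }
  w
}

# Benjamini-Hochberg from the step-up definition: q_i = min over j with
# p_(j) >= p_(i) of m p_(j) / j, capped at 1
oracle_bh <- function(p) {
  m <- length(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- sum(p <= p[i])
    cands <- c()
    for (j in seq_len(m)) {
      rank_j <- sum(p <= p[j])
      if (p[j] >= p[i]) cands <- c(cands, m * p[j] / rank_j)
    }
    q[i] <- min(1, min(cands))
  }
  q
}

# shortest interval holding ceiling(mass * S) draws, by scanning every
# start position
oracle_hdi <- function(draws, mass = 0.95) {
  s <- sort(draws)
  S <- length(s)
  keep <- min(S, max(2, ceiling(mass * S)))
  best <- c(-Inf, Inf)
  for (i in 1:(S - keep + 1)) {
    lo <- s[i]; hi <- s[i + keep - 1]
    if (hi - lo < best[2] - best[1]) best <- c(lo, hi)
  }
  best
}

# exhaustive minimum-cardinality set cover over drug coverage sets;
# returns the size of the smallest subset covering all coverable genes
oracle_min_cover_size <- function(cov_sets, genes) {
  coverable <- unique(unlist(cov_sets))
  target <- intersect(genes, coverable)
  drugs <- names(cov_sets)
  for (size in 0:length(drugs)) {
    for (subset in combn_list(drugs, size)) {
      got <- unique(unlist(cov_sets[subset]))
      if (all(target %in% got)) return(size)
    }
  }
  length(drugs)
}

combn_list <- function(x, m) {
  if (m == 0) return(list(character(0)))
  if (m > length(x)) return(list())
  lapply(seq_len(ncol(utils::combn(length(x), m))),
         function(i) x[utils::combn(length(x), m)[, i]])
}

# closed-form conjugate posterior of the group difference for the
# fixed-sigma normal model with Normal(0, tau2) priors on (mu, delta)
oracle_conjugate_delta <- function(y, g, sigma, tau2) {
  X <- cbind(1, g)
  prec <- crossprod(X) / sigma^2 + diag(1 / tau2, 2)
  V <- solve(prec)
  m <- V %*% crossprod(X, y) / sigma^2
  list(mean = m[2], sd = sqrt(V[2, 2]))
}
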