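# Bayesian two-group effect model and effect-existence summaries:
# posterior median (E_M), 95% highest-density interval, probability of
# direction (D_p), and proportion of the posterior inside a region of
# practical equivalence (ROPE_p).

#' Bayesian two-group normal model for a behavioral outcome
#'
#' Model: `y = mu + delta * I(CR) + eps`, `eps ~ Normal(0, sigma^2)`, with
#' weakly informative priors `mu, delta ~ Normal(0, (10 sd(y))^2)` and
#' `sigma ~ half-Cauchy(sd(y))`. Sampling is Metropolis-within-Gibbs:
#' (mu, delta) are drawn jointly from their conjugate conditional and
#' log(sigma) by a random-walk Metropolis step. Four chains are run, the
#' first half of each discarded as warm-up, and the retained delta draws
#' pooled. A split-R-hat above 1.05 triggers a warning (no hard gate).
#'
#' @param y numeric outcome per subject (finite, non-constant)
#' @param group factor/character with levels control and CR, >= 2 per group
#' @param S total retained draw count across chains (default 4000)
#' @param seed RNG seed (optional)
#' @param chains chain count (default 4)
#' @return numeric vector of pooled delta draws, class `cr_draws`, with
#'   attributes `parameter`, `sd_y` (for the default ROPE) and `rhat`
#' @export
fit_group_model <- function(y, group, S = 4000, seed = NULL, chains = 4) {
  if (any(!is.finite(y))) stop("non-finite outcome values")
  if (stats::var(y) == 0) stop("zero-variance outcome")
  g <- as.integer(factor(group, levels = TREATMENT_LEVELS)) - 1L
  if (any(is.na(g))) g <- as.integer(factor(group)) - 1L
  if (sum(g == 0) < 2 || sum(g == 1) < 2)
    stop("need >= 2 subjects per group")
  if (!is.null(seed)) set.seed(seed)
  n <- length(y)
  sdy <- stats::sd(y)
  tau2 <- (10 * sdy)^2          # prior variance of mu and delta
  cauchy_scale <- sdy
  X <- cbind(1, g)
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  per_chain <- ceiling(S / chains)
  warm <- per_chain                      # equal warm-up, discarded
  draws <- matrix(NA_real_, per_chain, chains)
  for (ch in seq_len(chains)) {
    beta <- c(mean(y), 0) + stats::rnorm(2, 0, sdy / 2)
    log_sigma <- log(sdy) + stats::rnorm(1, 0, 0.5)
    for (it in seq_len(warm + per_chain)) {
      # conjugate normal draw of (mu, delta) | sigma
      sigma2 <- exp(2 * log_sigma)
      prec <- XtX / sigma2 + diag(1 / tau2, 2)
      V <- solve(prec)
      m <- V %*% (Xty / sigma2)
      L <- chol(V)
      beta <- as.numeric(m + t(L) %*% stats::rnorm(2))
      # random-walk Metropolis on log sigma, half-Cauchy(sd_y) prior
      resid2 <- sum((y - X %*% beta)^2)
      logpost <- function(ls) {
        s <- exp(ls)
        -n * ls - resid2 / (2 * s^2) +
          stats::dcauchy(s, 0, cauchy_scale, log = TRUE) + ls
      }
      prop <- log_sigma + stats::rnorm(1, 0, 0.5)
      if (log(stats::runif(1)) < logpost(prop) - logpost(log_sigma))
        log_sigma <- prop
      if (it > warm) draws[it - warm, ch] <- beta[2]
    }
  }
  rhat <- split_rhat(draws)
  if (is.finite(rhat) && rhat > 1.05)
    warning(sprintf("split R-hat = %.3f exceeds 1.05; inspect convergence",
                    rhat))
  structure(as.numeric(draws)[seq_len(min(S, length(draws)))],
            parameter = "delta", sd_y = sdy, rhat = rhat,
            class = "cr_draws")
}

# split-R-hat over a draws-per-chain matrix (columns = chains)
split_rhat <- function(draws) {
  half <- floor(nrow(draws) / 2)
  if (half < 2) return(NA_real_)
  halves <- cbind(draws[seq_len(half), , drop = FALSE],
                  draws[half + seq_len(half), , drop = FALSE])
  m <- ncol(halves); n <- nrow(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, stats::var)
  B <- n * stats::var(means)
  W <- mean(vars)
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Highest-density interval of a draw vector
#'
#' Sliding-window shortest interval containing `ceiling(mass * S)` of the
#' sorted draws.
#'
#' @param draws numeric draw vector (length >= 2)
#' @param mass interval mass (default 0.95)
#' @return numeric c(low, high)
#' @export
hdi <- function(draws, mass = 0.95) {
  if (length(draws) < 2) stop("need >= 2 draws")
  if (mass <= 0 || mass > 1) stop("mass must be in (0, 1]")
  s <- sort(draws)
  S <- length(s)
  keep <- min(S, max(2L, ceiling(mass * S)))
  starts <- seq_len(S - keep + 1L)
  widths <- s[starts + keep - 1L] - s[starts]
  i <- starts[which.min(widths)]
  c(s[i], s[i + keep - 1L])
}

#' Probability of direction
#'
#' `max(P(delta > 0), P(delta < 0))` as a percentage; draws exactly zero
#' count in neither side.
#'
#' @param draws numeric draw vector
#' @return percentage in \[50, 100\] (for a two-sided posterior)
#' @export
probability_of_direction <- function(draws) {
  pos <- mean(draws > 0)
  neg <- mean(draws < 0)
  100 * max(pos, neg)
}

#' Proportion of the posterior inside a region of practical equivalence
#'
#' Full-posterior convention: the fraction of all draws in
#' `[rope_low, rope_high]`.
#'
#' @param draws numeric draw vector
#' @param rope_low,rope_high ROPE bounds, `rope_low < rope_high`
#' @return fraction in \[0, 1\]
#' @export
rope_proportion <- function(draws, rope_low, rope_high) {
  if (!(rope_low < rope_high)) stop("rope_low must be < rope_high")
  mean(draws >= rope_low & draws <= rope_high)
}

#' Four-statistic effect-existence summary of a posterior
#'
#' Computes the posterior median E_M, the 95% HDI, the probability of
#' direction D_p (percent) and the ROPE proportion. When the draws come from
#' [fit_group_model()] the default ROPE is `+/- 0.1 sd(y)`; otherwise bounds
#' must be supplied.
#'
#' @param draws a `cr_draws` vector (or any numeric draw vector)
#' @param mass HDI mass (default 0.95)
#' @param rope_low,rope_high ROPE bounds; default `+/- 0.1 * attr(draws,
#'   "sd_y")` when available
#' @return list of class `cr_posterior_summary`
#' @export
posterior_summary <- function(draws, mass = 0.95,
                              rope_low = NULL, rope_high = NULL) {
  if (is.null(rope_low) || is.null(rope_high)) {
    sdy <- attr(draws, "sd_y")
    if (is.null(sdy))
      stop("rope bounds required when draws carry no sd_y attribute")
    rope_low <- -0.1 * sdy
    rope_high <- 0.1 * sdy
  }
  h <- hdi(draws, mass)
  structure(list(E_M = stats::median(draws),
                 hdi_low = h[1], hdi_high = h[2],
                 D_p = probability_of_direction(draws),
                 ROPE_p = rope_proportion(draws, rope_low, rope_high),
                 rope_low = rope_low, rope_high = rope_high,
                 mass = mass),
            class = "cr_posterior_summary")
}

#' @export
format.cr_posterior_summary <- function(x, ...) {
  rope <- if (x$ROPE_p < 0.01) "ROPE_p < 0.01"
          else if (x$ROPE_p > 0.99) "ROPE_p > 0.99"
          else sprintf("ROPE_p = %.2f", x$ROPE_p)
  sprintf("E_M = %.2f (%.2f, %.2f), D_p = %.0f%%, %s",
          x$E_M, x$hdi_low, x$hdi_high, x$D_p, rope)
}

#' @export
print.cr_posterior_summary <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
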