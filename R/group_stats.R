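# Group-level inference on per-participant decoding accuracies: bootstrap
# resampling, BCa confidence intervals, and the shifted-to-chance Monte
# Carlo significance test.

#' Bootstrap distribution of the group mean
#'
#' @param values Per-participant accuracies (n >= 2).
#' @param B Number of with-replacement resamples (default 10,000).
#' @param seed RNG seed.
#' @return Numeric vector of B resampled means.
#' @export
bootstrap_means <- function(values, B = 10000, seed = 1L) {
  n <- length(values)
  if (n < 2) stop("need at least 2 values")
  if (B < 1) stop("B must be at least 1")
  withr::with_seed(seed, {
    idx <- sample.int(n, n * B, replace = TRUE)
  })
  .colMeans(values[idx], n, B)
}

#' Bias-corrected and accelerated (BCa) bootstrap confidence interval
#'
#' Standard BCa: the bias-correction term comes from the fraction of
#' bootstrap means below the observed mean, the acceleration term from the
#' skewness of the jackknife means; the interval is given by adjusted
#' percentiles of the bootstrap distribution of the mean.
#'
#' @param values Sample values (n >= 2).
#' @param B Bootstrap resamples.
#' @param level Confidence level (0.95).
#' @param seed RNG seed.
#' @return Length-2 numeric `(lo, hi)`. Identical values give a degenerate
#'   zero-width interval with a warning.
#' @export
bca_interval <- function(values, B = 10000, level = 0.95, seed = 1L) {
  n <- length(values)
  if (n < 2) stop("need at least 2 values")
  obs <- mean(values)
  if (length(unique(values)) == 1L) {
    warning("all values identical; returning a degenerate interval")
    return(c(obs, obs))
  }
  boot <- bootstrap_means(values, B, seed)
  prop <- sum(boot < obs) / B
  prop <- min(max(prop, 1 / (B + 1)), B / (B + 1))   # keep z0 finite
  z0 <- qnorm(prop)
  jack <- (sum(values) - values) / (n - 1)
  dif <- mean(jack) - jack
  a <- sum(dif^3) / (6 * sum(dif^2)^1.5)
  alpha <- (1 - level) / 2
  z <- qnorm(c(alpha, 1 - alpha))
  adj <- pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
  unname(quantile(boot, adj, type = 6, names = FALSE))
}

#' Shifted-to-chance Monte Carlo significance test for group accuracy
#'
#' The null sample is formed by subtracting the observed group mean from
#' every participant's accuracy and adding the chance level, recentring
#' the empirical distribution on chance; B bootstrap means of the null
#' sample form the null distribution. The one-tailed p-value counts the
#' null means that reach the observed group mean, with 1 added to both
#' numerator and denominator so p is never exactly 0.
#'
#' @param values Per-participant accuracies in `[0, 1]` (n >= 2).
#' @param chance Chance accuracy (0.25 for 4-way classification).
#' @param B Bootstrap resamples (10,000).
#' @param level Confidence level of the reported BCa interval.
#' @param seed RNG seed (null resampling and CI use derived sub-seeds).
#' @return Object of class `group_result`: `n`, `observed_mean`, `B`,
#'   `exceed_count`, `p_value = (exceed_count + 1) / (B + 1)`, `bca_ci`,
#'   `chance`, `boot_seed`, and `null_means` (the null distribution).
#' @export
monte_carlo_p <- function(values, chance = 0.25, B = 10000, level = 0.95,
                          seed = 1L) {
  if (any(values < 0 | values > 1)) stop("accuracies must lie in [0, 1]")
  if (length(values) < 2) stop("need at least 2 values")
  obs <- mean(values)
  null_values <- values - obs + chance
  null_means <- bootstrap_means(null_values, B, derive_seed(seed, 1))
  exceed <- sum(null_means >= obs)
  ci <- if (length(unique(values)) == 1L) c(obs, obs) else
    bca_interval(values, B, level, derive_seed(seed, 2))
  structure(
    list(n = length(values), observed_mean = obs, B = B,
         exceed_count = exceed, p_value = (exceed + 1) / (B + 1),
         bca_ci = ci, ci_level = level, chance = chance, boot_seed = seed,
         null_means = null_means),
    class = "group_result")
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf(
    "Group decoding: mean %.4f (chance %.2f), n = %d\n  BCa %d%% CI [%.4f, %.4f], Monte Carlo p = %.4g (B = %d)\n",
    x$observed_mean, x$chance, x$n, round(100 * x$ci_level),
    x$bca_ci[1], x$bca_ci[2], x$p_value, x$B))
  invisible(x)
}

#' Bonferroni-adjusted alpha level
#'
#' @param alpha Family-wise alpha (0.05).
#' @param m Number of comparisons (>= 1).
#' @return List with `alpha_adjusted` (full precision) and `rounded`
#'   (3 decimals, as conventionally reported).
#' @export
bonferroni_alpha <- function(alpha = 0.05, m) {
  if (m < 1) stop("m must be at least 1")
  adj <- alpha / m
  list(alpha_adjusted = adj, rounded = round(adj, 3))
}
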