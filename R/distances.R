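shannon_entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

check_prob <- function(p, name) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop(name, " is not a probability distribution (non-negative, sum 1)",
         call. = FALSE)
  }
}

#' Jensen-Shannon divergence between two discrete distributions
#'
#' A symmetric, bounded relative of the Kullback-Leibler divergence:
#' `JSD(p, q) = H((p+q)/2) - (H(p) + H(q))/2` with Shannon entropy `H` in
#' base-2 logarithms and the convention `0 log 0 = 0`. With base 2 the
#' value lies in `[0, 1]`, reaching 1 exactly for distributions with
#' disjoint supports.
#'
#' @param p,q Non-negative numeric vectors of equal length summing to 1.
#' @return JSD in bits, in `[0, 1]`.
#' @export
jsd <- function(p, q) {
  stopifnot(length(p) == length(q))
  check_prob(p, "p")
  check_prob(q, "q")
  m <- (p + q) / 2
  v <- shannon_entropy_bits(m) -
    (shannon_entropy_bits(p) + shannon_entropy_bits(q)) / 2
  min(max(v, 0), 1)  # clamp floating-point noise at the bounds
}

#' Square-root Jensen-Shannon distance
#'
#' The square root of [jsd()] is a true metric on probability
#' distributions (identity, symmetry, triangle inequality), used as the
#' dissimilarity `D` between daily rhythms.
#'
#' @inheritParams jsd
#' @return Distance in `[0, 1]`.
#' @export
sqrt_jsd <- function(p, q) sqrt(jsd(p, q))

#' Euclidean (L2) distance between two distributions
#'
#' The classic alternative to the square-root Jensen-Shannon distance for
#' the persistence analysis; bounded by `sqrt(2)` on probability vectors.
#'
#' @inheritParams jsd
#' @return Non-negative distance.
#' @export
l2_distance <- function(p, q) {
  stopifnot(length(p) == length(q))
  sqrt(sum((p - q)^2))
}

rhythm_distance <- function(p, q, metric = c("sqrt_jsd", "l2")) {
  metric <- match.arg(metric)
  if (metric == "sqrt_jsd") sqrt_jsd(p, q) else l2_distance(p, q)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Thin wrapper around `stats::ks.test` (two-sided, asymptotic p-value)
#' that tolerates the ties arising from minute-resolution call times. The
#' statistic is the exact supremum of the absolute ECDF difference.
#'
#' @param x,y Non-empty numeric samples (here, times of day in hours).
#' @return List with `statistic` and `p_value`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    stop("KS comparison requires two non-empty samples", call. = FALSE)
  }
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Holm-Sidak step-down multiple-comparison adjustment
#'
#' Step-down Sidak correction: with the raw p-values sorted ascending,
#' `p_adj(i) = 1 - (1 - p(i))^(m - i + 1)` with a running maximum to
#' enforce monotonicity; results are returned in the input order.
#' `stats::p.adjust` offers Holm-Bonferroni but not the Sidak variant,
#' hence the closed form here.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, elementwise `>=` the raw ones.
#' @export
holm_sidak <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  adj_sorted <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj_sorted <- cummax(adj_sorted)
  out <- numeric(m)
  out[o] <- pmin(adj_sorted, 1)
  out
}
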