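#' Kendall's coefficient of concordance
#'
#' Agreement among `m` raters scoring `n` items. Scores are converted to
#' within-rater ranks with mid-rank ties; `W = 12 S / (m^2 (n^3 - n) - m T)`
#' where `S` is the sum of squared deviations of the item rank sums from
#' their mean and `T` the usual tie correction. The associated chi-square is
#' `m (n - 1) W` on `n - 1` degrees of freedom. A single rater is perfectly
#' concordant with itself: `W = 1`, flagged degenerate.
#'
#' @param ratings numeric matrix, raters in rows, items in columns; no
#'   missing cells.
#' @return list with `W`, `chi_square`, `df`, `p_value`, `degenerate`.
#' @export
kendall_w <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings))
    stop_tosrr("Kendall's W requires a complete rating matrix", "tosrr_input_error")
  m <- nrow(ratings); n <- ncol(ratings)
  if (n < 2L)
    stop_tosrr("Kendall's W needs at least two items", "tosrr_input_error")
  if (m == 1L)
    return(list(W = 1, chi_square = (n - 1), df = n - 1L,
                p_value = stats::pchisq(n - 1, n - 1L, lower.tail = FALSE),
                degenerate = TRUE))
  ranks <- t(apply(ratings, 1L, rank))
  Rj <- colSums(ranks)
  S <- sum((Rj - m * (n + 1) / 2)^2)
  Tcorr <- sum(apply(ranks, 1L, function(r) {
    t <- table(r)
    sum(t^3 - t)
  }))
  denom <- m^2 * (n^3 - n) - m * Tcorr
  W <- if (denom > 0) 12 * S / denom else 0
  chi <- kendall_chisq(W, m, n)
  list(W = W, chi_square = chi, df = n - 1L,
       p_value = stats::pchisq(chi, n - 1L, lower.tail = FALSE),
       degenerate = FALSE)
}

#' @rdname kendall_w
#' @param W concordance coefficient.
#' @param m number of raters.
#' @param n number of items.
#' @export
kendall_chisq <- function(W, m, n) {
  m * (n - 1) * W
}

#' McNemar's test on paired correctness
#'
#' Compares two systems on the same items through the discordant counts
#' `b` (A correct, B wrong) and `c` (A wrong, B correct). The statistic is
#' the continuity-corrected chi-square `max(|b - c| - 1, 0)^2 / (b + c)`;
#' the p-value comes from the exact binomial when `b + c < 25` and from the
#' chi-square approximation (1 df) otherwise. `b + c = 0` is degenerate with
#' `p = 1`.
#'
#' @param correct_a,correct_b logical vectors of per-item correctness.
#' @return list with `statistic`, `p_value`, `b`, `c`, `method`.
#' @export
mcnemar_test <- function(correct_a, correct_b) {
  stopifnot(length(correct_a) == length(correct_b))
  a <- as.logical(correct_a); bb <- as.logical(correct_b)
  b <- sum(a & !bb); cc <- sum(!a & bb)
  nd <- b + cc
  if (nd == 0L)
    return(list(statistic = 0, p_value = 1, b = b, c = cc,
                method = "degenerate"))
  statistic <- max(abs(b - cc) - 1, 0)^2 / nd
  if (nd < 25L) {
    p <- min(1, 2 * stats::pbinom(min(b, cc), nd, 0.5))
    method <- "exact binomial"
  } else {
    p <- stats::pchisq(statistic, 1L, lower.tail = FALSE)
    method <- "continuity-corrected chi-square"
  }
  list(statistic = statistic, p_value = p, b = b, c = cc, method = method)
}

#' Paired t test with Cohen's d
#'
#' Standard paired t on the differences, with the paired effect size
#' `d = mean(diff) / sd(diff)`. Identical samples (zero-variance differences)
#' are degenerate: `t` and `p` are `NA`, `d = 0`.
#'
#' @param scores_a,scores_b paired numeric vectors.
#' @return list with `t`, `p_value`, `d`, `degenerate`.
#' @export
paired_t_cohens_d <- function(scores_a, scores_b) {
  stopifnot(length(scores_a) == length(scores_b), length(scores_a) >= 2L)
  d <- scores_a - scores_b
  if (stats::sd(d) == 0)
    return(list(t = NA_real_, p_value = NA_real_, d = 0, degenerate = TRUE))
  tt <- stats::t.test(scores_a, scores_b, paired = TRUE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       d = mean(d) / stats::sd(d), degenerate = FALSE)
}

#' Percentile bootstrap confidence interval for the mean
#'
#' Resamples the scored units with replacement `B` times under a fixed seed
#' and returns the percentile interval of the resampled means. Constant input
#' gives a degenerate interval at the mean.
#'
#' @param values numeric vector of per-unit scores.
#' @param B number of resamples (default 10000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return named numeric vector `c(lo, hi)`.
#' @export
bootstrap_ci <- function(values, B = 10000L, level = 0.95, seed = 1L) {
  stopifnot(length(values) >= 1L, level > 0, level < 1)
  n <- length(values)
  means <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n)
    colMeans(matrix(values[idx], nrow = n))
  })
  alpha <- (1 - level) / 2
  q <- stats::quantile(means, c(alpha, 1 - alpha), names = FALSE)
  c(lo = q[1], hi = q[2])
}
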