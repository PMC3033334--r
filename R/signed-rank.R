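# Exact Wilcoxon signed-rank machinery for probe-level comparisons.
#
# The per-pair change caller tests the per-probe log-ratios of one sample
# against another; probe counts are small (typically 11), so exactness of
# the tail probability matters. Zero differences are dropped; tied
# absolute differences receive averaged ranks. Exactness policy:
#   - no ties: exact via the classical signed-rank distribution (psignrank)
#     for n <= 25;
#   - ties and n <= 12: exact by enumeration of all 2^n sign assignments;
#   - otherwise: normal approximation with tie correction and continuity
#     correction.

#' Wilcoxon signed-rank test of a difference vector against zero
#'
#' @param d Numeric vector of differences (e.g. per-probe log2 ratios).
#' @param alternative `"two.sided"`, `"greater"` (positive shift) or
#'   `"less"`.
#' @param exact_max_n Largest n for which the exact untied distribution is
#'   used (default 25).
#' @param enum_max_n Largest n for which ties are handled by exact sign
#'   enumeration (default 12).
#' @return List with `statistic` (sum of positive-difference ranks),
#'   `n_used` (non-zero differences), `p_value`, and `method`
#'   (`"exact"`, `"enumeration"` or `"normal"`).
#' @export
signed_rank_test <- function(d, alternative = c("two.sided", "greater", "less"),
                             exact_max_n = 25, enum_max_n = 12) {
  alternative <- match.arg(alternative)
  d <- d[is.finite(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(statistic = 0, n_used = 0L, p_value = 1, method = "degenerate"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  has_ties <- anyDuplicated(abs(d)) > 0
  if (!has_ties && n <= exact_max_n) {
    p <- signed_rank_p_untied(w, n, alternative)
    method <- "exact"
  } else if (n <= enum_max_n) {
    p <- signed_rank_p_enum(w, r, alternative)
    method <- "enumeration"
  } else {
    p <- signed_rank_p_normal(w, r, alternative)
    method <- "normal"
  }
  list(statistic = w, n_used = as.integer(n), p_value = p, method = method)
}

signed_rank_p_untied <- function(w, n, alternative) {
  lower <- stats::psignrank(w, n)                      # P(W <= w)
  upper <- stats::psignrank(w - 1, n, lower.tail = FALSE)  # P(W >= w)
  switch(alternative,
         greater = upper,
         less = lower,
         two.sided = min(1, 2 * min(lower, upper)))
}

# Exact distribution of W under H0 for an arbitrary (possibly tied-averaged)
# rank vector, by enumerating every sign assignment. Ranks are doubled so
# half-ranks become integers and the distribution can be tabulated.
signed_rank_p_enum <- function(w, r, alternative) {
  n <- length(r)
  r2 <- as.integer(round(2 * r))
  w2 <- round(2 * w)
  # distribution over sum of a random subset of r2 (each included w.p. 1/2)
  counts <- c(1, numeric(sum(r2)))  # counts[s+1] = #assignments with sum s
  for (ri in r2) {
    shifted <- c(numeric(ri), counts[seq_len(length(counts) - ri)])
    counts <- counts + shifted
  }
  total <- 2^n
  sums <- seq_along(counts) - 1
  lower <- sum(counts[sums <= w2]) / total
  upper <- sum(counts[sums >= w2]) / total
  switch(alternative,
         greater = upper,
         less = lower,
         two.sided = min(1, 2 * min(lower, upper)))
}

signed_rank_p_normal <- function(w, r, alternative) {
  n <- length(r)
  mu <- sum(r) / 2
  sigma2 <- sum(r^2) / 4
  if (sigma2 == 0) return(1)
  z_upper <- (w - mu - 0.5) / sqrt(sigma2)
  z_lower <- (w - mu + 0.5) / sqrt(sigma2)
  upper <- stats::pnorm(z_upper, lower.tail = FALSE)
  lower <- stats::pnorm(z_lower)
  switch(alternative,
         greater = upper,
         less = lower,
         two.sided = min(1, 2 * min(lower, upper)))
}
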