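#' Paired two-sided Wilcoxon signed-rank test
#'
#' Classic signed-rank procedure for paired percentages: zero differences
#' are dropped before ranking, tied absolute differences receive midranks,
#' and the two-sided p-value is
#' `P(|W - mu| >= |w_obs - mu|)` where `W` is the signed-rank sum under the
#' null of symmetric differences. For effective sample size n <= 25 the null
#' distribution is computed exactly (all `2^n` sign assignments, via dynamic
#' programming over doubled midranks, so ties are handled exactly rather
#' than by falling back to an approximation); for larger n the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param fecal_values,oral_values Equal-length numeric vectors, paired by
#'   subject.
#' @return Two-sided p-value in \[0, 1\].
#' @export
paired_wilcoxon <- function(fecal_values, oral_values) {
  if (length(fecal_values) != length(oral_values) ||
      length(fecal_values) < 1L) {
    abort_argument("fecal_values and oral_values must have equal length >= 1")
  }
  if (anyNA(fecal_values) || anyNA(oral_values)) {
    abort_argument("paired values must not contain NA")
  }
  d <- fecal_values - oral_values
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    abort_degenerate(
      "all paired differences are zero; signed-rank test undefined"
    )
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= 25L) {
    signed_rank_exact_p(r, w)
  } else {
    signed_rank_normal_p(r, w, n)
  }
}

# Exact two-sided tail by convolution: doubling midranks makes every rank an
# integer, so the distribution of 2*W is a vector indexed by achievable sums.
signed_rank_exact_p <- function(ranks, w) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  dp <- numeric(total + 1L)
  dp[1L] <- 1
  for (ri in r2) {
    shifted <- c(numeric(ri), dp[seq_len(total + 1L - ri)])
    dp <- dp + shifted
  }
  dp <- dp / 2^length(r2)
  support <- 0:total
  mu2 <- total / 2
  dev2 <- abs(round(2 * w) - mu2)
  p <- sum(dp[abs(support - mu2) >= dev2 - 1e-7])
  min(1, p)
}

# Normal approximation with midrank tie correction and continuity
# correction, as in the standard large-sample signed-rank test.
signed_rank_normal_p <- function(ranks, w, n) {
  z <- w - n * (n + 1) / 4
  nties <- table(ranks)
  sigma <- sqrt(
    n * (n + 1) * (2 * n + 1) / 24 - sum(nties^3 - nties) / 48
  )
  correction <- sign(z) * 0.5
  z <- (z - correction) / sigma
  min(1, 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)))
}
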