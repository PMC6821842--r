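# Internal numeric helpers shared across modules.

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  ifelse(x > 30, x, log1p(exp(x)))
}

#' Fisher z transform of a correlation coefficient
#'
#' Correlations at exactly +/-1 are clipped to 1 - 1e-7 in magnitude (with a
#' warning) so the transform stays finite; this matters when pooling profiles
#' from noiseless synthetic data.
#'
#' @param r Correlation coefficient(s) in `[-1, 1]`.
#' @return `atanh` of the (possibly clipped) input.
#' @export
fisher_z <- function(r) {
  lim <- 1 - 1e-7
  if (any(abs(r) > lim, na.rm = TRUE)) {
    warning("correlation(s) at |rho| = 1 clipped before Fisher z transform")
    r <- pmin(pmax(r, -lim), lim)
  }
  atanh(r)
}

#' @rdname fisher_z
#' @param z Fisher z value(s).
#' @export
fisher_z_inv <- function(z) tanh(z)

# Running average with a centred window; edges renormalized by the number of
# samples actually inside the window, so a constant series is left unchanged.
moving_average <- function(x, k) {
  if (k <= 1L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- k %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (k - half - 1L), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Deterministic per-stage seed derivation from a single base seed.
derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 7919 + counter * 104729) %% 2147483647)
}

# Rank-based (Spearman-consistent) correlation of a vector against the columns
# of a pre-ranked matrix; used in permutation loops where the layer side is
# fixed and can be ranked once.
spearman_vs_ranked <- function(x, ranked_mat) {
  as.vector(stats::cor(rank(x), ranked_mat))
}

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " contains non-finite values")
  invisible(x)
}
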