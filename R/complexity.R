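# Sample entropy, multiscale sample entropy, detrended fluctuation
# analysis.

#' Sample entropy of a series
#'
#' `-ln(A/B)` where `B` counts pairs of length-`m` templates within
#' Chebyshev distance `r` (self-matches excluded, each unordered pair
#' counted once) and `A` counts the pairs still matching when extended to
#' length `m + 1`. Both counts run over the first `n - m` templates so
#' every counted template has an extension.
#'
#' When no extended match exists (`A = 0`) the entropy is undefined; a
#' finite cap `log(B * (B - 1) + 1)` is returned instead (and flagged via
#' attribute `capped`), keeping the feature usable in downstream
#' statistics.
#'
#' @param series numeric vector, length > m + 1.
#' @param m template length (default 2).
#' @param r tolerance (same units as the series), > 0.
#' @return sample entropy (dimensionless, >= 0).
#' @export
sample_entropy <- function(series, m = 2, r) {
  n <- length(series)
  if (n <= m + 1)
    stopf("invalid_argument", "series too short (n = %d, m = %d)", n, m)
  if (!is.finite(r) || r <= 0)
    stopf("invalid_argument", "tolerance r must be positive")
  cnt <- sampen_counts(as.numeric(series), as.integer(m), r)
  if (cnt$B == 0) return(structure(0, capped = TRUE))
  if (cnt$A == 0)
    return(structure(log(cnt$B * (cnt$B - 1) + 1), capped = TRUE))
  -log(cnt$A / cnt$B)
}

#' Multiscale sample entropy
#'
#' Scale tau replaces the series by non-overlapping means of tau
#' consecutive points (coarse-graining), then computes [sample_entropy()]
#' with a tolerance fixed at `r_factor` x the SD of the *original* series,
#' the standard multiscale convention.
#'
#' @param series numeric vector.
#' @param scales integer scales (default 1:5).
#' @param m template length.
#' @param r_factor tolerance as a fraction of the original SD.
#' @return named numeric vector `mse_scale_<tau>`.
#' @export
multiscale_sample_entropy <- function(series, scales = 1:5, m = 2,
                                      r_factor = 0.15) {
  s <- sd(series)
  if (s == 0) {
    # constant series: every template matches and extends at any scale
    return(setNames(rep(0, length(scales)),
                    paste0("mse_scale_", scales)))
  }
  r <- r_factor * s
  out <- vapply(scales, function(tau) {
    nb <- floor(length(series) / tau)
    if (nb <= m + 1)
      stopf("invalid_argument",
            "series too short for scale %d (coarse length %d)", tau, nb)
    cg <- if (tau == 1) series[seq_len(nb)]
          else colMeans(matrix(series[seq_len(nb * tau)], nrow = tau))
    as.numeric(sample_entropy(cg, m, r))
  }, 0)
  setNames(out, paste0("mse_scale_", scales))
}

#' Detrended fluctuation analysis
#'
#' Integrates the mean-subtracted series, splits the profile into
#' non-overlapping windows of each size `n`, removes an order-`order`
#' polynomial trend per window, and regresses `log F(n)` on `log n`, where
#' `F(n)` is the RMS residual. Scaling exponents are fit over the short,
#' long and overall window ranges.
#'
#' @param series numeric vector, length >= 4 x the largest window.
#' @param short_range,long_range inclusive window-size ranges (samples).
#' @param order polynomial detrending order (default 1).
#' @param n_windows number of log-spaced window sizes across the overall
#'   range.
#' @return list with `alpha_short`, `alpha_long`, `alpha_overall`, plus
#'   `window_sizes` and `fluctuation` for inspection.
#' @export
dfa <- function(series, short_range = c(4, 16), long_range = c(16, 64),
                order = 1, n_windows = 12) {
  n <- length(series)
  wmax <- max(short_range, long_range)
  wmin <- min(short_range, long_range)
  if (n < 4 * wmax)
    stopf("invalid_argument", "series too short (n = %d) for windows up to %d",
          n, wmax)
  sizes <- unique(round(exp(seq(log(wmin), log(wmax),
                                length.out = n_windows))))
  prof <- cumsum(series - mean(series))
  fl <- vapply(sizes, function(L) {
    k <- floor(n / L)
    mat <- matrix(prof[seq_len(k * L)], nrow = L)
    tt <- seq_len(L)
    X <- outer(tt, 0:order, "^")
    resid <- mat - X %*% qr.solve(X, mat)
    sqrt(mean(resid^2))
  }, 0)
  fit_alpha <- function(rng) {
    keep <- sizes >= rng[1] & sizes <= rng[2] & fl > 0
    if (sum(keep) < 2) return(NA_real_)
    unname(coef(lm.fit(cbind(1, log(sizes[keep])),
                       log(fl[keep])))[2])
  }
  list(alpha_short = fit_alpha(short_range),
       alpha_long = fit_alpha(long_range),
       alpha_overall = fit_alpha(range(c(short_range, long_range))),
       window_sizes = sizes, fluctuation = fl)
}
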