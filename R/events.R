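# Per-channel wave-event detection and waveform features.

#' Band-pass signals to the analysis band
#'
#' Zero-phase spectral filtering: each channel's FFT is masked to the
#' analysis band with raised-cosine (Tukey) transitions of 20% of each
#' band edge, then inverted. All channels of a matrix are filtered in one
#' FFT call.
#'
#' @param channel numeric vector; or for `bandpass_matrix` a channels x
#'   samples matrix.
#' @param fs sampling frequency, Hz.
#' @param config an [ef_config()].
#' @return filtered vector / matrix of the same shape.
#' @export
bandpass_channel <- function(channel, fs, config = ef_config()) {
  as.numeric(bandpass_matrix(matrix(channel, nrow = 1), fs, config))
}

#' @rdname bandpass_channel
#' @export
bandpass_matrix <- function(signals, fs, config = ef_config()) {
  n <- ncol(signals)
  freq <- (seq_len(n) - 1) / n * fs
  freq <- pmin(freq, fs - freq)  # two-sided
  lo <- config$band_cpm[1] / 60
  hi <- min(config$band_cpm[2] / 60, 0.95 * fs / 2)
  mask <- numeric(n)
  ramp_lo <- 0.2 * lo; ramp_hi <- 0.2 * hi
  up <- freq >= lo & freq <= hi
  mask[up] <- 1
  tl <- freq >= lo - ramp_lo & freq < lo
  mask[tl] <- 0.5 - 0.5 * cos(pi * (freq[tl] - (lo - ramp_lo)) / ramp_lo)
  th <- freq > hi & freq <= hi + ramp_hi
  mask[th] <- 0.5 + 0.5 * cos(pi * (freq[th] - hi) / ramp_hi)
  ft <- stats::mvfft(t(signals))
  out <- Re(stats::mvfft(ft * mask, inverse = TRUE)) / n
  t(out)
}

# robust noise scale: MAD of the first difference, rescaled
.noise_mad <- function(x) mad(diff(x)) / sqrt(2)

# vectorized local-maximum picking with a height floor and greedy
# refractory suppression (tallest peak wins); returns sorted indices
.find_peaks <- function(x, min_height, min_distance) {
  n <- length(x)
  if (n < 3) return(integer())
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n] &
                  x[2:(n - 1)] > min_height) + 1L
  if (!length(cand)) return(integer())
  cand <- cand[order(x[cand], decreasing = TRUE)]
  taken <- logical(n)
  keep <- integer()
  for (i in cand) {
    if (taken[i]) next
    keep <- c(keep, i)
    lo <- max(1L, i - min_distance); hi <- min(n, i + min_distance)
    taken[lo:hi] <- TRUE
  }
  sort(keep)
}

#' Detect slow-wave events on one channel
#'
#' Peaks are picked on the band-passed trace with prominence at least
#' `peak_prominence_mad` x the noise MAD and a refractory interval of
#' `refractory_frac` x the dominant period. For each peak the preceding
#' trough and the maximum-upstroke onset between trough and peak are
#' located.
#'
#' @param channel numeric vector (microvolts).
#' @param fs sampling frequency, Hz.
#' @param config an [ef_config()].
#' @param dominant_cpm optional dominant frequency (cpm); estimated from a
#'   whole-record periodogram when NULL.
#' @param filtered optional pre-band-passed trace (avoids refiltering).
#' @return data.frame with columns `peak_time`, `trough_time`,
#'   `onset_time` (seconds), `peak_value`, `trough_value` (microvolts, on
#'   the band-passed trace); zero rows when nothing is detectable.
#' @export
detect_events <- function(channel, fs, config = ef_config(),
                          dominant_cpm = NULL, filtered = NULL) {
  empty <- data.frame(peak_time = numeric(), trough_time = numeric(),
                      onset_time = numeric(), peak_value = numeric(),
                      trough_value = numeric())
  if (sd(channel) == 0) return(empty)
  x <- filtered %||% bandpass_channel(channel, fs, config)
  if (is.null(dominant_cpm))
    dominant_cpm <- .rough_dominant_hz(channel, fs, config) * 60
  refract <- max(1, round(config$refractory_frac * 60 / dominant_cpm * fs))
  thr <- config$peak_prominence_mad * .noise_mad(x)
  peaks <- .find_peaks(x, thr, refract)
  if (!length(peaks)) return(empty)
  trough_idx <- integer(length(peaks))
  onset_idx <- integer(length(peaks))
  prev_peak <- c(1, peaks[-length(peaks)])
  dx <- diff(x)
  for (i in seq_along(peaks)) {
    lo <- max(prev_peak[i], peaks[i] - 2 * refract)
    trough_idx[i] <- lo + which.min(x[lo:peaks[i]]) - 1
    onset_idx[i] <- if (trough_idx[i] < peaks[i])
      trough_idx[i] + which.max(dx[trough_idx[i]:(peaks[i] - 1)]) - 1
    else trough_idx[i]
  }
  data.frame(peak_time = (peaks - 1) / fs,
             trough_time = (trough_idx - 1) / fs,
             onset_time = (onset_idx - 1) / fs,
             peak_value = x[peaks], trough_value = x[trough_idx])
}

#' Waveform features from detected events
#'
#' @param events data.frame from [detect_events()] (>= 2 events).
#' @param channel the band-passed channel the events were detected on.
#' @param fs sampling frequency, Hz.
#' @return list with `average_frequency` (cpm,
#'   `60 * (n_events - 1) / elapsed`), `amplitude` (mean peak-to-trough,
#'   uV), `period` (mean inter-peak interval, s) and `slope` (mean maximum
#'   upstroke rate per event, uV/s).
#' @export
waveform_features <- function(events, channel, fs) {
  n <- nrow(events)
  if (n < 2) stopf("insufficient_events", "need >= 2 events, got %d", n)
  elapsed <- events$peak_time[n] - events$peak_time[1]
  dx <- diff(channel) * fs
  slopes <- vapply(seq_len(n), function(i) {
    a <- round(events$trough_time[i] * fs) + 1
    b <- round(events$peak_time[i] * fs) + 1
    if (b <= a) return(NA_real_)
    max(dx[a:(b - 1)])
  }, 0)
  list(average_frequency = 60 * (n - 1) / elapsed,
       amplitude = mean(events$peak_value - events$trough_value),
       period = mean(diff(events$peak_time)),
       slope = mean(slopes, na.rm = TRUE))
}
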