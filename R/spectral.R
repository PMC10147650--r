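# Welch power spectra and spectral features.

#' Welch power spectral density of one channel
#'
#' Hann-windowed, mean-detrended, 50%-overlapping segments averaged into a
#' one-sided PSD. Segments are zero-padded so the frequency grid resolves
#' at least `min_resolution_cpm` regardless of segment length. When the
#' series is shorter than one segment the whole record is used as a single
#' segment.
#'
#' @param channel numeric vector (microvolts).
#' @param fs sampling frequency, Hz.
#' @param segment_s segment length in seconds; NULL picks
#'   `welch_periods / f` from a coarse dominant-frequency pre-pass over the
#'   analysis band.
#' @param config an [ef_config()].
#' @param pad zero-pad segments so the grid resolves
#'   `min_resolution_cpm` (default). `FALSE` keeps the natural (nearly
#'   independent) bin spacing, which the quality gate uses for its
#'   peak-to-median ratio.
#' @return list with `freq_cpm`, `freq_hz` and `power` (uV^2 per bin;
#'   `sum(power)` approximates the series variance).
#' @export
welch_spectrum <- function(channel, fs, segment_s = NULL,
                           config = ef_config(), pad = TRUE) {
  n <- length(channel)
  if (n < 16) stopf("invalid_argument", "series too short for a spectrum")
  if (is.null(segment_s)) {
    f_rough <- .rough_dominant_hz(channel, fs, config)
    segment_s <- config$welch_periods / f_rough
  }
  seg_n <- min(n, max(32, round(segment_s * fs)))
  step <- max(1, floor(seg_n / 2))
  starts <- seq(1, n - seg_n + 1, by = step)
  nfft <- if (pad)
    2^ceiling(log2(max(seg_n, fs / (config$min_resolution_cpm / 60))))
  else 2^ceiling(log2(seg_n))
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, seg_n - 1) / (seg_n - 1))
  segs <- vapply(starts, function(s) {
    x <- channel[s:(s + seg_n - 1)]
    c((x - mean(x)) * win, numeric(nfft - seg_n))
  }, numeric(nfft))
  spec <- Mod(stats::mvfft(segs))^2
  # one-sided scaling so that sum(power) ~ variance of the detrended series
  pw <- rowMeans(spec)[seq_len(nfft %/% 2 + 1)] / (nfft * sum(win^2))
  pw <- pw * 2
  pw[1] <- pw[1] / 2
  freq_hz <- (seq_len(nfft %/% 2 + 1) - 1) * fs / nfft
  list(freq_cpm = freq_hz * 60, freq_hz = freq_hz, power = pw)
}

# coarse argmax of a single whole-record periodogram within the band
.rough_dominant_hz <- function(channel, fs, config) {
  n <- length(channel)
  x <- channel - mean(channel)
  nfft <- 2^ceiling(log2(max(n, fs / (config$min_resolution_cpm / 60))))
  pw <- (Mod(fft(c(x, numeric(nfft - n))))^2)[seq_len(nfft %/% 2 + 1)]
  fr <- (seq_len(nfft %/% 2 + 1) - 1) * fs / nfft * 60
  keep <- fr >= config$band_cpm[1] & fr <= config$band_cpm[2]
  if (!any(keep) || all(pw[keep] == 0)) return(mean(config$band_cpm) / 60)
  fr[keep][which.max(pw[keep])] / 60
}

#' Dominant frequency and dominant power from a spectrum
#'
#' Argmax of power within the analysis band; ties resolve toward the lower
#' frequency.
#'
#' @param spectrum result of [welch_spectrum()].
#' @param config an [ef_config()].
#' @return list with `dominant_frequency` (cpm) and `dominant_power`
#'   (uV^2, power in the peak bin).
#' @export
dominant_frequency_power <- function(spectrum, config = ef_config()) {
  keep <- spectrum$freq_cpm >= config$band_cpm[1] &
    spectrum$freq_cpm <= config$band_cpm[2]
  if (!any(keep)) stopf("no_rhythm", "empty analysis band")
  pw <- spectrum$power[keep]
  fr <- spectrum$freq_cpm[keep]
  i <- which.max(pw)  # first maximum = lowest-frequency tie
  list(dominant_frequency = fr[i], dominant_power = pw[i])
}

#' Rhythm-band power percentages
#'
#' Splits analysis-band power into brady / normal / tachy fractions around
#' the tissue's base frequency: normal is `normal_band_rel` x f0
#' (default 0.5-1.5 x), brady below, tachy above, all within the analysis
#' band. Percentages sum to 100 by construction.
#'
#' @param spectrum result of [welch_spectrum()].
#' @param tissue one of [gi_tissues].
#' @param config an [ef_config()].
#' @return named list `pct_brady`, `pct_normal`, `pct_tachy`.
#' @export
rhythm_percentages <- function(spectrum, tissue, config = ef_config()) {
  f0 <- config$tissue_f0[[tissue]]
  fr <- spectrum$freq_cpm
  keep <- fr >= config$band_cpm[1] & fr <= config$band_cpm[2]
  total <- sum(spectrum$power[keep])
  if (total <= 0) stopf("no_rhythm", "zero analysis-band power")
  lo <- config$normal_band_rel[1] * f0
  hi <- config$normal_band_rel[2] * f0
  brady <- sum(spectrum$power[keep & fr < lo])
  normal <- sum(spectrum$power[keep & fr >= lo & fr <= hi])
  tachy <- sum(spectrum$power[keep & fr > hi])
  list(pct_brady = 100 * brady / total, pct_normal = 100 * normal / total,
       pct_tachy = 100 * tachy / total)
}
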