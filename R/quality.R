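# Baseline signal-quality gating.

# live channel closest to the grid centre; the array's reference trace
# (a cross-channel average would cancel for waves spanning ~one period)
.centre_channel <- function(rec, live) {
  pos <- electrode_positions(rec)
  d2 <- (pos$row - (rec$grid_rows + 1) / 2)^2 +
    (pos$col - (rec$grid_cols + 1) / 2)^2
  live[order(d2[live])][1]
}

#' Check a recording against baseline quality requirements
#'
#' A recording fails when (a) more than `flatline_channel_frac` of the
#' channels are flatline (SD below `flatline_sd_uv`), (b) the array-median
#' Welch spectrum has no analysis-band peak exceeding
#' `peak_ratio_min` x the in-band median power (no detectable rhythm), or
#' (c) the median per-channel peak-to-peak span of the band-passed signal
#' falls below `min_amplitude_uv` (low signal-to-noise).
#'
#' @param rec an [mea_recording()].
#' @param config an [ef_config()].
#' @return list of class `quality_verdict` with `passed` (logical) and
#'   `reasons` (character vector among `"flatline"`, `"no_rhythm"`,
#'   `"low_snr"`); `passed` is TRUE iff `reasons` is empty.
#' @export
quality_check <- function(rec, config = ef_config()) {
  reasons <- character()
  ch_sd <- apply(rec$signals, 1, sd)
  live <- ch_sd >= config$flatline_sd_uv
  if (mean(!live) > config$flatline_channel_frac) {
    reasons <- c(reasons, "flatline")
  } else {
    ref <- rec$signals[.centre_channel(rec, which(live)), ]
    spec <- welch_spectrum(ref, rec$fs, config = config, pad = FALSE)
    keep <- spec$freq_cpm >= config$band_cpm[1] &
      spec$freq_cpm <= config$band_cpm[2]
    pw <- spec$power[keep]
    if (all(pw <= 0) ||
        max(pw) < config$peak_ratio_min * median(pw))
      reasons <- c(reasons, "no_rhythm")
    amp <- median(apply(rec$signals[live, , drop = FALSE], 1,
                        function(x) diff(range(x))))
    if (amp < config$min_amplitude_uv)
      reasons <- c(reasons, "low_snr")
  }
  structure(list(passed = length(reasons) == 0, reasons = reasons),
            class = "quality_verdict")
}

#' @export
print.quality_verdict <- function(x, ...) {
  cat(if (x$passed) "<quality_verdict> passed\n"
      else sprintf("<quality_verdict> FAILED: %s\n",
                   paste(x$reasons, collapse = ", ")))
  invisible(x)
}
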