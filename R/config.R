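#' Canonical tissue identifiers and slow-wave base frequencies
#'
#' The four gastrointestinal segments analysed by the pipeline and their
#' species-typical slow-wave base frequencies in cycles per minute (cpm).
#' Only relative changes matter downstream; the values set the centre of each
#' tissue's normal rhythm band.
#'
#' @format `gi_tissues` is a character vector of length four; `tissue_f0_cpm`
#'   a named numeric vector (cpm).
#' @export
gi_tissues <- c("stomach", "duodenum", "ileum", "colon")

#' @rdname gi_tissues
#' @export
tissue_f0_cpm <- c(stomach = 5, duodenum = 17, ileum = 12, colon = 7)

#' Canonical names of the 24 electrical features
#'
#' Seven waveform features (dominant/average frequency, dominant power,
#' amplitude, period, slope, velocity), three rhythm-band percentages, five
#' multiscale sample-entropy scales, three detrended-fluctuation-analysis
#' exponents and six propagation features (five pattern percentages plus a
#' pattern-change index).
#'
#' @return character vector of length 24, in canonical column order.
#' @export
ef_feature_names <- function() {
  c("dominant_frequency", "average_frequency", "dominant_power",
    "amplitude", "period", "slope", "velocity",
    "pct_brady", "pct_normal", "pct_tachy",
    paste0("mse_scale_", 1:5),
    "dfa_alpha_short", "dfa_alpha_long", "dfa_alpha_overall",
    "pct_prop_forward", "pct_prop_backward", "pct_prop_radial",
    "pct_prop_colliding", "pct_prop_unorganized",
    "prop_pattern_change_index")
}

#' Features normalized by arithmetic difference rather than percentage change
#'
#' Rhythm and propagation percentages are differenced in percentage points,
#' mirroring the treatment of "percentage of contribution" features.
#' Entropy scales, DFA exponents and the pattern-change index are unit-free
#' and may legitimately be zero at baseline, so they are also differenced
#' (a ratio would be undefined on clean recordings).
#'
#' @return character vector, subset of [ef_feature_names()].
#' @export
ef_difference_features <- function() {
  c("pct_brady", "pct_normal", "pct_tachy",
    paste0("mse_scale_", 1:5),
    "dfa_alpha_short", "dfa_alpha_long", "dfa_alpha_overall",
    "pct_prop_forward", "pct_prop_backward", "pct_prop_radial",
    "pct_prop_colliding", "pct_prop_unorganized",
    "prop_pattern_change_index")
}

#' Feature-extraction configuration
#'
#' All tunable parameters of the extraction pipeline with their defaults.
#' Values can be overridden by arguments or loaded from a YAML file with
#' [read_ef_config()].
#'
#' @param ... name-value overrides of the defaults listed below.
#' @return a list of class `ef_config`.
#' @details Defaults: analysis band 0.5-60 cpm; normal rhythm band
#'   0.5-1.5 x the tissue base frequency (brady below, tachy above); Welch
#'   spectra use Hann windows of eight dominant periods with 50% overlap and
#'   zero-padding so the frequency grid resolves at least 0.5 cpm; event
#'   detection uses a band-passed trace, peak prominence at least 3 x the
#'   noise MAD and a refractory interval of half the dominant period;
#'   multiscale sample entropy uses m = 2, r = 0.15 x SD at scales 1..5 on a
#'   2 Hz decimated trace over `complexity_channels` evenly spaced
#'   electrodes; DFA windows are 4-16 (short), 16-64 (long) and 4-64
#'   (overall) samples with order-1 detrending; propagation plane fits
#'   require R^2 >= 0.7 and a +/-45 degree cone around the longitudinal
#'   axis; quality gating uses a 1 uV flatline SD, a spectral
#'   peak-to-median ratio of 4 and a 5 uV minimum amplitude.
#' @export
ef_config <- function(...) {
  cfg <- list(
    band_cpm = c(0.5, 60),
    normal_band_rel = c(0.5, 1.5),
    welch_periods = 8,
    min_resolution_cpm = 0.5,
    flatline_sd_uv = 1,
    flatline_channel_frac = 0.5,
    peak_ratio_min = 4,
    min_amplitude_uv = 5,
    peak_prominence_mad = 3,
    refractory_frac = 0.5,
    mse_scales = 1:5,
    mse_m = 2,
    mse_r_factor = 0.15,
    complexity_fs = 2,
    complexity_channels = 8,
    spectral_channels = 16,
    dfa_short = c(4, 16),
    dfa_long = c(16, 64),
    dfa_order = 1,
    max_prop_waves = 60,
    plane_r2_min = 0.7,
    forward_halfangle_deg = 45,
    max_velocity_um_s = 5e4,
    tissue_f0 = tissue_f0_cpm
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stopf("invalid_argument", "unknown config fields: %s",
                         paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "ef_config")
}

#' Read or write an extraction configuration as YAML
#'
#' @param path file path.
#' @param cfg an [ef_config()] object (for writing).
#' @return [read_ef_config()] returns an `ef_config`; `write_ef_config()`
#'   returns `path` invisibly.
#' @export
read_ef_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$tissue_f0)) vals$tissue_f0 <- unlist(vals$tissue_f0)
  do.call(ef_config, vals)
}

#' @rdname read_ef_config
#' @export
write_ef_config <- function(cfg, path) {
  vals <- unclass(cfg)
  vals$tissue_f0 <- as.list(vals$tissue_f0)  # keep names in YAML
  yaml::write_yaml(vals, path)
  invisible(path)
}
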