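# Assembly of the 24-feature EF vector for one recording, and streaming
# extraction over a whole study.

# Per-channel Welch PSDs computed jointly (one big FFT) for speed.
# Returns bins x channels power matrix plus the frequency grid.
.welch_psd_matrix <- function(sig, fs, segment_s, config) {
  n <- ncol(sig); n_ch <- nrow(sig)
  seg_n <- min(n, max(32, round(segment_s * fs)))
  step <- max(1, floor(seg_n / 2))
  starts <- seq(1, n - seg_n + 1, by = step)
  nfft <- 2^ceiling(log2(max(seg_n, fs / (config$min_resolution_cpm / 60))))
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, seg_n - 1) / (seg_n - 1))
  cols <- matrix(0, nfft, length(starts) * n_ch)
  for (k in seq_along(starts)) {
    blk <- sig[, starts[k]:(starts[k] + seg_n - 1), drop = FALSE]
    blk <- sweep(blk, 1, rowMeans(blk), "-")
    blk <- sweep(blk, 2, win, "*")
    cols[seq_len(seg_n), (k - 1) * n_ch + seq_len(n_ch)] <- t(blk)
  }
  spec <- Mod(stats::mvfft(cols))^2
  half <- seq_len(nfft %/% 2 + 1)
  pw <- matrix(0, length(half), n_ch)
  for (k in seq_along(starts))
    pw <- pw + spec[half, (k - 1) * n_ch + seq_len(n_ch), drop = FALSE]
  pw <- pw / length(starts) / (nfft * sum(win^2)) * 2
  pw[1, ] <- pw[1, ] / 2
  list(freq_cpm = (half - 1) * fs / nfft * 60, power = pw)
}

# decimation of an already band-limited trace (analysis band tops out at
# 1 Hz, below the target Nyquist, so plain subsampling cannot alias)
.decimate_banded <- function(x, fs, target_fs) {
  fac <- round(fs / target_fs)
  if (fac <= 1) return(x)
  x[seq(1, length(x), by = fac)]
}

#' Extract the 24 electrical features from one recording
#'
#' Runs the quality gate, band-passes every channel, computes per-channel
#' Welch spectra, slow-wave events, temporal-complexity measures and the
#' grid-level spatial features, and assembles the canonical 24-feature
#' vector. Per-channel scalars are aggregated across channels by the
#' median; velocity and propagation are computed jointly on the grid;
#' multiscale entropy and DFA use a 2 Hz decimated trace on
#' `complexity_channels` evenly spaced electrodes.
#'
#' @param rec an [mea_recording()].
#' @param config an [ef_config()].
#' @param verdict optional precomputed [quality_check()] verdict.
#' @return named numeric vector of class `ef_vector` (see
#'   [ef_feature_names()]) with the recording metadata attached as
#'   attribute `meta`.
#' @export
extract_features <- function(rec, config = ef_config(), verdict = NULL) {
  verdict <- verdict %||% quality_check(rec, config)
  if (!verdict$passed)
    stopf("rejected_recording", "recording failed quality checks: %s",
          paste(verdict$reasons, collapse = ", "))
  n_ch <- nrow(rec$signals)
  flt <- bandpass_matrix(rec$signals, rec$fs, config)
  ch_sd <- apply(rec$signals, 1, sd)
  live <- which(ch_sd >= config$flatline_sd_uv)
  ref <- flt[.centre_channel(rec, live), ]
  f_rough <- .rough_dominant_hz(ref, rec$fs, config)
  spec_ch <- live[unique(round(seq(1, length(live),
                                   length.out = min(config$spectral_channels,
                                                    length(live)))))]
  psd <- .welch_psd_matrix(rec$signals[spec_ch, , drop = FALSE], rec$fs,
                           segment_s = config$welch_periods / f_rough,
                           config = config)
  keep <- psd$freq_cpm >= config$band_cpm[1] &
    psd$freq_cpm <= config$band_cpm[2]
  fr <- psd$freq_cpm[keep]
  f0 <- config$tissue_f0[[rec$tissue]]
  lo <- config$normal_band_rel[1] * f0; hi <- config$normal_band_rel[2] * f0
  per_ch <- vapply(seq_along(spec_ch), function(ci) {
    pw <- psd$power[keep, ci]
    tot <- sum(pw)
    i <- which.max(pw)
    c(dom_f = fr[i], dom_p = pw[i],
      brady = 100 * sum(pw[fr < lo]) / tot,
      normal = 100 * sum(pw[fr >= lo & fr <= hi]) / tot,
      tachy = 100 * sum(pw[fr > hi]) / tot)
  }, numeric(5))
  dom_cpm <- median(per_ch["dom_f", ])

  # peak times on every live channel (propagation needs the full grid);
  # full event structures only where waveform features are computed
  refract <- max(1, round(config$refractory_frac * 60 / dom_cpm * rec$fs))
  peak_times <- lapply(seq_len(n_ch), function(ci) {
    if (!(ci %in% live)) return(numeric())
    x <- flt[ci, ]
    (.find_peaks(x, config$peak_prominence_mad * .noise_mad(x),
                 refract) - 1) / rec$fs
  })
  wf <- vapply(spec_ch, function(ci) {
    ev <- detect_events(rec$signals[ci, ], rec$fs, config,
                        dominant_cpm = dom_cpm, filtered = flt[ci, ])
    if (nrow(ev) < 2) return(c(NA_real_, NA, NA, NA))
    w <- waveform_features(ev, flt[ci, ], rec$fs)
    c(w$average_frequency, w$amplitude, w$period, w$slope)
  }, numeric(4))

  sub <- live[unique(round(seq(1, length(live),
                               length.out = min(config$complexity_channels,
                                                length(live)))))]
  cx <- vapply(sub, function(ci) {
    dec <- .decimate_banded(flt[ci, ], rec$fs, config$complexity_fs)
    mse <- multiscale_sample_entropy(dec, config$mse_scales,
                                     config$mse_m, config$mse_r_factor)
    df <- dfa(dec, config$dfa_short, config$dfa_long, config$dfa_order)
    c(mse, df$alpha_short, df$alpha_long, df$alpha_overall)
  }, numeric(length(config$mse_scales) + 3))

  vel <- estimate_velocity(rec, config, filtered = flt)
  prop <- propagation_features(rec, config, events = peak_times)

  out <- c(
    dominant_frequency = dom_cpm,
    average_frequency = median(wf[1, ], na.rm = TRUE),
    dominant_power = median(per_ch["dom_p", ]),
    amplitude = median(wf[2, ], na.rm = TRUE),
    period = median(wf[3, ], na.rm = TRUE),
    slope = median(wf[4, ], na.rm = TRUE),
    velocity = as.numeric(vel),
    pct_brady = median(per_ch["brady", ]),
    pct_normal = median(per_ch["normal", ]),
    pct_tachy = median(per_ch["tachy", ]),
    apply(cx[seq_along(config$mse_scales), , drop = FALSE], 1, median),
    dfa_alpha_short = median(cx[length(config$mse_scales) + 1, ]),
    dfa_alpha_long = median(cx[length(config$mse_scales) + 2, ]),
    dfa_alpha_overall = median(cx[length(config$mse_scales) + 3, ]),
    pct_prop_forward = prop$pct_prop_forward,
    pct_prop_backward = prop$pct_prop_backward,
    pct_prop_radial = prop$pct_prop_radial,
    pct_prop_colliding = prop$pct_prop_colliding,
    pct_prop_unorganized = prop$pct_prop_unorganized,
    prop_pattern_change_index = prop$prop_pattern_change_index
  )
  # rhythm medians are taken per band and may not sum exactly to 100;
  # renormalize so the conservation invariant holds after aggregation
  rb <- c("pct_brady", "pct_normal", "pct_tachy")
  out[rb] <- 100 * out[rb] / sum(out[rb])
  out <- setNames(as.numeric(out), ef_feature_names())
  structure(out, class = "ef_vector",
            meta = list(tissue = rec$tissue, drug_id = rec$drug_id,
                        dose = rec$dose, phase = rec$phase,
                        repeat_idx = rec$repeat_idx))
}

#' @export
print.ef_vector <- function(x, ...) {
  m <- attr(x, "meta")
  cat(sprintf("<ef_vector> %s %s %s\n", m$drug_id, m$tissue, m$phase))
  print(round(unclass(setNames(as.numeric(x), names(x))), 3))
  invisible(x)
}

#' Extract normalized features for every manifest row of a study
#'
#' For each (drug, dose, tissue, repeat): simulates (or reads) the baseline
#' and post-drug recordings, applies the baseline quality gate (failing
#' rows are excluded and logged), extracts both 24-feature vectors and
#' normalizes post against baseline ([normalize_features()]).
#'
#' @param study a `gi_study` from [generate_study()].
#' @param config an [ef_config()].
#' @param store_dir optional directory of a materialized study; recordings
#'   are simulated on the fly when NULL.
#' @param progress print a dot every 50 rows.
#' @return data.frame with metadata columns (`drug_id`, `dose`,
#'   `dose_rank`, `tissue`, `repeat_idx`) and the 24 normalized feature
#'   columns; excluded rows are recorded in attribute `rejections`.
#' @export
extract_study_features <- function(study, config = ef_config(),
                                   store_dir = NULL, progress = FALSE) {
  m <- study$manifest
  rows <- vector("list", nrow(m))
  rejections <- list()
  for (i in seq_len(nrow(m))) {
    if (progress && i %% 50 == 0) cat(".")
    base <- if (is.null(store_dir)) study_recording(study, i, "baseline")
            else read_recording(store_dir,
                                paste0(m$recording_id[i], "_baseline"))
    vb <- quality_check(base, config)
    if (!vb$passed) {
      rejections[[length(rejections) + 1]] <-
        data.frame(recording_id = m$recording_id[i],
                   reasons = paste(vb$reasons, collapse = ";"))
      next
    }
    post <- if (is.null(store_dir)) study_recording(study, i, "post_drug")
            else read_recording(store_dir,
                                paste0(m$recording_id[i], "_post_drug"))
    efb <- extract_features(base, config, verdict = vb)
    efp <- extract_features(post, config)
    delta <- tryCatch(normalize_features(efb, efp),
                      gipace_error = function(e) NULL)
    if (is.null(delta)) {
      rejections[[length(rejections) + 1]] <-
        data.frame(recording_id = m$recording_id[i],
                   reasons = "degenerate_baseline")
      next
    }
    rows[[i]] <- cbind(data.frame(drug_id = m$drug_id[i], dose = m$dose[i],
                                  dose_rank = match(m$dose[i],
                                                    study$design$doses),
                                  tissue = m$tissue[i],
                                  repeat_idx = m$repeat_idx[i]),
                       as.data.frame(as.list(delta)))
  }
  if (progress) cat("\n")
  kept <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(kept))
    stopf("no_rhythm", "every recording failed quality checks")
  out <- do.call(rbind, kept)
  rownames(out) <- NULL
  attr(out, "rejections") <- if (length(rejections))
    do.call(rbind, rejections) else NULL
  out
}
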