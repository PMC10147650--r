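# Spatial features: propagation velocity and per-wave pattern
# classification over the electrode grid.

# FFT cross-correlation lag (seconds) of b relative to a, restricted to
# |lag| <= max_lag_s, with parabolic sub-sample refinement.
.xcorr_lag <- function(A, B, fs, max_lag_s, nfft) {
  r <- Re(fft(Conj(A) * B, inverse = TRUE))
  L <- min(nfft %/% 2 - 1, max(1, floor(max_lag_s * fs)))
  lags <- c(0:L, -(L:1))
  idx <- c(seq_len(L + 1), nfft - (L:1) + 1)
  vals <- r[idx]
  k <- which.max(vals)
  lag <- lags[k]
  # parabolic interpolation around the peak when neighbours exist
  km <- which(lags == lag - 1); kp <- which(lags == lag + 1)
  if (length(km) == 1 && length(kp) == 1) {
    y1 <- vals[km]; y2 <- vals[k]; y3 <- vals[kp]
    den <- y1 - 2 * y2 + y3
    if (den < 0) lag <- lag + 0.5 * (y1 - y3) / den
  }
  lag / fs
}

#' Estimate slow-wave propagation speed
#'
#' Cross-correlates every adjacent electrode pair (horizontal and vertical
#' neighbours) on the band-passed signals, with lags wrapped to within half
#' a dominant period, and fits the lag gradient over electrode coordinates
#' by least squares: `lag = g . delta_position`. The speed is `1 / |g|`.
#' Near-zero gradients (synchronous array) are capped at
#' `max_velocity_um_s` and flagged via attribute `capped`.
#'
#' @param rec an [mea_recording()].
#' @param config an [ef_config()].
#' @param filtered optional precomputed band-passed signal matrix.
#' @return speed in micrometres per second.
#' @export
estimate_velocity <- function(rec, config = ef_config(), filtered = NULL) {
  ch_sd <- apply(rec$signals, 1, sd)
  live <- which(ch_sd >= config$flatline_sd_uv)
  if (length(live) < 4)
    stopf("invalid_argument", "need >= 4 non-flat channels")
  pos <- electrode_positions(rec)
  if (qr(cbind(pos$x_um[live] - mean(pos$x_um[live]),
               pos$y_um[live] - mean(pos$y_um[live])))$rank < 2)
    stopf("degenerate_geometry", "electrode coordinates are collinear")
  flt <- filtered %||% bandpass_matrix(rec$signals, rec$fs, config)
  ref <- flt[.centre_channel(rec, live), ]
  f_dom <- .rough_dominant_hz(ref, rec$fs, config)
  half_period <- 0.5 / f_dom
  n <- ncol(flt)
  nfft <- 2^ceiling(log2(n + ceiling(half_period * rec$fs) + 2))
  X <- stats::mvfft(t(cbind(flt, matrix(0, nrow(flt), nfft - n))))
  # adjacent pairs: right and down neighbours on the grid
  pairs <- .grid_adjacent_pairs(rec$grid_rows, rec$grid_cols)
  keep <- pairs$a %in% live & pairs$b %in% live
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) < 2)
    stopf("invalid_argument", "too few live adjacent pairs")
  lag <- vapply(seq_len(nrow(pairs)), function(i)
    .xcorr_lag(X[, pairs$a[i]], X[, pairs$b[i]], rec$fs, half_period,
               nfft), 0)
  dx <- pos$x_um[pairs$b] - pos$x_um[pairs$a]
  dy <- pos$y_um[pairs$b] - pos$y_um[pairs$a]
  g <- qr.solve(cbind(dx, dy), lag)
  speed <- 1 / sqrt(sum(g^2))
  if (!is.finite(speed) || speed > config$max_velocity_um_s)
    return(structure(config$max_velocity_um_s, capped = TRUE))
  speed
}

.grid_adjacent_pairs <- function(rows, cols) {
  idx <- function(r, c) (r - 1) * cols + c
  h <- expand.grid(r = seq_len(rows), c = seq_len(cols - 1))
  v <- expand.grid(r = seq_len(rows - 1), c = seq_len(cols))
  data.frame(a = c(idx(h$r, h$c), idx(v$r, v$c)),
             b = c(idx(h$r, h$c + 1), idx(v$r + 1, v$c)))
}

# Assemble the per-wave onset field by region growing from the anchor
# channel: each channel adopts its event time closest to the mean of its
# already-assigned neighbours, within +/- tol_s. Avoids cross-cycle
# aliasing on short-period tissues.
.grid_neighbours <- function(rows, cols) {
  lapply(seq_len(rows * cols), function(c_i) {
    r <- (c_i - 1) %/% cols + 1; c <- (c_i - 1) %% cols + 1
    c(if (r > 1) c_i - cols, if (r < rows) c_i + cols,
      if (c > 1) c_i - 1, if (c < cols) c_i + 1)
  })
}

.grow_onset_field <- function(anchor, t0, peak_times, nbrs, tol_s) {
  n_ch <- length(nbrs)
  onset <- rep(NA_real_, n_ch)
  onset[anchor] <- t0
  queue <- anchor; qhead <- 1L
  visited <- rep(FALSE, n_ch)
  visited[anchor] <- TRUE
  while (qhead <= length(queue)) {
    cur <- queue[qhead]; qhead <- qhead + 1L
    for (nb in nbrs[[cur]]) {
      if (visited[nb]) next
      visited[nb] <- TRUE
      pts <- peak_times[[nb]]
      assigned <- onset[nbrs[[nb]]]
      target <- mean(assigned, na.rm = TRUE)
      if (length(pts) && is.finite(target)) {
        j <- which.min(abs(pts - target))
        if (abs(pts[j] - target) <= tol_s) onset[nb] <- pts[j]
      }
      queue[length(queue) + 1L] <- nb
    }
  }
  onset
}

.plane_fit <- function(x, y, t) {
  ok <- is.finite(t)
  if (sum(ok) < 4) return(list(r2 = -Inf, gx = NA_real_, gy = NA_real_))
  X <- cbind(1, x[ok], y[ok])
  fit <- lm.fit(X, t[ok])
  tot <- sum((t[ok] - mean(t[ok]))^2)
  if (tot == 0) return(list(r2 = 0, gx = 0, gy = 0))
  list(r2 = 1 - sum(fit$residuals^2) / tot,
       gx = unname(coef(fit)[2]), gy = unname(coef(fit)[3]))
}

.classify_wave <- function(onset, pos, rows, cols, config) {
  x <- pos$x_um; y <- pos$y_um
  if (sum(is.finite(onset)) < (rows * cols) / 2) return("unorganized")
  pf <- .plane_fit(x, y, onset)
  half <- config$forward_halfangle_deg * pi / 180
  if (pf$r2 >= config$plane_r2_min) {
    ang <- atan2(pf$gy, pf$gx)  # direction of propagation (+x longitudinal)
    if (abs(ang) <= half) return("forward")
    if (abs(abs(ang) - pi) <= half) return("backward")
  }
  # radial: onset grows with distance from some interior source point
  if (rows > 2 && cols > 2) {
    best <- list(r2 = -Inf, b = NA_real_)
    interior <- which(pos$row > 1 & pos$row < rows &
                        pos$col > 1 & pos$col < cols)
    for (s in interior) {
      d <- sqrt((x - x[s])^2 + (y - y[s])^2)
      ok <- is.finite(onset)
      X <- cbind(1, d[ok])
      fit <- lm.fit(X, onset[ok])
      tot <- sum((onset[ok] - mean(onset[ok]))^2)
      r2 <- if (tot == 0) 0 else 1 - sum(fit$residuals^2) / tot
      if (r2 > best$r2) best <- list(r2 = r2, b = unname(coef(fit)[2]))
    }
    if (best$r2 >= config$plane_r2_min && is.finite(best$b) && best$b > 0)
      return("radial")
  }
  # colliding: opposing plane fits on the two column-halves
  lh <- pos$col <= cols / 2
  pl <- .plane_fit(x[lh], y[lh], onset[lh])
  pr <- .plane_fit(x[!lh], y[!lh], onset[!lh])
  if (pl$r2 >= config$plane_r2_min && pr$r2 >= config$plane_r2_min &&
      is.finite(pl$gx) && is.finite(pr$gx) && pl$gx * pr$gx < 0)
    return("colliding")
  "unorganized"
}

#' Propagation-pattern percentages and pattern-change index
#'
#' Detects slow-wave events on every channel, assembles a per-wave onset
#' field (anchored at the centre electrode, grown outwards to the nearest
#' event within half a period), and classifies each wave by its fitted lag
#' field into forward / backward / radial / colliding / unorganized.
#' Percentages are taken over all anchor waves and sum to 100; the change
#' index is `1 - (fraction of waves sharing the modal pattern)`.
#'
#' @param rec an [mea_recording()].
#' @param config an [ef_config()].
#' @param events optional precomputed per-channel events: a list of
#'   [detect_events()] data.frames or of numeric peak-time vectors.
#' @return list with the five `pct_prop_*` percentages and
#'   `prop_pattern_change_index`.
#' @export
propagation_features <- function(rec, config = ef_config(),
                                 events = NULL) {
  pos <- electrode_positions(rec)
  n_ch <- nrow(rec$signals)
  if (is.null(events)) {
    live <- which(apply(rec$signals, 1, sd) >= config$flatline_sd_uv)
    ref <- rec$signals[.centre_channel(rec, live), ]
    f_dom <- .rough_dominant_hz(ref, rec$fs, config) * 60
    flt <- bandpass_matrix(rec$signals, rec$fs, config)
    events <- lapply(seq_len(n_ch), function(i) {
      if (!(i %in% live)) return(numeric())
      detect_events(rec$signals[i, ], rec$fs, config,
                    dominant_cpm = f_dom, filtered = flt[i, ])
    })
  }
  peak_times <- lapply(events, function(e)
    if (is.data.frame(e)) e$peak_time else as.numeric(e))
  n_events <- lengths(peak_times)
  if (mean(n_events >= 2) < 0.5)
    stopf("no_rhythm", "events detectable on fewer than half the channels")
  anchor <- order((pos$row - (rec$grid_rows + 1) / 2)^2 +
                    (pos$col - (rec$grid_cols + 1) / 2)^2)
  anchor <- anchor[n_events[anchor] >= 2][1]
  if (is.na(anchor)) stopf("no_rhythm", "no usable anchor channel")
  anchor_peaks <- peak_times[[anchor]]
  if (length(anchor_peaks) > config$max_prop_waves)
    anchor_peaks <- anchor_peaks[seq_len(config$max_prop_waves)]
  period <- median(diff(anchor_peaks))
  nbrs <- .grid_neighbours(rec$grid_rows, rec$grid_cols)
  cls <- vapply(anchor_peaks, function(t0) {
    onset <- .grow_onset_field(anchor, t0, peak_times, nbrs,
                               tol_s = period / 2)
    .classify_wave(onset, pos, rec$grid_rows, rec$grid_cols, config)
  }, "")
  lv <- c("forward", "backward", "radial", "colliding", "unorganized")
  pct <- 100 * as.numeric(table(factor(cls, levels = lv))) / length(cls)
  out <- as.list(setNames(pct, paste0("pct_prop_", lv)))
  out$prop_pattern_change_index <- 1 - max(table(cls)) / length(cls)
  out
}
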