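#' Construct an MEA recording object
#'
#' A grid multi-electrode recording: a channels x samples voltage matrix plus
#' acquisition metadata. Channels are stored row-major over the electrode
#' grid (row 1 col 1, row 1 col 2, ...).
#'
#' @param signals numeric matrix, channels x samples, in microvolts.
#' @param fs sampling frequency in Hz.
#' @param tissue one of [gi_tissues].
#' @param grid_rows,grid_cols electrode grid dimensions; their product must
#'   equal `nrow(signals)`.
#' @param pitch_um electrode pitch in micrometres.
#' @param drug_id,dose,phase,repeat_idx treatment metadata; `phase` is
#'   `"baseline"` or `"post_drug"`, `dose` in mol/L (NA for baseline).
#' @return an object of class `mea_recording`.
#' @export
mea_recording <- function(signals, fs, tissue, grid_rows, grid_cols,
                          pitch_um = 300, drug_id = NA_character_,
                          dose = NA_real_, phase = "baseline",
                          repeat_idx = 1L) {
  signals <- as.matrix(signals)
  if (fs <= 0) stopf("invalid_argument", "fs must be positive")
  if (!tissue %in% gi_tissues)
    stopf("invalid_argument", "unknown tissue '%s'", tissue)
  if (grid_rows * grid_cols != nrow(signals))
    stopf("invalid_argument", "grid %dx%d does not match %d channels",
          grid_rows, grid_cols, nrow(signals))
  if (!phase %in% c("baseline", "post_drug"))
    stopf("invalid_argument", "phase must be baseline or post_drug")
  structure(list(signals = signals, fs = fs, tissue = tissue,
                 grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 pitch_um = pitch_um, drug_id = drug_id, dose = dose,
                 phase = phase, repeat_idx = as.integer(repeat_idx)),
            class = "mea_recording")
}

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf("<mea_recording> %s %s %s (%d x %d grid, %.0f um, fs %g Hz, %d ch x %d samples)\n",
              x$drug_id, x$tissue, x$phase, x$grid_rows, x$grid_cols,
              x$pitch_um, x$fs, nrow(x$signals), ncol(x$signals)))
  invisible(x)
}

#' Electrode coordinates of a recording grid
#'
#' @param rec an `mea_recording`.
#' @return data.frame with columns `channel`, `row`, `col`, `x_um`, `y_um`;
#'   x runs along columns (the longitudinal axis), y along rows.
#' @export
electrode_positions <- function(rec) {
  g <- expand.grid(col = seq_len(rec$grid_cols), row = seq_len(rec$grid_rows))
  g <- g[order(g$row, g$col), ]
  data.frame(channel = seq_len(rec$grid_rows * rec$grid_cols),
             row = g$row, col = g$col,
             x_um = (g$col - 1) * rec$pitch_um,
             y_um = (g$row - 1) * rec$pitch_um)
}

#' Write / read a recording in the plain-text store
#'
#' One recording is stored as `<id>.csv` (the channels x samples signal
#' matrix, no header) plus `<id>.json` carrying the attributes
#' (fs, tissue, drug_id, dose, phase, repeat, grid geometry).
#'
#' @param rec an `mea_recording`.
#' @param dir store directory (created if needed).
#' @param id recording identifier used as the file stem.
#' @return `write_recording()` the file path invisibly; `read_recording()`
#'   the `mea_recording`.
#' @export
write_recording <- function(rec, dir, id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sig_path <- file.path(dir, paste0(id, ".csv"))
  utils::write.table(round(rec$signals, 4), sig_path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  attrs <- rec[setdiff(names(rec), "signals")]
  jsonlite::write_json(attrs, file.path(dir, paste0(id, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(sig_path)
}

#' @rdname write_recording
#' @export
read_recording <- function(dir, id) {
  attrs <- jsonlite::read_json(file.path(dir, paste0(id, ".json")),
                               simplifyVector = TRUE)
  sig <- as.matrix(utils::read.table(file.path(dir, paste0(id, ".csv")),
                                     sep = ",", header = FALSE))
  dimnames(sig) <- NULL
  mea_recording(sig, fs = attrs$fs, tissue = attrs$tissue,
                grid_rows = attrs$grid_rows, grid_cols = attrs$grid_cols,
                pitch_um = attrs$pitch_um, drug_id = attrs$drug_id,
                dose = if (is.null(attrs$dose)) NA_real_ else attrs$dose,
                phase = attrs$phase, repeat_idx = attrs$repeat_idx)
}
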