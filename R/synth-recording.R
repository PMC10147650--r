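# Seeded simulation of grid slow-wave recordings under drug effects, and
# whole-study generation.

#' Define a synthetic study design
#'
#' @param n_drugs number of drugs.
#' @param doses ordered dose vector in mol/L, strictly descending, at least
#'   three doses (typically ~tenfold apart).
#' @param n_repeats experimental repeats per (drug, dose, tissue), within
#'   3..10.
#' @param duration_s recording length in seconds.
#' @param fs sampling frequency in Hz; must exceed twice the top of the
#'   analysis band (1 Hz).
#' @param grid_rows,grid_cols,pitch_um electrode grid geometry.
#' @param master_seed integer; every recording derives its own stream from
#'   it, so studies are reproducible and order-independent.
#' @param amplitude_uv,noise_uv baseline waveform amplitude and additive
#'   Gaussian noise SD, in microvolts.
#' @param base_velocity_um_s baseline propagation speed along the
#'   longitudinal (column) axis.
#' @param base_jitter_sd baseline per-cycle period jitter (SD as a fraction
#'   of the period); drug `irregularity_add` adds to it.
#' @return object of class `study_design`.
#' @export
study_design <- function(n_drugs, doses = c(1e-5, 1e-6, 1e-7),
                         n_repeats = 3, duration_s = 300, fs = 10,
                         grid_rows = 8, grid_cols = 8, pitch_um = 300,
                         master_seed = 1, amplitude_uv = 100,
                         noise_uv = 10, base_velocity_um_s = 600,
                         base_jitter_sd = 0.03) {
  assert_count(n_drugs, "n_drugs")
  if (length(doses) < 3)
    stopf("invalid_argument", "at least 3 doses per drug are required")
  if (any(diff(doses) >= 0))
    stopf("invalid_argument", "doses must be strictly descending")
  if (n_repeats < 3 || n_repeats > 10)
    stopf("invalid_argument", "n_repeats must be within [3, 10]")
  if (fs <= 2 * max(tissue_f0_cpm) / 60)
    stopf("invalid_argument", "fs too low for the analysed rhythms")
  structure(list(n_drugs = as.integer(n_drugs), doses = doses,
                 n_repeats = as.integer(n_repeats),
                 tissues = gi_tissues, duration_s = duration_s, fs = fs,
                 grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols), pitch_um = pitch_um,
                 master_seed = master_seed, amplitude_uv = amplitude_uv,
                 noise_uv = noise_uv,
                 base_velocity_um_s = base_velocity_um_s,
                 base_jitter_sd = base_jitter_sd),
            class = "study_design")
}

#' Dose-response exponent of a dose within a design
#'
#' The highest dose exerts the full planted effect (exponent 1); lower
#' doses attenuate geometrically: exponent = rank / n_doses with rank
#' counted ascending from the lowest dose. Gives a monotone dose-response.
#'
#' @param dose one dose from `design$doses`.
#' @param design a `study_design`.
#' @return exponent in (0, 1].
#' @export
dose_effect_exponent <- function(dose, design) {
  i <- match(dose, design$doses)
  if (is.na(i)) stopf("invalid_argument", "dose %g not in design", dose)
  (length(design$doses) - i + 1) / length(design$doses)
}

# Phase function of a jittered oscillation: cycle boundaries accumulate
# period * (1 + eps_k); phase is linearly interpolated between boundaries.
# Covers [t_min, t_max] so channel delays can be applied by shifting time.
.jitter_phase <- function(f0_hz, jitter_sd, t_min, t_max) {
  period <- 1 / f0_hz
  n_cycles <- ceiling((t_max - t_min) / period) + 4
  eps <- pmax(pmin(rnorm(n_cycles, 0, jitter_sd), 0.4), -0.4)
  bounds <- t_min - period + cumsum(c(0, period * (1 + eps)))
  phase <- 2 * pi * seq(0, n_cycles)
  function(t) approx(bounds, phase, t, rule = 2)$y
}

#' Simulate one grid slow-wave recording
#'
#' Channels carry a travelling periodic wave at the tissue-typical base
#' frequency: a fundamental plus one harmonic, with per-cycle period jitter
#' shared across channels (waves propagate coherently) and additive
#' Gaussian noise. A plane wave travels along the longitudinal (column)
#' axis at the design's base velocity. For `phase = "post_drug"` the drug
#' profile's per-tissue multipliers are applied, attenuated by
#' [dose_effect_exponent()] (multiplier^exponent), and `irregularity_add`
#' adds to the period jitter SD.
#'
#' @param profile a `drug_profile`, or NULL for baseline.
#' @param tissue one of [gi_tissues].
#' @param dose dose in mol/L (must be one of `design$doses` for
#'   post-drug).
#' @param phase `"baseline"` or `"post_drug"`.
#' @param design a [study_design()].
#' @param seed integer; the recording is a pure function of the arguments.
#' @param repeat_idx repeat index stored in the metadata.
#' @return an [mea_recording()].
#' @export
simulate_recording <- function(profile, tissue, dose, phase, design, seed,
                               repeat_idx = 1L) {
  if (phase == "post_drug" && is.null(profile))
    stopf("invalid_argument", "post_drug simulation requires a drug profile")
  f0 <- tissue_f0_cpm[[tissue]] / 60
  amp <- design$amplitude_uv
  harm <- 1
  vel <- design$base_velocity_um_s
  jit <- design$base_jitter_sd
  if (phase == "post_drug") {
    ex <- dose_effect_exponent(dose, design)
    eff <- profile$effects[match(tissue, profile$effects$tissue), ]
    f0 <- f0 * eff$freq_mult^ex
    amp <- amp * eff$amp_mult^ex
    harm <- harm * eff$slope_mult^ex
    vel <- vel * eff$velocity_mult^ex
    jit <- jit + eff$irregularity_add * ex
  }
  if (design$fs <= 2 * f0)
    stopf("invalid_argument", "fs %g too low for base frequency %g Hz",
          design$fs, f0)
  set.seed(seed)
  n <- round(design$duration_s * design$fs)
  tt <- (seq_len(n) - 1) / design$fs
  n_ch <- design$grid_rows * design$grid_cols
  pos_x <- rep((seq_len(design$grid_cols) - 1) * design$pitch_um,
               times = design$grid_rows)
  delays <- pos_x / vel
  phi <- .jitter_phase(f0, jit, -max(delays) - 1, max(tt) + 1)
  sig <- matrix(0, n_ch, n)
  for (c_i in seq_len(n_ch)) {
    ph <- phi(tt - delays[c_i])
    sig[c_i, ] <- amp / 2 * (sin(ph) + 0.25 * harm * sin(2 * ph))
  }
  if (design$noise_uv > 0)
    sig <- sig + matrix(rnorm(n_ch * n, 0, design$noise_uv), n_ch, n)
  mea_recording(sig, fs = design$fs, tissue = tissue,
                grid_rows = design$grid_rows,
                grid_cols = design$grid_cols, pitch_um = design$pitch_um,
                drug_id = if (is.null(profile)) NA_character_ else
                  profile$drug_id,
                dose = if (phase == "post_drug") dose else NA_real_,
                phase = phase, repeat_idx = repeat_idx)
}

#' Generate a full synthetic study
#'
#' Builds (or perturbs) the drug library, draws the planted AE label table,
#' and lays out the recording manifest: one baseline and one post-drug
#' recording per (drug, dose, tissue, repeat), each with its own seed
#' derived from the master seed. Signals are simulated lazily from the
#' manifest (see [study_recording()]) unless `dir` is given, in which case
#' every recording is also written to the plain-text store together with
#' `manifest.csv` and `label_rows.csv`.
#'
#' @param design a [study_design()].
#' @param library optional list of `drug_profile`; generated with
#'   `n_classes` classes when NULL.
#' @param rules list of [ae_rule()] objects to plant.
#' @param n_classes receptor classes when generating the library.
#' @param dir optional directory; when given, recordings are materialized
#'   on disk.
#' @return object of class `gi_study`: `design`, `library` (perturbed),
#'   `labels`, `raw_rows`, `manifest` (one row per (drug, dose, tissue,
#'   repeat) with baseline and post-drug seeds).
#' @export
generate_study <- function(design, library = NULL, rules = list(),
                           n_classes = 1, dir = NULL) {
  if (is.null(library))
    library <- make_drug_library(design$n_drugs, n_classes,
                                 design$master_seed)
  if (length(library) != design$n_drugs)
    stopf("invalid_argument", "library size does not match design")
  lab <- if (length(rules)) make_ae_label_table(library, rules,
                                                design$master_seed)
         else list(labels = NULL, raw_rows = NULL, library = library)
  library <- lab$library
  drug_ids <- vapply(library, function(p) p$drug_id, "")
  manifest <- expand.grid(repeat_idx = seq_len(design$n_repeats),
                          tissue = design$tissues, dose = design$doses,
                          drug_id = drug_ids, stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE)
  manifest <- manifest[, c("drug_id", "dose", "tissue", "repeat_idx")]
  manifest <- manifest[order(manifest$drug_id, -manifest$dose,
                             manifest$tissue, manifest$repeat_idx), ]
  rownames(manifest) <- NULL
  for (ph in c("baseline", "post_drug")) {
    manifest[[paste0("seed_", ph)]] <- mapply(
      function(d, q, ti, r) derive_seed(design$master_seed, d, q, ti, r, ph),
      manifest$drug_id, manifest$dose, manifest$tissue, manifest$repeat_idx)
  }
  manifest$recording_id <- sprintf("rec_%05d", seq_len(nrow(manifest)))
  study <- structure(list(design = design, library = library,
                          labels = lab$labels, raw_rows = lab$raw_rows,
                          manifest = manifest),
                     class = "gi_study")
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(nrow(manifest))) {
      for (ph in c("baseline", "post_drug")) {
        rec <- study_recording(study, i, ph)
        write_recording(rec, dir,
                        paste0(manifest$recording_id[i], "_", ph))
      }
    }
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
    if (!is.null(lab$raw_rows))
      write.csv(lab$raw_rows, file.path(dir, "label_rows.csv"),
                row.names = FALSE)
  }
  study
}

#' Materialize one recording of a study
#'
#' @param study a `gi_study`.
#' @param i manifest row index.
#' @param phase `"baseline"` or `"post_drug"`.
#' @return an [mea_recording()].
#' @export
study_recording <- function(study, i, phase) {
  m <- study$manifest[i, ]
  prof <- study$library[[match(m$drug_id,
                               vapply(study$library,
                                      function(p) p$drug_id, ""))]]
  simulate_recording(prof, tissue = m$tissue, dose = m$dose, phase = phase,
                     design = study$design,
                     seed = m[[paste0("seed_", phase)]],
                     repeat_idx = m$repeat_idx)
}

#' @export
print.gi_study <- function(x, ...) {
  cat(sprintf("<gi_study> %d drugs x %d doses x %d tissues x %d repeats = %d manifest rows (%d recordings)\n",
              x$design$n_drugs, length(x$design$doses),
              length(x$design$tissues), x$design$n_repeats,
              nrow(x$manifest), 2L * nrow(x$manifest)))
  invisible(x)
}
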