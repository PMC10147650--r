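# Canonical synthetic benchmark studies used by the test-suite and the
# acceptance script.

#' Standard planted benchmark studies
#'
#' Two fixed synthetic study configurations exercising the whole
#' pipeline:
#'
#' * `"classification"`: 40 drugs in 4 receptor classes, 3 tenfold doses,
#'   4 tissues, 3 repeats, default 300 s recordings, with one excitatory
#'   AE rule planted at effect size d = 1 and prevalence 0.5 — a
#'   moderate-signal study for classifier-protocol benchmarks.
#' * `"network"`: 16 drugs in 2 receptor classes, 150 s recordings, with
#'   the excitatory rule at d = 3 (well-separated classes) — a
#'   strong-signal study for network / clustering benchmarks.
#'
#' @param kind which benchmark.
#' @param master_seed integer seed.
#' @return a `gi_study` (see [generate_study()]).
#' @export
planted_benchmark_study <- function(kind = c("classification", "network"),
                                    master_seed = 1) {
  kind <- match.arg(kind)
  if (kind == "classification") {
    des <- study_design(40, n_repeats = 3, master_seed = master_seed)
    generate_study(des, rules = list(excitatory_rule(d = 1,
                                                     prevalence = 0.5)),
                   n_classes = 4)
  } else {
    des <- study_design(16, n_repeats = 3, duration_s = 150,
                        master_seed = master_seed)
    generate_study(des, rules = list(excitatory_rule(d = 3,
                                                     prevalence = 0.5)),
                   n_classes = 2)
  }
}

#' Permute dataset labels (null control)
#'
#' Returns a copy of the dataset with labels permuted at row level,
#' destroying any feature-label association while keeping the feature
#' rows and label balance intact. Used for harness-leakage checks.
#'
#' @param ds a `learning_dataset`.
#' @param seed integer.
#' @return a `learning_dataset`.
#' @export
permute_labels <- function(ds, seed) {
  set.seed(derive_seed(seed, "permute_labels", ds$ae, ds$kind))
  new_learning_dataset(ds$features, sample(ds$labels), ds$meta,
                       ds$kind, ds$ae, ds$ratio)
}
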