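# Assembly of the 24-feature vector: invariants and recovery.

test_that("a clean plane wave yields the expected feature profile", {
  des <- study_design(1, master_seed = 1)
  rec <- simulate_recording(NULL, "ileum", NA, "baseline", des, 9)
  ef <- extract_features(rec)
  expect_named(as.vector(ef), NULL)
  expect_equal(names(ef), ef_feature_names())
  expect_equal(ef[["dominant_frequency"]], 12, tolerance = 0.05)
  expect_equal(ef[["average_frequency"]], 12, tolerance = 0.05)
  # fundamental sits in the normal band; the built-in first harmonic
  # carries ~6% of the power into the tachy band
  expect_gt(ef[["pct_normal"]], 90)
  expect_equal(ef[["pct_prop_forward"]], 100)
  expect_equal(ef[["period"]], 5, tolerance = 0.05)
})

test_that("feature extraction is deterministic", {
  des <- study_design(1, master_seed = 2)
  rec <- simulate_recording(NULL, "colon", NA, "baseline", des, 10)
  expect_identical(extract_features(rec), extract_features(rec))
})

test_that("EF invariants hold across random recordings", {
  des <- study_design(3, master_seed = 5)
  lib <- make_drug_library(3, 1, 5)
  combos <- expand.grid(tissue = gi_tissues, seed = 1:3,
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    rec <- simulate_recording(lib[[1 + combos$seed[i] %% 3]],
                              combos$tissue[i], 1e-6, "post_drug", des,
                              derive_seed(5, "inv", i))
    ef <- extract_features(rec)
    expect_true(all(is.finite(ef)))
    expect_equal(ef[["pct_brady"]] + ef[["pct_normal"]] + ef[["pct_tachy"]],
                 100, tolerance = 1e-6)
    expect_equal(sum(ef[paste0("pct_prop_", c("forward", "backward",
                                              "radial", "colliding",
                                              "unorganized"))]),
                 100, tolerance = 1e-6)
    expect_gt(ef[["period"]], 0)
    expect_gt(ef[["dominant_frequency"]], 0)
    expect_gt(ef[["average_frequency"]], 0)
  }
})

test_that("voltage scaling moves only amplitude-bearing features", {
  des <- study_design(1, master_seed = 3)
  rec <- simulate_recording(NULL, "duodenum", NA, "baseline", des, 11)
  ef1 <- extract_features(rec)
  rec3 <- rec
  rec3$signals <- rec$signals * 3
  ef3 <- extract_features(rec3)
  expect_equal(ef3[["amplitude"]] / ef1[["amplitude"]], 3,
               tolerance = 1e-8)
  expect_equal(ef3[["slope"]] / ef1[["slope"]], 3, tolerance = 1e-8)
  expect_equal(ef3[["dominant_power"]] / ef1[["dominant_power"]], 9,
               tolerance = 1e-8)
  same <- setdiff(ef_feature_names(),
                  c("amplitude", "slope", "dominant_power"))
  expect_equal(unclass(ef3)[same], unclass(ef1)[same], tolerance = 1e-8)
})

test_that("planted multipliers move their features in the planted direction", {
  des <- study_design(1, noise_uv = 0, base_jitter_sd = 0.01,
                      master_seed = 4)
  cases <- list(
    list(param = "freq_mult", value = 1.4, feature = "dominant_frequency",
         up = TRUE),
    list(param = "freq_mult", value = 1.4, feature = "period", up = FALSE),
    list(param = "amp_mult", value = 1.5, feature = "amplitude",
         up = TRUE),
    list(param = "amp_mult", value = 0.6, feature = "dominant_power",
         up = FALSE),
    list(param = "velocity_mult", value = 1.5, feature = "velocity",
         up = TRUE),
    list(param = "slope_mult", value = 1.8, feature = "slope", up = TRUE))
  for (cs in cases) {
    prof <- profile_with("ileum", cs$param, cs$value)
    base <- extract_features(
      simulate_recording(prof, "ileum", NA, "baseline", des, 12))
    post <- extract_features(
      simulate_recording(prof, "ileum", 1e-5, "post_drug", des, 12))
    delta <- post[[cs$feature]] - base[[cs$feature]]
    if (cs$up) expect_gt(delta, 0) else expect_lt(delta, 0)
  }
})

test_that("configurations round-trip through YAML and reject unknown fields", {
  dir <- withr::local_tempdir()
  cfg <- ef_config(peak_ratio_min = 6, complexity_channels = 4)
  path <- file.path(dir, "cfg.yaml")
  write_ef_config(cfg, path)
  rt <- read_ef_config(path)
  expect_equal(rt$peak_ratio_min, 6)
  expect_equal(rt$complexity_channels, 4)
  expect_equal(rt$tissue_f0, cfg$tissue_f0)
  expect_error(ef_config(nonsense = 1), class = "invalid_argument")
})

test_that("rejected recordings raise a typed error", {
  rec <- mea_recording(matrix(0, 64, 3000), 10, "ileum", 8, 8)
  expect_error(extract_features(rec), class = "rejected_recording")
})

test_that("study extraction produces one normalized row per manifest entry", {
  des <- study_design(1, n_repeats = 3, duration_s = 150, master_seed = 6)
  st <- generate_study(des)
  rows <- extract_study_features(st)
  expect_equal(nrow(rows), 1 * 3 * 4 * 3)
  expect_true(all(ef_feature_names() %in% colnames(rows)))
  expect_true(all(is.finite(as.matrix(rows[ef_feature_names()]))))
  expect_equal(sort(unique(rows$dose_rank)), 1:3)
})
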