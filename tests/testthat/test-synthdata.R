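# Synthetic-study generator: drug libraries, recordings, label tables,
# study manifests.

test_that("drug libraries are deterministic and validate their arguments", {
  one <- make_drug_library(1, 1, 7)
  expect_length(one, 1)
  m <- as.matrix(one[[1]]$effects[c("freq_mult", "amp_mult", "slope_mult",
                                    "velocity_mult")])
  expect_true(all(is.finite(m)) && all(m > 0))
  expect_equal(nrow(one[[1]]$effects), 4)

  a <- make_drug_library(20, 4, 1)
  b <- make_drug_library(20, 4, 1)
  expect_identical(a, b)
  expect_setequal(unique(vapply(a, function(p) p$receptor_class, "")),
                  sprintf("class_%02d", 1:4))

  expect_error(make_drug_library(0, 1, 1), class = "invalid_argument")
  expect_error(make_drug_library(3, 5, 1), class = "invalid_argument")
})

test_that("within-class effect maps are closer than between-class maps", {
  lib <- make_drug_library(40, 5, 3)
  cls <- vapply(lib, function(p) p$receptor_class, "")
  within <- c(); between <- c()
  for (i in 1:39) for (j in (i + 1):40) {
    d <- profile_distance(lib[[i]], lib[[j]])
    if (cls[i] == cls[j]) within <- c(within, d)
    else between <- c(between, d)
  }
  expect_lt(mean(within), mean(between))
})

test_that("noiseless recordings are exact time-shifted copies along the wave path", {
  des <- study_design(1, noise_uv = 0, master_seed = 1)
  rec <- simulate_recording(NULL, "ileum", NA, "baseline", des, 5)
  lag <- round(des$pitch_um / des$base_velocity_um_s * des$fs)
  n <- ncol(rec$signals)
  for (col in 1:3) {  # adjacent columns within the first row
    a <- rec$signals[col, ]
    b <- rec$signals[col + 1, ]
    expect_lt(max(abs(b[(lag + 1):n] - a[1:(n - lag)])), 1e-8)
  }
})

test_that("recordings are bit-identical under the same seed", {
  des <- study_design(2, master_seed = 9)
  lib <- make_drug_library(2, 1, 9)
  r1 <- simulate_recording(lib[[1]], "colon", 1e-6, "post_drug", des, 77)
  r2 <- simulate_recording(lib[[1]], "colon", 1e-6, "post_drug", des, 77)
  expect_identical(r1$signals, r2$signals)
  expect_error(simulate_recording(NULL, "colon", 1e-6, "post_drug", des, 1),
               class = "invalid_argument")
})

test_that("a planted frequency multiplier is recovered through the extractor", {
  prof <- profile_with("colon", "freq_mult", 1.5)
  des <- study_design(1, noise_uv = 0, base_jitter_sd = 0, master_seed = 1)
  base <- simulate_recording(prof, "colon", NA, "baseline", des, 3)
  post <- simulate_recording(prof, "colon", 1e-5, "post_drug", des, 3)
  fb <- extract_features(base)["dominant_frequency"]
  fp <- extract_features(post)["dominant_frequency"]
  expect_equal(unname(fp / fb), 1.5, tolerance = 0.02)
})

test_that("label tables respect prevalence, zero prevalence and the override", {
  lib <- make_drug_library(40, 4, 5)
  res <- make_ae_label_table(lib, list(excitatory_rule(d = 1,
                                                       prevalence = 0.5)), 5)
  n_pos <- sum(res$labels$labels[, "excitatory_ae"])
  expect_gte(n_pos, 10)  # binomial(40, .5) 99.9% bounds
  expect_lte(n_pos, 30)

  res0 <- make_ae_label_table(lib, list(excitatory_rule(d = 1,
                                                        prevalence = 0)), 5)
  expect_true(all(res0$labels$labels == 0))
  expect_equal(nrow(res0$raw_rows), 0)

  res1 <- make_ae_label_table(
    lib, list(excitatory_rule(d = 1, prevalence = 0.5,
                              indication_fraction = 1)), 5)
  expect_true(all(res1$labels$labels == 0))
  expect_true(any(res1$raw_rows$role == "indication"))

  expect_error(make_ae_label_table(list(), list(excitatory_rule()), 1),
               class = "invalid_argument")
})

test_that("study manifests count the design product and are reproducible", {
  des <- study_design(2, master_seed = 3)
  st <- generate_study(des)
  expect_equal(nrow(st$manifest), 2 * 3 * 4 * 3)
  st2 <- generate_study(des)
  expect_identical(st$manifest, st2$manifest)
})

test_that("a small study round-trips through the plain-text store", {
  dir <- withr::local_tempdir()
  des <- study_design(1, n_repeats = 3, duration_s = 60, master_seed = 4)
  st <- generate_study(des, rules = list(excitatory_rule(prevalence = 0.5)),
                       dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  rec <- study_recording(st, 1, "baseline")
  rt <- read_recording(dir, paste0(st$manifest$recording_id[1],
                                   "_baseline"))
  expect_equal(rt$signals, rec$signals, tolerance = 1e-3)
  expect_identical(rt$tissue, rec$tissue)
  expect_identical(rt$phase, "baseline")
})

test_that("design validation enforces dose and repeat constraints", {
  expect_error(study_design(2, doses = c(1e-5, 1e-6)),
               class = "invalid_argument")
  expect_error(study_design(2, doses = c(1e-7, 1e-6, 1e-5)),
               class = "invalid_argument")
  expect_error(study_design(2, n_repeats = 2), class = "invalid_argument")
  expect_error(study_design(2, n_repeats = 11), class = "invalid_argument")
  expect_error(study_design(2, fs = 0.2), class = "invalid_argument")
})

test_that("dose effects grow monotonically with dose", {
  des <- study_design(1, master_seed = 1)
  ex <- vapply(des$doses, dose_effect_exponent, 0, design = des)
  expect_equal(ex, c(1, 2 / 3, 1 / 3))
})
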