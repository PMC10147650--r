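# Feature selection, classifiers, ensemble, evaluation, random-dataset
# control and the randomized protocol.

test_that("t-test selection matches the closed-form pooled oracle", {
  ds <- planted_ds()
  sel <- select_features(ds)
  for (j in seq_len(24)) {
    nm <- ef_feature_names()[j]
    expect_equal(sel$p_values[[nm]],
                 pooled_t_p(ds$features[ds$labels == 1, j],
                            ds$features[ds$labels == 0, j]),
                 tolerance = 1e-10)
  }
  expect_true(all(ef_feature_names()[1:4] %in% sel$features))
  expect_lt(max(sel$p_values[1:4]), 1e-6)
})

test_that("identical groups give p = 1 and single-class data aborts", {
  ds <- planted_ds()
  ds$features[, 5] <- rep(c(1, 2), length.out = nrow(ds$features))
  ds$features[ds$labels == 1, 5] <- ds$features[ds$labels == 0, 5]
  sel <- select_features(ds)
  expect_equal(sel$p_values[[5]], 1)
  expect_false(ef_feature_names()[5] %in% sel$features)

  ds1 <- planted_ds()
  ds1$labels <- rep(1L, nrow(ds1$features))
  expect_error(select_features(ds1), class = "degenerate_labels")
})

test_that("training is deterministic and separable data is memorized", {
  ds <- planted_ds(d = 6)
  sel <- select_features(ds)
  for (alg in c("tree", "knn")) {
    m <- train_model(ds, sel, alg, seed = 3)
    pr_train <- predict(m, ds$features[m$train_idx, , drop = FALSE])
    expect_equal(mean(pr_train$class == ds$labels[m$train_idx]), 1)
  }
  m1 <- train_model(ds, sel, "svm", seed = 5)
  m2 <- train_model(ds, sel, "svm", seed = 5)
  expect_identical(m1$train_idx, m2$train_idx)
  expect_identical(predict(m1, ds$features), predict(m2, ds$features))
})

test_that("algorithm applicability follows dataset kind and missingness", {
  full <- planted_ds(kind = "full")
  expect_setequal(applicable_algorithms(full),
                  c("naive_bayes", "tree", "knn"))
  sel <- select_features(full)
  expect_error(train_model(full, sel, "discriminant", 1),
               class = "algorithm_incompatible")
  tis <- planted_ds()
  expect_length(applicable_algorithms(tis), 5)
})

test_that("scores threshold strictly at 0.5 and 1-NN memorizes", {
  ds <- planted_ds(d = 6)
  sel <- select_features(ds)
  m <- train_model(ds, sel, "knn", 1)
  # an exact 0.5 score maps to class 0
  expect_equal(as.integer(0.5 > 0.5), 0L)
  pr <- predict(m, ds$features)
  expect_true(all(pr$class == as.integer(pr$score > 0.5)))
})

test_that("the ensemble averages binary votes with a strict threshold", {
  votes3 <- c(1, 1, 0)
  expect_equal(round(mean(votes3), 3), 0.667)
  expect_equal(as.integer(mean(votes3) > 0.5), 1L)
  votes4 <- c(1, 1, 0, 0)
  expect_equal(as.integer(mean(votes4) > 0.5), 0L)

  ds <- planted_ds(d = 3)
  sel <- select_features(ds)
  m <- train_model(ds, sel, "tree", 2)
  same5 <- ensemble_predict(list(m, m, m, m, m), ds$features)
  expect_equal(same5$class, predict(m, ds$features)$class)
  expect_error(ensemble_predict(list(), ds$features),
               class = "invalid_argument")
})

test_that("confusion-matrix rates match a hand-counted toy", {
  ev <- evaluate_predictions(c(1, 0, 0, 0), c(1, 1, 0, 0))
  expect_equal(ev$accuracy, 0.75)
  expect_equal(ev$tpr, 0.5)
  expect_equal(ev$tnr, 1.0)
  expect_equal(evaluate_predictions(c(1, 1), c(1, 1))$accuracy, 1)
  expect_equal(evaluate_predictions(c(0, 0), c(1, 1))$accuracy, 0)
  expect_error(evaluate_predictions(integer(), integer()),
               class = "invalid_argument")
})

test_that("the Gaussian control preserves moments and labels but kills structure", {
  ds <- planted_ds(n = 200, d = 2)
  ctrl <- make_random_control(ds, 7)
  expect_identical(ctrl$labels, ds$labels)
  for (j in c(1, 10, 24)) {
    n <- nrow(ds$features)
    se_m <- sd(ds$features[, j]) / sqrt(n)
    expect_lt(abs(mean(ctrl$features[, j]) - mean(ds$features[, j])),
              3 * se_m)
    expect_lt(abs(sd(ctrl$features[, j]) - sd(ds$features[, j])),
              3 * sd(ds$features[, j]) / sqrt(2 * (n - 1)))
  }
  # planted separation is destroyed in >= 90% of seeds
  fewer <- vapply(1:20, function(s) {
    c2 <- make_random_control(ds, s)
    length(select_features(c2)$features) < length(select_features(ds)$features)
  }, TRUE)
  expect_gte(mean(fewer), 0.9)
})

test_that("validation compares means and bests with a 0.5-point margin", {
  mk <- function(mean_acc, best_acc, aborted = FALSE)
    structure(list(mean_accuracy = mean_acc, best_accuracy = best_acc,
                   aborted = aborted), class = "gip_protocol")
  expect_true(validate_against_control(mk(0.670, 0.70),
                                       mk(0.660, 0.70))$passed)
  expect_false(validate_against_control(mk(0.662, 0.700),
                                        mk(0.660, 0.698))$passed)
  expect_true(validate_against_control(mk(0.66, 0.70),
                                       mk(NA, NA, aborted = TRUE))$passed)
  expect_false(validate_against_control(mk(NA, NA, aborted = TRUE),
                                        mk(0.5, 0.5))$passed)
})

test_that("the protocol runs 7 seeds deterministically and recovers plants", {
  ds <- planted_ds(n = 60, d = 1.5)
  prot <- run_protocol(ds, master_seed = 11)
  expect_false(prot$aborted)
  expect_equal(length(unique(prot$per_eval$seed)), 7)
  per_alg <- table(prot$per_eval$algorithm)
  expect_true(all(per_alg == 7))
  expect_gte(prot$best_accuracy, prot$mean_accuracy)
  expect_true(all(prot$per_eval$accuracy >= 0 &
                    prot$per_eval$accuracy <= 1))
  expect_gt(prot$mean_accuracy, 0.7)
  expect_true(prot$coverage_ok)

  prot2 <- run_protocol(ds, master_seed = 11)
  expect_equal(prot$per_eval, prot2$per_eval)

  ctrl <- run_protocol(make_random_control(ds, 11), master_seed = 11)
  expect_true(validate_against_control(prot, ctrl)$passed)
})

test_that("row order does not change protocol results", {
  ds <- planted_ds(n = 40, d = 1.5, seed = 99)
  set.seed(1)
  perm <- sample(nrow(ds$features))
  ds2 <- ds
  ds2$features <- ds$features[perm, , drop = FALSE]
  ds2$labels <- ds$labels[perm]
  ds2$meta <- ds$meta[perm, ]
  # same rows, same labels: selection identical; accuracies statistically
  # indistinguishable (splits are index-based, so compare the pooled mean)
  s1 <- select_features(ds); s2 <- select_features(ds2)
  expect_setequal(s1$features, s2$features)
  p1 <- run_protocol(ds, master_seed = 5)
  p2 <- run_protocol(ds2, master_seed = 5)
  expect_lt(abs(p1$mean_accuracy - p2$mean_accuracy), 0.05)
})

test_that("label permutation keeps accuracy at chance (no harness leakage)", {
  ds <- planted_ds(n = 200, d = 1, seed = 77)
  means <- c()
  for (s in 1:5) {
    pds <- permute_labels(ds, s)
    prot <- run_protocol(pds, master_seed = s)
    if (!prot$aborted) means <- c(means, prot$mean_accuracy)
  }
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 0.5), 3 * max(se, 0.015))
})
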