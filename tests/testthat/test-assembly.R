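# Normalization, label assignment, balance filtering and dataset kinds.

toy_rows <- function() {
  set.seed(41)
  g <- expand.grid(repeat_idx = 1:3, tissue = gi_tissues,
                   dose = c(1e-5, 1e-6, 1e-7),
                   drug_id = c("drug_a", "drug_b"),
                   stringsAsFactors = FALSE)
  g$dose_rank <- match(g$dose, c(1e-5, 1e-6, 1e-7))
  feats <- matrix(rnorm(nrow(g) * 24), nrow(g),
                  dimnames = list(NULL, ef_feature_names()))
  cbind(g[c("drug_id", "dose", "dose_rank", "tissue", "repeat_idx")],
        as.data.frame(feats))
}

toy_table <- function(pos = "drug_a") {
  assign_labels(data.frame(drug_id = pos, ae_name = "nausea",
                           role = "side_effect"),
                c("drug_a", "drug_b"), "nausea")
}

test_that("normalization applies percent change and point differences", {
  b <- ef_vec(10, pct_normal = 40, pct_brady = 30, pct_tachy = 30)
  p <- ef_vec(15, pct_normal = 55, pct_brady = 20, pct_tachy = 25)
  d <- normalize_features(b, p)
  expect_equal(d[["amplitude"]], 50)          # (15-10)/10 * 100
  expect_equal(d[["pct_normal"]], 15)         # 55 - 40 points
  expect_equal(d[["mse_scale_1"]], 5)         # differenced, not ratioed
  expect_equal(unname(normalize_features(b, b)), rep(0, 24))
  z <- ef_vec(10, amplitude = 0)
  expect_error(normalize_features(z, p), class = "degenerate_baseline")
})

test_that("label assignment honours the indication override", {
  raw <- data.frame(
    drug_id = c("drug_a", "drug_b", "drug_b", "drug_x"),
    ae_name = c("nausea", "nausea", "nausea", "nausea"),
    role = c("side_effect", "side_effect", "indication", "side_effect"))
  tab <- assign_labels(raw, c("drug_a", "drug_b", "drug_c"), "nausea")
  expect_equal(tab$labels["drug_a", "nausea"], 1L)
  expect_equal(tab$labels["drug_b", "nausea"], 0L)
  expect_equal(tab$labels["drug_c", "nausea"], 0L)
  expect_equal(tab$provenance["drug_b", "nausea"], "indication_override")
  expect_equal(tab$provenance["drug_c", "nausea"], "absent")
  expect_equal(tab$skipped_drugs, "drug_x")
  # override wins regardless of row order
  tab2 <- assign_labels(raw[c(3, 2), ], c("drug_b"), "nausea")
  expect_equal(tab2$labels["drug_b", "nausea"], 0L)
})

test_that("balance ratios and the strict 0.25/0.75 filter behave as specified", {
  expect_equal(balance_ratio(c(1, 1, 1, rep(0, 7))), 0.3)
  expect_equal(balance_ratio(rep(0, 5)), 0)
  expect_error(balance_ratio(integer()), class = "invalid_argument")
  # 22 of 89 = 0.2472 -> excluded by the < 0.25 rule
  expect_lt(balance_ratio(c(rep(1, 22), rep(0, 67))), 0.25)

  mk <- function(ratios) {
    labs <- vapply(ratios, function(r) c(rep(1L, round(r * 20)),
                                         rep(0L, 20 - round(r * 20))),
                   integer(20))
    colnames(labs) <- names(ratios)
    rownames(labs) <- sprintf("d%02d", 1:20)
    structure(list(labels = labs), class = "ae_label_table")
  }
  tab <- mk(c(a = 0.5, b = 0.1, c = 0.8))
  expect_equal(as.character(filter_balanced(tab)), "a")
  tab2 <- mk(c(edge = 0.25))
  expect_equal(as.character(filter_balanced(tab2)), "edge")  # boundary kept
  tab3 <- mk(c(x = 0.9, y = 0.9))
  expect_length(filter_balanced(tab3), 0)
})

test_that("the full dataset has one labelled row per observation", {
  rows <- toy_rows()
  ds <- build_full_dataset(rows, toy_table(), "nausea")
  expect_equal(nrow(ds$features), 2 * 3 * 4 * 3)
  expect_equal(ncol(ds$features), 24)
  expect_true(all(ds$labels[ds$meta$drug_id == "drug_a"] == 1))
  expect_true(all(ds$labels[ds$meta$drug_id == "drug_b"] == 0))
  expect_equal(ds$ratio, 0.5)
})

test_that("the averaged dataset aligns 96 tissue-prefixed features", {
  rows <- toy_rows()
  ds <- build_averaged_dataset(rows, toy_table(), "nausea")
  expect_equal(dim(ds$features), c(2 * 3, 96))
  expect_false(anyNA(ds$features))
  # repeats identical -> average equals the repeat value
  rows_const <- rows
  for (nm in ef_feature_names())
    rows_const[[nm]] <- ave(rows_const[[nm]],
                            rows_const$drug_id, rows_const$dose,
                            rows_const$tissue, FUN = function(x) x[1])
  dsc <- build_averaged_dataset(rows_const, toy_table(), "nausea")
  one <- rows_const[rows_const$drug_id == "drug_a" &
                      rows_const$dose == 1e-5 &
                      rows_const$tissue == "colon", ][1, ]
  got <- dsc$features[dsc$meta$drug_id == "drug_a" &
                        dsc$meta$dose == 1e-5,
                      paste0("colon_", ef_feature_names())]
  expect_equal(unname(got), unlist(one[ef_feature_names()],
                                   use.names = FALSE))
  # a drug missing one tissue leaves 24 NA columns and drops lda/svm
  rows_miss <- rows[!(rows$drug_id == "drug_a" & rows$tissue == "colon"), ]
  dsm <- build_averaged_dataset(rows_miss, toy_table(), "nausea")
  na_cols <- colSums(is.na(dsm$features[dsm$meta$drug_id == "drug_a", ,
                                        drop = FALSE]))
  expect_equal(sum(na_cols > 0), 24)
  expect_setequal(applicable_algorithms(dsm),
                  c("naive_bayes", "tree", "knn"))
})

test_that("tissue splits partition the full dataset and support groupings", {
  rows <- toy_rows()
  ds <- build_full_dataset(rows, toy_table(), "nausea")
  sp <- split_by_tissue(ds)
  expect_named(sp, gi_tissues)
  expect_equal(vapply(sp, function(d) nrow(d$features), 0),
               setNames(rep(18, 4), gi_tissues))
  expect_equal(sum(vapply(sp, function(d) nrow(d$features), 0)),
               nrow(ds$features))
  spg <- split_by_tissue(ds, groups = list(
    intestine = c("duodenum", "ileum", "colon")))
  expect_equal(nrow(spg$intestine$features), 54)
})

test_that("learning datasets round-trip through CSV + sidecar", {
  dir <- withr::local_tempdir()
  ds <- build_full_dataset(toy_rows(), toy_table(), "nausea")
  path <- file.path(dir, "ds.csv")
  write_learning_dataset(ds, path)
  rt <- read_learning_dataset(path)
  expect_equal(rt$features, ds$features, tolerance = 1e-12)
  expect_identical(rt$labels, ds$labels)
  expect_equal(rt$kind, ds$kind)
  expect_equal(rt$ratio, ds$ratio)
})
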