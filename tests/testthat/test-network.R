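# Drug feature matrices, pole networks and class clustering (unit level;
# the planted-study network checks live in the acceptance suite).

toy_matrix <- function(n_per = 10, d = 4, seed = 71) {
  set.seed(seed)
  m <- rbind(matrix(rnorm(n_per * 5), n_per),
             matrix(rnorm(n_per * 5, d), n_per))
  rownames(m) <- sprintf("d%02d", seq_len(2 * n_per))
  m
}

test_that("drug feature matrices aggregate, restrict and z-score", {
  rows <- data.frame(drug_id = rep(c("a", "b"), each = 4),
                     amplitude = c(1, 1, 3, 3, 5, 5, 7, 7),
                     period = rep(2, 8))
  sel <- structure(list(features = c("amplitude", "period")),
                   class = "feature_selection")
  m <- drug_feature_matrix(rows, sel)
  expect_equal(rownames(m), c("a", "b"))
  # drug means 2 and 6, sample sd sqrt(8) -> z-scores -/+ 1/sqrt(2)
  expect_equal(unname(m[, "amplitude"]), c(-1, 1) / sqrt(2),
               tolerance = 1e-9)
  expect_equal(unname(m[, "period"]), c(0, 0))  # zero-variance guard
  expect_true(attr(m, "zscored"))
  # duplicate rows collapse to identical matrix rows
  rows2 <- rbind(rows, rows)
  expect_equal(drug_feature_matrix(rows2, sel), m)
  # single drug: z-scoring skipped and flagged
  m1 <- drug_feature_matrix(rows[rows$drug_id == "a", ], sel)
  expect_false(attr(m1, "zscored"))
  expect_equal(nrow(m1), 1)
  empty <- structure(list(features = character()),
                     class = "feature_selection")
  expect_error(drug_feature_matrix(rows, empty),
               class = "invalid_argument")
})

test_that("pole networks separate planted classes and degenerate cleanly", {
  m <- toy_matrix()
  labels <- setNames(rep(c(0, 1), each = 10), rownames(m))
  net <- build_network(m, labels)
  expect_gt(net$pole_separation, 5)
  expect_gte(nearest_pole_agreement(net), 0.9)
  expect_s3_class(net$graph, "igraph")
  expect_true(all(net$edges$weight >= 0))
  expect_equal(sum(net$edges$edge_type == "drug_pole"), 2 * nrow(m))

  # identical feature rows -> zero pole separation
  m0 <- matrix(1, 6, 3, dimnames = list(letters[1:6], NULL))
  net0 <- build_network(m0, setNames(rep(c(0, 1), 3), letters[1:6]))
  expect_equal(net0$pole_separation, 0)

  expect_error(build_network(m, setNames(rep(1, 20), rownames(m))),
               class = "invalid_argument")
})

test_that("label permutation shrinks the pole separation", {
  m <- toy_matrix()
  labels <- setNames(rep(c(0, 1), each = 10), rownames(m))
  real_sep <- build_network(m, labels)$pole_separation
  shrunk <- vapply(1:20, function(s) {
    set.seed(s)
    build_network(m, setNames(sample(labels), rownames(m)))$pole_separation <
      real_sep
  }, TRUE)
  expect_gte(mean(shrunk), 0.9)
})

test_that("class clustering scores separate and shuffled classes", {
  m <- toy_matrix(d = 6)
  cls <- setNames(rep(c("r1", "r2"), each = 10), rownames(m))
  expect_gte(class_cluster_score(m, cls), 0.9)

  # shuffled labels: expectation equals the nearest-neighbour baseline
  # E[score] = P(neighbour shares class) = (2 * 10 * 9) / (20 * 19)
  set.seed(72)
  scores <- vapply(1:200, function(i)
    class_cluster_score(m, setNames(sample(cls), rownames(m))), 0)
  expect_equal(mean(scores), 2 * 10 * 9 / (20 * 19), tolerance = 0.05)

  expect_error(class_cluster_score(m, setNames(rep("r1", 20),
                                               rownames(m))),
               class = "invalid_argument")
})

test_that("networks export to GraphML, CSV and JSON", {
  dir <- withr::local_tempdir()
  m <- toy_matrix()
  labels <- setNames(rep(c(0, 1), each = 10), rownames(m))
  cls <- setNames(rep(c("r1", "r2"), 10), rownames(m))
  net <- build_network(m, labels, receptor_classes = cls)
  stem <- file.path(dir, "net")
  write_network(net, stem, receptor_classes = cls)
  expect_true(file.exists(paste0(stem, ".graphml")))
  g <- igraph::read_graph(paste0(stem, ".graphml"), format = "graphml")
  expect_equal(igraph::vcount(g), 22)
  js <- jsonlite::read_json(paste0(stem, "_summary.json"))
  expect_equal(js$pole_separation, net$pole_separation, tolerance = 1e-6)
})
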