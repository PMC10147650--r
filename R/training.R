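# Classification protocol: t-test feature refinement, five classifier
# families plus ensemble, randomized half/half splits, evaluation and the
# Gaussian random-dataset validation control.

.algorithms <- c("naive_bayes", "discriminant", "tree", "knn", "svm")

#' Algorithms applicable to a learning dataset
#'
#' Full (single-row) datasets use naive Bayes, classification tree and
#' KNN; averaged and tissue-split datasets additionally use discriminant
#' analysis and SVM unless the feature matrix contains missing values
#' (which those two algorithms cannot handle).
#'
#' @param ds a `learning_dataset`.
#' @return character vector of algorithm names.
#' @export
applicable_algorithms <- function(ds) {
  if (ds$kind == "full") return(c("naive_bayes", "tree", "knn"))
  if (anyNA(ds$features)) return(c("naive_bayes", "tree", "knn"))
  .algorithms
}

#' Select features by two-sample Student's t-test
#'
#' For each feature, a pooled-variance t-test compares positive and
#' negative rows (missing values dropped per feature); features with
#' p < `alpha` are selected. No multiple-testing correction is applied
#' (the raw p-values are returned so users can re-filter).
#'
#' @param ds a `learning_dataset` with both classes present.
#' @param alpha selection threshold (default 0.05).
#' @return object of class `feature_selection`: `ae`, `features`
#'   (selected names), `p_values` (named, all features).
#' @export
select_features <- function(ds, alpha = 0.05) {
  y <- ds$labels
  if (length(unique(y)) < 2)
    stopf("degenerate_labels", "both classes must be present")
  p <- vapply(seq_len(ncol(ds$features)), function(j) {
    x1 <- ds$features[y == 1, j]; x0 <- ds$features[y == 0, j]
    x1 <- x1[is.finite(x1)]; x0 <- x0[is.finite(x0)]
    if (length(x1) < 2 || length(x0) < 2) return(NA_real_)
    tryCatch(t.test(x1, x0, var.equal = TRUE)$p.value,
             error = function(e)
               if (isTRUE(all.equal(mean(x1), mean(x0)))) 1 else 0)
  }, 0)
  names(p) <- colnames(ds$features)
  structure(list(ae = ds$ae,
                 features = names(p)[!is.na(p) & p < alpha],
                 p_values = p, alpha = alpha),
            class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat(sprintf("<feature_selection> %s: %d of %d features at p < %g\n",
              x$ae, length(x$features), length(x$p_values), x$alpha))
  invisible(x)
}

# run expr under a temporary RNG state so stochastic library internals
# (e.g. knn distance-tie resolution) stay deterministic without
# disturbing the caller's stream
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv())
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# stratified half/half split; returns training row indices
.protocol_split <- function(ds, seed, split_mode) {
  set.seed(seed)
  if (split_mode == "drug") {
    drugs <- unique(ds$meta$drug_id)
    tr_drugs <- sample(drugs, ceiling(length(drugs) / 2))
    return(which(ds$meta$drug_id %in% tr_drugs))
  }
  idx <- unlist(lapply(unique(ds$labels), function(cl) {
    rows <- which(ds$labels == cl)
    sample(rows, ceiling(length(rows) / 2))
  }))
  sort(idx)
}

#' Train one classifier on a randomized half of a dataset
#'
#' Rows are split half/half (stratified by label; row-wise by default, or
#' drug-wise with `split_mode = "drug"`), the selected features are
#' z-scored using training-half statistics, and the requested algorithm is
#' fitted: Gaussian naive Bayes, linear discriminant analysis,
#' a Gini classification tree (minimum leaf 3), 5-nearest-neighbours on
#' the standardized features, or a linear-kernel SVM (unit cost, margins
#' mapped to `[0, 1]` by a logistic link). Deterministic given `seed`.
#'
#' @param ds a `learning_dataset`.
#' @param selection a [select_features()] result.
#' @param algorithm one of `naive_bayes`, `discriminant`, `tree`, `knn`,
#'   `svm`.
#' @param seed integer split seed.
#' @param split_mode `"row"` (default) or `"drug"`.
#' @return object of class `trained_model`.
#' @export
train_model <- function(ds, selection, algorithm, seed,
                        split_mode = c("row", "drug")) {
  split_mode <- match.arg(split_mode)
  if (!algorithm %in% applicable_algorithms(ds))
    stopf("algorithm_incompatible", "%s is not applicable to kind '%s'%s",
          algorithm, ds$kind,
          if (anyNA(ds$features)) " (missing features)" else "")
  if (!length(selection$features))
    stopf("degenerate_labels", "no selected features")
  tr <- .protocol_split(ds, seed, split_mode)
  X <- ds$features[, selection$features, drop = FALSE]
  ctr <- colMeans(X[tr, , drop = FALSE], na.rm = TRUE)
  scl <- apply(X[tr, , drop = FALSE], 2, sd, na.rm = TRUE)
  scl[!is.finite(scl) | scl == 0] <- 1
  Z <- sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")
  ztr <- Z[tr, , drop = FALSE]
  ytr <- factor(ds$labels[tr], levels = c(0, 1))
  df_tr <- data.frame(ztr, check.names = FALSE)
  fit <- switch(algorithm,
    naive_bayes = e1071::naiveBayes(df_tr, ytr),
    discriminant = MASS::lda(ztr, grouping = ytr),
    tree = rpart::rpart(y ~ ., data = cbind(df_tr, y = ytr),
                        method = "class",
                        control = rpart::rpart.control(minbucket = 3,
                                                       cp = 0.01)),
    knn = list(train = ztr, cl = ytr),
    svm = {
      m <- e1071::svm(ztr, ytr, kernel = "linear", cost = 1, scale = FALSE)
      dv <- attr(predict(m, ztr, decision.values = TRUE),
                 "decision.values")[, 1]
      orient <- sign(mean(dv[ytr == 1]) - mean(dv[ytr == 0]))
      list(fit = m, orient = if (orient == 0) 1 else orient)
    })
  structure(list(algorithm = algorithm, fit = fit,
                 features = selection$features, center = ctr,
                 scale = scl, seed = seed, split_mode = split_mode,
                 train_idx = tr, ae = ds$ae, kind = ds$kind),
            class = "trained_model")
}

#' Predict positive-class scores and binary classes
#'
#' @param object a `trained_model`.
#' @param newdata numeric matrix/data.frame carrying the model's selected
#'   feature columns, or a `learning_dataset`.
#' @param ... unused.
#' @return data.frame with `score` in `[0, 1]` and `class` (0/1, strict
#'   `score > 0.5`).
#' @export
predict.trained_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "learning_dataset")) newdata$features
       else as.matrix(newdata)
  missing <- setdiff(object$features, colnames(X))
  if (length(missing))
    stopf("invalid_argument", "rows lack model features: %s",
          paste(missing, collapse = ", "))
  Z <- sweep(sweep(X[, object$features, drop = FALSE], 2, object$center,
                   "-"), 2, object$scale, "/")
  df <- data.frame(Z, check.names = FALSE)
  score <- switch(object$algorithm,
    naive_bayes = predict(object$fit, df, type = "raw")[, "1"],
    discriminant = predict(object$fit, Z)$posterior[, "1"],
    tree = predict(object$fit, df)[, "1"],
    knn = {
      pr <- .with_seed(derive_seed(object$seed, "knn_predict", nrow(Z)),
                       class::knn(object$fit$train, Z, object$fit$cl,
                                  k = 5, prob = TRUE))
      votes <- attr(pr, "prob")
      ifelse(pr == "1", votes, 1 - votes)
    },
    svm = {
      dv <- attr(predict(object$fit$fit, Z, decision.values = TRUE),
                 "decision.values")[, 1]
      stats::plogis(object$fit$orient * dv)
    })
  data.frame(score = as.numeric(score),
             class = as.integer(score > 0.5))
}

#' Ensemble prediction by averaging member binary votes
#'
#' The ensemble score is the unweighted mean of the members' *binary*
#' predictions; the class threshold is strict (`score > 0.5`, so an even
#' split votes negative).
#'
#' @param models non-empty list of `trained_model`s.
#' @param newdata feature rows (see [predict.trained_model()]).
#' @return data.frame with `score` and `class`.
#' @export
ensemble_predict <- function(models, newdata) {
  if (!length(models)) stopf("invalid_argument", "empty model list")
  votes <- vapply(models, function(m) predict(m, newdata)$class,
                  integer(if (inherits(newdata, "learning_dataset"))
                    nrow(newdata$features) else nrow(newdata)))
  score <- rowMeans(as.matrix(votes))
  data.frame(score = score, class = as.integer(score > 0.5))
}

#' Confusion-matrix rates of binary predictions
#'
#' @param predicted 0/1 vector.
#' @param labels 0/1 vector of the same length, non-empty.
#' @return list with `accuracy`, `tpr`, `tnr` (rates in `[0, 1]`; NA when
#'   a class is absent).
#' @export
evaluate_predictions <- function(predicted, labels) {
  if (!length(labels) || length(predicted) != length(labels))
    stopf("invalid_argument", "predictions and labels must align, non-empty")
  list(accuracy = mean(predicted == labels),
       tpr = if (any(labels == 1)) mean(predicted[labels == 1] == 1)
             else NA_real_,
       tnr = if (any(labels == 0)) mean(predicted[labels == 0] == 0)
             else NA_real_)
}

#' Gaussian random-dataset control
#'
#' Resamples every feature column independently from a normal distribution
#' with that column's mean and sample SD, preserving shape, labels and
#' missing-value positions. Used to detect overfitting: a real model must
#' beat its control (see [validate_against_control()]).
#'
#' @param ds a `learning_dataset`.
#' @param seed integer.
#' @return a `learning_dataset` with attribute `random_control = TRUE`.
#' @export
make_random_control <- function(ds, seed) {
  set.seed(derive_seed(seed, "random_control", ds$ae, ds$kind))
  feat <- ds$features
  for (j in seq_len(ncol(feat))) {
    ok <- is.finite(feat[, j])
    feat[ok, j] <- rnorm(sum(ok), mean(feat[ok, j]), sd(feat[ok, j]))
  }
  out <- new_learning_dataset(feat, ds$labels, ds$meta, ds$kind, ds$ae,
                              ds$ratio)
  attr(out, "random_control") <- TRUE
  out
}

#' Run the randomized training/evaluation protocol
#'
#' Features are selected once on the dataset; then for each of
#' `n_randomizations` seeds the rows are split half/half, every applicable
#' algorithm is trained on the training half and evaluated on the test
#' half, and the ensemble of the algorithms' binary votes is evaluated as
#' an additional model. Reported alongside accuracy are the true
#' positive/negative rates and the drug-coverage fraction of the training
#' half (models whose mean coverage is below `coverage_threshold` are
#' flagged).
#'
#' @param ds a `learning_dataset` (should have passed the balance filter).
#' @param algorithms algorithms to train; defaults to
#'   [applicable_algorithms()].
#' @param n_randomizations number of randomized splits (default 7).
#' @param master_seed integer; the whole protocol is deterministic given
#'   it.
#' @param split_mode `"row"` or `"drug"` (see [train_model()]).
#' @param coverage_threshold minimum acceptable drug-coverage fraction.
#' @return object of class `gip_protocol`: `per_eval` (one row per seed x
#'   algorithm incl. `"ensemble"`), `mean_accuracy`, `best_accuracy`,
#'   `best_seed`, `best_algorithm`, `models` (models[[seed]][[algorithm]]),
#'   `selection`, `coverage_ok`, `aborted`.
#' @export
run_protocol <- function(ds, algorithms = NULL, n_randomizations = 7,
                         master_seed = 1, split_mode = "row",
                         coverage_threshold = 0.8) {
  selection <- tryCatch(select_features(ds),
                        gipace_error = function(e) NULL)
  if (is.null(selection) || !length(selection$features)) {
    return(structure(list(ae = ds$ae, kind = ds$kind, aborted = TRUE,
                          selection = selection,
                          mean_accuracy = NA_real_,
                          best_accuracy = NA_real_),
                     class = "gip_protocol"))
  }
  algorithms <- algorithms %||% applicable_algorithms(ds)
  n_drugs <- length(unique(ds$meta$drug_id))
  rows <- list(); models <- vector("list", n_randomizations)
  for (s in seq_len(n_randomizations)) {
    seed_s <- derive_seed(master_seed, "protocol", ds$ae, ds$kind, s)
    seed_models <- list()
    tr <- .protocol_split(ds, seed_s, split_mode)
    te <- setdiff(seq_len(nrow(ds$features)), tr)
    coverage <- length(unique(ds$meta$drug_id[tr])) / n_drugs
    test_rows <- ds$features[te, , drop = FALSE]
    ytest <- ds$labels[te]
    votes <- list()
    for (alg in algorithms) {
      mod <- tryCatch(train_model(ds, selection, alg, seed_s, split_mode),
                      gipace_error = function(e) NULL)
      if (is.null(mod)) next
      seed_models[[alg]] <- mod
      pred <- predict(mod, test_rows)
      votes[[alg]] <- pred$class
      ev <- evaluate_predictions(pred$class, ytest)
      rows[[length(rows) + 1]] <-
        data.frame(seed = s, algorithm = alg, accuracy = ev$accuracy,
                   tpr = ev$tpr, tnr = ev$tnr, coverage = coverage)
    }
    if (length(votes) > 1) {
      esc <- rowMeans(do.call(cbind, votes))
      ev <- evaluate_predictions(as.integer(esc > 0.5), ytest)
      rows[[length(rows) + 1]] <-
        data.frame(seed = s, algorithm = "ensemble",
                   accuracy = ev$accuracy, tpr = ev$tpr, tnr = ev$tnr,
                   coverage = coverage)
    }
    models[[s]] <- seed_models
  }
  per_eval <- do.call(rbind, rows)
  if (is.null(per_eval) || nrow(per_eval) == 0)
    return(structure(list(ae = ds$ae, kind = ds$kind, aborted = TRUE,
                          selection = selection,
                          mean_accuracy = NA_real_,
                          best_accuracy = NA_real_),
                     class = "gip_protocol"))
  ord <- order(-per_eval$accuracy, -per_eval$tpr, per_eval$seed)
  best <- per_eval[ord[1], ]
  structure(list(ae = ds$ae, kind = ds$kind, aborted = FALSE,
                 per_eval = per_eval,
                 mean_accuracy = mean(per_eval$accuracy),
                 best_accuracy = max(per_eval$accuracy),
                 best_seed = best$seed, best_algorithm = best$algorithm,
                 models = models, selection = selection,
                 coverage_ok = mean(per_eval$coverage) > coverage_threshold,
                 n_randomizations = n_randomizations,
                 master_seed = master_seed, split_mode = split_mode),
            class = "gip_protocol")
}

#' @export
print.gip_protocol <- function(x, ...) {
  if (x$aborted) {
    cat(sprintf("<gip_protocol> %s / %s: ABORTED (no significant features)\n",
                x$ae, x$kind))
  } else {
    cat(sprintf("<gip_protocol> %s / %s: mean acc %.3f, best %.3f (%s, seed %d)\n",
                x$ae, x$kind, x$mean_accuracy, x$best_accuracy,
                x$best_algorithm, x$best_seed))
  }
  invisible(x)
}

#' Validate a protocol result against its random-dataset control
#'
#' Passes iff the actual model beats the control by more than
#' `margin_points` accuracy points in either the mean or the best
#' accuracy across seeds, or the control failed to select any significant
#' feature at all. An actual protocol that itself aborted fails.
#'
#' @param actual,control `gip_protocol` results evaluated under the same
#'   protocol.
#' @param margin_points required improvement, in accuracy percentage
#'   points (default 0.5).
#' @return list with `passed`, `mean_margin_points`, `best_margin_points`,
#'   `control_aborted`.
#' @export
validate_against_control <- function(actual, control,
                                     margin_points = 0.5) {
  if (isTRUE(actual$aborted))
    return(list(passed = FALSE, mean_margin_points = NA_real_,
                best_margin_points = NA_real_, control_aborted = FALSE))
  if (isTRUE(control$aborted))
    return(list(passed = TRUE, mean_margin_points = NA_real_,
                best_margin_points = NA_real_, control_aborted = TRUE))
  mm <- (actual$mean_accuracy - control$mean_accuracy) * 100
  bm <- (actual$best_accuracy - control$best_accuracy) * 100
  list(passed = mm > margin_points || bm > margin_points,
       mean_margin_points = mm, best_margin_points = bm,
       control_aborted = FALSE)
}

#' Run the full protocol for every balanced AE of a study
#'
#' Builds the requested dataset kinds per retained AE, runs the actual
#' protocol and its Gaussian random-dataset control under the same seeds,
#' and validates each. The best validated configuration per AE (highest
#' mean accuracy among kinds passing validation and the coverage rule) is
#' identified for report generation.
#'
#' @param rows normalized feature rows from [extract_study_features()].
#' @param table an `ae_label_table`.
#' @param kinds dataset kinds to evaluate: subset of `"full"`,
#'   `"averaged"`, `"tissue"`.
#' @param n_randomizations,master_seed,split_mode,coverage_threshold see
#'   [run_protocol()].
#' @param margin_points see [validate_against_control()].
#' @return object of class `gip_analysis`: per retained AE a list of
#'   per-kind results (`ds`, `protocol`, `control`, `validation`) plus
#'   `best` (kind name or NA).
#' @export
analyze_study <- function(rows, table, kinds = c("full", "tissue"),
                          n_randomizations = 7, master_seed = 1,
                          split_mode = "row", coverage_threshold = 0.8,
                          margin_points = 0.5) {
  retained <- filter_balanced(table)
  out <- list()
  for (ae in retained) {
    ds_list <- list()
    if ("full" %in% kinds)
      ds_list$full <- build_full_dataset(rows, table, ae)
    if ("averaged" %in% kinds)
      ds_list$averaged <- build_averaged_dataset(rows, table, ae)
    if ("tissue" %in% kinds) {
      full <- ds_list$full %||% build_full_dataset(rows, table, ae)
      sp <- split_by_tissue(full)
      names(sp) <- paste0("tissue_", names(sp))
      ds_list <- c(ds_list, sp)
    }
    res <- lapply(names(ds_list), function(kind) {
      ds <- ds_list[[kind]]
      prot <- run_protocol(ds, n_randomizations = n_randomizations,
                           master_seed = master_seed,
                           split_mode = split_mode,
                           coverage_threshold = coverage_threshold)
      ctrl <- run_protocol(make_random_control(ds, master_seed),
                           n_randomizations = n_randomizations,
                           master_seed = master_seed,
                           split_mode = split_mode,
                           coverage_threshold = coverage_threshold)
      list(ds = ds, protocol = prot, control = ctrl,
           validation = validate_against_control(prot, ctrl,
                                                 margin_points))
    })
    names(res) <- names(ds_list)
    ok <- vapply(res, function(r)
      r$validation$passed && !r$protocol$aborted &&
        isTRUE(r$protocol$coverage_ok), TRUE)
    means <- vapply(res, function(r)
      if (r$protocol$aborted) -Inf else r$protocol$mean_accuracy, 0)
    out[[ae]] <- list(kinds = res,
                      best = if (any(ok)) names(res)[ok][
                        which.max(means[ok])] else NA_character_)
  }
  structure(list(aes = out, retained = retained,
                 ratios = attr(retained, "ratios")),
            class = "gip_analysis")
}
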