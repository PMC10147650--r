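# Post-prediction refinement (repeat averaging, dose weighting) and
# per-drug AE probability reports.

#' Average repeated predictions within (drug, dose) groups
#'
#' The mean of the member binary predictions is thresholded strictly:
#' a group votes positive only when its mean exceeds 0.5 (an even split
#' is negative).
#'
#' @param predictions 0/1 vector.
#' @param drug_id,dose optional grouping vectors aligned with
#'   `predictions`; when omitted the whole vector is one group.
#' @return with grouping, a data.frame (`drug_id`, `dose`, `pred`);
#'   without, a single 0/1 integer.
#' @export
average_repeats <- function(predictions, drug_id = NULL, dose = NULL) {
  if (!length(predictions)) stopf("invalid_argument", "empty group")
  vote <- function(x) as.integer(mean(x) > 0.5)
  if (is.null(drug_id)) return(vote(predictions))
  agg <- aggregate(list(pred = predictions),
                   by = list(drug_id = drug_id, dose = dose), FUN = vote)
  agg[order(agg$drug_id, -agg$dose), ]
}

#' Default dose weights
#'
#' Approximately twofold-decreasing weights applied to predictions in
#' descending order of tested dose (doses mostly separated by tenfold):
#' the highest dose carries full weight.
#'
#' @return numeric vector `c(1, 0.5, 0.3, 0.1, 0.05)` of class
#'   `dose_weights`.
#' @export
dose_weights <- function() {
  structure(c(1, 0.5, 0.3, 0.1, 0.05), class = "dose_weights")
}

#' Dose-weight adjustment of per-dose predictions
#'
#' Combines per-dose binary predictions (ordered by descending dose) into
#' one binary by a weighted vote `sum(w * pred) / sum(w) > 0.5`. With
#' fewer than five doses the first `k` weights are used (the highest dose
#' always carries weight 1); more than five doses is an error.
#'
#' @param predictions 0/1 vector ordered by descending dose.
#' @param weights a [dose_weights()] vector (strictly decreasing, first
#'   element 1).
#' @return single 0/1 integer (weighted mean in attribute `weighted_mean`).
#' @export
dose_weight_adjust <- function(predictions, weights = dose_weights()) {
  if (any(diff(weights) >= 0) || weights[1] != 1)
    stopf("invalid_argument",
          "weights must be strictly decreasing with first weight 1")
  k <- length(predictions)
  if (k < 1 || k > length(weights))
    stopf("invalid_argument", "need 1..%d per-dose predictions, got %d",
          length(weights), k)
  w <- weights[seq_len(k)]
  wm <- sum(w * predictions) / sum(w)
  structure(as.integer(wm > 0.5), weighted_mean = wm)
}

# per-(drug, dose) rows with the 96 tissue-prefixed feature columns,
# matching the averaged dataset layout (for averaged-kind predictors)
.averaged_rows <- function(rows) {
  nm <- ef_feature_names()
  key <- interaction(rows$drug_id, rows$dose, drop = TRUE)
  groups <- split(rows, key)
  out <- lapply(groups, function(gr) {
    row <- data.frame(drug_id = gr$drug_id[1], dose = gr$dose[1])
    for (ti in gi_tissues) {
      vals <- if (any(gr$tissue == ti))
        colMeans(gr[gr$tissue == ti, nm, drop = FALSE])
      else setNames(rep(NA_real_, 24), nm)
      row[paste(ti, nm, sep = "_")] <- as.list(vals)
    }
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# predictor = a trained_model or a list of them (ensemble)
.predict_binary <- function(predictor, X) {
  if (inherits(predictor, "trained_model")) predict(predictor, X)$class
  else ensemble_predict(predictor, X)$class
}

#' Probability that a drug induces an AE, over randomized models
#'
#' Each of the per-seed models (typically seven) predicts every feature
#' row of the drug; predictions are refined by repeat averaging within
#' each dose and, optionally, dose-weight adjustment across doses
#' (in that fixed order), yielding one binary per model. The reported
#' probability is `100 x positives / n_models`, so probabilities are
#' multiples of `100 / n_models`.
#'
#' @param rows normalized feature rows of one drug (any metadata columns
#'   plus the model's features). The drug need not appear in the training
#'   labels.
#' @param models list of per-seed predictors (`trained_model`s, or lists
#'   of them for ensembles).
#' @param refine average experimental repeats within dose (default TRUE).
#' @param dose_adjust apply [dose_weight_adjust()] across doses.
#' @param weights dose weights.
#' @return list with `probability_pct` (exact), `probability_rounded`
#'   (nearest integer percent) and `n_models`.
#' @export
predict_probability <- function(rows, models, refine = TRUE,
                                dose_adjust = TRUE,
                                weights = dose_weights()) {
  if (!length(models)) stopf("invalid_argument", "no applicable model")
  X <- as.matrix(rows[, intersect(colnames(rows),
                                  c(ef_feature_names(),
                                    as.vector(outer(gi_tissues,
                                                    ef_feature_names(),
                                                    paste, sep = "_")))),
                 drop = FALSE])
  finals <- vapply(models, function(m) {
    cls <- .predict_binary(m, X)
    if (refine) {
      per_dose <- average_repeats(cls, rows$drug_id, rows$dose)
      ordered <- per_dose$pred[order(-per_dose$dose)]
    } else {
      ordered <- as.integer(mean(cls) > 0.5)
    }
    if (dose_adjust && length(ordered) > 1)
      as.integer(dose_weight_adjust(ordered, weights))
    else as.integer(mean(ordered) > 0.5)
  }, integer(1))
  p <- 100 * sum(finals) / length(models)
  list(probability_pct = p, probability_rounded = round(p),
       n_models = length(models))
}

# per-seed predictors for the chosen algorithm of a protocol
.protocol_predictors <- function(protocol, algorithm = NULL) {
  algorithm <- algorithm %||% protocol$best_algorithm
  lapply(protocol$models, function(seed_models) {
    if (algorithm == "ensemble") seed_models else seed_models[[algorithm]]
  })
}

#' Generate the per-drug AE probability report
#'
#' For every AE whose best configuration passed validation and the
#' coverage rule, the seven per-seed models of that configuration predict
#' every drug's rows; refined probabilities are reported together with
#' the known label (when available) and a hit flag (probability > 50%
#' matching a positive label, <= 50% matching a negative one).
#'
#' @param rows normalized feature rows of the whole study.
#' @param analysis a [analyze_study()] result.
#' @param table the `ae_label_table` (known labels; drugs absent from it
#'   get `known_label = NA`).
#' @param refine,dose_adjust,weights see [predict_probability()].
#' @return data.frame of class `prediction_report` with one row per
#'   (drug, validated AE): `drug_id`, `ae_name`, `probability_pct_exact`,
#'   `probability_pct_rounded`, `n_randomizations`, `refined`,
#'   `dose_adjusted`, `known_label`, `hit`.
#' @export
generate_report <- function(rows, analysis, table, refine = TRUE,
                            dose_adjust = TRUE, weights = dose_weights()) {
  validated <- names(analysis$aes)[!is.na(vapply(analysis$aes,
                                                 function(a) a$best, ""))]
  if (!length(validated))
    stopf("invalid_argument", "no validated model to report on")
  out <- list()
  for (ae in validated) {
    best_kind <- analysis$aes[[ae]]$best
    res <- analysis$aes[[ae]]$kinds[[best_kind]]
    predictors <- .protocol_predictors(res$protocol)
    use_rows <- if (startsWith(best_kind, "tissue_")) {
      tis <- unique(res$ds$meta$tissue)
      rows[rows$tissue %in% tis, , drop = FALSE]
    } else if (best_kind == "averaged") {
      .averaged_rows(rows)
    } else rows
    for (drug in unique(use_rows$drug_id)) {
      dr <- use_rows[use_rows$drug_id == drug, , drop = FALSE]
      pr <- predict_probability(dr, predictors, refine = refine,
                                dose_adjust = dose_adjust,
                                weights = weights)
      known <- if (drug %in% rownames(table$labels))
        table$labels[drug, ae] else NA_integer_
      out[[length(out) + 1]] <- data.frame(
        drug_id = drug, ae_name = ae,
        probability_pct_exact = pr$probability_pct,
        probability_pct_rounded = pr$probability_rounded,
        n_randomizations = pr$n_models,
        refined = refine, dose_adjusted = dose_adjust,
        known_label = known,
        hit = if (is.na(known)) NA else
          as.integer((pr$probability_pct > 50) == (known == 1)))
    }
  }
  structure(do.call(rbind, out), class = c("prediction_report",
                                           "data.frame"))
}

#' Write a report as CSV and a human-readable summary
#'
#' @param report a [generate_report()] result.
#' @param path CSV path; a `.txt` summary (probabilities rounded to
#'   integer percent) is written alongside.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  write.csv(as.data.frame(report), path, row.names = FALSE)
  txt <- sub("\\.csv$", ".txt", path)
  lines <- c("Adverse-effect prediction report",
             sprintf("(%d randomized predictions per value)",
                     report$n_randomizations[1]), "")
  for (ae in unique(report$ae_name)) {
    sub_rep <- report[report$ae_name == ae, ]
    sub_rep <- sub_rep[order(-sub_rep$probability_pct_exact), ]
    lines <- c(lines, sprintf("== %s ==", ae),
               sprintf("  %-12s %3d%%%s", sub_rep$drug_id,
                       sub_rep$probability_pct_rounded,
                       ifelse(is.na(sub_rep$known_label), "  (unlabelled)",
                              ifelse(sub_rep$hit == 1, "  (hit)",
                                     "  (miss)"))), "")
  }
  writeLines(lines, txt)
  invisible(path)
}
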