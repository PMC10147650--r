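# Learning-dataset assembly: percentage-change normalization, SIDER-style
# label merge with the indication override, balance-ratio filtering, and
# the three dataset kinds.

#' Normalize a post-drug feature vector against its baseline
#'
#' Unit-bearing features become percentage changes,
#' `(post - baseline) / baseline x 100`; features already expressed as
#' percentages of contribution (and the unit-free entropy / DFA / change
#' index, see [ef_difference_features()]) become arithmetic differences
#' `post - baseline`.
#'
#' @param baseline,post `ef_vector` objects (or named numeric vectors with
#'   the canonical 24 names).
#' @return named numeric vector of 24 normalized values.
#' @export
normalize_features <- function(baseline, post) {
  nm <- ef_feature_names()
  b <- unclass(baseline)[nm]; p <- unclass(post)[nm]
  if (anyNA(b) || anyNA(p))
    stopf("invalid_argument", "feature vectors must carry all 24 features")
  diff_f <- nm %in% ef_difference_features()
  out <- numeric(24)
  if (any(b[!diff_f] == 0))
    stopf("degenerate_baseline",
          "zero baseline on unit-bearing feature(s): %s",
          paste(nm[!diff_f][b[!diff_f] == 0], collapse = ", "))
  out[!diff_f] <- (p[!diff_f] - b[!diff_f]) / b[!diff_f] * 100
  out[diff_f] <- p[diff_f] - b[diff_f]
  setNames(out, nm)
}

#' Assign binary AE labels with the indication override
#'
#' A (drug, AE) pair is labelled 1 iff a `side_effect` row exists and no
#' `indication` row exists: a drug clinically indicated for a condition is
#' forced to 0 regardless of side-effect reports, minimizing false AE
#' reports due to pre-existing conditions. Per-cell provenance is kept.
#'
#' @param raw_rows data.frame with columns `drug_id`, `ae_name`, `role`
#'   (`"side_effect"` or `"indication"`).
#' @param drugs character vector of drugs to label.
#' @param aes character vector of AE names to label.
#' @return object of class `ae_label_table`: `labels` (drugs x AEs 0/1
#'   matrix) and `provenance` (same shape, values `sider_positive`,
#'   `indication_override` or `absent`).
#' @export
assign_labels <- function(raw_rows, drugs, aes) {
  aes <- tolower(aes)
  labels <- matrix(0L, length(drugs), length(aes),
                   dimnames = list(drugs, aes))
  prov <- matrix("absent", length(drugs), length(aes),
                 dimnames = list(drugs, aes))
  skipped <- character()
  for (i in seq_len(nrow(raw_rows))) {
    d <- raw_rows$drug_id[i]; a <- tolower(raw_rows$ae_name[i])
    if (!d %in% drugs) { skipped <- c(skipped, d); next }
    if (!a %in% aes) next
    if (raw_rows$role[i] == "indication") {
      labels[d, a] <- 0L
      prov[d, a] <- "indication_override"
    } else if (prov[d, a] != "indication_override") {
      labels[d, a] <- 1L
      prov[d, a] <- "sider_positive"
    }
  }
  structure(list(labels = labels, provenance = prov,
                 skipped_drugs = unique(skipped)),
            class = "ae_label_table")
}

#' @export
print.ae_label_table <- function(x, ...) {
  cat(sprintf("<ae_label_table> %d drugs x %d AEs; positives per AE: %s\n",
              nrow(x$labels), ncol(x$labels),
              paste(colSums(x$labels), collapse = ", ")))
  invisible(x)
}

#' Balance ratio of one AE
#'
#' `Ratio = positive drugs / total drugs`.
#'
#' @param labels 0/1 vector of per-drug labels for one AE.
#' @return numeric in `[0, 1]`.
#' @export
balance_ratio <- function(labels) {
  if (length(labels) == 0) stopf("invalid_argument", "no drugs")
  sum(labels == 1) / length(labels)
}

#' Retain AEs whose balance ratio is acceptable
#'
#' An AE is kept iff `low <= ratio <= high` (the exclusion rule is strict:
#' ratios below 0.25 or above 0.75 are imbalanced, boundary values are
#' retained).
#'
#' @param table an `ae_label_table`.
#' @param low,high acceptable ratio range (defaults 0.25 and 0.75).
#' @return character vector of retained AE names (with ratios as the
#'   `ratios` attribute).
#' @export
filter_balanced <- function(table, low = 0.25, high = 0.75) {
  ratios <- apply(table$labels, 2, balance_ratio)
  keep <- names(ratios)[ratios >= low & ratios <= high]
  structure(keep, ratios = ratios)
}

#' Build the full (single-dataset) learning dataset for one AE
#'
#' One row per (drug, dose, tissue, repeat); 24 feature columns; every
#' row inherits its drug's AE label.
#'
#' @param rows normalized feature rows from [extract_study_features()].
#' @param table an `ae_label_table`.
#' @param ae AE name.
#' @return object of class `learning_dataset`: `features` (numeric
#'   matrix), `labels` (0/1), `meta` (row metadata), `kind`, `ae`,
#'   `ratio`.
#' @export
build_full_dataset <- function(rows, table, ae) {
  if (nrow(rows) == 0) stopf("invalid_argument", "no feature rows")
  lab <- table$labels[rows$drug_id, ae]
  new_learning_dataset(as.matrix(rows[ef_feature_names()]),
                       as.integer(lab),
                       rows[c("drug_id", "dose", "dose_rank", "tissue",
                              "repeat_idx")],
                       kind = "full", ae = ae,
                       ratio = balance_ratio(table$labels[, ae]))
}

#' Build the averaged learning dataset (96 tissue-aligned features)
#'
#' One row per (drug, dose): experimental repeats are averaged per tissue
#' and the four per-tissue means are aligned into `24 x 4 = 96`
#' tissue-prefixed columns. Tissues missing for a (drug, dose) leave their
#' 24 columns NA; datasets containing NAs are flagged incompatible with
#' discriminant analysis and SVM (see [applicable_algorithms()]).
#'
#' @inheritParams build_full_dataset
#' @return a `learning_dataset` of kind `"averaged"`.
#' @export
build_averaged_dataset <- function(rows, table, ae) {
  if (nrow(rows) == 0) stopf("invalid_argument", "no feature rows")
  nm <- ef_feature_names()
  key <- interaction(rows$drug_id, rows$dose, drop = TRUE)
  groups <- split(rows, key)
  cols <- as.vector(vapply(gi_tissues, function(ti) paste(ti, nm, sep = "_"),
                           character(24)))
  feat <- matrix(NA_real_, length(groups), length(cols),
                 dimnames = list(NULL, cols))
  meta <- data.frame(drug_id = character(length(groups)),
                     dose = numeric(length(groups)),
                     dose_rank = integer(length(groups)))
  for (g in seq_along(groups)) {
    gr <- groups[[g]]
    meta$drug_id[g] <- gr$drug_id[1]
    meta$dose[g] <- gr$dose[1]
    meta$dose_rank[g] <- gr$dose_rank[1]
    for (ti in unique(gr$tissue)) {
      sel <- gr$tissue == ti
      feat[g, paste(ti, nm, sep = "_")] <-
        colMeans(gr[sel, nm, drop = FALSE])
    }
  }
  ord <- order(meta$drug_id, -meta$dose)
  new_learning_dataset(feat[ord, , drop = FALSE],
                       as.integer(table$labels[meta$drug_id[ord], ae]),
                       meta[ord, ], kind = "averaged", ae = ae,
                       ratio = balance_ratio(table$labels[, ae]))
}

#' Split the full dataset by tissue
#'
#' @param ds a `learning_dataset` of kind `"full"`.
#' @param groups optional named list of tissue groupings to return in
#'   addition to the four single-tissue splits (e.g.
#'   `list(intestine = c("duodenum", "ileum", "colon"))`).
#' @return named list of `learning_dataset`s of kind `tissue_split`, one
#'   per tissue (plus any requested groups); the single-tissue splits
#'   partition the rows of `ds`.
#' @export
split_by_tissue <- function(ds, groups = NULL) {
  if (is.null(ds$meta$tissue))
    stopf("invalid_argument", "dataset has no tissue metadata")
  sets <- c(setNames(as.list(gi_tissues), gi_tissues), groups)
  lapply(sets, function(tis) {
    sel <- ds$meta$tissue %in% tis
    new_learning_dataset(ds$features[sel, , drop = FALSE],
                         ds$labels[sel], ds$meta[sel, ],
                         kind = paste0("tissue_split(",
                                       paste(tis, collapse = "+"), ")"),
                         ae = ds$ae, ratio = ds$ratio)
  })
}

#' @noRd
new_learning_dataset <- function(features, labels, meta, kind, ae, ratio) {
  stopifnot(nrow(features) == length(labels))
  rownames(features) <- NULL; rownames(meta) <- NULL
  structure(list(features = features, labels = labels, meta = meta,
                 kind = kind, ae = ae, ratio = ratio),
            class = "learning_dataset")
}

#' @export
print.learning_dataset <- function(x, ...) {
  cat(sprintf("<learning_dataset> %s / %s: %d rows x %d features, ratio %.3f%s\n",
              x$ae, x$kind, nrow(x$features), ncol(x$features), x$ratio,
              if (anyNA(x$features)) " (has missing values)" else ""))
  invisible(x)
}

#' Write / read a learning dataset as CSV plus a JSON sidecar
#'
#' The CSV holds metadata, label and feature columns under canonical
#' names; the sidecar records kind, AE, ratio and the feature column
#' names so datasets round-trip exactly.
#'
#' @param ds a `learning_dataset`.
#' @param path CSV path (`.json` sidecar placed alongside).
#' @return `write_learning_dataset()` returns `path` invisibly;
#'   `read_learning_dataset()` the dataset.
#' @export
write_learning_dataset <- function(ds, path) {
  df <- cbind(ds$meta, label = ds$labels, as.data.frame(ds$features))
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(kind = ds$kind, ae = ds$ae, ratio = ds$ratio,
                            feature_names = colnames(ds$features),
                            meta_names = names(ds$meta)),
                       sub("\\.csv$", ".json", path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_learning_dataset
#' @export
read_learning_dataset <- function(path) {
  side <- jsonlite::read_json(sub("\\.csv$", ".json", path),
                              simplifyVector = TRUE)
  df <- read.csv(path, check.names = FALSE)
  new_learning_dataset(as.matrix(df[side$feature_names]), df$label,
                       df[side$meta_names], side$kind, side$ae,
                       side$ratio)
}
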