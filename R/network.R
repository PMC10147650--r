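# Drug-AE similarity network: drugs clustered by refined features plus
# positive / negative correlation poles.

#' Per-drug matrix of refined (selected) features
#'
#' Averages each drug's normalized rows over all (dose, tissue, repeat)
#' combinations, restricted to the selected features, then z-scores each
#' feature column. With a single drug z-scoring is degenerate and skipped
#' (flagged via attribute `zscored = FALSE`).
#'
#' @param rows normalized feature rows ([extract_study_features()]).
#' @param selection a [select_features()] result (non-empty), or NULL to
#'   use all 24 features.
#' @return numeric matrix, drugs x features, row names = drug ids.
#' @export
drug_feature_matrix <- function(rows, selection = NULL) {
  feats <- if (is.null(selection)) ef_feature_names()
           else selection$features
  if (!length(feats)) stopf("invalid_argument", "empty feature selection")
  feats <- intersect(feats, colnames(rows))
  if (!length(feats))
    stopf("invalid_argument", "selected features not present in rows")
  agg <- aggregate(rows[feats], by = list(drug_id = rows$drug_id), mean)
  m <- as.matrix(agg[feats])
  rownames(m) <- agg$drug_id
  if (nrow(m) < 2) return(structure(m, zscored = FALSE))
  structure(zscore_cols(m), zscored = TRUE)
}

#' Build the drug-AE network for one adverse effect
#'
#' Nodes are the drugs plus two pole nodes placed at the centroids of the
#' positive- and negative-labelled drugs in refined-feature space. Every
#' drug connects to both poles with weight `1 / (1 + distance)`;
#' drug-drug edges are kept for the most similar pairs (top
#' `edge_quantile` fraction). The pole separation (Euclidean distance
#' between the two centroids) measures how well the refined features
#' distinguish the classes.
#'
#' @param matrix drugs x features matrix from [drug_feature_matrix()].
#' @param labels named (or aligned) 0/1 vector of per-drug AE labels;
#'   both classes must be present.
#' @param edge_quantile fraction of most-similar drug pairs kept as
#'   drug-drug edges (default 0.1).
#' @param receptor_classes optional named character vector of per-drug
#'   receptor classes, stored on the nodes.
#' @return object of class `drug_ae_network`: `graph` (igraph),
#'   `pole_separation`, `edges` (data.frame), `matrix`, `labels`.
#' @export
build_network <- function(matrix, labels, edge_quantile = 0.1,
                          receptor_classes = NULL) {
  if (!is.null(names(labels))) labels <- labels[rownames(matrix)]
  if (length(unique(labels)) < 2)
    stopf("invalid_argument", "both label classes must be present")
  pos_c <- colMeans(matrix[labels == 1, , drop = FALSE])
  neg_c <- colMeans(matrix[labels == 0, , drop = FALSE])
  pole_sep <- sqrt(sum((pos_c - neg_c)^2))
  dd <- as.matrix(stats::dist(matrix))
  sim <- 1 / (1 + dd)
  pairs <- which(upper.tri(dd), arr.ind = TRUE)
  psim <- sim[pairs]
  thr <- quantile(psim, 1 - edge_quantile, names = FALSE)
  keep <- psim >= thr
  drugs <- rownames(matrix)
  pole_dist <- function(centroid)
    sqrt(rowSums(sweep(matrix, 2, centroid, "-")^2))
  edges <- rbind(
    data.frame(source = drugs[pairs[keep, 1]],
               target = drugs[pairs[keep, 2]],
               weight = psim[keep], edge_type = "drug_drug"),
    data.frame(source = drugs, target = "pole_positive",
               weight = 1 / (1 + pole_dist(pos_c)),
               edge_type = "drug_pole"),
    data.frame(source = drugs, target = "pole_negative",
               weight = 1 / (1 + pole_dist(neg_c)),
               edge_type = "drug_pole"))
  nodes <- data.frame(
    name = c(drugs, "pole_positive", "pole_negative"),
    node_type = c(rep("drug", length(drugs)), "pole", "pole"),
    label = c(as.integer(labels), NA, NA),
    receptor_class = c(if (is.null(receptor_classes)) rep(NA_character_,
                                                          length(drugs))
                       else unname(receptor_classes[drugs]), NA, NA))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  structure(list(graph = g, pole_separation = pole_sep, edges = edges,
                 matrix = matrix, labels = labels),
            class = "drug_ae_network")
}

#' @export
print.drug_ae_network <- function(x, ...) {
  cat(sprintf("<drug_ae_network> %d drugs, %d edges, pole separation %.3f\n",
              nrow(x$matrix), nrow(x$edges), x$pole_separation))
  invisible(x)
}

#' Fraction of drugs whose nearest pole matches their label
#'
#' @param network a `drug_ae_network`.
#' @return numeric in `[0, 1]`.
#' @export
nearest_pole_agreement <- function(network) {
  m <- network$matrix
  pos_c <- colMeans(m[network$labels == 1, , drop = FALSE])
  neg_c <- colMeans(m[network$labels == 0, , drop = FALSE])
  dpos <- rowSums(sweep(m, 2, pos_c, "-")^2)
  dneg <- rowSums(sweep(m, 2, neg_c, "-")^2)
  mean((dpos < dneg) == (network$labels == 1))
}

#' Receptor-class clustering score
#'
#' Fraction of drugs whose nearest neighbour in feature space shares
#' their receptor class. Equals ~the class-frequency baseline for
#' shuffled labels and approaches 1 for well-separated classes.
#'
#' @param matrix drugs x features matrix (or a `drug_ae_network`).
#' @param receptor_classes named character vector of per-drug classes;
#'   at least two distinct classes required.
#' @return numeric in `[0, 1]`.
#' @export
class_cluster_score <- function(matrix, receptor_classes) {
  if (inherits(matrix, "drug_ae_network")) matrix <- matrix$matrix
  cls <- receptor_classes[rownames(matrix)]
  if (any(is.na(cls))) stopf("invalid_argument", "unknown receptor classes")
  if (length(unique(cls)) < 2)
    stopf("invalid_argument", "need >= 2 receptor classes")
  dd <- as.matrix(stats::dist(matrix))
  diag(dd) <- Inf
  nn <- apply(dd, 1, which.min)
  mean(cls[nn] == cls)
}

#' Export a network as GraphML and an edge-list CSV with a JSON summary
#'
#' @param network a `drug_ae_network`.
#' @param stem output path stem; writes `<stem>.graphml`,
#'   `<stem>_edges.csv` and `<stem>_summary.json`.
#' @param receptor_classes optional classes for the cluster score in the
#'   summary.
#' @return `stem`, invisibly.
#' @export
write_network <- function(network, stem, receptor_classes = NULL) {
  igraph::write_graph(network$graph, paste0(stem, ".graphml"),
                      format = "graphml")
  write.csv(network$edges, paste0(stem, "_edges.csv"), row.names = FALSE)
  summary <- list(pole_separation = network$pole_separation,
                  nearest_pole_agreement = nearest_pole_agreement(network),
                  n_drugs = nrow(network$matrix),
                  metric = "euclidean on z-scored refined features")
  if (!is.null(receptor_classes))
    summary$class_cluster_score <-
      class_cluster_score(network, receptor_classes)
  jsonlite::write_json(summary, paste0(stem, "_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(stem)
}
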