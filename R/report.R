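#' Consensus features across LOOCV folds
#'
#' Features selected in every fold. Selection varies slightly from fold to
#' fold; only the intersection is considered reliably discriminative.
#'
#' @param folds List of fold records (from an `evaluation_report`).
#' @return Integer feature indices in canonical order (possibly empty).
#' @export
consensus_features <- function(folds) {
  if (length(folds) == 0) stop("empty fold list")
  sel <- lapply(folds, `[[`, "selected_features")
  sort(Reduce(intersect, sel))
}

#' Fold-averaged discriminative feature weights
#'
#' For each consensus feature, in every fold, the absolute hyperplane
#' coefficient of its network is multiplied by that fold's kernel weight
#' of the network, and the products are averaged across folds. Defined
#' only for linear-kernel runs (the hyperplane has no input-space
#' coefficients otherwise).
#'
#' @param folds Fold records carrying `primal_weights`, `beta` and
#'   `selected_per_network`.
#' @param consensus Integer feature indices from [consensus_features()].
#' @return Named numeric vector of mean weights (names = feature index).
#' @export
feature_weights <- function(folds, consensus) {
  if (any(vapply(folds, function(f) is.null(f$primal_weights), logical(1))))
    stop("fold records lack hyperplane coefficients; ",
         "the discriminative-feature procedure is defined for the linear kernel")
  w <- matrix(0, length(folds), length(consensus))
  for (fi in seq_along(folds)) {
    f <- folds[[fi]]
    for (m in seq_along(f$selected_per_network)) {
      sel_m <- f$selected_per_network[[m]]
      hit <- match(consensus, sel_m)
      has <- !is.na(hit)
      if (any(has))
        w[fi, has] <- abs(f$primal_weights[[m]][hit[has]]) * f$beta[m]
    }
  }
  stats::setNames(colMeans(w), consensus)
}

#' Aggregate consensus weights per edge and per network
#'
#' Edge weights sum a node pair's consensus feature weights across
#' networks; network totals sum the consensus weights of each network. By
#' construction the network totals, the edge weights and the consensus
#' weights all share one grand total.
#'
#' @param tab The `feature_table` the evaluation ran on (for provenance
#'   and region names).
#' @param folds Fold records of a linear-kernel `evaluation_report`.
#' @return A `discriminative_report`: `consensus` data frame (feature,
#'   network, nodes, regions, mean_weight), `edge_weights`,
#'   `network_totals`.
#' @export
discriminative_report <- function(tab, folds) {
  cons <- consensus_features(folds)
  mw <- feature_weights(folds, cons)
  prov <- tab$provenance[cons, , drop = FALSE]
  consensus <- data.frame(
    feature = cons, network = prov$network, i = prov$i, j = prov$j,
    region_i = prov$region_i, region_j = prov$region_j,
    mean_weight = as.numeric(mw))
  edge_key <- paste(consensus$i, consensus$j, sep = "-")
  ew <- tapply(consensus$mean_weight, edge_key, sum)
  first <- !duplicated(edge_key)
  edge_weights <- data.frame(
    i = consensus$i[first], j = consensus$j[first],
    region_i = consensus$region_i[first], region_j = consensus$region_j[first],
    weight = as.numeric(ew[edge_key[first]]))
  edge_weights <- edge_weights[order(-edge_weights$weight), ]
  network_totals <- vapply(c("FN", "FA", "MD"), function(k)
    sum(consensus$mean_weight[consensus$network == k]), numeric(1))
  structure(list(consensus = consensus[order(-consensus$mean_weight), ],
                 edge_weights = edge_weights,
                 network_totals = network_totals),
            class = "discriminative_report")
}

#' @export
print.discriminative_report <- function(x, ...) {
  cat(sprintf("discriminative_report: %d consensus features, %d edges\n",
              nrow(x$consensus), nrow(x$edge_weights)))
  cat("network totals:",
      paste(names(x$network_totals),
            sprintf("%.3f", x$network_totals), collapse = ", "), "\n")
  invisible(x)
}

#' Write a discriminative report as CSVs and a brain-net edge file
#'
#' Writes `<prefix>_features.csv` (network, regions, mean weight),
#' `<prefix>_edges.csv`, `<prefix>_network_totals.csv`, plus a node file
#' and an n x n edge-weight matrix in the plain-text layout that standard
#' brain-network viewers import.
#'
#' @param report A `discriminative_report`.
#' @param tab The originating `feature_table`.
#' @param prefix Output path prefix.
#' @return Invisibly, the written file paths.
#' @export
write_discriminative_report <- function(report, tab, prefix) {
  p1 <- paste0(prefix, "_features.csv")
  utils::write.csv(report$consensus, p1, row.names = FALSE)
  p2 <- paste0(prefix, "_edges.csv")
  utils::write.csv(report$edge_weights, p2, row.names = FALSE)
  p3 <- paste0(prefix, "_network_totals.csv")
  utils::write.csv(data.frame(network = names(report$network_totals),
                              total_weight = as.numeric(report$network_totals)),
                   p3, row.names = FALSE)
  n <- tab$n_nodes
  m <- matrix(0, n, n)
  for (r in seq_len(nrow(report$edge_weights))) {
    i <- report$edge_weights$i[r]; j <- report$edge_weights$j[r]
    m[i, j] <- m[j, i] <- report$edge_weights$weight[r]
  }
  p4 <- paste0(prefix, "_edge_matrix.txt")
  utils::write.table(m, p4, sep = "\t", row.names = FALSE, col.names = FALSE)
  p5 <- paste0(prefix, "_nodes.txt")
  utils::write.table(data.frame(label = tab$node_labels,
                                degree = colSums(m > 0)),
                     p5, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(c(p1, p2, p3, p4, p5))
}
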