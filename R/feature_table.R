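#' Canonical edge-feature provenance for an n-node cohort
#'
#' Column order of a vectorized cohort: network blocks in the order FN, FA,
#' MD; within each block the upper-triangle node pairs `(i, j)`, `i < j`,
#' sorted lexicographically by `(i, j)` with 1-based region ids. For 90
#' nodes this yields 4,005 columns per network and 12,015 in total.
#'
#' @param n_nodes Number of nodes.
#' @param node_labels Optional region names (default AAL-90 / generic).
#' @return Data frame with columns `network`, `i`, `j`, `region_i`,
#'   `region_j`, `name`; one row per feature column.
#' @export
feature_provenance <- function(n_nodes, node_labels = NULL) {
  if (is.null(node_labels)) node_labels <- aal90_labels(n_nodes)
  i <- rep(seq_len(n_nodes - 1), times = (n_nodes - 1):1)
  j <- unlist(lapply(seq_len(n_nodes - 1), function(a) (a + 1):n_nodes))
  one <- data.frame(i = i, j = j)
  prov <- do.call(rbind, lapply(c("FN", "FA", "MD"), function(k)
    cbind(network = k, one)))
  prov$region_i <- node_labels[prov$i]
  prov$region_j <- node_labels[prov$j]
  prov$name <- paste0(prov$network, ":", prov$region_i, "-", prov$region_j)
  prov
}

#' Vectorize a cohort of multi-weight connectomes into a feature table
#'
#' Each subject becomes one row of `3 * n(n-1)/2` edge weights in the
#' canonical order of [feature_provenance()].
#'
#' @param cohort List of elements each holding `connectome`
#'   (a [multiweight_connectome()]) and `label` (-1 or +1).
#' @param subject_ids Optional character ids (default `sub_001`, ...).
#' @return An object of class `feature_table`: list with `features`
#'   (n x p matrix), `labels`, `subject_ids`, `provenance`, `n_nodes`,
#'   `node_labels`, `n_networks`.
#' @export
vectorize_cohort <- function(cohort, subject_ids = NULL) {
  if (length(cohort) < 2) stop("cohort must contain at least two subjects")
  labels <- vapply(cohort, function(s) as.numeric(s$label), numeric(1))
  if (!all(labels %in% c(-1, 1))) stop("labels must be -1 or +1")
  if (length(unique(labels)) < 2) stop("both classes must be present")
  n <- cohort[[1]]$connectome$n_nodes
  labs <- cohort[[1]]$connectome$node_labels
  if (!all(vapply(cohort, function(s) s$connectome$n_nodes, numeric(1)) == n))
    stop("all connectomes must share n_nodes")
  prov <- feature_provenance(n, labs)
  ut <- cbind(prov$i[prov$network == "FN"], prov$j[prov$network == "FN"])
  feat <- t(vapply(cohort, function(s) {
    cx <- s$connectome
    c(cx$fn[ut], cx$fa[ut], cx$md[ut])
  }, numeric(3 * nrow(ut))))
  if (is.null(subject_ids)) subject_ids <- sprintf("sub_%03d", seq_along(cohort))
  rownames(feat) <- subject_ids
  colnames(feat) <- prov$name
  structure(list(features = feat, labels = labels,
                 subject_ids = as.character(subject_ids), provenance = prov,
                 n_nodes = n, node_labels = labs, n_networks = 3L),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d subjects x %d features (%d nodes, %d networks), labels %d/%d\n",
              nrow(x$features), ncol(x$features), x$n_nodes, x$n_networks,
              sum(x$labels == 1), sum(x$labels == -1)))
  invisible(x)
}

#' Rebuild one subject's matrices from a feature-table row
#'
#' Inverse of [vectorize_cohort()] via the stored provenance.
#'
#' @param tab A `feature_table`.
#' @param row Subject row index.
#' @return A [multiweight_connectome()].
#' @export
devectorize_subject <- function(tab, row) {
  n <- tab$n_nodes
  mk <- function(kind) {
    sel <- tab$provenance$network == kind
    m <- matrix(0, n, n)
    m[cbind(tab$provenance$i[sel], tab$provenance$j[sel])] <-
      tab$features[row, sel]
    m + t(m)
  }
  multiweight_connectome(mk("FN"), mk("FA"), mk("MD"), tab$node_labels)
}

#' Column indices of one network's block
#'
#' @param tab A `feature_table`.
#' @param kind `"FN"`, `"FA"` or `"MD"`.
#' @return Integer column indices.
#' @export
network_block <- function(tab, kind) {
  which(tab$provenance$network == match.arg(kind, c("FN", "FA", "MD")))
}

#' Write / read a feature table as CSV
#'
#' Header = provenance strings (`MD:Frontal_Sup_Orb_L-Rectus_L` style),
#' preceded by `subject_id` and `label` columns.
#'
#' @param tab A `feature_table`.
#' @param path File path.
#' @return `read_feature_csv` returns a `feature_table`.
#' @export
write_feature_csv <- function(tab, path) {
  df <- data.frame(subject_id = tab$subject_ids, label = tab$labels,
                   tab$features, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @param n_nodes Node count of the stored cohort (needed to rebuild
#'   provenance; inferred from the column count when omitted).
#' @export
read_feature_csv <- function(path, n_nodes = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  feat <- as.matrix(df[, -(1:2), drop = FALSE])
  if (is.null(n_nodes)) {
    p1 <- ncol(feat) / 3
    n_nodes <- as.integer(round((1 + sqrt(1 + 8 * p1)) / 2))
  }
  labs <- sub("^FN:", "", grep("^FN:", colnames(feat), value = TRUE))
  first <- sub("-.*$", "", labs[1])
  node_labels <- unique(c(first, sub("^[^-]*-", "", labs)))
  if (length(node_labels) != n_nodes) node_labels <- NULL
  prov <- feature_provenance(n_nodes, node_labels)
  if (!identical(colnames(feat), prov$name))
    stop("CSV columns are not in canonical provenance order")
  rownames(feat) <- as.character(df$subject_id)
  structure(list(features = feat, labels = df$label,
                 subject_ids = as.character(df$subject_id),
                 provenance = prov, n_nodes = n_nodes,
                 node_labels = if (is.null(node_labels))
                   aal90_labels(n_nodes) else node_labels,
                 n_networks = 3L),
            class = "feature_table")
}
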