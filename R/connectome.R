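#' Multi-weight structural connectome
#'
#' Container for the three co-topological weighted networks of one subject:
#' a fiber-number (FN) network holding streamline counts, a fractional
#' anisotropy (FA) network holding the mean FA over the voxels of the
#' connecting fibers, and a mean diffusivity (MD) network on the mm^2/s
#' scale (typical white-matter values around 0.7e-3). The three matrices
#' share one binary topology: an edge is present in all three networks or
#' in none.
#'
#' @param fn,fa,md Symmetric `n x n` numeric matrices with zero diagonal.
#'   `fn` holds non-negative integer counts; on the common support `fa`
#'   must lie in (0, 1] and `md` must be strictly positive.
#' @param node_labels Character vector of region names (defaults to AAL-90
#'   names for 90 nodes, generic labels otherwise).
#' @return An object of class `multiweight_connectome` with elements
#'   `n_nodes`, `fn`, `fa`, `md`, `node_labels`.
#' @export
multiweight_connectome <- function(fn, fa, md, node_labels = NULL) {
  fn <- as.matrix(fn); fa <- as.matrix(fa); md <- as.matrix(md)
  n <- nrow(fn)
  if (is.null(node_labels)) node_labels <- aal90_labels(n)
  x <- structure(
    list(n_nodes = n, fn = fn, fa = fa, md = md,
         node_labels = as.character(node_labels)),
    class = "multiweight_connectome")
  validate_connectome(x)
  x
}

#' Validate a multi-weight connectome
#'
#' Checks symmetry, zero diagonal, the shared binary topology of the three
#' matrices, and the per-weight value ranges on the support.
#'
#' @param x A `multiweight_connectome`.
#' @param tol Numeric tolerance for symmetry checks.
#' @return `x` invisibly; errors on the first violated invariant.
#' @export
validate_connectome <- function(x, tol = 1e-8) {
  n <- x$n_nodes
  for (k in c("fn", "fa", "md")) {
    m <- x[[k]]
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != n)
      stop(sprintf("'%s' must be a %d x %d matrix", k, n, n))
    if (any(!is.finite(m))) stop(sprintf("'%s' contains non-finite values", k))
    if (max(abs(m - t(m))) > tol) stop(sprintf("'%s' is not symmetric", k))
    if (any(diag(m) != 0)) stop(sprintf("'%s' has non-zero diagonal", k))
    if (any(m < 0)) stop(sprintf("'%s' has negative entries", k))
  }
  if (length(x$node_labels) != n)
    stop("node_labels length does not match n_nodes")
  sup <- x$fn > 0
  if (!identical(sup, x$fa > 0) || !identical(sup, x$md > 0))
    stop("fn, fa and md do not share the same binary topology")
  if (any(x$fn[sup] != round(x$fn[sup])))
    stop("fn entries must be integer streamline counts")
  if (any(x$fa[sup] > 1))
    stop("fa entries on the support must lie in (0, 1]")
  invisible(x)
}

#' @export
print.multiweight_connectome <- function(x, ...) {
  ne <- sum(x$fn[upper.tri(x$fn)] > 0)
  cat(sprintf("multiweight_connectome: %d nodes, %d edges (density %.3f)\n",
              x$n_nodes, ne, ne / (x$n_nodes * (x$n_nodes - 1) / 2)))
  invisible(x)
}

#' Upper-triangle edge list of the shared topology
#'
#' @param x A `multiweight_connectome`.
#' @return Two-column integer matrix of node pairs `(i, j)`, `i < j`,
#'   in lexicographic order, restricted to the support.
#' @export
connectome_edges <- function(x) {
  idx <- which(upper.tri(x$fn) & x$fn > 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  colnames(idx) <- c("i", "j")
  idx
}

#' Read one subject's connectome from delimited matrix files
#'
#' Each file holds one `n x n` numeric matrix, whitespace- or
#' comma-delimited, no header.
#'
#' @param fn_path,fa_path,md_path Paths to the FN, FA and MD matrix files.
#' @param node_labels Optional region names.
#' @return A `multiweight_connectome`.
#' @export
read_connectome <- function(fn_path, fa_path, md_path, node_labels = NULL) {
  rd <- function(p) {
    if (!file.exists(p)) stop("matrix file not found: ", p)
    first <- readLines(p, n = 1L)
    sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
    as.matrix(utils::read.table(p, sep = sep, header = FALSE))
  }
  fn <- unname(rd(fn_path)); fa <- unname(rd(fa_path)); md <- unname(rd(md_path))
  multiweight_connectome(fn, fa, md, node_labels)
}

#' Write one subject's connectome as three delimited matrix files
#'
#' @param x A `multiweight_connectome`.
#' @param fn_path,fa_path,md_path Output paths.
#' @export
write_connectome <- function(x, fn_path, fa_path, md_path) {
  wr <- function(m, p) utils::write.table(
    m, p, sep = "\t", row.names = FALSE, col.names = FALSE)
  wr(x$fn, fn_path); wr(x$fa, fa_path); wr(x$md, md_path)
  invisible(x)
}

#' Read a subject manifest and its connectome files
#'
#' The manifest is a CSV with columns `subject_id`, `group`, `fn_path`,
#' `fa_path`, `md_path`. Relative paths are resolved against the manifest's
#' directory. Group labels must be coercible to -1/+1 (either numeric or
#' two level names, in which case the second sorted level is coded +1 and
#' should be the patient group).
#'
#' @param manifest_path Path to the manifest CSV.
#' @param positive_group Optional group name to code as +1.
#' @return List with `cohort` (list of `(connectome, label)` pairs) and
#'   `subject_ids`.
#' @export
read_manifest <- function(manifest_path, positive_group = NULL) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "fn_path", "fa_path", "md_path")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  base <- dirname(normalizePath(manifest_path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  grp <- man$group
  if (is.numeric(grp) || all(grp %in% c("-1", "1", "+1"))) {
    lab <- as.numeric(sub("^\\+", "", grp))
  } else {
    lev <- sort(unique(grp))
    if (length(lev) != 2) stop("manifest group must have exactly two levels")
    pos <- if (is.null(positive_group)) lev[2] else positive_group
    if (!pos %in% lev) stop("positive_group not found in manifest groups")
    lab <- ifelse(grp == pos, 1, -1)
  }
  if (!all(lab %in% c(-1, 1))) stop("group labels must code to -1/+1")
  cohort <- lapply(seq_len(nrow(man)), function(i) {
    cx <- read_connectome(resolve(man$fn_path[i]), resolve(man$fa_path[i]),
                          resolve(man$md_path[i]))
    list(connectome = cx, label = lab[i])
  })
  list(cohort = cohort, subject_ids = as.character(man$subject_id))
}
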