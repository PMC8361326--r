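#' Labeled streamline phantom
#'
#' A minimal tractography input: a 3-D integer label volume (0 background,
#' 1..R region ids), FA and MD scalar volumes of the same shape, and a list
#' of streamlines given as ordered voxel-index sequences (one voxel per
#' row, 1-based array indices).
#'
#' @param label_volume 3-D integer array.
#' @param fa_volume,md_volume 3-D numeric arrays, same dim as
#'   `label_volume`.
#' @param streamlines List of integer matrices, each `k x 3` with `k >= 2`,
#'   rows being voxel indices within the volume bounds.
#' @return An object of class `streamline_phantom`.
#' @export
streamline_phantom <- function(label_volume, fa_volume, md_volume,
                               streamlines) {
  dm <- dim(label_volume)
  if (length(dm) != 3) stop("label_volume must be a 3-D array")
  if (!identical(dim(fa_volume), dm) || !identical(dim(md_volume), dm))
    stop("fa_volume and md_volume must match label_volume dimensions")
  if (any(label_volume != round(label_volume)) || any(label_volume < 0))
    stop("label_volume must hold non-negative integer region ids")
  for (s in streamlines) {
    if (!is.matrix(s) || ncol(s) != 3 || nrow(s) < 2)
      stop("each streamline must be a k x 3 voxel-index matrix with k >= 2")
    if (any(s < 1) || any(t(s) > dm))
      stop("streamline voxel index outside volume bounds")
  }
  structure(list(label_volume = label_volume, fa_volume = fa_volume,
                 md_volume = md_volume, streamlines = streamlines),
            class = "streamline_phantom")
}

#' Build FN/FA/MD networks from a labeled streamline set
#'
#' A node pair `(i, j)`, `i != j`, is connected if at least one streamline
#' has its two endpoint voxels in regions `i` and `j`. The FN weight is the
#' number of such streamlines; the FA (MD) weight is the mean of the FA
#' (MD) volume over the voxels traversed by all streamlines of that pair.
#' By default each voxel enters the mean once however often it is visited;
#' with `voxel_multiset = TRUE` every visit counts.
#'
#' Streamlines with an endpoint in the background (label 0) are skipped and
#' counted in the `n_skipped` attribute. Streamlines with both endpoints in
#' one region are self-connections and contribute nothing (the diagonal is
#' structurally zero).
#'
#' @param phantom A [streamline_phantom()].
#' @param n_nodes Number of network nodes; must be at least the largest
#'   region id present.
#' @param voxel_multiset Logical; weight voxels by visit count instead of
#'   deduplicating.
#' @param node_labels Optional region names.
#' @return A [multiweight_connectome()] with attribute `n_skipped`.
#' @export
build_networks <- function(phantom, n_nodes, voxel_multiset = FALSE,
                           node_labels = NULL) {
  stopifnot(inherits(phantom, "streamline_phantom"))
  dm <- dim(phantom$label_volume)
  if (max(phantom$label_volume) > n_nodes)
    stop("n_nodes smaller than the largest region id in the label volume")
  lin <- function(v) v[, 1] + dm[1] * (v[, 2] - 1) + dm[1] * dm[2] * (v[, 3] - 1)
  fn <- matrix(0, n_nodes, n_nodes)
  vox <- vector("list", 0)   # per-edge linear voxel indices, keyed "i_j"
  n_skipped <- 0L
  for (s in phantom$streamlines) {
    li <- lin(s)
    a <- phantom$label_volume[li[1]]
    b <- phantom$label_volume[li[length(li)]]
    if (a == 0 || b == 0) { n_skipped <- n_skipped + 1L; next }
    if (a == b) next
    i <- min(a, b); j <- max(a, b)
    key <- paste0(i, "_", j)
    fn[i, j] <- fn[i, j] + 1
    vox[[key]] <- c(vox[[key]], li)
  }
  fa <- matrix(0, n_nodes, n_nodes)
  md <- matrix(0, n_nodes, n_nodes)
  for (key in names(vox)) {
    ij <- as.integer(strsplit(key, "_", fixed = TRUE)[[1]])
    v <- vox[[key]]
    if (!voxel_multiset) v <- unique(v)
    fa[ij[1], ij[2]] <- mean(phantom$fa_volume[v])
    md[ij[1], ij[2]] <- mean(phantom$md_volume[v])
  }
  fn <- fn + t(fn); fa <- fa + t(fa); md <- md + t(md)
  out <- multiweight_connectome(fn, fa, md, node_labels = node_labels)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write / read the JSON phantom interchange format
#'
#' Schema: an object with `dim` (3 integers), `label`, `fa`, `md` (flat
#' arrays in R column-major order) and `streamlines` (array of k x 3 arrays
#' of 1-based voxel indices).
#'
#' @param phantom A `streamline_phantom`.
#' @param path Output / input file path.
#' @return `read_phantom_json` returns a `streamline_phantom`.
#' @export
write_phantom_json <- function(phantom, path) {
  obj <- list(dim = dim(phantom$label_volume),
              label = as.integer(phantom$label_volume),
              fa = as.vector(phantom$fa_volume),
              md = as.vector(phantom$md_volume),
              streamlines = lapply(phantom$streamlines, unname))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_phantom_json
#' @export
read_phantom_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dm <- as.integer(obj$dim)
  sl <- obj$streamlines
  if (is.null(sl)) sl <- list()
  if (is.array(sl) && length(dim(sl)) == 3)  # homogeneous lengths simplify
    sl <- lapply(seq_len(dim(sl)[1]), function(i) sl[i, , ])
  streamline_phantom(array(as.integer(obj$label), dm),
                     array(as.numeric(obj$fa), dm),
                     array(as.numeric(obj$md), dm),
                     lapply(sl, function(s) matrix(as.integer(s), ncol = 3)))
}

#' Assemble a phantom from NIfTI label/FA/MD volumes
#'
#' Thin wrapper reading the three volumes with RNifti; streamlines are
#' supplied separately as voxel-index matrices (e.g. from an external
#' tractography export).
#'
#' @param label_path,fa_path,md_path NIfTI file paths.
#' @param streamlines List of `k x 3` voxel-index matrices.
#' @return A `streamline_phantom`.
#' @export
read_phantom_nifti <- function(label_path, fa_path, md_path, streamlines) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required to read NIfTI volumes")
  as3d <- function(p) {
    a <- as.array(RNifti::readNifti(p))
    array(a, dim(a)[1:3])
  }
  lab <- as3d(label_path)
  streamline_phantom(array(as.integer(round(lab)), dim(lab)),
                     as3d(fa_path), as3d(md_path), streamlines)
}
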