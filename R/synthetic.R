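#' Group-effect specification for synthetic cohorts
#'
#' Signed group shifts applied to the patient (+1) group on a subset of
#' edges, expressed in units of the edge's between-subject standard
#' deviation, separately per weight kind. The defaults emulate the
#' degeneration pattern expected in early cognitive decline: fewer
#' streamlines and lower FA, higher MD.
#'
#' @param affected_edges Two-column matrix of node pairs `(i, j)`, `i < j`,
#'   or `NULL` to let [generate_cohort()] draw `n_affected` edges from the
#'   topology.
#' @param effect_fn,effect_fa,effect_md Signed shifts in between-subject SD
#'   units.
#' @param n_affected Number of edges drawn when `affected_edges` is `NULL`.
#' @return A `group_effect_spec` list.
#' @export
group_effect_spec <- function(affected_edges = NULL, effect_fn = -1,
                              effect_fa = -1, effect_md = 1,
                              n_affected = 12L) {
  if (!is.null(affected_edges)) {
    affected_edges <- as.matrix(affected_edges)
    if (ncol(affected_edges) != 2 || any(affected_edges[, 1] >= affected_edges[, 2]))
      stop("affected_edges must be pairs (i, j) with i < j")
  }
  structure(list(affected_edges = affected_edges, effect_fn = effect_fn,
                 effect_fa = effect_fa, effect_md = effect_md,
                 n_affected = as.integer(n_affected)),
            class = "group_effect_spec")
}

#' Synthetic cohort configuration
#'
#' @param n_nodes Nodes per network (default 90, the AAL cerebrum).
#' @param density Edge density of the shared topology in (0, 1]; 0.15 is a
#'   typical deterministic-tractography connectome density at 90 nodes.
#' @param n_per_group Subjects in the control (-1) and patient (+1) group.
#' @param noise_sd Length-3 positive multipliers of the nominal
#'   between-subject SD per weight kind (FN, FA, MD).
#' @param effect A [group_effect_spec()].
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_nodes = 90L, density = 0.15,
                          n_per_group = c(40L, 40L),
                          noise_sd = c(fn = 1, fa = 1, md = 1),
                          effect = group_effect_spec(), seed = 1L) {
  stopifnot(density > 0, density <= 1, all(n_per_group >= 1),
            length(noise_sd) == 3, all(noise_sd > 0))
  structure(list(n_nodes = as.integer(n_nodes), density = density,
                 n_per_group = as.integer(n_per_group),
                 noise_sd = as.numeric(noise_sd), effect = effect,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# deterministic sub-stream seeds below 2^31, one per generator stage
.sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7 + k * 1000003) %% 2147483629)
}

# nominal between-subject SDs; FN scales with the edge's baseline count
.kind_sd <- function(fn_base) {
  list(fn = pmax(0.15 * fn_base, 0.5), fa = 0.04, md = 0.04e-3)
}

#' Generate a labeled cohort of co-topological multi-weight connectomes
#'
#' All subjects share one random binary topology at the configured density.
#' Per-edge baselines are drawn once (FN lognormal counts, FA in
#' (0.2, 0.8), MD near 0.7e-3 mm^2/s) and each subject adds independent
#' Gaussian noise per edge and weight kind. Patients (+1) additionally
#' receive the signed effect shifts on the affected edges, expressed in
#' between-subject SD units so that the standardized group difference
#' equals the requested effect size. Values are kept physical: FN rounded
#' to counts >= 1, FA clamped to (0, 1], MD kept positive.
#'
#' Sub-streams (topology, affected-edge draw, baselines, noise) use seeds
#' derived deterministically from `config$seed`, so e.g. the topology is
#' reproducible independently of the cohort size.
#'
#' @param config A [cohort_config()].
#' @param topology_jitter Fraction in [0, 1) of support edges toggled
#'   per subject (adds/removes that fraction of present/absent edges) for
#'   robustness experiments; 0 keeps the strict shared topology.
#' @return List of `list(connectome, label)`, controls first, with
#'   attributes `topology` (edge matrix), `affected_edges` and `config`.
#' @export
generate_cohort <- function(config, topology_jitter = 0) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_nodes
  npairs <- n * (n - 1) / 2
  m <- max(1L, round(config$density * npairs))
  prov <- feature_provenance(n)[seq_len(npairs), c("i", "j")]

  set.seed(.sub_seed(config$seed, 1))
  sup <- sort(sample.int(npairs, m))
  edges <- as.matrix(prov[sup, ])

  eff <- config$effect
  if (is.null(eff$affected_edges)) {
    if (eff$n_affected > m)
      stop("density too low to host the requested number of affected edges")
    set.seed(.sub_seed(config$seed, 2))
    aff_rows <- sort(sample.int(m, eff$n_affected))
  } else {
    key <- paste(edges[, 1], edges[, 2])
    aff_rows <- match(paste(eff$affected_edges[, 1], eff$affected_edges[, 2]), key)
    if (anyNA(aff_rows)) stop("affected_edges must lie within the topology support")
  }

  set.seed(.sub_seed(config$seed, 3))
  base_fn <- pmax(1, round(stats::rlnorm(m, meanlog = log(30), sdlog = 1)))
  base_fa <- 0.2 + 0.6 * stats::rbeta(m, 2, 2)
  base_md <- pmax(0.3e-3, stats::rnorm(m, 0.7e-3, 0.05e-3))
  sds <- .kind_sd(base_fn)
  sd_fn <- sds$fn * config$noise_sd[1]
  sd_fa <- sds$fa * config$noise_sd[2]
  sd_md <- sds$md * config$noise_sd[3]

  labels <- rep(c(-1, 1), times = config$n_per_group)
  set.seed(.sub_seed(config$seed, 4))
  cohort <- lapply(seq_along(labels), function(s) {
    is_pat <- labels[s] == 1
    shift <- function(effect, sd_vec) {
      sh <- numeric(m)
      if (is_pat) sh[aff_rows] <- effect * (if (length(sd_vec) > 1)
        sd_vec[aff_rows] else sd_vec)
      sh
    }
    v_fn <- base_fn + stats::rnorm(m, 0, sd_fn) + shift(eff$effect_fn, sd_fn)
    v_fa <- base_fa + stats::rnorm(m, 0, sd_fa) + shift(eff$effect_fa, sd_fa)
    v_md <- base_md + stats::rnorm(m, 0, sd_md) + shift(eff$effect_md, sd_md)
    v_fn <- pmax(1, round(v_fn))
    v_fa <- pmin(1, pmax(0.01, v_fa))
    v_md <- pmax(1e-5, v_md)
    keep <- rep(TRUE, m)
    extra <- NULL
    if (topology_jitter > 0) {
      n_tog <- round(topology_jitter * m)
      if (n_tog > 0) {
        keep[sample.int(m, n_tog)] <- FALSE
        absent <- setdiff(seq_len(npairs), sup)
        if (length(absent) > 0) {
          add <- sample(absent, min(n_tog, length(absent)))
          extra <- as.matrix(prov[add, , drop = FALSE])
        }
      }
    }
    mk <- function(v, fill) {
      mm <- matrix(0, n, n)
      mm[edges[keep, , drop = FALSE]] <- v[keep]
      if (!is.null(extra)) mm[extra] <- fill(nrow(extra))
      mm + t(mm)
    }
    cx <- multiweight_connectome(
      mk(v_fn, function(k) pmax(1, round(stats::rlnorm(k, log(30), 1)))),
      mk(v_fa, function(k) 0.2 + 0.6 * stats::rbeta(k, 2, 2)),
      mk(v_md, function(k) pmax(0.3e-3, stats::rnorm(k, 0.7e-3, 0.05e-3))))
    list(connectome = cx, label = labels[s])
  })
  attr(cohort, "topology") <- edges
  attr(cohort, "affected_edges") <- edges[aff_rows, , drop = FALSE]
  attr(cohort, "config") <- config
  cohort
}

#' Generate a streamline phantom realizing requested endpoint-pair counts
#'
#' Regions are contiguous slabs along the x axis of a small volume (the top
#' z slice is background); FA and MD are smooth sinusoidal fields within
#' physical ranges. For every requested node pair exactly `count` straight
#' streamlines are laid from a voxel in one region to a voxel in the other,
#' so [build_networks()] on the result reproduces the request table in its
#' FN matrix.
#'
#' @param n_regions Number of regions (>= 2).
#' @param pair_counts Data frame with columns `i`, `j`, `count`
#'   (`i < j <= n_regions`, counts >= 0), or `NULL` for no streamlines.
#' @param seed Integer seed (varies streamline offsets only).
#' @return A [streamline_phantom()].
#' @export
generate_phantom <- function(n_regions, pair_counts = NULL, seed = 1L) {
  stopifnot(n_regions >= 2)
  w <- 3L                       # slab width per region
  dm <- c(w * n_regions, 6L, 6L)
  lab <- array(0L, dm)
  for (r in seq_len(n_regions))
    lab[((r - 1) * w + 1):(r * w), , 1:5] <- r
  xg <- array(rep(seq_len(dm[1]), times = dm[2] * dm[3]), dm)
  yg <- array(rep(rep(seq_len(dm[2]), each = dm[1]), times = dm[3]), dm)
  zg <- array(rep(seq_len(dm[3]), each = dm[1] * dm[2]), dm)
  fa <- array(pmin(0.95, pmax(0.05, 0.4 + 0.2 * sin(xg / 5) +
                                0.1 * cos(yg / 3))), dm)
  md <- array((0.65 + 0.1 * sin(xg / 7 + zg / 4)) * 1e-3, dm)
  sl <- list()
  if (!is.null(pair_counts) && nrow(pair_counts) > 0) {
    if (any(pair_counts$j > n_regions) || any(pair_counts$i >= pair_counts$j))
      stop("pair_counts must have i < j <= n_regions")
    set.seed(seed)
    for (r in seq_len(nrow(pair_counts))) {
      i <- pair_counts$i[r]; j <- pair_counts$j[r]
      cnt <- pair_counts$count[r]
      if (cnt < 1) next
      for (t in seq_len(cnt)) {
        y <- sample.int(dm[2], 1); z <- sample.int(5L, 1)
        xs <- ((i - 1) * w + 2):((j - 1) * w + 2)
        sl[[length(sl) + 1]] <- cbind(xs, y, z, deparse.level = 0)
      }
    }
  }
  streamline_phantom(lab, fa, md, sl)
}

#' Simulate a cohort and write it in the on-disk connectome dialect
#'
#' Writes per-subject FN/FA/MD matrix files, a `manifest.csv`
#' (subject_id, group, fn_path, fa_path, md_path) and a `config.json`
#' recording the resolved configuration and seed.
#'
#' @param config A [cohort_config()].
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
simulate_to_dir <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(config)
  ids <- sprintf("sub_%03d", seq_along(cohort))
  rows <- lapply(seq_along(cohort), function(s) {
    p <- file.path(dir, paste0(ids[s], c("_fn.txt", "_fa.txt", "_md.txt")))
    write_connectome(cohort[[s]]$connectome, p[1], p[2], p[3])
    data.frame(subject_id = ids[s], group = cohort[[s]]$label,
               fn_path = basename(p[1]), fa_path = basename(p[2]),
               md_path = basename(p[3]))
  })
  man <- do.call(rbind, rows)
  man_path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, man_path, row.names = FALSE)
  cfg <- attr(cohort, "config")
  jsonlite::write_json(
    list(n_nodes = cfg$n_nodes, density = cfg$density,
         n_per_group = cfg$n_per_group, noise_sd = cfg$noise_sd,
         effect = cfg$effect[c("effect_fn", "effect_fa", "effect_md",
                               "n_affected")],
         affected_edges = attr(cohort, "affected_edges"),
         seed = cfg$seed),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  invisible(man_path)
}
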