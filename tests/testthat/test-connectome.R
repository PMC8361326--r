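test_that("connectome invariants are enforced", {
  fn <- matrix(0, 3, 3); fn[1, 2] <- fn[2, 1] <- 2
  fa <- matrix(0, 3, 3); fa[1, 2] <- fa[2, 1] <- 0.5
  md <- matrix(0, 3, 3); md[1, 2] <- md[2, 1] <- 0.7e-3
  expect_s3_class(multiweight_connectome(fn, fa, md), "multiweight_connectome")

  bad_fa <- fa; bad_fa[1, 3] <- bad_fa[3, 1] <- 0.4  # support mismatch
  expect_error(multiweight_connectome(fn, bad_fa, md), "topology")
  asym <- fn; asym[1, 2] <- 3
  expect_error(multiweight_connectome(asym, fa, md), "symmetric")
  over <- fa; over[1, 2] <- over[2, 1] <- 1.5
  expect_error(multiweight_connectome(fn, over, md), "fa entries")
  diag_fn <- fn; diag(diag_fn) <- 1
  expect_error(multiweight_connectome(diag_fn, fa, md), "diagonal")
})

test_that("build_networks computes FN counts and voxel-set FA/MD means", {
  ph <- generate_phantom(4, data.frame(i = 1, j = 2, count = 2), seed = 3)
  cx <- build_networks(ph, 4)
  expect_equal(cx$fn[1, 2], 2)
  # voxel-enumeration oracle: endpoints + traversed voxels, deduplicated
  lin <- function(v) v[, 1] + dim(ph$label_volume)[1] * (v[, 2] - 1) +
    prod(dim(ph$label_volume)[1:2]) * (v[, 3] - 1)
  vox <- unique(unlist(lapply(ph$streamlines, lin)))
  expect_equal(cx$fa[1, 2], mean(ph$fa_volume[vox]))
  expect_equal(cx$md[1, 2], mean(ph$md_volume[vox]))
  expect_true(all(cx$fn[-c(2, 5)] == 0))   # only (1,2)/(2,1) populated
  # multiset reading weights voxels by visit count
  cx2 <- build_networks(ph, 4, voxel_multiset = TRUE)
  vox_all <- unlist(lapply(ph$streamlines, lin))
  expect_equal(cx2$fa[1, 2], mean(ph$fa_volume[vox_all]))
})

test_that("self-connections and background endpoints are excluded", {
  ph <- generate_phantom(3, NULL, seed = 1)
  dm <- dim(ph$label_volume)
  sl_self <- cbind(1:2, 1, 1)                 # both endpoints in region 1
  sl_bg <- rbind(c(1, 1, dm[3]), c(4, 1, 1))  # starts in background (z top)
  ph2 <- streamline_phantom(ph$label_volume, ph$fa_volume, ph$md_volume,
                            list(sl_self, sl_bg))
  cx <- build_networks(ph2, 3)
  expect_true(all(cx$fn == 0))
  expect_equal(attr(cx, "n_skipped"), 1L)
  # empty streamline list is a valid all-zero connectome
  cx0 <- build_networks(generate_phantom(3, NULL), 3)
  expect_true(all(cx0$fn == 0) && all(cx0$fa == 0) && all(cx0$md == 0))
})

test_that("fn totals equal accepted streamlines and match the request table", {
  set.seed(5)
  req <- expand.grid(i = 1:4, j = 1:5)
  req <- req[req$i < req$j, ]
  req$count <- sample(0:3, nrow(req), replace = TRUE)
  ph <- generate_phantom(5, req, seed = 9)
  cx <- build_networks(ph, 5)
  expect_equal(sum(cx$fn[upper.tri(cx$fn)]), sum(req$count))
  for (r in seq_len(nrow(req)))
    expect_equal(cx$fn[req$i[r], req$j[r]], req$count[r])
  validate_connectome(cx)
})

test_that("relabeling regions permutes all three matrices consistently", {
  req <- data.frame(i = c(1, 1, 2), j = c(2, 3, 3), count = c(2, 1, 3))
  ph <- generate_phantom(3, req, seed = 2)
  cx <- build_networks(ph, 3)
  perm <- c(3L, 1L, 2L)   # region r renamed perm[r]
  lab2 <- array(c(0L, perm)[ph$label_volume + 1L], dim(ph$label_volume))
  ph2 <- streamline_phantom(lab2, ph$fa_volume, ph$md_volume, ph$streamlines)
  cx2 <- build_networks(ph2, 3)
  inv <- order(perm)
  for (k in c("fn", "fa", "md"))
    expect_equal(cx2[[k]][perm, perm], cx[[k]])
})

test_that("vectorization follows the canonical order and round-trips", {
  # 4-node toy, manual upper-triangle enumeration (1,2),(1,3),(1,4),(2,3),(2,4),(3,4)
  fn <- matrix(0, 4, 4); fa <- matrix(0, 4, 4); md <- matrix(0, 4, 4)
  pairs <- rbind(c(1, 2), c(1, 4), c(2, 3), c(3, 4))
  fn[pairs] <- c(5, 2, 7, 1); fn <- fn + t(fn)
  fa[pairs] <- c(0.5, 0.3, 0.8, 0.2); fa <- fa + t(fa)
  md[pairs] <- c(0.7, 0.6, 0.9, 0.8) * 1e-3; md <- md + t(md)
  cx <- multiweight_connectome(fn, fa, md)
  cx0 <- multiweight_connectome(fn * 0, fa * 0, md * 0)
  tab <- vectorize_cohort(list(list(connectome = cx, label = 1),
                               list(connectome = cx0, label = -1)))
  expect_equal(ncol(tab$features), 3 * 6)
  expect_equal(unname(tab$features[1, 1:6]), c(5, 0, 2, 7, 0, 1))
  expect_equal(unname(tab$features[2, ]), rep(0, 18))
  expect_equal(tab$provenance$network, rep(c("FN", "FA", "MD"), each = 6))
  back <- devectorize_subject(tab, 1)
  expect_equal(back$fn, fn); expect_equal(back$fa, fa); expect_equal(back$md, md)
})

test_that("vectorization rejects mixed sizes and bad labels", {
  tab <- toy_cohort_tab(n_nodes = 8, n_per_group = c(3, 3), seed = 2,
                        n_affected = 2)
  co8 <- devectorize_subject(tab, 1)
  fn <- matrix(0, 5, 5)
  co5 <- multiweight_connectome(fn, fn, fn)
  expect_error(vectorize_cohort(list(list(connectome = co8, label = 1),
                                     list(connectome = co5, label = -1))),
               "n_nodes")
  expect_error(vectorize_cohort(list(list(connectome = co8, label = 1),
                                     list(connectome = co8, label = 2))),
               "label")
})

test_that("connectome, manifest and feature-table files round-trip", {
  dir <- withr::local_tempdir()
  cfg <- cohort_config(n_nodes = 10, density = 0.4, n_per_group = c(3, 3),
                       effect = group_effect_spec(n_affected = 2), seed = 5)
  man_path <- simulate_to_dir(cfg, dir)
  man <- read_manifest(man_path)
  expect_length(man$cohort, 6)
  co <- generate_cohort(cfg)
  for (s in seq_along(co))
    expect_equal(man$cohort[[s]]$connectome$fn, co[[s]]$connectome$fn)
  tab <- vectorize_cohort(man$cohort, man$subject_ids)
  csv <- file.path(dir, "features.csv")
  write_feature_csv(tab, csv)
  tab2 <- read_feature_csv(csv)
  expect_equal(tab2$features, tab$features, tolerance = 1e-7)
  expect_equal(tab2$labels, tab$labels)
})

test_that("JSON phantom serialization round-trips", {
  req <- data.frame(i = c(1, 2), j = c(2, 3), count = c(2, 1))
  ph <- generate_phantom(3, req, seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_phantom_json(ph, path)
  ph2 <- read_phantom_json(path)
  expect_equal(ph2$label_volume, ph$label_volume)
  expect_equal(ph2$fa_volume, ph$fa_volume)
  expect_equal(length(ph2$streamlines), length(ph$streamlines))
  cx <- build_networks(ph, 3); cx2 <- build_networks(ph2, 3)
  expect_equal(cx2$fa, cx$fa)
})
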