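test_that("scaler uses train statistics only", {
  set.seed(4)
  Xtr <- matrix(rnorm(40, mean = 3, sd = 2), 10)
  Xtr[, 2] <- 7                       # constant feature
  sc <- fit_scaler(Xtr)
  Ztr <- apply_scaler(Xtr, sc)
  expect_equal(colMeans(Ztr), rep(0, 4), tolerance = 1e-12)
  expect_equal(apply(Ztr[, -2], 2, sd), rep(1, 3), tolerance = 1e-12)
  expect_equal(Ztr[, 2], rep(0, 10))
  Xte <- matrix(rnorm(8, mean = -1), 2)
  Zte <- apply_scaler(Xte, sc)
  # constant train feature: test value is (x - mean)/1
  expect_equal(Zte[, 2], Xte[, 2] - 7)
  # scaling test rows with their own stats would differ (leakage contract)
  Zte_own <- apply_scaler(Xte, fit_scaler(Xte))
  expect_false(isTRUE(all.equal(Zte, Zte_own)))
  expect_error(fit_scaler(Xtr[1, , drop = FALSE]), "at least 2")
})

test_that("confusion metrics implement the three ratio definitions", {
  m <- confusion_metrics(5, 0, 5, 0)
  expect_equal(unlist(m), c(accuracy = 1, sensitivity = 1, specificity = 1))
  m2 <- confusion_metrics(42, 9, 43, 8)
  expect_equal(round(unlist(m2), 3),
               c(accuracy = 0.833, sensitivity = 0.824, specificity = 0.843))
  expect_error(confusion_metrics(0, 0, 3, 1), "at least one subject")
  expect_error(confusion_metrics(-1, 1, 1, 1), "non-negative")
})

test_that("rank-statistic AUC matches brute-force pairwise counting", {
  set.seed(20)
  for (t in 1:10) {
    y <- balanced_labels(20)[sample(20)]
    s <- round(rnorm(20), 1)          # rounding forces some ties
    got <- roc_auc(s, y)$auc
    pos <- s[y == 1]; neg <- s[y == -1]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(got, mean(cmp))
  }
  expect_equal(roc_auc(c(3, 4, 1, 2), c(1, 1, -1, -1))$auc, 1)
  expect_equal(roc_auc(rep(1, 6), balanced_labels(6))$auc, 0.5)
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(26)
  y <- balanced_labels(18)[sample(18)]
  s <- rnorm(18)
  a1 <- roc_auc(s, y)$auc
  expect_equal(roc_auc(exp(2 * s) + 3, y)$auc, a1)
  expect_equal(roc_auc(rank(s), y)$auc, a1)
})

test_that("LOOCV holds out each subject exactly once and is leakage-safe", {
  tab <- toy_cohort_tab(n_nodes = 10, n_per_group = c(6, 6), effect_md = 1,
                        n_affected = 3, seed = 44)
  rep <- loocv(tab, C = 1, count_or_fraction = 5)
  expect_length(rep$folds, 12)
  expect_setequal(vapply(rep$folds, `[[`, character(1), "test_subject_id"),
                  tab$subject_ids)
  expect_equal(sum(rep$counts), 12)
  expect_equal(rep$accuracy * 12, rep$counts[["TP"]] + rep$counts[["TN"]])
  # corrupting the held-out subject's features must not change the fold model
  i <- 3L
  tr <- setdiff(seq_len(12), i)
  f1 <- mklconn:::.fit_fold(tab, tr, i, 1, 5, kernel_spec("linear"),
                            "fscore", "multi_kernel")
  tab2 <- tab
  tab2$features[i, ] <- tab2$features[i, ] * 50 + 1000
  f2 <- mklconn:::.fit_fold(tab2, tr, i, 1, 5, kernel_spec("linear"),
                            "fscore", "multi_kernel")
  expect_identical(f2$model$alpha, f1$model$alpha)
  expect_identical(f2$model$beta, f1$model$beta)
  expect_identical(f2$selected, f1$selected)
})

test_that("a wide-margin synthetic effect yields perfect LOOCV accuracy", {
  tab <- toy_cohort_tab(n_nodes = 12, n_per_group = c(8, 8), effect_md = 4,
                        n_affected = 6, seed = 10)
  rep <- loocv(tab, C = 1, count_or_fraction = 6)
  expect_equal(rep$accuracy, 1)
  expect_equal(rep$auc, 1)
})

test_that("permuted labels give chance-level accuracy", {
  tab <- toy_cohort_tab(n_nodes = 10, n_per_group = c(12, 12), effect_md = 0,
                        n_affected = 1, seed = 77)
  set.seed(123)
  accs <- replicate(15, {
    tab2 <- tab
    tab2$labels <- sample(tab$labels)
    loocv(tab2, C = 1, count_or_fraction = 4)$accuracy
  })
  # mean over permutations sits near 0.5 (LOOCV is slightly pessimistic
  # under the null because the held-out class is the training minority)
  expect_gt(mean(accs), 0.38)
  expect_lt(mean(accs), 0.62)
})

test_that("all evaluation modes run and agree on the fold structure", {
  tab <- toy_cohort_tab(n_nodes = 10, n_per_group = c(5, 5), effect_md = 2,
                        n_affected = 3, seed = 91)
  for (mode in c("multi_kernel", "single_kernel_fused",
                 "single_network:MD", "single_network:FA")) {
    rep <- loocv(tab, C = 1, count_or_fraction = 4, mode = mode)
    expect_length(rep$folds, 10)
    if (mode == "multi_kernel")
      expect_length(rep$folds[[1]]$beta, 3)
    else
      expect_length(rep$folds[[1]]$beta, 1)
  }
  expect_error(loocv(tab, mode = "nope"), "unknown mode")
})

test_that("lasso-based LOOCV runs end to end", {
  tab <- toy_cohort_tab(n_nodes = 8, n_per_group = c(6, 6), effect_md = 3,
                        n_affected = 4, seed = 15)
  rep <- loocv(tab, C = 1, selection = "lasso", seed = 2)
  expect_length(rep$folds, 12)
  expect_gte(rep$accuracy, 0.5)
})

test_that("default grids reproduce the documented search space", {
  cg <- default_c_grid()
  fg <- default_fraction_grid()
  expect_length(cg, 10)
  expect_equal(range(cg), c(0.5, 5))
  expect_equal(diff(cg), rep(0.5, 9))
  expect_length(fg, 29)
  expect_equal(range(fg), c(0.0014, 0.0028))
  expect_equal(diff(fg), rep(0.00005, 28), tolerance = 1e-12)
})

test_that("grid-search surface cells equal independently run LOOCVs", {
  tab <- toy_cohort_tab(n_nodes = 8, n_per_group = c(5, 5), effect_md = 2,
                        n_affected = 3, seed = 52)
  gs <- grid_search(tab, c_grid = c(0.5, 1), fraction_grid = c(3, 6))
  expect_equal(nrow(gs$surface), 4)
  cell <- gs$surface[gs$surface$C == 1 & gs$surface$fraction == 6, ]
  indep <- loocv(tab, C = 1, count_or_fraction = 6)
  expect_equal(cell$accuracy, indep$accuracy)
  expect_equal(cell$auc, indep$auc)
  expect_gte(gs$best$accuracy, max(gs$surface$accuracy) - 1e-12)
})
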