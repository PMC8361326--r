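test_that("kernel evaluations match closed forms", {
  I2 <- diag(2)
  expect_equal(compute_kernel(I2, I2, kernel_spec("linear")), I2)
  X <- matrix(rnorm(12), 4)
  Kr <- compute_kernel(X, X, kernel_spec("rbf", gamma = 0.7))
  expect_equal(diag(Kr), rep(1, 4))
  expect_true(all(Kr <= 1 + 1e-12))
  # polynomial degree 3, coef0 1, inner product 1 -> (1+1)^3 = 8
  expect_equal(compute_kernel(matrix(1), matrix(1),
                              kernel_spec("polynomial"))[1, 1], 8)
  expect_error(compute_kernel(matrix(1, 2, 3), matrix(1, 2, 2),
                              kernel_spec("linear")), "column counts")
})

test_that("SMO solves the separable two-point problem analytically", {
  K <- matrix(c(1, -1, -1, 1), 2)
  s <- train_svm(K, c(1, -1), C = 10)
  expect_equal(s$alpha, c(0.5, 0.5), tolerance = 1e-8)
  expect_equal(s$bias, 0, tolerance = 1e-8)
  expect_equal(s$objective, 0.5, tolerance = 1e-8)
})

test_that("SMO iterates are always dual-feasible", {
  set.seed(33)
  for (t in 1:15) {
    n <- sample(8:25, 1)
    y <- balanced_labels(n)[sample(n)]
    K <- rand_linear_kernel(n)
    C <- runif(1, 0.2, 5)
    s <- train_svm(K, y, C)
    expect_lt(abs(sum(s$alpha * y)), 1e-8)
    expect_true(all(s$alpha >= -1e-12 & s$alpha <= C + 1e-12))
    expect_true(s$converged)
  }
})

test_that("indefinite kernels are rejected with a diagnostic", {
  K <- diag(c(1, 1, -1))
  expect_error(train_svm(K, c(1, -1, 1), 1), "positive semidefinite")
})

test_that("single-kernel MKL degenerates to the plain SVM", {
  set.seed(7)
  n <- 14
  y <- balanced_labels(n)
  K <- rand_linear_kernel(n)
  m1 <- train_mkl(list(K), y, C = 2)
  s <- train_svm(K, y, C = 2)
  expect_equal(m1$beta, 1)
  expect_equal(m1$objective, s$objective, tolerance = 1e-8)
  expect_equal(m1$alpha, s$alpha, tolerance = 1e-6)
})

test_that("identical kernels leave the objective and decisions invariant", {
  set.seed(17)
  n <- 16
  y <- balanced_labels(n)
  K <- rand_linear_kernel(n)
  m2 <- train_mkl(list(K, K), y, C = 1)
  s <- train_svm(K, y, C = 1)
  expect_equal(m2$objective, s$objective, tolerance = 1e-6)
  expect_equal(sum(m2$beta), 1, tolerance = 1e-12)
  # mixed kernel is K for any beta split, so decision values match
  f_mkl <- K %*% (m2$alpha * y) + m2$bias
  f_svm <- K %*% (s$alpha * y) + s$bias
  expect_equal(as.numeric(f_mkl), as.numeric(f_svm), tolerance = 1e-5)
})

test_that("MKL puts its weight on the informative kernel", {
  set.seed(55)
  n <- 30
  y <- balanced_labels(n)[sample(n)]
  Xi <- matrix(rnorm(n * 4), n) + outer(y, rep(1.5, 4))  # separates classes
  Xn <- Xi[sample(n), ]                                   # label-permuted noise
  Ki <- tcrossprod(Xi) / mean(diag(tcrossprod(Xi)))
  Kn <- tcrossprod(Xn) / mean(diag(tcrossprod(Xn)))
  m <- train_mkl(list(Ki, Kn), y, C = 1)
  expect_gte(m$beta[1], 0.9)
  expect_true(all(diff(m$objective_history) <= 1e-8))
})

test_that("MKL objective history is monotone non-increasing", {
  set.seed(71)
  n <- 20
  y <- balanced_labels(n)[sample(n)]
  ks <- lapply(1:3, function(i) rand_linear_kernel(n))
  m <- train_mkl(ks, y, C = 1.5)
  expect_true(all(diff(m$objective_history) <= 1e-8))
  expect_true(all(m$beta >= 0))
  expect_equal(sum(m$beta), 1, tolerance = 1e-10)
})

test_that("decision values expand exactly as the dual decision function", {
  set.seed(5)
  rows <- list(matrix(rnorm(6), 3), matrix(rnorm(9), 3))
  y <- c(1, 1, -1)
  model <- fit_mkl_model(rows, y, C = 5, kernel_spec("linear"))
  te <- list(matrix(rnorm(4), 2), matrix(rnorm(6), 2))
  f <- decision_values(model, te)
  # manual expansion: sum_i alpha_i y_i sum_m beta_m k_m(x_i, x) + b
  f_manual <- vapply(1:2, function(q) {
    s <- model$bias
    for (i in 1:3) {
      km <- 0
      for (m in 1:2)
        km <- km + model$beta[m] *
          sum(rows[[m]][i, ] * te[[m]][q, ]) / model$norm_factors[m]
      s <- s + model$alpha[i] * y[i] * km
    }
    s
  }, numeric(1))
  expect_equal(f, f_manual, tolerance = 1e-10)
  # separable training data classify themselves correctly
  ftr <- decision_values(model, rows)
  expect_equal(predict_labels(ftr), y)
})

test_that("duplicating a network leaves decision values unchanged", {
  set.seed(23)
  X <- matrix(rnorm(20 * 3), 20)
  y <- balanced_labels(20)[sample(20)]
  m1 <- fit_mkl_model(list(X), y, C = 1, kernel_spec("linear"))
  m2 <- fit_mkl_model(list(X, X), y, C = 1, kernel_spec("linear"))
  te <- list(matrix(rnorm(9), 3))
  expect_equal(decision_values(m2, list(te[[1]], te[[1]])),
               decision_values(m1, te), tolerance = 1e-5)
})

test_that("linear primal weights reproduce the decision values", {
  set.seed(9)
  rows <- list(matrix(rnorm(24), 8), matrix(rnorm(16), 8))
  y <- balanced_labels(8)
  model <- fit_mkl_model(rows, y, C = 2, kernel_spec("linear"))
  w <- primal_weights_linear(model)
  te <- list(matrix(rnorm(6), 2), matrix(rnorm(4), 2))
  f_w <- model$bias +
    model$beta[1] * (te[[1]] %*% w[[1]]) + model$beta[2] * (te[[2]] %*% w[[2]])
  expect_equal(as.numeric(f_w), decision_values(model, te), tolerance = 1e-10)
})

test_that("only the separating coordinate receives primal weight", {
  X <- cbind(c(1, 1, -1, -1), 0)       # coordinate 2 carries nothing
  y <- c(1, 1, -1, -1)
  model <- fit_mkl_model(list(X), y, C = 10, kernel_spec("linear"))
  w <- primal_weights_linear(model)[[1]]
  expect_gt(abs(w[1]), 0.1)
  expect_equal(w[2], 0, tolerance = 1e-10)
})

test_that("primal weights are refused for nonlinear kernels", {
  set.seed(2)
  X <- matrix(rnorm(30), 10)
  y <- balanced_labels(10)
  model <- fit_mkl_model(list(X), y, C = 1, kernel_spec("rbf"))
  expect_error(primal_weights_linear(model), "linear")
})

test_that("a network with no selected features is dropped and beta renormalized", {
  set.seed(13)
  rows <- list(matrix(rnorm(30), 10), matrix(numeric(0), 10, 0))
  y <- balanced_labels(10)
  model <- fit_mkl_model(rows, y, C = 1, kernel_spec("linear"),
                         network_kinds = c("FN", "MD"))
  expect_equal(model$beta[2], 0)
  expect_equal(sum(model$beta), 1)
})

test_that("model JSON serialization round-trips decision values exactly", {
  set.seed(3)
  rows <- list(matrix(rnorm(40), 10), matrix(rnorm(20), 10))
  y <- balanced_labels(10)[sample(10)]
  model <- fit_mkl_model(rows, y, C = 1.5, kernel_spec("rbf"),
                         selected_per_network = list(1:4, 5:6),
                         network_kinds = c("FN", "MD"),
                         scaler = list(mean = rep(0, 6), sd = rep(1, 6)))
  path <- withr::local_tempfile(fileext = ".json")
  write_mkl_model(model, path)
  model2 <- read_mkl_model(path)
  te <- list(matrix(rnorm(8), 2), matrix(rnorm(4), 2))
  expect_identical(decision_values(model2, te), decision_values(model, te))
  expect_identical(model2$alpha, model$alpha)
  expect_identical(model2$beta, model$beta)
  expect_equal(model2$selected_per_network, list(1:4, 5:6))
})
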