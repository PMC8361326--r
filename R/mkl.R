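#' Train a multiple-kernel SVM with simplex-constrained kernel weights
#'
#' Learns non-negative kernel weights `beta` summing to 1 together with the
#' SVM dual variables, for the mixed kernel
#' \eqn{k(x_i, x_j) = \sum_m \beta_m k^{(m)}(x_i^{(m)}, x_j^{(m)})}.
#' Alternating optimization: for fixed `beta` the single-kernel dual on the
#' mixed kernel is solved by SMO; `beta` is then updated by a reduced
#' gradient step on the probability simplex with an Armijo backtracking
#' line search (the simpleMKL scheme). The objective `J(beta)` (the dual
#' optimum at `beta`) is convex and is minimized; iterations stop when the
#' `beta` change falls below `tol_beta`, the objective change below
#' `tol_obj`, or after `max_outer` iterations (then the best iterate is
#' returned with a warning).
#'
#' @param kernels List of `M >= 1` square symmetric PSD kernel matrices of
#'   identical shape.
#' @param labels -1/+1 vector.
#' @param C Positive box constraint.
#' @param tol_beta,tol_obj,max_outer Outer-loop stopping parameters.
#' @param svm_tol KKT tolerance of the inner SMO solves.
#' @return List with `alpha`, `bias`, `beta`, `objective`,
#'   `objective_history`, `iterations`, `converged`.
#' @export
train_mkl <- function(kernels, labels, C, tol_beta = 1e-4, tol_obj = 1e-5,
                      max_outer = 200L, svm_tol = 1e-8) {
  M <- length(kernels)
  if (M < 1) stop("at least one kernel is required")
  y <- as.numeric(labels)
  n <- length(y)
  for (K in kernels) {
    K <- as.matrix(K)
    if (nrow(K) != n || ncol(K) != n) stop("kernel/label dimension mismatch")
    if (max(abs(K - t(K))) > 1e-6) stop("kernel matrix is not symmetric")
    ev <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-6 * max(1, max(abs(K))))
      stop("kernel matrix is not positive semidefinite within tolerance")
  }
  kernels <- lapply(kernels, as.matrix)
  mix <- function(beta) Reduce(`+`, Map(function(b, K) b * K, beta, kernels))

  beta <- rep(1 / M, M)
  sol <- .svm_objective(mix(beta), y, C, svm_tol)
  J <- sol$objective
  hist <- J
  converged <- M == 1L
  it <- 0L
  while (!converged && it < max_outer) {
    it <- it + 1L
    ay <- sol$alpha * y
    grad <- -0.5 * vapply(kernels, function(K)
      as.numeric(crossprod(ay, K %*% ay)), numeric(1))
    mu <- which.max(beta)
    r <- grad - grad[mu]
    D <- -r
    D[beta <= 1e-12 & r > 0] <- 0
    D[mu] <- -sum(D[-mu])
    if (max(abs(D)) < 1e-12) { converged <- TRUE; break }
    neg <- which(D < 0)
    gamma_max <- min(-beta[neg] / D[neg])
    # Armijo backtracking from the full step to the simplex boundary
    gamma <- gamma_max
    slope <- sum(grad * D)      # < 0 along a descent direction
    best <- NULL
    for (k in 1:20) {
      bt <- pmax(beta + gamma * D, 0)
      bt <- bt / sum(bt)
      st <- .svm_objective(mix(bt), y, C, svm_tol, alpha0 = sol$alpha)
      if (st$objective <= J + 1e-4 * gamma * slope) {
        best <- list(beta = bt, sol = st, gamma = gamma); break
      }
      if (is.null(best) || st$objective < best$sol$objective)
        best <- list(beta = bt, sol = st, gamma = gamma)
      gamma <- gamma / 2
    }
    if (best$sol$objective >= J - tol_obj * max(1, abs(J)) &&
        max(abs(best$beta - beta)) < tol_beta) {
      converged <- TRUE
      if (best$sol$objective < J) { beta <- best$beta; sol <- best$sol; J <- sol$objective; hist <- c(hist, J) }
      break
    }
    if (best$sol$objective < J) {
      d_beta <- max(abs(best$beta - beta))
      d_obj <- J - best$sol$objective
      beta <- best$beta; sol <- best$sol; J <- sol$objective
      hist <- c(hist, J)
      if (d_beta < tol_beta || d_obj < tol_obj * max(1, abs(J)))
        converged <- TRUE
    } else converged <- TRUE   # no descent found along the reduced gradient
  }
  if (!converged)
    warning("MKL outer iteration cap reached; returning best iterate")
  bias_sol <- train_svm(mix(beta), y, C, tol = svm_tol, alpha0 = sol$alpha)
  list(alpha = bias_sol$alpha, bias = bias_sol$bias, beta = beta,
       objective = bias_sol$objective, objective_history = hist,
       iterations = it, converged = converged)
}

#' Fit a full multi-kernel model on per-network training rows
#'
#' Computes one kernel per network (each normalized by its mean diagonal
#' entry so the learned weights are comparable across networks of
#' different scales), resolves an `"auto"` RBF gamma to `1/d_m` per
#' network, trains the MKL dual, and packages everything needed to score
#' new subjects. Networks with zero selected features are dropped from the
#' mixture (`beta = 0`) and the remaining weights renormalized.
#'
#' @param rows_per_network List of training matrices (same row count), one
#'   per network, already normalized by the caller's scaler.
#' @param labels -1/+1 vector.
#' @param C Box constraint.
#' @param spec A [kernel_spec()].
#' @param selected_per_network Optional list of global feature indices per
#'   network (stored for provenance).
#' @param network_kinds Character names of the networks.
#' @param scaler Optional scaler (stored for serialization).
#' @param ... Passed to [train_mkl()].
#' @return An object of class `mkl_model`.
#' @export
fit_mkl_model <- function(rows_per_network, labels, C, spec = kernel_spec(),
                          selected_per_network = NULL,
                          network_kinds = NULL, scaler = NULL, ...) {
  M <- length(rows_per_network)
  if (is.null(network_kinds)) network_kinds <- paste0("net", seq_len(M))
  d <- vapply(rows_per_network, ncol, integer(1))
  active <- which(d > 0)
  if (length(active) == 0) stop("no network has any selected feature")
  gammas <- rep(NA_real_, M)
  kernels <- vector("list", length(active))
  norm_factors <- rep(NA_real_, M)
  specs <- vector("list", M)
  for (ii in seq_along(active)) {
    m <- active[ii]
    sp <- spec
    if (sp$kind == "rbf")
      sp$gamma <- if (identical(spec$gamma, "auto")) 1 / d[m] else spec$gamma
    specs[[m]] <- sp
    K <- compute_kernel(rows_per_network[[m]], rows_per_network[[m]], sp)
    norm_factors[m] <- mean(diag(K))
    if (norm_factors[m] <= 0) norm_factors[m] <- 1
    kernels[[ii]] <- K / norm_factors[m]
    if (sp$kind == "rbf") gammas[m] <- sp$gamma
  }
  fit <- train_mkl(kernels, labels, C, ...)
  beta <- numeric(M)
  beta[active] <- fit$beta
  structure(list(
    alpha = fit$alpha, bias = fit$bias, beta = beta, C = C,
    kernel = spec, kernel_per_network = specs,
    norm_factors = norm_factors, network_kinds = network_kinds,
    selected_per_network = selected_per_network,
    scaler = scaler, train_rows = rows_per_network,
    train_labels = as.numeric(labels),
    objective = fit$objective, objective_history = fit$objective_history,
    converged = fit$converged),
    class = "mkl_model")
}

#' @export
print.mkl_model <- function(x, ...) {
  cat(sprintf("mkl_model: %d networks (%s), %d training subjects, C = %g\n",
              length(x$beta), paste(x$network_kinds, collapse = ", "),
              length(x$train_labels), x$C))
  cat("beta:", paste(sprintf("%.3f", x$beta), collapse = " "), "\n")
  invisible(x)
}

#' Decision values of a trained multi-kernel model
#'
#' Evaluates \eqn{f(x) = \sum_i \alpha_i y_i \sum_m \beta_m
#' k^{(m)}(x_i^{(m)}, x^{(m)}) + b} for each test subject. The predicted
#' label is `sign(f(x))` with `sign(0)` defined as +1. Test rows must be on
#' the same (train-statistics) scale as the stored training rows; the
#' caller applies the scaler.
#'
#' @param model An `mkl_model`.
#' @param test_rows_per_network List of test matrices, columns matching the
#'   per-network training rows.
#' @return Numeric vector of decision values.
#' @export
decision_values <- function(model, test_rows_per_network) {
  ay <- model$alpha * model$train_labels
  n_test <- nrow(as.matrix(test_rows_per_network[[which(model$beta > 0)[1]]]))
  f <- rep(model$bias, n_test)
  for (m in seq_along(model$beta)) {
    if (model$beta[m] <= 0) next
    te <- as.matrix(test_rows_per_network[[m]])
    tr <- model$train_rows[[m]]
    if (ncol(te) != ncol(tr))
      stop("test columns do not match the selected features of network ", m)
    Kt <- compute_kernel(te, tr, model$kernel_per_network[[m]]) /
      model$norm_factors[m]
    f <- f + model$beta[m] * as.numeric(Kt %*% ay)
  }
  f
}

#' Predicted -1/+1 labels (sign(0) = +1)
#'
#' @param decision Numeric decision values.
#' @return -1/+1 vector.
#' @export
predict_labels <- function(decision) ifelse(decision >= 0, 1, -1)

#' Hyperplane coefficients of a linear multi-kernel model
#'
#' For a linear kernel the decision function is affine in the input and
#' the per-network hyperplane coefficients are
#' \eqn{w^{(m)} = \sum_i \alpha_i y_i x_i^{(m)}} (divided by the kernel
#' normalization factor so that
#' \eqn{\sum_m \beta_m \langle w^{(m)}, x^{(m)}\rangle + b} reproduces the
#' decision values exactly). The kernel-weight factor `beta` is applied
#' downstream when features are ranked.
#'
#' @param model An `mkl_model` with a linear kernel.
#' @return List of per-network coefficient vectors (length 0 for dropped
#'   networks).
#' @export
primal_weights_linear <- function(model) {
  if (model$kernel$kind != "linear")
    stop("hyperplane coefficients are defined only for the linear kernel")
  ay <- model$alpha * model$train_labels
  lapply(seq_along(model$beta), function(m) {
    tr <- model$train_rows[[m]]
    if (is.null(tr) || ncol(tr) == 0 || model$beta[m] <= 0)
      return(numeric(if (is.null(tr)) 0 else ncol(tr)))
    as.numeric(crossprod(tr, ay)) / model$norm_factors[m]
  })
}

#' Serialize / restore a trained model as JSON
#'
#' Numbers are written at full precision so that a written-and-reread
#' model reproduces decision values bit-exactly.
#'
#' @param model An `mkl_model`.
#' @param path JSON file path.
#' @return `read_mkl_model` returns the restored `mkl_model`.
#' @export
write_mkl_model <- function(model, path) {
  obj <- list(
    alpha = model$alpha, bias = model$bias, beta = model$beta, C = model$C,
    kernel = model$kernel[c("kind", "degree", "gamma", "coef0")],
    gammas = vapply(model$kernel_per_network, function(s)
      if (is.null(s) || !is.numeric(s$gamma)) NA_real_ else s$gamma,
      numeric(1)),
    norm_factors = model$norm_factors,
    network_kinds = model$network_kinds,
    selected_per_network = model$selected_per_network,
    scaler = model$scaler,
    train_rows = lapply(model$train_rows, function(m)
      list(dim = dim(m), data = as.vector(m))),
    train_labels = model$train_labels,
    objective = model$objective)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_mkl_model
#' @export
read_mkl_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- kernel_spec(obj$kernel$kind, obj$kernel$degree,
                      if (identical(obj$kernel$gamma, "auto")) "auto"
                      else as.numeric(obj$kernel$gamma), obj$kernel$coef0)
  specs <- lapply(seq_along(obj$beta), function(m) {
    sp <- spec
    if (sp$kind == "rbf" && !is.na(obj$gammas[m])) sp$gamma <- obj$gammas[m]
    sp
  })
  train_rows <- if (is.data.frame(obj$train_rows)) {
    lapply(seq_len(nrow(obj$train_rows)), function(i)
      matrix(obj$train_rows$data[[i]], obj$train_rows$dim[[i]][1],
             obj$train_rows$dim[[i]][2]))
  } else {
    lapply(obj$train_rows, function(tr)
      matrix(as.numeric(tr$data), tr$dim[1], tr$dim[2]))
  }
  sel <- obj$selected_per_network
  if (!is.null(sel)) sel <- lapply(sel, as.integer)
  structure(list(
    alpha = as.numeric(obj$alpha), bias = obj$bias,
    beta = as.numeric(obj$beta), C = obj$C,
    kernel = spec, kernel_per_network = specs,
    norm_factors = as.numeric(obj$norm_factors),
    network_kinds = obj$network_kinds,
    selected_per_network = sel,
    scaler = if (is.null(obj$scaler)) NULL else
      list(mean = as.numeric(obj$scaler$mean), sd = as.numeric(obj$scaler$sd)),
    train_rows = train_rows,
    train_labels = as.numeric(obj$train_labels),
    objective = obj$objective, objective_history = NULL, converged = TRUE),
    class = "mkl_model")
}
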