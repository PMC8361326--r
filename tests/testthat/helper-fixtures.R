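# Shared fixtures and independent oracles for the suite.

# literal loop transcription of the two-class F-score definition,
# kept deliberately independent of the vectorized implementation
fscore_literal <- function(x, y) {
  xp <- x[y == 1]; xn <- x[y == -1]
  xbar <- mean(x); xbp <- mean(xp); xbn <- mean(xn)
  num <- (xbp - xbar)^2 + (xbn - xbar)^2
  den <- sum((xp - xbp)^2) / (length(xp) - 1) +
    sum((xn - xbn)^2) / (length(xn) - 1)
  if (den == 0) return(if (num > 0) Inf else 0)
  num / den
}

# generic QP solution of the SVM dual via kernlab's interior-point solver
ipop_dual_objective <- function(K, y, C) {
  n <- length(y)
  H <- (y %*% t(y)) * K
  sv <- kernlab::ipop(c = rep(-1, n), H = H, A = matrix(y, 1), b = 0,
                      l = rep(0, n), u = rep(C, n), r = 0,
                      sigf = 8, maxiter = 200)
  a <- kernlab::primal(sv)
  sum(a) - 0.5 * as.numeric(t(a) %*% H %*% a)
}

rand_linear_kernel <- function(n, d = 3, ridge = 1e-8) {
  X <- matrix(stats::rnorm(n * d), n)
  K <- tcrossprod(X)
  # small ridge keeps low-rank kernels full rank so interior-point
  # oracles stay well-conditioned
  K + ridge * mean(diag(K)) * diag(n)
}

balanced_labels <- function(n) c(rep(1, floor(n / 2)), rep(-1, ceiling(n / 2)))

# small cohort with an MD-only group effect, used across modules
toy_cohort_tab <- function(n_nodes = 16, n_per_group = c(10, 10),
                           effect_md = 2, n_affected = 6, seed = 7,
                           density = 0.3) {
  cfg <- cohort_config(
    n_nodes = n_nodes, density = density, n_per_group = n_per_group,
    effect = group_effect_spec(effect_fn = 0, effect_fa = 0,
                               effect_md = effect_md,
                               n_affected = n_affected),
    seed = seed)
  co <- generate_cohort(cfg)
  tab <- vectorize_cohort(co)
  attr(tab, "affected_edges") <- attr(co, "affected_edges")
  tab
}

# hand-built fold records for the discriminative-report unit tests
fake_fold <- function(selected_per_network, beta, weights_per_network,
                      selected = sort(unlist(selected_per_network))) {
  list(test_subject_id = "s", true_label = 1, predicted_label = 1,
       decision_value = 1, selected_features = selected,
       selected_per_network = selected_per_network, beta = beta,
       primal_weights = weights_per_network)
}
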