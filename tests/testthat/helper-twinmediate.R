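# Shared fixtures: all simulated data are built in code at fixed seeds.

# two-mediator loading matrix (keeps generated cohorts small)
loadings2 <- function() default_factor_loadings(2)

# single observed mediator identical to factor 1 (loading 1, no uniqueness)
loadings_single <- function() {
  matrix(c(1, 0), 1, 2, dimnames = list("med_01", NULL))
}

# cohort with independent traits (no paths, no confounding)
null_config <- function(seed, n_mz = 2000, n_dz = 2000,
                        ace_exposure = c(1, 1, 1) / 3,
                        ace_outcome = c(0.17, 0.07, 0.76),
                        confounder_cor = c(r_a = 0, r_c = 0, r_e = 0)) {
  sim_config(n_pairs_mz = n_mz, n_pairs_dz = n_dz, measurement = "latent",
             instrumental_path = 0, pleiotropy_outcome = 0,
             pleiotropy_factors = c(0, 0), a_paths = c(0, 0),
             b_paths = c(0, 0), c_prime = 0,
             ace_exposure = ace_exposure, ace_outcome = ace_outcome,
             confounder_cor = confounder_cor,
             factor_loadings = loadings2(), seed = seed)
}

# AE-only config with one observed mediator, for MR-DoC mediation tests
simple_mrdoc_config <- function(seed, n_mz = 1000, n_dz = 1800,
                                a = 0.29, b = 0.15, c_prime = 0.05,
                                instrumental = 0.09, pleiotropy = 0.06,
                                r_a = 0.3) {
  sim_config(n_pairs_mz = n_mz, n_pairs_dz = n_dz, measurement = "latent",
             a_paths = c(a, 0), b_paths = c(b, 0), c_prime = c_prime,
             instrumental_path = instrumental,
             pleiotropy_outcome = pleiotropy,
             pleiotropy_factors = c(0.02, 0),
             ace_exposure = c(0.35, 0, 0.65),
             ace_outcome = c(0.25, 0, 0.75),
             ace_factors = matrix(c(0.3, 0.3, 0, 0, 0.7, 0.7), 2),
             confounder_cor = c(r_a = r_a, r_c = 0, r_e = 0),
             factor_loadings = loadings_single(),
             ace_mediators = matrix(c(0.3, 0, 0.7), 1),
             seed = seed)
}

mrdoc_ae_spec <- function() {
  build_mrdoc_mediation_spec(mediators = "med_01", drop_c_exposure = TRUE,
                             drop_c_outcome = TRUE, free_means = FALSE)
}

mrdoc_truth_start <- function(a = 0.29, b = 0.15) {
  c(g1 = 0.09, cp = 0.05, g2 = 0.06, a_med_01 = a, b_med_01 = b,
    gm_med_01 = 0.02)
}

scaled_pairs <- function(cohort, spec) {
  base_vars <- unique(sub("_[12]$", "", spec$observed))
  for (v in base_vars) {
    cohort[[v]] <- (cohort[[v]] - mean(cohort[[v]], na.rm = TRUE)) /
      stats::sd(cohort[[v]], na.rm = TRUE)
  }
  pair_wide(cohort, vars = base_vars)
}

# Tucker congruence after matching columns by best absolute agreement
factor_congruence <- function(L, L0) {
  cong <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  sapply(seq_len(ncol(L0)), function(j) {
    max(apply(L, 2, function(col) abs(cong(col, L0[, j]))))
  })
}

# direct per-row -2 log-likelihood oracle (independent of the engine)
direct_minus2ll <- function(X, sigma, mu) {
  tot <- 0
  for (i in seq_len(nrow(X))) {
    x <- X[i, ]
    obs <- which(!is.na(x))
    if (!length(obs)) next
    S <- sigma[obs, obs, drop = FALSE]
    d <- x[obs] - mu[obs]
    tot <- tot + length(obs) * log(2 * pi) +
      determinant(S, logarithm = TRUE)$modulus +
      drop(t(d) %*% solve(S) %*% d)
  }
  as.numeric(tot)
}
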