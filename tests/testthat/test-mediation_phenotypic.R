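# Factor analysis and phenotypic mediation SEM.

mediation_data <- function(n, a, b, cp, seed) {
  set.seed(seed)
  fam <- rep(seq_len(n / 2), each = 2)
  x <- rnorm(n)
  m <- a * x + rnorm(n, sd = sqrt(1 - a^2))
  vy <- 1 - (cp^2 + b^2 + 2 * a * b * cp)
  y <- cp * x + b * m + rnorm(n, sd = sqrt(vy))
  data.frame(family_id = fam, x = x, m = m, y = y)
}

test_that("EFA recovers a clean two-factor structure up to rotation", {
  cfg <- sim_config(n_pairs_mz = 1200, n_pairs_dz = 1200,
                    measurement = "latent", seed = 131)
  coh <- generate_cohort(cfg)
  meds <- grep("^med_", names(coh), value = TRUE)
  fs <- efa_two_factor(coh, meds)
  cong <- factor_congruence(fs$loadings, cfg$factor_loadings)
  expect_true(all(cong > 0.95))
  expect_gt(fs$factor_correlation, 0.2)   # factors correlate by construction
  expect_true(all(fs$uniquenesses >= 0 & fs$uniquenesses <= 1))
  expect_error(efa_two_factor(coh, meds[1:2]), "at least 3")
})

test_that("orthogonal generating factors give near-zero factor correlation", {
  cfg <- sim_config(n_pairs_mz = 1200, n_pairs_dz = 1200,
                    measurement = "latent", factor_correlation = 0,
                    a_paths = c(0, 0), b_paths = c(0, 0),
                    pleiotropy_factors = c(0, 0),
                    confounder_cor = c(r_a = 0, r_c = 0, r_e = 0),
                    seed = 132)
  coh <- generate_cohort(cfg)
  fs <- efa_two_factor(coh, grep("^med_", names(coh), value = TRUE))
  expect_lt(abs(fs$factor_correlation), 0.1)
})

test_that("simple mediation recovers paths; ab equals separate regressions", {
  d <- mediation_data(6000, a = 0.3, b = 0.2, cp = 0.15, seed = 133)
  spec <- build_simple_mediation_spec("x", "m", "y")
  fit <- fit_mediation_model(d, spec)
  expect_true(fit$converged)
  eff <- mediation_effects(fit)
  tab <- eff$table
  expect_lt(abs(tab$a - 0.3), 3 * (tab$a_upper - tab$a) / 1.96)
  expect_lt(abs(tab$b - 0.2), 3 * (tab$b_upper - tab$b) / 1.96)
  # indirect effect equals the product of the two separately fitted
  # standardized regressions (complete data, large n)
  a_hat <- unname(coef(lm(scale(m) ~ scale(x), d))[2])
  b_hat <- unname(coef(lm(scale(y) ~ scale(m) + scale(x), d))[2])
  expect_equal(tab$ab, a_hat * b_hat, tolerance = 0.005)
  # total = direct + indirect, exactly, and ab = a * b
  expect_equal(eff$c_total[["estimate"]],
               eff$c_prime[["estimate"]] + eff$sum_ab[["estimate"]],
               tolerance = 1e-8)
  expect_equal(tab$ab, tab$a * tab$b, tolerance = 1e-8)
})

test_that("parallel mediation sums indirect effects over active mediators", {
  set.seed(134)
  n <- 6000
  x <- rnorm(n)
  m1 <- 0.15 * x + rnorm(n, sd = sqrt(1 - 0.15^2))
  m2 <- 0.10 * x + rnorm(n, sd = sqrt(1 - 0.10^2))
  m3 <- rnorm(n)                                    # inert
  y <- 0.1 * x + 0.2 * m1 + 0.2 * m2 + rnorm(n, sd = 0.9)
  d <- data.frame(family_id = rep(1:(n / 2), each = 2),
                  x = x, m1 = m1, m2 = m2, m3 = m3, y = y)
  spec <- build_parallel_mediation_spec("x", c("m1", "m2"), "y")
  fit <- fit_mediation_model(d, spec)
  eff <- mediation_effects(fit)
  truth <- 0.15 * 0.2 + 0.10 * 0.2   # ~ 0.05 on the standardized scale
  se_sab <- eff$sum_ab[["se"]]
  expect_lt(abs(eff$sum_ab[["estimate"]] - truth), 3 * se_sab + 0.01)

  # adding an inert mediator leaves the total indirect effect essentially
  # unchanged
  spec3 <- build_parallel_mediation_spec("x", c("m1", "m2", "m3"), "y")
  fit3 <- fit_mediation_model(d, spec3)
  eff3 <- mediation_effects(fit3)
  expect_lt(abs(eff3$sum_ab[["estimate"]] - eff$sum_ab[["estimate"]]),
            2 * se_sab)
  expect_lt(abs(eff3$table$ab[3]), 0.01)
})

test_that("latent-factor mediation: label invariance and zeroed b-path", {
  cfg <- sim_config(n_pairs_mz = 800, n_pairs_dz = 800,
                    measurement = "latent",
                    factor_loadings = default_factor_loadings(6),
                    ace_mediators = matrix(rep(c(0.3, 0.1, 0.6), each = 6), 6),
                    seed = 135)
  coh <- generate_cohort(cfg)
  f1 <- sprintf("med_%02d", 1:3)
  f2 <- sprintf("med_%02d", 4:6)
  spec <- build_latent_factor_mediation_spec("exposure", f1, f2, "outcome")
  fit <- fit_mediation_model(coh, spec)
  expect_true(fit$converged)

  # permuting indicators within a factor leaves the likelihood unchanged
  spec_p <- build_latent_factor_mediation_spec("exposure", f1[c(2, 1, 3)],
                                               f2, "outcome")
  fit_p <- fit_mediation_model(coh, spec_p)
  expect_equal(fit$minus2ll, fit_p$minus2ll, tolerance = 1e-3)

  # fixing one factor's b path to zero removes its contribution to sum(ab)
  spec0 <- spec
  for (i in seq_along(spec0$entries)) {
    e <- spec0$entries[[i]]
    if (identical(e$label, "b_f2")) {
      spec0$entries[[i]]$label <- NA_character_
      spec0$entries[[i]]$value <- 0
    }
  }
  attr(spec0, "mediation_map") <- attr(spec, "mediation_map")
  fit0 <- fit_mediation_model(coh, spec0)
  eff0 <- mediation_effects(fit0)
  expect_equal(eff0$table$ab[eff0$table$mediator == "f2"], 0,
               tolerance = 1e-10)
  expect_error(build_latent_factor_mediation_spec("x", "m1", c("m2", "m3"),
                                                  "y"),
               "2 indicators")
})

test_that("percent mediated reproduces printed-value arithmetic", {
  expect_equal(round(percent_mediated(0.14, 0.10)), 58)
  expect_equal(round(percent_mediated(0.11, 0.12)), 48)
  expect_equal(percent_mediated(0.2, 0), 100)
  expect_error(percent_mediated(0.1, -0.1), "undefined")
})
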