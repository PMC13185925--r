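# MR-DoC baseline and mediation models.

test_that("baseline model recovers instrumental, pleiotropic and causal paths", {
  cfg <- sim_config(n_pairs_mz = 3000, n_pairs_dz = 3000,
                    measurement = "latent", a_paths = c(0, 0),
                    b_paths = c(0, 0), c_prime = 0.14,
                    pleiotropy_factors = c(0, 0),
                    factor_loadings = loadings2(), seed = 141)
  coh <- generate_cohort(cfg)
  fit <- fit_mrdoc(coh, build_mrdoc_baseline_spec())
  expect_true(fit$converged)
  eff <- extract_mrdoc_effects(fit)
  expect_lt(abs(eff$instrumental[["estimate"]] - 0.09),
            3 * eff$instrumental[["se"]])
  expect_lt(abs(eff$pleiotropy_outcome[["estimate"]] - 0.06),
            3 * eff$pleiotropy_outcome[["se"]])
  expect_lt(abs(eff$causal[["estimate"]] - 0.14), 3 * eff$causal[["se"]])
  expect_false(eff$weak_instrument)
  expect_true("re=0" %in% eff$constraint_tags)
})

test_that("identification guard rejects freeing pleiotropy and E-correlation", {
  expect_error(build_mrdoc_baseline_spec(pleiotropy = TRUE, free_re = TRUE),
               "not identified")
  s <- build_mrdoc_baseline_spec(pleiotropy = FALSE, free_re = TRUE)
  expect_s3_class(s, "pm_spec")
})

test_that("without generating pleiotropy the pgs-outcome link is fully mediated", {
  cfg <- sim_config(n_pairs_mz = 2500, n_pairs_dz = 2500,
                    measurement = "latent", a_paths = c(0, 0),
                    b_paths = c(0, 0), c_prime = 0.2,
                    pleiotropy_outcome = 0, pleiotropy_factors = c(0, 0),
                    factor_loadings = loadings2(), seed = 142)
  coh <- generate_cohort(cfg)
  fit <- fit_mrdoc(coh, build_mrdoc_baseline_spec(pleiotropy = FALSE))
  eff <- extract_mrdoc_effects(fit)
  # path tracing: cor(pgs, outcome) = instrumental x causal
  implied <- implied_moments(fit$spec, fit$estimates, "DZ")
  r_py <- stats::cov2cor(implied$cov)["pgs_1", "outcome_1"]
  expect_equal(r_py,
               eff$instrumental[["estimate"]] * eff$causal[["estimate"]],
               tolerance = 1e-6)
  expect_lt(abs(eff$causal[["estimate"]] - 0.2), 3 * eff$causal[["se"]])
})

test_that("weak instrument is flagged when the instrumental path vanishes", {
  cfg_strong <- sim_config(n_pairs_mz = 1500, n_pairs_dz = 1500,
                           measurement = "latent", a_paths = c(0, 0),
                           b_paths = c(0, 0), c_prime = 0.14,
                           pleiotropy_factors = c(0, 0),
                           factor_loadings = loadings2(), seed = 143)
  cfg_weak <- sim_config(n_pairs_mz = 1500, n_pairs_dz = 1500,
                         measurement = "latent", a_paths = c(0, 0),
                         b_paths = c(0, 0), c_prime = 0.14,
                         instrumental_path = 0,
                         pleiotropy_factors = c(0, 0),
                         factor_loadings = loadings2(), seed = 143)
  f_s <- fit_mrdoc(generate_cohort(cfg_strong), build_mrdoc_baseline_spec())
  f_w <- fit_mrdoc(generate_cohort(cfg_weak), build_mrdoc_baseline_spec())
  e_s <- extract_mrdoc_effects(f_s)
  e_w <- extract_mrdoc_effects(f_w)
  expect_false(e_s$weak_instrument)
  expect_true(e_w$weak_instrument)
  # the causal path stays estimable through the twin (DoC) structure, so the
  # flag, not a blown-up standard error, is the diagnostic
  expect_true(is.finite(e_w$causal[["se"]]))
})

test_that("simple MR-DoC mediation recovers a, b, c-prime and their product", {
  cfg <- simple_mrdoc_config(144, n_mz = 2500, n_dz = 2500,
                             a = 0.46, b = 0.13, c_prime = 0.09)
  coh <- generate_cohort(cfg)
  fit <- fit_mrdoc(coh, build_mrdoc_mediation_spec(mediators = "med_01"))
  expect_true(fit$converged)
  eff <- extract_mrdoc_effects(fit)
  tab <- eff$mediation$table
  a_se <- (tab$a_upper - tab$a) / 1.96
  b_se <- (tab$b_upper - tab$b) / 1.96
  expect_lt(abs(tab$a - 0.46), 3 * a_se)
  expect_lt(abs(tab$b - 0.13), 3 * b_se)
  expect_equal(tab$ab, tab$a * tab$b, tolerance = 1e-8)
  cp <- eff$mediation$c_prime
  expect_lt(abs(cp[["estimate"]] - 0.09), 3 * cp[["se"]])
  # pleiotropy toward the mediator was generated at zero
  expect_lt(abs(eff$pleiotropy_mediators["med_01", "estimate"]),
            3 * eff$pleiotropy_mediators["med_01", "se"])
  # flattened results table mirrors the published column order
  rt <- mrdoc_results_table(eff, fit)
  expect_identical(names(rt)[1:13],
                   c("mediator", "a", "a_lCI", "a_uCI", "b", "b_lCI",
                     "b_uCI", "c_prime", "c_prime_lCI", "c_prime_uCI",
                     "ab", "ab_lCI", "ab_uCI"))
  expect_equal(rt$ab, rt$a * rt$b, tolerance = 1e-8)
  expect_true(grepl("c_med_01=0", rt$constraint_tags))
  expect_equal(rt$minus2ll, fit$minus2ll)
})

test_that("a zero generating a-path yields a vanishing indirect effect", {
  cfg <- simple_mrdoc_config(145, n_mz = 1500, n_dz = 1500, a = 0,
                             b = 0.15)
  coh <- generate_cohort(cfg)
  fit <- fit_mrdoc(coh, build_mrdoc_mediation_spec(mediators = "med_01"))
  eff <- extract_mrdoc_effects(fit)
  ab <- eff$mediation$table$ab
  ab_se <- (eff$mediation$table$ab_upper - ab) / 1.96
  expect_lt(abs(ab), 3 * ab_se + 1e-3)
})

test_that("freeing the mediator C component leaves estimates consistent when C is zero", {
  cfg <- simple_mrdoc_config(146, n_mz = 2000, n_dz = 2000)
  coh <- generate_cohort(cfg)
  fit0 <- fit_mrdoc(coh, build_mrdoc_mediation_spec(mediators = "med_01",
                                                    drop_c = TRUE))
  fit1 <- fit_mrdoc(coh, build_mrdoc_mediation_spec(mediators = "med_01",
                                                    drop_c = FALSE))
  e0 <- extract_mrdoc_effects(fit0)$mediation
  e1 <- extract_mrdoc_effects(fit1)$mediation
  a_se <- (e0$table$a_upper - e0$table$a) / 1.96
  expect_lt(abs(e0$table$a - e1$table$a), 3 * a_se)
  expect_lt(abs(e0$table$b - e1$table$b),
            3 * (e0$table$b_upper - e0$table$b) / 1.96)
  expect_lt(abs(e0$c_prime[["estimate"]] - e1$c_prime[["estimate"]]),
            3 * e0$c_prime[["se"]])
})

test_that("latent-factor MR-DoC mediation recovers factor-level effects", {
  lf <- matrix(0, 6, 2)
  lf[1:3, 1] <- c(0.75, 0.7, 0.65)
  lf[4:6, 2] <- c(0.7, 0.65, 0.6)
  rownames(lf) <- sprintf("med_%02d", 1:6)
  cfg <- sim_config(n_pairs_mz = 1500, n_pairs_dz = 1500,
                    measurement = "latent",
                    a_paths = c(0.29, 0.29), b_paths = c(0.17, 0.14),
                    c_prime = 0.05, pleiotropy_factors = c(0.04, 0.03),
                    ace_factors = matrix(c(0.3, 0.3, 0, 0, 0.7, 0.7), 2),
                    factor_loadings = lf,
                    ace_mediators = matrix(rep(c(0.3, 0, 0.7), each = 6), 6),
                    seed = 147)
  coh <- generate_cohort(cfg)
  spec <- build_mrdoc_mediation_spec(
    mediators = list(f1 = sprintf("med_%02d", 1:3),
                     f2 = sprintf("med_%02d", 4:6)))
  fit <- fit_mrdoc(coh, spec)
  expect_true(fit$converged)
  eff <- extract_mrdoc_effects(fit)
  truth_sab <- 0.29 * 0.17 + 0.29 * 0.14
  sab <- eff$mediation$sum_ab
  expect_lt(abs(sab[["estimate"]] - truth_sab), 3 * sab[["se"]])
  expect_equal(eff$mediation$table$ab,
               eff$mediation$table$a * eff$mediation$table$b,
               tolerance = 1e-8)
})

test_that("stratified equality test is calibrated and detects a real contrast", {
  spec <- mrdoc_ae_spec()
  truth <- mrdoc_truth_start()
  # null: exogenous random strata, equal generating paths
  coh <- generate_cohort(simple_mrdoc_config(148))
  pw <- scaled_pairs(coh, spec)
  set.seed(149)
  strata <- sample(c("low", "high"), nrow(pw), replace = TRUE)
  res <- stratified_equality_test(spec, pw, strata,
                                  options = list(start = truth))
  expect_equal(res$lrt$df, 3)   # a, b, c' freed across two strata
  expect_gt(res$lrt$p, 0.001)
  expect_gte(res$lrt$chi2, 0)

  # power: a-path 0.34 vs 0.23 across strata
  coh_lo <- generate_cohort(simple_mrdoc_config(150, a = 0.34))
  coh_hi <- generate_cohort(simple_mrdoc_config(151, a = 0.23))
  coh_hi$family_id <- coh_hi$family_id + max(coh_lo$family_id)
  both <- rbind(coh_lo, coh_hi)
  pw2 <- scaled_pairs(both, spec)
  strata2 <- rep(c("low", "high"),
                 c(nrow(pw2) / 2, nrow(pw2) - nrow(pw2) / 2))
  res2 <- stratified_equality_test(spec, pw2, strata2,
                                   options = list(start = truth))
  expect_lt(res2$lrt$p, 0.003)
  # the freed model places the larger a-path in the first stratum
  est <- res2$free$estimates
  expect_gt(est[["a_med_01.low"]], est[["a_med_01.high"]])
})

test_that("missing strata cells and malformed labels are rejected", {
  spec <- mrdoc_ae_spec()
  coh <- generate_cohort(simple_mrdoc_config(152, n_mz = 50, n_dz = 50))
  pw <- scaled_pairs(coh, spec)
  expect_error(stratified_equality_test(spec, pw, rep("low", nrow(pw))),
               "2 strata")
  strata <- rep(c("low", "high"), length.out = nrow(pw))
  strata[pw$zygosity == "MZ"] <- "low"   # empty MZ.high cell
  expect_error(stratified_equality_test(spec, pw, strata), "empty")
})
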