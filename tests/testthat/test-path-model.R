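# RAM path-model engine: implied moments, FIML objective, fitting,
# likelihood-ratio tests, delta method and standardization.

simple_regression_spec <- function() {
  s <- pm_spec(c("x", "y"))
  s <- pm_path(s, "x", "y", label = "b", value = 0.2)
  s <- pm_cov(s, "x", "x", label = "vx", value = 1, lower = 1e-8)
  s <- pm_cov(s, "y", "y", label = "vy", value = 1, lower = 1e-8)
  s <- pm_mean(s, "x", label = "mx")
  s <- pm_mean(s, "y", label = "my")
  s
}

test_that("implied moments follow the RAM algebra", {
  s <- pm_spec(c("x", "y"))
  s <- pm_path(s, "x", "y", value = 0.5)
  s <- pm_cov(s, "x", "x", value = 1)
  s <- pm_cov(s, "y", "y", value = 0.75)
  im <- implied_moments(s)
  expect_equal(im$cov, matrix(c(1, 0.5, 0.5, 1), 2,
                              dimnames = list(c("x", "y"), c("x", "y"))))
  expect_equal(im$mean, c(x = 0, y = 0))

  # with all directed paths zero the observed covariance is the symmetric
  # matrix itself
  s0 <- pm_spec(c("a", "b"))
  s0 <- pm_cov(s0, "a", "a", value = 2)
  s0 <- pm_cov(s0, "b", "b", value = 3)
  s0 <- pm_cov(s0, "a", "b", value = 0.5)
  expect_equal(unname(implied_moments(s0)$cov),
               matrix(c(2, 0.5, 0.5, 3), 2))

  # univariate ACE cross-twin covariances: a2 + c2 (MZ), a2/2 + c2 (DZ)
  ace <- twinmediate:::build_univariate_ace_spec("ACE")
  pars <- c(a = sqrt(0.3), c = sqrt(0.2), e = sqrt(0.5))
  expect_equal(implied_moments(ace, pars, "MZ")$cov["t1", "t2"], 0.5,
               tolerance = 1e-10)
  expect_equal(implied_moments(ace, pars, "DZ")$cov["t1", "t2"], 0.35,
               tolerance = 1e-10)
  # implied covariances are symmetric
  expect_true(isSymmetric(implied_moments(ace, pars, "MZ")$cov))
})

test_that("cyclic path structures are rejected with the offending variables", {
  s <- pm_spec(c("x", "y"))
  s <- pm_path(s, "x", "y", label = "b1")
  s <- pm_path(s, "y", "x", label = "b2")
  s <- pm_cov(s, "x", "x", value = 1)
  s <- pm_cov(s, "y", "y", value = 1)
  expect_error(implied_moments(s), "cycle")
  expect_error(pm_path(pm_spec("x"), "x", "z"), "unknown variable")
})

test_that("FIML equals a direct per-row summation oracle, with and without missingness", {
  set.seed(71)
  n <- 60
  X <- MASS::mvrnorm(n, c(0.2, -0.1, 0.3),
                     matrix(c(1, .4, .3, .4, 1.2, .5, .3, .5, 0.9), 3))
  colnames(X) <- c("x", "m", "y")
  spec <- build_simple_mediation_spec("x", "m", "y")
  pars <- c(a = 0.4, b = 0.3, cp = 0.1, vx = 1.1, vm = 0.9, vy = 0.8,
            mu_x = 0.1, mu_m = 0, mu_y = 0.2)
  im <- implied_moments(spec, pars)

  d <- as.data.frame(X)
  expect_equal(fiml_minus2ll(spec, pars, d),
               direct_minus2ll(X, im$cov, im$mean), tolerance = 1e-8)

  Xm <- X
  Xm[sample(length(Xm), 25)] <- NA
  dm <- as.data.frame(Xm)
  expect_equal(fiml_minus2ll(spec, pars, dm),
               direct_minus2ll(Xm, im$cov, im$mean), tolerance = 1e-8)

  # duplicating every row doubles the objective
  expect_equal(fiml_minus2ll(spec, pars, rbind(d, d)),
               2 * fiml_minus2ll(spec, pars, d), tolerance = 1e-10)
})

test_that("saturated Gaussian MLE recovers n-denominator moments", {
  set.seed(72)
  x <- rnorm(200, mean = 1.5, sd = 2)
  s <- pm_spec("x")
  s <- pm_cov(s, "x", "x", label = "v", value = 1, lower = 1e-8)
  s <- pm_mean(s, "x", label = "m")
  fit <- fit_path_model(s, data.frame(x = x))
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates["m"]), mean(x), tolerance = 1e-5)
  expect_equal(unname(fit$estimates["v"]), mean((x - mean(x))^2),
               tolerance = 1e-4)
  # aic identity
  expect_equal(fit$aic, fit$minus2ll + 2 * fit$n_params)
})

test_that("refitting from the solution is a fixed point", {
  set.seed(73)
  d <- data.frame(x = rnorm(300))
  d$m <- 0.4 * d$x + rnorm(300, sd = 0.9)
  d$y <- 0.3 * d$m + 0.1 * d$x + rnorm(300, sd = 0.8)
  spec <- build_simple_mediation_spec("x", "m", "y")
  fit1 <- fit_path_model(spec, d)
  fit2 <- fit_path_model(spec, d, options = list(start = fit1$estimates))
  expect_true(fit1$converged && fit2$converged)
  expect_equal(fit1$minus2ll, fit2$minus2ll, tolerance = 1e-6)
})

test_that("likelihood-ratio test compares nested fits", {
  set.seed(74)
  d <- data.frame(x = rnorm(400))
  d$y <- 0.0 * d$x + rnorm(400)
  full <- fit_path_model(simple_regression_spec(), d)
  nested_spec <- pm_spec(c("x", "y"))
  nested_spec <- pm_cov(nested_spec, "x", "x", label = "vx", value = 1,
                        lower = 1e-8)
  nested_spec <- pm_cov(nested_spec, "y", "y", label = "vy", value = 1,
                        lower = 1e-8)
  nested_spec <- pm_mean(nested_spec, "x", label = "mx")
  nested_spec <- pm_mean(nested_spec, "y", label = "my")
  nested <- fit_path_model(nested_spec, d)
  out <- lrt(full, nested)
  expect_equal(out$df, 1)
  expect_gte(out$chi2, 0)
  expect_equal(out$p, stats::pchisq(out$chi2, 1, lower.tail = FALSE))

  # identical models: zero statistic, p = 1
  refit <- fit_path_model(simple_regression_spec(), d)
  same <- lrt(full, refit)
  expect_equal(same$chi2, 0, tolerance = 1e-4)
  expect_equal(same$p, 1)
  expect_error(lrt(nested, full), "more free parameters")
})

test_that("delta method matches closed forms for identity and product", {
  set.seed(75)
  d <- data.frame(x = rnorm(500))
  d$m <- 0.4 * d$x + rnorm(500, sd = 0.9)
  d$y <- 0.3 * d$m + 0.1 * d$x + rnorm(500, sd = 0.8)
  fit <- fit_path_model(build_simple_mediation_spec("x", "m", "y"), d)
  # identity expression returns the parameter's own standard error
  dm <- delta_method(fit, function(th) th[["a"]])
  expect_equal(dm$value, unname(fit$estimates["a"]))
  expect_equal(dm$se, unname(fit$se["a"]), tolerance = 1e-5)
  # product rule: var(ab) ~ b^2 var(a) + a^2 var(b) + 2ab cov(a,b)
  dm2 <- delta_method(fit, function(th) th[["a"]] * th[["b"]])
  a <- fit$estimates[["a"]]; b <- fit$estimates[["b"]]
  v <- b^2 * fit$vcov["a", "a"] + a^2 * fit$vcov["b", "b"] +
    2 * a * b * fit$vcov["a", "b"]
  expect_equal(dm2$se, sqrt(v), tolerance = 1e-5)
})

test_that("standardized solution is invariant to rescaling observed inputs", {
  set.seed(76)
  d <- data.frame(x = rnorm(600))
  d$m <- 0.4 * d$x + rnorm(600, sd = 0.9)
  d$y <- 0.3 * d$m + 0.1 * d$x + rnorm(600, sd = 0.8)
  spec <- build_simple_mediation_spec("x", "m", "y")
  fit1 <- fit_path_model(spec, d)
  d2 <- d; d2$m <- 10 * d2$m
  fit2 <- fit_path_model(spec, d2)
  s1 <- standardize_fit(fit1); s2 <- standardize_fit(fit2)
  expect_equal(s1$std, s2$std, tolerance = 1e-3)
  # raw coefficients do change under rescaling
  expect_false(isTRUE(all.equal(s1$raw, s2$raw, tolerance = 1e-4)))
  expect_equal(std_path(fit1, "x", "m"),
               s1$std[s1$from == "x" & s1$to == "m"], tolerance = 1e-10)
})

test_that("a single free mean on fixed-variance data recovers the sample mean", {
  set.seed(77)
  x <- rnorm(400, mean = 0.4)
  s <- pm_spec("x")
  s <- pm_cov(s, "x", "x", value = 1)
  s <- pm_mean(s, "x", label = "m")
  fit <- fit_path_model(s, data.frame(x = x))
  expect_equal(unname(fit$estimates["m"]), mean(x), tolerance = 1e-5)
})
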