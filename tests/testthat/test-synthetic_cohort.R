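# Synthetic twin-cohort generator: configuration validation, implied
# moment structure, composite/missingness rules, file round trips.

test_that("invalid configurations are rejected with the offending field", {
  expect_error(sim_config(ace_exposure = c(0.5, 0.5, 0.5)), "ace_exposure")
  expect_error(sim_config(ace_outcome = c(-0.1, 0.5, 0.6)), "ace_outcome")
  expect_error(sim_config(n_pairs_mz = 0), "n_pairs")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(thresholds_mediator = c(0.5, 0.5, 1, 2)),
               "thresholds_mediator")
  expect_error(sim_config(instrumental_path = 1.2), "instrumental_path")
  expect_error(sim_config(a_paths = c(2, 2)), "variance > 1")
})

test_that("cross-twin covariance structure matches the generating ACE triples", {
  # equal thirds: MZ correlation a2 + c2 = 2/3, DZ correlation 1/2
  coh <- generate_cohort(null_config(101, n_mz = 4000, n_dz = 4000))
  pw <- pair_wide(coh, "exposure")
  r_mz <- cor(pw$exposure_1[pw$zygosity == "MZ"],
              pw$exposure_2[pw$zygosity == "MZ"])
  r_dz <- cor(pw$exposure_1[pw$zygosity == "DZ"],
              pw$exposure_2[pw$zygosity == "DZ"])
  tol_mz <- 3 * (1 - (2 / 3)^2) / sqrt(4000)
  tol_dz <- 3 * (1 - 0.25) / sqrt(4000)
  expect_lt(abs(r_mz - 2 / 3), tol_mz)
  expect_lt(abs(r_dz - 0.5), tol_dz)

  # pure nonshared environment: no within-pair covariance in either group
  cfg_e <- null_config(102, n_mz = 3000, n_dz = 3000,
                       ace_exposure = c(0, 0, 1))
  pw_e <- pair_wide(generate_cohort(cfg_e), "exposure")
  for (z in c("MZ", "DZ")) {
    r <- cor(pw_e$exposure_1[pw_e$zygosity == z],
             pw_e$exposure_2[pw_e$zygosity == z])
    expect_lt(abs(r), 3 / sqrt(3000))
  }
})

test_that("polygenic scores have the twin structure of a shared genome", {
  coh <- generate_cohort(null_config(103, n_mz = 1500, n_dz = 1500))
  pw <- pair_wide(coh, "pgs")
  mz <- pw[pw$zygosity == "MZ", ]
  expect_true(all(mz$pgs_1 == mz$pgs_2))
  dz <- pw[pw$zygosity == "DZ", ]
  expect_lt(abs(cor(dz$pgs_1, dz$pgs_2) - 0.5), 3 * 0.75 / sqrt(1500))
})

test_that("instrumental path is reproduced in the pgs-exposure correlation", {
  cfg <- sim_config(n_pairs_mz = 4000, n_pairs_dz = 4000,
                    measurement = "latent",
                    factor_loadings = loadings2(), seed = 104)
  coh <- generate_cohort(cfg)
  expect_lt(abs(cor(coh$pgs, coh$exposure) - 0.09), 3 / sqrt(nrow(coh)))
})

test_that("composite rule: mean of observed items under the >=50% rule", {
  expect_equal(composite_score(c(0, 4, NA, 2, 2)), 2)
  expect_true(is.na(composite_score(c(1, NA, NA))))  # 1/3 observed < 50%
  expect_equal(composite_score(rep(3, 6)), 3)
  expect_error(composite_score(numeric(0)), "non-empty")
  expect_error(composite_score(1:3, min_fraction = 0), "min_fraction")
  # order invariance and idempotence on the resulting score
  set.seed(105)
  for (i in 1:20) {
    items <- sample(c(0:4, NA), 7, replace = TRUE)
    expect_identical(composite_score(items),
                     composite_score(sample(items)))
  }
  expect_equal(composite_score(rep(composite_score(c(1, 3)), 4)),
               composite_score(c(1, 3)))
})

test_that("injected missingness is MCAR at the requested rate", {
  cfg <- sim_config(n_pairs_mz = 400, n_pairs_dz = 400, missing_rate = 0,
                    factor_loadings = loadings2(), seed = 106)
  coh <- generate_cohort(cfg)
  expect_identical(inject_missingness(coh, 0, seed = 1)$exposure,
                   coh$exposure)
  expect_error(inject_missingness(coh, 1), "rate")

  m2 <- inject_missingness(coh, 0.2, seed = 2)
  obs_rate <- mean(is.na(attr(m2, "items")$exposure))
  n_items <- length(attr(m2, "items")$exposure)
  expect_lt(abs(obs_rate - 0.2), 3 * sqrt(0.2 * 0.8 / n_items))

  # 5-item mediator scales at rate 0.9: composite missing when > half the
  # items are missing, P(>=3 of 5) by the binomial tail
  m9 <- inject_missingness(coh, 0.9, seed = 3)
  p_expected <- 1 - stats::pbinom(2, 5, 0.9)
  p_obs <- mean(is.na(m9$med_01))
  expect_lt(abs(p_obs - p_expected), 3 * sqrt(p_expected * (1 - p_expected) /
                                                nrow(coh)))
})

test_that("cohort files round-trip and violations are caught by row", {
  cfg <- sim_config(n_pairs_mz = 30, n_pairs_dz = 30,
                    factor_loadings = loadings2(), seed = 107)
  coh <- generate_cohort(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(back$exposure, coh$exposure)
  expect_equal(back$pgs, coh$pgs, tolerance = 1e-12)
  expect_identical(back$zygosity, coh$zygosity)

  # odd row count for one family
  broken <- utils::read.csv(path)[-1, ]
  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(broken, p2, row.names = FALSE, na = "")
  expect_error(read_cohort(p2), "expected exactly 2")

  # MZ co-twins with different pgs: error when strict, warning otherwise
  tampered <- utils::read.csv(path)
  mz_rows <- which(tampered$zygosity == "MZ")
  tampered$pgs[mz_rows[1]] <- tampered$pgs[mz_rows[1]] + 1
  p3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tampered, p3, row.names = FALSE, na = "")
  expect_error(read_cohort(p3), "differing pgs")
  expect_warning(read_cohort(p3, strict = FALSE), "differing pgs")

  # inconsistent zygosity within a pair
  tampered2 <- utils::read.csv(path)
  tampered2$zygosity[1] <- "DZss"
  p4 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tampered2, p4, row.names = FALSE, na = "")
  expect_error(read_cohort(p4), "zygosity")
})

test_that("simulation configurations round-trip through YAML with revalidation", {
  cfg <- sim_config(n_pairs_mz = 40, n_pairs_dz = 60,
                    factor_loadings = loadings2(), seed = 109)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(back$ace_exposure, cfg$ace_exposure)
  expect_equal(back$factor_loadings, cfg$factor_loadings)
  expect_equal(back$confounder_cor, cfg$confounder_cor)
  expect_identical(generate_cohort(back)$exposure,
                   generate_cohort(cfg)$exposure)
  # hand-edited invariant violations are rejected on load
  txt <- readLines(path)
  txt <- sub("^missing_rate.*", "missing_rate: 1.5", txt)
  writeLines(txt, path)
  expect_error(read_sim_config(path), "missing_rate")
})

test_that("ordinal composites stay on the item scale", {
  cfg <- sim_config(n_pairs_mz = 200, n_pairs_dz = 200,
                    factor_loadings = loadings2(), seed = 108)
  coh <- generate_cohort(cfg)
  for (v in c("exposure", "med_01", "med_02", "outcome")) {
    x <- coh[[v]]
    expect_true(all(is.na(x) | (x >= 0 & x <= 4)), label = v)
  }
})
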