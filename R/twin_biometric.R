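# Univariate and bivariate ACE twin models.
#
# Parameterized through path coefficients (a, c, e) whose squares are the
# variance components, which keeps implied covariances positive definite
# without negative-variance boundary handling; cross-twin additive-genetic
# covariance fixed at 1 (MZ) / 0.5 (DZ), shared environment at 1, nonshared
# at 0. DZ same-sex and opposite-sex pairs are pooled.

build_univariate_ace_spec <- function(submodel = c("ACE", "AE", "CE", "E"),
                                      start_sd = 1) {
  submodel <- match.arg(submodel)
  s <- pm_spec(c("t1", "t2"),
               latent = c("A1", "C1", "E1", "A2", "C2", "E2"),
               groups = c("MZ", "DZ"))
  st <- start_sd / sqrt(3)
  free_a <- submodel %in% c("ACE", "AE")
  free_c <- submodel %in% c("ACE", "CE")
  for (i in 1:2) {
    ti <- paste0("t", i)
    if (free_a) s <- pm_path(s, paste0("A", i), ti, label = "a", value = st,
                             lower = 0)
    if (free_c) s <- pm_path(s, paste0("C", i), ti, label = "c", value = st,
                             lower = 0)
    s <- pm_path(s, paste0("E", i), ti, label = "e", value = st,
                 lower = 1e-6)
    for (l in c("A", "C", "E")) {
      s <- pm_cov(s, paste0(l, i), paste0(l, i), value = 1)
    }
    s <- pm_mean(s, ti, label = "mu", value = 0)
  }
  s <- pm_cov(s, "A1", "A2", value = c(MZ = 1, DZ = 0.5))
  s <- pm_cov(s, "C1", "C2", value = 1)
  attr(s, "submodel") <- submodel
  s
}

ace_proportions <- function(fit, labels = c(a = "a", c = "c", e = "e")) {
  est <- fit$estimates
  sq <- function(l) if (l %in% names(est)) unname(est[[l]]^2) else 0
  tot <- sq(labels[["a"]]) + sq(labels[["c"]]) + sq(labels[["e"]])
  props <- c(a2 = sq(labels[["a"]]), c2 = sq(labels[["c"]]),
             e2 = sq(labels[["e"]])) / tot
  ci <- matrix(NA_real_, 3, 2, dimnames = list(names(props),
                                               c("lower", "upper")))
  se <- stats::setNames(rep(NA_real_, 3), names(props))
  if (fit$vcov_ok) {
    for (i in seq_along(props)) {
      l <- labels[[i]]
      if (!(l %in% names(est))) next
      dm <- delta_method(fit, function(th) {
        s2 <- function(x) if (x %in% names(th)) th[[x]]^2 else 0
        s2(l) / (s2(labels[["a"]]) + s2(labels[["c"]]) + s2(labels[["e"]]))
      })
      se[i] <- dm$se
      ci[i, ] <- pmin(pmax(dm$ci, 0), 1)
    }
  }
  list(proportions = props, se = se, ci = ci)
}

#' Univariate ACE twin model
#'
#' Two-group (MZ/DZ) FIML fit of the classical ACE decomposition, with the
#' cross-twin additive-genetic covariance fixed at 1.0 in MZ and 0.5 in DZ
#' pairs and the shared-environment covariance at 1.0 in both. Returns
#' standardized variance proportions with delta-method 95% intervals.
#'
#' @param cohort A cohort data frame (one row per individual).
#' @param trait Name of the trait column.
#' @param submodel `"ACE"` (default), `"AE"`, `"CE"` or `"E"`.
#' @param options Passed to [fit_path_model()].
#' @return A list of class `ace_fit`: `a2`, `c2`, `e2` (with `se` and `ci`),
#'   `model_tag` and the underlying `fit`.
#' @export
fit_univariate_ace <- function(cohort, trait, submodel = "ACE",
                               options = list()) {
  if (!(trait %in% names(cohort))) stop("trait '", trait, "' not in cohort")
  pw <- pair_wide(cohort, vars = trait)
  names(pw)[match(paste0(trait, c("_1", "_2")), names(pw))] <- c("t1", "t2")
  zyg <- unique(pw$zygosity)
  if (length(zyg) < 2) {
    stop("both zygosity groups are required; cohort has only ",
         paste(zyg, collapse = ", "))
  }
  sdt <- stats::sd(c(pw$t1, pw$t2), na.rm = TRUE)
  mu0 <- mean(c(pw$t1, pw$t2), na.rm = TRUE)
  spec <- build_univariate_ace_spec(submodel, start_sd = sdt)
  fit <- fit_path_model(spec, pw, group = "zygosity",
                        options = utils::modifyList(list(start = c(mu = mu0)),
                                                    options))
  pr <- ace_proportions(fit)
  structure(list(a2 = pr$proportions[["a2"]], c2 = pr$proportions[["c2"]],
                 e2 = pr$proportions[["e2"]], se = pr$se, ci = pr$ci,
                 model_tag = submodel, trait = trait, fit = fit),
            class = "ace_fit")
}

#' @export
print.ace_fit <- function(x, ...) {
  cat(sprintf("%s twin model for '%s'\n", x$model_tag, x$trait))
  tab <- data.frame(estimate = c(x$a2, x$c2, x$e2), se = x$se,
                    lower = x$ci[, 1], upper = x$ci[, 2],
                    row.names = c("a2", "c2", "e2"))
  print(round(tab, 3))
  invisible(x)
}

#' Falconer's closed-form ACE decomposition
#'
#' The textbook moment estimator from twin correlations:
#' `h2 = 2 (r_mz - r_dz)`, `c2 = 2 r_dz - r_mz`, `e2 = 1 - r_mz`. Serves as
#' an independent sanity oracle for the likelihood-based fits.
#'
#' @param r_mz,r_dz MZ and DZ within-pair correlations, each in `[-1, 1]`.
#' @return A list with `h2`, `c2`, `e2` and `admissible` (`FALSE` when a
#'   component falls outside `[0, 1]`).
#' @export
falconer_oracle <- function(r_mz, r_dz) {
  stopifnot(abs(r_mz) <= 1, abs(r_dz) <= 1)
  h2 <- 2 * (r_mz - r_dz)
  c2 <- 2 * r_dz - r_mz
  e2 <- 1 - r_mz
  list(h2 = h2, c2 = c2, e2 = e2,
       admissible = all(c(h2, c2, e2) >= 0 & c(h2, c2, e2) <= 1))
}

build_bivariate_ace_spec <- function(start_sd = c(1, 1), start_r = 0.3) {
  obs <- c("x1", "y1", "x2", "y2")
  lat <- as.vector(outer(c("Ax", "Cx", "Ex", "Ay", "Cy", "Ey"), 1:2, paste0))
  s <- pm_spec(obs, latent = lat, groups = c("MZ", "DZ"))
  st <- start_sd / sqrt(3)
  for (i in 1:2) {
    xi <- paste0("x", i); yi <- paste0("y", i)
    s <- pm_path(s, paste0("Ax", i), xi, label = "ax", value = st[1], lower = 0)
    s <- pm_path(s, paste0("Cx", i), xi, label = "cx", value = st[1], lower = 0)
    s <- pm_path(s, paste0("Ex", i), xi, label = "ex", value = st[1], lower = 1e-6)
    s <- pm_path(s, paste0("Ay", i), yi, label = "ay", value = st[2], lower = 0)
    s <- pm_path(s, paste0("Cy", i), yi, label = "cy", value = st[2], lower = 0)
    s <- pm_path(s, paste0("Ey", i), yi, label = "ey", value = st[2], lower = 1e-6)
    for (l in lat) s <- pm_cov(s, l, l, value = 1)
    s <- pm_mean(s, xi, label = "mux", value = 0)
    s <- pm_mean(s, yi, label = "muy", value = 0)
  }
  # cross-twin, within-trait
  s <- pm_cov(s, "Ax1", "Ax2", value = c(MZ = 1, DZ = 0.5))
  s <- pm_cov(s, "Ay1", "Ay2", value = c(MZ = 1, DZ = 0.5))
  s <- pm_cov(s, "Cx1", "Cx2", value = 1)
  s <- pm_cov(s, "Cy1", "Cy2", value = 1)
  # cross-trait correlations (latent variances are 1)
  for (i in 1:2) {
    s <- pm_cov(s, paste0("Ax", i), paste0("Ay", i), label = "ra",
                value = start_r, lower = -0.999, upper = 0.999)
    s <- pm_cov(s, paste0("Cx", i), paste0("Cy", i), label = "rc",
                value = start_r, lower = -0.999, upper = 0.999)
    s <- pm_cov(s, paste0("Ex", i), paste0("Ey", i), label = "re",
                value = start_r / 2, lower = -0.999, upper = 0.999)
  }
  # cross-twin, cross-trait
  s <- pm_cov(s, "Ax1", "Ay2", label = "ra", scale = c(MZ = 1, DZ = 0.5))
  s <- pm_cov(s, "Ax2", "Ay1", label = "ra", scale = c(MZ = 1, DZ = 0.5))
  s <- pm_cov(s, "Cx1", "Cy2", label = "rc")
  s <- pm_cov(s, "Cx2", "Cy1", label = "rc")
  s
}

#' Bivariate ACE twin model (correlated factors)
#'
#' Two-group FIML fit of the correlated-factors bivariate ACE model, which
#' yields the genetic, shared-environmental and nonshared-environmental
#' correlations (`r_g`, `r_c`, `r_e`) between two traits directly as free
#' parameters, together with each trait's variance decomposition.
#'
#' @param cohort A cohort data frame.
#' @param trait1,trait2 Names of the two trait columns.
#' @param options Passed to [fit_path_model()].
#' @return A list of class `biv_ace_fit` with elements `r_g`, `r_c`, `r_e`
#'   (estimate, se, ci), per-trait proportion tables, and `fit`.
#' @export
fit_bivariate_ace <- function(cohort, trait1, trait2, options = list()) {
  for (tr in c(trait1, trait2)) {
    if (!(tr %in% names(cohort))) stop("trait '", tr, "' not in cohort")
  }
  pw <- pair_wide(cohort, vars = c(trait1, trait2))
  names(pw)[match(c(paste0(trait1, c("_1", "_2")),
                    paste0(trait2, c("_1", "_2"))), names(pw))] <-
    c("x1", "x2", "y1", "y2")
  if (length(unique(pw$zygosity)) < 2) {
    stop("both zygosity groups are required")
  }
  sds <- c(stats::sd(c(pw$x1, pw$x2), na.rm = TRUE),
           stats::sd(c(pw$y1, pw$y2), na.rm = TRUE))
  mus <- c(mux = mean(c(pw$x1, pw$x2), na.rm = TRUE),
           muy = mean(c(pw$y1, pw$y2), na.rm = TRUE))
  spec <- build_bivariate_ace_spec(start_sd = sds)
  fit <- fit_path_model(spec, pw, group = "zygosity",
                        options = utils::modifyList(list(start = mus),
                                                    options))
  est <- fit$estimates
  corr <- function(l) {
    ci <- fit$ci[l, ]
    unstable <- FALSE
    # near-zero variance in either trait's component makes the correlation
    # weakly identified
    comp <- switch(l, ra = c("ax", "ay"), rc = c("cx", "cy"),
                   re = c("ex", "ey"))
    tots <- c(sum(est[c("ax", "cx", "ex")]^2), sum(est[c("ay", "cy", "ey")]^2))
    if (any(est[comp]^2 / tots < 1e-3)) unstable <- TRUE
    list(estimate = unname(est[[l]]), se = unname(fit$se[[l]]),
         ci = unname(ci), unstable = unstable)
  }
  props <- list(
    trait1 = ace_proportions(fit, c(a = "ax", c = "cx", e = "ex")),
    trait2 = ace_proportions(fit, c(a = "ay", c = "cy", e = "ey")))
  names(props) <- c(trait1, trait2)
  structure(list(r_g = corr("ra"), r_c = corr("rc"), r_e = corr("re"),
                 proportions = props, traits = c(trait1, trait2), fit = fit),
            class = "biv_ace_fit")
}

#' @export
print.biv_ace_fit <- function(x, ...) {
  cat(sprintf("Bivariate ACE (correlated factors): %s ~ %s\n",
              x$traits[1], x$traits[2]))
  for (nm in c("r_g", "r_c", "r_e")) {
    v <- x[[nm]]
    cat(sprintf("  %s = %.3f [%.3f, %.3f]%s\n", nm, v$estimate, v$ci[1],
                v$ci[2], if (v$unstable) " (unstable)" else ""))
  }
  invisible(x)
}

#' Within-pair discordance summary
#'
#' Fraction of complete twin pairs whose absolute within-pair difference in
#' a trait exceeds `threshold_sd` sample standard deviations.
#'
#' @param cohort A cohort data frame.
#' @param trait Trait column name.
#' @param threshold_sd Threshold in sample-SD units (default 1).
#' @return A list with `proportion`, `n_pairs` (complete pairs) and
#'   `threshold` (on the trait scale).
#' @export
concordance_summary <- function(cohort, trait, threshold_sd = 1) {
  if (!(trait %in% names(cohort))) stop("trait '", trait, "' not in cohort")
  pw <- pair_wide(cohort, vars = trait)
  v1 <- pw[[paste0(trait, "_1")]]
  v2 <- pw[[paste0(trait, "_2")]]
  ok <- !is.na(v1) & !is.na(v2)
  if (!any(ok)) stop("no complete pairs for trait '", trait, "'")
  s <- stats::sd(cohort[[trait]], na.rm = TRUE)
  thr <- threshold_sd * s
  list(proportion = mean(abs(v1[ok] - v2[ok]) > thr),
       n_pairs = sum(ok), threshold = thr)
}
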