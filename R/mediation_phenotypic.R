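# Factor analysis over the mediator battery and phenotypic mediation SEM.
#
# Phenotypic mediation models are fitted at the individual level (two rows
# per family) with a family-clustered sandwich covariance for inference;
# this matches the use of a family identifier as clustering variable in
# individual-level SEM.

#' Two-factor exploratory factor analysis of the mediator battery
#'
#' Maximum-likelihood factor extraction with oblique (promax) rotation on
#' the Pearson correlation matrix of the mediator composites (pairwise
#' complete observations).
#'
#' @param cohort A cohort data frame.
#' @param mediators Character vector of mediator column names (>= 3).
#' @return A list of class `factor_solution`: `loadings` (K x 2),
#'   `factor_correlation`, `uniquenesses`, `n_obs`, `method_tag`.
#' @export
efa_two_factor <- function(cohort, mediators) {
  if (length(mediators) < 3) stop("need at least 3 mediators")
  miss <- setdiff(mediators, names(cohort))
  if (length(miss)) stop("mediator(s) not in cohort: ",
                         paste(miss, collapse = ", "))
  M <- as.matrix(cohort[, mediators])
  R <- stats::cor(M, use = "pairwise.complete.obs")
  if (anyNA(R)) stop("correlation matrix has missing entries")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8) {
    stop("correlation matrix is not positive definite; consider smoothing ",
         "(e.g. nearest positive-definite projection) or dropping collinear ",
         "mediators")
  }
  n_obs <- min(colSums(!is.na(M)))
  fa <- stats::factanal(covmat = R, factors = 2, n.obs = n_obs,
                        rotation = "promax")
  L <- unclass(fa$loadings)
  # promax: $rotmat transforms the loadings, so the factor transformation is
  # its inverse transpose and the factor covariance is crossprod(rotmat);
  # verified by reconstructing L Phi L' + Psi ~ R
  Phi <- if (!is.null(fa$rotmat)) {
    crossprod(fa$rotmat)
  } else diag(2)
  Phi <- stats::cov2cor((Phi + t(Phi)) / 2)
  # canonicalize factor signs: dominant loading of each factor positive
  signs <- apply(L, 2, function(col) sign(col[which.max(abs(col))]))
  signs[signs == 0] <- 1
  L <- sweep(L, 2, signs, "*")
  Phi <- diag(signs) %*% Phi %*% diag(signs)
  structure(list(loadings = L, factor_correlation = Phi[1, 2],
                 uniquenesses = fa$uniquenesses, n_obs = n_obs,
                 method_tag = "ml+promax"),
            class = "factor_solution")
}

#' @export
print.factor_solution <- function(x, ...) {
  cat("Two-factor solution (", x$method_tag, "), n =", x$n_obs, "\n")
  print(round(x$loadings, 3))
  cat("factor correlation:", round(x$factor_correlation, 3), "\n")
  invisible(x)
}

new_mediation_map <- function(exposure, outcome, mediators, c_prime = "cp") {
  list(exposure = exposure, outcome = outcome, c_prime = c_prime,
       mediators = mediators)
}

#' Simple phenotypic mediation model
#'
#' Builds the three-variable path model `exposure -> mediator -> outcome`
#' with direct path `c'`: free paths `a`, `b`, `cp`, free (residual)
#' variances and means.
#'
#' @param exposure,mediator,outcome Observed variable (column) names.
#' @return A `pm_spec` carrying a mediation map used by
#'   [mediation_effects()].
#' @export
build_simple_mediation_spec <- function(exposure, mediator, outcome) {
  vars <- c(exposure, mediator, outcome)
  if (anyDuplicated(vars)) stop("exposure, mediator and outcome must differ")
  s <- pm_spec(vars)
  s <- pm_path(s, exposure, mediator, label = "a", value = 0.1)
  s <- pm_path(s, mediator, outcome, label = "b", value = 0.1)
  s <- pm_path(s, exposure, outcome, label = "cp", value = 0.1)
  s <- pm_cov(s, exposure, exposure, label = "vx", value = 1, lower = 1e-8)
  s <- pm_cov(s, mediator, mediator, label = "vm", value = 1, lower = 1e-8)
  s <- pm_cov(s, outcome, outcome, label = "vy", value = 1, lower = 1e-8)
  for (v in vars) s <- pm_mean(s, v, label = paste0("mu_", v), value = 0)
  attr(s, "mediation_map") <- new_mediation_map(
    exposure, outcome,
    data.frame(name = mediator, med_var = mediator, a_label = "a",
               b_label = "b", stringsAsFactors = FALSE))
  s
}

#' Parallel phenotypic mediation model with observed mediators
#'
#' All mediators enter simultaneously with per-mediator `a` and `b` paths,
#' a direct path `c'`, and freely correlated mediator residuals.
#'
#' @param exposure Observed exposure name.
#' @param mediators Character vector (>= 2) of mediator names.
#' @param outcome Observed outcome name.
#' @return A `pm_spec` with a mediation map.
#' @export
build_parallel_mediation_spec <- function(exposure, mediators, outcome) {
  if (length(mediators) < 2) stop("need >= 2 mediators (use the simple model)")
  vars <- c(exposure, mediators, outcome)
  if (anyDuplicated(vars)) stop("variable names must be distinct")
  s <- pm_spec(vars)
  K <- length(mediators)
  amap <- character(K); bmap <- character(K)
  for (k in seq_len(K)) {
    m <- mediators[k]
    amap[k] <- paste0("a_", m); bmap[k] <- paste0("b_", m)
    s <- pm_path(s, exposure, m, label = amap[k], value = 0.1)
    s <- pm_path(s, m, outcome, label = bmap[k], value = 0.1)
    s <- pm_cov(s, m, m, label = paste0("vm_", m), value = 1, lower = 1e-8)
  }
  for (j in seq_len(K - 1)) {
    for (k in (j + 1):K) {
      s <- pm_cov(s, mediators[j], mediators[k],
                  label = paste0("rm_", j, "_", k), value = 0.1)
    }
  }
  s <- pm_path(s, exposure, outcome, label = "cp", value = 0.1)
  s <- pm_cov(s, exposure, exposure, label = "vx", value = 1, lower = 1e-8)
  s <- pm_cov(s, outcome, outcome, label = "vy", value = 1, lower = 1e-8)
  for (v in vars) s <- pm_mean(s, v, label = paste0("mu_", v), value = 0)
  attr(s, "mediation_map") <- new_mediation_map(
    exposure, outcome,
    data.frame(name = mediators, med_var = mediators, a_label = amap,
               b_label = bmap, stringsAsFactors = FALSE))
  s
}

#' Parallel phenotypic mediation with two latent factor mediators
#'
#' The mediators are two latent factors measured by disjoint indicator
#' sets; factors are scaled by a marker variable (first indicator loading
#' fixed to 1), carry factor-level `a` and `b` paths, and have freely
#' correlated disturbances. Standardized output is invariant to the
#' marker-scaling choice.
#'
#' @param exposure Observed exposure name.
#' @param indicators_f1,indicators_f2 Indicator names per factor (>= 2
#'   each).
#' @param outcome Observed outcome name.
#' @return A `pm_spec` with a mediation map (mediators `f1`, `f2`).
#' @export
build_latent_factor_mediation_spec <- function(exposure, indicators_f1,
                                               indicators_f2, outcome) {
  if (length(indicators_f1) < 2 || length(indicators_f2) < 2) {
    stop("each factor needs at least 2 indicators for identification")
  }
  inds <- c(indicators_f1, indicators_f2)
  vars <- c(exposure, inds, outcome)
  if (anyDuplicated(vars)) stop("variable names must be distinct")
  s <- pm_spec(vars, latent = c("f1", "f2"))
  for (fj in c("f1", "f2")) {
    ind <- if (fj == "f1") indicators_f1 else indicators_f2
    s <- pm_path(s, fj, ind[1], value = 1)      # marker scaling
    for (v in ind[-1]) {
      s <- pm_path(s, fj, v, label = paste0("l_", v), value = 0.8)
    }
    s <- pm_path(s, exposure, fj, label = paste0("a_", fj), value = 0.1)
    s <- pm_path(s, fj, outcome, label = paste0("b_", fj), value = 0.1)
    s <- pm_cov(s, fj, fj, label = paste0("vf_", fj), value = 0.5,
                lower = 1e-8)
  }
  s <- pm_cov(s, "f1", "f2", label = "cf_12", value = 0.1)
  for (v in inds) {
    s <- pm_cov(s, v, v, label = paste0("u_", v), value = 0.5, lower = 1e-8)
  }
  s <- pm_path(s, exposure, outcome, label = "cp", value = 0.1)
  s <- pm_cov(s, exposure, exposure, label = "vx", value = 1, lower = 1e-8)
  s <- pm_cov(s, outcome, outcome, label = "vy", value = 1, lower = 1e-8)
  for (v in vars) s <- pm_mean(s, v, label = paste0("mu_", v), value = 0)
  attr(s, "mediation_map") <- new_mediation_map(
    exposure, outcome,
    data.frame(name = c("f1", "f2"), med_var = c("f1", "f2"),
               a_label = c("a_f1", "a_f2"), b_label = c("b_f1", "b_f2"),
               stringsAsFactors = FALSE))
  s
}

#' Fit a mediation model on individual-level cohort rows
#'
#' Convenience wrapper: selects the model's observed columns, z-scores
#' them, and fits by FIML with family-clustered sandwich standard errors.
#'
#' @param cohort A cohort data frame.
#' @param spec A mediation `pm_spec` (single group).
#' @param cluster Cluster-id column (default `"family_id"`).
#' @param scale Z-score observed variables first (default `TRUE`).
#' @param se Standard-error method passed to [fit_path_model()] (default:
#'   cluster-robust).
#' @param options Passed to [fit_path_model()].
#' @return A `pm_fit`.
#' @export
fit_mediation_model <- function(cohort, spec, cluster = "family_id",
                                scale = TRUE, se = NULL, options = list()) {
  need <- c(spec$observed, cluster)
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("cohort lacks column(s): ",
                         paste(miss, collapse = ", "))
  d <- cohort[, need]
  if (scale) for (v in spec$observed) d[[v]] <- zscore(d[[v]])
  fit_path_model(spec, d, cluster = cluster, se = se, options = options)
}

#' Mediation effect decomposition from a fitted model
#'
#' Extracts standardized `a`, `b` and `c'` paths, per-mediator indirect
#' effects `ab`, the total indirect effect, the total effect
#' `c = c' + sum(ab)` and the percentage mediated
#' `100 * sum(ab) / (sum(ab) + c')`, with first-order delta-method standard
#' errors and Wald 95% intervals computed on the standardized scale, and
#' Bonferroni-adjusted significance flags.
#'
#' @param fit A converged `pm_fit` of a spec built by one of the
#'   `build_*_mediation_spec()` functions.
#' @param p_threshold Adjusted significance threshold (default `0.05 / 18`).
#' @param group Group in which standardization is evaluated (default:
#'   first group; for twin models the two twins share all labels, so the
#'   choice is immaterial).
#' @return A list of class `mediation_effects`: `table` (per-mediator
#'   rows), `c_prime`, `sum_ab`, `c_total`, `percent_mediated`.
#' @export
mediation_effects <- function(fit, p_threshold = bonferroni_threshold(0.05, 18)$threshold,
                              group = NULL) {
  stopifnot(inherits(fit, "pm_fit"))
  if (!fit$converged) stop("fit has not converged")
  map <- attr(fit$spec, "mediation_map")
  if (is.null(map)) stop("spec carries no mediation map")
  if (is.null(group)) group <- fit$spec$groups[1]
  compiled <- fit$compiled
  meds <- map$mediators

  sp <- function(th, from, to) std_path_at(compiled, th, from, to, group)
  if (!fit$vcov_ok) {
    warning("parameter covariance unusable (boundary or singular Hessian); ",
            "reporting point estimates without intervals")
  }
  qty <- function(f) {
    if (!fit$vcov_ok) {
      return(c(estimate = unname(f(fit$estimates)), se = NA_real_,
               lower = NA_real_, upper = NA_real_, p = NA_real_))
    }
    dm <- delta_method(fit, f)
    c(estimate = dm$value, se = dm$se, lower = dm$ci[1], upper = dm$ci[2],
      p = dm$p)
  }
  sum_ab_fn <- function(th) {
    s <- 0
    for (k in seq_len(nrow(meds))) {
      s <- s + sp(th, map$exposure, meds$med_var[k]) *
        sp(th, meds$med_var[k], map$outcome)
    }
    s
  }
  cp_fn <- function(th) sp(th, map$exposure, map$outcome)

  rows <- list()
  for (k in seq_len(nrow(meds))) {
    mv <- meds$med_var[k]
    a <- qty(function(th) sp(th, map$exposure, mv))
    b <- qty(function(th) sp(th, mv, map$outcome))
    ab <- qty(function(th) sp(th, map$exposure, mv) * sp(th, mv, map$outcome))
    rows[[k]] <- data.frame(
      mediator = meds$name[k],
      a = a[["estimate"]], a_lower = a[["lower"]], a_upper = a[["upper"]],
      a_sig = a[["p"]] < p_threshold,
      b = b[["estimate"]], b_lower = b[["lower"]], b_upper = b[["upper"]],
      b_sig = b[["p"]] < p_threshold,
      ab = ab[["estimate"]], ab_lower = ab[["lower"]],
      ab_upper = ab[["upper"]], ab_sig = ab[["p"]] < p_threshold,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  cp <- qty(cp_fn)
  sab <- qty(sum_ab_fn)
  ctot <- qty(function(th) cp_fn(th) + sum_ab_fn(th))
  denom <- sab[["estimate"]] + cp[["estimate"]]
  pm_val <- if (abs(denom) < 1e-12) NA_real_ else
    100 * sab[["estimate"]] / denom
  structure(list(
    table = tab,
    c_prime = cp, sum_ab = sab, c_total = ctot,
    percent_mediated = pm_val,
    percent_mediated_defined = abs(denom) >= 1e-12,
    p_threshold = p_threshold), class = "mediation_effects")
}

#' Percentage of a total effect carried by mediation
#'
#' `100 * sum_ab / (sum_ab + c_prime)`: the total indirect effect as a
#' percentage of the total effect recomposed from its indirect and direct
#' parts.
#'
#' @param sum_ab Total indirect effect.
#' @param c_prime Direct effect.
#' @return Percentage (scalar); errors when `sum_ab + c_prime` is zero.
#' @examples
#' percent_mediated(0.14, 0.10)  # 58.33
#' percent_mediated(0.11, 0.12)  # 47.83
#' @export
percent_mediated <- function(sum_ab, c_prime) {
  denom <- sum_ab + c_prime
  if (any(abs(denom) < 1e-12)) {
    stop("percent mediated undefined: sum_ab + c_prime is zero")
  }
  100 * sum_ab / denom
}

#' @export
print.mediation_effects <- function(x, ...) {
  cat("Mediation decomposition (standardized)\n")
  tab <- x$table[, c("mediator", "a", "b", "ab", "ab_sig")]
  tab[, 2:4] <- round(tab[, 2:4], 3)
  print(tab, row.names = FALSE)
  cat(sprintf("  c' = %.3f [%.3f, %.3f]\n", x$c_prime[["estimate"]],
              x$c_prime[["lower"]], x$c_prime[["upper"]]))
  cat(sprintf("  sum(ab) = %.3f [%.3f, %.3f]\n", x$sum_ab[["estimate"]],
              x$sum_ab[["lower"]], x$sum_ab[["upper"]]))
  if (x$percent_mediated_defined) {
    cat(sprintf("  percent mediated = %.1f%%\n", x$percent_mediated))
  } else {
    cat("  percent mediated undefined (sum_ab + c_prime = 0)\n")
  }
  invisible(x)
}
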