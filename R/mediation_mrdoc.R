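# MR-DoC models: Mendelian randomization combined with direction-of-causation
# twin modelling, using a polygenic score (PGS) as genetic instrument for the
# exposure. The PGS enters once per twin as an exogenous variable with fixed
# cross-twin covariance (1 in MZ, 0.5 in DZ under random mating) and is not
# itself decomposed into ACE components. Identification follows the standard
# MR-DoC convention: with the pleiotropic PGS -> outcome path free, the
# nonshared-environmental correlation between exposure and outcome residuals
# is fixed to zero.

mrdoc_var <- function(v, i) paste0(v, "_", i)

#' Baseline MR-DoC model specification
#'
#' Two-group (MZ/DZ) twin-pair model with, per twin, an instrumental path
#' PGS -> exposure, a causal path exposure -> outcome and a pleiotropic
#' path PGS -> outcome; exposure and outcome each carry A/C/E components
#' whose A and C parts are correlated across traits (genetic and
#' shared-environmental confounding). Cross-twin covariances are fixed at
#' 1/0.5 (A), 1 (C), 0 (E) and 1/`dz_pgs_cor` for the PGS.
#'
#' @param pgs,exposure,outcome Variable base names; the spec expects
#'   pair-wide columns `<name>_1`, `<name>_2` (see [pair_wide()]).
#' @param pleiotropy Free the PGS -> outcome path (default `TRUE`).
#' @param causal Free the exposure -> outcome causal path (default `TRUE`);
#'   fixing it at zero gives the nested model for a likelihood-ratio test
#'   of the causal effect, which is better calibrated than the Wald test
#'   when the instrument is weak.
#' @param free_re Free the exposure-outcome E correlation. Freeing it
#'   together with the pleiotropic path is not identified and errors.
#' @param dz_pgs_cor DZ cross-twin PGS correlation (default 0.5).
#' @return A `pm_spec` with attributes `mrdoc_map` and `constraint_tags`.
#' @export
build_mrdoc_baseline_spec <- function(pgs = "pgs", exposure = "exposure",
                                      outcome = "outcome",
                                      pleiotropy = TRUE, causal = TRUE,
                                      free_re = FALSE,
                                      dz_pgs_cor = 0.5) {
  if (anyDuplicated(c(pgs, exposure, outcome))) {
    stop("pgs, exposure and outcome names must be distinct")
  }
  if (pleiotropy && free_re) {
    stop("freeing both the pleiotropic path and the E-correlation is not ",
         "identified; fix one of them")
  }
  obs <- c(t(outer(c(pgs, exposure, outcome), 1:2, mrdoc_var)))
  lat <- c(t(outer(c("Ax", "Cx", "Ex", "Ay", "Cy", "Ey"), 1:2, paste0)))
  s <- pm_spec(obs, latent = lat, groups = c("MZ", "DZ"))
  for (i in 1:2) {
    p <- mrdoc_var(pgs, i); x <- mrdoc_var(exposure, i)
    y <- mrdoc_var(outcome, i)
    s <- pm_path(s, p, x, label = "g1", value = 0.1)
    if (causal) s <- pm_path(s, x, y, label = "causal", value = 0.1)
    if (pleiotropy) s <- pm_path(s, p, y, label = "g2", value = 0.05)
    s <- pm_path(s, paste0("Ax", i), x, label = "ax", value = 0.5, lower = 0)
    s <- pm_path(s, paste0("Cx", i), x, label = "cx", value = 0.5, lower = 0)
    s <- pm_path(s, paste0("Ex", i), x, label = "ex", value = 0.5,
                 lower = 1e-6)
    s <- pm_path(s, paste0("Ay", i), y, label = "ay", value = 0.4, lower = 0)
    s <- pm_path(s, paste0("Cy", i), y, label = "cy", value = 0.3, lower = 0)
    s <- pm_path(s, paste0("Ey", i), y, label = "ey", value = 0.7,
                 lower = 1e-6)
    for (l in c("Ax", "Cx", "Ex", "Ay", "Cy", "Ey")) {
      s <- pm_cov(s, paste0(l, i), paste0(l, i), value = 1)
    }
    s <- pm_cov(s, paste0("Ax", i), paste0("Ay", i), label = "ra",
                value = 0.2, lower = -0.999, upper = 0.999)
    s <- pm_cov(s, paste0("Cx", i), paste0("Cy", i), label = "rc",
                value = 0.2, lower = -0.999, upper = 0.999)
    if (free_re) {
      s <- pm_cov(s, paste0("Ex", i), paste0("Ey", i), label = "re",
                  value = 0.1, lower = -0.999, upper = 0.999)
    }
    s <- pm_cov(s, p, p, label = "vp", value = 1, lower = 1e-8)
    s <- pm_mean(s, p, label = "mu_p", value = 0)
    s <- pm_mean(s, x, label = "mu_x", value = 0)
    s <- pm_mean(s, y, label = "mu_y", value = 0)
  }
  s <- pm_cov(s, "Ax1", "Ax2", value = c(MZ = 1, DZ = 0.5))
  s <- pm_cov(s, "Ay1", "Ay2", value = c(MZ = 1, DZ = 0.5))
  s <- pm_cov(s, "Cx1", "Cx2", value = 1)
  s <- pm_cov(s, "Cy1", "Cy2", value = 1)
  s <- pm_cov(s, "Ax1", "Ay2", label = "ra", scale = c(MZ = 1, DZ = 0.5))
  s <- pm_cov(s, "Ax2", "Ay1", label = "ra", scale = c(MZ = 1, DZ = 0.5))
  s <- pm_cov(s, "Cx1", "Cy2", label = "rc")
  s <- pm_cov(s, "Cx2", "Cy1", label = "rc")
  s <- pm_cov(s, mrdoc_var(pgs, 1), mrdoc_var(pgs, 2), label = "vp",
              scale = c(MZ = 1, DZ = dz_pgs_cor))
  attr(s, "mrdoc_map") <- list(
    pgs = mrdoc_var(pgs, 1), exposure = mrdoc_var(exposure, 1),
    outcome = mrdoc_var(outcome, 1),
    instrumental = "g1", causal = "causal",
    pleiotropy_outcome = if (pleiotropy) "g2" else NULL,
    pleiotropy_mediators = character(0), mediators = NULL)
  attr(s, "constraint_tags") <- c(
    if (!free_re) "re=0", if (!pleiotropy) "g2=0",
    if (!causal) "causal=0")
  s
}

# Adds a lower-triangular Cholesky system over `traits` (observed variable
# names per twin) for one variance component; cross-twin factor covariance
# `cross` (per-group fixed values).
add_cholesky <- function(s, traits, prefix, cross, start = 0.4) {
  k <- length(traits)
  for (j in seq_len(k)) {
    for (i in 1:2) {
      f <- paste0(prefix, j, "_", i)
      s <- pm_cov(s, f, f, value = 1)
      for (t in j:k) {
        lab <- paste0("l", tolower(prefix), j, "_", t)
        s <- pm_path(s, f, mrdoc_var(traits[t], i), label = lab,
                     value = if (t == j) start else 0.1,
                     lower = if (t == j) 0 else -Inf)
      }
    }
    s <- pm_cov(s, paste0(prefix, j, "_1"), paste0(prefix, j, "_2"),
                value = cross)
  }
  s
}

#' MR-DoC mediation model specification
#'
#' Extends the baseline MR-DoC model with mediators between exposure and
#' outcome: per twin, paths `a` (exposure -> mediator), `b` (mediator ->
#' outcome) and pleiotropic PGS -> mediator paths, with the direct path
#' `c'` retained. Genetic (and retained shared-environmental) confounding
#' across exposure, mediators and outcome is carried by triangular
#' Cholesky systems ordered (exposure, mediators, outcome); all cross-trait
#' E covariances are fixed at zero. Shared-environmental components are
#' dropped per mediator via `drop_c`, mirroring the practice of
#' constraining nonsignificant C components to stabilise estimation.
#'
#' Mediators may be observed composites (character vector) or two latent
#' factors (a named list of two indicator sets). Latent factors are scaled
#' by a marker indicator; indicator uniquenesses carry their own AE
#' decomposition (cross-twin uniqueness correlation 1/0.5 for the A part).
#'
#' @inheritParams build_mrdoc_baseline_spec
#' @param mediators Character vector of observed mediator names, or a named
#'   list of two character vectors of indicator names (latent-factor
#'   variant).
#' @param drop_c Logical per mediator: drop its shared-environmental
#'   component (default all `TRUE`). Latent factors always use AE.
#' @param drop_c_exposure,drop_c_outcome Drop the shared-environmental
#'   component of the exposure / outcome (default `FALSE`); an AE-only
#'   model with all C dropped is useful for calibration studies whose
#'   generating model has no shared-environmental variance.
#' @param free_means Estimate means (default `TRUE`); fix them at zero for
#'   pre-centred simulated data.
#' @return A `pm_spec` with `mrdoc_map`, `mediation_map` and
#'   `constraint_tags` attributes.
#' @export
build_mrdoc_mediation_spec <- function(pgs = "pgs", exposure = "exposure",
                                       mediators, outcome = "outcome",
                                       drop_c = NULL, pleiotropy = TRUE,
                                       dz_pgs_cor = 0.5,
                                       drop_c_exposure = FALSE,
                                       drop_c_outcome = FALSE,
                                       free_means = TRUE) {
  latent_factors <- is.list(mediators)
  if (latent_factors) {
    if (length(mediators) != 2) stop("latent variant needs exactly 2 factors")
    if (any(lengths(mediators) < 2)) {
      stop("each latent factor needs >= 2 indicators for identification")
    }
    med_names <- if (!is.null(names(mediators))) names(mediators) else
      c("f1", "f2")
    indicators <- mediators
  } else {
    if (!length(mediators)) stop("`mediators` must be non-empty")
    med_names <- mediators
    indicators <- NULL
  }
  K <- length(med_names)
  if (is.null(drop_c)) drop_c <- rep(TRUE, K)
  if (length(drop_c) != K) {
    stop("`drop_c` must have one flag per mediator (", K, ")")
  }
  if (latent_factors && !all(drop_c)) {
    stop("latent factors are modelled AE; `drop_c` must be TRUE for them")
  }

  traits <- c(exposure, med_names, outcome)       # Cholesky order
  c_traits <- c(if (!drop_c_exposure) exposure, med_names[!drop_c],
                if (!drop_c_outcome) outcome)
  obs_traits <- if (latent_factors) {
    c(pgs, exposure, unlist(indicators), outcome)
  } else c(pgs, exposure, med_names, outcome)
  obs <- c(t(outer(obs_traits, 1:2, mrdoc_var)))
  lat <- character(0)
  if (latent_factors) {
    lat <- c(lat, c(t(outer(med_names, 1:2, mrdoc_var))))
    lat <- c(lat, c(t(outer(paste0("UA_", unlist(indicators)), 1:2,
                            mrdoc_var))))
  }
  nt <- length(traits)
  lat <- c(lat, c(t(outer(paste0("Af", seq_len(nt)), 1:2, mrdoc_var))))
  lat <- c(lat, c(t(outer(paste0("Cf", seq_along(c_traits)), 1:2,
                          mrdoc_var))))
  s <- pm_spec(obs, latent = lat, groups = c("MZ", "DZ"))

  tvar <- function(tr, i) {
    if (latent_factors && tr %in% med_names) mrdoc_var(tr, i) else
      mrdoc_var(tr, i)
  }
  amap <- paste0("a_", med_names)
  bmap <- paste0("b_", med_names)
  gmap <- paste0("gm_", med_names)
  for (i in 1:2) {
    p <- mrdoc_var(pgs, i); x <- mrdoc_var(exposure, i)
    y <- mrdoc_var(outcome, i)
    s <- pm_path(s, p, x, label = "g1", value = 0.1)
    s <- pm_path(s, x, y, label = "cp", value = 0.1)
    if (pleiotropy) s <- pm_path(s, p, y, label = "g2", value = 0.05)
    for (k in seq_len(K)) {
      m <- mrdoc_var(med_names[k], i)
      s <- pm_path(s, x, m, label = amap[k], value = 0.2)
      s <- pm_path(s, m, y, label = bmap[k], value = 0.1)
      s <- pm_path(s, p, m, label = gmap[k], value = 0.02)
    }
    # E components: residual variances, no cross-trait E covariances
    for (t in seq_along(traits)) {
      tv <- tvar(traits[t], i)
      s <- pm_cov(s, tv, tv, label = paste0("ve_", traits[t]), value = 0.5,
                  lower = 1e-8)
    }
    s <- pm_cov(s, p, p, label = "vp", value = 1, lower = 1e-8)
    if (free_means) {
      s <- pm_mean(s, p, label = "mu_p", value = 0)
      s <- pm_mean(s, x, label = paste0("mu_", exposure), value = 0)
      s <- pm_mean(s, y, label = paste0("mu_", outcome), value = 0)
    }
    if (latent_factors) {
      for (fj in med_names) {
        ind <- indicators[[fj]]
        fv <- mrdoc_var(fj, i)
        s <- pm_path(s, fv, mrdoc_var(ind[1], i), value = 1)  # marker
        for (v in ind[-1]) {
          s <- pm_path(s, fv, mrdoc_var(v, i), label = paste0("l_", v),
                       value = 0.8)
        }
      }
      for (v in unlist(indicators)) {
        vv <- mrdoc_var(v, i); ua <- mrdoc_var(paste0("UA_", v), i)
        s <- pm_path(s, ua, vv, label = paste0("ua_", v), value = 0.3,
                     lower = 0)
        s <- pm_cov(s, ua, ua, value = 1)
        s <- pm_cov(s, vv, vv, label = paste0("ue_", v), value = 0.3,
                    lower = 1e-8)
        if (free_means) {
          s <- pm_mean(s, vv, label = paste0("mu_", v), value = 0)
        }
      }
    } else if (free_means) {
      for (m in med_names) {
        s <- pm_mean(s, mrdoc_var(m, i), label = paste0("mu_", m), value = 0)
      }
    }
  }
  s <- pm_cov(s, mrdoc_var(pgs, 1), mrdoc_var(pgs, 2), label = "vp",
              scale = c(MZ = 1, DZ = dz_pgs_cor))
  s <- add_cholesky(s, traits, "Af", cross = c(MZ = 1, DZ = 0.5))
  if (length(c_traits)) {
    s <- add_cholesky(s, c_traits, "Cf", cross = c(MZ = 1, DZ = 1),
                      start = 0.3)
  }
  if (latent_factors) {
    for (v in unlist(indicators)) {
      s <- pm_cov(s, mrdoc_var(paste0("UA_", v), 1),
                  mrdoc_var(paste0("UA_", v), 2),
                  value = c(MZ = 1, DZ = 0.5))
    }
  }
  attr(s, "mrdoc_map") <- list(
    pgs = mrdoc_var(pgs, 1), exposure = mrdoc_var(exposure, 1),
    outcome = mrdoc_var(outcome, 1),
    instrumental = "g1", causal = NULL,
    pleiotropy_outcome = if (pleiotropy) "g2" else NULL,
    pleiotropy_mediators = stats::setNames(gmap, med_names),
    mediators = med_names)
  attr(s, "mediation_map") <- new_mediation_map(
    mrdoc_var(exposure, 1), mrdoc_var(outcome, 1),
    data.frame(name = med_names, med_var = mrdoc_var(med_names, 1),
               a_label = amap, b_label = bmap, stringsAsFactors = FALSE))
  attr(s, "constraint_tags") <- c(
    "re=0", "re_cross_trait=0",
    paste0("c_", med_names[drop_c], "=0"),
    if (drop_c_exposure) paste0("c_", exposure, "=0"),
    if (drop_c_outcome) paste0("c_", outcome, "=0"),
    if (!free_means) "means=0",
    if (!pleiotropy) "g2=0")
  s
}

# MZ co-twins carry one and the same polygenic score, so a pair-level
# multivariate-normal likelihood containing both copies is singular. The
# score therefore enters the MZ likelihood once per pair: the second
# twin's copy is masked and the pattern-wise FIML handles the reduced
# observed pattern exactly.
mask_mz_pgs <- function(pairs, spec) {
  map <- attr(spec, "mrdoc_map")
  if (is.null(map)) return(pairs)
  pgs2 <- sub("_1$", "_2", map$pgs)
  if (pgs2 %in% names(pairs)) {
    pairs[[pgs2]][pairs$zygosity == "MZ"] <- NA_real_
  }
  pairs
}

#' Fit an MR-DoC specification to a cohort
#'
#' Reshapes the cohort to twin pairs, z-scores the observed variables and
#' fits the two-group model by FIML.
#'
#' @param cohort A cohort data frame (one row per individual).
#' @param spec A `pm_spec` built by [build_mrdoc_baseline_spec()] or
#'   [build_mrdoc_mediation_spec()].
#' @param scale Z-score observed columns before pairing (default `TRUE`).
#' @param se Standard-error method passed to [fit_path_model()].
#' @param options Passed to [fit_path_model()].
#' @return A `pm_fit`.
#' @export
fit_mrdoc <- function(cohort, spec, scale = TRUE, se = NULL,
                      options = list()) {
  base_vars <- unique(sub("_[12]$", "", spec$observed))
  miss <- setdiff(base_vars, names(cohort))
  if (length(miss)) stop("cohort lacks column(s): ",
                         paste(miss, collapse = ", "))
  d <- cohort
  if (scale) for (v in base_vars) d[[v]] <- zscore(d[[v]])
  pw <- pair_wide(d, vars = base_vars)
  if (length(unique(pw$zygosity)) < 2) {
    stop("both zygosity groups are required")
  }
  pw <- mask_mz_pgs(pw, spec)
  fit_path_model(spec, pw, group = "zygosity", se = se, options = options)
}

#' Extract standardized MR-DoC effects
#'
#' Standardized instrumental, causal/direct and pleiotropic paths with
#' delta-method intervals, plus (for mediation specs) the full mediation
#' decomposition of [mediation_effects()].
#'
#' @param fit A converged `pm_fit` of an MR-DoC spec.
#' @param p_threshold Adjusted significance threshold (default `0.05 / 18`).
#' @return A list of class `mrdoc_effects`: `instrumental`,
#'   `pleiotropy_outcome`, `pleiotropy_mediators`, `causal` (baseline) or
#'   `mediation` (mediation specs), and `constraint_tags`.
#' @export
extract_mrdoc_effects <- function(fit, p_threshold = bonferroni_threshold(0.05, 18)$threshold) {
  stopifnot(inherits(fit, "pm_fit"))
  if (!fit$converged) stop("fit has not converged")
  map <- attr(fit$spec, "mrdoc_map")
  if (is.null(map)) stop("spec carries no mrdoc map")
  g <- fit$spec$groups[1]
  compiled <- fit$compiled
  qty_path <- function(from, to) {
    if (!fit$vcov_ok) {
      v <- std_path_at(compiled, fit$estimates, from, to, g)
      return(c(estimate = v, se = NA_real_, lower = NA_real_,
               upper = NA_real_, p = NA_real_))
    }
    dm <- delta_method(fit, function(th) std_path_at(compiled, th, from, to, g))
    c(estimate = dm$value, se = dm$se, lower = dm$ci[1], upper = dm$ci[2],
      p = dm$p)
  }
  out <- list(instrumental = qty_path(map$pgs, map$exposure))
  # weak-instrument diagnostic: instrument-exposure association below the
  # conventional z ~ 3.2 (F ~ 10) strength rule
  inst_z <- abs(out$instrumental[["estimate"]]) / out$instrumental[["se"]]
  out$weak_instrument <- !is.finite(inst_z) || inst_z < sqrt(10)
  if (!is.null(map$pleiotropy_outcome)) {
    out$pleiotropy_outcome <- qty_path(map$pgs, map$outcome)
  }
  if (length(map$pleiotropy_mediators)) {
    med1 <- paste0(names(map$pleiotropy_mediators), "_1")
    pm_rows <- lapply(med1, function(mv) qty_path(map$pgs, mv))
    out$pleiotropy_mediators <- do.call(rbind, pm_rows)
    rownames(out$pleiotropy_mediators) <- names(map$pleiotropy_mediators)
  }
  if (!is.null(map$causal)) {
    out$causal <- qty_path(map$exposure, map$outcome)
  }
  if (!is.null(attr(fit$spec, "mediation_map"))) {
    out$mediation <- mediation_effects(fit, p_threshold = p_threshold,
                                       group = g)
  }
  out$constraint_tags <- attr(fit$spec, "constraint_tags")
  class(out) <- "mrdoc_effects"
  out
}

#' @export
print.mrdoc_effects <- function(x, ...) {
  show <- function(nm, v) {
    cat(sprintf("  %s = %.3f [%.3f, %.3f]\n", nm, v[["estimate"]],
                v[["lower"]], v[["upper"]]))
  }
  cat("MR-DoC effects (standardized)\n")
  show("instrumental", x$instrumental)
  if (isTRUE(x$weak_instrument)) cat("    [weak instrument]\n")
  if (!is.null(x$pleiotropy_outcome)) {
    show("pleiotropic (outcome)", x$pleiotropy_outcome)
  }
  if (!is.null(x$causal)) show("causal", x$causal)
  if (!is.null(x$mediation)) print(x$mediation)
  cat("  constraints:", paste(x$constraint_tags, collapse = ", "), "\n")
  invisible(x)
}

#' MR-DoC results table
#'
#' Flattens extracted MR-DoC effects into one row per mediator in the
#' column order of published mediation tables — `a`, `b`, `c_prime`, `ab`,
#' and the pleiotropic path, each with lower/upper 95% bounds — plus the
#' constraint tags and fit indices of the model.
#'
#' @param effects An `mrdoc_effects` object from [extract_mrdoc_effects()].
#' @param fit The `pm_fit` the effects were extracted from (for fit
#'   indices); optional.
#' @return A data frame; write it with `utils::write.csv()`.
#' @export
mrdoc_results_table <- function(effects, fit = NULL) {
  stopifnot(inherits(effects, "mrdoc_effects"))
  tags <- paste(effects$constraint_tags, collapse = ";")
  if (is.null(effects$mediation)) {
    med <- effects$causal
    out <- data.frame(
      mediator = NA_character_,
      a = NA_real_, a_lCI = NA_real_, a_uCI = NA_real_,
      b = NA_real_, b_lCI = NA_real_, b_uCI = NA_real_,
      c_prime = med[["estimate"]], c_prime_lCI = med[["lower"]],
      c_prime_uCI = med[["upper"]],
      ab = NA_real_, ab_lCI = NA_real_, ab_uCI = NA_real_,
      pleiotropic = effects$pleiotropy_outcome[["estimate"]],
      pleiotropic_lCI = effects$pleiotropy_outcome[["lower"]],
      pleiotropic_uCI = effects$pleiotropy_outcome[["upper"]],
      stringsAsFactors = FALSE)
  } else {
    tab <- effects$mediation$table
    cp <- effects$mediation$c_prime
    pm <- effects$pleiotropy_mediators
    out <- data.frame(
      mediator = tab$mediator,
      a = tab$a, a_lCI = tab$a_lower, a_uCI = tab$a_upper,
      b = tab$b, b_lCI = tab$b_lower, b_uCI = tab$b_upper,
      c_prime = cp[["estimate"]], c_prime_lCI = cp[["lower"]],
      c_prime_uCI = cp[["upper"]],
      ab = tab$ab, ab_lCI = tab$ab_lower, ab_uCI = tab$ab_upper,
      pleiotropic = pm[tab$mediator, "estimate"],
      pleiotropic_lCI = pm[tab$mediator, "lower"],
      pleiotropic_uCI = pm[tab$mediator, "upper"],
      stringsAsFactors = FALSE)
  }
  out$instrumental <- effects$instrumental[["estimate"]]
  if (!is.null(effects$mediation)) {
    out$sum_ab <- effects$mediation$sum_ab[["estimate"]]
    out$percent_mediated <- effects$mediation$percent_mediated
  }
  out$constraint_tags <- tags
  if (!is.null(fit)) {
    out$minus2ll <- fit$minus2ll
    out$aic <- fit$aic
    out$bic <- fit$bic
    out$n_params <- fit$n_params
  }
  rownames(out) <- NULL
  out
}

#' Assign twin pairs to exposure strata
#'
#' Median split of the pair-mean exposure, keeping families intact: pairs
#' whose mean exposure is strictly above the cohort median of pair means
#' are labelled `"high"`.
#'
#' @param cohort A cohort data frame.
#' @param trait Stratifying trait (default `"exposure"`).
#' @return A data frame with `family_id` and `stratum`.
#' @export
pair_strata <- function(cohort, trait = "exposure") {
  pw <- pair_wide(cohort, vars = trait)
  pmean <- rowMeans(pw[, paste0(trait, c("_1", "_2"))], na.rm = TRUE)
  lab <- median_split(pmean)
  data.frame(family_id = pw$family_id, stratum = as.character(lab),
             stringsAsFactors = FALSE)
}

# Expand a two-group spec into zygosity-by-stratum groups, freeing the
# given labels separately per stratum.
pm_stratify <- function(spec, strata_levels, free_labels = character(0)) {
  new_groups <- as.vector(outer(spec$groups, strata_levels, paste, sep = "."))
  out <- pm_spec(spec$observed, spec$latent, groups = new_groups)
  expand_named <- function(x) {
    if (is.null(names(x))) return(x)
    vals <- unlist(lapply(names(x), function(g) {
      stats::setNames(rep(x[[g]], length(strata_levels)),
                      paste(g, strata_levels, sep = "."))
    }))
    vals
  }
  for (e in spec$entries) {
    gr <- if (is.null(e$groups)) NULL else
      as.vector(outer(e$groups, strata_levels, paste, sep = "."))
    val <- expand_named(e$value)
    sc <- expand_named(e$scale)
    if (!is.na(e$label) && e$label %in% free_labels) {
      for (st in strata_levels) {
        gst <- if (is.null(gr)) {
          as.vector(outer(spec$groups, st, paste, sep = "."))
        } else grep(paste0("\\.", st, "$"), gr, value = TRUE)
        out$entries[[length(out$entries) + 1L]] <- utils::modifyList(
          e, list(label = paste(e$label, st, sep = "."), value = val,
                  scale = sc, groups = gst))
      }
    } else {
      out$entries[[length(out$entries) + 1L]] <- utils::modifyList(
        e, list(value = val, scale = sc, groups = gr))
    }
  }
  out
}

#' Test equality of mediation paths across exposure strata
#'
#' Fits a zygosity-by-stratum multi-group version of a two-group MR-DoC (or
#' other twin) specification twice -- once with the selected path labels
#' freely estimated per stratum and once with them constrained equal -- and
#' compares the two by likelihood-ratio test.
#'
#' @param spec A two-group `pm_spec` (groups MZ, DZ).
#' @param pairs Pair-wide data frame (from [pair_wide()]) with a `zygosity`
#'   column.
#' @param strata Stratum labels: a vector aligned with `pairs` rows, or a
#'   data frame with `family_id` and `stratum` (e.g. from [pair_strata()]).
#' @param free_labels Labels freed across strata; defaults to the mediation
#'   paths (`a`, `b`, `c'`) recorded in the spec's mediation map.
#' @param options Passed to [fit_path_model()].
#' @return A list with `free`, `constrained` (both `pm_fit`) and `lrt`.
#' @export
stratified_equality_test <- function(spec, pairs, strata,
                                     free_labels = NULL, options = list()) {
  if (is.data.frame(strata)) {
    idx <- match(pairs$family_id, strata$family_id)
    if (anyNA(idx)) stop("strata data frame lacks some families")
    strata <- strata$stratum[idx]
  }
  if (length(strata) != nrow(pairs)) {
    stop("`strata` must supply one label per pair")
  }
  lev <- sort(unique(as.character(strata)))
  if (length(lev) != 2) stop("exactly 2 strata are required")
  if (is.null(free_labels)) {
    mm <- attr(spec, "mediation_map")
    if (is.null(mm)) stop("spec has no mediation map; supply `free_labels`")
    free_labels <- c(mm$mediators$a_label, mm$mediators$b_label, mm$c_prime)
  }
  d <- mask_mz_pgs(pairs, spec)
  d$.group <- paste(d$zygosity, strata, sep = ".")
  counts <- table(factor(d$.group,
                         as.vector(outer(spec$groups, lev, paste, sep = "."))))
  if (any(counts == 0)) {
    stop("empty zygosity-by-stratum cell: ",
         names(counts)[counts == 0][1])
  }
  spec_c <- pm_stratify(spec, lev, character(0))
  spec_f <- pm_stratify(spec, lev, free_labels)
  opt_c <- utils::modifyList(list(se = "none"), options)
  fit_c <- fit_path_model(spec_c, d, group = ".group",
                          se = opt_c$se, options = opt_c[names(opt_c) != "se"])
  # warm-start the free model from the constrained solution
  st <- fit_c$estimates
  extra <- unlist(lapply(free_labels, function(l) {
    stats::setNames(rep(st[[l]], 2), paste(l, lev, sep = "."))
  }))
  st_f <- c(st[setdiff(names(st), free_labels)], extra)
  opt_f <- utils::modifyList(opt_c, list(start = st_f))
  fit_f <- fit_path_model(spec_f, d, group = ".group",
                          se = opt_f$se,
                          options = opt_f[names(opt_f) != "se"])
  list(free = fit_f, constrained = fit_c, lrt = lrt(fit_f, fit_c))
}
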