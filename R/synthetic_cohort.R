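# Seeded synthetic twin cohorts with the genetic, environmental, factor and
# measurement structure assumed by the downstream models:
#   pgs -> exposure (instrumental), pgs -> mediators/outcome (pleiotropic),
#   exposure -> two latent mediator factors -> outcome (a / b paths) plus a
#   direct path (c'), ACE-structured residuals with cross-trait confounding,
#   18 mediator composites loading on the two factors, and 5-point ordinal
#   items averaged into composites under a >=50%-non-missing rule.

#' Default mediator factor-loading matrix
#'
#' Two-factor loading pattern for the mediator battery: the first factor
#' (negative/disordered affect) loads the internalizing-type composites,
#' the second (externalizing tendencies) the externalizing-type ones, with
#' reversed-keyed traits loading negatively. For mediator counts other
#' than 18 a generic half-split pattern is returned.
#'
#' @param n_mediators Number of mediator composites (default 18).
#' @return An `n_mediators` x 2 matrix with mediator row names.
#' @export
default_factor_loadings <- function(n_mediators = 18) {
  if (n_mediators == 18) {
    # factor 1: negative/disordered affect; factor 2: externalizing
    l1 <- c(0.70, -0.55, 0.75, 0.78, 0.55, 0.65, -0.60,
            rep(0, 11))
    l2 <- c(rep(0, 7),
            0.55, -0.60, 0.70, 0.65, -0.55, 0.68, 0.62, -0.50, -0.45,
            0.60, 0.30)
  } else {
    k1 <- ceiling(n_mediators / 2)
    l1 <- c(rep(0.65, k1), rep(0, n_mediators - k1))
    l2 <- c(rep(0, k1), rep(0.60, n_mediators - k1))
  }
  m <- cbind(f1 = l1, f2 = l2)
  rownames(m) <- sprintf("med_%02d", seq_len(n_mediators))
  m
}

check_ace <- function(x, field) {
  x <- as.numeric(x)
  if (length(x) != 3 || anyNA(x)) {
    stop("`", field, "` must be three variance proportions")
  }
  if (any(x < 0) || any(x > 1)) {
    stop("`", field, "` has proportions outside [0, 1]")
  }
  if (abs(sum(x) - 1) > 1e-12) {
    stop("`", field, "` must sum to 1 (got ", format(sum(x)), ")")
  }
  x
}

check_thresholds <- function(x, field) {
  if (anyNA(x) || is.unsorted(x, strictly = TRUE)) {
    stop("`", field, "` must be strictly increasing")
  }
  x
}

#' Simulation configuration for a synthetic twin cohort
#'
#' Bundles and validates every generating quantity of the synthetic cohort:
#' pair counts, ACE variance triples for the exposure, outcome, mediator
#' factors and mediator uniquenesses, the polygenic-score instrumental and
#' pleiotropic paths, the mediation paths (`a_paths`, `b_paths`, `c_prime`),
#' the 18-by-2 factor loading matrix, residual cross-trait confounding
#' correlations, and the ordinal measurement layer (items per composite,
#' thresholds, item reliability, missingness rate).
#'
#' Defaults follow the conditions of a large UK twin register study of
#' childhood maltreatment and intimate partner violence victimization:
#' 1988 MZ and 3683 DZ pairs; maltreatment ACE about a third each;
#' IPV ACE (0.17, 0.07, 0.76); instrumental path 0.09; pleiotropic path to
#' the outcome 0.06; factor-level mediation paths a = 0.29 (both factors),
#' b = (0.17, 0.14), direct effect c' = 0.05 (total causal effect 0.14);
#' residual A and C confounding correlations calibrated so that the implied
#' phenotypic exposure-outcome correlation is about 0.23.
#'
#' @param n_pairs_mz,n_pairs_dz Number of MZ / DZ twin pairs.
#' @param ace_exposure,ace_outcome ACE variance-proportion triples for the
#'   exposure and outcome residuals (each sums to 1).
#' @param ace_factors 2-by-3 matrix of ACE triples for the two mediator
#'   factor disturbances.
#' @param ace_mediators K-by-3 matrix of ACE triples for the mediator
#'   uniquenesses.
#' @param instrumental_path Standardized PGS -> exposure coefficient.
#' @param pleiotropy_outcome Standardized PGS -> outcome coefficient.
#' @param pleiotropy_factors Length-2 PGS -> factor coefficients.
#' @param pleiotropy_mediators Length-K PGS -> mediator-uniqueness
#'   coefficients.
#' @param a_paths Length-2 exposure -> factor coefficients.
#' @param b_paths Length-2 factor -> outcome coefficients.
#' @param c_prime Direct exposure -> outcome coefficient.
#' @param factor_loadings K-by-2 loading matrix of mediators on the two
#'   factors; row names become mediator column names.
#' @param factor_correlation Residual correlation between the two factor
#'   disturbances.
#' @param confounder_cor Named vector `c(r_a, r_c, r_e)`: cross-trait
#'   correlations among the A, C and E residual components of exposure,
#'   factors and outcome.
#' @param dz_pgs_cor Cross-twin PGS correlation in DZ pairs (0.5 under
#'   random mating; MZ pairs always share the PGS exactly).
#' @param measurement `"ordinal"` (5-point items averaged into composites)
#'   or `"latent"` (continuous latent scores returned directly, used for
#'   parameter-recovery studies free of measurement attenuation).
#' @param items_exposure,items_outcome,items_mediator Items per composite.
#' @param thresholds_exposure,thresholds_outcome,thresholds_mediator
#'   Strictly increasing cut points on the standard-normal item scale;
#'   defaults give right-skewed exposure/outcome scores and symmetric
#'   mediator scores.
#' @param item_reliability Proportion of item variance due to the latent
#'   composite score.
#' @param missing_rate Per-item missing-completely-at-random probability.
#' @param seed Integer seed for the generator stream.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_pairs_mz = 1988, n_pairs_dz = 3683,
                       ace_exposure = c(1, 1, 1) / 3,
                       ace_outcome = c(0.17, 0.07, 0.76),
                       ace_factors = matrix(rep(c(0.3, 0.1, 0.6), each = 2), 2),
                       ace_mediators = NULL,
                       instrumental_path = 0.09,
                       pleiotropy_outcome = 0.06,
                       pleiotropy_factors = c(0.04, 0.03),
                       pleiotropy_mediators = NULL,
                       a_paths = c(0.29, 0.29),
                       b_paths = c(0.17, 0.14),
                       c_prime = 0.05,
                       factor_loadings = default_factor_loadings(),
                       factor_correlation = 0.45,
                       confounder_cor = c(r_a = 0.17, r_c = 0.17, r_e = 0),
                       dz_pgs_cor = 0.5,
                       measurement = c("ordinal", "latent"),
                       items_exposure = 8L, items_outcome = 6L,
                       items_mediator = 5L,
                       thresholds_exposure = stats::qnorm(c(0.55, 0.75, 0.88, 0.96)),
                       thresholds_outcome = stats::qnorm(c(0.55, 0.75, 0.88, 0.96)),
                       thresholds_mediator = stats::qnorm(c(0.2, 0.4, 0.6, 0.8)),
                       item_reliability = 0.8,
                       missing_rate = 0.02,
                       seed = 1L) {
  measurement <- match.arg(measurement)
  factor_loadings <- as.matrix(factor_loadings)
  if (ncol(factor_loadings) != 2) stop("`factor_loadings` must have 2 columns")
  K <- nrow(factor_loadings)
  if (is.null(rownames(factor_loadings))) {
    rownames(factor_loadings) <- sprintf("med_%02d", seq_len(K))
  }
  if (is.null(ace_mediators)) {
    ace_mediators <- matrix(rep(c(0.3, 0.1, 0.6), each = max(K, 1)),
                            nrow = max(K, 1))[seq_len(K), , drop = FALSE]
  }
  ace_mediators <- as.matrix(ace_mediators)
  if (nrow(ace_mediators) != K) {
    stop("`ace_mediators` must have one row per mediator (", K, ")")
  }
  if (is.null(pleiotropy_mediators)) pleiotropy_mediators <- rep(0, K)
  if (length(pleiotropy_mediators) != K) {
    stop("`pleiotropy_mediators` must have length ", K)
  }

  if (n_pairs_mz < 1 || n_pairs_dz < 1) {
    stop("`n_pairs_mz` and `n_pairs_dz` must be >= 1")
  }
  check_ace(ace_exposure, "ace_exposure")
  check_ace(ace_outcome, "ace_outcome")
  for (j in 1:2) check_ace(ace_factors[j, ], sprintf("ace_factors[%d,]", j))
  for (k in seq_len(K)) {
    check_ace(ace_mediators[k, ], sprintf("ace_mediators[%d,]", k))
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("`missing_rate` must be in [0, 1)")
  }
  if (abs(factor_correlation) >= 1) {
    stop("`factor_correlation` must be in (-1, 1)")
  }
  if (dz_pgs_cor < 0 || dz_pgs_cor > 1) stop("`dz_pgs_cor` must be in [0, 1]")
  if (item_reliability <= 0 || item_reliability > 1) {
    stop("`item_reliability` must be in (0, 1]")
  }
  cc <- confounder_cor
  if (is.null(names(cc))) names(cc) <- c("r_a", "r_c", "r_e")
  if (any(abs(cc) > 1)) stop("`confounder_cor` entries must be in [-1, 1]")
  check_thresholds(thresholds_exposure, "thresholds_exposure")
  check_thresholds(thresholds_outcome, "thresholds_outcome")
  check_thresholds(thresholds_mediator, "thresholds_mediator")

  cfg <- list(
    n_pairs_mz = as.integer(n_pairs_mz), n_pairs_dz = as.integer(n_pairs_dz),
    ace_exposure = ace_exposure, ace_outcome = ace_outcome,
    ace_factors = ace_factors, ace_mediators = ace_mediators,
    instrumental_path = instrumental_path,
    pleiotropy_outcome = pleiotropy_outcome,
    pleiotropy_factors = pleiotropy_factors,
    pleiotropy_mediators = pleiotropy_mediators,
    a_paths = a_paths, b_paths = b_paths, c_prime = c_prime,
    factor_loadings = factor_loadings,
    factor_correlation = factor_correlation,
    confounder_cor = cc, dz_pgs_cor = dz_pgs_cor,
    measurement = measurement,
    items_exposure = as.integer(items_exposure),
    items_outcome = as.integer(items_outcome),
    items_mediator = as.integer(items_mediator),
    thresholds_exposure = thresholds_exposure,
    thresholds_outcome = thresholds_outcome,
    thresholds_mediator = thresholds_mediator,
    item_reliability = item_reliability,
    missing_rate = missing_rate, seed = as.integer(seed),
    n_mediators = K
  )
  class(cfg) <- "sim_config"
  # structural solve fails early on inadmissible configurations
  invisible(sim_structure(cfg))
  cfg
}

# Residual correlation matrix for one variance component over the four
# structural traits (exposure, factor 1, factor 2, outcome).
residual_cor <- function(r, rho_f) {
  R <- matrix(r, 4, 4)
  diag(R) <- 1
  R[2, 3] <- R[3, 2] <- rho_f
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop("`confounder_cor`/`factor_correlation` imply a non-positive-definite ",
         "residual correlation matrix")
  }
  R
}

# Solve residual variances so every structural trait has unit variance, and
# return the linear structure shared by both zygosity groups.
sim_structure <- function(cfg) {
  B <- matrix(0, 4, 4, dimnames = list(c("X", "F1", "F2", "Y"),
                                       c("X", "F1", "F2", "Y")))
  B["F1", "X"] <- cfg$a_paths[1]
  B["F2", "X"] <- cfg$a_paths[2]
  B["Y", "X"] <- cfg$c_prime
  B["Y", "F1"] <- cfg$b_paths[1]
  B["Y", "F2"] <- cfg$b_paths[2]
  Gam <- c(cfg$instrumental_path, cfg$pleiotropy_factors,
           cfg$pleiotropy_outcome)
  Ks <- solve(diag(4) - B)

  props <- rbind(cfg$ace_exposure, cfg$ace_factors[1, ], cfg$ace_factors[2, ],
                 cfg$ace_outcome)
  r <- cfg$confounder_cor
  Rc <- list(A = residual_cor(r[["r_a"]], cfg$factor_correlation),
             C = residual_cor(r[["r_c"]], cfg$factor_correlation),
             E = residual_cor(r[["r_e"]], cfg$factor_correlation))

  within_res <- function(vres) {
    W <- matrix(0, 4, 4)
    for (ci in 1:3) {
      d <- sqrt(props[, ci] * vres)
      W <- W + (d %o% d) * Rc[[ci]]
    }
    W
  }
  implied_var <- function(vres, t) {
    W <- within_res(vres)
    V <- Ks %*% (tcrossprod(Gam) + W) %*% t(Ks)
    V[t, t]
  }
  vres <- c(1 - cfg$instrumental_path^2, 0.5, 0.5, 0.5)
  if (vres[1] <= 0) stop("`instrumental_path` implies exposure variance > 1")
  for (t in 2:4) {
    f <- function(v) {
      vv <- vres; vv[t] <- v
      implied_var(vv, t) - 1
    }
    if (f(1e-10) > 0) {
      stop("paths imply variance > 1 for trait '",
           c("exposure", "factor_1", "factor_2", "outcome")[t], "'")
    }
    vres[t] <- stats::uniroot(f, c(1e-10, 2), tol = 1e-12)$root
  }
  W <- within_res(vres)
  comp_cov <- lapply(1:3, function(ci) {
    d <- sqrt(props[, ci] * vres)
    (d %o% d) * Rc[[ci]]
  })
  names(comp_cov) <- c("A", "C", "E")
  list(B = B, Gam = Gam, Ks = Ks, vres = vres, W = W,
       comp_cov = comp_cov, props = props)
}

# Full pair covariance over (pgs, exposure, F1, F2, Y, med_1..K) x 2 twins.
pair_covariance <- function(cfg, zygosity, struct = sim_structure(cfg)) {
  alpha <- if (zygosity == "MZ") 1 else 0.5
  alpha_p <- if (zygosity == "MZ") 1 else cfg$dz_pgs_cor
  K <- cfg$n_mediators
  Ks <- struct$Ks
  Gam <- struct$Gam
  coefP <- drop(Ks %*% Gam)          # structural coefficients on own-twin pgs

  # basis: P1, P2, r1 (4), r2 (4), u1 (K), u2 (K)
  nb <- 2 + 8 + 2 * K
  SigU <- matrix(0, nb, nb)
  SigU[1:2, 1:2] <- matrix(c(1, alpha_p, alpha_p, 1), 2)
  Bz <- alpha * struct$comp_cov$A + struct$comp_cov$C
  SigU[3:6, 3:6] <- struct$W
  SigU[7:10, 7:10] <- struct$W
  SigU[3:6, 7:10] <- Bz
  SigU[7:10, 3:6] <- t(Bz)

  # mediator uniqueness variances from unit-variance targets
  uvar <- ucross <- numeric(K)
  if (K > 0) {
    # within-twin covariance of (F1, F2, P)
    Vfull <- Ks %*% (tcrossprod(Gam) + struct$W) %*% t(Ks)
    SFP <- matrix(0, 3, 3)
    SFP[1:2, 1:2] <- Vfull[2:3, 2:3]
    SFP[3, 3] <- 1
    SFP[1:2, 3] <- SFP[3, 1:2] <- coefP[2:3]
    for (k in seq_len(K)) {
      w <- c(cfg$factor_loadings[k, ], cfg$pleiotropy_mediators[k])
      expl <- drop(t(w) %*% SFP %*% w)
      if (expl > 1 + 1e-10) {
        stop("`factor_loadings` row ", k, " implies mediator variance > 1")
      }
      uvar[k] <- max(1 - expl, 0)
      pk <- cfg$ace_mediators[k, ]
      ucross[k] <- (alpha * pk[1] + pk[2]) * uvar[k]
    }
    iu1 <- 10 + seq_len(K); iu2 <- 10 + K + seq_len(K)
    diag(SigU)[c(iu1, iu2)] <- rep(uvar, 2)
    SigU[cbind(iu1, iu2)] <- ucross
    SigU[cbind(iu2, iu1)] <- ucross
  }

  # loading matrix: rows = output variables, twin 1 block then twin 2 block
  nv <- 5 + K
  L <- matrix(0, 2 * nv, nb)
  vn <- c("pgs", "exposure", "f1", "f2", "outcome",
          rownames(cfg$factor_loadings))
  for (tw in 1:2) {
    off <- (tw - 1) * nv
    iP <- tw
    ir <- if (tw == 1) 3:6 else 7:10
    iu <- if (tw == 1) 10 + seq_len(K) else 10 + K + seq_len(K)
    L[off + 1, iP] <- 1
    for (t in 1:4) {                  # X, F1, F2, Y
      L[off + 1 + t, iP] <- coefP[t]
      L[off + 1 + t, ir] <- Ks[t, ]
    }
    for (k in seq_len(K)) {
      lam <- cfg$factor_loadings[k, ]
      L[off + 5 + k, ] <- lam[1] * L[off + 3, ] + lam[2] * L[off + 4, ]
      L[off + 5 + k, iP] <- L[off + 5 + k, iP] + cfg$pleiotropy_mediators[k]
      L[off + 5 + k, iu[k]] <- 1
    }
  }
  Sig <- L %*% SigU %*% t(L)
  Sig <- (Sig + t(Sig)) / 2
  rownames(Sig) <- colnames(Sig) <- c(paste0(vn, "_1"), paste0(vn, "_2"))
  Sig
}

make_items <- function(latent, n_items, thresholds, reliability) {
  n <- length(latent)
  items <- matrix(NA_real_, n, n_items)
  sl <- sqrt(reliability); sn <- sqrt(1 - reliability)
  for (j in seq_len(n_items)) {
    x <- sl * latent + sn * stats::rnorm(n)
    items[, j] <- findInterval(x, thresholds)
  }
  items
}

#' Generate a synthetic twin cohort
#'
#' Draws twin pairs from the multivariate-normal latent model implied by a
#' [sim_config()]: cross-twin correlations 1.0 (MZ) / 0.5 (DZ) for additive
#' genetic components, 1.0 for shared environment in both zygosities, 0 for
#' nonshared environment, and a polygenic score shared exactly by MZ
#' co-twins and correlated `dz_pgs_cor` in DZ pairs. Under ordinal
#' measurement, continuous mediator/exposure/outcome indicators are
#' discretized into 5-point items (scored 0-4), thinned by
#' missing-completely-at-random item nonresponse and averaged into
#' composites requiring at least half the items observed.
#'
#' @param config A [sim_config()].
#' @return A data frame with one row per individual: `family_id`,
#'   `zygosity` (`MZ`, `DZss`, `DZos`), `twin` (1 or 2), `pgs`, `exposure`,
#'   mediator composites, `outcome`. Under ordinal measurement the item
#'   matrices are attached as attribute `"items"`; the generating
#'   configuration is attached as `"config"`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("`config` must be created with sim_config()")
  }
  cfg <- config
  set.seed(cfg$seed)
  struct <- sim_structure(cfg)
  K <- cfg$n_mediators
  med_names <- rownames(cfg$factor_loadings)

  draw_group <- function(n_pairs, zygosity) {
    Sig <- pair_covariance(cfg, zygosity, struct)
    Z <- MASS::mvrnorm(n_pairs, mu = rep(0, ncol(Sig)), Sigma = Sig,
                       tol = 1e-6)
    if (n_pairs == 1) Z <- matrix(Z, nrow = 1)
    colnames(Z) <- colnames(Sig)
    Z
  }
  mz <- draw_group(cfg$n_pairs_mz, "MZ")
  dz <- draw_group(cfg$n_pairs_dz, "DZ")
  mz[, "pgs_2"] <- mz[, "pgs_1"]      # MZ co-twins share the genome exactly

  nv <- 5 + K
  to_long <- function(Z, fam0, zyg_labels) {
    n <- nrow(Z)
    one <- function(tw) {
      cols <- (tw - 1) * nv + seq_len(nv)
      d <- as.data.frame(Z[, cols, drop = FALSE])
      names(d) <- c("pgs", "exposure", "f1", "f2", "outcome", med_names)
      cbind(family_id = fam0 + seq_len(n), zygosity = zyg_labels,
            twin = tw, d)
    }
    rbind(one(1), one(2))
  }
  n_dzss <- ceiling(cfg$n_pairs_dz / 2)
  dz_labels <- rep(c("DZss", "DZos"),
                   c(n_dzss, cfg$n_pairs_dz - n_dzss))
  long <- rbind(to_long(mz, 0L, "MZ"),
                to_long(dz, cfg$n_pairs_mz, dz_labels))
  long <- long[order(long$family_id, long$twin), ]
  rownames(long) <- NULL

  if (cfg$measurement == "latent") {
    cohort <- long[, c("family_id", "zygosity", "twin", "pgs", "exposure",
                       med_names, "outcome")]
    attr(cohort, "config") <- cfg
    attr(cohort, "latent") <- long[, c("f1", "f2")]
    return(cohort)
  }

  items <- list()
  items$exposure <- make_items(long$exposure, cfg$items_exposure,
                               cfg$thresholds_exposure, cfg$item_reliability)
  items$outcome <- make_items(long$outcome, cfg$items_outcome,
                              cfg$thresholds_outcome, cfg$item_reliability)
  for (m in med_names) {
    items[[m]] <- make_items(long[[m]], cfg$items_mediator,
                             cfg$thresholds_mediator, cfg$item_reliability)
  }
  cohort <- long[, c("family_id", "zygosity", "twin")]
  cohort$pgs <- long$pgs
  cohort$exposure <- NA_real_
  for (m in med_names) cohort[[m]] <- NA_real_
  cohort$outcome <- NA_real_
  attr(cohort, "items") <- items
  attr(cohort, "config") <- cfg
  attr(cohort, "latent") <- long[, c("exposure", "f1", "f2", med_names,
                                     "outcome")]
  inject_missingness(cohort, cfg$missing_rate,
                     seed = cfg$seed + 1L)
}

#' Composite score from ordinal items
#'
#' Mean of the non-missing items, provided at least `min_fraction` of the
#' items are observed; otherwise missing.
#'
#' @param items Numeric vector of item values (may contain `NA`).
#' @param min_fraction Minimum observed fraction in `(0, 1]`; default 0.5.
#' @return The composite score, or `NA` if too few items are observed.
#' @export
composite_score <- function(items, min_fraction = 0.5) {
  if (length(items) == 0) stop("`items` must be non-empty")
  if (min_fraction <= 0 || min_fraction > 1) {
    stop("`min_fraction` must be in (0, 1]")
  }
  obs <- !is.na(items)
  if (mean(obs) >= min_fraction) mean(items[obs]) else NA_real_
}

composite_matrix <- function(items, min_fraction = 0.5) {
  obs <- !is.na(items)
  frac <- rowMeans(obs)
  out <- rowMeans(items, na.rm = TRUE)
  out[frac < min_fraction] <- NA_real_
  out[is.nan(out)] <- NA_real_
  out
}

#' Inject item-level missingness and recompute composites
#'
#' Sets each item value missing independently with probability `rate`
#' (missing completely at random) and recomputes the composite scores under
#' the >=50%-observed rule. Requires the item matrices attached by
#' [generate_cohort()] under ordinal measurement; for cohorts without item
#' data the composite values themselves are set missing at `rate`.
#'
#' @param cohort A cohort data frame.
#' @param rate Missingness probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return The cohort with updated composites (and `"items"` attribute).
#' @export
inject_missingness <- function(cohort, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) stop("`rate` must be in [0, 1)")
  set.seed(seed)
  items <- attr(cohort, "items")
  if (is.null(items)) {
    if (rate == 0) return(cohort)
    cols <- setdiff(names(cohort), c("family_id", "zygosity", "twin", "pgs"))
    for (cn in cols) {
      drop_i <- stats::runif(nrow(cohort)) < rate
      cohort[[cn]][drop_i] <- NA_real_
    }
    return(cohort)
  }
  for (nm in names(items)) {
    m <- items[[nm]]
    if (rate > 0) {
      m[matrix(stats::runif(length(m)) < rate, nrow(m))] <- NA_real_
      items[[nm]] <- m
    }
    cohort[[nm]] <- composite_matrix(m)
  }
  attr(cohort, "items") <- items
  cohort
}

cohort_columns <- function(cohort) {
  base <- c("family_id", "zygosity", "twin", "pgs")
  meds <- grep("^med_", names(cohort), value = TRUE)
  c(base, "exposure", meds, "outcome")
}

#' Write / read a simulation configuration as YAML
#'
#' Serializes a [sim_config()] to a structured text file whose keys mirror
#' the configuration fields exactly; matrices are stored row-wise.
#' `read_sim_config()` revalidates on load, so a hand-edited file that
#' violates an invariant (an ACE triple not summing to 1, say) is rejected
#' with the offending field named.
#'
#' @param config A `sim_config`.
#' @param path File path.
#' @return `write_sim_config()` returns `path` invisibly;
#'   `read_sim_config()` returns a validated `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  x$n_mediators <- NULL
  med_names <- rownames(x$factor_loadings)
  fac_names <- colnames(x$factor_loadings)
  for (m in c("factor_loadings", "ace_mediators", "ace_factors")) {
    x[[m]] <- apply(x[[m]], 1, as.numeric, simplify = FALSE)
  }
  x$mediator_names <- med_names
  x$factor_names <- fac_names
  # full double precision so validated invariants (ACE sums) survive the
  # round trip
  yaml::write_yaml(x, path, precision = 17L)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  med_names <- x$mediator_names
  fac_names <- x$factor_names
  x$mediator_names <- NULL
  x$factor_names <- NULL
  as_mat <- function(rows, ncol) {
    if (!length(rows)) return(matrix(numeric(0), 0, ncol))
    do.call(rbind, lapply(rows, as.numeric))
  }
  x$factor_loadings <- as_mat(x$factor_loadings, 2)
  if (nrow(x$factor_loadings)) rownames(x$factor_loadings) <- med_names
  if (!is.null(fac_names)) colnames(x$factor_loadings) <- fac_names
  x$ace_mediators <- as_mat(x$ace_mediators, 3)
  x$ace_factors <- as_mat(x$ace_factors, 3)
  x$confounder_cor <- unlist(x$confounder_cor)
  do.call(sim_config, x)
}

#' Write a twin cohort to CSV
#'
#' Columns: `family_id`, `zygosity` (MZ, DZss, DZos), `twin` (1, 2), `pgs`,
#' `exposure`, `med_01`..`med_K`, `outcome`; empty cells denote missing
#' values; UTF-8 with a single header line.
#'
#' @param cohort A cohort data frame.
#' @param path Output file path.
#' @export
write_cohort <- function(cohort, path) {
  cols <- cohort_columns(cohort)
  miss <- setdiff(cols, names(cohort))
  if (length(miss)) stop("cohort lacks column(s): ", paste(miss, collapse = ", "))
  utils::write.csv(cohort[, cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a twin cohort from CSV
#'
#' Validates the documented schema: exactly two rows per family with twin
#' indices 1 and 2, consistent zygosity within pairs, and identical
#' polygenic scores for MZ co-twins.
#'
#' @param path CSV file written by [write_cohort()] or conforming to its
#'   schema.
#' @param strict If `TRUE` (default) schema violations are errors; if
#'   `FALSE`, MZ polygenic-score mismatches are downgraded to warnings.
#' @return A cohort data frame.
#' @export
read_cohort <- function(path, strict = TRUE) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("family_id", "zygosity", "twin", "pgs", "exposure", "outcome")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("cohort file lacks column(s): ",
                         paste(miss, collapse = ", "))
  bad_z <- which(!d$zygosity %in% c("MZ", "DZss", "DZos"))
  if (length(bad_z)) {
    stop("invalid zygosity at row ", bad_z[1], ": '", d$zygosity[bad_z[1]], "'")
  }
  bad_t <- which(!d$twin %in% c(1L, 2L))
  if (length(bad_t)) stop("invalid twin index at row ", bad_t[1])
  tab <- table(d$family_id)
  if (any(tab != 2)) {
    fam <- names(tab)[tab != 2][1]
    stop("family ", fam, " has ", tab[[fam]], " row(s); expected exactly 2 ",
         "(first at row ", which(d$family_id == fam)[1], ")")
  }
  ord <- order(d$family_id, d$twin)
  d <- d[ord, ]
  i1 <- seq(1, nrow(d), 2); i2 <- i1 + 1
  if (any(d$twin[i1] != 1 | d$twin[i2] != 2)) {
    fam <- d$family_id[i1][which(d$twin[i1] != 1 | d$twin[i2] != 2)[1]]
    stop("family ", fam, " does not have twin indices {1, 2}")
  }
  zmis <- which(d$zygosity[i1] != d$zygosity[i2])
  if (length(zmis)) {
    stop("inconsistent zygosity within family ", d$family_id[i1][zmis[1]])
  }
  mz <- d$zygosity[i1] == "MZ"
  pgs_mis <- which(mz & !is.na(d$pgs[i1]) & !is.na(d$pgs[i2]) &
                     abs(d$pgs[i1] - d$pgs[i2]) > 1e-8)
  if (length(pgs_mis)) {
    msg <- paste0("MZ co-twins with differing pgs in family ",
                  d$family_id[i1][pgs_mis[1]])
    if (strict) stop(msg) else warning(msg)
  }
  rownames(d) <- NULL
  d
}

#' Reshape a cohort to one row per twin pair
#'
#' Produces the pair-wide layout consumed by the twin models: for each
#' requested variable, columns `<var>_1` and `<var>_2`, plus the zygosity
#' group collapsed to MZ vs DZ.
#'
#' @param cohort A cohort data frame.
#' @param vars Variables to spread (default: `pgs`, `exposure`, mediators,
#'   `outcome`).
#' @return A data frame with `family_id`, `zygosity` (factor MZ/DZ) and the
#'   paired columns.
#' @export
pair_wide <- function(cohort, vars = NULL) {
  if (is.null(vars)) {
    vars <- setdiff(cohort_columns(cohort),
                    c("family_id", "zygosity", "twin"))
  }
  d <- cohort[order(cohort$family_id, cohort$twin), ]
  tab <- table(d$family_id)
  if (any(tab != 2)) {
    stop("family ", names(tab)[tab != 2][1], " does not have exactly 2 rows")
  }
  i1 <- seq(1, nrow(d), 2); i2 <- i1 + 1
  out <- data.frame(family_id = d$family_id[i1],
                    zygosity = ifelse(d$zygosity[i1] == "MZ", "MZ", "DZ"),
                    stringsAsFactors = FALSE)
  for (v in vars) {
    out[[paste0(v, "_1")]] <- d[[v]][i1]
    out[[paste0(v, "_2")]] <- d[[v]][i2]
  }
  out
}
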