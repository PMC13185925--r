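# Family-clustered association screening.
#
# Point estimates come from ordinary least squares on z-scored variables
# (equivalent to a GEE with independence working correlation); standard
# errors use a family-clustered sandwich estimator, so the two rows each
# twin pair contributes are never treated as independent.

zscore <- function(x) {
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) stop("variable is constant; cannot z-score")
  (x - mean(x, na.rm = TRUE)) / s
}

#' Family-clustered standardized regression
#'
#' Regresses a z-scored outcome on z-scored predictors by least squares and
#' reports standardized coefficients with family-clustered (CR1 sandwich)
#' standard errors, Wald 95% intervals and p-values.
#'
#' @param cohort A cohort data frame (one row per individual).
#' @param outcome Outcome column name.
#' @param predictors Character vector of predictor column names.
#' @param cluster Cluster-id column (default `"family_id"`).
#' @return A data frame with one row per predictor: `predictor`, `outcome`,
#'   `beta`, `se`, `lower`, `upper`, `p`, `n_used`, `n_clusters`.
#' @export
cluster_robust_regression <- function(cohort, outcome, predictors,
                                      cluster = "family_id") {
  for (v in c(outcome, predictors, cluster)) {
    if (!(v %in% names(cohort))) stop("column '", v, "' not in cohort")
  }
  d <- cohort[, c(cluster, outcome, predictors)]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) < 3) stop("too few complete rows")
  if (length(unique(d[[cluster]])) < 2) stop("need at least 2 clusters")
  for (v in c(outcome, predictors)) d[[v]] <- zscore(d[[v]])
  fml <- stats::reformulate(predictors, response = outcome)
  m <- stats::lm(fml, data = d)
  V <- sandwich::vcovCL(m, cluster = d[[cluster]])
  ct <- lmtest::coeftest(m, vcov. = V)
  z <- stats::qnorm(0.975)
  rows <- predictors
  data.frame(
    predictor = rows, outcome = outcome,
    beta = unname(ct[rows, "Estimate"]),
    se = unname(ct[rows, "Std. Error"]),
    lower = unname(ct[rows, "Estimate"] - z * ct[rows, "Std. Error"]),
    upper = unname(ct[rows, "Estimate"] + z * ct[rows, "Std. Error"]),
    p = unname(ct[rows, 4]),
    n_used = nrow(d), n_clusters = length(unique(d[[cluster]])),
    stringsAsFactors = FALSE)
}

#' Moderation test with a binary moderator
#'
#' Fits `outcome ~ predictor * moderator` with family-clustered errors and
#' returns the interaction term, testing whether the predictor-outcome
#' association differs between moderator levels.
#'
#' @inheritParams cluster_robust_regression
#' @param predictor Predictor column name.
#' @param moderator Binary moderator column name (both levels must occur).
#' @return A one-row data frame for the interaction coefficient.
#' @export
moderation_test <- function(cohort, outcome, predictor, moderator,
                            cluster = "family_id") {
  for (v in c(outcome, predictor, moderator, cluster)) {
    if (!(v %in% names(cohort))) stop("column '", v, "' not in cohort")
  }
  d <- cohort[, c(cluster, outcome, predictor, moderator)]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  lev <- unique(d[[moderator]])
  if (length(lev) != 2) {
    stop("moderator must have exactly 2 observed levels (has ",
         length(lev), ")")
  }
  d$.mod <- as.numeric(d[[moderator]] == max(lev))
  d[[outcome]] <- zscore(d[[outcome]])
  d[[predictor]] <- zscore(d[[predictor]])
  fml <- stats::as.formula(paste(outcome, "~", predictor, "* .mod"))
  m <- stats::lm(fml, data = d)
  V <- sandwich::vcovCL(m, cluster = d[[cluster]])
  ct <- lmtest::coeftest(m, vcov. = V)
  term <- paste0(predictor, ":.mod")
  z <- stats::qnorm(0.975)
  data.frame(
    predictor = term, outcome = outcome,
    beta = unname(ct[term, "Estimate"]), se = unname(ct[term, "Std. Error"]),
    lower = unname(ct[term, "Estimate"] - z * ct[term, "Std. Error"]),
    upper = unname(ct[term, "Estimate"] + z * ct[term, "Std. Error"]),
    p = unname(ct[term, 4]), n_used = nrow(d),
    n_clusters = length(unique(d[[cluster]])), stringsAsFactors = FALSE)
}

#' Median split into low/high strata
#'
#' Values strictly above the median are labelled `"high"`, values at or
#' below it `"low"`. With heavy ties at the median the groups can be
#' unbalanced; the counts are reported as observed.
#'
#' @param values Numeric vector (missing values get `NA` labels).
#' @return A character vector of labels with attributes `counts` (table of
#'   low/high) and `median`.
#' @export
median_split <- function(values) {
  obs <- values[!is.na(values)]
  if (length(obs) < 2) stop("need at least 2 non-missing values")
  if (min(obs) == max(obs)) stop("all values identical; split is degenerate")
  med <- stats::median(obs)
  lab <- ifelse(values > med, "high", "low")
  structure(lab, counts = table(factor(lab, c("low", "high"))), median = med)
}

#' Polygenic-score validation regression
#'
#' Standardized association between a phenotype and its polygenic score
#' with family-clustered standard errors.
#'
#' @inheritParams cluster_robust_regression
#' @param phenotype Phenotype column name.
#' @param pgs Polygenic-score column name (default `"pgs"`).
#' @export
pgs_validation <- function(cohort, phenotype, pgs = "pgs",
                           cluster = "family_id") {
  cluster_robust_regression(cohort, outcome = phenotype, predictors = pgs,
                            cluster = cluster)
}

#' Screen candidate mediators for inclusion
#'
#' For each candidate mediator, estimates its family-clustered standardized
#' association with the exposure and with the outcome. A mediator is
#' excluded when either association fails the Bonferroni-adjusted
#' significance threshold.
#'
#' @inheritParams cluster_robust_regression
#' @param exposure,outcome Column names.
#' @param mediators Character vector of mediator column names.
#' @param alpha_adjusted Adjusted significance threshold (default
#'   `0.05 / 18`).
#' @return A data frame with one row per mediator: both betas and p-values,
#'   significance flags, and `include`.
#' @export
screen_mediators <- function(cohort, exposure, outcome, mediators,
                             alpha_adjusted = bonferroni_threshold(0.05, 18)$threshold,
                             cluster = "family_id") {
  rows <- lapply(mediators, function(m) {
    r1 <- cluster_robust_regression(cohort, outcome = m,
                                    predictors = exposure, cluster = cluster)
    r2 <- cluster_robust_regression(cohort, outcome = outcome,
                                    predictors = m, cluster = cluster)
    data.frame(mediator = m,
               beta_exposure = r1$beta, p_exposure = r1$p,
               beta_outcome = r2$beta, p_outcome = r2$p,
               sig_exposure = r1$p < alpha_adjusted,
               sig_outcome = r2$p < alpha_adjusted,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$include <- out$sig_exposure & out$sig_outcome
  out
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Family-wise error rate in `(0, 1)`.
#' @param m Number of tests (>= 1).
#' @return A list with `threshold` (`alpha / m`) and `rounded` (3 decimals).
#' @examples
#' bonferroni_threshold(0.05, 18)  # threshold 0.00278, rounded 0.003
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")
  if (length(m) != 1 || is.na(m) || m < 1) stop("`m` must be a count >= 1")
  thr <- alpha / m
  list(threshold = thr, rounded = round(thr, 3))
}
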