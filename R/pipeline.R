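# End-to-end orchestration: simulate -> screen -> factors -> mediate ->
# MR-DoC -> report, with seeded reproducibility and machine-readable
# outputs (CSV tables plus a JSON manifest and headline summary).

#' Pipeline configuration
#'
#' @param sim A [sim_config()] used when no cohort file is supplied. The
#'   default is a deliberately small demonstration cohort (800 pairs, six
#'   mediators) so the full pipeline completes in well under a minute.
#' @param cohort_path Optional path to an existing cohort CSV (read with
#'   [read_cohort()]); overrides `sim`.
#' @param stages Stages to run, a prefix-closed subset of
#'   `c("simulate", "screen", "factors", "mediate", "mrdoc", "report")` in
#'   dependency order.
#' @param alpha Family-wise error rate (default 0.05).
#' @param n_mediators Number of candidate mediators used for the Bonferroni
#'   threshold (default 18, regardless of how many are simulated).
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed.
#' @param verbose Print stage progress.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, cohort_path = NULL,
                            stages = c("simulate", "screen", "factors",
                                       "mediate", "mrdoc", "report"),
                            alpha = 0.05, n_mediators = 18,
                            out_dir = tempfile("twinmediate_run_"),
                            seed = 1L, verbose = TRUE) {
  all_stages <- c("simulate", "screen", "factors", "mediate", "mrdoc",
                  "report")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  if (!identical(stages, all_stages[seq_along(stages)])) {
    stop("`stages` must be a prefix of the dependency order: ",
         paste(all_stages, collapse = " -> "))
  }
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")
  if (is.null(sim)) {
    sim <- sim_config(n_pairs_mz = 300, n_pairs_dz = 500,
                      factor_loadings = default_factor_loadings(6),
                      seed = seed)
  }
  structure(list(sim = sim, cohort_path = cohort_path, stages = stages,
                 alpha = alpha, n_mediators = n_mediators,
                 out_dir = out_dir, seed = as.integer(seed),
                 verbose = verbose),
            class = "pipeline_config")
}

pipe_log <- function(cfg, ...) {
  if (cfg$verbose) message("[twinmediate] ", ...)
  invisible(NULL)
}

effects_row <- function(name, v) {
  data.frame(effect = name, estimate = v[["estimate"]], se = v[["se"]],
             lower = v[["lower"]], upper = v[["upper"]], p = v[["p"]],
             stringsAsFactors = FALSE)
}

mediation_table <- function(model, eff) {
  tab <- eff$table
  tab <- cbind(model = model, tab,
               c_prime = eff$c_prime[["estimate"]],
               sum_ab = eff$sum_ab[["estimate"]],
               c_total = eff$c_total[["estimate"]],
               percent_mediated = eff$percent_mediated)
  tab
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order on a simulated (or supplied)
#' cohort: association screening with family-clustered errors, two-factor
#' EFA of the mediator battery, phenotypic mediation (simple per mediator
#' plus the two-factor latent model), MR-DoC baseline and simple mediation
#' models with a stratified equality test, and a report stage writing a
#' JSON manifest and headline summary. All outputs are deterministic
#' functions of the configuration and seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results and the paths of
#'   all written files.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  res <- list()
  thr <- bonferroni_threshold(cfg$alpha, cfg$n_mediators)
  failed <- NULL

  run_stage <- function(name, fun) {
    pipe_log(cfg, "stage: ", name)
    tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- simulate -------------------------------------------------------
  run_stage("simulate", function() {
    if (!is.null(cfg$cohort_path)) {
      res$cohort <<- read_cohort(cfg$cohort_path)
    } else {
      sim <- cfg$sim
      sim$seed <- cfg$seed
      res$cohort <<- generate_cohort(sim)
    }
    paths$cohort <<- file.path(cfg$out_dir, "cohort.csv")
    write_cohort(res$cohort, paths$cohort)
  })
  cohort <- res$cohort
  meds <- grep("^med_", names(cohort), value = TRUE)

  # --- screen ---------------------------------------------------------
  if ("screen" %in% cfg$stages) {
    run_stage("screen", function() {
      assoc <- rbind(
        cluster_robust_regression(cohort, "outcome", "exposure"),
        pgs_validation(cohort, "exposure"))
      res$associations <<- assoc
      res$screen <<- screen_mediators(cohort, "exposure", "outcome", meds,
                                      alpha_adjusted = thr$threshold)
      paths$associations <<- file.path(cfg$out_dir, "associations.csv")
      paths$screen <<- file.path(cfg$out_dir, "mediator_screen.csv")
      utils::write.csv(assoc, paths$associations, row.names = FALSE)
      utils::write.csv(res$screen, paths$screen, row.names = FALSE)
    })
  }

  # --- factors --------------------------------------------------------
  if ("factors" %in% cfg$stages) {
    run_stage("factors", function() {
      fs <- efa_two_factor(cohort, meds)
      res$factors <<- fs
      paths$loadings <<- file.path(cfg$out_dir, "factor_loadings.csv")
      out <- data.frame(mediator = rownames(fs$loadings),
                        round(unclass(fs$loadings), 4),
                        uniqueness = round(fs$uniquenesses, 4))
      utils::write.csv(out, paths$loadings, row.names = FALSE)
    })
  }

  # --- mediate (phenotypic) ------------------------------------------
  if ("mediate" %in% cfg$stages) {
    run_stage("mediate", function() {
      included <- if (!is.null(res$screen)) {
        res$screen$mediator[res$screen$include]
      } else meds
      if (!length(included)) included <- meds[1]
      tabs <- list()
      for (m in included) {
        spec <- build_simple_mediation_spec("exposure", m, "outcome")
        fit <- fit_mediation_model(cohort, spec)
        if (fit$converged) {
          eff <- mediation_effects(fit, p_threshold = thr$threshold)
          tabs[[m]] <- mediation_table(paste0("simple:", m), eff)
        }
      }
      half <- split(meds, rep(1:2, each = ceiling(length(meds) / 2),
                              length.out = length(meds)))
      lspec <- build_latent_factor_mediation_spec("exposure", half[[1]],
                                                  half[[2]], "outcome")
      lfit <- fit_mediation_model(cohort, lspec)
      leff <- mediation_effects(lfit, p_threshold = thr$threshold)
      tabs[["latent"]] <- mediation_table("latent", leff)
      res$mediation_phenotypic <<- do.call(rbind, tabs)
      res$mediation_latent <<- leff
      paths$mediation <<- file.path(cfg$out_dir, "mediation_phenotypic.csv")
      utils::write.csv(res$mediation_phenotypic, paths$mediation,
                       row.names = FALSE)
    })
  }

  # --- mrdoc ----------------------------------------------------------
  if ("mrdoc" %in% cfg$stages) {
    run_stage("mrdoc", function() {
      bspec <- build_mrdoc_baseline_spec()
      bfit <- fit_mrdoc(cohort, bspec)
      beff <- extract_mrdoc_effects(bfit, p_threshold = thr$threshold)
      res$mrdoc_baseline <<- beff
      rows <- rbind(effects_row("instrumental", beff$instrumental),
                    effects_row("pleiotropic_outcome",
                                beff$pleiotropy_outcome),
                    effects_row("causal", beff$causal))
      # simple MR-DoC mediation for the first included mediator
      included <- if (!is.null(res$screen)) {
        res$screen$mediator[res$screen$include]
      } else meds
      med1 <- if (length(included)) included[1] else meds[1]
      mspec <- build_mrdoc_mediation_spec(mediators = med1)
      mfit <- fit_mrdoc(cohort, mspec)
      meff <- extract_mrdoc_effects(mfit, p_threshold = thr$threshold)
      res$mrdoc_mediation <<- meff
      paths$mrdoc <<- file.path(cfg$out_dir, "mrdoc_effects.csv")
      utils::write.csv(rows, paths$mrdoc, row.names = FALSE)
      paths$mrdoc_mediation <<- file.path(cfg$out_dir, "mrdoc_mediation.csv")
      utils::write.csv(mrdoc_results_table(meff, mfit),
                       paths$mrdoc_mediation, row.names = FALSE)
      # stratified equality test, pairs stratified by pair-mean exposure
      strata <- pair_strata(cohort, "exposure")
      base_vars <- unique(sub("_[12]$", "", mspec$observed))
      d <- cohort
      for (v in base_vars) d[[v]] <- zscore(d[[v]])
      pw <- pair_wide(d, vars = base_vars)
      stest <- stratified_equality_test(mspec, pw, strata)
      res$stratified <<- stest
      paths$stratified <<- file.path(cfg$out_dir, "stratified_test.csv")
      utils::write.csv(data.frame(chi2 = stest$lrt$chi2, df = stest$lrt$df,
                                  p = stest$lrt$p),
                       paths$stratified, row.names = FALSE)
    })
  }

  # --- report ---------------------------------------------------------
  if ("report" %in% cfg$stages) {
    run_stage("report", function() {
      manifest <- list(
        package = "twinmediate",
        version = as.character(utils::packageVersion("twinmediate")),
        seed = cfg$seed, stages = cfg$stages,
        alpha = cfg$alpha, n_mediators = cfg$n_mediators,
        adjusted_threshold = thr$rounded,
        adjusted_threshold_raw = thr$threshold,
        n_pairs = nrow(cohort) / 2,
        constraint_tags = if (!is.null(res$mrdoc_mediation)) {
          res$mrdoc_mediation$constraint_tags
        } else character(0),
        files = unlist(paths))
      paths$manifest <<- file.path(cfg$out_dir, "manifest.json")
      jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                           pretty = TRUE, digits = NA)
      headline <- list()
      if (!is.null(res$associations)) {
        headline$beta_exposure_outcome <- res$associations$beta[1]
      }
      if (!is.null(res$mediation_latent)) {
        headline$phenotypic_sum_ab <-
          res$mediation_latent$sum_ab[["estimate"]]
        headline$phenotypic_percent_mediated <-
          res$mediation_latent$percent_mediated
      }
      if (!is.null(res$mrdoc_baseline)) {
        headline$mrdoc_instrumental <-
          res$mrdoc_baseline$instrumental[["estimate"]]
        headline$mrdoc_causal <- res$mrdoc_baseline$causal[["estimate"]]
      }
      if (!is.null(res$stratified)) {
        headline$stratified_p <- res$stratified$lrt$p
      }
      paths$summary <<- file.path(cfg$out_dir, "summary.json")
      jsonlite::write_json(headline, paths$summary, auto_unbox = TRUE,
                           pretty = TRUE, digits = NA)
    })
  }
  pipe_log(cfg, "done: ", cfg$out_dir)
  invisible(list(results = res, paths = paths, config = cfg))
}

#' Percentage table from counts
#'
#' Turns counts over categories into percentages of a denominator, rounded
#' to 2 decimals (the convention of cohort descriptive tables). Given a
#' cohort data frame, tabulates its zygosity composition.
#'
#' @param x A named numeric vector of counts, or a cohort data frame with a
#'   `zygosity` column.
#' @param denominator Denominator for the percentages; defaults to
#'   `sum(x)`.
#' @return A data frame with `category`, `n`, `percent`.
#' @examples
#' descriptive_summary(c(dz_opposite_sex = 3726), denominator = 11342)
#' @export
descriptive_summary <- function(x, denominator = NULL) {
  if (is.data.frame(x)) {
    if (!("zygosity" %in% names(x))) stop("data frame lacks 'zygosity'")
    counts <- table(x$zygosity)
    x <- stats::setNames(as.numeric(counts), names(counts))
  }
  if (is.null(names(x)) || anyNA(x) || any(x < 0)) {
    stop("`x` must be named non-negative counts")
  }
  if (is.null(denominator)) denominator <- sum(x)
  if (denominator <= 0) stop("`denominator` must be positive")
  data.frame(category = names(x), n = as.numeric(x),
             percent = round(100 * as.numeric(x) / denominator, 2),
             stringsAsFactors = FALSE)
}
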