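# Full-information maximum likelihood on (possibly incomplete) rows.
#
# Rows are grouped by missing-data pattern; per pattern the -2 log-likelihood
# reduces to sufficient statistics (n, mean, scatter), so an objective
# evaluation costs O(k^3) per pattern regardless of sample size.

LOG2PI <- log(2 * pi)
BIG <- 1e10

pm_prepare_data <- function(compiled, data, group = NULL, cluster = NULL) {
  spec <- compiled$spec
  obs <- spec$observed
  miss <- setdiff(obs, names(data))
  if (length(miss)) {
    stop("data lacks observed variable(s): ", paste(miss, collapse = ", "))
  }
  if (is.null(group)) {
    if (length(spec$groups) != 1) {
      stop("spec has ", length(spec$groups),
           " groups; supply `group` naming the grouping column")
    }
    gvec <- rep(spec$groups, nrow(data))
  } else {
    if (!(group %in% names(data))) stop("grouping column '", group,
                                        "' not found in data")
    gvec <- as.character(data[[group]])
    bad <- setdiff(unique(gvec), spec$groups)
    if (length(bad)) stop("data contains group(s) absent from spec: ",
                          paste(bad, collapse = ", "))
  }
  cvec <- if (is.null(cluster)) NULL else {
    if (!(cluster %in% names(data))) stop("cluster column '", cluster,
                                          "' not found in data")
    data[[cluster]]
  }
  X_all <- as.matrix(data[, obs, drop = FALSE])
  if (!is.numeric(X_all)) stop("observed variables must be numeric")

  groups_present <- intersect(spec$groups, unique(gvec))
  out <- list()
  n_used <- stats::setNames(integer(length(spec$groups)), spec$groups)
  for (g in groups_present) {
    rows <- which(gvec == g)
    X <- X_all[rows, , drop = FALSE]
    ok <- rowSums(!is.na(X)) > 0
    X <- X[ok, , drop = FALSE]
    grows <- rows[ok]
    if (!nrow(X)) next
    key <- apply(!is.na(X), 1, function(z) paste(which(z), collapse = ","))
    patterns <- list()
    for (k in unique(key)) {
      ridx <- which(key == k)
      idx <- as.integer(strsplit(k, ",")[[1]])
      Xp <- X[ridx, idx, drop = FALSE]
      np <- nrow(Xp)
      xbar <- colMeans(Xp)
      Xc <- sweep(Xp, 2, xbar)
      Sc <- crossprod(Xc) / np
      patterns[[length(patterns) + 1L]] <- list(
        idx = idx, n = np, xbar = xbar, S = Sc, X = Xp,
        cluster = if (is.null(cvec)) NULL else cvec[grows[ridx]])
    }
    n_used[g] <- nrow(X)
    out[[g]] <- patterns
  }
  if (!length(out)) stop("no usable rows in data")
  list(patterns = out, n_used = n_used, n_total = sum(n_used))
}

group_minus2ll <- function(patterns, im) {
  tot <- 0
  for (p in patterns) {
    Sig <- im$cov[p$idx, p$idx, drop = FALSE]
    ch <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(ch)) {
      ev <- min(eigen(Sig, symmetric = TRUE, only.values = TRUE)$values)
      return(BIG * (1 + abs(ev)))
    }
    logdet <- 2 * sum(log(diag(ch)))
    Sinv <- chol2inv(ch)
    d <- p$xbar - im$mean[p$idx]
    tot <- tot + p$n * (length(p$idx) * LOG2PI + logdet +
                          sum(Sinv * (p$S + tcrossprod(d))))
  }
  tot
}

make_objective <- function(compiled, prep) {
  gnames <- names(prep$patterns)
  function(theta) {
    tot <- 0
    for (g in gnames) {
      im <- tryCatch(pm_implied(compiled, theta, g),
                     error = function(e) NULL)
      if (is.null(im)) return(BIG)
      val <- group_minus2ll(prep$patterns[[g]], im)
      if (val >= BIG) return(val)
      tot <- tot + val
    }
    tot
  }
}

# per-cluster -2 log-likelihood contributions (for sandwich covariance)
make_cluster_fn <- function(compiled, prep) {
  gnames <- names(prep$patterns)
  all_cl <- unlist(lapply(gnames, function(g)
    lapply(prep$patterns[[g]], function(p) p$cluster)))
  levels_cl <- unique(all_cl)
  function(theta) {
    out <- stats::setNames(numeric(length(levels_cl)), levels_cl)
    for (g in gnames) {
      im <- pm_implied(compiled, theta, g)
      for (p in prep$patterns[[g]]) {
        Sig <- im$cov[p$idx, p$idx, drop = FALSE]
        ch <- chol(Sig)
        Sinv <- chol2inv(ch)
        logdet <- 2 * sum(log(diag(ch)))
        D <- sweep(p$X, 2, im$mean[p$idx])
        q <- rowSums((D %*% Sinv) * D)
        lli <- length(p$idx) * LOG2PI + logdet + q
        agg <- rowsum(lli, p$cluster)
        out[rownames(agg)] <- out[rownames(agg)] + agg[, 1]
      }
    }
    out
  }
}

num_grad <- function(f, x, eps = 1e-6) {
  p <- length(x)
  g <- numeric(p)
  for (j in seq_len(p)) {
    h <- eps * max(1, abs(x[j]))
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    g[j] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

num_jacobian <- function(f, x, eps = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- eps * max(1, abs(x[j]))
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  rownames(J) <- names(f0)
  J
}

#' FIML -2 log-likelihood of a path model
#'
#' Evaluates the full-information maximum-likelihood objective: the sum over
#' rows of minus twice the multivariate-normal log density, where each row
#' contributes only through its observed-variable pattern. Rows sharing a
#' pattern are pooled through their sufficient statistics.
#'
#' @param spec A `pm_spec`.
#' @param params Named vector of free-parameter values (missing labels keep
#'   start values).
#' @param data Data frame with the observed variables (and the grouping
#'   column for multi-group specs).
#' @param group Name of the grouping column, or `NULL` for single-group.
#' @return The scalar -2 log-likelihood.
#' @export
fiml_minus2ll <- function(spec, params = NULL, data, group = NULL) {
  compiled <- pm_compile(spec)
  prep <- pm_prepare_data(compiled, data, group)
  theta <- compiled$start
  if (!is.null(params)) theta[names(params)] <- params
  make_objective(compiled, prep)(theta)
}

#' Fit a path model by full-information maximum likelihood
#'
#' Minimizes the FIML objective with a quasi-Newton optimizer under the box
#' bounds declared in the spec. On failure the fit is restarted from
#' jittered start values before non-convergence is reported. Standard
#' errors come from the inverse numerical Hessian of the -2 log-likelihood;
#' with a `cluster` column, a CR1-adjusted sandwich covariance over
#' cluster-level score contributions is used instead, which is the
#' appropriate choice when rows are individuals nested in families.
#'
#' @param spec A `pm_spec`.
#' @param data Data frame of observed variables (plus grouping/cluster
#'   columns as needed). One row per independent sampling unit (a twin pair
#'   for twin models; an individual for family-clustered phenotypic models).
#' @param group Name of the grouping column, or `NULL`.
#' @param cluster Optional name of a cluster-id column; triggers
#'   cluster-robust standard errors.
#' @param se One of `"hessian"`, `"cluster"`, `"none"`. Defaults to
#'   `"cluster"` when `cluster` is given, else `"hessian"`.
#' @param options List of optimizer options: `tol` (relative tolerance,
#'   default 1e-8), `max_iter` (default 2000), `n_starts` (jittered restarts
#'   on failure, default 5), `seed` (for the jitter, default 1),
#'   `start` (named vector overriding declared start values).
#' @return An object of class `pm_fit`: estimates, standard errors, 95%
#'   Wald intervals, `minus2ll`, `aic`, `bic`, convergence diagnostics and
#'   per-group counts.
#' @export
fit_path_model <- function(spec, data, group = NULL, cluster = NULL,
                           se = NULL, options = list()) {
  opt <- utils::modifyList(
    list(tol = 1e-8, max_iter = 2000, n_starts = 5, seed = 1, start = NULL),
    options)
  if (is.null(se)) se <- if (is.null(cluster)) "hessian" else "cluster"
  se <- match.arg(se, c("hessian", "cluster", "none"))
  compiled <- pm_compile(spec)
  if (compiled$n_params < 1) stop("spec has no free parameters")
  prep <- pm_prepare_data(compiled, data, group, cluster)
  obj <- make_objective(compiled, prep)

  start <- compiled$start
  if (!is.null(opt$start)) {
    known <- intersect(names(opt$start), names(start))
    start[known] <- opt$start[known]
  }
  start <- pmin(pmax(start, compiled$lower), compiled$upper)

  ctrl <- list(rel.tol = opt$tol, iter.max = opt$max_iter,
               eval.max = 10L * opt$max_iter)
  run <- function(s) {
    tryCatch(stats::nlminb(s, obj, lower = compiled$lower,
                           upper = compiled$upper, control = ctrl),
             error = function(e) list(par = s, objective = Inf,
                                      convergence = 1L,
                                      message = conditionMessage(e)))
  }
  res <- run(start)
  ok <- function(r) is.finite(r$objective) && r$objective < BIG &&
    r$convergence == 0L
  tries <- 0L
  best <- res
  while (!ok(best) && tries < opt$n_starts) {
    tries <- tries + 1L
    set.seed(opt$seed + tries)
    jit <- start * (1 + 0.3 * stats::rnorm(length(start))) +
      0.1 * stats::rnorm(length(start))
    jit <- pmin(pmax(jit, compiled$lower), compiled$upper)
    cand <- run(jit)
    if (cand$objective < best$objective) best <- cand
  }
  # polish once from the solution
  if (ok(best)) {
    pol <- run(best$par)
    if (ok(pol) && pol$objective <= best$objective) best <- pol
  }
  est <- stats::setNames(best$par, compiled$labels)
  grad <- if (is.finite(best$objective) && best$objective < BIG) {
    num_grad(obj, best$par)
  } else rep(NA_real_, length(est))
  # nlminb may report "false convergence" at a genuine optimum; accept a
  # solution whose gradient is negligible relative to the objective scale
  converged <- ok(best) ||
    (is.finite(best$objective) && best$objective < BIG &&
       all(is.finite(grad)) &&
       sqrt(sum(grad^2)) < 1e-3 * (1 + abs(best$objective)))

  vcov <- matrix(NA_real_, length(est), length(est),
                 dimnames = list(names(est), names(est)))
  se_vec <- rep(NA_real_, length(est))
  vcov_ok <- FALSE
  if (converged && se != "none") {
    H <- tryCatch(stats::optimHess(best$par, obj), error = function(e) NULL)
    if (!is.null(H)) {
      Vh <- tryCatch(2 * solve(H), error = function(e) 2 * MASS::ginv(H))
      if (se == "cluster" && !is.null(cluster)) {
        clfn <- make_cluster_fn(compiled, prep)
        J <- num_jacobian(clfn, best$par)        # d(-2 ll_c)/d theta
        Sc <- -0.5 * J                           # cluster scores (log lik)
        G <- nrow(Sc)
        meat <- crossprod(Sc) * G / (G - 1)
        bread <- tryCatch(solve(H / 2), error = function(e) MASS::ginv(H / 2))
        vcov <- bread %*% meat %*% bread
      } else {
        vcov <- Vh
      }
      dimnames(vcov) <- list(names(est), names(est))
      dvc <- diag(vcov)
      if (all(is.finite(dvc)) && all(dvc > -1e-8)) {
        se_vec <- sqrt(pmax(dvc, 0))
        vcov_ok <- TRUE
      }
    }
  }
  z <- stats::qnorm(0.975)
  ci <- cbind(lower = est - z * se_vec, upper = est + z * se_vec)
  m2ll <- best$objective
  k <- length(est)
  structure(list(
    estimates = est, se = stats::setNames(se_vec, names(est)),
    ci = ci, vcov = vcov, vcov_ok = vcov_ok,
    minus2ll = m2ll, n_params = k,
    aic = m2ll + 2 * k, bic = m2ll + log(prep$n_total) * k,
    converged = converged, gradient_norm = sqrt(sum(grad^2)),
    n_used = prep$n_used, se_type = se, restarts = tries,
    message = best$message, spec = spec, compiled = compiled
  ), class = "pm_fit")
}

#' @export
print.pm_fit <- function(x, ...) {
  cat("Path model fit (FIML)\n")
  cat(sprintf("  -2lnL = %.3f  params = %d  AIC = %.3f  converged = %s\n",
              x$minus2ll, x$n_params, x$aic, x$converged))
  tab <- data.frame(estimate = x$estimates, se = x$se,
                    lower = x$ci[, "lower"], upper = x$ci[, "upper"])
  print(round(tab, 4))
  invisible(x)
}

#' Likelihood-ratio test of nested path models
#'
#' @param full Fit of the less constrained model.
#' @param nested Fit of the constrained model (free parameters a subset of
#'   `full`'s).
#' @param tol Tolerance below which a negative chi-square statistic is
#'   treated as an optimization failure.
#' @return A list with `chi2`, `df` and `p`.
#' @export
lrt <- function(full, nested, tol = 1e-4) {
  stopifnot(inherits(full, "pm_fit"), inherits(nested, "pm_fit"))
  if (!full$converged || !nested$converged) {
    stop("both fits must have converged")
  }
  df <- full$n_params - nested$n_params
  if (df < 0) stop("nested model must not have more free parameters")
  chi2 <- nested$minus2ll - full$minus2ll
  if (chi2 < -tol) {
    stop(sprintf(
      "nested -2lnL (%.4f) is below the full model's (%.4f): optimization failure",
      nested$minus2ll, full$minus2ll))
  }
  chi2 <- max(chi2, 0)
  # identical models: zero statistic on zero degrees of freedom
  p <- if (df == 0) 1 else stats::pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p)
}

#' Delta-method inference for a function of fitted parameters
#'
#' First-order delta-method standard error and Wald 95% interval for a
#' scalar function of the free parameters, e.g. an indirect effect `a * b`
#' or a standardized variance proportion.
#'
#' @param fit A converged `pm_fit` with an available parameter covariance.
#' @param expression A function taking the named estimate vector and
#'   returning a scalar.
#' @return A list with `value`, `se`, `ci` (length-2 vector) and `p`
#'   (Wald test against zero).
#' @export
delta_method <- function(fit, expression) {
  stopifnot(inherits(fit, "pm_fit"))
  if (!fit$converged || !fit$vcov_ok) {
    stop("parameter covariance unavailable (fit not converged or Hessian not usable)")
  }
  est <- fit$estimates
  val <- unname(expression(est))
  g <- num_grad(function(th) {
    names(th) <- names(est)
    expression(th)
  }, est)
  v <- drop(t(g) %*% fit$vcov %*% g)
  s <- sqrt(max(v, 0))
  z <- stats::qnorm(0.975)
  list(value = val, se = s,
       ci = unname(c(val - z * s, val + z * s)),
       p = unname(if (s > 0) 2 * stats::pnorm(-abs(val) / s)
                  else as.numeric(val == 0)))
}

# Standardized coefficient of directed edge from -> to at parameter theta.
std_path_at <- function(compiled, theta, from, to, group) {
  im <- pm_implied(compiled, theta, group)
  m <- pm_matrices(compiled, theta, group)
  i <- compiled$vidx[[to]]; j <- compiled$vidx[[from]]
  vf <- im$cov_full[j, j]; vt <- im$cov_full[i, i]
  if (vt <= 0 || vf <= 0) {
    stop("zero implied variance for '", if (vt <= 0) to else from, "'")
  }
  m$A[i, j] * sqrt(vf) / sqrt(vt)
}

#' Standardized path coefficient from a fitted model
#'
#' Rescales the raw coefficient of the directed edge `from -> to` by the
#' model-implied standard deviations of its tail and head variables.
#'
#' @param fit A converged `pm_fit`.
#' @param from,to Variable names of the edge.
#' @param group Group name (default: first group).
#' @export
std_path <- function(fit, from, to, group = NULL) {
  stopifnot(inherits(fit, "pm_fit"))
  if (is.null(group)) group <- fit$spec$groups[1]
  std_path_at(fit$compiled, fit$estimates, from, to, group)
}

#' Standardized solution of a fitted path model
#'
#' Every free directed path is rescaled by the model-implied standard
#' deviations of its tail and head variables; results are reported per
#' group. Standardized coefficients are invariant to affine rescaling of
#' the observed inputs.
#'
#' @param fit A converged `pm_fit`.
#' @return A data frame with columns `group`, `from`, `to`, `label`, `raw`,
#'   `std`.
#' @export
standardize_fit <- function(fit) {
  stopifnot(inherits(fit, "pm_fit"))
  spec <- fit$spec
  compiled <- fit$compiled
  theta <- fit$estimates
  rows <- list()
  for (g in spec$groups) {
    im <- tryCatch(pm_implied(compiled, theta, g), error = function(e) NULL)
    if (is.null(im)) next
    m <- pm_matrices(compiled, theta, g)
    sds <- sqrt(pmax(diag(im$cov_full), 0))
    for (e in spec$entries) {
      if (e$type != "path" || is.na(e$label)) next
      if (!is.null(e$groups) && !(g %in% e$groups)) next
      i <- compiled$vidx[[e$to]]; j <- compiled$vidx[[e$from]]
      raw <- m$A[i, j]
      if (sds[i] <= 0) stop("zero implied variance for '", e$to, "'")
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, from = e$from, to = e$to, label = e$label,
        raw = raw, std = raw * sds[j] / sds[i], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
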