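#' Create a path model specification
#'
#' A path model is specified in RAM form: a matrix of directed paths among
#' observed and latent variables, a symmetric matrix of (co)variances, and a
#' mean vector. Entries are added with [pm_path()], [pm_cov()] and
#' [pm_mean()]; each entry is either fixed at a value or free, with free
#' entries identified by a label. Entries sharing a label share one
#' parameter (equality constraint), possibly scaled by an entry-specific
#' multiplier. Multi-group models (e.g. MZ vs DZ twin pairs) are supported
#' through per-group fixed values and scales, the standard device for fixing
#' the cross-twin additive-genetic covariance to 1 in MZ and 0.5 in DZ pairs.
#'
#' @param observed Character vector of observed variable names, in the order
#'   they appear in data supplied to [fit_path_model()].
#' @param latent Character vector of latent variable names.
#' @param groups Character vector of group names. Use a single group (the
#'   default `"all"`) for ungrouped data.
#' @return An object of class `pm_spec`.
#' @seealso [pm_path()], [pm_cov()], [pm_mean()], [implied_moments()],
#'   [fit_path_model()]
#' @export
pm_spec <- function(observed, latent = character(), groups = "all") {
  stopifnot(is.character(observed), length(observed) >= 1)
  vars <- c(observed, latent)
  if (anyDuplicated(vars)) {
    stop("duplicated variable names: ",
         paste(unique(vars[duplicated(vars)]), collapse = ", "))
  }
  structure(
    list(observed = observed, latent = latent, variables = vars,
         groups = groups, entries = list()),
    class = "pm_spec"
  )
}

pm_entry <- function(spec, type, from, to, label, value, scale, lower, upper,
                     groups) {
  for (v in c(from, to)) {
    if (!is.na(v) && !(v %in% spec$variables)) {
      stop("unknown variable '", v, "' in ", type, " entry")
    }
  }
  if (!is.null(groups) && !all(groups %in% spec$groups)) {
    stop("unknown group(s): ",
         paste(setdiff(groups, spec$groups), collapse = ", "))
  }
  if (!is.null(names(value)) && !all(names(value) %in% spec$groups)) {
    stop("per-group value names must match spec groups")
  }
  spec$entries[[length(spec$entries) + 1L]] <- list(
    type = type, from = from, to = to,
    label = if (is.null(label)) NA_character_ else label,
    value = value, scale = scale, lower = lower, upper = upper,
    groups = groups
  )
  spec
}

#' Add a directed path to a path model
#'
#' @param spec A `pm_spec` object.
#' @param from,to Tail and head variable names of the directed path.
#' @param label Parameter label; entries sharing a label share one free
#'   parameter. `NULL` (default) fixes the entry at `value`.
#' @param value Start value (free entry) or fixed value. Fixed values may be
#'   a named vector with one value per group.
#' @param scale Multiplier applied to the free parameter for this entry;
#'   scalar or named per-group vector (e.g. `c(MZ = 1, DZ = 0.5)`).
#' @param lower,upper Box bounds for the free parameter.
#' @param groups Restrict the entry to these groups (`NULL` = all groups).
#' @return The updated `pm_spec`.
#' @export
pm_path <- function(spec, from, to, label = NULL, value = 0, scale = 1,
                    lower = -Inf, upper = Inf, groups = NULL) {
  pm_entry(spec, "path", from, to, label, value, scale, lower, upper, groups)
}

#' Add a (co)variance to a path model
#'
#' Adds an entry to the symmetric matrix of the RAM specification; the
#' mirrored entry is filled automatically.
#'
#' @inheritParams pm_path
#' @param v1,v2 The two variables; `v1 == v2` specifies a variance.
#' @return The updated `pm_spec`.
#' @export
pm_cov <- function(spec, v1, v2, label = NULL, value = 0, scale = 1,
                   lower = -Inf, upper = Inf, groups = NULL) {
  pm_entry(spec, "cov", v1, v2, label, value, scale, lower, upper, groups)
}

#' Add a mean to a path model
#'
#' @inheritParams pm_path
#' @param var Variable name.
#' @return The updated `pm_spec`.
#' @export
pm_mean <- function(spec, var, label = NULL, value = 0, scale = 1,
                    lower = -Inf, upper = Inf, groups = NULL) {
  pm_entry(spec, "mean", var, NA_character_, label, value, scale, lower,
           upper, groups)
}

resolve_group <- function(x, group, default) {
  if (is.null(x)) return(default)
  if (!is.null(names(x))) {
    if (group %in% names(x)) return(unname(x[[group]]))
    return(default)
  }
  unname(x[1])
}

#' @keywords internal
pm_compile <- function(spec) {
  stopifnot(inherits(spec, "pm_spec"))
  v <- length(spec$variables)
  vidx <- stats::setNames(seq_len(v), spec$variables)
  obs_idx <- vidx[spec$observed]

  # parameter table: first appearance fixes start value and bounds
  labels <- character(0); start <- numeric(0)
  lower <- numeric(0); upper <- numeric(0)
  for (e in spec$entries) {
    if (!is.na(e$label) && !(e$label %in% labels)) {
      labels <- c(labels, e$label)
      start <- c(start, unname(e$value[1]))
      lower <- c(lower, e$lower)
      upper <- c(upper, e$upper)
    }
  }
  pidx <- stats::setNames(seq_along(labels), labels)

  groups <- spec$groups
  per_group <- vector("list", length(groups))
  names(per_group) <- groups
  for (g in groups) {
    A0 <- matrix(0, v, v); S0 <- matrix(0, v, v); M0 <- numeric(v)
    A_idx <- integer(0); A_par <- integer(0); A_scale <- numeric(0)
    S_idx <- integer(0); S_par <- integer(0); S_scale <- numeric(0)
    M_idx <- integer(0); M_par <- integer(0); M_scale <- numeric(0)
    for (e in spec$entries) {
      if (!is.null(e$groups) && !(g %in% e$groups)) next
      sc <- resolve_group(e$scale, g, 1)
      if (e$type == "mean") {
        i <- vidx[[e$from]]
        if (is.na(e$label)) {
          M0[i] <- resolve_group(e$value, g, 0) * sc
        } else {
          M_idx <- c(M_idx, i); M_par <- c(M_par, pidx[[e$label]])
          M_scale <- c(M_scale, sc)
        }
      } else if (e$type == "path") {
        # A[to, from]: row = head, column = tail
        i <- vidx[[e$to]]; j <- vidx[[e$from]]
        li <- i + (j - 1L) * v
        if (is.na(e$label)) {
          A0[li] <- resolve_group(e$value, g, 0) * sc
        } else {
          A_idx <- c(A_idx, li); A_par <- c(A_par, pidx[[e$label]])
          A_scale <- c(A_scale, sc)
        }
      } else {
        i <- vidx[[e$from]]; j <- vidx[[e$to]]
        lis <- unique(c(i + (j - 1L) * v, j + (i - 1L) * v))
        if (is.na(e$label)) {
          S0[lis] <- resolve_group(e$value, g, 0) * sc
        } else {
          S_idx <- c(S_idx, lis)
          S_par <- c(S_par, rep(pidx[[e$label]], length(lis)))
          S_scale <- c(S_scale, rep(sc, length(lis)))
        }
      }
    }
    per_group[[g]] <- list(A0 = A0, S0 = S0, M0 = M0,
                           A_idx = A_idx, A_par = A_par, A_scale = A_scale,
                           S_idx = S_idx, S_par = S_par, S_scale = S_scale,
                           M_idx = M_idx, M_par = M_par, M_scale = M_scale)
  }

  # structural acyclicity: positions that can ever be non-zero in A
  B <- per_group[[1]]$A0 != 0
  for (g in groups) {
    pg <- per_group[[g]]
    B <- B | (pg$A0 != 0)
    if (length(pg$A_idx)) B[pg$A_idx] <- TRUE
  }
  P <- B
  for (k in seq_len(v)) {
    if (!any(P)) break
    if (any(diag(P))) {
      cyc <- spec$variables[diag(P)]
      stop("directed paths contain a cycle involving: ",
           paste(cyc, collapse = ", "))
    }
    P <- (P %*% B) > 0
  }

  list(spec = spec, v = v, vidx = vidx, obs_idx = obs_idx,
       labels = labels, start = stats::setNames(start, labels),
       lower = lower, upper = upper, per_group = per_group,
       n_params = length(labels))
}

pm_matrices <- function(compiled, theta, group) {
  pg <- compiled$per_group[[group]]
  A <- pg$A0; S <- pg$S0; M <- pg$M0
  if (length(pg$A_idx)) A[pg$A_idx] <- theta[pg$A_par] * pg$A_scale
  if (length(pg$S_idx)) S[pg$S_idx] <- theta[pg$S_par] * pg$S_scale
  if (length(pg$M_idx)) M[pg$M_idx] <- theta[pg$M_par] * pg$M_scale
  list(A = A, S = S, M = M)
}

pm_implied <- function(compiled, theta, group) {
  m <- pm_matrices(compiled, theta, group)
  IA <- diag(compiled$v) - m$A
  Binv <- tryCatch(solve(IA), error = function(e) {
    stop("(I - A) is singular; check directed paths for group '", group, "'")
  })
  Sfull <- Binv %*% m$S %*% t(Binv)
  Sfull <- (Sfull + t(Sfull)) / 2
  mu_full <- drop(Binv %*% m$M)
  oi <- compiled$obs_idx
  list(cov = Sfull[oi, oi, drop = FALSE], mean = mu_full[oi],
       cov_full = Sfull, mean_full = mu_full)
}

#' Model-implied covariance matrix and mean vector
#'
#' Computes the covariance matrix and mean vector of the observed variables
#' implied by a path model at a given parameter value, using the RAM
#' identity `F (I - A)^-1 S (I - A)^-T F'`.
#'
#' @param spec A `pm_spec`.
#' @param params Named numeric vector of free-parameter values; omitted
#'   parameters keep their start values. `NULL` uses all start values.
#' @param group Group name; defaults to the first group.
#' @return A list with elements `cov` (observed covariance matrix, with
#'   dimnames), `mean` (observed mean vector) and `cov_full` (covariance of
#'   all variables, including latent ones).
#' @examples
#' spec <- pm_spec(c("x", "y"))
#' spec <- pm_path(spec, "x", "y", value = 0.5)
#' spec <- pm_cov(spec, "x", "x", value = 1)
#' spec <- pm_cov(spec, "y", "y", value = 0.75)
#' implied_moments(spec)$cov
#' @export
implied_moments <- function(spec, params = NULL, group = NULL) {
  compiled <- pm_compile(spec)
  if (is.null(group)) group <- spec$groups[1]
  if (!(group %in% spec$groups)) stop("unknown group '", group, "'")
  theta <- compiled$start
  if (!is.null(params)) {
    if (is.null(names(params)) || !all(names(params) %in% compiled$labels)) {
      stop("params must be a named vector of free-parameter labels")
    }
    theta[names(params)] <- params
  }
  im <- pm_implied(compiled, theta, group)
  dimnames(im$cov) <- list(spec$observed, spec$observed)
  names(im$mean) <- spec$observed
  dimnames(im$cov_full) <- list(spec$variables, spec$variables)
  im
}

#' @export
print.pm_spec <- function(x, ...) {
  nfree <- length(unique(stats::na.omit(
    vapply(x$entries, function(e) e$label, character(1)))))
  cat("Path model specification\n")
  cat("  observed:", length(x$observed), " latent:", length(x$latent),
      " groups:", paste(x$groups, collapse = ", "), "\n")
  cat("  entries:", length(x$entries), " free parameters:", nfree, "\n")
  invisible(x)
}
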