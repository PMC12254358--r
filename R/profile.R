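# Natural search bounds per profiled quantity.
profile_bounds <- function(name) {
  if (grepl("^(pA|pC|pE|a2|c2|e2)", name)) c(0, 1)
  else if (grepl("^share", name)) c(-4, 4)
  else if (grepl("^(r|ctct|rph|rPh)", name)) c(-0.9999, 0.9999)
  else c(-Inf, Inf)
}

#' Profile-likelihood confidence interval
#'
#' Likelihood-based interval for a parameter of a fitted twin model: the
#' bounds are the values at which the profile -2 log-likelihood (minimized
#' over all other parameters) exceeds its minimum by the chi-square(1)
#' quantile (3.841 at 95%). The model is re-expressed in an equivalent
#' parameterization in which the requested quantity is a coordinate, so fixing
#' it is exact. Component and correlation bounds are respected; when the
#' profile never crosses the threshold before a natural bound, that bound is
#' returned and flagged as open.
#'
#' For `ace_fit` objects the supported parameters are the standardized
#' components `"a2_1"`, `"c2_1"`, `"e2_1"` (and `_2`; `"a2"`, `"c2"`, `"e2"`
#' address trait 1, the univariate case), the factor correlations `"rA"`,
#' `"rC"`, `"rE"`, the model-implied phenotypic correlation `"rPh"`, and the
#' covariance shares `"share_A"`, `"share_C"`, `"share_E"`. For
#' `saturated_fit` objects at constraint level `"zygosity"`: `"r_mz_<t>"`,
#' `"r_dz_<t>"`, `"ctct_mz"`, `"ctct_dz"`, `"rph"`.
#'
#' @param fit An `ace_fit` or `saturated_fit`.
#' @param parameter Parameter name (see Details).
#' @param level Confidence level.
#' @return List with `lower`, `upper`, `estimate`, `level`, and logical flags
#'   `lower_open`, `upper_open` for bounds truncated at the parameter-space
#'   edge.
#' @export
profile_ci <- function(fit, parameter, level = 0.95) {
  UseMethod("profile_ci")
}

#' @export
profile_ci.ace_fit <- function(fit, parameter, level = 0.95) {
  nt <- length(fit$a2)
  comps <- model_components(fit$model)
  cm <- list(A = fit$A, C = fit$C, E = fit$E, mean = fit$mean)

  # choose a parameterization in which `parameter` is a coordinate
  std_map <- c(a2_1 = "A", a2_2 = "A", c2_1 = "C", c2_2 = "C",
               e2_1 = "E", e2_2 = "E", a2 = "A", c2 = "C", e2 = "E")
  if (parameter %in% names(std_map)) {
    comp <- std_map[[parameter]]
    t <- if (grepl("_2$", parameter)) 2L else 1L
    if (!comp %in% comps)
      stop("component ", comp, " is not free in the ", fit$model, " model")
    ref <- setdiff(comps, comp)[1]
    spec <- ace_param_spec(nt, fit$model, "proportions", ref = ref)
    coord <- paste0("p", comp, t)
    est <- switch(comp, A = fit$a2[t], C = fit$c2[t], E = fit$e2[t])
  } else if (parameter %in% c("rA", "rC", "rE")) {
    if (!sub("r", "", parameter) %in% comps)
      stop("component ", sub("r", "", parameter), " is not free in the ",
           fit$model, " model")
    spec <- ace_param_spec(nt, fit$model, "proportions",
                           ref = if (length(comps) > 1) "E" else comps[1])
    coord <- parameter
    est <- fit[[parameter]]
  } else if (parameter == "rPh" || grepl("^share_", parameter)) {
    if (nt != 2) stop("'", parameter, "' requires a bivariate fit")
    share_ref <- if (parameter == "rPh") comps[length(comps)] else {
      cc <- sub("share_", "", parameter)
      if (!cc %in% comps)
        stop("component ", cc, " is not free in the ", fit$model, " model")
      setdiff(comps, cc)[1]
    }
    if (parameter != "rPh" && length(comps) == 1)
      stop("share of a single-component model is identically 1")
    spec <- ace_param_spec(nt, fit$model, "shares", share_ref = share_ref)
    coord <- parameter
    est <- if (parameter == "rPh") fit$rPh else
      unname(spec$init(cm)[parameter])
  } else {
    stop("unsupported parameter for profiling: ", parameter)
  }
  prof <- profile_fun(ace_objective_spec(fit$data, spec), spec$init(cm),
                      spec, coord)
  search_profile_bounds(prof, est, fit$neg2ll, profile_bounds(parameter),
                        level)
}

#' @export
profile_ci.saturated_fit <- function(fit, parameter, level = 0.95) {
  if (fit$constraint_level != "zygosity")
    stop("profiling is supported for zygosity-constrained saturated fits")
  if (!parameter %in% names(fit$param))
    stop("unknown saturated-model parameter: ", parameter)
  est <- unname(fit$param[parameter])
  b <- saturated_bounds(names(fit$param))
  spec <- list(names = names(fit$param), lower = b$lower, upper = b$upper)
  prof <- profile_fun(saturated_objective(fit$data, fit$constraint_level),
                      fit$param, spec, parameter)
  search_profile_bounds(prof, est, fit$neg2ll, profile_bounds(parameter),
                        level)
}

# Profile objective: returns function(value) -> -2LL minimized over the other
# parameters with coordinate `coord` held fixed. Warm-starts each solve from
# the previous optimum.
profile_fun <- function(full_obj, mle_par, spec, coord) {
  nms <- spec$names
  names(mle_par) <- nms
  free <- setdiff(nms, coord)
  lower <- stats::setNames(spec$lower, nms)[free]
  upper <- stats::setNames(spec$upper, nms)[free]
  last <- mle_par[free]
  template <- mle_par
  function(value) {
    obj <- function(p) {
      par <- template
      par[free] <- p
      par[coord] <- value
      full_obj(par)
    }
    opt <- minimize_neg2ll(obj, last, lower, upper, n_restarts = 2)
    last <<- opt$par
    opt$objective
  }
}

# Walk outward from the estimate until the profile crosses min2ll + crit,
# then refine by uniroot. Returns the natural bound (flagged open) when the
# profile stays below the threshold all the way to it.
search_profile_bounds <- function(prof, est, min2ll, bounds, level) {
  crit <- stats::qchisq(level, 1)
  target <- min2ll + crit
  f <- function(v) prof(v) - target
  one_side <- function(dir) {
    bound <- if (dir > 0) bounds[2] else bounds[1]
    if (!is.finite(bound)) bound <- est + dir * 50 * max(abs(est), 0.5)
    step <- max(0.02, 0.1 * max(abs(est), 0.1))
    v_in <- est
    f_in <- -crit
    repeat {
      v <- est + dir * step
      hit_bound <- (dir > 0 && v >= bound) || (dir < 0 && v <= bound)
      if (hit_bound) v <- bound
      fv <- f(v)
      if (is.finite(fv) && fv > 0) {
        root <- stats::uniroot(f, lower = min(v_in, v), upper = max(v_in, v),
                               f.lower = if (v_in < v) f_in else fv,
                               f.upper = if (v_in < v) fv else f_in,
                               tol = 1e-7)
        return(list(value = root$root, open = FALSE))
      }
      if (hit_bound) return(list(value = bound, open = TRUE))
      if (is.finite(fv)) { v_in <- v; f_in <- fv }
      step <- step * 2
      if (step > 1e4) return(list(value = bound, open = TRUE))
    }
  }
  lo <- one_side(-1)
  hi <- one_side(1)
  list(lower = lo$value, upper = hi$value, estimate = est, level = level,
       lower_open = lo$open, upper_open = hi$open)
}
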