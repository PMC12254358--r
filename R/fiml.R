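#' Bundle per-pair observations for twin modelling
#'
#' Each pair contributes an observation vector of length `2 * n_traits`
#' (all traits of twin 1, then all traits of twin 2), entries possibly
#' missing. Zygosity is pooled to MZ vs DZ. Internally, rows are grouped by
#' missing-data pattern and reduced to sufficient statistics (n, mean,
#' n-divisor scatter), which makes every likelihood evaluation independent of
#' the number of pairs.
#'
#' @param mz,dz Numeric matrices (`n_pairs x 2*n_traits`), `NA` allowed;
#'   rows with no observed entry are dropped.
#' @return An object of class `pair_data`.
#' @export
pair_data <- function(mz, dz) {
  mz <- as.matrix(mz); dz <- as.matrix(dz)
  if (ncol(mz) != ncol(dz)) stop("MZ and DZ must have the same columns")
  d <- ncol(mz)
  if (d %% 2 != 0) stop("observation vectors must have even length")
  structure(list(groups = list(MZ = pattern_stats(mz), DZ = pattern_stats(dz)),
                 nt = d %/% 2, d = d,
                 n = c(MZ = sum(rowSums(!is.na(mz)) > 0),
                       DZ = sum(rowSums(!is.na(dz)) > 0)),
                 complete = !anyNA(mz) && !anyNA(dz)),
            class = "pair_data")
}

#' Pair data from exact population moments
#'
#' Builds a `pair_data` object whose sufficient statistics equal the supplied
#' mean and covariance exactly, as if an infinite sample had been observed at
#' size `n` per group. Used as a closed-form oracle: maximum-likelihood fits
#' on exact moments must reproduce the generating parameters.
#'
#' @param mu Mean vector (length `2 * n_traits`).
#' @param sigma_mz,sigma_dz Population covariance matrices per zygosity.
#' @param n_mz,n_dz Nominal group sizes.
#' @return A `pair_data` object.
#' @export
population_pair_data <- function(mu, sigma_mz, sigma_dz, n_mz = 1000,
                                 n_dz = 1000) {
  d <- length(mu)
  one <- function(S, n) list(list(obs = seq_len(d), n = n, xbar = mu, S = S))
  structure(list(groups = list(MZ = one(sigma_mz, n_mz),
                               DZ = one(sigma_dz, n_dz)),
                 nt = d %/% 2, d = d, n = c(MZ = n_mz, DZ = n_dz),
                 complete = TRUE),
            class = "pair_data")
}

#' @export
print.pair_data <- function(x, ...) {
  cat("Twin pair data:", x$nt, "trait(s);",
      x$n["MZ"], "MZ and", x$n["DZ"], "DZ pairs;",
      length(x$groups$MZ) + length(x$groups$DZ), "missingness patterns\n")
  invisible(x)
}

# Group rows by missing-data pattern; per pattern keep the sufficient
# statistics of the observed subvector (n, mean, scatter with n divisor).
pattern_stats <- function(Y) {
  Y <- as.matrix(Y)
  obs <- !is.na(Y)
  keep <- rowSums(obs) > 0
  Y <- Y[keep, , drop = FALSE]
  obs <- obs[keep, , drop = FALSE]
  if (nrow(Y) == 0) return(list())
  key <- apply(obs, 1, function(z) paste(as.integer(z), collapse = ""))
  out <- lapply(split(seq_len(nrow(Y)), key), function(idx) {
    o <- which(obs[idx[1], ])
    X <- Y[idx, o, drop = FALSE]
    xbar <- colMeans(X)
    Xc <- sweep(X, 2, xbar)
    list(obs = o, n = nrow(X), xbar = xbar, S = crossprod(Xc) / nrow(X))
  })
  unname(out)
}

# -2 log-likelihood of one group's pattern statistics under N(mu, Sigma),
# each pattern contributing its observed-subvector marginal density.
# Returns Inf when an observed sub-block is not positive definite.
neg2ll_stats <- function(stats, mu, Sigma) {
  total <- 0
  for (p in stats) {
    o <- p$obs
    d <- length(o)
    R <- tryCatch(chol(Sigma[o, o, drop = FALSE]), error = function(e) NULL)
    if (is.null(R)) return(Inf)
    Sinv <- chol2inv(R)
    delta <- p$xbar - mu[o]
    total <- total + p$n * (d * log(2 * pi) + 2 * sum(log(diag(R))) +
                              sum(Sinv * p$S) +
                              drop(crossprod(delta, Sinv %*% delta)))
  }
  total
}

#' Casewise full-information maximum-likelihood -2 log-likelihood
#'
#' `-2 * sum` over rows of the log multivariate-normal density of each row's
#' OBSERVED subvector, with the mean and covariance subset to the observed
#' indices. This handles arbitrary missingness without imputation; on complete
#' data it equals the ordinary multivariate-normal -2 log-likelihood.
#'
#' @param observations Numeric matrix (rows = cases), `NA` allowed; rows with
#'   no observed entry are dropped.
#' @param mu Mean vector.
#' @param Sigma Covariance matrix (must be positive definite on every observed
#'   sub-block).
#' @return Scalar -2 log-likelihood.
#' @export
fiml_neg2ll <- function(observations, mu, Sigma) {
  if (!is.matrix(observations)) observations <- matrix(observations, nrow = 1)
  if (ncol(observations) != length(mu))
    stop("mu must have one entry per column of observations")
  val <- neg2ll_stats(pattern_stats(observations), mu, Sigma)
  if (!is.finite(val))
    stop("singular or non-positive-definite observed sub-block")
  val
}

# Robust minimization of a -2LL objective: nlminb, then repeated restarts
# from the incumbent optimum until the objective is stable (within 1e-9),
# with deterministic jittered restarts when the first pass fails outright.
# `convergence` is 0 when a stable finite optimum was reached.
minimize_neg2ll <- function(obj, start, lower = -Inf, upper = Inf,
                            n_restarts = 5) {
  ctl <- list(eval.max = 10000, iter.max = 5000, rel.tol = 1e-14)
  run <- function(par) {
    par <- pmin(pmax(par, lower + 1e-9), upper - 1e-9)
    out <- tryCatch(stats::nlminb(par, obj, lower = lower, upper = upper,
                                  control = ctl),
                    error = function(e) list(par = par, objective = Inf,
                                             convergence = 1L,
                                             message = conditionMessage(e)))
    # tight bounded quasi-Newton polish
    if (is.finite(out$objective)) {
      pol <- tryCatch(stats::optim(out$par, obj, method = "L-BFGS-B",
                                   lower = lower, upper = upper,
                                   control = list(factr = 1e2, maxit = 500)),
                      error = function(e) NULL)
      if (!is.null(pol) && is.finite(pol$value) && pol$value <= out$objective)
        out <- list(par = pol$par, objective = pol$value,
                    convergence = out$convergence, message = out$message)
    }
    out
  }
  best <- run(start)
  if (!is.finite(best$objective)) {
    for (k in seq_len(n_restarts)) {
      jit <- start * (1 + 0.1 * k * rep_len(c(1, -1), length(start))) +
        0.05 * k * rep_len(c(-1, 1), length(start))
      cand <- run(jit)
      if (is.finite(cand$objective) && cand$objective < best$objective)
        best <- cand
      if (is.finite(best$objective)) break
    }
  }
  # polish: restart from the optimum until no further improvement
  polish <- function(best) {
    stable <- FALSE
    for (k in seq_len(8)) {
      cand <- run(best$par)
      if (is.finite(cand$objective) && cand$objective < best$objective - 1e-12)
        best <- cand
      if (abs(cand$objective - best$objective) < 1e-6 &&
          cand$objective <= best$objective + 1e-6) {
        if (cand$objective < best$objective) best <- cand
        stable <- TRUE
        break
      }
    }
    best$stable <- stable
    best
  }
  if (is.finite(best$objective)) best <- polish(best)
  # flat ridges (e.g. an unidentified factor correlation when its component
  # sits on the zero boundary) can trap a single start: restart around the
  # incumbent before accepting a non-stable or suspect optimum
  if (!is.finite(best$objective) || !isTRUE(best$stable)) {
    for (k in seq_len(n_restarts)) {
      jit <- best$par * (1 + 0.05 * k * rep_len(c(1, -1), length(best$par))) +
        0.02 * k * rep_len(c(-1, 1), length(best$par))
      cand <- run(jit)
      if (is.finite(cand$objective) && cand$objective < best$objective - 1e-8)
        best <- polish(cand)
    }
  }
  best$convergence <- if (isTRUE(best$stable)) 0L else 1L
  best
}
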