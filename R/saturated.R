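# Moment-based starting values: per group, a rough mean vector and covariance
# assembled from the missing-data patterns (weighted by pattern size).
moment_estimates <- function(stats, d) {
  mu <- rep(0, d)
  wmu <- rep(0, d)
  S <- diag(d) * 0
  wS <- matrix(0, d, d)
  for (p in stats) {
    o <- p$obs
    mu[o] <- mu[o] + p$n * p$xbar
    wmu[o] <- wmu[o] + p$n
    S[o, o] <- S[o, o] + p$n * p$S
    wS[o, o] <- wS[o, o] + p$n
  }
  mu <- ifelse(wmu > 0, mu / pmax(wmu, 1), 0)
  S <- S / pmax(wS, 1)
  diag(S)[diag(S) <= 0] <- 1
  list(mu = mu, S = S)
}

sigma_from_blocks <- function(W, B) {
  rbind(cbind(W, B), cbind(t(B), W))
}

# Assemble W (within-twin) from variances v and within-twin correlations rw,
# and B (cross-twin) from v, within-trait cross-twin correlations rt and the
# cross-twin cross-trait correlation ctct (nt <= 2).
blocks_from_cor <- function(v, rw, rt, ctct, nt) {
  s <- sqrt(v)
  W <- diag(v, nt)
  B <- diag(rt * v, nt)
  if (nt == 2) {
    W[1, 2] <- W[2, 1] <- rw * s[1] * s[2]
    B[1, 2] <- B[2, 1] <- ctct * s[1] * s[2]
  }
  list(W = W, B = B)
}

# Parameter layout of the constrained saturated models (nt = 1 or 2).
saturated_layout <- function(nt, level) {
  mean_nm <- paste0("mean", seq_len(nt))
  v_nm <- paste0("v", seq_len(nt))
  rw_nm <- if (nt == 2) "rph" else character(0)
  bg <- function(g) c(paste0("r_", g, "_", seq_len(nt)),
                      if (nt == 2) paste0("ctct_", g))
  if (level == "twin_order") {
    nms <- c(paste0(mean_nm, "_mz"), paste0(v_nm, "_mz"),
             if (nt == 2) "rph_mz", bg("mz"),
             paste0(mean_nm, "_dz"), paste0(v_nm, "_dz"),
             if (nt == 2) "rph_dz", bg("dz"))
  } else {
    nms <- c(mean_nm, v_nm, rw_nm, bg("mz"), bg("dz"))
  }
  nms
}

saturated_bounds <- function(nms) {
  lower <- ifelse(grepl("^v", nms), 1e-8,
                  ifelse(grepl("^(r_|ctct|rph)", nms), -0.9999, -Inf))
  upper <- ifelse(grepl("^v", nms), Inf,
                  ifelse(grepl("^(r_|ctct|rph)", nms), 0.9999, Inf))
  list(lower = lower, upper = upper)
}

# Build per-group (mu, Sigma) from a named constrained-saturated parameter
# vector.
saturated_build <- function(par, nt, level) {
  g <- function(nm) unname(par[nm])
  if (level == "twin_order") {
    out <- lapply(c("mz", "dz"), function(z) {
      v <- g(paste0("v", seq_len(nt), "_", z))
      bl <- blocks_from_cor(v, if (nt == 2) g(paste0("rph_", z)) else 0,
                            g(paste0("r_", z, "_", seq_len(nt))),
                            if (nt == 2) g(paste0("ctct_", z)) else 0, nt)
      list(mu = rep(g(paste0("mean", seq_len(nt), "_", z)), 2),
           Sigma = sigma_from_blocks(bl$W, bl$B))
    })
  } else {
    v <- g(paste0("v", seq_len(nt)))
    rw <- if (nt == 2) g("rph") else 0
    mu <- rep(g(paste0("mean", seq_len(nt))), 2)
    out <- lapply(c("mz", "dz"), function(z) {
      bl <- blocks_from_cor(v, rw, g(paste0("r_", z, "_", seq_len(nt))),
                            if (nt == 2) g(paste0("ctct_", z)) else 0, nt)
      list(mu = mu, Sigma = sigma_from_blocks(bl$W, bl$B))
    })
  }
  names(out) <- c("MZ", "DZ")
  out
}

saturated_objective <- function(data, level) {
  nt <- data$nt
  nms <- saturated_layout(nt, level)
  function(par) {
    names(par) <- nms
    mod <- saturated_build(par, nt, level)
    val <- neg2ll_stats(data$groups$MZ, mod$MZ$mu, mod$MZ$Sigma) +
      neg2ll_stats(data$groups$DZ, mod$DZ$mu, mod$DZ$Sigma)
    if (!is.finite(val)) 1e10 else val
  }
}

saturated_start <- function(data, level) {
  nt <- data$nt
  nms <- saturated_layout(nt, level)
  start <- numeric(length(nms))
  names(start) <- nms
  for (z in c("mz", "dz")) {
    me <- moment_estimates(data$groups[[toupper(z)]], data$d)
    v <- (diag(me$S)[seq_len(nt)] + diag(me$S)[nt + seq_len(nt)]) / 2
    m <- (me$mu[seq_len(nt)] + me$mu[nt + seq_len(nt)]) / 2
    Dc <- stats::cov2cor(me$S + diag(1e-8, data$d))
    rt <- vapply(seq_len(nt), function(t) Dc[t, nt + t], 0)
    sfx <- if (level == "twin_order") paste0("_", z) else ""
    start[paste0("mean", seq_len(nt), sfx)] <- m
    start[paste0("v", seq_len(nt), sfx)] <- pmax(v, 1e-4)
    if (nt == 2) {
      start[paste0("rph", sfx)] <- (Dc[1, 2] + Dc[3, 4]) / 2
      start[paste0("ctct_", z)] <- (Dc[1, 4] + Dc[2, 3]) / 2
    }
    start[paste0("r_", z, "_", seq_len(nt))] <- pmin(pmax(rt, -0.9), 0.9)
  }
  if (level != "twin_order") {
    # shared means/variances averaged over groups (start values only)
    start
  } else start
}

#' Fit a saturated twin model
#'
#' Fits the per-zygosity multivariate-normal model by FIML at one of three
#' constraint levels used to test the twin-design assumptions:
#' \describe{
#'   \item{`"none"`}{free mean vector and covariance matrix per zygosity
#'     group (the fully saturated model).}
#'   \item{`"twin_order"`}{per-trait means and variances equated across twin
#'     order within each group, and the two cross-twin cross-trait covariances
#'     equated (symmetric cross block).}
#'   \item{`"zygosity"`}{additionally, means and variances (and the
#'     within-twin cross-trait covariance) equated across zygosity; cross-twin
#'     blocks remain group-specific. This is the constrained model from which
#'     twin and CTCT correlations are extracted.}
#' }
#'
#' @param data A [pair_data()] object (1 or 2 traits).
#' @param constraint_level `"none"`, `"twin_order"` or `"zygosity"`.
#' @return An object of class `saturated_fit`: group means/covariances,
#'   `neg2ll`, `n_free_params`, `convergence`, and (for constrained fits) the
#'   named parameter vector.
#' @export
fit_saturated <- function(data, constraint_level = c("none", "twin_order",
                                                     "zygosity")) {
  stopifnot(inherits(data, "pair_data"))
  constraint_level <- match.arg(constraint_level)
  if (data$nt > 2) stop("saturated twin models support 1 or 2 traits")
  if (any(data$n < 30))
    warning("fewer than 30 pairs in a zygosity group; estimates unstable")
  d <- data$d
  if (constraint_level == "none") {
    fits <- lapply(c("MZ", "DZ"), function(z) fit_group_free(data$groups[[z]], d))
    names(fits) <- c("MZ", "DZ")
    out <- list(constraint_level = constraint_level,
                groups = lapply(fits, function(f) f[c("mu", "Sigma")]),
                neg2ll = fits$MZ$neg2ll + fits$DZ$neg2ll,
                n_free_params = 2 * (d + d * (d + 1) / 2),
                convergence = max(fits$MZ$convergence, fits$DZ$convergence),
                param = NULL, data = data)
  } else {
    obj <- saturated_objective(data, constraint_level)
    start <- saturated_start(data, constraint_level)
    b <- saturated_bounds(names(start))
    opt <- minimize_neg2ll(obj, start, b$lower, b$upper)
    par <- opt$par
    names(par) <- names(start)
    mod <- saturated_build(par, data$nt, constraint_level)
    out <- list(constraint_level = constraint_level, groups = mod,
                neg2ll = opt$objective, n_free_params = length(par),
                convergence = opt$convergence, param = par, data = data)
  }
  out$AIC <- out$neg2ll + 2 * out$n_free_params
  if (out$convergence != 0)
    warning("saturated fit did not report clean convergence (level ",
            constraint_level, ")")
  class(out) <- "saturated_fit"
  out
}

# Free (mu, Sigma) for one group. With a single complete pattern the ML
# solution is closed form (sample mean, n-divisor covariance); otherwise the
# Cholesky-parameterized FIML objective is minimized.
fit_group_free <- function(stats, d) {
  if (length(stats) == 1 && length(stats[[1]]$obs) == d) {
    mu <- stats[[1]]$xbar
    Sigma <- stats[[1]]$S
    return(list(mu = mu, Sigma = Sigma,
                neg2ll = neg2ll_stats(stats, mu, Sigma), convergence = 0L))
  }
  me <- moment_estimates(stats, d)
  L0 <- t(chol(me$S + diag(1e-6, d)))
  start <- c(me$mu, L0[lower.tri(L0, diag = TRUE)])
  obj <- function(par) {
    mu <- par[seq_len(d)]
    L <- matrix(0, d, d)
    L[lower.tri(L, diag = TRUE)] <- par[-seq_len(d)]
    val <- neg2ll_stats(stats, mu, tcrossprod(L))
    if (!is.finite(val)) 1e10 else val
  }
  opt <- minimize_neg2ll(obj, start)
  mu <- opt$par[seq_len(d)]
  L <- matrix(0, d, d)
  L[lower.tri(L, diag = TRUE)] <- opt$par[-seq_len(d)]
  list(mu = mu, Sigma = tcrossprod(L), neg2ll = opt$objective,
       convergence = opt$convergence)
}

#' @export
print.saturated_fit <- function(x, ...) {
  cat("Saturated twin model (constraint level:", x$constraint_level, ")\n")
  cat(sprintf("  -2LL = %.4f, free parameters = %d\n", x$neg2ll,
              x$n_free_params))
  invisible(x)
}

#' Extract twin and cross-twin cross-trait correlations
#'
#' From a constrained (`"zygosity"`-level) saturated fit, returns per-trait
#' within-trait cross-twin correlations for each zygosity group and, for
#' bivariate fits, the cross-twin cross-trait (CTCT) correlation per group and
#' the phenotypic correlation, each with a profile-likelihood confidence
#' interval. The equality constraint guarantees CTCT(trait1 -> trait2) equals
#' CTCT(trait2 -> trait1) exactly.
#'
#' @param fit A `saturated_fit` at constraint level `"zygosity"`.
#' @param cis Compute profile-likelihood CIs (slower).
#' @param level Confidence level.
#' @return Data.frame with columns `quantity`, `estimate`, `ci_low`,
#'   `ci_high`.
#' @export
extract_correlations <- function(fit, cis = TRUE, level = 0.95) {
  stopifnot(inherits(fit, "saturated_fit"))
  if (fit$constraint_level != "zygosity")
    stop("correlations are extracted from the zygosity-constrained fit")
  nt <- fit$data$nt
  qs <- c(paste0("r_mz_", seq_len(nt)), paste0("r_dz_", seq_len(nt)),
          if (nt == 2) c("ctct_mz", "ctct_dz", "rph"))
  rows <- lapply(qs, function(q) {
    est <- unname(fit$param[q])
    ci <- if (cis) profile_ci(fit, q, level) else list(lower = NA, upper = NA)
    data.frame(quantity = q, estimate = est, ci_low = ci$lower,
               ci_high = ci$upper, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
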