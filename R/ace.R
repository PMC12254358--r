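# Components included per model.
model_components <- function(model) {
  switch(model,
         ACE = c("A", "C", "E"),
         AE = c("A", "E"),
         CE = c("C", "E"),
         E = "E",
         stop("unknown model: ", model))
}

# Parameterization specification: names/bounds, a builder mapping a named
# parameter vector to component matrices (NULL when inadmissible), and an
# initializer mapping fitted component matrices back to parameters.
#
# Types:
#   cholesky    — lower-triangular factor per component (PSD by construction)
#   correlated  — per-trait component variances + factor correlation
#   proportions — total variance per trait + standardized proportions for all
#                 components except `ref` (whose proportion is the remainder)
#                 + factor correlations; standardized components are
#                 coordinates, used for profile CIs
#   shares      — like proportions, but the cross-trait linkage is carried by
#                 the model-implied phenotypic correlation `rPh` and the
#                 shares of it contributed by each component except
#                 `share_ref` (remainder); factor correlations are derived.
#                 Makes rPh and the covariance shares exact coordinates.
ace_param_spec <- function(nt, model, type, ref = "E", share_ref = "E") {
  comps <- model_components(model)
  stopifnot(ref %in% comps, share_ref %in% comps)
  mean_nm <- paste0("mean", seq_len(nt))
  zero <- matrix(0, nt, nt)
  cormat <- function(r) {
    R <- diag(nt)
    if (nt == 2) R[1, 2] <- R[2, 1] <- r
    R
  }
  seqt <- seq_len(nt)
  if (type == "cholesky") {
    k <- nt * (nt + 1) / 2
    nms <- c(mean_nm, unlist(lapply(tolower(comps), function(cc)
      paste0(cc, seq_len(k)))))
    build <- function(par) {
      out <- list(A = zero, C = zero, E = zero,
                  mean = unname(par[mean_nm]))
      for (cc in comps) {
        L <- matrix(0, nt, nt)
        L[lower.tri(L, diag = TRUE)] <- unname(par[paste0(tolower(cc),
                                                          seq_len(k))])
        out[[cc]] <- tcrossprod(L)
      }
      out
    }
    init <- function(cm) {
      par <- cm$mean
      for (cc in comps) {
        L <- t(chol(cm[[cc]] + diag(1e-10, nt)))
        par <- c(par, L[lower.tri(L, diag = TRUE)])
      }
      stats::setNames(par, nms)
    }
  } else if (type == "correlated") {
    nms <- c(mean_nm, unlist(lapply(comps, function(cc)
      c(paste0(cc, seqt), if (nt == 2) paste0("r", cc)))))
    build <- function(par) {
      out <- list(A = zero, C = zero, E = zero, mean = unname(par[mean_nm]))
      for (cc in comps) {
        v <- unname(par[paste0(cc, seqt)])
        if (any(v < 0)) return(NULL)
        R <- cormat(if (nt == 2) unname(par[paste0("r", cc)]) else 0)
        out[[cc]] <- outer(sqrt(v), sqrt(v)) * R
      }
      out
    }
    init <- function(cm) {
      par <- cm$mean
      for (cc in comps) {
        v <- diag(cm[[cc]])
        par <- c(par, v, if (nt == 2) fac_cor_of(cm[[cc]]))
        names(par) <- NULL
      }
      stats::setNames(par, nms)
    }
  } else if (type == "proportions") {
    prop <- setdiff(comps, ref)
    nms <- c(mean_nm, paste0("T", seqt),
             unlist(lapply(prop, function(cc) paste0("p", cc, seqt))),
             if (nt == 2) paste0("r", comps))
    build <- function(par) {
      Tv <- unname(par[paste0("T", seqt)])
      p <- list(A = rep(0, nt), C = rep(0, nt), E = rep(0, nt))
      for (cc in prop) p[[cc]] <- unname(par[paste0("p", cc, seqt)])
      p[[ref]] <- 1 - Reduce(`+`, p[setdiff(names(p), ref)])
      if (any(p[[ref]] < 0)) return(NULL)
      out <- list(A = zero, C = zero, E = zero, mean = unname(par[mean_nm]))
      for (cc in comps) {
        s <- sqrt(Tv * p[[cc]])
        R <- cormat(if (nt == 2) unname(par[paste0("r", cc)]) else 0)
        out[[cc]] <- outer(s, s) * R
      }
      out
    }
    init <- function(cm) {
      W <- cm$A + cm$C + cm$E
      par <- c(cm$mean, diag(W))
      for (cc in prop) par <- c(par, diag(cm[[cc]]) / diag(W))
      if (nt == 2) for (cc in comps) par <- c(par, fac_cor_of(cm[[cc]]))
      stats::setNames(par, nms)
    }
  } else if (type == "shares") {
    if (nt != 2) stop("'shares' parameterization is bivariate-only")
    prop <- setdiff(comps, ref)
    sh <- setdiff(comps, share_ref)
    nms <- c(mean_nm, paste0("T", seqt),
             unlist(lapply(prop, function(cc) paste0("p", cc, seqt))),
             "rPh", paste0("share_", sh))
    build <- function(par) {
      Tv <- unname(par[paste0("T", seqt)])
      p <- list(A = rep(0, nt), C = rep(0, nt), E = rep(0, nt))
      for (cc in prop) p[[cc]] <- unname(par[paste0("p", cc, seqt)])
      p[[ref]] <- 1 - Reduce(`+`, p[setdiff(names(p), ref)])
      if (any(p[[ref]] < 0)) return(NULL)
      rPh <- unname(par["rPh"])
      s <- stats::setNames(rep(0, 3), c("A", "C", "E"))
      for (cc in sh) s[cc] <- unname(par[paste0("share_", cc)])
      s[share_ref] <- 1 - sum(s[sh])
      out <- list(A = zero, C = zero, E = zero, mean = unname(par[mean_nm]))
      for (cc in comps) {
        contrib <- s[cc] * rPh            # standardized cross-trait term
        den <- sqrt(p[[cc]][1] * p[[cc]][2])
        if (den < 1e-10) {
          if (abs(contrib) > 1e-10) return(NULL)
          r <- 0
        } else {
          r <- contrib / den
          if (abs(r) > 1) return(NULL)
        }
        sd_c <- sqrt(Tv * p[[cc]])
        out[[cc]] <- outer(sd_c, sd_c) * cormat(r)
      }
      out
    }
    init <- function(cm) {
      W <- cm$A + cm$C + cm$E
      sw <- sqrt(W[1, 1] * W[2, 2])
      rPh <- W[1, 2] / sw
      par <- c(cm$mean, diag(W))
      for (cc in prop) par <- c(par, diag(cm[[cc]]) / diag(W))
      par <- c(par, rPh)
      for (cc in sh) par <- c(par, if (abs(rPh) < 1e-12) 0 else
        (cm[[cc]][1, 2] / sw) / rPh)
      stats::setNames(par, nms)
    }
  } else stop("unknown parameterization: ", type)
  lower <- rep(-Inf, length(nms))
  upper <- rep(Inf, length(nms))
  lower[grepl("^(A|C|E)[0-9]$", nms)] <- 0
  lower[grepl("^T[0-9]$", nms)] <- 1e-8
  lower[grepl("^p[ACE][0-9]$", nms)] <- 0
  upper[grepl("^p[ACE][0-9]$", nms)] <- 1
  # factor correlations may sit on the +/-1 boundary (singular component,
  # full Sigma still PD); the phenotypic correlation cannot
  lower[grepl("^r[ACE]$", nms)] <- -1
  upper[grepl("^r[ACE]$", nms)] <- 1
  lower[nms == "rPh"] <- -0.9999
  upper[nms == "rPh"] <- 0.9999
  lower[grepl("^share_", nms)] <- -10
  upper[grepl("^share_", nms)] <- 10
  list(names = nms, lower = lower, upper = upper, build = build, init = init)
}

fac_cor_of <- function(M) {
  den <- sqrt(M[1, 1] * M[2, 2])
  if (den < 1e-12) 0 else M[1, 2] / den
}

# Build component matrices from a named vector under a public
# parameterization (compatibility wrapper over ace_param_spec).
ace_build <- function(par, nt, model, parameterization) {
  spec <- ace_param_spec(nt, model, parameterization)
  names(par) <- spec$names
  spec$build(par)
}

# Corner escape for explicit-correlation parameterizations: when a component
# variance sits on its zero boundary, the likelihood is flat in that
# component's factor correlation and gradient methods cannot discover that a
# small variance with the OPPOSITE correlation sign fits better (the Cholesky
# form has no such corner). Retry from bumped-variance starts with the factor
# correlation at both signs and keep the best solution.
boundary_retry <- function(opt, spec, obj, nt, model) {
  if (nt != 2 || !is.finite(opt$objective)) return(opt)
  par <- stats::setNames(opt$par, spec$names)
  comps <- spec$build(par)
  if (is.null(comps)) return(opt)
  W <- comps$A + comps$C + comps$E
  for (cc in model_components(model)) {
    rnm <- paste0("r", cc)
    if (!rnm %in% spec$names) next
    prop <- diag(comps[[cc]]) / diag(W)
    if (min(prop) > 0.01) next
    vnm <- intersect(c(paste0(cc, 1:2), paste0("p", cc, 1:2)), spec$names)
    for (rtry in c(-0.9, 0.9)) {
      st <- par
      if (length(vnm) == 2) {
        bump <- if (all(grepl("^p", vnm))) rep(0.02, 2) else 0.02 * diag(W)
        st[vnm] <- pmax(st[vnm], bump)
      }
      st[rnm] <- rtry
      cand <- minimize_neg2ll(obj, st, spec$lower, spec$upper, n_restarts = 0)
      if (is.finite(cand$objective) &&
          cand$objective < opt$objective - 1e-8) opt <- cand
    }
  }
  opt
}

ace_sigma <- function(comps) {
  W <- comps$A + comps$C + comps$E
  list(MZ = sigma_from_blocks(W, comps$A + comps$C),
       DZ = sigma_from_blocks(W, 0.5 * comps$A + comps$C))
}

ace_objective_spec <- function(data, spec) {
  nms <- spec$names
  build <- spec$build
  mz <- data$groups$MZ
  dz <- data$groups$DZ
  function(par) {
    names(par) <- nms
    comps <- build(par)
    if (is.null(comps)) return(1e10)
    Sig <- ace_sigma(comps)
    mu <- rep(comps$mean, 2)
    val <- neg2ll_stats(mz, mu, Sig$MZ) + neg2ll_stats(dz, mu, Sig$DZ)
    if (!is.finite(val)) 1e10 else val
  }
}

# Falconer-style moment starting values, expressed in any parameterization
# through its init() mapping.
ace_start <- function(data, model, spec) {
  nt <- data$nt
  me_mz <- moment_estimates(data$groups$MZ, data$d)
  me_dz <- moment_estimates(data$groups$DZ, data$d)
  v <- (diag(me_mz$S) + diag(me_dz$S)) / 2
  v <- pmax((v[seq_len(nt)] + v[nt + seq_len(nt)]) / 2, 1e-4)
  m <- (me_mz$mu + me_dz$mu) / 2
  m <- (m[seq_len(nt)] + m[nt + seq_len(nt)]) / 2
  Rmz <- stats::cov2cor(me_mz$S + diag(1e-8, data$d))
  Rdz <- stats::cov2cor(me_dz$S + diag(1e-8, data$d))
  fal <- vapply(seq_len(nt), function(t)
    falconer_estimates(Rmz[t, nt + t], Rdz[t, nt + t]), numeric(3))
  a2 <- pmin(pmax(fal[1, ], 0.05), 0.9)
  c2 <- pmin(pmax(fal[2, ], 0.02), 0.9 - a2)
  comps <- model_components(model)
  if (!"A" %in% comps) a2 <- rep(0, nt)
  if (!"C" %in% comps) c2 <- rep(0, nt)
  e2 <- pmax(1 - a2 - c2, 0.05)
  tot <- a2 + c2 + e2
  a2 <- a2 / tot; c2 <- c2 / tot; e2 <- e2 / tot
  props <- list(A = a2, C = c2, E = e2)
  cormat0 <- function(r) {
    R <- diag(nt)
    if (nt == 2) R[1, 2] <- R[2, 1] <- r
    R
  }
  cm <- list(mean = m)
  for (cc in c("A", "C", "E")) {
    s <- if (cc %in% comps) sqrt(v * props[[cc]]) else rep(0, nt)
    cm[[cc]] <- outer(s, s) * cormat0(if (cc %in% comps) 0.1 else 0)
  }
  spec$init(cm)
}

#' Fit a bivariate (or univariate) ACE twin model by FIML
#'
#' The expected `2*nt x 2*nt` covariance per zygosity group is assembled from
#' `nt x nt` blocks: within-twin = A + C + E; cross-twin = A + C for MZ and
#' 0.5*A + C for DZ pairs (additive-genetic correlation fixed at 1.0/0.5 by
#' the classical twin design). Each included component is parameterized either
#' by a lower-triangular Cholesky factor (`"cholesky"`, the default —
#' guarantees positive semi-definiteness) or as per-trait variances plus a
#' factor correlation (`"correlated"`, the mathematically equivalent
#' correlated-factors solution; `"proportions"` is an equivalent internal form
#' used for profile confidence intervals). Means are equated across twins and
#' zygosity. Nested models drop components: AE (no C), CE (no A), E only.
#'
#' @param data A [pair_data()] object (1 or 2 traits).
#' @param model `"ACE"`, `"AE"`, `"CE"` or `"E"`.
#' @param parameterization `"cholesky"`, `"correlated"` or `"proportions"`.
#' @param start Optional named start vector.
#' @return An object of class `ace_fit` with standardized components `a2`,
#'   `c2`, `e2` per trait, factor correlations `rA`, `rC`, `rE` (bivariate),
#'   the model-implied phenotypic correlation `rPh`, `neg2ll`,
#'   `n_free_params`, `AIC`, and `convergence`.
#' @export
fit_bivariate_ace <- function(data, model = c("ACE", "AE", "CE", "E"),
                              parameterization = c("cholesky", "correlated",
                                                   "proportions"),
                              start = NULL) {
  stopifnot(inherits(data, "pair_data"))
  model <- match.arg(model)
  parameterization <- match.arg(parameterization)
  nt <- data$nt
  if (nt > 2) stop("only univariate and bivariate models are supported")
  spec <- ace_param_spec(nt, model, parameterization)
  obj <- ace_objective_spec(data, spec)
  if (is.null(start)) start <- ace_start(data, model, spec)
  opt <- minimize_neg2ll(obj, start, spec$lower, spec$upper)
  if (parameterization != "cholesky")
    opt <- boundary_retry(opt, spec, obj, nt, model)
  par <- opt$par
  names(par) <- spec$names
  comps <- spec$build(par)
  if (is.null(comps))
    stop("ACE fit failed to reach an admissible solution (model ", model, ")")
  W <- comps$A + comps$C + comps$E
  std <- function(M) diag(M) / diag(W)
  fac_cor <- function(M) {
    if (nt < 2) return(NA_real_)
    den <- sqrt(M[1, 1] * M[2, 2])
    if (den < 1e-12) NA_real_ else M[1, 2] / den
  }
  out <- list(model = model, parameterization = parameterization,
              param = par,
              mean = comps$mean, A = comps$A, C = comps$C, E = comps$E,
              a2 = std(comps$A), c2 = std(comps$C), e2 = std(comps$E),
              rA = if ("A" %in% model_components(model)) fac_cor(comps$A) else NA_real_,
              rC = if ("C" %in% model_components(model)) fac_cor(comps$C) else NA_real_,
              rE = fac_cor(comps$E),
              rPh = if (nt == 2) W[1, 2] / sqrt(W[1, 1] * W[2, 2]) else NA_real_,
              neg2ll = opt$objective, n_free_params = length(par),
              AIC = opt$objective + 2 * length(par),
              convergence = opt$convergence, data = data)
  if (opt$convergence != 0)
    warning("ACE fit (", model, ") did not report clean convergence: ",
            opt$message %||% "")
  class(out) <- "ace_fit"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ace_fit <- function(x, ...) {
  nt <- length(x$a2)
  cat(sprintf("%s twin model (%s parameterization), %d trait(s)\n",
              x$model, x$parameterization, nt))
  for (t in seq_len(nt))
    cat(sprintf("  trait %d: a2 = %.3f, c2 = %.3f, e2 = %.3f\n",
                t, x$a2[t], x$c2[t], x$e2[t]))
  if (nt == 2)
    cat(sprintf("  rA = %.3f, rC = %.3f, rE = %.3f, rPh = %.3f\n",
                x$rA, x$rC, x$rE, x$rPh))
  cat(sprintf("  -2LL = %.4f, free parameters = %d, AIC = %.2f\n",
              x$neg2ll, x$n_free_params, x$AIC))
  invisible(x)
}

#' Likelihood-ratio comparison of nested model fits
#'
#' `delta(-2LL)` against a central chi-square with degrees of freedom equal to
#' the difference in free parameters. The nested (more parsimonious) model is
#' preferred when p >= `alpha`. When the parameter counts are equal (a pure
#' reparameterization up to boundary constraints), p is 1 when the fits agree
#' and 0 when the constrained model fits worse.
#'
#' @param full,nested Fits with `neg2ll` and `n_free_params` fields (e.g.
#'   `ace_fit`, `saturated_fit`); the nested parameter space must be a subset.
#' @param alpha Selection threshold.
#' @return List of class `lrt_result`: `delta_neg2ll`, `delta_df`, `p_value`,
#'   `preferred`.
#' @export
lrt_compare <- function(full, nested, alpha = 0.05) {
  delta <- nested$neg2ll - full$neg2ll
  ddf <- nested$n_free_params
  ddf <- full$n_free_params - ddf
  if (ddf < 0) stop("'nested' has more free parameters than 'full'")
  if (delta < -1e-6)
    stop("nested model fits better than the full model; optimizer failure ",
         sprintf("(delta = %.3g)", delta))
  delta <- max(delta, 0)
  p <- if (ddf == 0) {
    if (delta <= 1e-6) 1 else 0
  } else stats::pchisq(delta, ddf, lower.tail = FALSE)
  structure(list(delta_neg2ll = delta, delta_df = ddf, p_value = p,
                 preferred = if (p >= alpha) "nested" else "full"),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: delta(-2LL) = %.4f, delta df = %d, p = %.4g -> prefer %s\n",
              x$delta_neg2ll, x$delta_df, x$p_value, x$preferred))
  invisible(x)
}

#' Falconer closed-form variance-component estimates
#'
#' The classical moment identities `a2 = 2(r_MZ - r_DZ)`,
#' `c2 = 2 r_DZ - r_MZ`, `e2 = 1 - r_MZ`. No truncation is applied — negative
#' values are returned as-is and interpreted by the caller. Used as an
#' independent oracle for the maximum-likelihood engine.
#'
#' @param r_mz,r_dz Within-trait cross-twin correlations.
#' @return Named vector `c(a2, c2, e2)`.
#' @export
falconer_estimates <- function(r_mz, r_dz) {
  if (abs(r_mz) > 1 || abs(r_dz) > 1) stop("correlations must lie in [-1, 1]")
  c(a2 = 2 * (r_mz - r_dz), c2 = 2 * r_dz - r_mz, e2 = 1 - r_mz)
}

#' Decompose the phenotypic correlation into A/C/E shares
#'
#' With `h_i = sqrt(a2_i)`, `c_i = sqrt(c2_i)`, `e_i = sqrt(e2_i)`, the
#' model-implied phenotypic correlation is
#' `rPh = h1*h2*rA + c1*c2*rC + e1*e2*rE`; the A, C and E shares are each term
#' divided by rPh (the bivariate heritability decomposition). The three
#' contributions sum to rPh by algebraic identity.
#'
#' @param fit A converged bivariate `ace_fit`.
#' @param cis Compute profile-likelihood CIs for the shares.
#' @param level Confidence level.
#' @return Object of class `rph_decomposition`: `rPh_model`, `share_A`,
#'   `share_C`, `share_E` (with CI bounds when requested).
#' @export
decompose_rph <- function(fit, cis = FALSE, level = 0.95) {
  stopifnot(inherits(fit, "ace_fit"))
  if (length(fit$a2) != 2) stop("rPh decomposition requires a bivariate fit")
  contr <- c(A = fit$A[1, 2], C = fit$C[1, 2], E = fit$E[1, 2]) /
    sqrt((fit$A + fit$C + fit$E)[1, 1] * (fit$A + fit$C + fit$E)[2, 2])
  rPh <- sum(contr)
  if (abs(rPh) < 1e-6)
    stop("model-implied phenotypic correlation is zero; shares undefined")
  shares <- contr / rPh
  out <- list(rPh_model = rPh, share_A = unname(shares["A"]),
              share_C = unname(shares["C"]), share_E = unname(shares["E"]))
  if (cis) {
    for (q in c("share_A", "share_E")) {
      ci <- profile_ci(fit, q, level)
      out[[paste0(q, "_ci")]] <- c(ci$lower, ci$upper)
    }
    ci <- profile_ci(fit, "rPh", level)
    out$rPh_ci <- c(ci$lower, ci$upper)
  }
  structure(out, class = "rph_decomposition")
}

#' @export
print.rph_decomposition <- function(x, ...) {
  cat(sprintf("rPh = %.3f; shares: A = %.3f, C = %.3f, E = %.3f\n",
              x$rPh_model, x$share_A, x$share_C, x$share_E))
  invisible(x)
}
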