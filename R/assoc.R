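#' Randomly select one twin per pair
#'
#' Twin observations are not independent, so phenotypic correlation analyses
#' use one randomly selected twin per pair (uniform Bernoulli(0.5) choice,
#' deterministic given the seed).
#'
#' @param scored Individual-level data.frame with columns `pair_id` and `twin`
#'   (e.g. from [score_cohort()]).
#' @param seed Integer seed for the selection.
#' @return The selected rows, one per pair.
#' @export
select_one_per_pair <- function(scored, seed = 1L) {
  ids <- unique(scored$pair_id)
  if (length(ids) == 0) stop("empty input")
  set.seed(seed)
  chosen <- ifelse(stats::runif(length(ids)) < 0.5, 1L, 2L)
  names(chosen) <- ids
  sel <- scored$twin == chosen[as.character(scored$pair_id)]
  scored[sel, , drop = FALSE]
}

#' Pearson correlation with a Fisher-z 95% confidence interval
#'
#' Standard Pearson r on pairwise-complete cases, with the confidence interval
#' from the Fisher z-transform with normal quantiles and a two-sided p-value
#' from the t reference distribution (as `stats::cor.test`). The degenerate
#' case |r| = 1 returns the point interval.
#'
#' @param x,y Numeric vectors; missing values deleted pairwise.
#' @param level Confidence level.
#' @return List with `r`, `ci_low`, `ci_high`, `n`, `p_value`.
#' @export
pearson_with_ci <- function(x, y, level = 0.95) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete cases")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance in x or y")
  r <- stats::cor(x, y)
  if (abs(r) >= 1 - 1e-15) {
    return(list(r = r, ci_low = r, ci_high = r, n = n, p_value = 0))
  }
  ct <- stats::cor.test(x, y, conf.level = level)
  list(r = unname(ct$estimate), ci_low = ct$conf.int[1],
       ci_high = ct$conf.int[2], n = n, p_value = ct$p.value)
}

#' Pearson-Filon z test for two overlapping dependent correlations
#'
#' Compares `r_jk` and `r_jh` — two correlations sharing variable j (here the
#' synaesthesia score) and measured on the same n individuals — using the
#' classical Pearson-Filon (1898) statistic:
#' \deqn{z = \sqrt{n}\,(r_{jk} - r_{jh}) /
#'   \sqrt{(1 - r_{jk}^2)^2 + (1 - r_{jh}^2)^2 - 2k}}
#' with
#' \deqn{k = r_{kh}(1 - r_{jk}^2 - r_{jh}^2) -
#'   \tfrac{1}{2} r_{jk} r_{jh} (1 - r_{jk}^2 - r_{jh}^2 - r_{kh}^2),}
#' and a two-sided p-value from the standard normal.
#'
#' @param r_jk,r_jh Correlations of the shared variable j with traits k and h.
#' @param r_kh Correlation between traits k and h.
#' @param n Sample size (shared by the three correlations; with pairwise
#'   deletion, use the minimum of the three pairwise n's).
#' @return List with `r_jk`, `r_jh`, `r_kh`, `n`, `z`, `p_value`.
#' @export
pearson_filon_compare <- function(r_jk, r_jh, r_kh, n) {
  for (r in c(r_jk, r_jh, r_kh))
    if (abs(r) >= 1) stop("correlations must lie in (-1, 1)")
  if (n <= 3) stop("n must exceed 3")
  R <- matrix(c(1, r_jk, r_jh, r_jk, 1, r_kh, r_jh, r_kh, 1), 3, 3)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("correlation triple is not positive semi-definite")
  k <- r_kh * (1 - r_jk^2 - r_jh^2) -
    0.5 * r_jk * r_jh * (1 - r_jk^2 - r_jh^2 - r_kh^2)
  denom2 <- (1 - r_jk^2)^2 + (1 - r_jh^2)^2 - 2 * k
  z <- sqrt(n) * (r_jk - r_jh) / sqrt(denom2)
  list(r_jk = r_jk, r_jh = r_jh, r_kh = r_kh, n = n, z = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}

#' Compare the strongest correlation against all others
#'
#' Identifies the trait whose correlation with the shared variable
#' (synaesthesia) is largest and compares it pairwise against each remaining
#' trait with [pearson_filon_compare()], flagging Bonferroni-adjusted
#' significance.
#'
#' @param results Data.frame with columns `trait`, `r`, `n` (correlations of
#'   each trait with the shared variable; e.g. stacked [pearson_with_ci()]
#'   results).
#' @param cross_cor Named function or matrix giving the correlation between
#'   two compared traits on the same subsample: either a symmetric matrix with
#'   dimnames = trait names, or a function `(trait_k, trait_h) -> list(r, n)`.
#' @param alpha Significance level before adjustment.
#' @param family_size Bonferroni family size (number of primary correlations).
#' @return Data.frame: one row per comparison (`top_trait`, `other_trait`,
#'   `r_top`, `r_other`, `r_between`, `n`, `z`, `p_value`, `p_bonferroni`,
#'   `significant`).
#' @export
compare_strongest <- function(results, cross_cor, alpha = 0.05,
                              family_size = 8L) {
  if (nrow(results) < 2) stop("need at least 2 correlations to compare")
  top <- results$trait[which.max(results$r)]
  rest <- results[results$trait != top, , drop = FALSE]
  r_top <- results$r[results$trait == top]
  n_top <- results$n[results$trait == top]
  get_cross <- if (is.function(cross_cor)) cross_cor else {
    function(a, b) list(r = cross_cor[a, b], n = n_top)
  }
  rows <- lapply(seq_len(nrow(rest)), function(i) {
    other <- rest$trait[i]
    cc <- get_cross(top, other)
    n <- min(n_top, rest$n[i], cc$n)
    pf <- pearson_filon_compare(r_top, rest$r[i], cc$r, n)
    data.frame(top_trait = top, other_trait = other, r_top = r_top,
               r_other = rest$r[i], r_between = cc$r, n = n, z = pf$z,
               p_value = pf$p_value,
               p_bonferroni = min(1, pf$p_value * family_size),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_bonferroni < alpha
  out
}
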