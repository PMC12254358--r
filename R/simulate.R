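#' Specify one simulated trait
#'
#' A trait is generated as a standardized Gaussian latent variable with a
#' classical ACE decomposition (additive genetic A, shared environment C,
#' non-shared environment E), then expressed as ordinal questionnaire items.
#'
#' @param name Trait label (no underscores; used in column names).
#' @param a2,c2,e2 Standardized variance components; must be non-negative and
#'   sum to 1 (within 1e-12).
#' @param n_items Number of questionnaire items for the trait.
#' @param n_response_levels Ordinal levels per item (items take values
#'   `0:(n_response_levels-1)`).
#' @param skew_transform `"none"` or `"exponentiate"`. With `"exponentiate"`
#'   the item thresholds are placed on an exponentiated (lognormal) scale,
#'   which induces strong positive skew in the item-sum score; the
#'   preprocessing stage's `log(1+x)` transform approximately restores
#'   symmetry.
#' @param target_alpha Desired Cronbach's alpha of the item set; the per-item
#'   noise standard deviation is calibrated from it (see
#'   [item_noise_for_alpha()]). Ignored when `item_noise_sd` is given.
#' @param item_noise_sd Per-item Gaussian noise standard deviation on the
#'   latent scale; overrides `target_alpha`.
#' @param item_missing_rate Probability that an item response is missing.
#' @param dontknow_rate Probability that an item is answered
#'   "I don't know / don't want to answer" (coded `-1` in memory, `DK` on disk).
#'
#' @return An object of class `trait_spec`.
#' @export
trait_spec <- function(name, a2, c2, e2, n_items = 12L,
                       n_response_levels = 4L,
                       skew_transform = c("none", "exponentiate"),
                       target_alpha = 0.8, item_noise_sd = NULL,
                       item_missing_rate = 0, dontknow_rate = 0) {
  skew_transform <- match.arg(skew_transform)
  if (grepl("_", name)) stop("trait name must not contain underscores: ", name)
  comps <- c(a2 = a2, c2 = c2, e2 = e2)
  if (any(comps < 0)) stop("variance components must be non-negative")
  if (abs(sum(comps) - 1) > 1e-12)
    stop("a2 + c2 + e2 must sum to 1 (got ", sum(comps), ")")
  if (n_items < 1) stop("n_items must be >= 1")
  if (n_response_levels < 2) stop("n_response_levels must be >= 2")
  for (r in c(item_missing_rate, dontknow_rate))
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]")
  if (is.null(item_noise_sd))
    item_noise_sd <- item_noise_for_alpha(target_alpha, n_items,
                                          n_response_levels, skew_transform)
  structure(list(name = name, a2 = a2, c2 = c2, e2 = e2,
                 n_items = as.integer(n_items),
                 n_response_levels = as.integer(n_response_levels),
                 skew_transform = skew_transform,
                 item_noise_sd = item_noise_sd,
                 item_missing_rate = item_missing_rate,
                 dontknow_rate = dontknow_rate),
            class = "trait_spec")
}

#' Item discretization thresholds
#'
#' Thresholds on the standardized latent+noise scale that carve it into
#' `n_levels` ordinal categories. For `"none"` the categories are
#' equiprobable; for `"exponentiate"` the thresholds are equally spaced on the
#' scale of `exp(z)` (truncated at `exp(2)`), so low categories absorb most of
#' the mass and the item sum is right-skewed.
#'
#' @param n_levels Number of ordinal categories.
#' @param skew_transform `"none"` or `"exponentiate"`.
#' @return Numeric vector of `n_levels - 1` increasing thresholds.
#' @export
item_thresholds <- function(n_levels, skew_transform = "none") {
  if (skew_transform == "exponentiate") {
    edges <- exp(2) * seq_len(n_levels - 1) / n_levels
    log(edges)
  } else {
    stats::qnorm(seq_len(n_levels - 1) / n_levels)
  }
}

# Upper orthant probability P(Z1 > a, Z2 > b) for standard bivariate normal
# with correlation rho, via one-dimensional quadrature.
binorm_upper <- function(a, b, rho) {
  if (abs(rho) < 1e-12) return((1 - stats::pnorm(a)) * (1 - stats::pnorm(b)))
  s <- sqrt(1 - rho^2)
  stats::integrate(function(x)
    stats::dnorm(x) * stats::pnorm((b - rho * x) / s, lower.tail = FALSE),
    lower = a, upper = Inf, rel.tol = 1e-9)$value
}

# Exact Pearson correlation between two ordinal items that are graded
# discretizations (thresholds tau) of equicorrelated standard normals.
ordinal_item_cor <- function(rho, tau) {
  pbar <- stats::pnorm(tau, lower.tail = FALSE)
  covd <- 0
  for (i in seq_along(tau))
    for (j in seq_along(tau))
      covd <- covd + binorm_upper(tau[i], tau[j], rho) - pbar[i] * pbar[j]
  vard <- 0
  for (i in seq_along(tau))
    for (j in seq_along(tau))
      vard <- vard + stats::pnorm(max(tau[i], tau[j]), lower.tail = FALSE) -
        pbar[i] * pbar[j]
  covd / vard
}

#' Calibrate item noise for a target Cronbach's alpha
#'
#' Inverts the Spearman-Brown/alpha relation: for `k` items with common
#' inter-item correlation `rbar`, `alpha = k * rbar / (1 + (k - 1) * rbar)`.
#' Items are graded discretizations of latent value plus noise, so the
#' required underlying continuous inter-item correlation `rho = 1/(1 + s^2)`
#' is found by numerically inverting the exact ordinal item correlation under
#' the bivariate normal.
#'
#' @inheritParams item_thresholds
#' @param alpha Target Cronbach's alpha in (0, 1).
#' @param n_items Number of items.
#' @return Item noise standard deviation `s`.
#' @export
item_noise_for_alpha <- function(alpha, n_items, n_levels = 4L,
                                 skew_transform = "none") {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  rbar <- alpha / (n_items - alpha * (n_items - 1))
  tau <- item_thresholds(n_levels, skew_transform)
  f <- function(rho) ordinal_item_cor(rho, tau) - rbar
  if (f(0.999) < 0) {
    warning("target alpha unattainable at this item count/levels; using zero noise")
    return(0)
  }
  rho <- stats::uniroot(f, c(1e-6, 0.999), tol = 1e-8)$root
  sqrt(1 / rho - 1)
}

#' Configure a synthetic twin cohort
#'
#' @param traits List of [trait_spec()] objects (>= 1).
#' @param n_mz,n_dz_ss,n_dz_os Numbers of monozygotic, same-sex dizygotic and
#'   opposite-sex dizygotic pairs.
#' @param rA,rC,rE Cross-trait factor correlations. Either a single scalar
#'   (two traits), a vector of length `n_traits - 1` giving the correlation of
#'   trait 1 (the hub, e.g. synaesthesia) with each remaining trait — the
#'   remaining traits are then correlated through the hub via the single-factor
#'   product rule, which guarantees positive semi-definiteness — or a full
#'   `n_traits x n_traits` correlation matrix.
#' @param sex_effect,birthyear_effect Per-trait fixed-effect slopes (recycled):
#'   latent shift for female sex, and per-year slope on centred birth year.
#' @param birth_years Integer vector of possible birth years (sampled
#'   uniformly).
#' @param p_female Probability that a same-sex pair is female.
#' @param frac_undetermined Proportion of same-sex pairs relabelled as
#'   undetermined zygosity.
#' @param seed Integer seed; the dataset is deterministic given the config.
#'
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(traits, n_mz = 814L, n_dz_ss = 923L,
                              n_dz_os = 835L, rA = 0, rC = 0, rE = 0,
                              sex_effect = 0, birthyear_effect = 0,
                              birth_years = 1999:2004, p_female = 0.6,
                              frac_undetermined = 0, seed = 1L) {
  if (inherits(traits, "trait_spec")) traits <- list(traits)
  stopifnot(length(traits) >= 1,
            all(vapply(traits, inherits, TRUE, "trait_spec")))
  nt <- length(traits)
  nm <- vapply(traits, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate trait names")
  if (any(c(n_mz, n_dz_ss, n_dz_os) < 0)) stop("pair counts must be >= 0")
  if (frac_undetermined < 0 || frac_undetermined > 1)
    stop("frac_undetermined must lie in [0, 1]")
  RA <- expand_factor_cor(rA, nt, "rA")
  RC <- expand_factor_cor(rC, nt, "rC")
  RE <- expand_factor_cor(rE, nt, "rE")
  structure(list(traits = traits, n_mz = as.integer(n_mz),
                 n_dz_ss = as.integer(n_dz_ss), n_dz_os = as.integer(n_dz_os),
                 rA = RA, rC = RC, rE = RE,
                 sex_effect = rep_len(sex_effect, nt),
                 birthyear_effect = rep_len(birthyear_effect, nt),
                 birth_years = as.integer(birth_years),
                 p_female = p_female,
                 frac_undetermined = frac_undetermined,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Expand scalar / hub-vector / matrix factor correlations to an n x n
# correlation matrix and check positive semi-definiteness.
expand_factor_cor <- function(r, nt, label) {
  if (is.matrix(r)) {
    if (!all(dim(r) == nt)) stop(label, " matrix must be ", nt, "x", nt)
    R <- r
  } else if (nt == 1) {
    R <- matrix(1, 1, 1)
  } else {
    hub <- rep_len(r, nt - 1)
    if (any(abs(hub) > 1)) stop(label, " must lie in [-1, 1]")
    # single-factor structure: cor(1, j) = hub[j-1], cor(j, k) = hub_j * hub_k
    load <- c(1, hub)
    R <- outer(load, load)
    diag(R) <- 1
  }
  if (any(abs(R) > 1 + 1e-12)) stop(label, " entries must lie in [-1, 1]")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop(label, " correlation matrix is not positive semi-definite")
  R
}

#' Simulate latent ACE trait values for twin pairs
#'
#' Draws per-twin multivariate-normal latent trait values
#' `t = a*A + c*C + e*E`, with the additive-genetic factor A correlated 1.0
#' across MZ co-twins and 0.5 across DZ co-twins, C identical within a pair
#' and E independent across twins. Cross-trait factor correlations are `rA`,
#' `rC`, `rE`. Uses the ambient RNG state.
#'
#' @param n_mz,n_dz Pair counts per zygosity group.
#' @param a2,c2,e2 Per-trait standardized components (vectors of equal length).
#' @param rA,rC,rE Cross-trait factor correlations (scalar, hub vector, or
#'   matrix; see [simulation_config()]).
#' @return List with matrices `mz` and `dz` (`n x 2*n_traits`; columns ordered
#'   trait-within-twin: all traits of twin 1, then all traits of twin 2).
#' @export
simulate_latent_pairs <- function(n_mz, n_dz, a2, c2, e2, rA = 0, rC = 0,
                                  rE = 0) {
  nt <- length(a2)
  stopifnot(length(c2) == nt, length(e2) == nt)
  if (any(abs(a2 + c2 + e2 - 1) > 1e-12))
    stop("a2 + c2 + e2 must sum to 1 for each trait")
  RA <- expand_factor_cor(rA, nt, "rA")
  RC <- expand_factor_cor(rC, nt, "rC")
  RE <- expand_factor_cor(rE, nt, "rE")
  SA <- outer(sqrt(a2), sqrt(a2)) * RA
  SC <- outer(sqrt(c2), sqrt(c2)) * RC
  SE <- outer(sqrt(e2), sqrt(e2)) * RE
  sigma_pair <- function(kA) {
    W <- SA + SC + SE
    X <- kA * SA + SC
    rbind(cbind(W, X), cbind(X, W))
  }
  draw <- function(n, S) {
    if (n == 0) return(matrix(0, 0, 2 * nt))
    MASS::mvrnorm(n, mu = rep(0, 2 * nt), Sigma = S)
  }
  list(mz = draw(n_mz, sigma_pair(1)), dz = draw(n_dz, sigma_pair(0.5)))
}

#' Generate ordinal item responses from latent trait values
#'
#' Items are graded-threshold discretizations of the latent value plus
#' independent Gaussian item noise; larger noise lowers the expected internal
#' consistency. Missing and "don't know" codes are inserted independently per
#' item slot at the configured rates (`NA` and `-1` respectively).
#'
#' @param latent Numeric vector of per-individual latent trait values.
#' @param spec A [trait_spec()].
#' @param seed Optional integer seed; if `NULL`, the ambient RNG state is used.
#' @return Integer matrix (`length(latent) x n_items`) of responses in
#'   `0:(n_response_levels - 1)`, with `NA` = missing and `-1` = don't know.
#' @export
generate_item_responses <- function(latent, spec, seed = NULL) {
  stopifnot(inherits(spec, "trait_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(latent)
  k <- spec$n_items
  s <- spec$item_noise_sd
  tau <- item_thresholds(spec$n_response_levels, spec$skew_transform)
  u <- (matrix(latent, n, k) + matrix(stats::rnorm(n * k, sd = s), n, k)) /
    sqrt(1 + s^2)
  items <- matrix(findInterval(u, tau), n, k)
  if (spec$item_missing_rate > 0 || spec$dontknow_rate > 0) {
    miss <- matrix(stats::runif(n * k) < spec$item_missing_rate, n, k)
    dk <- matrix(stats::runif(n * k) < spec$dontknow_rate, n, k) & !miss
    items[dk] <- -1L
    items[miss] <- NA_integer_
  }
  storage.mode(items) <- "integer"
  items
}

#' Generate a synthetic twin cohort
#'
#' Produces one wide row per twin pair, with latent ACE trait values expressed
#' as ordinal item responses, fixed effects of sex and birth year added before
#' the optional skew-inducing transform, and a configurable fraction of
#' same-sex pairs relabelled as undetermined zygosity. Deterministic given
#' `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return An object of class `twin_cohort`: a list with `pairs` (wide
#'   data.frame: `pair_id, zygosity, sex_1, sex_2, birth_year`, then
#'   `<trait>_<item>_<twin>` columns), `latent` (per-individual true latent
#'   values, for testing/calibration), and `config`.
#' @export
generate_twin_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  traits <- config$traits
  nt <- length(traits)
  a2 <- vapply(traits, `[[`, 0, "a2")
  c2 <- vapply(traits, `[[`, 0, "c2")
  e2 <- vapply(traits, `[[`, 0, "e2")

  n_dz <- config$n_dz_ss + config$n_dz_os
  lat <- simulate_latent_pairs(config$n_mz, n_dz, a2, c2, e2,
                               config$rA, config$rC, config$rE)
  n_pairs <- config$n_mz + n_dz
  zyg <- c(rep("MZ", config$n_mz), rep("DZ_ss", config$n_dz_ss),
           rep("DZ_os", config$n_dz_os))
  L <- rbind(lat$mz, lat$dz)                     # n_pairs x 2*nt

  # demographics
  ss <- zyg != "DZ_os"
  sex_pair <- ifelse(stats::runif(n_pairs) < config$p_female, "F", "M")
  sex_1 <- sex_pair
  sex_2 <- sex_pair
  first_f <- stats::runif(n_pairs) < 0.5
  sex_1[!ss] <- ifelse(first_f[!ss], "F", "M")
  sex_2[!ss] <- ifelse(first_f[!ss], "M", "F")
  birth_year <- sample(config$birth_years, n_pairs, replace = TRUE)

  # undetermined zygosity: random relabelling of same-sex pairs
  if (config$frac_undetermined > 0) {
    idx <- which(ss)
    relab <- idx[stats::runif(length(idx)) < config$frac_undetermined]
    zyg[relab] <- "undetermined"
  }

  # fixed effects (added to the Gaussian latent, before any skew transform)
  by_c <- birth_year - mean(config$birth_years)
  for (t in seq_len(nt)) {
    fx1 <- config$sex_effect[t] * (sex_1 == "F") + config$birthyear_effect[t] * by_c
    fx2 <- config$sex_effect[t] * (sex_2 == "F") + config$birthyear_effect[t] * by_c
    L[, t] <- L[, t] + fx1
    L[, nt + t] <- L[, nt + t] + fx2
  }

  pairs <- data.frame(pair_id = seq_len(n_pairs), zygosity = zyg,
                      sex_1 = sex_1, sex_2 = sex_2, birth_year = birth_year,
                      stringsAsFactors = FALSE)
  for (t in seq_len(nt)) {
    sp <- traits[[t]]
    for (tw in 1:2) {
      items <- generate_item_responses(L[, (tw - 1) * nt + t], sp)
      colnames(items) <- sprintf("%s_%d_%d", sp$name, seq_len(sp$n_items), tw)
      pairs <- cbind(pairs, as.data.frame(items))
    }
  }
  colnames(L) <- c(sprintf("%s_1", vapply(traits, `[[`, "", "name")),
                   sprintf("%s_2", vapply(traits, `[[`, "", "name")))
  structure(list(pairs = pairs, latent = as.data.frame(L), config = config),
            class = "twin_cohort")
}

#' @export
print.twin_cohort <- function(x, ...) {
  tab <- table(x$pairs$zygosity)
  cat("Synthetic twin cohort:", nrow(x$pairs), "pairs (",
      paste(names(tab), tab, sep = " = ", collapse = ", "), ")\n")
  cat("Traits:", paste(vapply(x$config$traits, `[[`, "", "name"),
                       collapse = ", "), "\n")
  invisible(x)
}

#' Default study-like cohort configuration
#'
#' A nine-trait configuration emulating the population twin cohort the
#' pipeline is designed for: 814 MZ, 923 same-sex DZ and 835 opposite-sex DZ
#' pairs assessed at age 18 on an 8-item synaesthesia screen and eight symptom
#' scales (obsessive-compulsive 12 items, anxiety 38, depression 11,
#' psychotic-like experiences 6, ADHD 18, autism 12, eating 23, (hypo-)mania
#' 13). Internal consistencies are calibrated to the reported per-scale
#' alphas (0.65-0.93); the synaesthesia, OC, PLE and autism scores are
#' generated right-skewed so the skew-gated log(1+x) rule is exercised.
#' Cross-trait genetic correlations between synaesthesia and the feature
#' scales are graded 0.07-0.33, non-shared environmental correlations
#' 0.07-0.18, with no shared-environment linkage; per-trait heritability is
#' 0.45 for synaesthesia and 0.50 for the feature scales with C = 0.
#'
#' @param seed Integer seed.
#' @param n_mz,n_dz_ss,n_dz_os Pair counts (defaults match the emulated
#'   cohort).
#' @return A [simulation_config()].
#' @export
study_config <- function(seed = 1L, n_mz = 814L, n_dz_ss = 923L,
                         n_dz_os = 835L) {
  tr <- list(
    trait_spec("synaesthesia", 0.45, 0, 0.55, n_items = 8L,
               n_response_levels = 3L, skew_transform = "exponentiate",
               target_alpha = 0.80, item_missing_rate = 0.025,
               dontknow_rate = 0.05),
    trait_spec("oc",         0.5, 0, 0.5, n_items = 12L, target_alpha = 0.77,
               skew_transform = "exponentiate", item_missing_rate = 0.02),
    trait_spec("anxiety",    0.5, 0, 0.5, n_items = 38L, target_alpha = 0.93,
               item_missing_rate = 0.02),
    trait_spec("depression", 0.5, 0, 0.5, n_items = 11L, target_alpha = 0.86,
               item_missing_rate = 0.02),
    trait_spec("ple",        0.5, 0, 0.5, n_items = 6L, target_alpha = 0.65,
               skew_transform = "exponentiate", item_missing_rate = 0.02),
    trait_spec("adhd",       0.5, 0, 0.5, n_items = 18L, target_alpha = 0.92,
               item_missing_rate = 0.015),
    trait_spec("autism",     0.5, 0, 0.5, n_items = 12L, target_alpha = 0.72,
               skew_transform = "exponentiate", item_missing_rate = 0.05,
               dontknow_rate = 0.03),
    trait_spec("eating",     0.5, 0, 0.5, n_items = 23L, target_alpha = 0.93,
               item_missing_rate = 0.02),
    trait_spec("mania",      0.5, 0, 0.5, n_items = 13L, target_alpha = 0.84,
               item_missing_rate = 0.025)
  )
  simulation_config(
    traits = tr, n_mz = n_mz, n_dz_ss = n_dz_ss, n_dz_os = n_dz_os,
    rA = c(0.33, 0.29, 0.27, 0.26, 0.25, 0.27, 0.07, 0.21),
    rC = 0,
    rE = c(0.18, 0.09, 0.10, 0.10, 0.07, 0.10, 0.11, 0.12),
    sex_effect = c(0.1, 0.1, 0.25, 0.2, 0, 0, 0.05, 0.3, 0.05),
    birthyear_effect = 0.02,
    frac_undetermined = 0.008,
    seed = seed
  )
}
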