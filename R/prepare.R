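#' Prepare an analysis-ready phenotype
#'
#' Applies the skew-gated transform — `log(1 + x)` when the raw-score skewness
#' exceeds 1, otherwise no transform — then regresses the (possibly
#' transformed) score on sex and birth year by ordinary least squares and
#' standardizes the residuals to unit variance. Missing scores propagate. The
#' transform decision is made once, on the raw scores; re-running on prepared
#' output never re-applies the log (prepared values are standardized and can
#' be negative, with skewness no longer above the gate).
#'
#' @param scores Numeric vector of raw scale scores (non-negative where the
#'   transform may apply); `NA` allowed.
#' @param sex Character or factor vector (`"F"`/`"M"`) or 0/1 indicator.
#' @param birth_year Numeric vector.
#' @return An object of class `prepared_phenotype`: list with `values`
#'   (standardized residuals, `NA` propagated), `transform_applied`,
#'   `skew_raw`, `skew_after_transform` (NA if untransformed), and
#'   `covariates_used`.
#' @export
prepare_phenotype <- function(scores, sex, birth_year) {
  if (all(is.na(scores))) stop("all scores missing")
  ok <- !is.na(scores)
  if (stats::var(scores[ok]) == 0) stop("constant scores: cannot standardize")
  skew_raw <- skewness(scores)
  # the gate applies to raw (non-negative) scale scores only; already-prepared
  # values contain negatives, so re-running never re-applies the log
  transform <- skew_raw > 1 && all(scores[ok] >= 0)
  x <- scores
  skew_after <- NA_real_
  if (transform) {
    x <- log1p(scores)
    skew_after <- skewness(x)
  }
  sexi <- if (is.numeric(sex)) sex else as.integer(sex == "F")
  fit <- stats::lm(x ~ sexi + birth_year, na.action = stats::na.exclude)
  res <- stats::residuals(fit)
  values <- res / stats::sd(res, na.rm = TRUE)
  structure(list(values = as.numeric(values), transform_applied = transform,
                 skew_raw = skew_raw, skew_after_transform = skew_after,
                 covariates_used = c("sex", "birth_year")),
            class = "prepared_phenotype")
}

#' @export
print.prepared_phenotype <- function(x, ...) {
  cat("Prepared phenotype:", sum(!is.na(x$values)), "values;",
      if (x$transform_applied) "log(1+x) applied" else "untransformed",
      sprintf("(raw skew %.2f)\n", x$skew_raw))
  invisible(x)
}

#' Apply the pair-level inclusion filters
#'
#' Reproduces the cohort's exclusion cascade, in order: (1) individuals with
#' more than one missing/"don't know" item on the synaesthesia screen are
#' excluded; (2) individuals whose co-twin is absent or was excluded in step 1
#' are excluded (only complete pairs are analysed); (3) pairs of undetermined
#' zygosity are excluded. An absent co-twin is encoded by `sex_2 = NA`.
#'
#' @param pairs Wide pairs data.frame (see [write_twin_dataset()]); must
#'   contain the synaesthesia screen items named `<screen_trait>_<i>_<twin>`.
#' @param screen_trait Name of the screen trait (default `"synaesthesia"`).
#' @return List with `pairs` (surviving rows), `tally` (data.frame of
#'   individuals removed per reason, in application order) and `n_individuals`
#'   (individuals present in the input). The tally counts plus surviving
#'   individuals partition the input individuals.
#' @export
apply_inclusion_filters <- function(pairs, screen_trait = "synaesthesia") {
  if (anyDuplicated(pairs$pair_id)) stop("duplicate pair ids")
  present <- cbind(rep(TRUE, nrow(pairs)), !is.na(pairs$sex_2))
  screen_fail <- matrix(FALSE, nrow(pairs), 2)
  for (tw in 1:2) {
    cols <- trait_item_columns(names(pairs), screen_trait, tw)
    if (length(cols) != 8)
      stop("expected 8 screen items for trait '", screen_trait, "'")
    sc <- score_synaesthesia_screen(pairs[, cols])
    screen_fail[, tw] <- sc$excluded & present[, tw]
  }
  n_screen <- sum(screen_fail)
  # co-twin absent or excluded by the screen rule
  cot_screen <- screen_fail[, c(2, 1), drop = FALSE]
  cot_present <- present[, c(2, 1), drop = FALSE]
  cotwin_fail <- present & !screen_fail & (cot_screen | !cot_present)
  pair_ok <- present[, 1] & present[, 2] & !screen_fail[, 1] & !screen_fail[, 2]
  n_pairrule <- sum(cotwin_fail)
  undet <- pairs$zygosity == "undetermined"
  n_undet <- sum(2 * (pair_ok & undet))
  keep <- pair_ok & !undet
  tally <- data.frame(
    reason = c("screen_missingness", "incomplete_pair", "undetermined_zygosity"),
    n_individuals = c(n_screen, n_pairrule, n_undet))
  list(pairs = pairs[keep, , drop = FALSE], tally = tally,
       n_individuals = sum(present))
}

#' Score every trait of a wide twin dataset, per individual
#'
#' Builds the long individual-level table used by the preparation,
#' correlation and twin-modelling stages: two rows per pair (twin 1 and twin
#' 2) with demographics and one score column per trait. The synaesthesia
#' screen is scored by its own rule ([score_synaesthesia_screen()]); all other
#' traits by the 80%-completeness prorating rule ([score_scale()]).
#'
#' @inheritParams apply_inclusion_filters
#' @return Data.frame with columns `pair_id, twin, zygosity, sex, birth_year`
#'   and one column per trait.
#' @export
score_cohort <- function(pairs, screen_trait = "synaesthesia") {
  traits <- dataset_traits(pairs)
  out <- data.frame(
    pair_id = rep(pairs$pair_id, 2),
    twin = rep(1:2, each = nrow(pairs)),
    zygosity = rep(pairs$zygosity, 2),
    sex = c(pairs$sex_1, pairs$sex_2),
    birth_year = rep(pairs$birth_year, 2),
    stringsAsFactors = FALSE)
  for (tr in traits) {
    sc <- numeric(0)
    for (tw in 1:2) {
      cols <- trait_item_columns(names(pairs), tr, tw)
      items <- as.matrix(pairs[, cols, drop = FALSE])
      s <- if (tr == screen_trait) score_synaesthesia_screen(items)$score
           else score_scale(items)
      sc <- c(sc, s)
    }
    out[[tr]] <- sc
  }
  out
}

#' Descriptive statistics per trait
#'
#' One row per trait: included n and percentage of the sample, raw skewness
#' (and skewness after `log(1+x)` when the transform gate fires), Cronbach's
#' alpha with its 95% CI, and means/SDs overall and by zygosity (MZ vs pooled
#' DZ).
#'
#' @param pairs Filtered wide pairs data.frame.
#' @inheritParams apply_inclusion_filters
#' @return Data.frame, one row per trait.
#' @export
descriptives_table <- function(pairs, screen_trait = "synaesthesia") {
  if (nrow(pairs) == 0) stop("empty dataset")
  scored <- score_cohort(pairs, screen_trait)
  traits <- dataset_traits(pairs)
  is_mz <- scored$zygosity == "MZ"
  n_total <- nrow(scored)
  rows <- lapply(traits, function(tr) {
    s <- scored[[tr]]
    items <- rbind(
      as.matrix(pairs[, trait_item_columns(names(pairs), tr, 1), drop = FALSE]),
      as.matrix(pairs[, trait_item_columns(names(pairs), tr, 2), drop = FALSE]))
    al <- cronbach_alpha(items)
    sk <- skewness(s)
    data.frame(
      trait = tr, n_items = ncol(items),
      n_included = sum(!is.na(s)),
      pct_of_sample = 100 * sum(!is.na(s)) / n_total,
      skew_raw = sk,
      skew_after_transform = if (sk > 1) skewness(log1p(s)) else NA_real_,
      alpha = al$alpha, alpha_ci_low = al$ci_low, alpha_ci_high = al$ci_high,
      mean_all = mean(s, na.rm = TRUE),
      mean_mz = mean(s[is_mz], na.rm = TRUE),
      mean_dz = mean(s[!is_mz], na.rm = TRUE),
      sd_all = stats::sd(s, na.rm = TRUE),
      sd_mz = stats::sd(s[is_mz], na.rm = TRUE),
      sd_dz = stats::sd(s[!is_mz], na.rm = TRUE),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
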