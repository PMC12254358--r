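#' Configure a full analysis run
#'
#' @param input Either a path to a twin dataset CSV (the
#'   [write_twin_dataset()] dialect) or a [simulation_config()] to simulate
#'   the cohort in-process.
#' @param seed_selection Seed for the one-twin-per-pair selection (independent
#'   of the simulation seed, so the correlation subsample can be varied with
#'   the cohort held fixed).
#' @param alpha Significance level.
#' @param bonferroni_family Family size for the Bonferroni note on the primary
#'   correlations.
#' @param screen_trait Name of the synaesthesia screen trait.
#' @param trait_pairs Character vector of feature traits to model against the
#'   screen trait (default: all other traits in the dataset).
#' @param compute_cis Compute profile-likelihood CIs in the twin-model tables
#'   (slower).
#' @param outdir Output directory for [write_report_tables()] (optional).
#' @return Object of class `run_config`.
#' @export
run_config <- function(input, seed_selection = 1L, alpha = 0.05,
                       bonferroni_family = 8L, screen_trait = "synaesthesia",
                       trait_pairs = NULL, compute_cis = TRUE,
                       outdir = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (bonferroni_family < 1) stop("bonferroni_family must be >= 1")
  structure(list(input = input, seed_selection = as.integer(seed_selection),
                 alpha = alpha, bonferroni_family = as.integer(bonferroni_family),
                 screen_trait = screen_trait, trait_pairs = trait_pairs,
                 compute_cis = compute_cis, outdir = outdir),
            class = "run_config")
}

#' Run the full twin analysis pipeline
#'
#' Executes every stage in order: cohort acquisition (simulation or CSV),
#' inclusion filtering, scale scoring, descriptive statistics, phenotype
#' preparation (skew-gated log(1+x), residualization on sex and birth year,
#' standardization), one-twin-per-pair Pearson correlations with
#' Pearson-Filon comparisons of the strongest correlation against the rest,
#' and — for each feature trait paired with the screen trait — saturated
#' models at three constraint levels, twin/CTCT correlations, bivariate ACE
#' and nested AE/CE/E models with likelihood-ratio selection of the
#' parsimonious solution, and the decomposition of the phenotypic correlation
#' into A/C/E shares. Twin models use all complete pairs; correlations use the
#' one-per-pair subsample. Per-trait-pair failures are recorded and do not
#' abort the run.
#'
#' @param config A [run_config()].
#' @return Object of class `run_report`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cohort_seed <- NA_integer_
  if (inherits(config$input, "simulation_config")) {
    cohort <- generate_twin_dataset(config$input)
    pairs <- cohort$pairs
    cohort_seed <- config$input$seed
  } else {
    pairs <- read_twin_dataset(config$input)
  }
  screen <- config$screen_trait

  filt <- apply_inclusion_filters(pairs, screen)
  pairs <- filt$pairs
  desc <- descriptives_table(pairs, screen)
  scored <- score_cohort(pairs, screen)
  traits <- dataset_traits(pairs)
  features <- config$trait_pairs %||% setdiff(traits, screen)

  # prepared phenotypes (all included individuals jointly)
  prepared <- scored[, c("pair_id", "twin", "zygosity", "sex", "birth_year")]
  transform_applied <- logical(length(traits))
  names(transform_applied) <- traits
  for (tr in traits) {
    ph <- prepare_phenotype(scored[[tr]], scored$sex, scored$birth_year)
    prepared[[tr]] <- ph$values
    transform_applied[tr] <- ph$transform_applied
  }

  # correlation stage: one randomly selected twin per pair
  half <- select_one_per_pair(prepared, config$seed_selection)
  empty_cors <- data.frame(trait = character(0), r = numeric(0),
                           ci_low = numeric(0), ci_high = numeric(0),
                           n = integer(0), p_value = numeric(0))
  cors <- do.call(rbind, lapply(features, function(tr) {
    tryCatch({
      pc <- pearson_with_ci(half[[screen]], half[[tr]])
      data.frame(trait = tr, r = pc$r, ci_low = pc$ci_low,
                 ci_high = pc$ci_high, n = pc$n, p_value = pc$p_value,
                 stringsAsFactors = FALSE)
    }, error = function(e) NULL)
  })) %||% empty_cors
  cross <- function(a, b) {
    ok <- !is.na(half[[a]]) & !is.na(half[[b]])
    list(r = stats::cor(half[[a]][ok], half[[b]][ok]), n = sum(ok))
  }
  comparisons <- if (nrow(cors) >= 2)
    compare_strongest(cors, cross, config$alpha, config$bonferroni_family)
  else data.frame(top_trait = character(0), other_trait = character(0),
                  r_top = numeric(0), r_other = numeric(0),
                  r_between = numeric(0), n = integer(0), z = numeric(0),
                  p_value = numeric(0), p_bonferroni = numeric(0),
                  significant = logical(0))

  # twin-model stage: all complete pairs, MZ vs pooled DZ
  fits <- lapply(features, function(tr) {
    tryCatch(fit_trait_pair(prepared, screen, tr, config),
             error = function(e) list(trait = tr, error = conditionMessage(e)))
  })
  names(fits) <- features

  structure(list(
    exclusion_tally = filt$tally, n_individuals_input = filt$n_individuals,
    n_pairs_included = nrow(pairs), descriptives = desc,
    prepared = prepared,
    transform_applied = transform_applied, correlations = cors,
    comparisons = comparisons, twin_models = fits,
    provenance = list(seed_simulation = cohort_seed,
                      seed_selection = config$seed_selection,
                      alpha = config$alpha,
                      bonferroni_family = config$bonferroni_family,
                      screen_trait = screen, features = features,
                      compute_cis = config$compute_cis,
                      partial_response_scoring = "prorated",
                      zygosity_pooling = "MZ vs all DZ",
                      package_version = as.character(utils::packageVersion("twinlink")))),
    class = "run_report")
}

# Assemble pair_data for (screen, feature) from the prepared long table and
# fit the full model ladder for one trait pair.
fit_trait_pair <- function(prepared, screen, feature, config) {
  wide <- function(zyg) {
    sub <- prepared[prepared$zygosity %in% zyg, ]
    t1 <- sub[sub$twin == 1, c("pair_id", screen, feature)]
    t2 <- sub[sub$twin == 2, c("pair_id", screen, feature)]
    m <- merge(t1, t2, by = "pair_id", suffixes = c("_1", "_2"))
    as.matrix(m[, c(paste0(screen, c("_1")), paste0(feature, "_1"),
                    paste0(screen, "_2"), paste0(feature, "_2"))])
  }
  data <- pair_data(wide("MZ"), wide(c("DZ_ss", "DZ_os", "DZ")))

  sat0 <- fit_saturated(data, "none")
  sat1 <- fit_saturated(data, "twin_order")
  sat2 <- fit_saturated(data, "zygosity")
  assumption_lrts <- list(twin_order = lrt_compare(sat0, sat1, config$alpha),
                          zygosity = lrt_compare(sat1, sat2, config$alpha))
  correlations <- extract_correlations(sat2, cis = config$compute_cis)

  ace <- fit_bivariate_ace(data, "ACE")
  ae <- fit_bivariate_ace(data, "AE")
  ce <- fit_bivariate_ace(data, "CE")
  e <- fit_bivariate_ace(data, "E")
  lrt_sat <- lrt_compare(sat0, ace, config$alpha)
  lrts <- list(AE = lrt_compare(ace, ae, config$alpha),
               CE = lrt_compare(ace, ce, config$alpha),
               E = lrt_compare(ace, e, config$alpha))

  # parsimonious-model selection: among nested models not significantly worse
  # than ACE, the one with the fewest parameters (AIC breaks ties); ACE kept
  # when every reduction is rejected
  cand <- list(AE = ae, CE = ce, E = e)
  ok <- names(cand)[vapply(names(cand), function(m)
    lrts[[m]]$p_value >= config$alpha, TRUE)]
  selected_name <- if (length(ok) == 0) "ACE" else {
    np <- vapply(ok, function(m) cand[[m]]$n_free_params, 0)
    aic <- vapply(ok, function(m) cand[[m]]$AIC, 0)
    ok[order(np, aic)][1]
  }
  selected <- if (selected_name == "ACE") ace else cand[[selected_name]]
  decomposition <- decompose_rph(selected, cis = config$compute_cis)
  rA_ci <- rE_ci <- c(NA_real_, NA_real_)
  if (config$compute_cis) {
    if (!is.na(selected$rA)) {
      ci <- profile_ci(selected, "rA")
      rA_ci <- c(ci$lower, ci$upper)
    }
    if (!is.na(selected$rE)) {
      ci <- profile_ci(selected, "rE")
      rE_ci <- c(ci$lower, ci$upper)
    }
  }
  list(trait = feature, data_n = data$n, saturated = list(sat0, sat1, sat2),
       assumption_lrts = assumption_lrts, correlations = correlations,
       fits = list(ACE = ace, AE = ae, CE = ce, E = e),
       lrt_vs_saturated = lrt_sat, lrts_vs_ace = lrts,
       selected_model = selected_name, selected_fit = selected,
       decomposition = decomposition, rA_ci = rA_ci, rE_ci = rE_ci)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Twin analysis run:", x$n_pairs_included, "included pairs\n")
  cat("Exclusions:", paste(x$exclusion_tally$reason,
                           x$exclusion_tally$n_individuals,
                           sep = " = ", collapse = ", "), "\n")
  cat("Strongest correlation:",
      x$correlations$trait[which.max(x$correlations$r)],
      sprintf("(r = %.3f)\n", max(x$correlations$r)))
  ok <- !vapply(x$twin_models, function(m) !is.null(m$error), TRUE)
  cat("Twin models fitted:", sum(ok), "of", length(ok), "trait pairs\n")
  invisible(x)
}

#' Write the report tables of a pipeline run
#'
#' Emits `table2.csv` (descriptives), `fig1.csv` (forest-plot-ready
#' correlations), `table3.csv` (rPh, rA, rE, CTCT with CIs per trait pair),
#' `table4.csv` (A/E shares of the phenotypic correlation with CIs),
#' `comparisons.csv` (Pearson-Filon comparisons), `prepared.csv` (the
#' standardized residual phenotypes, one row per individual), `fits.json`
#' (the per-trait-pair model ladder: saturated levels, ACE/AE/CE/E estimates,
#' likelihood-ratio tests and the selected decomposition) and `run.json`
#' (provenance: seeds, settings, versions — sufficient to re-execute an
#' identical run).
#'
#' @param report A `run_report`.
#' @param outdir Output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
write_report_tables <- function(report, outdir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(outdir, name), row.names = FALSE)
    file.path(outdir, name)
  }
  files <- c(wr(report$descriptives, "table2.csv"),
             wr(report$correlations, "fig1.csv"),
             wr(report$comparisons, "comparisons.csv"),
             wr(report$prepared, "prepared.csv"))

  getq <- function(m, q, col) {
    i <- match(q, m$correlations$quantity)
    if (is.na(i)) NA_real_ else m$correlations[[col]][i]
  }
  ok <- Filter(function(m) is.null(m$error), report$twin_models)
  t3 <- do.call(rbind, lapply(ok, function(m) data.frame(
    trait = m$trait, model = m$selected_model,
    rPh = m$decomposition$rPh_model,
    rPh_ci_low = (m$decomposition$rPh_ci %||% c(NA, NA))[1],
    rPh_ci_high = (m$decomposition$rPh_ci %||% c(NA, NA))[2],
    rA = m$selected_fit$rA, rA_ci_low = m$rA_ci[1], rA_ci_high = m$rA_ci[2],
    rE = m$selected_fit$rE, rE_ci_low = m$rE_ci[1], rE_ci_high = m$rE_ci[2],
    ctct_mz = getq(m, "ctct_mz", "estimate"),
    ctct_mz_ci_low = getq(m, "ctct_mz", "ci_low"),
    ctct_mz_ci_high = getq(m, "ctct_mz", "ci_high"),
    ctct_dz = getq(m, "ctct_dz", "estimate"),
    ctct_dz_ci_low = getq(m, "ctct_dz", "ci_low"),
    ctct_dz_ci_high = getq(m, "ctct_dz", "ci_high"),
    stringsAsFactors = FALSE)))
  t4 <- do.call(rbind, lapply(ok, function(m) data.frame(
    trait = m$trait, model = m$selected_model,
    share_A = m$decomposition$share_A,
    share_A_ci_low = (m$decomposition$share_A_ci %||% c(NA, NA))[1],
    share_A_ci_high = (m$decomposition$share_A_ci %||% c(NA, NA))[2],
    share_C = m$decomposition$share_C,
    share_E = m$decomposition$share_E,
    share_E_ci_low = (m$decomposition$share_E_ci %||% c(NA, NA))[1],
    share_E_ci_high = (m$decomposition$share_E_ci %||% c(NA, NA))[2],
    stringsAsFactors = FALSE)))
  empty3 <- data.frame(trait = character(0), model = character(0),
                       rPh = numeric(0))
  files <- c(files, wr(t3 %||% empty3, "table3.csv"),
             wr(t4 %||% empty3, "table4.csv"))
  fit_json <- lapply(report$twin_models, function(m) {
    if (!is.null(m$error)) return(list(error = m$error))
    fit_fields <- function(f) list(
      model = f$model, neg2ll = f$neg2ll, n_free_params = f$n_free_params,
      AIC = f$AIC, convergence = f$convergence,
      a2 = f$a2, c2 = f$c2, e2 = f$e2,
      rA = f$rA, rC = f$rC, rE = f$rE, rPh = f$rPh)
    lrt_fields <- function(l) list(delta_neg2ll = l$delta_neg2ll,
                                   delta_df = l$delta_df,
                                   p_value = l$p_value,
                                   preferred = l$preferred)
    list(
      trait = m$trait,
      n_pairs = as.list(m$data_n),
      saturated = lapply(m$saturated, function(s)
        list(constraint_level = s$constraint_level, neg2ll = s$neg2ll,
             n_free_params = s$n_free_params, convergence = s$convergence)),
      assumption_lrts = lapply(m$assumption_lrts, lrt_fields),
      correlations = m$correlations,
      fits = lapply(m$fits, fit_fields),
      lrt_vs_saturated = lrt_fields(m$lrt_vs_saturated),
      lrts_vs_ace = lapply(m$lrts_vs_ace, lrt_fields),
      selected_model = m$selected_model,
      decomposition = unclass(m$decomposition),
      rA_ci = m$rA_ci, rE_ci = m$rE_ci)
  })
  jsonlite::write_json(fit_json, file.path(outdir, "fits.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  files <- c(files, file.path(outdir, "fits.json"))
  failures <- Filter(function(m) !is.null(m$error), report$twin_models)
  prov <- c(report$provenance,
            list(n_pairs_included = report$n_pairs_included,
                 exclusion_tally = report$exclusion_tally,
                 failures = lapply(failures, `[[`, "error")))
  jsonlite::write_json(prov, file.path(outdir, "run.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(files, file.path(outdir, "run.json")))
}
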