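#' Write a twin dataset to CSV
#'
#' One row per pair, wide format:
#' `pair_id, zygosity, sex_1, sex_2, birth_year, <trait>_<item>_1, ...,
#' <trait>_<item>_2, ...`. Missing item responses are written as empty cells
#' and "don't know" responses (in-memory code `-1`) as the literal code `DK`.
#' `read_twin_dataset(write_twin_dataset(x, path))` reproduces `x`
#' field-for-field, including the missing-value codes.
#'
#' @param pairs A `twin_cohort` or its wide `pairs` data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_twin_dataset <- function(pairs, path) {
  if (inherits(pairs, "twin_cohort")) pairs <- pairs$pairs
  stopifnot(is.data.frame(pairs))
  out <- pairs
  for (j in item_columns(names(out))) {
    v <- as.character(out[[j]])
    v[!is.na(out[[j]]) & out[[j]] == -1] <- "DK"
    v[is.na(out[[j]])] <- ""
    out[[j]] <- v
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a twin dataset written by [write_twin_dataset()]
#'
#' @param path CSV file path.
#' @return Wide data.frame with item columns as integers (`NA` = missing,
#'   `-1` = don't know).
#' @export
read_twin_dataset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE,
                        na.strings = "")
  if (nrow(df) > 0) {
    df$pair_id <- as.integer(df$pair_id)
    df$birth_year <- as.integer(df$birth_year)
  } else {
    df$pair_id <- integer(0)
    df$birth_year <- integer(0)
  }
  for (j in item_columns(names(df))) {
    v <- df[[j]]
    v[which(v == "DK")] <- "-1"
    df[[j]] <- as.integer(v)
  }
  df
}

# Indices of <trait>_<item>_<twin> columns in a header.
item_columns <- function(nms) {
  grep("^[^_]+_[0-9]+_[12]$", nms)
}

# Parse item column names into (trait, item, twin).
parse_item_columns <- function(nms) {
  idx <- item_columns(nms)
  m <- regmatches(nms[idx], regexec("^([^_]+)_([0-9]+)_([12])$", nms[idx]))
  data.frame(column = nms[idx],
             trait = vapply(m, `[[`, "", 2),
             item = as.integer(vapply(m, `[[`, "", 3)),
             twin = as.integer(vapply(m, `[[`, "", 4)),
             stringsAsFactors = FALSE)
}

# Item columns of one trait for one twin, in item order.
trait_item_columns <- function(nms, trait, twin) {
  info <- parse_item_columns(nms)
  info <- info[info$trait == trait & info$twin == twin, ]
  info$column[order(info$item)]
}

#' Trait names present in a wide twin dataset
#' @param pairs Wide pairs data.frame.
#' @return Character vector of trait names, in column order of appearance.
#' @export
dataset_traits <- function(pairs) {
  unique(parse_item_columns(names(pairs))$trait)
}

#' Write a simulation configuration to a YAML file
#' @param config A [simulation_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_simulation_config <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  x <- unclass(config)
  x$traits <- lapply(x$traits, unclass)
  x$rA <- as.vector(x$rA); x$rC <- as.vector(x$rC); x$rE <- as.vector(x$rE)
  x$n_traits <- length(config$traits)
  yaml::write_yaml(x, path, precision = 17)
  invisible(path)
}

#' Read a simulation configuration from a YAML file
#' @param path YAML path written by [write_simulation_config()].
#' @return A [simulation_config()].
#' @export
read_simulation_config <- function(path) {
  x <- yaml::read_yaml(path)
  nt <- x$n_traits
  traits <- lapply(x$traits, function(tr)
    trait_spec(tr$name, tr$a2, tr$c2, tr$e2, tr$n_items,
               tr$n_response_levels, tr$skew_transform,
               item_noise_sd = tr$item_noise_sd,
               item_missing_rate = tr$item_missing_rate,
               dontknow_rate = tr$dontknow_rate))
  simulation_config(traits,
                    n_mz = x$n_mz, n_dz_ss = x$n_dz_ss, n_dz_os = x$n_dz_os,
                    rA = matrix(x$rA, nt, nt), rC = matrix(x$rC, nt, nt),
                    rE = matrix(x$rE, nt, nt),
                    sex_effect = x$sex_effect,
                    birthyear_effect = x$birthyear_effect,
                    birth_years = x$birth_years, p_female = x$p_female,
                    frac_undetermined = x$frac_undetermined, seed = x$seed)
}
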