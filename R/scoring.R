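#' Score the eight-item synaesthesia screen
#'
#' Responses are weighted "yes" = 1.0, "yes, to some extent" = 0.5, "no" = 0;
#' "I don't know / don't want to answer" and missing responses carry no
#' weight. The score is the sum of weights over answered items; an individual
#' is flagged excluded when more than one of the eight items is missing or
#' answered "don't know" (a single such item is tolerated and contributes 0).
#'
#' @param responses Either a vector of 8 responses for one individual or a
#'   matrix/data.frame with 8 columns (one row per individual). Responses may
#'   be character labels (`"yes"`, `"some_extent"`/`"Yes, to some extent"`,
#'   `"no"`, `"dk"`) or ordinal codes (`0` = no, `1` = some extent, `2` = yes,
#'   `-1` = don't know, `NA` = missing).
#' @return A data.frame with columns `score` and `excluded` (one row per
#'   individual); excluded individuals have `score = NA`.
#' @export
score_synaesthesia_screen <- function(responses) {
  if (is.data.frame(responses)) responses <- as.matrix(responses)
  if (!is.matrix(responses)) responses <- matrix(responses, nrow = 1)
  if (ncol(responses) != 8)
    stop("the synaesthesia screen has exactly 8 items; got ", ncol(responses))
  w <- screen_weights(responses)
  unanswered <- matrix(is.na(w), nrow(responses), 8)
  n_un <- rowSums(unanswered)
  score <- rowSums(w, na.rm = TRUE)
  excluded <- n_un > 1
  score[excluded] <- NA_real_
  data.frame(score = score, excluded = excluded)
}

# Map screen responses to item weights (NA = unanswered).
screen_weights <- function(x) {
  if (is.character(x)) {
    key <- tolower(trimws(x))
    key[key == "yes, to some extent"] <- "some_extent"
    key[key %in% c("i don't know / don't want to answer", "dk")] <- NA
    out <- rep(NA_real_, length(key))
    out[key == "yes"] <- 1
    out[key == "some_extent"] <- 0.5
    out[key == "no"] <- 0
    bad <- !is.na(key) & !key %in% c("yes", "some_extent", "no")
    if (any(bad)) stop("unknown response label: ", key[which(bad)[1]])
    dim(out) <- dim(x)
    out
  } else {
    bad <- !is.na(x) & !x %in% c(-1, 0, 1, 2)
    if (any(bad)) stop("unknown response code: ", x[which(bad)[1]])
    out <- x / 2
    out[!is.na(x) & x == -1] <- NA_real_
    out
  }
}

#' Score a symptom scale from its item responses
#'
#' Individuals answering less than 80% of a scale's items (missing or "don't
#' know") do not contribute: their score is `NA`. The boundary is strict —
#' exactly 80% answered is included. Partially complete responses (answered
#' fraction in \[0.8, 1)) are prorated: score = `n_items` times the mean of
#' the answered items, avoiding the downward bias of a raw sum.
#'
#' @param responses Vector (one individual) or matrix/data.frame (rows =
#'   individuals) of ordinal item responses (`NA` = missing, `-1` = don't
#'   know).
#' @param n_items Expected item count (defaults to the number of columns).
#' @return Numeric vector of scores (`NA` where excluded by the 80% rule).
#' @export
score_scale <- function(responses, n_items = NULL) {
  if (is.data.frame(responses)) responses <- as.matrix(responses)
  if (!is.matrix(responses)) responses <- matrix(responses, nrow = 1)
  if (!is.null(n_items) && ncol(responses) != n_items)
    stop("expected ", n_items, " items, got ", ncol(responses))
  if (any(responses < -1, na.rm = TRUE))
    stop("unknown response codes (negative values other than -1)")
  k <- ncol(responses)
  x <- responses
  x[!is.na(x) & x == -1] <- NA   # don't know counts as unanswered
  answered <- rowSums(!is.na(x))
  score <- k * rowMeans(x, na.rm = TRUE)
  score[answered / k < 0.8] <- NA_real_
  score[answered == 0] <- NA_real_
  score
}

#' Cronbach's alpha with a Feldt 95% confidence interval
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance(total score))`,
#' computed on complete cases. The confidence interval uses Feldt's
#' F-distribution method: `1 - (1 - alpha) * qf(p, n - 1, (n - 1)(k - 1))`.
#'
#' @param item_matrix Numeric matrix/data.frame, rows = respondents, columns =
#'   items (`-1` treated as unanswered).
#' @param level Confidence level (default 0.95).
#' @return List with `alpha`, `ci_low`, `ci_high`, `n` (complete cases), `k`.
#' @export
cronbach_alpha <- function(item_matrix, level = 0.95) {
  x <- as.matrix(item_matrix)
  if (is.integer(x)) x[!is.na(x) & x == -1L] <- NA  # ordinal don't-know code
  x <- x[stats::complete.cases(x), , drop = FALSE]
  k <- ncol(x)
  n <- nrow(x)
  if (k < 2) stop("need at least 2 items")
  if (n < 3) stop("need at least 3 complete respondents")
  total_var <- stats::var(rowSums(x))
  if (total_var <= 0) stop("zero total-score variance: alpha undefined")
  alpha <- k / (k - 1) * (1 - sum(apply(x, 2, stats::var)) / total_var)
  a <- 1 - level
  q <- stats::qf(c(1 - a / 2, a / 2), n - 1, (n - 1) * (k - 1))
  list(alpha = alpha, ci_low = 1 - (1 - alpha) * q[1],
       ci_high = 1 - (1 - alpha) * q[2], n = n, k = k)
}

#' Sample skewness (adjusted Fisher-Pearson G1)
#'
#' `G1 = g1 * sqrt(n(n-1)) / (n-2)` where `g1 = m3 / m2^(3/2)` with n-divisor
#' central moments — the default reported by common statistical packages.
#'
#' @param values Numeric vector; `NA`s are dropped.
#' @return Skewness statistic.
#' @export
skewness <- function(values) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 3) stop("need at least 3 non-missing values")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) stop("zero variance: skewness undefined")
  g1 <- mean((x - m)^3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}
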