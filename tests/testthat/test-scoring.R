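test_that("synaesthesia screen scoring follows the item weights", {
  expect_equal(score_synaesthesia_screen(rep("no", 8))$score, 0)
  expect_equal(score_synaesthesia_screen(
    c("yes", "Yes, to some extent", rep("no", 6)))$score, 1.5)
  # numeric ordinal codes: 0 = no, 1 = some extent, 2 = yes
  expect_equal(score_synaesthesia_screen(c(2L, 1L, rep(0L, 6)))$score, 1.5)
  expect_error(score_synaesthesia_screen(rep("no", 7)), "8 items")
  expect_error(score_synaesthesia_screen(c("maybe", rep("no", 7))),
               "unknown response label")
  expect_error(score_synaesthesia_screen(c(5L, rep(0L, 7))),
               "unknown response code")
})

test_that("screen tolerates one unanswered item but excludes at two", {
  one_dk <- score_synaesthesia_screen(c(-1L, 2L, rep(0L, 6)))
  expect_false(one_dk$excluded)
  expect_equal(one_dk$score, 1)        # unanswered item contributes 0
  two_dk <- score_synaesthesia_screen(c(-1L, -1L, rep(0L, 6)))
  expect_true(two_dk$excluded)
  expect_true(is.na(two_dk$score))
  mixed <- score_synaesthesia_screen(c(-1L, NA, rep(0L, 6)))
  expect_true(mixed$excluded)
})

test_that("scale scoring applies the strict <80% completeness rule", {
  expect_equal(score_scale(rep(0L, 12)), 0)
  # 38 items with 8 missing: 78.9% answered -> excluded
  x <- c(rep(1L, 30), rep(NA_integer_, 8))
  expect_true(is.na(score_scale(x)))
  # exactly 80% answered is INCLUDED (boundary is strict)
  y <- c(rep(1L, 8), rep(NA_integer_, 2))
  expect_equal(score_scale(y), 10)     # prorated: 10 * mean(answered)
  # prorating: 9 of 10 answered, each 1 -> 10 * (9/9 * 1) = 10
  z <- c(rep(1L, 9), NA_integer_)
  expect_equal(score_scale(z), 10)
  # don't-know counts as unanswered
  w <- c(rep(1L, 30), rep(-1L, 8))
  expect_true(is.na(score_scale(w)))
  expect_error(score_scale(c(1L, -3L, rep(0L, 8))), "unknown response codes")
  expect_error(score_scale(rep(0L, 11), n_items = 12), "expected 12 items")
})

test_that("cronbach alpha matches hand computations and bounds", {
  # k parallel identical items -> alpha = 1
  x <- rnorm(50)
  expect_equal(cronbach_alpha(cbind(x, x, x))$alpha, 1)
  # constructed matrix with item variances 1,1,1 and total variance 6:
  # alpha = (3/2) * (1 - 3/6) = 0.75
  i1 <- c(-1, 0, 1)
  i3 <- 0.25 * i1 + sqrt(0.3125) * c(1, -2, 1)
  m <- cbind(i1, i1, i3)
  expect_equal(var(m[, 1]), 1)
  expect_equal(var(m[, 3]), 1)
  expect_equal(var(rowSums(m)), 6)
  expect_equal(cronbach_alpha(m)$alpha, 0.75, tolerance = 1e-12)
  # mutually independent items -> alpha ~ 0
  set.seed(42)
  ind <- matrix(rnorm(5000 * 12), 5000, 12)
  expect_lt(abs(cronbach_alpha(ind)$alpha), 0.05)
  # alpha <= 1 always; Feldt CI ordered around the estimate
  al <- cronbach_alpha(matrix(rnorm(600), 100, 6) +
                         rnorm(100))
  expect_lte(al$alpha, 1)
  expect_lt(al$ci_low, al$alpha)
  expect_gt(al$ci_high, al$alpha)
  expect_error(cronbach_alpha(matrix(1, 10, 3)), "zero total-score variance")
})

test_that("skewness is the adjusted Fisher-Pearson G1", {
  expect_equal(skewness(c(-1, 0, 1)), 0)
  set.seed(11)
  expect_lt(abs(skewness(rexp(1e5)) - 2), 0.1)
  # adjustment factor: G1 = g1 * sqrt(n(n-1))/(n-2)
  x <- c(1, 2, 4, 8)
  m2 <- mean((x - mean(x))^2)
  g1 <- mean((x - mean(x))^3) / m2^1.5
  expect_equal(skewness(x), g1 * sqrt(4 * 3) / 2)
  expect_error(skewness(c(1, 1, 1)), "zero variance")
  expect_error(skewness(c(1, 2)), "at least 3")
})
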