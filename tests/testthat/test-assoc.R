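test_that("one-per-pair selection is deterministic, complete and balanced", {
  sc <- data.frame(pair_id = rep(1:50, 2), twin = rep(1:2, each = 50),
                   y = rnorm(100))
  s1 <- select_one_per_pair(sc, seed = 7)
  expect_equal(nrow(s1), 50)
  expect_equal(sort(unique(s1$pair_id)), 1:50)
  expect_identical(s1, select_one_per_pair(sc, seed = 7))
  # selection is Bernoulli(0.5) per pair across seeds
  frac <- mean(vapply(1:200, function(s)
    mean(select_one_per_pair(sc, seed = s)$twin == 1), 0))
  expect_lt(abs(frac - 0.5), 0.02)
  expect_error(select_one_per_pair(sc[0, ]), "empty")
})

test_that("pearson_with_ci matches hand computation and handles degeneracy", {
  pc <- pearson_with_ci(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(pc$r, 0.8)
  expect_equal(pc$n, 5)
  x <- rnorm(20)
  ident <- pearson_with_ci(x, x)
  expect_equal(ident$r, 1)
  expect_equal(c(ident$ci_low, ident$ci_high), c(1, 1))
  expect_error(pearson_with_ci(x, rep(1, 20)), "zero variance")
  expect_error(pearson_with_ci(1:2, 2:1), "at least 3")
  # affine invariance
  y <- rnorm(20)
  expect_equal(pearson_with_ci(x, y)$r,
               pearson_with_ci(2 * x - 5, 0.1 * y + 3)$r, tolerance = 1e-12)
})

test_that("Fisher-z confidence intervals achieve nominal coverage", {
  set.seed(55)
  rho <- 0.3
  n <- 1000
  cover <- vapply(1:2000, function(i) {
    z1 <- rnorm(n)
    y <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    pc <- pearson_with_ci(z1, y)
    pc$ci_low <= rho && rho <= pc$ci_high
  }, TRUE)
  expect_lt(abs(mean(cover) - 0.95), 0.015)
})

test_that("Pearson-Filon z matches an independent implementation", {
  # independent brute-force transcription of the 1898 covariance form
  pf_oracle <- function(rjk, rjh, rkh, n) {
    cov_term <- rkh * (1 - rjk^2 - rjh^2) -
      0.5 * (rjk * rjh) * (1 - rjk^2 - rjh^2 - rkh^2)
    (rjk - rjh) * sqrt(n) /
      sqrt((1 - rjk^2)^2 + (1 - rjh^2)^2 - 2 * cov_term)
  }
  got <- pearson_filon_compare(0.28, 0.19, 0.40, 1286)
  expect_equal(got$z, pf_oracle(0.28, 0.19, 0.40, 1286), tolerance = 1e-10)
  expect_equal(got$p_value, 2 * pnorm(-abs(got$z)))

  # z = 0 exactly when the two correlations are equal
  eq <- pearson_filon_compare(0.25, 0.25, 0.1, 500)
  expect_identical(eq$z, 0)
  expect_identical(eq$p_value, 1)

  # sqrt(n) scaling
  z1 <- pearson_filon_compare(0.3, 0.2, 0.25, 400)$z
  z2 <- pearson_filon_compare(0.3, 0.2, 0.25, 800)$z
  expect_equal(z2 / z1, sqrt(2), tolerance = 1e-10)

  expect_error(pearson_filon_compare(0.9, -0.9, 0.9, 100),
               "positive semi-definite")
  expect_error(pearson_filon_compare(1, 0.2, 0.1, 100), "\\(-1, 1\\)")
  expect_error(pearson_filon_compare(0.3, 0.2, 0.1, 3), "exceed 3")
})

test_that("Pearson-Filon p agrees with a parametric-bootstrap null", {
  # observed configuration: r_jk = 0.28, r_jh = 0.19, r_kh = 0.40, n = 1286
  n <- 1286
  obs <- pearson_filon_compare(0.28, 0.19, 0.40, n)
  r0 <- (0.28 + 0.19) / 2
  R <- matrix(c(1, r0, r0, r0, 1, 0.40, r0, 0.40, 1), 3, 3)
  L <- t(chol(R))
  set.seed(99)
  zs <- vapply(1:10000, function(i) {
    X <- matrix(rnorm(n * 3), n, 3) %*% t(L)
    cr <- cor(X)
    pearson_filon_compare(cr[1, 2], cr[1, 3], cr[2, 3], n)$z
  }, 0)
  p_boot <- mean(abs(zs) >= abs(obs$z))
  expect_lt(abs(p_boot - obs$p_value), 0.01)
})

test_that("compare_strongest identifies the top trait and adjusts p-values", {
  res <- data.frame(trait = c("a", "b", "c"), r = c(0.3, 0.3, 0.3),
                    n = c(1000, 1000, 1000))
  cc <- matrix(0.2, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  diag(cc) <- 1
  out <- compare_strongest(res, cc)
  expect_equal(nrow(out), 2)
  expect_true(all(out$z == 0))
  expect_true(all(out$p_bonferroni == 1))
  # two-trait input -> exactly one comparison row
  out2 <- compare_strongest(res[1:2, ], cc[1:2, 1:2])
  expect_equal(nrow(out2), 1)
  expect_error(compare_strongest(res[1, , drop = FALSE], cc), "at least 2")
})

test_that("a genuinely stronger association is detected in simulation", {
  # graded true correlations with the shared variable: 0.30, 0.20, 0.15
  set.seed(77)
  n <- 5000
  rj <- c(0.30, 0.20, 0.15)
  f <- rnorm(n)
  X <- sapply(rj, function(r) r * f + sqrt(1 - r^2) * rnorm(n))
  scored <- data.frame(j = f, k = X[, 1], h = X[, 2], g = X[, 3])
  res <- do.call(rbind, lapply(c("k", "h", "g"), function(tr) {
    pc <- pearson_with_ci(scored$j, scored[[tr]])
    data.frame(trait = tr, r = pc$r, n = pc$n)
  }))
  cross <- function(a, b) list(r = cor(scored[[a]], scored[[b]]), n = n)
  out <- compare_strongest(res, cross, family_size = 3)
  expect_equal(unique(out$top_trait), "k")
  expect_true(all(out$significant))
})
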