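test_that("falconer closed forms", {
  expect_equal(falconer_estimates(0.8, 0.4), c(a2 = 0.8, c2 = 0.0, e2 = 0.2))
  expect_equal(falconer_estimates(0.4, 0.4), c(a2 = 0.0, c2 = 0.4, e2 = 0.6))
  # no truncation: negative components returned as-is
  expect_lt(falconer_estimates(0.2, 0.3)[["a2"]], 0)
  expect_error(falconer_estimates(1.2, 0.5), "\\[-1, 1\\]")
})

test_that("univariate ML on exact population moments matches Falconer", {
  a2 <- 0.5; c2 <- 0.2
  r_mz <- a2 + c2; r_dz <- 0.5 * a2 + c2
  smz <- matrix(c(1, r_mz, r_mz, 1), 2)
  sdz <- matrix(c(1, r_dz, r_dz, 1), 2)
  pd <- population_pair_data(c(0, 0), smz, sdz, 1000, 1000)
  fit <- fit_bivariate_ace(pd, "ACE")
  oracle <- falconer_estimates(r_mz, r_dz)
  expect_lt(abs(fit$a2 - oracle[["a2"]]), 1e-4)
  expect_lt(abs(fit$c2 - oracle[["c2"]]), 1e-4)
  expect_lt(abs(fit$e2 - oracle[["e2"]]), 1e-4)
})

test_that("bivariate ML on exact population moments recovers the generating structure", {
  truth <- list(a2 = c(0.6, 0.5), c2 = c(0.2, 0.1), e2 = c(0.2, 0.4),
                rA = 0.5, rC = 0.3, rE = 0.2)
  S <- oracle_sigma(truth$a2, truth$c2, truth$e2, truth$rA, truth$rC, truth$rE)
  pd <- population_pair_data(rep(0, 4), S$mz, S$dz, 3000, 3000)
  fit <- fit_bivariate_ace(pd, "ACE")
  expect_equal(fit$a2, truth$a2, tolerance = 1e-3)
  expect_equal(fit$c2, truth$c2, tolerance = 1e-3)
  expect_equal(fit$rA, truth$rA, tolerance = 1e-3)
  expect_equal(fit$rE, truth$rE, tolerance = 1e-3)
})

test_that("cholesky and correlated-factors parameterizations are equivalent", {
  set.seed(71)
  lat <- simulate_latent_pairs(800, 800, a2 = c(0.6, 0.5), c2 = c(0, 0),
                               e2 = c(0.4, 0.5), rA = 0.5, rE = 0.2)
  lat$mz[matrix(runif(length(lat$mz)) < 0.1, nrow(lat$mz))] <- NA
  lat$dz[matrix(runif(length(lat$dz)) < 0.1, nrow(lat$dz))] <- NA
  d <- pair_data(lat$mz, lat$dz)
  for (model in c("ACE", "AE", "E")) {
    f1 <- suppressWarnings(fit_bivariate_ace(d, model, "cholesky"))
    f2 <- suppressWarnings(fit_bivariate_ace(d, model, "correlated"))
    expect_lt(abs(f1$neg2ll - f2$neg2ll), 1e-6)
    expect_equal(f1$n_free_params, f2$n_free_params)
  }
})

test_that("the nesting chain holds: saturated <= ACE <= AE <= E", {
  set.seed(72)
  lat <- simulate_latent_pairs(600, 600, a2 = c(0.5, 0.5), c2 = c(0.1, 0.1),
                               e2 = c(0.4, 0.4), rA = 0.4, rC = 0.2, rE = 0.1)
  d <- pair_data(lat$mz, lat$dz)
  sat <- fit_saturated(d, "none")
  ace <- fit_bivariate_ace(d, "ACE")
  ae <- fit_bivariate_ace(d, "AE")
  e <- fit_bivariate_ace(d, "E")
  expect_lte(sat$neg2ll, ace$neg2ll + 1e-6)
  expect_lte(ace$neg2ll, ae$neg2ll + 1e-6)
  expect_lte(ae$neg2ll, e$neg2ll + 1e-6)
  # LRT degrees of freedom along the chain
  expect_equal(lrt_compare(sat, ace)$delta_df, 17)
  expect_equal(lrt_compare(ace, ae)$delta_df, 3)
  expect_equal(lrt_compare(ace, e)$delta_df, 6)
})

test_that("E-only data drive fitted familial components to zero", {
  set.seed(73)
  lat <- simulate_latent_pairs(4000, 4000, a2 = c(0, 0), c2 = c(0, 0),
                               e2 = c(1, 1), rE = 0.3)
  fit <- fit_bivariate_ace(pair_data(lat$mz, lat$dz), "ACE")
  expect_lt(max(fit$a2), 0.05)
  expect_lt(max(fit$c2), 0.05)
})

test_that("twin-order permutation leaves the ACE fit unchanged", {
  set.seed(74)
  lat <- simulate_latent_pairs(300, 300, a2 = c(0.6, 0.5), c2 = c(0, 0),
                               e2 = c(0.4, 0.5), rA = 0.5, rE = 0.2)
  d1 <- pair_data(lat$mz, lat$dz)
  perm <- function(m) m[, c(3, 4, 1, 2)]
  d2 <- pair_data(perm(lat$mz), perm(lat$dz))
  f1 <- fit_bivariate_ace(d1, "AE")
  f2 <- fit_bivariate_ace(d2, "AE")
  expect_lt(abs(f1$neg2ll - f2$neg2ll), 1e-6)
})

test_that("lrt_compare follows the chi-square reference distribution", {
  f <- structure(list(neg2ll = 100, n_free_params = 11), class = "ace_fit")
  n1 <- structure(list(neg2ll = 103.84, n_free_params = 10), class = "ace_fit")
  same <- structure(list(neg2ll = 100, n_free_params = 11), class = "ace_fit")
  out <- lrt_compare(f, n1)
  expect_lt(abs(out$p_value - 0.05), 1e-3)
  expect_equal(out$delta_df, 1)
  ident <- lrt_compare(f, same)
  expect_equal(ident$delta_neg2ll, 0)
  expect_equal(ident$p_value, 1)
  expect_identical(ident$preferred, "nested")
  worse <- structure(list(neg2ll = 99, n_free_params = 10), class = "ace_fit")
  expect_error(lrt_compare(f, worse), "optimizer failure")
})

test_that("rPh decomposition satisfies its algebraic identities", {
  set.seed(75)
  lat <- simulate_latent_pairs(1000, 1000, a2 = c(0.6, 0.5), c2 = c(0, 0),
                               e2 = c(0.4, 0.5), rA = 0.5, rE = 0.2)
  fit <- fit_bivariate_ace(pair_data(lat$mz, lat$dz), "AE")
  dec <- decompose_rph(fit)
  # contribution identity: h1 h2 rA + c1 c2 rC + e1 e2 rE = rPh
  contr <- sqrt(fit$a2[1] * fit$a2[2]) * fit$rA +
    sqrt(fit$e2[1] * fit$e2[2]) * fit$rE
  expect_lt(abs(contr - dec$rPh_model), 1e-8)
  expect_lt(abs(dec$share_A + dec$share_C + dec$share_E - 1), 1e-8)
  expect_equal(dec$rPh_model, fit$rPh, tolerance = 1e-12)

  # c2 = 0 and rE = 0: the association is entirely genetic
  S <- oracle_sigma(c(0.5, 0.5), c(0, 0), c(0.5, 0.5), 0.4, 0, 0)
  pd <- population_pair_data(rep(0, 4), S$mz, S$dz, 2000, 2000)
  f2 <- fit_bivariate_ace(pd, "AE")
  d2 <- decompose_rph(f2)
  expect_equal(d2$share_A, 1, tolerance = 1e-4)

  # degenerate rPh = 0
  S0 <- oracle_sigma(c(0.5, 0.5), c(0, 0), c(0.5, 0.5), 0, 0, 0)
  pd0 <- population_pair_data(rep(0, 4), S0$mz, S0$dz, 2000, 2000)
  f0 <- fit_bivariate_ace(pd0, "AE")
  expect_error(decompose_rph(f0), "undefined")
})

test_that("standardized components always sum to one per trait", {
  set.seed(76)
  lat <- simulate_latent_pairs(500, 500, a2 = c(0.3, 0.7), c2 = c(0.3, 0.1),
                               e2 = c(0.4, 0.2), rA = 0.3, rC = 0.5, rE = 0.1)
  for (model in c("ACE", "AE", "CE", "E")) {
    f <- suppressWarnings(fit_bivariate_ace(pair_data(lat$mz, lat$dz), model))
    expect_lt(max(abs(f$a2 + f$c2 + f$e2 - 1)), 1e-8)
    expect_true(all(f$a2 >= 0 & f$c2 >= 0 & f$e2 >= 0))
  }
})
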