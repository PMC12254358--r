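make_biv_data <- function(n_mz = 800, n_dz = 800, seed = 1, miss = 0) {
  set.seed(seed)
  lat <- simulate_latent_pairs(n_mz, n_dz, a2 = c(0.6, 0.5), c2 = c(0.1, 0.1),
                               e2 = c(0.3, 0.4), rA = 0.5, rC = 0.2, rE = 0.2)
  if (miss > 0) {
    lat$mz[matrix(runif(length(lat$mz)) < miss, nrow(lat$mz))] <- NA
    lat$dz[matrix(runif(length(lat$dz)) < miss, nrow(lat$dz))] <- NA
  }
  pair_data(lat$mz, lat$dz)
}

test_that("unconstrained saturated ML equals sample moments on complete data", {
  d <- make_biv_data(200, 200, seed = 3)
  fit <- fit_saturated(d, "none")
  # reconstruct raw data moments from the single complete pattern
  st <- d$groups$MZ[[1]]
  expect_equal(fit$groups$MZ$mu, st$xbar, tolerance = 1e-6)
  expect_equal(fit$groups$MZ$Sigma, st$S, tolerance = 1e-6)
  expect_equal(fit$n_free_params, 28)
})

test_that("constraint levels are nested and ordered in -2LL", {
  d <- make_biv_data(400, 400, seed = 4, miss = 0.1)
  s0 <- fit_saturated(d, "none")
  s1 <- fit_saturated(d, "twin_order")
  s2 <- fit_saturated(d, "zygosity")
  expect_lte(s0$neg2ll, s1$neg2ll + 1e-6)
  expect_lte(s1$neg2ll, s2$neg2ll + 1e-6)
  expect_equal(s1$n_free_params, 16)
  expect_equal(s2$n_free_params, 11)
  lrt <- lrt_compare(s0, s1)
  expect_gte(lrt$delta_neg2ll, -1e-6)
  expect_equal(lrt$delta_df, 12)
})

test_that("constrained fits respect twin-order exchangeability", {
  d <- make_biv_data(300, 300, seed = 5)
  set.seed(5)
  lat <- simulate_latent_pairs(300, 300, a2 = c(0.6, 0.5), c2 = c(0.1, 0.1),
                               e2 = c(0.3, 0.4), rA = 0.5, rC = 0.2, rE = 0.2)
  perm <- function(m) m[, c(3, 4, 1, 2)]
  d_perm <- pair_data(perm(lat$mz), perm(lat$dz))
  f1 <- fit_saturated(d, "zygosity")
  f2 <- fit_saturated(d_perm, "zygosity")
  expect_lt(abs(f1$neg2ll - f2$neg2ll), 1e-6)
})

test_that("twin-order constraints are calibrated on exchangeable data", {
  reps <- 150
  ps <- vapply(seq_len(reps), function(i) {
    set.seed(1000 + i)
    lat <- simulate_latent_pairs(200, 200, a2 = 0.5, c2 = 0.2, e2 = 0.3)
    d <- pair_data(lat$mz, lat$dz)
    s0 <- suppressWarnings(fit_saturated(d, "none"))
    s1 <- suppressWarnings(fit_saturated(d, "twin_order"))
    lrt_compare(s0, s1)$p_value
  }, 0)
  # ~95% of replicates should not reject the (true) equality constraints
  expect_gt(mean(ps > 0.05), 0.90)
  expect_lt(mean(ps > 0.05), 0.995)
})

test_that("CTCT and twin correlations match closed forms on population moments", {
  # AE process, h1^2 = h2^2 = 0.5, rA = 0.4: CTCT_MZ = 0.20, CTCT_DZ = 0.10
  S <- oracle_sigma(c(0.5, 0.5), c(0, 0), c(0.5, 0.5), 0.4, 0, 0)
  pd <- population_pair_data(rep(0, 4), S$mz, S$dz, 2000, 2000)
  fit <- fit_saturated(pd, "zygosity")
  cors <- extract_correlations(fit, cis = FALSE)
  get <- function(q) cors$estimate[cors$quantity == q]
  expect_equal(get("ctct_mz"), 0.20, tolerance = 1e-3)
  expect_equal(get("ctct_dz"), 0.10, tolerance = 1e-3)
  expect_equal(get("r_mz_1"), 0.5, tolerance = 1e-3)
  expect_equal(get("r_dz_1"), 0.25, tolerance = 1e-3)
  expect_equal(get("rph"), 0.20, tolerance = 1e-3)
  expect_error(extract_correlations(fit_saturated(pd, "none")),
               "zygosity-constrained")
})

test_that("no cross-trait linkage yields near-zero CTCT", {
  set.seed(8)
  lat <- simulate_latent_pairs(5000, 5000, a2 = c(0.5, 0.5), c2 = c(0, 0),
                               e2 = c(0.5, 0.5), rA = 0, rC = 0, rE = 0)
  fit <- fit_saturated(pair_data(lat$mz, lat$dz), "zygosity")
  cors <- extract_correlations(fit, cis = FALSE)
  expect_lt(max(abs(cors$estimate[cors$quantity %in%
                                    c("ctct_mz", "ctct_dz")])), 0.03)
})
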