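test_that("invalid configurations are rejected", {
  expect_error(trait_spec("x", 0.5, 0.2, 0.2), "sum to 1")
  expect_error(trait_spec("x", -0.1, 0.4, 0.7), "non-negative")
  expect_error(trait_spec("bad_name", 0.5, 0, 0.5), "underscores")
  expect_error(trait_spec("x", 0.5, 0, 0.5, item_missing_rate = 1.2), "rates")
  tr <- list(trait_spec("a", 0.5, 0, 0.5), trait_spec("b", 0.5, 0, 0.5),
             trait_spec("c", 0.5, 0, 0.5))
  # a non-PSD user-supplied factor correlation matrix is rejected
  R <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_error(simulation_config(tr, rA = R), "positive semi-definite")
  expect_error(simulation_config(tr[1:2], rA = 1.5), "\\[-1, 1\\]")
  expect_error(simulation_config(tr[1:2], frac_undetermined = 2),
               "frac_undetermined")
})

test_that("latent twin moments match the classical twin-model closed forms", {
  set.seed(101)
  # no familial variance: co-twin correlation ~ 0
  lat <- simulate_latent_pairs(5000, 5000, a2 = c(0, 0), c2 = c(0, 0),
                               e2 = c(1, 1))
  expect_lt(abs(cor(lat$mz[, 1], lat$mz[, 3])), 0.05)
  expect_lt(abs(cor(lat$dz[, 1], lat$dz[, 3])), 0.05)

  # r_MZ = a2 + c2, r_DZ = 0.5 a2 + c2
  lat <- simulate_latent_pairs(5000, 5000, a2 = c(0.6, 0.6), c2 = c(0.2, 0.2),
                               e2 = c(0.2, 0.2))
  expect_equal(cor(lat$mz[, 1], lat$mz[, 3]), 0.8, tolerance = 0.04 / 0.8)
  expect_equal(cor(lat$dz[, 1], lat$dz[, 3]), 0.5, tolerance = 0.04 / 0.5)

  # CTCT_MZ = h1 h2 rA, CTCT_DZ = 0.5 h1 h2 rA; here 0.20 and 0.10
  lat <- simulate_latent_pairs(5000, 5000, a2 = c(0.5, 0.5), c2 = c(0, 0),
                               e2 = c(0.5, 0.5), rA = 0.4)
  expect_lt(abs(cor(lat$mz[, 1], lat$mz[, 4]) - 0.20), 0.04)
  expect_lt(abs(cor(lat$dz[, 1], lat$dz[, 4]) - 0.10), 0.04)

  # within-person cross-trait correlation = h1h2 rA + c1c2 rC + e1e2 rE
  lat <- simulate_latent_pairs(5000, 0, a2 = c(0.6, 0.4), c2 = c(0.2, 0.2),
                               e2 = c(0.2, 0.4), rA = 0.5, rC = 0.3, rE = 0.2)
  expected <- sqrt(0.6 * 0.4) * 0.5 + sqrt(0.2 * 0.2) * 0.3 +
    sqrt(0.2 * 0.4) * 0.2
  expect_lt(abs(cor(lat$mz[, 1], lat$mz[, 2]) - expected), 0.04)
})

test_that("datasets are deterministic given seed and config", {
  cfg <- two_trait_config(30, 30, frac_undetermined = 0.1,
                          sex_effect = c(0.2, 0), seed = 99L)
  c1 <- generate_twin_dataset(cfg)
  c2 <- generate_twin_dataset(cfg)
  expect_identical(c1$pairs, c2$pairs)
  expect_identical(c1$latent, c2$latent)
  c3 <- generate_twin_dataset(two_trait_config(30, 30,
                                               frac_undetermined = 0.1,
                                               sex_effect = c(0.2, 0),
                                               seed = 100L))
  expect_false(identical(c1$pairs, c3$pairs))
})

test_that("pair demographics respect zygosity", {
  cfg <- two_trait_config(200, 200, seed = 5L)
  cfg$n_dz_os <- 200L
  co <- generate_twin_dataset(cfg)
  p <- co$pairs
  expect_true(all(p$sex_1[p$zygosity %in% c("MZ", "DZ_ss")] ==
                    p$sex_2[p$zygosity %in% c("MZ", "DZ_ss")]))
  expect_true(all(p$sex_1[p$zygosity == "DZ_os"] !=
                    p$sex_2[p$zygosity == "DZ_os"]))
})

test_that("single noiseless item preserves latent ordering", {
  sp <- trait_spec("x", 0.5, 0, 0.5, n_items = 1L, n_response_levels = 6L,
                   item_noise_sd = 0)
  lat <- seq(-3, 3, length.out = 200)
  items <- generate_item_responses(lat, sp, seed = 1)
  expect_true(all(diff(items[, 1]) >= 0))
})

test_that("item noise calibration hits the target alpha", {
  set.seed(7)
  lat <- rnorm(5000)
  sp <- trait_spec("x", 0.5, 0, 0.5, n_items = 12L, target_alpha = 0.8)
  items <- generate_item_responses(lat, sp, seed = 11)
  expect_lt(abs(cronbach_alpha(items)$alpha - 0.8), 0.05)
  # and under the skew-inducing thresholds
  sps <- trait_spec("x", 0.5, 0, 0.5, n_items = 8L, n_response_levels = 3L,
                    skew_transform = "exponentiate", target_alpha = 0.8)
  items_s <- generate_item_responses(lat, sps, seed = 12)
  expect_lt(abs(cronbach_alpha(items_s)$alpha - 0.8), 0.05)
})

test_that("missing and don't-know codes are inserted at the configured rates", {
  sp <- trait_spec("x", 0.5, 0, 0.5, n_items = 20L, item_missing_rate = 0.10,
                   dontknow_rate = 0.05)
  items <- generate_item_responses(rnorm(5000), sp, seed = 3)  # 1e5 slots
  expect_lt(abs(mean(is.na(items)) - 0.10), 0.01)
  # DK drawn at 0.05 among slots not already missing
  expect_lt(abs(mean(items == -1, na.rm = TRUE) - 0.05), 0.01)
})

test_that("skew transform induces positive skew in the scale score", {
  set.seed(21)
  lat <- rnorm(4000)
  sp_sym <- trait_spec("x", 0.5, 0, 0.5, n_items = 12L, target_alpha = 0.8)
  sp_skw <- trait_spec("x", 0.5, 0, 0.5, n_items = 12L, target_alpha = 0.8,
                       skew_transform = "exponentiate")
  s_sym <- score_scale(generate_item_responses(lat, sp_sym, seed = 1))
  s_skw <- score_scale(generate_item_responses(lat, sp_skw, seed = 1))
  expect_lt(abs(skewness(s_sym)), 0.5)
  expect_gt(skewness(s_skw), 1)
})
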