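# Hand-built 10-pair fixture for the inclusion filters:
#   pairs 1, 2: one twin fails the synaesthesia screen (2 DK / 2 missing)
#   pair 3:     singleton (twin 2 absent)
#   pair 4:     undetermined zygosity, complete data
#   pairs 5-10: clean
# -> 6 pairs survive; per-individual tally: screen 2, incomplete-pair 3
#    (2 co-twins + the singleton's present twin), undetermined 2.
filter_fixture <- function() {
  n <- 10
  df <- data.frame(
    pair_id = 1:10,
    zygosity = c("MZ", "DZ_ss", "MZ", "undetermined", "MZ", "MZ",
                 "DZ_ss", "DZ_os", "DZ_os", "MZ"),
    sex_1 = c("F", "M", "F", "F", "M", "F", "F", "F", "M", "M"),
    sex_2 = c("F", "M", NA, "F", "M", "F", "F", "M", "F", "M"),
    birth_year = rep(2000:2001, 5),
    stringsAsFactors = FALSE)
  for (tw in 1:2) {
    items <- matrix(0L, n, 8)
    if (tw == 1) items[1, 1:2] <- -1L           # pair 1 twin 1: 2 DK
    if (tw == 2) items[2, 1:2] <- NA_integer_   # pair 2 twin 2: 2 missing
    if (tw == 2) items[3, ] <- NA_integer_      # singleton
    items[5, ] <- rep(c(1L, 2L), 4)             # some scores to vary
    colnames(items) <- sprintf("synaesthesia_%d_%d", 1:8, tw)
    df <- cbind(df, as.data.frame(items))
  }
  for (tw in 1:2) {
    items <- matrix(1L, n, 3)
    if (tw == 2) items[3, ] <- NA_integer_
    items[6, ] <- c(0L, 2L, 3L)
    colnames(items) <- sprintf("oc_%d_%d", 1:3, tw)
    df <- cbind(df, as.data.frame(items))
  }
  df
}

# Two-trait simulation config for engine tests.
two_trait_config <- function(n_mz, n_dz_ss, a2 = c(0.6, 0.5),
                             c2 = c(0, 0), rA = 0.5, rC = 0, rE = 0.2,
                             seed = 1L, ...) {
  traits <- list(
    trait_spec("syn", a2[1], c2[1], 1 - a2[1] - c2[1], n_items = 4L,
               target_alpha = 0.85),
    trait_spec("feat", a2[2], c2[2], 1 - a2[2] - c2[2], n_items = 4L,
               target_alpha = 0.85))
  simulation_config(traits, n_mz = n_mz, n_dz_ss = n_dz_ss, n_dz_os = 0L,
                    rA = rA, rC = rC, rE = rE, seed = seed, ...)
}

# Model-implied 4x4 covariances for a bivariate ACE process on the
# standardized scale (independent construction used as test oracle).
oracle_sigma <- function(a2, c2, e2, rA, rC, rE) {
  blk <- function(p, r) {
    s <- sqrt(p)
    m <- outer(s, s)
    m[1, 2] <- m[1, 2] * r
    m[2, 1] <- m[2, 1] * r
    m
  }
  A <- blk(a2, rA); C <- blk(c2, rC); E <- blk(e2, rE)
  W <- A + C + E
  list(mz = rbind(cbind(W, A + C), cbind(A + C, W)),
       dz = rbind(cbind(W, 0.5 * A + C), cbind(0.5 * A + C, W)))
}
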