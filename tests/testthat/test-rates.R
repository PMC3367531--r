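test_that("committor flips on energy ordering with ties committed to neither", {
  M <- default_interaction_matrix()
  lo <- ss_structure("lo", 8L, NULL, n_hbonds = 5L)   # E = -5 always
  hi <- ss_structure("hi", 8L, NULL, n_hbonds = 2L)   # E = -2 always
  expect_equal(unname(committor("AAAAAAAA", hi, lo, M)), c(1L, 0L))
  expect_equal(unname(committor("AAAAAAAA", lo, hi, M)), c(0L, 1L))
  expect_equal(unname(committor("AAAAAAAA", lo, lo, M)), c(0L, 0L))

  pair <- toy_structure_pair()
  set.seed(5)
  for (rep in 1:10) {
    s <- paste(sample(AA_ALPHABET, 8, replace = TRUE), collapse = "")
    lam <- committor(s, pair$A, pair$B, M)
    eA <- total_energy(s, pair$A, M); eB <- total_energy(s, pair$B, M)
    expect_equal(unname(lam), c(as.integer(eB < eA), as.integer(eA < eB)))
  }
})

test_that("joint acceptance is the symmetric biased-ensemble Metropolis rule", {
  cfg <- rate_config(T = 1, E_R = 0)
  expect_equal(joint_acceptance(-1, 0.5, 0, cfg), 1)
  expect_equal(joint_acceptance(0.5, -1, 0, cfg), 1)
  expect_equal(joint_acceptance(2, 1, 0, cfg), joint_acceptance(1, 2, 0, cfg))
  cfg2 <- rate_config(T = 2, E_R = 0)
  expect_equal(joint_acceptance(1, 1, 0, cfg2), exp(-1))
  cfg3 <- rate_config(T = 1, E_R = 2)
  expect_equal(joint_acceptance(1, 1, 1, cfg3), 1)
  expect_error(rate_config(T = 0), "positive")
})

test_that("joint sampling of an identical pair yields only ties", {
  A <- toy_structure_pair()$A
  cfg <- rate_config(n_samples = 500L, rng_seed = 3L)
  sam <- sample_joint(A, A, cfg = cfg, alphabet = c("A", "G"))
  expect_true(all(sam$committed_AB == 0L))
  expect_true(all(sam$committed_BA == 0L))
  expect_equal(sam$E_A, sam$E_B)
  est <- estimate_rate_constants(sam, cfg)
  expect_equal(est$k_AB, 0)
  expect_equal(est$k_BA, 0)
})

test_that("committor fractions partition the joint samples", {
  pair <- toy_structure_pair()
  cfg <- rate_config(n_samples = 2000L, rng_seed = 4L)
  sam <- sample_joint(pair$A, pair$B, cfg = cfg)
  tied <- 1L - sam$committed_AB - sam$committed_BA
  expect_true(all(tied %in% c(0L, 1L)))
  expect_equal(mean(sam$committed_AB) + mean(sam$committed_BA) + mean(tied), 1)
})

test_that("a dominated pair gives rate constants exactly 0 and 1", {
  fx <- make_fixtures(1L)
  cfg <- rate_config(n_samples = 2000L, rng_seed = 5L)
  # B is 3 hydrogen bonds lower for every sequence
  sam <- sample_joint(fx$dominated$A, fx$dominated$B, cfg = cfg,
                      alphabet = c("A", "G"))
  est <- estimate_rate_constants(sam, cfg)
  expect_equal(est$k_AB, 1)
  expect_equal(est$k_BA, 0)
  orc <- exact_rate_oracle(fx$dominated$A, fx$dominated$B, cfg = cfg,
                           alphabet = c("A", "G"))
  expect_equal(orc$k_AB, 1)
  expect_equal(orc$k_BA, 0)
})

test_that("Monte Carlo estimates agree with the exhaustive oracle", {
  pair <- toy_structure_pair()
  for (alphabet in list(c("A", "G"), c("I", "N"))) {
    cfg <- rate_config(T = 0.5, E_R = 1, n_samples = 20000L, rng_seed = 11L)
    orc <- exact_rate_oracle(pair$A, pair$B, cfg = cfg, alphabet = alphabet)
    est <- estimate_rate_constants(
      sample_joint(pair$A, pair$B, cfg = cfg, alphabet = alphabet), cfg)
    expect_lt(abs(est$k_AB - orc$k_AB), 3 * max(est$se_AB, 1e-3))
    expect_lt(abs(est$k_BA - orc$k_BA), 3 * max(est$se_BA, 1e-3))
    expect_true(all(c(orc$k_AB, orc$k_BA) >= 0 & c(orc$k_AB, orc$k_BA) <= 1))
  }
  expect_error(
    exact_rate_oracle(ss_structure("big", 40L, NULL),
                      ss_structure("big2", 40L, NULL),
                      alphabet = c("A", "C", "D")),
    "too large")
})

test_that("relabelling the pair swaps the estimated rate constants", {
  pair <- toy_structure_pair()
  cfg <- rate_config(T = 0.5, E_R = 1, n_samples = 20000L, rng_seed = 12L)
  fwd <- estimate_rate_constants(
    sample_joint(pair$A, pair$B, cfg = cfg, alphabet = c("A", "G")), cfg)
  cfg2 <- rate_config(T = 0.5, E_R = 1, n_samples = 20000L, rng_seed = 13L)
  rev <- estimate_rate_constants(
    sample_joint(pair$B, pair$A, cfg = cfg2, alphabet = c("A", "G")), cfg2)
  expect_lt(abs(fwd$k_AB - rev$k_BA), 3 * (fwd$se_AB + rev$se_BA + 1e-3))
  expect_lt(abs(fwd$k_BA - rev$k_AB), 3 * (fwd$se_BA + rev$se_AB + 1e-3))
})

test_that("Monte Carlo estimates converge to the oracle with sample size", {
  pair <- toy_structure_pair()
  orc <- exact_rate_oracle(pair$A, pair$B,
                           cfg = rate_config(T = 0.5, E_R = 1),
                           alphabet = c("A", "G"))
  errs <- vapply(c(1000L, 10000L, 100000L), function(n) {
    cfg <- rate_config(T = 0.5, E_R = 1, n_samples = n, rng_seed = 21L)
    est <- estimate_rate_constants(
      sample_joint(pair$A, pair$B, cfg = cfg, alphabet = c("A", "G")), cfg)
    abs(est$k_AB - orc$k_AB)
  }, numeric(1))
  expect_lt(errs[3], 0.01)
  expect_lt(errs[3], errs[1] + 0.005)
})

test_that("mirror-image structures have equal rates within error", {
  fx <- make_fixtures(1L)
  cfg <- rate_config(n_samples = 20000L, rng_seed = 6L)
  sam <- sample_joint(fx$symmetric$A, fx$symmetric$B, cfg = cfg,
                      alphabet = c("A", "G"))
  est <- estimate_rate_constants(sam, cfg)
  expect_lt(abs(est$k_AB - est$k_BA), 3 * (est$se_AB + est$se_BA + 1e-3))
})

test_that("relative probabilities rescale along the pair graph", {
  pairs <- data.frame(A = c("s1", "s2"), B = c("s2", "s3"),
                      k_AB = c(0.2, 0.4), k_BA = c(0.2, 0.2))
  rp <- relative_probabilities(pairs, "s1")
  expect_equal(unname(rp$P["s1"]), 1)
  expect_equal(unname(rp$P["s2"]), 1)
  expect_equal(unname(rp$P["s3"]), 2)
  expect_length(rp$cycle_residuals, 0)

  # a consistent cycle has zero residual
  pairs3 <- rbind(pairs, data.frame(A = "s1", B = "s3", k_AB = 0.4, k_BA = 0.2))
  rp3 <- relative_probabilities(pairs3, "s1")
  expect_equal(unname(rp3$cycle_residuals), 0, tolerance = 1e-12)

  # rates generated exactly from the fitted family have all-zero residuals
  fx <- make_fixtures(2L)
  st <- fx$network6$structures; par <- fx$network6$params
  combos <- t(combn(6L, 2L))
  fam <- do.call(rbind, lapply(seq_len(nrow(combos)), function(r) {
    A <- st[[combos[r, 1]]]; B <- st[[combos[r, 2]]]
    data.frame(A = A$id, B = B$id,
               k_AB = rate_surface(par, B$e_hb - A$e_hb,
                                   B$n_contacts - A$n_contacts),
               k_BA = rate_surface(par, A$e_hb - B$e_hb,
                                   A$n_contacts - B$n_contacts))
  }))
  rpf <- relative_probabilities(fam, st[[1]]$id)
  expect_lt(max(abs(rpf$cycle_residuals)), 1e-12)

  # disconnected graph is rejected with the components listed
  disc <- data.frame(A = c("a", "c"), B = c("b", "d"),
                     k_AB = c(1, 1), k_BA = c(1, 1))
  expect_error(relative_probabilities(disc, "a"), "disconnected")
  expect_error(relative_probabilities(pairs, "zz"), "reference")
  expect_error(
    relative_probabilities(
      data.frame(A = "a", B = "b", k_AB = 0, k_BA = 1), "a"),
    "zero")
})

test_that("low effective sample size raises the degeneracy flag", {
  fx <- make_fixtures(1L)
  cfg <- rate_config(n_samples = 200L, rng_seed = 9L)
  sam <- sample_joint(fx$dominated$A, fx$dominated$B, cfg = cfg,
                      alphabet = c("A", "G"))
  est <- estimate_rate_constants(sam, cfg, ess_threshold = 1e9)
  expect_true(est$low_ess)
})
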