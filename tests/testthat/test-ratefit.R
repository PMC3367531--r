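make_family_obs <- function(params, n_pairs = 24L, seed = 1L,
                            noise_sd = 0, q = NULL) {
  set.seed(seed)
  dE <- round(runif(n_pairs, -6, 6))
  dN <- round(runif(n_pairs, -20, 20))
  if (is.null(q)) q <- runif(n_pairs, 0.3, 0.95)
  k_AB <- rate_surface(params, dE, dN, q) * exp(rnorm(n_pairs, 0, noise_sd))
  k_BA <- rate_surface(params, -dE, -dN, q) * exp(rnorm(n_pairs, 0, noise_sd))
  data.frame(A = paste0("a", seq_len(n_pairs)), B = paste0("b", seq_len(n_pairs)),
             dE_HB = dE, dN_c = dN, q = q, k_AB = k_AB, k_BA = k_BA)
}

test_that("the midpoint-0 family satisfies the detailed-balance identity exactly", {
  set.seed(7)
  for (rep in 1:20) {
    par <- rate_surface_params(log_k_max = rnorm(1), alpha_HB = runif(1, 0.2, 3),
                               alpha_c = runif(1, 0.05, 1),
                               alpha_q = runif(1, 0, 30), q_mid = runif(1))
    dE <- runif(1, -8, 8); dN <- runif(1, -30, 30); q <- runif(1)
    lhs <- rate_surface(par, dE, dN, q, log = TRUE) -
      rate_surface(par, -dE, -dN, q, log = TRUE)
    expect_equal(lhs, -par$alpha_HB * dE + par$alpha_c * dN, tolerance = 1e-12)
  }
})

test_that("the rate surface is monotone and step-like in both descriptors", {
  par <- rate_surface_params(log_k_max = 0, alpha_HB = 1, alpha_c = 0.3)
  dE <- seq(-10, 10, by = 0.5)
  expect_true(all(diff(rate_surface(par, dE, 0)) < 0))   # fewer H-bonds: slower
  dN <- seq(-40, 40, by = 1)
  expect_true(all(diff(rate_surface(par, 0, dN)) > 0))   # more compact: faster
  # plateau: deep on the favourable side ln k is flat
  fav <- rate_surface(par, c(-10, -12, -16), c(35, 40, 50), log = TRUE)
  rng_all <- diff(range(rate_surface(par, c(-16, 16), c(-50, 50), log = TRUE)))
  expect_lt(diff(range(fav)), 0.05 * rng_all)
})

test_that("G(1) = 1 and the common-contact factor cancels in every ratio", {
  par <- rate_surface_params(alpha_q = 12, q_mid = 0.4)
  expect_equal(rate_surface(par, 2, 5, q = 1) /
                 rate_surface(rate_surface_params(), 2, 5, q = 1) *
                 exp(rate_surface_params()$log_k_max - par$log_k_max), 1)
  for (q in c(0.2, 0.5, 0.9)) {
    ratio <- rate_surface(par, 3, -7, q) / rate_surface(par, -3, 7, q)
    expect_equal(log(ratio), -par$alpha_HB * 3 + par$alpha_c * (-7),
                 tolerance = 1e-12)
  }
})

test_that("plane fit of family-generated log-ratios is exact", {
  par <- rate_surface_params(log_k_max = -0.3, alpha_HB = 1.4, alpha_c = 0.25,
                             alpha_q = 8, q_mid = 0.5)
  obs <- make_family_obs(par, seed = 3L)
  pl <- suppressWarnings(plane_fit_log_ratio(obs))
  expect_equal(pl$c_HB, -par$alpha_HB, tolerance = 1e-10)
  expect_equal(pl$c_c, par$alpha_c, tolerance = 1e-10)
  expect_equal(pl$r_squared, 1, tolerance = 1e-12)
  # flipping the ratio orientation negates both coefficients; a full A/B
  # relabel (flipping descriptors as well) leaves them invariant
  flip <- obs
  flip$k_AB <- obs$k_BA; flip$k_BA <- obs$k_AB
  pl_flip <- suppressWarnings(plane_fit_log_ratio(flip))
  expect_equal(pl_flip$c_HB, -pl$c_HB, tolerance = 1e-10)
  expect_equal(pl_flip$c_c, -pl$c_c, tolerance = 1e-10)
  relabel <- flip
  relabel$dE_HB <- -obs$dE_HB; relabel$dN_c <- -obs$dN_c
  pl_rel <- suppressWarnings(plane_fit_log_ratio(relabel))
  expect_equal(pl_rel$c_HB, pl$c_HB, tolerance = 1e-10)
  expect_equal(pl_rel$c_c, pl$c_c, tolerance = 1e-10)
})

test_that("surface fitting recovers generating parameters on noiseless data", {
  par <- rate_surface_params(log_k_max = -0.5, alpha_HB = 1.2, alpha_c = 0.3)
  obs <- make_family_obs(par, seed = 5L, q = rep(1, 24L))
  for (method in c("balance", "joint")) {
    fit <- suppressWarnings(fit_rate_surface(obs, method = method))
    expect_equal(fit$params$alpha_HB, par$alpha_HB, tolerance = 0.01)
    expect_equal(fit$params$alpha_c, par$alpha_c, tolerance = 0.01)
    expect_equal(fit$params$log_k_max, par$log_k_max, tolerance = 0.01)
  }
})

test_that("noisy synthetic data recover the alphas within two standard errors", {
  par <- rate_surface_params(log_k_max = -0.2, alpha_HB = 1.1, alpha_c = 0.35)
  ok <- 0L
  for (seed in 1:5) {
    obs <- make_family_obs(par, n_pairs = 40L, seed = seed, noise_sd = 0.1,
                           q = rep(1, 40L))
    fit <- fit_rate_surface(obs)
    ok <- ok + as.integer(
      abs(fit$params$alpha_HB - par$alpha_HB) <= 2 * fit$se[["ahb"]] &&
      abs(fit$params$alpha_c - par$alpha_c) <= 2 * fit$se[["ac"]])
  }
  expect_gte(ok, 4L)  # 2 SE covers ~95% per axis
})

test_that("the common-contact factor is recovered from family data", {
  par <- rate_surface_params(log_k_max = -0.4, alpha_HB = 1.3, alpha_c = 0.3,
                             alpha_q = 10, q_mid = 0.5)
  obs <- make_family_obs(par, n_pairs = 40L, seed = 9L)
  base <- rate_surface_params(par$log_k_max, par$alpha_HB, par$alpha_c)
  fit <- fit_common_contact_factor(obs, base)
  expect_false(fit$fixed)
  expect_equal(fit$params$alpha_q, par$alpha_q, tolerance = 0.05)
  expect_equal(fit$params$q_mid, par$q_mid, tolerance = 0.02)
  # joint fit with the q-factor also recovers
  jf <- suppressWarnings(fit_rate_surface(obs, fit_q = TRUE, method = "joint"))
  expect_equal(jf$params$alpha_HB, par$alpha_HB, tolerance = 0.02)
  expect_equal(jf$params$alpha_q, par$alpha_q, tolerance = 0.5)

  flat <- make_family_obs(par, seed = 10L, q = rep(0.6, 24L))
  expect_warning(fit_common_contact_factor(flat, base), "insufficient")
})

test_that("fitting is invariant to a uniform rescaling of all rates", {
  par <- rate_surface_params(log_k_max = -0.5, alpha_HB = 1.2, alpha_c = 0.3)
  obs <- make_family_obs(par, seed = 6L, q = rep(1, 24L))
  sc <- obs
  sc$k_AB <- obs$k_AB * 5; sc$k_BA <- obs$k_BA * 5
  f1 <- suppressWarnings(fit_rate_surface(obs))
  f2 <- suppressWarnings(fit_rate_surface(sc))
  expect_equal(f2$params$alpha_HB, f1$params$alpha_HB, tolerance = 1e-6)
  expect_equal(f2$params$alpha_c, f1$params$alpha_c, tolerance = 1e-6)
  expect_equal(f2$params$log_k_max - f1$params$log_k_max, log(5), tolerance = 1e-6)
})

test_that("sign-deficient observations are rejected with the axis named", {
  par <- rate_surface_params()
  # both directions of every pair are stacked, so a one-signed pair table is
  # still identifiable; deficiency arises when one direction's rates vanish
  obs <- make_family_obs(par, seed = 8L)
  obs$dE_HB <- abs(obs$dE_HB)
  obs$k_BA <- 0
  expect_error(fit_rate_surface(obs), "dE_HB")
  # and when an axis has no spread at all
  obs2 <- make_family_obs(par, seed = 8L)
  obs2$dN_c <- 0L
  obs2$k_AB <- rate_surface(par, obs2$dE_HB, 0)
  obs2$k_BA <- rate_surface(par, -obs2$dE_HB, 0)
  expect_error(fit_rate_surface(obs2), "dN_c")
})

test_that("equilibrium probabilities normalize and satisfy pairwise balance", {
  fx <- make_fixtures(3L)
  st <- fx$network6$structures; par <- fx$network6$params
  p <- equilibrium_probabilities(st, par)
  expect_equal(sum(p), 1)
  for (r in 1:5) {
    A <- st[[r]]; B <- st[[r + 1L]]
    k_AB <- rate_surface(par, B$e_hb - A$e_hb, B$n_contacts - A$n_contacts)
    k_BA <- rate_surface(par, A$e_hb - B$e_hb, A$n_contacts - B$n_contacts)
    expect_equal(p[[A$id]] * k_AB, p[[B$id]] * k_BA, tolerance = 1e-12)
  }
  # identical descriptors: equal probabilities
  twins <- list(ss_structure("t1", 8L, rbind(c(0L, 4L)), n_hbonds = 2L),
                ss_structure("t2", 8L, rbind(c(1L, 5L)), n_hbonds = 2L))
  pt <- equilibrium_probabilities(twins, par)
  expect_equal(unname(pt["t1"]), unname(pt["t2"]))
})

test_that("designability grows with hydrogen bonds and compactness", {
  par <- rate_surface_params(alpha_HB = 0.8, alpha_c = 0.3)
  base <- ss_structure("base", 12L, rbind(c(0L, 4L), c(2L, 7L)), n_hbonds = 2L)
  more_hb <- ss_structure("hb", 12L, rbind(c(0L, 4L), c(2L, 7L)), n_hbonds = 4L)
  more_c <- ss_structure("nc", 12L, rbind(c(0L, 4L), c(2L, 7L), c(3L, 9L)),
                         n_hbonds = 2L)
  p <- equilibrium_probabilities(list(base, more_hb, more_c), par)
  expect_gt(p[["hb"]], p[["base"]])
  expect_gt(p[["nc"]], p[["base"]])
})

test_that("total-rate ratios are exactly 1 on family-generated data", {
  par <- rate_surface_params(log_k_max = -0.6, alpha_HB = 1.5, alpha_c = 0.2,
                             alpha_q = 6, q_mid = 0.4)
  obs <- make_family_obs(par, seed = 12L)
  expect_equal(total_rate_ratios(obs, par), rep(1, nrow(obs)), tolerance = 1e-10)
})
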