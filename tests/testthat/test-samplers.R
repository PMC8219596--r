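test_that("Wald sampler reproduces the inverse-Gaussian moments", {
  n <- 1e6
  x <- rwald(n, alpha = 2, xi = 4, seed = 21)
  expect_true(all(x > 0))
  expect_lt(abs(mean(x) - wald_mean(2, 4)), 3 * sqrt(wald_var(2, 4) / n))
  expect_lt(abs(var(x) - wald_var(2, 4)), 3 * wald_se_var(2, 4, n))
  expect_error(rwald(10, 2, 0), "Levy")
})

test_that("shifted draws respect the support and the location-family property", {
  x <- rsw(1e5, alpha = 1, theta = 0.2, xi = 8, seed = 22)
  expect_gt(min(x), 0.2)
  # same seed: a theta shift is exactly a translation of the draws
  expect_equal(rsw(100, 1, 0, 8, seed = 5) + 0.3,
               rsw(100, 1, 0.3, 8, seed = 5))
})

test_that("shifted-Wald draws match the model CDF by KS", {
  n <- 1e5
  x <- rsw(n, alpha = 1, theta = 0.13, xi = 10, seed = 23)
  Fm <- function(q) psw(q, 1, 0.13, 10)
  expect_lt(ks_distance(x, Fm), ks_crit_1pct(n))
})

test_that("truncated-normal sampler hits the closed-form moments on both branches", {
  n <- 1e6
  # rejection branch (little truncated mass)
  y <- rtnorm0(n, 8, 1, seed = 24)
  expect_true(all(y >= 0))
  expect_lt(abs(mean(y) - tn0_mean(8, 1)), 3 * sqrt(tn0_var(8, 1) / n))
  # inverse-CDF tail branch (almost all mass truncated away)
  y2 <- rtnorm0(n, -3, 1, seed = 25)
  expect_true(all(y2 >= 0))
  expect_lt(abs(mean(y2) - tn0_mean(-3, 1)), 3 * sqrt(tn0_var(-3, 1) / n))
  # far from the bound the truncation is invisible
  y3 <- rtnorm0(1e5, 8, 0.5, seed = 26)
  expect_lt(ks_distance(y3, function(q) pnorm(q, 8, 0.5)),
            ks_crit_1pct(1e5))
})

test_that("participant generation matches the marginal mixture densities", {
  n <- 1e5
  # fixed drift: marginal is the plain SW
  p <- simulate_participant(drift_mixture("fixed", 10), alpha = 1,
                            theta = 0.13, n_trials = n, seed = 31)
  expect_lt(ks_distance(p$rts, function(q) psw(q, 1, 0.13, 10)),
            ks_crit_1pct(n))
  expect_gt(min(p$rts), 0.13)
  # truncated-normal drift: marginal is the closed-form mixture
  p <- simulate_participant(drift_mixture("tn", 10, 2), alpha = 1,
                            theta = 0.13, n_trials = n, seed = 32)
  Fm <- cdf_from_density(function(t) dswtn(t, 1, 0.13, 10, sqrt(2)),
                         0.13, max(p$rts) * 1.5)
  expect_lt(ks_distance(p$rts, Fm), ks_crit_1pct(n))
  # gamma drift: marginal is the quadrature mixture
  gp <- gamma_from_moments(10, 2)
  p <- simulate_participant(drift_mixture("gam", 10, 2), alpha = 1,
                            theta = 0.13, n_trials = n, seed = 33)
  Fm <- cdf_from_density(function(t)
    exp(waldmix:::.swgam_logpdf_cpp(t, 1, 0.13, gp$kappa, gp$tau)),
    0.13, max(p$rts) * 1.5)
  expect_lt(ks_distance(p$rts, Fm), ks_crit_1pct(n))
})

test_that("dataset generation is deterministic and has the stated shape", {
  tab <- default_recovery_params(30)
  tab$family <- "tn"
  d1 <- simulate_dataset(tab, n_trials = 120, master_seed = 99)
  d2 <- simulate_dataset(tab, n_trials = 120, master_seed = 99)
  expect_equal(length(d1), 30)
  expect_equal(sum(lengths(lapply(d1, `[[`, "rts"))), 30 * 120)
  expect_identical(lapply(d1, `[[`, "rts"), lapply(d2, `[[`, "rts"))
  # different master seed: different data
  d3 <- simulate_dataset(tab, n_trials = 120, master_seed = 100)
  expect_false(identical(d1[[1]]$rts, d3[[1]]$rts))
  # participants are mutually distinct
  expect_false(identical(d1[[1]]$rts, d1[[2]]$rts))
  # the 1200-trial variant
  d4 <- simulate_dataset(tab[1:2, ], n_trials = 1200, master_seed = 99)
  expect_equal(lengths(lapply(d4, `[[`, "rts")), c(1200L, 1200L),
               ignore_attr = TRUE)
})

test_that("per-participant seeds are spawned reproducibly from the master seed", {
  s <- vapply(1:10, function(i) waldmix:::.spawn_seed(42, i), integer(1))
  expect_identical(s, vapply(1:10, function(i) waldmix:::.spawn_seed(42, i),
                             integer(1)))
  expect_equal(length(unique(s)), 10)
  expect_true(all(s > 0 & s < 2^31))
})
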