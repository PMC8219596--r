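test_that("default priors are the documented four laws", {
  pr <- default_priors()
  expect_identical(dprior(pr, "alpha", -1), 0)
  expect_equal(dprior(pr, "sigma2_xi", c(-1, 2, 6)), c(0, 1/5, 0))
  expect_equal(pr$theta$mean, 0.180)
  expect_equal(pr$alpha$sd, sqrt(5/2))
  expect_equal(pr$mu_xi$sd, sqrt(10))
  # truncated normals are properly normalized
  expect_equal(integrate(function(z) dprior(pr, "theta", z), 0, Inf)$value,
               1, tolerance = 1e-8)
})

test_that("log posterior composes likelihood and priors term by term", {
  pr <- default_priors()
  pars <- c(alpha = 1, theta = 0.1, mu_xi = 8, sigma2_xi = 2)
  lp <- log_posterior(pars, rts = 0.5, family = "tn", priors = pr)
  by_hand <- dswtn(0.5, 1, 0.1, 8, sqrt(2), log = TRUE) +
    dtnorm0(1, 2, sqrt(5/2), log = TRUE) +
    dtnorm0(0.1, 0.180, 0.5, log = TRUE) +
    dtnorm0(8, 8, sqrt(10), log = TRUE) +
    dunif(2, 0, 5, log = TRUE)
  expect_equal(lp, by_hand)
})

test_that("log posterior enforces support and dimension contracts", {
  rt <- c(0.3, 0.5, 0.6)
  pars <- c(alpha = 1, theta = 0.35, mu_xi = 8, sigma2_xi = 2)
  expect_identical(log_posterior(pars, rt, "tn"), -Inf)   # theta >= min(rt)
  pars["theta"] <- 0.1
  pars["sigma2_xi"] <- 7                                  # outside U(0, 5)
  expect_identical(log_posterior(pars, rt, "tn"), -Inf)
  expect_error(log_posterior(pars, rt, "tn", fix_sigma2 = TRUE),
               "sigma2_xi")
  expect_error(log_posterior(pars, numeric(0), "tn"), "nonempty")
  # restricted model: plain SW likelihood with xi = mu_xi
  p3 <- c(alpha = 1, theta = 0.1, mu_xi = 8)
  expect_equal(log_posterior(p3, rt, "tn", fix_sigma2 = TRUE),
               sum(dsw(rt, 1, 0.1, 8, log = TRUE)) +
                 dtnorm0(1, 2, sqrt(5/2), log = TRUE) +
                 dtnorm0(0.1, 0.180, 0.5, log = TRUE) +
                 dtnorm0(8, 8, sqrt(10), log = TRUE))
})

test_that("Gelman-Rubin diagnostic behaves at its reference points", {
  # i.i.d. chains from a common law stay close to 1
  set.seed(41)
  m <- matrix(rnorm(3 * 4000), 4000, 3)
  expect_lt(rhat(m), 1.05)
  # grossly separated chain means blow past 1.1 (brute-force formula check)
  m2 <- cbind(rnorm(500), rnorm(500), rnorm(500, 10))
  W <- mean(apply(m2, 2, var)); B <- var(colMeans(m2))
  expect_equal(rhat(m2), sqrt((499/500 * W + B) / W))
  expect_gt(rhat(m2), 1.1)
  # degenerate conventions
  expect_equal(rhat(matrix(5, 10, 3)), 1)
  expect_equal(rhat(cbind(rep(1, 10), rep(2, 10))), Inf)
  expect_error(rhat(matrix(1:10, 10, 1)), "2 chains")
  expect_error(rhat(matrix(1:2, 1, 2)), "2 draws")
})

test_that("posterior mode estimator finds the density peak", {
  expect_equal(posterior_mode(rep(3.7, 50)), 3.7)
  set.seed(42)
  x <- rnorm(1e5)
  # the KDE-argmax error for a standard normal at n = 1e5 with Silverman
  # bandwidth has sd ~ sqrt(f(0) R(K') / (n h^3)) / |f''(0)| ~ 0.05; allow 3 sd
  expect_lt(abs(posterior_mode(x)), 0.15)
  # global argmax on a bimodal sample lands on the heavier mode
  xb <- c(rnorm(7000, -3, 0.1), rnorm(3000, 3, 0.1))
  expect_lt(abs(posterior_mode(xb) + 3), 0.1)
  expect_true(posterior_mode(x) >= min(x) && posterior_mode(x) <= max(x))
})

test_that("posterior IQR uses the linear-interpolation convention", {
  expect_equal(posterior_iqr(1:100), c(q25 = 25.75, q75 = 75.25))
  expect_equal(unname(diff(posterior_iqr(rep(2, 10)))), 0)
})

test_that("MCMC is reproducible and respects the retention protocol", {
  rt <- rsw(120, 1, 0.13, 10, seed = 51)
  f1 <- fit_mcmc(rt, "tn", chains = 2, draws = 150, burn_in = 150, seed = 9)
  f2 <- fit_mcmc(rt, "tn", chains = 2, draws = 150, burn_in = 150, seed = 9)
  expect_identical(f1$draws, f2$draws)
  expect_equal(dim(f1$draws), c(150L, 2L, 4L))
  expect_error(fit_mcmc(rt, "tn", chains = 1), "chains")
  # every retained draw has finite posterior density
  lp <- apply(f1$draws, c(1, 2), function(v)
    log_posterior(setNames(v, f1$parameters), rt, "tn"))
  expect_true(all(is.finite(lp)))
  # extension continues rather than restarts
  f3 <- mcmc_extend(f1, n_add = 50)
  expect_equal(dim(f3$draws)[1], 200L)
  expect_identical(f3$draws[1:150, , ], f1$draws)
  expect_equal(f3$extensions, 1L)
})

test_that("the shift parameter is recovered from a long synthetic run", {
  p <- simulate_participant(drift_mixture("tn", 10, 1), alpha = 1,
                            theta = 0.13, n_trials = 1200, seed = 52)
  fit <- swfit(p$rts, family = "tn", chains = 3, draws = 2000,
               burn_in = 1000, seed = 53)
  expect_true(fit$report$converged)
  expect_true(all(fit$report$rhat < 1.05))
  expect_lt(abs(coef(fit)[["theta"]] - 0.13), 0.02)
})

test_that("fit methods expose the posterior sensibly", {
  rt <- rsw(200, 1, 0.13, 10, seed = 54)
  fit <- swfit(rt, family = "tn", fix_sigma2 = TRUE, chains = 2,
               draws = 400, burn_in = 400, seed = 55)
  expect_named(coef(fit), c("alpha", "theta", "mu_xi"))
  s <- summary(fit)
  expect_true(all(s[, "q25"] <= s[, "q75"]))
  expect_true(all(s[, "mode"] >= apply(fit$samples$draws, 3, min)))
  sim <- simulate(fit, nsim = 50, seed = 1)
  expect_length(sim, 50)
  expect_true(all(sim > coef(fit)[["theta"]]))
  dens <- predict(fit, type = "density", newdata = c(0.2, 0.4))
  expect_true(all(dens >= 0))
  q <- predict(fit, type = "quantiles", seed = 2)
  expect_true(all(diff(q) >= 0))
  expect_true(is.finite(logLik(fit)))
  # samples serialize to the columnar layout
  df <- as.data.frame(fit$samples)
  expect_named(df, c("chain", "draw", "parameter", "value"))
  expect_equal(nrow(df), prod(dim(fit$samples$draws)))
})

test_that("a clamped one-parameter reduction samples only that parameter", {
  rt <- rsw(200, 1.2, 0.13, 10, seed = 56)
  f <- fit_mcmc(rt, "tn", chains = 2, draws = 300, burn_in = 300,
                seed = 57, fix_sigma2 = TRUE,
                fixed = list(theta = 0.13, mu_xi = 10))
  expect_identical(f$parameters, "alpha")
  expect_equal(dim(f$draws)[3], 1L)
})
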