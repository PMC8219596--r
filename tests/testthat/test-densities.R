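test_that("shifted-Wald density matches its closed form and support rules", {
  # exponent vanishes when alpha = xi (t - theta)
  expect_equal(dsw(1, alpha = 1, theta = 0, xi = 1, log = TRUE),
               log(1 / sqrt(2 * pi)))
  # zero density at and below the shift
  expect_identical(dsw(0.5, 1, 0.5, 1, log = TRUE), -Inf)
  expect_identical(dsw(0.2, 1, 0.5, 1), 0)
  # theta is a pure location shift
  expect_equal(dsw(2, 1, 1, 1, log = TRUE), dsw(1, 1, 0, 1, log = TRUE))
  # invalid inputs
  expect_error(dsw(NaN, 1, 0, 1), "finite")
  expect_error(dsw(1, -1, 0, 1), "alpha")
  expect_error(dsw(1, 1, -0.1, 1), "theta")
  expect_error(dsw(1, 1, 0, -1), "xi")
})

test_that("shifted-Wald CDF agrees with numerical integration of the density", {
  for (p in list(c(1, 0.1, 8), c(2, 0, 3), c(0.8, 0.2, 12))) {
    q <- p[2] + c(0.05, 0.2, 0.8)
    num <- vapply(q, function(qq)
      integrate(function(u) dsw(u, p[1], p[2], p[3]), p[2], qq,
                rel.tol = 1e-10)$value, numeric(1))
    expect_equal(psw(q, p[1], p[2], p[3]), num, tolerance = 1e-8)
  }
  expect_equal(psw(Inf, 1, 0, 5), 1)
  expect_equal(psw(0.1, 1, 0.1, 8), 0)
  # Levy case xi = 0: closed form 2 * Phi(-alpha / sqrt(s))
  expect_equal(psw(1.1, 1.5, 0.1, 0), 2 * pnorm(-1.5), tolerance = 1e-12)
})

test_that("zero-truncated normal drift density is correct", {
  expect_identical(dtnorm0(-1, 5, 2), 0)
  expect_equal(dtnorm0(0, 0, 1), 2 * dnorm(0))        # half-normal at zero
  expect_equal(integrate(function(z) dtnorm0(z, 3, 1), 0, Inf,
                         rel.tol = 1e-12)$value, 1, tolerance = 1e-10)
  # log route stays finite deep in the truncation regime
  expect_true(is.finite(dtnorm0(0.5, -40, 1, log = TRUE)))
  expect_error(dtnorm0(1, 0, 0), "sigma")
})

test_that("closed-form TN mixture equals the quadrature oracle", {
  pt <- list(t = 0.5, a = 1, th = 0.1, m = 3, s = 1)
  o <- sw_mix_quadrature(pt$t, pt$a, pt$th,
                         function(z) dtnorm0(z, pt$m, pt$s))
  expect_equal(exp(dswtn(pt$t, pt$a, pt$th, pt$m, pt$s, log = TRUE)), o,
               tolerance = 1e-6)
  # random spot checks across the working parameter ranges
  set.seed(11)
  for (k in 1:15) {
    a <- runif(1, 0.5, 4); th <- runif(1, 0, 0.3)
    m <- runif(1, 1, 20); sg <- runif(1, 0.1, 2)
    t <- th + runif(1, 1e-3, 2)
    o <- sw_mix_quadrature(t, a, th, function(z) dtnorm0(z, m, sg))
    expect_equal(dswtn(t, a, th, m, sg), o, tolerance = 1e-6)
  }
})

test_that("TN mixture collapses to the plain SW as the drift scale vanishes", {
  x <- c(0.2, 0.5, 1, 3)
  # below the degeneracy threshold: exact routing
  expect_equal(dswtn(x, 1, 0.1, 3, 1e-8, log = TRUE),
               dsw(x, 1, 0.1, 3, log = TRUE))
  # just above it: continuous approach
  expect_equal(dswtn(x, 1, 0.1, 3, 1e-5, log = TRUE),
               dsw(x, 1, 0.1, 3, log = TRUE), tolerance = 1e-6)
})

test_that("TN mixture integrates to one and stays finite at extreme times", {
  for (p in list(c(1, 0.1, 8, 1.2), c(2.5, 0.05, 3, 0.5))) {
    z <- integrate(function(t) dswtn(t, p[1], p[2], p[3], p[4]),
                   p[2], Inf, rel.tol = 1e-9)$value
    expect_equal(z, 1, tolerance = 1e-6)
  }
  v <- dswtn(0.1 + c(1e-6, 1e-3, 1, 1e2, 1e3), 2, 0.1, 8, 2, log = TRUE)
  expect_true(all(is.finite(v)))
})

test_that("gamma moment reparameterization is exact and self-inverse", {
  expect_equal(gamma_from_moments(8, 4), list(kappa = 16, tau = 2))
  expect_equal(gamma_to_moments(16, 2), list(mu_xi = 8, sigma2_xi = 4))
  expect_equal(gamma_from_moments(1, 1), list(kappa = 1, tau = 1))
  set.seed(3)
  for (k in 1:20) {
    mu <- runif(1, 0.5, 20); s2 <- runif(1, 0.01, 5)
    gp <- gamma_from_moments(mu, s2)
    back <- gamma_to_moments(gp$kappa, gp$tau)
    expect_equal(back$mu_xi, mu)
    expect_equal(back$sigma2_xi, s2)
  }
  expect_error(gamma_from_moments(-1, 1), "mu_xi")
  expect_error(gamma_to_moments(1, 0), "tau")
})

test_that("gamma mixture agrees with the oracle and its own tightened re-evaluation", {
  o <- sw_mix_quadrature(0.5, 1, 0.1, function(z) dgamma(z, 9, rate = 3))
  expect_equal(dswgam(0.5, 1, 0.1, kappa = 9, tau = 3), o, tolerance = 1e-6)
  set.seed(12)
  for (k in 1:10) {
    a <- runif(1, 0.5, 4); th <- runif(1, 0, 0.3)
    mu <- runif(1, 1, 20); s2 <- runif(1, 0.05, 4)
    gp <- gamma_from_moments(mu, s2)
    t <- th + runif(1, 0.01, 2)
    o <- sw_mix_quadrature(t, a, th,
                           function(z) dgamma(z, gp$kappa, rate = gp$tau))
    f <- dswgam(t, a, th, gp$kappa, gp$tau)
    expect_equal(f, o, tolerance = 1e-6)
    # deterministic given tolerances; tighter tolerance changes little
    f2 <- dswgam(t, a, th, gp$kappa, gp$tau, rel.tol = 1e-12)
    expect_equal(f, f2, tolerance = 1e-8)
  }
})

test_that("gamma mixture collapses to the plain SW as the variance vanishes", {
  x <- c(0.2, 0.5, 1, 3)
  gp <- gamma_from_moments(3, 1e-10)
  expect_equal(dswgam(x, 1, 0.1, gp$kappa, gp$tau, log = TRUE),
               dsw(x, 1, 0.1, 3, log = TRUE), tolerance = 1e-4)
})

test_that("gamma mixture integrates to one", {
  gp <- gamma_from_moments(9, 2)
  z <- integrate(function(t) dswgam(t, 1.2, 0.15, gp$kappa, gp$tau),
                 0.15, Inf, rel.tol = 1e-8)$value
  expect_equal(z, 1, tolerance = 1e-6)
})

test_that("the C++ likelihood kernels match the R densities", {
  set.seed(4)
  t <- rsw(300, 1, 0.13, 10)
  expect_equal(waldmix:::.sw_loglik_cpp(t, 1.1, 0.12, 9),
               sum(dsw(t, 1.1, 0.12, 9, log = TRUE)))
  expect_equal(waldmix:::.swtn_loglik_cpp(t, 1.1, 0.12, 9, sqrt(1.5)),
               sum(dswtn(t, 1.1, 0.12, 9, sqrt(1.5), log = TRUE)))
  for (m in list(c(9, 1.5), c(1.5, 4), c(15, 0.2))) {
    gp <- gamma_from_moments(m[1], m[2])
    expect_equal(waldmix:::.swgam_loglik_cpp(t, 1.1, 0.12, gp$kappa, gp$tau),
                 sum(dswgam(t, 1.1, 0.12, gp$kappa, gp$tau, log = TRUE)),
                 tolerance = 1e-8)
  }
  # RTs at or below theta void the likelihood
  expect_identical(waldmix:::.swtn_loglik_cpp(c(t, 0.1), 1, 0.12, 9, 1), -Inf)
})

test_that("the oracle recovers a near point mass when given a support hint", {
  m <- 3; sg <- 1e-8
  o <- sw_mix_quadrature(0.5, 1, 0.1, function(z) dtnorm0(z, m, sg),
                         lower = m - 1e-6, upper = m + 1e-6)
  expect_equal(o, dsw(0.5, 1, 0.1, m), tolerance = 1e-6)
})

test_that("oracle weights are a valid quadrature rule", {
  expect_equal(sum(waldmix:::.GL20_W), 2, tolerance = 1e-12)
})
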