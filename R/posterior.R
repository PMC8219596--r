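# Bayesian machinery: log posterior, adaptive-Metropolis MCMC, Gelman-Rubin
# diagnostic, and posterior summaries.

.par_names <- function(fix_sigma2) {
  if (fix_sigma2) c("alpha", "theta", "mu_xi")
  else c("alpha", "theta", "mu_xi", "sigma2_xi")
}

# log likelihood of a full natural-scale parameter vector; -Inf outside the
# model's support (including any RT <= theta)
.sw_loglik <- function(rts, family, pars, fix_sigma2) {
  alpha <- pars[["alpha"]]; theta <- pars[["theta"]]
  mu <- pars[["mu_xi"]]
  if (!is.finite(alpha) || alpha <= 0 || !is.finite(theta) || theta < 0 ||
      !is.finite(mu) || mu < 0)
    return(-Inf)
  if (fix_sigma2)
    return(.sw_loglik_cpp(rts, alpha, theta, mu))
  s2 <- pars[["sigma2_xi"]]
  if (!is.finite(s2) || s2 <= 0) return(-Inf)
  if (family == "tn") {
    .swtn_loglik_cpp(rts, alpha, theta, mu, sqrt(s2))
  } else {
    if (mu <= 0) return(-Inf)
    gp <- gamma_from_moments(mu, s2)
    .swgam_loglik_cpp(rts, alpha, theta, gp$kappa, gp$tau)
  }
}

.sw_logprior <- function(priors, pars, fix_sigma2) {
  lp <- dprior(priors, "alpha", pars[["alpha"]], log = TRUE) +
    dprior(priors, "theta", pars[["theta"]], log = TRUE) +
    dprior(priors, "mu_xi", pars[["mu_xi"]], log = TRUE)
  if (!fix_sigma2)
    lp <- lp + dprior(priors, "sigma2_xi", pars[["sigma2_xi"]], log = TRUE)
  lp
}

#' Log posterior density of the shifted-Wald mixture
#'
#' Sum of the per-trial log likelihood (the closed-form truncated-normal
#' mixture for `family = "tn"`, the quadrature gamma marginal for
#' `family = "gam"`) and the log prior densities.  Returns `-Inf` whenever
#' any trial RT is at or below `theta` or any parameter falls outside its
#' prior support.  With `fix_sigma2 = TRUE` the restricted model is
#' evaluated: the likelihood is the plain shifted-Wald with drift `mu_xi`
#' and the parameter vector must not contain a `sigma2_xi` coordinate.
#'
#' @param pars named numeric vector with elements `alpha`, `theta`, `mu_xi`
#'   and, unless `fix_sigma2`, `sigma2_xi` (drift variance).
#' @param rts numeric vector of reaction times in seconds, nonempty.
#' @param family `"tn"` or `"gam"`.
#' @param priors an `sw_priors` object.
#' @param fix_sigma2 logical; fit the restricted model with drift variance
#'   fixed to zero.
#' @return scalar log posterior density (unnormalized).
#' @examples
#' rt <- rsw(20, alpha = 1, theta = 0.13, xi = 10, seed = 1)
#' log_posterior(c(alpha = 1, theta = 0.13, mu_xi = 10, sigma2_xi = 1),
#'               rt, family = "tn")
#' @export
log_posterior <- function(pars, rts, family = c("tn", "gam"),
                          priors = default_priors(), fix_sigma2 = FALSE) {
  family <- match.arg(family)
  if (length(rts) == 0) stop("'rts' must be nonempty")
  if (!all(is.finite(rts))) stop("'rts' must be finite")
  want <- .par_names(fix_sigma2)
  if (fix_sigma2 && "sigma2_xi" %in% names(pars))
    stop("'sigma2_xi' must not be present when fix_sigma2 = TRUE")
  if (!all(want %in% names(pars)))
    stop("'pars' must be named with ", paste(want, collapse = ", "))
  pars <- pars[want]
  ll <- .sw_loglik(rts, family, pars, fix_sigma2)
  if (!is.finite(ll)) return(-Inf)
  lp <- .sw_logprior(priors, pars, fix_sigma2)
  if (!is.finite(lp)) return(-Inf)
  ll + lp
}

# ---- transformed coordinates -------------------------------------------
# MCMC runs on z = (log alpha, log theta, log mu_xi, logit(sigma2/max)).
# The Jacobian of the back-transform is added to the target so the chain
# samples the posterior of the natural-scale parameters.

.to_z <- function(pars, s2max) {
  z <- log(pars[setdiff(names(pars), "sigma2_xi")])
  if ("sigma2_xi" %in% names(pars))
    z <- c(z, sigma2_xi = qlogis(pars[["sigma2_xi"]] / s2max))
  z
}

.from_z <- function(z, s2max) {
  p <- exp(z[setdiff(names(z), "sigma2_xi")])
  if ("sigma2_xi" %in% names(z))
    p <- c(p, sigma2_xi = s2max * plogis(z[["sigma2_xi"]]))
  p
}

.log_jacobian <- function(z, s2max) {
  j <- sum(z[setdiff(names(z), "sigma2_xi")])
  if ("sigma2_xi" %in% names(z)) {
    u <- plogis(z[["sigma2_xi"]])
    j <- j + log(s2max) + log(u) + log1p(-u)
  }
  j
}

# builds the z-space log target over the free coordinates
.make_target <- function(rts, family, priors, fix_sigma2, fixed) {
  s2max <- priors$sigma2_xi$max
  all_names <- .par_names(fix_sigma2)
  fixed <- fixed %||% list()
  if (length(fixed) && !all(names(fixed) %in% all_names))
    stop("'fixed' may only name ", paste(all_names, collapse = ", "))
  free <- setdiff(all_names, names(fixed))
  if (!length(free)) stop("no free parameters left to sample")
  fixed_vec <- unlist(fixed)
  list(
    free = free,
    s2max = s2max,
    logpost_z = function(z) {
      names(z) <- free
      pars <- c(.from_z(z, s2max), fixed_vec)[all_names]
      names(pars) <- all_names
      ll <- .sw_loglik(rts, family, pars, fix_sigma2)
      if (!is.finite(ll)) return(-Inf)
      lp <- .sw_logprior(priors, pars, fix_sigma2)
      if (!is.finite(lp)) return(-Inf)
      ll + lp + .log_jacobian(z, s2max)
    },
    start = function() {
      draw <- .rprior(priors, free)
      .to_z(draw, s2max)
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Laplace approximation at the posterior mode in z-space: Nelder-Mead from
# the best of a handful of prior draws, numerical Hessian at the optimum.
# Supplies the initial proposal covariance and overdispersed chain starts.
.laplace_init <- function(target) {
  best <- NULL
  for (k in seq_len(25)) {
    z0 <- target$start()
    lp <- target$logpost_z(z0)
    if (is.finite(lp) && (is.null(best) || lp > best$lp))
      best <- list(z = z0, lp = lp)
  }
  if (is.null(best)) return(NULL)
  d <- length(best$z)
  nll <- function(z) {
    v <- -target$logpost_z(z)
    if (!is.finite(v)) 1e10 else v
  }
  # Nelder-Mead stalls on ridge-shaped targets; restart from the incumbent
  # until no further improvement so the chains are anchored at the dominant
  # mode rather than a shoulder
  opt <- list(par = best$z, value = -best$lp)
  for (r in seq_len(10)) {
    nxt <- tryCatch(
      suppressWarnings(stats::optim(opt$par, nll, method = "Nelder-Mead",
                                    control = list(maxit = 2000))),
      error = function(e) NULL)
    if (is.null(nxt)) break
    improved <- opt$value - nxt$value
    opt <- nxt
    if (improved < 0.01) break
  }
  if (!is.finite(opt$value) || opt$value >= 1e10) return(NULL)
  H <- tryCatch(suppressWarnings(stats::optimHess(opt$par, nll)),
                error = function(e) NULL)
  ch <- NULL
  if (!is.null(H)) {
    Sig <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(Sig))
      ch <- tryCatch(chol((Sig + t(Sig)) / 2), error = function(e) NULL)
  }
  if (is.null(ch)) ch <- diag(0.05, d)
  list(mode = opt$par, chol = ch)
}

# ---- adaptive Metropolis chain -----------------------------------------
# Joint random-walk Metropolis with a multivariate normal proposal whose
# covariance is the running empirical covariance of the burn-in draws
# (Haario-style) and whose global scale is tuned toward ~30% acceptance.
# Adaptation happens during burn-in only; retained draws and extensions use
# the frozen proposal, so the retained chain is a valid Markov chain.

.run_chain <- function(target, z, n_burn, n_keep, prop = NULL) {
  d <- length(z)
  free <- target$free
  if (is.null(prop)) {
    prop <- list(chol = diag(0.1, d), log_lambda = log(2.38 / sqrt(d)))
  }
  # optimal-scaling acceptance targets: ~0.44 for a scalar chain, ~0.3 jointly
  acc_target <- if (d == 1) 0.44 else 0.30
  lp <- target$logpost_z(z)
  adapt <- n_burn > 0
  hist_z <- if (adapt) matrix(0, n_burn, d) else NULL
  out <- matrix(0, n_keep, d)
  acc <- 0L
  for (i in seq_len(n_burn + n_keep)) {
    step <- exp(prop$log_lambda) * drop(rnorm(d) %*% prop$chol)
    z_new <- z + step
    lp_new <- target$logpost_z(z_new)
    a <- if (lp_new == -Inf) 0 else min(1, exp(lp_new - lp))
    if (runif(1) < a) {
      z <- z_new; lp <- lp_new
      if (i > n_burn) acc <- acc + 1L
    }
    if (i <= n_burn) {
      hist_z[i, ] <- z
      prop$log_lambda <- prop$log_lambda + (a - acc_target) / sqrt(i)
      if (i >= 100 && i %% 25 == 0) {
        cv <- var(hist_z[ceiling(i / 2):i, , drop = FALSE]) +
          diag(1e-8, d)
        ch <- tryCatch(chol(cv), error = function(e) NULL)
        if (!is.null(ch)) prop$chol <- ch
      }
    } else {
      out[i - n_burn, ] <- z
    }
  }
  colnames(out) <- free
  list(z = out, state = z, lp = lp, prop = prop,
       acceptance = acc / max(n_keep, 1))
}

#' Fit the shifted-Wald mixture by adaptive-Metropolis MCMC
#'
#' Runs `chains` Markov chains of joint random-walk Metropolis on
#' log-transformed coordinates (`log alpha`, `log theta`, `log mu_xi`, and a
#' logit map of `sigma2_xi` onto the support of its uniform prior), with
#' Jacobian corrections so the draws are posterior samples of the
#' natural-scale parameters.  The proposal covariance and global scale are
#' adapted during burn-in only (targeting 20-50% acceptance); retained
#' draws come from the frozen kernel.  Starting values are drawn from the
#' priors and redrawn until the posterior is finite.
#'
#' @inheritParams log_posterior
#' @param chains number of chains, >= 2 (the Gelman-Rubin diagnostic
#'   requires at least two).
#' @param draws retained draws per chain after burn-in.
#' @param burn_in discarded (and adaptation) draws per chain.
#' @param seed optional integer seed; the same seed yields bit-identical
#'   chains.
#' @param fixed optional named list clamping a subset of parameters at
#'   fixed values (they are removed from the sampled vector); useful for
#'   reduced-model checks.
#' @return object of class `sw_samples` holding the post-burn-in draws as a
#'   `draws x chains x parameters` array (natural scale) plus the fit
#'   configuration needed to extend the chains.
#' @examples
#' rt <- rsw(100, alpha = 1, theta = 0.13, xi = 10, seed = 1)
#' fit <- fit_mcmc(rt, family = "tn", chains = 2, draws = 200,
#'                 burn_in = 200, seed = 2)
#' posterior_mode(fit, "theta")
#' @export
fit_mcmc <- function(rts, family = c("tn", "gam"),
                     priors = default_priors(), chains = 3, draws = 4000,
                     burn_in = 1000, seed = NULL, fix_sigma2 = FALSE,
                     fixed = NULL) {
  family <- match.arg(family)
  if (length(rts) == 0) stop("'rts' must be nonempty")
  if (chains < 2) stop("'chains' must be >= 2")
  target <- .make_target(rts, family, priors, fix_sigma2, fixed)
  .with_seed(seed, {
    laplace <- .laplace_init(target)
    d <- length(target$free)
    res <- lapply(seq_len(chains), function(ch) {
      z0 <- NULL
      for (k in seq_len(1000)) {
        # overdispersed start around the Laplace mode when available,
        # otherwise a raw prior draw
        cand <- if (!is.null(laplace) && k <= 500)
          laplace$mode + 2 * drop(rnorm(d) %*% laplace$chol)
        else target$start()
        if (is.finite(target$logpost_z(cand))) { z0 <- cand; break }
      }
      if (is.null(z0))
        stop("no finite-posterior starting value found in 1000 attempts")
      prop0 <- if (is.null(laplace)) NULL
        else list(chol = laplace$chol, log_lambda = log(2.38 / sqrt(d)))
      .run_chain(target, z0, n_burn = burn_in, n_keep = draws,
                 prop = prop0)
    })
    arr <- array(NA_real_, c(draws, chains, length(target$free)),
                 dimnames = list(NULL, NULL, target$free))
    for (ch in seq_len(chains)) {
      nat <- t(apply(res[[ch]]$z, 1, .from_z, s2max = target$s2max))
      arr[, ch, ] <- nat
    }
    structure(list(
      draws = arr,
      parameters = target$free,
      family = family, fix_sigma2 = fix_sigma2, fixed = fixed,
      priors = priors, rts = rts,
      burn_in = burn_in, extensions = 0L,
      acceptance = vapply(res, `[[`, numeric(1), "acceptance"),
      .state = lapply(res, function(r) r[c("state", "lp", "prop")]),
      .target = target
    ), class = "sw_samples")
  })
}

#' Extend the chains of an existing fit
#'
#' Continues every chain of an [fit_mcmc()] result from its last state with
#' the frozen proposal kernel (a continuation, not a restart) and appends
#' `n_add` retained draws per chain.
#'
#' @param samples an `sw_samples` object.
#' @param n_add additional retained draws per chain.
#' @return the extended `sw_samples` object.
#' @export
mcmc_extend <- function(samples, n_add = 1000) {
  stopifnot(inherits(samples, "sw_samples"))
  target <- samples$.target
  chains <- dim(samples$draws)[2]
  old_n <- dim(samples$draws)[1]
  arr <- array(NA_real_, c(old_n + n_add, chains, length(target$free)),
               dimnames = dimnames(samples$draws))
  arr[seq_len(old_n), , ] <- samples$draws
  for (ch in seq_len(chains)) {
    st <- samples$.state[[ch]]
    r <- .run_chain(target, st$state, n_burn = 0, n_keep = n_add,
                    prop = st$prop)
    arr[old_n + seq_len(n_add), ch, ] <-
      t(apply(r$z, 1, .from_z, s2max = target$s2max))
    samples$.state[[ch]] <- r[c("state", "lp", "prop")]
  }
  samples$draws <- arr
  samples$extensions <- samples$extensions + 1L
  samples
}

#' @export
print.sw_samples <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("posterior samples: %d chains x %d retained draws (%d burn-in, %d extensions)\n",
              d[2], d[1], x$burn_in, x$extensions))
  cat(sprintf("model: SW-%s%s; parameters: %s\n", toupper(x$family),
              if (x$fix_sigma2) " (drift variance fixed to 0)" else "",
              paste(x$parameters, collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.sw_samples <- function(x, ...) {
  d <- dim(x$draws)
  data.frame(
    chain = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    draw = rep(seq_len(d[1]), times = d[2] * d[3]),
    parameter = rep(x$parameters, each = d[1] * d[2]),
    value = as.vector(x$draws))
}

# pooled post-burn-in draws of one parameter
.pooled <- function(samples, parameter) {
  if (!parameter %in% samples$parameters)
    stop("unknown parameter '", parameter, "'")
  as.vector(samples$draws[, , parameter])
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classical (non-split) Gelman-Rubin diagnostic comparing between-chain to
#' within-chain variability over the retained draws:
#' \eqn{\hat{R} = \sqrt{(\frac{n-1}{n} W + \frac{B}{n}) / W}} with `W` the
#' mean within-chain variance and `B/n` the variance of the chain means.
#' Values near 1 indicate convergence.  If every chain is constant and
#' equal, 1 is returned by convention; constant chains with different
#' values give `Inf`.
#'
#' @param samples an `sw_samples` object (or a `draws x chains` matrix).
#' @param parameter parameter name; `NULL` returns all.
#' @return named vector of R-hat values.
#' @export
rhat <- function(samples, parameter = NULL) {
  m <- if (inherits(samples, "sw_samples")) {
    if (is.null(parameter))
      return(vapply(samples$parameters, function(p) rhat(samples, p),
                    numeric(1)))
    samples$draws[, , parameter]
  } else as.matrix(samples)
  n <- nrow(m); k <- ncol(m)
  if (k < 2) stop("R-hat requires at least 2 chains")
  if (n < 2) stop("R-hat requires at least 2 draws per chain")
  W <- mean(apply(m, 2, var))
  B_over_n <- var(colMeans(m))
  if (W == 0) return(if (B_over_n == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' Posterior mode and interquartile range
#'
#' `posterior_mode` estimates the mode of the pooled retained draws with a
#' Gaussian kernel density (Silverman's rule-of-thumb bandwidth) evaluated
#' on a 512-point grid spanning the sample range; the result always lies
#' within the range of the draws.  `posterior_iqr` returns the 25th and
#' 75th percentiles under the linear-interpolation quantile convention
#' (type 7).
#'
#' @param samples an `sw_samples` object or a numeric vector of draws.
#' @param parameter parameter name (ignored when `samples` is a vector).
#' @return `posterior_mode`: scalar mode; `posterior_iqr`: named vector
#'   `c(q25, q75)`.
#' @export
posterior_mode <- function(samples, parameter = NULL) {
  x <- if (inherits(samples, "sw_samples")) .pooled(samples, parameter)
       else as.numeric(samples)
  if (length(unique(x)) == 1L) return(x[1])
  de <- density(x, bw = "nrd0", n = 512, from = min(x), to = max(x))
  de$x[which.max(de$y)]
}

#' @rdname posterior_mode
#' @export
posterior_iqr <- function(samples, parameter = NULL) {
  x <- if (inherits(samples, "sw_samples")) .pooled(samples, parameter)
       else as.numeric(samples)
  q <- quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  c(q25 = q[1], q75 = q[2])
}
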