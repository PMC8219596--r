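# The user-facing model fit: MCMC with convergence monitoring and automatic
# chain extension, returning a classed object with the usual methods.

#' Fit a shifted-Wald drift-variability mixture to one participant
#'
#' Estimates the parameters of the shifted-Wald model with across-trial
#' drift-rate variability (`family = "tn"` for the zero-truncated normal
#' mixing law, `"gam"` for the gamma law) from one participant's reaction
#' times by MCMC ([fit_mcmc()]).  After the initial run, convergence is
#' assessed with the Gelman-Rubin diagnostic [rhat()]; while any parameter's
#' R-hat is at or above `rhat_threshold` the chains are extended — a
#' continuation with the frozen proposal kernel, not a restart — by
#' `extend_by` retained draws each, up to `max_extensions` times.  Failure
#' to converge within the cap raises an error of class
#' `"waldmix_convergence_error"` carrying the convergence report.
#'
#' With `fix_sigma2 = TRUE` the restricted model is fit: drift variance
#' fixed to zero, i.e. the plain shifted-Wald with constant drift `mu_xi`.
#'
#' @inheritParams fit_mcmc
#' @param rhat_threshold convergence threshold on R-hat (default 1.05).
#' @param max_extensions cap on the number of chain extensions.
#' @param extend_by retained draws added per chain and extension.
#' @return object of class `swfit` with components `samples`
#'   (`sw_samples`), `report` (per-parameter R-hat, extension count,
#'   `converged` flag), `summary` (per-parameter posterior mode and
#'   interquartile range), `rts`, `family`, `fix_sigma2`, `priors`, `call`.
#' @seealso [coef.swfit()], [summary.swfit()], [simulate.swfit()],
#'   [predict.swfit()], [plot.swfit()]
#' @examples
#' rt <- rsw(150, alpha = 1, theta = 0.13, xi = 10, seed = 5)
#' fit <- swfit(rt, family = "tn", fix_sigma2 = TRUE, chains = 2,
#'              draws = 300, burn_in = 300, seed = 11)
#' coef(fit)
#' @export
swfit <- function(rts, family = c("tn", "gam"), fix_sigma2 = FALSE,
                  priors = default_priors(), chains = 3, draws = 4000,
                  burn_in = 1000, rhat_threshold = 1.05,
                  max_extensions = 10, extend_by = 1000, seed = NULL) {
  family <- match.arg(family)
  cl <- match.call()
  fit <- .with_seed(seed, {
    samples <- fit_mcmc(rts, family = family, priors = priors,
                        chains = chains, draws = draws, burn_in = burn_in,
                        fix_sigma2 = fix_sigma2)
    rh <- rhat(samples)
    while (any(rh >= rhat_threshold) &&
           samples$extensions < max_extensions) {
      samples <- mcmc_extend(samples, n_add = extend_by)
      rh <- rhat(samples)
    }
    list(samples = samples, rh = rh)
  })
  report <- structure(list(rhat = fit$rh,
                           extensions = fit$samples$extensions,
                           threshold = rhat_threshold,
                           converged = all(fit$rh < rhat_threshold)),
                      class = "sw_convergence")
  if (!report$converged) {
    cond <- structure(
      class = c("waldmix_convergence_error", "error", "condition"),
      list(message = sprintf(
        "chains failed to reach R-hat < %g within %d extensions (max R-hat %.3f)",
        rhat_threshold, max_extensions, max(fit$rh)),
        call = cl, report = report))
    stop(cond)
  }
  summ <- t(vapply(fit$samples$parameters, function(p)
    c(mode = posterior_mode(fit$samples, p), posterior_iqr(fit$samples, p),
      rhat = unname(fit$rh[p])), numeric(4)))
  structure(list(samples = fit$samples, report = report,
                 summary = summ, rts = rts, family = family,
                 fix_sigma2 = fix_sigma2, priors = priors, seed = seed,
                 call = cl),
            class = "swfit")
}

#' @export
print.swfit <- function(x, ...) {
  cat(sprintf("Shifted-Wald %s mixture fit%s (%d RTs)\n",
              toupper(x$family),
              if (x$fix_sigma2) ", drift variance fixed to 0" else "",
              length(x$rts)))
  cat("posterior modes:\n")
  print(round(x$summary[, "mode"], 4))
  invisible(x)
}

#' Posterior summary of a shifted-Wald mixture fit
#'
#' @param object an `swfit` object.
#' @param ... unused.
#' @return matrix with one row per parameter: posterior mode, 25th and 75th
#'   percentiles, and R-hat.
#' @export
summary.swfit <- function(object, ...) {
  structure(object$summary, class = c("summary.swfit", "matrix"))
}

#' @export
print.summary.swfit <- function(x, ...) {
  cat("posterior summary (mode, interquartile range, R-hat):\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' @export
print.sw_convergence <- function(x, ...) {
  cat(sprintf("convergence: %s after %d extension(s); R-hat threshold %g\n",
              if (x$converged) "reached" else "NOT reached",
              x$extensions, x$threshold))
  print(round(x$rhat, 4))
  invisible(x)
}

#' Posterior-mode point estimates
#'
#' @param object an `swfit` object.
#' @param ... unused.
#' @return named vector of posterior modes, the point summary used
#'   throughout (recovery studies, predicted quantiles).
#' @export
coef.swfit <- function(object, ...) {
  setNames(object$summary[, "mode"], rownames(object$summary))
}

#' Simulate reaction times from a fitted model
#'
#' Draws `nsim` RTs from the fitted family at the posterior modes — the
#' parametric-bootstrap sample used for predicted quantiles.
#'
#' @param object an `swfit` object.
#' @param nsim number of RTs to draw.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return numeric vector of simulated RTs (seconds).
#' @export
simulate.swfit <- function(object, nsim = 120, seed = NULL, ...) {
  modes <- coef(object)
  mix <- if (object$fix_sigma2)
    drift_mixture("fixed", mu = modes[["mu_xi"]])
  else
    drift_mixture(object$family, mu = modes[["mu_xi"]],
                  sigma2 = modes[["sigma2_xi"]])
  simulate_participant(mix, alpha = modes[["alpha"]],
                       theta = modes[["theta"]], n_trials = nsim,
                       seed = seed)$rts
}

#' Predictions from a fitted shifted-Wald mixture
#'
#' `type = "quantiles"` returns model-predicted RT quantiles at the
#' posterior modes from a fresh simulated sample of `n` trials (the
#' goodness-of-fit convention); `type = "density"` evaluates the fitted
#' marginal density at `newdata`.
#'
#' @param object an `swfit` object.
#' @param type `"quantiles"` or `"density"`.
#' @param levels quantile levels for `type = "quantiles"`.
#' @param n simulated sample size behind the predicted quantiles.
#' @param newdata times at which to evaluate the density (defaults to the
#'   fitted RTs).
#' @param seed optional integer seed for the simulation.
#' @param ... unused.
#' @return named vector of quantiles, or density values.
#' @export
predict.swfit <- function(object, type = c("quantiles", "density"),
                          levels = c(.1, .3, .5, .7, .9), n = 120,
                          newdata = NULL, seed = NULL, ...) {
  type <- match.arg(type)
  modes <- coef(object)
  if (type == "quantiles")
    return(observed_quantiles(simulate.swfit(object, nsim = n, seed = seed),
                              levels = levels))
  x <- newdata %||% object$rts
  if (object$fix_sigma2)
    dsw(x, modes[["alpha"]], modes[["theta"]], modes[["mu_xi"]])
  else if (object$family == "tn")
    dswtn(x, modes[["alpha"]], modes[["theta"]], modes[["mu_xi"]],
          sqrt(modes[["sigma2_xi"]]))
  else {
    gp <- gamma_from_moments(modes[["mu_xi"]], modes[["sigma2_xi"]])
    dswgam(x, modes[["alpha"]], modes[["theta"]], gp$kappa, gp$tau)
  }
}

#' Diagnostic plots for a fitted shifted-Wald mixture
#'
#' Draws, per parameter, the trace of all chains and the pooled posterior
#' density with the mode marked, followed by a histogram of the data with
#' the fitted density overlaid.
#'
#' @param x an `swfit` object.
#' @param ... unused.
#' @export
plot.swfit <- function(x, ...) {
  pars <- x$samples$parameters
  op <- par(mfrow = c(length(pars) + 1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  d <- dim(x$samples$draws)
  for (p in pars) {
    matplot(x$samples$draws[, , p], type = "l", lty = 1,
            col = adjustcolor(seq_len(d[2]), 0.6),
            xlab = "draw", ylab = p, main = paste("trace:", p))
    de <- density(.pooled(x$samples, p))
    plot(de, main = paste("posterior:", p), xlab = p)
    abline(v = posterior_mode(x$samples, p), lty = 2)
  }
  hist(x$rts, breaks = 40, freq = FALSE, xlab = "RT (s)",
       main = "data and fitted density")
  xs <- seq(min(x$rts), max(x$rts), length.out = 200)
  lines(xs, predict(x, type = "density", newdata = xs), lwd = 2)
  invisible(x)
}

#' Log likelihood at the posterior modes
#'
#' @param object an `swfit` object.
#' @param ... unused.
#' @return `logLik` object evaluated at the posterior-mode estimates.
#' @export
logLik.swfit <- function(object, ...) {
  modes <- coef(object)
  ll <- .sw_loglik(object$rts, object$family, modes, object$fix_sigma2)
  structure(ll, df = length(modes), nobs = length(object$rts),
            class = "logLik")
}
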