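# Prior specification for the per-participant Bayesian fit.

#' Default priors for the shifted-Wald mixture parameters
#'
#' Returns the four independent priors used throughout: positive-truncated
#' normals on the threshold, shift, and drift mean, and a uniform on the
#' drift variance.  They are weakly informative on the scale of one-choice
#' RT tasks measured in seconds:
#' \itemize{
#'   \item `alpha ~ N+(2, sqrt(5/2))`
#'   \item `theta ~ N+(0.180, 1/2)`  (seconds)
#'   \item `mu_xi ~ N+(8, sqrt(10))`
#'   \item `sigma2_xi ~ U(0, 5)`
#' }
#' The second hyperparameter of each truncated normal is a standard
#' deviation.
#'
#' @return object of class `sw_priors`: named list of prior descriptors,
#'   each a list with `family` (`"tnorm"` or `"unif"`) and hyperparameters.
#' @examples
#' default_priors()
#' dprior(default_priors(), "sigma2_xi", 2)  # 1/5
#' @export
default_priors <- function() {
  structure(list(
    alpha     = list(family = "tnorm", mean = 2,     sd = sqrt(5 / 2)),
    theta     = list(family = "tnorm", mean = 0.180, sd = 0.5),
    mu_xi     = list(family = "tnorm", mean = 8,     sd = sqrt(10)),
    sigma2_xi = list(family = "unif",  min = 0,      max = 5)
  ), class = "sw_priors")
}

#' Prior density evaluation
#'
#' @param priors an `sw_priors` object, e.g. [default_priors()].
#' @param parameter one of `"alpha"`, `"theta"`, `"mu_xi"`, `"sigma2_xi"`.
#' @param x values at which to evaluate the prior density.
#' @param log logical; return the log density.
#' @return (log) prior density, vectorized over `x`.
#' @export
dprior <- function(priors, parameter, x, log = FALSE) {
  stopifnot(inherits(priors, "sw_priors"))
  p <- priors[[parameter]]
  if (is.null(p)) stop("unknown parameter '", parameter, "'")
  out <- switch(p$family,
                tnorm = dtnorm0(x, p$mean, p$sd, log = TRUE),
                unif = dunif(x, p$min, p$max, log = TRUE),
                stop("unknown prior family '", p$family, "'"))
  if (log) out else exp(out)
}

# one draw from each prior, as a named vector (used for MCMC starts)
.rprior <- function(priors, parameters) {
  vapply(parameters, function(nm) {
    p <- priors[[nm]]
    switch(p$family,
           tnorm = rtnorm0(1, p$mean, p$sd),
           unif = runif(1, p$min, p$max))
  }, numeric(1))
}

#' @export
print.sw_priors <- function(x, ...) {
  cat("priors:\n")
  for (nm in names(x)) {
    p <- x[[nm]]
    cat(sprintf("  %-9s ~ %s\n", nm, switch(p$family,
      tnorm = sprintf("N+(%g, %g)", p$mean, p$sd),
      unif = sprintf("U(%g, %g)", p$min, p$max))))
  }
  invisible(x)
}
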