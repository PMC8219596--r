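# Exact random-variate generation for all model distributions and
# synthetic-participant generation.

# run expr with a locally seeded RNG, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop("'seed' must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Random first-passage times of the single-boundary diffusion process
#'
#' `rwald` draws exact Wald (inverse Gaussian) first-passage times with
#' threshold `alpha` and drift `xi` — mean `alpha/xi`, shape `alpha^2` —
#' using the Michael-Schucany-Haas transformation.  `rsw` shifts the draws
#' by the nondecision time `theta`.
#'
#' @param n number of draws.
#' @param alpha decision threshold, > 0.
#' @param xi drift rate, > 0 (the `xi = 0` Levy case has infinite mean and
#'   is not supported by the sampler).
#' @param theta shift in seconds, >= 0.
#' @param seed optional integer; when supplied the draws are generated from
#'   a locally seeded RNG and the caller's RNG state is untouched.
#' @return vector of `n` times, strictly greater than 0 (`rwald`) or
#'   `theta` (`rsw`).
#' @examples
#' mean(rwald(1e4, alpha = 2, xi = 4, seed = 1))  # ~ alpha/xi = 0.5
#' @export
rwald <- function(n, alpha, xi, seed = NULL) {
  if (!is.finite(alpha) || alpha <= 0) stop("'alpha' must be > 0")
  if (!is.finite(xi) || xi <= 0)
    stop("'xi' must be > 0 (sampling the Levy case is unsupported)")
  if (n < 1) stop("'n' must be >= 1")
  .with_seed(seed, .rwald_msh(n, alpha, xi))
}

# Michael-Schucany-Haas transform, vectorized over the drift; uses the
# current RNG stream
.rwald_msh <- function(n, alpha, xi) {
  m <- alpha / xi
  lambda <- alpha^2
  y <- rchisq(n, df = 1)
  x <- m + m^2 * y / (2 * lambda) -
    m / (2 * lambda) * sqrt(4 * m * lambda * y + m^2 * y^2)
  u <- runif(n)
  ifelse(u <= m / (m + x), x, m^2 / x)
}

#' @rdname rwald
#' @export
rsw <- function(n, alpha, theta = 0, xi, seed = NULL) {
  if (!is.finite(theta) || theta < 0) stop("'theta' must be >= 0")
  theta + rwald(n, alpha, xi, seed = seed)
}

#' Random zero-truncated normal drift rates
#'
#' Exact draws from the normal distribution with location `mu` and scale
#' `sigma` truncated to `[0, Inf)`.  When the truncation discards little
#' mass (`Phi(mu/sigma) > 0.05`) simple rejection from the untruncated
#' normal is used; otherwise a tail-safe inverse-CDF method that works in
#' the upper tail of the survival function, so draws remain accurate even
#' when `mu/sigma` is far below zero.
#'
#' @param n number of draws.
#' @param mu location.
#' @param sigma scale, > 0.
#' @param seed optional integer seed (see [rwald()]).
#' @return vector of `n` nonnegative drift rates.
#' @examples
#' range(rtnorm0(1e4, mu = -2, sigma = 1, seed = 1))
#' @export
rtnorm0 <- function(n, mu, sigma, seed = NULL) {
  if (!is.finite(sigma) || sigma <= 0) stop("'sigma' must be > 0")
  if (!is.finite(mu)) stop("'mu' must be finite")
  if (n < 1) stop("'n' must be >= 1")
  .with_seed(seed, {
    if (pnorm(mu / sigma) > 0.05) {
      out <- numeric(0)
      while (length(out) < n) {
        m <- ceiling((n - length(out)) / pnorm(mu / sigma)) + 10L
        z <- rnorm(m, mu, sigma)
        out <- c(out, z[z >= 0])
      }
      out[seq_len(n)]
    } else {
      # P(X > x) = u * P(X > 0), inverted through the survival function
      q0 <- pnorm(0, mu, sigma, lower.tail = FALSE)
      qnorm(runif(n) * q0, mu, sigma, lower.tail = FALSE)
    }
  })
}

#' Across-trial drift-rate law
#'
#' Constructor for the drift-mixture specification shared by the samplers,
#' densities, and fitting code: either a fixed drift (`"fixed"`), a
#' zero-truncated normal with location `mu` and scale `sqrt(sigma2)`
#' (`"tn"`), or a gamma with mean `mu` and variance `sigma2` (`"gam"`).
#'
#' @param family `"fixed"`, `"tn"`, or `"gam"`.
#' @param mu drift location/mean (fixed drift value for `"fixed"`).
#' @param sigma2 drift variance, > 0 for the mixing families; ignored for
#'   `"fixed"`.
#' @return object of class `drift_mixture`.
#' @examples
#' drift_mixture("tn", mu = 10, sigma2 = 1)
#' @export
drift_mixture <- function(family = c("fixed", "tn", "gam"), mu, sigma2 = 0) {
  family <- match.arg(family)
  if (!is.finite(mu)) stop("'mu' must be finite")
  if (family == "fixed") {
    if (mu < 0) stop("fixed drift must be >= 0")
    sigma2 <- 0
  } else {
    if (!is.finite(sigma2) || sigma2 <= 0)
      stop("'sigma2' must be > 0 for mixing families")
    if (family == "gam" && mu <= 0) stop("gamma drift mean must be > 0")
  }
  structure(list(family = family, mu = mu, sigma2 = sigma2),
            class = "drift_mixture")
}

#' @export
print.drift_mixture <- function(x, ...) {
  lab <- switch(x$family, fixed = "fixed drift",
                tn = "zero-truncated normal drift",
                gam = "gamma drift")
  cat(sprintf("%s: mu = %g, sigma2 = %g\n", lab, x$mu, x$sigma2))
  invisible(x)
}

# one drift draw per trial from the mixing law; zero draws (possible at
# floating-point level) are redrawn because the Wald sampler rejects xi = 0
.draw_drifts <- function(mixture, n) {
  xi <- switch(mixture$family,
               fixed = rep(mixture$mu, n),
               tn = rtnorm0(n, mixture$mu, sqrt(mixture$sigma2)),
               gam = {
                 gp <- gamma_from_moments(mixture$mu, mixture$sigma2)
                 rgamma(n, shape = gp$kappa, rate = gp$tau)
               })
  bad <- which(xi == 0 & mixture$family != "fixed")
  while (length(bad)) {
    xi[bad] <- .draw_drifts(mixture, length(bad))
    bad <- which(xi == 0)
  }
  xi
}

#' Generate one synthetic participant
#'
#' Per trial, draws a trial-level drift rate from the mixing law (or uses
#' the fixed drift) and then an RT from the shifted-Wald distribution with
#' that drift, so the marginal RT law is the corresponding mixture density.
#'
#' @param mixture a [drift_mixture()].
#' @param alpha decision threshold, > 0.
#' @param theta shift in seconds, >= 0.
#' @param n_trials number of trials, >= 1.
#' @param seed optional integer seed; the participant is fully reproducible
#'   given it.
#' @param id participant label.
#' @return object of class `sw_participant`: list with `id`, `mixture`,
#'   `alpha`, `theta`, `n_trials`, `seed`, and the RT vector `rts` (seconds,
#'   all `> theta`).
#' @examples
#' p <- simulate_participant(drift_mixture("tn", 10, 1), alpha = 1,
#'                           theta = 0.13, n_trials = 5, seed = 1)
#' p$rts
#' @export
simulate_participant <- function(mixture, alpha, theta, n_trials,
                                 seed = NULL, id = "p1") {
  stopifnot(inherits(mixture, "drift_mixture"))
  if (n_trials < 1) stop("'n_trials' must be >= 1")
  .check_sw_params(alpha, theta)
  rts <- .with_seed(seed, {
    xi <- .draw_drifts(mixture, n_trials)
    theta + .rwald_msh(n_trials, alpha, xi)
  })
  structure(list(id = as.character(id), mixture = mixture, alpha = alpha,
                 theta = theta, n_trials = as.integer(n_trials),
                 seed = seed, rts = rts),
            class = "sw_participant")
}

#' @export
print.sw_participant <- function(x, ...) {
  cat(sprintf("synthetic participant '%s': %d trials, alpha=%g, theta=%g, %s\n",
              x$id, x$n_trials, x$alpha, x$theta,
              sprintf("%s drift (mu=%g, sigma2=%g)", x$mixture$family,
                      x$mixture$mu, x$mixture$sigma2)))
  invisible(x)
}

# Deterministic per-participant seed spawning: participant i receives the
# (i+1)-th state of a minimal-standard Lehmer generator (multiplier 16807,
# modulus 2^31 - 1) started at the master seed.  All quantities stay below
# 2^53 so the arithmetic is exact in doubles, making datasets citable by
# (master_seed, i).
.spawn_seed <- function(master_seed, i) {
  s <- (abs(as.double(master_seed)) %% 2147483646) + 1
  for (k in seq_len(i + 1L)) s <- (16807 * s) %% 2147483647
  as.integer(s)
}

#' Generate a synthetic dataset of independent participants
#'
#' Applies [simulate_participant()] to each row of a generating-parameter
#' table.  Each participant's seed is spawned deterministically from
#' `master_seed` and the participant index (see [simulate_participant()]
#' `seed` fields for the values used), so the same `master_seed` always
#' yields the identical dataset while participants remain statistically
#' independent.
#'
#' @param params data frame with columns `family` (`"fixed"`, `"tn"`,
#'   `"gam"`), `alpha`, `theta`, `mu_xi`, `sigma2_xi`, and optionally `id`.
#' @param n_trials trials per participant.
#' @param master_seed integer master seed.
#' @return object of class `sw_dataset`: list of `sw_participant`s with the
#'   generating table attached as attribute `"params"`.
#' @seealso [default_recovery_params()] for the shipped generating table,
#'   [write_rt_table()] to serialize.
#' @examples
#' tab <- data.frame(family = "tn", alpha = 1, theta = 0.13,
#'                   mu_xi = 10, sigma2_xi = 1)
#' simulate_dataset(tab, n_trials = 10, master_seed = 7)
#' @export
simulate_dataset <- function(params, n_trials, master_seed) {
  stopifnot(is.data.frame(params), nrow(params) >= 1)
  need <- c("family", "alpha", "theta", "mu_xi", "sigma2_xi")
  if (!all(need %in% names(params)))
    stop("'params' must have columns ", paste(need, collapse = ", "))
  ids <- if ("id" %in% names(params)) as.character(params$id)
         else sprintf("p%02d", seq_len(nrow(params)))
  out <- lapply(seq_len(nrow(params)), function(i) {
    mix <- drift_mixture(params$family[i], mu = params$mu_xi[i],
                         sigma2 = params$sigma2_xi[i])
    simulate_participant(mix, alpha = params$alpha[i],
                         theta = params$theta[i], n_trials = n_trials,
                         seed = .spawn_seed(master_seed, i), id = ids[i])
  })
  structure(out, class = "sw_dataset", params = params,
            master_seed = master_seed, n_trials = n_trials)
}

#' @export
print.sw_dataset <- function(x, ...) {
  cat(sprintf("synthetic dataset: %d participants x %d trials (master seed %s)\n",
              length(x), attr(x, "n_trials"),
              format(attr(x, "master_seed"))))
  invisible(x)
}

#' @export
as.data.frame.sw_dataset <- function(x, ...) {
  do.call(rbind, lapply(x, function(p)
    data.frame(participant = p$id, trial = seq_len(p$n_trials),
               rt = p$rts, stringsAsFactors = FALSE)))
}
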