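# Parameter-recovery studies: generate synthetic participants with known
# parameters, fit the matched family, and compare generating values with
# posterior modes.

#' Default generating-parameter table for recovery studies
#'
#' Thirty synthetic-participant parameter sets spanning threshold
#' `alpha` 0.6-1.8, shift `theta` 0.08-0.20 s, drift mean `mu_xi` 5-15 and
#' drift variance `sigma2_xi` 0.2-3 — ranges centred on values typical of
#' simple RT tasks (threshold near 1, shift near 0.13 s, drift mean near
#' 10).  The table is a fixed fixture shipped with the package
#' (`inst/extdata/recovery_params.csv`); the four columns are deliberately
#' scrambled against each other so no two parameters are collinear across
#' participants.
#'
#' @param n number of rows to return (`<= 30`); for `n < 30`, rows are
#'   picked at evenly spaced positions so the parameter ranges stay covered.
#' @return data frame with columns `id`, `alpha`, `theta`, `mu_xi`,
#'   `sigma2_xi`.
#' @export
default_recovery_params <- function(n = 30) {
  path <- system.file("extdata", "recovery_params.csv", package = "waldmix")
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (n > nrow(tab)) stop("at most ", nrow(tab), " rows available")
  tab[round(seq(1, nrow(tab), length.out = n)), , drop = FALSE]
}

#' Select participants at the quantiles of the mean-RT distribution
#'
#' Picks `n_select` participants whose mean RTs are nearest the evenly
#' spaced quantile levels `k/(n_select + 1)`, `k = 1..n_select`, of the
#' mean-RT distribution (linear-interpolation quantiles).  Levels are
#' processed in increasing order and each participant can be chosen only
#' once; ties are broken toward the lowest index.  This reproduces the
#' "representative spread of task performance" selection used to pick
#' generating values for recovery studies.
#'
#' @param rt_means per-participant mean RTs.
#' @param n_select how many participants to select.
#' @return integer vector of selected indices into `rt_means` (one per
#'   quantile level, in level order).
#' @examples
#' representative_params(seq(0.2, 0.8, length.out = 100), n_select = 2)
#' @export
representative_params <- function(rt_means, n_select = 30) {
  if (length(rt_means) == 0) stop("'rt_means' must be nonempty")
  if (n_select > length(rt_means))
    stop("'n_select' exceeds the number of participants")
  lv <- seq_len(n_select) / (n_select + 1)
  qs <- quantile(rt_means, lv, names = FALSE, type = 7)
  chosen <- integer(0)
  for (q in qs) {
    d <- abs(rt_means - q)
    d[chosen] <- Inf
    chosen <- c(chosen, which.min(d))  # which.min takes the lowest index on ties
  }
  chosen
}

#' Specify a parameter-recovery study
#'
#' Bundles everything one recovery run needs: the generating family, the
#' per-participant generating values, the trial count, whether the
#' restricted (drift variance fixed to zero) model is fit, and the master
#' seed from which all per-participant seeds are spawned.
#'
#' @param family generating and fitting family, `"tn"` or `"gam"`.
#' @param n_participants number of synthetic participants.
#' @param n_trials trials per participant (the canonical designs use 120 or
#'   1200).
#' @param fix_sigma2 fit the restricted model.
#' @param master_seed integer master seed.
#' @param params generating-parameter table; defaults to
#'   [default_recovery_params()] subsampled to `n_participants`.
#' @return object of class `recovery_design`.
#' @export
recovery_design <- function(family = c("tn", "gam"), n_participants = 30,
                            n_trials = 120, fix_sigma2 = FALSE,
                            master_seed = 1,
                            params = default_recovery_params(n_participants)) {
  family <- match.arg(family)
  stopifnot(nrow(params) == n_participants)
  params$family <- family
  structure(list(family = family, n_participants = n_participants,
                 n_trials = n_trials, fix_sigma2 = fix_sigma2,
                 master_seed = master_seed, params = params),
            class = "recovery_design")
}

#' @export
print.recovery_design <- function(x, ...) {
  cat(sprintf("recovery design: SW-%s, %d participants x %d trials, %s, master seed %s\n",
              toupper(x$family), x$n_participants, x$n_trials,
              if (x$fix_sigma2) "drift variance fixed to 0" else "free drift variance",
              format(x$master_seed)))
  invisible(x)
}

#' Run a parameter-recovery study
#'
#' Generates the synthetic dataset from the design, fits each participant
#' with the matched family via [swfit()] (recovery protocol: `draws`
#' retained draws per chain after `burn_in` burn-in, extensions until all
#' R-hat values fall below 1.05), and tabulates generating values against
#' posterior modes and interquartile ranges.  A participant that hits the
#' extension cap is recorded as non-converged and excluded with a warning,
#' not a crash.
#'
#' @param design a [recovery_design()].
#' @param chains,draws,burn_in MCMC protocol (defaults: 3 chains, 2000
#'   retained draws after 1000 burn-in).
#' @param max_extensions extension cap per participant.
#' @param verbose print per-participant progress lines.
#' @return object of class `recovery_result`: data frame `table` with one
#'   row per participant and parameter (columns `participant`, `parameter`,
#'   `generating`, `mode`, `q25`, `q75`, `rhat`, `extensions`,
#'   `converged`), plus the design and the dataset.
#' @export
run_recovery <- function(design, chains = 3, draws = 2000, burn_in = 1000,
                         max_extensions = 10, verbose = FALSE) {
  stopifnot(inherits(design, "recovery_design"))
  dat <- simulate_dataset(design$params, design$n_trials,
                          design$master_seed)
  par_names <- .par_names(design$fix_sigma2)
  rows <- list()
  for (i in seq_along(dat)) {
    p <- dat[[i]]
    fit <- tryCatch(
      swfit(p$rts, family = design$family, fix_sigma2 = design$fix_sigma2,
            chains = chains, draws = draws, burn_in = burn_in,
            max_extensions = max_extensions,
            seed = .spawn_seed(design$master_seed + 1, i)),
      waldmix_convergence_error = function(e) e)
    failed <- inherits(fit, "waldmix_convergence_error")
    if (failed)
      warning("participant ", p$id, " did not converge and is excluded: ",
              conditionMessage(fit), call. = FALSE)
    gen <- c(alpha = p$alpha, theta = p$theta, mu_xi = p$mixture$mu,
             sigma2_xi = p$mixture$sigma2)
    for (nm in par_names) {
      rows[[length(rows) + 1L]] <- data.frame(
        participant = p$id, parameter = nm,
        generating = unname(gen[nm]),
        mode = if (failed) NA_real_ else unname(fit$summary[nm, "mode"]),
        q25 = if (failed) NA_real_ else unname(fit$summary[nm, "q25"]),
        q75 = if (failed) NA_real_ else unname(fit$summary[nm, "q75"]),
        rhat = if (failed) max(fit$report$rhat) else
          unname(fit$summary[nm, "rhat"]),
        extensions = if (failed) fit$report$extensions else
          fit$report$extensions,
        converged = !failed, stringsAsFactors = FALSE)
    }
    if (verbose)
      message(sprintf("participant %s: %s (extensions %d)", p$id,
                      if (failed) "NOT converged" else "converged",
                      if (failed) fit$report$extensions else
                        fit$report$extensions))
  }
  structure(list(table = do.call(rbind, rows), design = design,
                 dataset = dat),
            class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  print(x$design)
  cat(sprintf("%d/%d participants converged\n",
              sum(x$table$converged[!duplicated(x$table$participant)]),
              x$design$n_participants))
  print(summarize_recovery(x))
  invisible(x)
}

#' Summarize a recovery study
#'
#' Per parameter: the Pearson correlation between generating values and
#' posterior modes, the mean signed error (mode minus generating value), and
#' the mean width of the posterior interquartile range — the numerical twin
#' of the recovery scatter plots.  Non-converged participants are excluded.
#' A correlation that is undefined (constant modes or a single participant)
#' is reported as `NA`.  When a second, restricted-model result on the same
#' dataset is supplied, the free-vs-fixed comparison is appended: the share
#' of participants whose drift-mean mode is lower under the restricted fit
#' than under the free fit, and lower than the generating value.
#'
#' @param result a `recovery_result` (free-variance fit).
#' @param fixed_result optional `recovery_result` from the matching
#'   `fix_sigma2 = TRUE` design on the same dataset.
#' @return data frame of per-parameter summaries, with the comparison (if
#'   any) attached as attribute `"fixed_comparison"`.
#' @export
summarize_recovery <- function(result, fixed_result = NULL) {
  stopifnot(inherits(result, "recovery_result"))
  tab <- result$table[result$table$converged, ]
  out <- do.call(rbind, lapply(split(tab, tab$parameter), function(d) {
    r <- if (nrow(d) < 2 || sd(d$mode) == 0 || sd(d$generating) == 0)
      NA_real_ else cor(d$generating, d$mode)
    data.frame(parameter = d$parameter[1], n = nrow(d), correlation = r,
               mean_signed_error = mean(d$mode - d$generating),
               mean_iqr_width = mean(d$q75 - d$q25),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (!is.null(fixed_result)) {
    stopifnot(inherits(fixed_result, "recovery_result"))
    free_mu <- result$table[result$table$parameter == "mu_xi" &
                              result$table$converged, ]
    fix_mu <- fixed_result$table[fixed_result$table$parameter == "mu_xi" &
                                   fixed_result$table$converged, ]
    common <- intersect(free_mu$participant, fix_mu$participant)
    f1 <- free_mu[match(common, free_mu$participant), ]
    f2 <- fix_mu[match(common, fix_mu$participant), ]
    attr(out, "fixed_comparison") <- list(
      n = length(common),
      prop_below_free = mean(f2$mode < f1$mode),
      prop_below_generating = mean(f2$mode < f2$generating))
  }
  out
}

#' Write a recovery table as tidy delimited text
#'
#' @param result a `recovery_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_recovery <- function(result, path) {
  stopifnot(inherits(result, "recovery_result"))
  write.csv(result$table, path, row.names = FALSE)
  invisible(path)
}
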