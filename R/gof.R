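# Data ingestion with the standard RT exclusion filter, and quantile-based
# goodness-of-fit.

#' Read trial-level reaction times from delimited text
#'
#' Parses a CSV or TSV file with header columns `participant`, `trial`,
#' `rt` (additional columns are ignored).  Millisecond input is converted
#' to seconds when `unit = "ms"`.  Within-participant trial order is
#' preserved as it appears in the file.
#'
#' @param path file path.
#' @param unit `"s"` (default) or `"ms"`.
#' @return named list of numeric RT vectors (seconds), one per participant,
#'   in order of first appearance.
#' @export
read_rt_table <- function(path, unit = c("s", "ms")) {
  unit <- match.arg(unit)
  sep <- if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
  tab <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  colClasses = "character")
  need <- c("participant", "trial", "rt")
  if (!all(need %in% names(tab)))
    stop("input must have header columns ", paste(need, collapse = ", "))
  rt_chr <- trimws(tab$rt)
  bad <- which(is.na(rt_chr) | rt_chr == "")
  if (length(bad))
    stop("missing rt value at data row ", bad[1])
  rt <- suppressWarnings(as.numeric(rt_chr))
  bad <- which(is.na(rt))
  if (length(bad))
    stop("non-numeric rt value '", rt_chr[bad[1]], "' at data row ", bad[1])
  bad <- which(rt < 0)
  if (length(bad))
    stop("negative rt value at data row ", bad[1])
  if (unit == "ms") rt <- rt / 1000
  ids <- as.character(tab$participant)
  lapply(split(rt, factor(ids, levels = unique(ids))), as.numeric)
}

#' Write a synthetic dataset as delimited text
#'
#' Serializes an [simulate_dataset()] result (or any list of RT vectors) to
#' the same `participant,trial,rt` CSV format that [read_rt_table()] reads,
#' with 15 significant digits so a write-read round trip is lossless.  For
#' an `sw_dataset`, a JSON sidecar of the generating parameters is written
#' next to the table when `params_path` is given.
#'
#' @param x an `sw_dataset`, or a named list of numeric RT vectors.
#' @param path output CSV path.
#' @param params_path optional path for the JSON sidecar with the
#'   generating-parameter table and master seed.
#' @return `path`, invisibly.
#' @export
write_rt_table <- function(x, path, params_path = NULL) {
  tab <- if (inherits(x, "sw_dataset")) as.data.frame(x)
  else do.call(rbind, lapply(names(x), function(id)
    data.frame(participant = id, trial = seq_along(x[[id]]), rt = x[[id]],
               stringsAsFactors = FALSE)))
  tab$rt <- formatC(tab$rt, digits = 15, format = "g")
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  if (!is.null(params_path)) {
    if (!inherits(x, "sw_dataset"))
      stop("'params_path' requires an sw_dataset")
    jsonlite::write_json(
      list(master_seed = attr(x, "master_seed"),
           n_trials = attr(x, "n_trials"),
           params = attr(x, "params"),
           seeds = vapply(x, `[[`, integer(1), "seed")),
      params_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Exclude implausibly fast and slow reaction times
#'
#' Retains RTs within `[lower, upper]`; the canonical screen for simple RT
#' tasks drops RTs below 110 ms or above 1000 ms.  The comparison is
#' strict, so values exactly at a boundary are retained.  Filtering twice
#' with the same bounds is a no-op.
#'
#' @param rts numeric vector of RTs in seconds.
#' @param lower,upper retention bounds in seconds.
#' @return the retained RTs, with the number of excluded trials attached as
#'   attribute `"n_excluded"`.  An error is raised if nothing survives (the
#'   participant is unfittable).
#' @examples
#' filter_rts(c(0.100, 0.500, 1.100))  # keeps only 0.500
#' @export
filter_rts <- function(rts, lower = 0.110, upper = 1.000) {
  if (!is.numeric(rts)) stop("'rts' must be numeric")
  keep <- !(rts < lower | rts > upper)
  out <- as.numeric(rts[keep])
  if (!length(out))
    stop("no RTs remain after filtering; participant is unfittable")
  structure(out, n_excluded = sum(!keep))
}

#' Empirical RT quantiles
#'
#' Quantiles under the linear-interpolation convention (type 7), by default
#' at the five canonical levels .1, .3, .5, .7, .9 used for quantile
#' goodness-of-fit.
#'
#' @param rts numeric vector of RTs.
#' @param levels quantile levels in (0, 1).
#' @return named vector of quantiles, nondecreasing in level.
#' @examples
#' observed_quantiles(1:9, levels = 0.5)
#' @export
observed_quantiles <- function(rts, levels = c(.1, .3, .5, .7, .9)) {
  if (!length(rts)) stop("'rts' must be nonempty")
  setNames(quantile(rts, levels, names = FALSE, type = 7),
           sprintf("q%g", levels * 100))
}

#' Model-predicted RT quantiles at the posterior modes
#'
#' Generates `n` RTs from the fitted family at the posterior-mode
#' parameters (via [simulate_participant()]) and returns their empirical
#' quantiles — the parametric prediction convention for quantile
#' goodness-of-fit.  The default `n = 120` mirrors a typical session
#' length, so predictions carry the same sampling noise as an observed
#' session; increase `reps` to average several replicate samples for
#' smoother predictions.
#'
#' @param modes named vector with `alpha`, `theta`, `mu_xi` and (unless
#'   `family = "fixed"`) `sigma2_xi`; typically `coef(fit)`.
#' @param family `"tn"`, `"gam"`, or `"fixed"` (plain shifted-Wald).
#' @param n simulated RTs per replicate.
#' @param levels quantile levels.
#' @param seed optional integer seed.
#' @param reps number of replicate samples averaged.
#' @return named vector of predicted quantiles.
#' @export
predicted_quantiles <- function(modes, family = c("tn", "gam", "fixed"),
                                n = 120, levels = c(.1, .3, .5, .7, .9),
                                seed = NULL, reps = 1) {
  family <- match.arg(family)
  mix <- if (family == "fixed") drift_mixture("fixed", mu = modes[["mu_xi"]])
  else drift_mixture(family, mu = modes[["mu_xi"]],
                     sigma2 = modes[["sigma2_xi"]])
  qs <- .with_seed(seed, vapply(seq_len(reps), function(r) {
    rt <- simulate_participant(mix, alpha = modes[["alpha"]],
                               theta = modes[["theta"]], n_trials = n)$rts
    observed_quantiles(rt, levels)
  }, numeric(length(levels))))
  rowMeans(matrix(qs, nrow = length(levels),
                  dimnames = list(sprintf("q%g", levels * 100), NULL)))
}

#' Quantile goodness-of-fit report
#'
#' For each participant, pairs the observed RT quantiles with the
#' model-predicted quantiles obtained by simulating `n_pred` RTs at that
#' participant's posterior modes, and computes the observed-vs-predicted
#' correlation across participants at each quantile level.
#'
#' @param data named list of RT vectors (seconds), e.g. from
#'   [read_rt_table()] or `lapply` over an `sw_dataset`.
#' @param fits list of `swfit` objects (or named mode vectors), parallel to
#'   `data`.
#' @param family mixture family used for prediction; defaults to the family
#'   of the first fit.
#' @param levels quantile levels.
#' @param n_pred simulated RTs behind each prediction (stored in the
#'   report).
#' @param seed integer seed for the predictive simulations.
#' @param reps replicate predictive samples averaged per participant.
#' @return object of class `sw_gof`: data frame `table` (participant,
#'   level, observed, predicted), per-level correlations `correlations`,
#'   and `n_pred`.
#' @export
gof_report <- function(data, fits, family = NULL,
                       levels = c(.1, .3, .5, .7, .9), n_pred = 120,
                       seed = NULL, reps = 1) {
  stopifnot(length(data) == length(fits), length(data) >= 1)
  ids <- names(data) %||% sprintf("p%02d", seq_along(data))
  rows <- .with_seed(seed, lapply(seq_along(data), function(i) {
    f <- fits[[i]]
    if (inherits(f, "swfit")) {
      modes <- coef(f)
      fam <- if (f$fix_sigma2) "fixed" else f$family
    } else {
      modes <- f
      fam <- family %||% stop("'family' is required for raw mode vectors")
    }
    obs <- observed_quantiles(data[[i]], levels)
    pred <- predicted_quantiles(modes, fam, n = n_pred, levels = levels,
                                reps = reps)
    data.frame(participant = ids[i], level = levels, observed = obs,
               predicted = pred, row.names = NULL,
               stringsAsFactors = FALSE)
  }))
  tab <- do.call(rbind, rows)
  cors <- vapply(levels, function(lv) {
    d <- tab[tab$level == lv, ]
    if (nrow(d) < 2) NA_real_ else cor(d$observed, d$predicted)
  }, numeric(1))
  structure(list(table = tab,
                 correlations = setNames(cors, sprintf("q%g", levels * 100)),
                 n_pred = n_pred),
            class = "sw_gof")
}

#' @export
print.sw_gof <- function(x, ...) {
  cat(sprintf("quantile goodness-of-fit: %d participants, %d predicted RTs each\n",
              length(unique(x$table$participant)), x$n_pred))
  cat("observed-vs-predicted correlation per quantile level:\n")
  print(round(x$correlations, 4))
  invisible(x)
}
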