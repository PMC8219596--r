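test_that("RT tables read correctly in both units and orders are preserved", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("participant,trial,rt", "a,1,0.5", "a,2,0.31", "a,3,0.42",
               "b,1,0.6", "b,2,0.55", "b,3,0.7"), f)
  d <- read_rt_table(f)
  expect_named(d, c("a", "b"))
  expect_equal(d$a, c(0.5, 0.31, 0.42))
  # millisecond input is converted to seconds
  writeLines(c("participant,trial,rt", "a,1,500"), f)
  expect_equal(read_rt_table(f, unit = "ms")$a, 0.5)
  # malformed rows are reported by position
  writeLines(c("participant,trial,rt", "a,1,0.5", "a,2,"), f)
  expect_error(read_rt_table(f), "row 2")
  writeLines(c("participant,trial,rt", "a,1,oops"), f)
  expect_error(read_rt_table(f), "non-numeric")
  writeLines(c("participant,trial,rt", "a,1,-0.2"), f)
  expect_error(read_rt_table(f), "negative")
})

test_that("write-read round trip is lossless at 15 significant digits", {
  tab <- default_recovery_params(2)
  tab$family <- "tn"
  ds <- simulate_dataset(tab, n_trials = 25, master_seed = 3)
  f <- tempfile(fileext = ".csv"); fp <- tempfile(fileext = ".json")
  write_rt_table(ds, f, params_path = fp)
  back <- read_rt_table(f)
  for (p in ds) expect_equal(back[[p$id]], p$rts, tolerance = 1e-14)
  side <- jsonlite::read_json(fp, simplifyVector = TRUE)
  expect_equal(side$master_seed, 3)
  expect_equal(side$params$alpha, tab$alpha)
})

test_that("the RT exclusion filter keeps the closed interval and is idempotent", {
  out <- filter_rts(c(0.100, 0.500, 1.100))
  expect_equal(as.numeric(out), 0.5)
  expect_equal(attr(out, "n_excluded"), 2L)
  # boundary values are retained under the strict-inequality reading
  expect_equal(as.numeric(filter_rts(c(0.110, 1.000))), c(0.110, 1.000))
  once <- filter_rts(runif(50, 0, 1.2))
  twice <- filter_rts(as.numeric(once))
  expect_equal(as.numeric(twice), as.numeric(once))
  expect_equal(attr(twice, "n_excluded"), 0L)
  expect_error(filter_rts(c(0.05, 1.5)), "unfittable")
})

test_that("empirical quantiles follow the linear-interpolation convention", {
  expect_equal(unname(observed_quantiles(1:9, levels = 0.5)), 5)
  expect_equal(unname(observed_quantiles(1:10, levels = 0.1)), 1.9)
  expect_equal(unname(observed_quantiles(rep(2, 7))), rep(2, 5))
  q <- observed_quantiles(rexp(100))
  expect_true(all(diff(q) >= 0))
})

test_that("predicted quantiles are reproducible and honour the family", {
  modes <- c(alpha = 1, theta = 0.13, mu_xi = 10, sigma2_xi = 1)
  q1 <- predicted_quantiles(modes, "tn", seed = 71)
  q2 <- predicted_quantiles(modes, "tn", seed = 71)
  expect_identical(q1, q2)
  expect_true(all(diff(q1) >= 0))
  # the fixed family reduces to a plain SW sample
  q3 <- predicted_quantiles(modes[1:3], "fixed", n = 500, seed = 72)
  rtref <- simulate_participant(drift_mixture("fixed", 10), 1, 0.13,
                                n_trials = 500, seed = 72)$rts
  expect_equal(unname(q3), unname(observed_quantiles(rtref)))
  # replicate averaging smooths but keeps the location
  q4 <- predicted_quantiles(modes, "tn", seed = 73, reps = 20)
  expect_lt(max(abs(q4 - q1)), 0.2)
})

test_that("the goodness-of-fit report pairs observed and predicted quantiles", {
  modes <- c(alpha = 1, theta = 0.13, mu_xi = 10, sigma2_xi = 1)
  rts <- simulate_participant(drift_mixture("tn", 10, 1), 1, 0.13,
                              n_trials = 400, seed = 74)$rts
  rep1 <- gof_report(list(p1 = rts), list(modes), family = "tn", seed = 75)
  expect_s3_class(rep1, "sw_gof")
  expect_equal(nrow(rep1$table), 5)
  expect_equal(rep1$n_pred, 120)
  expect_true(all(diff(rep1$table$observed) >= 0))
  expect_true(all(diff(rep1$table$predicted) >= 0))
  # single participant: per-level correlation is undefined
  expect_true(all(is.na(rep1$correlations)))
})
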