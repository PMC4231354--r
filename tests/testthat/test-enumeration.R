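# Semi-quantitative enumeration and survey summaries.

test_that("log-count estimation follows the last-positive-dilution rule", {
  s <- dilution_series("a", "A", "t", 0:6,
                       c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  e <- estimate_log_count(s)
  expect_equal(e$log_count, 4)
  expect_true(e$detected)

  all_neg <- estimate_log_count(
    dilution_series("b", "A", "t", 0:6, rep(FALSE, 7)))
  expect_equal(all_neg$log_count, 0)
  expect_false(all_neg$detected)

  # detection at d = 0 only: count 0 but detected, the two are decoupled
  d0 <- estimate_log_count(
    dilution_series("c", "A", "t", 0:6, c(TRUE, rep(FALSE, 6))))
  expect_equal(d0$log_count, 0)
  expect_true(d0$detected)

  # non-monotone series resolves to the highest positive, flagged
  nm <- estimate_log_count(
    dilution_series("d", "A", "t", 0:6,
                    c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)))
  expect_equal(nm$log_count, 2)
  expect_match(nm$flags, "non-monotone")

  expect_error(dilution_series("e", "A", "t", integer(0), logical(0)),
               class = "invalid_input")
  expect_error(dilution_series("e", "A", "t", c(0, 0), c(TRUE, TRUE)),
               class = "invalid_input")
})

test_that("making any tube positive never decreases the estimate", {
  set.seed(21)
  for (i in 1:20) {
    pos <- stats::runif(7) < 0.4
    base <- estimate_log_count(dilution_series("s", "A", "t", 0:6, pos))
    j <- sample(which(!pos), 1)
    if (!length(j)) next
    pos2 <- pos; pos2[j] <- TRUE
    up <- estimate_log_count(dilution_series("s", "A", "t", 0:6, pos2))
    expect_gte(up$log_count, base$log_count)
  }
})

test_that("group summaries reproduce the retail-cheese worked examples", {
  # St Marcellin: counts 4, 4, 5, 5 in the positives, one non-detection
  sm <- summarize_survey(estimates_from_counts(c(4, 4, 5, 5, 0)))
  expect_equal(sm$n_positive, 4)
  expect_equal(sm$n, 5)
  expect_equal(round(sm$mean_log, 2), 3.6)
  expect_equal(round(sm$sd_log, 2), 2.07)

  # Picodon 7, plus 5, 5, 6, and one non-detection
  pc <- summarize_survey(estimates_from_counts(c(7, 5, 5, 6, 0)))
  expect_equal(round(pc$mean_log, 2), 4.6)
  expect_equal(round(pc$sd_log, 2), 2.70)

  # all-zero group
  z <- summarize_survey(estimates_from_counts(c(0, 0, 0)))
  expect_equal(z$n_positive, 0)
  expect_equal(z$mean_log, 0)
  expect_equal(z$sd_log, 0)
  expect_equal(z$percent_positive, 0)

  # single-sample cell reports SD 0
  one <- summarize_survey(estimates_from_counts(4))
  expect_equal(one$sd_log, 0)
})

test_that("percentages round half-up as printed", {
  pct <- function(k, n) summarize_survey(
    estimates_from_counts(c(rep(3, k), rep(0, n - k))))$percent_positive
  expect_equal(pct(36, 44), 82)
  expect_equal(pct(34, 44), 77)
  expect_equal(pct(4, 44), 9)
  expect_equal(pct(13, 44), 30)   # 29.54..., and 13/44 prints as 30
  expect_equal(pct(10, 44), 23)
  expect_equal(pct(7, 44), 16)
  expect_equal(pct(1, 44), 2)
  expect_equal(pct(11, 40), 28)   # 27.5: half rounds up, not to even
})

test_that("formatted survey rows carry integer percents and 2-decimal counts", {
  tab <- survey_table(summarize_survey(estimates_from_counts(c(4, 4, 5, 5, 0))))
  expect_identical(tab$positives, "4/5 (80%)")
  expect_identical(tab$mean_count, "3.60 ± 2.07")
})

test_that("simulated surveys recover planted prevalence and counts", {
  # degenerate corners are exact
  fixed <- simulate_survey(prevalence = c(A = 1), n = 20,
                           count_sampler = function(k) rep(4L, k), seed = 1)
  est <- lapply(fixed, estimate_log_count)
  expect_true(all(vapply(est, `[[`, 0, "log_count") == 4))

  none <- simulate_survey(prevalence = c(A = 0), n = 20, seed = 1)
  s0 <- summarize_survey(lapply(none, estimate_log_count))
  expect_equal(s0$n_positive, 0)
  expect_equal(s0$mean_log, 0)

  # moderate prevalence lands inside the binomial 95% band
  sim <- simulate_survey(prevalence = c(A = 0.77), n = 44, seed = 99)
  sm <- summarize_survey(lapply(sim, estimate_log_count))
  expect_gte(sm$n_positive, qbinom(0.025, 44, 0.77))
  expect_lte(sm$n_positive, qbinom(0.975, 44, 0.77))
  # estimated counts equal the planted truth sample by sample
  truth <- attr(sim, "truth")
  est <- vapply(lapply(sim, estimate_log_count), `[[`, 0, "log_count")
  expect_equal(est, as.numeric(truth$true_log))
})

test_that("dilution CSV round-trips losslessly", {
  sim <- simulate_survey(prevalence = c(A = 0.5, B = 0.9), n = 6, seed = 3)
  path <- tempfile(fileext = ".csv")
  write_dilution_csv(sim, path)
  back <- read_dilution_csv(path)
  expect_equal(length(back), length(sim))
  for (i in seq_along(sim)) {
    expect_identical(back[[i]]$positive, sim[[i]]$positive)
    expect_identical(back[[i]]$sample_id, sim[[i]]$sample_id)
  }
  unlink(path)
})
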