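test_that("raw two-sample t tests match the expected arithmetic", {
  res <- ttest_raw(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)

  res <- ttest_raw(c(1, 2, 3), c(4, 5, 6), "pooled")
  expect_equal(res$t, -3.674235, tolerance = 1e-6)
  expect_equal(res$df, 4)
  expect_equal(res$p, 0.02131164, tolerance = 1e-6)

  # equal n and equal sd: pooled and welch coincide exactly
  welch <- ttest_raw(c(1, 2, 3), c(4, 5, 6), "welch")
  expect_equal(welch$t, res$t)
  expect_equal(welch$df, res$df)
  expect_equal(welch$p, res$p)

  expect_error(ttest_raw(1, c(1, 2)), "n >= 2")
  expect_equal(ttest_raw(c(2, 2, 2), c(2, 2))$p, 1)
  expect_error(ttest_raw(c(2, 2, 2), c(3, 3)), "zero variance")
})

test_that("summary-statistic tests agree with raw tests to 1e-10", {
  withr::local_seed(88)
  for (i in 1:25) {
    x <- rnorm(sample(2:9, 1), mean = runif(1, -5, 5), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(2:9, 1), mean = runif(1, -5, 5), sd = runif(1, 0.5, 3))
    for (method in c("pooled", "welch")) {
      raw <- ttest_raw(x, y, method)
      summ <- ttest_from_summary(
        group_summary(mean(x), sd(x), length(x)),
        group_summary(mean(y), sd(y), length(y)), method)
      expect_equal(summ$t, raw$t, tolerance = 1e-10)
      expect_equal(summ$df, raw$df, tolerance = 1e-10)
      expect_equal(summ$p, raw$p, tolerance = 1e-10)
    }
  }
})

test_that("swapping groups flips t and leaves the two-sided p unchanged", {
  a <- group_summary(10, 2, 5)
  b <- group_summary(7, 3, 4)
  for (method in c("pooled", "welch")) {
    ab <- ttest_from_summary(a, b, method)
    ba <- ttest_from_summary(b, a, method)
    expect_equal(ab$t, -ba$t)
    expect_equal(ab$p, ba$p)
  }
})

test_that("the published index-step contrasts are reproduced from summaries", {
  # colpotomy vs vaginal cuff closure, duration of the step
  dur <- ttest_from_summary(group_summary(281.1, 83.7, 6),
                            group_summary(677.5, 81.0, 6), "pooled")
  expect_lt(dur$p, 0.001)
  expect_equal(dur$df, 10)
  # colpotomy vs cuff closure, energy activation events
  energy <- ttest_from_summary(group_summary(38.2, 11.3, 6),
                               group_summary(6.3, 3.1, 6), "pooled")
  expect_lt(energy$p, 0.001)
  # surgeon A vs B, camera movement during colpotomy: p rounds to 0.03
  camera <- ttest_from_summary(group_summary(35.3, 7.6, 3),
                               group_summary(18.3, 5.3, 3), "pooled")
  expect_equal(round(camera$p, 2), 0.03)
  expect_equal(camera$df, 4)
  # equal summaries give the null result
  same <- ttest_from_summary(group_summary(5, 1, 3), group_summary(5, 1, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("discordant published p-values are flagged, concordant ones pass", {
  # reproducible: camera movement during colpotomy, published p = 0.03
  ok <- check_printed_p(group_summary(35.3, 7.6, 3),
                        group_summary(18.3, 5.3, 3), 0.03)
  expect_true(ok$concordant)

  # five published p-values that do not follow from their own summaries
  # under either the pooled or the Welch two-sided test
  discordant <- list(
    list(a = c(7.3, 3.1, 3), b = c(2.7, 0.5, 3), p = 0.051),   # clutch, colpotomy
    list(a = c(21.7, 15.1, 3), b = c(14.7, 5.3, 3), p = 0.28), # camera, cuff
    list(a = c(9.0, 0.8, 3), b = c(6.3, 4.9, 3), p = 0.25),    # clutch, cuff
    list(a = c(35.3, 9.3, 3), b = c(41.0, 12.3, 3), p = 0.09), # energy, colpotomy
    list(a = c(4.3, 2.4, 3), b = c(8.3, 2.5, 3), p = 0.32)     # energy, cuff
  )
  for (case in discordant) {
    chk <- check_printed_p(group_summary(case$a[1], case$a[2], case$a[3]),
                           group_summary(case$b[1], case$b[2], case$b[3]),
                           case$p)
    expect_false(chk$concordant)
  }
})

test_that("p-value formatting follows the <0.001 reporting convention", {
  expect_equal(format_p(c(0.5004, 0.0336, 0.0009)),
               c("0.500", "0.034", "<0.001"))
})

test_that("step comparisons build unpaired samples from per-case values", {
  no_events <- ev_rows(numeric(), character())
  tls <- lapply(1:3, function(i) {
    timeline_with_durations(paste0("c", i),
                            c("Colpotomy", "Vaginal Cuff Closure"),
                            c(c(200, 280, 360)[i], c(600, 680, 760)[i]))
  })
  opi <- cohort_opi_table(tls, no_events)
  res <- compare_steps(opi, "Colpotomy", "Vaginal Cuff Closure", "duration_s")
  expect_equal(res$mean_a, 280)
  expect_equal(res$mean_b, 680)
  expect_equal(res$n_a, 3)
  expect_true(res$significant)
  expect_equal(res$df, 4)

  expect_error(compare_steps(opi, "Colpotomy", "Bladder Flap Creation",
                             "duration_s"), "Bladder Flap Creation")
  expect_error(compare_steps(opi, "Colpotomy", "Vaginal Cuff Closure",
                             "path_length"), "unknown OPI metric")

  # the same values entered as both steps give the exact null
  dup <- opi
  dup$duration_s[dup$step_name == "Vaginal Cuff Closure"] <-
    dup$duration_s[dup$step_name == "Colpotomy"]
  null_res <- compare_steps(dup, "Colpotomy", "Vaginal Cuff Closure",
                            "duration_s")
  expect_equal(null_res$t, 0)
  expect_equal(null_res$p, 1)
})

test_that("surgeon comparisons group cases and enforce n >= 2", {
  no_events <- ev_rows(numeric(), character())
  tls <- lapply(1:4, function(i) {
    timeline_with_durations(paste0("c", i), "Colpotomy",
                            c(250, 310, 260, 330)[i])
  })
  opi <- cohort_opi_table(tls, no_events)
  groups <- c(c1 = "A", c2 = "A", c3 = "B", c4 = "B")
  res <- compare_surgeons(opi, groups, "Colpotomy", "duration_s")
  expect_equal(res$step, "Colpotomy")
  expect_equal(c(res$group_a, res$group_b), c("A", "B"))
  expect_equal(res$n_a, 2)
  expect_equal(res$df, 2)

  # n = 2 per group with identical values everywhere: the exact null
  flat <- lapply(1:4, function(i) {
    timeline_with_durations(paste0("f", i), "Colpotomy", 300)
  })
  flat_opi <- cohort_opi_table(flat, no_events)
  same <- compare_surgeons(flat_opi,
                           c(f1 = "A", f2 = "A", f3 = "B", f4 = "B"),
                           "Colpotomy", "duration_s")
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  expect_error(compare_surgeons(opi, c(c1 = "A", c2 = "A", c3 = "A",
                                       c4 = "B"),
                                "Colpotomy", "duration_s"), ">= 2")
  expect_error(compare_surgeons(opi, c(c1 = "A", c2 = "A", c3 = "B",
                                       c4 = "C"),
                                "Colpotomy", "duration_s"), "exactly 2")
})
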