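test_that("default profiles carry the published calibration", {
  p <- default_profiles()
  expect_equal(p$A$start_side, "left")
  expect_equal(p$B$start_side, "right")

  # lognormal duration parameters match the target first two moments
  for (target in list(c("Colpotomy", 281.1, 83.7),
                      c("Vaginal Cuff Closure", 677.5, 81.0))) {
    dp <- p$A$duration_params[[target[1]]]
    m <- exp(dp$meanlog + dp$sdlog^2 / 2)
    v <- (exp(dp$sdlog^2) - 1) * m^2
    expect_equal(m, as.numeric(target[2]), tolerance = 1e-10)
    expect_equal(sqrt(v), as.numeric(target[3]), tolerance = 1e-10)
  }

  # event rates are published mean counts over published mean durations
  expect_equal(p$A$event_rates$Colpotomy[["camera_move"]], 35.3 / 281.1)
  expect_equal(p$B$event_rates$Colpotomy[["camera_move"]], 18.3 / 281.1)
  # pooled colpotomy energy rate ~ 38.2 events / 281.1 s
  pooled_energy <- mean(c(p$A$event_rates$Colpotomy[["energy"]],
                          p$B$event_rates$Colpotomy[["energy"]]))
  expect_equal(pooled_energy, 38.2 / 281.1, tolerance = 0.01)
  # cuff closure energy ~ 6.3 events / 677.5 s pooled
  pooled_cuff <- mean(c(p$A$event_rates$`Vaginal Cuff Closure`[["energy"]],
                        p$B$event_rates$`Vaginal Cuff Closure`[["energy"]]))
  expect_equal(pooled_cuff, 6.3 / 677.5, tolerance = 1e-10)

  for (prof in p) {
    expect_true(all(unlist(prof$event_rates) >= 0))
    probs <- c(unlist(prof$optional_step_prob), unlist(prof$interrupt_prob),
               prof$gap_prob, prof$reversal_prob)
    expect_true(all(probs >= 0 & probs <= 1))
  }

  expect_error(surgeon_profile("X", "left", c(S = 1.5), list(), list(),
                               c(.default = 0), 0.5,
                               list(meanlog = 3, sdlog = 1)),
               "\\[0, 1\\]")
})

test_that("step plans follow the card with the profile's side preference", {
  card <- default_card()
  p <- default_profiles()
  no_optional <- p$A
  no_optional$optional_step_prob[] <- 0
  set.seed(1)
  plan <- build_step_plan(card, no_optional, reversed = FALSE)
  # mandatory steps only: three paired (both sides) + four midline... the
  # mandatory block is steps 5-11: 3 paired x 2 sides + 4 midline = 10
  expect_equal(nrow(plan), 10)
  expect_false(any(plan$step_name %in% card$name[card$optional]))
  for (nm in unique(plan$step_name[plan$side != "none"])) {
    sides <- plan$side[plan$step_name == nm]
    expect_equal(sides, c("left", "right"))  # start side first
  }
  expect_lt(which(plan$step_name == "Colpotomy"),
            which(plan$step_name == "Removal of the Uterus"))
  expect_lt(which(plan$step_name == "Removal of the Uterus"),
            which(plan$step_name == "Vaginal Cuff Closure"))

  set.seed(2)
  plan_b <- build_step_plan(card, p$B, reversed = FALSE)
  right_first <- plan_b$side[plan_b$side != "none"]
  expect_equal(right_first[1], "right")

  # vaginal morcellation variant: removal after cuff closure
  set.seed(3)
  rev_plan <- build_step_plan(card, p$B, reversed = TRUE)
  expect_gt(which(rev_plan$step_name == "Removal of the Uterus"),
            which(rev_plan$step_name == "Vaginal Cuff Closure"))

  set.seed(11); plan1 <- build_step_plan(card, p$A)
  set.seed(11); plan2 <- build_step_plan(card, p$A)
  expect_identical(plan1, plan2)
})

test_that("case simulation is seed-deterministic", {
  card <- default_card()
  p <- default_profiles()$A
  c1 <- simulate_case(card, p, "case_x", seed = 99)
  c2 <- simulate_case(card, p, "case_x", seed = 99)
  expect_identical(c1$segments, c2$segments)
  expect_identical(c1$events, c2$events)
  expect_identical(c1$truth$realized_sequence, c2$truth$realized_sequence)
  c3 <- simulate_case(card, p, "case_x", seed = 100)
  expect_false(identical(c1$segments, c3$segments))
})

test_that("zero event rates produce an empty stream", {
  p <- default_profiles()$A
  p$event_rates <- lapply(p$event_rates, function(r) r * 0)
  case <- simulate_case(default_card(), p, "c0", seed = 4)
  expect_equal(nrow(case$events), 0)
})

test_that("simulated cases resolve into valid timelines", {
  card <- default_card()
  profiles <- default_profiles()
  for (i in 1:10) {
    p <- profiles[[1 + i %% 2]]
    case <- simulate_case(card, p, paste0("v", i), seed = 1000 + i)
    tl <- case$timeline
    # non-overlap, ordering, gap bounds
    expect_true(all(diff(tl$segments$start_s) > 0))
    expect_true(all(tl$segments$end_s > tl$segments$start_s))
    if (nrow(tl$gaps) > 0) {
      expect_true(all(tl$gaps$t_end - tl$gaps$t_start > tl$gap_threshold_s))
    }
    # the functional sequence equals the realized generative sequence
    expect_equal(functional_sequence(tl)[-1], case$truth$realized_sequence)
    # rebuilding from the resolved segments is a fixed point
    tl2 <- build_timeline(tl$segments[c("case_id", "step_name", "side",
                                        "start_s", "end_s")], card = card)
    expect_equal(tl2$segments, tl$segments)
  }
})

test_that("cohorts are reproducible, extensible and file round-trippable", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(3, seed = 42, out_dir = dir)
  expect_length(co$cases, 6)
  expect_equal(length(unique(co$meta$case_id)), 6)
  expect_equal(unname(table(co$meta$surgeon)[c("A", "B")]), c(3L, 3L),
               ignore_attr = TRUE)

  co2 <- simulate_cohort(3, seed = 42)
  expect_identical(co$segments, co2$segments)
  expect_identical(co$events, co2$events)

  # extending the cohort preserves the existing cases (per-case seeds)
  co_big <- simulate_cohort(4, seed = 42)
  expect_identical(co_big$cases[[1]]$segments, co$cases[[1]]$segments)

  seg <- read_segments(file.path(dir, "segments.csv"))
  ev <- read_events(file.path(dir, "events.csv"))
  expect_equal(nrow(seg), nrow(co$segments))
  expect_equal(nrow(ev), nrow(co$events))
  expect_equal(seg$start_s, co$segments$start_s, tolerance = 1e-12)
  expect_equal(seg$step_name, co$segments$step_name)
})

test_that("surgeon profiles round-trip through JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  profiles <- default_profiles()
  write_profiles(profiles, path)
  reread <- read_profiles(path)
  expect_equal(names(reread), names(profiles))
  expect_equal(reread$A$event_rates$Colpotomy,
               profiles$A$event_rates$Colpotomy, tolerance = 1e-12)
  expect_equal(reread$B$reversal_prob, profiles$B$reversal_prob)
  expect_equal(reread$A$duration_params$Colpotomy$meanlog,
               profiles$A$duration_params$Colpotomy$meanlog,
               tolerance = 1e-12)
})

test_that("simulated event counts recover the profile rates", {
  # moderate-n spot check of Poisson rate recovery on the two index steps
  card <- default_card()
  p <- default_profiles()$A
  opi <- dplyr::bind_rows(lapply(1:60, function(i) {
    case <- simulate_case(card, p, paste0("r", i), seed = 5000 + i)
    compute_case_opi(case$timeline, case$events)
  }))
  for (step in c("Colpotomy", "Vaginal Cuff Closure")) {
    rows <- opi[opi$step_name == step, ]
    total_t <- sum(rows$duration_s)
    for (kind in c("camera_count", "energy_count")) {
      rate_name <- c(camera_count = "camera_move", energy_count = "energy")
      truth <- p$event_rates[[step]][[rate_name[[kind]]]]
      est <- sum(rows[[kind]]) / total_t
      se <- sqrt(sum(rows[[kind]])) / total_t
      expect_lt(abs(est - truth), 4 * se + 1e-12)
    }
  }
})
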