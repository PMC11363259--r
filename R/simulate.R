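#' Lognormal parameters matching a target mean and SD
#'
#' Moment-matches a lognormal to a desired arithmetic mean and standard
#' deviation. Used to calibrate step-duration distributions to published
#' mean ± SD values.
#'
#' @param mean,sd Target arithmetic mean and standard deviation (`> 0`).
#' @return List with `meanlog` and `sdlog`.
#' @export
lognormal_params <- function(mean, sd) {
  stopifnot(mean > 0, sd > 0)
  sdlog <- sqrt(log1p((sd / mean)^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Construct a surgeon profile
#'
#' A surgeon profile is the generative parameter set of the case simulator:
#' which side the surgeon starts paired steps on, how likely each optional
#' step is, per-step lognormal duration parameters, per-step Poisson event
#' rates (events per second), the chance a step is interrupted and resumed,
#' and the distribution of inter-step gaps.
#'
#' @param name Profile name (used as surgeon id).
#' @param start_side `"left"` or `"right"`: side on which paired steps begin.
#' @param optional_step_prob Named numeric: inclusion probability per optional
#'   step name.
#' @param duration_params Named list: step name -> list(meanlog, sdlog).
#' @param event_rates Named list: step name -> named numeric rates per event
#'   kind (see [event_kinds()]); missing kinds default to rate 0.
#' @param interrupt_prob Named numeric: per-step probability the step is
#'   split into two occurrences around a gap. A `".default"` entry covers
#'   unlisted steps.
#' @param gap_prob Probability that a step transition exceeds the 2 s
#'   threshold and produces an annotated gap.
#' @param gap_duration_params list(meanlog, sdlog) of gap lengths (seconds),
#'   truncated below at `min_gap_s`.
#' @param min_gap_s Lower truncation of gap lengths; must exceed the gap
#'   threshold so simulated gaps survive timeline building (default 2).
#' @param reversal_prob Probability that uterus removal follows vaginal cuff
#'   closure (vaginal morcellation variant) instead of preceding it.
#' @return A list of class `opi_profile`.
#' @export
surgeon_profile <- function(name, start_side, optional_step_prob,
                            duration_params, event_rates, interrupt_prob,
                            gap_prob, gap_duration_params,
                            min_gap_s = 2, reversal_prob = 0) {
  stopifnot(start_side %in% c("left", "right"))
  probs <- c(unlist(optional_step_prob), unlist(interrupt_prob),
             gap_prob, reversal_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  rates <- unlist(event_rates)
  if (any(rates < 0)) stop("event rates must be >= 0", call. = FALSE)
  unknown <- setdiff(unique(unlist(lapply(event_rates, names))),
                     event_kinds())
  if (length(unknown) > 0) {
    stop("unknown event kind(s) in rates: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(list(
    name = name, start_side = start_side,
    optional_step_prob = optional_step_prob,
    duration_params = duration_params, event_rates = event_rates,
    interrupt_prob = interrupt_prob, gap_prob = gap_prob,
    gap_duration_params = gap_duration_params, min_gap_s = min_gap_s,
    reversal_prob = reversal_prob
  ), class = "opi_profile")
}

#' @export
print.opi_profile <- function(x, ...) {
  cat("Surgeon profile '", x$name, "': starts ", x$start_side,
      ", ", length(x$duration_params), " step duration models\n", sep = "")
  invisible(x)
}

#' Default calibrated surgeon profiles
#'
#' Two profiles, A and B, calibrated so that the simulated cohort reproduces
#' the published first moments of the two index steps: colpotomy duration
#' with mean 281.1 s (SD 83.7) and vaginal cuff closure with mean 677.5 s
#' (SD 81.0); per-step Poisson event rates equal the published mean event
#' counts divided by the published mean step duration (e.g. colpotomy energy
#' ~38.2 events / 281.1 s ~ 0.136 per second, camera movement 0.126/s for
#' surgeon A vs 0.065/s for surgeon B). A starts paired steps on the left,
#' B on the right; B occasionally performs vaginal morcellation, reversing
#' uterus removal and cuff closure. Durations and rates for steps without
#' published values are fixed at plausible magnitudes for an experienced
#' surgeon (documented in the methods vignette).
#'
#' @return Named list with profiles `A` and `B`.
#' @export
default_profiles <- function() {
  dur <- list(
    "Mobilize Colon/Removal of Adhesions" = lognormal_params(240, 180),
    "Dissection of Fallopian Tube" = lognormal_params(90, 40),
    "Dissection of IP Ligament" = lognormal_params(120, 50),
    "Dissection of Utero-Ovarian Ligament" = lognormal_params(100, 45),
    "Division of the Round Ligament" = lognormal_params(110, 40),
    "Division of the Broad Ligament" = lognormal_params(140, 50),
    "Bladder Flap Creation" = lognormal_params(200, 80),
    "Division of Uterine Vessels" = lognormal_params(160, 60),
    "Colpotomy" = lognormal_params(281.1, 83.7),
    "Removal of the Uterus" = lognormal_params(290, 200),
    "Vaginal Cuff Closure" = lognormal_params(677.5, 81.0)
  )
  dissect <- c(camera_move = 0.06, energy = 0.12, clutch_left = 0.008,
               clutch_right = 0.008, clutch_both = 0.002)
  clutch_split <- c(clutch_left = 0.45, clutch_right = 0.45,
                    clutch_both = 0.10)
  colpo_rates <- function(camera_n, energy_n, clutch_n) {
    c(camera_move = camera_n / 281.1, energy = energy_n / 281.1,
      clutch_split * clutch_n / 281.1)
  }
  cuff_rates <- function(camera_n, energy_n, clutch_n) {
    c(camera_move = camera_n / 677.5, energy = energy_n / 677.5,
      clutch_split * clutch_n / 677.5)
  }
  base_rates <- list(
    "Mobilize Colon/Removal of Adhesions" = dissect,
    "Dissection of Fallopian Tube" = dissect,
    "Dissection of IP Ligament" = dissect,
    "Dissection of Utero-Ovarian Ligament" = dissect,
    "Division of the Round Ligament" = dissect,
    "Division of the Broad Ligament" = dissect,
    "Bladder Flap Creation" = dissect,
    "Division of Uterine Vessels" = dissect,
    "Removal of the Uterus" = c(camera_move = 0.04, energy = 0.02,
                                clutch_left = 0.005, clutch_right = 0.005,
                                clutch_both = 0.001)
  )
  optional <- c("Mobilize Colon/Removal of Adhesions" = 0.5,
                "Dissection of Fallopian Tube" = 0.85,
                "Dissection of IP Ligament" = 0.15,
                "Dissection of Utero-Ovarian Ligament" = 0.5)
  interrupt <- c(".default" = 0.12, "Colpotomy" = 0.15,
                 "Vaginal Cuff Closure" = 0.35)
  gap_par <- lognormal_params(45, 40)

  rates_A <- c(base_rates, list(
    "Colpotomy" = colpo_rates(35.3, 35.3, 7.3),
    "Vaginal Cuff Closure" = cuff_rates(21.7, 4.3, 9.0)
  ))
  rates_B <- c(base_rates, list(
    "Colpotomy" = colpo_rates(18.3, 41.0, 2.7),
    "Vaginal Cuff Closure" = cuff_rates(14.7, 8.3, 6.3)
  ))
  list(
    A = surgeon_profile("A", "left", optional, dur, rates_A, interrupt,
                        gap_prob = 0.6, gap_duration_params = gap_par),
    B = surgeon_profile("B", "right", optional, dur, rates_B, interrupt,
                        gap_prob = 0.6, gap_duration_params = gap_par,
                        reversal_prob = 1 / 3)
  )
}

profile_interrupt_prob <- function(profile, step) {
  ip <- profile$interrupt_prob
  p <- unname(unlist(ip)[step])
  if (is.null(p) || is.na(p)) p <- unname(unlist(ip)[".default"])
  if (is.null(p) || is.na(p)) p <- 0
  p
}

#' Draw a step plan for one case
#'
#' Walks the annotation card in order: optional steps are included with
#' their profile probability; paired steps emit the profile's start side
#' first, then the contralateral side; mandatory midline steps are always
#' present. With `reversed = TRUE` (vaginal morcellation variant) the uterus
#' is removed after the vaginal cuff is closed. Uses the current RNG state.
#'
#' @param card An `opi_card`.
#' @param profile An `opi_profile`.
#' @param reversed Reverse uterus removal and cuff closure; `NULL` (default)
#'   draws from the profile's `reversal_prob`.
#' @return Tibble with columns `step_name` and `side`, in operative order.
#' @export
build_step_plan <- function(card, profile, reversed = NULL) {
  stopifnot(inherits(card, "opi_card"), inherits(profile, "opi_profile"))
  if (is.null(reversed)) {
    reversed <- stats::runif(1) < profile$reversal_prob
  }
  sides <- if (profile$start_side == "left") c("left", "right")
           else c("right", "left")
  rows <- list()
  for (i in seq_len(nrow(card))) {
    if (card$optional[i]) {
      p <- profile$optional_step_prob[[card$name[i]]]
      if (is.null(p)) p <- 0
      if (stats::runif(1) >= p) next
    }
    if (card$laterality[i] == "paired") {
      rows[[length(rows) + 1]] <- tibble::tibble(step_name = card$name[i],
                                                 side = sides)
    } else {
      rows[[length(rows) + 1]] <- tibble::tibble(step_name = card$name[i],
                                                 side = "none")
    }
  }
  plan <- dplyr::bind_rows(rows)
  if (isTRUE(reversed)) {
    i_rem <- which(plan$step_name == "Removal of the Uterus")
    i_cuf <- which(plan$step_name == "Vaginal Cuff Closure")
    if (length(i_rem) == 1 && length(i_cuf) == 1) {
      plan[c(i_rem, i_cuf), ] <- plan[c(i_cuf, i_rem), ]
    }
  }
  plan
}

#' Realized label sequence implied by a profile
#'
#' Draws a step plan and, for each planned step, the interruption indicator,
#' returning the resulting label sequence (interrupted steps repeat their
#' label). This is the plan-level generative path, without durations, gaps
#' or events; the full simulator's functional sequences should be
#' distributed identically.
#'
#' @param card An `opi_card`.
#' @param profile An `opi_profile`.
#' @return Character vector of labels (no START).
#' @export
simulate_plan_sequence <- function(card, profile) {
  plan <- build_step_plan(card, profile)
  labels <- step_label(plan$step_name, plan$side)
  reps <- 1L + (stats::runif(nrow(plan)) <
                  vapply(plan$step_name, profile_interrupt_prob,
                         numeric(1), profile = profile))
  rep(labels, reps)
}

draw_gap <- function(profile) {
  gp <- profile$gap_duration_params
  repeat {
    g <- stats::rlnorm(1, gp$meanlog, gp$sdlog)
    if (g > profile$min_gap_s) return(g)
  }
}

draw_events <- function(profile, step, t0, t1, case_id) {
  rates <- profile$event_rates[[step]]
  if (is.null(rates)) rates <- numeric(0)
  out <- lapply(event_kinds(), function(kind) {
    r <- if (kind %in% names(rates)) rates[[kind]] else 0
    n <- stats::rpois(1, r * (t1 - t0))
    if (n == 0) return(NULL)
    tibble::tibble(case_id = case_id,
                   time_s = sort(stats::runif(n, t0, t1)),
                   event_type = kind)
  })
  dplyr::bind_rows(out)
}

#' Simulate one annotated rTLH case
#'
#' Walks a drawn step plan as a semi-Markov process: each step's duration is
#' lognormal; with the step's interruption probability it is split into two
#' occurrences around a gap; transitions between steps produce either an
#' annotated gap (length from the profile's truncated lognormal) with
#' probability `gap_prob` or an immediate change (interval uniform on
#' `[0, 2]` s, never exceeding the gap threshold). Within each segment every
#' event kind's count is Poisson(rate x duration) with timestamps uniform in
#' the segment; gaps carry no events. Fully deterministic given the seed.
#'
#' @param card An `opi_card`.
#' @param profile An `opi_profile`.
#' @param case_id Case identifier.
#' @param seed Integer seed.
#' @param gap_threshold_s Gap threshold used when resolving the timeline.
#' @return A list of class `opi_simcase`: `case_id`, raw `segments`,
#'   `events`, resolved `timeline`, and `truth` (profile name, plan,
#'   realized label sequence, seed).
#' @export
simulate_case <- function(card, profile, case_id, seed,
                          gap_threshold_s = 2) {
  set.seed(as.integer(seed))
  plan <- build_step_plan(card, profile)
  t <- stats::runif(1, 5, 30)
  seg_rows <- list()
  ev_rows <- list()
  realized <- character(0)

  emit <- function(step, side, t0, t1) {
    seg_rows[[length(seg_rows) + 1]] <<- tibble::tibble(
      case_id = case_id, step_name = step, side = side,
      start_s = t0, end_s = t1)
    ev <- draw_events(profile, step, t0, t1, case_id)
    if (nrow(ev) > 0) ev_rows[[length(ev_rows) + 1]] <<- ev
    realized <<- c(realized, step_label(step, side))
  }

  for (i in seq_len(nrow(plan))) {
    step <- plan$step_name[i]
    dp <- profile$duration_params[[step]]
    if (is.null(dp)) {
      stop("profile '", profile$name, "' has no duration model for step '",
           step, "'", call. = FALSE)
    }
    dur <- stats::rlnorm(1, dp$meanlog, dp$sdlog)
    if (stats::runif(1) < profile_interrupt_prob(profile, step)) {
      frac <- stats::runif(1, 0.35, 0.65)
      emit(step, plan$side[i], t, t + dur * frac)
      t <- t + dur * frac + draw_gap(profile)
      emit(step, plan$side[i], t, t + dur * (1 - frac))
      t <- t + dur * (1 - frac)
    } else {
      emit(step, plan$side[i], t, t + dur)
      t <- t + dur
    }
    if (i < nrow(plan)) {
      t <- t + if (stats::runif(1) < profile$gap_prob) draw_gap(profile)
               else stats::runif(1, 0, gap_threshold_s)
    }
  }

  segments <- dplyr::bind_rows(seg_rows)
  events <- if (length(ev_rows) > 0) {
    ev <- dplyr::bind_rows(ev_rows)
    ev[order(ev$time_s), , drop = FALSE]
  } else {
    tibble::tibble(case_id = character(), time_s = numeric(),
                   event_type = character())
  }
  structure(list(
    case_id = case_id, segments = segments, events = events,
    timeline = build_timeline(segments, gap_threshold_s = gap_threshold_s,
                              card = card,
                              meta = list(surgeon = profile$name)),
    truth = list(profile = profile$name, plan = plan,
                 realized_sequence = realized, seed = as.integer(seed))
  ), class = "opi_simcase")
}

#' Simulate a cohort of annotated cases
#'
#' Generates `n_per_profile` cases per surgeon profile with deterministic
#' per-case seeds (`seed + case index`), so a cohort can be extended without
#' reshuffling existing cases. Optionally writes `segments.csv`,
#' `events.csv` and `truth.json` conforming to the package's file
#' interfaces.
#'
#' @param n_per_profile Cases per profile (`>= 1`).
#' @param profiles Named list of `opi_profile` (default [default_profiles()]).
#' @param card An `opi_card`.
#' @param seed Master integer seed.
#' @param out_dir Optional output directory for the CSV/JSON artifacts.
#' @param gap_threshold_s Gap threshold in seconds.
#' @return A list of class `opi_cohort`: `cases` (list of `opi_simcase`),
#'   bound `segments` and `events` tibbles, `meta` (case_id -> surgeon), and
#'   the master `seed`.
#' @export
simulate_cohort <- function(n_per_profile, profiles = default_profiles(),
                            card = default_card(), seed = 1,
                            out_dir = NULL, gap_threshold_s = 2) {
  stopifnot(n_per_profile >= 1)
  n_total <- n_per_profile * length(profiles)
  cases <- vector("list", n_total)
  idx <- 0
  for (p in profiles) {
    for (k in seq_len(n_per_profile)) {
      idx <- idx + 1
      id <- sprintf("case_%03d", idx)
      cases[[idx]] <- simulate_case(card, p, id, seed = seed + idx,
                                    gap_threshold_s = gap_threshold_s)
    }
  }
  segments <- dplyr::bind_rows(lapply(cases, `[[`, "segments"))
  events <- dplyr::bind_rows(lapply(cases, `[[`, "events"))
  meta <- tibble::tibble(
    case_id = vapply(cases, `[[`, character(1), "case_id"),
    surgeon = vapply(cases, function(cs) cs$truth$profile, character(1))
  )
  cohort <- structure(list(cases = cases, segments = segments,
                           events = events, meta = meta, seed = seed),
                      class = "opi_cohort")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_segments(segments, file.path(out_dir, "segments.csv"))
    write_events(events, file.path(out_dir, "events.csv"))
    truth <- lapply(cases, function(cs) {
      list(case_id = cs$case_id, profile = cs$truth$profile,
           seed = cs$truth$seed,
           realized_sequence = cs$truth$realized_sequence)
    })
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  cohort
}

#' @export
print.opi_cohort <- function(x, ...) {
  cat("Simulated cohort:", length(x$cases), "cases,",
      nrow(x$segments), "segments,", nrow(x$events), "events\n")
  invisible(x)
}

#' Write surgeon profiles to JSON
#'
#' @param profiles Named list of `opi_profile`.
#' @param path Destination `.json` path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  ser <- lapply(profiles, function(p) {
    list(name = p$name, start_side = p$start_side,
         optional_step_prob = as.list(p$optional_step_prob),
         duration_params = p$duration_params,
         event_rates = lapply(p$event_rates, as.list),
         interrupt_prob = as.list(p$interrupt_prob),
         gap_prob = p$gap_prob,
         gap_duration_params = p$gap_duration_params,
         min_gap_s = p$min_gap_s, reversal_prob = p$reversal_prob)
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read surgeon profiles from JSON
#'
#' @param path JSON path written by [write_profiles()].
#' @return Named list of `opi_profile`.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) {
    stop("profiles file not found: ", path, call. = FALSE)
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(p) {
    surgeon_profile(
      name = p$name, start_side = p$start_side,
      optional_step_prob = unlist(p$optional_step_prob),
      duration_params = p$duration_params,
      event_rates = lapply(p$event_rates, unlist),
      interrupt_prob = unlist(p$interrupt_prob),
      gap_prob = p$gap_prob,
      gap_duration_params = p$gap_duration_params,
      min_gap_s = p$min_gap_s, reversal_prob = p$reversal_prob)
  })
}
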