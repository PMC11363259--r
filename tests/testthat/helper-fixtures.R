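# Fixture builders shared across test files. All fixtures are generated in
# code; nothing is read from disk except files the tests write themselves.

# minimal card with generic midline steps A, B, C and one paired step P
toy_card <- function(paired = FALSE) {
  steps <- tibble::tibble(
    name = c("A", "B", "C"),
    laterality = "none",
    optional = FALSE,
    start_action = "start",
    stop_action = "stop",
    card_index = 1:3
  )
  if (paired) {
    steps <- dplyr::bind_rows(steps, tibble::tibble(
      name = "P", laterality = "paired", optional = FALSE,
      start_action = "start", stop_action = "stop", card_index = 4L))
  }
  annotation_card(steps)
}

seg_rows <- function(steps, starts, ends, case_id = "c1", side = NULL) {
  tibble::tibble(
    case_id = case_id, step_name = steps,
    side = if (is.null(side)) "none" else side,
    start_s = starts, end_s = ends
  )
}

ev_rows <- function(times, kinds, case_id = "c1") {
  tibble::tibble(case_id = case_id, time_s = times, event_type = kinds)
}

# Brute-force reference for the timeline rules, written directly from the
# stated conventions and kept independent of build_timeline's implementation:
# repeatedly merge any adjacent same-label pair with interval <= threshold,
# then classify every remaining adjacent interval.
reference_timeline <- function(segments, threshold = 2) {
  seg <- segments[order(segments$start_s), , drop = FALSE]
  seg$label <- step_label(seg$step_name,
                          ifelse(seg$side == "", "none", seg$side))
  repeat {
    merged <- FALSE
    for (i in seq_len(nrow(seg) - 1)) {
      if (seg$label[i] == seg$label[i + 1] &&
          seg$start_s[i + 1] - seg$end_s[i] <= threshold) {
        seg$end_s[i] <- seg$end_s[i + 1]
        seg <- seg[-(i + 1), , drop = FALSE]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  gaps <- list()
  for (i in seq_len(nrow(seg) - 1)) {
    if (seg$start_s[i + 1] - seg$end_s[i] > threshold) {
      gaps[[length(gaps) + 1]] <- c(seg$end_s[i], seg$start_s[i + 1])
    }
  }
  list(segments = seg[c("case_id", "step_name", "side", "start_s", "end_s")],
       gaps = gaps)
}

# random non-overlapping toy segment list with integer times
random_toy_segments <- function(n_max = 10) {
  n <- sample(1:n_max, 1)
  durs <- sample(1:10, n, replace = TRUE)
  intervals <- sample(0:6, n, replace = TRUE)  # straddles the threshold
  starts <- cumsum(intervals) + cumsum(c(0, durs[-n]))
  seg_rows(sample(c("A", "B", "C"), n, replace = TRUE),
           starts, starts + durs)
}

# a timeline whose colpotomy / cuff-closure durations are set exactly
timeline_with_durations <- function(case_id, steps, durations, gap = 10) {
  starts <- cumsum(c(0, durations[-length(durations)] + gap))
  build_timeline(seg_rows(steps, starts, starts + durations,
                          case_id = case_id))
}
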