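#' Functional step sequence of a case
#'
#' Drops gaps and lists the merged segment labels in time order, with the
#' START pseudo-state prepended. Because same-label segments separated by at
#' most the gap threshold were merged when the timeline was built, any
#' repeated adjacent label in the sequence reflects a genuine interruption
#' (the surgeon left the step across a gap and resumed it), and contributes a
#' self-transition.
#'
#' @param timeline An `opi_timeline`.
#' @return Character vector of labels, starting with `"START"`.
#' @export
functional_sequence <- function(timeline) {
  stopifnot(inherits(timeline, "opi_timeline"))
  if (nrow(timeline$segments) == 0) {
    stop("empty timeline has no functional sequence", call. = FALSE)
  }
  c(start_state(), timeline$segments$label)
}

#' Pooled step-transition counts
#'
#' Counts adjacent label pairs over all sequences. Labels listed in
#' `excluded` (e.g. steps too rare to estimate) are deleted from each
#' sequence before pairing, so their neighbours become adjacent. Any label
#' neither in `states` nor in `excluded` is an error.
#'
#' @param sequences List of step sequences (character vectors beginning with
#'   `"START"`), as from [functional_sequence()].
#' @param states Ordered state labels. `"START"` is added in front if absent.
#' @param excluded Labels to drop from the sequences before counting.
#' @return An `opi_transitions` object: list with `states`, integer matrix
#'   `counts`, and `probs = NULL` until [transition_probabilities()] is run.
#' @export
transition_counts <- function(sequences, states, excluded = character()) {
  if (!start_state() %in% states) states <- c(start_state(), states)
  counts <- matrix(0L, length(states), length(states),
                   dimnames = list(from = states, to = states))
  for (s in sequences) {
    unknown <- setdiff(s, c(states, excluded))
    if (length(unknown) > 0) {
      stop("label(s) not in states and not excluded: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    s <- s[!s %in% excluded]
    if (length(s) < 2) next
    for (i in seq_len(length(s) - 1)) {
      counts[s[i], s[i + 1]] <- counts[s[i], s[i + 1]] + 1L
    }
  }
  structure(list(states = states, counts = counts, probs = NULL),
            class = "opi_transitions")
}

#' Row-normalize transition counts into probabilities
#'
#' Each row with positive total becomes row-stochastic; all-zero rows
#' (terminal states, typically vaginal cuff closure) stay all-zero — no END
#' pseudo-state is added.
#'
#' @param tm An `opi_transitions` with counts filled.
#' @return The same object with `probs` filled.
#' @export
transition_probabilities <- function(tm) {
  stopifnot(inherits(tm, "opi_transitions"))
  totals <- rowSums(tm$counts)
  probs <- tm$counts / ifelse(totals > 0, totals, 1)
  probs[totals == 0, ] <- 0
  tm$probs <- probs
  tm
}

#' Estimate a transition matrix from timelines
#'
#' Convenience wrapper: builds functional sequences, pools transition counts
#' and row-normalizes.
#'
#' @param timelines List of `opi_timeline`.
#' @param states Ordered state labels; defaults to the labels observed,
#'   in card order of [default_card()].
#' @param excluded Labels to exclude (see [transition_counts()]).
#' @return An `opi_transitions` with counts and probs filled.
#' @export
transition_matrix <- function(timelines, states = NULL,
                              excluded = character()) {
  seqs <- lapply(timelines, functional_sequence)
  if (is.null(states)) {
    observed <- unique(unlist(seqs))
    states <- intersect(card_labels(default_card()), observed)
    states <- c(states, setdiff(setdiff(observed, start_state()), states))
  }
  transition_probabilities(transition_counts(seqs, states, excluded))
}

#' @export
print.opi_transitions <- function(x, ...) {
  cat("Step-transition matrix:", length(x$states), "states,",
      sum(x$counts), "transitions",
      if (is.null(x$probs)) "(counts only)" else "(row-stochastic)", "\n")
  invisible(x)
}

#' Write a transition matrix to JSON
#'
#' @param tm An `opi_transitions`.
#' @param path Destination `.json` path.
#' @return `path`, invisibly.
#' @export
write_transitions <- function(tm, path) {
  jsonlite::write_json(
    list(states = tm$states,
         counts = unname(apply(tm$counts, 1, as.integer, simplify = FALSE)),
         probs = if (is.null(tm$probs)) NULL else
           unname(apply(tm$probs, 1, as.numeric, simplify = FALSE))),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Median fractional step order
#'
#' In a case whose merged, gap-free sequence has `m` segments, the `k`-th
#' segment (1-based) sits at fractional position `k/m`. Every occurrence of a
#' step contributes its position; the per-label median over all cases gives
#' the step's typical position in the workflow. Labels occurring fewer than
#' `min_occurrences` times in the whole cohort are set aside as excluded
#' (too rare to place reliably). Entries are sorted by median position, with
#' the right and left variants of a paired step forced adjacent, right first
#' — the fixed convention used for transition-matrix axes.
#'
#' @param timelines List of `opi_timeline`.
#' @param min_occurrences Minimum cohort-wide occurrence count (default 3).
#' @return An `opi_ordering` tibble: `step_name`, `side`, `label`,
#'   `median_fractional_order`, `occurrences`, `excluded` (logical; excluded
#'   rows are listed after the ordered entries).
#' @export
fractional_step_order <- function(timelines, min_occurrences = 3) {
  if (length(timelines) == 0) {
    stop("fractional_step_order needs at least one timeline", call. = FALSE)
  }
  pos <- dplyr::bind_rows(lapply(timelines, function(tl) {
    m <- nrow(tl$segments)
    tibble::tibble(label = tl$segments$label, frac = seq_len(m) / m)
  }))
  stats_tbl <- pos |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(median_fractional_order = stats::median(.data$frac),
                     occurrences = dplyr::n(), .groups = "drop")
  parts <- split_label(stats_tbl$label)
  stats_tbl$step_name <- parts$name
  stats_tbl$side <- parts$side
  stats_tbl$excluded <- stats_tbl$occurrences < min_occurrences

  kept <- stats_tbl[!stats_tbl$excluded, , drop = FALSE]
  # paired variants sort on their pair's earliest median so they stay adjacent
  pair_key <- vapply(seq_len(nrow(kept)), function(i) {
    if (kept$side[i] == "none") return(kept$median_fractional_order[i])
    mates <- kept$median_fractional_order[kept$step_name == kept$step_name[i]]
    min(mates)
  }, numeric(1))
  side_rank <- match(kept$side, c("none", "right", "left"))
  kept <- kept[order(pair_key, kept$step_name, side_rank), , drop = FALSE]

  out <- dplyr::bind_rows(kept,
                          stats_tbl[stats_tbl$excluded, , drop = FALSE])
  out <- out[c("step_name", "side", "label", "median_fractional_order",
               "occurrences", "excluded")]
  structure(out, class = c("opi_ordering", class(out)))
}

#' Write a step ordering to CSV
#'
#' @param ordering An `opi_ordering`.
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_ordering <- function(ordering, path) {
  cols <- c("step_name", "side", "median_fractional_order", "occurrences",
            "excluded")
  utils::write.csv(as.data.frame(ordering)[cols], path, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}

#' Count step switches in a case
#'
#' A switch is a segment whose label already occurred earlier in the
#' sequence: the surgeon left a step and later returned to it (including
#' resumptions across gaps).
#'
#' @param timeline An `opi_timeline`.
#' @return Integer switch count.
#' @export
switch_count <- function(timeline) {
  stopifnot(inherits(timeline, "opi_timeline"))
  sum(duplicated(timeline$segments$label))
}
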