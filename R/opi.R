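#' OPI metric names
#'
#' @return Character vector of the per-step objective performance indicator
#'   (OPI) metrics computed by [compute_case_opi()].
#' @export
opi_metrics <- function() {
  c("duration_s", "camera_count", "energy_count",
    "clutch_left", "clutch_right", "clutch_both", "clutch_total")
}

#' Compute per-step OPIs for one case
#'
#' For every step of the timeline, sums the durations of its occurrences and
#' counts the robotic events of each kind falling inside them (half-open
#' `[start, end)` per segment). Events in gaps, in sub-threshold inter-step
#' intervals, before the first segment or after the last are counted in no
#' step. The clutch total is the sum of left, right and both-hand clutch
#' events. With `collapse_sides = TRUE` the left and right variants of a
#' paired step are aggregated into a single row.
#'
#' @param timeline An `opi_timeline`.
#' @param events Events tibble for the same case.
#' @param collapse_sides Merge left/right variants of paired steps?
#' @return A tibble with one row per (case, step): columns `case_id`,
#'   `step_name`, `side`, `n_occurrences`, `duration_s`, `camera_count`,
#'   `energy_count`, `clutch_left`, `clutch_right`, `clutch_both`,
#'   `clutch_total`.
#' @export
compute_case_opi <- function(timeline, events, collapse_sides = TRUE) {
  stopifnot(inherits(timeline, "opi_timeline"))
  ev_ids <- unique(events$case_id)
  if (length(ev_ids) > 0 && !identical(ev_ids, timeline$case_id)) {
    stop("timeline case '", timeline$case_id,
         "' does not match event stream case(s) ",
         paste(ev_ids, collapse = ", "), call. = FALSE)
  }
  seg <- timeline$segments
  per_seg <- lapply(seq_len(nrow(seg)), function(i) {
    counts <- count_events_in_interval(events, seg$start_s[i], seg$end_s[i])
    tibble::tibble(
      step_name = seg$step_name[i],
      side = if (collapse_sides) "" else seg$side[i],
      duration_s = seg$end_s[i] - seg$start_s[i],
      camera_count = counts[["camera_move"]],
      energy_count = counts[["energy"]],
      clutch_left = counts[["clutch_left"]],
      clutch_right = counts[["clutch_right"]],
      clutch_both = counts[["clutch_both"]]
    )
  })
  agg <- dplyr::bind_rows(per_seg) |>
    dplyr::group_by(.data$step_name, .data$side) |>
    dplyr::summarise(
      n_occurrences = dplyr::n(),
      dplyr::across(dplyr::all_of(c("duration_s", "camera_count",
                                    "energy_count", "clutch_left",
                                    "clutch_right", "clutch_both")), sum),
      .groups = "drop"
    )
  agg$clutch_total <- agg$clutch_left + agg$clutch_right + agg$clutch_both
  agg <- dplyr::bind_cols(tibble::tibble(case_id = timeline$case_id), agg)
  agg[c("case_id", "step_name", "side", "n_occurrences", opi_metrics())]
}

#' Compute the cohort OPI table
#'
#' Applies [compute_case_opi()] to every case and binds the rows.
#'
#' @param timelines List of `opi_timeline` (as from [build_timelines()]).
#' @param events Multi-case events tibble.
#' @param collapse_sides Merge left/right variants of paired steps?
#' @return Cohort OPI tibble, one row per (case, step).
#' @export
cohort_opi_table <- function(timelines, events, collapse_sides = TRUE) {
  rows <- lapply(timelines, function(tl) {
    compute_case_opi(tl, events[events$case_id == tl$case_id, , drop = FALSE],
                     collapse_sides = collapse_sides)
  })
  dplyr::bind_rows(rows)
}

#' Per-group mean and standard deviation of OPIs
#'
#' Summarises an OPI table per (group, step, metric) as mean, sample
#' (n - 1) standard deviation and n. Groups with a single case report the
#' standard deviation as `NA` (undefined). Cases where a step never occurred
#' contribute no row for that step.
#'
#' @param opi Cohort OPI tibble from [cohort_opi_table()].
#' @param groups Optional assignment of cases to groups: a data frame with
#'   columns `case_id` and `group`, or a named character vector
#'   (`names = case_id`). `NULL` pools all cases into one group.
#' @param metrics Metrics to summarise (default all of [opi_metrics()]).
#' @return Tibble with columns `group`, `step_name`, `metric`, `mean`, `sd`,
#'   `n`.
#' @export
opi_summary <- function(opi, groups = NULL, metrics = opi_metrics()) {
  bad <- setdiff(metrics, opi_metrics())
  if (length(bad) > 0) {
    stop("unknown OPI metric(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  opi$group <- resolve_groups(opi$case_id, groups)
  long <- do.call(rbind, lapply(metrics, function(m) {
    data.frame(group = opi$group, step_name = opi$step_name,
               metric = m, value = opi[[m]], stringsAsFactors = FALSE)
  }))
  tibble::as_tibble(long) |>
    dplyr::group_by(.data$group, .data$step_name, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = if (dplyr::n() > 1) stats::sd(.data$value) else NA_real_,
      n = dplyr::n(),
      .groups = "drop"
    )
}

resolve_groups <- function(case_id, groups) {
  if (is.null(groups)) return(rep("all", length(case_id)))
  if (is.data.frame(groups)) {
    if (!all(c("case_id", "group") %in% names(groups))) {
      stop("groups data frame needs columns case_id and group",
           call. = FALSE)
    }
    map <- stats::setNames(as.character(groups$group),
                           as.character(groups$case_id))
  } else if (!is.null(names(groups))) {
    map <- stats::setNames(as.character(groups), names(groups))
  } else {
    stop("groups must be NULL, a named vector, or a case_id/group data frame",
         call. = FALSE)
  }
  g <- unname(map[case_id])
  if (anyNA(g)) {
    stop("no group assignment for case(s): ",
         paste(unique(case_id[is.na(g)]), collapse = ", "), call. = FALSE)
  }
  g
}

#' Write an OPI table to CSV
#'
#' @param opi Cohort OPI tibble.
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_opi_table <- function(opi, path) {
  utils::write.csv(as.data.frame(opi), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read an OPI table written by [write_opi_table()]
#'
#' @param path CSV path.
#' @return Cohort OPI tibble.
#' @export
read_opi_table <- function(path) {
  if (!file.exists(path)) {
    stop("OPI table not found: ", path, call. = FALSE)
  }
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                          colClasses = c(case_id = "character")))
  df$side[is.na(df$side)] <- ""
  df
}
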