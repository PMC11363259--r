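#' Read step-annotation segments from CSV
#'
#' The segments file has header `case_id,step_name,side,start_s,end_s`, one
#' row per annotated step occurrence, with times in seconds from camera
#' insertion. Labels are validated against the annotation card: unknown step
#' names, sides inconsistent with the step's laterality, and non-positive
#' durations are rejected with the offending row named.
#'
#' @param path Path to the CSV file.
#' @param card An `opi_card` used for validation.
#' @return A tibble with columns `case_id`, `step_name`, `side`, `start_s`,
#'   `end_s`, sorted by `(case_id, start_s)`.
#' @export
read_segments <- function(path, card = default_card()) {
  if (!file.exists(path)) {
    stop("segments file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(case_id = "character"))
  required <- c("case_id", "step_name", "side", "start_s", "end_s")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("segments file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- tibble::as_tibble(df[required])
  validate_segments(df, card)
  df[order(df$case_id, df$start_s), , drop = FALSE]
}

#' Write segments to CSV
#'
#' @param segments A segments tibble (`case_id,step_name,side,start_s,end_s`).
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  cols <- c("case_id", "step_name", "side", "start_s", "end_s")
  seg <- as.data.frame(segments)[cols]
  seg$side[seg$side == "none"] <- ""
  utils::write.csv(seg, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

validate_segments <- function(df, card) {
  if (nrow(df) == 0) return(invisible(TRUE))
  df$side <- ifelse(is.na(df$side) | df$side == "", "none", df$side)
  if (anyNA(df$start_s) || anyNA(df$end_s)) {
    stop("non-numeric start_s/end_s in segments", call. = FALSE)
  }
  bad_neg <- which(df$start_s < 0)
  if (length(bad_neg) > 0) {
    stop("negative start time at row ", bad_neg[1], call. = FALSE)
  }
  bad <- which(df$end_s <= df$start_s)
  if (length(bad) > 0) {
    stop("segment with end_s <= start_s at row ", bad[1], " (case ",
         df$case_id[bad[1]], ", step '", df$step_name[bad[1]], "')",
         call. = FALSE)
  }
  check_labels(df$step_name, df$side, card)
  invisible(TRUE)
}

#' Resolve raw segments into a case timeline
#'
#' Applies the annotation conventions of the workflow model: segments are
#' time-ordered and checked for overlap (intervals are half-open
#' `[start, end)`, so a segment may start exactly where the previous one
#' ends); consecutive occurrences of the *same* step separated by at most
#' `gap_threshold_s` seconds are merged into one segment (transitively);
#' any remaining inter-segment interval longer than `gap_threshold_s` becomes
#' a gap (instrument change, camera cleaning, idle time), while shorter
#' intervals count as an immediate step change and are assigned to no step.
#' An interval of exactly `gap_threshold_s` counts as "within" the threshold
#' and produces no gap.
#'
#' @param segments Segments tibble for a single case
#'   (`case_id,step_name,side,start_s,end_s`).
#' @param gap_threshold_s Gap threshold in seconds (default 2).
#' @param card An `opi_card` for label validation.
#' @param meta Optional named list of case metadata (surgeon, indication, ...).
#' @return An `opi_timeline`: a list with `case_id`, `segments` (merged,
#'   with a `label` column), `gaps`, `gap_threshold_s` and `meta`.
#' @export
build_timeline <- function(segments, gap_threshold_s = 2,
                           card = default_card(), meta = list()) {
  stopifnot(gap_threshold_s > 0)
  seg <- tibble::as_tibble(segments)
  seg$side <- ifelse(is.na(seg$side) | seg$side == "", "none", seg$side)
  if (nrow(seg) == 0) {
    stop("cannot build a timeline from zero segments", call. = FALSE)
  }
  if (length(unique(seg$case_id)) != 1) {
    stop("all segments must share one case_id; got: ",
         paste(unique(seg$case_id), collapse = ", "), call. = FALSE)
  }
  validate_segments(seg, card)
  seg <- seg[order(seg$start_s), , drop = FALSE]
  overlap <- which(seg$start_s[-1] < seg$end_s[-nrow(seg)])
  if (length(overlap) > 0) {
    i <- overlap[1]
    stop(sprintf(
      "overlapping segments in case %s: '%s' [%g, %g) and '%s' [%g, %g)",
      seg$case_id[1], seg$step_name[i], seg$start_s[i], seg$end_s[i],
      seg$step_name[i + 1], seg$start_s[i + 1], seg$end_s[i + 1]),
      call. = FALSE)
  }
  seg$label <- step_label(seg$step_name, seg$side)

  # transitive same-label merge across sub-threshold intervals: assign each
  # raw segment to a merge group in one scan, then collapse groups
  n <- nrow(seg)
  group <- integer(n)
  group[1] <- 1L
  cur_end <- seg$end_s[1]
  for (i in seq_len(n)[-1]) {
    if (seg$label[i] == seg$label[i - 1] &&
        seg$start_s[i] - cur_end <= gap_threshold_s) {
      group[i] <- group[i - 1]
    } else {
      group[i] <- group[i - 1] + 1L
    }
    cur_end <- seg$end_s[i]
  }
  first <- !duplicated(group)
  out <- seg[first, , drop = FALSE]
  out$end_s <- seg$end_s[cumsum(tabulate(group))]

  gaps <- NULL
  if (nrow(out) > 1) {
    interval <- out$start_s[-1] - out$end_s[-nrow(out)]
    gi <- which(interval > gap_threshold_s)
    gaps <- tibble::tibble(
      case_id = out$case_id[1],
      t_start = out$end_s[gi],
      t_end = out$start_s[gi + 1]
    )
  } else {
    gaps <- tibble::tibble(case_id = character(), t_start = numeric(),
                           t_end = numeric())
  }

  structure(list(
    case_id = out$case_id[1],
    segments = out[c("case_id", "step_name", "side", "label",
                     "start_s", "end_s")],
    gaps = gaps,
    gap_threshold_s = gap_threshold_s,
    meta = meta
  ), class = "opi_timeline")
}

#' Build timelines for every case in a segments table
#'
#' @param segments Multi-case segments tibble.
#' @param gap_threshold_s Gap threshold in seconds.
#' @param card An `opi_card`.
#' @param meta Optional data frame of per-case metadata with a `case_id`
#'   column; matching rows are attached to each timeline.
#' @return A named list of `opi_timeline`, one per case.
#' @export
build_timelines <- function(segments, gap_threshold_s = 2,
                            card = default_card(), meta = NULL) {
  ids <- unique(segments$case_id)
  out <- lapply(ids, function(id) {
    m <- list()
    if (!is.null(meta) && "case_id" %in% names(meta)) {
      row <- meta[meta$case_id == id, , drop = FALSE]
      if (nrow(row) == 1) m <- as.list(row)
    }
    build_timeline(segments[segments$case_id == id, , drop = FALSE],
                   gap_threshold_s = gap_threshold_s, card = card, meta = m)
  })
  names(out) <- ids
  out
}

#' @export
print.opi_timeline <- function(x, ...) {
  cat("Case timeline:", x$case_id, "\n")
  cat("  ", nrow(x$segments), "segments spanning [",
      min(x$segments$start_s), ",", max(x$segments$end_s), ") s;",
      nrow(x$gaps), "gaps (threshold", x$gap_threshold_s, "s)\n")
  if (length(x$meta) > 0 && !is.null(x$meta$surgeon)) {
    cat("   surgeon:", x$meta$surgeon, "\n")
  }
  invisible(x)
}

#' Segment durations of a timeline
#' @param timeline An `opi_timeline`.
#' @return Numeric vector of per-segment durations in seconds.
#' @export
segment_durations <- function(timeline) {
  timeline$segments$end_s - timeline$segments$start_s
}
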