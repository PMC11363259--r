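#' Recognized robotic event kinds
#'
#' The five event streams extracted from the robotic system: camera movement,
#' energy activation, and clutch presses (left, right, both hands). Events are
#' modelled as instantaneous onsets; continuous activations must be reduced to
#' onset events upstream.
#'
#' @return Character vector of valid `event_type` values.
#' @export
event_kinds <- function() {
  c("camera_move", "energy", "clutch_left", "clutch_right", "clutch_both")
}

#' Read robotic event streams from CSV
#'
#' Header `case_id,time_s,event_type`; times in seconds from camera insertion.
#' Unknown event kinds and negative times are rejected.
#'
#' @param path Path to the CSV file.
#' @return A tibble `case_id,time_s,event_type` sorted by `(case_id, time_s)`.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) {
    stop("events file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(case_id = "character"))
  required <- c("case_id", "time_s", "event_type")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("events file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- tibble::as_tibble(df[required])
  validate_events(df)
  df[order(df$case_id, df$time_s), , drop = FALSE]
}

#' Write events to CSV
#'
#' @param events Events tibble (`case_id,time_s,event_type`).
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  cols <- c("case_id", "time_s", "event_type")
  utils::write.csv(as.data.frame(events)[cols], path, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}

validate_events <- function(df) {
  if (nrow(df) == 0) return(invisible(TRUE))
  if (anyNA(df$time_s)) {
    stop("non-numeric time_s in events", call. = FALSE)
  }
  neg <- which(df$time_s < 0)
  if (length(neg) > 0) {
    stop("negative event time at row ", neg[1], call. = FALSE)
  }
  unknown <- setdiff(unique(df$event_type), event_kinds())
  if (length(unknown) > 0) {
    stop("unknown event kind(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Count events of each kind inside a half-open interval
#'
#' An event at time `t` is counted iff `t0 <= t < t1`. The half-open
#' convention prevents double-counting an event sitting exactly on a shared
#' segment boundary.
#'
#' @param events Events tibble for one case.
#' @param t0,t1 Interval bounds in seconds, `t1 > t0`.
#' @return Named integer vector with one entry per kind in [event_kinds()].
#' @export
count_events_in_interval <- function(events, t0, t1) {
  if (t1 <= t0) {
    stop("interval must satisfy t1 > t0 (got [", t0, ", ", t1, "))",
         call. = FALSE)
  }
  kinds <- event_kinds()
  if (nrow(events) == 0) {
    return(stats::setNames(integer(length(kinds)), kinds))
  }
  inside <- events$time_s >= t0 & events$time_s < t1
  tab <- table(factor(events$event_type[inside], levels = kinds))
  stats::setNames(as.integer(tab), kinds)
}
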