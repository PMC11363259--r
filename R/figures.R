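step_palette <- function(card = default_card()) {
  cols <- grDevices::hcl.colors(nrow(card), palette = "Dark 3")
  stats::setNames(cols, card$name)
}

#' Workflow timeline chart
#'
#' One horizontal lane per case, one colored bar per step segment (color
#' fixed by the step's card position for cross-case comparability), white
#' space where gaps occur. The workflow "signature" view: step switching
#' shows as repeated bars of one color, side preference as the order of
#' paired steps.
#'
#' @param timelines List of `opi_timeline`.
#' @param card An `opi_card` (fixes the color mapping).
#' @return A ggplot object.
#' @export
plot_timelines <- function(timelines, card = default_card()) {
  if (length(timelines) == 0) stop("no timelines to plot", call. = FALSE)
  seg <- dplyr::bind_rows(lapply(timelines, `[[`, "segments"))
  seg$step_name <- factor(seg$step_name, levels = card$name)
  seg$case <- factor(seg$case_id, levels = rev(unique(seg$case_id)))
  ggplot2::ggplot(seg) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$start_s / 60, xmax = .data$end_s / 60,
      ymin = as.integer(.data$case) - 0.4,
      ymax = as.integer(.data$case) + 0.4,
      fill = .data$step_name)) +
    ggplot2::scale_y_continuous(breaks = seq_along(levels(seg$case)),
                                labels = levels(seg$case)) +
    ggplot2::scale_fill_manual(values = step_palette(card),
                               drop = FALSE, name = "Surgical step") +
    ggplot2::labs(x = "Time since camera insertion (min)", y = NULL,
                  title = "Surgical workflow signatures") +
    ggplot2::theme_minimal()
}

#' Step-transition probability heatmap
#'
#' Rows are source states, columns destination states, both ordered by the
#' median fractional step order (START first, right before left for paired
#' steps). Transitions that never occurred are black; brightness increases
#' with probability, so a standardized workflow appears as a bright diagonal.
#'
#' @param tm An `opi_transitions` with probabilities filled.
#' @param ordering Optional `opi_ordering`; its non-excluded labels define
#'   the axis order (states absent from the ordering keep matrix order).
#' @return A ggplot object.
#' @export
plot_transition_heatmap <- function(tm, ordering = NULL) {
  stopifnot(inherits(tm, "opi_transitions"))
  if (is.null(tm$probs)) tm <- transition_probabilities(tm)
  states <- tm$states
  if (!is.null(ordering)) {
    ordered <- ordering$label[!ordering$excluded]
    states <- c(start_state(), intersect(ordered, states),
                setdiff(states, c(start_state(), ordered)))
  }
  df <- expand.grid(from = states, to = states, stringsAsFactors = FALSE)
  df$prob <- tm$probs[cbind(df$from, df$to)]
  df$from <- factor(df$from, levels = rev(states))
  df$to <- factor(df$to, levels = states)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$to, y = .data$from,
                                   fill = .data$prob)) +
    ggplot2::geom_tile(color = "grey30", linewidth = 0.1) +
    ggplot2::scale_fill_gradient(low = "black", high = "#ffe680",
                                 limits = c(0, 1),
                                 name = "Transition\nprobability") +
    ggplot2::labs(x = "To step", y = "From step",
                  title = "Step-transition probabilities") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' OPI box-and-whisker chart
#'
#' Box plots of per-case OPI values, faceted by metric, with an "x" marking
#' the group mean. Groups on the x-axis are either surgical steps or
#' surgeons (via `groups`).
#'
#' @param opi Cohort OPI tibble.
#' @param metrics Metrics to show (subset of [opi_metrics()]).
#' @param steps Optional step names to keep (default: all).
#' @param groups Optional case-to-group assignment (see [opi_summary()]);
#'   when given, the x-axis is the group and panels are step x metric.
#' @return A ggplot object.
#' @export
plot_opi_boxplot <- function(opi, metrics = c("camera_count", "energy_count",
                                              "clutch_total"),
                             steps = NULL, groups = NULL) {
  bad <- setdiff(metrics, opi_metrics())
  if (length(bad) > 0) {
    stop("unknown OPI metric(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(steps)) opi <- opi[opi$step_name %in% steps, , drop = FALSE]
  if (nrow(opi) == 0) stop("no OPI rows to plot", call. = FALSE)
  long <- dplyr::bind_rows(lapply(metrics, function(m) {
    tibble::tibble(case_id = opi$case_id, step_name = opi$step_name,
                   metric = m, value = opi[[m]])
  }))
  if (is.null(groups)) {
    long$x <- long$step_name
    facet <- ggplot2::facet_wrap(~metric, scales = "free_y")
    xlab <- "Surgical step"
  } else {
    long$x <- resolve_groups(long$case_id, groups)
    facet <- ggplot2::facet_grid(metric ~ step_name, scales = "free_y")
    xlab <- "Surgeon"
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = 1) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 4, size = 3) +
    facet +
    ggplot2::labs(x = xlab, y = "Value", title = "OPI comparison") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Save a figure as PNG and SVG
#'
#' @param plot A ggplot object.
#' @param stem Output path without extension.
#' @param formats Subset of `c("png", "svg")`.
#' @param width,height Size in inches.
#' @return Character vector of files written, invisibly.
#' @export
save_figure <- function(plot, stem, formats = c("png", "svg"),
                        width = 9, height = 6) {
  written <- character(0)
  if ("png" %in% formats) {
    f <- paste0(stem, ".png")
    ggplot2::ggsave(f, plot, width = width, height = height, dpi = 120)
    written <- c(written, f)
  }
  if ("svg" %in% formats) {
    f <- paste0(stem, ".svg")
    grDevices::svg(f, width = width, height = height)
    print(plot)
    grDevices::dev.off()
    written <- c(written, f)
  }
  invisible(written)
}
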