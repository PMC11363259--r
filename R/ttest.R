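#' Group summary statistics
#'
#' A (mean, sd, n) triple, the form in which clinical papers report OPIs
#' ("mean ± standard deviation"). Two-sample t tests can be computed from
#' these triples alone, so published comparisons can be re-derived without
#' the raw per-case values.
#'
#' @param mean Group mean.
#' @param sd Sample standard deviation (n - 1 denominator), `>= 0`.
#' @param n Group size, `>= 2`.
#' @return A list of class `opi_group_summary`.
#' @export
group_summary <- function(mean, sd, n) {
  if (n < 2) stop("group_summary requires n >= 2", call. = FALSE)
  if (sd < 0) stop("sd must be non-negative", call. = FALSE)
  structure(list(mean = as.numeric(mean), sd = as.numeric(sd),
                 n = as.integer(n)),
            class = "opi_group_summary")
}

#' Two-sample t test from summary statistics
#'
#' Student's two-sided two-sample t test computed from (mean, sd, n)
#' triples. `method = "pooled"` uses the pooled variance with
#' `df = n1 + n2 - 2`; `method = "welch"` uses the Welch-Satterthwaite
#' approximation. When both standard deviations are zero the statistic is
#' degenerate: equal means give `t = 0, p = 1`; unequal means are an error.
#'
#' @param a,b `opi_group_summary` objects (or lists with mean/sd/n).
#' @param method `"pooled"` (default) or `"welch"`.
#' @return A list of class `opi_ttest` with `t`, `df`, `p`, `method`,
#'   `two_sided = TRUE`.
#' @export
ttest_from_summary <- function(a, b, method = c("pooled", "welch")) {
  method <- match.arg(method)
  for (g in list(a, b)) {
    if (is.null(g$mean) || is.null(g$sd) || is.null(g$n)) {
      stop("summaries must provide mean, sd and n", call. = FALSE)
    }
    if (g$n < 2) stop("t test requires n >= 2 in each group", call. = FALSE)
  }
  if (a$sd == 0 && b$sd == 0) {
    if (isTRUE(all.equal(a$mean, b$mean))) {
      return(new_ttest(0, a$n + b$n - 2, 1, method))
    }
    stop("zero variance in both groups with unequal means: t is undefined",
         call. = FALSE)
  }
  if (method == "pooled") {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  } else {
    v1 <- a$sd^2 / a$n
    v2 <- b$sd^2 / b$n
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (a$n - 1) + v2^2 / (b$n - 1))
  }
  t <- (a$mean - b$mean) / se
  new_ttest(t, df, 2 * stats::pt(-abs(t), df), method)
}

new_ttest <- function(t, df, p, method) {
  structure(list(t = as.numeric(t), df = as.numeric(df),
                 p = as.numeric(p), method = method, two_sided = TRUE),
            class = "opi_ttest")
}

#' @export
print.opi_ttest <- function(x, ...) {
  cat(sprintf("Two-sample t test (%s): t = %.4g, df = %.4g, p = %s\n",
              x$method, x$t, x$df, format_p(x$p)))
  invisible(x)
}

#' Two-sample t test from raw values
#'
#' Same test as [ttest_from_summary()], computed from the raw samples
#' via [stats::t.test()] (`var.equal = TRUE` for the pooled method).
#'
#' @param x,y Numeric vectors, each of length `>= 2`.
#' @param method `"pooled"` (default) or `"welch"`.
#' @return An `opi_ttest`.
#' @export
ttest_raw <- function(x, y, method = c("pooled", "welch")) {
  method <- match.arg(method)
  if (length(x) < 2 || length(y) < 2) {
    stop("t test requires n >= 2 in each group", call. = FALSE)
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y)))) {
      return(new_ttest(0, length(x) + length(y) - 2, 1, method))
    }
    stop("zero variance in both groups with unequal means: t is undefined",
         call. = FALSE)
  }
  fit <- stats::t.test(x, y, var.equal = (method == "pooled"))
  new_ttest(unname(fit$statistic), unname(fit$parameter), fit$p.value, method)
}

#' Format a p-value for reporting
#'
#' Three decimals, with values below 0.001 reported as `"<0.001"` —
#' the convention used in the clinical literature.
#'
#' @param p Numeric p-value(s).
#' @param digits Decimals to print (default 3).
#' @return Character vector.
#' @export
format_p <- function(p, digits = 3) {
  floor_val <- 10^(-digits)
  ifelse(p < floor_val, paste0("<", format(floor_val, scientific = FALSE)),
         formatC(p, digits = digits, format = "f"))
}

#' Check a published p-value against recomputation
#'
#' Recomputes the two-sided two-sample test from the published (mean, sd, n)
#' summaries under both the pooled and the Welch variant, and reports whether
#' either reproduces the published value at its printed precision. Useful to
#' flag published p-values that are discordant with their own printed
#' summary statistics.
#'
#' @param a,b `opi_group_summary` objects.
#' @param printed The published p-value.
#' @param digits Decimals at which the published value was printed; if
#'   `NULL`, inferred from `printed`'s decimal representation.
#' @return A list: `pooled_p`, `welch_p`, `digits`, and `concordant`
#'   (`TRUE` iff pooled or Welch rounds to the published value).
#' @export
check_printed_p <- function(a, b, printed, digits = NULL) {
  if (is.null(digits)) {
    s <- sub("0+$", "", sub("^[^.]*\\.?", "", format(printed,
                                                     scientific = FALSE)))
    digits <- max(nchar(s), 2)
  }
  pooled_p <- ttest_from_summary(a, b, "pooled")$p
  welch_p <- ttest_from_summary(a, b, "welch")$p
  concordant <- round(pooled_p, digits) == round(printed, digits) ||
    round(welch_p, digits) == round(printed, digits)
  list(pooled_p = pooled_p, welch_p = welch_p, digits = digits,
       concordant = concordant)
}

# ---- cohort comparisons ----------------------------------------------------

comparison_row <- function(metric, step, group_a, group_b, xs, ys,
                           method, alpha) {
  test <- ttest_raw(xs, ys, method)
  tibble::tibble(
    metric = metric, step = step, group_a = group_a, group_b = group_b,
    mean_a = mean(xs), sd_a = stats::sd(xs), n_a = length(xs),
    mean_b = mean(ys), sd_b = stats::sd(ys), n_b = length(ys),
    t = test$t, df = test$df, p = test$p, method = method,
    significant = test$p < alpha
  )
}

step_metric_values <- function(opi, step, metric) {
  if (!metric %in% opi_metrics()) {
    stop("unknown OPI metric: ", metric, call. = FALSE)
  }
  rows <- opi[opi$step_name == step, , drop = FALSE]
  if (nrow(rows) == 0) {
    stop("step '", step, "' not present in the OPI table", call. = FALSE)
  }
  stats::setNames(rows[[metric]], rows$case_id)
}

#' Compare two surgical steps on one OPI metric
#'
#' Per-case values of `metric` for each step form the two samples; the test
#' is unpaired even though the steps come from the same cases, matching the
#' mean ± SD presentation used for such comparisons.
#'
#' @param opi Cohort OPI tibble (side-collapsed: one row per case and step).
#' @param step_x,step_y Step names to compare.
#' @param metric One of [opi_metrics()].
#' @param method `"pooled"` or `"welch"`.
#' @param alpha Significance level (default 0.05).
#' @return One-row comparison tibble (see [write_comparisons()] for columns).
#' @export
compare_steps <- function(opi, step_x, step_y, metric,
                          method = c("pooled", "welch"), alpha = 0.05) {
  method <- match.arg(method)
  xs <- step_metric_values(opi, step_x, metric)
  ys <- step_metric_values(opi, step_y, metric)
  if (length(xs) < 2 || length(ys) < 2) {
    stop("each step must be present in >= 2 cases", call. = FALSE)
  }
  comparison_row(metric, "", step_x, step_y, xs, ys, method, alpha)
}

#' Compare two surgeons on one OPI metric within a step
#'
#' @param opi Cohort OPI tibble.
#' @param groups Case-to-surgeon assignment (see [opi_summary()]); exactly
#'   two groups must be present among the cases performing `step`.
#' @param step Step name.
#' @inheritParams compare_steps
#' @return One-row comparison tibble.
#' @export
compare_surgeons <- function(opi, groups, step, metric,
                             method = c("pooled", "welch"), alpha = 0.05) {
  method <- match.arg(method)
  vals <- step_metric_values(opi, step, metric)
  g <- resolve_groups(names(vals), groups)
  levels <- sort(unique(g))
  if (length(levels) != 2) {
    stop("surgeon comparison needs exactly 2 groups, got ",
         length(levels), call. = FALSE)
  }
  xs <- vals[g == levels[1]]
  ys <- vals[g == levels[2]]
  if (length(xs) < 2 || length(ys) < 2) {
    stop("each surgeon must contribute >= 2 cases with step '", step, "'",
         call. = FALSE)
  }
  comparison_row(metric, step, levels[1], levels[2], xs, ys, method, alpha)
}

#' Write comparison rows to CSV
#'
#' Columns: `metric,step,group_a,group_b,mean_a,sd_a,n_a,mean_b,sd_b,n_b,`
#' `t,df,p,method,significant`.
#'
#' @param comparisons Tibble of rows from [compare_steps()] /
#'   [compare_surgeons()].
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_comparisons <- function(comparisons, path) {
  utils::write.csv(as.data.frame(comparisons), path, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}
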