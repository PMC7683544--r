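#' Sampling schedule for a diet-challenge trial
#'
#' Describes the calendar layout of the nine sampling days of a
#' high-concentrate diet challenge: the calendar offset of each sampling day,
#' the day on which the new diet starts, and the experimental week each
#' sampling day belongs to.
#'
#' The default layout follows the study design this package was built around:
#' two sampling days on the standard diet (d1, d2 with d2 = d1 + 3), four
#' consecutive days immediately after the diet change (d3..d6), then one day
#' per week for three weeks (d7 = d6 + 4, d8 = d7 + 6, d9 = d8 + 7). Weeks
#' are W1 = \{d1, d2\} (standard diet), W2 = \{d3..d6\} (first week on the
#' high-concentrate diet), W3 = \{d7\}, W4 = \{d8\}, W5 = \{d9\}.
#'
#' The calendar gap between d2 and d3 is not constrained by the week
#' structure; the default of 4 days places d3..d6 in the second experimental
#' week. It only enters the analysis through the step weight of the d2 -> d3
#' phase-plane step, and can be changed via `d3_gap`.
#'
#' @param day_offsets Integer vector of length 9, strictly increasing
#'   calendar offsets of sampling days d1..d9. Default derived from the
#'   canonical spacing and `d3_gap`.
#' @param diet_change_before Day label (1..9) on which the high-concentrate
#'   diet starts; default 3.
#' @param week_of_day Integer vector of length 9 mapping day label to
#'   experimental week 1..5.
#' @param d3_gap Calendar days between d2 and d3 when `day_offsets` is not
#'   supplied; default 4.
#' @return An object of class `sampling_schedule`: a list with elements
#'   `day_offsets`, `diet_change_before`, `week_of_day`.
#' @examples
#' sch <- sampling_schedule()
#' sch$day_offsets   # 0 3 7 8 9 10 14 20 27
#' @export
sampling_schedule <- function(day_offsets = NULL,
                              diet_change_before = 3L,
                              week_of_day = c(1L, 1L, 2L, 2L, 2L, 2L, 3L, 4L, 5L),
                              d3_gap = 4L) {
  if (is.null(day_offsets)) {
    d2 <- 3L
    d3 <- d2 + as.integer(d3_gap)
    day_offsets <- c(0L, d2, d3, d3 + 1L, d3 + 2L, d3 + 3L,
                     d3 + 7L, d3 + 13L, d3 + 20L)
  }
  day_offsets <- as.integer(day_offsets)
  if (length(day_offsets) != 9L || any(diff(day_offsets) <= 0)) {
    stop("`day_offsets` must be 9 strictly increasing integers", call. = FALSE)
  }
  week_of_day <- as.integer(week_of_day)
  if (length(week_of_day) != 9L || any(week_of_day < 1L)) {
    stop("`week_of_day` must map the 9 day labels to weeks >= 1", call. = FALSE)
  }
  structure(
    list(day_offsets = day_offsets,
         diet_change_before = as.integer(diet_change_before),
         week_of_day = week_of_day),
    class = "sampling_schedule"
  )
}

#' @export
print.sampling_schedule <- function(x, ...) {
  cat("Sampling schedule (9 days)\n")
  cat("  day offsets:", x$day_offsets, "\n")
  cat("  diet change before day:", x$diet_change_before, "\n")
  cat("  week of day:", x$week_of_day, "\n")
  invisible(x)
}

#' Annotate measurement records with the experimental schedule
#'
#' Adds `week` (experimental week 1..5), `day_offset` (calendar offset) and
#' `days_since_change` to a measurement table. `days_since_change` is the
#' "days" covariate of the longitudinal model: it counts sampling days since
#' the diet change within the first post-change week (1..4 for d3..d6 under
#' the default schedule) and is 0 on every other day, implementing the
#' indicator-gated day slope.
#'
#' The operation is idempotent: annotating an already annotated table
#' recomputes the same columns.
#'
#' @param records A data frame with a `day_label` column (integer 1..9),
#'   e.g. from [read_measurements()].
#' @param schedule A [sampling_schedule()].
#' @return `records` with columns `week`, `day_offset`, `days_since_change`
#'   added (replaced if present).
#' @export
annotate_schedule <- function(records, schedule = sampling_schedule()) {
  stopifnot(is.data.frame(records))
  if (!inherits(schedule, "sampling_schedule")) {
    stop("`schedule` must be a sampling_schedule object", call. = FALSE)
  }
  lab <- as.integer(records$day_label)
  if (any(is.na(lab)) || any(lab < 1L | lab > 9L)) {
    stop("day_label values outside the schedule (must be 1..9)", call. = FALSE)
  }
  records$week <- schedule$week_of_day[lab]
  records$day_offset <- schedule$day_offsets[lab]
  post_week <- schedule$week_of_day[schedule$diet_change_before]
  # sampling-day count since the diet change, active only in the first
  # post-change week
  dsc <- integer(length(lab))
  in_first <- records$week == post_week
  dsc[in_first] <- lab[in_first] - schedule$diet_change_before + 1L
  records$days_since_change <- dsc
  records
}
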