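# Subject-specific incomplete-blink rule: the median maximal eyelid
# descent of labelled complete blinks in the calibration window (mmD_uc)
# sets a threshold at 75% of itself; any blink whose maxD_uc falls below
# that threshold is incomplete.

#' Calibrate the incomplete-blink threshold
#'
#' Computes `mm_duc`, the median of the per-blink maximal eyelid-descent
#' values (`max_duc`) of labelled complete blinks inside the calibration
#' window at the start of a session. The classification threshold is
#' `threshold_fraction * mm_duc`. Even-sized samples use the usual
#' mid-mean median.
#'
#' @param max_duc Numeric vector of `max_duc` values of labelled complete
#'   blinks within the calibration window.
#' @param threshold_fraction Fraction of `mm_duc` below which a blink is
#'   incomplete; default 0.75, must lie in (0, 1).
#' @param min_events Minimum number of calibration blinks required
#'   (default 5); fewer raises a calibration-insufficient error.
#' @return An object of class `duc_calibration`: list with `mm_duc`,
#'   `threshold_fraction`, `threshold` and `n`.
#' @export
#' @examples
#' calibrate_duc(c(8, 10, 12), min_events = 3)$mm_duc  # 10
calibrate_duc <- function(max_duc, threshold_fraction = 0.75,
                          min_events = 5L) {
  max_duc <- max_duc[!is.na(max_duc)]
  if (length(max_duc) < min_events)
    stop("calibration insufficient: ", length(max_duc),
         " labelled complete blink(s) in the calibration window, need >= ",
         min_events, call. = FALSE)
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("`threshold_fraction` must lie strictly between 0 and 1",
         call. = FALSE)
  mm <- stats::median(max_duc)
  if (!is.finite(mm) || mm <= 0)
    stop("calibration failed: non-positive median max_duc", call. = FALSE)
  structure(list(mm_duc = mm, threshold_fraction = threshold_fraction,
                 threshold = threshold_fraction * mm,
                 n = length(max_duc)),
            class = "duc_calibration")
}

#' @export
print.duc_calibration <- function(x, ...) {
  cat(sprintf("D_uc calibration: mm_duc = %.3f from %d complete blinks; ",
              x$mm_duc, x$n))
  cat(sprintf("incomplete below %.3f (%.0f%%)\n", x$threshold,
              100 * x$threshold_fraction))
  invisible(x)
}

#' Calibrate from a manual label file
#'
#' Joins a calibration label table (columns `start_frame`,
#' `completeness`) onto detected events, keeps events labelled
#' `"complete"` that start inside the calibration window, and calibrates
#' on their `max_duc`.
#'
#' @param events A [blink_events()] table with `max_duc` filled.
#' @param labels Data frame (or CSV path) with columns `start_frame` and
#'   `completeness`.
#' @param config A [session_config()].
#' @inheritParams calibrate_duc
#' @return A `duc_calibration` object.
#' @export
calibrate_from_labels <- function(events, labels, config = session_config(),
                                  threshold_fraction = 0.75,
                                  min_events = 5L) {
  if (is.character(labels))
    labels <- data.table::fread(labels, showProgress = FALSE)
  window_end <- config$calibration_window * config$frame_rate
  lab <- labels$completeness[match(events$start_frame, labels$start_frame)]
  use <- !is.na(lab) & lab == "complete" & events$start_frame < window_end
  calibrate_duc(events$max_duc[use], threshold_fraction, min_events)
}

#' Unattended calibration from the calibration window
#'
#' When no manual labels are available, treats the upper quartile of
#' calibration-window `max_duc` values as pseudo-complete blinks and
#' calibrates on their median. Complete blinks dominate real sessions,
#' so the upper quartile is a conservative stand-in for labelled
#' completes.
#'
#' @inheritParams calibrate_from_labels
#' @param quantile_cut Quantile above which events count as
#'   pseudo-complete (default 0.75).
#' @return A `duc_calibration` object.
#' @export
auto_calibrate <- function(events, config = session_config(),
                           threshold_fraction = 0.75, min_events = 5L,
                           quantile_cut = 0.75) {
  window_end <- config$calibration_window * config$frame_rate
  vals <- events$max_duc[events$start_frame < window_end &
                           !is.na(events$max_duc)]
  if (length(vals) < min_events)
    stop("calibration insufficient: only ", length(vals),
         " blinks with max_duc in the calibration window", call. = FALSE)
  cut <- stats::quantile(vals, quantile_cut, names = FALSE)
  calibrate_duc(vals[vals >= cut], threshold_fraction, min_events = 1L)
}

#' Classify blinks as complete or incomplete
#'
#' A blink is incomplete when its `max_duc` is strictly below
#' `threshold_fraction * mm_duc`; equality and anything above count as
#' complete. Events without a `max_duc` value are labelled
#' `"unclassified"` (and noted).
#'
#' @param events A [blink_events()] table with `max_duc` filled.
#' @param model A [calibrate_duc()] result.
#' @return The events table with the `completeness` column set.
#' @export
classify_blinks <- function(events, model) {
  stopifnot(inherits(model, "duc_calibration"))
  known <- !is.na(events$max_duc)
  if (any(!known))
    message(sum(!known), " blink(s) left unclassified (no max_duc)")
  events$completeness[!known] <- "unclassified"
  events$completeness[known] <-
    ifelse(events$max_duc[known] < model$threshold, "incomplete", "complete")
  events
}
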