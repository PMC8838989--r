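#' Eye aspect ratio of one eye
#'
#' The eye aspect ratio (EAR) is the mean of the two eye heights divided
#' by the eye length,
#' \deqn{EAR = (|p_2 p_6| + |p_3 p_5|) / (2 |p_1 p_4|),}
#' all distances Euclidean. It sits around 0.3 for an open eye and drops
#' towards 0 as the lids close; frames with EAR below 0.2 are treated as
#' blink frames downstream.
#'
#' @param eye An [extract_eye_points()] result (6 x 2 matrix, rows
#'   `p1..p6`).
#' @return A single non-negative ratio.
#' @export
#' @examples
#' eye <- rbind(c(0, 0), c(3, -1), c(7, -1), c(10, 0), c(7, 1), c(3, 1))
#' rownames(eye) <- paste0("p", 1:6)
#' compute_ear(eye)  # (2 + 2) / (2 * 10) = 0.2
compute_ear <- function(eye) {
  eye <- unclass(eye)
  stopifnot(is.matrix(eye), nrow(eye) == 6L, ncol(eye) == 2L)
  len <- sqrt(sum((eye[1L, ] - eye[4L, ])^2))
  if (len == 0)
    stop("degenerate eye geometry: zero eye length", call. = FALSE)
  h1 <- sqrt(sum((eye[2L, ] - eye[6L, ])^2))
  h2 <- sqrt(sum((eye[3L, ] - eye[5L, ])^2))
  (h1 + h2) / (2 * len)
}

# Vectorized EAR over all frames of a stream for one eye; returns NA for
# degenerate (zero-length) frames.
.ear_vec <- function(stream, side) {
  idx <- .EYE_IDX[[side]] + 1L
  x <- stream$x[, idx, drop = FALSE]
  y <- stream$y[, idx, drop = FALSE]
  len <- sqrt((x[, 1] - x[, 4])^2 + (y[, 1] - y[, 4])^2)
  h1 <- sqrt((x[, 2] - x[, 6])^2 + (y[, 2] - y[, 6])^2)
  h2 <- sqrt((x[, 3] - x[, 5])^2 + (y[, 3] - y[, 5])^2)
  out <- (h1 + h2) / (2 * len)
  out[len == 0] <- NA_real_
  out
}

#' Per-frame EAR trace of a session
#'
#' Computes one EAR value per frame from a landmark stream. With
#' `mode = "mean"` (default) the left- and right-eye ratios are averaged,
#' which damps unilateral landmark jitter; either single eye can be
#' selected instead. Frames with degenerate eye geometry, and frames
#' missing from the stream (dropped frames), are imputed with the
#' previous valid value and recorded in the `imputed` element.
#'
#' @param stream A [landmark_stream()].
#' @param mode `"mean"`, `"left"` or `"right"`.
#' @return An object of class `ear_trace`: list with `values` (one per
#'   frame of the covered frame range), `frame_rate`, `start_frame`, and
#'   `imputed` (frame indices whose value was imputed).
#' @export
build_ear_trace <- function(stream, mode = c("mean", "left", "right")) {
  stopifnot(inherits(stream, "landmark_stream"))
  mode <- match.arg(mode)
  ear <- switch(mode,
                mean = rowMeans(cbind(.ear_vec(stream, "left"),
                                      .ear_vec(stream, "right"))),
                left = .ear_vec(stream, "left"),
                right = .ear_vec(stream, "right"))
  start <- stream$frame[1L]
  n <- stream$frame[length(stream$frame)] - start + 1L
  values <- rep(NA_real_, n)
  values[stream$frame - start + 1L] <- ear
  imputed <- which(is.na(values))
  if (length(imputed)) {
    if (is.na(values[1L])) {
      first_ok <- which(!is.na(values))[1L]
      if (is.na(first_ok))
        stop("no valid EAR value in stream", call. = FALSE)
      values[seq_len(first_ok - 1L)] <- values[first_ok]
    }
    # carry the last valid value forward
    filled <- !is.na(values)
    values <- values[cummax(seq_len(n) * filled)]
    message(length(imputed), " EAR value(s) imputed from the previous ",
            "valid frame")
  }
  structure(list(values = values, frame_rate = stream$frame_rate,
                 start_frame = start,
                 imputed = as.integer(imputed + start - 1L)),
            class = "ear_trace")
}

#' Construct an EAR trace directly from values
#'
#' @param values Non-negative per-frame EAR values.
#' @param frame_rate Frames per second.
#' @param start_frame Frame index of the first value.
#' @return An `ear_trace` object.
#' @export
ear_trace <- function(values, frame_rate = 60, start_frame = 0L) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("EAR trace must be non-empty", call. = FALSE)
  if (anyNA(values) || any(values < 0))
    stop("EAR values must be non-negative and non-missing", call. = FALSE)
  structure(list(values = values, frame_rate = frame_rate,
                 start_frame = as.integer(start_frame), imputed = integer(0)),
            class = "ear_trace")
}

#' @export
print.ear_trace <- function(x, ...) {
  cat(sprintf("EAR trace: %d frames from frame %d at %g frames/s (range %.3f..%.3f)\n",
              length(x$values), x$start_frame, x$frame_rate,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Segment blinks from an EAR trace
#'
#' A blink is a maximal run of consecutive frames with EAR strictly below
#' `threshold`; it begins when EAR drops below the threshold and ends when
#' EAR reaches it again (frames with EAR exactly at the threshold count
#' as open). Runs shorter than `min_blink_frames` are discarded as
#' landmark noise; runs truncated by the start or end of the trace are
#' kept and flagged `open_ended`.
#'
#' @param trace An [ear_trace()] (or [build_ear_trace()] result).
#' @param threshold Positive EAR threshold; default 0.2.
#' @param min_blink_frames Minimum run length kept, default 2
#'   (about 33 ms at 60 frames/s).
#' @return A `blink_events` data frame with columns `start_frame`,
#'   `n_frames`, `end_frame`, `open_ended`, `completeness`
#'   (initially `"unclassified"`) and `max_duc` (initially `NA`),
#'   sorted and non-overlapping.
#' @export
#' @examples
#' tr <- ear_trace(c(0.3, 0.15, 0.1, 0.15, 0.3))
#' segment_blinks(tr)  # one blink: start 1, 3 frames
segment_blinks <- function(trace, threshold = 0.2, min_blink_frames = 2L) {
  stopifnot(inherits(trace, "ear_trace"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("config error: `threshold` must be a single positive number",
         call. = FALSE)
  min_blink_frames <- max(1L, as.integer(min_blink_frames))
  v <- trace$values
  r <- rle(v < threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_blink_frames
  starts <- starts[keep]; lens <- r$lengths[keep]; ends <- ends[keep]
  open_ended <- (starts == 1L) | (ends == length(v))
  blink_events(start_frame = trace$start_frame + starts - 1L,
               n_frames = lens,
               open_ended = open_ended)
}

#' Construct a blink event table
#'
#' @param start_frame Integer start frames `f_i` (must be sorted; events
#'   must not overlap).
#' @param n_frames Frame counts `n_i` (>= 1); the end frame is
#'   `f_i + n_i - 1`.
#' @param open_ended Logical; run truncated by a trace boundary.
#' @param completeness One of `"complete"`, `"incomplete"`,
#'   `"unclassified"` per event.
#' @param max_duc Per-event maximal upper-eyelid descent (pixels), or NA.
#' @return A data frame of class `blink_events`.
#' @export
blink_events <- function(start_frame, n_frames,
                         open_ended = FALSE,
                         completeness = "unclassified",
                         max_duc = NA_real_) {
  start_frame <- as.integer(start_frame)
  n_frames <- as.integer(n_frames)
  n <- length(start_frame)
  if (length(n_frames) != n)
    stop("start_frame and n_frames differ in length", call. = FALSE)
  if (any(n_frames < 1L)) stop("n_frames must be >= 1", call. = FALSE)
  df <- data.frame(start_frame = start_frame,
                   n_frames = n_frames,
                   end_frame = start_frame + n_frames - 1L,
                   open_ended = rep_len(as.logical(open_ended), n),
                   completeness = rep_len(as.character(completeness), n),
                   max_duc = rep_len(as.numeric(max_duc), n))
  if (n > 1L) {
    if (is.unsorted(df$start_frame, strictly = TRUE))
      stop("blink events must be sorted by start frame", call. = FALSE)
    if (any(df$start_frame[-1L] <= df$end_frame[-n]))
      stop("blink events must not overlap", call. = FALSE)
  }
  class(df) <- c("blink_events", "data.frame")
  df
}

#' Start-to-start intervals between consecutive blinks
#'
#' The interval between adjacent blinks is measured between their start
#' frames, `(f_{k+1} - f_k) / frame_rate`.
#'
#' @param events A [blink_events()] table.
#' @param frame_rate Frames per second.
#' @return Numeric vector of seconds, length `nrow(events) - 1`; empty
#'   when fewer than two events.
#' @export
blink_intervals <- function(events, frame_rate) {
  stopifnot(inherits(events, "data.frame"))
  if (nrow(events) < 2L) return(numeric(0))
  diff(events$start_frame) / frame_rate
}

#' Write a blink event table to CSV
#'
#' @param events A [blink_events()] table.
#' @param path Output path.
#' @param subject Subject identifier recorded in the file.
#' @param frame_rate Frames per second used to derive the `start_s` and
#'   `duration_s` columns.
#' @return `path`, invisibly.
#' @export
write_blink_events <- function(events, path, subject = "s1", frame_rate = 60) {
  out <- data.table::data.table(
    subject = subject,
    start_frame = events$start_frame,
    n_frames = events$n_frames,
    start_s = events$start_frame / frame_rate,
    duration_s = events$n_frames / frame_rate,
    completeness = events$completeness,
    max_duc = events$max_duc)
  data.table::fwrite(out, path)
  invisible(path)
}

#' Read a blink event table written by [write_blink_events()]
#'
#' @param path CSV path.
#' @return A [blink_events()] table (subject column attached as an
#'   attribute).
#' @export
read_blink_events <- function(path) {
  dt <- data.table::fread(path, showProgress = FALSE)
  ev <- blink_events(start_frame = dt$start_frame, n_frames = dt$n_frames,
                     completeness = if ("completeness" %in% names(dt))
                       dt$completeness else "unclassified",
                     max_duc = if ("max_duc" %in% names(dt))
                       dt$max_duc else NA_real_)
  attr(ev, "subject") <- if ("subject" %in% names(dt)) dt$subject[1L] else NA
  ev
}
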