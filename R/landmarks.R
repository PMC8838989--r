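#' @importFrom data.table fread fwrite data.table
NULL

# Indices (0-based, standard 68-point facial annotation) of the six key
# points of each eye, in the order corner / upper lid x2 / corner /
# lower lid x2 used by the aspect-ratio formula.
.EYE_IDX <- list(right = 36:41, left = 42:47)

#' Construct a landmark stream
#'
#' A landmark stream holds, per video frame, the 68 facial key points of
#' the standard annotation scheme (indices 0--67; the eyes occupy 36--47).
#' Coordinates follow image convention: x rightward, y downward, 0-based
#' pixels.
#'
#' @param frame Integer vector of frame indices, strictly increasing,
#'   all >= 0.
#' @param x,y Numeric matrices with one row per frame and 68 columns of
#'   pixel coordinates; all finite and non-negative.
#' @param frame_rate Frames per second (default 60).
#'
#' @return An object of class `landmark_stream`: a list with elements
#'   `frame`, `x`, `y`, `frame_rate` and `gaps` (frame indices missing
#'   from the covered range; dropped frames are reported, never silently
#'   filled).
#' @export
landmark_stream <- function(frame, x, y, frame_rate = 60) {
  frame <- as.integer(frame)
  x <- as.matrix(x); y <- as.matrix(y)
  if (length(frame) == 0L) stop("empty landmark stream", call. = FALSE)
  if (ncol(x) != 68L || ncol(y) != 68L)
    stop("landmark frames must carry exactly 68 points", call. = FALSE)
  if (nrow(x) != length(frame) || nrow(y) != length(frame))
    stop("coordinate matrices and frame vector differ in length",
         call. = FALSE)
  if (anyNA(frame) || any(frame < 0L))
    stop("frame indices must be non-negative integers", call. = FALSE)
  if (is.unsorted(frame, strictly = TRUE))
    stop("ordering error: frame indices must be strictly increasing",
         call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("landmark coordinates must be finite", call. = FALSE)
  if (min(x) < 0 || min(y) < 0)
    stop("landmark coordinates must be non-negative", call. = FALSE)
  gaps <- setdiff(seq(frame[1L], frame[length(frame)]), frame)
  if (length(gaps))
    message(length(gaps), " dropped frame(s) in landmark stream (e.g. frame ",
            gaps[1L], ")")
  structure(list(frame = frame, x = unname(x), y = unname(y),
                 frame_rate = frame_rate, gaps = as.integer(gaps)),
            class = "landmark_stream")
}

#' @export
print.landmark_stream <- function(x, ...) {
  cat(sprintf("Landmark stream: %d frames (%d..%d) at %g frames/s",
              length(x$frame), x$frame[1], x$frame[length(x$frame)],
              x$frame_rate))
  if (length(x$gaps)) cat(sprintf(", %d dropped", length(x$gaps)))
  cat("\n")
  invisible(x)
}

#' Parse a landmark stream from CSV
#'
#' Expects a header with columns `frame`, `x0`..`x67`, `y0`..`y67`. Rows
#' with missing or non-numeric values raise a parse error naming the
#' offending row; non-monotonic frame indices raise an ordering error.
#' Gaps (dropped frames) are reported in the returned object, not filled.
#'
#' @param path CSV file path.
#' @param frame_rate Frames per second to attach (default 60).
#' @return A [landmark_stream()].
#' @export
read_landmarks <- function(path, frame_rate = 60) {
  if (!file.exists(path)) stop("landmark file not found: ", path, call. = FALSE)
  if (file.size(path) == 0)
    stop("parse error: ", path, " is empty", call. = FALSE)
  dt <- tryCatch(
    data.table::fread(path, header = TRUE, fill = TRUE, showProgress = FALSE),
    error = function(e) stop("parse error reading ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  wanted <- c("frame", paste0("x", 0:67), paste0("y", 0:67))
  miss <- setdiff(wanted, names(dt))
  if (length(miss))
    stop("landmark file lacks required columns (first missing: ", miss[1L],
         ")", call. = FALSE)
  dt <- dt[, wanted, with = FALSE]
  bad <- which(!stats::complete.cases(dt))
  if (length(bad))
    stop("parse error: row ", bad[1L], " of ", path,
         " has missing or malformed values", call. = FALSE)
  landmark_stream(frame = dt[["frame"]],
                  x = as.matrix(dt[, paste0("x", 0:67), with = FALSE]),
                  y = as.matrix(dt[, paste0("y", 0:67), with = FALSE]),
                  frame_rate = frame_rate)
}

#' Write a landmark stream to CSV
#'
#' Inverse of [read_landmarks()]; the round trip is lossless for frame
#' indices and coordinates.
#'
#' @param stream A [landmark_stream()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(stream, path) {
  stopifnot(inherits(stream, "landmark_stream"))
  xs <- data.table::as.data.table(stream$x)
  ys <- data.table::as.data.table(stream$y)
  data.table::setnames(xs, paste0("x", 0:67))
  data.table::setnames(ys, paste0("y", 0:67))
  dt <- cbind(data.table::data.table(frame = stream$frame), xs, ys)
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Extract the six eye key points of one frame
#'
#' Maps landmark indices 36--41 (right eye of the annotation scheme) or
#' 42--47 (left eye) onto the six aspect-ratio roles: `p1` and `p4` are
#' the corners whose separation is the eye length, `p2`/`p6` and
#' `p3`/`p5` are the upper/lower lid pairs whose separations are the two
#' eye heights.
#'
#' @param frame Either a [landmark_stream()] (then `index` selects the
#'   row) or a numeric vector of length 136 (`x0..x67, y0..y67`).
#' @param side `"left"` or `"right"` (annotation-scheme side).
#' @param index Row position within the stream (default 1).
#'
#' @return An object of class `eye_points`: a 6 x 2 matrix with rows
#'   `p1..p6` and columns `x`, `y`.
#' @export
extract_eye_points <- function(frame, side = c("right", "left"), index = 1L) {
  side <- match.arg(side)
  idx <- .EYE_IDX[[side]]
  if (inherits(frame, "landmark_stream")) {
    px <- frame$x[index, idx + 1L]
    py <- frame$y[index, idx + 1L]
  } else {
    frame <- as.numeric(frame)
    if (length(frame) != 136L)
      stop("a raw frame must be 136 values (x0..x67, y0..y67)", call. = FALSE)
    px <- frame[idx + 1L]
    py <- frame[idx + 69L]
  }
  m <- cbind(x = px, y = py)
  rownames(m) <- paste0("p", 1:6)
  if (sqrt(sum((m[1L, ] - m[4L, ])^2)) == 0)
    stop("degenerate eye geometry: zero eye length (|p1 p4| = 0)",
         call. = FALSE)
  structure(m, class = c("eye_points", class(m)), side = side)
}

#' Crop the eye region from a frame image
#'
#' Returns the grayscale crop covering the eye bounding box expanded by
#' `margin_px` and clipped to the image; the crop origin within the full
#' frame is recorded so crop coordinates map back to frame coordinates.
#'
#' @param img Numeric matrix, rows = image rows (y), columns = x, grayscale
#'   intensities 0--255.
#' @param eye An [extract_eye_points()] result, in frame coordinates.
#' @param margin_px Non-negative integer margin added on each side.
#' @return An [eye_image()] whose `offset` attribute is `c(x0, y0)`
#'   (0-based position of the crop's top-left pixel in the frame).
#' @export
crop_eye_region <- function(img, eye, margin_px = 0L) {
  stopifnot(is.matrix(img), margin_px >= 0)
  w <- ncol(img); h <- nrow(img)
  x0 <- floor(min(eye[, "x"])); x1 <- ceiling(max(eye[, "x"]))
  y0 <- floor(min(eye[, "y"])); y1 <- ceiling(max(eye[, "y"]))
  if (x1 < 0 || y1 < 0 || x0 > w - 1L || y0 > h - 1L)
    stop("out-of-bounds: eye lies outside the frame image", call. = FALSE)
  x0 <- max(0L, x0 - margin_px); x1 <- min(w - 1L, x1 + margin_px)
  y0 <- max(0L, y0 - margin_px); y1 <- min(h - 1L, y1 + margin_px)
  eye_image(img[(y0 + 1L):(y1 + 1L), (x0 + 1L):(x1 + 1L), drop = FALSE],
            offset = c(x0, y0))
}

#' Grayscale eye-region image
#'
#' Thin wrapper marking a numeric matrix as a grayscale eye crop
#' (intensities on the 0--255 scale) and carrying its origin offset
#' within the source frame.
#'
#' @param pixels Numeric matrix, rows = y, columns = x.
#' @param offset `c(x0, y0)` 0-based position of pixel `[1, 1]` in the
#'   full frame.
#' @param frame_index Optional source frame index.
#' @return The matrix with class `eye_image` and attributes `offset`,
#'   `frame_index`.
#' @export
eye_image <- function(pixels, offset = c(0L, 0L), frame_index = NA_integer_) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) < 4L || ncol(pixels) < 4L)
    stop("eye image must be at least 4 x 4 pixels", call. = FALSE)
  structure(pixels, class = c("eye_image", "matrix", "array"),
            offset = as.numeric(offset), frame_index = frame_index)
}

#' Map crop coordinates back to frame coordinates
#'
#' @param crop An [eye_image()].
#' @param xy Two-column matrix (or length-2 vector) of 0-based crop
#'   coordinates `(x, y)`.
#' @return Matrix of frame coordinates.
#' @export
crop_to_frame_coords <- function(crop, xy) {
  off <- attr(crop, "offset")
  xy <- rbind(xy)
  cbind(x = xy[, 1] + off[1], y = xy[, 2] + off[2])
}
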