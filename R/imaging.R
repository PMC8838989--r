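# Imaging chain for incomplete-blink detection: single-scale retinex
# enhancement, bicubic magnification, fixed-threshold binarization, and
# eyelid-contour extraction yielding the upper-eyelid-to-corner distance
# D_uc per frame.

# Row-normalized truncated Gaussian weight matrix mapping n input
# positions onto themselves; truncation to the image extent plays the
# role of replicate padding.
.gauss_weights <- function(n, sigma) {
  d <- outer(seq_len(n), seq_len(n), "-")
  w <- exp(-(d * d) / (2 * sigma * sigma))
  w / rowSums(w)
}

#' Single-scale retinex enhancement
#'
#' Removes slow illumination variation from a grayscale eye image by
#' subtracting, in the log domain, a large-scale Gaussian surround:
#' `log(I + eps) - log(G_sigma * I + eps)`, then rescales the result to
#' the 0--255 intensity range. The surround scale defaults to 300 px,
#' far larger than a typical eye crop, so the surround is close to the
#' global mean and the transform mainly compresses dynamic range.
#'
#' @param img Grayscale numeric matrix (0--255), e.g. an [eye_image()].
#' @param scale Gaussian surround standard deviation in pixels
#'   (default 300).
#' @param eps Positive offset applied before taking logs so that
#'   zero-intensity pixels are defined (default 1; a message notes when
#'   it takes effect).
#' @return Matrix of the same dimensions on the 0--255 scale; a constant
#'   input yields a constant (zero) output.
#' @export
enhance_ssr <- function(img, scale = 300, eps = 1) {
  stopifnot(is.matrix(img), scale > 0, eps > 0)
  m <- unclass(img)
  if (any(m <= 0))
    message("zero-intensity pixels present; epsilon offset ", eps, " applied")
  surround <- .gauss_weights(nrow(m), scale) %*% m %*%
    t(.gauss_weights(ncol(m), scale))
  r <- log(m + eps) - log(surround + eps)
  rng <- range(r)
  # a (numerically) constant log-ratio means illumination was all there
  # was; return a flat zero image rather than amplifying rounding noise
  out <- if (rng[2] - rng[1] > 1e-8) (r - rng[1]) / (rng[2] - rng[1]) * 255
         else r * 0
  attributes(out) <- attributes(m)[c("dim")]
  if (inherits(img, "eye_image"))
    out <- eye_image(out, offset = attr(img, "offset"),
                     frame_index = attr(img, "frame_index"))
  out
}

# Keys bicubic convolution kernel, a = -0.5 (reproduces quadratics).
.keys_kernel <- function(t) {
  t <- abs(t)
  ifelse(t <= 1, 1.5 * t^3 - 2.5 * t^2 + 1,
         ifelse(t < 2, -0.5 * t^3 + 2.5 * t^2 - 4 * t + 2, 0))
}

# (n_out x n_in) interpolation weight matrix for one axis; border samples
# replicated. Centers aligned: output pixel i samples input coordinate
# (i + 0.5)/f - 0.5.
.resize_weights <- function(n_in, n_out, kernel_fun, support) {
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5   # 0-based
  base <- floor(src)
  offs <- seq(-support + 1L, support)
  w <- matrix(0, n_out, n_in)
  for (k in offs) {
    j <- base + k
    wt <- kernel_fun(src - j)
    j <- pmin(pmax(j, 0L), n_in - 1L)                  # replicate border
    idx <- cbind(seq_len(n_out), j + 1L)
    w[idx] <- w[idx] + wt
  }
  w / rowSums(w)
}

#' Magnify an image by cubic interpolation
#'
#' Resizes by a factor >= 1 with separable Keys bicubic convolution
#' (`a = -0.5`); output dimensions are `round(dim * factor)`. The default
#' factor of 33 matches the enlargement applied before binarization in
#' the contour chain; since the downstream incompleteness rule is
#' ratio-based, the factor does not affect classification.
#'
#' @param img Grayscale numeric matrix.
#' @param factor Magnification factor, >= 1 (default 33).
#' @param method `"cubic"` (default) or `"bilinear"` (for comparison).
#' @return Resized matrix.
#' @export
magnify <- function(img, factor = 33, method = c("cubic", "bilinear")) {
  stopifnot(is.matrix(img))
  method <- match.arg(method)
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1)
    stop("config error: magnification factor must be >= 1", call. = FALSE)
  m <- unclass(img)
  h_out <- as.integer(round(nrow(m) * factor))
  w_out <- as.integer(round(ncol(m) * factor))
  if (h_out == nrow(m) && w_out == ncol(m)) return(m)
  if (method == "cubic") {
    wr <- .resize_weights(nrow(m), h_out, .keys_kernel, 2L)
    wc <- .resize_weights(ncol(m), w_out, .keys_kernel, 2L)
  } else {
    tri <- function(t) pmax(0, 1 - abs(t))
    wr <- .resize_weights(nrow(m), h_out, tri, 1L)
    wc <- .resize_weights(ncol(m), w_out, tri, 1L)
  }
  wr %*% m %*% t(wc)
}

#' Binarize a grayscale image at a fixed threshold
#'
#' Pixels with intensity greater than or equal to `threshold` become
#' foreground (`TRUE`), all others background. On enhanced eye images the
#' bright foreground is the visible eye opening (sclera); iris and skin
#' fall below the default threshold of 139.
#'
#' @param img Grayscale numeric matrix on the 0--255 scale.
#' @param threshold Intensity threshold (default 139).
#' @return Logical matrix of the same dimensions.
#' @export
binarize <- function(img, threshold = 139) {
  stopifnot(is.matrix(img))
  unclass(img) >= threshold
}

#' Extract the eye contour from a binarized image
#'
#' Keeps the largest connected foreground component, applies
#' morphological cleanup (closing to seal pixel gaps, then hole filling
#' so interior dark structure such as the iris does not puncture the
#' shape), and returns its ordered boundary chain. Two reference points
#' are located on the boundary: `upper_mid`, the topmost boundary pixel
#' in the component's horizontal midpoint column (the upper-eyelid
#' midpoint), and `corner`, the boundary pixel at the component's
#' extreme x on the designated corner side.
#'
#' @param bin Logical (or 0/1) matrix, `TRUE` = foreground.
#' @param corner Which horizontal extreme is the reference eye corner:
#'   `"right"` (default; the temporal side for the scheme's right eye)
#'   or `"left"`.
#' @param cleanup Apply morphological closing + hole filling
#'   (default TRUE).
#' @return An object of class `eye_contour`: list with `boundary`
#'   (m x 2 matrix of 0-based `(x, y)` boundary pixels in chain order),
#'   `upper_mid` and `corner` (`(x, y)` points), and `area` (component
#'   pixel count). Warns when the component touches all four image
#'   borders (unreliable contour).
#' @export
extract_contour <- function(bin, corner = c("right", "left"),
                            cleanup = TRUE) {
  corner <- match.arg(corner)
  m <- unclass(bin) * 1
  if (!any(m > 0)) stop("no-contour: empty foreground", call. = FALSE)
  lab <- EBImage::bwlabel(m)
  sizes <- tabulate(as.integer(lab))
  biggest <- which.max(sizes)
  mask <- (lab == biggest) * 1
  if (cleanup) {
    mask <- EBImage::closing(mask, EBImage::makeBrush(3, "box"))
    mask <- EBImage::fillHull(mask)
  }
  mm <- as.matrix(mask) > 0
  rows <- row(mm)[mm]; cols <- col(mm)[mm]   # 1-based y, x
  if (min(rows) == 1L && max(rows) == nrow(mm) &&
      min(cols) == 1L && max(cols) == ncol(mm))
    warning("unreliable contour: component touches all image borders",
            call. = FALSE)
  oc <- EBImage::ocontour(EBImage::bwlabel(mask))[[1L]]
  boundary <- cbind(x = oc[, 2L], y = oc[, 1L])  # ocontour: (row, col) 0-based
  cx <- as.integer(round((min(cols) + max(cols)) / 2))
  ys <- which(mm[, cx])
  if (!length(ys)) {  # midpoint column empty (e.g. crescent shape)
    cx <- cols[which.min(abs(cols - cx))]
    ys <- which(mm[, cx])
  }
  upper_mid <- c(x = cx - 1L, y = min(ys) - 1L)
  xc <- if (corner == "right") max(cols) else min(cols)
  yc_rows <- which(mm[, xc])
  corner_pt <- c(x = xc - 1L, y = as.integer(floor(mean(range(yc_rows)))) - 1L)
  structure(list(boundary = boundary, upper_mid = upper_mid,
                 corner = corner_pt, area = sum(mm)),
            class = "eye_contour")
}

#' Upper-eyelid-to-corner distance of one frame
#'
#' The signed vertical (image-row) offset between the upper-eyelid
#' midpoint and the eye corner,
#' `D_uc = y(upper_mid) - y(corner)`. With y pointing down, an upper
#' eyelid above the corner gives a negative value and a descending lid
#' increases `D_uc`; the per-blink maximum of `D_uc` therefore indexes
#' the deepest lid descent of the blink.
#'
#' @param contour An [extract_contour()] result.
#' @return Signed distance in (magnified-image) pixels.
#' @export
compute_duc <- function(contour) {
  stopifnot(inherits(contour, "eye_contour"))
  unname(contour$upper_mid["y"] - contour$corner["y"])
}

#' Run the full imaging chain on one eye image
#'
#' Convenience wrapper applying, in order, single-scale retinex
#' enhancement, cubic magnification, binarization and contour
#' extraction, and returning the frame's `D_uc`.
#'
#' @param img Grayscale eye image (0--255 matrix).
#' @param scale SSR surround scale (default 300 px).
#' @param factor Magnification factor (default 33).
#' @param threshold Binarization threshold (default 139).
#' @param corner Corner side passed to [extract_contour()].
#' @return `D_uc` in magnified-image pixels (scalar).
#' @export
duc_from_image <- function(img, scale = 300, factor = 33, threshold = 139,
                           corner = "right") {
  enhanced <- enhance_ssr(img, scale = scale)
  big <- magnify(enhanced, factor = factor)
  bin <- binarize(big, threshold = threshold)
  compute_duc(extract_contour(bin, corner = corner))
}

#' Maximal eyelid descent per blink
#'
#' Attaches to each blink event the maximum of the per-frame `D_uc`
#' values over the event's frames. Events with some frames missing from
#' the supplied values are computed over the available frames and
#' flagged; events with no available frame keep `NA`.
#'
#' @param events A [blink_events()] table.
#' @param duc Numeric vector of per-frame `D_uc` values.
#' @param duc_frames Frame indices corresponding to `duc` (default
#'   `seq_along(duc) - 1`).
#' @return The events table with `max_duc` filled; a logical attribute
#'   `duc_partial` marks events with missing frames.
#' @export
max_duc_per_blink <- function(events, duc,
                              duc_frames = seq_along(duc) - 1L) {
  stopifnot(length(duc) == length(duc_frames))
  partial <- logical(nrow(events))
  for (i in seq_len(nrow(events))) {
    want <- events$start_frame[i]:events$end_frame[i]
    hit <- duc_frames %in% want
    if (!any(hit)) {
      partial[i] <- TRUE
      next
    }
    if (sum(hit) < length(want)) partial[i] <- TRUE
    events$max_duc[i] <- max(duc[hit])
  }
  if (any(partial))
    message(sum(partial), " blink(s) had missing D_uc frames")
  attr(events, "duc_partial") <- partial
  events
}
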