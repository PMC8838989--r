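#' Session configuration
#'
#' Bundles the recording-session parameters used throughout the pipeline:
#' camera frame rate, the partition of the session into equal phases, the
#' length of the calibration window at the start of the session, and the
#' target resolution to which face frames are downsampled before
#' landmarking.
#'
#' @param frame_rate Frames per second of the landmark stream. Default 60.
#' @param phase_duration Length of one phase in seconds. Default 1800
#'   (30 min).
#' @param n_phases Number of consecutive phases. Default 4.
#' @param calibration_window Length, in seconds, of the initial window used
#'   to calibrate the incomplete-blink threshold. Default 600 (10 min).
#'   Must not exceed the total session duration.
#' @param downsample_target Integer vector `c(width, height)` giving the
#'   resolution face frames are reduced to before landmark extraction.
#'   Default `c(600, 450)`.
#'
#' @return An object of class `session_config` (a named list).
#' @export
#' @examples
#' cfg <- session_config()
#' cfg$frame_rate
session_config <- function(frame_rate = 60,
                           phase_duration = 1800,
                           n_phases = 4,
                           calibration_window = 600,
                           downsample_target = c(600L, 450L)) {
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0)
    stop("`frame_rate` must be a single positive number", call. = FALSE)
  if (!is.numeric(phase_duration) || phase_duration <= 0)
    stop("`phase_duration` must be positive", call. = FALSE)
  n_phases <- as.integer(n_phases)
  if (is.na(n_phases) || n_phases < 1L)
    stop("`n_phases` must be a positive integer", call. = FALSE)
  if (calibration_window <= 0 || calibration_window > phase_duration * n_phases)
    stop("`calibration_window` must lie within the total session duration",
         call. = FALSE)
  if (length(downsample_target) != 2L || any(downsample_target < 1))
    stop("`downsample_target` must be c(width, height)", call. = FALSE)
  structure(list(frame_rate = frame_rate,
                 phase_duration = phase_duration,
                 n_phases = n_phases,
                 calibration_window = calibration_window,
                 downsample_target = as.integer(downsample_target)),
            class = "session_config")
}

#' @export
print.session_config <- function(x, ...) {
  cat("Session configuration\n")
  cat(sprintf("  frame rate        : %g frames/s\n", x$frame_rate))
  cat(sprintf("  phases            : %d x %g s\n", x$n_phases, x$phase_duration))
  cat(sprintf("  calibration window: %g s\n", x$calibration_window))
  cat(sprintf("  downsample target : %d x %d px\n",
              x$downsample_target[1], x$downsample_target[2]))
  invisible(x)
}

#' Read a session configuration from a YAML-like key: value file
#'
#' Accepts a plain-text file with one `key: value` pair per line (a subset
#' of YAML); unknown keys are rejected so typos surface early.
#'
#' @param path Path to the config file.
#' @return A [session_config()] object.
#' @export
read_session_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- vapply(kv, function(p) trimws(p[1]), character(1))
  vals <- vapply(kv, function(p) trimws(paste(p[-1], collapse = ":")),
                 character(1))
  allowed <- c("frame_rate", "phase_duration", "n_phases",
               "calibration_window", "downsample_width", "downsample_height")
  bad <- setdiff(keys, allowed)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  get_num <- function(key, default) {
    if (key %in% keys) as.numeric(vals[match(key, keys)]) else default
  }
  session_config(
    frame_rate = get_num("frame_rate", 60),
    phase_duration = get_num("phase_duration", 1800),
    n_phases = get_num("n_phases", 4),
    calibration_window = get_num("calibration_window", 600),
    downsample_target = c(get_num("downsample_width", 600),
                          get_num("downsample_height", 450)))
}
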