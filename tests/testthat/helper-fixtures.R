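# Shared fixtures and independent oracles used across the suite.

# Random valid six-point eye geometry (rows p1..p6), guaranteed
# non-degenerate eye length.
random_eye <- function() {
  repeat {
    m <- matrix(runif(12, 0, 200), 6, 2)
    rownames(m) <- paste0("p", 1:6)
    colnames(m) <- c("x", "y")
    if (sqrt(sum((m[1, ] - m[4, ])^2)) > 1e-6) return(m)
  }
}

# Independently coded aspect-ratio oracle using stats::dist.
ear_oracle <- function(eye) {
  d <- function(a, b) as.numeric(stats::dist(rbind(eye[a, ], eye[b, ])))
  (d(2, 6) + d(3, 5)) / (2 * d(1, 4))
}

# Brute-force blink-group scanner: walks every event and grows a group
# while the next start-to-start gap is below the window.
groups_bruteforce <- function(starts_s, window = 1.0) {
  n <- length(starts_s)
  out <- list()
  i <- 1L
  while (i < n) {
    j <- i
    while (j < n && (starts_s[j + 1L] - starts_s[j]) < window) j <- j + 1L
    if (j > i) out[[length(out) + 1L]] <- c(first = i, size = j - i + 1L)
    i <- j + 1L
  }
  out
}

# Minimal 68-point frame vector (x0..x67, y0..y67) with the eye points
# set; all other landmarks at a constant.
flat_frame <- function(eyes = list()) {
  x <- rep(50, 68); y <- rep(50, 68)
  for (side in names(eyes)) {
    idx <- if (side == "right") 37:42 else 43:48
    x[idx] <- eyes[[side]][, 1]
    y[idx] <- eyes[[side]][, 2]
  }
  c(x, y)
}

# A short synthetic spec (4 x 2.5 min) used where session length is
# irrelevant; keeps unit tests quick.
short_spec <- function(seed = 1L, ...) {
  synthetic_spec(seed = seed, phase_duration = 150, ...)
}

write_landmark_csv <- function(stream, dir = tempdir()) {
  path <- tempfile("lms", fileext = ".csv", tmpdir = dir)
  write_landmarks(stream, path)
  path
}
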