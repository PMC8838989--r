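# Ground-truthed synthetic blink sessions: eyelid-aperture kinematics,
# 68-point landmark streams whose EAR follows the aperture exactly, and
# minimal rendered eye images (sclera / iris / skin bands under moving
# lids) for exercising the contour chain. Defaults emulate the study
# conditions: 60 frames/s, four 30-min phases, per-phase blink rates and
# durations that drift the way a fatiguing session does.

# inverse-CDF truncated normal
.rtnorm <- function(n, mean, sd, lower, upper) {
  p <- stats::runif(n, stats::pnorm(lower, mean, sd),
                    stats::pnorm(upper, mean, sd))
  stats::qnorm(p, mean, sd)
}

#' Synthetic-session specification
#'
#' Collects every knob of the generator. The defaults encode a
#' fatiguing four-phase session: blink rate rising from about 14.8 to
#' 23.6 blinks/min, blink duration lengthening from 0.57 to 0.75 s,
#' burst (group-blink) probability rising, and the incomplete-blink
#' fraction falling from about 10% to 5%. Complete blinks descend to a
#' lid-closure depth near 1 (full closure), incomplete blinks bottom out
#' around 0.55 of full closure; the two depth distributions are
#' separated by more than three standard deviations, as the manual
#' complete/incomplete labelling of real sessions presumes.
#'
#' @param seed Integer seed; all generator randomness flows from it.
#' @param frame_rate Frames per second (default 60).
#' @param n_phases Number of phases (default 4).
#' @param phase_duration Phase length in seconds (default 1800).
#' @param blink_rate Per-phase blink rates, blinks/min.
#' @param duration_mean,duration_sd Per-phase blink-duration mean and
#'   common sd, seconds (duration = time the eye spends below the
#'   detection threshold).
#' @param burst_prob Per-phase probability that a blink anchors a burst
#'   of rapid follow-up blinks.
#' @param burst_gap Range (s) of start-to-start gaps inside a burst;
#'   must stay below 1 s.
#' @param burst_size_prob Geometric parameter for the number of
#'   follow-up blinks per burst (mean extras = 1/prob).
#' @param incomplete_prob Per-phase probability that a blink is
#'   incomplete.
#' @param complete_depth,incomplete_depth Length-4 vectors
#'   `c(mean, sd, lower, upper)` of the truncated-normal lid-descent
#'   depth (fraction of full closure) for the two classes; complete must
#'   lie above incomplete.
#' @param duc_scale Pixels of maximal eyelid descent (`max_duc`) per
#'   unit lid-closure depth in the ground truth (default 400, roughly a
#'   12-px descent at 33x magnification).
#' @param landmark_noise_sd Gaussian pixel noise added to every landmark
#'   coordinate (default 0.5 px).
#' @param baseline_ear Open-eye EAR (default 0.3).
#' @param detect_threshold EAR blink threshold the session is built
#'   around (default 0.2).
#' @param min_gap Refractory floor (s) between non-burst blink starts;
#'   keeps spontaneous sub-second gaps out so group structure is
#'   plantable (default 1.3).
#' @param eye_length_px Eye length in the landmark template (default 60).
#' @param render_size `c(width, height)` of rendered eye images.
#' @param render_intensity `c(sclera, skin, iris)` gray levels.
#' @param lid_amp,lower_depth,iris_radius Render geometry (px): maximal
#'   upper-lid excursion above the corner line, lower-lid pocket depth,
#'   iris radius.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L,
                           frame_rate = 60,
                           n_phases = 4L,
                           phase_duration = 1800,
                           blink_rate = c(443, 545, 664, 708) / 30,
                           duration_mean = c(0.57, 0.63, 0.68, 0.75),
                           duration_sd = 0.12,
                           burst_prob = c(0.06, 0.08, 0.10, 0.11),
                           burst_gap = c(0.5, 0.8),
                           burst_size_prob = 0.6,
                           incomplete_prob = c(0.104, 0.061, 0.048, 0.047),
                           complete_depth = c(0.95, 0.04, 0.85, 1.00),
                           incomplete_depth = c(0.55, 0.06, 0.40, 0.65),
                           duc_scale = 400,
                           landmark_noise_sd = 0.5,
                           baseline_ear = 0.3,
                           detect_threshold = 0.2,
                           min_gap = 1.3,
                           eye_length_px = 60,
                           render_size = c(64L, 44L),
                           render_intensity = c(230, 90, 40),
                           lid_amp = 14,
                           lower_depth = 6,
                           iris_radius = 3) {
  n_phases <- as.integer(n_phases)
  rep_phase <- function(v) rep_len(as.numeric(v), n_phases)
  blink_rate <- rep_phase(blink_rate)
  if (any(blink_rate <= 0)) stop("blink rates must be positive", call. = FALSE)
  if (burst_gap[2] >= 1)
    stop("burst gaps must stay below one second", call. = FALSE)
  if (incomplete_depth[1] >= complete_depth[1] ||
      incomplete_depth[4] >= complete_depth[3])
    stop("depth distributions must be ordered: complete deeper than incomplete",
         call. = FALSE)
  delta <- 1 - detect_threshold / baseline_ear
  if (incomplete_depth[3] <= delta)
    warning("shallowest incomplete blinks barely cross the detection ",
            "threshold; expect marginal events", call. = FALSE)
  structure(list(seed = as.integer(seed), frame_rate = frame_rate,
                 n_phases = n_phases, phase_duration = phase_duration,
                 blink_rate = blink_rate,
                 duration_mean = rep_phase(duration_mean),
                 duration_sd = duration_sd,
                 burst_prob = rep_phase(burst_prob),
                 burst_gap = burst_gap,
                 burst_size_prob = burst_size_prob,
                 incomplete_prob = rep_phase(incomplete_prob),
                 complete_depth = complete_depth,
                 incomplete_depth = incomplete_depth,
                 duc_scale = duc_scale,
                 landmark_noise_sd = landmark_noise_sd,
                 baseline_ear = baseline_ear,
                 detect_threshold = detect_threshold,
                 min_gap = min_gap,
                 eye_length_px = eye_length_px,
                 render_size = as.integer(render_size),
                 render_intensity = render_intensity,
                 lid_amp = lid_amp, lower_depth = lower_depth,
                 iris_radius = iris_radius),
            class = "synthetic_spec")
}

#' Session configuration matching a synthetic spec
#'
#' @param spec A [synthetic_spec()].
#' @return A [session_config()] with the spec's frame rate and phase
#'   layout.
#' @export
spec_config <- function(spec) {
  total <- spec$n_phases * spec$phase_duration
  session_config(frame_rate = spec$frame_rate,
                 phase_duration = spec$phase_duration,
                 n_phases = spec$n_phases,
                 calibration_window = min(600, total))
}

# Sample one phase's planted events (times in seconds within the phase).
# Returns start_s, duration_s, completeness, depth, burst. Consumes RNG
# state; callers seed.
.sample_phase_events <- function(spec, k) {
  T <- spec$phase_duration
  mean_extra <- 1 / spec$burst_size_prob
  anchor_rate <- spec$blink_rate[k] / (1 + spec$burst_prob[k] * mean_extra)
  m_gap <- 60 / anchor_rate
  mexc <- max(m_gap - spec$min_gap, 0.05)
  starts <- stats::runif(1, 0.3, m_gap)
  repeat {
    n_draw <- max(ceiling((T - max(starts)) / m_gap * 1.4) + 20, 20)
    gaps <- spec$min_gap + stats::rexp(n_draw, 1 / mexc)
    starts <- c(starts, max(starts) + cumsum(gaps))
    if (max(starts) >= T) break
  }
  anchors <- starts[starts < T - 1]
  n_a <- length(anchors)
  dm <- spec$duration_mean[k]; ds <- spec$duration_sd
  dur_a <- .rtnorm(n_a, dm, ds, 0.2, dm + 0.45)
  is_burst <- stats::runif(n_a) < spec$burst_prob[k]
  # burst anchors and followers blink quickly so the eye re-opens between
  dur_a[is_burst] <- .rtnorm(sum(is_burst), 0.25, 0.05, 0.15, 0.35)
  fol_start <- numeric(0); fol_dur <- numeric(0)
  if (any(is_burst)) {
    n_extra <- pmin(stats::rgeom(sum(is_burst), spec$burst_size_prob) + 1L, 2L)
    anc <- anchors[is_burst]
    for (i in seq_along(anc)) {
      g <- cumsum(stats::runif(n_extra[i], spec$burst_gap[1],
                               spec$burst_gap[2]))
      fol_start <- c(fol_start, anc[i] + g)
    }
    fol_dur <- .rtnorm(length(fol_start), 0.25, 0.05, 0.15, 0.35)
  }
  ev <- data.frame(start_s = c(anchors, fol_start),
                   duration_s = c(dur_a, fol_dur),
                   burst = c(is_burst, rep(TRUE, length(fol_start))))
  ev <- ev[order(ev$start_s), , drop = FALSE]
  ev <- ev[ev$start_s < T - 1, , drop = FALSE]
  # resolve overlaps: an event must start after the previous one has
  # re-opened; drop offenders (rare, bursts colliding with the next anchor)
  fr <- spec$frame_rate
  repeat {
    need <- (round(ev$duration_s[-nrow(ev)] * fr) + 3) / fr
    bad <- which(diff(ev$start_s) <= need) + 1L
    if (!length(bad) || nrow(ev) < 2L) break
    ev <- ev[-bad, , drop = FALSE]
  }
  n <- nrow(ev)
  inc <- stats::runif(n) < spec$incomplete_prob[k]
  cd <- spec$complete_depth; id <- spec$incomplete_depth
  depth <- numeric(n)
  depth[!inc] <- .rtnorm(sum(!inc), cd[1], cd[2], cd[3], cd[4])
  depth[inc] <- .rtnorm(sum(inc), id[1], id[2], id[3], id[4])
  ev$completeness <- ifelse(inc, "incomplete", "complete")
  ev$depth <- depth
  ev
}

# Planted events for a whole session, frame-indexed.
.sample_session_events <- function(spec) {
  fr <- spec$frame_rate
  out <- lapply(seq_len(spec$n_phases), function(k) {
    ev <- .sample_phase_events(spec, k)
    ev$start_frame <- as.integer(round(ev$start_s * fr)) +
      as.integer((k - 1) * spec$phase_duration * fr)
    ev$n_frames <- pmax(as.integer(round(ev$duration_s * fr)), 3L)
    ev$phase <- rep(k, nrow(ev))
    ev
  })
  do.call(rbind, out)
}

#' Generate eyelid-aperture kinematics with planted blinks
#'
#' Builds a per-frame eyelid-aperture trace (1 = fully open, 0 = fully
#' closed) for a whole session. Each planted blink is a raised-cosine
#' closure whose width is chosen so the aperture stays below the
#' detection level for the sampled number of frames; complete blinks
#' reach a depth near full closure, incomplete blinks bottom out at
#' their planted partial depth. Ground-truth events are read back off
#' the finished trace (runs below the detection aperture), so the
#' bookkeeping and the emitted stream agree frame by frame.
#'
#' @param spec A [synthetic_spec()]; `spec$seed` drives all randomness.
#' @return List with `aperture` (numeric vector, one value per frame),
#'   `truth` (data frame: `start_frame`, `n_frames`, `end_frame`,
#'   `completeness`, `depth`, `burst`, `phase`), and `spec`.
#' @export
generate_kinematics <- function(spec = synthetic_spec()) {
  set.seed(spec$seed)
  fr <- spec$frame_rate
  n_total <- as.integer(round(spec$n_phases * spec$phase_duration * fr))
  delta <- 1 - spec$detect_threshold / spec$baseline_ear
  ev <- .sample_session_events(spec)
  closure <- numeric(n_total)
  win_peak <- integer(nrow(ev))
  keep <- logical(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    d <- ev$depth[i]
    if (d <= delta) next                      # undetectable; skip
    phi <- acos(1 - 2 * delta / d)
    frac <- 1 - phi / pi
    w <- max(round(ev$n_frames[i] / frac), ev$n_frames[i] + 4L)
    ws <- as.integer(round(ev$start_frame[i] - (w - 1) * phi / (2 * pi)))
    if (ws < 1L || ws + w > n_total - 1L) next # clipped by session edge
    j <- ws:(ws + w - 1L)
    c_i <- d * (1 - cos(2 * pi * (j - ws) / (w - 1))) / 2
    closure[j + 1L] <- pmax(closure[j + 1L], c_i)
    win_peak[i] <- ws + as.integer((w - 1) %/% 2)
    keep[i] <- TRUE
  }
  aperture <- 1 - closure
  # ground truth from the trace itself
  below <- aperture < (spec$detect_threshold / spec$baseline_ear)
  r <- rle(below)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  run_start <- run_start[r$values]; run_len <- r$lengths[r$values]
  ev <- ev[keep, , drop = FALSE]
  run_of <- findInterval(win_peak[keep], run_start)
  stopifnot(length(run_start) == nrow(ev),
            identical(run_of, seq_len(nrow(ev))))
  truth <- data.frame(start_frame = as.integer(run_start - 1L),
                      n_frames = as.integer(run_len),
                      end_frame = as.integer(run_start + run_len - 2L),
                      completeness = ev$completeness,
                      depth = ev$depth,
                      max_duc = spec$duc_scale * ev$depth,
                      burst = ev$burst,
                      phase = ev$phase)
  list(aperture = aperture, truth = truth, spec = spec)
}

# Static 68-point face template for a 600 x 450 frame; only the eye
# points (36-47) move. Returns a 68 x 2 matrix (x, y).
.face_template <- function() {
  pts <- matrix(0, 68, 2)
  t <- seq(0, pi, length.out = 17)                      # jaw 0-16
  pts[1:17, ] <- cbind(300 - 170 * cos(t), 230 + 170 * sin(t))
  pts[18:22, ] <- cbind(seq(150, 250, length.out = 5), 165)  # brows
  pts[23:27, ] <- cbind(seq(350, 450, length.out = 5), 165)
  pts[28:31, ] <- cbind(300, seq(195, 270, length.out = 4))  # nose bridge
  pts[32:36, ] <- cbind(seq(270, 330, length.out = 5), 285)  # nose base
  t2 <- seq(0, 2 * pi, length.out = 21)[-21]                 # mouth 48-67
  pts[49:68, ] <- cbind(300 + 55 * cos(t2), 345 + 22 * sin(t2))
  pts
}

#' Landmark stream from an aperture trace
#'
#' Emits 68-point frames in which the six eye key points of each eye are
#' placed so the computed EAR equals `baseline_ear * aperture` exactly
#' before noise; Gaussian pixel noise of sd `spec$landmark_noise_sd` is
#' then added to every coordinate.
#'
#' @param aperture Numeric vector of per-frame apertures in `[0, 1]`
#'   (e.g. from [generate_kinematics()]).
#' @param spec A [synthetic_spec()].
#' @param noise_sd Override for the landmark noise sd (default
#'   `spec$landmark_noise_sd`; use 0 for a noiseless stream).
#' @return A [landmark_stream()].
#' @export
kinematics_to_landmarks <- function(aperture, spec = synthetic_spec(),
                                    noise_sd = spec$landmark_noise_sd) {
  stopifnot(all(aperture >= 0), all(aperture <= 1))
  n <- length(aperture)
  tmpl <- .face_template()
  L <- spec$eye_length_px
  half_h <- spec$baseline_ear * L * aperture / 2
  x <- matrix(rep(tmpl[, 1], each = n), n, 68)
  y <- matrix(rep(tmpl[, 2], each = n), n, 68)
  eye_y <- 200
  # right eye of the scheme: indices 36-41 (0-based)
  ex <- 200 - L / 2
  x[, 37:42] <- matrix(rep(c(ex, ex + L / 3, ex + 2 * L / 3, ex + L,
                             ex + 2 * L / 3, ex + L / 3), each = n), n, 6)
  y[, 37] <- eye_y; y[, 40] <- eye_y
  y[, 38] <- eye_y - half_h; y[, 39] <- eye_y - half_h
  y[, 41] <- eye_y + half_h; y[, 42] <- eye_y + half_h
  # left eye: indices 42-47, mirrored
  ex2 <- 400 - L / 2
  x[, 43:48] <- matrix(rep(c(ex2, ex2 + L / 3, ex2 + 2 * L / 3, ex2 + L,
                             ex2 + 2 * L / 3, ex2 + L / 3), each = n), n, 6)
  y[, 43] <- eye_y; y[, 46] <- eye_y
  y[, 44] <- eye_y - half_h; y[, 45] <- eye_y - half_h
  y[, 47] <- eye_y + half_h; y[, 48] <- eye_y + half_h
  if (noise_sd > 0) {
    x <- pmax(x + matrix(stats::rnorm(n * 68, 0, noise_sd), n, 68), 0)
    y <- pmax(y + matrix(stats::rnorm(n * 68, 0, noise_sd), n, 68), 0)
  }
  landmark_stream(frame = 0:(n - 1), x = x, y = y,
                  frame_rate = spec$frame_rate)
}

#' Render synthetic grayscale eye images
#'
#' Minimal three-band eye render: bright sclera between two parabolic
#' eyelid curves, a dark iris disc, and mid-gray skin elsewhere. The
#' upper lid's apex follows the aperture linearly; at aperture 0 the
#' lids meet and no sclera remains visible. Lid edges are anti-aliased
#' (pixel intensity blends by edge coverage) so sub-pixel lid positions
#' survive magnification. Deliberately simple -- enough to exercise
#' thresholding and contour logic, cheap to verify.
#'
#' @param aperture Numeric vector of apertures in `[0, 1]`.
#' @param spec A [synthetic_spec()].
#' @param frames 0-based frame indices to render (default: all).
#' @return List with `images` (list of [eye_image()]) and `truth`
#'   (data frame: `frame`, `aperture`, `apex_x`, `apex_y`, `corner_x`,
#'   `corner_y`, in original-scale 0-based pixel coordinates).
#' @export
render_eye_images <- function(aperture, spec = synthetic_spec(),
                              frames = seq_along(aperture) - 1L) {
  W <- spec$render_size[1]; H <- spec$render_size[2]
  x0 <- 5; x1 <- W - 7; cx <- (x0 + x1) / 2
  yc <- round(H * 0.55)
  amp <- spec$lid_amp; low <- spec$lower_depth; r <- spec$iris_radius
  ints <- spec$render_intensity   # sclera, skin, iris
  gx <- matrix(rep(0:(W - 1), each = H), H, W)
  gy <- matrix(rep(0:(H - 1), W), H, W)
  s <- 1 - ((gx - cx) / (cx - x0))^2
  s[gx <= x0 | gx >= x1] <- 0
  iris <- (gx - cx)^2 + (gy - yc)^2 <= r^2
  images <- vector("list", length(frames))
  truth <- data.frame(frame = frames, aperture = aperture[frames + 1L],
                      apex_x = cx,
                      apex_y = yc + low - (amp + low) * aperture[frames + 1L],
                      corner_x = x1, corner_y = yc)
  clamp01 <- function(v) pmin(pmax(v, 0), 1)
  for (i in seq_along(frames)) {
    ap <- aperture[frames[i] + 1L]
    y_u <- yc + (low - (amp + low) * ap) * s
    y_l <- yc + low * s
    # fraction of each pixel lying inside the opening (vertical coverage)
    open_frac <- clamp01(gy - y_u + 0.5) * clamp01(y_l - gy + 0.5)
    open_frac[s <= 0] <- 0
    img <- ints[2] + open_frac * (ints[1] - ints[2])
    solid <- open_frac >= 0.5 & iris
    img[solid] <- ints[3]
    images[[i]] <- eye_image(img, frame_index = frames[i])
  }
  list(images = images, truth = truth)
}

#' Generate a complete synthetic session
#'
#' Convenience wrapper: kinematics, landmark stream, ground-truth events
#' and (optionally) rendered eye images for selected frames, plus the
#' true per-phase features computed from the ground-truth events with
#' the same feature code used on detected events (the generator never
#' duplicates feature math).
#'
#' @param spec A [synthetic_spec()].
#' @param noise_sd Landmark noise override (default from spec).
#' @param render_frames 0-based frame indices to render, or `NULL`
#'   (default) for none.
#' @return List with `landmarks`, `aperture`, `truth` (event table),
#'   `truth_features` (per-phase feature table), `images` (or NULL),
#'   `config`, `spec`.
#' @export
generate_session <- function(spec = synthetic_spec(),
                             noise_sd = spec$landmark_noise_sd,
                             render_frames = NULL) {
  kin <- generate_kinematics(spec)
  lms <- kinematics_to_landmarks(kin$aperture, spec, noise_sd = noise_sd)
  cfg <- spec_config(spec)
  truth_ev <- truth_events(kin$truth)
  feats <- session_features(truth_ev, cfg)
  imgs <- if (!is.null(render_frames))
    render_eye_images(kin$aperture, spec, render_frames)
  list(landmarks = lms, aperture = kin$aperture, truth = kin$truth,
       truth_features = feats, images = imgs, config = cfg, spec = spec)
}

#' Ground-truth table as a blink-event table
#'
#' @param truth Ground-truth data frame from [generate_kinematics()].
#' @return A [blink_events()] table carrying the true completeness
#'   labels (and `max_duc` when the truth table has one).
#' @export
truth_events <- function(truth) {
  blink_events(start_frame = truth$start_frame, n_frames = truth$n_frames,
               completeness = truth$completeness,
               max_duc = if ("max_duc" %in% names(truth)) truth$max_duc
                         else NA_real_)
}

#' Generate a synthetic cohort with a planted phase trend
#'
#' Simulates `n_subjects` sessions at the event level (no frame traces),
#' applying a per-subject multiplicative random effect to the blink
#' rates and an additive one to the blink durations, and computes each
#' subject's true per-phase features through the regular feature code.
#' Because the subject effects scale all phases alike, the planted
#' phase trend (rising blink number, falling intervals) survives within
#' every subject, emulating the repeated-measures structure the phase
#' statistics are designed for.
#'
#' @param n_subjects Number of subjects (default 23).
#' @param spec A [synthetic_spec()]; per-phase rates/durations define
#'   the planted trend.
#' @param seed Seed for the cohort (default `spec$seed`).
#' @param rate_sdlog Log-sd of the subject rate multiplier
#'   (default 0.2).
#' @param dur_sd Sd of the subject duration shift in seconds
#'   (default 0.04).
#' @return List with `features` (per-subject list of per-phase feature
#'   tables) and `events` (per-subject ground-truth event tables).
#' @export
generate_cohort <- function(n_subjects = 23L, spec = synthetic_spec(),
                            seed = spec$seed, rate_sdlog = 0.2,
                            dur_sd = 0.04) {
  stopifnot(n_subjects >= 2L)
  set.seed(seed)
  cfg <- spec_config(spec)
  rate_mult <- exp(stats::rnorm(n_subjects, 0, rate_sdlog))
  dur_shift <- stats::rnorm(n_subjects, 0, dur_sd)
  feats <- vector("list", n_subjects)
  events <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    sp <- spec
    sp$blink_rate <- spec$blink_rate * rate_mult[i]
    sp$duration_mean <- pmax(spec$duration_mean + dur_shift[i], 0.3)
    ev <- .sample_session_events(sp)
    tev <- blink_events(start_frame = ev$start_frame,
                        n_frames = ev$n_frames,
                        completeness = ev$completeness,
                        max_duc = spec$duc_scale * ev$depth)
    events[[i]] <- tev
    feats[[i]] <- session_features(tev, cfg)
  }
  names(feats) <- names(events) <- sprintf("s%02d", seq_len(n_subjects))
  list(features = feats, events = events)
}
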