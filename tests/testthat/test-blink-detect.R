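test_that("EAR arithmetic matches the distance-ratio definition", {
  eye <- rbind(c(0, 0), c(3, -1), c(7, -1), c(10, 0), c(7, 1), c(3, 1))
  rownames(eye) <- paste0("p", 1:6)
  expect_equal(compute_ear(eye), 0.2)  # heights 2 and 2, length 10

  closed <- eye; closed[c(2, 3), 2] <- 0; closed[c(5, 6), 2] <- 0
  closed[2, 1] <- closed[6, 1]; closed[3, 1] <- closed[5, 1]
  expect_equal(compute_ear(closed), 0)

  degenerate <- eye; degenerate[4, ] <- degenerate[1, ]
  expect_error(compute_ear(degenerate), "degenerate")
})

test_that("EAR agrees with an independent oracle on random geometries", {
  set.seed(101)
  for (i in 1:200) {
    eye <- random_eye()
    expect_equal(compute_ear(eye), ear_oracle(eye), tolerance = 1e-12)
  }
})

test_that("EAR is invariant under rigid transforms and uniform scaling", {
  set.seed(102)
  for (i in 1:50) {
    eye <- random_eye()
    theta <- runif(1, 0, 2 * pi)
    rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    s <- runif(1, 0.1, 10)
    shift <- matrix(runif(2, -50, 50), 6, 2, byrow = TRUE)
    eye2 <- s * (unclass(eye) %*% rot) + shift
    rownames(eye2) <- rownames(eye)
    expect_equal(compute_ear(eye2), compute_ear(eye), tolerance = 1e-9)
  }
})

test_that("EAR traces fuse the two eyes and impute degenerate frames", {
  spec <- short_spec()
  stream <- kinematics_to_landmarks(c(1, 1, 0.5), spec, noise_sd = 0)
  tr_mean <- build_ear_trace(stream, "mean")
  tr_left <- build_ear_trace(stream, "left")
  expect_equal(tr_mean$values, tr_left$values)  # identical eyes
  expect_equal(tr_mean$values, spec$baseline_ear * c(1, 1, 0.5),
               tolerance = 1e-12)

  # degenerate frame imputed from the previous valid value
  broken <- stream
  broken$x[2, 37:42] <- broken$x[2, 40]  # collapse right eye length
  broken$y[2, 37:42] <- broken$y[2, 40]
  expect_message(tr <- build_ear_trace(broken, "right"), "imputed")
  expect_equal(tr$values[2], tr$values[1])
  expect_identical(tr$imputed, 1L)
})

test_that("blink segmentation follows the strict-threshold rule", {
  tr <- ear_trace(c(0.3, 0.15, 0.1, 0.15, 0.3))
  ev <- segment_blinks(tr)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start_frame, 1L)
  expect_equal(ev$n_frames, 3L)
  expect_false(ev$open_ended)

  expect_equal(nrow(segment_blinks(ear_trace(rep(0.3, 10)))), 0L)

  # a frame exactly at the threshold counts as open and ends the run
  tr2 <- ear_trace(c(0.3, 0.1, 0.1, 0.2, 0.1, 0.1, 0.3))
  ev2 <- segment_blinks(tr2)
  expect_equal(ev2$start_frame, c(1L, 4L))
  expect_equal(ev2$n_frames, c(2L, 2L))

  # short runs are discarded; boundary-truncated runs are flagged
  tr3 <- ear_trace(c(0.1, 0.1, 0.3, 0.1, 0.3, 0.1, 0.1))
  ev3 <- segment_blinks(tr3, min_blink_frames = 2)
  expect_equal(ev3$start_frame, c(0L, 5L))
  expect_equal(ev3$open_ended, c(TRUE, TRUE))

  expect_error(segment_blinks(tr, threshold = 0), "config")

  # start_frame offsets carry through
  tr4 <- ear_trace(c(0.3, 0.1, 0.1, 0.3), start_frame = 100L)
  expect_equal(segment_blinks(tr4)$start_frame, 101L)
})

test_that("segmentation is time-symmetric and threshold-monotone", {
  set.seed(103)
  for (i in 1:20) {
    v <- runif(200, 0, 0.4)
    tr <- ear_trace(v)
    ev <- segment_blinks(tr, min_blink_frames = 1)
    rev_ev <- segment_blinks(ear_trace(rev(v)), min_blink_frames = 1)
    # mirror image: reversed events map onto the originals
    expect_equal(sort(length(v) - 1 - rev_ev$end_frame), ev$start_frame)
    expect_equal(rev(rev_ev$n_frames), ev$n_frames)
    # raising the threshold never shrinks total covered frames
    cov1 <- sum(segment_blinks(tr, 0.15, 1)$n_frames)
    cov2 <- sum(segment_blinks(tr, 0.25, 1)$n_frames)
    expect_gte(cov2, cov1)
  }
})

test_that("events are disjoint and every frame joins at most one blink", {
  set.seed(104)
  v <- runif(500, 0, 0.4)
  ev <- segment_blinks(ear_trace(v), min_blink_frames = 1)
  frames <- unlist(Map(seq, ev$start_frame, ev$end_frame))
  expect_false(any(duplicated(frames)))
  expect_true(all(diff(ev$start_frame) > 0))
  expect_true(all(v[frames + 1] < 0.2))
  expect_true(all(v[setdiff(0:499, frames) + 1] >= 0.2))
})

test_that("blink intervals are start-to-start in seconds", {
  ev <- blink_events(c(0L, 120L), c(5L, 5L))
  expect_equal(blink_intervals(ev, 60), 2.0)
  expect_identical(blink_intervals(ev[1, ], 60), numeric(0))

  set.seed(105)
  starts <- cumsum(sample(30:300, 20))
  ev2 <- blink_events(starts, rep(5L, 20))
  expect_equal(blink_intervals(ev2, 60), diff(starts) / 60)
})

test_that("planted blinks in a synthetic trace cross the threshold exactly", {
  spec <- short_spec(seed = 9)
  kin <- generate_kinematics(spec)
  lms <- kinematics_to_landmarks(kin$aperture, spec, noise_sd = 0)
  tr <- build_ear_trace(lms)
  ev <- segment_blinks(tr)
  expect_identical(ev$start_frame, kin$truth$start_frame)
  expect_identical(ev$n_frames, kin$truth$n_frames)
})
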