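test_that("phase partitioning uses the start-frame rule", {
  cfg <- session_config(frame_rate = 60, phase_duration = 10, n_phases = 2,
                        calibration_window = 10)
  # phase window = 600 frames; second event starts in phase 1 but spills over
  ev <- blink_events(c(0L, 595L), c(5L, 20L))
  ph <- partition_phases(ev, cfg)
  expect_equal(nrow(ph$phase1), 2L)
  expect_equal(nrow(ph$phase2), 0L)

  ev2 <- blink_events(c(0L, 600L, 1500L), rep(5L, 3))
  expect_warning(ph2 <- partition_phases(ev2, cfg), "dropped")
  expect_equal(attr(ph2, "dropped"), 1L)
  expect_equal(ph2$phase2$start_frame, 600L)
})

test_that("group finding matches the sub-second interval rule", {
  ev <- blink_events(as.integer(c(0, 0.5, 0.9, 5) * 60), rep(5L, 4))
  g <- find_groups(ev, 1.0, 60)
  expect_equal(nrow(g), 1L)
  expect_equal(g$n_members, 3L)
  expect_equal(g$start_frame, 0L)

  spread <- blink_events(seq(0L, by = 90L, length.out = 10), rep(5L, 10))
  expect_equal(nrow(find_groups(spread, 1.0, 60)), 0L)
})

test_that("group finding agrees with a brute-force scanner", {
  set.seed(401)
  for (i in 1:100) {
    gaps <- sample(c(runif(30, 0.3, 0.95), runif(30, 1.05, 8)))
    starts <- as.integer(round(cumsum(c(1, gaps)) * 60))
    ev <- blink_events(starts, rep(3L, length(starts)))
    g <- find_groups(ev, 1.0, 60)
    bf <- groups_bruteforce(starts / 60, 1.0)
    expect_equal(nrow(g), length(bf))
    if (length(bf)) {
      expect_equal(g$first_event, vapply(bf, `[[`, integer(1), "first"))
      expect_equal(g$n_members, vapply(bf, `[[`, integer(1), "size"))
    }
  }
})

test_that("shrinking the group window only splits or shrinks groups", {
  set.seed(402)
  gaps <- c(runif(40, 0.2, 1.4))
  ev <- blink_events(as.integer(round(cumsum(c(1, gaps)) * 60)),
                     rep(3L, 41))
  g1 <- find_groups(ev, 1.0, 60)
  g2 <- find_groups(ev, 0.5, 60)
  expect_lte(sum(g2$n_members), sum(g1$n_members))
  expect_lte(max(g2$n_members, 0), max(g1$n_members, 0))
})

test_that("the seven features follow their definitions", {
  ev <- blink_events(c(0L, 120L), c(6L, 9L))
  f <- blink_features(ev, frame_rate = 60)
  expect_equal(f$Mean_BD, (6 + 9) / (60 * 2))  # duration formula
  expect_equal(f$BN, 2L)
  expect_equal(f$Mean_BI, 2)
  expect_equal(f$GBN, 0L)

  # single blink: duration defined, interval absent
  f1 <- blink_features(ev[1, ], 60)
  expect_equal(f1$BN, 1L)
  expect_true(is.na(f1$Mean_BI))
  expect_equal(f1$Mean_BD, 6 / 60)

  # empty phase
  f0 <- blink_features(ev[0, ], 60)
  expect_equal(f0$BN, 0L)
  expect_equal(f0$IBN, 0L)
  expect_true(all(is.na(c(f0$Mean_BI, f0$Mean_BD, f0$Mean_GBI, f0$Mean_IBI))))

  # incomplete features are start-to-start over incomplete blinks only
  ev2 <- blink_events(c(0L, 60L, 120L, 300L), rep(6L, 4),
                      completeness = c("incomplete", "complete",
                                       "incomplete", "incomplete"))
  f2 <- blink_features(ev2, 60)
  expect_equal(f2$IBN, 3L)
  expect_equal(f2$Mean_IBI, mean(c(120, 180) / 60))
  # burst of three (gaps 1 s are NOT grouped: strict < 1 s)
  expect_equal(f2$GBN, 0L)
  ev3 <- blink_events(c(0L, 50L, 100L, 300L), rep(6L, 4))
  expect_equal(blink_features(ev3, 60)$GBN, 1L)
  expect_equal(blink_features(ev3, 60, group_count = "members")$GBN, 3L)
})

test_that("Mean_BD equals the hand-computed duration formula", {
  set.seed(403)
  for (i in 1:30) {
    n <- sample(2:40, 1)
    starts <- cumsum(sample(60:400, n))
    lens <- sample(3:50, n, replace = TRUE)
    fr <- sample(c(30, 60, 120), 1)
    f <- blink_features(blink_events(starts, lens), fr)
    expect_equal(f$Mean_BD, sum(lens) / (fr * n), tolerance = 1e-12)
  }
})

test_that("per-phase features conserve events and match planted truth", {
  spec <- short_spec(seed = 11)
  kin <- generate_kinematics(spec)
  cfg <- spec_config(spec)
  ev <- truth_events(kin$truth)
  feats <- session_features(ev, cfg)
  expect_equal(sum(feats$BN), nrow(kin$truth))
  expect_true(all(feats$BN >= feats$IBN))
  expect_true(all(feats$GBN <= floor(feats$BN / 2)))
  # per-phase counts match the generator's own phase bookkeeping
  expect_equal(feats$BN,
               as.integer(table(factor(kin$truth$phase, levels = 1:4))))
  expect_equal(feats$IBN, as.integer(
    table(factor(kin$truth$phase[kin$truth$completeness == "incomplete"],
                 levels = 1:4))))
  # features invariant to appending empty phases
  cfg6 <- session_config(frame_rate = spec$frame_rate,
                         phase_duration = spec$phase_duration,
                         n_phases = 6, calibration_window = 150)
  feats6 <- session_features(ev, cfg6)
  expect_equal(feats6[1:4, ], feats, ignore_attr = TRUE)
  expect_equal(feats6$BN[5:6], c(0L, 0L))
})

test_that("intervals never span phase boundaries", {
  cfg <- session_config(frame_rate = 60, phase_duration = 10, n_phases = 2,
                        calibration_window = 10)
  # one blink late in phase 1, one early in phase 2: no interval anywhere
  ev <- blink_events(c(590L, 610L), c(5L, 5L))
  feats <- session_features(ev, cfg)
  expect_true(all(is.na(feats$Mean_BI)))
  expect_equal(feats$BN, c(1L, 1L))
})
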