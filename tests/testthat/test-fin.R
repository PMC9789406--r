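test_that("fin angle is the interior angle at the back of the skull", {
  nf <- 3
  nose <- cbind(rep(10, nf), 0)
  skull <- cbind(rep(0, nf), 0)
  # collinear: tip directly opposite the nose
  lt <- make_landmarks(list(nose = nose, back_of_skull = skull,
                            right_fin_tip = cbind(rep(-5, nf), 0)))
  expect_equal(fin_angle(lt, "right")$angle_deg, rep(180, nf))
  # perpendicular
  lt90 <- make_landmarks(list(nose = nose, back_of_skull = skull,
                              right_fin_tip = cbind(rep(0, nf), -5)))
  expect_equal(fin_angle(lt90, "right")$angle_deg, rep(90, nf))
  # coincident landmarks are flagged, not fabricated
  ltc <- make_landmarks(list(nose = nose, back_of_skull = skull,
                             right_fin_tip = skull))
  expect_true(all(is.na(fin_angle(ltc, "right")$angle_deg)))
})

test_that("stroke segmentation finds alternating events of a sinusoid", {
  fr <- 200
  t <- seq(0, 5, by = 1 / fr)
  per <- 0.8
  ang <- 90 + 30 * sin(2 * pi * t / per)
  seg <- segment_strokes(ang, fr, "fin")
  expect_s3_class(seg, "stroke_segmentation")
  expect_true(all(diff(seg$events$time_s) > 0))
  expect_equal(seg$cycles$end - seg$cycles$start,
               rep(per, nrow(seg$cycles)), tolerance = 0.01)
  expect_equal(seg$cycles$mid - seg$cycles$start,
               rep(per / 2, nrow(seg$cycles)), tolerance = 0.01)
  expect_error(segment_strokes(rep(90, 100), fr, "fin"), "constant")
})

test_that("detected adduction starts match ground truth within 2 frames", {
  tr <- clean_trial()
  seg <- polygait:::trial_fin_segmentation(tr, "right")
  det <- seg$events$time_s[seg$events$event_type == "adduction_start"]
  truth <- tr$truth$fin_events$adduction_right
  for (tt in truth) {
    expect_lt(min(abs(det - tt)), 2 / tr$spec$frame_rate)
  }
  tseg <- polygait:::trial_tail_segmentation(tr)
  det_t <- tseg$events$time_s[tseg$events$event_type == "tail_swing_right_start"]
  for (tt in tr$truth$tail_events$swing_right_start) {
    expect_lt(min(abs(det_t - tt)), 2 / tr$spec$frame_rate)
  }
})

test_that("fin frequency is the mean of reciprocal cycle durations", {
  seg <- regular_fin_seg(0.1, 0.5, 6)
  expect_equal(fin_frequency(seg), 2.0)
  # jittered cycles: mean of reciprocals, not reciprocal of the mean
  set.seed(4)
  durs <- 0.5 + runif(6, -0.1, 0.1)
  adds <- cumsum(c(0.05, durs))
  ev <- data.frame(
    event_type = c(rbind(rep("adduction_start", 6), rep("abduction_start", 6)),
                   "adduction_start"),
    time_s = sort(c(adds, adds[-length(adds)] + durs * 0.45)))
  segj <- stroke_segmentation("fin", ev)
  expect_equal(fin_frequency(segj), mean(1 / durs), tolerance = 1e-9)
  expect_gt(abs(fin_frequency(segj) - 1 / mean(durs)), 1e-4)
  seg1 <- regular_fin_seg(0.1, 0.5, 1)
  expect_error(fin_frequency(seg1), "fewer than 2")
})

test_that("fin range of motion averages per-cycle max minus min", {
  fr <- 200
  t <- seq(0, 4, by = 1 / fr)
  ang <- data.frame(time_s = t, angle_deg = 90 + 30 * sin(2 * pi * 1.25 * t))
  seg <- segment_strokes(ang$angle_deg, fr, "fin")
  expect_equal(fin_rom(ang, seg), 60, tolerance = 0.6)
  flat <- data.frame(time_s = t, angle_deg = rep(95, length(t)))
  expect_lt(fin_rom(flat, seg), 0.01)
  expect_equal(trial_fin_rom(50, 70), 60)
})

test_that("left-fin phase anchors 0 and 180 deg to the named right events", {
  segR <- regular_fin_seg(0.0, 1.0, 5)
  expect_equal(left_fin_phase(segR, segR), rep(0, 5))
  # left adduction at right abduction start: 180 deg
  segL <- regular_fin_seg(0.5, 1.0, 4)
  ph <- suppressMessages(left_fin_phase(segL, segR))
  expect_equal(ph, rep(180, length(ph)))
  # asymmetric half-cycles still map the mid event to 180
  ev <- data.frame(event_type = rep(c("adduction_start", "abduction_start"), 3),
                   time_s = c(0, 0.3, 1, 1.3, 2, 2.3))
  segA <- stroke_segmentation("fin", ev)
  phA <- suppressMessages(left_fin_phase(regular_fin_seg(0.3, 1, 2), segA))
  expect_equal(phA, rep(180, length(phA)))
})

test_that("out-of-phase fins are recovered near 180 deg", {
  tr <- cached_trial("outphase",
                     trial_spec(duration = 4, seed = 21, fin_phase_offset = 180,
                                fin_phase_kappa = 50))
  ph <- suppressMessages(left_fin_phase(
    polygait:::trial_fin_segmentation(tr, "left"),
    polygait:::trial_fin_segmentation(tr, "right")))
  cm <- circular_mean_variance(ph)
  expect_lt(abs(cm$mean_deg - 180), 5)
  # swapping sides maps phase to 360 - phase (mod 360)
  ph_swap <- suppressMessages(left_fin_phase(
    polygait:::trial_fin_segmentation(tr, "right"),
    polygait:::trial_fin_segmentation(tr, "left")))
  cms <- circular_mean_variance(ph_swap)
  d <- abs(((cm$mean_deg + cms$mean_deg) %% 360))
  expect_lt(min(d, 360 - d), 10)
})

test_that("mixed in/out-of-phase trials pool to a non-uniform, non-unimodal sample", {
  specs <- lapply(1:4, function(i) {
    trial_spec(duration = 4, seed = 300 + i, fin_phase_offset = c(0, 180),
               fin_phase_kappa = 30)
  })
  pool <- unlist(lapply(specs, function(sp) {
    tr <- generate_trial(sp)
    suppressMessages(left_fin_phase(
      polygait:::trial_fin_segmentation(tr, "left"),
      polygait:::trial_fin_segmentation(tr, "right")))
  }))
  expect_gte(length(pool), 12)
  hr <- hermans_rasson_test(pool, n_mc = 999, seed = 17)
  expect_lte(hr$p, 0.05)
  expect_gt(rayleigh_test(pool)$p, 0.05)
})
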