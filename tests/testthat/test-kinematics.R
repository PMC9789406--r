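test_that("curvature coefficient hits its analytic anchors", {
  expect_equal(curvature_coefficient(straight_midlines()), 0)
  # nose touching tail: a closed circular posture in one frame
  closed <- arc_frame_midlines(2 * pi)
  expect_equal(curvature_coefficient(closed), 1, tolerance = 1e-9)
  # semicircular most-curved frame: 1 - 2/pi
  semi <- arc_frame_midlines(pi)
  expect_equal(curvature_coefficient(semi), 1 - 2 / pi, tolerance = 1e-9)
})

test_that("curvature coefficient is invariant to rigid motion and scale", {
  semi <- arc_frame_midlines(pi)
  base <- curvature_coefficient(semi)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  xy <- semi$xy
  rot <- xy
  for (i in seq_len(dim(xy)[1])) {
    rot[i, , ] <- sweep(xy[i, , ] %*% R, 2, c(13, -4), "+")
  }
  mlr <- midline_sequence(rot, semi$body_length, semi$frame_rate, validate = FALSE)
  expect_equal(curvature_coefficient(mlr), base, tolerance = 1e-12)
  mls <- midline_sequence(xy * 3.5, semi$body_length * 3.5, semi$frame_rate,
                          validate = FALSE)
  expect_equal(curvature_coefficient(mls), base, tolerance = 1e-12)
})

test_that("inconsistent calibration (nose-tail beyond BL) is an error", {
  st <- straight_midlines(bl = 100)
  st$body_length <- 90  # claimed BL below the actual 100-unit span
  expect_error(curvature_coefficient(st), "calibration")
})

test_that("locomotion speed is net nose displacement over duration", {
  nf <- 101
  t <- (seq_len(nf) - 1) / 100
  lt <- make_landmarks(list(nose = cbind(200 * t, 0)), bl = 100,
                       frame_rate = 100)
  expect_equal(locomotion_speed(lt), 2.0)
  lt0 <- make_landmarks(list(nose = cbind(rep(5, nf), 3)), bl = 100,
                        frame_rate = 100)
  expect_equal(locomotion_speed(lt0), 0)
  lt_no <- make_landmarks(list(tail_tip = cbind(t, 0)), bl = 100,
                          frame_rate = 100)
  expect_error(locomotion_speed(lt_no), "nose")
})

test_that("swing distance matches the closed form for a pure lateral wave", {
  bl <- 100
  nf <- 400
  fr <- 100
  a <- 0.04 * bl
  xy <- array(0, dim = c(nf, 100, 2))
  s <- seq(0, bl, length.out = 100)
  for (i in seq_len(nf)) {
    t <- (i - 1) / fr
    xy[i, , 1] <- s
    xy[i, , 2] <- a * sin(2 * pi * 1.5 * t) * (s / bl)
  }
  ml <- midline_sequence(xy, bl, fr, validate = FALSE)
  # site at the tail: lateral-only motion, path between extrema = 2a
  expect_equal(swing_distance(ml, 1.0), 2 * a / bl, tolerance = 0.01)
  # zero-amplitude site has no extrema
  expect_error(swing_distance(ml, 0), "extrema")
  # forward translation can only lengthen the path
  xy2 <- xy
  for (i in seq_len(nf)) xy2[i, , 1] <- xy2[i, , 1] + 40 * (i - 1) / fr
  ml2 <- midline_sequence(xy2, bl, fr, validate = FALSE)
  expect_gte(swing_distance(ml2, 1.0), swing_distance(ml, 1.0) - 1e-6)
  expect_error(swing_distance(ml, 1.2), "site")
})

test_that("wave frequency is recovered and is sampling-rate invariant", {
  for (fr in c(250, 500)) {
    t <- seq(0, 3, by = 1 / fr)
    lat <- 0.05 * sin(2 * pi * 2 * t)
    expect_equal(wave_frequency(lat, fr), 2.0, tolerance = 0.02)
  }
  expect_error(wave_frequency(rep(1, 100), 100), "constant")
  expect_error(wave_frequency(0.05 * sin(2 * pi * seq(0, 0.4, by = 0.002)), 500),
               "peaks")
})

test_that("nose elevation magnitude and phase follow the injected signal", {
  fr <- 200
  nf <- 1201
  t <- (seq_len(nf) - 1) / fr
  bl <- 100
  period <- 1
  # peak exactly at fin-cycle midpoint, height 0.1 BL above 0 baseline
  z <- 0.1 * bl * 0.5 * (1 - cos(2 * pi * (t - 0.2) / period))
  lt <- make_landmarks(list(nose = cbind(50 * t, 0, z)), bl = bl,
                       frame_rate = fr)
  seg <- regular_fin_seg(t0 = 0.2, period = period, n_cycles = 5)
  ne <- nose_elevation(lt, seg)
  expect_equal(ne$magnitude, 0.1, tolerance = 0.01)
  expect_true(all(abs(ne$per_cycle$deg - 180) < 4))
  # flat trajectory: zero magnitude
  lt0 <- make_landmarks(list(nose = cbind(50 * t, 0, 0 * t)), bl = bl,
                        frame_rate = fr)
  expect_equal(nose_elevation(lt0, seg)$magnitude, 0, tolerance = 1e-6)
  ltna <- make_landmarks(list(nose = cbind(50 * t, 0, NA * t)), bl = bl,
                         frame_rate = fr)
  expect_error(nose_elevation(ltna, seg), "z-coordinate")
})

test_that("maximum-amplitude timing lags along the body by the wave lag", {
  tr <- clean_trial()
  tseg <- polygait:::trial_tail_segmentation(tr)
  ap <- max_amplitude_phase(tr$midlines, tseg)
  expect_true(all(ap$deg >= 0 & ap$deg < 360))
  # measured phases match the generator's realized site timing
  for (k in seq_along(tr$truth$sites)) {
    s <- tr$truth$sites[k]
    mL <- circular_mean_variance(ap$deg[ap$site == s & ap$side == "left"])
    dL <- abs(((mL$mean_deg - tr$truth$site_max_phase_left[k] + 180) %% 360) - 180)
    expect_lt(dL, 6)
  }
  # timing lags tailward by roughly the traveling-wave delay
  m40 <- circular_mean_variance(ap$deg[ap$site == 0.4 & ap$side == "left"])
  m80 <- circular_mean_variance(ap$deg[ap$site == 0.8 & ap$side == "left"])
  lag <- (m80$mean_deg - m40$mean_deg) %% 360
  expect_lt(abs(lag - 360 * (0.8 - 0.4) / tr$truth$wavelength), 30)
  # left and right extrema at the same site are half a cycle apart
  m40r <- circular_mean_variance(ap$deg[ap$site == 0.4 & ap$side == "right"])
  expect_lt(abs(((m40r$mean_deg - m40$mean_deg) %% 360) - 180), 8)
  expect_error(max_amplitude_phase(tr$midlines, tseg, sites = 1.4), "sites")
})
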