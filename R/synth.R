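# Synthetic trial generator with recorded ground truth.
#
# The body is a traveling wave y(s,t) = A(s) sin(2*pi*(f*t - s/lambda))
# superimposed on steady forward translation; pectoral fin angles are
# sinusoids about 90 deg with a controllable left-right phase offset; EMG
# channels carry raised-cosine amplitude-modulated Gaussian bursts arranged
# as an anterior-to-posterior wave alternating between body sides.

#' Default electrode layout
#'
#' One pectoral-fin adductor electrode plus five evenly spaced left-side red
#' axial muscle electrodes and right-side electrodes opposite axial positions
#' 2 and 4.
#'
#' @return data.frame with columns `channel`, `muscle`, `side`, `position`
#'   (\%BL) and `site_rank` (anterior-to-posterior order among axial sites).
#' @export
default_emg_sites <- function() {
  data.frame(
    channel = c("add_L", paste0("ax", 1:5, "_L"), "ax2_R", "ax4_R"),
    muscle = c("adductor", rep("axial_red", 7)),
    side = c("left", rep("left", 5), "right", "right"),
    position = c(12, 19.8, 33.1, 42.8, 57.4, 67.4, 33.1, 57.4),
    site_rank = c(NA, 1:5, 2, 4),
    stringsAsFactors = FALSE
  )
}

#' Specification of one synthetic trial
#'
#' All magnitudes are standardized to body length (BL); angles are degrees.
#'
#' @param body_length total body length, mm.
#' @param body_depth water depth as a fraction of body depth (BD).
#' @param frame_rate video frame rate, frames per second.
#' @param emg_rate EMG sampling rate, samples per second.
#' @param duration trial duration, s.
#' @param speed forward locomotion speed, BL per second.
#' @param wave_frequency body-wave frequency, cycles per second.
#' @param wave_amplitude_envelope function of arc position (0 = nose, 1 =
#'   tail) returning lateral amplitude in BL; must be non-negative.
#' @param wavelength body-wave arc wavelength in BL.
#' @param fin_frequency pectoral-fin stroke frequency, cycles per second.
#' @param fin_amplitude half-range of the fin angle about 90 deg, so the fin
#'   range of motion is `2 * fin_amplitude`.
#' @param fin_phase_offset mean phase of left-fin adduction within the
#'   right-fin cycle (deg); a vector gives mixture components sampled
#'   uniformly per cycle (e.g. `c(0, 180)` for the mixed condition).
#' @param fin_phase_kappa von Mises concentration of the per-cycle jitter on
#'   the left-fin phase; `Inf` = no jitter.
#' @param nose_elev_height peak nose elevation above the substrate, BL.
#' @param nose_elev_phase phase of peak nose elevation within the right-fin
#'   cycle, deg.
#' @param emg_sites electrode table as in [default_emg_sites()].
#' @param burst_duty fraction of the cycle each EMG burst occupies (0-1).
#' @param burst_gain per-channel burst amplitude; a scalar applies to all
#'   channels, or a named vector keyed by channel.
#' @param onset_base tail-cycle phase (deg) of the most anterior axial burst
#'   onset.
#' @param onset_lag_per_site additional onset phase (deg) per axial site,
#'   anterior to posterior.
#' @param emg_baseline_sd standard deviation of baseline EMG noise, in the
#'   same amplitude units as `burst_gain`.
#' @param noise_sd landmark/midline digitization jitter, BL.
#' @param seed integer RNG seed; a fixed seed makes the trial bit-reproducible.
#' @return object of class `trial_spec`.
#' @export
trial_spec <- function(body_length = 95, body_depth = 3.0, frame_rate = 500,
                       emg_rate = 10000, duration = 4, speed = 1.0,
                       wave_frequency = 2.0,
                       wave_amplitude_envelope = function(s) 0.015 + 0.045 * s,
                       wavelength = 1.0, fin_frequency = 1.2,
                       fin_amplitude = 30, fin_phase_offset = 0,
                       fin_phase_kappa = Inf, nose_elev_height = 0.08,
                       nose_elev_phase = 180, emg_sites = default_emg_sites(),
                       burst_duty = 0.35, burst_gain = 1, onset_base = 20,
                       onset_lag_per_site = 30, emg_baseline_sd = 0.02,
                       noise_sd = 0, seed = 1L) {
  spec <- list(body_length = body_length, body_depth = body_depth,
               frame_rate = frame_rate, emg_rate = emg_rate,
               duration = duration, speed = speed,
               wave_frequency = wave_frequency,
               wave_amplitude_envelope = wave_amplitude_envelope,
               wavelength = wavelength, fin_frequency = fin_frequency,
               fin_amplitude = fin_amplitude,
               fin_phase_offset = fin_phase_offset,
               fin_phase_kappa = fin_phase_kappa,
               nose_elev_height = nose_elev_height,
               nose_elev_phase = nose_elev_phase, emg_sites = emg_sites,
               burst_duty = burst_duty, burst_gain = burst_gain,
               onset_base = onset_base,
               onset_lag_per_site = onset_lag_per_site,
               emg_baseline_sd = emg_baseline_sd, noise_sd = noise_sd,
               seed = as.integer(seed))
  validate_trial_spec(spec)
  structure(spec, class = "trial_spec")
}

validate_trial_spec <- function(spec) {
  if (!is.numeric(spec$duration) || spec$duration <= 0) stop_field("duration", "must be > 0")
  if (spec$frame_rate <= 0) stop_field("frame_rate", "must be > 0")
  if (spec$emg_rate <= 0) stop_field("emg_rate", "must be > 0")
  if (spec$body_length <= 0) stop_field("body_length", "must be > 0")
  if (spec$burst_duty <= 0 || spec$burst_duty >= 1) stop_field("burst_duty", "must lie in (0, 1)")
  if (!is.function(spec$wave_amplitude_envelope)) {
    stop_field("wave_amplitude_envelope", "must be a function of arc position")
  }
  env_vals <- spec$wave_amplitude_envelope(seq(0, 1, length.out = 21))
  if (any(!is.finite(env_vals)) || any(env_vals < 0)) {
    stop_field("wave_amplitude_envelope", "must be finite and non-negative on [0, 1]")
  }
  if (spec$wavelength <= 0) stop_field("wavelength", "must be > 0")
  if (spec$wave_frequency < 0) stop_field("wave_frequency", "must be >= 0")
  if (spec$fin_frequency <= 0) stop_field("fin_frequency", "must be > 0")
  if (spec$noise_sd < 0) stop_field("noise_sd", "must be >= 0")
  if (!(is.infinite(spec$fin_phase_kappa) || spec$fin_phase_kappa >= 0)) {
    stop_field("fin_phase_kappa", "must be >= 0 or Inf")
  }
  invisible(spec)
}

resolve_gains <- function(spec) {
  ch <- spec$emg_sites$channel
  g <- spec$burst_gain
  if (length(g) == 1L && is.null(names(g))) {
    gains <- rep(as.numeric(g), length(ch))
  } else {
    gains <- rep(1, length(ch))
    hit <- match(ch, names(g))
    gains[!is.na(hit)] <- as.numeric(g[hit[!is.na(hit)]])
  }
  names(gains) <- ch
  gains
}

#' Generate one synthetic trial
#'
#' Produces landmark trajectories, an arc-length-resampled midline sequence,
#' per-channel EMG, and a `truth` record holding every generative parameter
#' plus derived true values (event times, burst windows, per-site Eulerian
#' amplitude and swing distance computed from the continuous model).
#'
#' @param spec a [trial_spec()].
#' @param sites arc positions (fractions of BL) at which ground-truth site
#'   kinematics are tabulated.
#' @return object of class `fish_trial`: list with elements `spec`,
#'   `landmarks`, `midlines`, `emg` (list of [emg_channel()]) and `truth`.
#' @export
generate_trial <- function(spec, sites = c(0.4, 0.6, 0.8)) {
  validate_trial_spec(spec)
  with_seed(spec$seed, function() generate_trial_impl(spec, sites))
}

generate_trial_impl <- function(spec, sites) {
  BL <- spec$body_length
  fr <- spec$frame_rate
  nf <- as.integer(round(spec$duration * fr)) + 1L
  t_f <- (seq_len(nf) - 1L) / fr
  env <- spec$wave_amplitude_envelope
  fw <- spec$wave_frequency
  lam <- spec$wavelength
  v <- spec$speed

  # Unit-speed construction: the body curve is defined by its tangent angle
  # psi(s,t) = -(2*pi/lambda) * A(s) * cos(2*pi*(f*t - s/lambda)) and
  # positions are arc-length integrals of (cos psi, sin psi), so total body
  # length is exactly BL in every frame, equally spaced points are material
  # points, and bending shortens the nose-tail chord as in a real fish. To
  # first order in A this realizes the traveling wave
  # y(s,t) = A(s) * sin(2*pi*(f*t - s/lambda)).
  n_sub <- 4L
  s_dense <- seq(0, 1, length.out = n_sub * 99L + 1L)
  ds <- s_dense[2] - s_dense[1]
  amp_d <- env(s_dense)
  body_xy <- function(times) {
    phase <- outer(-2 * pi * s_dense / lam, 2 * pi * fw * times, "+")
    psi <- -(2 * pi / lam) * amp_d * cos(phase)
    cp <- cos(psi); sp <- sin(psi)
    ctrap <- function(m) {
      out <- (rbind(0, m[-nrow(m), , drop = FALSE] + m[-1, , drop = FALSE]) / 2) * ds
      apply(out, 2, cumsum)
    }
    xs <- ctrap(cp)
    ys <- ctrap(sp)
    # global lateral offset gives the nose its own amplitude A(0)
    ys <- sweep(ys, 2, amp_d[1] * sin(2 * pi * fw * times), "+")
    xs <- sweep(xs, 2, v * times, "+")
    list(x = xs * BL, y = ys * BL)  # [s_dense, time]
  }
  b <- body_xy(t_f)
  pick <- seq(1L, length(s_dense), by = n_sub)
  ml <- array(NA_real_, dim = c(nf, 100L, 2L))
  ml[, , 1] <- t(b$x[pick, ])
  ml[, , 2] <- t(b$y[pick, ])
  skull_frac <- 0.12
  si <- which.min(abs(s_dense - skull_frac))
  skull <- cbind(b$x[si, ], b$y[si, ])
  site_idx <- round(sites * 99) + 1L
  site_track <- lapply(site_idx, function(ii) ml[, ii, ])
  nose <- ml[, 1, ]
  tail <- ml[, 100, ]
  chord <- sqrt((nose[, 1] - tail[, 1])^2 + (nose[, 2] - tail[, 2])^2) / BL

  # --- pectoral fins ------------------------------------------------------
  ff <- spec$fin_frequency
  theta_r <- 90 + spec$fin_amplitude * sin(2 * pi * ff * t_f)
  # right-fin adduction (cycle start) times
  k <- seq(floor(-0.25 - 1), ceiling(ff * spec$duration))
  add_r <- (k + 0.25) / ff
  add_r <- add_r[add_r >= 0 & add_r <= spec$duration]
  abd_r <- add_r + 0.5 / ff
  abd_r <- abd_r[abd_r <= spec$duration]

  # per-cycle left-fin phase offsets
  offs <- numeric(length(add_r))
  for (i in seq_along(add_r)) {
    mu <- if (length(spec$fin_phase_offset) > 1L) {
      spec$fin_phase_offset[sample.int(length(spec$fin_phase_offset), 1L)]
    } else spec$fin_phase_offset
    draw <- if (is.finite(spec$fin_phase_kappa)) {
      rvonmises(1L, mu, spec$fin_phase_kappa)
    } else mu
    # unwrap around the component mean so interpolation between cycles does
    # not sweep through a full turn
    offs[i] <- mu + circ_diff_deg(draw, mu)
  }
  # left-fin angle: a time-warped sinusoid whose maxima fall exactly at the
  # jittered adduction times, so realized phases equal the von Mises draws
  add_l <- add_r + offs / (360 * ff)
  ord <- order(add_l)
  anchor_t <- add_l[ord]
  anchor_phi <- pi / 2 + 2 * pi * (seq_along(anchor_t) - 1L)
  if (length(anchor_t) >= 2L) {
    Phi <- stats::approx(anchor_t, anchor_phi, xout = t_f, rule = 1)$y
    before <- t_f < anchor_t[1]
    after <- t_f > anchor_t[length(anchor_t)]
    Phi[before] <- anchor_phi[1] + 2 * pi * ff * (t_f[before] - anchor_t[1])
    Phi[after] <- anchor_phi[length(anchor_phi)] +
      2 * pi * ff * (t_f[after] - anchor_t[length(anchor_t)])
  } else {
    Phi <- pi / 2 + 2 * pi * ff * (t_f - anchor_t[1])
  }
  theta_l <- 90 + spec$fin_amplitude * sin(Phi)

  rot <- function(u, ang_deg) {
    a <- deg2rad(ang_deg)
    cbind(cos(a) * u[, 1] - sin(a) * u[, 2],
          sin(a) * u[, 1] + cos(a) * u[, 2])
  }
  u <- nose - skull
  u <- u / sqrt(rowSums(u^2))
  fin_len <- 0.18 * BL
  tip_r <- skull + fin_len * rot(u, -theta_r)
  tip_l <- skull + fin_len * rot(u, theta_l)

  # --- nose elevation -----------------------------------------------------
  h <- spec$nose_elev_height
  z_nose <- h * BL * 0.5 *
    (1 + cos(2 * pi * ff * t_f - 2 * pi * (0.25 + spec$nose_elev_phase / 360)))

  # --- tail stroke truth --------------------------------------------------
  # event times located on the noiseless generated tail-tip signal and
  # refined by quadratic interpolation (sub-frame accuracy)
  y_tail <- ml[, 100L, 2]
  dyt <- diff(y_tail)
  ext_i <- which(dyt[-1] * dyt[-length(dyt)] < 0) + 1L
  ext_t <- vapply(ext_i, function(i) {
    r <- refine_extremum(y_tail, i, half_window = max(3L, round(0.06 * fr)))
    t_f[1] + (r[["index"]] - 1) / fr
  }, numeric(1))
  is_max <- vapply(ext_i, function(i) y_tail[i] >= y_tail[i - 1L], logical(1))
  swing_r <- ext_t[is_max]   # maximum-left excursion: tail starts swinging right
  swing_l <- ext_t[!is_max]
  tail_cycles <- if (length(swing_r) >= 2L) {
    data.frame(start = swing_r[-length(swing_r)], end = swing_r[-1])
  } else data.frame(start = numeric(), end = numeric())

  # --- EMG ----------------------------------------------------------------
  gains <- resolve_gains(spec)
  ner <- as.integer(round(spec$duration * spec$emg_rate)) + 1L
  t_e <- (seq_len(ner) - 1L) / spec$emg_rate
  emg <- list()
  burst_tab <- list()
  for (ci in seq_len(nrow(spec$emg_sites))) {
    site <- spec$emg_sites[ci, ]
    sig <- stats::rnorm(ner, 0, spec$emg_baseline_sd)
    if (site$muscle == "adductor") {
      onsets <- add_r[add_r + spec$burst_duty / ff <= spec$duration]
      offsets <- onsets + spec$burst_duty / ff
      cyc_id <- seq_along(onsets)
      phase <- rep(0, length(onsets))
    } else {
      p <- spec$onset_base + (site$site_rank - 1) * spec$onset_lag_per_site +
        ifelse(site$side == "right", 180, 0)
      onsets <- offsets <- numeric(0)
      cyc_id <- integer(0)
      phase <- numeric(0)
      for (cy in seq_len(nrow(tail_cycles))) {
        D <- tail_cycles$end[cy] - tail_cycles$start[cy]
        on <- tail_cycles$start[cy] + (p / 360) * D
        off <- on + spec$burst_duty * D
        if (off <= spec$duration) {
          onsets <- c(onsets, on); offsets <- c(offsets, off)
          cyc_id <- c(cyc_id, cy); phase <- c(phase, p)
        }
      }
    }
    for (b in seq_along(onsets)) {
      i0 <- max(1L, as.integer(floor(onsets[b] * spec$emg_rate)) + 1L)
      i1 <- min(ner, as.integer(ceiling(offsets[b] * spec$emg_rate)) + 1L)
      idx <- i0:i1
      uu <- (t_e[idx] - onsets[b]) / (offsets[b] - onsets[b])
      uu <- pmin(pmax(uu, 0), 1)
      envb <- 0.5 * (1 - cos(2 * pi * uu))
      sig[idx] <- sig[idx] + gains[ci] * envb * stats::rnorm(length(idx))
    }
    emg[[site$channel]] <- emg_channel(sig, spec$emg_rate,
                                       muscle = site$muscle, side = site$side,
                                       position = site$position,
                                       fish_id = "fish1")
    if (length(onsets)) {
      burst_tab[[length(burst_tab) + 1L]] <- data.frame(
        channel = site$channel, side = site$side, position = site$position,
        cycle = cyc_id, onset_s = onsets, offset_s = offsets,
        onset_phase_deg = wrap360(phase), gain = unname(gains[ci]))
    }
  }
  bursts <- if (length(burst_tab)) do.call(rbind, burst_tab) else NULL

  # --- observation noise --------------------------------------------------
  sdn <- spec$noise_sd * BL
  lm_list <- list(nose = cbind(nose, z_nose), tail_tip = cbind(tail, 0),
                  back_of_skull = cbind(skull, 0),
                  right_fin_tip = cbind(tip_r, 0),
                  left_fin_tip = cbind(tip_l, 0))
  lm_df <- do.call(rbind, lapply(names(lm_list), function(nm) {
    m <- lm_list[[nm]]
    data.frame(frame = seq_len(nf), time_s = t_f, landmark = nm,
               x = m[, 1], y = m[, 2], z = m[, 3])
  }))
  if (sdn > 0) {
    lm_df$x <- lm_df$x + stats::rnorm(nrow(lm_df), 0, sdn)
    lm_df$y <- lm_df$y + stats::rnorm(nrow(lm_df), 0, sdn)
    lm_df$z <- lm_df$z + stats::rnorm(nrow(lm_df), 0, sdn)
    ml <- ml + array(stats::rnorm(length(ml), 0, sdn), dim = dim(ml))
  }
  landmarks <- landmark_trajectory(lm_df, body_length = BL, frame_rate = fr)
  midlines <- midline_sequence(ml, body_length = BL, frame_rate = fr,
                               time_s = t_f, validate = FALSE)

  # --- ground-truth site kinematics from the continuous model -------------
  site_amp <- site_swing <- site_phase_left <- site_phase_right <-
    stats::setNames(numeric(length(sites)), paste0("s", sites * 100))
  tail_phase_of <- function(tt) {
    k <- findInterval(tt, swing_r)
    out <- rep(NA_real_, length(tt))
    ok <- k >= 1L & k < length(swing_r)
    out[ok] <- 360 * (tt[ok] - swing_r[k[ok]]) /
      (swing_r[k[ok] + 1L] - swing_r[k[ok]])
    out
  }
  cmean <- function(p) {
    p <- p[!is.na(p)]
    wrap360(rad2deg(atan2(mean(sin(deg2rad(p))), mean(cos(deg2rad(p))))))
  }
  for (j in seq_along(sites)) {
    tr <- site_track[[j]]
    y <- tr[, 2]
    ex <- which(diff(sign(diff(y))) != 0) + 1L
    site_amp[j] <- (max(y) - min(y)) / 2 / BL
    if (length(ex) >= 2L) {
      segs <- vapply(seq_len(length(ex) - 1L), function(q) {
        path_length(tr[ex[q]:ex[q + 1L], , drop = FALSE]) / BL
      }, numeric(1))
      site_swing[j] <- mean(segs)
      ext_t <- vapply(ex, function(i) {
        t_f[1] + (refine_extremum(y, i, max(3L, round(0.06 * fr)))[["index"]] - 1) / fr
      }, numeric(1))
      emax <- vapply(ex, function(i) y[i] >= y[i - 1L], logical(1))
      site_phase_left[j] <- cmean(tail_phase_of(ext_t[emax]))
      site_phase_right[j] <- cmean(tail_phase_of(ext_t[!emax]))
    } else {
      site_swing[j] <- NA_real_
      site_phase_left[j] <- site_phase_right[j] <- NA_real_
    }
  }

  truth <- list(
    body_depth = spec$body_depth, speed = v, wave_frequency = fw,
    wavelength = lam, fin_frequency = ff, fin_rom = 2 * spec$fin_amplitude,
    nose_elevation = h, nose_elev_phase = spec$nose_elev_phase,
    amplitude_envelope_sites = stats::setNames(env(sites), paste0("s", sites * 100)),
    site_amplitude = site_amp, site_swing_distance = site_swing,
    site_max_phase_left = site_phase_left,
    site_max_phase_right = site_phase_right,
    curvature_coefficient = 1 - min(chord),
    sites = sites, burst_duty = spec$burst_duty, gains = gains,
    onset_base = spec$onset_base, onset_lag_per_site = spec$onset_lag_per_site,
    left_fin_phase = wrap360(offs[vapply(add_l, function(tt) {
      k <- findInterval(tt, add_r)
      k >= 1L && k < length(add_r)
    }, logical(1))]),
    fin_events = list(adduction_right = add_r, abduction_right = abd_r,
                      adduction_left = sort(add_l)),
    tail_events = list(swing_right_start = swing_r, swing_left_start = swing_l),
    tail_cycles = tail_cycles, bursts = bursts, noise_sd = spec$noise_sd,
    seed = spec$seed)

  structure(list(spec = spec, landmarks = landmarks, midlines = midlines,
                 emg = emg, truth = truth),
            class = "fish_trial")
}

#' @export
print.fish_trial <- function(x, ...) {
  cat(sprintf("<fish_trial> depth %.1f BD, %.3g s @ %g fps, %d EMG channels, seed %d\n",
              x$spec$body_depth, x$spec$duration, x$spec$frame_rate,
              length(x$emg), x$spec$seed))
  invisible(x)
}

#' Generate a set of trials across a water-depth gradient
#'
#' Applies a documented depth-to-parameter mapping to a base trial spec:
#' the body-wave amplitude envelope is scaled up as depth decreases below
#' 1 BD (more body bending when buoyant support is lost), the left-right fin
#' phase offset switches from 0 (in-phase) to 180 deg (out-of-phase) below
#' `threshold_depth`, and anterior burst gain rises smoothly as depth
#' decreases. All mapping parameters are recorded in the returned object.
#'
#' @param base a [trial_spec()] used for every trial, before the depth
#'   mapping is applied.
#' @param depths water depths (BD fractions), unique, any order.
#' @param trials_per_depth number of trials per depth (>= 1); replicate `r`
#'   at every depth is assigned to `fish<r>`, mirroring a repeated-measures
#'   design.
#' @param threshold_depth depth (BD) at or below which fins switch to
#'   out-of-phase.
#' @param curvature_gain scaling of the amplitude envelope at 0 BD relative
#'   to fully supported depths.
#' @param gain_slope increase of anterior burst gain from the reference depth
#'   down to 0 BD.
#' @param anterior_max_bl electrodes at or anterior to this \%BL (and the fin
#'   adductor) receive the depth-dependent gain.
#' @param ref_depth reference depth for the gain mapping.
#' @param seed base seed; each trial gets a derived sub-seed.
#' @return object of class `trial_set`: list with `trials`, a `design` table
#'   and the `mapping` parameters.
#' @export
generate_depth_sweep <- function(base, depths, trials_per_depth = 3L,
                                 threshold_depth = 0.8, curvature_gain = 0.8,
                                 gain_slope = 1.5, anterior_max_bl = 35,
                                 ref_depth = 3.0, seed = base$seed) {
  if (length(depths) == 0L) stop_field("depths", "must be non-empty")
  if (anyDuplicated(depths)) stop_field("depths", "must be unique")
  if (trials_per_depth < 1L) stop_field("trials_per_depth", "must be >= 1")
  amp_scale_fn <- function(d) 1 + curvature_gain * pmax(0, 1 - pmin(d, 1))
  gain_fn <- function(d) 1 + gain_slope * (pmax(0, ref_depth - d) / ref_depth)^2
  ant <- with(base$emg_sites,
              muscle == "adductor" | (!is.na(position) & position <= anterior_max_bl))
  trials <- list()
  design <- list()
  i <- 0L
  for (d in depths) {
    for (r in seq_len(trials_per_depth)) {
      i <- i + 1L
      sp <- base
      sp$body_depth <- d
      sc <- amp_scale_fn(d)
      base_env <- base$wave_amplitude_envelope
      sp$wave_amplitude_envelope <- local({
        sc_ <- sc; be <- base_env
        function(s) sc_ * be(s)
      })
      sp$fin_phase_offset <- if (d <= threshold_depth) 180 else 0
      g <- rep(1, nrow(base$emg_sites))
      g[ant] <- gain_fn(d)
      names(g) <- base$emg_sites$channel
      sp$burst_gain <- g
      sp$seed <- as.integer((seed + 7919 * i) %% 2147483647)
      class(sp) <- "trial_spec"
      tr <- generate_trial(sp)
      tr$trial_id <- sprintf("d%s_r%d", format(d, nsmall = 1), r)
      tr$fish_id <- paste0("fish", r)
      for (ch in names(tr$emg)) tr$emg[[ch]]$fish_id <- tr$fish_id
      trials[[tr$trial_id]] <- tr
      design[[i]] <- data.frame(trial_id = tr$trial_id, depth = d, rep = r,
                                fish_id = tr$fish_id, seed = sp$seed,
                                amp_scale = sc,
                                fin_phase_offset = sp$fin_phase_offset,
                                anterior_gain = gain_fn(d))
    }
  }
  structure(list(trials = trials, design = do.call(rbind, design),
                 mapping = list(threshold_depth = threshold_depth,
                                curvature_gain = curvature_gain,
                                gain_slope = gain_slope,
                                anterior_max_bl = anterior_max_bl,
                                ref_depth = ref_depth, seed = seed)),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> %d trials across depths: %s\n",
              length(x$trials),
              paste(sort(unique(x$design$depth), decreasing = TRUE), collapse = ", ")))
  invisible(x)
}
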