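# Trial-level body kinematic variables and body-timing phase samples.

#' Curvature coefficient over a locomotor cycle
#'
#' One minus the minimum straight-line nose-tail distance within the cycle,
#' standardized to BL: 0 for a fish that stays perfectly straight, 1 when the
#' nose and tail touch in some frame.
#'
#' @param ml a [midline_sequence()].
#' @param frames optional integer vector of frame indices delimiting the
#'   cycle; defaults to all frames.
#' @return dimensionless value in `[0, 1]`.
#' @export
curvature_coefficient <- function(ml, frames = NULL) {
  nf <- dim(ml$xy)[1]
  if (is.null(frames)) frames <- seq_len(nf)
  if (length(frames) < 2L) stop_field("frames", "cycle must span at least 2 frames")
  np <- dim(ml$xy)[2]
  nose <- ml$xy[frames, 1, , drop = FALSE]
  tail <- ml$xy[frames, np, , drop = FALSE]
  d <- sqrt((nose[, 1, 1] - tail[, 1, 1])^2 + (nose[, 1, 2] - tail[, 1, 2])^2) /
    ml$body_length
  if (any(d > 1.02)) {
    stop(sprintf("nose-tail distance exceeds BL by more than 2%% (max %.3f BL): inconsistent calibration",
                 max(d)), call. = FALSE)
  }
  1 - min(d)
}

#' Locomotion speed
#'
#' Net straight-line displacement of the nose in the x-y plane over the
#' trial, divided by trial duration, in BL per second.
#'
#' @param lt a [landmark_trajectory()].
#' @param body_length BL; defaults to the trajectory's attribute.
#' @return speed in BL s^-1.
#' @export
locomotion_speed <- function(lt, body_length = attr(lt, "body_length")) {
  tr <- landmark_track(lt, "nose")
  dur <- diff(range(tr$time_s))
  if (dur <= 0) stop_field("lt", "trial duration must be > 0")
  disp <- sqrt(sum((tr$xyz[nrow(tr$xyz), 1:2] - tr$xyz[1, 1:2])^2))
  disp / dur / body_length
}

#' Body-wave frequency at a site
#'
#' Mean of 1/period over successive same-sign amplitude peaks (maximum-left
#' to the next maximum-left).
#'
#' @param lateral lateral displacement series at one body site.
#' @param frame_rate frames per second.
#' @param cutoff_hz zero-phase low-pass cutoff applied first (`NULL` =
#'   none).
#' @param smooth_window moving-average window (frames) used before peak
#'   detection.
#' @param min_prominence_frac minimum peak prominence as a fraction of the
#'   signal range.
#' @return cycles per second.
#' @export
wave_frequency <- function(lateral, frame_rate, cutoff_hz = 6,
                           smooth_window = 5L, min_prominence_frac = 0.1) {
  if (diff(range(lateral, na.rm = TRUE)) <= 0) {
    stop("constant signal: no amplitude peaks", call. = FALSE)
  }
  lateral <- lowpass(lateral, frame_rate, cutoff_hz)
  rng <- diff(range(lateral))
  ex <- find_extrema(lateral, smooth_window, min_prominence_frac * rng)
  mx <- ex[ex$type == "max", , drop = FALSE]
  if (nrow(mx) < 2L) stop("fewer than 2 same-sign amplitude peaks", call. = FALSE)
  xs <- movavg(lateral, smooth_window)
  t_peak <- vapply(mx$index, function(i) {
    refine_extremum(xs, i, half_window = max(3L, round(0.1 * frame_rate)))["index"]
  }, numeric(1)) / frame_rate
  mean(1 / diff(t_peak))
}

#' Swing distance at a body site
#'
#' For each half-cycle, the Euclidean path length travelled by the site point
#' in the x-y plane between the frames of maximum-left and maximum-right
#' lateral amplitude; the trial mean is returned in BL.
#'
#' @param ml a [midline_sequence()].
#' @param site arc position of the site as a fraction of BL (0-1).
#' @param cutoff_hz zero-phase low-pass cutoff applied to the site trajectory
#'   before extremum detection and path integration (`NULL` = none).
#' @param smooth_window,min_prominence_frac peak-detection parameters as in
#'   [wave_frequency()].
#' @return mean swing distance, BL per half-cycle.
#' @export
swing_distance <- function(ml, site, cutoff_hz = 6, smooth_window = 5L,
                           min_prominence_frac = 0.1) {
  np <- dim(ml$xy)[2]
  if (site < 0 || site > 1) stop_field("site", "must lie in [0, 1] (fraction of BL)")
  idx <- round(site * (np - 1L)) + 1L
  x <- lowpass(ml$xy[, idx, 1], ml$frame_rate, cutoff_hz)
  y <- lowpass(ml$xy[, idx, 2], ml$frame_rate, cutoff_hz)
  bf <- body_frame(ml)
  lat <- lowpass(bf$lateral[, idx], ml$frame_rate, cutoff_hz)
  rng <- diff(range(lat))
  ex <- find_extrema(lat, smooth_window, min_prominence_frac * rng)
  if (nrow(ex) < 2L) stop("no detectable amplitude extrema at this site", call. = FALSE)
  traj <- cbind(x, y)
  segs <- vapply(seq_len(nrow(ex) - 1L), function(q) {
    path_length(traj[ex$index[q]:ex$index[q + 1L], , drop = FALSE])
  }, numeric(1))
  mean(segs) / ml$body_length
}

#' Nose elevation magnitude and timing
#'
#' Per-cycle maximum nose height above the trial baseline (the minimum nose
#' z), standardized to BL, and the phase of each maximum within the
#' corresponding pectoral-fin cycle (0 deg = start of that fin's adduction).
#' Extremum values and times are refined by a local quadratic fit to avoid
#' the upward bias of a pointwise max over noisy samples.
#'
#' @param lt a [landmark_trajectory()] with finite nose z.
#' @param fin_seg a fin [stroke_segmentation()] giving the cycles against
#'   which elevation timing is expressed.
#' @param cutoff_hz zero-phase low-pass cutoff for the z series (`NULL` =
#'   none).
#' @param side label copied into the output phase table.
#' @return list with `magnitude` (trial mean, BL), `baseline` (BL),
#'   `per_cycle` data.frame (`cycle`, `height_bl`, `time_s`, `deg`).
#' @export
nose_elevation <- function(lt, fin_seg, cutoff_hz = 6, side = "right") {
  tr <- landmark_track(lt, "nose")
  z <- tr$xyz[, 3]
  if (all(!is.finite(z))) stop_field("lt", "nose z-coordinate missing")
  rate <- 1 / stats::median(diff(tr$time_s))
  zf <- lowpass(z, rate, cutoff_hz)
  cyc <- fin_seg$cycles
  if (nrow(cyc) == 0L) stop_field("fin_seg", "no complete fin cycles")
  out <- data.frame(side = character(), cycle = integer(), height = numeric(),
                    time_s = numeric(), deg = numeric())
  mins <- numeric(0)
  for (k in seq_len(nrow(cyc))) {
    inwin <- which(tr$time_s >= cyc$start[k] & tr$time_s < cyc$end[k])
    if (length(inwin) < 5L) next
    hw <- max(3L, round(0.125 * length(inwin)))
    imax <- inwin[which.max(zf[inwin])]
    rmax <- refine_extremum(zf, imax, hw)
    imin <- inwin[which.min(zf[inwin])]
    rmin <- refine_extremum(zf, imin, hw)
    mins <- c(mins, rmin["value"])
    t_pk <- tr$time_s[1] + (rmax["index"] - 1) / rate
    out <- rbind(out, data.frame(side = side, cycle = k, height = rmax["value"],
                                 time_s = t_pk, deg = NA_real_))
  }
  if (nrow(out) == 0L) stop("no usable fin cycles for nose elevation", call. = FALSE)
  baseline <- min(mins)
  ph <- cycle_phase(out$time_s, fin_seg)
  out$deg <- ph$deg
  out$height_bl <- (out$height - baseline) / attr(lt, "body_length")
  list(magnitude = mean(out$height_bl),
       baseline = baseline / attr(lt, "body_length"),
       per_cycle = out[, c("side", "cycle", "height_bl", "time_s", "deg")])
}

#' Timing of maximum body amplitude relative to the tail stroke
#'
#' Phase samples (degrees, 0 deg = start of tail swing to the right, 180 deg
#' = start of tail swing to the left) of the frames of maximum-left and
#' maximum-right lateral amplitude at the given body sites.
#'
#' @param ml a [midline_sequence()].
#' @param tail_seg a tail [stroke_segmentation()].
#' @param sites arc positions (fractions of BL), default 40/60/80\%.
#' @param cutoff_hz low-pass cutoff for the lateral series (`NULL` = none).
#' @param smooth_window,min_prominence_frac peak-detection parameters.
#' @return data.frame `site`, `side` (`"left"`/`"right"` extremum), `cycle`,
#'   `deg` in `[0, 360)`; extrema outside every tail cycle are dropped.
#' @export
max_amplitude_phase <- function(ml, tail_seg, sites = c(0.4, 0.6, 0.8),
                                cutoff_hz = 6, smooth_window = 5L,
                                min_prominence_frac = 0.1) {
  if (any(sites < 0 | sites > 1)) stop_field("sites", "must lie in [0, 1] (fraction of BL)")
  bf <- body_frame(ml)
  np <- dim(ml$xy)[2]
  rate <- ml$frame_rate
  res <- list()
  for (s in sites) {
    idx <- round(s * (np - 1L)) + 1L
    lat <- lowpass(bf$lateral[, idx], rate, cutoff_hz)
    ex <- find_extrema(lat, smooth_window, min_prominence_frac * diff(range(lat)))
    if (nrow(ex) == 0L) next
    t_ex <- vapply(seq_len(nrow(ex)), function(q) {
      refine_extremum(lat, ex$index[q], max(3L, round(0.1 * rate)))["index"]
    }, numeric(1))
    t_ex <- ml$time_s[1] + (t_ex - 1) / rate
    ph <- cycle_phase(t_ex, tail_seg)
    keep <- !is.na(ph$deg)
    if (!any(keep)) next
    res[[length(res) + 1L]] <- data.frame(
      site = s, side = ifelse(ex$type == "max", "left", "right")[keep],
      cycle = ph$cycle[keep], deg = ph$deg[keep])
  }
  if (length(res) == 0L) {
    return(data.frame(site = numeric(), side = character(), cycle = integer(),
                      deg = numeric()))
  }
  do.call(rbind, res)
}
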