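# Pectoral-fin stroke segmentation, fin angle, frequency, range of motion
# and left-fin phase.

#' Pectoral fin angle
#'
#' Per-frame interior angle at the back-of-skull vertex between the rays to
#' the nose and to the fin-lobe tip, computed in the x-y plane projection.
#' Frames with coincident landmarks are flagged `NA` rather than fabricated.
#'
#' @param lt a [landmark_trajectory()] containing `nose`, `back_of_skull`
#'   and `<side>_fin_tip`.
#' @param side `"left"` or `"right"`.
#' @return data.frame `time_s`, `angle_deg` in `(0, 180]`.
#' @export
fin_angle <- function(lt, side = c("right", "left")) {
  side <- match.arg(side)
  nose <- landmark_track(lt, "nose")
  skull <- landmark_track(lt, "back_of_skull")
  tip <- landmark_track(lt, paste0(side, "_fin_tip"))
  a <- nose$xyz[, 1:2, drop = FALSE] - skull$xyz[, 1:2, drop = FALSE]
  b <- tip$xyz[, 1:2, drop = FALSE] - skull$xyz[, 1:2, drop = FALSE]
  na <- sqrt(rowSums(a^2))
  nb <- sqrt(rowSums(b^2))
  cosang <- rowSums(a * b) / (na * nb)
  cosang[na < 1e-9 | nb < 1e-9] <- NA_real_
  cosang <- pmin(pmax(cosang, -1), 1)
  data.frame(time_s = nose$time_s, angle_deg = rad2deg(acos(cosang)))
}

#' Segment strokes from a fin-angle or tail-lateral signal
#'
#' For fin strokes, adduction starts are placed at local maxima of the fin
#' angle (the fin beginning to sweep toward the body) and abduction starts at
#' local minima. For tail strokes, swing-right starts are placed where the
#' lateral tail velocity crosses zero from positive to negative (maximum-left
#' excursion, left positive) and swing-left starts at the opposite crossings.
#' Event times are refined by a local quadratic fit.
#'
#' @param x numeric signal: fin angle (deg) or lateral tail displacement.
#' @param rate sampling rate of `x`, samples per second.
#' @param kind `"fin"` or `"tail"`.
#' @param t0 time of the first sample (s).
#' @param smooth_window moving-average window (samples) before extremum
#'   detection.
#' @param min_prominence_frac minimum extremum prominence as a fraction of
#'   the signal range.
#' @param cutoff_hz optional zero-phase low-pass cutoff applied first.
#' @return a [stroke_segmentation()].
#' @export
segment_strokes <- function(x, rate, kind = c("fin", "tail"), t0 = 0,
                            smooth_window = 5L, min_prominence_frac = 0.1,
                            cutoff_hz = NULL) {
  kind <- match.arg(kind)
  x <- as.numeric(x)
  if (anyNA(x)) {
    x <- zoo::na.approx(x, na.rm = FALSE)
    x <- zoo::na.locf(zoo::na.locf(x, na.rm = FALSE), fromLast = TRUE, na.rm = FALSE)
  }
  x <- lowpass(x, rate, cutoff_hz)
  rng <- diff(range(x))
  if (rng <= 0) stop("constant signal: no stroke events detectable", call. = FALSE)
  ex <- find_extrema(x, smooth_window, min_prominence_frac * rng)
  if (nrow(ex) < 2L) {
    stop(sprintf("no alternation achievable: detected %d extremum/extrema (%s)",
                 nrow(ex), paste(ex$type, collapse = ", ")), call. = FALSE)
  }
  xs <- movavg(x, smooth_window)
  t_ref <- vapply(seq_len(nrow(ex)), function(q) {
    refine_extremum(xs, ex$index[q], max(3L, round(0.04 * rate)))["index"]
  }, numeric(1))
  times <- t0 + (t_ref - 1) / rate
  type <- if (kind == "fin") {
    ifelse(ex$type == "max", "adduction_start", "abduction_start")
  } else {
    ifelse(ex$type == "max", "tail_swing_right_start", "tail_swing_left_start")
  }
  stroke_segmentation(kind, data.frame(event_type = type, time_s = times))
}

#' Build a stroke segmentation from a manual annotation table
#'
#' Allows manually scored event times (the original workflow) to be supplied
#' verbatim instead of the automatic extremum detector.
#'
#' @param ann data.frame with columns `event_type`, `time_s`.
#' @param kind `"fin"` or `"tail"`.
#' @return a [stroke_segmentation()].
#' @export
segmentation_from_annotations <- function(ann, kind = c("fin", "tail")) {
  stroke_segmentation(match.arg(kind), ann[, c("event_type", "time_s")])
}

#' Pectoral fin stroke frequency
#'
#' Mean of 1/cycle-duration over complete stroke cycles.
#'
#' @param seg a fin [stroke_segmentation()] with at least 2 complete cycles.
#' @return cycles per second.
#' @export
fin_frequency <- function(seg) {
  cyc <- seg$cycles
  if (nrow(cyc) < 2L) stop("fewer than 2 complete stroke cycles", call. = FALSE)
  mean(1 / (cyc$end - cyc$start))
}

#' Pectoral fin range of motion
#'
#' Per-cycle (maximum - minimum) fin angle, averaged over cycles. Extremum
#' values are refined by a local quadratic fit within each cycle.
#'
#' @param angle data.frame from [fin_angle()] (columns `time_s`,
#'   `angle_deg`).
#' @param seg a fin [stroke_segmentation()].
#' @param cutoff_hz zero-phase low-pass cutoff for the angle series before
#'   extremum estimation (`NULL` = none).
#' @return degrees.
#' @export
fin_rom <- function(angle, seg, cutoff_hz = 4) {
  cyc <- seg$cycles
  if (nrow(cyc) == 0L) stop("no complete stroke cycles", call. = FALSE)
  x <- angle$angle_deg
  if (anyNA(x)) {
    x <- zoo::na.approx(x, na.rm = FALSE)
    x <- zoo::na.locf(zoo::na.locf(x, na.rm = FALSE), fromLast = TRUE, na.rm = FALSE)
  }
  rate <- 1 / stats::median(diff(angle$time_s))
  xf <- lowpass(x, rate, cutoff_hz)
  roms <- numeric(0)
  for (k in seq_len(nrow(cyc))) {
    inwin <- which(angle$time_s >= cyc$start[k] & angle$time_s < cyc$end[k])
    if (length(inwin) < 5L) stop(sprintf("cycle %d contains too few samples", k), call. = FALSE)
    hw <- max(3L, round(0.125 * length(inwin)))
    vmax <- refine_extremum(xf, inwin[which.max(xf[inwin])], hw)["value"]
    vmin <- refine_extremum(xf, inwin[which.min(xf[inwin])], hw)["value"]
    roms <- c(roms, vmax - vmin)
  }
  mean(roms)
}

#' Trial-level fin range of motion from both sides
#'
#' @param rom_left,rom_right per-side RoM values (deg).
#' @return their arithmetic mean.
#' @export
trial_fin_rom <- function(rom_left, rom_right) mean(c(rom_left, rom_right))

#' Left-fin phase within the right-fin stroke cycle
#'
#' Phase (degrees) of each start of left-fin adduction within the enclosing
#' right-fin cycle: 0 deg = start of right adduction, 180 deg = start of
#' right abduction, with the two half-cycles mapped piecewise-linearly.
#' Left events falling outside every right cycle are skipped (with a
#' message).
#'
#' @param left_seg,right_seg fin [stroke_segmentation()]s.
#' @return numeric vector of phases in `[0, 360)`.
#' @export
left_fin_phase <- function(left_seg, right_seg) {
  ev <- left_seg$events
  t_add <- ev$time_s[ev$event_type == "adduction_start"]
  ph <- cycle_phase(t_add, right_seg)
  n_skip <- sum(is.na(ph$deg))
  if (n_skip > 0L) {
    message(sprintf("left_fin_phase: %d left adduction event(s) outside any right-fin cycle; skipped", n_skip))
  }
  ph$deg[!is.na(ph$deg)]
}
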