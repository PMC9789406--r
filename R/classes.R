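#' Midline sequence
#'
#' A time-ordered set of body midlines, one per video frame, each resampled to
#' a fixed number of points equally spaced in arc length from nose to tail.
#'
#' @param xy numeric array `frames x points x 2` (x, y in calibrated units),
#'   or a list of `points x 2` matrices, point 1 at the nose in every frame.
#' @param body_length total body length (BL) in the same units as `xy`.
#' @param frame_rate frames per second.
#' @param time_s optional frame times; defaults to `(0:(frames-1))/frame_rate`.
#' @param validate check equal arc-length spacing (1\% tolerance per frame).
#' @return An object of class `midline_sequence`.
#' @export
midline_sequence <- function(xy, body_length, frame_rate, time_s = NULL,
                             validate = TRUE) {
  if (is.list(xy)) {
    np <- unique(vapply(xy, nrow, integer(1)))
    if (length(np) != 1L) stop_field("xy", "all frames must have the same number of points")
    arr <- array(NA_real_, dim = c(length(xy), np, 2L))
    for (i in seq_along(xy)) arr[i, , ] <- as.matrix(xy[[i]])
    xy <- arr
  }
  if (length(dim(xy)) != 3L || dim(xy)[3] != 2L) {
    stop_field("xy", "must be a frames x points x 2 array")
  }
  if (!is.numeric(body_length) || body_length <= 0) stop_field("body_length", "must be > 0")
  if (!is.numeric(frame_rate) || frame_rate <= 0) stop_field("frame_rate", "must be > 0")
  nf <- dim(xy)[1]
  if (is.null(time_s)) time_s <- (seq_len(nf) - 1L) / frame_rate
  if (length(time_s) != nf) stop_field("time_s", "length must equal number of frames")
  if (validate && dim(xy)[2] >= 3L) {
    for (i in seq_len(nf)) {
      seg <- sqrt(rowSums(diff(xy[i, , ])^2))
      m <- mean(seg)
      if (m > 0 && max(abs(seg - m)) > 0.01 * m + 1e-12) {
        stop(sprintf("frame %d: points are not equally spaced in arc length (tolerance 1%%); resample with resample_midline()", i),
             call. = FALSE)
      }
    }
  }
  structure(list(xy = xy, body_length = body_length, frame_rate = frame_rate,
                 time_s = time_s),
            class = "midline_sequence")
}

#' @export
print.midline_sequence <- function(x, ...) {
  cat(sprintf("<midline_sequence> %d frames x %d points, BL = %.4g, %.4g fps\n",
              dim(x$xy)[1], dim(x$xy)[2], x$body_length, x$frame_rate))
  invisible(x)
}

#' Landmark trajectory
#'
#' Per-frame 3-D coordinates of named anatomical landmarks for one trial.
#'
#' @param df data.frame with columns `frame`, `time_s`, `landmark`, `x`, `y`,
#'   `z`.
#' @param body_length body length (BL) in the same units as the coordinates.
#' @param frame_rate frames per second.
#' @return An object of class `landmark_trajectory` (a data.frame with
#'   attributes `body_length` and `frame_rate`).
#' @export
landmark_trajectory <- function(df, body_length, frame_rate) {
  need <- c("frame", "time_s", "landmark", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_field("df", paste("missing columns:", paste(miss, collapse = ", ")))
  if (!is.numeric(body_length) || body_length <= 0) stop_field("body_length", "must be > 0")
  df <- as.data.frame(df)[, need]
  attr(df, "body_length") <- body_length
  attr(df, "frame_rate") <- frame_rate
  class(df) <- c("landmark_trajectory", "data.frame")
  df
}

# Extract one landmark as a frames x 3 matrix ordered by time, plus times.
landmark_track <- function(lt, name) {
  sub <- lt[lt$landmark == name, , drop = FALSE]
  if (nrow(sub) == 0L) stop(sprintf("landmark '%s' not present", name), call. = FALSE)
  sub <- sub[order(sub$time_s), , drop = FALSE]
  list(time_s = sub$time_s, xyz = as.matrix(sub[, c("x", "y", "z")]))
}

#' EMG channel
#'
#' One electrode's signal together with its metadata.
#'
#' @param samples numeric amplitude series (signed).
#' @param rate sampling rate, samples per second.
#' @param muscle `"adductor"` or `"axial_red"`.
#' @param side `"left"` or `"right"`.
#' @param position electrode position in \%BL (0--100); `NA` for the fin
#'   adductor.
#' @param fish_id identifier used to pool signals for the theoretical-maximum
#'   normalization.
#' @return An object of class `emg_channel`.
#' @export
emg_channel <- function(samples, rate, muscle = c("axial_red", "adductor"),
                        side = c("left", "right"), position = NA_real_,
                        fish_id = "fish1") {
  muscle <- match.arg(muscle)
  side <- match.arg(side)
  if (!is.numeric(rate) || rate <= 0) stop_field("rate", "must be > 0")
  if (!is.na(position) && (position < 0 || position > 100)) {
    stop_field("position", "must lie in [0, 100] %BL")
  }
  structure(list(samples = as.numeric(samples), rate = rate, muscle = muscle,
                 side = side, position = position, fish_id = fish_id),
            class = "emg_channel")
}

#' @export
print.emg_channel <- function(x, ...) {
  cat(sprintf("<emg_channel> %s %s @ %s%%BL, %d samples @ %g Hz, fish %s\n",
              x$side, x$muscle,
              ifelse(is.na(x$position), "-", format(x$position)),
              length(x$samples), x$rate, x$fish_id))
  invisible(x)
}

#' Stroke segmentation
#'
#' Ordered stroke events and the cycles they delimit. For fin strokes the
#' events are `adduction_start` (cycle start, 0 deg) and `abduction_start`
#' (mid-stroke, 180 deg); for tail strokes `tail_swing_right_start` (0 deg)
#' and `tail_swing_left_start` (180 deg).
#'
#' @param kind `"fin"` or `"tail"`.
#' @param events data.frame with columns `event_type`, `time_s`, strictly
#'   increasing in time with alternating types.
#' @return An object of class `stroke_segmentation` with an `events`
#'   data.frame and a derived `cycles` data.frame (`start`, `mid`, `end`).
#' @export
stroke_segmentation <- function(kind = c("fin", "tail"), events) {
  kind <- match.arg(kind)
  start_type <- if (kind == "fin") "adduction_start" else "tail_swing_right_start"
  mid_type <- if (kind == "fin") "abduction_start" else "tail_swing_left_start"
  allowed <- c(start_type, mid_type)
  if (!all(events$event_type %in% allowed)) {
    stop_field("events", paste("event_type must be one of:", paste(allowed, collapse = ", ")))
  }
  events <- events[order(events$time_s), , drop = FALSE]
  if (any(diff(events$time_s) <= 0)) stop_field("events", "times must be strictly increasing")
  if (any(events$event_type[-1] == events$event_type[-nrow(events)])) {
    stop_field("events", "event types must alternate")
  }
  starts <- which(events$event_type == start_type)
  cyc <- list()
  for (s in starts) {
    if (s + 2L <= nrow(events)) {
      cyc[[length(cyc) + 1L]] <- data.frame(start = events$time_s[s],
                                            mid = events$time_s[s + 1L],
                                            end = events$time_s[s + 2L])
    }
  }
  cycles <- if (length(cyc)) do.call(rbind, cyc) else
    data.frame(start = numeric(), mid = numeric(), end = numeric())
  structure(list(kind = kind, events = events, cycles = cycles),
            class = "stroke_segmentation")
}

#' @export
print.stroke_segmentation <- function(x, ...) {
  cat(sprintf("<stroke_segmentation> kind = %s, %d events, %d complete cycles\n",
              x$kind, nrow(x$events), nrow(x$cycles)))
  invisible(x)
}

#' Map event times to phase within stroke cycles
#'
#' Piecewise-linear phase convention anchored at both named events: the first
#' half-cycle (start to mid) maps to 0--180 deg and the second (mid to end) to
#' 180--360 deg, so 0 deg is the cycle-start event and 180 deg the mid-stroke
#' event even when half-cycles are asymmetric.
#'
#' @param times numeric event times (s).
#' @param seg a [stroke_segmentation()].
#' @return data.frame `time_s`, `cycle` (index or `NA` when outside every
#'   cycle), `deg` in `[0, 360)`.
#' @export
cycle_phase <- function(times, seg) {
  cyc <- seg$cycles
  out <- data.frame(time_s = times, cycle = NA_integer_, deg = NA_real_)
  if (nrow(cyc) == 0L) return(out)
  for (i in seq_along(times)) {
    t <- times[i]
    k <- which(cyc$start <= t & t < cyc$end)
    if (length(k) == 0L) next
    k <- k[1]
    d <- if (t < cyc$mid[k]) {
      180 * (t - cyc$start[k]) / (cyc$mid[k] - cyc$start[k])
    } else {
      180 + 180 * (t - cyc$mid[k]) / (cyc$end[k] - cyc$mid[k])
    }
    out$cycle[i] <- k
    out$deg[i] <- wrap360(d)
  }
  out
}
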