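# EMG conditioning and burst-level metrics: duty factor, normalized RIA,
# onset/offset phase and contralateral co-activation.

#' Condition an EMG signal
#'
#' Zero-phase 60 Hz notch followed by a zero-phase Butterworth band-pass
#' (default 40-4000 Hz). Filters are applied forward-backward (filtfilt) so
#' burst onset times are not biased. Cutoffs at or above Nyquist are clipped
#' with a warning.
#'
#' @param ch an [emg_channel()].
#' @param low,high band-pass corner frequencies, Hz.
#' @param notch notch centre frequency, Hz (`NULL` to skip); a 2nd-order
#'   band-stop of width `notch_width` Hz is used.
#' @param notch_width width of the notch stop band, Hz.
#' @param order band-pass Butterworth order.
#' @return the channel with filtered samples (same length as the input).
#' @export
condition_signal <- function(ch, low = 40, high = 4000, notch = 60,
                             notch_width = 10, order = 4) {
  x <- ch$samples
  if (any(!is.finite(x))) stop("non-finite samples in EMG channel", call. = FALSE)
  nyq <- ch$rate / 2
  if (!is.null(notch) && notch < nyq) {
    w <- c(notch - notch_width / 2, notch + notch_width / 2) / nyq
    bf <- signal::butter(2, w, type = "stop")
    x <- filtfilt_pad(bf, x)
  }
  if (high >= nyq) {
    warning(sprintf("high cutoff %g Hz clipped below Nyquist (%g Hz)", high, nyq))
    high <- 0.99 * nyq
  }
  if (low <= 0 || low >= high) stop_field("low", "band-pass corners must satisfy 0 < low < high")
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  x <- filtfilt_pad(bf, x)
  ch$samples <- x
  ch
}

#' Detect EMG bursts automatically
#'
#' Threshold on a smoothed rectified envelope: threshold = baseline mean +
#' `k` x baseline SD, with the baseline estimated robustly (median and MAD of
#' the envelope). Bursts separated by gaps shorter than `merge_gap_s` are
#' merged and bursts shorter than `min_dur_s` are dropped. Manually scored
#' annotations, when available, should be supplied instead via
#' [read_burst_annotations()].
#'
#' @param ch a conditioned [emg_channel()].
#' @param k threshold multiplier (default 3).
#' @param merge_gap_s merge gaps shorter than this, s (default 0.025).
#' @param min_dur_s drop bursts shorter than this, s (default 0.020).
#' @param smooth_s envelope moving-average window, s.
#' @return data.frame `onset_s`, `offset_s` (possibly empty).
#' @export
detect_bursts <- function(ch, k = 3, merge_gap_s = 0.025, min_dur_s = 0.020,
                          smooth_s = 0.010) {
  x <- abs(ch$samples)
  if (all(x == 0)) return(data.frame(onset_s = numeric(), offset_s = numeric()))
  env <- movavg(x, max(3L, round(smooth_s * ch$rate)))
  m <- stats::median(env)
  s <- stats::mad(env)
  thr <- m + k * s
  above <- env > thr
  if (!any(above)) return(data.frame(onset_s = numeric(), offset_s = numeric()))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on_i <- starts[r$values]
  off_i <- ends[r$values]
  # backtrack each crossing to a lower secondary threshold (baseline + 1 SD)
  # so the slow rise of a burst envelope does not delay the onset estimate
  low <- m + s
  for (j in seq_along(on_i)) {
    i <- on_i[j]
    while (i > 1L && env[i - 1L] > low) i <- i - 1L
    on_i[j] <- i
    i <- off_i[j]
    while (i < length(env) && env[i + 1L] > low) i <- i + 1L
    off_i[j] <- i
  }
  t_on <- (on_i - 1L) / ch$rate
  t_off <- (off_i - 1L) / ch$rate
  # merge short gaps
  if (length(t_on) > 1L) {
    keep_on <- t_on[1]
    out_on <- numeric(0); out_off <- numeric(0)
    cur_off <- t_off[1]
    for (i in 2:length(t_on)) {
      if (t_on[i] - cur_off < merge_gap_s) {
        cur_off <- t_off[i]
      } else {
        out_on <- c(out_on, keep_on); out_off <- c(out_off, cur_off)
        keep_on <- t_on[i]; cur_off <- t_off[i]
      }
    }
    out_on <- c(out_on, keep_on); out_off <- c(out_off, cur_off)
    t_on <- out_on; t_off <- out_off
  }
  keep <- (t_off - t_on) >= min_dur_s
  data.frame(onset_s = t_on[keep], offset_s = t_off[keep])
}

#' EMG duty factor
#'
#' Burst duration as a percentage of the tailbeat cycle duration. Values
#' above 100 are allowed (bursts longer than one cycle) and should be flagged
#' by the caller.
#'
#' @param burst length-2 numeric `(onset_s, offset_s)`.
#' @param cycle length-2 numeric `(start, end)` of the cycle containing the
#'   burst onset.
#' @return percentage.
#' @export
duty_factor <- function(burst, cycle) {
  if (burst[2] <= burst[1]) stop_field("burst", "offset must exceed onset")
  dur <- cycle[2] - cycle[1]
  if (dur <= 0) stop_field("cycle", "duration must be > 0")
  100 * (burst[2] - burst[1]) / dur
}

#' Theoretical maximum EMG rate
#'
#' Mean of the top 5\% of rectified sample amplitudes pooled across all of a
#' fish's recordings on one electrode; the normalization constant for
#' [ria()].
#'
#' @param x numeric vector of (conditioned) signal amplitudes, or a list of
#'   such vectors / [emg_channel()]s pooled together.
#' @param top_frac pooled upper fraction (default 0.05).
#' @return amplitude in the units of `x`.
#' @export
theoretical_max_rate <- function(x, top_frac = 0.05) {
  if (is.list(x)) {
    x <- unlist(lapply(x, function(el) if (inherits(el, "emg_channel")) el$samples else el))
  }
  x <- abs(as.numeric(x))
  if (length(x) == 0L) stop("empty amplitude pool", call. = FALSE)
  if (length(x) < 20L) stop("need at least 20 samples to estimate the top-5% rate", call. = FALSE)
  n_top <- max(1L, round(top_frac * length(x)))
  mean(sort(x, decreasing = TRUE)[seq_len(n_top)])
}

#' Rectified integrated area of a burst
#'
#' Sum of rectified amplitudes within the burst as a percentage of the
#' theoretical maximum (top-5\% rate times burst duration). Durations enter
#' as sample counts on both sides so the time base cancels exactly.
#'
#' @param samples signal samples within `[onset, offset]`.
#' @param max_rate theoretical maximum rate from [theoretical_max_rate()].
#' @return percentage (>= 0, typically <= 100).
#' @export
ria <- function(samples, max_rate) {
  if (length(samples) == 0L) stop_field("samples", "burst is empty")
  if (!is.numeric(max_rate) || max_rate <= 0) stop_field("max_rate", "must be > 0")
  100 * sum(abs(samples)) / (max_rate * length(samples))
}

#' Burst onset/offset phase within the tailbeat cycle
#'
#' Each burst is assigned to the tail cycle containing its onset; onset and
#' offset are mapped to degrees with the tail-stroke convention (0 deg =
#' start of tail swing right, 180 deg = start of tail swing left). Bursts
#' whose onset falls outside every cycle are skipped with a message. An
#' offset phase smaller than the onset phase indicates wrapping into the
#' next cycle and is flagged.
#'
#' @param bursts data.frame with `onset_s`, `offset_s`.
#' @param tail_seg a tail [stroke_segmentation()].
#' @return data.frame `onset_s`, `offset_s`, `cycle`, `onset_deg`,
#'   `offset_deg`, `wrapped`.
#' @export
burst_phase <- function(bursts, tail_seg) {
  on <- cycle_phase(bursts$onset_s, tail_seg)
  out <- data.frame(onset_s = bursts$onset_s, offset_s = bursts$offset_s,
                    cycle = on$cycle, onset_deg = on$deg,
                    offset_deg = NA_real_, wrapped = NA)
  cyc <- tail_seg$cycles
  for (i in seq_len(nrow(out))) {
    k <- out$cycle[i]
    if (is.na(k)) next
    # express the offset in the onset's cycle, allowing it to exceed the end
    t <- bursts$offset_s[i]
    d <- if (t < cyc$mid[k]) {
      180 * (t - cyc$start[k]) / (cyc$mid[k] - cyc$start[k])
    } else {
      180 + 180 * (t - cyc$mid[k]) / (cyc$end[k] - cyc$mid[k])
    }
    out$offset_deg[i] <- wrap360(d)
    out$wrapped[i] <- d >= 360
  }
  n_skip <- sum(is.na(out$cycle))
  if (n_skip > 0L) {
    message(sprintf("burst_phase: %d burst(s) outside any tail cycle; skipped", n_skip))
  }
  out[!is.na(out$cycle), , drop = FALSE]
}

#' Contralateral co-activation count
#'
#' A left-side burst is counted co-active when its `[onset, offset]` interval
#' overlaps any right-side burst interval by more than `min_overlap_s`.
#'
#' @param left,right burst tables (`onset_s`, `offset_s`) at the same \%BL
#'   position on opposite sides.
#' @param min_overlap_s minimum overlap (s) to count, default 0 (any
#'   overlap).
#' @return list `n_coactive`, `n_total` (total left-side bursts).
#' @export
coactivation_count <- function(left, right, min_overlap_s = 0) {
  n_total <- nrow(left) %||% 0L
  if (is.null(n_total) || n_total == 0L || is.null(right) || nrow(right) == 0L) {
    return(list(n_coactive = 0L, n_total = as.integer(n_total %||% 0L)))
  }
  n_co <- 0L
  for (i in seq_len(nrow(left))) {
    ov <- pmin(left$offset_s[i], right$offset_s) - pmax(left$onset_s[i], right$onset_s)
    if (any(ov > min_overlap_s)) n_co <- n_co + 1L
  }
  list(n_coactive = n_co, n_total = as.integer(n_total))
}
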