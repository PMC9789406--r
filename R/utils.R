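# Internal numeric helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

# Evaluate fn() with a private RNG state so callers' streams are untouched.
with_seed <- function(seed, fn) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  fn()
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Signed circular difference a - b in (-180, 180].
circ_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

# Absolute circular distance in [0, 180].
circ_dist_deg <- function(a, b) abs(circ_diff_deg(a, b))

wrap360 <- function(x) x %% 360

# Zero-phase filtering with odd-reflection end padding, which removes the
# large edge transients signal::filtfilt otherwise produces on trending
# signals (the padding is exact for linear trends).
filtfilt_pad <- function(bf, x, n_pad = NULL) {
  n <- length(x)
  if (is.null(n_pad)) n_pad <- min(n - 1L, 3L * (length(bf$b) + length(bf$a)) * 10L)
  n_pad <- max(1L, min(n - 1L, n_pad))
  head_pad <- 2 * x[1] - x[(n_pad + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - n_pad)]
  y <- as.numeric(signal::filtfilt(bf, c(head_pad, x, tail_pad)))
  y[(n_pad + 1L):(n_pad + n)]
}

# Zero-phase Butterworth low-pass; cutoff clipped just below Nyquist.
lowpass <- function(x, rate, cutoff, order = 4) {
  if (is.null(cutoff) || !is.finite(cutoff)) return(x)
  nyq <- rate / 2
  if (cutoff >= nyq) return(x)
  bf <- signal::butter(order, cutoff / nyq, type = "low")
  n_pad <- min(length(x) - 1L, as.integer(ceiling(3 * rate / cutoff)))
  filtfilt_pad(bf, x, n_pad)
}

# Centered moving average (odd window), edges padded by replication.
movavg <- function(x, window) {
  window <- max(1L, as.integer(window))
  if (window %% 2L == 0L) window <- window + 1L
  if (window == 1L || length(x) < window) return(x)
  h <- (window - 1L) %/% 2L
  xp <- c(rep(x[1], h), x, rep(x[length(x)], h))
  as.numeric(zoo::rollmean(xp, window, align = "center"))
}

# Alternating local extrema of a (possibly pre-smoothed) signal.
# Small wiggles are pruned until every adjacent max/min pair differs by at
# least `min_prominence` in signal units. Returns a data.frame
# (index, type in {"max","min"}, value).
find_extrema <- function(x, smooth_window = 5L, min_prominence = NULL) {
  xs <- movavg(x, smooth_window)
  n <- length(xs)
  if (n < 3L) return(data.frame(index = integer(), type = character(), value = numeric()))
  if (is.null(min_prominence)) min_prominence <- 0.1 * diff(range(xs))
  d <- diff(xs)
  s <- sign(d)
  # carry last non-zero sign through plateaus
  nz <- s != 0
  if (!any(nz)) return(data.frame(index = integer(), type = character(), value = numeric()))
  carry <- cummax(seq_along(s) * nz)  # replace leading/embedded zeros
  carry[carry == 0L] <- which(nz)[1L]
  s <- s[carry]
  turns <- which(diff(s) != 0) + 1L
  if (length(turns) == 0L) return(data.frame(index = integer(), type = character(), value = numeric()))
  type <- ifelse(s[turns - 1L] > 0, "max", "min")
  idx <- turns
  val <- xs[idx]
  # enforce alternation: merge runs of same type keeping the most extreme
  keep <- rep(TRUE, length(idx))
  i <- 1L
  while (i < length(idx)) {
    j <- i + 1L
    if (keep[j] && type[j] == type[i]) {
      better_j <- (type[i] == "max" && val[j] > val[i]) ||
        (type[i] == "min" && val[j] < val[i])
      if (better_j) keep[i] <- FALSE else keep[j] <- FALSE
      idx <- idx[keep]; type <- type[keep]; val <- val[keep]
      keep <- rep(TRUE, length(idx))
      i <- max(1L, i - 1L)
    } else {
      i <- i + 1L
    }
  }
  # prune low-prominence adjacent pairs
  repeat {
    if (length(idx) < 2L) break
    gaps <- abs(diff(val))
    bad <- which(gaps < min_prominence)
    if (length(bad) == 0L) break
    b <- bad[which.min(gaps[bad])]
    sel <- setdiff(seq_along(idx), c(b, b + 1L))
    idx <- idx[sel]; type <- type[sel]; val <- val[sel]
    # re-merge same-type neighbours created by the removal
    i <- 1L
    while (i < length(idx)) {
      if (type[i + 1L] == type[i]) {
        better <- if (type[i] == "max") val[i + 1L] > val[i] else val[i + 1L] < val[i]
        drop_i <- if (better) i else i + 1L
        sel <- setdiff(seq_along(idx), drop_i)
        idx <- idx[sel]; type <- type[sel]; val <- val[sel]
      } else i <- i + 1L
    }
  }
  data.frame(index = idx, type = type, value = val, stringsAsFactors = FALSE)
}

# Refine an extremum by least-squares quadratic fit over a symmetric window
# around `index`; returns c(index = fractional index, value = vertex value).
# Unbiased for smooth peaks and, unlike a pointwise max over noisy samples,
# free of selection bias.
refine_extremum <- function(x, index, half_window) {
  n <- length(x)
  h <- max(2L, as.integer(round(half_window)))
  lo <- max(1L, index - h)
  hi <- min(n, index + h)
  if (hi - lo < 4L) return(c(index = as.numeric(index), value = x[index]))
  t <- (lo:hi) - index
  y <- x[lo:hi]
  fit <- stats::lm.fit(cbind(1, t, t^2), y)
  b <- fit$coefficients
  if (!is.finite(b[3]) || abs(b[3]) < .Machine$double.eps) {
    return(c(index = as.numeric(index), value = x[index]))
  }
  tv <- -b[2] / (2 * b[3])
  tv <- max(min(tv, h), -h)
  c(index = index + tv, value = b[1] + b[2] * tv + b[3] * tv^2)
}

# Path length of a polyline given as an n x d matrix.
path_length <- function(xy) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 2L) return(0)
  sum(sqrt(rowSums(diff(xy)^2)))
}
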