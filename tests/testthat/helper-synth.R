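# Shared fixtures, built once per test run.

with_seed_test <- function(seed, fn) {
  set.seed(seed)
  fn()
}

# memoized trials so several test files can reuse the same generated data
.trial_cache <- new.env(parent = emptyenv())

cached_trial <- function(key, spec) {
  if (is.null(.trial_cache[[key]])) .trial_cache[[key]] <- generate_trial(spec)
  .trial_cache[[key]]
}

clean_trial <- function() {
  cached_trial("clean", trial_spec(duration = 4, seed = 7, noise_sd = 0))
}

noisy_trial <- function() {
  cached_trial("noisy", trial_spec(duration = 4, seed = 7, noise_sd = 0.01))
}

# a straight, translating fish: collinear equally spaced points, nose first
straight_midlines <- function(n_frames = 20, bl = 100, speed_bl_s = 1,
                              frame_rate = 100) {
  xy <- array(0, dim = c(n_frames, 100, 2))
  s <- seq(0, bl, length.out = 100)
  for (i in seq_len(n_frames)) {
    xy[i, , 1] <- s + speed_bl_s * bl * (i - 1) / frame_rate
  }
  midline_sequence(xy, body_length = bl, frame_rate = frame_rate)
}

# one frame bent as an arc spanning `angle` radians (angle = pi: semicircle;
# angle = 2*pi: nose touches tail), other frames straight
arc_frame_midlines <- function(angle, bl = 100, n_frames = 3) {
  R <- bl / angle
  th <- seq(0, angle, length.out = 100)
  arcx <- R * sin(th)
  arcy <- R * (1 - cos(th))
  xy <- array(0, dim = c(n_frames, 100, 2))
  s <- seq(0, bl, length.out = 100)
  for (i in seq_len(n_frames)) xy[i, , 1] <- s + (i - 1)
  xy[2, , 1] <- arcx
  xy[2, , 2] <- arcy
  midline_sequence(xy, body_length = bl, frame_rate = 100, validate = FALSE)
}

# minimal landmark trajectory from per-frame named coordinate list
make_landmarks <- function(coords, bl = 100, frame_rate = 100) {
  nf <- nrow(coords[[1]])
  df <- do.call(rbind, lapply(names(coords), function(nm) {
    m <- coords[[nm]]
    data.frame(frame = seq_len(nf), time_s = (seq_len(nf) - 1) / frame_rate,
               landmark = nm, x = m[, 1], y = m[, 2],
               z = if (ncol(m) > 2) m[, 3] else 0)
  }))
  landmark_trajectory(df, body_length = bl, frame_rate = frame_rate)
}

# regular fin segmentation: adduction starts at t0, t0+T, ...; abductions
# at midpoints
regular_fin_seg <- function(t0, period, n_cycles) {
  adds <- t0 + period * (0:n_cycles)
  abds <- adds[-length(adds)] + period / 2
  ev <- data.frame(event_type = rep(c("adduction_start", "abduction_start"),
                                    n_cycles),
                   time_s = as.vector(rbind(adds[-length(adds)], abds)))
  ev <- rbind(ev, data.frame(event_type = "adduction_start",
                             time_s = adds[length(adds)]))
  stroke_segmentation("fin", ev)
}
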