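# Plain-text interchange: landmark/midline/EMG CSVs with sidecar metadata,
# ground truth as JSON, burst annotations as CSV.

#' Write one trial to a directory of plain-text files
#'
#' Writes `landmarks.csv` (frame, time_s, landmark, x, y, z), `midline.csv`
#' (frame, point_index 0-99, x, y), one `emg_<channel>.csv` per channel with
#' a YAML sidecar (side, percent_BL, muscle, rate, fish), `meta.yml`, and
#' the ground truth (when present) as `truth.json`.
#'
#' @param trial a `fish_trial`.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_trial <- function(trial, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(trial$landmarks),
                   file.path(dir, "landmarks.csv"), row.names = FALSE)
  ml <- trial$midlines
  nf <- dim(ml$xy)[1]; np <- dim(ml$xy)[2]
  mldf <- data.frame(frame = rep(seq_len(nf), each = np),
                     point_index = rep(seq_len(np) - 1L, nf),
                     x = as.vector(t(ml$xy[, , 1])),
                     y = as.vector(t(ml$xy[, , 2])))
  utils::write.csv(mldf, file.path(dir, "midline.csv"), row.names = FALSE)
  for (chn in names(trial$emg)) {
    ch <- trial$emg[[chn]]
    utils::write.csv(data.frame(value = ch$samples),
                     file.path(dir, paste0("emg_", chn, ".csv")),
                     row.names = FALSE)
    yaml::write_yaml(list(channel = chn, side = ch$side,
                          percent_BL = ch$position, muscle = ch$muscle,
                          rate = ch$rate, fish = ch$fish_id),
                     file.path(dir, paste0("emg_", chn, ".yml")))
  }
  yaml::write_yaml(list(body_length = ml$body_length,
                        frame_rate = ml$frame_rate,
                        trial_id = trial$trial_id %||% "trial1",
                        fish_id = trial$fish_id %||% "fish1",
                        body_depth = trial$spec$body_depth),
                   file.path(dir, "meta.yml"))
  if (!is.null(trial$truth)) {
    tr <- trial$truth
    tr$bursts <- if (!is.null(tr$bursts)) tr$bursts else NULL
    jsonlite::write_json(tr, file.path(dir, "truth.json"), auto_unbox = TRUE,
                         digits = NA, force = TRUE)
  }
  invisible(dir)
}

#' Read a landmark CSV
#'
#' @param path CSV with columns frame, time_s, landmark, x, y, z.
#' @param body_length,frame_rate trial metadata.
#' @return a [landmark_trajectory()].
#' @export
read_landmark_csv <- function(path, body_length, frame_rate) {
  landmark_trajectory(utils::read.csv(path), body_length, frame_rate)
}

#' Read a midline CSV
#'
#' @param path CSV with columns frame, point_index, x, y.
#' @param body_length,frame_rate trial metadata.
#' @param validate check equal arc-length spacing.
#' @return a [midline_sequence()].
#' @export
read_midline_csv <- function(path, body_length, frame_rate, validate = TRUE) {
  df <- utils::read.csv(path)
  frames <- sort(unique(df$frame))
  np <- length(unique(df$point_index))
  arr <- array(NA_real_, dim = c(length(frames), np, 2L))
  for (i in seq_along(frames)) {
    sub <- df[df$frame == frames[i], ]
    sub <- sub[order(sub$point_index), ]
    arr[i, , 1] <- sub$x
    arr[i, , 2] <- sub$y
  }
  midline_sequence(arr, body_length, frame_rate, validate = validate)
}

#' Read an EMG channel CSV plus its YAML sidecar
#'
#' @param path CSV with a `value` column.
#' @param sidecar YAML file with channel metadata; defaults to `path` with
#'   extension `.yml`.
#' @return an [emg_channel()].
#' @export
read_emg_csv <- function(path, sidecar = sub("\\.csv$", ".yml", path)) {
  meta <- yaml::read_yaml(sidecar)
  emg_channel(utils::read.csv(path)$value, rate = meta$rate,
              muscle = meta$muscle, side = meta$side,
              position = meta$percent_BL %||% NA_real_,
              fish_id = meta$fish %||% "fish1")
}

#' Read manually scored burst annotations
#'
#' @param path CSV with columns trial, channel, onset_s, offset_s.
#' @return data.frame.
#' @export
read_burst_annotations <- function(path) {
  df <- utils::read.csv(path)
  need <- c("trial", "channel", "onset_s", "offset_s")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_field("path", paste("missing columns:", paste(miss, collapse = ", ")))
  if (any(df$offset_s <= df$onset_s)) stop_field("path", "offsets must exceed onsets")
  df
}

#' Read a binary mask image (PNG) as a 0/1 matrix
#'
#' @param path PNG file; any non-zero channel value is foreground.
#' @return integer matrix.
#' @export
read_mask_png <- function(path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("reading PNG masks requires the 'png' package", call. = FALSE)
  }
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  (img > 0.5) * 1L
}
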