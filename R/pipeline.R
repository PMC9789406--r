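# Study-level orchestration: trials -> kinematic and EMG metric tables ->
# circular classification and group comparisons across water depths.

#' Study configuration
#'
#' @param depths water-depth treatments (BD fractions), unique.
#' @param trials_per_depth trials per depth.
#' @param base_spec base [trial_spec()] for the synthetic sweep.
#' @param threshold_depth depth at or below which fins switch out-of-phase.
#' @param alpha significance level for all circular tests.
#' @param n_mc Hermans-Rasson Monte-Carlo replicates.
#' @param n_boot von Mises bootstrap replicates.
#' @param sites body sites (fractions of BL) for amplitude timing and swing
#'   distance.
#' @param phase_positions axial electrode site ranks whose burst timing is
#'   reported (posterior sites, matching the body sites assessed).
#' @param coactivation_positions axial site ranks at which contralateral
#'   co-activation is counted.
#' @param min_cycles minimum complete tailbeat cycles for a trial to enter
#'   the analysis.
#' @param use_truth_bursts use the generator's burst annotations (emulating
#'   manual scoring) instead of automatic detection.
#' @param seed master seed; every random stage derives a sub-seed from it.
#' @return list of class `study_config`.
#' @export
study_config <- function(depths = c(3.0, 1.1, 1.0, 0.9, 0.7),
                         trials_per_depth = 4L, base_spec = trial_spec(),
                         threshold_depth = 0.8, alpha = 0.05, n_mc = 1999L,
                         n_boot = 199L, sites = c(0.4, 0.6, 0.8),
                         phase_positions = 3:5,
                         coactivation_positions = c(2L, 4L),
                         min_cycles = 5L, use_truth_bursts = TRUE,
                         seed = 42L) {
  if (anyDuplicated(depths)) stop_field("depths", "must be unique")
  if (alpha <= 0 || alpha >= 1) stop_field("alpha", "must lie in (0, 1)")
  structure(list(depths = depths, trials_per_depth = trials_per_depth,
                 base_spec = base_spec, threshold_depth = threshold_depth,
                 alpha = alpha, n_mc = n_mc, n_boot = n_boot, sites = sites,
                 phase_positions = phase_positions,
                 coactivation_positions = coactivation_positions,
                 min_cycles = min_cycles, use_truth_bursts = use_truth_bursts,
                 seed = as.integer(seed)),
            class = "study_config")
}

# Segment the tail stroke of one trial from the lateral displacement of the
# tail tip (last midline point).
trial_tail_segmentation <- function(trial, cutoff_hz = 6) {
  bf <- body_frame(trial$midlines)
  np <- dim(trial$midlines$xy)[2]
  segment_strokes(bf$lateral[, np], rate = trial$midlines$frame_rate,
                  kind = "tail", t0 = trial$midlines$time_s[1],
                  cutoff_hz = cutoff_hz)
}

trial_fin_segmentation <- function(trial, side, cutoff_hz = 4) {
  ang <- fin_angle(trial$landmarks, side)
  rate <- 1 / stats::median(diff(ang$time_s))
  segment_strokes(ang$angle_deg, rate = rate, kind = "fin",
                  t0 = ang$time_s[1], cutoff_hz = cutoff_hz)
}

#' Trial-level kinematic summary
#'
#' Computes the linear kinematic variables for one trial: locomotion speed,
#' curvature coefficient (mean of per-tail-cycle values), body-wave
#' frequency, pectoral fin frequency and range of motion (mean of left and
#' right), nose elevation, and swing distance at each site.
#'
#' @param trial a `fish_trial`.
#' @param sites body sites (fractions of BL).
#' @return one-row data.frame.
#' @export
trial_kinematics <- function(trial, sites = c(0.4, 0.6, 0.8)) {
  ml <- trial$midlines
  tail_seg <- trial_tail_segmentation(trial)
  segR <- trial_fin_segmentation(trial, "right")
  segL <- trial_fin_segmentation(trial, "left")

  cyc <- tail_seg$cycles
  cc <- vapply(seq_len(nrow(cyc)), function(k) {
    fr <- which(ml$time_s >= cyc$start[k] & ml$time_s <= cyc$end[k])
    curvature_coefficient(ml, fr)
  }, numeric(1))

  bf <- body_frame(ml)
  np <- dim(ml$xy)[2]
  idx60 <- round(0.6 * (np - 1L)) + 1L
  wf <- wave_frequency(bf$lateral[, idx60], ml$frame_rate)

  romR <- fin_rom(fin_angle(trial$landmarks, "right"), segR)
  romL <- fin_rom(fin_angle(trial$landmarks, "left"), segL)
  ne <- nose_elevation(trial$landmarks, segR)

  out <- data.frame(
    trial_id = trial$trial_id %||% "trial1",
    fish_id = trial$fish_id %||% "fish1",
    depth = trial$spec$body_depth,
    n_tail_cycles = nrow(cyc),
    speed_bls = locomotion_speed(trial$landmarks),
    curvature_coefficient = mean(cc),
    wave_frequency_hz = wf,
    fin_frequency_hz = fin_frequency(segR),
    fin_rom_deg = trial_fin_rom(romL, romR),
    nose_elevation_bl = ne$magnitude)
  for (s in sites) {
    out[[sprintf("swing_bl_s%d", round(s * 100))]] <- swing_distance(ml, s)
  }
  out
}

# Per-fish, per-channel theoretical maximum rates pooled across trials.
study_max_rates <- function(trials, conditioned) {
  keys <- unique(unlist(lapply(trials, function(tr) {
    paste(tr$fish_id %||% "fish1", names(tr$emg), sep = "|")
  })))
  rates <- stats::setNames(numeric(length(keys)), keys)
  for (key in keys) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    pool <- unlist(lapply(seq_along(trials), function(i) {
      tr <- trials[[i]]
      if ((tr$fish_id %||% "fish1") == parts[1] && parts[2] %in% names(tr$emg)) {
        conditioned[[i]][[parts[2]]]
      } else NULL
    }))
    rates[key] <- theoretical_max_rate(pool)
  }
  rates
}

#' Run the full synthetic depth-sweep study
#'
#' Generates a depth sweep, computes per-trial kinematic and burst metrics,
#' pools phase samples per depth, applies the circular classification
#' procedure, and performs the group comparisons (Watson-Williams on angular
#' means where defined, Kruskal-Wallis on nose-elevation angular dispersion)
#' with Bonferroni-corrected pairwise follow-ups. Every random stage derives
#' its sub-seed from `config$seed`, so two runs of the same configuration
#' are identical.
#'
#' @param config a [study_config()].
#' @return object of class `study_report`: list of tidy tables (`design`,
#'   `kinematics`, `fin_phase`, `fin_phase_class`, `amp_phase`,
#'   `amp_phase_class`, `emg_bursts`, `emg_phase_class`, `ria_summary`,
#'   `coactivation`, `watson_williams`, `dispersion`) plus a `log` recording
#'   every parameter and seed.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  if (length(config$depths) == 0L) stop_field("depths", "empty trial list")
  sweep <- generate_depth_sweep(config$base_spec, config$depths,
                                config$trials_per_depth,
                                threshold_depth = config$threshold_depth,
                                seed = config$seed)
  trials <- sweep$trials
  keep <- vapply(trials, function(tr) {
    nrow(trial_tail_segmentation(tr)$cycles) >= config$min_cycles
  }, logical(1))
  if (!any(keep)) stop("no trial has the required number of tailbeat cycles", call. = FALSE)
  trials <- trials[keep]
  design <- sweep$design[sweep$design$trial_id %in% names(trials), , drop = FALSE]

  # ---- kinematics --------------------------------------------------------
  kin <- do.call(rbind, lapply(trials, trial_kinematics, sites = config$sites))
  rownames(kin) <- NULL

  # ---- phase samples -----------------------------------------------------
  fin_phase <- do.call(rbind, lapply(trials, function(tr) {
    segR <- trial_fin_segmentation(tr, "right")
    segL <- trial_fin_segmentation(tr, "left")
    deg <- suppressMessages(left_fin_phase(segL, segR))
    if (length(deg) == 0L) return(NULL)
    data.frame(trial_id = tr$trial_id, depth = tr$spec$body_depth,
               cycle = seq_along(deg), deg = deg)
  }))
  amp_phase <- do.call(rbind, lapply(trials, function(tr) {
    tseg <- trial_tail_segmentation(tr)
    ap <- max_amplitude_phase(tr$midlines, tseg, sites = config$sites)
    if (nrow(ap) == 0L) return(NULL)
    ap$trial_id <- tr$trial_id
    ap$depth <- tr$spec$body_depth
    ap
  }))

  # ---- EMG ---------------------------------------------------------------
  conditioned <- lapply(trials, function(tr) {
    lapply(tr$emg, function(ch) condition_signal(ch)$samples)
  })
  max_rates <- study_max_rates(trials, conditioned)
  emg_bursts <- do.call(rbind, lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    tseg <- trial_tail_segmentation(tr)
    finR <- trial_fin_segmentation(tr, "right")
    rows <- list()
    for (chn in names(tr$emg)) {
      ch <- tr$emg[[chn]]
      bs <- if (config$use_truth_bursts) {
        b <- tr$truth$bursts
        b <- b[b$channel == chn, c("onset_s", "offset_s"), drop = FALSE]
        b
      } else {
        ch2 <- ch; ch2$samples <- conditioned[[i]][[chn]]
        detect_bursts(ch2)
      }
      if (is.null(bs) || nrow(bs) == 0L) next
      seg_for_cycle <- if (ch$muscle == "adductor") finR else tseg
      ph <- suppressMessages(burst_phase(bs, seg_for_cycle))
      if (nrow(ph) == 0L) next
      mr <- max_rates[paste(tr$fish_id %||% "fish1", chn, sep = "|")]
      sig <- conditioned[[i]][[chn]]
      rows[[chn]] <- do.call(rbind, lapply(seq_len(nrow(ph)), function(b) {
        cyc <- seg_for_cycle$cycles[ph$cycle[b], ]
        i0 <- max(1L, floor(ph$onset_s[b] * ch$rate) + 1L)
        i1 <- min(length(sig), ceiling(ph$offset_s[b] * ch$rate) + 1L)
        data.frame(trial_id = tr$trial_id, fish_id = tr$fish_id %||% "fish1",
                   depth = tr$spec$body_depth, channel = chn,
                   muscle = ch$muscle, side = ch$side, position = ch$position,
                   cycle = ph$cycle[b], onset_s = ph$onset_s[b],
                   offset_s = ph$offset_s[b],
                   duty_factor = duty_factor(c(ph$onset_s[b], ph$offset_s[b]),
                                             c(cyc$start, cyc$end)),
                   ria = ria(sig[i0:i1], mr),
                   onset_deg = ph$onset_deg[b], offset_deg = ph$offset_deg[b],
                   wrapped = ph$wrapped[b])
      }))
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  }))
  rownames(emg_bursts) <- NULL

  # ---- circular classifications -----------------------------------------
  hr_cache <- new.env(parent = emptyenv())
  hr_null_for <- function(n, seed) {
    key <- as.character(n)
    if (is.null(hr_cache[[key]])) {
      hr_cache[[key]] <- with_seed(seed, function() {
        vapply(seq_len(config$n_mc), function(i) hr_statistic(stats::runif(n, 0, 360)),
               numeric(1))
      })
    }
    hr_cache[[key]]
  }
  classify_by <- function(df, by_cols, seed_off) {
    if (is.null(df) || nrow(df) == 0L) return(NULL)
    key <- interaction(df[by_cols], drop = TRUE)
    res <- list()
    for (lev in levels(key)) {
      sub <- df[key == lev, , drop = FALSE]
      if (nrow(sub) < 5L) next
      sd1 <- (config$seed + seed_off + match(lev, levels(key))) %% 2147483647L
      cl <- classify_distribution(sub$deg, alpha = config$alpha,
                                  n_mc = config$n_mc, n_boot = config$n_boot,
                                  seed = sd1,
                                  hr_null = hr_null_for(nrow(sub), config$seed + seed_off))
      row <- sub[1, by_cols, drop = FALSE]
      row$n <- cl$n
      row$hr_p <- cl$hr_p
      row$vonmises_ok <- cl$vonmises_ok
      row$rayleigh_p <- cl$rayleigh_p
      row$classification <- cl$classification
      row$mean_deg <- cl$mean_deg
      row$ang_var <- cl$ang_var
      res[[lev]] <- row
    }
    if (length(res)) { out <- do.call(rbind, res); rownames(out) <- NULL; out } else NULL
  }
  fin_phase_class <- classify_by(fin_phase, "depth", 1000L)
  amp_phase_class <- classify_by(amp_phase, c("depth", "site", "side"), 2000L)
  emg_phase <- NULL
  if (!is.null(emg_bursts) && nrow(emg_bursts) > 0L) {
    ax <- emg_bursts[emg_bursts$muscle == "axial_red" & emg_bursts$side == "left", ]
    ranks <- config$base_spec$emg_sites
    ax$site_rank <- ranks$site_rank[match(ax$channel, ranks$channel)]
    ax <- ax[ax$site_rank %in% config$phase_positions, ]
    if (nrow(ax)) {
      emg_phase <- rbind(
        data.frame(ax[, c("depth", "site_rank")], event = "onset", deg = ax$onset_deg),
        data.frame(ax[, c("depth", "site_rank")], event = "offset", deg = ax$offset_deg))
    }
  }
  emg_phase_class <- classify_by(emg_phase, c("depth", "site_rank", "event"), 3000L)

  # ---- group comparisons -------------------------------------------------
  ww <- list()
  if (!is.null(amp_phase_class)) {
    combos <- unique(amp_phase_class[, c("site", "side")])
    for (r in seq_len(nrow(combos))) {
      cls <- amp_phase_class[amp_phase_class$site == combos$site[r] &
                               amp_phase_class$side == combos$side[r] &
                               amp_phase_class$classification == "nonuniform_unimodal", ]
      if (nrow(cls) < 2L) next
      grp <- lapply(cls$depth, function(d) {
        amp_phase$deg[amp_phase$depth == d & amp_phase$site == combos$site[r] &
                        amp_phase$side == combos$side[r]]
      })
      if (any(lengths(grp) < 5L)) next
      w <- suppressWarnings(watson_williams(grp))
      ww[[length(ww) + 1L]] <- data.frame(
        variable = "max_amplitude_phase", site = combos$site[r],
        side = combos$side[r], n_groups = length(grp), F = w$F, p = w$p)
    }
  }
  watson <- if (length(ww)) do.call(rbind, ww) else NULL

  dispersion <- NULL
  ne_phase <- do.call(rbind, lapply(trials, function(tr) {
    segR <- trial_fin_segmentation(tr, "right")
    ne <- nose_elevation(tr$landmarks, segR)
    pc <- ne$per_cycle[!is.na(ne$per_cycle$deg), ]
    if (nrow(pc) == 0L) return(NULL)
    data.frame(trial_id = tr$trial_id, depth = tr$spec$body_depth, deg = pc$deg)
  }))
  if (!is.null(ne_phase) && length(unique(ne_phase$depth)) >= 2L) {
    grp <- split(ne_phase$deg, ne_phase$depth)
    grp <- grp[lengths(grp) >= 5L]
    if (length(grp) >= 2L) dispersion <- dispersion_compare(grp)
  }

  # ---- co-activation -----------------------------------------------------
  coact <- NULL
  if (!is.null(emg_bursts) && nrow(emg_bursts) > 0L) {
    ranks <- config$base_spec$emg_sites
    rows <- list()
    for (d in sort(unique(emg_bursts$depth), decreasing = TRUE)) {
      for (pos in config$coactivation_positions) {
        chL <- ranks$channel[ranks$side == "left" & !is.na(ranks$site_rank) &
                               ranks$site_rank == pos]
        chR <- ranks$channel[ranks$side == "right" & !is.na(ranks$site_rank) &
                               ranks$site_rank == pos]
        if (!length(chL) || !length(chR)) next
        cc_tot <- c(0L, 0L)
        for (tid in unique(emg_bursts$trial_id[emg_bursts$depth == d])) {
          bl <- emg_bursts[emg_bursts$trial_id == tid & emg_bursts$channel == chL, ]
          br <- emg_bursts[emg_bursts$trial_id == tid & emg_bursts$channel == chR, ]
          cc <- coactivation_count(bl, br)
          cc_tot <- cc_tot + c(cc$n_coactive, cc$n_total)
        }
        rows[[length(rows) + 1L]] <- data.frame(depth = d, position = pos,
                                                n_coactive = cc_tot[1],
                                                n_total = cc_tot[2])
      }
    }
    if (length(rows)) coact <- do.call(rbind, rows)
  }

  ria_summary <- NULL
  if (!is.null(emg_bursts) && nrow(emg_bursts) > 0L) {
    agg <- stats::aggregate(cbind(ria, duty_factor) ~ depth + channel,
                            data = emg_bursts, FUN = mean)
    ria_summary <- agg[order(agg$channel, -agg$depth), ]
    rownames(ria_summary) <- NULL
  }

  structure(list(design = design, kinematics = kin, fin_phase = fin_phase,
                 fin_phase_class = fin_phase_class, amp_phase = amp_phase,
                 amp_phase_class = amp_phase_class, emg_bursts = emg_bursts,
                 emg_phase_class = emg_phase_class, ria_summary = ria_summary,
                 coactivation = coact, watson_williams = watson,
                 dispersion = dispersion,
                 log = list(config = config[setdiff(names(config), "base_spec")],
                            mapping = sweep$mapping,
                            n_trials = length(trials),
                            trials_excluded = names(keep)[!keep],
                            seed = config$seed)),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d trials, depths: %s\n", nrow(x$design),
              paste(sort(unique(x$design$depth), decreasing = TRUE), collapse = ", ")))
  if (!is.null(x$fin_phase_class)) {
    cat("left-fin phase classification by depth:\n")
    print(x$fin_phase_class[, c("depth", "n", "classification", "mean_deg")])
  }
  invisible(x)
}

#' Write all report tables as CSV
#'
#' @param report a `study_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(report)) {
    obj <- report[[nm]]
    if (is.data.frame(obj)) {
      p <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(obj, p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  if (!is.null(report$dispersion)) {
    p <- file.path(dir, "dispersion_pairwise.csv")
    utils::write.csv(report$dispersion$pairwise, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "run_log.json")
  jsonlite::write_json(report$log, p, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}
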