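#' Simulation configuration for the synthetic classroom-behavior dataset
#'
#' The simulator emulates the study design of a wearable-IMU classroom
#' behavior corpus: 13 participants x 5 trials, each trial one recording
#' of a 20-s calibration window followed by 14 motion blocks of 20 s at
#' 100 Hz (2000 samples each). Every dynamic motion consists of a
#' sitting-still baseline (channel rest levels plus low-amplitude noise)
#' with one contiguous class-templated burst at a participant-jittered
#' onset; class 1 is pure baseline and classes in `near_static` get
#' low-amplitude slow drifts comparable to the noise floor (a deliberate
#' stress case for segment extraction).
#'
#' @param n_participants number of participants (default 13).
#' @param n_trials trials per participant (default 5).
#' @param motion_classes motion classes per recording, in order
#'   (default 1:14; class 1 is sitting still).
#' @param sample_rate samples per second (default 100).
#' @param motion_sec seconds per motion block (default 20).
#' @param calib_sec leading calibration seconds (default 20).
#' @param burst_fraction named/numeric vector, fraction of the motion
#'   block that is valid motion per class; 0 for class 1.
#' @param noise_sd baseline noise standard deviation.
#' @param near_static classes with drift amplitude comparable to noise
#'   (default 2 and 3, emulating lying on the desktop / writing notes).
#' @param near_static_amp drift amplitude for those classes.
#' @param amp_jitter,freq_jitter lognormal sd of per-participant
#'   amplitude/frequency scaling.
#' @param onset_jitter sd of trial-level onset jitter, as a fraction of
#'   the motion length.
#' @param include_temp emit the (never analyzed) temperature channel.
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of the config.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_participants = 13, n_trials = 5,
                       motion_classes = 1:14, sample_rate = 100,
                       motion_sec = 20, calib_sec = 20,
                       burst_fraction = default_burst_fractions(),
                       noise_sd = 0.02, near_static = c(2L, 3L),
                       near_static_amp = 0.04, amp_jitter = 0.12,
                       freq_jitter = 0.02, onset_jitter = 0.02,
                       include_temp = TRUE, seed = 42) {
  cfg <- structure(
    list(n_participants = as.integer(n_participants),
         n_trials = as.integer(n_trials),
         motion_classes = as.integer(motion_classes),
         sample_rate = sample_rate, motion_sec = motion_sec,
         calib_sec = calib_sec, burst_fraction = burst_fraction,
         noise_sd = noise_sd, near_static = as.integer(near_static),
         near_static_amp = near_static_amp, amp_jitter = amp_jitter,
         freq_jitter = freq_jitter, onset_jitter = onset_jitter,
         include_temp = include_temp, seed = as.integer(seed)),
    class = "sim_config"
  )
  if (is.null(names(cfg$burst_fraction))) {
    names(cfg$burst_fraction) <- as.character(seq_along(cfg$burst_fraction))
  }
  dyn <- setdiff(cfg$motion_classes, 1L)
  bf <- cfg$burst_fraction[as.character(dyn)]
  if (any(is.na(bf)) || any(bf <= 0) || any(bf > 1)) {
    abort("burst_fraction must lie in (0, 1] for all non-sitting classes",
          class = "vbdtw_validation_error")
  }
  if (1L %in% cfg$motion_classes && cfg$burst_fraction["1"] != 0) {
    abort("class 1 (sitting still) must have burst_fraction 0",
          class = "vbdtw_validation_error")
  }
  cfg
}

#' Default per-class valid-motion fractions
#'
#' Class 1 is pure baseline; near-static classes 2 and 3 keep a nominal
#' burst interval (their drift is what a labeler would mark); dynamic
#' classes use class-specific fractions between 0.3 and 0.6 of the 20-s
#' block.
#'
#' @return named numeric vector of length 14.
#' @export
default_burst_fractions <- function() {
  c(`1` = 0, `2` = 0.5, `3` = 0.5, `4` = 0.35, `5` = 0.35, `6` = 0.45,
    `7` = 0.45, `8` = 0.5, `9` = 0.6, `10` = 0.4, `11` = 0.3,
    `12` = 0.35, `13` = 0.55, `14` = 0.5)
}

# Fixed per-class template parameters. Channel saliency is
# class-dependent; classes 4/5 share their accelerometer template and
# differ in the gyroscope, classes 6/7 the reverse, so combined channels
# carry strictly more information than either sensor alone.
#
# Min-max normalization erases amplitude scale and canonical-length
# resampling rescales time, so what a classifier observes per channel is
# the cycle count (f0 + chirp*dur/2) * dur over the kept duration, plus
# the waveform shape. The base frequencies below place those observed
# cycle counts on a geometric grid (ratio 1.25, so the spacing stays
# constant relative to the multiplicative jitter of the kept duration),
# and each class mixes in a group-specific harmonic signature (2nd/3rd
# harmonic amplitudes) as a waveform-shape cue, so that classes adjacent
# on the cycle grid always differ in shape as well. Harmonics are kept
# off high-cycle groups, whose harmonics would alias under canonical
# resampling. The chirp rate is shared so that template-sharing class
# pairs stay identical in the shared sensor group.
class_template_table <- function() {
  freq_acc <- c(NA, 0.25, 0.70, 0.871, 0.871, 3.767, 1.011, 0.880, 3.767,
                1.888, 3.883, 4.100, 4.864, 5.560)
  freq_ypr <- c(NA, 0.25, 0.70, 1.757, 4.100, 0.633, 0.633, 3.700, 1.192,
                0.575, 8.133, 8.671, 1.345, 3.200)
  h2_acc <- c(NA, 0, 0.35, 0.35, 0.35, 0, 0.3, 0, 0, 0.35, 0.3, 0.35, 0, 0)
  h3_acc <- c(NA, 0, 0, 0, 0, 0, 0.3, 0.35, 0, 0, 0.3, 0, 0, 0)
  h2_ypr <- c(NA, 0, 0.35, 0, 0.35, 0, 0, 0, 0.3, 0, 0, 0, 0, 0.35)
  h3_ypr <- c(NA, 0, 0, 0.35, 0, 0.35, 0.35, 0, 0.3, 0, 0, 0, 0.35, 0)
  # channel saliency patterns: which channels respond at all is itself a
  # class signature (a weak channel normalizes to noise-dominated
  # texture); weak channels stay well above the noise floor so that
  # per-channel segment extraction still sees the burst
  amp_acc <- rbind(
    NA, c(1, 1, 1), c(1, 0.3, 1),
    c(1.5, 0.2, 0.9), c(1.5, 0.2, 0.9),        # 4,5 share acc
    c(0.2, 1.2, 0.2), c(1.0, 1.4, 0.2),       # 6,7 differ in acc
    c(1.2, 0.8, 1.5), c(0.2, 0.2, 1.3), c(1.4, 0.2, 0.2),
    c(0.2, 1.1, 1.5), c(1.3, 0.9, 0.2), c(0.2, 1.5, 0.2),
    c(1.1, 0.2, 1.4)
  )
  amp_ypr <- rbind(
    NA, c(1, 1, 1), c(0.3, 1, 0.3),
    c(1.3, 0.2, 0.2), c(0.2, 1.5, 0.9),       # 4,5 differ in ypr
    c(1.0, 1.3, 0.2), c(1.0, 1.3, 0.2),        # 6,7 share ypr
    c(0.2, 0.2, 1.2), c(1.4, 0.2, 1.0), c(1.2, 1.0, 1.5),
    c(0.2, 1.3, 0.2), c(0.2, 0.2, 1.5), c(1.2, 0.2, 1.4),
    c(0.2, 1.1, 0.2)
  )
  # classes 8 and 9 sweep half as fast: their cycle budget is reached
  # from a higher starting frequency, keeping the burst onset clearly
  # non-stationary at slice scale
  chirp <- c(NA, 0, 0, 0.2, 0.2, 0.2, 0.2, 0.1, 0.1, 0.2, 0.2, 0.2,
             0.2, 0.2)
  list(freq_acc = freq_acc, freq_ypr = freq_ypr, amp_acc = amp_acc,
       amp_ypr = amp_ypr, chirp = chirp, h2_acc = h2_acc, h3_acc = h3_acc,
       h2_ypr = h2_ypr, h3_ypr = h3_ypr)
}

#' Class motion template
#'
#' The waveform recipe for one motion class: per-channel burst amplitudes,
#' sinusoid base frequencies (slightly detuned within each sensor triad),
#' a chirp rate that makes the burst non-stationary, transient spike
#' settings, and the valid-motion fraction. Templates are qualitative:
#' they reproduce burst-in-baseline structure, class-dependent channel
#' saliency and inter-participant variation, not real IMU physics.
#'
#' @param motion_class integer class 1..14.
#' @param cfg a [sim_config()].
#' @return object of class `motion_template`.
#' @export
motion_template <- function(motion_class, cfg = sim_config()) {
  k <- as.integer(motion_class)
  tab <- class_template_table()
  near_static <- k %in% cfg$near_static
  detune <- c(1, 1.13, 0.89)
  if (k == 1L) {
    amp <- rep(0, 6)
    freq <- rep(0, 6)
    chirp <- 0
    harm2 <- harm3 <- rep(0, 6)
  } else {
    base_amp <- if (near_static) cfg$near_static_amp else 1
    amp <- base_amp * c(tab$amp_acc[k, ], tab$amp_ypr[k, ])
    freq <- c(tab$freq_acc[k] * detune, tab$freq_ypr[k] * detune)
    chirp <- if (near_static) 0 else tab$chirp[k]
    harm2 <- c(rep(tab$h2_acc[k], 3), rep(tab$h2_ypr[k], 3))
    harm3 <- c(rep(tab$h3_acc[k], 3), rep(tab$h3_ypr[k], 3))
  }
  structure(
    list(motion_class = k, amp = amp, freq = freq, chirp = chirp,
         harm2 = harm2, harm3 = harm3,
         phase = rep(0, 6),
         n_spikes = if (k == 1L || near_static) 0L else 3L,
         spike_gain = 1.5, spike_width = 0.06,
         burst_fraction = unname(cfg$burst_fraction[as.character(k)]),
         onset_center = 0.5, near_static = near_static,
         amp_scale = rep(1, 6), freq_scale = 1),
    class = "motion_template"
  )
}

#' Perturb a template for one participant
#'
#' Applies seeded per-participant amplitude, frequency, phase, and onset
#' jitter while preserving class identity: at the default scales the
#' between-class template distance exceeds the within-class jitter by a
#' comfortable margin.
#'
#' @param template a [motion_template()].
#' @param participant_id participant index (integer) or id string ending
#'   in digits.
#' @param scales list with elements `amp`, `freq`, `onset` (sds; see
#'   [sim_config()]); all-zero scales return the template unchanged apart
#'   from the (then zero) jitter draws.
#' @param seed base seed the participant draw is derived from.
#' @return the perturbed `motion_template`.
#' @export
participant_variation <- function(template, participant_id,
                                  scales = list(amp = 0.12, freq = 0.02,
                                                onset = 0.02),
                                  seed = 42) {
  pid <- as.integer(gsub("\\D", "", as.character(participant_id)))
  sub_seed <- (seed + 7919L * pid + 131L * template$motion_class) %% .Machine$integer.max
  withr::with_seed(sub_seed, {
    template$amp_scale <- exp(rnorm(6, 0, scales$amp))
    template$freq_scale <- exp(rnorm(1, 0, scales$freq))
    template$phase <- runif(6, 0, 2 * pi) * (scales$amp > 0)
    template$onset_center <- 0.5 + rnorm(1, 0, 4 * scales$onset)
  })
  template$amp <- template$amp * template$amp_scale
  template$freq <- template$freq * template$freq_scale
  template
}

# One motion block: baseline + templated burst. Draws trial-level jitter
# from the current RNG stream; returns the block matrix and the burst
# sample interval (0-based, half-open; NA for class 1).
generate_motion_block <- function(template, cfg) {
  L <- round(cfg$motion_sec * cfg$sample_rate)
  rest <- c(0, 0, 1, 0, 0, 0)
  X <- matrix(rnorm(L * 6, 0, cfg$noise_sd), L, 6)
  X <- sweep(X, 2, rest, "+")
  colnames(X) <- sensor_channels()
  if (template$motion_class == 1L || template$burst_fraction <= 0) {
    return(list(data = X, burst = c(NA_integer_, NA_integer_)))
  }
  blen <- round(template$burst_fraction * L)
  margin <- round(0.05 * L)
  center <- template$onset_center +
    rnorm(1, 0, cfg$onset_jitter)  # trial-level jitter
  start <- round(center * L - blen / 2)
  lo <- min(margin, L - blen)
  hi <- max(lo, L - blen - margin)
  start <- max(lo, min(start, hi))
  tt <- (seq_len(blen) - 1) / cfg$sample_rate
  ramp <- max(2L, round(0.05 * blen))
  env <- pmin(1, pmin(seq_len(blen), rev(seq_len(blen))) / ramp)
  # slow amplitude modulation keeps adjacent slices dissimilar across the
  # whole burst, not just where the chirp has raised the frequency
  am <- 1 + 0.5 * sin(2 * pi * 0.9 * tt + template$phase[1])
  for (ch in 1:6) {
    f0 <- template$freq[ch]
    # harmonic phases track the (participant-shifted) fundamental so the
    # waveform shape is a stable class cue, shifted but not reshaped
    theta <- 2 * pi * (f0 + 0.5 * template$chirp * tt) * tt +
      template$phase[ch]
    h2 <- template$harm2[ch]
    h3 <- template$harm3[ch]
    wave <- (sin(theta) + h2 * sin(2 * theta + 1) +
               h3 * sin(3 * theta + 2)) / (1 + h2 + h3)
    X[(start + 1):(start + blen), ch] <-
      X[(start + 1):(start + blen), ch] + template$amp[ch] * env * am * wave
  }
  if (template$n_spikes > 0) {
    sw <- max(2L, round(template$spike_width * cfg$sample_rate))
    centers <- sort(round(runif(template$n_spikes, 0.1, 0.9) * blen))
    for (j in seq_along(centers)) {
      pos <- start + centers[j]
      win <- max(1, pos - sw):min(L, pos + sw)
      bump <- exp(-0.5 * ((win - pos) / (sw / 2))^2)
      sgn <- if (j %% 2 == 0) -1 else 1
      for (ch in 1:6) {
        X[win, ch] <- X[win, ch] +
          sgn * template$spike_gain * template$amp[ch] * bump
      }
    }
  }
  list(data = X, burst = c(start, start + blen))
}

#' Generate a synthetic multi-participant sensor dataset
#'
#' Emits `n_participants x n_trials` recordings, each a calibration
#' baseline followed by one block per motion class in order, with
#' ground-truth burst boundaries carried in the motion index (columns
#' `burst_start`, `burst_end`, relative to the block). Deterministic per
#' config seed.
#'
#' @param cfg a [sim_config()].
#' @return list of [sensor_recording()] objects.
#' @export
generate_dataset <- function(cfg = sim_config()) {
  L <- round(cfg$motion_sec * cfg$sample_rate)
  calib <- round(cfg$calib_sec * cfg$sample_rate)
  templates <- lapply(cfg$motion_classes, motion_template, cfg = cfg)
  names(templates) <- as.character(cfg$motion_classes)
  scales <- list(amp = cfg$amp_jitter, freq = cfg$freq_jitter,
                 onset = cfg$onset_jitter)
  recs <- list()
  withr::with_seed(cfg$seed, {
    for (p in seq_len(cfg$n_participants)) {
      ptempl <- lapply(templates, participant_variation,
                       participant_id = p, scales = scales,
                       seed = cfg$seed)
      for (tr in seq_len(cfg$n_trials)) {
        blocks <- vector("list", length(cfg$motion_classes))
        motions <- vector("list", length(cfg$motion_classes))
        calib_block <- matrix(rnorm(calib * 6, 0, cfg$noise_sd), calib, 6)
        calib_block <- sweep(calib_block, 2, c(0, 0, 1, 0, 0, 0), "+")
        colnames(calib_block) <- sensor_channels()
        for (i in seq_along(cfg$motion_classes)) {
          g <- generate_motion_block(ptempl[[i]], cfg)
          blocks[[i]] <- g$data
          start <- calib + (i - 1L) * L
          motions[[i]] <- tibble::tibble(
            class = cfg$motion_classes[i],
            start = start, end = start + L,
            burst_start = g$burst[1], burst_end = g$burst[2]
          )
        }
        data <- rbind(calib_block, do.call(rbind, blocks))
        d <- tibble::as_tibble(data)
        if (cfg$include_temp) {
          d$temp <- 30 + cumsum(rnorm(nrow(d), 0, 0.002))
        }
        recs[[length(recs) + 1]] <- sensor_recording(
          data = d,
          motions = dplyr::bind_rows(motions),
          participant_id = sprintf("P%02d", p),
          trial_id = sprintf("T%d", tr),
          sample_rate = cfg$sample_rate
        )
      }
    }
  })
  recs
}

#' Segment every motion of a list of recordings with VB-DTW
#'
#' Convenience harness: splits each recording into motions, runs the full
#' VB-DTW extraction on each, and returns the valid segments (optionally
#' skipping extraction and whole-resampling instead, the "without
#' extraction" ablation arm).
#'
#' @param recordings list of [sensor_recording()].
#' @param use_vbdtw if FALSE, resample each whole motion block to
#'   `target_len` without extraction.
#' @param slice_len,vote_radius,vote_count,mode,target_len extractor
#'   settings (see [vbdtw_segment_motion()]). Classification input uses
#'   joint multivariate extraction by default: the per-channel union can
#'   accumulate false-positive slices from individually noisy channels,
#'   diluting a segment with baseline, whereas the joint profile is
#'   dominated by the channels that actually move.
#' @return list of [valid_segment()] objects.
#' @export
segment_recordings <- function(recordings, use_vbdtw = TRUE, slice_len = 50,
                               vote_radius = 2, vote_count = 3,
                               mode = "dependent", target_len = 285) {
  out <- list()
  for (rec in recordings) {
    for (seq in split_motions(rec, slice_len = slice_len)) {
      seg <- if (use_vbdtw) {
        vbdtw_segment_motion(seq, slice_len, vote_radius, vote_count,
                             mode = mode, target_len = target_len)$segment
      } else {
        nrm <- suppressWarnings(normalize_minmax(seq))
        valid_segment(resample_uniform(nrm$data, target_len),
                      seq$motion_class, integer(0),
                      seq$participant_id, seq$trial_id)
      }
      out[[length(out) + 1]] <- seg
    }
  }
  out
}
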