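#' Configuration for the synthetic recording generator
#'
#' The generator emulates the statistical structure the downstream pipeline
#' assumes: a pulsatile PPG whose heart rate and pulse amplitude depend on the
#' condition (stressed beats are faster and weaker), slow baseline wander,
#' broadband sensor noise, and motion artifacts that enter the optical channels
#' as a per-axis weighted linear mixture of the accelerometer channels.
#'
#' @param fs Sampling rate in Hz.
#' @param duration_s Seconds of signal per condition per subject.
#' @param n_subjects Number of subjects in a generated dataset.
#' @param hr_nonstressed,hr_stressed Mean heart rates in beats per minute for
#'   the two conditions; `hr_stressed` must exceed `hr_nonstressed`.
#' @param amp_ratio_stressed Pulse-amplitude multiplier for the stressed
#'   condition relative to non-stressed, in (0, 1).
#' @param hrv_sd Standard deviation of the beat-to-beat interval jitter, in
#'   seconds.
#' @param dc_drift_amp Amplitude of the slow (< 0.1 Hz) sinusoidal baseline
#'   wander, in the same arbitrary units as the pulse (whose non-stressed
#'   amplitude is 1).
#' @param noise_sd Standard deviation of the white sensor noise added
#'   independently to each optical channel.
#' @param ma_gain Overall gain with which the weighted acceleration mixture is
#'   added to the PPG channels.
#' @param ma_axis_weights Length-3 vector of per-axis coupling weights
#'   (x, y, z).
#' @param seed Integer seed; identical configuration and seed give
#'   bit-identical output.
#'
#' @return An object of class `generator_config`.
#' @seealso [generate_recording()], [generate_dataset()]
#' @export
generator_config <- function(fs = 100,
                             duration_s = 180,
                             n_subjects = 14,
                             hr_nonstressed = 70,
                             hr_stressed = 95,
                             amp_ratio_stressed = 0.6,
                             hrv_sd = 0.05,
                             dc_drift_amp = 2,
                             noise_sd = 0.3,
                             ma_gain = 1.2,
                             ma_axis_weights = c(1, 0.5, 0.2),
                             seed = 1L) {
  assert_scalar_number(fs, "fs")
  assert_scalar_number(duration_s, "duration_s")
  assert_scalar_number(amp_ratio_stressed, "amp_ratio_stressed")
  if (fs <= 0) stop("`fs` must be positive", call. = FALSE)
  if (duration_s <= 0) stop("`duration_s` must be positive", call. = FALSE)
  if (n_subjects < 1) stop("`n_subjects` must be at least 1", call. = FALSE)
  if (amp_ratio_stressed <= 0 || amp_ratio_stressed >= 1) {
    stop("`amp_ratio_stressed` must lie in (0, 1)", call. = FALSE)
  }
  if (hr_stressed <= hr_nonstressed) {
    stop("`hr_stressed` must exceed `hr_nonstressed`", call. = FALSE)
  }
  if (hrv_sd < 0 || noise_sd < 0 || dc_drift_amp < 0 || ma_gain < 0) {
    stop("noise/jitter/drift/gain parameters must be non-negative",
         call. = FALSE)
  }
  if (length(ma_axis_weights) != 3L || !is.numeric(ma_axis_weights)) {
    stop("`ma_axis_weights` must be a numeric 3-vector", call. = FALSE)
  }
  structure(
    list(
      fs = fs, duration_s = duration_s, n_subjects = as.integer(n_subjects),
      hr_nonstressed = hr_nonstressed, hr_stressed = hr_stressed,
      amp_ratio_stressed = amp_ratio_stressed, hrv_sd = hrv_sd,
      dc_drift_amp = dc_drift_amp, noise_sd = noise_sd,
      ma_gain = ma_gain, ma_axis_weights = as.numeric(ma_axis_weights),
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat(sprintf("  %d subject(s), %g s per condition at %g Hz\n",
              x$n_subjects, x$duration_s, x$fs))
  cat(sprintf("  HR %g / %g bpm (non-stressed / stressed), amp ratio %g\n",
              x$hr_nonstressed, x$hr_stressed, x$amp_ratio_stressed))
  cat(sprintf("  hrv_sd %g s, drift %g, noise_sd %g, ma_gain %g, seed %d\n",
              x$hrv_sd, x$dc_drift_amp, x$noise_sd, x$ma_gain, x$seed))
  invisible(x)
}

condition_levels <- c("stressed", "non_stressed")

check_condition <- function(condition) {
  if (!is.character(condition) || length(condition) != 1L ||
      !(condition %in% condition_levels)) {
    stop_named(
      "earppg_invalid_condition",
      sprintf("`condition` must be one of: %s",
              paste(condition_levels, collapse = ", "))
    )
  }
  condition
}

# Two-lobe pulse template: a dominant systolic peak followed by a smaller
# dicrotic component, both scaled with the beat interval so that faster beats
# also have more closely spaced intra-beat peaks.  Evaluated on the sample
# grid over a local window around each beat.
add_pulse <- function(pulse, tt, onset, interval, amp) {
  t_sys <- onset + 0.30 * interval
  t_dic <- onset + 0.65 * interval
  w_sys <- 0.11 * interval
  w_dic <- 0.10 * interval
  fs <- 1 / (tt[2] - tt[1])
  i0 <- max(1L, floor((onset - 0.2) * fs) + 1L)
  i1 <- min(length(tt), ceiling((onset + interval + 0.3) * fs) + 1L)
  if (i0 > i1) return(pulse)
  tw <- tt[i0:i1]
  pulse[i0:i1] <- pulse[i0:i1] +
    amp * (exp(-0.5 * ((tw - t_sys) / w_sys)^2) +
             0.35 * exp(-0.5 * ((tw - t_dic) / w_dic)^2))
  pulse
}

# Shared bursty movement signal plus per-axis smoothed baseline noise.  All
# three axes see scaled copies of the same movement (a physical motion moves
# the whole head), which is exactly the regime in which a single-axis RLS
# reference can cancel most of the coupled artifact.
make_acceleration <- function(tt, duration_s) {
  T <- length(tt)
  n_bursts <- max(1L, round(duration_s / 25))
  mv <- numeric(T)
  for (b in seq_len(n_bursts)) {
    centre <- runif(1, 0, duration_s)
    width <- runif(1, 1.2, 2.5)       # Gaussian-envelope SD in seconds
    freq <- runif(1, 1, 3)            # within the pulse band on purpose
    phase <- runif(1, 0, 2 * pi)
    ampl <- runif(1, 2, 4)
    mv <- mv + ampl * exp(-0.5 * ((tt - centre) / width)^2) *
      sin(2 * pi * freq * tt + phase)
  }
  smooth25 <- function(x) {
    y <- as.numeric(stats::filter(x, rep(1 / 25, 25), sides = 2))
    y[is.na(y)] <- 0
    y
  }
  baseline <- function(scale) {
    b <- smooth25(rnorm(T))
    s <- sd(b)
    if (s > 0) b <- b / s
    scale * b
  }
  axis_mix <- c(1, 0.6, 0.3)
  gravity <- c(0.02, -0.01, 1)
  acc <- rbind(
    x = axis_mix[1] * mv + baseline(0.3) + gravity[1],
    y = axis_mix[2] * mv + baseline(0.3) + gravity[2],
    z = axis_mix[3] * mv + baseline(0.3) + gravity[3]
  )
  acc
}

#' Generate one synthetic recording
#'
#' Produces a raw recording for one subject under one condition: two PPG
#' channels (infrared and red) and a 3 x T acceleration matrix, all sampled at
#' `cfg$fs`.  The PPG is a sum of per-beat two-lobe pulse templates (beat
#' intervals `60/HR` with Gaussian jitter `hrv_sd`), a slow sinusoidal
#' baseline drift, white sensor noise, and `ma_gain` times the
#' `ma_axis_weights`-weighted acceleration mixture.  The red channel is a
#' scaled copy of the same pulsatile/artifact source with its own independent
#' noise, which is what justifies normalize-and-average fusion downstream.
#'
#' The RNG stream is derived deterministically from
#' `(cfg$seed, subject_id, condition)`, so recordings are reproducible and
#' distinct across subjects and conditions.
#'
#' @param cfg A [generator_config()].
#' @param subject_id Subject identifier string.
#' @param condition `"stressed"` or `"non_stressed"`.
#'
#' @return An object of class `raw_recording`: a list with `subject_id`,
#'   `condition`, `fs`, `ppg_ir`, `ppg_red` (length-T vectors) and `acc`
#'   (3 x T matrix with rows x, y, z).
#' @export
#' @examples
#' cfg <- generator_config(duration_s = 10, seed = 42)
#' rec <- generate_recording(cfg, "S01", "stressed")
#' str(rec$ppg_ir)
generate_recording <- function(cfg, subject_id, condition) {
  stopifnot(inherits(cfg, "generator_config"))
  check_condition(condition)
  seed <- derive_seed(cfg$seed, subject_id, condition)
  with_seed(seed, {
    T <- round(cfg$fs * cfg$duration_s)
    tt <- (seq_len(T) - 1) / cfg$fs
    hr <- if (condition == "stressed") cfg$hr_stressed else cfg$hr_nonstressed
    amp <- if (condition == "stressed") cfg$amp_ratio_stressed else 1
    mean_ibi <- 60 / hr

    n_beats <- ceiling((cfg$duration_s + 4 * mean_ibi) / mean_ibi) + 8L
    ibi <- mean_ibi + rnorm(n_beats, 0, cfg$hrv_sd)
    ibi <- pmin(pmax(ibi, 0.3), 2)
    onsets <- cumsum(c(-mean_ibi, ibi[-n_beats]))
    keep <- onsets < cfg$duration_s + mean_ibi
    onsets <- onsets[keep]
    ibi <- ibi[keep]

    pulse <- numeric(T)
    for (b in seq_along(onsets)) {
      pulse <- add_pulse(pulse, tt, onsets[b], ibi[b], amp)
    }

    drift_freq <- runif(1, 0.03, 0.08)
    drift_phase <- runif(1, 0, 2 * pi)
    drift <- cfg$dc_drift_amp * sin(2 * pi * drift_freq * tt + drift_phase)

    acc <- make_acceleration(tt, cfg$duration_s)
    ma <- cfg$ma_gain * as.numeric(cfg$ma_axis_weights %*% acc)

    source_sig <- 10 + pulse + drift + ma
    ppg_ir <- source_sig + rnorm(T, 0, cfg$noise_sd)
    ppg_red <- 0.6 * source_sig + rnorm(T, 0, cfg$noise_sd)

    structure(
      list(
        subject_id = subject_id,
        condition = condition,
        fs = cfg$fs,
        ppg_ir = ppg_ir,
        ppg_red = ppg_red,
        acc = acc
      ),
      class = "raw_recording"
    )
  })
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> subject %s, %s, %d samples at %g Hz\n",
              x$subject_id, x$condition, length(x$ppg_ir), x$fs))
  invisible(x)
}

#' Generate a full synthetic dataset
#'
#' One recording per condition per subject (`2 * n_subjects` recordings).
#' Subject ids are `"S01"`, `"S02"`, ...; per-recording RNG streams are
#' derived from `(cfg$seed, subject_id, condition)`, so the whole dataset is a
#' pure function of the configuration.
#'
#' @param cfg A [generator_config()] with `n_subjects >= 2`.
#' @return A list of [generate_recording()] results, ordered by subject and
#'   then condition (`non_stressed`, `stressed`).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  if (cfg$n_subjects < 2) {
    stop("`n_subjects` must be at least 2 for a dataset", call. = FALSE)
  }
  ids <- sprintf("S%02d", seq_len(cfg$n_subjects))
  recs <- list()
  for (id in ids) {
    for (cond in c("non_stressed", "stressed")) {
      recs[[length(recs) + 1L]] <- generate_recording(cfg, id, cond)
    }
  }
  recs
}

#' Write / read a recording as CSV plus JSON sidecar
#'
#' The CSV has one row per sample with header
#' `t,ppg_ir,ppg_red,acc_x,acc_y,acc_z` (`t` is the 0-based sample index
#' divided by `fs`); the JSON sidecar (same path with extension `.json`)
#' stores `subject_id`, `condition` and `fs`.
#'
#' @param rec A `raw_recording`.
#' @param path CSV output path; the sidecar is written next to it.
#' @return `path`, invisibly (writer); a `raw_recording` (reader).
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  T <- length(rec$ppg_ir)
  df <- data.frame(
    t = (seq_len(T) - 1) / rec$fs,
    ppg_ir = rec$ppg_ir,
    ppg_red = rec$ppg_red,
    acc_x = rec$acc["x", ],
    acc_y = rec$acc["y", ],
    acc_z = rec$acc["z", ]
  )
  write.csv(df, path, row.names = FALSE)
  meta <- list(subject_id = rec$subject_id, condition = rec$condition,
               fs = rec$fs)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

sidecar_path <- function(path) {
  paste0(sub("\\.csv$", "", path), ".json")
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  df <- read.csv(path)
  needed <- c("t", "ppg_ir", "ppg_red", "acc_x", "acc_y", "acc_z")
  if (!all(needed %in% names(df))) {
    stop("CSV is missing required columns: ",
         paste(setdiff(needed, names(df)), collapse = ", "), call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  structure(
    list(
      subject_id = meta$subject_id,
      condition = meta$condition,
      fs = meta$fs,
      ppg_ir = df$ppg_ir,
      ppg_red = df$ppg_red,
      acc = rbind(x = df$acc_x, y = df$acc_y, z = df$acc_z)
    ),
    class = "raw_recording"
  )
}
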