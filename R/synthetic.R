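#' Class profile for the synthetic tremor generator
#'
#' Describes the tremor phenotype of one diagnostic class. The oscillation
#' is pseudo-rhythmic: its instantaneous frequency performs a reflected
#' Gaussian random walk inside `tremor_band`, and a second harmonic at
#' twice the instantaneous frequency is added with relative amplitude
#' `harmonic_ratio`. Task-dependent amplitudes encode the clinical
#' phenomenology (rest-dominant tremor for PD, postural/kinetic for ET);
#' `axis_weights` project the common oscillator onto the three
#' accelerometer axes; `bilateral_prob` controls how often both hands are
#' recorded.
#'
#' @param tremor_band c(f_low, f_high) in Hz.
#' @param freq_jitter_sd random-walk scale of the instantaneous frequency,
#'   Hz per sqrt(second).
#' @param harmonic_ratio relative amplitude of the 2f component.
#' @param task_amplitude named numeric vector over the 6 included tasks,
#'   relative RMS amplitude per task.
#' @param axis_weights 3 non-negative projection weights (x, y, z).
#' @param bilateral_prob probability that both hands are recorded.
#' @param amplitude_cv between-patient coefficient of variation of the
#'   overall amplitude (log-normal).
#' @param asym_factor amplitude factor of the non-dominant hand in
#'   bilateral recordings (1 = symmetric).
#' @return a `class_profile` object.
#' @export
class_profile <- function(tremor_band, freq_jitter_sd = 0.3,
                          harmonic_ratio = 0.3,
                          task_amplitude = stats::setNames(rep(1, 6),
                                                           included_tasks()),
                          axis_weights = c(1, 0.7, 0.4),
                          bilateral_prob = 0.5, amplitude_cv = 0.3,
                          asym_factor = 1) {
  stopifnot(length(tremor_band) == 2L, tremor_band[1] < tremor_band[2],
            tremor_band[1] > 0)
  task_amplitude <- task_amplitude[included_tasks()]
  if (anyNA(task_amplitude) || any(task_amplitude < 0)) {
    stop("task_amplitude must cover the 6 included tasks with values >= 0")
  }
  stopifnot(length(axis_weights) == 3L, all(axis_weights >= 0),
            bilateral_prob >= 0, bilateral_prob <= 1,
            freq_jitter_sd >= 0, harmonic_ratio >= 0, amplitude_cv >= 0,
            asym_factor >= 0, asym_factor <= 1)
  structure(list(tremor_band = as.numeric(tremor_band),
                 freq_jitter_sd = freq_jitter_sd,
                 harmonic_ratio = harmonic_ratio,
                 task_amplitude = task_amplitude,
                 axis_weights = as.numeric(axis_weights),
                 bilateral_prob = bilateral_prob,
                 amplitude_cv = amplitude_cv,
                 asym_factor = asym_factor),
            class = "class_profile")
}

#' Default class profiles
#'
#' `paper_like` follows the clinical phenomenology: PD tremor in 4-6 Hz,
#' rest-dominant, mostly unilateral (bilateral probability 0.3); ET tremor
#' in 4-8 Hz, posture/load-dominant with a weaker rest component (rest
#' tremor does occur in a sizeable minority of ET patients), always
#' bilateral. `easy` uses disjoint bands (4-5.5 vs 6.5-8 Hz) and a stronger
#' task contrast so that the classes are separable by construction --
#' the configuration the acceptance tests rely on.
#'
#' @param separation "paper_like" or "easy".
#' @return list with elements `PD` and `ET`, both [class_profile()]s.
#' @export
default_profiles <- function(separation = c("paper_like", "easy")) {
  separation <- match.arg(separation)
  amp <- function(r1, r2, p1, p2, l1, l2) {
    stats::setNames(c(r1, r2, p1, p2, l1, l2), included_tasks())
  }
  if (separation == "paper_like") {
    list(
      PD = class_profile(tremor_band = c(4, 6), freq_jitter_sd = 0.3,
                         harmonic_ratio = 0.35,
                         task_amplitude = amp(1, 0.9, 0.4, 0.4, 0.5, 0.5),
                         axis_weights = c(1, 0.7, 0.4),
                         bilateral_prob = 0.3, amplitude_cv = 0.4,
                         asym_factor = 0.35),
      ET = class_profile(tremor_band = c(4, 8), freq_jitter_sd = 0.4,
                         harmonic_ratio = 0.2,
                         task_amplitude = amp(0.35, 0.35, 1, 0.95, 0.9, 0.9),
                         axis_weights = c(1, 0.8, 0.5),
                         bilateral_prob = 1, amplitude_cv = 0.4,
                         asym_factor = 1))
  } else {
    list(
      PD = class_profile(tremor_band = c(4, 5.5), freq_jitter_sd = 0.15,
                         harmonic_ratio = 0.3,
                         task_amplitude = amp(1, 1, 0.15, 0.15, 0.2, 0.2),
                         axis_weights = c(1, 0.7, 0.4),
                         bilateral_prob = 0.3, amplitude_cv = 0.2,
                         asym_factor = 0.5),
      ET = class_profile(tremor_band = c(6.5, 8), freq_jitter_sd = 0.15,
                         harmonic_ratio = 0.2,
                         task_amplitude = amp(0.15, 0.15, 1, 1, 0.9, 0.9),
                         axis_weights = c(1, 0.8, 0.5),
                         bilateral_prob = 1, amplitude_cv = 0.2,
                         asym_factor = 1))
  }
}

#' Synthetic cohort specification
#'
#' @param n_pd,n_et patient counts per class.
#' @param visits 1 or 2 visits per patient.
#' @param raw_fs raw sampling rate in Hz (clinically 1500).
#' @param duration_s recording duration per signal (20 s).
#' @param snr_db tremor-to-noise ratio in dB, relative to the patient's
#'   base amplitude.
#' @param drift_amp relative amplitude of the < 0.5 Hz postural drift.
#' @param seed RNG seed; a fixed seed gives byte-identical cohorts.
#' @param profiles list with `PD` and `ET` [class_profile()]s.
#' @param include_action_task also emit the excluded finger-to-nose task.
#' @return a `cohort_spec` object.
#' @export
cohort_spec <- function(n_pd, n_et, visits = 1L, raw_fs = 1500,
                        duration_s = 20, snr_db = 20, drift_amp = 0.1,
                        seed = 1L,
                        profiles = default_profiles("paper_like"),
                        include_action_task = FALSE) {
  stopifnot(n_pd >= 0, n_et >= 0, visits %in% c(1L, 2L), raw_fs > 0,
            duration_s > 0, inherits(profiles$PD, "class_profile"),
            inherits(profiles$ET, "class_profile"))
  structure(list(n_pd = as.integer(n_pd), n_et = as.integer(n_et),
                 visits = as.integer(visits), raw_fs = raw_fs,
                 duration_s = duration_s, snr_db = snr_db,
                 drift_amp = drift_amp, seed = as.integer(seed),
                 profiles = profiles,
                 include_action_task = isTRUE(include_action_task)),
            class = "cohort_spec")
}

# Fold a vector into [lo, hi] by reflection (triangle map).
reflect_into <- function(x, lo, hi) {
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  lo + ifelse(y > w, 2 * w - y, y)
}

#' Simulate one tremor signal
#'
#' samples = A * (sin(phi) + harmonic_ratio * sin(2 phi)) + drift + noise,
#' with d(phi)/dt = 2*pi*f(t) and f(t) a Gaussian random walk reflected at
#' the profile's band edges. A combines the task amplitude, the patient's
#' amplitude scale and the hand factor. Noise is white Gaussian with a
#' standard deviation set by `snr_db` relative to the patient's base
#' amplitude (RMS of a unit sinusoid), so a zero-amplitude task still
#' carries noise and drift. Draws from the current R RNG stream.
#'
#' @param profile a [class_profile()].
#' @param task included task name (or "FingerToNose" when explicitly
#'   simulating the excluded task).
#' @param effects patient effects: list(base_freq, amp_scale, hand_factor).
#' @param fs sampling rate in Hz.
#' @param duration_s duration in seconds.
#' @param snr_db tremor-to-noise ratio in dB.
#' @param drift_amp relative postural drift amplitude.
#' @return list(tremor, drift, noise_sd) where `tremor` is the noiseless
#'   oscillation (shared across axes) -- used internally by
#'   [simulate_cohort()]; the per-axis signal is
#'   `w_axis * tremor + drift_axis + noise_axis`.
#' @export
simulate_signal <- function(profile, task, effects, fs = 1500,
                            duration_s = 20, snr_db = 20, drift_amp = 0.1) {
  n <- round(duration_s * fs)
  dt <- 1 / fs
  task <- canonical_task(task)
  amp_task <- if (task == "FingerToNose") 1 else profile$task_amplitude[[task]]
  a <- amp_task * effects$amp_scale * effects$hand_factor
  if (a > 0) {
    steps <- stats::rnorm(n, 0, profile$freq_jitter_sd * sqrt(dt))
    f <- reflect_into(effects$base_freq + cumsum(steps),
                      profile$tremor_band[1], profile$tremor_band[2])
    phi <- 2 * pi * cumsum(f) * dt
    tremor <- a * (sin(phi) + profile$harmonic_ratio * sin(2 * phi))
  } else {
    tremor <- numeric(n)
  }
  noise_sd <- (effects$amp_scale / sqrt(2)) * 10^(-snr_db / 20)
  list(tremor = tremor, n = n,
       drift_scale = drift_amp * effects$amp_scale, noise_sd = noise_sd)
}

# Per-axis additive components: slow (< 0.5 Hz) sinusoidal drift plus
# white Gaussian noise.
axis_nuisance <- function(n, fs, drift_scale, noise_sd) {
  t <- (seq_len(n) - 1L) / fs
  f_d <- stats::runif(1, 0.05, 0.4)
  ph <- stats::runif(1, 0, 2 * pi)
  drift_scale * sin(2 * pi * f_d * t + ph) + stats::rnorm(n, 0, noise_sd)
}

# Seeded draw of the patient table: ids, groups, recorded hands and
# per-patient random effects. Shared by simulate_cohort() and
# plan_cohort() so both enumerate the identical cohort.
draw_patients <- function(spec) {
  set.seed(spec$seed)
  groups <- c(rep("PD", spec$n_pd), rep("ET", spec$n_et))
  ids <- c(sprintf("PD%03d", seq_len(spec$n_pd)),
           sprintf("ET%03d", seq_len(spec$n_et)))
  patients <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    prof <- spec$profiles[[groups[i]]]
    band <- prof$tremor_band
    base_freq <- stats::runif(1, band[1] + 0.1 * diff(band),
                              band[2] - 0.1 * diff(band))
    sdlog <- sqrt(log(1 + prof$amplitude_cv^2))
    amp_scale <- stats::rlnorm(1, -sdlog^2 / 2, sdlog)
    bilateral <- stats::runif(1) < prof$bilateral_prob
    dominant <- sample(hand_levels(), 1L)
    hands <- if (bilateral) hand_levels() else dominant
    patients[[i]] <- list(patient_id = ids[i], group = groups[i],
                          base_freq = base_freq, amp_scale = amp_scale,
                          dominant = dominant, hands = hands)
  }
  patients
}

cohort_tasks <- function(spec) {
  if (spec$include_action_task) task_levels() else included_tasks()
}

#' Enumerate a synthetic cohort without generating samples
#'
#' Returns the manifest rows that [simulate_cohort()] would produce for
#' `spec` (same seed, same patients, hands and visits) with `file_path`
#' left `NA`. Useful for cohort bookkeeping at scales where generating the
#' waveforms would be wasteful.
#'
#' @param spec a [cohort_spec()].
#' @return data frame with the manifest columns plus `excluded`.
#' @export
plan_cohort <- function(spec) {
  patients <- draw_patients(spec)
  tasks <- cohort_tasks(spec)
  rows <- list()
  for (p in patients) {
    for (visit in seq_len(spec$visits)) {
      for (hand in p$hands) {
        for (task in tasks) {
          for (trial in 1:3) {
            for (axis in axis_levels()) {
              rows[[length(rows) + 1L]] <- data.frame(
                patient_id = p$patient_id, group = p$group, visit = visit,
                hand = hand, task = task, trial = trial, axis = axis,
                fs = spec$raw_fs, file_path = NA_character_)
            }
          }
        }
      }
    }
  }
  df <- do.call(rbind, rows)
  df$excluded <- task_excluded(df$task)
  df
}

#' Simulate a synthetic tremor cohort
#'
#' Draws per-patient effects (base frequency inside the class band,
#' log-normal amplitude scale, laterality), then emits all included tasks x
#' 3 trials x 3 axes for every recorded hand and visit. Within one
#' (task, trial) the three axes share the oscillator and differ by the
#' profile's axis weights plus independent drift and noise. Second-visit
#' recordings redraw the waveforms from mildly perturbed patient effects.
#' With `out_dir` given, signal files (one sample per line) and a
#' `manifest.csv` are written; otherwise the cohort stays in memory.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir optional output directory.
#' @return a [tremor_cohort()]; when `out_dir` is given its manifest
#'   points at the written files.
#' @export
simulate_cohort <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  patients <- draw_patients(spec)
  tasks <- cohort_tasks(spec)
  rows <- list()
  signals <- list()
  for (p in patients) {
    prof <- spec$profiles[[p$group]]
    for (visit in seq_len(spec$visits)) {
      base_freq <- p$base_freq
      amp_scale <- p$amp_scale
      if (visit > 1L) {
        base_freq <- reflect_into(base_freq + stats::rnorm(1, 0, 0.15),
                                  prof$tremor_band[1], prof$tremor_band[2])
        amp_scale <- amp_scale * stats::rlnorm(1, 0, 0.1)
      }
      for (hand in p$hands) {
        hand_factor <- if (hand == p$dominant) 1 else prof$asym_factor
        effects <- list(base_freq = base_freq, amp_scale = amp_scale,
                        hand_factor = hand_factor)
        for (task in tasks) {
          for (trial in 1:3) {
            comp <- simulate_signal(prof, task, effects, fs = spec$raw_fs,
                                    duration_s = spec$duration_s,
                                    snr_db = spec$snr_db,
                                    drift_amp = spec$drift_amp)
            for (ai in seq_along(axis_levels())) {
              axis <- axis_levels()[ai]
              x <- prof$axis_weights[ai] * comp$tremor +
                axis_nuisance(comp$n, spec$raw_fs, comp$drift_scale,
                              comp$noise_sd)
              key <- signal_key(p$patient_id, visit, hand, task, trial, axis)
              signals[[key]] <- x
              rows[[length(rows) + 1L]] <- data.frame(
                patient_id = p$patient_id, group = p$group, visit = visit,
                hand = hand, task = task, trial = trial, axis = axis,
                fs = spec$raw_fs, file_path = NA_character_)
            }
          }
        }
      }
    }
  }
  manifest <- do.call(rbind, rows)
  manifest$excluded <- task_excluded(manifest$task)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nrow(manifest))) {
      e <- manifest[i, ]
      fname <- sprintf("%s_v%d_%s_%s_t%d_%s.txt", e$patient_id, e$visit,
                       e$hand, e$task, e$trial, e$axis)
      path <- file.path(out_dir, fname)
      key <- signal_key(e$patient_id, e$visit, e$hand, e$task, e$trial,
                        e$axis)
      write_signal_file(signals[[key]], path)
      manifest$file_path[i] <- path
    }
    write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  }
  tremor_cohort(manifest, signals)
}

#' Total recording time of a cohort
#'
#' Bookkeeping helper: hours of raw recordings for `n_assessments`
#' assessments of `n_tasks` tasks x `n_trials` trials x `n_channels`
#' channels, `duration_s` seconds each. The clinical protocol (250
#' assessments, 7 tasks, 3 trials, 3 channels, 20 s) totals 87.5 h.
#'
#' @param n_assessments number of tremor assessments.
#' @param n_tasks,n_trials,n_channels,duration_s protocol shape.
#' @return hours of recording.
#' @export
cohort_recording_hours <- function(n_assessments, n_tasks = 7,
                                   n_trials = 3, n_channels = 3,
                                   duration_s = 20) {
  n_assessments * n_tasks * n_trials * n_channels * duration_s / 3600
}
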