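#' Motion-model parameters for one simulated recording
#'
#' Bundles every knob of the wrist-motion signal model for a single
#' subject x task recording: an optional voluntary-movement sinusoid with
#' exponential within-trial amplitude decay (the bradykinesia "sequence
#' effect"), an optional narrowband tremor sinusoid projected on the three
#' sensor axes through a random unit direction vector, broadband Gaussian
#' noise, random-walk baseline drift, and sparse outlier spikes.
#'
#' Accelerometer and gyroscope channels live on different physical scales
#' (G vs degrees per second), so every amplitude-like field comes as a
#' `_g` / `_dps` pair.
#'
#' @param class_label One of `"healthy"`, `"tremor"`, `"bradykinesia"`.
#' @param task One of `r paste0('"', TASKS, '"', collapse = ", ")`.
#' @param tremor_freq_hz Tremor frequency (Hz). Pathological rest tremor
#'   sits at 4-6 Hz, postural at 4-12 Hz, kinetic at 2-7 Hz.
#' @param tremor_amp_g,tremor_amp_dps Tremor amplitude on the accelerometer
#'   (G) and gyroscope (dps) triads; the per-channel amplitude is this value
#'   scaled by the random unit direction vector.
#' @param voluntary_freq_hz Voluntary movement rate (Hz), e.g. the finger-tap
#'   rate.
#' @param voluntary_amp_g,voluntary_amp_dps Voluntary-movement amplitude per
#'   sensor.
#' @param amp_decay_rate Per-second fractional decline of the voluntary
#'   amplitude (`exp(-rate * t)`); positive only for bradykinesia.
#' @param noise_sd_g,noise_sd_dps Gaussian sensor-noise SD per sample.
#' @param drift_sd_g,drift_sd_dps Random-walk drift step SD per sample.
#' @param outlier_rate Expected outlier spikes per second (Poisson).
#' @param outlier_magnitude Spike magnitude in multiples of the channel SD.
#' @param am_depth Depth of the slow (0.1-0.5 Hz) amplitude modulation of
#'   the deterministic components, in [0, 1]: neither tapping nor tremor
#'   holds a perfectly constant amplitude, it waxes and wanes.
#' @return An object of class `pd_motion_params` (a validated list).
#' @examples
#' motion_params("tremor", "rest", tremor_freq_hz = 5,
#'               tremor_amp_g = 0.3, tremor_amp_dps = 40)
#' @export
motion_params <- function(class_label, task,
                          tremor_freq_hz = 0, tremor_amp_g = 0,
                          tremor_amp_dps = 0,
                          voluntary_freq_hz = 0, voluntary_amp_g = 0,
                          voluntary_amp_dps = 0, amp_decay_rate = 0,
                          noise_sd_g = 0.02, noise_sd_dps = 1.5,
                          drift_sd_g = 0.002, drift_sd_dps = 0.1,
                          outlier_rate = 0.05, outlier_magnitude = 8,
                          am_depth = 0.4) {
  class_label <- match.arg(class_label, CLASS_LEVELS)
  task <- match.arg(task, TASKS)
  p <- list(class_label = class_label, task = task,
            tremor_freq_hz = tremor_freq_hz, tremor_amp_g = tremor_amp_g,
            tremor_amp_dps = tremor_amp_dps,
            voluntary_freq_hz = voluntary_freq_hz,
            voluntary_amp_g = voluntary_amp_g,
            voluntary_amp_dps = voluntary_amp_dps,
            amp_decay_rate = amp_decay_rate,
            noise_sd_g = noise_sd_g, noise_sd_dps = noise_sd_dps,
            drift_sd_g = drift_sd_g, drift_sd_dps = drift_sd_dps,
            outlier_rate = outlier_rate, outlier_magnitude = outlier_magnitude,
            am_depth = am_depth)
  nonneg <- c("tremor_freq_hz", "tremor_amp_g", "tremor_amp_dps",
              "voluntary_freq_hz", "voluntary_amp_g", "voluntary_amp_dps",
              "amp_decay_rate", "noise_sd_g", "noise_sd_dps", "drift_sd_g",
              "drift_sd_dps", "outlier_rate", "outlier_magnitude", "am_depth")
  for (f in nonneg) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0)
      abort_invalid(sprintf("`%s` must be a single non-negative number.", f))
  }
  if (am_depth > 1) abort_invalid("`am_depth` must be in [0, 1].")
  if (class_label == "healthy" &&
      (tremor_amp_g > 0 || tremor_amp_dps > 0 || amp_decay_rate > 0))
    abort_invalid("healthy-class parameters must have zero tremor amplitude and zero amplitude decay.")
  if (class_label == "bradykinesia" && (tremor_amp_g > 0 || tremor_amp_dps > 0))
    abort_invalid("bradykinesia-class parameters must have zero tremor amplitude (no tremor sign).")
  if (class_label == "tremor" && (tremor_amp_g > 0 || tremor_amp_dps > 0)) {
    band <- tremor_band(task)
    if (tremor_freq_hz < band[1] || tremor_freq_hz > band[2])
      abort_invalid(sprintf(
        "tremor_freq_hz = %g outside the %s-task band %g-%g Hz.",
        tremor_freq_hz, task, band[1], band[2]))
  }
  structure(p, class = "pd_motion_params")
}

# Clinically expected tremor band per assessment task; tasks outside the
# three dedicated tremor tests inherit the rest-tremor band.
tremor_band <- function(task) {
  switch(task,
         rest = c(4, 6),
         postural = c(4, 12),
         kinetic = c(2, 7),
         c(4, 6))
}

#' Simulate one 6-axis wrist recording
#'
#' Synthesizes a six-channel inertial time series (3-axis accelerometer in
#' G, 3-axis gyroscope in dps) under a [motion_params()] signal model. Each
#' channel is the sum of a voluntary sinusoid (per-channel random phase,
#' exponentially decaying amplitude), a tremor sinusoid (per-sensor random
#' unit direction vector and common phase), white Gaussian noise, cumulative
#' random-walk drift, and Poisson-distributed outlier spikes scaled to the
#' channel SD. Both deterministic components share a slow random
#' amplitude modulation (`am_depth`) emulating the natural waxing and
#' waning of movement amplitude. Fully deterministic under a fixed
#' `seed`.
#'
#' @param params A [motion_params()] object.
#' @param fs Sampling rate (Hz); must exceed twice every model frequency.
#' @param duration Recording length (s).
#' @param seed Integer seed; identical seeds give bit-identical recordings.
#' @param subject_id Identifier stored on the recording.
#' @return A `pd_recording`: a tibble with columns `t, ax, ay, az, gx, gy,
#'   gz` and attributes `subject_id`, `class_label`, `task`,
#'   `sampling_rate_hz`.
#' @examples
#' rec <- simulate_recording(
#'   motion_params("tremor", "rest", tremor_freq_hz = 5,
#'                 tremor_amp_g = 0.3, tremor_amp_dps = 40),
#'   fs = 100, duration = 10, seed = 1)
#' @export
simulate_recording <- function(params, fs = 100, duration = 60, seed = 1,
                               subject_id = "S1") {
  if (!inherits(params, "pd_motion_params"))
    abort_invalid("`params` must be a `pd_motion_params` object.")
  if (!is.numeric(fs) || fs <= 0) abort_invalid("`fs` must be positive.")
  if (!is.numeric(duration) || duration <= 0)
    abort_invalid("`duration` must be positive.")
  for (f in c("tremor_freq_hz", "voluntary_freq_hz")) {
    if (params[[f]] >= fs / 2)
      abort_invalid(sprintf("`%s` (%g Hz) is at or above Nyquist (%g Hz).",
                            f, params[[f]], fs / 2))
  }
  n <- round(fs * duration)
  t <- (seq_len(n) - 1) / fs
  withr::with_seed(as.integer(seed), {
    dir_a <- random_unit_direction()
    dir_g <- random_unit_direction()
    tremor_phase_a <- runif(1, 0, 2 * pi)
    tremor_phase_g <- runif(1, 0, 2 * pi)
    vol_phase <- runif(6, 0, 2 * pi)
    am <- if (params$am_depth > 0)
      1 + params$am_depth * sin(2 * pi * runif(1, 0.1, 0.5) * t +
                                  runif(1, 0, 2 * pi))
    else rep(1, n)
    env <- exp(-params$amp_decay_rate * t) * am
    ch <- vector("list", 6)
    names(ch) <- CHANNELS
    for (i in seq_along(CHANNELS)) {
      accel <- i <= 3
      amp_t <- if (accel) params$tremor_amp_g else params$tremor_amp_dps
      amp_v <- if (accel) params$voluntary_amp_g else params$voluntary_amp_dps
      nsd <- if (accel) params$noise_sd_g else params$noise_sd_dps
      dsd <- if (accel) params$drift_sd_g else params$drift_sd_dps
      u <- if (accel) dir_a[i] else dir_g[i - 3]
      ph <- if (accel) tremor_phase_a else tremor_phase_g
      x <- amp_v * env * sin(2 * pi * params$voluntary_freq_hz * t + vol_phase[i]) +
        amp_t * u * am * sin(2 * pi * params$tremor_freq_hz * t + ph)
      if (nsd > 0) x <- x + rnorm(n, 0, nsd)
      if (dsd > 0) x <- x + cumsum(rnorm(n, 0, dsd))
      if (params$outlier_rate > 0) {
        n_out <- min(rpois(1, params$outlier_rate * duration), n)
        if (n_out > 0) {
          idx <- sample.int(n, n_out)
          scale <- sd(x)
          if (scale == 0) scale <- 1
          x[idx] <- x[idx] +
            sample(c(-1, 1), n_out, replace = TRUE) *
            params$outlier_magnitude * scale
        }
      }
      ch[[i]] <- x
    }
    new_recording(tibble::tibble(t = t, !!!ch), subject_id = subject_id,
                  class_label = params$class_label, task = params$task,
                  sampling_rate_hz = fs)
  })
}

# Random unit 3-vector with every component bounded away from zero, so no
# axis ever loses the tremor projection entirely (wrist tremor reaches all
# axes in practice).
random_unit_direction <- function() {
  u <- sample(c(-1, 1), 3, replace = TRUE) * runif(3, 0.5, 1)
  u / sqrt(sum(u^2))
}

new_recording <- function(df, subject_id, class_label, task,
                          sampling_rate_hz) {
  structure(df,
            class = c("pd_recording", class(df)),
            subject_id = subject_id, class_label = class_label, task = task,
            sampling_rate_hz = sampling_rate_hz)
}

#' @export
print.pd_recording <- function(x, ...) {
  cat(sprintf("<pd_recording> subject %s, class %s, task %s, %g Hz, %d samples\n",
              attr(x, "subject_id"), attr(x, "class_label"), attr(x, "task"),
              attr(x, "sampling_rate_hz"), nrow(x)))
  NextMethod()
}

recording_meta <- function(rec) {
  list(subject_id = attr(rec, "subject_id"),
       class_label = attr(rec, "class_label"),
       task = attr(rec, "task"),
       sampling_rate_hz = attr(rec, "sampling_rate_hz"))
}

#' Specify a synthetic study cohort
#'
#' Parameterizes a full synthetic study: class sizes, task list, sampling
#' rate and duration, per-class motion-model distributions (means plus
#' between-subject jitter SDs) and the master seed. The defaults reproduce
#' the study design this package targets: 20 healthy, 10 tremor-dominant
#' and 10 bradykinesia-dominant subjects recorded at 100 Hz for 60 s per
#' task. The default task list pairs one tremor-assessment task (`rest`)
#' with one bradykinesia-assessment task (`finger_tap`).
#'
#' @param n_healthy,n_tremor,n_bradykinesia Class sizes.
#' @param tasks Ordered character vector of tasks each subject performs.
#' @param sampling_rate_hz Sampling rate (Hz).
#' @param duration_s Duration per task (s).
#' @param profiles Per-class motion-model distributions; see
#'   [motion_defaults()].
#' @param seed Integer master seed; identical specs give bit-identical
#'   cohorts.
#' @return A `pd_cohort_spec` list.
#' @export
cohort_spec <- function(n_healthy = 20, n_tremor = 10, n_bradykinesia = 10,
                        tasks = c("rest", "finger_tap"),
                        sampling_rate_hz = 100, duration_s = 60,
                        profiles = motion_defaults(), seed = 1) {
  for (nm in c("n_healthy", "n_tremor", "n_bradykinesia")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v != round(v))
      abort_invalid(sprintf("`%s` must be a non-negative integer.", nm))
  }
  if (n_healthy + n_tremor + n_bradykinesia == 0)
    abort_invalid("cohort is empty: all class sizes are zero.")
  if (length(tasks) < 1) abort_invalid("at least one task is required.")
  tasks <- vapply(tasks, function(tk) match.arg(tk, TASKS), character(1),
                  USE.NAMES = FALSE)
  if (sampling_rate_hz <= 0 || duration_s <= 0)
    abort_invalid("`sampling_rate_hz` and `duration_s` must be positive.")
  structure(list(n_healthy = n_healthy, n_tremor = n_tremor,
                 n_bradykinesia = n_bradykinesia, tasks = tasks,
                 sampling_rate_hz = sampling_rate_hz, duration_s = duration_s,
                 profiles = profiles, seed = as.integer(seed)),
            class = "pd_cohort_spec")
}

#' Frozen per-class motion-model distributions
#'
#' Means and between-subject jitter SDs of the motion model for each class.
#' These defaults are the study conditions of the synthetic cohort and are
#' frozen: healthy subjects tap briskly at ~3 Hz with no tremor; tremor
#' subjects add a 4-6 Hz rest-tremor oscillation (attenuated by
#' `tremor_action_scale` during voluntary tasks) but move normally
#' otherwise; bradykinesia subjects show no tremor but a slowed (~1.8 Hz),
#' attenuated tap whose amplitude decays within the trial. Noise, drift and
#' outlier levels are identical across classes so that class contrasts come
#' from movement structure, not from the sensor floor.
#'
#' @return A nested list, one element per class label.
#' @export
motion_defaults <- function() {
  noise <- list(noise_sd_g = 0.02, noise_sd_dps = 1.5, noise_mult_sd = 0.3,
                drift_sd_g = 0.002, drift_sd_dps = 0.1,
                outlier_rate = 0.05, outlier_magnitude = 8)
  list(
    healthy = c(list(
      voluntary_freq_hz = c(mean = 3.0, sd = 0.25),
      voluntary_amp_g = 0.35, voluntary_amp_dps = 45,
      amp_mult_sd = 0.35,
      amp_decay_rate = c(mean = 0, sd = 0),
      tremor = FALSE), noise),
    tremor = c(list(
      voluntary_freq_hz = c(mean = 3.0, sd = 0.25),
      voluntary_amp_g = 0.35, voluntary_amp_dps = 45,
      amp_mult_sd = 0.35,
      amp_decay_rate = c(mean = 0, sd = 0),
      tremor = TRUE,
      tremor_amp_g = 0.35, tremor_amp_dps = 40,
      tremor_action_scale = 0.6), noise),
    bradykinesia = c(list(
      voluntary_freq_hz = c(mean = 1.8, sd = 0.2),
      voluntary_amp_g = 0.12, voluntary_amp_dps = 16,
      amp_mult_sd = 0.35,
      amp_decay_rate = c(mean = 0.02, sd = 0.005),
      tremor = FALSE), noise)
  )
}

# Tasks during which the subject moves voluntarily. rest and postural are
# (quasi-)static holds; kinetic is a slow reaching movement.
is_action_task <- function(task) {
  task %in% c("kinetic", "finger_tap", "fist_open_close",
              "pronation_supination")
}

# Draw one subject's motion parameters for one task from the class profile.
draw_subject_params <- function(class_label, task, prof, traits) {
  vol_freq <- 0
  vol_amp_g <- 0
  vol_amp_dps <- 0
  decay <- 0
  if (is_action_task(task)) {
    vol_freq <- if (task == "kinetic") 0.5 else traits$voluntary_freq_hz
    vol_amp_g <- prof$voluntary_amp_g * traits$amp_mult
    vol_amp_dps <- prof$voluntary_amp_dps * traits$amp_mult
    decay <- traits$amp_decay_rate
  }
  tr_freq <- 0
  tr_amp_g <- 0
  tr_amp_dps <- 0
  if (isTRUE(prof$tremor)) {
    tr_freq <- traits$tremor_freq_hz[[task]]
    scale <- if (is_action_task(task)) prof$tremor_action_scale else 1
    tr_amp_g <- prof$tremor_amp_g * traits$tremor_amp_mult * scale
    tr_amp_dps <- prof$tremor_amp_dps * traits$tremor_amp_mult * scale
  }
  motion_params(class_label, task,
                tremor_freq_hz = tr_freq, tremor_amp_g = tr_amp_g,
                tremor_amp_dps = tr_amp_dps,
                voluntary_freq_hz = vol_freq, voluntary_amp_g = vol_amp_g,
                voluntary_amp_dps = vol_amp_dps, amp_decay_rate = decay,
                noise_sd_g = prof$noise_sd_g * traits$noise_mult,
                noise_sd_dps = prof$noise_sd_dps * traits$noise_mult,
                drift_sd_g = prof$drift_sd_g, drift_sd_dps = prof$drift_sd_dps,
                outlier_rate = prof$outlier_rate,
                outlier_magnitude = prof$outlier_magnitude)
}

#' Generate a labeled synthetic cohort
#'
#' Draws per-subject motion parameters from the class distributions of a
#' [cohort_spec()] (between-subject amplitude/frequency jitter, per-task
#' tremor frequency within the clinically expected band) and simulates one
#' recording per subject per task. Generation is a pure function of the
#' spec: identical specs give bit-identical cohorts.
#'
#' @param spec A [cohort_spec()].
#' @return A `pd_cohort`: a tibble with one row per recording and columns
#'   `subject_id`, `class_label`, `task`, and a `data` list-column of
#'   `pd_recording` objects.
#' @examples
#' co <- generate_cohort(cohort_spec(n_healthy = 2, n_tremor = 1,
#'                                   n_bradykinesia = 1, duration_s = 5,
#'                                   seed = 7))
#' dplyr::count(co, class_label)
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "pd_cohort_spec"))
    abort_invalid("`spec` must be a `pd_cohort_spec`.")
  counts <- c(healthy = spec$n_healthy, tremor = spec$n_tremor,
              bradykinesia = spec$n_bradykinesia)
  plan <- withr::with_seed(spec$seed, {
    rows <- list()
    sid <- 0
    for (cls in CLASS_LEVELS) {
      prof <- spec$profiles[[cls]]
      for (s in seq_len(counts[[cls]])) {
        sid <- sid + 1
        traits <- list(
          amp_mult = max(rnorm(1, 1, prof$amp_mult_sd), 0.3),
          tremor_amp_mult = max(rnorm(1, 1, 0.2), 0.4),
          noise_mult = max(rnorm(1, 1, prof$noise_mult_sd), 0.4),
          voluntary_freq_hz = max(rnorm(1, prof$voluntary_freq_hz[["mean"]],
                                        prof$voluntary_freq_hz[["sd"]]),
                                  prof$voluntary_freq_hz[["mean"]] / 2),
          amp_decay_rate = max(rnorm(1, prof$amp_decay_rate[["mean"]],
                                     prof$amp_decay_rate[["sd"]]), 0),
          tremor_freq_hz = if (isTRUE(prof$tremor)) {
            fr <- lapply(spec$tasks, function(tk) {
              b <- tremor_band(tk)
              runif(1, b[1], b[2])
            })
            names(fr) <- spec$tasks
            fr
          } else NULL)
        subject_id <- sprintf("%s_%02d", substr(cls, 1, 4), s)
        for (tk in spec$tasks) {
          rows[[length(rows) + 1]] <- list(
            subject_id = subject_id, class_label = cls, task = tk,
            params = draw_subject_params(cls, tk, prof, traits),
            rec_seed = sample.int(.Machine$integer.max - 1L, 1))
        }
      }
    }
    rows
  })
  recs <- purrr::map(plan, function(r) {
    simulate_recording(r$params, fs = spec$sampling_rate_hz,
                       duration = spec$duration_s, seed = r$rec_seed,
                       subject_id = r$subject_id)
  })
  out <- tibble::tibble(
    subject_id = purrr::map_chr(plan, "subject_id"),
    class_label = purrr::map_chr(plan, "class_label"),
    task = purrr::map_chr(plan, "task"),
    data = recs)
  class(out) <- c("pd_cohort", class(out))
  out
}

#' Per-subject class labels of a cohort
#'
#' @param cohort A `pd_cohort` tibble.
#' @return A tibble with one row per subject (`subject_id`, `class_label`).
#' @export
cohort_labels <- function(cohort) {
  dplyr::distinct(tibble::as_tibble(cohort)[c("subject_id", "class_label")])
}
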