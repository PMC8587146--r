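#' Activity profile for the synthetic cohort generator
#'
#' An activity profile collects the generator parameters for one activity:
#' the gait/motion fundamental and per-axis amplitudes seen by the wrist
#' accelerometer, the wideband motion noise, the mean and spread of the
#' heart rate the activity elicits, the PPG motion-artifact coupling gain,
#' and the (unit) gravity orientation of the wrist while performing it.
#'
#' @param activity_name activity label.
#' @param motion_fundamental_hz fundamental frequency of the periodic arm
#'   motion, Hz (0 for stationary activities).
#' @param motion_amp length-3 vector of per-axis motion amplitudes, g.
#' @param motion_noise_sd standard deviation of wideband accelerometer
#'   noise, g.
#' @param heart_rate_mean_bpm population-mean heart rate during the
#'   activity, beats/min (must lie in \[40, 220\]).
#' @param heart_rate_sd_bpm per-beat heart-rate jitter, beats/min.
#' @param artifact_coupling dimensionless gain from instantaneous
#'   acceleration magnitude into the PPG channel (motion artifact).
#' @param gravity length-3 wrist gravity orientation (normalised to 1 g).
#' @param posture posture group label; subjects share one wrist-orientation
#'   perturbation per posture group, so activities performed in the same
#'   posture (walking and stairs) keep identical gravity signatures.
#' @return an object of class `activity_profile`.
#' @export
activity_profile <- function(activity_name, motion_fundamental_hz,
                             motion_amp, motion_noise_sd,
                             heart_rate_mean_bpm, heart_rate_sd_bpm,
                             artifact_coupling, gravity, posture) {
  stopifnot(motion_fundamental_hz >= 0,
            heart_rate_mean_bpm >= 40, heart_rate_mean_bpm <= 220,
            heart_rate_sd_bpm >= 0, motion_noise_sd >= 0,
            length(motion_amp) == 3, all(motion_amp >= 0),
            length(gravity) == 3)
  gravity <- gravity / sqrt(sum(gravity^2))
  structure(list(activity_name = activity_name,
                 motion_fundamental_hz = motion_fundamental_hz,
                 motion_amp = as.numeric(motion_amp),
                 motion_noise_sd = motion_noise_sd,
                 heart_rate_mean_bpm = heart_rate_mean_bpm,
                 heart_rate_sd_bpm = heart_rate_sd_bpm,
                 artifact_coupling = artifact_coupling,
                 gravity = as.numeric(gravity),
                 posture = posture),
            class = "activity_profile")
}

#' Default activity profiles for the five studied activities
#'
#' The defaults encode the qualitative structure the analysis depends on:
#' \itemize{
#'   \item walking and stairs are *motion-confusable*: near-identical
#'     fundamentals (1.9 vs 1.8 Hz), per-axis amplitudes within a few
#'     percent of each other and the same posture (gravity signature), but
#'     mean heart rates separated by 30 bpm;
#'   \item sitting has the lowest heart rate and near-zero motion;
#'   \item heart rate increases with physical demand
#'     (sitting < table soccer < walking < cycling < stairs);
#'   \item every non-stationary activity couples motion into the PPG
#'     channel (motion artifacts).
#' }
#'
#' @return named list of [activity_profile()] objects, one per activity
#'   (`sitting`, `stairs`, `table_soccer`, `cycling`, `walking`).
#' @export
default_profiles <- function() {
  list(
    sitting = activity_profile("sitting", 0.0, c(0.010, 0.010, 0.010), 0.02,
                               62, 3, 0.3, c(0.10, 0.97, 0.22), "seated"),
    walking = activity_profile("walking", 1.9, c(0.35, 0.45, 0.30), 0.08,
                               95, 6, 0.8, c(0.55, 0.75, 0.37), "upright"),
    stairs = activity_profile("stairs", 1.8, c(0.36, 0.46, 0.31), 0.08,
                              125, 7, 0.8, c(0.55, 0.75, 0.37), "upright"),
    cycling = activity_profile("cycling", 1.0, c(0.18, 0.12, 0.22), 0.10,
                               115, 6, 0.6, c(0.80, 0.40, 0.45), "cycle"),
    table_soccer = activity_profile("table_soccer", 2.8, c(0.22, 0.18, 0.14),
                                    0.15, 85, 6, 0.7, c(0.30, 0.90, 0.32),
                                    "standing")
  )
}

#' Per-subject generator parameters
#'
#' @param subject_id identifier string.
#' @param baseline_hr_offset_bpm additive shift of this subject's heart
#'   rate, beats/min.
#' @param motion_amplitude_scale multiplicative scale on all motion
#'   amplitudes (> 0); captures body-size / vigour differences.
#' @param fitness_factor divides the heart-rate response above rest (> 0);
#'   fitter subjects show a smaller rate rise for the same exertion.
#' @return an object of class `subject_params`.
#' @export
subject_params <- function(subject_id, baseline_hr_offset_bpm = 0,
                           motion_amplitude_scale = 1, fitness_factor = 1) {
  stopifnot(motion_amplitude_scale > 0, fitness_factor > 0)
  structure(list(subject_id = subject_id,
                 baseline_hr_offset_bpm = baseline_hr_offset_bpm,
                 motion_amplitude_scale = motion_amplitude_scale,
                 fitness_factor = fitness_factor),
            class = "subject_params")
}

#' Default recording protocol
#'
#' Ordered activity schedule: each of the five activities for a fixed
#' duration (default 120 s, a desk-scale stand-in for the multi-hour
#' sessions such studies record).
#'
#' @param duration_s per-activity duration in seconds.
#' @return data frame with columns `activity`, `duration_s`.
#' @export
default_protocol <- function(duration_s = 120) {
  data.frame(activity = c("sitting", "stairs", "table_soccer",
                          "cycling", "walking"),
             duration_s = duration_s)
}

#' Imbalanced protocol mirroring daily-life class proportions
#'
#' Allocates the total duration as walking 27%, sitting 24%, stairs 19%,
#' cycling 17%, table soccer 13% -- the class-imbalance pattern typical of
#' daily-life wearable recordings (walking and sitting dominate, table
#' soccer is the smallest class).
#'
#' @param total_s total recording duration in seconds.
#' @return data frame with columns `activity`, `duration_s`.
#' @export
imbalanced_protocol <- function(total_s = 600) {
  props <- c(sitting = 0.24, stairs = 0.19, table_soccer = 0.13,
             cycling = 0.17, walking = 0.27)
  data.frame(activity = names(props),
             duration_s = as.numeric(round(total_s * props)))
}

# Piecewise-linear random drift: values drawn at regular knots, linearly
# interpolated. Used for slow within-segment wander of heart rate and of
# the motion-amplitude envelope.
random_drift <- function(duration_s, knot_every_s, sd) {
  knots <- seq(0, duration_s + knot_every_s, by = knot_every_s)
  vals <- rnorm(length(knots), 0, sd)
  function(t) approx(knots, vals, xout = t, rule = 2)$y
}

# Beat times over one activity segment: sequential RR intervals from the
# (drifting) instantaneous heart rate with Gaussian per-beat jitter.
generate_beats <- function(duration_s, hr_bpm, hr_sd_bpm, drift) {
  out <- numeric(ceiling(duration_s * 4) + 8)
  t <- runif(1, 0, 60 / hr_bpm)
  n <- 0L
  while (t < duration_s) {
    n <- n + 1L
    out[n] <- t
    hr_t <- min(220, max(40, hr_bpm + drift(t)))
    rr <- 60 / hr_t + rnorm(1, 0, 60 * hr_sd_bpm / hr_t^2)
    t <- t + max(0.25, rr)
  }
  out[seq_len(n)]
}

# One activity segment for one subject: returns per-channel sample blocks.
simulate_segment <- function(profile, params, posture_jitter, duration_s) {
  n32 <- round(duration_s * 32)
  n64 <- round(duration_s * 64)
  n700 <- round(duration_s * 700)
  t32 <- (seq_len(n32) - 1) / 32
  t64 <- (seq_len(n64) - 1) / 64

  # --- accelerometer: gravity + periodic gait motion + noise ------------
  grav <- profile$gravity + posture_jitter
  grav <- grav / sqrt(sum(grav^2))
  f <- profile$motion_fundamental_hz
  env <- random_drift(duration_s, 5, 1)      # slow shared intensity envelope
  env32 <- 1 + 0.15 * env(t32)
  acc <- vector("list", 3)
  for (ax in 1:3) {
    amp <- profile$motion_amp[ax] * params$motion_amplitude_scale
    motion <- 0
    if (f > 0) {
      ph1 <- runif(1, 0, 2 * pi)
      ph2 <- runif(1, 0, 2 * pi)
      motion <- amp * env32 * (sin(2 * pi * f * t32 + ph1) +
                                 0.4 * sin(2 * pi * 2 * f * t32 + ph2))
    }
    acc[[ax]] <- grav[ax] + motion + rnorm(n32, 0, profile$motion_noise_sd)
  }

  # --- heart rate: rest + exertion scaled by fitness, plus slow drift ---
  hr <- 60 + (profile$heart_rate_mean_bpm - 60) / params$fitness_factor +
    params$baseline_hr_offset_bpm
  hr <- min(220, max(40, hr))
  hr_drift <- random_drift(duration_s, 10, 6)
  beats <- generate_beats(duration_s, hr, profile$heart_rate_sd_bpm, hr_drift)

  # --- ECG: train of Gaussian R-peak pulses at 700 Hz -------------------
  sigma <- 0.02
  ecg <- rnorm(n700, 0, 0.05)
  half <- ceiling(4 * sigma * 700)
  for (b in beats) {
    c_idx <- round(b * 700) + 1
    idx <- max(1, c_idx - half):min(n700, c_idx + half)
    tt <- (idx - 1) / 700
    ecg[idx] <- ecg[idx] + exp(-((tt - b)^2) / (2 * sigma^2))
  }

  # --- PPG: smooth pulse wave at the same beats + artifact + wander -----
  if (length(beats) >= 2) {
    rr_med <- median(diff(beats))
    bx <- c(beats[1] - rr_med, beats, beats[length(beats)] + rr_med)
  } else {
    bx <- c(0, duration_s)
  }
  phase <- approx(bx, seq_along(bx) - 1, xout = t64, rule = 2)$y
  pulse <- 0.6 * (0.5 - 0.5 * cos(2 * pi * phase) +
                    0.25 * cos(4 * pi * phase + 1.0))
  mag32 <- sqrt(acc[[1]]^2 + acc[[2]]^2 + acc[[3]]^2)
  mag64 <- upsample_by_pairwise_average(mag32)
  wander <- 0.4 * sin(2 * pi * 0.08 * t64 + runif(1, 0, 2 * pi)) +
    0.2 * sin(2 * pi * 0.05 * t64 + runif(1, 0, 2 * pi))
  ppg <- pulse + wander + profile$artifact_coupling * mag64 +
    rnorm(n64, 0, 0.3)

  list(`ACC-X` = acc[[1]], `ACC-Y` = acc[[2]], `ACC-Z` = acc[[3]],
       PPG = ppg, ECG = ecg)
}

#' Simulate one subject's multi-rate recording
#'
#' Generates the five channels (ACC-X/Y/Z at 32 Hz, PPG at 64 Hz, ECG at
#' 700 Hz) for an ordered activity protocol.  The accelerometer is a
#' constant 1 g gravity vector plus a sum of sinusoids at the activity's
#' motion fundamental and its first harmonic (with a slow shared amplitude
#' envelope) plus Gaussian noise; the ECG is a train of Gaussian-shaped
#' R peaks whose RR intervals follow the activity- and subject-dependent
#' heart rate with per-beat jitter and slow drift; the PPG is a smooth
#' periodic pulse wave locked to the same beats, corrupted by baseline
#' wander, wideband noise and a motion artifact proportional to the
#' instantaneous acceleration magnitude.
#'
#' @param params [subject_params()] object.
#' @param protocol data frame with columns `activity`, `duration_s`
#'   (see [default_protocol()]).
#' @param profiles named list of [activity_profile()]s.
#' @param seed integer seed; identical inputs and seed give a bit-identical
#'   record.
#' @return an object of class `subject_record`: list with `subject_id`,
#'   `channels` (named list of `list(name, rate_hz, samples)`) and `labels`
#'   (data frame `start_s`, `end_s`, `activity`; intervals are half-open
#'   `[start_s, end_s)`).
#' @export
simulate_subject <- function(params, protocol, profiles = default_profiles(),
                             seed = 1L) {
  stopifnot(inherits(params, "subject_params"),
            is.data.frame(protocol), nrow(protocol) >= 1,
            all(protocol$duration_s > 0))
  unknown <- setdiff(protocol$activity, names(profiles))
  if (length(unknown) > 0) {
    stop("unknown activity in protocol: ", paste(unknown, collapse = ", "))
  }
  set.seed(as.integer(seed))

  # one wrist-orientation perturbation per posture group, shared across all
  # activities performed in that posture
  postures <- sort(unique(vapply(profiles, `[[`, "", "posture")))
  jitters <- lapply(postures, function(p) rnorm(3, 0, 0.08))
  names(jitters) <- postures

  chans <- lapply(CHANNEL_NAMES, function(nm) numeric(0))
  names(chans) <- CHANNEL_NAMES
  labels <- data.frame(start_s = numeric(0), end_s = numeric(0),
                       activity = character(0))
  t0 <- 0
  for (i in seq_len(nrow(protocol))) {
    act <- protocol$activity[i]
    dur <- protocol$duration_s[i]
    prof <- profiles[[act]]
    seg <- simulate_segment(prof, params, jitters[[prof$posture]], dur)
    for (nm in CHANNEL_NAMES) chans[[nm]] <- c(chans[[nm]], seg[[nm]])
    labels <- rbind(labels, data.frame(start_s = t0, end_s = t0 + dur,
                                       activity = act))
    t0 <- t0 + dur
  }
  channels <- lapply(CHANNEL_NAMES, function(nm) {
    list(name = nm, rate_hz = unname(CHANNEL_RATES[nm]),
         samples = chans[[nm]])
  })
  names(channels) <- CHANNEL_NAMES
  structure(list(subject_id = params$subject_id, channels = channels,
                 labels = labels),
            class = "subject_record")
}

#' Simulate a cohort of subjects
#'
#' Subject parameters (heart-rate offset, motion-amplitude scale, fitness
#' factor) are drawn from fixed population ranges; per-subject seeds are
#' derived deterministically from the master seed, so the cohort is a pure
#' function of `(n_subjects, protocol, profiles, seed)`.
#'
#' @param n_subjects number of subjects (>= 2; leave-one-subject-out
#'   evaluation is undefined for a single subject).
#' @param protocol activity schedule shared by all subjects.
#' @param profiles named list of [activity_profile()]s.
#' @param seed master seed.
#' @return list of `subject_record`s with distinct `subject_id`s.
#' @export
simulate_cohort <- function(n_subjects, protocol = default_protocol(),
                            profiles = default_profiles(), seed = 1L) {
  if (n_subjects < 2) {
    stop("n_subjects must be >= 2 (leave-one-subject-out needs >= 2 subjects)")
  }
  set.seed(as.integer(seed))
  offs <- rnorm(n_subjects, 0, 6)
  scales <- runif(n_subjects, 0.8, 1.2)
  fits <- runif(n_subjects, 0.85, 1.25)
  sub_seeds <- sample.int(10000000L, n_subjects)
  lapply(seq_len(n_subjects), function(i) {
    p <- subject_params(sprintf("S%02d", i), offs[i], scales[i], fits[i])
    simulate_subject(p, protocol, profiles, seed = sub_seeds[i])
  })
}
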