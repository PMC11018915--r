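## Synthetic trot-trial generator.
##
## Every stochastic draw is tied to a seed derived deterministically from
## (config$seed, horse_index, condition), so a cohort is reproducible
## trial-by-trial and generate_trial() can be called standalone.

## Seed arithmetic keeps everything strictly below .Machine$integer.max.
trial_seed <- function(config, horse_index, tag) {
  base <- config$seed %% 50000L
  as.integer(base * 40000L + horse_index * 50L + tag)
}

cond_index <- function(condition) match(condition, CONDITIONS)

## Per-horse stride frequency: fixed if the config says so, otherwise drawn
## once per horse from the configured range.
horse_stride_frequency <- function(config, horse_index) {
  if (!is.null(config$stride_frequency_hz)) {
    f <- rep_len(config$stride_frequency_hz, config$n_horses)
    return(f[horse_index])
  }
  set.seed(trial_seed(config, horse_index, 45L))
  stats::runif(1, config$stride_frequency_range[1], config$stride_frequency_range[2])
}

## Induced side per horse, balanced across the cohort (floor/ceil split when
## n_horses is odd) and shared by the iFL and iHL sessions of a horse.
## A forced side in the config overrides the randomization.
horse_induced_side <- function(config, horse_index) {
  if (!is.null(config$induced_side)) return(config$induced_side)
  n <- config$n_horses
  n_left <- floor(n / 2)
  set.seed(trial_seed(config, 0L, 49L))
  left_ids <- sample(seq_len(n), n_left)
  if (horse_index %in% left_ids) "left" else "right"
}

## Zero-mean broadband noise band-limited to [20, 450] Hz (clipped below
## Nyquist), rescaled to an exact standard deviation so that amplitude
## factors act linearly on the ARV.
band_limited_noise <- function(n, fs, sd, band = c(20, 450)) {
  hi <- min(band[2], 0.45 * fs)
  bf <- signal::butter(4, c(band[1], hi) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n))
  x / stats::sd(x) * sd
}

## Stride-locked activation envelope: Gaussian burst at a muscle-specific
## phase (circular distance), on a tonic floor; peak value 1.
burst_envelope <- function(t, impact0, f, phase_centre, width, tonic) {
  p <- ((t - impact0) * f) %% 1
  d <- pmin(abs(p - phase_centre), 1 - abs(p - phase_centre))
  tonic + (1 - tonic) * exp(-d^2 / (2 * width^2))
}

## Hind-hoof height: zero-height stance plateau, half-sine swing arc;
## impact (phase 0) is the swing-to-stance transition.
hoof_height <- function(t, impact0, f, duty, swing_height) {
  p <- ((t - impact0) * f) %% 1
  ifelse(p < duty, 0, swing_height * sin(pi * (p - duty) / (1 - duty)))
}

## Noise-free oscillation of an upper-body landmark, relative to the left
## hind impact at tau = 0. The 2f term gives the trot double oscillation
## (extrema at stride phases 1/8, 3/8, 5/8, 7/8, away from stride
## boundaries); the 1f term, scaled by the signed asymmetry, offsets the
## two per-stride minima/maxima in opposite directions.
upper_body_wave <- function(tau, f, amplitude, asym_signed) {
  amplitude * sin(4 * pi * f * tau) - (asym_signed / 2) * sin(2 * pi * f * tau)
}

## Which landmarks carry injected asymmetry under each condition: the head
## (poll) and withers respond to forelimb induction, the pelvis and tubera
## coxae to hindlimb induction; baselines are symmetric.
applied_asymmetry <- function(config, condition) {
  a <- c(poll = 0, withers = 0, pelvis = 0, tuber_coxae = 0)
  if (condition == "iFL") {
    a[c("poll", "withers")] <- config$asymmetry_mm[c("poll", "withers")]
  } else if (condition == "iHL") {
    a[c("pelvis", "tuber_coxae")] <- config$asymmetry_mm[c("pelvis", "tuber_coxae")]
  }
  a
}

## Numeric oracle for the asymmetry a noise-free trial realizes: evaluates
## the oscillation over one dense stride and measures MinDiff/MaxDiff
## (first-half minus second-half extremum) and Hip Hike directly.
realized_asymmetry <- function(config, condition, induced_side) {
  f <- 1 # phase-only computation; frequency cancels
  s <- if (induced_side == "right") -1 else 1
  a <- applied_asymmetry(config, condition)
  tau <- seq(0, 1, length.out = 4001)[-4001]
  out <- lapply(ASYM_LANDMARKS, function(lm) {
    y <- upper_body_wave(tau, f, config$displacement_amplitude_mm[[lm]],
                         s * a[[lm]])
    first <- y[tau < 0.5]; second <- y[tau >= 0.5]
    data.frame(landmark = lm,
               min_diff = min(first) - min(second),
               max_diff = max(first) - max(second))
  })
  tc_amp <- config$displacement_amplitude_mm[["tuber_coxae"]]
  al <- tc_amp - s * a[["tuber_coxae"]] / 4
  ar <- tc_amp + s * a[["tuber_coxae"]] / 4
  yl <- al * sin(4 * pi * f * tau)
  yr <- ar * sin(4 * pi * f * tau + pi)
  amp <- function(y, win) max(y[win]) - min(y[win])
  st_l <- tau < 0.5; sw_l <- !st_l
  hip_stance <- amp(yl, st_l) - amp(yr, sw_l)  # right stance = left swing window
  hip_swing <- amp(yl, sw_l) - amp(yr, st_l)
  list(min_max = do.call(rbind, out),
       hip_hike_stance = hip_stance, hip_hike_swing = hip_swing)
}

#' Generate one synthetic trot trial
#'
#' Builds a [trial_recording()] for one horse and condition, together with
#' the ground truth the generator injected: true hind-hoof impact times,
#' the per-channel sEMG amplitude factors, and the asymmetry the noise-free
#' kinematic signal realizes (measured by a numeric oracle, since the
#' injected millimetre value maps through the waveform shape).
#'
#' @param config a [sim_config()].
#' @param horse_index 1-based horse number (`<= config$n_horses`).
#' @param condition one of `baseline1`, `iFL`, `baseline2`, `iHL`.
#' @return list with elements `recording` (a `trial_recording`) and
#'   `truth` (impact times, amplitude factors, realized asymmetry).
#' @export
generate_trial <- function(config, horse_index, condition) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  if (!condition %in% CONDITIONS)
    stop(sprintf("unknown condition '%s'", condition))
  if (horse_index < 1 || horse_index > config$n_horses)
    stop("horse_index out of range")

  f <- horse_stride_frequency(config, horse_index)
  induced_side <- if (condition %in% c("iFL", "iHL"))
    horse_induced_side(config, horse_index) else "none"
  side_for_scale <- horse_induced_side(config, horse_index)
  s_dir <- if (side_for_scale == "right") -1 else 1

  pad <- 0.3
  n_cycles <- config$strides_per_trial + 1L
  duration <- 2 * pad + n_cycles / f
  impacts_left <- pad + (0:n_cycles) / f
  impacts_right <- pad + 0.5 / f + (0:(n_cycles - 1)) / f

  set.seed(trial_seed(config, horse_index, cond_index(condition)))

  nk <- floor(duration * config$kin_sampling_hz)
  tk <- (seq_len(nk) - 1) / config$kin_sampling_hz
  asym <- applied_asymmetry(config, condition)
  drift <- config$drift_amplitude_mm * sin(2 * pi * 0.07 * tk + 1)

  kin <- list()
  for (lm in ASYM_LANDMARKS) {
    kin[[lm]] <- upper_body_wave(tk - impacts_left[1], f,
                                 config$displacement_amplitude_mm[[lm]],
                                 s_dir * asym[[lm]]) +
      drift + stats::rnorm(nk, sd = config$kin_noise_sd_mm)
  }
  tc_amp <- config$displacement_amplitude_mm[["tuber_coxae"]]
  al <- tc_amp - s_dir * asym[["tuber_coxae"]] / 4
  ar <- tc_amp + s_dir * asym[["tuber_coxae"]] / 4
  tau <- tk - impacts_left[1]
  kin$tuber_coxae_left <- al * sin(4 * pi * f * tau) + drift +
    stats::rnorm(nk, sd = config$kin_noise_sd_mm)
  kin$tuber_coxae_right <- ar * sin(4 * pi * f * tau + pi) + drift +
    stats::rnorm(nk, sd = config$kin_noise_sd_mm)
  kin$hoof_hind_left <- hoof_height(tk, impacts_left[1], f, config$stance_duty,
                                    config$hoof_swing_height_mm) +
    stats::rnorm(nk, sd = 0.3)
  kin$hoof_hind_right <- hoof_height(tk, impacts_right[1], f, config$stance_duty,
                                     config$hoof_swing_height_mm) +
    stats::rnorm(nk, sd = 0.3)

  ne <- floor(duration * config$emg_sampling_hz)
  te <- (seq_len(ne) - 1) / config$emg_sampling_hz
  emg <- list()
  scales <- data.frame()
  for (muscle in MUSCLES) {
    for (side in SIDES) {
      sc <- resolve_muscle_scale(config, muscle, side, condition, side_for_scale)
      imp0 <- if (side == "left") impacts_left[1] else impacts_right[1]
      env <- burst_envelope(te, imp0, f, BURST_PHASE[[muscle]],
                            config$burst_width, config$tonic_level)
      ## stride-to-stride amplitude variability: one lognormal factor per
      ## stride per channel (mean 1 on the log scale)
      if (config$stride_amp_cv > 0) {
        g <- exp(stats::rnorm(n_cycles + 3L, sd = config$stride_amp_cv))
        k <- pmin(pmax(floor((te - imp0) * f) + 2L, 1L), length(g))
        env <- env * g[k]
      }
      carrier <- band_limited_noise(ne, config$emg_sampling_hz, config$emg_noise_sd)
      emg[[emg_channel_name(muscle, side)]] <- config$dc_offset + sc * env * carrier
      scales <- rbind(scales, data.frame(muscle = muscle, side = side,
                                         condition = condition, scale = sc))
    }
  }

  recording <- trial_recording(
    horse_id = sprintf("H%02d", horse_index), condition = condition,
    induced_side = induced_side, kin = kin, emg = emg,
    kin_sampling_hz = config$kin_sampling_hz,
    emg_sampling_hz = config$emg_sampling_hz)

  truth <- list(
    stride_frequency_hz = f,
    impacts_left = impacts_left,
    impacts_right = impacts_right,
    induced_side = induced_side,
    muscle_scales = scales,
    injected_asymmetry_mm = asym,
    realized = realized_asymmetry(config, condition, side_for_scale))

  list(recording = recording, truth = truth)
}

#' Generate a full synthetic cohort
#'
#' All horses times all four conditions, with induced side balanced across
#' horses (4/4 for the default eight) and shared between a horse's iFL and
#' iHL sessions, emulating a two-day cross-over design. Deterministic given
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list of `list(recording, truth)`, one element per trial, in
#'   horse-major order.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  if (config$n_horses %% 2 == 1)
    warning("n_horses is odd; induced sides cannot balance exactly")
  trials <- list()
  for (h in seq_len(config$n_horses)) {
    for (cond in CONDITIONS) {
      trials[[length(trials) + 1L]] <- generate_trial(config, h, cond)
    }
  }
  trials
}
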