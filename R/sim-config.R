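#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic trot-trial
#' generator. The generator emulates the acquisition set-up of an induced
#' lameness cross-over experiment: vertical displacement of upper-body and
#' hind-hoof markers sampled at 200 Hz, and bilateral sEMG from seven
#' muscles sampled at 2000 Hz, with four conditions per horse
#' (`baseline1`, `iFL`, `baseline2`, `iHL`).
#'
#' Kinematic model per upper-body landmark: a double oscillation at twice
#' the stride frequency (two displacement minima/maxima per stride, as in
#' trot), plus a component at stride frequency whose amplitude is set by
#' `asymmetry_mm` and which makes the two per-stride minima (and maxima)
#' differ — the injected lameness asymmetry. Positive `asymmetry_mm`
#' produces lameness-typical *negative* MinDiff/MaxDiff for left-side
#' inductions. Slow drift and white measurement noise are added on top.
#' Poll and withers receive their asymmetry only under `iFL`; pelvis and
#' tuber coxae only under `iHL`.
#'
#' sEMG model per muscle and side: `dc_offset` plus a stride-locked
#' Gaussian activation burst (envelope) multiplying zero-mean broadband
#' noise band-limited to 20-450 Hz, scaled by the per
#' (muscle, side, condition) factor from `muscle_scale`.
#'
#' @param n_horses number of horses (cohort size).
#' @param strides_per_trial number of full strides each trial must contain
#'   (>= 2); the generator adds one lead-in and one tail stride.
#' @param stride_frequency_hz optional fixed stride frequency (strides/s);
#'   default `NULL` draws one per horse uniformly from
#'   `stride_frequency_range`.
#' @param stride_frequency_range range the per-horse frequency is drawn
#'   from; default `c(1.3, 1.6)` strides/s, typical of in-hand trot.
#' @param kin_sampling_hz kinematic sampling rate (Hz).
#' @param emg_sampling_hz sEMG sampling rate (Hz).
#' @param displacement_amplitude_mm named vector of double-oscillation
#'   amplitudes (mm) for `poll`, `withers`, `pelvis`, `tuber_coxae`.
#' @param asymmetry_mm named vector (same names) of injected asymmetry
#'   magnitudes (mm); the realized MinDiff is measured by a numeric oracle
#'   on the noise-free signal and returned in the ground truth, not assumed
#'   equal to this value.
#' @param muscle_scale `NULL` (all factors 1) or a data frame with columns
#'   `muscle`, `side`, `condition`, `scale`. `side` may be anatomical
#'   (`left`/`right`), relative to the induction (`LS` = ipsilateral lame
#'   side, `NLS` = contralateral), or `both`.
#' @param emg_noise_sd standard deviation of the broadband sEMG carrier
#'   before envelope scaling (arbitrary units).
#' @param dc_offset constant offset added to every sEMG channel.
#' @param kin_noise_sd_mm white measurement noise on kinematic channels (mm).
#' @param drift_amplitude_mm amplitude of the slow (0.07 Hz) drift shared
#'   by upper-body channels (mm).
#' @param hoof_swing_height_mm peak hoof height during swing (mm).
#' @param stance_duty fraction of the stride the hind hoof is on the
#'   ground (0-1).
#' @param burst_width stride-phase standard deviation of the muscle
#'   activation burst.
#' @param tonic_level envelope floor (fraction of burst peak) so muscles
#'   are never fully silent.
#' @param stride_amp_cv coefficient of variation of the lognormal
#'   stride-to-stride amplitude factor applied to each channel's envelope;
#'   emulates the physiological burst-to-burst variability of locomotor
#'   EMG. Set to 0 for a perfectly stationary amplitude process.
#' @param induced_side `NULL` to randomize the induction side per horse
#'   (balanced across the cohort), or `"left"`/`"right"` to force one side
#'   for every horse.
#' @param seed integer seed; identical configurations generate bit-identical
#'   cohorts.
#'
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_horses = 8L,
                       strides_per_trial = 25L,
                       stride_frequency_hz = NULL,
                       stride_frequency_range = c(1.3, 1.6),
                       kin_sampling_hz = 200,
                       emg_sampling_hz = 2000,
                       displacement_amplitude_mm = c(poll = 45, withers = 30,
                                                     pelvis = 35, tuber_coxae = 30),
                       asymmetry_mm = c(poll = 0, withers = 0,
                                        pelvis = 0, tuber_coxae = 0),
                       muscle_scale = NULL,
                       emg_noise_sd = 1,
                       dc_offset = 0.2,
                       kin_noise_sd_mm = 0.5,
                       drift_amplitude_mm = 15,
                       hoof_swing_height_mm = 80,
                       stance_duty = 0.4,
                       burst_width = 0.08,
                       tonic_level = 0.3,
                       stride_amp_cv = 0.15,
                       induced_side = NULL,
                       seed = 1L) {
  stop_cfg <- function(msg) stop("invalid sim_config: ", msg, call. = FALSE)
  if (n_horses < 1) stop_cfg("n_horses must be >= 1")
  if (strides_per_trial < 2) stop_cfg("strides_per_trial must be >= 2")
  if (kin_sampling_hz <= 0 || emg_sampling_hz <= 0)
    stop_cfg("sampling rates must be positive")
  if (!is.null(stride_frequency_hz) && any(stride_frequency_hz <= 0))
    stop_cfg("stride_frequency_hz must be positive")
  if (any(stride_frequency_range <= 0) ||
      stride_frequency_range[2] < stride_frequency_range[1])
    stop_cfg("stride_frequency_range must be positive and increasing")
  amp_names <- c("poll", "withers", "pelvis", "tuber_coxae")
  if (!all(amp_names %in% names(displacement_amplitude_mm)))
    stop_cfg("displacement_amplitude_mm must name poll, withers, pelvis, tuber_coxae")
  if (any(displacement_amplitude_mm <= 0))
    stop_cfg("displacement amplitudes must be positive")
  if (!all(amp_names %in% names(asymmetry_mm)))
    stop_cfg("asymmetry_mm must name poll, withers, pelvis, tuber_coxae")
  if (emg_noise_sd <= 0) stop_cfg("emg_noise_sd must be positive")
  if (stance_duty <= 0 || stance_duty >= 1) stop_cfg("stance_duty must be in (0, 1)")
  if (stride_amp_cv < 0) stop_cfg("stride_amp_cv must be non-negative")
  if (!is.null(induced_side) && !induced_side %in% SIDES)
    stop_cfg("induced_side must be NULL, 'left' or 'right'")
  if (!is.null(muscle_scale)) {
    needed <- c("muscle", "side", "condition", "scale")
    if (!is.data.frame(muscle_scale) || !all(needed %in% names(muscle_scale)))
      stop_cfg("muscle_scale needs columns muscle, side, condition, scale")
    if (any(muscle_scale$scale <= 0)) stop_cfg("muscle_scale factors must be positive")
    if (!all(muscle_scale$muscle %in% MUSCLES))
      stop_cfg("unknown muscle in muscle_scale")
    if (!all(muscle_scale$side %in% c(SIDES, "LS", "NLS", "both")))
      stop_cfg("muscle_scale side must be left/right/LS/NLS/both")
    if (!all(muscle_scale$condition %in% CONDITIONS))
      stop_cfg("unknown condition in muscle_scale")
  }
  structure(list(
    n_horses = as.integer(n_horses),
    strides_per_trial = as.integer(strides_per_trial),
    stride_frequency_hz = stride_frequency_hz,
    stride_frequency_range = stride_frequency_range,
    kin_sampling_hz = kin_sampling_hz,
    emg_sampling_hz = emg_sampling_hz,
    displacement_amplitude_mm = displacement_amplitude_mm,
    asymmetry_mm = asymmetry_mm,
    muscle_scale = muscle_scale,
    emg_noise_sd = emg_noise_sd,
    dc_offset = dc_offset,
    kin_noise_sd_mm = kin_noise_sd_mm,
    drift_amplitude_mm = drift_amplitude_mm,
    hoof_swing_height_mm = hoof_swing_height_mm,
    stance_duty = stance_duty,
    burst_width = burst_width,
    tonic_level = tonic_level,
    stride_amp_cv = stride_amp_cv,
    induced_side = induced_side,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Build a muscle scale table
#'
#' Convenience constructor for the `muscle_scale` argument of
#' [sim_config()]: rows for the given muscles/sides/conditions with the
#' given factors, recycled against each other.
#'
#' @param muscle,side,condition,scale vectors recycled to a common length.
#' @return a data frame usable as `sim_config(muscle_scale = )`.
#' @export
muscle_scale_table <- function(muscle, side, condition, scale) {
  data.frame(muscle = muscle, side = side, condition = condition,
             scale = scale, stringsAsFactors = FALSE)
}

## Look up the amplitude factor for one channel of one trial.
## LS/NLS rows are resolved against the horse's induced side.
resolve_muscle_scale <- function(config, muscle, side, condition, induced_side) {
  tab <- config$muscle_scale
  if (is.null(tab) || nrow(tab) == 0) return(1)
  ls_side <- if (induced_side %in% SIDES) induced_side else "left"
  nls_side <- setdiff(SIDES, ls_side)
  side_resolved <- vapply(tab$side, function(s) {
    switch(s, LS = ls_side, NLS = nls_side, s)
  }, character(1))
  hit <- tab$muscle == muscle & tab$condition == condition &
    (side_resolved == side | tab$side == "both")
  if (!any(hit)) return(1)
  prod(tab$scale[hit])
}
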