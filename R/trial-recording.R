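#' Trial recording container
#'
#' A `trial_recording` holds one trot trial: synchronized vertical
#' displacement channels (mm, positive up, sampled at `kin_sampling_hz`)
#' and bilateral sEMG channels (arbitrary units, `emg_sampling_hz`),
#' sharing the time origin `t0` (hardware-synchronized streams).
#'
#' @param horse_id character label.
#' @param condition one of `baseline1`, `iFL`, `baseline2`, `iHL`.
#' @param induced_side `left`, `right` or `none`.
#' @param kin named list of numeric vertical-displacement series; must
#'   contain `poll`, `withers`, `pelvis`, `tuber_coxae_left/right`,
#'   `hoof_hind_left/right`, all of equal length.
#' @param emg named list of numeric sEMG series, names `"<muscle>_<side>"`,
#'   all of equal length.
#' @param kin_sampling_hz,emg_sampling_hz sampling rates (Hz).
#' @param t0 shared time of the first sample (s).
#' @return an object of class `trial_recording`.
#' @export
trial_recording <- function(horse_id, condition, induced_side,
                            kin, emg, kin_sampling_hz, emg_sampling_hz,
                            t0 = 0) {
  rec <- structure(list(
    horse_id = as.character(horse_id),
    condition = condition,
    induced_side = induced_side,
    kin = kin,
    emg = emg,
    kin_sampling_hz = kin_sampling_hz,
    emg_sampling_hz = emg_sampling_hz,
    t0 = t0
  ), class = "trial_recording")
  validate_trial_recording(rec)
}

#' @rdname trial_recording
#' @param rec object to validate.
#' @export
validate_trial_recording <- function(rec) {
  fail <- function(msg) stop("invalid trial_recording: ", msg, call. = FALSE)
  if (!rec$condition %in% CONDITIONS)
    fail(sprintf("unknown condition '%s'", rec$condition))
  if (!rec$induced_side %in% c(SIDES, "none"))
    fail(sprintf("unknown induced_side '%s'", rec$induced_side))
  if (length(rec$kin) == 0 || length(rec$emg) == 0)
    fail("empty channel map")
  missing_lm <- setdiff(REQUIRED_LANDMARKS, names(rec$kin))
  if (length(missing_lm))
    fail(sprintf("missing kinematic channel(s): %s",
                 paste(missing_lm, collapse = ", ")))
  if (length(unique(lengths(rec$kin))) != 1)
    fail("kinematic series lengths differ")
  if (length(unique(lengths(rec$emg))) != 1)
    fail("sEMG series lengths differ")
  valid_emg <- as.vector(outer(MUSCLES, SIDES, emg_channel_name))
  bad <- setdiff(names(rec$emg), valid_emg)
  if (length(bad))
    fail(sprintf("unknown sEMG channel(s): %s", paste(bad, collapse = ", ")))
  if (rec$kin_sampling_hz <= 0 || rec$emg_sampling_hz <= 0)
    fail("sampling rates must be positive")
  invisible(rec)
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf("<trial_recording> horse %s, %s (induced side: %s)\n",
              x$horse_id, x$condition, x$induced_side))
  cat(sprintf("  kinematics: %d channels x %d samples @ %g Hz\n",
              length(x$kin), length(x$kin[[1]]), x$kin_sampling_hz))
  cat(sprintf("  sEMG:       %d channels x %d samples @ %g Hz\n",
              length(x$emg), length(x$emg[[1]]), x$emg_sampling_hz))
  invisible(x)
}

## Time vectors for the two streams.
kin_time <- function(rec) rec$t0 + (seq_along(rec$kin[[1]]) - 1) / rec$kin_sampling_hz
emg_time <- function(rec) rec$t0 + (seq_along(rec$emg[[1]]) - 1) / rec$emg_sampling_hz
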