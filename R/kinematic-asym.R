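#' Per-stride minimum and maximum difference
#'
#' For one stride of high-pass-filtered vertical displacement (two minima
#' and two maxima per stride at trot), MinDiff is the minimum reached in
#' the first half-stride minus the minimum in the second half-stride, and
#' MaxDiff the analogue for maxima; halves are split at the stride's time
#' midpoint. Positive values mean the first (left-hindlimb-referenced)
#' half carries the larger value. A stride whose half-extrema sit on a
#' half-window boundary lacks the biphasic double oscillation and is
#' flagged invalid.
#'
#' @param stride_series filtered displacement samples of one
#'   left-referenced stride (mm).
#' @return list with `min_diff`, `max_diff` (mm) and `valid`.
#' @export
min_max_diff <- function(stride_series) {
  n <- length(stride_series)
  if (n < 8)
    return(list(min_diff = NA_real_, max_diff = NA_real_, valid = FALSE))
  half <- floor(n / 2)
  first <- stride_series[seq_len(half)]
  second <- stride_series[(half + 1):n]
  interior <- function(idx, len) idx > 1 && idx < len
  i_min1 <- which.min(first); i_min2 <- which.min(second)
  i_max1 <- which.max(first); i_max2 <- which.max(second)
  valid <- interior(i_min1, half) && interior(i_min2, n - half) &&
    interior(i_max1, half) && interior(i_max2, n - half)
  if (!valid)
    return(list(min_diff = NA_real_, max_diff = NA_real_, valid = FALSE))
  list(min_diff = min(first) - min(second),
       max_diff = max(first) - max(second),
       valid = TRUE)
}

#' Hip hike within one stride
#'
#' Vertical movement amplitude (max minus min) of each tuber coxae within
#' that limb's stance and swing windows, differenced left minus right.
#' With only hind impact events available, a limb's stance window is
#' approximated by the interval from its own impact to the contralateral
#' impact, and its swing window by the remainder of the stride.
#'
#' @param left_tc,right_tc filtered tuber coxae series (mm).
#' @param sampling_hz sampling rate (Hz).
#' @param stride one row of a stride table (left-referenced).
#' @param events a `gait_events` object (for the contralateral impact).
#' @param t0 time of the first sample (s).
#' @return list with `hip_hike_stance`, `hip_hike_swing` (mm) and `valid`.
#' @export
hip_hike <- function(left_tc, right_tc, sampling_hz, stride, events, t0 = 0) {
  if (is.null(left_tc) || is.null(right_tc))
    stop("missing tuber coxae channel", call. = FALSE)
  t <- t0 + (seq_along(left_tc) - 1) / sampling_hz
  tr <- events$impacts_right[events$impacts_right > stride$start &
                             events$impacts_right < stride$end]
  if (length(tr) != 1)
    return(list(hip_hike_stance = NA_real_, hip_hike_swing = NA_real_,
                valid = FALSE))
  amp <- function(y, lo, hi) {
    w <- y[t >= lo & t < hi]
    if (length(w) < 3) return(NA_real_)
    max(w) - min(w)
  }
  l_stance <- amp(left_tc, stride$start, tr)   # left on ground until right lands
  l_swing <- amp(left_tc, tr, stride$end)
  r_stance <- amp(right_tc, tr, stride$end)
  r_swing <- amp(right_tc, stride$start, tr)
  hs <- l_stance - r_stance
  hw <- l_swing - r_swing
  list(hip_hike_stance = hs, hip_hike_swing = hw,
       valid = is.finite(hs) && is.finite(hw))
}

#' Stride-level upper-body asymmetry table for one trial
#'
#' Runs the kinematic chain on one trial: adaptive high-pass on the poll,
#' withers, pelvis and tuber coxae channels (cut-off adapted to the trial's
#' stride frequency), left-referenced stride segmentation, then per-stride
#' MinDiff/MaxDiff for the three upper-body landmarks and stance/swing hip
#' hike. Strides missing the biphasic extremum structure are dropped and
#' counted.
#'
#' @param rec a [trial_recording()].
#' @param events optional precomputed `gait_events` (detected from the hoof
#'   channels when `NULL`).
#' @param cutoff_factor passed to [adaptive_highpass()].
#' @return data frame of class `stride_asymmetry`, one row per valid
#'   stride, with attribute `n_invalid`.
#' @export
stride_asymmetry <- function(rec, events = NULL, cutoff_factor = 0.5) {
  validate_trial_recording(rec)
  if (is.null(events)) events <- detect_hind_impacts(rec)
  strides <- segment_strides(events, "left")
  f <- stride_frequency(strides)
  t <- kin_time(rec)
  filt <- lapply(rec$kin[c(ASYM_LANDMARKS, "tuber_coxae_left", "tuber_coxae_right")],
                 adaptive_highpass, sampling_hz = rec$kin_sampling_hz,
                 stride_freq = f, cutoff_factor = cutoff_factor)
  rows <- vector("list", nrow(strides))
  n_invalid <- 0L
  for (k in seq_len(nrow(strides))) {
    st <- strides[k, ]
    in_stride <- t >= st$start & t < st$end
    row <- list(horse_id = rec$horse_id, condition = rec$condition,
                induced_side = rec$induced_side, stride = st$index)
    ok <- TRUE
    for (lm in ASYM_LANDMARKS) {
      mm <- min_max_diff(filt[[lm]][in_stride])
      row[[paste0("min_diff_", lm)]] <- mm$min_diff
      row[[paste0("max_diff_", lm)]] <- mm$max_diff
      ok <- ok && mm$valid
    }
    hh <- hip_hike(filt$tuber_coxae_left, filt$tuber_coxae_right,
                   rec$kin_sampling_hz, st, events, t0 = rec$t0)
    row$hip_hike_stance <- hh$hip_hike_stance
    row$hip_hike_swing <- hh$hip_hike_swing
    ok <- ok && hh$valid
    if (ok) rows[[k]] <- as.data.frame(row) else n_invalid <- n_invalid + 1L
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) stop("no valid strides in trial", call. = FALSE)
  if (n_invalid > 0)
    message(sprintf("stride_asymmetry: dropped %d invalid stride(s) for %s/%s",
                    n_invalid, rec$horse_id, rec$condition))
  attr(out, "n_invalid") <- n_invalid
  class(out) <- c("stride_asymmetry", "data.frame")
  out
}

#' Induction sufficiency check
#'
#' A forelimb induction counts as sufficient when the absolute difference
#' in mean head asymmetry between induced and baseline strides reaches
#' 13 mm on MinDiff Poll or MaxDiff Poll; a hindlimb induction when the
#' pelvic difference reaches 5 mm on MinDiff and/or MaxDiff Pelvis. In
#' addition the triggering parameter must be consistent across induced
#' strides: its standard deviation must be smaller than the absolute mean
#' in the induced condition.
#'
#' @param baseline,induced `stride_asymmetry` tables for the paired
#'   baseline and induced conditions.
#' @param limb `"fore"` or `"hind"`.
#' @param head_threshold_mm,pelvis_threshold_mm reference values (mm).
#' @return list of class `induction_check` with the per-parameter deltas,
#'   the SD check and the overall verdict.
#' @export
induction_sufficient <- function(baseline, induced, limb = c("fore", "hind"),
                                 head_threshold_mm = 13,
                                 pelvis_threshold_mm = 5) {
  limb <- match.arg(limb)
  if (nrow(baseline) < 2 || nrow(induced) < 2)
    stop("need >= 2 strides per condition", call. = FALSE)
  params <- if (limb == "fore") c("min_diff_poll", "max_diff_poll")
            else c("min_diff_pelvis", "max_diff_pelvis")
  threshold <- if (limb == "fore") head_threshold_mm else pelvis_threshold_mm
  detail <- do.call(rbind, lapply(params, function(p) {
    delta <- abs(mean(induced[[p]]) - mean(baseline[[p]]))
    sd_ok <- stats::sd(induced[[p]]) < abs(mean(induced[[p]]))
    data.frame(parameter = p, delta_mm = delta,
               exceeds = delta >= threshold, sd_ok = sd_ok)
  }))
  trigger <- detail$exceeds & detail$sd_ok
  sd_ok <- if (any(detail$exceeds)) any(detail$sd_ok[detail$exceeds])
           else all(detail$sd_ok)
  structure(list(
    limb = limb,
    threshold_mm = threshold,
    delta_mm = stats::setNames(detail$delta_mm, detail$parameter),
    sd_ok = sd_ok,
    sufficient = any(trigger),
    detail = detail
  ), class = "induction_check")
}

#' @export
print.induction_check <- function(x, ...) {
  cat(sprintf("<induction_check> %slimb: %s\n", x$limb,
              if (x$sufficient) "SUFFICIENT" else "insufficient"))
  print(x$detail, row.names = FALSE)
  invisible(x)
}
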