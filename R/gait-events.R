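#' Detect hindlimb impact events from hoof height
#'
#' Impact (ground contact) is taken as the downward crossing of a height
#' threshold set at 10% of the channel's range above its per-trial minimum,
#' with negative vertical velocity at the crossing. Candidate crossings are
#' debounced with a refractory window of 60% of the expected stride period
#' (median spacing of the raw crossings), and a crossing only counts as an
#' impact if it is followed by an actual stance (the hoof stays below the
#' threshold for at least a tenth of a stride period), so a trial truncated
#' mid-descent does not emit a final spurious event.
#'
#' @param rec a [trial_recording()] with `hoof_hind_left/right` channels.
#' @return list of class `gait_events` with numeric vectors `impacts_left`
#'   and `impacts_right` (seconds, strictly increasing).
#' @export
detect_hind_impacts <- function(rec) {
  validate_trial_recording(rec)
  t <- kin_time(rec)
  ev <- lapply(c(left = "hoof_hind_left", right = "hoof_hind_right"),
               function(ch) detect_impacts_1d(rec$kin[[ch]], t))
  for (side in names(ev)) {
    if (length(ev[[side]]) < 3)
      stop(sprintf("insufficient data: only %d impact(s) detected on %s hind",
                   length(ev[[side]]), side), call. = FALSE)
  }
  structure(list(impacts_left = ev$left, impacts_right = ev$right),
            class = "gait_events")
}

detect_impacts_1d <- function(h, t) {
  rng <- range(h)
  if (diff(rng) < 1e-6) return(numeric(0))
  thr <- rng[1] + 0.10 * diff(rng)
  n <- length(h)
  cross <- which(h[-n] >= thr & h[-1] < thr) + 1L
  if (length(cross) == 0) return(numeric(0))
  dt <- t[2] - t[1]
  period <- if (length(cross) >= 2) stats::median(diff(t[cross])) else Inf
  if (!is.finite(period) || period <= 0) return(numeric(0))
  ## debounce: keep first crossing, then only crossings > 60% period later
  kept <- cross[1]
  for (i in cross[-1]) {
    if (t[i] - t[kept[length(kept)]] > 0.6 * period) kept <- c(kept, i)
  }
  ## require a real stance to follow: hoof below threshold for >= 10% of a
  ## period after the crossing (drops a partial contact at the trial edge)
  stance_n <- max(2L, ceiling(0.1 * period / dt))
  ok <- vapply(kept, function(i) {
    j <- i:min(n, i + stance_n - 1L)
    length(j) == stance_n && all(h[j] < thr)
  }, logical(1))
  kept <- kept[ok]
  ## snap forward from the threshold crossing to touchdown: the first
  ## sample at stance level (2.5% of range above the minimum), searched
  ## within a fifth of a period
  lo <- rng[1] + 0.025 * diff(rng)
  snap_n <- ceiling(0.2 * period / dt)
  snapped <- vapply(kept, function(i) {
    j <- i:min(n, i + snap_n)
    hit <- j[h[j] < lo]
    if (length(hit)) hit[1] else i
  }, integer(1))
  t[snapped]
}

#' Segment a trial into strides
#'
#' A stride is the half-open interval between two successive impacts of the
#' reference hindlimb: stride *k* = `[impact_k, impact_{k+1})`. A sample on
#' a boundary belongs to the later stride.
#'
#' @param events a `gait_events` object.
#' @param reference_limb `"left"` or `"right"`.
#' @return data frame with columns `index`, `start`, `end`,
#'   `reference_limb` (class `stride_table`).
#' @export
segment_strides <- function(events, reference_limb = c("left", "right")) {
  reference_limb <- match.arg(reference_limb)
  imp <- events[[paste0("impacts_", reference_limb)]]
  if (length(imp) < 2)
    stop("insufficient data: need >= 2 impacts on the ", reference_limb,
         " hind to segment strides", call. = FALSE)
  if (any(diff(imp) <= 0)) stop("impact times must be strictly increasing")
  n <- length(imp) - 1L
  structure(data.frame(index = seq_len(n), start = imp[-length(imp)],
                       end = imp[-1], reference_limb = reference_limb),
            class = c("stride_table", "data.frame"))
}

#' Stride frequency of a segmented trial
#'
#' Reciprocal of the median stride duration, in strides per second. Drives
#' the adaptive cut-off of the kinematic high-pass filter.
#'
#' @param strides a stride table from [segment_strides()].
#' @return positive scalar (strides/s).
#' @export
stride_frequency <- function(strides) {
  if (is.null(strides) || nrow(strides) < 1)
    stop("insufficient data: no strides", call. = FALSE)
  1 / stats::median(strides$end - strides$start)
}
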