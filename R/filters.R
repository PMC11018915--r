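## Zero-phase Butterworth filtering for both streams. Filters are designed
## at 4th order and applied forward-backward (signal::filtfilt), so the
## effective magnitude response is the squared 4th-order response and no
## phase lag is introduced into stride-locked quantities.

butter_highpass_filtfilt <- function(x, sampling_hz, cutoff_hz) {
  nyq <- sampling_hz / 2
  if (cutoff_hz <= 0) stop("cut-off must be positive", call. = FALSE)
  if (cutoff_hz >= nyq)
    stop(sprintf("cut-off %.3g Hz is at or above Nyquist (%.3g Hz)",
                 cutoff_hz, nyq), call. = FALSE)
  bf <- signal::butter(4, cutoff_hz / nyq, type = "high")
  n <- length(x)
  if (n < 12 * length(bf$b))
    stop("series shorter than filter warm-up", call. = FALSE)
  ## centre and odd-reflect both ends (continuous value and slope) before
  ## the forward-backward pass, so the filter start-up transient lands in
  ## the padding, not in the data
  mu <- mean(x)
  xc <- x - mu
  len <- min(n - 1, ceiling(3 * sampling_hz / cutoff_hz))
  ext <- c(2 * xc[1] - xc[(len + 1):2], xc, 2 * xc[n] - xc[(n - 1):(n - len)])
  y <- as.numeric(signal::filtfilt(bf, ext))
  y[(len + 1):(len + n)]
}

#' Stride-adaptive high-pass for kinematic displacement
#'
#' Removes inter-stride drift and DC offset from an upper-body vertical
#' displacement series with a zero-phase 4th-order Butterworth high-pass
#' whose cut-off adapts to the trial's stride frequency
#' (`cutoff_factor * stride_freq`). The default factor 0.5 places the
#' cut-off well below both the stride-frequency asymmetry component (1f)
#' and the double oscillation (2f) of trot, so both pass essentially
#' unattenuated while drift is removed.
#'
#' @param series displacement series (mm).
#' @param sampling_hz sampling rate (Hz).
#' @param stride_freq stride frequency (strides/s).
#' @param cutoff_factor multiple of the stride frequency used as cut-off.
#' @return filtered series (mm), mean approximately zero.
#' @export
adaptive_highpass <- function(series, sampling_hz, stride_freq,
                              cutoff_factor = 0.5) {
  if (stride_freq <= 0) stop("stride_freq must be positive", call. = FALSE)
  butter_highpass_filtfilt(series, sampling_hz, cutoff_factor * stride_freq)
}

#' Condition a raw sEMG channel
#'
#' DC-offset removal (subtract the series mean), zero-phase 4th-order
#' Butterworth high-pass at `cutoff_hz` (default 40 Hz, removing motion
#' artefact below the sEMG band), then full-wave rectification.
#'
#' @param raw voltage series (arbitrary units).
#' @param sampling_hz sampling rate (Hz); must exceed twice the cut-off.
#' @param cutoff_hz high-pass cut-off (Hz).
#' @return non-negative rectified series, same length as input.
#' @export
preprocess_emg <- function(raw, sampling_hz, cutoff_hz = 40) {
  if (sampling_hz <= 2 * cutoff_hz)
    stop("sampling rate must exceed twice the sEMG cut-off", call. = FALSE)
  abs(butter_highpass_filtfilt(raw - mean(raw), sampling_hz, cutoff_hz))
}
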