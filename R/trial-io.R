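## On-disk dialect: one trial = two comma-separated files sharing a stem,
##   <stem>_kin.csv  kinematic stream (mm, one column per landmark)
##   <stem>_emg.csv  sEMG stream (one column per muscle_side channel)
## each opened by a '#'-prefixed header block declaring horse, condition,
## induced side, sampling rate, t0 and units. Plain text so fixtures stay
## inspectable; column order is fixed alphabetically for determinism.

trial_paths <- function(stem) {
  list(kin = paste0(stem, "_kin.csv"), emg = paste0(stem, "_emg.csv"))
}

write_stream <- function(path, header, channels) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(header))
    writeLines(sprintf("# %s: %s", k, header[[k]]), con)
  ord <- sort(names(channels))
  df <- as.data.frame(channels[ord], check.names = FALSE)
  df[] <- lapply(df, function(col) sprintf("%.17g", col))  # lossless doubles
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  path
}

read_stream <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, n = 50)
  hdr_lines <- grep("^#", lines, value = TRUE)
  header <- list()
  for (l in hdr_lines) {
    m <- regmatches(l, regexec("^#\\s*([^:]+):\\s*(.*)$", l))[[1]]
    if (length(m) == 3) header[[trimws(m[2])]] <- trimws(m[3])
  }
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (nrow(df) == 0) stop("format error: no samples in ", path, call. = FALSE)
  list(header = header, channels = as.list(df))
}

#' Write a trial recording to disk
#'
#' Serializes a [trial_recording()] as two plain CSV files (`<stem>_kin.csv`
#' and `<stem>_emg.csv`) with `#`-prefixed header blocks carrying the
#' metadata. Values round-trip through [read_trial()] to full double
#' precision.
#'
#' @param rec a `trial_recording`.
#' @param stem path stem (no extension); directory must exist.
#' @param overwrite overwrite existing files? Default `FALSE` errors if
#'   either target exists.
#' @return the stem, invisibly.
#' @export
write_trial <- function(rec, stem, overwrite = FALSE) {
  validate_trial_recording(rec)
  p <- trial_paths(stem)
  if (!overwrite && any(file.exists(unlist(p))))
    stop("trial files exist at stem '", stem, "' (use overwrite = TRUE)",
         call. = FALSE)
  meta <- list(horse_id = rec$horse_id, condition = rec$condition,
               induced_side = rec$induced_side, t0 = format(rec$t0, digits = 17))
  write_stream(p$kin, c(meta, list(sampling_hz = format(rec$kin_sampling_hz, digits = 17),
                                   units = "mm")), rec$kin)
  write_stream(p$emg, c(meta, list(sampling_hz = format(rec$emg_sampling_hz, digits = 17),
                                   units = "au")), rec$emg)
  invisible(stem)
}

#' Read a trial recording from disk
#'
#' Counterpart of [write_trial()]: loads the kinematic and sEMG streams at
#' a path stem and returns a validated [trial_recording()].
#'
#' @param stem path stem used when writing.
#' @return a `trial_recording`.
#' @export
read_trial <- function(stem) {
  p <- trial_paths(stem)
  kin <- read_stream(p$kin)
  emg <- read_stream(p$emg)
  need <- c("horse_id", "condition", "induced_side", "sampling_hz", "t0")
  for (k in need) {
    if (is.null(kin$header[[k]]))
      stop("format error: header key '", k, "' missing in ", p$kin, call. = FALSE)
  }
  if (!kin$header$condition %in% CONDITIONS)
    stop("format error: unknown condition label '", kin$header$condition, "'",
         call. = FALSE)
  trial_recording(
    horse_id = kin$header$horse_id,
    condition = kin$header$condition,
    induced_side = kin$header$induced_side,
    kin = lapply(kin$channels, as.numeric),
    emg = lapply(emg$channels, as.numeric),
    kin_sampling_hz = as.numeric(kin$header$sampling_hz),
    emg_sampling_hz = as.numeric(emg$header$sampling_hz),
    t0 = as.numeric(kin$header$t0))
}

#' Write / read generator ground truth
#'
#' Sidecar key-value file (`<stem>_truth.txt`) holding what the simulator
#' injected into one trial: stride frequency, true impact times per limb,
#' per-channel amplitude factors, and the realized asymmetry.
#'
#' @param truth the `truth` element returned by [generate_trial()].
#' @param stem path stem shared with [write_trial()].
#' @return the stem (write) or a truth list (read).
#' @export
write_ground_truth <- function(truth, stem) {
  path <- paste0(stem, "_truth.txt")
  num <- function(x) paste(format(x, digits = 17), collapse = ",")
  lines <- c(
    sprintf("stride_frequency_hz: %s", num(truth$stride_frequency_hz)),
    sprintf("induced_side: %s", truth$induced_side),
    sprintf("impacts_left: %s", num(truth$impacts_left)),
    sprintf("impacts_right: %s", num(truth$impacts_right)),
    sprintf("injected_asymmetry_mm: %s", num(truth$injected_asymmetry_mm)),
    sprintf("muscle_scales: %s",
            paste(sprintf("%s_%s_%s=%s", truth$muscle_scales$muscle,
                          truth$muscle_scales$side, truth$muscle_scales$condition,
                          format(truth$muscle_scales$scale, digits = 17)),
                  collapse = ",")))
  writeLines(lines, path)
  invisible(stem)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(stem) {
  path <- paste0(stem, "_truth.txt")
  lines <- readLines(path)
  kv <- list()
  for (l in lines) {
    m <- regmatches(l, regexec("^([^:]+):\\s*(.*)$", l))[[1]]
    kv[[trimws(m[2])]] <- trimws(m[3])
  }
  nums <- function(x) as.numeric(strsplit(x, ",")[[1]])
  sc <- strsplit(strsplit(kv$muscle_scales, ",")[[1]], "=")
  parts <- strsplit(vapply(sc, `[`, "", 1), "_(?=left|right)|_(?=baseline|iFL|iHL)",
                    perl = TRUE)
  list(stride_frequency_hz = nums(kv$stride_frequency_hz),
       induced_side = kv$induced_side,
       impacts_left = nums(kv$impacts_left),
       impacts_right = nums(kv$impacts_right),
       injected_asymmetry_mm = nums(kv$injected_asymmetry_mm),
       muscle_scales = data.frame(
         muscle = vapply(parts, `[`, "", 1),
         side = vapply(parts, `[`, "", 2),
         condition = vapply(parts, `[`, "", 3),
         scale = as.numeric(vapply(sc, `[`, "", 2))))
}
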