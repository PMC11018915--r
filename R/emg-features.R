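#' Average rectified value over one stride
#'
#' Arithmetic mean of a rectified sEMG series over the half-open stride
#' window `[start, end)` — the stride duration is the temporal domain.
#'
#' @param rectified non-negative series from [preprocess_emg()].
#' @param stride one row of a stride table.
#' @param sampling_hz sampling rate (Hz).
#' @param t0 time of the first sample (s).
#' @return scalar ARV (signal units).
#' @export
stride_arv <- function(rectified, stride, sampling_hz, t0 = 0) {
  t <- t0 + (seq_along(rectified) - 1) / sampling_hz
  w <- rectified[t >= stride$start & t < stride$end]
  if (length(w) == 0) stop("empty stride window", call. = FALSE)
  mean(w)
}

#' Per-stride ARV table for one trial
#'
#' Conditions every sEMG channel ([preprocess_emg()]) and computes the ARV
#' per stride under the requested stride-reference convention:
#' `"ipsilateral"` segments each side's muscles on that side's own hind
#' impacts (the convention for the absolute parameter), `"left"` segments
#' both sides on left hind impacts so the two sides share a temporal
#' domain (the convention for the asymmetry parameter).
#'
#' @param rec a [trial_recording()].
#' @param events optional precomputed `gait_events`.
#' @param reference `"ipsilateral"` or `"left"`.
#' @param cutoff_hz sEMG high-pass cut-off (Hz).
#' @return data frame with columns `horse_id`, `muscle`, `side`,
#'   `condition`, `stride`, `arv_raw`, `reference`.
#' @export
trial_arv <- function(rec, events = NULL, reference = c("ipsilateral", "left"),
                      cutoff_hz = 40) {
  validate_trial_recording(rec)
  reference <- match.arg(reference)
  if (is.null(events)) events <- detect_hind_impacts(rec)
  strides <- list(left = segment_strides(events, "left"),
                  right = segment_strides(events, "right"))
  rows <- list()
  for (ch in names(rec$emg)) {
    side <- sub(".*_", "", ch)
    muscle <- sub("_(left|right)$", "", ch)
    ref_limb <- if (reference == "ipsilateral") side else "left"
    st <- strides[[ref_limb]]
    rect <- preprocess_emg(rec$emg[[ch]], rec$emg_sampling_hz, cutoff_hz)
    arv <- vapply(seq_len(nrow(st)), function(k)
      stride_arv(rect, st[k, ], rec$emg_sampling_hz, t0 = rec$t0), numeric(1))
    rows[[ch]] <- data.frame(horse_id = rec$horse_id, muscle = muscle,
                             side = side, condition = rec$condition,
                             stride = st$index, arv_raw = arv,
                             reference = reference)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

arv_group_key <- function(records)
  interaction(records$horse_id, records$muscle, records$side,
              records$condition, records$reference, drop = TRUE)

#' Remove ARV outliers
#'
#' Single-pass removal within each horse x muscle x side x condition group:
#' limits are the group mean plus/minus `sd_multiplier` sample standard
#' deviations, computed on the group *before* any removal. Groups smaller
#' than 3 are kept untouched with a warning.
#'
#' @param records ARV table from [trial_arv()] (rows from several trials
#'   may be concatenated).
#' @param sd_multiplier outlier limit width in standard deviations.
#' @return list with data frames `kept` and `removed`.
#' @export
remove_arv_outliers <- function(records, sd_multiplier = 2) {
  if (sd_multiplier <= 0) stop("sd_multiplier must be positive", call. = FALSE)
  key <- arv_group_key(records)
  keep <- logical(nrow(records))
  for (g in levels(key)) {
    idx <- which(key == g)
    x <- records$arv_raw[idx]
    if (length(idx) < 3) {
      warning("ARV group ", g, " has fewer than 3 strides; no outlier removal")
      keep[idx] <- TRUE
      next
    }
    m <- mean(x); s <- stats::sd(x)
    keep[idx] <- x >= m - sd_multiplier * s & x <= m + sd_multiplier * s
  }
  n_removed <- sum(!keep)
  if (n_removed > 0)
    message(sprintf("remove_arv_outliers: removed %d of %d ARV record(s)",
                    n_removed, nrow(records)))
  list(kept = records[keep, , drop = FALSE],
       removed = records[!keep, , drop = FALSE])
}

#' Normalize ARV to the baseline maximum
#'
#' Within each horse x muscle x side and session, ARVs are expressed as a
#' percentage of the maximum ARV observed across all (outlier-surviving)
#' strides of the session's baseline condition: `baseline1` for itself and
#' `iFL`, `baseline2` for itself and `iHL`. The baseline maximum thus maps
#' to 100%, and induced-condition values may exceed 100%.
#'
#' @param records ARV table (one or more horses) with outliers already
#'   removed.
#' @return the table with an `arv_norm` column (percent) added.
#' @export
normalize_to_baseline_max <- function(records) {
  session_of <- c(baseline1 = "day1", iFL = "day1",
                  baseline2 = "day2", iHL = "day2")
  records$arv_norm <- NA_real_
  grp <- interaction(records$horse_id, records$muscle, records$side,
                     records$reference, session_of[records$condition],
                     drop = TRUE)
  for (g in levels(grp)) {
    idx <- which(grp == g)
    base <- idx[records$condition[idx] %in% c("baseline1", "baseline2")]
    if (length(base) == 0)
      stop("missing baseline strides for group ", g, call. = FALSE)
    ref_max <- max(records$arv_raw[base])
    if (!is.finite(ref_max) || ref_max <= 0)
      stop("degenerate (non-positive) baseline ARV maximum for group ", g,
           call. = FALSE)
    records$arv_norm[idx] <- 100 * records$arv_raw[idx] / ref_max
  }
  records
}

param_class <- function(condition)
  ifelse(condition %in% c("iFL", "iHL"), "lame", "baseline")

#' Absolute sEMG parameter samples (sEMGabs)
#'
#' One sample per stride per muscle and side: the baseline-normalized ARV
#' itself, taken from records segmented on ipsilateral hind impacts.
#'
#' @param records normalized ARV table (`reference == "ipsilateral"`).
#' @return parameter-sample data frame (`family`, `muscle`, `side`,
#'   `horse_id`, `condition`, `class`, `stride`, `value`).
#' @export
semg_abs <- function(records) {
  if (is.null(records$arv_norm)) stop("records are not normalized", call. = FALSE)
  if (length(unique(records$reference)) != 1 ||
      records$reference[1] != "ipsilateral")
    stop("sEMGabs requires ipsilateral-referenced records", call. = FALSE)
  data.frame(family = "semg_abs", muscle = records$muscle, side = records$side,
             parameter = sprintf("sEMGabs %s %s", records$side, records$muscle),
             horse_id = records$horse_id, condition = records$condition,
             class = param_class(records$condition), stride = records$stride,
             value = records$arv_norm)
}

#' sEMG asymmetry parameter samples (sEMGasym)
#'
#' Left-side minus right-side normalized ARV within each left-referenced
#' stride, per muscle. Strides where either side is missing (e.g. removed
#' as an ARV outlier) are skipped and counted.
#'
#' @param records normalized ARV table (`reference == "left"`).
#' @return parameter-sample data frame (side is `NA`).
#' @export
semg_asym <- function(records) {
  if (is.null(records$arv_norm)) stop("records are not normalized", call. = FALSE)
  if (length(unique(records$reference)) != 1 || records$reference[1] != "left")
    stop("sEMGasym requires left-referenced records", call. = FALSE)
  left <- records[records$side == "left", ]
  right <- records[records$side == "right", ]
  merged <- merge(left, right,
                  by = c("horse_id", "muscle", "condition", "stride"),
                  suffixes = c("_l", "_r"))
  n_dropped <- (nrow(left) + nrow(right) - 2 * nrow(merged))
  if (n_dropped > 0)
    message(sprintf("semg_asym: skipped %d unpaired side record(s)", n_dropped))
  data.frame(family = "semg_asym", muscle = merged$muscle, side = NA_character_,
             parameter = sprintf("sEMGasym %s", merged$muscle),
             horse_id = merged$horse_id, condition = merged$condition,
             class = param_class(merged$condition), stride = merged$stride,
             value = merged$arv_norm_l - merged$arv_norm_r)
}
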