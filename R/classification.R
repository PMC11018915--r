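## Stride-level ROC analysis: mirroring to a common (left-induction) frame,
## ROC curves over midpoint thresholds, trapezoidal AUC, Youden-optimal
## cut-offs, and the per-induction results table.

KINEMATIC_PARAMS <- c(min_diff_poll = "MinDiff Poll",
                      min_diff_withers = "MinDiff Withers",
                      min_diff_pelvis = "MinDiff Pelvis",
                      max_diff_poll = "MaxDiff Poll",
                      max_diff_withers = "MaxDiff Withers",
                      max_diff_pelvis = "MaxDiff Pelvis",
                      hip_hike_stance = "Hip Hike Stance",
                      hip_hike_swing = "Hip Hike Swing")

## Classification direction fixed a priori per parameter family: absolute
## sEMG rises with lameness; signed asymmetry indices move negative under
## the left-induction sign convention. Never auto-selected, so AUC < 0.5
## is possible and reported as-is.
param_direction <- function(family)
  ifelse(family == "semg_abs", "greater", "lesser")

#' Convert a stride-asymmetry table to parameter samples
#'
#' Reshapes the per-stride MinDiff/MaxDiff/Hip-Hike columns of
#' [stride_asymmetry()] output into long parameter-sample form, one row
#' per stride per kinematic parameter.
#'
#' @param asym a `stride_asymmetry` data frame (rows from several trials
#'   may be concatenated).
#' @return parameter-sample data frame (`family`, `parameter`, `horse_id`,
#'   `condition`, `class`, `stride`, `value`).
#' @export
kinematic_samples <- function(asym) {
  out <- lapply(names(KINEMATIC_PARAMS), function(col) {
    data.frame(family = "kinematic", muscle = NA_character_,
               side = NA_character_, parameter = KINEMATIC_PARAMS[[col]],
               horse_id = asym$horse_id, condition = asym$condition,
               class = param_class(asym$condition), stride = asym$stride,
               value = asym[[col]])
  })
  do.call(rbind, out)
}

#' Mirror parameter samples to the left-induction frame
#'
#' For a horse whose lameness was induced on the right, signed asymmetry
#' values (kinematic parameters and sEMGasym) are multiplied by -1 and the
#' side labels of sEMGabs samples are swapped, so all data read as if the
#' induction were on the left. With `relabel = TRUE` sides are then renamed
#' LS (ipsilateral to the induction) / NLS (contralateral); left-induction
#' samples pass through unchanged apart from that relabelling. Without
#' relabelling the operation is an involution.
#'
#' @param samples parameter-sample data frame for one horse.
#' @param induced_side `"left"` or `"right"` (the horse's induction side).
#' @param relabel rename sides to LS/NLS after mirroring?
#' @return the mirrored parameter-sample data frame.
#' @export
mirror_parameters <- function(samples, induced_side, relabel = TRUE) {
  if (!induced_side %in% SIDES) {
    if (any(samples$class == "lame"))
      stop("induced_side must be left or right for lame samples", call. = FALSE)
    induced_side <- "left"
  }
  if (induced_side == "right") {
    signed <- samples$family %in% c("kinematic", "semg_asym")
    samples$value[signed] <- -samples$value[signed]
    is_abs <- samples$family == "semg_abs"
    samples$side[is_abs] <- c(left = "right", right = "left")[samples$side[is_abs]]
  }
  if (relabel) {
    is_abs <- samples$family == "semg_abs"
    samples$side[is_abs] <- c(left = "LS", right = "NLS")[samples$side[is_abs]]
    samples$parameter[is_abs] <- sprintf("sEMGabs %s %s",
                                         samples$side[is_abs],
                                         samples$muscle[is_abs])
  }
  samples
}

#' ROC curve over midpoint thresholds
#'
#' Thresholds are the midpoints between consecutive distinct pooled sorted
#' values, plus -Inf/+Inf sentinels. With `direction = "greater"` a stride
#' is called lame when its value exceeds the threshold (absolute sEMG);
#' with `"lesser"` when it falls below (signed asymmetry indices).
#' Sensitivity is the fraction of lame strides called lame, specificity
#' the fraction of baseline strides called non-lame.
#'
#' @param baseline_values,lame_values numeric vectors (>= 2 each).
#' @param direction `"greater"` or `"lesser"`.
#' @return data frame with columns `threshold`, `sensitivity`,
#'   `specificity`, ordered from no-positives to all-positives.
#' @export
roc_curve <- function(baseline_values, lame_values,
                      direction = c("greater", "lesser")) {
  direction <- match.arg(direction)
  if (length(baseline_values) < 2 || length(lame_values) < 2)
    stop("need >= 2 values per class", call. = FALSE)
  if (anyNA(baseline_values) || anyNA(lame_values))
    stop("NA values in ROC input", call. = FALSE)
  v <- sort(unique(c(baseline_values, lame_values)))
  thr <- if (length(v) > 1) (v[-1] + v[-length(v)]) / 2 else numeric(0)
  thr <- c(-Inf, thr, Inf)
  if (direction == "greater") {
    sens <- vapply(thr, function(x) mean(lame_values > x), numeric(1))
    spec <- vapply(thr, function(x) mean(baseline_values <= x), numeric(1))
    ord <- order(-thr)
  } else {
    sens <- vapply(thr, function(x) mean(lame_values < x), numeric(1))
    spec <- vapply(thr, function(x) mean(baseline_values >= x), numeric(1))
    ord <- order(thr)
  }
  out <- data.frame(threshold = thr, sensitivity = sens,
                    specificity = spec)[ord, ]
  rownames(out) <- NULL
  attr(out, "direction") <- direction
  class(out) <- c("roc_points", "data.frame")
  out
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the (1 - specificity, sensitivity) curve built
#' by [roc_curve()]. Numerically identical to the Mann-Whitney
#' probability that a random lame stride scores beyond a random baseline
#' stride, with ties counted half.
#'
#' @inheritParams roc_curve
#' @return scalar in `[0, 1]`.
#' @export
roc_auc <- function(baseline_values, lame_values,
                    direction = c("greater", "lesser")) {
  roc <- roc_curve(baseline_values, lame_values, direction)
  x <- 1 - roc$specificity
  y <- roc$sensitivity
  ord <- order(x, y)
  x <- x[ord]; y <- y[ord]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Youden-optimal operating point
#'
#' The threshold maximizing J = sensitivity + specificity - 1. Ties are
#' broken in favour of higher specificity, then smaller `|threshold|`.
#'
#' @param roc output of [roc_curve()].
#' @return list with `cutoff`, `sensitivity`, `specificity`, `j`.
#' @export
youden_optimal <- function(roc) {
  if (nrow(roc) == 0) stop("empty ROC curve", call. = FALSE)
  j <- roc$sensitivity + roc$specificity - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[order(-roc$specificity[best], abs(roc$threshold[best]))]
  i <- best[1]
  list(cutoff = roc$threshold[i], sensitivity = roc$sensitivity[i],
       specificity = roc$specificity[i], j = j[i])
}

#' Interpretation band for an AUC
#'
#' Bands: excellent (AUC >= 0.90), good (0.90 > AUC >= 0.80), fair
#' (0.80 > AUC >= 0.70), poor (0.70 > AUC >= 0.60); anything below 0.60 —
#' including below-chance AUCs, which the fixed classification direction
#' can produce — is labelled discrimination no better than chance.
#'
#' @param auc scalar in `[0, 1]`.
#' @return one of `"excellent"`, `"good"`, `"fair"`, `"poor"`, `"chance"`.
#' @export
interpret_auc <- function(auc) {
  if (!is.finite(auc) || auc < 0 || auc > 1)
    stop("AUC must lie in [0, 1]", call. = FALSE)
  if (auc >= 0.90) "excellent"
  else if (auc >= 0.80) "good"
  else if (auc >= 0.70) "fair"
  else if (auc >= 0.60) "poor"
  else "chance"
}

#' Per-induction ROC results table
#'
#' One row per parameter and induction, pairing each induced condition
#' with its same-session baseline (`baseline1` with iFL, `baseline2` with
#' iHL): 14 sEMGabs rows (7 muscles x LS/NLS), 7 sEMGasym rows and 8
#' kinematic rows per induction. Strides are the classification unit,
#' pooled across horses. Input samples must already be mirrored to the
#' left-induction frame ([mirror_parameters()]).
#'
#' @param samples pooled, mirrored parameter-sample data frame.
#' @param inductions induced conditions to tabulate.
#' @return data frame with columns `parameter`, `family`, `induction`,
#'   `auc`, `sensitivity`, `specificity`, `cutoff`, `interpretation`,
#'   `direction`, `n_baseline`, `n_lame`.
#' @export
build_results_table <- function(samples, inductions = c("iFL", "iHL")) {
  if (!all(inductions %in% names(SESSION_PAIRING)))
    stop("unknown induction label", call. = FALSE)
  rows <- list()
  for (ind in inductions) {
    base_cond <- SESSION_PAIRING[[ind]]
    sub <- samples[samples$condition %in% c(base_cond, ind), ]
    if (nrow(sub) == 0)
      stop("no samples for pairing ", base_cond, "/", ind, call. = FALSE)
    specs <- parameter_specs(sub)
    for (k in seq_len(nrow(specs))) {
      sel <- sub$family == specs$family[k] &
        (is.na(specs$muscle[k]) | sub$muscle %in% specs$muscle[k]) &
        (is.na(specs$side[k]) | sub$side %in% specs$side[k]) &
        (specs$family[k] != "kinematic" | sub$parameter == specs$parameter[k])
      b <- sub$value[sel & sub$class == "baseline"]
      l <- sub$value[sel & sub$class == "lame"]
      if (length(b) < 2 || length(l) < 2)
        stop("missing class for parameter ", specs$parameter[k], call. = FALSE)
      dir <- param_direction(specs$family[k])
      roc <- roc_curve(b, l, dir)
      opt <- youden_optimal(roc)
      a <- roc_auc(b, l, dir)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = specs$parameter[k], family = specs$family[k],
        induction = ind, auc = a, sensitivity = opt$sensitivity,
        specificity = opt$specificity, cutoff = opt$cutoff,
        interpretation = interpret_auc(a), direction = dir,
        n_baseline = length(b), n_lame = length(l))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## Row plan mirroring the published table structure: sEMGabs by muscle and
## NLS/LS side, then sEMGasym by muscle, then the kinematic indices.
parameter_specs <- function(samples) {
  specs <- list()
  for (m in MUSCLES) {
    for (s in c("NLS", "LS")) {
      specs[[length(specs) + 1L]] <- data.frame(
        family = "semg_abs", muscle = m, side = s,
        parameter = sprintf("sEMGabs %s %s", s, m))
    }
  }
  for (m in MUSCLES) {
    specs[[length(specs) + 1L]] <- data.frame(
      family = "semg_asym", muscle = m, side = NA_character_,
      parameter = sprintf("sEMGasym %s", m))
  }
  for (p in unname(KINEMATIC_PARAMS)) {
    specs[[length(specs) + 1L]] <- data.frame(
      family = "kinematic", muscle = NA_character_, side = NA_character_,
      parameter = p)
  }
  specs <- do.call(rbind, specs)
  specs[specs$family %in% unique(samples$family), ]
}
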