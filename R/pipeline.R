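#' Pipeline run configuration
#'
#' Bundles every tunable of an end-to-end run. All method constants are
#' configuration defaults rather than hard-coded values: the 40 Hz sEMG
#' high-pass cut-off, the kinematic cut-off factor (0.5 x stride
#' frequency), the 2-SD ARV outlier limits, and the 13 mm head / 5 mm
#' pelvis induction-sufficiency thresholds.
#'
#' @param mode `"simulate"` (generate a synthetic cohort) or `"load"`
#'   (read trials previously written with [write_trial()]).
#' @param sim a [sim_config()] (simulate mode).
#' @param trial_stems character vector of path stems (load mode).
#' @param emg_cutoff_hz sEMG high-pass cut-off (Hz).
#' @param kin_cutoff_factor kinematic high-pass cut-off as a multiple of
#'   the stride frequency.
#' @param outlier_sd ARV outlier limit width (standard deviations).
#' @param head_threshold_mm,pelvis_threshold_mm induction-sufficiency
#'   reference values (mm).
#' @param output_dir optional directory for the results/induction tables.
#' @return an object of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "load"),
                       sim = sim_config(),
                       trial_stems = NULL,
                       emg_cutoff_hz = 40,
                       kin_cutoff_factor = 0.5,
                       outlier_sd = 2,
                       head_threshold_mm = 13,
                       pelvis_threshold_mm = 5,
                       output_dir = NULL) {
  mode <- match.arg(mode)
  if (emg_cutoff_hz <= 0 || kin_cutoff_factor <= 0 || outlier_sd <= 0 ||
      head_threshold_mm <= 0 || pelvis_threshold_mm <= 0)
    stop("run_config thresholds must be positive", call. = FALSE)
  if (mode == "load" && length(trial_stems) == 0)
    stop("load mode needs trial_stems", call. = FALSE)
  structure(list(mode = mode, sim = sim, trial_stems = trial_stems,
                 emg_cutoff_hz = emg_cutoff_hz,
                 kin_cutoff_factor = kin_cutoff_factor,
                 outlier_sd = outlier_sd,
                 head_threshold_mm = head_threshold_mm,
                 pelvis_threshold_mm = pelvis_threshold_mm,
                 output_dir = output_dir),
            class = "run_config")
}

#' Run the full stride-classification pipeline
#'
#' Simulates or loads a cohort, detects hind impacts, computes stride-level
#' kinematic asymmetry and per-stride normalized ARVs (with outlier
#' removal), checks induction sufficiency per horse, mirrors right-side
#' inductions into the left-induction frame, and assembles the per-induction
#' ROC results table. Deterministic given the simulation seed.
#'
#' An insufficient induction does not abort the ROC stage; it is flagged in
#' the induction report and a warning is raised.
#'
#' @param config a [run_config()].
#' @return list of class `emgait_run` with elements `results` (ROC table),
#'   `induction` (per-horse sufficiency report), `samples` (mirrored
#'   parameter samples), and `log` (per-stage counts).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop("config must be a run_config")
  trials <- switch(config$mode,
    simulate = generate_cohort(config$sim),
    load = lapply(config$trial_stems,
                  function(s) list(recording = read_trial(s), truth = NULL)))

  asym_all <- list(); arv_ipsi <- list(); arv_left <- list()
  induced_side_of <- list()
  n_strides <- 0L; n_invalid <- 0L
  for (tr in trials) {
    rec <- tr$recording
    events <- detect_hind_impacts(rec)
    asym <- stride_asymmetry(rec, events,
                             cutoff_factor = config$kin_cutoff_factor)
    n_strides <- n_strides + nrow(asym) + attr(asym, "n_invalid")
    n_invalid <- n_invalid + attr(asym, "n_invalid")
    asym_all[[length(asym_all) + 1L]] <- as.data.frame(asym)
    arv_ipsi[[length(arv_ipsi) + 1L]] <-
      trial_arv(rec, events, "ipsilateral", cutoff_hz = config$emg_cutoff_hz)
    arv_left[[length(arv_left) + 1L]] <-
      trial_arv(rec, events, "left", cutoff_hz = config$emg_cutoff_hz)
    if (rec$induced_side %in% SIDES)
      induced_side_of[[rec$horse_id]] <- rec$induced_side
  }
  asym_all <- do.call(rbind, asym_all)

  filt_ipsi <- remove_arv_outliers(do.call(rbind, arv_ipsi), config$outlier_sd)
  filt_left <- remove_arv_outliers(do.call(rbind, arv_left), config$outlier_sd)
  norm_ipsi <- normalize_to_baseline_max(filt_ipsi$kept)
  norm_left <- normalize_to_baseline_max(filt_left$kept)

  samples <- rbind(kinematic_samples(asym_all),
                   semg_abs(norm_ipsi),
                   semg_asym(norm_left))

  ## mirror each horse's samples according to its induction side
  mirrored <- lapply(split(samples, samples$horse_id), function(s) {
    side <- induced_side_of[[s$horse_id[1]]] %||% "left"
    mirror_parameters(s, side, relabel = TRUE)
  })
  samples <- do.call(rbind, unname(mirrored))

  ## per-horse induction sufficiency on the unmirrored asymmetry tables
  induction <- list()
  for (h in unique(asym_all$horse_id)) {
    for (ind in c("iFL", "iHL")) {
      base <- asym_all[asym_all$horse_id == h &
                       asym_all$condition == SESSION_PAIRING[[ind]], ]
      lame <- asym_all[asym_all$horse_id == h & asym_all$condition == ind, ]
      if (nrow(base) < 2 || nrow(lame) < 2) next
      chk <- induction_sufficient(base, lame,
                                  limb = if (ind == "iFL") "fore" else "hind",
                                  head_threshold_mm = config$head_threshold_mm,
                                  pelvis_threshold_mm = config$pelvis_threshold_mm)
      induction[[length(induction) + 1L]] <- data.frame(
        horse_id = h, induction = ind,
        delta_mm = max(chk$delta_mm), sd_ok = chk$sd_ok,
        sufficient = chk$sufficient)
    }
  }
  induction <- do.call(rbind, induction)
  if (!is.null(induction) && any(!induction$sufficient))
    warning(sprintf("%d of %d inductions below the sufficiency thresholds; ROC computed anyway",
                    sum(!induction$sufficient), nrow(induction)))

  results <- build_results_table(samples)

  log <- list(n_trials = length(trials),
              n_strides = n_strides,
              n_invalid_strides = n_invalid,
              n_arv_outliers_ipsilateral = nrow(filt_ipsi$removed),
              n_arv_outliers_left = nrow(filt_left$removed))
  message(sprintf("run_pipeline: %d trials, %d strides (%d invalid), %d/%d ARV outliers removed",
                  log$n_trials, log$n_strides, log$n_invalid_strides,
                  log$n_arv_outliers_ipsilateral, log$n_arv_outliers_left))

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(results, file.path(config$output_dir, "roc_results.csv"),
                     row.names = FALSE)
    if (!is.null(induction))
      utils::write.csv(induction, file.path(config$output_dir, "induction_report.csv"),
                       row.names = FALSE)
  }

  structure(list(results = results, induction = induction,
                 samples = samples, log = log),
            class = "emgait_run")
}

#' @export
print.emgait_run <- function(x, ...) {
  cat(sprintf("<emgait_run> %d trials, %d strides, %d parameter rows\n",
              x$log$n_trials, x$log$n_strides, nrow(x$results)))
  top <- x$results[order(-x$results$auc), ][1:min(5, nrow(x$results)), ]
  cat("top parameters by AUC:\n")
  print(top[, c("parameter", "induction", "auc", "interpretation")],
        row.names = FALSE)
  invisible(x)
}
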