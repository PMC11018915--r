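# Independent oracles and small fixtures shared across the suite.

# Closed-form magnitude response of an order-n Butterworth high-pass.
# Zero-phase (forward-backward) application squares this.
butter_hp_gain <- function(f, cutoff, order = 4) {
  1 / sqrt(1 + (cutoff / f)^(2 * order))
}

# All-pairs Mann-Whitney AUC: P(lame beyond baseline) + half-ties.
auc_bruteforce <- function(baseline, lame, direction = "greater") {
  wins <- 0
  for (b in baseline) {
    for (l in lame) {
      cmp <- if (direction == "greater") sign(l - b) else sign(b - l)
      wins <- wins + if (cmp > 0) 1 else if (cmp == 0) 0.5 else 0
    }
  }
  wins / (length(baseline) * length(lame))
}

# Exhaustive Youden search over all midpoint thresholds (direction "greater").
youden_bruteforce <- function(baseline, lame) {
  v <- sort(unique(c(baseline, lame)))
  thr <- c(-Inf, (v[-1] + v[-length(v)]) / 2, Inf)
  best <- -Inf
  for (x in thr) {
    j <- mean(lame > x) + mean(baseline <= x) - 1
    if (j > best) best <- j
  }
  best
}

# Small, fast simulation configs.
quick_config <- function(...) {
  sim_config(n_horses = 2, strides_per_trial = 8, seed = 101, ...)
}

# Mirror a trial's channels left <-> right (the physical mirroring of the
# input data: hoof, tuber coxae and sEMG sides swap).
mirror_trial <- function(rec) {
  swap <- function(nms) {
    out <- nms
    out[grepl("_left$", nms)] <- sub("_left$", "_right", nms[grepl("_left$", nms)])
    out[grepl("_right$", nms)] <- sub("_right$", "_left", nms[grepl("_right$", nms)])
    out
  }
  names(rec$kin) <- swap(names(rec$kin))
  names(rec$emg) <- swap(names(rec$emg))
  side <- rec$induced_side
  if (side %in% c("left", "right"))
    rec$induced_side <- setdiff(c("left", "right"), side)
  rec
}

# Swap the limb labels of a gait_events object.
mirror_events <- function(events) {
  structure(list(impacts_left = events$impacts_right,
                 impacts_right = events$impacts_left),
            class = "gait_events")
}

# Noise-free config on a sampling-commensurate stride frequency
# (1.5625 strides/s = 128 kinematic samples per stride), used where exact
# left-right antisymmetry is asserted.
noiseless_config <- function(...) {
  sim_config(n_horses = 1, strides_per_trial = 10,
             stride_frequency_hz = 1.5625,
             kin_noise_sd_mm = 0, drift_amplitude_mm = 0,
             seed = 77, ...)
}

# Random parameter-sample table for mirroring/involution properties.
random_samples <- function(n = 40, seed = 1) {
  set.seed(seed)
  fam <- sample(c("kinematic", "semg_abs", "semg_asym"), n, replace = TRUE)
  side <- ifelse(fam == "semg_abs",
                 sample(c("left", "right"), n, replace = TRUE), NA_character_)
  muscle <- ifelse(fam == "kinematic", NA_character_,
                   sample(c("triceps", "biceps", "gluteal"), n, TRUE))
  data.frame(family = fam, muscle = muscle, side = side,
             parameter = paste0("p", seq_len(n)),
             horse_id = "H01",
             condition = sample(c("baseline2", "iHL"), n, TRUE),
             class = NA, stride = seq_len(n),
             value = rnorm(n, sd = 10)) |>
    transform(class = ifelse(condition == "iHL", "lame", "baseline"))
}
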