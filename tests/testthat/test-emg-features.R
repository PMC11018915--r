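test_that("stride ARV matches closed forms", {
  fs <- 2000
  stride <- data.frame(index = 1, start = 0, end = 1, reference_limb = "left")
  # constant rectified signal
  expect_equal(stride_arv(rep(3.2, fs), stride, fs), 3.2)
  # rectified unit sinusoid over integer cycles: mean |sin| = 2/pi
  t <- (0:(fs - 1)) / fs
  expect_equal(stride_arv(abs(sin(2 * pi * 50 * t)), stride, fs), 2 / pi,
               tolerance = 0.005)
  # rectified Gaussian noise: half-normal mean = sigma * sqrt(2/pi)
  set.seed(12)
  sigma <- 1.7
  x <- abs(rnorm(1e5, sd = sigma))
  stride_long <- data.frame(index = 1, start = 0, end = 1e5 / fs,
                            reference_limb = "left")
  expect_equal(stride_arv(x, stride_long, fs), sigma * sqrt(2 / pi),
               tolerance = 0.02)
  expect_error(stride_arv(x, data.frame(start = 999, end = 1000), fs),
               "empty stride")
})

test_that("outlier limits are two sample SDs either side of the group mean", {
  rec <- data.frame(horse_id = "H01", muscle = "biceps", side = "left",
                    condition = "baseline1", stride = 1:11,
                    arv_raw = c(rep(1, 10), 5), reference = "ipsilateral")
  out <- suppressMessages(remove_arv_outliers(rec))
  expect_equal(nrow(out$kept), 10)
  expect_equal(out$removed$arv_raw, 5)
  # brute-force limits: mean 1.364, sample SD 1.206 -> [-1.05, 3.78]
  expect_equal(mean(rec$arv_raw) + 2 * sd(rec$arv_raw), 3.78, tolerance = 0.01)

  allsame <- transform(rec, arv_raw = 2)
  expect_equal(nrow(remove_arv_outliers(allsame)$kept), 11)

  tiny <- rec[1:2, ]
  expect_warning(out2 <- remove_arv_outliers(tiny), "fewer than 3")
  expect_equal(nrow(out2$kept), 2)
})

test_that("the 2-SD rule removes the expected normal tail mass", {
  set.seed(33)
  rec <- data.frame(horse_id = "H01", muscle = "gluteal", side = "right",
                    condition = "iHL", stride = 1:1000,
                    arv_raw = rnorm(1000), reference = "ipsilateral")
  out <- suppressMessages(remove_arv_outliers(rec))
  frac <- nrow(out$removed) / 1000
  expect_lt(abs(frac - 2 * pnorm(-2)), 0.015)
})

test_that("normalization maps the baseline maximum to exactly 100%", {
  rec <- data.frame(horse_id = "H01", muscle = "biceps", side = "left",
                    condition = c("baseline2", "baseline2", "iHL"),
                    stride = 1:3, arv_raw = c(2, 4, 5),
                    reference = "ipsilateral")
  out <- normalize_to_baseline_max(rec)
  expect_equal(out$arv_norm, c(50, 100, 125))

  zero <- transform(rec, arv_raw = 0)
  expect_error(normalize_to_baseline_max(zero), "baseline ARV maximum")
  nobase <- rec[3, ]
  expect_error(normalize_to_baseline_max(nobase), "missing baseline")
})

test_that("normalization and sessions are kept per horse x muscle x side", {
  set.seed(2)
  grid <- expand.grid(horse_id = c("H01", "H02"), muscle = "biceps",
                      side = c("left", "right"),
                      condition = c("baseline1", "iFL", "baseline2", "iHL"),
                      stride = 1:5, stringsAsFactors = FALSE)
  grid$arv_raw <- runif(nrow(grid), 0.5, 2)
  grid$reference <- "ipsilateral"
  out <- normalize_to_baseline_max(grid)
  agg <- aggregate(arv_norm ~ horse_id + side + condition, out, max)
  base <- agg[agg$condition %in% c("baseline1", "baseline2"), ]
  expect_true(all(abs(base$arv_norm - 100) < 1e-12))
})

test_that("sEMGabs yields one sample per stride and recovers scale effects", {
  ms <- muscle_scale_table("gluteal", "LS", "iHL", 1.5)
  cfg <- sim_config(n_horses = 1, strides_per_trial = 20, muscle_scale = ms,
                    stride_amp_cv = 0, induced_side = "left", seed = 31)
  arv <- rbind(
    trial_arv(generate_trial(cfg, 1, "baseline2")$recording, reference = "ipsilateral"),
    trial_arv(generate_trial(cfg, 1, "iHL")$recording, reference = "ipsilateral"))
  out <- suppressMessages(remove_arv_outliers(arv))
  samples <- semg_abs(normalize_to_baseline_max(out$kept))
  gl <- samples[samples$muscle == "gluteal" & samples$side == "left", ]
  expect_equal(nrow(gl), nrow(arv[arv$muscle == "gluteal" & arv$side == "left", ]) -
                 sum(out$removed$muscle == "gluteal" & out$removed$side == "left"))
  ratio <- mean(gl$value[gl$class == "lame"]) /
    mean(gl$value[gl$class == "baseline"])
  expect_equal(ratio, 1.5, tolerance = 0.05)
  # untouched muscle stays at its baseline level
  tri <- samples[samples$muscle == "triceps" & samples$side == "left", ]
  expect_equal(mean(tri$value[tri$class == "lame"]) /
                 mean(tri$value[tri$class == "baseline"]), 1, tolerance = 0.05)
  expect_error(semg_abs(normalize_to_baseline_max(transform(arv, reference = "left"))),
               "ipsilateral")
})

test_that("sEMGasym is the left-minus-right difference and is odd under relabeling", {
  rec <- expand.grid(horse_id = "H01", muscle = c("biceps", "gluteal"),
                     side = c("left", "right"),
                     condition = c("baseline2", "iHL"), stride = 1:6,
                     stringsAsFactors = FALSE)
  set.seed(14)
  rec$arv_raw <- runif(nrow(rec), 0.5, 2)
  rec$reference <- "left"
  norm <- normalize_to_baseline_max(rec)
  asym <- semg_asym(norm)
  one <- norm[norm$muscle == "biceps" & norm$condition == "iHL" & norm$stride == 3, ]
  expect_equal(asym$value[asym$muscle == "biceps" & asym$condition == "iHL" &
                            asym$stride == 3],
               one$arv_norm[one$side == "left"] - one$arv_norm[one$side == "right"])

  flipped <- norm
  flipped$side <- c(left = "right", right = "left")[norm$side]
  asym_f <- semg_asym(flipped)
  m <- merge(asym, asym_f, by = c("muscle", "condition", "stride"))
  expect_equal(m$value.y, -m$value.x)

  # unpaired strides are skipped
  norm_gap <- norm[!(norm$side == "right" & norm$stride == 2 &
                       norm$muscle == "biceps" & norm$condition == "iHL"), ]
  expect_message(asym_g <- semg_asym(norm_gap), "skipped 1")
  expect_equal(nrow(asym_g), nrow(asym) - 1)

  expect_error(semg_asym(transform(norm, reference = "ipsilateral")), "left")
})

test_that("left 80% and right 60% give sEMGasym +20%", {
  rec <- data.frame(horse_id = "H01", muscle = "biceps",
                    side = c("left", "right", "left", "right"),
                    condition = c("baseline2", "baseline2", "iHL", "iHL"),
                    stride = c(1, 1, 1, 1),
                    arv_norm = c(100, 100, 80, 60),
                    arv_raw = 1, reference = "left")
  asym <- semg_asym(rec)
  expect_equal(asym$value[asym$condition == "iHL"], 20)
  expect_equal(asym$value[asym$condition == "baseline2"], 0)
})
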