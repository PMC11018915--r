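test_that("a symmetric double sinusoid gives zero MinDiff and MaxDiff", {
  # 256 samples per stride: all four extrema fall exactly on the grid
  u <- seq(0, 1, length.out = 257)[-257]
  mm <- min_max_diff(sin(4 * pi * u))
  expect_true(mm$valid)
  expect_lt(abs(mm$min_diff), 1e-9)
  expect_lt(abs(mm$max_diff), 1e-9)
})

test_that("crafted half-stride minima of -12 and -4 mm give MinDiff -8", {
  u <- seq(0, 1, length.out = 513)[-513]
  y <- ifelse(u < 0.5, 12 * sin(4 * pi * u), 4 * sin(4 * pi * u))
  mm <- min_max_diff(y)
  expect_true(mm$valid)
  # numeric argmin oracle
  expect_equal(min(y[u < 0.5]) - min(y[u >= 0.5]), -8, tolerance = 1e-3)
  expect_equal(mm$min_diff, -8, tolerance = 1e-3)
  expect_equal(mm$max_diff, 8, tolerance = 1e-3)
})

test_that("flat strides are flagged invalid", {
  expect_false(min_max_diff(rep(0, 100))$valid)
  expect_false(min_max_diff(seq(0, 1, length.out = 100))$valid)
})

test_that("measured |MinDiff| increases with the injected asymmetry", {
  got <- vapply(c(2, 5, 10, 20), function(a) {
    cfg <- sim_config(n_horses = 1, strides_per_trial = 6,
                      asymmetry_mm = c(poll = 0, withers = 0, pelvis = a,
                                       tuber_coxae = 0),
                      kin_noise_sd_mm = 0, induced_side = "left", seed = 21)
    tr <- generate_trial(cfg, 1, "iHL")
    asym <- stride_asymmetry(tr$recording)
    # sign matches the generator's oracle for a left induction
    expect_lt(mean(asym$min_diff_pelvis), 0)
    expect_equal(mean(asym$min_diff_pelvis),
                 tr$truth$realized$min_max$min_diff[3], tolerance = 0.15)
    abs(mean(asym$min_diff_pelvis))
  }, numeric(1))
  expect_true(all(diff(got) > 0))
})

test_that("hip hike reflects the stance/swing amplitude difference", {
  fs <- 200
  t <- (0:199) / fs                       # one 1 Hz stride
  stride <- data.frame(index = 1, start = 0, end = 1, reference_limb = "left")
  ev <- structure(list(impacts_left = c(0, 1), impacts_right = 0.5),
                  class = "gait_events")
  same <- 15 * sin(4 * pi * t)
  hh0 <- hip_hike(same, same, fs, stride, ev)
  expect_true(hh0$valid)
  expect_equal(hh0$hip_hike_stance, 0, tolerance = 1e-9)
  expect_equal(hh0$hip_hike_swing, 0, tolerance = 1e-9)

  left <- 15 * sin(4 * pi * t)            # 30 mm peak-to-peak
  right <- 10 * sin(4 * pi * t)           # 20 mm
  hh <- hip_hike(left, right, fs, stride, ev)
  expect_equal(hh$hip_hike_stance, 10, tolerance = 0.05)
  expect_equal(hh$hip_hike_swing, 10, tolerance = 0.05)

  swapped <- hip_hike(right, left, fs, stride, ev)
  expect_equal(swapped$hip_hike_stance, -hh$hip_hike_stance, tolerance = 1e-9)
  expect_equal(swapped$hip_hike_swing, -hh$hip_hike_swing, tolerance = 1e-9)

  expect_error(hip_hike(NULL, right, fs, stride, ev), "tuber coxae")
})

test_that("all asymmetry indices negate exactly under left-right mirroring", {
  cfg <- noiseless_config(asymmetry_mm = c(poll = 0, withers = 0, pelvis = 10,
                                           tuber_coxae = 10),
                          induced_side = "left")
  tr <- generate_trial(cfg, 1, "iHL")
  ev <- structure(list(impacts_left = tr$truth$impacts_left,
                       impacts_right = tr$truth$impacts_right),
                  class = "gait_events")
  orig <- stride_asymmetry(tr$recording, ev)
  mirr <- stride_asymmetry(mirror_trial(tr$recording), mirror_events(ev))
  cols <- c("min_diff_poll", "min_diff_withers", "min_diff_pelvis",
            "max_diff_poll", "max_diff_withers", "max_diff_pelvis",
            "hip_hike_stance", "hip_hike_swing")
  # interior strides only: the first/last strides carry the (tiny) residual
  # start-up transient of the zero-phase filter
  io <- 3:(nrow(orig) - 2); im <- 3:(nrow(mirr) - 2)
  for (col in cols)
    expect_lt(abs(median(mirr[[col]][im]) + median(orig[[col]][io])), 0.05)
})

test_that("the induction-sufficiency rule matches its reference thresholds", {
  set.seed(8)
  base <- data.frame(min_diff_poll = rnorm(20, 0, 0.5),
                     max_diff_poll = rnorm(20, 0, 0.5),
                     min_diff_pelvis = rnorm(20, 0, 0.3),
                     max_diff_pelvis = rnorm(20, 0, 0.3))
  shift <- function(col, mu, sd = 1) {
    ind <- base
    ind[[col]] <- rnorm(20, mu, sd)
    ind
  }
  # head delta 14 mm with consistent strides: sufficient
  expect_true(induction_sufficient(base, shift("min_diff_poll", -14),
                                   "fore")$sufficient)
  # pelvis delta 6 mm: sufficient
  expect_true(induction_sufficient(base, shift("min_diff_pelvis", -6, 0.5),
                                   "hind")$sufficient)
  # large delta but SD above the mean: insufficient
  noisy <- base
  noisy$min_diff_poll <- rnorm(20, -20, 30)
  noisy$max_diff_poll <- rnorm(20, -20, 30)
  chk <- induction_sufficient(base, noisy, "fore")
  expect_false(chk$sufficient)
  # no shift at all: insufficient
  expect_false(induction_sufficient(base, base, "fore")$sufficient)
  expect_false(induction_sufficient(base, base, "hind")$sufficient)
  expect_error(induction_sufficient(base[1, ], base, "fore"), "strides")
})
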