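test_that("mirroring negates signed parameters and swaps sEMGabs sides", {
  s <- data.frame(family = c("kinematic", "semg_asym", "semg_abs"),
                  muscle = c(NA, "biceps", "biceps"),
                  side = c(NA, NA, "left"),
                  parameter = c("MinDiff Poll", "sEMGasym biceps",
                                "sEMGabs left biceps"),
                  horse_id = "H01", condition = "iFL", class = "lame",
                  stride = 1, value = c(10, 5, 80))
  m <- mirror_parameters(s, "right", relabel = FALSE)
  expect_equal(m$value, c(-10, -5, 80))
  expect_equal(m$side, c(NA, NA, "right"))

  l <- mirror_parameters(s, "left", relabel = FALSE)
  expect_equal(l$value, s$value)
  expect_equal(l$side, s$side)

  rel <- mirror_parameters(s, "right", relabel = TRUE)
  expect_equal(rel$side[3], "NLS")
  expect_equal(rel$parameter[3], "sEMGabs NLS biceps")
  rel_l <- mirror_parameters(s, "left", relabel = TRUE)
  expect_equal(rel_l$side[3], "LS")

  expect_error(mirror_parameters(s, "none"), "induced_side")
})

test_that("mirroring without relabeling is an involution", {
  for (seed in 1:5) {
    s <- random_samples(seed = seed)
    twice <- mirror_parameters(mirror_parameters(s, "right", relabel = FALSE),
                               "right", relabel = FALSE)
    expect_equal(twice, s)
  }
})

test_that("ROC curves enumerate midpoint thresholds with sentinels", {
  roc <- roc_curve(c(1, 2), c(5, 6), "greater")
  i <- which(roc$threshold == 3.5)
  expect_equal(roc$sensitivity[i], 1)
  expect_equal(roc$specificity[i], 1)

  roc2 <- roc_curve(c(1, 3), c(2, 4), "greater")
  pairs <- unique(roc2[, c("sensitivity", "specificity")])
  expect_true(any(pairs$sensitivity == 1 & pairs$specificity == 0.5))
  expect_true(any(pairs$sensitivity == 0.5 & pairs$specificity == 1))

  same <- roc_curve(rep(2, 3), rep(2, 3), "greater")
  expect_true(all(abs(same$sensitivity + same$specificity - 1) < 1e-12))

  expect_error(roc_curve(numeric(0), 1:3), ">= 2 values")
})

test_that("AUC matches hand-enumerated examples", {
  expect_equal(roc_auc(c(1, 2, 3), c(4, 5, 6)), 1.0)
  expect_equal(roc_auc(c(1, 3), c(2, 4)), 0.75)       # 3 of 4 pairs win
  expect_equal(roc_auc(c(1, 2), c(2, 3)), 0.875)      # 3 wins + half a tie
})

test_that("trapezoidal AUC equals the all-pairs Mann-Whitney oracle", {
  set.seed(99)
  for (i in 1:200) {
    n1 <- sample(2:30, 1); n2 <- sample(2:30, 1)
    # coarse rounding forces ties within and between classes
    b <- round(rnorm(n1, sd = 2), sample(0:1, 1))
    l <- round(rnorm(n2, 0.5, 2), sample(0:1, 1))
    dir <- sample(c("greater", "lesser"), 1)
    expect_equal(roc_auc(b, l, dir), auc_bruteforce(b, l, dir),
                 tolerance = 1e-12)
  }
})

test_that("AUC complement and monotone-transform invariance hold", {
  set.seed(7)
  for (i in 1:20) {
    b <- round(rnorm(8), 1); l <- round(rnorm(12, 1), 1)
    expect_equal(roc_auc(b, l, "greater") + roc_auc(l, b, "greater"), 1,
                 tolerance = 1e-12)
    tr <- function(x) exp(0.3 * x) + x   # strictly increasing
    expect_equal(roc_auc(tr(b), tr(l), "greater"), roc_auc(b, l, "greater"),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with pROC on random data", {
  skip_if_not_installed("pROC")
  set.seed(123)
  for (i in 1:20) {
    b <- rnorm(15); l <- rnorm(20, 0.8)
    ours <- roc_auc(b, l, "greater")
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = c(rep(0, 15), rep(1, 20)), predictor = c(b, l),
      direction = "<", quiet = TRUE)))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("the Youden optimum maximizes J with the documented tie-breaks", {
  opt <- youden_optimal(roc_curve(c(1, 2), c(5, 6), "greater"))
  expect_equal(opt$cutoff, 3.5)
  expect_equal(opt$j, 1)

  opt2 <- youden_optimal(roc_curve(c(1, 3), c(2, 4), "greater"))
  expect_equal(opt2$j, 0.5)
  expect_equal(opt2$cutoff, 3.5)          # tie broken towards specificity
  expect_equal(opt2$specificity, 1)

  flat <- youden_optimal(roc_curve(rep(1, 3), rep(1, 3), "greater"))
  expect_equal(flat$j, 0)

  set.seed(41)
  for (i in 1:30) {
    b <- round(rnorm(10), 1); l <- round(rnorm(10, 0.7), 1)
    opt <- youden_optimal(roc_curve(b, l, "greater"))
    expect_equal(opt$j, youden_bruteforce(b, l), tolerance = 1e-12)
  }
})

test_that("AUC interpretation bands follow the published cut-points", {
  expect_equal(interpret_auc(0.95), "excellent")
  expect_equal(interpret_auc(0.90), "excellent")
  expect_equal(interpret_auc(0.85), "good")
  expect_equal(interpret_auc(0.75), "fair")
  expect_equal(interpret_auc(0.65), "poor")
  expect_equal(interpret_auc(0.55), "chance")
  expect_equal(interpret_auc(0.48), "chance")  # below-chance kept as-is
  expect_error(interpret_auc(1.2), "\\[0, 1\\]")
  expect_error(interpret_auc(-0.1), "\\[0, 1\\]")
})

make_full_samples <- function(n = 12, seed = 5) {
  set.seed(seed)
  rows <- list()
  add <- function(family, muscle, side, parameter) {
    for (cond in c("baseline1", "iFL", "baseline2", "iHL")) {
      rows[[length(rows) + 1]] <<- data.frame(
        family = family, muscle = muscle, side = side, parameter = parameter,
        horse_id = "H01", condition = cond,
        class = ifelse(cond %in% c("iFL", "iHL"), "lame", "baseline"),
        stride = 1:n, value = rnorm(n))
    }
  }
  muscles <- c("triceps", "latissimus", "gluteal", "biceps",
               "semitendinosus", "longissimus_T14", "longissimus_L1")
  for (m in muscles) {
    for (s in c("LS", "NLS"))
      add("semg_abs", m, s, sprintf("sEMGabs %s %s", s, m))
    add("semg_asym", m, NA, sprintf("sEMGasym %s", m))
  }
  for (p in c("MinDiff Poll", "MinDiff Withers", "MinDiff Pelvis",
              "MaxDiff Poll", "MaxDiff Withers", "MaxDiff Pelvis",
              "Hip Hike Stance", "Hip Hike Swing"))
    add("kinematic", NA, NA, p)
  do.call(rbind, rows)
}

test_that("the results table has 29 rows per induction in table order", {
  samples <- make_full_samples()
  res <- build_results_table(samples)
  expect_equal(nrow(res), 58)
  for (ind in c("iFL", "iHL")) {
    sub <- res[res$induction == ind, ]
    expect_equal(nrow(sub), 29)
    expect_equal(sum(sub$family == "semg_abs"), 14)
    expect_equal(sum(sub$family == "semg_asym"), 7)
    expect_equal(sum(sub$family == "kinematic"), 8)
  }
  expect_true(all(res$auc >= 0 & res$auc <= 1))
  expect_true(all(res$sensitivity >= 0 & res$sensitivity <= 1))
  expect_true(all(res$specificity >= 0 & res$specificity <= 1))
  # direction metadata recorded per family
  expect_true(all(res$direction[res$family == "semg_abs"] == "greater"))
  expect_true(all(res$direction[res$family != "semg_abs"] == "lesser"))

  expect_error(build_results_table(samples[samples$condition != "baseline1", ]),
               "missing class|no samples")
  expect_error(build_results_table(samples, inductions = "iXL"),
               "unknown induction")
})
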