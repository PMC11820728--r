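test_that("segmentation metrics match hand cases and a counting oracle", {
  a <- label_mask(matrix(c(1L, 1L, 0L, 0L), 2))
  expect_equal(unname(seg_metrics(a, a, 1L)), c(1, 1, 1))
  # disjoint prediction and truth of equal area
  p <- label_mask(matrix(c(1L, 1L, 0L, 0L, 0L, 0L), 2))
  t_ <- label_mask(matrix(c(0L, 0L, 0L, 0L, 1L, 1L), 2))
  m <- seg_metrics(p, t_, 1L)
  expect_equal(unname(m["IOU"]), 0)
  expect_equal(unname(m["Dice"]), 0)
  set.seed(14)
  for (trial in 1:100) {
    pm <- matrix(sample(0:2, 256, TRUE), 16)
    tm <- matrix(sample(0:2, 256, TRUE), 16)
    for (cl in 1:2) {
      tp <- tn <- fp <- fn <- 0L
      for (i in 1:16) for (j in 1:16) {
        pp <- pm[i, j] == cl; tt <- tm[i, j] == cl
        if (pp && tt) tp <- tp + 1L
        else if (!pp && !tt) tn <- tn + 1L
        else if (pp) fp <- fp + 1L else fn <- fn + 1L
      }
      got <- seg_metrics(pm, tm, cl)
      expect_identical(unname(got["PA"]), (tp + tn) / 256)
      expect_identical(unname(got["IOU"]), tp / (tp + fp + fn))
      expect_identical(unname(got["Dice"]), 2 * tp / (2 * tp + fp + fn))
      # Dice-IoU identity
      expect_equal(unname(got["Dice"]),
                   2 * got[["IOU"]] / (1 + got[["IOU"]]), tolerance = 1e-12)
    }
  }
})

test_that("a class absent from both masks reports NA, never zero", {
  z <- matrix(0L, 4, 4)
  m <- seg_metrics(z, z, 2L)
  expect_true(is.na(m["IOU"]))
  expect_true(is.na(m["Dice"]))
  expect_identical(unname(m["PA"]), 1)
})

test_that("error metrics follow the MAE/MRE formulas", {
  same <- paired_measurements(c(3, 4, 5), c(3, 4, 5))
  em0 <- error_metrics(same)
  expect_identical(em0$MAE, 0)
  expect_identical(em0$MRE, 0)
  em <- error_metrics(paired_measurements(c(1, 2), c(2, 4)))
  expect_identical(em$MAE, 1.5)
  expect_identical(em$MRE, 0.5)
  expect_error(error_metrics(paired_measurements(c(1, 2), c(0, 4))),
               "positive")
  set.seed(15)
  for (trial in 1:100) {
    n <- sample(2:100, 1)
    a <- stats::runif(n, 40, 90)
    b <- stats::runif(n, 40, 90)
    em <- error_metrics(paired_measurements(a, b))
    mae <- mre <- 0
    for (i in seq_len(n)) {
      mae <- mae + abs(a[i] - b[i])
      mre <- mre + abs(a[i] - b[i]) / b[i]
    }
    expect_equal(em$MAE, mae / n, tolerance = 1e-12)
    expect_equal(em$MRE, mre / n, tolerance = 1e-12)
    expect_equal(em$mean_diff, mean(a - b), tolerance = 1e-12)
    expect_equal(em$sd_diff, sqrt(sum((a - b - mean(a - b))^2) / (n - 1)),
                 tolerance = 1e-12)
  }
})

test_that("ICC(2,1) equals 1 on duplicated columns and penalizes offsets", {
  set.seed(16)
  a <- stats::rnorm(20, 67, 4)
  dup <- icc_absolute_agreement(paired_measurements(a, a))
  expect_equal(dup$icc, 1, tolerance = 1e-12)
  shifted <- icc_absolute_agreement(paired_measurements(a, a + 6))
  expect_lt(shifted$icc, 1)  # absolute agreement is NOT shift-invariant
  # near-zero subject variance with a large offset pushes ICC toward 0
  b <- stats::rnorm(20, 0, 0.05)
  low <- icc_absolute_agreement(paired_measurements(b, b + 10))
  expect_lt(low$icc, 0.1)
  expect_warning(icc_absolute_agreement(paired_measurements(rep(5, 10),
                                                            rep(5, 10))),
                 "between-subject")
})

test_that("ICC(2,1) matches mean squares computed independently by aov", {
  set.seed(17)
  for (trial in 1:20) {
    n <- 30
    subj <- stats::rnorm(n, 70, 5)
    x <- cbind(subj + stats::rnorm(n, 0, 2), subj + 1 + stats::rnorm(n, 0, 2))
    df <- data.frame(y = c(x[, 1], x[, 2]),
                     subject = factor(rep(seq_len(n), 2)),
                     rater = factor(rep(1:2, each = n)))
    ms <- summary(stats::aov(y ~ subject + rater, data = df))[[1]]$`Mean Sq`
    MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
    k <- 2
    icc_oracle <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
    got <- icc_absolute_agreement(paired_measurements(x[, 1], x[, 2]))
    expect_equal(got$icc, icc_oracle, tolerance = 1e-9)
    expect_equal(got$MSR, MSR, tolerance = 1e-9)
    expect_equal(got$MSE, MSE, tolerance = 1e-9)
    expect_true(got$ci95[1] < got$icc && got$icc < got$ci95[2])
  }
})

test_that("Bland-Altman limits follow mean +/- 1.96 sd of the differences", {
  const <- paired_measurements(c(61, 72, 83, 54, 65, 76, 87, 58, 69, 70),
                               c(61, 72, 83, 54, 65, 76, 87, 58, 69, 70) - 2)
  ba <- bland_altman(const)
  expect_equal(ba$loa95, c(2, 2))
  two <- paired_measurements(c(0, 0), c(1, -1))
  ba2 <- bland_altman(two)
  expect_equal(ba2$mean_diff, 0)
  expect_equal(ba2$loa95, 1.96 * sqrt(2) * c(-1, 1), tolerance = 1e-12)
})

test_that("simulated-rater statistics recover the injected bias within CLT bounds", {
  set.seed(18)
  truths <- stats::rnorm(116, 67.79, 4.609)
  rated <- simulate_rater(truths, bias_deg = -1.869, sd_deg = 3.967, seed = 3)
  pairs <- paired_measurements(rated, truths, labels = c("junior", "truth"))
  ba <- bland_altman(pairs)
  clt <- 3 * 3.967 / sqrt(116)
  expect_lt(abs(ba$mean_diff - (-1.869)), clt)
  # limits of agreement near bias +/- 1.96 sd, within CLT-scale slack
  expect_lt(abs(ba$loa95[1] - (-1.869 - 1.96 * 3.967)), 3 * clt)
  expect_lt(abs(ba$loa95[2] - (-1.869 + 1.96 * 3.967)), 3 * clt)
})

test_that("Bland-Altman writes a plot file when asked", {
  pairs <- paired_measurements(stats::rnorm(20, 67, 3), stats::rnorm(20, 67, 3))
  f <- withr::local_tempfile(fileext = ".png")
  bland_altman(pairs, plot_path = f)
  expect_true(file.exists(f) && file.size(f) > 0)
})

test_that("Pearson correlation and normality gating behave", {
  a <- stats::rnorm(30, 60, 5)
  expect_equal(pearson_and_normality(paired_measurements(a, 2 * a))$r, 1,
               tolerance = 1e-12)
  expect_equal(pearson_and_normality(paired_measurements(a, -a))$r, -1,
               tolerance = 1e-12)
  set.seed(19)
  rho <- 0.7
  z <- matrix(stats::rnorm(1000), ncol = 2)
  x <- z[, 1]; y <- rho * z[, 1] + sqrt(1 - rho^2) * z[, 2]
  got <- pearson_and_normality(paired_measurements(x, y))
  expect_lt(abs(got$r - rho), 0.08)
  expect_true(all(got$normality_pass))
  # exponential column fails the gate and yields the nonparametric summary
  skew <- pearson_and_normality(paired_measurements(stats::rexp(100),
                                                    stats::rnorm(100)))
  expect_false(all(skew$normality_pass))
  expect_s3_class(skew$nonparametric_summary, "data.frame")
  # zero variance -> NA
  expect_true(is.na(suppressWarnings(
    pearson_and_normality(paired_measurements(rep(1, 10),
                                              stats::rnorm(10)))$r)))
})

test_that("cross-validation partitions the cohort and emits the Dice table", {
  co <- generate_cohort(10, small_spec(), seed = 20L)
  cfg <- small_seg_config(epochs = 2L)
  cv <- crossvalidate_segmentation(co$samples, k = 5, cfg, seed = 1L)
  sizes <- lengths(cv$folds)
  expect_identical(unname(sizes), rep(2L, 5))
  all_ids <- sort(unlist(cv$folds))
  expect_identical(all_ids, sort(co$manifest$sample_id))
  expect_identical(names(cv$dice),
                   c("class", paste0("fold", 1:5), "mean", "sd"))
  expect_identical(cv$dice$class, c("palate", "frontal_bone"))
  # identical split under the same seed
  cv2 <- crossvalidate_segmentation(co$samples, k = 5, cfg, seed = 1L)
  expect_identical(cv$folds, cv2$folds)
})
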