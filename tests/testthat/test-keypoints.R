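test_that("heatmap encoding matches the Gaussian formula", {
  cfg <- kp_config(input_size_px = 64L, sigma_px = 2)
  # keypoint exactly on a heatmap cell center -> that cell's value is 1
  kp <- keypoint_set(c(20, 24), c(40, 8), c(8, 40))
  hm <- encode_heatmaps(kp, cfg)
  expect_identical(dim(hm$maps), c(16L, 16L, 3L))
  expect_equal(hm$maps[24 / 4 + 1, 20 / 4 + 1, 1], 1)
  expect_true(all(hm$maps >= 0 & hm$maps <= 1 + 1e-6))
  # all invisible -> all-zero stack
  inv <- keypoint_set(c(1, 1), c(2, 2), c(3, 3),
                      visibility = c(vertex = 0L, palate_ray = 0L,
                                     frontal_ray = 0L))
  expect_true(all(encode_heatmaps(inv, cfg)$maps == 0))
  # random point: brute-force truncated-Gaussian evaluation over all cells
  set.seed(21)
  for (trial in 1:20) {
    p <- stats::runif(2, 0, 60)
    kpr <- keypoint_set(p, c(1, 1), c(2, 2))
    got <- encode_heatmaps(kpr, cfg)$maps[, , 1]
    want <- matrix(0, 16, 16)
    for (i in 1:16) for (j in 1:16) {
      d2 <- (j - 1 - p[1] / 4)^2 + (i - 1 - p[2] / 4)^2
      if (d2 <= 36) want[i, j] <- exp(-d2 / 8)
    }
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("decoding inverts encoding on cell centers and is bounded elsewhere", {
  cfg <- kp_config(input_size_px = 64L)
  oncenter <- keypoint_set(c(20, 24), c(40, 8), c(8, 40))
  dec <- decode_heatmaps(encode_heatmaps(oncenter, cfg))
  expect_identical(kp_mat(dec), kp_mat(oncenter))
  # arbitrary sub-cell positions: error bounded by stride * sqrt(2) / 2
  set.seed(8)
  worst <- 0
  for (i in 1:100) {
    p <- stats::runif(6, 0, 60)
    kp <- keypoint_set(p[1:2], p[3:4], p[5:6])
    dec <- decode_heatmaps(encode_heatmaps(kp, cfg))
    worst <- max(worst, sqrt(rowSums((kp_mat(dec) - kp_mat(kp))^2)))
  }
  expect_lte(worst, 4 * sqrt(2) / 2 + 1e-9)
})

test_that("argmax ties resolve to the row-major first occurrence", {
  maps <- array(0, c(4, 4, 3))
  maps[2, 3, 1] <- 1; maps[3, 2, 1] <- 1   # tie: row 1 (y=1) scans first
  maps[1, 1, 2] <- 1
  maps[4, 4, 3] <- 1
  st <- structure(list(maps = maps, stride = 4L, sigma_px = 2),
                  class = "fmf_heatmap_stack")
  dec <- decode_heatmaps(st)
  expect_identical(dec$vertex, c(2 * 4, 1 * 4))   # (x=2,y=1) before (x=1,y=2)
})

test_that("an all-zero map marks its keypoint invisible", {
  maps <- array(0, c(4, 4, 3))
  maps[2, 2, 1] <- 1
  st <- structure(list(maps = maps, stride = 4L, sigma_px = 2),
                  class = "fmf_heatmap_stack")
  dec <- decode_heatmaps(st)
  expect_identical(unname(dec$visibility), c(2L, 0L, 0L))
})

test_that("encoding is equivariant to affine transforms of the keypoints", {
  cfg <- kp_config(input_size_px = 64L)
  set.seed(17)
  for (i in 1:50) {
    p <- stats::runif(2, 16, 48)
    s <- stats::runif(1, 0.8, 1.2)
    th <- stats::runif(1, -pi / 6, pi / 6)
    R <- s * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    q <- as.numeric(R %*% (p - 32)) + 32
    if (any(q < 0) || any(q > 63)) next
    hm <- encode_heatmaps(keypoint_set(q, c(1, 1), c(2, 2)), cfg)
    peak <- which(hm$maps[, , 1] == max(hm$maps[, , 1]), arr.ind = TRUE)[1, ]
    # the peak cell must be the nearest cell to the transformed point
    expect_lte(max(abs(c(peak[2] - 1, peak[1] - 1) - q / 4)), 0.5 + 1e-9)
  }
})

test_that("MSE heatmap loss matches a brute-force summation", {
  a <- array(stats::runif(3 * 8 * 8), c(8, 8, 3))
  expect_identical(mse_heatmap_loss(a, a), 0)
  expect_equal(mse_heatmap_loss(a + 1, a), 1, tolerance = 1e-12)
  set.seed(5)
  for (trial in 1:100) {
    p <- array(stats::rnorm(3 * 8 * 8), c(8, 8, 3))
    q <- array(stats::rnorm(3 * 8 * 8), c(8, 8, 3))
    acc <- 0
    for (k in 1:3) for (i in 1:8) for (j in 1:8)
      acc <- acc + (p[i, j, k] - q[i, j, k])^2
    expect_equal(mse_heatmap_loss(p, q), acc / 192, tolerance = 1e-9)
  }
  expect_error(mse_heatmap_loss(a, a[1:4, , ]), "shapes")
})

test_that("the keypoint network has the contracted shape and fused branches", {
  cfg <- kp_config(input_size_px = 96L, widths = "tiny", seed = 2L)
  net <- build_keypoint_net(cfg)
  x <- array(stats::rnorm(96 * 96 * cfg$in_channels),
             c(96, 96, cfg$in_channels))
  y <- net$forward(x)
  expect_identical(dim(y), c(24L, 24L, 3L))
  expect_true(all(is.finite(y)))
  # deterministic under a fixed seed
  net2 <- build_keypoint_net(cfg)
  expect_identical(net2$forward(x), y)
  # fusion ablation: silencing the cross-branch connections changes the
  # output, so the low-resolution branch genuinely contributes
  net$head$W[] <- stats::rnorm(length(net$head$W), sd = 0.1)
  y1 <- net$forward(x)
  for (st in net$stages) { st$up_conv$W[] <- 0; st$up_conv$b[] <- 0 }
  y2 <- net$forward(x)
  expect_gt(max(abs(y1 - y2)), 0)
})

test_that("keypoint training reduces the loss and is reproducible", {
  co <- generate_cohort(10, small_spec(), seed = 6L)
  cfg <- small_kp_config(epochs = 5L, input_mode = "mask_only", seed = 13L)
  f1 <- train_keypoint_net(build_keypoint_net(cfg), co$samples, cfg)
  expect_lt(f1$loss_log$loss[5], f1$loss_log$loss[1])
  f2 <- train_keypoint_net(build_keypoint_net(cfg), co$samples, cfg)
  expect_identical(f1$loss_log, f2$loss_log)
})
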