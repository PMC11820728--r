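test_that("segmenter forward obeys the shape and normalization contracts", {
  cfg <- small_seg_config(seed = 1L)
  net <- build_segmenter(cfg)
  expect_gt(net$n_params, 0)
  y <- net$forward(array(0, c(96, 96, 1)))
  expect_identical(dim(y), c(96L, 96L, 3L))
  expect_true(all(is.finite(y)))
  sc <- softmax_scores(net$forward(array(stats::rnorm(96 * 96), c(96, 96, 1))))
  sums <- sc[, , 1] + sc[, , 2] + sc[, , 3]
  expect_lt(max(abs(sums - 1)), 1e-5)
  expect_error(seg_config(input_size_px = 100L), "divisible")
  expect_error(seg_config(class_weights = c(0, 1, 1)), "positive")
  expect_error(seg_config(aspp_dilation_rates = c(12, 12, 36)), "increasing")
})

test_that("perturbations outside the local receptive field do not propagate", {
  # the global-pooling ASPP branch is image-level context by design; it is
  # ablated here so the probe measures the local convolutional pathway
  cfg <- seg_config(input_size_px = 256L, in_channels = 1L,
                    aspp_dilation_rates = c(2L, 4L, 6L), backbone = "tiny",
                    seed = 3L)
  net <- build_segmenter(cfg)
  net$aspp[[5]]$W[] <- 0
  net$aspp[[5]]$b[] <- 0
  set.seed(4)
  x <- array(stats::rnorm(256 * 256), c(256, 256, 1))
  y1 <- net$forward(x)
  x2 <- x
  x2[1:3, 1:3, 1] <- x2[1:3, 1:3, 1] + 10   # perturb the top-left corner
  y2 <- net$forward(x2)
  # local receptive-field radius of the tiny backbone + ASPP is ~200 px;
  # the opposite corner (distance > 350 px) must be untouched
  expect_equal(y2[256, 256, ], y1[256, 256, ], tolerance = 1e-12)
  # while nearby locations must change
  expect_gt(max(abs(y2[1:8, 1:8, ] - y1[1:8, 1:8, ])), 0)
})

test_that("weighted cross-entropy matches closed forms and a brute-force oracle", {
  onehot <- array(0, c(2, 2, 3)); onehot[, , 2] <- 1
  truth <- matrix(1L, 2, 2)
  expect_equal(weighted_cross_entropy(onehot, truth, c(1, 1, 1)), 0)
  unif <- array(1 / 3, c(4, 4, 3))
  expect_equal(weighted_cross_entropy(unif, matrix(sample(0:2, 16, TRUE), 4),
                                      c(1, 1, 1)),
               log(3), tolerance = 1e-12)
  set.seed(9)
  for (trial in 1:100) {
    h <- sample(2:8, 1); w <- sample(2:8, 1)
    q <- array(stats::runif(h * w * 3), c(h, w, 3))
    s <- q[, , 1] + q[, , 2] + q[, , 3]
    for (c_ in 1:3) q[, , c_] <- q[, , c_] / s
    lab <- matrix(sample(0:2, h * w, TRUE), h)
    wt <- stats::runif(3, 0.1, 2)
    # brute-force per-pixel double loop
    acc <- 0
    for (i in 1:h) for (j in 1:w)
      acc <- acc - wt[lab[i, j] + 1] * log(q[i, j, lab[i, j] + 1])
    expect_equal(weighted_cross_entropy(q, lab, wt), acc / (h * w),
                 tolerance = 1e-6)
  }
})

test_that("raising the background weight raises the loss iff background is misclassified", {
  q <- array(0, c(2, 2, 3))
  q[, , 1] <- 0.2; q[, , 2] <- 0.5; q[, , 3] <- 0.3  # background underrated
  truth <- matrix(0L, 2, 2)
  l1 <- weighted_cross_entropy(q, truth, c(0.4, 1, 1))
  l2 <- weighted_cross_entropy(q, truth, c(0.8, 1, 1))
  expect_gt(l2, l1)
  # perfectly classified background: weight has no effect (loss stays 0)
  p <- array(0, c(2, 2, 3)); p[, , 1] <- 1
  expect_equal(weighted_cross_entropy(p, truth, c(0.4, 1, 1)), 0)
  expect_equal(weighted_cross_entropy(p, truth, c(5, 1, 1)), 0)
})

test_that("training reduces the loss on learnable phantoms, deterministically", {
  co <- generate_cohort(10, small_spec(), seed = 4L)
  cfg <- small_seg_config(epochs = 6L, seed = 11L)
  f1 <- train_segmenter(build_segmenter(cfg), co$samples, cfg)
  expect_lt(f1$loss_log$loss[6], f1$loss_log$loss[1])
  f2 <- train_segmenter(build_segmenter(cfg), co$samples, cfg)
  expect_identical(f1$loss_log, f2$loss_log)
  expect_error(train_segmenter(build_segmenter(cfg), co$samples[1], cfg),
               "at least 2")
})

test_that("predict_mask applies argmax, tie-breaking and the component filter", {
  cfg <- small_seg_config()
  stub <- function(logits) {
    list(config = cfg, norm = list(mean = 0, sd = 1),
         forward = function(x) logits)
  }
  # forced one-hot palate everywhere
  lg <- array(c(0, 10, 0), c(1, 1, 3))[rep(1, 96), rep(1, 96), , drop = FALSE]
  all_pal <- predict_mask(stub(lg), matrix(0, 96, 96),
                          largest_component = FALSE)
  expect_true(all(all_pal$labels == 1L))
  # exact tie between background and palate -> lowest class index wins
  tie <- array(0, c(96, 96, 3))
  tie_mask <- predict_mask(stub(tie), matrix(0, 96, 96),
                           largest_component = FALSE)
  expect_true(all(tie_mask$labels == 0L))
  # two disjoint palate blobs: only the larger survives the post-filter
  lg2 <- array(0, c(96, 96, 3))
  lg2[5:10, 5:10, 2] <- 10     # 36 px blob
  lg2[50:70, 50:70, 2] <- 10   # 441 px blob
  filt <- predict_mask(stub(lg2), matrix(0, 96, 96),
                       largest_component = TRUE)
  expect_identical(sum(filt$labels == 1L), 441L)
  expect_true(all(filt$labels[5:10, 5:10] == 0L))
})
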