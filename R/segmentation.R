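# ------------------------------------------------------------------------
# Key-component segmentation stage: dilated residual encoder (output
# stride 8) + atrous spatial pyramid pooling (five parallel branches) +
# bilinear upsampling to input size, trained with class-weighted
# cross-entropy under random scale / horizontal flip / random crop
# augmentation and a polynomial SGD schedule.
# ------------------------------------------------------------------------

#' Segmentation stage configuration
#'
#' Defaults follow the training recipe of the measurement pipeline:
#' 480 px inputs, output stride 8, ASPP dilation rates 12/24/36, SGD with
#' initial LR 2e-3, momentum 0.9, weight decay 1e-4, batch 4, polynomial LR
#' decay (power 0.9), and scale-flip-crop augmentation with scales in
#' \[0.5, 2\]. The cross-entropy class weights down-weight the dominant
#' background class (default `c(0.4, 1, 1)`).
#'
#' The backbone is a parametric dilated residual encoder; `backbone`
#' selects a preset: `"small"` (default) or `"tiny"` (CPU desk-scale
#' training and tests).
#'
#' @param input_size_px Square input size; must be divisible by the output
#'   stride.
#' @param in_channels Input image channels (1 for grayscale phantoms,
#'   3 for RGB exports).
#' @param aspp_dilation_rates Strictly increasing atrous rates of the three
#'   3x3 ASPP branches.
#' @param class_weights Positive per-class cross-entropy weights
#'   (background, palate, frontal bone).
#' @param lr0,batch,epochs,momentum,weight_decay,poly_power SGD schedule.
#' @param scale_range Augmentation random-scale range.
#' @param backbone `"small"` or `"tiny"` preset.
#' @param normalization `NULL` to recompute per-channel mean/SD from the
#'   training set (the default), or `list(mean =, sd =)` to force explicit
#'   constants.
#' @param largest_component Keep only the largest connected component per
#'   foreground class when predicting (default on).
#' @param n_classes Number of classes (3: background, palate, frontal
#'   bone).
#' @param seed Training seed.
#' @return List of class `fmf_seg_config`.
#' @export
seg_config <- function(input_size_px = 480L, in_channels = 3L,
                       aspp_dilation_rates = c(12L, 24L, 36L),
                       class_weights = c(0.4, 1, 1),
                       lr0 = 2e-3, batch = 4L, epochs = 200L,
                       momentum = 0.9, weight_decay = 1e-4,
                       scale_range = c(0.5, 2.0), poly_power = 0.9,
                       backbone = c("small", "tiny"),
                       normalization = NULL, largest_component = TRUE,
                       n_classes = 3L, seed = 1L) {
  backbone <- match.arg(backbone)
  cfg <- list(input_size_px = as.integer(input_size_px),
              in_channels = as.integer(in_channels),
              output_stride = 8L,
              aspp_dilation_rates = as.integer(aspp_dilation_rates),
              class_weights = class_weights,
              lr0 = lr0, batch = as.integer(batch),
              epochs = as.integer(epochs), momentum = momentum,
              weight_decay = weight_decay, scale_range = scale_range,
              poly_power = poly_power, backbone = backbone,
              normalization = normalization,
              largest_component = largest_component,
              n_classes = as.integer(n_classes), seed = as.integer(seed))
  if (any(cfg$class_weights <= 0))
    stop("class_weights must be strictly positive")
  if (any(diff(cfg$aspp_dilation_rates) <= 0))
    stop("aspp_dilation_rates must be strictly increasing")
  if (cfg$input_size_px %% cfg$output_stride != 0)
    stop("input_size_px must be divisible by the output stride (",
         cfg$output_stride, ")")
  structure(cfg, class = "fmf_seg_config")
}

seg_preset <- function(backbone) {
  switch(backbone,
         tiny = list(stem = c(8L, 16L, 24L), blocks = 2L, block_dil = c(1L, 2L),
                     aspp_ch = 16L),
         small = list(stem = c(16L, 32L, 64L), blocks = 4L,
                      block_dil = c(1L, 1L, 2L, 2L), aspp_ch = 48L))
}

#' Build the segmentation network
#'
#' Encoder: three 3x3 stride-2 convolutions (output stride 8) followed by
#' residual blocks whose late blocks use dilation 2 (receptive-field growth
#' without further downsampling). ASPP: five parallel branches — a 1x1
#' convolution, three 3x3 atrous convolutions at the configured rates, and
#' a global-average-pooling branch (1x1 conv, broadcast back over the
#' grid) — concatenated and fused by a 1x1 convolution. A 1x1 classifier
#' then emits `n_classes` score maps, bilinearly upsampled to the input
#' size. The forward output is unnormalized logits (`H x W x n_classes`);
#' [softmax_scores()] normalizes them.
#'
#' @param config A [seg_config()].
#' @return A model handle (environment) with `$forward`, `$backward`,
#'   `$layers`, `$n_params` and `$config`.
#' @export
build_segmenter <- function(config) {
  set.seed(config$seed)
  pr <- seg_preset(config$backbone)
  net <- new.env(parent = emptyenv())
  net$config <- config
  s <- pr$stem
  net$stem <- list(nn_conv(config$in_channels, s[1], 3L, stride = 2L, act = "relu"),
                   nn_conv(s[1], s[2], 3L, stride = 2L, act = "relu"),
                   nn_conv(s[2], s[3], 3L, stride = 2L, act = "relu"))
  net$blocks <- lapply(seq_len(pr$blocks),
                       function(i) nn_resblock(s[3], dil = pr$block_dil[i]))
  ca <- pr$aspp_ch
  rates <- config$aspp_dilation_rates
  net$aspp <- list(nn_conv(s[3], ca, 1L, act = "relu"),
                   nn_conv(s[3], ca, 3L, dil = rates[1], act = "relu"),
                   nn_conv(s[3], ca, 3L, dil = rates[2], act = "relu"),
                   nn_conv(s[3], ca, 3L, dil = rates[3], act = "relu"),
                   nn_gap_branch(s[3], ca))
  net$fuse <- nn_conv(5L * ca, ca, 1L, act = "relu")
  net$cls <- nn_conv(ca, config$n_classes, 1L, act = "none")
  net$up <- nn_resize_bilinear()
  net$layers <- nn_collect_params(c(net$stem, net$blocks, net$aspp,
                                    list(net$fuse, net$cls)))
  net$n_params <- nn_param_count(net$layers)
  net$norm <- config$normalization

  net$forward <- function(x) {
    x <- as_t3(x)
    in_hw <- dim(x)[1:2]
    for (l in net$stem) x <- l$forward(x)
    for (l in net$blocks) x <- l$forward(x)
    br <- lapply(net$aspp, function(l) l$forward(x))
    net$split_ch <- vapply(br, function(b) dim(b)[3], integer(1))
    cat_ <- array(unlist(br), dim = c(dim(br[[1]])[1:2], sum(net$split_ch)))
    y <- net$cls$forward(net$fuse$forward(cat_))
    net$up$forward(y, in_hw)
  }
  net$backward <- function(dy) {
    dy <- net$up$backward(dy)
    dcat <- net$fuse$backward(net$cls$backward(dy))
    ends <- cumsum(net$split_ch)
    starts <- c(1L, utils::head(ends, -1) + 1L)
    dx <- 0
    for (i in seq_along(net$aspp)) {
      dbr <- dcat[, , starts[i]:ends[i], drop = FALSE]
      dx <- dx + net$aspp[[i]]$backward(dbr)
    }
    for (l in rev(net$blocks)) dx <- l$backward(dx)
    for (l in rev(net$stem)) dx <- l$backward(dx)
    dx
  }
  class(net) <- "fmf_segmenter"
  net
}

#' @export
print.fmf_segmenter <- function(x, ...) {
  cat(sprintf("Segmentation network (%s backbone, output stride %d): %d parameters\n",
              x$config$backbone, x$config$output_stride, x$n_params))
  invisible(x)
}

#' Softmax-normalize class score maps
#'
#' @param logits `H x W x C` array of unnormalized scores.
#' @return Array of the same shape whose per-pixel class scores sum to 1.
#' @export
softmax_scores <- function(logits) {
  C <- dim(logits)[3]
  sl <- lapply(seq_len(C), function(c_) logits[, , c_])
  m <- Reduce(pmax, sl)
  e <- lapply(sl, function(x) exp(x - m))
  s <- Reduce(`+`, e)
  array(unlist(lapply(e, function(x) x / s)), dim = dim(logits))
}

#' Class-weighted cross-entropy loss
#'
#' Mean over pixels of `-w[c] * log(Q[c])` evaluated at each pixel's true
#' class `c`, with `Q` the softmax-normalized predicted scores. Natural
#' logarithm is used (standard cross-entropy); any other base is a
#' constant factor absorbed by the learning rate. Probabilities are
#' clamped at `eps` so the loss is always finite.
#'
#' @param scores `H x W x C` array, normalized unless `normalized = FALSE`
#'   (then softmax is applied first).
#' @param truth [label_mask()] or integer matrix of true classes.
#' @param weights Positive per-class weights.
#' @param normalized Whether `scores` are already per-pixel normalized.
#' @param eps Probability clamp.
#' @return Non-negative scalar loss (0 iff predictions are one-hot correct
#'   wherever the weight is positive).
#' @export
weighted_cross_entropy <- function(scores, truth,
                                   weights = c(0.4, 1, 1),
                                   normalized = TRUE, eps = 1e-12) {
  tm <- if (inherits(truth, "fmf_label_mask")) truth$labels else truth
  stopifnot(all(dim(scores)[1:2] == dim(tm)),
            dim(scores)[3] == length(weights))
  if (!normalized) scores <- softmax_scores(scores)
  H <- dim(scores)[1]; W <- dim(scores)[2]
  idx <- cbind(rep(seq_len(H), W), rep(seq_len(W), each = H),
               as.integer(tm) + 1L)
  q <- pmax(scores[idx], eps)
  mean(-weights[as.integer(tm) + 1L] * log(q))
}

# Loss + gradient wrt logits for training (softmax + weighted CE fused).
wce_loss_grad <- function(logits, labels, weights, eps = 1e-12) {
  q <- softmax_scores(logits)
  H <- dim(q)[1]; W <- dim(q)[2]; C <- dim(q)[3]
  lab <- as.integer(labels)
  idx <- cbind(rep(seq_len(H), W), rep(seq_len(W), each = H), lab + 1L)
  wpix <- weights[lab + 1L]
  loss <- mean(-wpix * log(pmax(q[idx], eps)))
  onehot <- array(0, dim = c(H, W, C))
  onehot[idx] <- 1
  dlogits <- (q - onehot) * array(wpix, dim = c(H, W, C)) / (H * W)
  list(loss = loss, dlogits = dlogits)
}

# Compose the augmentation affine (output px -> input px, package
# convention) for random scale s, optional horizontal flip, and a crop
# offset (ox, oy) in the scaled frame.
seg_aug_affine <- function(s, flip, ox, oy, scaled_w) {
  # crop: xs = xout + ox; flip: xf = scaled_w - 1 - xs; unscale:
  # xin = (xf + 0.5)/s - 0.5
  if (flip) {
    a11 <- -1 / s
    tx <- (scaled_w - 1 - ox + 0.5) / s - 0.5
  } else {
    a11 <- 1 / s
    tx <- (ox + 0.5) / s - 0.5
  }
  a22 <- 1 / s
  ty <- (oy + 0.5) / s - 0.5
  c(a11, 0, 0, a22, tx, ty)
}

seg_normalize <- function(x, norm) {
  for (c_ in seq_len(dim(x)[3]))
    x[, , c_] <- (x[, , c_] - norm$mean[c_]) / norm$sd[c_]
  x
}

#' Train the segmentation network
#'
#' SGD with momentum and polynomial LR decay
#' `lr0 * (1 - step/total)^power`; per-sample augmentation draws a random
#' scale from `scale_range`, a horizontal flip with probability 0.5, and a
#' random crop to the input size (padding with background where the scaled
#' image is short). The identical geometric transform is applied to the
#' label mask (nearest-neighbour). Fully deterministic given
#' `config$seed`.
#'
#' @param model From [build_segmenter()].
#' @param samples List of samples with `$image` (matrix or `H x W x C`) and
#'   `$mask` ([label_mask()]).
#' @param config A [seg_config()]; `epochs`/`batch`/LR taken from here.
#' @return List with `model` (trained in place) and `loss_log`
#'   (data frame `epoch`, `loss`, `lr`).
#' @export
train_segmenter <- function(model, samples, config = model$config) {
  if (length(samples) < 2) stop("need at least 2 training samples")
  set.seed(config$seed + 1L)
  sz <- config$input_size_px
  imgs <- lapply(samples, function(s) as_t3(s$image))
  if (is.null(model$norm)) {
    nc <- dim(imgs[[1]])[3]
    ch_mean <- rowMeans(matrix(sapply(imgs, function(x) apply(x, 3, mean)), nc))
    ch_sd <- rowMeans(matrix(sapply(imgs, function(x) apply(x, 3, stats::sd)), nc))
    model$norm <- list(mean = ch_mean, sd = pmax(ch_sd, 1e-6))
  }
  steps_per_epoch <- ceiling(length(samples) / config$batch)
  opt <- opt_sgd_poly(model$layers, config$lr0, config$momentum,
                      config$weight_decay,
                      total_steps = steps_per_epoch * config$epochs,
                      poly_power = config$poly_power)
  log <- data.frame(epoch = integer(0), loss = numeric(0), lr = numeric(0))
  for (ep in seq_len(config$epochs)) {
    ord <- sample(length(samples))
    ep_loss <- 0
    in_batch <- 0L
    nn_zero_grad(model$layers)
    lr_now <- NA_real_
    for (ii in seq_along(ord)) {
      i <- ord[ii]
      x <- imgs[[i]]
      hw <- dim(x)[1:2]
      s <- stats::runif(1, config$scale_range[1], config$scale_range[2])
      flip <- stats::runif(1) < 0.5
      sh <- round(hw * s)
      oy <- if (sh[1] > sz) floor(stats::runif(1, 0, sh[1] - sz + 1))
            else -floor(stats::runif(1, 0, sz - sh[1] + 1))
      ox <- if (sh[2] > sz) floor(stats::runif(1, 0, sh[2] - sz + 1))
            else -floor(stats::runif(1, 0, sz - sh[2] + 1))
      m <- seg_aug_affine(s, flip, ox, oy, sh[2])
      xa <- cpp_affine_sample(x, m, sz, sz, FALSE, 0)
      ya <- cpp_affine_sample(as_t3(samples[[i]]$mask$labels), m, sz, sz,
                              TRUE, 0)[, , 1]
      xa <- seg_normalize(xa, model$norm)
      logits <- model$forward(xa)
      lg <- wce_loss_grad(logits, ya, config$class_weights)
      if (!is.finite(lg$loss))
        stop("non-finite training loss at epoch ", ep,
             " (sample ", samples[[i]]$sample_id, "); aborting")
      ep_loss <- ep_loss + lg$loss
      model$backward(lg$dlogits / config$batch)
      in_batch <- in_batch + 1L
      if (in_batch == config$batch || ii == length(ord)) {
        lr_now <- opt$step()
        nn_zero_grad(model$layers)
        in_batch <- 0L
      }
    }
    log <- rbind(log, data.frame(epoch = ep, loss = ep_loss / length(ord),
                                 lr = lr_now))
  }
  list(model = model, loss_log = log)
}

#' Predict a label mask for one image
#'
#' Per-pixel argmax of the softmax-normalized scores, ties broken toward
#' the lowest class index. Images whose size differs from the model input
#' size are bilinearly resized for inference and the predicted mask is
#' mapped back by nearest neighbour. When
#' `config$largest_component` is on, only the largest connected component
#' of each foreground class is kept (speckle-like false positives are
#' dropped).
#'
#' @param model Trained segmenter.
#' @param image Matrix or `H x W x C` array in \[0,1\].
#' @param largest_component Override the config flag.
#' @return A [label_mask()] at the original image size.
#' @export
predict_mask <- function(model, image,
                         largest_component = model$config$largest_component) {
  x <- as_t3(image)
  hw <- dim(x)[1:2]
  sz <- model$config$input_size_px
  if (dim(x)[3] != model$config$in_channels) {
    if (model$config$in_channels == 1L) {
      x <- array(apply(x, c(1, 2), mean), dim = c(hw, 1L))
    } else if (dim(x)[3] == 1L) {
      x <- array(rep(x, model$config$in_channels),
                 dim = c(hw, model$config$in_channels))
    } else stop("image channel count does not match the model")
  }
  xi <- if (all(hw == sz)) x else cpp_resize_bilinear(x, sz, sz)
  norm <- model$norm
  if (is.null(norm)) {
    norm <- list(mean = apply(xi, 3, mean), sd = pmax(apply(xi, 3, stats::sd), 1e-6))
  }
  logits <- model$forward(seg_normalize(xi, norm))
  C <- dim(logits)[3]
  flat <- matrix(logits, ncol = C)
  lab <- max.col(flat, ties.method = "first") - 1L   # lowest index wins ties
  lab <- matrix(lab, nrow = sz)
  if (!all(hw == sz)) {
    # nearest-neighbour map back to the original frame
    yi <- pmin(sz, pmax(1, round((seq_len(hw[1]) - 0.5) * sz / hw[1] + 0.5)))
    xj <- pmin(sz, pmax(1, round((seq_len(hw[2]) - 0.5) * sz / hw[2] + 0.5)))
    lab <- lab[yi, xj, drop = FALSE]
  }
  if (isTRUE(largest_component)) {
    for (cl in seq_len(C - 1L)) {
      bin <- lab == cl
      if (!any(bin)) next
      cc <- EBImage::bwlabel(matrix(as.numeric(bin), nrow = nrow(lab)))
      tab <- tabulate(cc[cc > 0])
      keep <- which.max(tab)
      lab[bin & cc != keep] <- 0L
    }
  }
  label_mask(lab)
}
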