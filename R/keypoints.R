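# ------------------------------------------------------------------------
# Keypoint detection stage: a two-branch high-resolution network that
# regresses one Gaussian heatmap per landmark (vertex, palate ray, frontal
# ray), trained with MSE against ground-truth encodings; plus the heatmap
# encode/decode utilities.
# ------------------------------------------------------------------------

#' Keypoint stage configuration
#'
#' Defaults: 256 px input, heatmap stride 4 (the stem's two stride-2
#' convolutions), Gaussian sigma 2 heatmap cells, AdamW (lr 3e-3, betas
#' 0.9/0.999, eps 1e-8, weight decay 1e-4), batch 16, 100 epochs,
#' augmentation scale \[0.65, 1.35\] and rotation ±45°.
#'
#' `input_mode` selects what the network sees: `"concat"` (image channels
#' plus the one-hot segmentation mask — the default, preserving intensity
#' cues while honouring the two-stage design), `"mask_only"`, or
#' `"image_only"`.
#'
#' @param input_size_px Square input size (divisible by the stride).
#' @param heatmap_stride Input pixels per heatmap cell; fixed at 4 by the
#'   stem architecture.
#' @param sigma_px Gaussian width at heatmap scale.
#' @param lr0,batch,epochs,beta1,beta2,eps,weight_decay AdamW settings.
#' @param scale_range,rotation_range_deg Augmentation ranges.
#' @param input_mode See above.
#' @param image_channels Channels of the raw image input (1 for
#'   grayscale).
#' @param widths `"tiny"` or `"small"` preset, or an explicit list
#'   `list(stem = c(s1, s2), w1 =, w2 =)` of branch channel widths.
#' @param n_fusion_stages Number of repeated cross-branch fusion stages.
#' @param refine_decode Quarter-cell sub-pixel refinement at decode
#'   (default off: plain argmax).
#' @param n_keypoints Number of landmarks (3).
#' @param normalization `NULL` (recompute from training inputs) or
#'   `list(mean =, sd =)`.
#' @param seed Training seed.
#' @return List of class `fmf_kp_config`.
#' @export
kp_config <- function(input_size_px = 256L, heatmap_stride = 4L,
                      sigma_px = 2, lr0 = 3e-3, batch = 16L, epochs = 100L,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 1e-4,
                      scale_range = c(0.65, 1.35),
                      rotation_range_deg = c(-45, 45),
                      input_mode = c("concat", "mask_only", "image_only"),
                      image_channels = 1L,
                      widths = c("small", "tiny"),
                      n_fusion_stages = 2L, refine_decode = FALSE,
                      n_keypoints = 3L, normalization = NULL, seed = 1L) {
  input_mode <- match.arg(input_mode)
  if (is.character(widths)) {
    widths <- switch(match.arg(widths),
                     tiny = list(stem = c(8L, 16L), w1 = 16L, w2 = 24L),
                     small = list(stem = c(16L, 32L), w1 = 32L, w2 = 64L))
  }
  cfg <- list(input_size_px = as.integer(input_size_px),
              heatmap_stride = as.integer(heatmap_stride),
              sigma_px = sigma_px, lr0 = lr0, batch = as.integer(batch),
              epochs = as.integer(epochs), beta1 = beta1, beta2 = beta2,
              eps = eps, weight_decay = weight_decay,
              scale_range = scale_range,
              rotation_range_deg = rotation_range_deg,
              input_mode = input_mode,
              image_channels = as.integer(image_channels),
              widths = widths, n_fusion_stages = as.integer(n_fusion_stages),
              refine_decode = refine_decode,
              n_keypoints = as.integer(n_keypoints),
              normalization = normalization, seed = as.integer(seed))
  if (cfg$heatmap_stride != 4L)
    stop("heatmap_stride is fixed at 4 by the two stride-2 stem convolutions")
  if (cfg$input_size_px %% (2L * cfg$heatmap_stride) != 0L)
    stop("input_size_px must be divisible by twice the heatmap stride")
  stopifnot(cfg$sigma_px > 0,
            diff(cfg$scale_range) >= 0, diff(cfg$rotation_range_deg) >= 0)
  cfg$in_channels <- switch(input_mode,
                            mask_only = 3L,
                            image_only = cfg$image_channels,
                            concat = cfg$image_channels + 3L)
  structure(cfg, class = "fmf_kp_config")
}

#' Encode keypoints as Gaussian heatmaps
#'
#' For each visible landmark an unnormalized Gaussian with peak value 1 is
#' rendered at the landmark's heatmap-scale position (`input px /
#' stride`), truncated at 3 sigma; invisible landmarks yield all-zero
#' maps. Centers falling outside the heatmap after the stride mapping are
#' clipped to the border (with a warning unless `warn = FALSE`).
#'
#' @param keypoints A [keypoint_set()] in input-pixel coordinates.
#' @param config A [kp_config()].
#' @param warn Warn on clipped centers.
#' @return Object of class `fmf_heatmap_stack`: list with `maps`
#'   (`H' x W' x K` array), `stride`, `sigma_px`.
#' @export
encode_heatmaps <- function(keypoints, config, warn = TRUE) {
  hw <- config$input_size_px %/% config$heatmap_stride
  K <- config$n_keypoints
  maps <- array(0, dim = c(hw, hw, K))
  m <- kp_matrix(keypoints)
  xs <- 0:(hw - 1)
  for (k in seq_len(K)) {
    if (keypoints$visibility[[k]] == 0L) next
    c_hm <- m[k, ] / config$heatmap_stride
    if (any(c_hm < 0) || any(c_hm > hw - 1)) {
      if (warn) warning("keypoint '", kp_names[k],
                        "' center outside the heatmap; clipped")
      c_hm <- pmin(pmax(c_hm, 0), hw - 1)
    }
    dx2 <- (xs - c_hm[1])^2
    dy2 <- (xs - c_hm[2])^2
    g <- exp(-(outer(dy2, dx2, "+")) / (2 * config$sigma_px^2))
    g[outer(dy2, dx2, "+") > (3 * config$sigma_px)^2] <- 0
    maps[, , k] <- g
  }
  structure(list(maps = maps, stride = config$heatmap_stride,
                 sigma_px = config$sigma_px),
            class = "fmf_heatmap_stack")
}

#' Decode heatmaps to keypoint coordinates
#'
#' Plain argmax per map: the highest-valued cell, ties broken by row-major
#' first occurrence, mapped back to input pixels as `cell * stride`
#' (exact inverse of the encoding's stride mapping on cell centers).
#' An all-zero (or non-positive) map marks its point invisible. With
#' `refine = TRUE` a quarter-cell offset toward the larger of the two
#' axis neighbours is added per axis.
#'
#' @param stack An `fmf_heatmap_stack`.
#' @param refine Sub-cell refinement flag (default: plain argmax).
#' @return A [keypoint_set()] in input-pixel coordinates; visibility 2 for
#'   decoded points, 0 for invisible ones.
#' @export
decode_heatmaps <- function(stack, refine = FALSE) {
  maps <- stack$maps
  K <- dim(maps)[3]
  pts <- matrix(NA_real_, nrow = K, ncol = 2)
  vis <- integer(K)
  for (k in seq_len(K)) {
    m <- maps[, , k]
    if (!any(is.finite(m)) || max(m) <= 0) { vis[k] <- 0L; pts[k, ] <- c(0, 0); next }
    idx <- which.max(t(m))          # row-major first occurrence
    Wp <- ncol(m)
    j <- (idx - 1) %% Wp            # 0-based column
    i <- (idx - 1) %/% Wp           # 0-based row
    ci <- i; cj <- j
    if (refine) {
      if (j > 0 && j < Wp - 1)
        cj <- cj + 0.25 * sign(m[i + 1, j + 2] - m[i + 1, j])
      Hp <- nrow(m)
      if (i > 0 && i < Hp - 1)
        ci <- ci + 0.25 * sign(m[i + 2, j + 1] - m[i, j + 1])
    }
    pts[k, ] <- c(cj, ci) * stack$stride
    vis[k] <- 2L
  }
  keypoint_set(vertex = pts[1, ], palate_ray = pts[2, ],
               frontal_ray = pts[3, ],
               visibility = c(vertex = vis[1], palate_ray = vis[2],
                              frontal_ray = vis[3]))
}

#' Mean-squared-error heatmap loss
#'
#' Mean of squared differences over all cells and maps; zero iff the two
#' stacks are identical.
#'
#' @param pred,truth `fmf_heatmap_stack` objects (or bare arrays) of equal
#'   shape.
#' @return Non-negative scalar.
#' @export
mse_heatmap_loss <- function(pred, truth) {
  p <- if (inherits(pred, "fmf_heatmap_stack")) pred$maps else pred
  t_ <- if (inherits(truth, "fmf_heatmap_stack")) truth$maps else truth
  if (!all(dim(p) == dim(t_))) stop("heatmap stack shapes differ")
  mean((p - t_)^2)
}

#' Build the two-branch high-resolution keypoint network
#'
#' Stem: two 3x3 stride-2 convolutions (4x downsample) followed by four
#' bottleneck blocks. Two parallel branches then run at the stem
#' resolution and at half of it; each fusion stage applies a residual
#' block per branch and exchanges information across scales — downward by
#' a 3x3 stride-2 convolution, upward by nearest-neighbour interpolation
#' followed by a 1x1 channel-matching convolution. A final 1x1 convolution
#' on the high-resolution branch emits one heatmap per landmark at
#' input/stride resolution.
#'
#' @param config A [kp_config()].
#' @return Model handle with `$forward`, `$backward`, `$layers`,
#'   `$n_params`, `$config`.
#' @export
build_keypoint_net <- function(config) {
  set.seed(config$seed)
  w <- config$widths
  net <- new.env(parent = emptyenv())
  net$config <- config
  net$stem <- list(nn_conv(config$in_channels, w$stem[1], 3L, stride = 2L,
                           act = "relu"),
                   nn_conv(w$stem[1], w$stem[2], 3L, stride = 2L,
                           act = "relu"))
  net$bottlenecks <- lapply(1:4, function(i) nn_bottleneck(w$stem[2]))
  net$trH <- nn_conv(w$stem[2], w$w1, 3L, act = "relu")
  net$trL <- nn_conv(w$stem[2], w$w2, 3L, stride = 2L, act = "relu")
  net$stages <- lapply(seq_len(config$n_fusion_stages), function(i) {
    st <- new.env(parent = emptyenv())
    st$blockH <- nn_resblock(w$w1)
    st$blockL <- nn_resblock(w$w2)
    st$up_conv <- nn_conv(w$w2, w$w1, 1L, act = "none")
    st$down_conv <- nn_conv(w$w1, w$w2, 3L, stride = 2L, act = "none")
    # damp the cross-branch injections at init so fused activations keep
    # unit-scale variance (no normalisation layers in this engine)
    st$up_conv$W <- st$up_conv$W * 0.1
    st$down_conv$W <- st$down_conv$W * 0.1
    st
  })
  net$head <- nn_conv(w$w1, config$n_keypoints, 1L, act = "none")
  net$head$W[] <- 0   # start from all-zero heatmaps (MSE target scale)
  net$layers <- nn_collect_params(c(
    net$stem, net$bottlenecks, list(net$trH, net$trL),
    unlist(lapply(net$stages, function(st)
      list(st$blockH, st$blockL, st$up_conv, st$down_conv)),
      recursive = FALSE),
    list(net$head)))
  net$n_params <- nn_param_count(net$layers)
  net$norm <- config$normalization

  net$forward <- function(x) {
    x <- as_t3(x)
    for (l in net$stem) x <- l$forward(x)
    for (b in net$bottlenecks) x <- b$forward(x)
    h <- net$trH$forward(x)
    l <- net$trL$forward(x)
    for (st in net$stages) {
      bh <- st$blockH$forward(h)
      bl <- st$blockL$forward(l)
      h_pre <- bh + st$up_conv$forward(cpp_upsample_nearest(bl, 2L))
      l_pre <- bl + st$down_conv$forward(bh)
      st$maskH <- h_pre > 0
      st$maskL <- l_pre > 0
      h <- h_pre * st$maskH
      l <- l_pre * st$maskL
    }
    net$head$forward(h)
  }
  net$backward <- function(dy) {
    dh <- net$head$backward(dy)
    dl <- 0
    for (st in rev(net$stages)) {
      dh_pre <- dh * st$maskH
      dl_pre <- if (is.array(dl)) dl * st$maskL else st$maskL * 0
      dbh <- dh_pre + st$down_conv$backward(dl_pre)
      dbl <- dl_pre + cpp_upsample_nearest_bwd(st$up_conv$backward(dh_pre), 2L)
      dh <- st$blockH$backward(dbh)
      dl <- st$blockL$backward(dbl)
    }
    dx <- net$trH$backward(dh) + net$trL$backward(dl)
    for (b in rev(net$bottlenecks)) dx <- b$backward(dx)
    for (l in rev(net$stem)) dx <- l$backward(dx)
    dx
  }
  class(net) <- "fmf_keypoint_net"
  net
}

#' @export
print.fmf_keypoint_net <- function(x, ...) {
  cat(sprintf("Keypoint network (two-branch, stride %d, input_mode %s): %d parameters\n",
              x$config$heatmap_stride, x$config$input_mode, x$n_params))
  invisible(x)
}

# Assemble the network input cube for one sample per input_mode.
kp_input_cube <- function(image, mask, mode, n_classes = 3L) {
  img <- as_t3(image)
  if (mode == "image_only") return(img)
  lm <- if (inherits(mask, "fmf_label_mask")) mask$labels else mask
  hw <- dim(lm)
  onehot <- array(0, dim = c(hw, n_classes))
  for (cl in 0:(n_classes - 1L)) onehot[, , cl + 1L] <- (lm == cl) * 1
  if (mode == "mask_only") return(onehot)
  array(c(img, onehot), dim = c(hw, dim(img)[3] + n_classes))
}

# Augmentation affine: output px (input_size frame) -> input px (original
# frame). Geometric model: rotate by theta and scale by s about the
# original image centre, then resize to the network input size.
# Returns the sampling vector m and the forward point map (orig -> net
# input frame) used for keypoints.
kp_aug_affine <- function(orig_hw, in_sz, s = 1, theta_deg = 0) {
  kx <- orig_hw[2] / in_sz
  ky <- orig_hw[1] / in_sz
  cx <- (orig_hw[2] - 1) / 2
  cy <- (orig_hw[1] - 1) / 2
  th <- theta_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2) * s
  Rinv <- solve(R)
  K <- diag(c(kx, ky))
  tres <- c(0.5 * kx - 0.5, 0.5 * ky - 0.5)
  A <- Rinv %*% K
  t_ <- as.numeric(Rinv %*% (tres - c(cx, cy))) + c(cx, cy)
  fwd <- function(p) {
    q <- as.numeric(R %*% (p - c(cx, cy))) + c(cx, cy)   # aug in orig frame
    (q - tres) / c(kx, ky)                               # resize to input
  }
  list(m = c(A[1, 1], A[1, 2], A[2, 1], A[2, 2], t_[1], t_[2]), fwd = fwd)
}

kp_normalize <- function(x, norm) {
  for (c_ in seq_len(dim(x)[3]))
    x[, , c_] <- (x[, , c_] - norm$mean[c_]) / norm$sd[c_]
  x
}

#' Train the keypoint network
#'
#' AdamW on the MSE heatmap loss. Per sample and epoch a random rotation
#' (±45° default) and scale (\[0.65, 1.35\] default) about the image
#' centre is drawn, composed with the resize to the network input size;
#' the identical affine maps the ground-truth keypoints before heatmap
#' encoding. Deterministic given `config$seed`.
#'
#' @param model From [build_keypoint_net()].
#' @param samples List of samples with `$image`, `$mask` and `$keypoints`.
#' @param config A [kp_config()].
#' @return List with `model` and `loss_log` (`epoch`, `loss`).
#' @export
train_keypoint_net <- function(model, samples, config = model$config) {
  if (length(samples) < 2) stop("need at least 2 training samples")
  set.seed(config$seed + 1L)
  sz <- config$input_size_px
  cubes <- lapply(samples, function(s)
    kp_input_cube(s$image, s$mask, config$input_mode))
  if (is.null(model$norm)) {
    nc <- dim(cubes[[1]])[3]
    ch_mean <- rowMeans(matrix(sapply(cubes, function(x) apply(x, 3, mean)), nc))
    ch_sd <- rowMeans(matrix(sapply(cubes, function(x) apply(x, 3, stats::sd)), nc))
    model$norm <- list(mean = ch_mean, sd = pmax(ch_sd, 1e-6))
  }
  opt <- opt_adamw(model$layers, config$lr0, config$beta1, config$beta2,
                   config$eps, config$weight_decay)
  log <- data.frame(epoch = integer(0), loss = numeric(0))
  for (ep in seq_len(config$epochs)) {
    ord <- sample(length(samples))
    ep_loss <- 0
    in_batch <- 0L
    nn_zero_grad(model$layers)
    for (ii in seq_along(ord)) {
      i <- ord[ii]
      s <- stats::runif(1, config$scale_range[1], config$scale_range[2])
      th <- stats::runif(1, config$rotation_range_deg[1],
                         config$rotation_range_deg[2])
      aug <- kp_aug_affine(dim(cubes[[i]])[1:2], sz, s, th)
      xa <- cpp_affine_sample(cubes[[i]], aug$m, sz, sz, FALSE, 0)
      xa <- kp_normalize(xa, model$norm)
      kp <- samples[[i]]$keypoints
      kpt <- keypoint_set(vertex = aug$fwd(kp$vertex),
                          palate_ray = aug$fwd(kp$palate_ray),
                          frontal_ray = aug$fwd(kp$frontal_ray),
                          visibility = kp$visibility)
      truth <- encode_heatmaps(kpt, config, warn = FALSE)
      pred <- model$forward(xa)
      diff <- pred - truth$maps
      loss <- mean(diff^2)
      if (!is.finite(loss))
        stop("non-finite training loss at epoch ", ep, "; aborting")
      ep_loss <- ep_loss + loss
      model$backward(2 * diff / length(diff) / config$batch)
      in_batch <- in_batch + 1L
      if (in_batch == config$batch || ii == length(ord)) {
        opt$step()
        nn_zero_grad(model$layers)
        in_batch <- 0L
      }
    }
    log <- rbind(log, data.frame(epoch = ep, loss = ep_loss / length(ord)))
  }
  list(model = model, loss_log = log)
}

#' Predict the three landmarks for one image
#'
#' Builds the network input per the model's `input_mode` (using `mask`
#' where required), resizes to the network input size, decodes the
#' predicted heatmaps (plain argmax unless the config enables
#' refinement) and maps coordinates back to the original frame.
#'
#' @param model Trained keypoint network.
#' @param image `H x W` matrix or `H x W x C` array.
#' @param mask [label_mask()] (predicted or ground truth); required unless
#'   `input_mode = "image_only"`.
#' @return A [keypoint_set()] in original-image pixel coordinates.
#' @export
predict_keypoints <- function(model, image, mask = NULL) {
  config <- model$config
  if (config$input_mode != "image_only" && is.null(mask))
    stop("input_mode '", config$input_mode, "' requires a mask")
  cube <- kp_input_cube(image, mask, config$input_mode)
  hw <- dim(cube)[1:2]
  sz <- config$input_size_px
  aug <- kp_aug_affine(hw, sz, s = 1, theta_deg = 0)
  xi <- cpp_affine_sample(cube, aug$m, sz, sz, FALSE, 0)
  norm <- model$norm
  if (is.null(norm))
    norm <- list(mean = apply(xi, 3, mean), sd = pmax(apply(xi, 3, stats::sd), 1e-6))
  maps <- model$forward(kp_normalize(xi, norm))
  stack <- structure(list(maps = maps, stride = config$heatmap_stride,
                          sigma_px = config$sigma_px),
                     class = "fmf_heatmap_stack")
  kp_in <- decode_heatmaps(stack, refine = isTRUE(config$refine_decode))
  back <- function(p) c((p[1] + 0.5) * hw[2] / sz - 0.5,
                        (p[2] + 0.5) * hw[1] / sz - 0.5)
  keypoint_set(vertex = back(kp_in$vertex),
               palate_ray = back(kp_in$palate_ray),
               frontal_ray = back(kp_in$frontal_ray),
               visibility = kp_in$visibility)
}
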