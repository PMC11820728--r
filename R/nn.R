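#' @useDynLib fmfangle, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ------------------------------------------------------------------------
# Minimal CNN engine.
#
# Layers are environments exposing forward(x)/backward(dy); parameterised
# layers carry W/b and accumulate dW/db. Tensors are numeric arrays with
# dim c(H, W, C). There is no autograd: each network wires its own backward
# pass, mirroring the forward graph explicitly. Weight matrices are
# (C_out x C_in*k*k) in the im2col column order of src/conv_ops.cpp.
# ------------------------------------------------------------------------

as_t3 <- function(x) {
  if (is.matrix(x)) array(x, dim = c(dim(x), 1L)) else x
}

nn_conv <- function(cin, cout, k, stride = 1L, dil = 1L,
                    act = c("none", "relu")) {
  act <- match.arg(act)
  fan_in <- cin * k * k
  e <- new.env(parent = emptyenv())
  e$W <- matrix(stats::rnorm(cout * fan_in, sd = sqrt(2 / fan_in)), nrow = cout)
  e$b <- numeric(cout)
  e$dW <- e$W * 0
  e$db <- e$b * 0
  e$k <- as.integer(k); e$stride <- as.integer(stride)
  e$dil <- as.integer(dil); e$pad <- as.integer(dil * (k - 1) / 2)
  e$act <- act
  e$forward <- function(x) {
    e$x <- x
    y <- cpp_conv_fwd(x, e$W, e$b, e$k, e$stride, e$pad, e$dil)
    if (e$act == "relu") {
      e$mask <- y > 0
      y[!e$mask] <- 0
    }
    y
  }
  e$backward <- function(dy) {
    if (e$act == "relu") dy <- dy * e$mask
    g <- cpp_conv_bwd(e$x, e$W, dy, e$k, e$stride, e$pad, e$dil)
    e$dW <- e$dW + g$dW
    e$db <- e$db + g$db
    g$dx
  }
  e
}

# Basic residual unit: conv-relu-conv + identity, relu after the add.
# The closing conv is zero-initialised so every block is the identity at
# init: with no normalisation layers this keeps activation variance flat
# regardless of depth (fixup-style residual initialisation).
nn_resblock <- function(ch, dil = 1L) {
  e <- new.env(parent = emptyenv())
  e$c1 <- nn_conv(ch, ch, 3L, dil = dil, act = "relu")
  e$c2 <- nn_conv(ch, ch, 3L, dil = dil, act = "none")
  e$c2$W[] <- 0
  e$forward <- function(x) {
    y <- e$c2$forward(e$c1$forward(x)) + x
    e$mask <- y > 0
    y[!e$mask] <- 0
    y
  }
  e$backward <- function(dy) {
    dy <- dy * e$mask
    dx_branch <- e$c1$backward(e$c2$backward(dy))
    dx_branch + dy
  }
  e$children <- function() list(e$c1, e$c2)
  e
}

# Bottleneck residual unit: 1x1 reduce, 3x3, 1x1 expand, relu after add;
# zero-initialised closing conv (identity at init), as in nn_resblock.
nn_bottleneck <- function(ch, mid = max(1L, ch %/% 2L)) {
  e <- new.env(parent = emptyenv())
  e$c1 <- nn_conv(ch, mid, 1L, act = "relu")
  e$c2 <- nn_conv(mid, mid, 3L, act = "relu")
  e$c3 <- nn_conv(mid, ch, 1L, act = "none")
  e$c3$W[] <- 0
  e$forward <- function(x) {
    y <- e$c3$forward(e$c2$forward(e$c1$forward(x))) + x
    e$mask <- y > 0
    y[!e$mask] <- 0
    y
  }
  e$backward <- function(dy) {
    dy <- dy * e$mask
    dx_branch <- e$c1$backward(e$c2$backward(e$c3$backward(dy)))
    dx_branch + dy
  }
  e$children <- function() list(e$c1, e$c2, e$c3)
  e
}

# ASPP global-average-pooling branch: GAP -> 1x1 conv (a linear map) ->
# relu -> broadcast back over the grid ("image-level" context).
nn_gap_branch <- function(cin, cout) {
  e <- new.env(parent = emptyenv())
  e$W <- matrix(stats::rnorm(cout * cin, sd = sqrt(2 / cin)), nrow = cout)
  e$b <- numeric(cout)
  e$dW <- e$W * 0
  e$db <- e$b * 0
  e$forward <- function(x) {
    d <- dim(x)
    e$hw <- d[1:2]
    e$m <- apply(x, 3, mean)
    v <- drop(e$W %*% e$m + e$b)
    e$mask <- v > 0
    v[!e$mask] <- 0
    e$v <- v
    array(rep(v, each = d[1] * d[2]), dim = c(d[1], d[2], length(v)))
  }
  e$backward <- function(dy) {
    dvec <- apply(dy, 3, sum)
    dvec[!e$mask] <- 0
    e$dW <- e$dW + dvec %*% t(e$m)
    e$db <- e$db + dvec
    dm <- drop(t(e$W) %*% dvec) / prod(e$hw)
    d <- dim(dy)
    array(rep(dm, each = d[1] * d[2]), dim = c(d[1], d[2], length(dm)))
  }
  e
}

nn_upsample_nearest <- function(f) {
  e <- new.env(parent = emptyenv())
  e$f <- as.integer(f)
  e$forward <- function(x) cpp_upsample_nearest(x, e$f)
  e$backward <- function(dy) cpp_upsample_nearest_bwd(dy, e$f)
  e
}

nn_resize_bilinear <- function() {
  e <- new.env(parent = emptyenv())
  e$forward <- function(x, out_hw) {
    e$in_hw <- dim(x)[1:2]
    cpp_resize_bilinear(x, out_hw[1], out_hw[2])
  }
  e$backward <- function(dy) cpp_resize_bilinear_bwd(dy, e$in_hw[1], e$in_hw[2])
  e
}

# Collect every parameterised layer (has $W) reachable from a list that may
# contain composite blocks exposing $children().
nn_collect_params <- function(objs) {
  out <- list()
  for (o in objs) {
    if (is.null(o)) next
    if (!is.null(o$children)) {
      out <- c(out, nn_collect_params(o$children()))
    } else if (!is.null(o$W)) {
      out <- c(out, list(o))
    }
  }
  out
}

nn_zero_grad <- function(layers) {
  for (l in layers) {
    l$dW <- l$dW * 0
    l$db <- l$db * 0
  }
  invisible(NULL)
}

nn_param_count <- function(layers) {
  sum(vapply(layers, function(l) length(l$W) + length(l$b), numeric(1)))
}

# SGD with momentum, L2 weight decay, and polynomial LR decay
# lr = lr0 * (1 - step/total)^power.
opt_sgd_poly <- function(layers, lr0, momentum, weight_decay,
                         total_steps, poly_power) {
  e <- new.env(parent = emptyenv())
  e$step_n <- 0L
  e$vW <- lapply(layers, function(l) l$dW * 0)
  e$vb <- lapply(layers, function(l) l$db * 0)
  e$lr_history <- numeric(0)
  e$step <- function() {
    lr <- lr0 * max(0, 1 - e$step_n / total_steps)^poly_power
    e$lr_history <- c(e$lr_history, lr)
    for (i in seq_along(layers)) {
      l <- layers[[i]]
      gW <- l$dW + weight_decay * l$W
      e$vW[[i]] <- momentum * e$vW[[i]] + gW
      e$vb[[i]] <- momentum * e$vb[[i]] + l$db
      l$W <- l$W - lr * e$vW[[i]]
      l$b <- l$b - lr * e$vb[[i]]
    }
    e$step_n <- e$step_n + 1L
    invisible(lr)
  }
  e
}

# AdamW: decoupled weight decay, bias-corrected moments.
opt_adamw <- function(layers, lr0, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 1e-4) {
  e <- new.env(parent = emptyenv())
  e$step_n <- 0L
  e$mW <- lapply(layers, function(l) l$dW * 0)
  e$vW <- lapply(layers, function(l) l$dW * 0)
  e$mb <- lapply(layers, function(l) l$db * 0)
  e$vb <- lapply(layers, function(l) l$db * 0)
  e$step <- function() {
    e$step_n <- e$step_n + 1L
    t <- e$step_n
    c1 <- 1 - beta1^t
    c2 <- 1 - beta2^t
    for (i in seq_along(layers)) {
      l <- layers[[i]]
      e$mW[[i]] <- beta1 * e$mW[[i]] + (1 - beta1) * l$dW
      e$vW[[i]] <- beta2 * e$vW[[i]] + (1 - beta2) * l$dW^2
      e$mb[[i]] <- beta1 * e$mb[[i]] + (1 - beta1) * l$db
      e$vb[[i]] <- beta2 * e$vb[[i]] + (1 - beta2) * l$db^2
      l$W <- l$W - lr0 * ((e$mW[[i]] / c1) / (sqrt(e$vW[[i]] / c2) + eps) +
                            weight_decay * l$W)
      l$b <- l$b - lr0 * (e$mb[[i]] / c1) / (sqrt(e$vb[[i]] / c2) + eps)
    }
    invisible(lr0)
  }
  e
}

# Serialise / restore parameters of a layer list (checkpointing).
nn_get_state <- function(layers) {
  lapply(layers, function(l) list(W = l$W, b = l$b))
}

nn_set_state <- function(layers, state) {
  stopifnot(length(layers) == length(state))
  for (i in seq_along(layers)) {
    stopifnot(all(dim(layers[[i]]$W) == dim(state[[i]]$W)))
    layers[[i]]$W <- state[[i]]$W
    layers[[i]]$b <- state[[i]]$b
  }
  invisible(NULL)
}
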