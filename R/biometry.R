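#' Euclidean distance between two landmark coordinates
#'
#' Side length of the measurement triangle,
#' \eqn{H = \sqrt{(x_1-x_2)^2 + (y_1-y_2)^2}}, in pixels. Pixels are assumed
#' square and isotropic; anisotropic pixel spacing is not supported anywhere
#' in the package (the angle is invariant to uniform but not anisotropic
#' scaling).
#'
#' @param p1,p2 Numeric length-2 vectors `c(x, y)` in pixel coordinates.
#' @return Non-negative numeric scalar.
#' @examples
#' side_length(c(0, 0), c(3, 4)) # 5
#' @export
side_length <- function(p1, p2) {
  stopifnot(length(p1) == 2, length(p2) == 2,
            all(is.finite(p1)), all(is.finite(p2)))
  sqrt(sum((as.numeric(p1) - as.numeric(p2))^2))
}

#' Frontomaxillary facial angle from three landmarks
#'
#' Computes the FMF angle at the vertex landmark (the anterosuperior corner
#' of the palate) between the ray to the posterior palate point and the ray
#' to the frontal-bone point. The three side lengths are taken with
#' [side_length()] and the angle at the vertex follows the law of cosines,
#' \deqn{\theta = \arccos\frac{b^2 + c^2 - a^2}{2bc},}
#' where `a` is the side opposite the vertex; the result is converted to
#' degrees. The arccos argument is clamped to \[-1, 1\] to guard against
#' floating-point overshoot on (near-)degenerate triangles.
#'
#' The measurement is invariant to translation, rotation, reflection and
#' uniform scaling of the three points.
#'
#' @param keypoints A [keypoint_set()] (or any list with `vertex`,
#'   `palate_ray`, `frontal_ray` length-2 numeric `c(x, y)` entries).
#' @param sample_id Optional sample identifier carried into the result.
#' @return An object of class `fmf_angle_measurement`: list with
#'   `angle_deg`, side lengths `side_a` (opposite the vertex), `side_b`,
#'   `side_c`, `vertex_used`, `degenerate` and `collinear` flags, and
#'   `sample_id`.
#' @examples
#' kp <- keypoint_set(vertex = c(0, 0), palate_ray = c(1, 0),
#'                    frontal_ray = c(0, 1))
#' fmf_angle(kp)$angle_deg # 90
#' @export
fmf_angle <- function(keypoints, sample_id = NA_character_) {
  v <- as.numeric(keypoints$vertex)
  p <- as.numeric(keypoints$palate_ray)
  f <- as.numeric(keypoints$frontal_ray)
  a <- side_length(p, f)          # opposite the vertex
  b <- side_length(v, p)
  c_ <- side_length(v, f)
  if (b < 1e-9 || c_ < 1e-9) {
    stop("degenerate measurement: a side incident to the vertex has ",
         "near-zero length (b = ", format(b), ", c = ", format(c_), ")")
  }
  arg <- (b^2 + c_^2 - a^2) / (2 * b * c_)
  arg <- min(1, max(-1, arg))
  angle <- acos(arg) * 180 / pi
  collinear <- abs(arg) >= 1 - 1e-12
  structure(list(angle_deg = angle,
                 side_a = a, side_b = b, side_c = c_,
                 vertex_used = "vertex",
                 degenerate = FALSE,
                 collinear = collinear,
                 sample_id = sample_id),
            class = "fmf_angle_measurement")
}

#' @export
print.fmf_angle_measurement <- function(x, ...) {
  cat(sprintf("FMF angle: %.3f deg (sides a=%.2f b=%.2f c=%.2f px)%s\n",
              x$angle_deg, x$side_a, x$side_b, x$side_c,
              if (isTRUE(x$collinear)) " [collinear]" else ""))
  invisible(x)
}

#' Measure one image end to end
#'
#' Runs the full three-stage pipeline on a single image: segmentation of the
#' palate and frontal bone with `seg_model`, keypoint inference with
#' `kp_model` (whose `input_mode` decides whether the image, the predicted
#' mask one-hot, or their concatenation is fed in), heatmap decoding, and
#' the law-of-cosines angle. If the keypoint stage returns an invisible
#' point the measurement is marked failed with stage attribution rather
#' than producing an angle.
#'
#' @param seg_model A trained segmenter from [build_segmenter()] /
#'   [train_segmenter()].
#' @param kp_model A trained keypoint network from [build_keypoint_net()] /
#'   [train_keypoint_net()].
#' @param image Numeric `H x W` matrix (grayscale, values in \[0,1\]) or
#'   `H x W x C` array.
#' @param sample_id Identifier recorded in the result.
#' @param debug If `TRUE`, the returned object carries the intermediate
#'   mask and decoded keypoints under `$mask` and `$keypoints`.
#' @return An `fmf_angle_measurement` on success, or a list with
#'   `status = "failed"` and `failed_stage` on failure; successful results
#'   carry `status = "ok"`.
#' @export
measure_sample <- function(seg_model, kp_model, image,
                           sample_id = NA_character_, debug = FALSE) {
  mask <- predict_mask(seg_model, image)
  kps <- predict_keypoints(kp_model, image, mask)
  if (any(kps$visibility < 1)) {
    bad <- names(kps$visibility)[kps$visibility < 1]
    return(list(status = "failed", failed_stage = "keypoints",
                detail = paste("invisible keypoint(s):",
                               paste(bad, collapse = ", ")),
                sample_id = sample_id,
                mask = if (debug) mask else NULL))
  }
  m <- tryCatch(fmf_angle(kps, sample_id = sample_id), error = function(e) e)
  if (inherits(m, "error")) {
    return(list(status = "failed", failed_stage = "biometry",
                detail = conditionMessage(m), sample_id = sample_id,
                mask = if (debug) mask else NULL,
                keypoints = if (debug) kps else NULL))
  }
  m$status <- "ok"
  if (debug) {
    m$mask <- mask
    m$keypoints <- kps
  }
  m
}
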