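# ------------------------------------------------------------------------
# Synthetic mid-sagittal fetal-profile phantoms.
#
# Anatomy is deliberately schematic: the palate is an elongated bright
# quadrilateral whose superior margin runs from the angle vertex V to a
# posterior point P, and the frontal bone is a bright circular-arc band
# whose point closest to V (the outermost anterior point) is F, placed so
# that angle(P, V, F) equals the requested FMF angle exactly before
# rasterization. Ground-truth masks, keypoints and angle are therefore
# exact by construction; speckle, acoustic shadow and blur degrade the
# image only, never the truth.
# ------------------------------------------------------------------------

#' Phantom generation parameters
#'
#' Defaults emulate a mid-trimester mid-sagittal profile at desk scale:
#' a 256 px frame, FMF angles centred on 67.79° with SD 4.609°
#' (the clinical distribution the simulator reproduces), palate roughly a
#' third of the frame, moderate multiplicative speckle, occasional acoustic
#' shadow and mild boundary blur.
#'
#' @param image_height_px,image_width_px Frame size (positive integers).
#' @param target_angle_deg FMF angle to construct, strictly inside (0, 180).
#' @param angle_mean_deg,angle_sd_deg Cohort angle distribution
#'   (truncated-normal parameters used by [generate_cohort()]).
#' @param palate_length_px,palate_thickness_px Palate bar geometry.
#' @param frontal_ray_length_px Distance from the vertex to the frontal
#'   bone point F.
#' @param speckle_strength Multiplicative speckle mixing weight in `[0, 1]`
#'   scale (0 = none); the speckle factor is `(1 - s) + s * E` with
#'   `E ~ Exp(1)`, a unit-mean squared-magnitude Rayleigh-type model.
#' @param shadow_probability Probability of rendering one dark distal
#'   shadow wedge.
#' @param blur_sigma_px Gaussian blur sigma applied to the image.
#' @param rotation_deg Rigid rotation of the whole construct.
#' @param center_xy Optional `c(x, y)` of the vertex V; default places V
#'   left of the frame centre.
#' @param seed Integer RNG seed; generation is deterministic given the spec.
#' @return A list of class `fmf_phantom_spec`.
#' @export
phantom_spec <- function(image_height_px = 256L, image_width_px = 256L,
                         target_angle_deg = 67.79,
                         angle_mean_deg = 67.790, angle_sd_deg = 4.609,
                         palate_length_px = 84, palate_thickness_px = 9,
                         frontal_ray_length_px = 74,
                         speckle_strength = 0.35, shadow_probability = 0.3,
                         blur_sigma_px = 1.2,
                         rotation_deg = 0, center_xy = NULL, seed = 1L) {
  spec <- list(image_height_px = as.integer(image_height_px),
               image_width_px = as.integer(image_width_px),
               target_angle_deg = target_angle_deg,
               angle_mean_deg = angle_mean_deg, angle_sd_deg = angle_sd_deg,
               palate_length_px = palate_length_px,
               palate_thickness_px = palate_thickness_px,
               frontal_ray_length_px = frontal_ray_length_px,
               speckle_strength = speckle_strength,
               shadow_probability = shadow_probability,
               blur_sigma_px = blur_sigma_px,
               rotation_deg = rotation_deg, center_xy = center_xy,
               seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "fmf_phantom_spec")
}

validate_phantom_spec <- function(s) {
  stopifnot(s$image_height_px >= 32, s$image_width_px >= 32)
  if (!(s$target_angle_deg > 0 && s$target_angle_deg < 180))
    stop("target_angle_deg must lie strictly inside (0, 180)")
  for (f in c("palate_length_px", "palate_thickness_px",
              "frontal_ray_length_px"))
    if (s[[f]] <= 0) stop(f, " must be strictly positive")
  stopifnot(s$speckle_strength >= 0,
            s$shadow_probability >= 0, s$shadow_probability <= 1,
            s$blur_sigma_px >= 0)
  invisible(s)
}

rot2 <- function(v, angle_deg) {
  a <- angle_deg * pi / 180
  c(cos(a) * v[1] - sin(a) * v[2], sin(a) * v[1] + cos(a) * v[2])
}

#' Generate one phantom frame with exact ground truth
#'
#' @param spec A [phantom_spec()].
#' @param sample_id Identifier stored on the sample.
#' @return An image sample: list of class `fmf_image_sample` with `image`
#'   (`H x W` matrix in \[0,1\]), `mask` ([label_mask()]), `keypoints`
#'   ([keypoint_set()]), `truth_angle_deg`, `polygons` (the exact structure
#'   outlines, Labelme-ready) and `sample_id`.
#' @export
generate_phantom <- function(spec, sample_id = "phantom") {
  validate_phantom_spec(spec)
  set.seed(spec$seed)
  H <- spec$image_height_px; W <- spec$image_width_px
  ctr <- if (is.null(spec$center_xy)) c(0.32 * (W - 1), 0.58 * (H - 1))
         else spec$center_xy

  u <- rot2(c(1, 0), spec$rotation_deg)          # palate direction V -> P
  n <- c(-u[2], u[1])                             # inferior normal (y-down)
  V <- ctr
  P <- V + spec$palate_length_px * u
  w <- rot2(u, -spec$target_angle_deg)            # ray V -> F
  F_ <- V + spec$frontal_ray_length_px * w

  inframe <- function(p) all(p >= 1) && p[1] <= W - 2 && p[2] <= H - 2
  if (!inframe(V))
    stop("vertex falls outside the frame; adjust center_xy/rotation_deg")
  if (!inframe(P))
    stop("posterior palate point falls outside the frame; ",
         "reduce palate_length_px or rotation_deg")
  if (!inframe(F_))
    stop("frontal bone point falls outside the frame; ",
         "reduce frontal_ray_length_px or rotation_deg")

  th <- spec$palate_thickness_px
  # Quad inflated ~0.6 px beyond the V-P margin so both landmark pixels
  # rasterize inside the structure; truth keypoints stay V and P.
  pal_quad <- rbind(V - 0.6 * u - 0.6 * n,
                    P + 0.6 * u - 0.6 * n,
                    P + 0.6 * u + 1.25 * th * n,   # posterior thickening
                    V - 0.6 * u + th * n)

  # Frontal bone: arc band of a circle centred beyond F along w, so F is
  # the band point closest to V.
  tb <- max(6, 0.8 * th)
  r_f <- 0.9 * spec$frontal_ray_length_px
  Cc <- F_ + r_f * w
  theta0 <- atan2(-w[2], -w[1])                   # direction C -> F
  thetas <- theta0 + seq(-0.8, 0.8, length.out = 41)
  outer_arc <- cbind(Cc[1] + (r_f + 0.6) * cos(thetas),
                     Cc[2] + (r_f + 0.6) * sin(thetas))
  inner_arc <- cbind(Cc[1] + (r_f - tb) * cos(rev(thetas)),
                     Cc[2] + (r_f - tb) * sin(rev(thetas)))
  fro_poly <- rbind(outer_arc, inner_arc)

  polygons <- list(list(label = "palate", points = pal_quad),
                   list(label = "frontal_bone", points = fro_poly))
  mask <- polygons_to_mask(polygons, H, W)

  img <- matrix(0.12, nrow = H, ncol = W)
  img[mask$labels == 1L] <- 0.85
  img[mask$labels == 2L] <- 0.78
  # faint soft-tissue halo above the palate for context
  gx <- matrix(0:(W - 1), H, W, byrow = TRUE)
  gy <- matrix(0:(H - 1), H, W)
  halo <- exp(-((gx - V[1])^2 + (gy - V[2])^2) / (2 * (0.9 * W)^2))
  img <- img + 0.03 * halo

  if (spec$blur_sigma_px > 0)
    img <- as.matrix(EBImage::gblur(img, sigma = spec$blur_sigma_px))
  if (stats::runif(1) < spec$shadow_probability) {
    # dark wedge distal (below) a random point on the palate
    q <- V + stats::runif(1, 0.3, 0.9) * spec$palate_length_px * u +
      1.1 * th * n
    wedge <- (gy > q[2]) & (abs(gx - q[1]) < 0.35 * (gy - q[2]))
    img[wedge] <- img[wedge] * 0.45
  }
  if (spec$speckle_strength > 0) {
    s <- spec$speckle_strength
    fac <- (1 - s) + s * stats::rexp(H * W)
    img <- img * matrix(fac, H, W)
  }
  img <- pmin(pmax(img, 0), 1)

  kps <- keypoint_set(vertex = V, palate_ray = P, frontal_ray = F_)
  structure(list(image = img, mask = mask, keypoints = kps,
                 truth_angle_deg = spec$target_angle_deg,
                 polygons = polygons, sample_id = sample_id),
            class = "fmf_image_sample")
}

#' Generate a phantom cohort with manifest
#'
#' Target angles are drawn from
#' `Normal(angle_mean_deg, angle_sd_deg)` truncated to (45°, 110°); each
#' sample additionally jitters palate length/thickness (±15 % / ±20 %),
#' frontal ray length (±15 %), whole-construct rotation (±20°) and vertex
#' position (±5 % of the frame), so the cohort has no fixed orientation or
#' location.
#'
#' @param n Number of samples (≥ 1).
#' @param base_spec A [phantom_spec()] giving the nominal geometry, noise
#'   and the angle distribution.
#' @param seed Cohort seed; per-sample seeds are derived as `seed * 1000 + i`
#'   so individual samples can be regenerated in isolation.
#' @return `list(samples = <list of fmf_image_sample>,
#'   manifest = <data.frame(sample_id, truth_angle_deg)>)`.
#' @export
generate_cohort <- function(n, base_spec = phantom_spec(), seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  angles <- rtrunc_norm(n, base_spec$angle_mean_deg, base_spec$angle_sd_deg,
                        45, 110)
  jit <- data.frame(pl = stats::runif(n, 0.85, 1.15),
                    pt = stats::runif(n, 0.8, 1.2),
                    fl = stats::runif(n, 0.85, 1.15),
                    rot = stats::runif(n, -20, 20),
                    cx = stats::runif(n, -0.05, 0.05),
                    cy = stats::runif(n, -0.05, 0.05))
  H <- base_spec$image_height_px; W <- base_spec$image_width_px
  samples <- vector("list", n)
  ids <- sprintf("phantom_%04d", seq_len(n))
  for (i in seq_len(n)) {
    sp <- base_spec
    sp$target_angle_deg <- angles[i]
    sp$palate_length_px <- base_spec$palate_length_px * jit$pl[i]
    sp$palate_thickness_px <- base_spec$palate_thickness_px * jit$pt[i]
    sp$frontal_ray_length_px <- base_spec$frontal_ray_length_px * jit$fl[i]
    sp$rotation_deg <- jit$rot[i]
    sp$center_xy <- c((0.32 + jit$cx[i]) * (W - 1), (0.58 + jit$cy[i]) * (H - 1))
    sp$seed <- as.integer(seed * 1000 + i)
    samples[[i]] <- generate_phantom(sp, sample_id = ids[i])
  }
  list(samples = samples,
       manifest = data.frame(sample_id = ids, truth_angle_deg = angles,
                             stringsAsFactors = FALSE))
}

# Truncated-normal draw by rejection (cheap at these acceptance rates).
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) {
    if (mean <= lo || mean >= hi) stop("degenerate mean outside truncation range")
    return(rep(mean, n))
  }
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * (n - length(out)) + 10, mean, sd)
    out <- c(out, x[x > lo & x < hi])
  }
  out[seq_len(n)]
}

#' Simulate a human rater re-measuring known angles
#'
#' Adds a systematic bias and independent Gaussian noise to a vector of
#' true angles, emulating an expert's repeated measurements for
#' agreement-statistics studies.
#'
#' @param truths Numeric vector of true angles (degrees).
#' @param bias_deg Systematic offset added to every measurement.
#' @param sd_deg Random per-measurement SD (≥ 0).
#' @param seed RNG seed.
#' @return Numeric vector of simulated measurements, same length.
#' @export
simulate_rater <- function(truths, bias_deg, sd_deg, seed = 1L) {
  if (sd_deg < 0) stop("sd_deg must be >= 0")
  set.seed(seed)
  truths + bias_deg + stats::rnorm(length(truths), 0, sd_deg)
}

#' Write a phantom cohort to disk in the package's exchange formats
#'
#' Emits, per sample, the image PNG, the indexed label-mask PNG and a
#' Labelme polygon JSON, plus one cohort-level COCO keypoint JSON and the
#' manifest CSV.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom_dataset <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  kp_all <- list()
  for (s in cohort$samples) {
    write_image_png(s$image, file.path(dir, paste0(s$sample_id, ".png")))
    write_mask_png(s$mask, file.path(dir, paste0(s$sample_id, "_mask.png")))
    write_labelme(s$polygons, nrow(s$image), ncol(s$image),
                  file.path(dir, paste0(s$sample_id, ".json")),
                  image_path = paste0(s$sample_id, ".png"))
    kp_all[[s$sample_id]] <- s$keypoints
  }
  write_coco_keypoints(kp_all, file.path(dir, "keypoints_coco.json"),
                       image_size = dim(cohort$samples[[1]]$image))
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}
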