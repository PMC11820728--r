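# Shared fixtures: all data is generated in code at test time.

# Noise-free phantom spec (exact geometry, no speckle/shadow/blur).
clean_spec <- function(...) {
  phantom_spec(speckle_strength = 0, shadow_probability = 0,
               blur_sigma_px = 0, ...)
}

# Small, fast phantom geometry (96 px frame) for training smoke tests.
small_spec <- function(...) {
  phantom_spec(image_height_px = 96L, image_width_px = 96L,
               palate_length_px = 32, palate_thickness_px = 6,
               frontal_ray_length_px = 28, ...)
}

# Tiny segmentation config matched to 96 px phantoms.
small_seg_config <- function(...) {
  seg_config(input_size_px = 96L, in_channels = 1L,
             aspp_dilation_rates = c(2L, 4L, 6L), backbone = "tiny",
             batch = 4L, ...)
}

# Tiny keypoint config matched to 96 px phantoms.
small_kp_config <- function(...) {
  kp_config(input_size_px = 96L, widths = "tiny", batch = 4L, ...)
}

# Independent angle oracle: normalized dot product via atan2 (never the
# law of cosines).
angle_oracle_deg <- function(v, p, f) {
  u1 <- p - v
  u2 <- f - v
  atan2(abs(u1[1] * u2[2] - u1[2] * u2[1]), sum(u1 * u2)) * 180 / pi
}

kp_mat <- function(kps) rbind(kps$vertex, kps$palate_ray, kps$frontal_ray)
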