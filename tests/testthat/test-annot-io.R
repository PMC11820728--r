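test_that("empty annotation rasterizes to all background", {
  m <- polygons_to_mask(list(), 10, 10)
  expect_true(all(m$labels == 0L))
  expect_identical(dim(m$labels), c(10L, 10L))
})

test_that("an axis-aligned square covers exactly the expected pixel centers", {
  sq <- list(label = "palate",
             points = rbind(c(1.5, 1.5), c(5.5, 1.5), c(5.5, 5.5), c(1.5, 5.5)))
  m <- polygons_to_mask(list(sq), 10, 10)
  # independent oracle: explicit point-in-polygon over all 100 pixel centers
  expected <- matrix(0L, 10, 10)
  for (y in 0:9) for (x in 0:9) {
    if (x > 1.5 && x < 5.5 && y > 1.5 && y < 5.5)
      expected[y + 1, x + 1] <- 1L
  }
  expect_identical(m$labels, expected)
  expect_identical(sum(m$labels == 1L), 16L)
})

test_that("later polygons overwrite earlier ones in the overlap", {
  a <- list(label = "palate",
            points = rbind(c(-0.5, -0.5), c(5.5, -0.5), c(5.5, 5.5), c(-0.5, 5.5)))
  b <- list(label = "frontal_bone",
            points = rbind(c(2.5, 2.5), c(7.5, 2.5), c(7.5, 7.5), c(2.5, 7.5)))
  m <- polygons_to_mask(list(a, b), 10, 10)
  expect_identical(m$labels[5, 5], 2L)  # pixel (4,4) lies in both
  expect_identical(m$labels[2, 2], 1L)  # pixel (1,1) only in the first
})

test_that("unknown class names and self-intersections are surfaced", {
  bad <- list(label = "mandible", points = rbind(c(0, 0), c(4, 0), c(4, 4)))
  expect_error(polygons_to_mask(list(bad), 8, 8), "accepted names")
  bowtie <- list(label = "palate",
                 points = rbind(c(0, 0), c(6, 6), c(6, 0), c(0, 6)))
  expect_warning(polygons_to_mask(list(bowtie), 8, 8), "self-intersecting")
})

test_that("the coordinate convention puts the origin at the top-left pixel center", {
  # a tiny square around the origin labels exactly pixel [1, 1]
  corner <- list(label = "palate",
                 points = rbind(c(-0.5, -0.5), c(0.5, -0.5), c(0.5, 0.5),
                                c(-0.5, 0.5)))
  m <- polygons_to_mask(list(corner), 4, 4)
  expect_identical(which(m$labels == 1L), 1L)
})

test_that("Labelme JSON round-trips polygons and dimensions", {
  pg <- list(list(label = "palate",
                  points = rbind(c(1.25, 2.5), c(10.75, 3.5), c(9, 12))),
             list(label = "frontal_bone",
                  points = rbind(c(20, 5), c(25, 6), c(22, 14), c(19, 10))))
  f <- withr::local_tempfile(fileext = ".json")
  write_labelme(pg, 64, 48, f, image_path = "img.png")
  got <- read_labelme(f)
  expect_identical(got$height, 64L)
  expect_identical(got$width, 48L)
  expect_equal(got$polygons[[1]]$points, pg[[1]]$points,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_identical(got$polygons[[2]]$label, "frontal_bone")
})

test_that("COCO keypoints round-trip exactly and reject malformed instances", {
  set.seed(3)
  kps <- list(
    a = keypoint_set(stats::runif(2, 0, 100), stats::runif(2, 0, 100),
                     stats::runif(2, 0, 100)),
    b = keypoint_set(c(10.123456789, 20.987654321), c(5, 6), c(7, 8),
                     visibility = c(vertex = 2L, palate_ray = 1L,
                                    frontal_ray = 0L)))
  f <- withr::local_tempfile(fileext = ".json")
  write_coco_keypoints(kps, f, image_size = c(128, 128))
  got <- read_coco_keypoints(f)
  expect_setequal(names(got), c("a", "b"))
  expect_equal(got$a$vertex, kps$a$vertex, tolerance = 1e-12)
  expect_equal(got$b$vertex, kps$b$vertex, tolerance = 1e-12)
  expect_identical(unname(got$b$visibility), c(2L, 1L, 0L))

  bad <- jsonlite::read_json(f)
  bad$annotations[[1]]$keypoints <- as.list(1:6)  # only 2 keypoints
  f2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(bad, f2, auto_unbox = TRUE)
  expect_error(read_coco_keypoints(f2), "exactly 3")
})

test_that("a phantom dataset export is read back consistent with its manifest", {
  co <- generate_cohort(5, small_spec(), seed = 9)
  d <- withr::local_tempdir()
  write_phantom_dataset(co, d)
  got <- read_coco_keypoints(file.path(d, "keypoints_coco.json"))
  expect_identical(length(got), 5L)
  man <- utils::read.csv(file.path(d, "manifest.csv"))
  for (i in seq_len(5)) {
    id <- man$sample_id[i]
    ang <- fmf_angle(got[[id]])$angle_deg
    expect_equal(ang, man$truth_angle_deg[i], tolerance = 1e-6)
  }
  # image and mask PNG round trips
  s <- co$samples[[1]]
  img2 <- read_image_png(file.path(d, paste0(s$sample_id, ".png")))
  expect_equal(dim(img2), dim(s$image))
  expect_lt(max(abs(img2 - s$image)), 1 / 255)
  m2 <- read_mask_png(file.path(d, paste0(s$sample_id, "_mask.png")))
  expect_identical(m2$labels, s$mask$labels)
})

test_that("mask round-trip: polygon outline of a rasterized rectangle", {
  rect <- list(label = "palate",
               points = rbind(c(2.5, 3.5), c(12.5, 3.5), c(12.5, 8.5),
                              c(2.5, 8.5)))
  m1 <- polygons_to_mask(list(rect), 16, 16)
  w <- which(m1$labels == 1L, arr.ind = TRUE)
  outline <- rbind(c(min(w[, 2]) - 1.5, min(w[, 1]) - 1.5),
                   c(max(w[, 2]) - 0.5, min(w[, 1]) - 1.5),
                   c(max(w[, 2]) - 0.5, max(w[, 1]) - 0.5),
                   c(min(w[, 2]) - 1.5, max(w[, 1]) - 0.5))
  m2 <- polygons_to_mask(list(list(label = "palate", points = outline)), 16, 16)
  expect_identical(m1$labels, m2$labels)
})

test_that("measurement CSVs round-trip", {
  df <- data.frame(sample_id = c("s1", "s2"), angle_deg = c(67.12, 71.9),
                   source = "ai")
  f <- withr::local_tempfile(fileext = ".csv")
  write_measurements_csv(df, f)
  expect_equal(read_measurements_csv(f), df)
})
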