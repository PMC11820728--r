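# ------------------------------------------------------------------------
# Coordinate convention (fixed package-wide): continuous 0-based pixel
# coordinates with the origin at the CENTER of the top-left pixel; x grows
# rightward along columns, y grows downward along rows (the COCO/Labelme
# convention). A continuous point (x, y) therefore lives in R-matrix cell
# [y + 1, x + 1] when x and y are integers.
# ------------------------------------------------------------------------

#' Construct a 3-class label mask
#'
#' @param labels Integer `H x W` matrix with values in
#'   `0:(length(class_names) - 1)`; 0 is background.
#' @param class_names Ordered class names; index 0 must be background.
#' @return Object of class `fmf_label_mask`.
#' @export
label_mask <- function(labels,
                       class_names = c("background", "palate", "frontal_bone")) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (any(labels < 0L | labels >= length(class_names)))
    stop("mask labels must lie in 0..", length(class_names) - 1L)
  structure(list(labels = labels, class_names = class_names),
            class = "fmf_label_mask")
}

#' Construct the three-landmark keypoint set of the FMF measurement
#'
#' The three named landmarks are the angle vertex (anterosuperior palate
#' corner), a point on the palate ray (posterior superior palate margin)
#' and the frontal-bone ray point (outermost anterior point of the frontal
#' bone). Visibility uses the COCO convention: 0 absent, 1 occluded,
#' 2 visible.
#'
#' @param vertex,palate_ray,frontal_ray Numeric `c(x, y)` in pixels.
#' @param visibility Named integer vector of per-point visibility flags.
#' @return Object of class `fmf_keypoint_set`.
#' @export
keypoint_set <- function(vertex, palate_ray, frontal_ray,
                         visibility = c(vertex = 2L, palate_ray = 2L,
                                        frontal_ray = 2L)) {
  pts <- list(vertex = as.numeric(vertex),
              palate_ray = as.numeric(palate_ray),
              frontal_ray = as.numeric(frontal_ray))
  for (nm in names(pts)) {
    if (length(pts[[nm]]) != 2)
      stop("keypoint '", nm, "' must be a length-2 c(x, y) vector")
    if (visibility[[nm]] > 0L && !all(is.finite(pts[[nm]])))
      stop("keypoint '", nm, "' has non-finite coordinates")
  }
  structure(c(pts, list(visibility = visibility[c("vertex", "palate_ray",
                                                  "frontal_ray")])),
            class = "fmf_keypoint_set")
}

kp_names <- c("vertex", "palate_ray", "frontal_ray")

kp_matrix <- function(kps) {
  rbind(vertex = kps$vertex, palate_ray = kps$palate_ray,
        frontal_ray = kps$frontal_ray)
}

# Even-odd point-in-polygon over a vector of query points (px, py).
pip_even_odd <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- (vy[i] > py) != (vy[j] > py)
    if (any(crosses)) {
      xint <- (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]
      inside <- xor(inside, crosses & (px < xint))
    }
    j <- i
  }
  inside
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

is_self_intersecting <- function(pts) {
  n <- nrow(pts)
  if (n < 4) return(FALSE)
  idx <- rbind(seq_len(n), c(seq_len(n)[-1], 1L))
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # shares the closing vertex
      if (segments_intersect(pts[idx[1, i], ], pts[idx[2, i], ],
                             pts[idx[1, j], ], pts[idx[2, j], ]))
        return(TRUE)
    }
  }
  FALSE
}

#' Rasterize polygon annotations into a label mask
#'
#' Polygons are filled by the even-odd rule, evaluated at pixel centers
#' (integer coordinates under the package's 0-based, y-down convention).
#' Polygons are rasterized in file order: later polygons overwrite earlier
#' ones where they overlap; unlabeled pixels stay background.
#' Self-intersecting polygons are still filled by the even-odd rule, with a
#' warning.
#'
#' @param polygons List of records, each `list(label = <class name>,
#'   points = <n x 2 matrix of (x, y)>)` — the layout returned by
#'   [read_labelme()].
#' @param height,width Output mask dimensions in pixels.
#' @param class_names Accepted class names; `label` entries must match a
#'   non-background name.
#' @return An [label_mask()] object.
#' @export
polygons_to_mask <- function(polygons, height, width,
                             class_names = c("background", "palate",
                                             "frontal_bone")) {
  labels <- matrix(0L, nrow = height, ncol = width)
  for (pg in polygons) {
    cls <- match(pg$label, class_names) - 1L
    if (is.na(cls))
      stop("unknown class name '", pg$label, "'; accepted names: ",
           paste(class_names, collapse = ", "))
    pts <- as.matrix(pg$points)
    stopifnot(ncol(pts) == 2, all(is.finite(pts)))
    if (is_self_intersecting(pts))
      warning("self-intersecting polygon for class '", pg$label,
              "'; filled by the even-odd rule")
    xr <- max(0L, floor(min(pts[, 1]))):min(width - 1L, ceiling(max(pts[, 1])))
    yr <- max(0L, floor(min(pts[, 2]))):min(height - 1L, ceiling(max(pts[, 2])))
    if (!length(xr) || !length(yr)) next
    grid <- expand.grid(x = xr, y = yr)
    inside <- pip_even_odd(grid$x, grid$y, pts[, 1], pts[, 2])
    if (any(inside))
      labels[cbind(grid$y[inside] + 1L, grid$x[inside] + 1L)] <- cls
  }
  label_mask(labels, class_names)
}

#' Write / read Labelme-style polygon annotations
#'
#' The JSON layout mirrors the Labelme tool's format (`shapes` with
#' `shape_type = "polygon"`, `imageHeight`/`imageWidth`); points are
#' continuous 0-based `(x, y)` pixel coordinates.
#'
#' @param polygons As in [polygons_to_mask()].
#' @param height,width Image dimensions.
#' @param path Output/input JSON file.
#' @param image_path Value stored under `imagePath`.
#' @return `read_labelme()`: `list(polygons, height, width)`.
#' @export
write_labelme <- function(polygons, height, width, path, image_path = "") {
  shapes <- lapply(polygons, function(pg) {
    list(label = pg$label,
         points = unname(lapply(seq_len(nrow(pg$points)),
                                function(i) as.numeric(pg$points[i, ]))),
         group_id = NULL, shape_type = "polygon", flags = structure(list(), names = character(0)))
  })
  doc <- list(version = "5.0.0", flags = structure(list(), names = character(0)),
              shapes = shapes, imagePath = image_path,
              imageData = NULL, imageHeight = height, imageWidth = width)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_labelme
#' @export
read_labelme <- function(path) {
  doc <- jsonlite::read_json(path)
  polygons <- lapply(doc$shapes, function(sh) {
    if (!identical(sh$shape_type, "polygon"))
      stop("unsupported Labelme shape_type '", sh$shape_type,
           "'; only polygons are read")
    pts <- do.call(rbind, lapply(sh$points, function(p) as.numeric(unlist(p))))
    list(label = sh$label, points = pts)
  })
  list(polygons = polygons, height = doc$imageHeight, width = doc$imageWidth)
}

#' Write / read COCO-style keypoint annotations
#'
#' One category with exactly three named keypoints
#' (`vertex`, `palate_ray`, `frontal_ray`); per-instance keypoints are the
#' flat COCO triplets `x, y, v` with visibility 0 (absent), 1 (occluded) or
#' 2 (visible). A write→read round trip reproduces coordinates exactly
#' (JSON is written at full double precision).
#'
#' @param keypoints Named list of [keypoint_set()] objects; names are the
#'   sample ids.
#' @param path JSON file.
#' @param image_size `c(height, width)` recorded per image.
#' @return `read_coco_keypoints()`: named list mapping sample id to
#'   [keypoint_set()].
#' @export
write_coco_keypoints <- function(keypoints, path, image_size = c(NA, NA)) {
  ids <- names(keypoints)
  stopifnot(!is.null(ids), !any(ids == ""))
  images <- lapply(seq_along(ids), function(i)
    list(id = i, file_name = paste0(ids[i], ".png"),
         height = image_size[1], width = image_size[2]))
  annotations <- lapply(seq_along(ids), function(i) {
    kp <- keypoints[[i]]
    m <- kp_matrix(kp)
    flat <- as.numeric(t(cbind(m, kp$visibility)))
    list(id = i, image_id = i, category_id = 1,
         keypoints = flat, num_keypoints = sum(kp$visibility > 0))
  })
  doc <- list(
    images = images,
    annotations = annotations,
    categories = list(list(
      id = 1, name = "fmf_landmarks", supercategory = "fetal_face",
      keypoints = as.list(kp_names), skeleton = list(c(1, 2), c(1, 3)))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_coco_keypoints
#' @export
read_coco_keypoints <- function(path) {
  doc <- jsonlite::read_json(path)
  id_by_image <- vapply(doc$images, function(im) {
    sub("\\.[A-Za-z]+$", "", im$file_name)
  }, character(1))
  names(id_by_image) <- vapply(doc$images, function(im) as.character(im$id),
                               character(1))
  out <- list()
  for (an in doc$annotations) {
    flat <- as.numeric(unlist(an$keypoints))
    if (length(flat) != 9)
      stop("COCO instance id ", an$id, " has ", length(flat) / 3,
           " keypoints; exactly 3 are required")
    m <- matrix(flat, ncol = 3, byrow = TRUE)
    sid <- id_by_image[[as.character(an$image_id)]]
    out[[sid]] <- keypoint_set(
      vertex = m[1, 1:2], palate_ray = m[2, 1:2], frontal_ray = m[3, 1:2],
      visibility = c(vertex = as.integer(m[1, 3]),
                     palate_ray = as.integer(m[2, 3]),
                     frontal_ray = as.integer(m[3, 3])))
  }
  out
}

#' Image and mask PNG I/O
#'
#' Images are numeric `H x W` (grayscale) or `H x W x C` arrays in \[0,1\].
#' Label masks are written as 8-bit grayscale PNGs holding the raw class
#' index (value `label/255` on the PNG intensity scale) and recovered by
#' rounding on read — lossless for < 256 classes.
#'
#' @param image,mask Image array / [label_mask()].
#' @param path PNG file.
#' @return Readers return the image array or [label_mask()].
#' @export
write_image_png <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3 && dim(img)[3] == 1) img <- img[, , 1]
  img
}

#' @rdname write_image_png
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask$labels / 255, path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_mask_png <- function(path, class_names = c("background", "palate",
                                                "frontal_bone")) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  label_mask(matrix(as.integer(round(img * 255)), nrow = nrow(img)),
             class_names)
}

#' Measurement table CSV I/O
#'
#' Plain CSV with columns `sample_id`, `angle_deg`, `source` (plus any
#' extra columns passed through).
#'
#' @param df Data frame of measurements.
#' @param path CSV file.
#' @export
write_measurements_csv <- function(df, path) {
  stopifnot(all(c("sample_id", "angle_deg") %in% names(df)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurements_csv
#' @export
read_measurements_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
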