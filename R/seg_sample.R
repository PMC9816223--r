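#' Ordered landmark contour
#'
#' A `landmark_shape` is an ordered set of n (x, y) landmarks tracing one
#' closed object contour. Landmark index i is assumed to denote the same
#' anatomical locus in every shape of a collection (point correspondence),
#' which is what makes both shape-model fitting and thin-plate-spline
#' control points meaningful.
#'
#' Coordinates are in pixel units with the origin at the top-left pixel
#' center, x running along columns and y along rows, 0-based.
#'
#' @param points numeric n x 2 matrix (columns x, y), n >= 3, all finite.
#' @return object of class `landmark_shape` (an n x 2 matrix).
#' @export
landmark_shape <- function(points) {
  points <- as.matrix(points)
  check_that(is.numeric(points) && ncol(points) == 2L,
             "axialseg_invalid_argument", "points must be an n x 2 numeric matrix")
  check_that(nrow(points) >= 3L, "axialseg_invalid_argument",
             "a landmark shape needs at least 3 points")
  check_that(all(is.finite(points)), "axialseg_invalid_argument",
             "landmark coordinates must be finite")
  colnames(points) <- c("x", "y")
  structure(points, class = c("landmark_shape", class(points)))
}

as_landmark_shape <- function(x) {
  if (inherits(x, "landmark_shape")) x else landmark_shape(x)
}

#' Flatten a landmark shape to an interleaved coordinate vector
#'
#' Shapes are vectorized as (x1, y1, x2, y2, ...), the layout used by the
#' shape-model mean and mode matrix.
#' @param shape a [landmark_shape()] or n x 2 matrix.
#' @return numeric vector of length 2n.
#' @export
flatten_shape <- function(shape) {
  as.vector(t(unclass(as_landmark_shape(shape))))
}

#' Rebuild a landmark shape from an interleaved coordinate vector
#' @param v numeric vector of length 2n, layout (x1, y1, x2, y2, ...).
#' @return a [landmark_shape()].
#' @export
unflatten_shape <- function(v) {
  check_that(length(v) %% 2L == 0L, "axialseg_invalid_argument",
             "flattened shape length must be even")
  landmark_shape(matrix(v, ncol = 2L, byrow = TRUE))
}

#' Segmentation sample
#'
#' The unit flowing through augmentation, training and evaluation: an image,
#' its binary mask, and optionally the contour the mask was rasterized from.
#'
#' @param image numeric H x W matrix (gray, values in `[0,1]`) or H x W x 3
#'   array (color).
#' @param mask H x W matrix with values exactly 0/1, same spatial size.
#' @param contour optional [landmark_shape()] tracing the mask boundary.
#' @param meta free-form provenance list (seed, generator parameters, ...).
#' @return object of class `seg_sample`.
#' @export
seg_sample <- function(image, mask, contour = NULL, meta = list()) {
  dim_img <- dim(image)[1:2]
  check_that(!is.null(dim(mask)) && all(dim(mask) == dim_img),
             "axialseg_invalid_argument",
             "image and mask must have identical spatial dimensions")
  check_that(all(mask %in% c(0, 1)), "axialseg_invalid_argument",
             "mask values must be exactly 0/1")
  if (!is.null(contour)) contour <- as_landmark_shape(contour)
  structure(list(image = image, mask = mask, contour = contour, meta = meta),
            class = "seg_sample")
}

#' @export
print.seg_sample <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<seg_sample> %dx%d %s, mask area %d px%s\n",
              d[1], d[2], if (length(d) == 3L) "color" else "gray",
              sum(x$mask == 1),
              if (is.null(x$contour)) "" else
                sprintf(", contour with %d landmarks", nrow(x$contour))))
  invisible(x)
}

#' Rasterize a closed contour into a binary mask
#'
#' Scanline polygon fill: a pixel is foreground iff its center lies inside
#' the closed polygon under the even-odd rule. Pixel centers sit at integer
#' coordinates (x = column, y = row, 0-based). The polygon is closed
#' implicitly (last vertex connects back to the first).
#'
#' @param contour a [landmark_shape()] or n x 2 matrix of vertices.
#' @param height,width output mask size in pixels.
#' @return H x W matrix of 0/1.
#' @export
rasterize_contour <- function(contour, height, width) {
  pts <- unclass(as_landmark_shape(contour))
  check_that(is_count(height) && height > 0 && is_count(width) && width > 0,
             "axialseg_invalid_argument", "height and width must be positive")
  n <- nrow(pts)
  x1 <- pts[, 1]; y1 <- pts[, 2]
  x2 <- pts[c(2:n, 1), 1]; y2 <- pts[c(2:n, 1), 2]
  keep <- y1 != y2                       # horizontal edges never cross a scanline
  x1 <- x1[keep]; y1 <- y1[keep]; x2 <- x2[keep]; y2 <- y2[keep]
  mask <- matrix(0, height, width)
  if (!length(x1)) return(mask)
  ylo <- pmin(y1, y2); yhi <- pmax(y1, y2)
  for (row in seq_len(height)) {
    y <- row - 1                         # pixel-center y
    # half-open rule [ylo, yhi): counts each vertex crossing exactly once
    hit <- ylo <= y & y < yhi
    if (!any(hit)) next
    xs <- x1[hit] + (y - y1[hit]) * (x2[hit] - x1[hit]) / (y2[hit] - y1[hit])
    xs <- sort(xs)
    for (k in seq(1L, length(xs) - 1L, by = 2L)) {
      # strict interior: centers with xs[k] < c < xs[k+1]
      lo <- floor(xs[k]) + 1; hi <- ceiling(xs[k + 1L]) - 1
      lo <- max(lo, 0); hi <- min(hi, width - 1)
      if (hi >= lo) mask[row, (lo:hi) + 1L] <- 1
    }
  }
  mask
}

#' Signed polygon area (shoelace formula)
#' @param contour a [landmark_shape()] or n x 2 matrix.
#' @return signed area in square pixels (positive for counter-clockwise in
#'   the y-down image convention when traversed clockwise on screen).
#' @export
polygon_area <- function(contour) {
  pts <- unclass(as_landmark_shape(contour))
  n <- nrow(pts)
  j <- c(2:n, 1)
  sum(pts[, 1] * pts[j, 2] - pts[j, 1] * pts[, 2]) / 2
}

# ---- plain-text / image I/O -------------------------------------------------

#' Write and read contours as CSV
#'
#' One landmark per row, header `x,y`, row order = landmark order.
#' @param contour a [landmark_shape()].
#' @param path file path.
#' @export
write_contour_csv <- function(contour, path) {
  pts <- as.data.frame(unclass(as_landmark_shape(contour)))
  utils::write.csv(pts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_contour_csv
#' @export
read_contour_csv <- function(path) {
  df <- utils::read.csv(path)
  check_that(all(c("x", "y") %in% names(df)), "axialseg_invalid_argument",
             "contour CSV must have columns x,y")
  landmark_shape(as.matrix(df[, c("x", "y")]))
}

#' Read an image file into a [0,1] array
#'
#' PNG via the png package, TIFF via the tiff package (if installed).
#' Gray images are returned as H x W matrices, color as H x W x 3.
#' @param path file path (.png, .tif/.tiff).
#' @return numeric matrix or array with values in `[0,1]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      check_that(requireNamespace("tiff", quietly = TRUE),
                 "axialseg_invalid_argument", "the tiff package is required")
      tiff::readTIFF(path)
    },
    stop_axialseg("axialseg_invalid_argument",
                  sprintf("unsupported image extension '%s'", ext)))
  if (length(dim(img)) == 3L && dim(img)[3] == 4L) img <- img[, , 1:3]  # drop alpha
  if (length(dim(img)) == 3L && dim(img)[3] == 1L) img <- img[, , 1L]
  img
}

#' Write a [0,1] image array to PNG
#' @param image H x W matrix or H x W x 3 array in `[0,1]`.
#' @param path output path (.png).
#' @export
write_image <- function(image, path) {
  png::writePNG(clamp01(image), path)
  invisible(path)
}

#' Write a binary mask as a 0/255 PNG
#' @param mask H x W matrix of 0/1.
#' @param path output path (.png).
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read a 0/255 PNG mask back to 0/1
#' @param path mask PNG path.
#' @export
read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  (m > 0.5) * 1
}

#' Write a list of segmentation samples to a directory
#'
#' For each sample writes `sample_<i>.png` (image), `sample_<i>_mask.png`
#' (0/255 mask) and, when a contour is present, `sample_<i>_contour.csv`.
#' @param samples list of [seg_sample()] objects.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_samples <- function(samples, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    write_image(s$image, file.path(dir, sprintf("sample_%03d.png", i)))
    write_mask(s$mask, file.path(dir, sprintf("sample_%03d_mask.png", i)))
    if (!is.null(s$contour))
      write_contour_csv(s$contour,
                        file.path(dir, sprintf("sample_%03d_contour.csv", i)))
  }
  invisible(dir)
}
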