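# 2D thin-plate-spline mapping: an affine part (the behavior at infinity)
# plus a weighted sum of radial kernels U(r) = r^2 log(r^2) centered at the
# control points, exact at the control points when unregularized. Used to
# pull real-image gray values into simulated shapes.

# U(r) computed from squared radius; U(0) := 0 (the r^2 log r^2 limit).
tps_kernel_rsq <- function(rsq) {
  out <- rsq * log(rsq)
  out[rsq == 0] <- 0
  out
}

#' Fit a 2D thin-plate-spline transform from point correspondences
#'
#' Solves the standard TPS linear system: the kernel matrix
#' `K[i,j] = U(|p_i - p_j|)` with `U(r) = r^2 log(r^2)` (and `U(0) = 0`),
#' bordered by the affine block `[1, x, y]`. With `regularization = 0` the
#' fitted map interpolates: `f(source_i) = target_i` exactly. A positive
#' regularization adds `reg * I` to K, trading exactness for smoothness
#' (useful for noisy landmarks). The side conditions `sum(w) = 0`,
#' `sum(w*x) = 0`, `sum(w*y) = 0` are enforced by the system itself.
#'
#' @param source_points n x 2 source landmarks (n >= 3, not all collinear).
#' @param target_points n x 2 target landmarks.
#' @param regularization nonnegative smoothing scalar (default 0: exact
#'   interpolation).
#' @return a `tps_transform`: `affine` (3 x 2 matrix, rows = constant, x, y
#'   coefficients; columns = output x, y), `weights` (n x 2 radial
#'   coefficients), `control_points`, `regularization`.
#' @export
fit_tps <- function(source_points, target_points, regularization = 0) {
  src <- unclass(as_landmark_shape(source_points))
  tgt <- unclass(as_landmark_shape(target_points))
  check_that(nrow(src) == nrow(tgt), "axialseg_invalid_argument",
             "source and target must have the same number of points")
  check_that(regularization >= 0, "axialseg_invalid_argument",
             "regularization must be nonnegative")
  n <- nrow(src)
  D2 <- outer(src[, 1], src[, 1], `-`)^2 + outer(src[, 2], src[, 2], `-`)^2
  K <- tps_kernel_rsq(D2) + regularization * diag(n)
  P <- cbind(1, src)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- rbind(tgt, matrix(0, 3, 2))
  sol <- tryCatch(solve(L, rhs), error = function(e)
    stop_axialseg("axialseg_singular_system",
                  paste0("TPS system is singular (collinear or duplicated ",
                         "control points with regularization 0)")))
  structure(list(affine = sol[n + (1:3), , drop = FALSE],
                 weights = sol[seq_len(n), , drop = FALSE],
                 control_points = src,
                 regularization = regularization),
            class = "tps_transform")
}

#' @export
print.tps_transform <- function(x, ...) {
  cat(sprintf("<tps_transform> %d control points, reg = %g, max|w| = %.3g\n",
              nrow(x$control_points), x$regularization, max(abs(x$weights))))
  invisible(x)
}

#' Apply a thin-plate-spline transform to points
#'
#' Evaluates f(x, y) = affine part + sum_i w_i U(|p_i - (x, y)|) for each
#' input point. The function is total: any finite point maps to a finite
#' point.
#'
#' @param transform a [fit_tps()] result.
#' @param points m x 2 matrix of (x, y) points.
#' @return m x 2 matrix of mapped points.
#' @export
apply_tps <- function(transform, points) {
  pts <- as.matrix(points)
  if (is.null(dim(pts)) || ncol(pts) != 2L) pts <- matrix(pts, ncol = 2L)
  cp <- transform$control_points
  D2 <- outer(pts[, 1], cp[, 1], `-`)^2 + outer(pts[, 2], cp[, 2], `-`)^2
  U <- tps_kernel_rsq(D2)
  unname(cbind(1, pts) %*% transform$affine + U %*% transform$weights)
}

# Bilinear sampling of a single-channel image at continuous 0-based
# coordinates; out-of-range samples get fill_value. Exact at integer
# coordinates.
bilinear_sample <- function(img, x, y, fill_value = 0) {
  H <- nrow(img); W <- ncol(img)
  tol <- 1e-6                          # absorb round-off at the image border
  inside <- x >= -tol & x <= W - 1 + tol & y >= -tol & y <= H - 1 + tol
  out <- rep(fill_value, length(x))
  if (!any(inside)) return(out)
  xi <- pmin(pmax(x[inside], 0), W - 1)
  yi <- pmin(pmax(y[inside], 0), H - 1)
  x0 <- pmin(floor(xi), W - 2); y0 <- pmin(floor(yi), H - 2)
  fx <- xi - x0; fy <- yi - y0
  i00 <- (x0) * H + y0 + 1         # column-major linear index, 0-based coords
  v00 <- img[i00];         v01 <- img[i00 + H]
  v10 <- img[i00 + 1];     v11 <- img[i00 + H + 1]
  out[inside] <- (1 - fy) * ((1 - fx) * v00 + fx * v01) +
    fy * ((1 - fx) * v10 + fx * v11)
  out
}

nearest_sample <- function(img, x, y, fill_value = 0) {
  H <- nrow(img); W <- ncol(img)
  xi <- round(x); yi <- round(y)
  tol <- 1e-6
  inside <- x >= -tol & x <= W - 1 + tol & y >= -tol & y <= H - 1 + tol
  xi <- pmin(pmax(xi, 0), W - 1); yi <- pmin(pmax(yi, 0), H - 1)
  out <- rep(fill_value, length(x))
  out[inside] <- img[cbind(yi[inside] + 1, xi[inside] + 1)]
  out
}

#' Warp real-image texture through a thin-plate-spline transform
#'
#' For every output pixel t = (x, y) (pixel centers at integer 0-based
#' coordinates), computes t' = f(t) and samples the real image at t' —
#' i.e. the transform must have been fitted with source = simulated-image
#' landmarks and target = real-image landmarks, so gray values of t' in the
#' real image are inserted at t in the simulated image. Sampling is
#' bilinear by default (nearest-neighbor available); t' outside the real
#' image yields `fill_value`.
#'
#' @param real_image H x W matrix or H x W x 3 array, values in `[0,1]`.
#' @param transform a [fit_tps()] result mapping output to input coordinates.
#' @param out_height,out_width output size in pixels (positive).
#' @param fill_value gray level for out-of-bounds samples (default 0).
#' @param interpolation "bilinear" (default) or "nearest".
#' @return warped image with the requested size and the input's channel
#'   count.
#' @export
warp_texture <- function(real_image, transform, out_height, out_width,
                         fill_value = 0,
                         interpolation = c("bilinear", "nearest")) {
  check_that(is_count(out_height) && out_height > 0 &&
               is_count(out_width) && out_width > 0,
             "axialseg_invalid_argument",
             "output dimensions must be positive integers")
  interpolation <- match.arg(interpolation)
  grid <- cbind(x = rep(0:(out_width - 1), each = out_height),
                y = rep(0:(out_height - 1), times = out_width))
  mapped <- apply_tps(transform, grid)
  sampler <- if (interpolation == "bilinear") bilinear_sample else nearest_sample
  if (length(dim(real_image)) == 3L) {
    ch <- dim(real_image)[3]
    out <- array(0, c(out_height, out_width, ch))
    for (c in seq_len(ch))
      out[, , c] <- matrix(sampler(real_image[, , c], mapped[, 1], mapped[, 2],
                                   fill_value), out_height, out_width)
    out
  } else {
    matrix(sampler(real_image, mapped[, 1], mapped[, 2], fill_value),
           out_height, out_width)
  }
}

#' Serialize / deserialize a TPS transform as JSON
#' @param transform a [fit_tps()] result.
#' @param path file path.
#' @export
write_tps <- function(transform, path) {
  obj <- list(format = "axialseg_tps", version = 1L,
              affine = as.vector(transform$affine),
              weights_row_major = as.vector(t(transform$weights)),
              control_points_row_major = as.vector(t(transform$control_points)),
              n_points = nrow(transform$control_points),
              regularization = transform$regularization)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tps
#' @export
read_tps <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  check_that(identical(obj$format, "axialseg_tps"),
             "axialseg_invalid_argument", "not a TPS transform file")
  n <- obj$n_points
  structure(list(affine = matrix(obj$affine, 3, 2),
                 weights = matrix(obj$weights_row_major, n, 2, byrow = TRUE),
                 control_points = matrix(obj$control_points_row_major, n, 2,
                                         byrow = TRUE),
                 regularization = obj$regularization),
            class = "tps_transform")
}
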