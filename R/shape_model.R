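# Statistical shape model (point distribution model): generalized Procrustes
# alignment, PCA over aligned landmark vectors, and simulated-shape sampling
# with mode coefficients bounded by an eigenvalue-scaled hyperrectangle.

centroid_size <- function(pts) {
  c0 <- colMeans(pts)
  sqrt(sum(sweep(pts, 2, c0)^2))
}

# Optimal similarity (rotation + isotropic scale) mapping centered X onto
# centered Y in the least-squares sense, row-vector convention X %*% R.
similarity_rotation_scale <- function(Xc, Yc) {
  C <- crossprod(Xc, Yc)
  sv <- svd(C)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, d)) %*% t(sv$v)
  s <- sum(sv$d * c(1, d)) / sum(Xc^2)
  list(rotation = R, scale = s)
}

# Make mode signs deterministic: largest-magnitude component positive.
fix_mode_signs <- function(E) {
  for (j in seq_len(ncol(E))) {
    i <- which.max(abs(E[, j]))
    if (E[i, j] < 0) E[, j] <- -E[, j]
  }
  E
}

new_shape_model <- function(mean_shape, modes, eigenvalues, n_landmarks,
                            alignment_record = NULL) {
  structure(list(mean_shape = mean_shape, modes = modes,
                 eigenvalues = eigenvalues, n_landmarks = n_landmarks,
                 alignment_record = alignment_record),
            class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  k <- length(x$eigenvalues)
  tot <- sum(x$eigenvalues)
  cat(sprintf("<shape_model> %d landmarks, %d mode%s", x$n_landmarks, k,
              if (k == 1) "" else "s"))
  if (tot > 0)
    cat(sprintf(", leading mode explains %.1f%% of retained variance",
                100 * x$eigenvalues[1] / tot))
  cat("\n")
  invisible(x)
}

#' Generalized Procrustes alignment of a landmark collection
#'
#' Iteratively similarity-aligns (translation, rotation, isotropic scale)
#' every shape to the running mean, renormalizing the mean to be centered at
#' the origin with unit centroid size, until the mean changes by less than
#' 1e-10 (or 100 iterations). Pose is thereby removed before PCA; the
#' per-shape transforms are returned so model-space shapes can be re-posed
#' into image coordinates.
#'
#' @param shapes list of [landmark_shape()] objects with equal landmark
#'   counts (>= 2 shapes).
#' @return list with `shapes` (aligned [landmark_shape()]s) and `record`
#'   (per-shape list of `rotation` (2x2), `scale`, `centroid`, such that
#'   aligned = scale * (original - centroid) %*% rotation).
#' @export
align_shapes <- function(shapes) {
  check_that(is.list(shapes) && length(shapes) >= 2,
             "axialseg_invalid_argument", "need at least 2 shapes")
  shapes <- lapply(shapes, as_landmark_shape)
  ns <- vapply(shapes, nrow, 0L)
  check_that(length(unique(ns)) == 1L, "axialseg_invalid_argument",
             "all shapes must have the same landmark count")
  Z <- vector("list", length(shapes))
  rec <- vector("list", length(shapes))
  for (i in seq_along(shapes)) {
    pts <- unclass(shapes[[i]])
    c0 <- colMeans(pts)
    sz <- centroid_size(pts)
    check_that(sz > 1e-12, "axialseg_degenerate_shape",
               sprintf("shape %d is degenerate (zero centroid size)", i))
    Z[[i]] <- sweep(pts, 2, c0) / sz
    rec[[i]] <- list(rotation = diag(2), scale = 1 / sz, centroid = c0)
  }
  normalize <- function(M) {
    M <- sweep(M, 2, colMeans(M))
    M / sqrt(sum(M^2))
  }
  mean_shape <- normalize(Reduce(`+`, Z) / length(Z))
  for (iter in seq_len(100L)) {
    for (i in seq_along(Z)) {
      fit <- similarity_rotation_scale(Z[[i]], mean_shape)
      Z[[i]] <- fit$scale * Z[[i]] %*% fit$rotation
      rec[[i]]$rotation <- rec[[i]]$rotation %*% fit$rotation
      rec[[i]]$scale <- rec[[i]]$scale * fit$scale
    }
    new_mean <- normalize(Reduce(`+`, Z) / length(Z))
    delta <- sqrt(sum((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < 1e-10) break
  }
  list(shapes = lapply(Z, landmark_shape), record = rec)
}

# Map a model-space (aligned-frame) shape into image coordinates using a
# pose record from align_shapes (the inverse of the alignment map).
repose_shape <- function(shape, pose) {
  pts <- unclass(as_landmark_shape(shape))
  img <- (pts %*% t(pose$rotation)) / pose$scale
  landmark_shape(sweep(img, 2, pose$centroid, `+`))
}

#' Fit a statistical shape model by PCA over aligned landmark vectors
#'
#' Shapes are flattened to interleaved 2n-vectors; the model keeps the
#' arithmetic mean and the top-k eigenpairs of the sample covariance
#' (divisor N-1). With `k = "auto"` the smallest k explaining at least 98%
#' of total variance is kept. Mode signs follow the convention that each
#' mode's largest-magnitude component is positive.
#'
#' @param shapes list of [landmark_shape()]s, already co-registered (or set
#'   `align = TRUE` to run [align_shapes()] first).
#' @param k number of modes to keep, or `"auto"`.
#' @param align if TRUE, generalized-Procrustes-align the shapes first.
#' @return a `shape_model`: `mean_shape` (2n vector), `modes` (2n x k,
#'   orthonormal columns), `eigenvalues` (nonincreasing), `n_landmarks`,
#'   and `alignment_record` (NULL unless `align = TRUE`).
#' @export
fit_shape_model <- function(shapes, k = "auto", align = FALSE) {
  check_that(is.list(shapes) && length(shapes) >= 2,
             "axialseg_invalid_argument", "need at least 2 shapes")
  record <- NULL
  if (align) {
    al <- align_shapes(shapes)
    shapes <- al$shapes
    record <- al$record
  }
  X <- t(vapply(shapes, flatten_shape, numeric(2L * nrow(shapes[[1]]))))
  N <- nrow(X); p <- ncol(X)
  kmax <- min(N - 1L, p)
  mean_v <- colMeans(X)
  S <- stats::cov(X)
  eig <- eigen(S, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  if (identical(k, "auto")) {
    tot <- sum(vals)
    k <- if (tot <= 0) 1L else which(cumsum(vals) / tot >= 0.98)[1L]
    k <- min(k, kmax)
  } else {
    check_that(is_count(k) && k >= 1, "axialseg_invalid_argument",
               "k must be a positive integer or \"auto\"")
    check_that(k <= kmax, "axialseg_invalid_argument",
               sprintf("k = %d exceeds available eigenpairs (%d)", k, kmax))
  }
  modes <- fix_mode_signs(eig$vectors[, seq_len(k), drop = FALSE])
  new_shape_model(mean_shape = mean_v, modes = modes,
                  eigenvalues = vals[seq_len(k)],
                  n_landmarks = p %/% 2L, alignment_record = record)
}

hyperrect_bound <- function(model, alpha = 1.5) alpha * sqrt(model$eigenvalues)

#' Generate a shape from mode coefficients
#'
#' Returns mean + modes %*% b as a landmark shape. The coefficients must lie
#' inside the plausibility hyperrectangle |b_j| <= 1.5 * sqrt(lambda_j);
#' values outside raise a bound-violation error rather than being clipped,
#' so implausible shapes can never be produced silently.
#'
#' @param model a [fit_shape_model()] result.
#' @param b numeric coefficient vector of length k.
#' @return a [landmark_shape()] in the model (aligned) frame.
#' @export
sample_shape <- function(model, b) {
  k <- length(model$eigenvalues)
  check_that(length(b) == k, "axialseg_invalid_argument",
             sprintf("b must have length %d", k))
  bound <- hyperrect_bound(model) * (1 + 1e-9) + 1e-12
  if (any(abs(b) > bound))
    stop_axialseg("axialseg_bound_violation",
                  "b lies outside the hyperrectangle |b_j| <= 1.5*sqrt(lambda_j)")
  unflatten_shape(model$mean_shape + as.vector(model$modes %*% b))
}

#' Draw a random simulated shape from the model
#'
#' Coefficients are drawn independently and uniformly on
#' `[-alpha*sqrt(lambda_j), +alpha*sqrt(lambda_j)]` (alpha <= 1.5), the full
#' plausible range, then passed through [sample_shape()].
#'
#' @param model a shape model with at least one mode.
#' @param rng_seed integer seed; fixed seed gives an identical shape.
#' @param alpha hyperrectangle half-width multiplier, in (0, 1.5].
#' @return list with `shape` (a [landmark_shape()]) and `b` (the drawn
#'   coefficients).
#' @export
random_shape <- function(model, rng_seed, alpha = 1.5) {
  k <- length(model$eigenvalues)
  check_that(k >= 1, "axialseg_invalid_argument", "model has no modes")
  check_that(alpha > 0 && alpha <= 1.5, "axialseg_invalid_argument",
             "alpha must be in (0, 1.5]")
  b <- with_seed(rng_seed,
                 stats::runif(k, -1, 1) * alpha * sqrt(model$eigenvalues))
  list(shape = sample_shape(model, b), b = b)
}

#' Project a shape onto the model's mode subspace
#'
#' @param model a shape model.
#' @param shape a [landmark_shape()] in the model frame.
#' @return coefficient vector b = t(E) (s - mean).
#' @export
project_shape <- function(model, shape) {
  v <- flatten_shape(shape) - model$mean_shape
  as.vector(crossprod(model$modes, v))
}

#' Reconstruct a shape from its first k mode coefficients
#'
#' Analysis helper (no hyperrectangle bound): reconstructs
#' mean + E[, 1:k] %*% b[1:k] from the projection of `shape`. Used to study
#' how reconstruction error decreases with the number of retained modes.
#'
#' @param model a shape model.
#' @param shape shape to reconstruct.
#' @param k number of leading modes to use (default: all).
#' @export
reconstruct_shape <- function(model, shape, k = length(model$eigenvalues)) {
  check_that(is_count(k) && k >= 0 && k <= length(model$eigenvalues),
             "axialseg_invalid_argument", "invalid k")
  b <- project_shape(model, shape)
  v <- model$mean_shape
  if (k > 0)
    v <- v + as.vector(model$modes[, seq_len(k), drop = FALSE] %*%
                         b[seq_len(k)])
  unflatten_shape(v)
}

#' Serialize / deserialize a shape model as JSON
#'
#' Stores mean, modes (row-major), eigenvalues, landmark count and the
#' alignment convention tag in a single JSON file.
#' @param model a shape model.
#' @param path file path.
#' @export
write_shape_model <- function(model, path) {
  obj <- list(format = "axialseg_shape_model", version = 1L,
              alignment = "gpa-similarity-unit-centroid-size",
              n_landmarks = model$n_landmarks,
              mean_shape = model$mean_shape,
              modes_row_major = as.vector(t(model$modes)),
              n_modes = ncol(model$modes),
              eigenvalues = model$eigenvalues)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_shape_model
#' @export
read_shape_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  check_that(identical(obj$format, "axialseg_shape_model"),
             "axialseg_invalid_argument", "not a shape model file")
  k <- obj$n_modes
  modes <- matrix(obj$modes_row_major, ncol = k, byrow = TRUE)
  new_shape_model(mean_shape = obj$mean_shape, modes = modes,
                  eigenvalues = obj$eigenvalues,
                  n_landmarks = obj$n_landmarks)
}
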