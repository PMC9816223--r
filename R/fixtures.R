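# Seeded synthetic fixtures: organ-like blobs with known contours, and
# landmark populations drawn from a known shape model. Everything here is a
# pure function of its arguments (including the seed), so downstream modules
# are testable without external data.

#' Generate a dataset of synthetic organ-like blob samples
#'
#' Each sample is a star-convex blob: radius as a function of polar angle is
#' a base radius plus a low-order Fourier perturbation (orders 2-5), with a
#' randomly jittered center and scale. The contour is sampled at
#' `n_landmarks` equal angular steps, which guarantees landmark
#' correspondence across samples by construction. The interior and exterior
#' carry visibly different textures; the mask is the even-odd rasterization
#' of the contour polygon, so mask and contour agree exactly.
#'
#' `round(noise_fraction * n)` samples (chosen at random) additionally carry
#' additive Gaussian noise with mean 0 and variance `noise_variance`,
#' clipped back to `[0,1]` — emulating a noisy acquisition subset.
#'
#' @param n number of samples (>= 1).
#' @param image_size side length in pixels (>= 32; images are square).
#' @param n_landmarks contour landmarks per sample (>= 8).
#' @param noise_fraction proportion of samples receiving additive noise.
#' @param noise_variance variance of the additive Gaussian noise.
#' @param seed integer seed; identical seed gives bit-identical output.
#' @param color if TRUE, produce 3-channel samples by mapping the gray
#'   texture through a fixed tongue-like palette.
#' @return list of [seg_sample()] objects.
#' @examples
#' ds <- make_blob_dataset(n = 4, image_size = 32, n_landmarks = 16, seed = 1)
#' ds[[1]]
#' @export
make_blob_dataset <- function(n, image_size = 64, n_landmarks = 32,
                              noise_fraction = 0, noise_variance = 0.02,
                              seed = 1, color = FALSE) {
  check_that(is_count(n) && n >= 1, "axialseg_invalid_argument",
             "n must be a positive integer")
  check_that(is_count(image_size) && image_size >= 32,
             "axialseg_invalid_argument", "image_size must be >= 32")
  check_that(is_count(n_landmarks) && n_landmarks >= 8,
             "axialseg_invalid_argument", "n_landmarks must be >= 8")
  check_that(noise_fraction >= 0 && noise_fraction <= 1,
             "axialseg_invalid_argument", "noise_fraction must be in [0,1]")
  with_seed(seed, {
    noisy <- rep(FALSE, n)
    n_noisy <- round(noise_fraction * n)
    if (n_noisy > 0) noisy[sample.int(n, n_noisy)] <- TRUE
    lapply(seq_len(n), function(i) {
      make_one_blob(image_size, n_landmarks, noisy[i], noise_variance,
                    seed = seed, index = i, color = color)
    })
  })
}

# One blob sample; consumes the active RNG stream.
make_one_blob <- function(image_size, n_landmarks, noisy, noise_variance,
                          seed, index, color) {
  H <- image_size; W <- image_size
  center <- W / 2 + stats::runif(2, -0.06, 0.06) * W
  r0 <- W * stats::runif(1, 0.22, 0.30)
  orders <- 2:5
  amp <- stats::rnorm(length(orders), 0, 0.05 / sqrt(orders))
  phase <- stats::runif(length(orders), 0, 2 * pi)
  theta <- 2 * pi * (seq_len(n_landmarks) - 1) / n_landmarks
  radius <- r0 * (1 + colSums(amp * cos(outer(orders, theta) +
                                          matrix(phase, length(orders), n_landmarks))))
  contour <- landmark_shape(cbind(x = center[1] + radius * cos(theta),
                                  y = center[2] + radius * sin(theta)))
  mask <- rasterize_contour(contour, H, W)

  # textures: bright, finely speckled interior; darker, smoothly graded exterior
  xg <- matrix(seq(0, 1, length.out = W), H, W, byrow = TRUE)
  yg <- matrix(seq(0, 1, length.out = H), H, W)
  interior <- 0.72 + 0.08 * sin(2 * pi * 6 * xg) * sin(2 * pi * 6 * yg) +
    matrix(stats::rnorm(H * W, 0, 0.04), H, W)
  exterior <- 0.22 + 0.10 * xg + 0.05 * yg +
    matrix(stats::rnorm(H * W, 0, 0.03), H, W)
  img <- clamp01(exterior * (1 - mask) + interior * mask)
  if (noisy) img <- clamp01(img + matrix(stats::rnorm(H * W, 0, sqrt(noise_variance)), H, W))
  if (color) {
    img <- array(c(0.55 + 0.45 * img, 0.25 + 0.55 * img, 0.30 + 0.40 * img),
                 c(H, W, 3))
    img <- clamp01(img)
  }
  seg_sample(img, mask, contour,
             meta = list(seed = seed, index = index, noisy = noisy,
                         noise_variance = if (noisy) noise_variance else 0,
                         center = center, base_radius = r0))
}

#' Generate a landmark population from a known shape model
#'
#' Draws `n_shapes` shapes as mean + sum_j b_j * mode_j with
#' b_j ~ Normal(0, lambda_j), from a randomly oriented orthonormal mode
#' basis, and returns both the sample and the generating model — the
#' ground truth for parameter-recovery tests of shape-model fitting.
#'
#' The mean shape is a unit-centroid-size circle of `n_landmarks` points
#' centered at the origin, i.e. shapes are generated directly in the
#' aligned (pose-free) frame.
#'
#' @param n_shapes number of shapes to draw.
#' @param n_landmarks landmarks per shape.
#' @param true_modes number of variation modes (>= 1, and at most
#'   2*n_landmarks - 4, the dimension left after similarity pose removal).
#' @param true_eigenvalues per-mode variances, strictly positive and
#'   nonincreasing, length `true_modes`.
#' @param seed integer seed.
#' @return list with elements `shapes` (list of [landmark_shape()]) and
#'   `model` (the generating [shape_model] with known mean/modes/eigenvalues).
#' @export
make_landmark_population <- function(n_shapes, n_landmarks = 32,
                                     true_modes = 2,
                                     true_eigenvalues = c(4e-3, 1e-3),
                                     seed = 1) {
  check_that(is_count(n_shapes) && n_shapes >= 1, "axialseg_invalid_argument",
             "n_shapes must be a positive integer")
  check_that(is_count(true_modes) && true_modes >= 1,
             "axialseg_invalid_argument", "true_modes must be >= 1")
  check_that(length(true_eigenvalues) == true_modes,
             "axialseg_invalid_argument",
             "true_eigenvalues must have length true_modes")
  check_that(all(true_eigenvalues >= 0) &&
               !is.unsorted(rev(true_eigenvalues)),
             "axialseg_invalid_argument",
             "eigenvalues must be nonnegative and nonincreasing")
  check_that(true_modes <= 2 * n_landmarks - 4, "axialseg_invalid_argument",
             "true_modes must be <= 2*n_landmarks - 4")
  p <- 2L * n_landmarks
  with_seed(seed, {
    theta <- 2 * pi * (seq_len(n_landmarks) - 1) / n_landmarks
    mean_pts <- cbind(cos(theta), sin(theta))
    mean_pts <- mean_pts / sqrt(sum(mean_pts^2))      # unit centroid size
    mean_v <- as.vector(t(mean_pts))
    E <- qr.Q(qr(matrix(stats::rnorm(p * true_modes), p, true_modes)))
    E <- fix_mode_signs(E)
    B <- matrix(stats::rnorm(n_shapes * true_modes), n_shapes, true_modes) %*%
      diag(sqrt(true_eigenvalues), true_modes)
    shapes <- lapply(seq_len(n_shapes), function(i)
      unflatten_shape(mean_v + as.vector(E %*% B[i, ])))
    model <- new_shape_model(mean_shape = mean_v, modes = E,
                             eigenvalues = as.numeric(true_eigenvalues),
                             n_landmarks = n_landmarks,
                             alignment_record = NULL)
    list(shapes = shapes, model = model)
  })
}
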