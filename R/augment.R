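# End-to-end augmentation: sample simulated contours from the shape model,
# re-pose them into image coordinates, transfer real-image texture via TPS,
# rasterize masks, and grow the training set by a configured fraction.

#' Augmentation configuration
#'
#' @param fraction proportion of simulated images to append relative to the
#'   real set size (default 0.30, i.e. the training set grows by 30%).
#' @param alpha hyperrectangle half-width multiplier for shape sampling,
#'   in (0, 1.5].
#' @param seed integer seed controlling source selection and shape draws.
#' @param source_selection policy for pairing simulated shapes with real
#'   texture sources; currently "uniform" (with replacement).
#' @return an `augment_config` list.
#' @export
augment_config <- function(fraction = 0.30, alpha = 1.5, seed = 1,
                           source_selection = "uniform") {
  check_that(is.numeric(fraction) && length(fraction) == 1 && fraction >= 0,
             "axialseg_invalid_argument", "fraction must be >= 0")
  check_that(alpha > 0 && alpha <= 1.5, "axialseg_invalid_argument",
             "alpha must be in (0, 1.5]")
  check_that(identical(source_selection, "uniform"),
             "axialseg_invalid_argument",
             "source_selection must be \"uniform\"")
  structure(list(fraction = fraction, alpha = alpha, seed = seed,
                 source_selection = source_selection),
            class = "augment_config")
}

# Similarity pose of a real contour relative to the model mean: the
# transform such that aligned = scale * (image_coords - centroid) %*% rotation
# lands the contour on the mean shape's frame. Its inverse re-poses
# model-space shapes into this sample's image coordinates.
pose_against_mean <- function(model, contour) {
  pts <- unclass(as_landmark_shape(contour))
  mean_pts <- unclass(unflatten_shape(model$mean_shape))
  c0 <- colMeans(pts)
  sz <- centroid_size(pts)
  check_that(sz > 1e-12, "axialseg_degenerate_shape", "degenerate contour")
  Z <- sweep(pts, 2, c0) / sz
  fit <- similarity_rotation_scale(Z, sweep(mean_pts, 2, colMeans(mean_pts)))
  list(rotation = fit$rotation, scale = fit$scale / sz, centroid = c0)
}

#' Generate one simulated training sample from a real sample
#'
#' Draws a random shape from the model (coefficients inside the
#' hyperrectangle), re-poses it into the real sample's image frame using the
#' real contour's Procrustes pose against the model mean, fits a TPS with
#' source = simulated landmarks and target = real landmarks, warps the real
#' image into the output frame, and rasterizes the simulated contour into
#' the mask. Degenerate simulated polygons (area collapsing to ~0) trigger
#' regeneration with the next seed; the retry count is recorded in `meta`.
#'
#' @param model a [fit_shape_model()] result.
#' @param real_sample a [seg_sample()] carrying a contour with the model's
#'   landmark count.
#' @param rng_seed integer seed for the shape draw.
#' @param alpha hyperrectangle multiplier passed to [random_shape()].
#' @param max_retries regeneration attempts for degenerate polygons.
#' @return a simulated [seg_sample()]; `meta` records `b`, `source_index`,
#'   `seed` and `retries`.
#' @export
generate_simulated_sample <- function(model, real_sample, rng_seed,
                                      alpha = 1.5, max_retries = 10L) {
  check_that(inherits(real_sample, "seg_sample") &&
               !is.null(real_sample$contour),
             "axialseg_invalid_argument", "real_sample must carry a contour")
  check_that(nrow(real_sample$contour) == model$n_landmarks,
             "axialseg_invalid_argument",
             sprintf("contour has %d landmarks but the model expects %d",
                     nrow(real_sample$contour), model$n_landmarks))
  H <- dim(real_sample$image)[1]; W <- dim(real_sample$image)[2]
  pose <- pose_against_mean(model, real_sample$contour)
  min_area <- 1  # square pixels; below this the polygon has collapsed
  for (attempt in seq_len(max_retries)) {
    seed_a <- rng_seed + attempt - 1L
    draw <- random_shape(model, seed_a, alpha = alpha)
    sim_contour <- repose_shape(draw$shape, pose)
    mask <- rasterize_contour(sim_contour, H, W)
    if (abs(polygon_area(sim_contour)) >= min_area && sum(mask) > 0) {
      tf <- fit_tps(sim_contour, real_sample$contour, regularization = 0)
      img <- warp_texture(real_sample$image, tf, H, W)
      return(seg_sample(img, mask, sim_contour,
                        meta = list(simulated = TRUE, b = draw$b,
                                    source_index = real_sample$meta$index,
                                    seed = rng_seed,
                                    retries = attempt - 1L)))
    }
    message(sprintf("degenerate simulated polygon at seed %d; retrying", seed_a))
  }
  stop_axialseg("axialseg_degenerate_shape",
                sprintf("no non-degenerate shape in %d attempts", max_retries))
}

#' Augment a real training set with simulated samples
#'
#' Appends exactly `round(fraction * N)` simulated samples to the N real
#' ones (the training set grows by `fraction`, default 30%). Texture source
#' images are chosen uniformly at random with replacement; every draw is
#' controlled by `config$seed`, so identical configurations reproduce the
#' augmented set exactly.
#'
#' @param real_samples nonempty list of [seg_sample()]s, all carrying
#'   contours with the model's landmark count.
#' @param model a [fit_shape_model()] result built from those contours.
#' @param config an [augment_config()].
#' @return list of N + round(fraction * N) samples; the simulated ones are
#'   appended after the real ones and flagged via `meta$simulated`.
#' @export
augment_dataset <- function(real_samples, model, config = augment_config()) {
  check_that(is.list(real_samples) && length(real_samples) >= 1,
             "axialseg_invalid_argument", "real_samples must be nonempty")
  N <- length(real_samples)
  n_new <- round(config$fraction * N)
  if (n_new == 0) return(real_samples)
  plan <- with_seed(config$seed, {
    list(src = sample.int(N, n_new, replace = TRUE),
         seeds = sample.int(.Machine$integer.max - 100L, n_new))
  })
  sims <- lapply(seq_len(n_new), function(j) {
    s <- generate_simulated_sample(model, real_samples[[plan$src[j]]],
                                   rng_seed = plan$seeds[j],
                                   alpha = config$alpha)
    s$meta$source_index <- plan$src[j]
    s
  })
  c(real_samples, sims)
}

#' Build a shape model from a list of segmentation samples
#'
#' Convenience pipeline head: extracts the contours, runs generalized
#' Procrustes alignment, and fits the shape model.
#'
#' @param samples list of [seg_sample()]s with contours.
#' @param k number of modes or `"auto"` (see [fit_shape_model()]).
#' @return a `shape_model` with the alignment record attached.
#' @export
fit_ssm_from_samples <- function(samples, k = "auto") {
  contours <- lapply(samples, function(s) {
    check_that(!is.null(s$contour), "axialseg_invalid_argument",
               "every sample must carry a contour")
    s$contour
  })
  fit_shape_model(contours, k = k, align = TRUE)
}
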