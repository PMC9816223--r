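rot2 <- function(theta) matrix(c(cos(theta), sin(theta),
                                 -sin(theta), cos(theta)), 2, 2)

test_that("Procrustes alignment removes similarity transforms", {
  set.seed(21)
  base <- landmark_shape(cbind(runif(10, 0, 40), runif(10, 0, 40)))
  twin <- landmark_shape(2.3 * unclass(base) %*% rot2(0.8) +
                           matrix(c(7, -4), 10, 2, byrow = TRUE))
  al <- align_shapes(list(base, twin))
  expect_lt(max(abs(unclass(al$shapes[[1]]) - unclass(al$shapes[[2]]))), 1e-8)
  # identical shapes map to the same aligned shape
  al2 <- align_shapes(list(base, base))
  expect_equal(al2$shapes[[1]], al2$shapes[[2]])
  # aligned mean: centered at origin, unit centroid size
  mean_pts <- Reduce(`+`, lapply(al$shapes, unclass)) / 2
  expect_lt(max(abs(colMeans(mean_pts))), 1e-8)
  expect_equal(sqrt(sum(sweep(mean_pts, 2, colMeans(mean_pts))^2)), 1,
               tolerance = 1e-6)
})

test_that("alignment reduces summed squared distance to the mean", {
  set.seed(22)
  shapes <- lapply(1:3, function(i)
    landmark_shape(cbind(runif(12, 0, 30), runif(12, 0, 30))))
  al <- align_shapes(shapes)
  ssd <- function(sh) {
    X <- t(vapply(sh, flatten_shape, numeric(24)))
    # compare in a common scale-free frame: normalize each shape first
    Xn <- t(apply(X, 1, function(v) {
      m <- matrix(v, ncol = 2, byrow = TRUE)
      m <- sweep(m, 2, colMeans(m)); as.vector(t(m / sqrt(sum(m^2))))
    }))
    sum(sweep(Xn, 2, colMeans(Xn))^2)
  }
  expect_lte(ssd(al$shapes), ssd(shapes) + 1e-12)
})

test_that("alignment rejects invalid input", {
  a <- landmark_shape(cbind(1:5, 2:6))
  b <- landmark_shape(cbind(1:4, 2:5))
  expect_error(align_shapes(list(a, b)), class = "axialseg_invalid_argument")
  expect_error(align_shapes(list(a)), class = "axialseg_invalid_argument")
  degen <- landmark_shape(matrix(1, 5, 2))
  expect_error(align_shapes(list(a, degen)),
               class = "axialseg_degenerate_shape")
})

test_that("two-shape fit matches the brute-force eigendecomposition", {
  set.seed(23)
  sa <- landmark_shape(cbind(rnorm(8), rnorm(8)))
  sb <- landmark_shape(cbind(rnorm(8), rnorm(8)))
  m <- fit_shape_model(list(sa, sb), k = 1)
  va <- flatten_shape(sa); vb <- flatten_shape(sb)
  expect_equal(m$mean_shape, (va + vb) / 2)
  # the single mode must be parallel to sb - sa
  dirv <- (vb - va) / sqrt(sum((vb - va)^2))
  expect_lt(min(sum((m$modes[, 1] - dirv)^2),
                sum((m$modes[, 1] + dirv)^2)), 1e-20)
  # eigenvalue from the 2-sample covariance: |sb-sa|^2 / 2 (divisor N-1)
  expect_equal(m$eigenvalues[1], sum((vb - va)^2) / 4 * 2, tolerance = 1e-12)
})

test_that("fitting recovers the generating subspace of a known population", {
  pop <- make_landmark_population(500, n_landmarks = 24, true_modes = 2,
                                  true_eigenvalues = c(4e-3, 1e-3), seed = 5)
  m <- fit_shape_model(pop$shapes, k = 2)
  expect_lt(max(principal_angles(m$modes, pop$model$modes)), 0.05)
  expect_lt(max(abs(m$eigenvalues - pop$model$eigenvalues) /
                  pop$model$eigenvalues), 0.15)
})

test_that("model structure invariants hold after fitting", {
  pop <- make_landmark_population(40, n_landmarks = 16, true_modes = 3,
                                  true_eigenvalues = c(4e-3, 2e-3, 1e-3),
                                  seed = 12)
  m <- fit_shape_model(pop$shapes, k = "auto")
  G <- crossprod(m$modes)
  expect_lt(max(abs(G - diag(ncol(m$modes)))), 1e-8)
  expect_false(is.unsorted(rev(m$eigenvalues)))
  expect_lte(ncol(m$modes), min(39, 32))
  # full-rank reconstruction reproduces each training shape
  mf <- fit_shape_model(pop$shapes, k = 32)
  for (s in pop$shapes[1:5]) {
    rec <- reconstruct_shape(mf, s)
    expect_lt(max(abs(unclass(rec) - unclass(s))), 1e-6)
  }
  # reconstruction error decreases monotonically with k
  held <- pop$shapes[[1]]
  errs <- vapply(0:6, function(k)
    sqrt(sum((flatten_shape(reconstruct_shape(mf, held, k)) -
                flatten_shape(held))^2)), 0)
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("fit is invariant to shape order up to mode sign", {
  pop <- make_landmark_population(30, n_landmarks = 12, true_modes = 2,
                                  true_eigenvalues = c(3e-3, 1e-3), seed = 14)
  m1 <- fit_shape_model(pop$shapes, k = 2)
  m2 <- fit_shape_model(rev(pop$shapes), k = 2)
  expect_equal(m1$mean_shape, m2$mean_shape, tolerance = 1e-12)
  expect_equal(m1$eigenvalues, m2$eigenvalues, tolerance = 1e-9)
  expect_lt(max(abs(abs(m1$modes) - abs(m2$modes))), 1e-8)
})

test_that("identical shapes give a zero-variance model", {
  s <- landmark_shape(cbind(1:6, c(2, 4, 3, 6, 5, 1)))
  m <- fit_shape_model(list(s, s, s), k = "auto")
  expect_equal(m$mean_shape, flatten_shape(s))
  expect_true(all(m$eigenvalues == 0))
})

test_that("k beyond the available eigenpairs is rejected", {
  pop <- make_landmark_population(4, n_landmarks = 10, true_modes = 1,
                                  true_eigenvalues = 1e-3, seed = 2)
  expect_error(fit_shape_model(pop$shapes, k = 4),   # kmax = N-1 = 3
               class = "axialseg_invalid_argument")
})

test_that("sample_shape honors the hyperrectangle bound", {
  pop <- make_landmark_population(100, n_landmarks = 12, true_modes = 2,
                                  true_eigenvalues = c(3e-3, 1e-3), seed = 31)
  m <- fit_shape_model(pop$shapes, k = 2)
  # b = 0 -> exactly the mean
  expect_identical(flatten_shape(sample_shape(m, c(0, 0))), m$mean_shape)
  # the boundary value 1.5*sqrt(lambda) is accepted
  b_edge <- c(1.5 * sqrt(m$eigenvalues[1]), 0)
  expect_equal(flatten_shape(sample_shape(m, b_edge)),
               m$mean_shape + m$modes %*% b_edge, ignore_attr = TRUE)
  # outside the hyperrectangle: error, not clipping
  expect_error(sample_shape(m, c(1.51 * sqrt(m$eigenvalues[1]), 0)),
               class = "axialseg_bound_violation")
  expect_error(sample_shape(m, c(0, 0, 0)),
               class = "axialseg_invalid_argument")
})

test_that("random_shape samples uniformly inside the hyperrectangle", {
  pop <- make_landmark_population(100, n_landmarks = 12, true_modes = 2,
                                  true_eigenvalues = c(3e-3, 1e-3), seed = 32)
  m <- fit_shape_model(pop$shapes, k = 2)
  B <- t(vapply(1:1000, function(i) random_shape(m, rng_seed = i)$b,
                numeric(2)))
  ratio <- sweep(abs(B), 2, sqrt(m$eigenvalues), `/`)
  expect_lte(max(ratio), 1.5)
  expect_gt(max(ratio), 1.2)          # the full range is actually used
  # determinism
  expect_identical(random_shape(m, 99), random_shape(m, 99))
  # shrinking lambda x0.01 shrinks the spread x~0.1 per mode
  m2 <- m; m2$eigenvalues <- m$eigenvalues * 0.01
  B2 <- t(vapply(1:1000, function(i) random_shape(m2, rng_seed = i)$b,
                 numeric(2)))
  expect_equal(apply(B2, 2, sd) / apply(B, 2, sd), c(0.1, 0.1),
               tolerance = 1e-6)
})

test_that("shape models round-trip through JSON", {
  pop <- make_landmark_population(20, n_landmarks = 10, true_modes = 2,
                                  true_eigenvalues = c(3e-3, 1e-3), seed = 4)
  m <- fit_shape_model(pop$shapes, k = 2)
  f <- withr::local_tempfile(fileext = ".json")
  write_shape_model(m, f)
  m2 <- read_shape_model(f)
  expect_equal(m2$mean_shape, m$mean_shape)
  expect_equal(m2$modes, m$modes)
  expect_equal(m2$eigenvalues, m$eigenvalues)
  expect_identical(m2$n_landmarks, m$n_landmarks)
})
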