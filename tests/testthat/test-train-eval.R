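test_that("intensity normalization follows the min-max convention", {
  img <- matrix(c(10, 130, 250, 70), 2, 2)
  out <- normalize_intensity(img)
  expect_equal(range(out), c(0, 1))
  expect_equal(out[1, 1], 0)
  expect_equal(out[1, 2], 1)
  already <- matrix(c(0, 0.25, 0.75, 1), 2, 2)
  expect_equal(normalize_intensity(already), already)
  expect_equal(normalize_intensity(matrix(5, 3, 3)), matrix(0, 3, 3))
  z <- normalize_intensity(matrix(rnorm(100), 10, 10), method = "zscore")
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(stats::sd(as.vector(z)), 1, tolerance = 1e-12)
})

test_that("spacing resampling is linear and preserves physical extent", {
  v <- matrix(runif(30), 5, 6)
  expect_equal(resample_spacing(v, c(1, 1), c(1, 1)), v)
  up <- resample_spacing(v, c(1, 1), c(0.5, 0.5))
  expect_identical(dim(up), c(10L, 12L))
  # a linear ramp resamples onto the closed-form line through its endpoints
  ramp <- matrix(seq(0, 1, length.out = 21), 21, 1)
  re <- resample_spacing(ramp, c(1, 1), c(0.5, 1))
  expect_equal(as.vector(re)[1:42],
               seq(0, 1, length.out = 42), tolerance = 1e-6)
  expect_error(resample_spacing(v, c(1, 1), c(0, 1)),
               class = "axialseg_invalid_argument")
  # 3D volumes resample along every axis
  vol <- array(runif(4 * 4 * 4), c(4, 4, 4))
  expect_identical(dim(resample_spacing(vol, 1, 0.5)), c(8L, 8L, 8L))
})

test_that("masked histogram equalization flattens the ROI histogram", {
  # two-level ROI: levels a (40% of pixels) and b (60%); the CDF mapping
  # sends a -> (0.4 - 0.4)/(1 - 0.4) = 0 and b -> 1
  img <- matrix(0.25, 10, 10)
  img[1:6, ] <- 0.75
  roi <- matrix(1, 10, 10)
  out <- equalize_us(img, roi)
  expect_equal(unique(as.vector(out[img == 0.25])), 0)
  expect_equal(unique(as.vector(out[img == 0.75])), 1)
  # pixels outside the ROI are zeroed
  roi2 <- matrix(0, 10, 10); roi2[, 6:10] <- 1
  out2 <- equalize_us(img, roi2)
  expect_true(all(out2[, 1:5] == 0))
  # an (approximately) uniform-histogram ROI is left unchanged up to
  # quantization
  u <- matrix(seq(0, 1 - 1e-9, length.out = 256), 16, 16)
  eq <- equalize_us(u, matrix(1, 16, 16))
  expect_lt(max(abs(eq - u)), 1 / 255 + 1e-9)
  expect_error(equalize_us(img, matrix(0, 10, 10)),
               class = "axialseg_invalid_argument")
})

test_that("overlap metrics follow their set-theoretic definitions", {
  X <- matrix(0, 4, 4); Y <- matrix(0, 4, 4)
  X[1, 1:3] <- 1; X[2, 1:3] <- 1               # |X| = 6
  Y[1, 1:3] <- 1; Y[3, 4] <- 1                 # |Y| = 4, |X ∩ Y| = 3
  expect_equal(dsc(X, Y), 0.6)
  expect_equal(iou(X, Y), 3 / 7)
  expect_equal(recall(X, Y), 0.75)
  expect_equal(dsc(Y, Y), 1); expect_equal(iou(Y, Y), 1)
  expect_equal(recall(Y, Y), 1)
  D <- matrix(0, 4, 4); D[4, 4] <- 1
  E <- matrix(0, 4, 4); E[1, 1] <- 1
  expect_equal(dsc(D, E), 0); expect_equal(iou(D, E), 0)
  expect_equal(recall(D, E), 0)
  # both-empty convention: all metrics 1; empty reference: recall 0
  Z <- matrix(0, 4, 4)
  expect_equal(dsc(Z, Z), 1); expect_equal(iou(Z, Z), 1)
  expect_equal(recall(Z, Z), 1)
  expect_equal(recall(X, Z), 0)
  expect_error(dsc(X, matrix(0, 3, 3)), class = "axialseg_shape_error")
  expect_error(dsc(X * 2, X), class = "axialseg_invalid_argument")
})

test_that("DSC = 2 IoU / (1 + IoU) and permutation invariance hold", {
  set.seed(71)
  for (i in 1:20) {
    X <- matrix(rbinom(64, 1, runif(1, 0.1, 0.9)), 8, 8)
    Y <- matrix(rbinom(64, 1, runif(1, 0.1, 0.9)), 8, 8)
    expect_equal(dsc(X, Y), 2 * iou(X, Y) / (1 + iou(X, Y)),
                 tolerance = 1e-12)
    perm <- sample(64)
    Xp <- matrix(X[perm], 8, 8); Yp <- matrix(Y[perm], 8, 8)
    expect_identical(dsc(Xp, Yp), dsc(X, Y))
    expect_identical(recall(Xp, Yp), recall(X, Y))
  }
})

small_train_setup <- function() {
  list(ds = make_blob_dataset(6, image_size = 32, n_landmarks = 12,
                              seed = 19),
       cfg = network_config(in_channels = 1, base_channels = 4,
                            global_depth = 1, local_depth = 1,
                            patch_grid = c(4, 4), n_heads = 2,
                            input_size = c(32, 32)))
}

test_that("a zero learning rate leaves the parameters untouched", {
  s <- small_train_setup()
  fit <- train(s$ds, net_config = s$cfg,
               train_cfg = train_config(learning_rate = 0, epochs = 1,
                                        batch_size = 2, seed = 9))
  expect_identical(fit$params, network_init(s$cfg, seed = 9))
})

test_that("training reduces the loss and is bit-reproducible on CPU", {
  s <- small_train_setup()
  cfgT <- train_config(learning_rate = 0.01, epochs = 40, batch_size = 2,
                       seed = 9, max_steps = 80)
  fit1 <- train(s$ds, net_config = s$cfg, train_cfg = cfgT)
  fit2 <- train(s$ds, net_config = s$cfg, train_cfg = cfgT)
  expect_identical(fit1$step_loss, fit2$step_loss)
  expect_identical(fit1$params, fit2$params)
  # loss decreases clearly over the run (epoch means smooth batch noise)
  expect_lt(mean(utils::tail(fit1$step_loss, 10)),
            0.7 * mean(utils::head(fit1$step_loss, 10)))
  # a different seed gives a different trajectory
  fit3 <- train(s$ds, net_config = s$cfg,
                train_cfg = train_config(learning_rate = 0.01, epochs = 40,
                                         batch_size = 2, seed = 10,
                                         max_steps = 80))
  expect_false(identical(fit1$step_loss, fit3$step_loss))
})

test_that("validation tracking keeps the best-DSC parameters", {
  s <- small_train_setup()
  fit <- train(s$ds[1:4], val_samples = s$ds[5:6], net_config = s$cfg,
               train_cfg = train_config(learning_rate = 3e-3, epochs = 6,
                                        batch_size = 2, seed = 9))
  expect_true(all(is.finite(fit$history$val_dsc)))
  expect_true(fit$best_epoch >= 1 && fit$best_epoch <= 6)
})

test_that("evaluation reports per-sample metrics with the identity intact", {
  s <- small_train_setup()
  fit <- train(s$ds, net_config = s$cfg,
               train_cfg = train_config(learning_rate = 3e-3, epochs = 5,
                                        batch_size = 2, seed = 9))
  rep <- evaluate(fit, s$ds)
  expect_identical(rep$n, 6L)
  expect_true(all(rep$per_sample$dsc >= 0 & rep$per_sample$dsc <= 1))
  expect_true(all(rep$per_sample$dsc >= rep$per_sample$iou))
  expect_equal(rep$per_sample$dsc,
               2 * rep$per_sample$iou / (1 + rep$per_sample$iou),
               tolerance = 1e-12)
  f <- withr::local_tempfile(fileext = ".json")
  write_eval_report(rep, f)
  expect_true(file.exists(f))
})

test_that("checkpoints restore a fit that predicts identically", {
  s <- small_train_setup()
  fit <- train(s$ds, net_config = s$cfg,
               train_cfg = train_config(learning_rate = 3e-3, epochs = 3,
                                        batch_size = 2, seed = 9))
  f <- withr::local_tempfile(fileext = ".json")
  write_checkpoint(fit, f)
  fit2 <- read_checkpoint(f)
  p1 <- predict(fit, s$ds[[1]], type = "prob")
  p2 <- predict(fit2, s$ds[[1]], type = "prob")
  expect_equal(p2, p1, tolerance = 1e-12)
  rep <- evaluate(f, s$ds[1:2])      # checkpoint path accepted directly
  expect_identical(rep$n, 2L)
})
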