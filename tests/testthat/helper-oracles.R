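# Independent oracles and small shared fixtures.  Everything here is kept
# deliberately naive (scalar loops, closed forms, third-party routines) so
# it cannot share a defect with the implementation it checks.

# principal angles (radians) between the column spaces of E1 and E2
principal_angles <- function(E1, E2) {
  q1 <- qr.Q(qr(E1)); q2 <- qr.Q(qr(E2))
  acos(pmin(1, svd(crossprod(q1, q2))$d))
}

# point-in-polygon rasterization oracle via mgcv::in.out at pixel centers
raster_oracle <- function(contour, height, width) {
  pts <- unclass(contour)
  bnd <- rbind(pts, pts[1, ])
  cx <- rep(0:(width - 1), each = height)
  cy <- rep(0:(height - 1), times = width)
  io <- mgcv::in.out(bnd, cbind(cx, cy))
  m <- matrix(0, height, width)
  m[cbind(cy + 1, cx + 1)] <- as.numeric(io)
  m
}

# literal scalar-loop evaluation of the thin-plate-spline map
tps_oracle <- function(tf, pts) {
  out <- matrix(0, nrow(pts), 2)
  for (m in seq_len(nrow(pts))) {
    x <- pts[m, 1]; y <- pts[m, 2]
    for (dim in 1:2) {
      v <- tf$affine[1, dim] + tf$affine[2, dim] * x + tf$affine[3, dim] * y
      for (i in seq_len(nrow(tf$control_points))) {
        r2 <- (tf$control_points[i, 1] - x)^2 + (tf$control_points[i, 2] - y)^2
        if (r2 > 0) v <- v + tf$weights[i, dim] * r2 * log(r2)
      }
      out[m, dim] <- v
    }
  }
  out
}

# per-pixel scalar-loop warp: TPS map then bilinear sampling
warp_oracle <- function(img, tf, H, W, fill = 0) {
  out <- matrix(fill, H, W)
  Hi <- nrow(img); Wi <- ncol(img)
  for (row in seq_len(H)) {
    for (col in seq_len(W)) {
      p <- tps_oracle(tf, matrix(c(col - 1, row - 1), 1, 2))
      x <- p[1]; y <- p[2]
      if (x >= -1e-6 && x <= Wi - 1 + 1e-6 && y >= -1e-6 && y <= Hi - 1 + 1e-6) {
        x <- min(max(x, 0), Wi - 1); y <- min(max(y, 0), Hi - 1)
        x0 <- min(floor(x), Wi - 2); y0 <- min(floor(y), Hi - 2)
        fx <- x - x0; fy <- y - y0
        out[row, col] <-
          (1 - fy) * ((1 - fx) * img[y0 + 1, x0 + 1] + fx * img[y0 + 1, x0 + 2]) +
          fy * ((1 - fx) * img[y0 + 2, x0 + 1] + fx * img[y0 + 2, x0 + 2])
      }
    }
  }
  out
}

# double-loop binary cross-entropy
bce_oracle <- function(pred, target, eps = 1e-7) {
  total <- 0
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      p <- min(max(pred[i, j], eps), 1 - eps)
      total <- total - (target[i, j] * log(p) + (1 - target[i, j]) * log(1 - p))
    }
  }
  total / length(pred)
}

# plain position-free axial attention by direct two-loop evaluation
plain_axial_oracle <- function(x, params, axis) {
  xf <- if (axis == "height") x else aperm(x, c(1, 3, 2))
  C <- dim(xf)[1]; S <- dim(xf)[2]; R <- dim(xf)[3]
  nh <- params$n_heads; d <- C %/% nh
  yf <- array(0, dim(xf))
  for (r in seq_len(R)) {
    Q <- params$Wq %*% xf[, , r]; K <- params$Wk %*% xf[, , r]
    V <- params$Wv %*% xf[, , r]
    for (h in seq_len(nh)) {
      rows <- ((h - 1) * d + 1):(h * d)
      for (i in seq_len(S)) {
        logits <- vapply(seq_len(S), function(w)
          sum(Q[rows, i] * K[rows, w]), 0)
        a <- exp(logits - max(logits)); a <- a / sum(a)
        yf[rows, i, r] <- V[rows, , drop = FALSE] %*% a
      }
    }
  }
  if (axis == "height") yf else aperm(yf, c(1, 3, 2))
}

# count 4-connected foreground components by repeated flood fill
flood_count <- function(mask) {
  todo <- which(mask == 1, arr.ind = TRUE)
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  comps <- 0L
  for (k in seq_len(nrow(todo))) {
    r <- todo[k, 1]; c <- todo[k, 2]
    if (seen[r, c]) next
    comps <- comps + 1L
    queue <- list(c(r, c)); seen[r, c] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        q <- p + d
        if (q[1] >= 1 && q[1] <= nrow(mask) && q[2] >= 1 &&
            q[2] <= ncol(mask) && mask[q[1], q[2]] == 1 &&
            !seen[q[1], q[2]]) {
          seen[q[1], q[2]] <- TRUE
          queue <- c(queue, list(q))
        }
      }
    }
  }
  comps
}

# single-seed fixture caches shared across test files
blob8_64 <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_blob_dataset(8, image_size = 64, n_landmarks = 24,
                                  noise_fraction = 0.25, seed = 11)
    cache
  }
})

# small training-scale network configuration used by the heavier tests
overfit_net_config <- function() {
  network_config(in_channels = 1, base_channels = 8, global_depth = 2,
                 local_depth = 2, patch_grid = c(4, 4), n_heads = 2,
                 input_size = c(64, 64))
}

# one memoized overfit run per seed (shared by the acceptance tests)
overfit_cache <- new.env(parent = emptyenv())
run_overfit <- function(seed, steps = 200) {
  key <- sprintf("s%d_%d", seed, steps)
  if (is.null(overfit_cache[[key]])) {
    fit <- train(blob8_64(), net_config = overfit_net_config(),
                 train_cfg = train_config(learning_rate = 1e-4,
                                          epochs = 1000, batch_size = 4,
                                          seed = seed, max_steps = steps))
    overfit_cache[[key]] <- fit
  }
  overfit_cache[[key]]
}
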