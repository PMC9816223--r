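random_gates <- function(p, seed) {
  set.seed(seed)
  p$G_Q <- runif(1, -1, 1); p$G_K <- runif(1, -1, 1)
  p$G_V1 <- runif(1, -1, 1); p$G_V2 <- runif(1, -1, 1)
  p
}

test_that("fast operator equals the brute-force reference on random cases", {
  set.seed(51)
  for (case in 1:20) {
    C <- sample(c(2, 4, 8), 1)
    H <- sample(3:12, 1); W <- sample(3:10, 1)
    nh <- sample(c(1, 2), 1)
    axis <- if (case %% 2 == 0) "height" else "width"
    S <- if (axis == "height") H else W
    x <- array(rnorm(C * H * W), c(C, H, W))
    p <- random_gates(axial_attention_params(C, S, n_heads = nh,
                                             seed = 100 + case), 200 + case)
    expect_lt(max(abs(gated_axial_attention(x, p, axis) -
                        brute_force_reference(x, p, axis))), 1e-10)
  }
})

test_that("dense positional tables behave like their gathered counterparts", {
  set.seed(52)
  x <- array(rnorm(4 * 5 * 6), c(4, 5, 6))
  pd <- random_gates(axial_attention_params(4, 6, n_heads = 2, seed = 8,
                                            table_mode = "dense"), 9)
  expect_lt(max(abs(gated_axial_attention(x, pd, "width") -
                      brute_force_reference(x, pd, "width"))), 1e-10)
})

test_that("the oracle matches a hand-computed 1x1x2 instance", {
  # one channel, one head, span 2: every quantity is scalar arithmetic
  p <- axial_attention_params(1, 2, n_heads = 1, seed = 1)
  p$Wq <- matrix(0.5); p$Wk <- matrix(-0.3); p$Wv <- matrix(0.8)
  p$rq <- matrix(c(0.1, 0.2, -0.1), 3, 1)   # offsets -1, 0, +1
  p$rk <- matrix(c(0.05, -0.2, 0.15), 3, 1)
  p$rv <- matrix(c(0.3, 0.1, -0.2), 3, 1)
  p$G_Q <- 0.9; p$G_K <- 1.1; p$G_V1 <- 0.7; p$G_V2 <- 1.3
  x <- array(c(1.5, -2), c(1, 1, 2))
  q <- 0.5 * c(1.5, -2); k <- -0.3 * c(1.5, -2); v <- 0.8 * c(1.5, -2)
  # table gathered at (i, w): offset i - w stored at index i - w + 2, so
  # R[1,1] = tab[2], R[2,1] = tab[3], R[1,2] = tab[1], R[2,2] = tab[2]
  Rq <- matrix(c(p$rq[2], p$rq[3], p$rq[1], p$rq[2]), 2, 2)
  Rk <- matrix(c(p$rk[2], p$rk[3], p$rk[1], p$rk[2]), 2, 2)
  Rv <- matrix(c(p$rv[2], p$rv[3], p$rv[1], p$rv[2]), 2, 2)
  y_hand <- numeric(2)
  for (i in 1:2) {
    logit <- vapply(1:2, function(w)
      q[i] * k[w] + 0.9 * q[i] * Rq[i, w] + 1.1 * k[w] * Rk[i, w], 0)
    a <- exp(logit) / sum(exp(logit))
    y_hand[i] <- sum(a * (0.7 * v + 1.3 * Rv[i, ]))
  }
  got <- brute_force_reference(x, p, "width")
  expect_equal(as.vector(got), y_hand, tolerance = 1e-12)
  expect_equal(as.vector(gated_axial_attention(x, p, "width")), y_hand,
               tolerance = 1e-12)
})

test_that("gate settings reduce the operator to its simpler forms", {
  set.seed(53)
  x <- array(rnorm(4 * 6 * 5), c(4, 6, 5))
  p <- axial_attention_params(4, 5, n_heads = 2, seed = 3)
  # G_Q = G_K = G_V2 = 0, G_V1 = 1: plain position-free axial attention
  p0 <- p; p0$G_Q <- 0; p0$G_K <- 0; p0$G_V2 <- 0; p0$G_V1 <- 1
  expect_lt(max(abs(gated_axial_attention(x, p0, "width") -
                      plain_axial_oracle(x, p0, "width"))), 1e-10)
  # all gates 1 (the ungated positional form) equals the brute force with
  # gates pinned to 1
  p1 <- p; p1$G_Q <- 1; p1$G_K <- 1; p1$G_V1 <- 1; p1$G_V2 <- 1
  expect_lt(max(abs(gated_axial_attention(x, p1, "width") -
                      brute_force_reference(x, p1, "width"))), 1e-10)
})

test_that("a span-1 axis returns G_V1*v + G_V2*rv at every position", {
  p <- random_gates(axial_attention_params(4, 1, n_heads = 2, seed = 5), 6)
  x <- array(rnorm(4 * 3 * 1), c(4, 3, 1))
  y <- gated_axial_attention(x, p, "width")
  V <- p$Wv %*% matrix(x, 4, 3)
  expected <- p$G_V1 * V
  for (h in 1:2) {
    rows <- ((h - 1) * 2 + 1):(h * 2)
    rv <- axialseg:::position_table(p, "rv", h)
    expected[rows, ] <- expected[rows, ] + p$G_V2 * rv[1, 1]
  }
  expect_equal(matrix(y, 4, 3), expected, tolerance = 1e-12)
})

test_that("output is linear in v: zero input with G_V2 = 0 gives zero", {
  p <- axial_attention_params(2, 4, n_heads = 1, seed = 7)
  p$G_V2 <- 0
  x <- array(0, c(2, 3, 4))
  expect_true(all(brute_force_reference(x, p, "width") == 0))
  expect_true(all(gated_axial_attention(x, p, "width") == 0))
})

test_that("rows are independent under width attention", {
  set.seed(54)
  x <- array(rnorm(2 * 6 * 5), c(2, 6, 5))
  p <- random_gates(axial_attention_params(2, 5, n_heads = 1, seed = 9), 10)
  perm <- sample(6)
  y <- gated_axial_attention(x, p, "width")
  y_perm <- gated_axial_attention(x[, perm, , drop = FALSE], p, "width")
  expect_equal(y_perm, y[, perm, , drop = FALSE], tolerance = 1e-12)
})

test_that("softmax weights along the attended axis sum to one", {
  set.seed(55)
  x <- array(rnorm(4 * 5 * 7), c(4, 5, 7))
  p <- random_gates(axial_attention_params(4, 7, n_heads = 2, seed = 11), 12)
  y <- gated_axial_attention(x, p, "width", debug = TRUE)
  maps <- attr(y, "attention")
  expect_length(maps, 2)
  for (A in maps) {
    expect_identical(dim(A), c(7L, 7L, 5L))
    sums <- apply(A, c(1, 3), sum)
    expect_lt(max(abs(sums - 1)), 1e-12)
    expect_true(all(A >= 0))
  }
})

test_that("softmax is stable for large-magnitude inputs", {
  p <- axial_attention_params(2, 4, n_heads = 1, seed = 13)
  x <- array(1e4 * rnorm(2 * 2 * 4), c(2, 2, 4))
  y <- gated_axial_attention(x, p, "width")
  expect_true(all(is.finite(y)))
})

test_that("shape violations raise typed errors", {
  p <- axial_attention_params(4, 5, n_heads = 2, seed = 15)
  x <- array(rnorm(4 * 3 * 6), c(4, 3, 6))
  expect_error(gated_axial_attention(x, p, "width"),   # span 6 != 5
               class = "axialseg_shape_error")
  expect_error(axial_attention_params(6, 5, n_heads = 4, seed = 1),
               class = "axialseg_invalid_argument")
})

test_that("backward pass agrees with finite differences", {
  set.seed(56)
  C <- 4; S <- 6; R <- 10
  x <- array(rnorm(C * S * R), c(C, S, R))
  p <- random_gates(axial_attention_params(C, S, n_heads = 2, seed = 17), 18)
  lossf <- function(pp, xx) sum(sin(axialseg:::axattn_forward(xx, pp)$out))
  fw <- axialseg:::axattn_forward(x, p)
  bw <- axialseg:::axattn_backward(cos(fw$out), fw$cache, p)
  eps <- 1e-6
  for (g in c("G_Q", "G_K", "G_V1", "G_V2")) {
    p2 <- p; p2[[g]] <- p[[g]] + eps
    p3 <- p; p3[[g]] <- p[[g]] - eps
    fd <- (lossf(p2, x) - lossf(p3, x)) / (2 * eps)
    expect_lt(abs(fd - bw$grads[[g]]) / max(1e-8, abs(fd)), 1e-3)
  }
  p2 <- p; p2$Wq[2, 3] <- p2$Wq[2, 3] + eps
  p3 <- p; p3$Wq[2, 3] <- p3$Wq[2, 3] - eps
  expect_lt(abs((lossf(p2, x) - lossf(p3, x)) / (2 * eps) -
                  bw$grads$Wq[2, 3]), 1e-5)
  p2 <- p; p2$rk[4, 2] <- p2$rk[4, 2] + eps
  p3 <- p; p3$rk[4, 2] <- p3$rk[4, 2] - eps
  expect_lt(abs((lossf(p2, x) - lossf(p3, x)) / (2 * eps) -
                  bw$grads$rk[4, 2]), 1e-5)
  x2 <- x; x2[3, 2, 5] <- x2[3, 2, 5] + eps
  x3 <- x; x3[3, 2, 5] <- x3[3, 2, 5] - eps
  expect_lt(abs((lossf(p, x2) - lossf(p, x3)) / (2 * eps) -
                  bw$dX[3, 2, 5]), 1e-5)
})
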