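# Gated axial self-attention along one image axis.
#
# For each position (i, j) and head, along the attended axis of length S:
#
#   y_i = sum_w softmax_w( q_i' k_w  +  G_Q * sum(q_i) * r^q[i,w]
#                                    +  G_K * sum(k_w) * r^k[i,w] )
#               * ( G_V1 * v_w + G_V2 * r^v[i,w] )
#
# q, k, v are per-head linear projections of the input channels; r^q, r^k,
# r^v are real-valued S x S positional tables per head, one scalar per
# (query, key) pair; G_Q, G_K, G_V1, G_V2 are learnable scalar gates. The
# positional tables hold one scalar per (query, key) position pair, so the
# query/key positional terms contract the channel dimension by summation and
# the value positional term is added to every channel. With all gates 1 the
# ungated positional form is recovered; with G_Q = G_K = G_V2 = 0, G_V1 = 1
# the operator reduces to plain position-free axial attention.
#
# Tables are realized, by default, from a learnable relative-offset vector
# of length 2S-1 gathered at offset i-w (standard relative position
# encoding); a literal dense S x S table is available via
# `table_mode = "dense"`.

#' Parameters for one gated axial attention layer
#'
#' @param in_channels number of input (= output) channels C; must be
#'   divisible by `n_heads`.
#' @param span length S of the attended axis.
#' @param n_heads number of attention heads (default 8).
#' @param table_mode "relative" (learnable offset vector of length 2S-1,
#'   gathered into the S x S table) or "dense" (literal S x S table).
#' @param seed integer seed for the random initialization.
#' @param gate_init initial value for all four gates (default 1: the pure
#'   ungated positional form at the start of training, letting the gates be
#'   learned down-weights for unreliable positional encodings).
#' @return an `axial_attention_params` list: `Wq`, `Wk`, `Wv` (C x C
#'   projection matrices with rows grouped by head), positional tables
#'   `rq`, `rk`, `rv`, gates `G_Q`, `G_K`, `G_V1`, `G_V2`, and shape fields.
#' @export
axial_attention_params <- function(in_channels, span, n_heads = 8,
                                   table_mode = c("relative", "dense"),
                                   seed = 1, gate_init = 1) {
  table_mode <- match.arg(table_mode)
  check_that(is_count(in_channels) && in_channels >= 1 &&
               is_count(span) && span >= 1,
             "axialseg_invalid_argument", "in_channels and span must be positive")
  check_that(in_channels %% n_heads == 0, "axialseg_invalid_argument",
             "in_channels must be divisible by n_heads")
  with_seed(seed, {
    C <- in_channels
    proj <- function() matrix(stats::rnorm(C * C, 0, sqrt(1 / C)), C, C)
    tab <- function() {
      if (table_mode == "relative")
        matrix(stats::rnorm((2 * span - 1) * n_heads, 0, 0.1),
               2 * span - 1, n_heads)
      else
        array(stats::rnorm(span * span * n_heads, 0, 0.1),
              c(span, span, n_heads))
    }
    structure(list(Wq = proj(), Wk = proj(), Wv = proj(),
                   rq = tab(), rk = tab(), rv = tab(),
                   G_Q = gate_init, G_K = gate_init,
                   G_V1 = gate_init, G_V2 = gate_init,
                   n_heads = as.integer(n_heads), span = as.integer(span),
                   in_channels = as.integer(C), table_mode = table_mode),
              class = "axial_attention_params")
  })
}

# Gather the S x S positional table for head h (relative mode indexes the
# offset vector at i - w + S).
position_table <- function(params, which, h) {
  S <- params$span
  tb <- params[[which]]
  if (params$table_mode == "relative") {
    off <- outer(seq_len(S), seq_len(S), `-`) + S    # values 1 .. 2S-1
    matrix(tb[off, h], S, S)
  } else {
    tb[, , h]
  }
}

# Scatter-add an S x S table gradient back onto the relative-offset vector.
table_grad <- function(params, dT, h) {
  S <- params$span
  if (params$table_mode == "relative") {
    off <- as.vector(outer(seq_len(S), seq_len(S), `-`) + S)
    as.vector(rowsum(as.vector(dT), off))            # length 2S-1, ordered
  } else {
    dT
  }
}

# Gather all heads' positional tables into an S x S x n_heads cube.
position_cube <- function(params, which) {
  S <- params$span; nh <- params$n_heads
  array(vapply(seq_len(nh), function(h) position_table(params, which, h),
               matrix(0, S, S)), c(S, S, nh))
}

gate_vector <- function(params) {
  c(params$G_Q, params$G_K, params$G_V1, params$G_V2)
}

# ---- batched core -----------------------------------------------------------
# X is [C, S, R]: channels x attended axis x everything else (batch and the
# non-attended axis folded together). The q/k/v projections are single BLAS
# calls here; the per-slice attention arithmetic runs in compiled code.
# Returns Y of the same shape plus a cache for the backward pass.
axattn_forward <- function(X, params, keep_attention = FALSE) {
  C <- dim(X)[1]; S <- dim(X)[2]; R <- dim(X)[3]
  check_that(S == params$span, "axialseg_shape_error",
             sprintf("attended axis length %d != params span %d", S, params$span))
  check_that(C == params$in_channels, "axialseg_shape_error",
             "channel count does not match params")
  nh <- params$n_heads; d <- C %/% nh
  Xm <- matrix(X, C, S * R)
  Qm <- params$Wq %*% Xm; Km <- params$Wk %*% Xm; Vm <- params$Wv %*% Xm
  cubes <- list(Rq = position_cube(params, "rq"),
                Rk = position_cube(params, "rk"),
                Rv = position_cube(params, "rv"))
  res <- axattn_fwd_cpp(Qm, Km, Vm, cubes$Rq, cubes$Rk, cubes$Rv,
                        gate_vector(params), d, S, R, nh, keep_attention)
  attention <- NULL
  if (keep_attention) {
    attention <- lapply(seq_len(nh), function(h)
      array(res$A[, seq(h, by = nh, length.out = R), drop = FALSE],
            c(S, S, R)))
  }
  list(out = array(res$Y, dim(X)),
       cache = list(Xm = Xm, Qm = Qm, Km = Km, Vm = Vm, cubes = cubes,
                    d = d, S = S, R = R, dims = dim(X),
                    attention = attention))
}

axattn_backward <- function(dY, cache, params) {
  d <- cache$d; S <- cache$S; R <- cache$R
  C <- params$in_channels; nh <- params$n_heads
  dYm <- matrix(dY, C, S * R)
  res <- axattn_bwd_cpp(dYm, cache$Qm, cache$Km, cache$Vm,
                        cache$cubes$Rq, cache$cubes$Rk, cache$cubes$Rv,
                        gate_vector(params), d, S, R, nh)
  g <- list(Wq = tcrossprod(res$dQm, cache$Xm),
            Wk = tcrossprod(res$dKm, cache$Xm),
            Wv = tcrossprod(res$dVm, cache$Xm),
            rq = params$rq * 0, rk = params$rk * 0, rv = params$rv * 0,
            G_Q = res$dgates[1], G_K = res$dgates[2],
            G_V1 = res$dgates[3], G_V2 = res$dgates[4])
  for (h in seq_len(nh)) {
    if (params$table_mode == "relative") {
      g$rq[, h] <- table_grad(params, res$dRq[, , h], h)
      g$rk[, h] <- table_grad(params, res$dRk[, , h], h)
      g$rv[, h] <- table_grad(params, res$dRv[, , h], h)
    } else {
      g$rq[, , h] <- res$dRq[, , h]
      g$rk[, , h] <- res$dRk[, , h]
      g$rv[, , h] <- res$dRv[, , h]
    }
  }
  dXm <- crossprod(params$Wq, res$dQm) + crossprod(params$Wk, res$dKm) +
    crossprod(params$Wv, res$dVm)
  list(dX = array(dXm, cache$dims), grads = g)
}

# Reorient a C x H x W feature map so the attended axis is dimension 2.
fold_axis <- function(x, axis) {
  if (axis == "height") x else aperm(x, c(1, 3, 2))
}
unfold_axis <- function(y, axis) {
  if (axis == "height") y else aperm(y, c(1, 3, 2))
}

#' Gated axial self-attention over one axis of a feature map
#'
#' Applies the gated axial attention operator along the height or width
#' axis of a C x H x W feature map. Rows (for width attention) or columns
#' (for height attention) are processed independently; heads are
#' concatenated back to C channels; the output has the input's shape.
#'
#' @param x numeric array C x H x W.
#' @param params an [axial_attention_params()] whose span equals the
#'   attended axis length.
#' @param axis "height" or "width".
#' @param debug if TRUE, attach the per-head attention maps (arrays
#'   query x key x slice) as attribute `"attention"`.
#' @return array C x H x W.
#' @export
gated_axial_attention <- function(x, params, axis = c("height", "width"),
                                  debug = FALSE) {
  axis <- match.arg(axis)
  check_that(length(dim(x)) == 3L, "axialseg_shape_error",
             "x must be a C x H x W array")
  xf <- fold_axis(x, axis)
  fw <- axattn_forward(xf, params, keep_attention = debug)
  out <- unfold_axis(fw$out, axis)
  if (debug)
    attr(out, "attention") <- fw$cache$attention
  out
}

#' Brute-force reference for gated axial attention
#'
#' Literal per-position scalar-loop evaluation of the gated axial attention
#' formula, including explicit scalar loops for the q/k/v projections and
#' the softmax. Intended as the correctness oracle at test scale; never
#' used in training.
#'
#' @inheritParams gated_axial_attention
#' @return array C x H x W.
#' @export
brute_force_reference <- function(x, params, axis = c("height", "width")) {
  axis <- match.arg(axis)
  xf <- fold_axis(x, axis)
  C <- dim(xf)[1]; S <- dim(xf)[2]; R <- dim(xf)[3]
  check_that(S == params$span, "axialseg_shape_error", "span mismatch")
  check_that(C %% params$n_heads == 0, "axialseg_invalid_argument",
             "channels not divisible by heads")
  nh <- params$n_heads; d <- C %/% nh
  yf <- array(0, c(C, S, R))
  for (r in seq_len(R)) {
    for (h in seq_len(nh)) {
      rows <- ((h - 1) * d + 1):(h * d)
      Rq <- position_table(params, "rq", h)
      Rk <- position_table(params, "rk", h)
      Rv <- position_table(params, "rv", h)
      # scalar-loop projections q, k, v at every position along the axis
      q <- matrix(0, d, S); k <- matrix(0, d, S); v <- matrix(0, d, S)
      for (pos in seq_len(S)) {
        for (dd in seq_len(d)) {
          for (cc in seq_len(C)) {
            q[dd, pos] <- q[dd, pos] + params$Wq[rows[dd], cc] * xf[cc, pos, r]
            k[dd, pos] <- k[dd, pos] + params$Wk[rows[dd], cc] * xf[cc, pos, r]
            v[dd, pos] <- v[dd, pos] + params$Wv[rows[dd], cc] * xf[cc, pos, r]
          }
        }
      }
      for (i in seq_len(S)) {
        logits <- numeric(S)
        for (w in seq_len(S)) {
          logits[w] <- sum(q[, i] * k[, w]) +
            params$G_Q * sum(q[, i]) * Rq[i, w] +
            params$G_K * sum(k[, w]) * Rk[i, w]
        }
        a <- exp(logits - max(logits))
        a <- a / sum(a)
        acc <- numeric(d)
        for (w in seq_len(S)) {
          acc <- acc + a[w] * (params$G_V1 * v[, w] + params$G_V2 * Rv[i, w])
        }
        yf[rows, i, r] <- acc
      }
    }
  }
  unfold_axis(yf, axis)
}
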