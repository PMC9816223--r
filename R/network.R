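# Dual-branch gated-axial-attention segmentation network.
#
# Global branch: 1x1 conv stem, then `global_depth` encoder blocks (1x1 conv,
# BN, gated axial attention along height then width, BN, residual) each
# followed by a strided 2x2 downsampling conv that doubles the channels, and
# matching decoders (nearest 2x upsampling, channel-halving 1x1 conv, ReLU,
# skip concatenation with the encoder feature, then three conv+BN+ReLU
# layers). Local branch: the image is evenly divided into a 4x4 grid of 16
# patches which share one sub-network of the same form at `local_depth`; the
# reassembled patch features are fused with the global features by a
# learnable scalar-weighted addition, projected by a final 1x1 conv, and
# passed through a sigmoid to a per-pixel probability map.
#
# All feature maps are [C, H, W, N] arrays; every layer implements an
# explicit backward pass, so the whole network trains on CPU without an
# autodiff framework.

#' Network configuration
#'
#' @param in_channels input image channels (1 gray, 3 color).
#' @param base_channels stem output channels (default 32); channels double
#'   at every downsampling step.
#' @param global_depth encoder/decoder pairs in the global branch (default 2).
#' @param local_depth encoder/decoder pairs in the local branch (default 4).
#' @param patch_grid local-branch patch grid as c(rows, cols); the default
#'   4 x 4 divides the image evenly into 16 patches.
#' @param n_heads attention heads (default 8; must divide every stage's
#'   channel count).
#' @param input_size c(H, W); both must be divisible by the patch grid, by
#'   2^global_depth, and the patch sizes by 2^local_depth.
#' @param decoder_convs convolution layers after the skip merge (default 3;
#'   set 1 for the single-conv variant).
#' @param table_mode positional-table realization for attention layers.
#' @return a `network_config` list.
#' @export
network_config <- function(in_channels = 1, base_channels = 32,
                           global_depth = 2, local_depth = 4,
                           patch_grid = c(4, 4), n_heads = 8,
                           input_size = c(64, 64), decoder_convs = 3,
                           table_mode = "relative") {
  H <- input_size[1]; W <- input_size[2]
  gr <- patch_grid[1]; gc <- patch_grid[2]
  check_that(H %% gr == 0 && W %% gc == 0, "axialseg_shape_error",
             "input_size must be divisible by patch_grid")
  check_that(H %% 2^global_depth == 0 && W %% 2^global_depth == 0,
             "axialseg_shape_error",
             "input_size must be divisible by 2^global_depth")
  ph <- H %/% gr; pw <- W %/% gc
  check_that(ph %% 2^local_depth == 0 && pw %% 2^local_depth == 0,
             "axialseg_shape_error",
             "patch size must be divisible by 2^local_depth")
  for (i in seq_len(max(global_depth, local_depth))) {
    ci <- base_channels * 2^(i - 1)
    check_that(ci %% n_heads == 0, "axialseg_invalid_argument",
               "every stage's channel count must be divisible by n_heads")
  }
  structure(list(in_channels = in_channels, base_channels = base_channels,
                 global_depth = global_depth, local_depth = local_depth,
                 patch_grid = as.integer(patch_grid),
                 n_heads = n_heads, input_size = as.integer(input_size),
                 decoder_convs = decoder_convs, table_mode = table_mode),
            class = "network_config")
}

# ---- elementary layers ------------------------------------------------------

conv1x1_init <- function(cin, cout) {
  list(W = matrix(stats::rnorm(cout * cin, 0, sqrt(2 / cin)), cout, cin),
       b = numeric(cout))
}
conv1x1_fwd <- function(p, x) {
  dm <- dim(x)
  Xm <- matrix(x, dm[1], prod(dm[-1]))
  Ym <- p$W %*% Xm + p$b
  list(out = array(Ym, c(nrow(p$W), dm[-1])), cache = list(Xm = Xm, dims = dm))
}
conv1x1_bwd <- function(p, dY, cache) {
  dm <- dim(dY)
  dYm <- matrix(dY, dm[1], prod(dm[-1]))
  list(dx = array(crossprod(p$W, dYm), cache$dims),
       grads = list(W = tcrossprod(dYm, cache$Xm), b = rowSums(dYm)))
}

bn_init <- function(c) list(gamma = rep(1, c), beta = numeric(c))
bn_state_init <- function(c) list(mean = numeric(c), var = rep(1, c))
bn_fwd <- function(p, x, state, train, momentum = 0.1, eps = 1e-5) {
  dm <- dim(x)
  Xm <- matrix(x, dm[1], prod(dm[-1]))
  if (train) {
    mu <- rowMeans(Xm)
    va <- rowMeans(Xm^2) - mu^2
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * va
  } else {
    mu <- state$mean; va <- state$var
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- (Xm - mu) * istd
  Ym <- p$gamma * xhat + p$beta
  list(out = array(Ym, dm), state = state,
       cache = list(xhat = xhat, istd = istd, dims = dm, train = train))
}
bn_bwd <- function(p, dY, cache) {
  dm <- cache$dims
  dYm <- matrix(dY, dm[1], prod(dm[-1]))
  M <- ncol(dYm)
  dgamma <- rowSums(dYm * cache$xhat)
  dbeta <- rowSums(dYm)
  dxhat <- dYm * p$gamma
  if (cache$train) {
    dXm <- cache$istd / M *
      (M * dxhat - rowSums(dxhat) - cache$xhat * rowSums(dxhat * cache$xhat))
  } else {
    dXm <- dxhat * cache$istd
  }
  list(dx = array(dXm, dm), grads = list(gamma = dgamma, beta = dbeta))
}

relu_fwd <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_bwd <- function(dY, cache) dY * cache

# strided 2x2 convolution: halves H and W, maps cin -> cout
down_init <- function(cin, cout) {
  list(W = matrix(stats::rnorm(cout * 4 * cin, 0, sqrt(2 / (4 * cin))),
                  cout, 4 * cin),
       b = numeric(cout))
}
down_fwd <- function(p, x) {
  dm <- dim(x)  # C,H,W,N
  xr <- array(x, c(dm[1], 2, dm[2] %/% 2, 2, dm[3] %/% 2, dm[4]))
  xp <- aperm(xr, c(1, 2, 4, 3, 5, 6))
  Xm <- matrix(xp, 4 * dm[1], prod(dm) %/% (4 * dm[1]))
  Ym <- p$W %*% Xm + p$b
  list(out = array(Ym, c(nrow(p$W), dm[2] %/% 2, dm[3] %/% 2, dm[4])),
       cache = list(Xm = Xm, dims = dm))
}
down_bwd <- function(p, dY, cache) {
  dm <- cache$dims
  dYm <- matrix(dY, dim(dY)[1], prod(dim(dY)[-1]))
  dXp <- crossprod(p$W, dYm)
  dXp <- array(dXp, c(dm[1], 2, 2, dm[2] %/% 2, dm[3] %/% 2, dm[4]))
  dx <- array(aperm(dXp, c(1, 2, 4, 3, 5, 6)), dm)
  list(dx = dx, grads = list(W = tcrossprod(dYm, cache$Xm), b = rowSums(dYm)))
}

# nearest-neighbor 2x upsampling
up_fwd <- function(x) {
  dm <- dim(x)
  out <- x[, rep(seq_len(dm[2]), each = 2), rep(seq_len(dm[3]), each = 2), ,
           drop = FALSE]
  list(out = out, cache = dm)
}
up_bwd <- function(dY, dm) {
  dr <- array(dY, c(dm[1], 2, dm[2], 2, dm[3], dm[4]))
  out <- dr[, 1, , 1, , , drop = FALSE] + dr[, 2, , 1, , , drop = FALSE] +
    dr[, 1, , 2, , , drop = FALSE] + dr[, 2, , 2, , , drop = FALSE]
  array(out, dm)
}

concat_channels <- function(x1, x2) {
  d1 <- dim(x1); d2 <- dim(x2)
  out <- array(0, c(d1[1] + d2[1], d1[2], d1[3], d1[4]))
  out[seq_len(d1[1]), , , ] <- x1
  out[d1[1] + seq_len(d2[1]), , , ] <- x2
  out
}

# attention over a [C,H,W,N] batch: fold batch (and the non-attended axis)
# into the slice dimension of the [C,S,R] core.
attn4_fwd <- function(p, x, axis) {
  dm <- dim(x)
  if (axis == "height") {
    xf <- array(x, c(dm[1], dm[2], dm[3] * dm[4]))
  } else {
    xf <- array(aperm(x, c(1, 3, 2, 4)), c(dm[1], dm[3], dm[2] * dm[4]))
  }
  fw <- axattn_forward(xf, p)
  out <- if (axis == "height") array(fw$out, dm) else
    aperm(array(fw$out, c(dm[1], dm[3], dm[2], dm[4])), c(1, 3, 2, 4))
  list(out = out, cache = list(core = fw$cache, dims = dm, axis = axis))
}
attn4_bwd <- function(p, dY, cache) {
  dm <- cache$dims
  dYf <- if (cache$axis == "height")
    array(dY, c(dm[1], dm[2], dm[3] * dm[4]))
  else
    array(aperm(dY, c(1, 3, 2, 4)), c(dm[1], dm[3], dm[2] * dm[4]))
  bw <- axattn_backward(dYf, cache$core, p)
  dx <- if (cache$axis == "height") array(bw$dX, dm) else
    aperm(array(bw$dX, c(dm[1], dm[3], dm[2], dm[4])), c(1, 3, 2, 4))
  list(dx = dx, grads = bw$grads)
}

# ---- encoder / decoder blocks ----------------------------------------------

encoder_block_init <- function(cin, cout, span_h, span_w, n_heads, table_mode) {
  list(conv = conv1x1_init(cin, cout),
       bn1 = bn_init(cout),
       attn_h = axial_attention_params(cout, span_h, n_heads, table_mode,
                                       seed = sample.int(2^30, 1)),
       attn_w = axial_attention_params(cout, span_w, n_heads, table_mode,
                                       seed = sample.int(2^30, 1)),
       bn2 = bn_init(cout))
}
encoder_block_state_init <- function(cout) {
  list(bn1 = bn_state_init(cout), bn2 = bn_state_init(cout))
}
encoder_block_fwd <- function(p, x, state, train) {
  cv <- conv1x1_fwd(p$conv, x)
  b1 <- bn_fwd(p$bn1, cv$out, state$bn1, train); state$bn1 <- b1$state
  ah <- attn4_fwd(p$attn_h, b1$out, "height")
  aw <- attn4_fwd(p$attn_w, ah$out, "width")
  b2 <- bn_fwd(p$bn2, aw$out, state$bn2, train); state$bn2 <- b2$state
  rl <- relu_fwd(b1$out + b2$out)     # residual around the attention pair
  list(out = rl$out, state = state,
       cache = list(cv = cv$cache, b1 = b1$cache, ah = ah$cache,
                    aw = aw$cache, b2 = b2$cache, rl = rl$cache))
}
encoder_block_bwd <- function(p, dY, cache) {
  dsum <- relu_bwd(dY, cache$rl)
  b2 <- bn_bwd(p$bn2, dsum, cache$b2)
  aw <- attn4_bwd(p$attn_w, b2$dx, cache$aw)
  ah <- attn4_bwd(p$attn_h, aw$dx, cache$ah)
  db1 <- dsum + ah$dx                  # residual path joins before bn1 output
  b1 <- bn_bwd(p$bn1, db1, cache$b1)
  cv <- conv1x1_bwd(p$conv, b1$dx, cache$cv)
  list(dx = cv$dx,
       grads = list(conv = cv$grads, bn1 = b1$grads, attn_h = ah$grads,
                    attn_w = aw$grads, bn2 = b2$grads))
}

decoder_block_init <- function(cbottom, n_convs) {
  chalf <- cbottom %/% 2
  convs <- vector("list", n_convs)
  cin <- cbottom                       # half from upsampling path + half skip
  for (j in seq_len(n_convs)) {
    convs[[j]] <- conv1x1_init(cin, chalf)
    cin <- chalf
  }
  list(conv_up = conv1x1_init(cbottom, chalf),
       convs = convs,
       bns = lapply(seq_len(n_convs), function(j) bn_init(chalf)))
}
decoder_block_state_init <- function(cbottom, n_convs) {
  lapply(seq_len(n_convs), function(j) bn_state_init(cbottom %/% 2))
}
decoder_block_fwd <- function(p, x, skip, state, train) {
  up <- up_fwd(x)
  cu <- conv1x1_fwd(p$conv_up, up$out)
  r0 <- relu_fwd(cu$out)
  z <- concat_channels(r0$out, skip)
  n_convs <- length(p$convs)
  caches <- vector("list", n_convs)
  for (j in seq_len(n_convs)) {
    cj <- conv1x1_fwd(p$convs[[j]], z)
    bj <- bn_fwd(p$bns[[j]], cj$out, state[[j]], train); state[[j]] <- bj$state
    rj <- relu_fwd(bj$out)
    caches[[j]] <- list(cj = cj$cache, bj = bj$cache, rj = rj$cache)
    z <- rj$out
  }
  list(out = z, state = state,
       cache = list(up = up$cache, cu = cu$cache, r0 = r0$cache,
                    chalf = nrow(p$conv_up$W), convs = caches))
}
decoder_block_bwd <- function(p, dY, cache) {
  n_convs <- length(p$convs)
  gconvs <- vector("list", n_convs); gbns <- vector("list", n_convs)
  dz <- dY
  for (j in rev(seq_len(n_convs))) {
    cj <- cache$convs[[j]]
    drj <- relu_bwd(dz, cj$rj)
    bj <- bn_bwd(p$bns[[j]], drj, cj$bj)
    cjb <- conv1x1_bwd(p$convs[[j]], bj$dx, cj$cj)
    gbns[[j]] <- bj$grads; gconvs[[j]] <- cjb$grads
    dz <- cjb$dx
  }
  ch <- cache$chalf
  d_up_path <- dz[seq_len(ch), , , , drop = FALSE]
  d_skip <- dz[ch + seq_len(dim(dz)[1] - ch), , , , drop = FALSE]
  dr0 <- relu_bwd(d_up_path, cache$r0)
  cu <- conv1x1_bwd(p$conv_up, dr0, cache$cu)
  dx <- up_bwd(cu$dx, cache$up)
  list(dx = dx, d_skip = d_skip,
       grads = list(conv_up = cu$grads, convs = gconvs, bns = gbns))
}

# ---- branches ---------------------------------------------------------------

branch_init <- function(cin, base, depth, H, W, n_heads, table_mode, n_convs) {
  enc <- vector("list", depth); dec <- vector("list", depth)
  for (i in seq_len(depth)) {
    ci <- base * 2^(i - 1)
    hi <- H %/% 2^(i - 1); wi <- W %/% 2^(i - 1)
    enc[[i]] <- list(block = encoder_block_init(ci, ci, hi, wi, n_heads,
                                                table_mode),
                     down = down_init(ci, 2 * ci))
  }
  for (i in seq_len(depth)) dec[[i]] <- decoder_block_init(base * 2^i, n_convs)
  list(stem = conv1x1_init(cin, base), enc = enc, dec = dec)
}
branch_state_init <- function(base, depth, n_convs) {
  list(enc = lapply(seq_len(depth), function(i)
         encoder_block_state_init(base * 2^(i - 1))),
       dec = lapply(seq_len(depth), function(i)
         decoder_block_state_init(base * 2^i, n_convs)))
}
branch_fwd <- function(p, x, state, train) {
  depth <- length(p$enc)
  st <- conv1x1_fwd(p$stem, x)
  z <- st$out
  enc_caches <- vector("list", depth)
  skips <- vector("list", depth)
  for (i in seq_len(depth)) {
    eb <- encoder_block_fwd(p$enc[[i]]$block, z, state$enc[[i]], train)
    state$enc[[i]] <- eb$state
    skips[[i]] <- eb$out
    dn <- down_fwd(p$enc[[i]]$down, eb$out)
    enc_caches[[i]] <- list(block = eb$cache, down = dn$cache)
    z <- dn$out
  }
  dec_caches <- vector("list", depth)
  for (i in rev(seq_len(depth))) {
    db <- decoder_block_fwd(p$dec[[i]], z, skips[[i]], state$dec[[i]], train)
    state$dec[[i]] <- db$state
    dec_caches[[i]] <- db$cache
    z <- db$out
  }
  list(out = z, state = state,
       cache = list(stem = st$cache, enc = enc_caches, dec = dec_caches))
}
branch_bwd <- function(p, dY, cache) {
  depth <- length(p$enc)
  genc <- vector("list", depth); gdec <- vector("list", depth)
  d_skips <- vector("list", depth)
  dz <- dY
  for (i in seq_len(depth)) {          # decoders in reverse of forward order
    db <- decoder_block_bwd(p$dec[[i]], dz, cache$dec[[i]])
    gdec[[i]] <- db$grads
    d_skips[[i]] <- db$d_skip
    dz <- db$dx
  }
  for (i in rev(seq_len(depth))) {
    dn <- down_bwd(p$enc[[i]]$down, dz, cache$enc[[i]]$down)
    d_block_out <- dn$dx + d_skips[[i]]
    eb <- encoder_block_bwd(p$enc[[i]]$block, d_block_out,
                            cache$enc[[i]]$block)
    genc[[i]] <- list(block = eb$grads, down = dn$grads)
    dz <- eb$dx
  }
  st <- conv1x1_bwd(p$stem, dz, cache$stem)
  list(dx = st$dx, grads = list(stem = st$grads, enc = genc, dec = gdec))
}

# ---- patch folding ----------------------------------------------------------

fold_patches <- function(x, grid) {
  dm <- dim(x)  # C,H,W,N
  gr <- grid[1]; gc <- grid[2]
  ph <- dm[2] %/% gr; pw <- dm[3] %/% gc
  xr <- array(x, c(dm[1], ph, gr, pw, gc, dm[4]))
  xp <- aperm(xr, c(1, 2, 4, 3, 5, 6))
  array(xp, c(dm[1], ph, pw, gr * gc * dm[4]))
}
unfold_patches <- function(y, grid, dims_orig) {
  gr <- grid[1]; gc <- grid[2]
  C <- dim(y)[1]; ph <- dim(y)[2]; pw <- dim(y)[3]
  N <- dims_orig[4]
  yr <- array(y, c(C, ph, pw, gr, gc, N))
  yp <- aperm(yr, c(1, 2, 4, 3, 5, 6))
  array(yp, c(C, ph * gr, pw * gc, N))
}

#' Split a feature map into a grid of non-overlapping patches
#'
#' Tiles a C x H x W array into `grid[1] * grid[2]` patches in row-major
#' order (patch (0,0) is the top-left block of rows and columns).
#'
#' @param x numeric C x H x W array.
#' @param grid c(rows, cols); H and W must be divisible by it.
#' @return list of patches, each C x (H/rows) x (W/cols).
#' @export
split_into_patches <- function(x, grid = c(4, 4)) {
  check_that(length(dim(x)) == 3L, "axialseg_shape_error",
             "x must be a C x H x W array")
  dm <- dim(x)
  check_that(dm[2] %% grid[1] == 0 && dm[3] %% grid[2] == 0,
             "axialseg_shape_error", "H and W must be divisible by the grid")
  ph <- dm[2] %/% grid[1]; pw <- dm[3] %/% grid[2]
  out <- vector("list", grid[1] * grid[2])
  idx <- 1L
  for (pr in seq_len(grid[1])) {
    for (pc in seq_len(grid[2])) {
      out[[idx]] <- x[, (pr - 1) * ph + seq_len(ph),
                      (pc - 1) * pw + seq_len(pw), drop = FALSE]
      idx <- idx + 1L
    }
  }
  out
}

#' Reassemble patches produced by [split_into_patches()]
#' @param patches list of C x ph x pw patches in row-major order.
#' @param grid c(rows, cols).
#' @return the reassembled C x H x W array.
#' @export
reassemble_patches <- function(patches, grid = c(4, 4)) {
  check_that(length(patches) == grid[1] * grid[2], "axialseg_shape_error",
             "patch count does not match the grid")
  dmp <- dim(patches[[1]])
  out <- array(0, c(dmp[1], dmp[2] * grid[1], dmp[3] * grid[2]))
  idx <- 1L
  for (pr in seq_len(grid[1])) {
    for (pc in seq_len(grid[2])) {
      out[, (pr - 1) * dmp[2] + seq_len(dmp[2]),
          (pc - 1) * dmp[3] + seq_len(dmp[3])] <- patches[[idx]]
      idx <- idx + 1L
    }
  }
  out
}

# ---- whole network ----------------------------------------------------------

#' Initialize network parameters
#'
#' @param config a [network_config()].
#' @param seed integer seed for the (deterministic) random initialization.
#' @return nested parameter list (`global`, `local`, `fuse`, `final`).
#' @export
network_init <- function(config, seed = 1) {
  H <- config$input_size[1]; W <- config$input_size[2]
  ph <- H %/% config$patch_grid[1]; pw <- W %/% config$patch_grid[2]
  with_seed(seed, list(
    global = branch_init(config$in_channels, config$base_channels,
                         config$global_depth, H, W, config$n_heads,
                         config$table_mode, config$decoder_convs),
    local = branch_init(config$in_channels, config$base_channels,
                        config$local_depth, ph, pw, config$n_heads,
                        config$table_mode, config$decoder_convs),
    fuse = list(gg = 0.5, gl = 0.5),
    final = conv1x1_init(config$base_channels, 1)))
}

#' Initialize batch-norm running statistics for a network
#' @param config a [network_config()].
#' @return nested state list matching [network_init()] parameters.
#' @export
network_state_init <- function(config) {
  list(global = branch_state_init(config$base_channels, config$global_depth,
                                  config$decoder_convs),
       local = branch_state_init(config$base_channels, config$local_depth,
                                 config$decoder_convs))
}

#' Network forward pass
#'
#' @param params from [network_init()].
#' @param x input batch, array C x H x W x N (or C x H x W for a single
#'   image) matching `config$input_size`.
#' @param config the [network_config()].
#' @param state batch-norm running statistics (from
#'   `network_state_init()`); required.
#' @param train TRUE for batch statistics (training), FALSE for running
#'   statistics (inference).
#' @return list with `prob` (H x W x N probability maps, values in (0,1)),
#'   `logits`, updated `state`, and (when `train = TRUE`) the `cache` for
#'   the backward pass.
#' @export
net_forward <- function(params, x, config, state, train = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  dm <- dim(x)
  check_that(dm[1] == config$in_channels &&
               dm[2] == config$input_size[1] &&
               dm[3] == config$input_size[2], "axialseg_shape_error",
             sprintf("input %dx%dx%d does not match the configured %dx%dx%d",
                     dm[1], dm[2], dm[3], config$in_channels,
                     config$input_size[1], config$input_size[2]))
  gb <- branch_fwd(params$global, x, state$global, train)
  state$global <- gb$state
  xp <- fold_patches(x, config$patch_grid)
  lb <- branch_fwd(params$local, xp, state$local, train)
  state$local <- lb$state
  lfeat <- unfold_patches(lb$out, config$patch_grid, dm)
  fused <- params$fuse$gg * gb$out + params$fuse$gl * lfeat
  fin <- conv1x1_fwd(params$final, fused)
  logits <- array(fin$out, dm[c(2, 3, 4)])
  prob <- 1 / (1 + exp(-logits))
  cache <- if (train)
    list(gb = gb$cache, lb = lb$cache, gout = gb$out, lfeat = lfeat,
         fin = fin$cache, dims = dm)
  else NULL
  list(prob = prob, logits = logits, state = state, cache = cache)
}

# Backward from d(loss)/d(logits); returns the full gradient tree.
net_backward <- function(params, dlogits, cache, config) {
  dm <- cache$dims
  dfin <- array(dlogits, c(1, dm[2], dm[3], dm[4]))
  fin <- conv1x1_bwd(params$final, dfin, cache$fin)
  dfused <- fin$dx
  g_fuse <- list(gg = sum(dfused * cache$gout),
                 gl = sum(dfused * cache$lfeat))
  dgb <- branch_bwd(params$global, params$fuse$gg * dfused, cache$gb)
  dlf <- fold_patches(params$fuse$gl * dfused, config$patch_grid)
  dlb <- branch_bwd(params$local, dlf, cache$lb)
  list(global = dgb$grads, local = dlb$grads, fuse = g_fuse,
       final = fin$grads)
}

#' Binary cross-entropy loss
#'
#' Mean over all pixels of -(p log p̂ + (1-p) log(1-p̂)). Predictions are
#' clipped to `[eps, 1-eps]` (eps = 1e-7) before the logarithms.
#'
#' @param pred predicted probabilities, any numeric array.
#' @param target true labels in {0, 1}, same shape.
#' @param eps clipping bound.
#' @return scalar loss.
#' @export
bce_loss <- function(pred, target, eps = 1e-7) {
  check_that(identical(dim(pred), dim(target)) &&
               length(pred) == length(target),
             "axialseg_shape_error", "pred and target shapes differ")
  p <- pmin(pmax(pred, eps), 1 - eps)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}
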