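# Preprocessing, the CPU training loop (Adam on the binary cross-entropy),
# and overlap evaluation metrics (Dice / IoU / Recall).

#' Training configuration
#'
#' Defaults follow the reference setting for this architecture family:
#' learning rate 1e-4, 25 epochs, batch size 4, Adam.
#'
#' @param learning_rate Adam step size (default 1e-4).
#' @param epochs passes over the training set (default 25).
#' @param batch_size mini-batch size (default 4).
#' @param optimizer "adam" (beta1 = 0.9, beta2 = 0.999).
#' @param seed integer seed controlling initialization and data order.
#' @param max_steps optional hard cap on optimizer steps (NULL = no cap).
#' @param verbose print per-epoch progress.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, epochs = 25, batch_size = 4,
                         optimizer = "adam", seed = 1, max_steps = NULL,
                         verbose = FALSE) {
  check_that(learning_rate >= 0, "axialseg_invalid_argument",
             "learning_rate must be >= 0")
  check_that(is_count(epochs) && epochs >= 1 &&
               is_count(batch_size) && batch_size >= 1,
             "axialseg_invalid_argument",
             "epochs and batch_size must be positive integers")
  check_that(identical(optimizer, "adam"), "axialseg_invalid_argument",
             "only the adam optimizer is implemented")
  structure(list(learning_rate = learning_rate, epochs = epochs,
                 batch_size = batch_size, optimizer = optimizer, seed = seed,
                 max_steps = max_steps, verbose = verbose),
            class = "train_config")
}

# ---- preprocessing ----------------------------------------------------------

#' Per-image min-max intensity normalization
#'
#' Scales the image linearly so its minimum maps to 0 and maximum to 1.
#' A constant image maps to all zeros (documented convention). Set
#' `method = "zscore"` for standardization to mean 0 / sd 1 instead.
#'
#' @param image numeric array with finite values.
#' @param method "minmax" (default) or "zscore".
#' @return normalized array of the same shape.
#' @export
normalize_intensity <- function(image, method = c("minmax", "zscore")) {
  method <- match.arg(method)
  check_that(all(is.finite(image)), "axialseg_invalid_argument",
             "image must be finite")
  if (method == "zscore") {
    s <- stats::sd(as.vector(image))
    if (s == 0) return(image * 0)
    return((image - mean(image)) / s)
  }
  rng <- range(image)
  if (rng[1] == rng[2]) return(image * 0)
  (image - rng[1]) / (rng[2] - rng[1])
}

#' Resample a 2D/3D volume to a target voxel spacing
#'
#' Separable linear interpolation along each axis; output dimensions are
#' `round(dim * spacing_in / spacing_out)` so the physical extent is
#' preserved as the spatial resolution is made consistent in each direction.
#'
#' @param volume 2D matrix or 3D array.
#' @param spacing_in input voxel spacing, one value per axis (recycled).
#' @param spacing_out target spacing, one value per axis (recycled).
#' @return resampled array.
#' @export
resample_spacing <- function(volume, spacing_in, spacing_out) {
  check_that(all(spacing_in > 0) && all(spacing_out > 0),
             "axialseg_invalid_argument", "spacings must be positive")
  nd <- length(dim(volume))
  spacing_in <- rep_len(spacing_in, nd)
  spacing_out <- rep_len(spacing_out, nd)
  out <- volume
  for (ax in seq_len(nd)) {
    d_in <- dim(out)[ax]
    d_out <- max(1L, round(dim(volume)[ax] * spacing_in[ax] / spacing_out[ax]))
    if (d_out == d_in && spacing_in[ax] == spacing_out[ax]) next
    # sample positions in input index space (0-based), endpoints preserved
    pos <- if (d_out == 1) 0 else seq(0, d_in - 1, length.out = d_out)
    out <- apply_along(out, ax, function(v) {
      if (length(v) == 1) rep(v, d_out)
      else stats::approx(x = 0:(length(v) - 1), y = v, xout = pos)$y
    }, d_out)
  }
  out
}

# apply a vector -> vector(n_out) function along axis `ax` of an array
apply_along <- function(arr, ax, f, n_out) {
  nd <- length(dim(arr))
  perm <- c(ax, setdiff(seq_len(nd), ax))
  ap <- aperm(arr, perm)
  dm <- dim(ap)
  m <- matrix(ap, dm[1], prod(dm[-1]))
  res <- vapply(seq_len(ncol(m)), function(j) f(m[, j]), numeric(n_out))
  res <- array(res, c(n_out, dm[-1]))
  aperm(res, order(perm))
}

#' Masked histogram equalization for ultrasound images
#'
#' Zeroes pixels outside the region of interest, then histogram-equalizes
#' the gray levels inside it (256 bins): inside the ROI, the output level is
#' the rescaled empirical CDF of the input level, which flattens the
#' histogram.
#'
#' @param image H x W matrix with values in `[0,1]`.
#' @param roi_mask binary H x W matrix; must contain at least one pixel.
#' @return equalized image, zero outside the ROI.
#' @export
equalize_us <- function(image, roi_mask) {
  check_that(identical(dim(image), dim(roi_mask)), "axialseg_shape_error",
             "image and roi_mask shapes differ")
  check_that(all(roi_mask %in% c(0, 1)), "axialseg_invalid_argument",
             "roi_mask must be binary")
  check_that(sum(roi_mask) > 0, "axialseg_invalid_argument", "empty ROI")
  nbins <- 256L
  inside <- roi_mask == 1
  lev <- pmin(floor(clamp01(image[inside]) * nbins), nbins - 1L)  # 0..255
  cdf <- cumsum(tabulate(lev + 1L, nbins)) / sum(inside)
  cdf_min <- cdf[which(cdf > 0)[1L]]
  mapped <- if (cdf_min >= 1) rep(1, length(lev)) else
    (cdf[lev + 1L] - cdf_min) / (1 - cdf_min)
  out <- image * 0
  out[inside] <- mapped
  out
}

# ---- metrics ----------------------------------------------------------------

check_binary_pair <- function(x, y) {
  check_that(identical(dim(x), dim(y)) && length(x) == length(y),
             "axialseg_shape_error", "masks must have identical shapes")
  check_that(all(x %in% c(0, 1)) && all(y %in% c(0, 1)),
             "axialseg_invalid_argument", "masks must be binary")
}

#' Overlap metrics between a predicted and a reference mask
#'
#' With X the prediction and Y the reference:
#' DSC = 2|X∩Y| / (|X|+|Y|), IoU = |X∩Y| / |X∪Y|, Recall = |X∩Y| / |Y|.
#' Conventions for degenerate cases: if both masks are empty all three
#' metrics are 1; an empty reference with a nonempty prediction gives
#' Recall 0.
#'
#' @param pred_mask,true_mask binary arrays of equal shape.
#' @return scalar in `[0,1]`.
#' @export
dsc <- function(pred_mask, true_mask) {
  check_binary_pair(pred_mask, true_mask)
  inter <- sum(pred_mask * true_mask)
  tot <- sum(pred_mask) + sum(true_mask)
  if (tot == 0) 1 else 2 * inter / tot
}

#' @rdname dsc
#' @export
iou <- function(pred_mask, true_mask) {
  check_binary_pair(pred_mask, true_mask)
  inter <- sum(pred_mask * true_mask)
  uni <- sum(pmax(pred_mask, true_mask))
  if (uni == 0) 1 else inter / uni
}

#' @rdname dsc
#' @export
recall <- function(pred_mask, true_mask) {
  check_binary_pair(pred_mask, true_mask)
  ny <- sum(true_mask)
  if (ny == 0) return(if (sum(pred_mask) == 0) 1 else 0)
  sum(pred_mask * true_mask) / ny
}

# ---- Adam on a nested gradient tree ----------------------------------------

adam_step <- function(params, grads, mstate, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, m) {
    if (is.list(g)) {
      if (is.null(m)) m <- vector("list", length(g))
      for (nm in names(g)) {
        if (is.null(g[[nm]])) next
        res <- walk(p[[nm]], g[[nm]], m[[nm]])
        p[[nm]] <- res$p; m[[nm]] <- res$m
      }
      list(p = p, m = m)
    } else {
      if (is.null(m)) m <- list(m1 = g * 0, m2 = g * 0)
      m$m1 <- beta1 * m$m1 + (1 - beta1) * g
      m$m2 <- beta2 * m$m2 + (1 - beta2) * g^2
      mhat <- m$m1 / (1 - beta1^t)
      vhat <- m$m2 / (1 - beta2^t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m)
    }
  }
  walk(params, grads, mstate)
}

# accumulate two gradient trees (same structure)
tree_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.list(b)) {
    for (nm in names(b)) if (!is.null(b[[nm]])) a[[nm]] <- tree_add(a[[nm]], b[[nm]])
    a
  } else a + b
}

# ---- sample conversion ------------------------------------------------------

sample_to_array <- function(s) {
  img <- s$image
  if (length(dim(img)) == 3L) aperm(img, c(3, 1, 2))
  else array(img, c(1, dim(img)))
}

stack_batch <- function(samples, idx) {
  arrs <- lapply(samples[idx], sample_to_array)
  dm <- dim(arrs[[1]])
  x <- array(0, c(dm, length(idx)))
  y <- array(0, c(dm[2], dm[3], length(idx)))
  for (j in seq_along(idx)) {
    x[, , , j] <- arrs[[j]]
    y[, , j] <- samples[[idx[j]]]$mask
  }
  list(x = x, y = y)
}

# ---- training loop ----------------------------------------------------------

#' Train the dual-branch segmentation network
#'
#' Minimizes the binary cross-entropy with Adam. Fully seeded: parameter
#' initialization and the per-epoch sample order both derive from
#' `train_config$seed`, so a repeated run on CPU reproduces the loss curve
#' bit-exactly. Per-epoch mean training loss (and validation DSC, when a
#' validation set is given) are logged; the returned fit keeps the
#' parameters that achieved the best validation DSC (or the final ones if
#' no validation set is supplied).
#'
#' @param train_samples nonempty list of [seg_sample()]s whose images match
#'   `net_config$input_size`.
#' @param val_samples optional validation list.
#' @param init_params optional starting parameters (e.g. from a previous
#'   fit); defaults to a fresh seeded [network_init()].
#' @param net_config a [network_config()].
#' @param train_cfg a [train_config()].
#' @return a `seg_fit`: `params`, `state` (batch-norm running statistics),
#'   `net_config`, `train_config`, `history` (data.frame with epoch, mean
#'   loss, validation DSC), `step_loss` (per-step losses), `best_epoch`.
#' @export
train <- function(train_samples, val_samples = NULL, net_config,
                  train_cfg = train_config(), init_params = NULL) {
  check_that(is.list(train_samples) && length(train_samples) >= 1,
             "axialseg_invalid_argument", "training set must be nonempty")
  n <- length(train_samples)
  params <- if (is.null(init_params)) network_init(net_config,
                                                   seed = train_cfg$seed)
            else init_params
  state <- network_state_init(net_config)
  mstate <- NULL
  t_step <- 0L
  step_loss <- numeric(0)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_dsc = numeric(0))
  best <- list(dsc = -Inf, params = params, state = state, epoch = 0L)
  done <- FALSE
  with_seed(train_cfg$seed + 1L, {
    for (epoch in seq_len(train_cfg$epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / train_cfg$batch_size))
      ep_losses <- numeric(0)
      for (bi in seq_along(batches)) {
        batch <- stack_batch(train_samples, batches[[bi]])
        fw <- net_forward(params, batch$x, net_config, state, train = TRUE)
        state <- fw$state
        loss <- bce_loss(fw$prob, batch$y)
        if (!is.finite(loss))
          stop_axialseg("axialseg_divergence",
                        sprintf("non-finite loss at epoch %d step %d",
                                epoch, t_step + 1L))
        # d(BCE)/d(logit) = (p_hat - p) / N_pixels
        dlogits <- (fw$prob - batch$y) / length(batch$y)
        grads <- net_backward(params, dlogits, fw$cache, net_config)
        t_step <- t_step + 1L
        if (train_cfg$learning_rate > 0) {
          upd <- adam_step(params, grads, mstate,
                           lr = train_cfg$learning_rate, t = t_step)
          params <- upd$p; mstate <- upd$m
        }
        ep_losses <- c(ep_losses, loss)
        step_loss <- c(step_loss, loss)
        if (!is.null(train_cfg$max_steps) && t_step >= train_cfg$max_steps) {
          done <- TRUE; break
        }
      }
      val_dsc <- NA_real_
      if (!is.null(val_samples) && length(val_samples)) {
        val_dsc <- mean(vapply(val_samples, function(s) {
          pr <- net_forward(params, sample_to_array(s), net_config, state,
                            train = FALSE)$prob
          dsc((pr[, , 1] >= 0.5) * 1, s$mask)
        }, 0))
        if (val_dsc > best$dsc)
          best <- list(dsc = val_dsc, params = params, state = state,
                       epoch = epoch)
      }
      history <- rbind(history, data.frame(epoch = epoch,
                                           loss = mean(ep_losses),
                                           val_dsc = val_dsc))
      if (train_cfg$verbose)
        message(sprintf("epoch %3d  loss %.5f  val DSC %s", epoch,
                        mean(ep_losses),
                        if (is.na(val_dsc)) "-" else sprintf("%.4f", val_dsc)))
      if (done) break
    }
  })
  if (!is.null(val_samples) && length(val_samples) && best$epoch > 0) {
    params <- best$params; state <- best$state
  }
  structure(list(params = params, state = state, net_config = net_config,
                 train_config = train_cfg, history = history,
                 step_loss = step_loss,
                 best_epoch = if (best$epoch > 0) best$epoch else nrow(history)),
            class = "seg_fit")
}

#' @export
print.seg_fit <- function(x, ...) {
  cat(sprintf("<seg_fit> %d epochs, final loss %.5f\n",
              nrow(x$history), utils::tail(x$history$loss, 1)))
  invisible(x)
}

#' Predict a probability map or binary mask for one image
#'
#' @param object a `seg_fit` from [train()].
#' @param image H x W matrix or H x W x 3 array matching the fit's input
#'   size, or a [seg_sample()].
#' @param threshold binarization threshold applied to the sigmoid output
#'   (default 0.5); use `type = "prob"` for the raw probability map.
#' @param type "mask" or "prob".
#' @param ... unused.
#' @return H x W matrix.
#' @export
predict.seg_fit <- function(object, image, threshold = 0.5,
                            type = c("mask", "prob"), ...) {
  type <- match.arg(type)
  if (inherits(image, "seg_sample")) image <- image$image
  x <- sample_to_array(list(image = image))
  pr <- net_forward(object$params, x, object$net_config, object$state,
                    train = FALSE)$prob[, , 1]
  if (type == "prob") pr else (pr >= threshold) * 1
}

#' Evaluate a fitted network on labeled samples
#'
#' Thresholds the network's sigmoid output at `threshold` and computes
#' per-sample and mean DSC, IoU and Recall.
#'
#' @param fit a `seg_fit` (or a checkpoint path readable by
#'   [read_checkpoint()]).
#' @param samples list of [seg_sample()]s.
#' @param threshold binarization threshold (default 0.5).
#' @return an `eval_report`: `per_sample` data.frame (sample, dsc, iou,
#'   recall), `mean_dsc`, `mean_iou`, `mean_recall`, `threshold`, `n`.
#' @export
evaluate <- function(fit, samples, threshold = 0.5) {
  if (is.character(fit)) fit <- read_checkpoint(fit)
  check_that(inherits(fit, "seg_fit"), "axialseg_invalid_argument",
             "fit must be a seg_fit or checkpoint path")
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    pm <- predict(fit, s, threshold = threshold)
    data.frame(sample = i, dsc = dsc(pm, s$mask), iou = iou(pm, s$mask),
               recall = recall(pm, s$mask))
  })
  per <- do.call(rbind, rows)
  structure(list(per_sample = per, mean_dsc = mean(per$dsc),
                 mean_iou = mean(per$iou), mean_recall = mean(per$recall),
                 threshold = threshold, n = nrow(per)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d  DSC %.4f  IoU %.4f  Recall %.4f\n",
              x$n, x$mean_dsc, x$mean_iou, x$mean_recall))
  invisible(x)
}

#' Write an evaluation report as JSON (and optionally CSV)
#' @param report an [evaluate()] result.
#' @param path output JSON path.
#' @param csv optional CSV path for the per-sample table.
#' @export
write_eval_report <- function(report, path, csv = NULL) {
  jsonlite::write_json(list(n = report$n, threshold = report$threshold,
                            mean_dsc = report$mean_dsc,
                            mean_iou = report$mean_iou,
                            mean_recall = report$mean_recall,
                            per_sample = report$per_sample),
                       path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (!is.null(csv)) utils::write.csv(report$per_sample, csv, row.names = FALSE)
  invisible(path)
}

# ---- checkpointing ----------------------------------------------------------

pack_tree <- function(x) {
  if (inherits(x, "axial_attention_params"))
    return(list(.attn = TRUE, fields = pack_tree(unclass(x))))
  if (is.list(x)) return(lapply(x, pack_tree))
  if (is.numeric(x)) return(list(.arr = TRUE, dim = dim(x), data = as.vector(x)))
  x
}
unpack_tree <- function(x) {
  if (is.list(x) && isTRUE(x$.attn))
    return(structure(unpack_tree(x$fields), class = "axial_attention_params"))
  if (is.list(x) && isTRUE(x$.arr)) {
    v <- as.numeric(unlist(x$data))
    dm <- unlist(x$dim)
    if (length(dm)) dim(v) <- dm
    return(v)
  }
  if (is.list(x)) return(lapply(x, unpack_tree))
  x
}

#' Write / read a training checkpoint
#'
#' A single JSON file holding a version header, the network and training
#' configuration, the batch-norm running statistics, and all parameters.
#'
#' @param fit a `seg_fit`.
#' @param path checkpoint path (.json).
#' @export
write_checkpoint <- function(fit, path) {
  obj <- list(format = "axialseg_checkpoint", version = 1L,
              net_config = unclass(fit$net_config),
              train_config = unclass(fit$train_config),
              state = pack_tree(fit$state),
              params = pack_tree(fit$params))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path)
  check_that(identical(obj$format, "axialseg_checkpoint"),
             "axialseg_invalid_argument", "not a checkpoint file")
  ncfg <- obj$net_config
  net_config <- network_config(
    in_channels = ncfg$in_channels, base_channels = ncfg$base_channels,
    global_depth = ncfg$global_depth, local_depth = ncfg$local_depth,
    patch_grid = unlist(ncfg$patch_grid), n_heads = ncfg$n_heads,
    input_size = unlist(ncfg$input_size), decoder_convs = ncfg$decoder_convs,
    table_mode = ncfg$table_mode)
  tcfg <- obj$train_config
  tc <- train_config(learning_rate = tcfg$learning_rate, epochs = tcfg$epochs,
                     batch_size = tcfg$batch_size, optimizer = tcfg$optimizer,
                     seed = tcfg$seed)
  structure(list(params = unpack_tree(obj$params),
                 state = unpack_tree(obj$state),
                 net_config = net_config, train_config = tc,
                 history = NULL, step_loss = NULL, best_epoch = NA),
            class = "seg_fit")
}
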