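#' Build an overlapping patch grid for a slice
#'
#' Regular anchors at multiples of the stride plus final anchors clamped so
#' patches end exactly at the image border; every pixel is covered by at
#' least one patch. The defaults (48-px patches, 12-px offset between
#' neighboring patches) give 75% overlap between row/column neighbors.
#'
#' @param slice_shape `c(rows, cols)` of the slice.
#' @param patch_size square patch edge in pixels.
#' @param stride offset between neighboring patch anchors in pixels.
#' @return An object of class `patch_grid`: anchors per axis (1-based) and
#'   a data.frame `positions` of all top-left corners.
#' @export
build_patch_grid <- function(slice_shape, patch_size = 48L, stride = 12L) {
  slice_shape <- as.integer(slice_shape[1:2])
  patch_size <- as.integer(patch_size); stride <- as.integer(stride)
  if (stride <= 0 || stride > patch_size)
    stop("need 0 < stride <= patch_size")
  if (any(patch_size > slice_shape))
    stop("patch larger than slice")
  ax <- function(n) {
    last <- n - patch_size + 1L
    a <- seq.int(1L, last, by = stride)
    if (a[length(a)] != last) a <- c(a, last)
    a
  }
  rows <- ax(slice_shape[1L]); cols <- ax(slice_shape[2L])
  structure(list(patch_size = patch_size, stride = stride,
                 slice_shape = slice_shape,
                 anchors_row = rows, anchors_col = cols,
                 positions = expand.grid(row = rows, col = cols,
                                         KEEP.OUT.ATTRS = FALSE)),
            class = "patch_grid")
}

#' Percent pixel overlap between neighboring patches
#'
#' `100 * (patch_size - stride) / patch_size`: the fraction of a patch's
#' pixels shared with its row or column neighbor. 48-px patches at 12-px
#' stride overlap by 75%.
#'
#' @param patch_size patch edge in pixels.
#' @param stride anchor offset in pixels.
#' @return Percent overlap.
#' @export
overlap_percent <- function(patch_size, stride) {
  if (stride <= 0 || stride > patch_size)
    stop("need 0 < stride <= patch_size")
  100 * (patch_size - stride) / patch_size
}

#' Distance-from-center cosine weight window
#'
#' Raised-cosine weights `(cos(pi * d / D) + 1) / 2` where `d` is Euclidean
#' distance from the patch center and `D` the corner distance, floored at a
#' small positive value: maximal at the center, minimal (but > 0) at the
#' four corners, symmetric under the patch's 8-fold symmetry group. Used to
#' down-weight patch borders during overlap-tile recombination.
#'
#' @param patch_size patch edge (>= 2).
#' @param floor_weight minimum weight (keeps corner pixels covered).
#' @return `patch_size` x `patch_size` numeric weight matrix.
#' @export
cosine_weight_window <- function(patch_size, floor_weight = 1e-3) {
  if (patch_size < 2) stop("patch_size must be >= 2")
  ctr <- (patch_size + 1) / 2
  g <- seq_len(patch_size) - ctr
  d <- sqrt(outer(g^2, g^2, `+`))
  D <- max(d)
  pmax((cos(pi * d / D) + 1) / 2, floor_weight)
}

# predictor dispatch: a decay_model or any function(patch matrix) -> matrix
.predict_patches <- function(model, patches) {
  if (is.function(model)) {
    d <- dim(patches)
    out <- array(0, d)
    for (n in seq_len(d[4L]))
      out[, , 1L, n] <- model(patches[, , 1L, n])
    out
  } else if (inherits(model, "decay_model")) {
    unet_forward(model$params, patches)
  } else stop("model must be a decay_model or a function")
}

#' Predict per-pixel decay probability for one slice
#'
#' Runs the model on every patch of the grid and recombines the
#' overlapping predictions as a weighted average with the cosine window:
#' `out(p) = sum_k w_k(p) pred_k(p) / sum_k w_k(p)`. The weights form a
#' partition of unity after normalization, so a constant predictor is
#' reproduced exactly.
#'
#' @param model a trained [train_decay_model()] model, or a function
#'   mapping a normalized patch matrix to a same-shape prediction.
#' @param slice normalized 2-D image in \[0, 1\].
#' @param grid a [build_patch_grid()]; default derives one from the model.
#' @param weights weight matrix; default [cosine_weight_window()].
#' @param batch patches per forward pass.
#' @return Matrix of decay probabilities in \[0, 1\].
#' @export
predict_slice <- function(model, slice, grid = NULL, weights = NULL,
                          batch = 256L) {
  ps <- if (inherits(model, "decay_model")) model$config$patch_size else
    if (!is.null(grid)) grid$patch_size else 48L
  stride <- if (inherits(model, "decay_model")) model$config$stride else 12L
  if (is.null(grid)) grid <- build_patch_grid(dim(slice), ps, stride)
  ps <- grid$patch_size
  if (any(dim(slice) < ps)) stop("slice smaller than patch")
  if (is.null(weights)) weights <- cosine_weight_window(ps)
  pos <- grid$positions
  num <- matrix(0, nrow(slice), ncol(slice))
  den <- matrix(0, nrow(slice), ncol(slice))
  for (start in seq(1L, nrow(pos), by = batch)) {
    take <- start:min(nrow(pos), start + batch - 1L)
    xs <- array(0, c(ps, ps, 1L, length(take)))
    for (i in seq_along(take)) {
      r <- pos$row[take[i]]; cl <- pos$col[take[i]]
      xs[, , 1L, i] <- slice[r:(r + ps - 1L), cl:(cl + ps - 1L)]
    }
    pr <- .predict_patches(model, xs)
    for (i in seq_along(take)) {
      r <- pos$row[take[i]]; cl <- pos$col[take[i]]
      rr <- r:(r + ps - 1L); cc <- cl:(cl + ps - 1L)
      num[rr, cc] <- num[rr, cc] + weights * pr[, , 1L, i]
      den[rr, cc] <- den[rr, cc] + weights
    }
  }
  num / den
}

#' Predict a decay probability volume
#'
#' Applies [predict_slice()] to every slice of a normalized volume.
#'
#' @param model trained decay model (or stub function).
#' @param norm a `normalized_volume`.
#' @param ... passed to [predict_slice()].
#' @return 3-D array of probabilities with attribute `model_digest`.
#' @export
predict_volume <- function(model, norm, ...) {
  vals <- if (inherits(norm, "normalized_volume")) norm$values else norm
  d <- dim(vals)
  out <- array(0, d)
  grid <- NULL
  for (z in seq_len(d[3L])) {
    pm <- predict_slice(model, vals[, , z], grid = grid, ...)
    out[, , z] <- pm
  }
  if (inherits(model, "decay_model"))
    attr(out, "model_digest") <- model$digest
  out
}

#' Pixel-annotated slices for training the decay classifier
#'
#' @param images list of normalized 2-D slices in \[0, 1\].
#' @param masks list of binary masks (1 = fungal decay, 0 = background).
#' @param split character vector per slice: `"train"`, `"validation"` or
#'   `"test"` (or CV fold labels).
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(images, masks, split = NULL) {
  if (length(images) == 0L) stop("empty annotation set")
  if (length(images) != length(masks)) stop("images/masks length mismatch")
  for (i in seq_along(images)) {
    if (!all(dim(images[[i]]) == dim(masks[[i]])))
      stop("image and mask shapes differ at slice ", i)
    if (!all(masks[[i]] %in% c(0, 1)))
      stop("masks must be binary")
  }
  if (is.null(split)) split <- rep("train", length(images))
  structure(list(images = images, masks = masks, split = split),
            class = "annotation_set")
}

#' Assign cross-validation folds to an annotation set
#'
#' Folds are assigned per slice, not per patch, so overlapping patches of
#' one slice never straddle folds.
#'
#' @param ann an [annotation_set()].
#' @param k number of folds.
#' @param seed integer seed.
#' @return The annotation set with `split` set to fold labels
#'   `"fold1"..."foldk"`.
#' @export
assign_cv_folds <- function(ann, k = 5L, seed = 1L) {
  stopifnot(inherits(ann, "annotation_set"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- length(ann$images)
  ann$split <- paste0("fold", sample(rep_len(seq_len(k), n)))
  ann
}

#' Training configuration for the decay classifier
#'
#' @param epochs training epochs.
#' @param batch minibatch size (patches).
#' @param lr Adam learning rate.
#' @param patch_size square patch edge (divisible by 4).
#' @param stride prediction-time anchor offset.
#' @param n_patches patches sampled from the training slices.
#' @param base_channels channels of the first encoder level.
#' @param augment random flips/transposes during training.
#' @param seed seed for initialization and sampling.
#' @return A list, class `train_config`.
#' @export
train_config <- function(epochs = 20L, batch = 8L, lr = 1e-3,
                         patch_size = 48L, stride = 12L, n_patches = 200L,
                         base_channels = 8L, augment = TRUE, seed = 1L) {
  structure(as.list(environment()), class = "train_config")
}

#' Train the patch-based decay classifier
#'
#' Trains an encoder-decoder convolutional network with skip connections
#' on patches sampled from the annotated training slices (half biased
#' toward decay regions, half uniform), with binary cross-entropy loss and
#' Adam. Deterministic given the config seed.
#'
#' @param annotations an [annotation_set()]; slices with split `"train"`
#'   (or all slices when no split is marked) are used.
#' @param config a [train_config()].
#' @return An object of class `decay_model`: network parameters, config,
#'   per-epoch loss `history`, and a config `digest`.
#' @export
train_decay_model <- function(annotations, config = train_config()) {
  stopifnot(inherits(annotations, "annotation_set"),
            inherits(config, "train_config"))
  use <- if (any(annotations$split == "train"))
    which(annotations$split == "train") else seq_along(annotations$images)
  if (length(use) == 0L) stop("no training slices")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  ps <- config$patch_size

  xs <- array(0, c(ps, ps, 1L, config$n_patches))
  ys <- array(0, c(ps, ps, 1L, config$n_patches))
  for (i in seq_len(config$n_patches)) {
    s <- use[1L + (i - 1L) %% length(use)]
    img <- annotations$images[[s]]; msk <- annotations$masks[[s]]
    d <- dim(img)
    if (any(d < ps)) stop("annotated slice smaller than patch")
    pos_idx <- which(msk == 1)
    if (i %% 2L == 0L && length(pos_idx) > 0L) {
      pick <- pos_idx[sample.int(length(pos_idx), 1L)]
      pr <- (pick - 1L) %% d[1L] + 1L
      pc <- (pick - 1L) %/% d[1L] + 1L
      r <- min(max(pr - ps %/% 2L, 1L), d[1L] - ps + 1L)
      cl <- min(max(pc - ps %/% 2L, 1L), d[2L] - ps + 1L)
    } else {
      r <- sample.int(d[1L] - ps + 1L, 1L)
      cl <- sample.int(d[2L] - ps + 1L, 1L)
    }
    xs[, , 1L, i] <- img[r:(r + ps - 1L), cl:(cl + ps - 1L)]
    ys[, , 1L, i] <- msk[r:(r + ps - 1L), cl:(cl + ps - 1L)]
  }

  params <- unet_init(ps, config$base_channels, seed = config$seed)
  state <- adam_init(params)
  history <- numeric(config$epochs)
  t <- 0L
  n <- config$n_patches
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1L, n, by = config$batch)) {
      take <- ord[start:min(n, start + config$batch - 1L)]
      xb <- xs[, , , take, drop = FALSE]
      yb <- ys[, , , take, drop = FALSE]
      if (isTRUE(config$augment)) {
        for (j in seq_along(take)) {
          if (runif(1) < 0.5) {
            xb[, , 1L, j] <- xb[ps:1L, , 1L, j]
            yb[, , 1L, j] <- yb[ps:1L, , 1L, j]
          }
          if (runif(1) < 0.5) {
            xb[, , 1L, j] <- xb[, ps:1L, 1L, j]
            yb[, , 1L, j] <- yb[, ps:1L, 1L, j]
          }
          if (runif(1) < 0.5) {
            xb[, , 1L, j] <- t(xb[, , 1L, j])
            yb[, , 1L, j] <- t(yb[, , 1L, j])
          }
        }
      }
      fw <- unet_forward(params, xb, cache = TRUE)
      losses <- c(losses, unet_bce(fw$p, yb))
      dzo <- (fw$p - yb) / length(yb)
      grads <- unet_backward(params, fw$cache, dzo)
      t <- t + 1L
      up <- adam_step(params, grads, state, config$lr, t)
      params <- up$params; state <- up$state
    }
    history[ep] <- mean(losses)
  }

  digest <- paste0("unet-", ps, "x", ps, "-c", config$base_channels,
                   "-e", config$epochs, "-n", config$n_patches,
                   "-seed", config$seed)
  structure(list(params = params, config = config, history = history,
                 digest = digest),
            class = "decay_model")
}

#' @export
print.decay_model <- function(x, ...) {
  cat("decay_model:", x$digest, "\n")
  cat(sprintf("  final training loss %.4f (epoch 1: %.4f)\n",
              tail(x$history, 1), x$history[1]))
  invisible(x)
}

#' Save / load a decay model
#'
#' Single-file JSON checkpoint (weights flattened) plus the config digest.
#'
#' @param model a `decay_model`.
#' @param path file path.
#' @return `path` / the restored model.
#' @export
save_decay_model <- function(model, path) {
  stopifnot(inherits(model, "decay_model"))
  flat <- lapply(model$params, function(l)
    list(w = as.numeric(l$w), wdim = dim(l$w), b = l$b))
  jsonlite::write_json(list(digest = model$digest,
                            config = unclass(model$config),
                            history = model$history, params = flat),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_decay_model
#' @export
load_decay_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(j$params, function(l)
    list(w = array(l$w, dim = l$wdim), b = as.numeric(l$b)))
  cfg <- j$config
  class(cfg) <- "train_config"
  structure(list(params = params, config = cfg, history = j$history,
                 digest = j$digest),
            class = "decay_model")
}

#' F1-maximizing binarization threshold
#'
#' Exhaustive search over a candidate grid for the threshold that
#' maximizes the F1 score of the binarized probabilities against the
#' labels; ties are broken toward the lower (more sensitive) threshold.
#'
#' @param probabilities numeric vector/array of decay probabilities.
#' @param labels binary vector/array of the same length.
#' @param candidates candidate thresholds inside (0, 1).
#' @return An object of class `binarization_threshold`: `threshold` and
#'   the `f1` achieved on the selection set.
#' @export
select_threshold <- function(probabilities, labels,
                             candidates = seq(0.01, 0.99, by = 0.01)) {
  p <- as.numeric(probabilities); y <- as.numeric(labels)
  if (length(p) != length(y)) stop("probabilities and labels misaligned")
  if (sum(y) == 0) stop("no positive labels: threshold undefined")
  f1s <- vapply(candidates, function(th) {
    pred <- p >= th
    tp <- sum(pred & y == 1)
    2 * tp / (2 * tp + sum(pred & y == 0) + sum(!pred & y == 1))
  }, numeric(1))
  best <- which(f1s >= max(f1s) - 1e-12)[1L]   # lowest among ties
  structure(list(threshold = candidates[best], f1 = f1s[best]),
            class = "binarization_threshold")
}

#' Blur predictions along the longitudinal axis
#'
#' 1-D Gaussian smoothing along the slice axis only, evening out
#' slice-to-slice irregularities of the 2-D classifier (fungal decay
#' spreads predominantly longitudinally). `sigma_slices = 0` is the
#' identity; the truncated kernel is renormalized at the volume ends.
#'
#' @param prob_volume 3-D probability array.
#' @param sigma_slices Gaussian sigma in slices.
#' @return Smoothed array of the same shape.
#' @export
smooth_longitudinal <- function(prob_volume, sigma_slices) {
  if (sigma_slices < 0) stop("sigma must be >= 0")
  if (sigma_slices == 0) return(prob_volume)
  d <- dim(prob_volume)
  half <- max(1L, ceiling(3 * sigma_slices))
  off <- -half:half
  w <- exp(-off^2 / (2 * sigma_slices^2))
  num <- array(0, d); den <- array(0, d)
  for (i in seq_along(off)) {
    src <- seq_len(d[3L]) + off[i]
    ok <- src >= 1L & src <= d[3L]
    num[, , ok] <- num[, , ok] + w[i] * prob_volume[, , src[ok]]
    den[, , ok] <- den[, , ok] + w[i]
  }
  num / den
}

#' Relative decay volume
#'
#' Binarizes the probability volume at the selected threshold, removes
#' crack voxels (cracks are not counted toward the area affected by
#' fungal decay), and reports decayed wood as percent of the wood volume.
#'
#' @param prob_volume 3-D probability array.
#' @param threshold scalar threshold or a [select_threshold()] result.
#' @param wood_mask logical mask of wood voxels (the denominator).
#' @param crack_mask optional logical mask excluded from the numerator.
#' @return Relative decay volume in percent.
#' @export
quantify_decay <- function(prob_volume, threshold, wood_mask,
                           crack_mask = NULL) {
  if (inherits(threshold, "binarization_threshold"))
    threshold <- threshold$threshold
  nw <- sum(wood_mask)
  if (nw == 0) stop("empty wood mask: relative decay undefined")
  dec <- (prob_volume >= threshold) & wood_mask
  if (!is.null(crack_mask)) dec <- dec & !crack_mask
  100 * sum(dec) / nw
}

#' Synthetic annotated decay slices
#'
#' Generates small decay-bearing log phantoms and returns their
#' cross-sections as an [annotation_set()]: images are the normalized HU
#' slices, masks the per-voxel decay ground truth. Used for the seeded
#' training harness.
#'
#' @param n_logs phantoms to generate.
#' @param slices_per_log slices sampled per phantom.
#' @param seed integer seed.
#' @param split fractions `c(train, validation)`; remainder is test.
#' @param ... overrides for [log_phantom_spec()].
#' @return An `annotation_set`.
#' @export
synthetic_decay_annotations <- function(n_logs = 4L, slices_per_log = 10L,
                                        seed = 1L, split = c(0.6, 0.2),
                                        ...) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  images <- list(); masks <- list()
  codes <- label_codes()
  for (g in seq_len(n_logs)) {
    spec <- log_phantom_spec(length_slices = slices_per_log + 2L,
                             radius_mm = 35, bark_thickness_mm = 4,
                             pixel_spacing_mm = 1, slice_thickness_mm = 2,
                             margin_mm = 12,
                             tunnel_count = 0, decay_patch_count = 4L,
                             decay_radius_mm = c(6, 14), ...)
    ph <- generate_phantom(spec, seed = seed + g)
    norm <- normalize_volume(ph$volume)
    zs <- seq_len(slices_per_log) + 1L
    for (z in zs) {
      images[[length(images) + 1L]] <- norm$values[, , z]
      masks[[length(masks) + 1L]] <-
        (ph$labels$classes[, , z] == codes[["decay"]]) * 1
    }
  }
  n <- length(images)
  ord <- sample.int(n)
  n_tr <- round(split[1L] * n); n_va <- round(split[2L] * n)
  sp <- rep("test", n)
  sp[ord[seq_len(n_tr)]] <- "train"
  sp[ord[n_tr + seq_len(n_va)]] <- "validation"
  annotation_set(images, masks, sp)
}
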