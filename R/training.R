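#' Shuffled train / validation / test split
#'
#' Indices are shuffled under the seed, the last 20% (rounded) become the
#' test set, and 20% of the remainder becomes the validation set — the
#' standard nested 80:20 / 80:20 protocol. For n = 100 the sizes are
#' 64 / 16 / 20.
#'
#' @param n_items number of records (>= 5).
#' @param seed integer shuffle seed.
#' @return `list(train, validation, test, seed)` of class `dataset_split`;
#'   the three index vectors are disjoint and exhaustive.
#' @export
split_dataset <- function(n_items, seed = 1L) {
  if (n_items < 5) stop_size("split_dataset: need at least 5 items")
  perm <- with_seed(seed, sample.int(n_items))
  n_test <- round(0.2 * n_items)
  test <- perm[seq_len(n_test)]
  rest <- perm[-seq_len(n_test)]
  n_val <- round(0.2 * length(rest))
  validation <- rest[seq_len(n_val)]
  train <- rest[-seq_len(n_val)]
  structure(list(train = train, validation = validation, test = test,
                 seed = seed), class = "dataset_split")
}

flip_h <- function(x) {
  # mirror across the vertical axis (left-right)
  d <- dim(x)
  if (length(d) == 2) x[, rev(seq_len(d[2])), drop = FALSE]
  else x[, rev(seq_len(d[2])), , drop = FALSE]
}

flip_v <- function(x) {
  d <- dim(x)
  if (length(d) == 2) x[rev(seq_len(d[1])), , drop = FALSE]
  else x[rev(seq_len(d[1])), , , drop = FALSE]
}

#' Flip augmentation
#'
#' Triples a training set: the originals followed by horizontally mirrored
#' then vertically mirrored copies, with masks transformed identically.
#'
#' @param pairs list of `list(image =, mask =)` (mask may be `NULL` for
#'   detection data).
#' @return list of length `3 * length(pairs)`, originals first.
#' @export
augment_flips <- function(pairs) {
  for (p in pairs)
    if (!is.null(p$mask) &&
        !identical(dim(p$image)[1:2], dim(p$mask)[1:2]))
      stop_shape("augment_flips: mask misaligned to image")
  fl <- function(f) lapply(pairs, function(p)
    list(image = f(p$image), mask = if (is.null(p$mask)) NULL else f(p$mask)))
  c(pairs, fl(flip_h), fl(flip_v))
}

clip_range <- function(x, hi) pmin(pmax(x, 0), hi)

# Centered zoom resampling: out(i) = in(c + (i - c)/z); bilinear for images,
# nearest for masks; samples falling outside the frame are 0.
zoom_resample <- function(x, z, method = "bilinear") {
  d <- dim(x)
  H <- d[1]; W <- d[2]
  ci <- (H - 1) / 2; cj <- (W - 1) / 2
  si <- ci + ((seq_len(H) - 1) - ci) / z
  sj <- cj + ((seq_len(W) - 1) - cj) / z
  sample_plane <- function(m) {
    out <- matrix(0, H, W)
    if (method == "nearest") {
      ii <- round(si); jj <- round(sj)
      ok_i <- ii >= 0 & ii <= H - 1; ok_j <- jj >= 0 & jj <= W - 1
      out[ok_i, ok_j] <- m[ii[ok_i] + 1, jj[ok_j] + 1]
    } else {
      i0 <- floor(si); j0 <- floor(sj)
      fi <- si - i0; fj <- sj - j0
      gi <- function(iv) { iv <- pmin(pmax(iv, 0), H - 1); iv + 1 }
      gj <- function(jv) { jv <- pmin(pmax(jv, 0), W - 1); jv + 1 }
      m00 <- m[gi(i0), gj(j0), drop = FALSE]
      m10 <- m[gi(i0 + 1), gj(j0), drop = FALSE]
      m01 <- m[gi(i0), gj(j0 + 1), drop = FALSE]
      m11 <- m[gi(i0 + 1), gj(j0 + 1), drop = FALSE]
      wfi <- matrix(fi, H, W); wfj <- matrix(fj, H, W, byrow = TRUE)
      out <- (1 - wfi) * ((1 - wfj) * m00 + wfj * m01) +
        wfi * ((1 - wfj) * m10 + wfj * m11)
      ok_i <- si >= 0 & si <= H - 1; ok_j <- sj >= 0 & sj <= W - 1
      out[!ok_i, ] <- 0; out[, !ok_j] <- 0
    }
    out
  }
  if (length(d) == 2) sample_plane(x)
  else {
    for (c3 in seq_len(d[3])) x[, , c3] <- sample_plane(x[, , c3])
    x
  }
}

perturb_pair <- function(image, mask, bright, zoom) {
  hi <- if (max(image) <= 1) 1 else 255
  img <- clip_range(image * bright, hi)
  if (zoom != 1) {
    img <- zoom_resample(img, zoom, "bilinear")
    if (!is.null(mask)) mask <- (zoom_resample(mask, zoom, "nearest") > 0.5) * 1
  }
  list(image = img, mask = mask)
}

#' Random brightness / zoom augmentation stream
#'
#' Deterministic generator over image(+mask) pairs: each draw picks the
#' next pair cyclically, scales its brightness by a factor uniform in
#' `[0.8, 1.2]` (image only, clipped to the valid range) and zooms by a
#' factor uniform in `[0.9, 1.1]` about the image center (bilinear for the
#' image, nearest for the mask, recropped to the original size). Masks stay
#' strictly binary. Two generators with the same seed produce identical
#' streams.
#'
#' @inheritParams augment_flips
#' @param seed integer stream seed.
#' @return a function; each call returns one perturbed
#'   `list(image, mask, brightness, zoom)`.
#' @export
random_augment <- function(pairs, seed = 1L) {
  for (p in pairs)
    if (!is.null(p$mask) &&
        !identical(dim(p$image)[1:2], dim(p$mask)[1:2]))
      stop_shape("random_augment: mask misaligned to image")
  rng <- with_seed(seed, .GlobalEnv$.Random.seed)
  i <- 0L
  function() {
    i <<- i + 1L
    p <- pairs[[(i - 1L) %% length(pairs) + 1L]]
    old <- .GlobalEnv$.Random.seed
    assign(".Random.seed", rng, envir = globalenv())
    bright <- stats::runif(1, 0.8, 1.2)
    zoom <- stats::runif(1, 0.9, 1.1)
    rng <<- .GlobalEnv$.Random.seed
    assign(".Random.seed", old, envir = globalenv())
    out <- perturb_pair(p$image, p$mask, bright, zoom)
    out$brightness <- bright
    out$zoom <- zoom
    out
  }
}

#' Training configuration
#'
#' Bundles the per-task hyperparameters. Defaults per task: image detection
#' 50 epochs, RMSprop, learning rate 1e-4, binary cross-entropy; feature
#' detection 100 epochs, Adam, cross-entropy; 2-D segmentation 60 epochs,
#' batch 8, Adam, learning rate 1e-3, hybrid Dice + cross-entropy loss;
#' multimodal segmentation 50 epochs, batch 8, Adam, learning rate 1e-4,
#' Dice loss.
#'
#' @param task one of `"detect_image"`, `"detect_features"`, `"seg2d_unet"`,
#'   `"seg2d_unetpp"`, `"seg3d_unet"`, `"seg3d_unetpp"`.
#' @param epochs,batch_size,optimizer,learning_rate,loss overrides of the
#'   task defaults.
#' @param seed run seed (splits, initialization, dropout, augmentation).
#' @param width_multiplier architecture width scale (1.0 = the audited
#'   published architecture).
#' @return list of class `train_config`.
#' @export
train_config <- function(task, epochs = NULL, batch_size = NULL,
                         optimizer = NULL, learning_rate = NULL, loss = NULL,
                         seed = 1L, width_multiplier = 1.0) {
  task <- match.arg(task, c("detect_image", "detect_features", "seg2d_unet",
                            "seg2d_unetpp", "seg3d_unet", "seg3d_unetpp"))
  def <- switch(task,
    detect_image = list(epochs = 50L, batch_size = 8L, optimizer = "rmsprop",
                        learning_rate = 1e-4, loss = "bce"),
    detect_features = list(epochs = 100L, batch_size = 8L, optimizer = "adam",
                           learning_rate = 1e-3, loss = "bce"),
    seg2d_unet = ,
    seg2d_unetpp = list(epochs = 60L, batch_size = 8L, optimizer = "adam",
                        learning_rate = 1e-3, loss = "hybrid"),
    seg3d_unet = ,
    seg3d_unetpp = list(epochs = 50L, batch_size = 8L, optimizer = "adam",
                        learning_rate = 1e-4, loss = "dice"))
  structure(list(task = task,
                 epochs = epochs %||% def$epochs,
                 batch_size = batch_size %||% def$batch_size,
                 optimizer = optimizer %||% def$optimizer,
                 learning_rate = learning_rate %||% def$learning_rate,
                 loss = loss %||% def$loss,
                 seed = as.integer(seed),
                 width_multiplier = width_multiplier),
            class = "train_config")
}

# Stack a list of (H,W,C) arrays (or matrices) into (H,W,C,N).
stack4 <- function(lst) {
  a1 <- lst[[1]]
  d <- dim(a1)
  if (length(d) == 2) d <- c(d, 1L)
  out <- array(0, c(d, length(lst)))
  for (i in seq_along(lst)) out[, , , i] <- lst[[i]]
  out
}

# batch augmenter used inside the fit loop: independent brightness/zoom
# draws per sample, consuming the governing RNG stream
batch_augment_fn <- function() {
  function(xb, yb) {
    n <- dim(xb)[4]
    for (i in seq_len(n)) {
      bright <- stats::runif(1, 0.8, 1.2)
      zoom <- stats::runif(1, 0.9, 1.1)
      seg <- length(dim(yb)) == 4
      pr <- perturb_pair(xb[, , , i],
                         if (seg) yb[, , , i] else NULL, bright, zoom)
      xb[, , , i] <- pr$image
      if (seg) yb[, , , i] <- pr$mask
    }
    list(x = xb, y = yb)
  }
}

#' Train a tumor detection model
#'
#' Splits the records 80:20:20 under the config seed, builds the matching
#' CNN (image or feature input, width multiplier applied) and trains with
#' binary cross-entropy. Image mode applies flip augmentation to the
#' training split (the detection pipeline names no other augmentation
#' operations); feature mode trains on the raw vectors.
#'
#' @param records image mode: list of `list(image = gray_image, label, name)`
#'   (e.g. from [read_image()] + [label_from_name()]); feature mode: a
#'   feature table data frame from [write_feature_table()] /
#'   [read_feature_table()].
#' @param config a [train_config()].
#' @param input_mode `"image"` or `"features"`.
#' @param feature_block for feature mode, which block to train on (see
#'   [feature_block_names()]).
#' @return `list(model, history, split, test)` where `test` is the
#'   [evaluate_detection()] report on the held-out split.
#' @export
train_detection <- function(records, config, input_mode = c("image", "features"),
                            feature_block = "all") {
  input_mode <- match.arg(input_mode)
  if (input_mode == "image") {
    labels <- vapply(records, function(r) as.integer(r$label), 0L)
    xs <- lapply(records, function(r) prep_detection(r$image))
    nms <- vapply(records, function(r) r$name %||% "record", "")
  } else {
    cols <- feature_block_names(feature_block)
    if (!all(cols %in% colnames(records)))
      stop_format("train_detection: feature table lacks requested block columns")
    labels <- as.integer(records$label)
    xs <- lapply(seq_len(nrow(records)), function(i)
      array(as.numeric(records[i, cols]), c(length(cols), 1, 1)))
    nms <- as.character(records$name)
  }
  n <- length(xs)
  sp <- split_dataset(n, config$seed)
  if (length(unique(labels[sp$train])) < 2)
    stop_degenerate("train_detection: training split holds a single class")

  if (input_mode == "image") {
    tr_pairs <- lapply(sp$train, function(i) list(image = xs[[i]], mask = NULL))
    tr_pairs <- augment_flips(tr_pairs)
    xtr <- stack4(lapply(tr_pairs, `[[`, "image"))
    ytr <- matrix(rep(labels[sp$train], 3), nrow = 1)
    graph <- build_detection_cnn(config$width_multiplier)
  } else {
    xtr <- stack4(xs[sp$train])
    ytr <- matrix(labels[sp$train], nrow = 1)
    graph <- build_feature_cnn(dim(xs[[1]])[1], config$width_multiplier)
  }
  xval <- stack4(xs[sp$validation])
  yval <- matrix(labels[sp$validation], nrow = 1)
  model <- nn_compile(graph, seed = config$seed)
  fit <- nn_fit(model, xtr, ytr, epochs = config$epochs,
                batch_size = config$batch_size, optimizer = config$optimizer,
                lr = config$learning_rate, loss = config$loss,
                seed = config$seed, validation = list(x = xval, y = yval),
                metric = "accuracy")
  xte <- stack4(xs[sp$test])
  test <- evaluate_detection(fit$model, xte, labels[sp$test], nms[sp$test])
  list(model = fit$model, history = fit$history, split = sp, test = test)
}

#' Train a tumor segmentation model
#'
#' Splits the samples 80:20:20, applies flip augmentation to the training
#' split (plus on-the-fly brightness/zoom perturbation for the 2-D tasks),
#' builds the architecture selected by `config$task` and trains with the
#' configured loss (hybrid for 2-D, Dice for multimodal). The held-out
#' test split is scored with the mean Dice over thresholded predictions.
#'
#' @param samples `list(x =, y =)`: input array (128, 128, C, N) and binary
#'   mask array (128, 128, 1, N), e.g. from [prep_seg2d_training()] or
#'   [prep_seg3d_training()].
#' @param config a [train_config()] with a `seg*` task.
#' @return `list(model, history, split, test)` where `test` is the
#'   [evaluate_segmentation()] report on the held-out split.
#' @export
train_segmentation <- function(samples, config) {
  x <- samples$x; y <- samples$y
  n <- dim(x)[4]
  if (sum(y) == 0)
    stop_degenerate("train_segmentation: every mask is empty")
  sp <- split_dataset(n, config$seed)
  builder <- switch(config$task,
                    seg2d_unet = build_unet2d,
                    seg2d_unetpp = build_unetpp2d,
                    seg3d_unet = build_unet_multimodal,
                    seg3d_unetpp = build_unetpp_multimodal,
                    stop_usage("train_segmentation: config task is not a segmentation task"))
  is2d <- config$task %in% c("seg2d_unet", "seg2d_unetpp")
  pairs <- lapply(sp$train, function(i)
    list(image = x[, , , i, drop = TRUE], mask = y[, , , i, drop = TRUE]))
  pairs <- lapply(pairs, function(p) {
    if (length(dim(p$image) %||% 1) < 3)
      p$image <- array(p$image, c(dim(x)[1:2], dim(x)[3]))
    p$mask <- matrix(p$mask, dim(y)[1], dim(y)[2])
    p
  })
  pairs <- augment_flips(pairs)
  xtr <- stack4(lapply(pairs, `[[`, "image"))
  ytr <- stack4(lapply(pairs, `[[`, "mask"))
  model <- nn_compile(builder(config$width_multiplier), seed = config$seed)
  fit <- nn_fit(model, xtr, ytr, epochs = config$epochs,
                batch_size = config$batch_size, optimizer = config$optimizer,
                lr = config$learning_rate, loss = config$loss,
                seed = config$seed,
                validation = list(x = x[, , , sp$validation, drop = FALSE],
                                  y = y[, , , sp$validation, drop = FALSE]),
                metric = "dice",
                augment = if (is2d) batch_augment_fn() else NULL)
  test <- evaluate_segmentation(fit$model, x[, , , sp$test, drop = FALSE],
                                y[, , , sp$test, drop = FALSE],
                                config$batch_size)
  list(model = fit$model, history = fit$history, split = sp, test = test)
}
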