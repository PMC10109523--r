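#' Resize a 2-D image or multi-channel raster
#'
#' Bilinear interpolation (pixel-center sampling) for intensity images,
#' nearest-neighbour for masks and anything whose value set must be
#' preserved.
#'
#' @param x numeric matrix or (H, W, C) array.
#' @param height,width output size.
#' @param method `"bilinear"` or `"nearest"`.
#' @return resized matrix/array.
#' @export
resize_image <- function(x, height, width, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (is.null(dim(x))) stop_shape("resize_image: input must have dim")
  was_matrix <- is.matrix(x)
  if (!was_matrix && length(dim(x)) != 3)
    stop_shape("resize_image: 2-D or 3-D input expected")
  if (height < 1 || width < 1) stop_shape("resize_image: degenerate target")
  y <- if (method == "bilinear")
    cpp_resize_bilinear(x, as.integer(height), as.integer(width))
  else cpp_resize_nearest(x, as.integer(height), as.integer(width))
  if (was_matrix) y <- matrix(y, nrow = height, ncol = width)
  y
}

to_byte <- function(img) {
  switch(img$value_range,
         byte = img$pixels,
         unit = img$pixels * 255,
         { rng <- range(img$pixels)
           if (rng[2] > rng[1]) (img$pixels - rng[1]) / (rng[2] - rng[1]) * 255
           else img$pixels * 0 })
}

#' Prepare an image for the detection CNN
#'
#' Resizes to 256x256 (bilinear), normalizes to the byte scale and
#' replicates the grayscale channel three times, producing the (256, 256, 3)
#' input the detection network expects.
#'
#' @param image a [gray_image()].
#' @return numeric array of shape (256, 256, 3), values in `[0, 255]`.
#' @export
prep_detection <- function(image) {
  if (!inherits(image, "gray_image")) stop_shape("prep_detection: gray_image expected")
  g <- resize_image(image$pixels, 256, 256, "bilinear")
  g <- to_byte(gray_image(g, image$value_range, image$source))
  array(rep(g, 3), dim = c(256, 256, 3))
}

#' Prepare an image for 2-D segmentation
#'
#' The stage order is fixed: grayscale, resize to 512x512, scale pixels to
#' `[0, 1]`, append a channel axis, then downsample to 128x128 (bilinear).
#' The intermediate 512x512 step is applied literally as specified for this
#' pipeline even though it is immediately downsampled.
#'
#' @param image a [gray_image()].
#' @return numeric array of shape (128, 128, 1), values in `[0, 1]`.
#' @export
prep_seg2d <- function(image) {
  if (!inherits(image, "gray_image")) stop_shape("prep_seg2d: gray_image expected")
  g <- resize_image(image$pixels, 512, 512, "bilinear")
  g <- to_byte(gray_image(g, image$value_range, image$source)) / 255
  g <- array(g, dim = c(512, 512, 1))
  resize_image(g, 128, 128, "bilinear")
}

#' Prepare an image + tumor mask pair for 2-D segmentation training
#'
#' The image follows [prep_seg2d()]; the mask is resized with
#' nearest-neighbour interpolation (512 then 128) and re-thresholded so it
#' stays strictly binary.
#'
#' @param image a [gray_image()].
#' @param mask binary matrix aligned to the image.
#' @return `list(x, y)`: both (128, 128, 1); `y` is binary.
#' @export
prep_seg2d_training <- function(image, mask) {
  if (!identical(dim(image$pixels), dim(mask)))
    stop_shape("prep_seg2d_training: mask shape differs from image")
  x <- prep_seg2d(image)
  m <- resize_image((mask != 0) * 1, 512, 512, "nearest")
  m <- resize_image(array(m, c(512, 512, 1)), 128, 128, "nearest")
  list(x = x, y = (m > 0.5) * 1)
}

slice_window <- function() 60:129  # 0-based axial indices retained

#' Prepare a multimodal volume for 3-D segmentation
#'
#' Per modality, voxels are standardized with that volume's global mean and
#' standard deviation (a constant modality maps to zeros). The 70 middle
#' axial slices — 0-based indices 60..129 — are retained, resized to
#' 128x128 (bilinear) and stacked channel-wise in the fixed order
#' T1, T2, T1ce, FLAIR.
#'
#' @param volume a [multimodal_volume()] with depth >= 131.
#' @return array of shape (128, 128, 4, 70) with attribute `slice_index`
#'   (the 0-based source slice of each sample).
#' @export
prep_seg3d <- function(volume) {
  if (!inherits(volume, "multimodal_volume"))
    stop_arity("prep_seg3d: multimodal_volume expected")
  mods <- list(volume$t1, volume$t2, volume$t1ce, volume$flair)
  if (any(vapply(mods, is.null, TRUE)))
    stop_arity("prep_seg3d: all four modalities required")
  d <- dim(mods[[1]])
  if (d[3] < 131)
    stop_shape(sprintf("prep_seg3d: depth %d < 131; middle-slice window needs full coverage", d[3]))
  win <- slice_window()
  out <- array(0, c(128, 128, 4, length(win)))
  for (m in seq_along(mods)) {
    v <- mods[[m]]
    mu <- mean(v); sdv <- stats::sd(as.numeric(v))
    z <- if (sdv > 0) (v - mu) / sdv else v * 0
    for (k in seq_along(win)) {
      out[, , m, k] <- resize_image(z[, , win[k] + 1], 128, 128, "bilinear")
    }
  }
  attr(out, "slice_index") <- win
  out
}

#' Prepare a multimodal volume with mask for 3-D segmentation training
#'
#' The label volume is binarized first (any nonzero tumor label becomes 1),
#' then windowed over the same 70 middle slices and resized with
#' nearest-neighbour interpolation.
#'
#' @param volume a [multimodal_volume()] carrying a mask.
#' @return `list(x, y)`: `x` as in [prep_seg3d()] (128, 128, 4, 70); `y` is
#'   a binary (128, 128, 1, 70) array.
#' @export
prep_seg3d_training <- function(volume) {
  if (is.null(volume$mask)) stop_arity("prep_seg3d_training: mask volume required")
  x <- prep_seg3d(volume)
  win <- slice_window()
  bin <- (volume$mask != 0) * 1
  y <- array(0, c(128, 128, 1, length(win)))
  for (k in seq_along(win)) {
    m <- resize_image(bin[, , win[k] + 1], 128, 128, "nearest")
    y[, , 1, k] <- (m > 0.5) * 1
  }
  attr(y, "slice_index") <- win
  list(x = x, y = y)
}
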