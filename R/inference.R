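#' Classify one preprocessed input with a trained detection model
#'
#' Runs the network and applies the strict decision rule: tumor (label 1)
#' when the sigmoid output exceeds 0.5, non-tumor otherwise (an output of
#' exactly 0.5 is non-tumor).
#'
#' @param model trained `nn_model` (image- or feature-input).
#' @param input a (256, 256, 3) detection array, a `feature_vector`, or a
#'   bare numeric feature vector matching the model input length.
#' @return `list(label, probability)` of class `detection_result`.
#' @export
detect <- function(model, input) {
  in_shape <- model$shapes[["in"]]
  if (inherits(input, "feature_vector")) input <- input$values
  x <- if (length(in_shape) == 3) {
    if (!identical(dim(input), as.integer(in_shape)))
      stop_shape(sprintf("detect: expected input (%s)",
                         paste(in_shape, collapse = ", ")))
    array(input, c(dim(input), 1))
  } else {
    if (length(input) != in_shape[1])
      stop_shape(sprintf("detect: expected %d features, got %d",
                         in_shape[1], length(input)))
    array(as.numeric(input), c(in_shape[1], 1, 1))
  }
  p <- as.numeric(nn_predict(model, x))
  structure(list(label = as.integer(p > 0.5), probability = p),
            class = "detection_result")
}

#' Classification accuracy
#'
#' Fraction of predictions equal to the truth.
#'
#' @param true_labels,predicted_labels equal-length label vectors.
#' @return proportion in `[0, 1]`.
#' @export
accuracy <- function(true_labels, predicted_labels) {
  if (length(true_labels) == 0 ||
      length(true_labels) != length(predicted_labels))
    stop_size("accuracy: label vectors must be non-empty and equal length")
  mean(true_labels == predicted_labels)
}

#' Dice similarity between two binary masks
#'
#' `2 |P intersect Q| / (|P| + |Q|)` for predicted mask P and reference Q.
#' When both masks are empty the score is defined as 1 (no lesion and none
#' predicted is perfect agreement).
#'
#' @param P,Q binary masks (logical or 0/1 numeric) of identical shape.
#' @return overlap score in `[0, 1]`.
#' @export
dice_score <- function(P, Q) {
  if (!identical(dim(P) %||% length(P), dim(Q) %||% length(Q)))
    stop_shape("dice_score: mask shapes differ")
  p <- P > 0.5; q <- Q > 0.5
  s <- sum(p) + sum(q)
  if (s == 0) return(1)
  2 * sum(p & q) / s
}

#' Post-process a segmentation probability map
#'
#' Thresholds the map at 0.5 into a binary tumor mask and derives the
#' review scores: tumor area (positive pixel count), tumor ratio (tumor
#' area over brain area, where brain pixels are those brighter than 5% of
#' the image maximum) and confidence (mean predicted probability over
#' mask-positive pixels; 0 for an empty mask).
#'
#' @param prob_map probability raster in `[0, 1]`.
#' @param brain_image the underlying image (matrix or [gray_image()]),
#'   aligned to `prob_map`, used for the brain-area estimate.
#' @return `list(prob_map, mask, tumor_area, tumor_ratio, confidence)` of
#'   class `segmentation_result`.
#' @export
postprocess_segmentation <- function(prob_map, brain_image) {
  px <- if (inherits(brain_image, "gray_image")) brain_image$pixels
        else brain_image
  pm <- prob_map
  if (length(dim(pm)) == 3 && dim(pm)[3] == 1) pm <- pm[, , 1]
  if (length(dim(px)) == 3 && dim(px)[3] == 1) px <- px[, , 1]
  if (!identical(dim(pm), dim(px)))
    stop_shape("postprocess_segmentation: probability map misaligned to image")
  mask <- pm > 0.5
  area <- sum(mask)
  brain <- sum(px > 0.05 * max(px))
  structure(list(
    prob_map = pm,
    mask = mask * 1,
    tumor_area = as.integer(area),
    tumor_ratio = if (brain > 0) area / brain else 0,
    confidence = if (area > 0) mean(pm[mask]) else 0
  ), class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> area %d px | ratio %.4f | confidence %.3f\n",
              x$tumor_area, x$tumor_ratio, x$confidence))
  invisible(x)
}

#' Evaluate a detection model on a labelled test set
#'
#' @param model trained `nn_model`.
#' @param x test inputs: (256, 256, 3, N) array for image mode or
#'   (n_features, 1, N) array for feature mode.
#' @param labels 0/1 truth vector of length N.
#' @param names optional record names.
#' @return `list(accuracy, results)`; `results` is a per-record data frame
#'   (`name`, `truth`, `prediction`, `probability`).
#' @export
evaluate_detection <- function(model, x, labels, names = NULL) {
  d <- dim(x)
  n <- d[length(d)]
  if (n == 0 || length(labels) != n)
    stop_size("evaluate_detection: empty test set or label length mismatch")
  p <- as.numeric(nn_predict(model, x))
  pred <- as.integer(p > 0.5)
  list(accuracy = accuracy(labels, pred),
       results = data.frame(
         name = names %||% sprintf("record_%d", seq_len(n)),
         truth = labels, prediction = pred, probability = p))
}

#' Evaluate a segmentation model on a labelled test set
#'
#' Predicts every sample, thresholds at 0.5 and reports the mean and
#' per-sample Dice scores plus the mean absolute tumor-ratio error versus
#' the ground-truth masks.
#'
#' @param model trained `nn_model`.
#' @param x input array (128, 128, C, N).
#' @param masks binary mask array (128, 128, 1, N).
#' @param batch_size prediction chunk size.
#' @return `list(mean_dice, dice, mean_ratio_error, results)`.
#' @export
evaluate_segmentation <- function(model, x, masks, batch_size = 8L) {
  n <- dim(x)[4]
  if (is.na(n) || n == 0) stop_size("evaluate_segmentation: empty test set")
  if (!identical(dim(masks)[c(1, 2, 4)], dim(x)[c(1, 2, 4)]))
    stop_shape("evaluate_segmentation: masks misaligned")
  p <- nn_predict(model, x, batch_size)
  dices <- numeric(n); rerr <- numeric(n)
  for (i in seq_len(n)) {
    pi <- p[, , 1, i]; mi <- masks[, , 1, i]
    dices[i] <- dice_score(pi > 0.5, mi > 0.5)
    rerr[i] <- abs(mean(pi > 0.5) - mean(mi > 0.5))
  }
  list(mean_dice = mean(dices), dice = dices, mean_ratio_error = mean(rerr),
       results = data.frame(sample = seq_len(n), dice = dices,
                            ratio_error = rerr))
}
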