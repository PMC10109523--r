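#' @title Hand-crafted image features
#' @description Texture and intensity descriptors used by the feature-input
#'   detection model: four intensity moments, six co-occurrence (GLCM)
#'   statistics, eight single-level Haar wavelet sub-band statistics, the
#'   gray-level histogram entropy, a 10-bin uniform local-binary-pattern
#'   histogram and the thirteen classic Haralick statistics — 42 values in a
#'   fixed order. Parameters are fixed to the common texture-analysis
#'   defaults: GLCM at distance 1, angle 0, 256 gray levels, symmetric and
#'   normalized; LBP with 8 neighbours at radius 1; Haralick averaged over
#'   the four principal directions; entropy in bits.
#' @name brainseg-features
NULL

img_pixels <- function(image) {
  if (inherits(image, "gray_image")) image$pixels else as.matrix(image)
}

quantize256 <- function(px) {
  # map to integer gray levels 0..255: integer byte data passes through,
  # fractional unit-range data is scaled, anything else min-max stretched
  rng <- range(px)
  if (rng[1] >= 0 && rng[2] <= 255 && all(px == round(px))) {
    q <- px
  } else if (rng[1] >= 0 && rng[2] <= 1) {
    q <- round(px * 255)
  } else {
    q <- if (rng[2] > rng[1]) round((px - rng[1]) / (rng[2] - rng[1]) * 255)
         else px * 0
  }
  pmin(pmax(q, 0), 255)
}

#' Intensity moment features
#'
#' Mean, population variance, skewness (third standardized moment) and
#' excess kurtosis (fourth standardized moment minus 3, so a normal
#' distribution scores 0). A constant image has zero variance; its skewness
#' and kurtosis are defined as 0.
#'
#' @param image a [gray_image()] or numeric matrix.
#' @return named numeric vector `int_mean`, `int_var`, `int_skew`,
#'   `int_kurt`.
#' @export
intensity_features <- function(image) {
  px <- img_pixels(image)
  if (length(px) == 0) stop_shape("intensity_features: empty image")
  n <- length(px)
  mu <- mean(px)
  v <- sum((px - mu)^2) / n
  if (v > 0) {
    s <- (sum((px - mu)^3) / n) / v^1.5
    k <- (sum((px - mu)^4) / n) / v^2 - 3
  } else {
    s <- 0; k <- 0
  }
  c(int_mean = mu, int_var = v, int_skew = s, int_kurt = k)
}

# Symmetric, normalized gray-level co-occurrence matrix at a given offset.
glcm_matrix <- function(q, dr, dc, levels = 256) {
  H <- nrow(q); W <- ncol(q)
  r0 <- max(1, 1 - dr):min(H, H - dr)
  c0 <- max(1, 1 - dc):min(W, W - dc)
  a <- q[r0, c0, drop = FALSE]
  b <- q[r0 + dr, c0 + dc, drop = FALSE]
  counts <- numeric(levels * levels)
  idx <- a * levels + b + 1
  t1 <- tabulate(idx, nbins = levels * levels)
  idx2 <- b * levels + a + 1
  t2 <- tabulate(idx2, nbins = levels * levels)
  m <- matrix(t1 + t2, levels, levels, byrow = TRUE)
  m / sum(m)
}

#' Gray-level co-occurrence features
#'
#' Co-occurrence matrix at distance 1, angle 0 (horizontal neighbours),
#' symmetric and normalized over 256 gray levels; returns contrast,
#' dissimilarity, homogeneity, angular second moment, energy (sqrt of ASM)
#' and correlation. The correlation of a constant image (zero marginal
#' variance) is defined as 1.
#'
#' @param image a [gray_image()] or numeric matrix with >= 2 columns.
#' @return named numeric vector of the six statistics.
#' @export
glcm_features <- function(image) {
  px <- img_pixels(image)
  if (ncol(px) < 2) stop_shape("glcm_features: need at least 2 columns")
  q <- quantize256(px)
  P <- glcm_matrix(q, 0, 1)
  i <- row(P) - 1; j <- col(P) - 1
  contrast <- sum(P * (i - j)^2)
  dissim <- sum(P * abs(i - j))
  homog <- sum(P / (1 + (i - j)^2))
  asm <- sum(P^2)
  mi <- sum(i * P); mj <- sum(j * P)
  si <- sqrt(sum((i - mi)^2 * P)); sj <- sqrt(sum((j - mj)^2 * P))
  corr <- if (si > 0 && sj > 0) sum((i - mi) * (j - mj) * P) / (si * sj) else 1
  c(glcm_contrast = contrast, glcm_dissimilarity = dissim,
    glcm_homogeneity = homog, glcm_asm = asm, glcm_energy = sqrt(asm),
    glcm_correlation = corr)
}

# Single-level orthonormal 2-D Haar transform; odd dimensions are padded by
# edge replication. Returns the four sub-bands. LH responds to variation
# along columns (vertical edges), HL to variation along rows.
haar2 <- function(px) {
  H <- nrow(px); W <- ncol(px)
  if (H %% 2 == 1) px <- rbind(px, px[H, , drop = FALSE])
  if (W %% 2 == 1) px <- cbind(px, px[, W, drop = FALSE])
  o <- seq(1, nrow(px), by = 2); e <- o + 1
  lo_r <- (px[o, , drop = FALSE] + px[e, , drop = FALSE]) / sqrt(2)
  hi_r <- (px[o, , drop = FALSE] - px[e, , drop = FALSE]) / sqrt(2)
  oc <- seq(1, ncol(px), by = 2); ec <- oc + 1
  list(
    LL = (lo_r[, oc, drop = FALSE] + lo_r[, ec, drop = FALSE]) / sqrt(2),
    LH = (lo_r[, oc, drop = FALSE] - lo_r[, ec, drop = FALSE]) / sqrt(2),
    HL = (hi_r[, oc, drop = FALSE] + hi_r[, ec, drop = FALSE]) / sqrt(2),
    HH = (hi_r[, oc, drop = FALSE] - hi_r[, ec, drop = FALSE]) / sqrt(2))
}

#' Discrete wavelet transform features
#'
#' Single-level orthonormal Haar decomposition into approximation (LL) and
#' horizontal/vertical/diagonal detail (LH, HL, HH) sub-bands; the feature
#' per band is its coefficient mean and energy (mean of squared
#' coefficients), in band order LL, LH, HL, HH. A constant image has zero
#' detail in all three high-pass bands.
#'
#' @param image a [gray_image()] or numeric matrix.
#' @return named numeric vector of length 8.
#' @export
dwt_features <- function(image) {
  px <- img_pixels(image)
  if (length(px) == 0) stop_shape("dwt_features: empty image")
  sb <- haar2(px)
  out <- unlist(lapply(sb, function(m) c(mean(m), mean(m^2))))
  names(out) <- as.vector(t(outer(c("ll", "lh", "hl", "hh"),
                                  c("mean", "energy"),
                                  function(a, b) paste0("dwt_", a, "_", b))))
  out
}

shannon_entropy <- function(q) {
  p <- tabulate(as.integer(q) + 1L, nbins = 256)
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Uniform LBP codes (8 neighbours, radius 1): patterns with at most two
# 0/1 transitions get the bin equal to their number of set bits (0..8);
# non-uniform patterns share bin 9.
lbp_hist10 <- function(q) {
  H <- nrow(q); W <- ncol(q)
  if (H < 3 || W < 3) stop_shape("lbp: image too small")
  ctr <- q[2:(H - 1), 2:(W - 1)]
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  bits <- lapply(offs, function(o) {
    (q[2:(H - 1) + o[1], 2:(W - 1) + o[2]] >= ctr) * 1L
  })
  trans <- 0L; ones <- 0L
  for (k in seq_along(bits)) {
    nk <- bits[[if (k == length(bits)) 1 else k + 1]]
    trans <- trans + (bits[[k]] != nk)
    ones <- ones + bits[[k]]
  }
  lab <- ifelse(trans <= 2L, ones, 9L)
  h <- tabulate(as.integer(lab) + 1L, nbins = 10)
  h / sum(h)
}

# The 13 classic co-occurrence statistics of one normalized GLCM.
# Logs are base 2; log(0) terms are dropped.
haralick_stats <- function(P) {
  n <- nrow(P)
  i <- row(P) - 1; j <- col(P) - 1
  px_i <- rowSums(P); px_j <- colSums(P)
  mu_i <- sum((0:(n - 1)) * px_i); mu_j <- sum((0:(n - 1)) * px_j)
  s_i <- sqrt(sum((0:(n - 1) - mu_i)^2 * px_i))
  s_j <- sqrt(sum((0:(n - 1) - mu_j)^2 * px_j))
  lg <- function(x) ifelse(x > 0, log2(x), 0)
  # p_{x+y}(k), k = 0..2n-2 and p_{x-y}(k), k = 0..n-1
  sums <- i + j; diffs <- abs(i - j)
  pxy_sum <- vapply(0:(2 * n - 2), function(k) sum(P[sums == k]), 0)
  pxy_dif <- vapply(0:(n - 1), function(k) sum(P[diffs == k]), 0)
  f1 <- sum(P^2)
  f2 <- sum((0:(n - 1))^2 * pxy_dif)
  f3 <- if (s_i > 0 && s_j > 0)
    (sum(i * j * P) - mu_i * mu_j) / (s_i * s_j) else 1
  f4 <- sum((i - mu_i)^2 * P)                      # sum of squares: variance
  f5 <- sum(P / (1 + (i - j)^2))                   # inverse difference moment
  kk <- 0:(2 * n - 2)
  f6 <- sum(kk * pxy_sum)                          # sum average
  f8 <- -sum(pxy_sum * lg(pxy_sum))                # sum entropy
  f7 <- sum((kk - f6)^2 * pxy_sum)                 # sum variance
  f9 <- -sum(P * lg(P))                            # entropy
  dm <- sum((0:(n - 1)) * pxy_dif)
  f10 <- sum((0:(n - 1) - dm)^2 * pxy_dif)         # difference variance
  f11 <- -sum(pxy_dif * lg(pxy_dif))               # difference entropy
  hxy <- f9
  pij <- outer(px_i, px_j)
  hxy1 <- -sum(P * lg(pij))
  hxy2 <- -sum(pij * lg(pij))
  hx <- -sum(px_i * lg(px_i)); hy <- -sum(px_j * lg(px_j))
  f12 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  f13 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))
  c(f1, f2, f3, f4, f5, f6, f7, f8, f9, f10, f11, f12, f13)
}

#' Entropy, local-binary-pattern and Haralick texture features
#'
#' Entropy is the Shannon entropy (bits) of the 256-bin gray-level
#' histogram. The LBP block is the normalized 10-bin histogram of uniform
#' local binary patterns (8 neighbours, radius 1; non-uniform patterns pool
#' into the last bin). The Haralick block holds the thirteen classic
#' second-order statistics averaged over the four principal co-occurrence
#' directions.
#'
#' @param image a [gray_image()] or numeric matrix.
#' @return `list(entropy, lbp, haralick)` with lengths 1, 10 and 13.
#' @export
texture_features <- function(image) {
  px <- img_pixels(image)
  if (length(px) == 0) stop_shape("texture_features: empty image")
  q <- quantize256(px)
  ent <- shannon_entropy(q)
  lbp <- lbp_hist10(q)
  names(lbp) <- paste0("lbp_", 0:9)
  dirs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  har <- rowMeans(vapply(dirs, function(d) {
    haralick_stats(glcm_matrix(q, d[1], d[2]))
  }, numeric(13)))
  names(har) <- sprintf("har_%02d", 1:13)
  list(entropy = c(entropy = ent), lbp = lbp, haralick = har)
}

#' Extract the full 42-element feature vector
#'
#' Resizes the image to 256x256 (byte scale), computes all blocks and
#' concatenates them in the fixed order intensity | GLCM | DWT | entropy |
#' LBP | Haralick (4 + 6 + 8 + 1 + 10 + 13 = 42 values).
#'
#' @param image a [gray_image()].
#' @param name record name stored with the vector.
#' @param label optional 0/1 class label.
#' @return object of class `feature_vector`: named numeric `values` plus
#'   `name` and `label`.
#' @export
extract_all <- function(image, name = "image", label = NA_integer_) {
  if (!inherits(image, "gray_image"))
    stop_shape("extract_all: gray_image expected")
  g <- gray_image(resize_image(image$pixels, 256, 256, "bilinear"),
                  image$value_range, image$source)
  px <- to_byte(g)
  tex <- texture_features(px)
  values <- c(intensity_features(px), glcm_features(px), dwt_features(px),
              tex$entropy, tex$lbp, tex$haralick)
  structure(list(values = values, name = name, label = label),
            class = "feature_vector")
}

#' Names and spans of the feature blocks
#'
#' Block selection mirrors the grouping used when training feature-input
#' detectors on subsets: `intensity`, `glcm`, `dwt`, `other` (entropy + LBP
#' + Haralick) or `all`.
#'
#' @param block one of `"intensity"`, `"glcm"`, `"dwt"`, `"other"`, `"all"`.
#' @return character vector of feature names in the fixed vector order.
#' @export
feature_block_names <- function(block = "all") {
  intensity <- c("int_mean", "int_var", "int_skew", "int_kurt")
  glcm <- c("glcm_contrast", "glcm_dissimilarity", "glcm_homogeneity",
            "glcm_asm", "glcm_energy", "glcm_correlation")
  dwt <- as.vector(t(outer(c("ll", "lh", "hl", "hh"), c("mean", "energy"),
                           function(a, b) paste0("dwt_", a, "_", b))))
  other <- c("entropy", paste0("lbp_", 0:9), sprintf("har_%02d", 1:13))
  switch(match.arg(block, c("intensity", "glcm", "dwt", "other", "all")),
         intensity = intensity, glcm = glcm, dwt = dwt, other = other,
         all = c(intensity, glcm, dwt, other))
}

#' Write / read a feature table
#'
#' CSV with columns `name`, `label`, then the 42 feature columns in fixed
#' order.
#'
#' @param vectors list of `feature_vector` objects.
#' @param path CSV file.
#' @return the data frame written (invisibly for write).
#' @export
write_feature_table <- function(vectors, path) {
  rows <- lapply(vectors, function(v) {
    data.frame(name = v$name, label = v$label, t(v$values),
               check.names = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("no such file: %s", path))
  utils::read.csv(path, check.names = FALSE)
}
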