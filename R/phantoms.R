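#' @title Synthetic phantom data
#' @description Deterministic generators for every input family the pipeline
#'   reads: 2-D detection images with Y/N file names, CjData-style
#'   HDF5 records (image + tumor mask + label), and four-modality volumes
#'   with integer-labelled tumor masks. Anatomy is a bright "brain" ellipse
#'   on a dark background with additive Gaussian noise; a tumor (when
#'   present) is a brighter ellipse strictly inside the brain, so the mask
#'   ground truth is analytically exact and tumor/non-tumor classes are
#'   separable by construction at the default contrast. Identical spec +
#'   seed always reproduces the phantom bit-for-bit.
#' @name brainseg-phantoms
NULL

#' Phantom specification
#'
#' @param size `(H, W)` for 2-D phantoms or `(H, W, D)` for volumes.
#' @param with_tumor logical.
#' @param tumor_center ellipse center (row, col); default slightly off the
#'   brain center.
#' @param tumor_axes ellipse semi-axes (rows, cols) in pixels.
#' @param contrast additive tumor-to-background intensity offset (byte
#'   scale); must be nonzero when `with_tumor`.
#' @param noise_sd additive Gaussian noise standard deviation (byte scale).
#' @param seed integer generator seed.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(size = c(128, 128), with_tumor = TRUE,
                         tumor_center = NULL, tumor_axes = NULL,
                         contrast = 60, noise_sd = 8, seed = 1L) {
  H <- size[1]; W <- size[2]
  if (is.null(tumor_center)) tumor_center <- c(H * 0.45, W * 0.58)
  if (is.null(tumor_axes)) tumor_axes <- c(H / 10, W / 13)
  if (with_tumor && contrast == 0)
    stop_spec("phantom_spec: tumor requires nonzero contrast")
  structure(list(size = size, with_tumor = with_tumor,
                 tumor_center = tumor_center, tumor_axes = tumor_axes,
                 contrast = contrast, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Draw a randomized phantom specification
#'
#' Dataset-level generator: tumor position (anywhere that keeps the ellipse
#' inside the brain), semi-axes (4–12% of the image height), contrast
#' (uniform in 40–90) and noise level (uniform in 6–12) are drawn from the
#' seed, so a collection of phantoms varies the way a patient cohort does
#' instead of repeating one anatomy. Tumor/non-tumor classes remain
#' separable at the minimum contrast.
#'
#' @param size `(H, W)` image size.
#' @param with_tumor logical.
#' @param seed integer; fully determines the drawn spec (and, through
#'   [make_phantom2d()], the phantom).
#' @return a [phantom_spec()].
#' @export
random_phantom_spec <- function(size = c(128, 128), with_tumor = TRUE,
                                seed = 1L) {
  H <- size[1]; W <- size[2]
  with_seed(seed * 2L + 1L, {
    bg <- brain_geometry(H, W)
    repeat {  # rejection sampling: keep the tumor wholly inside the brain
      ax <- stats::runif(2, 0.04, 0.12) * H
      u <- stats::runif(2, -1, 1)
      ctr <- c(bg$center[1] + u[1] * (bg$axes[1] - ax[1] - 2),
               bg$center[2] + u[2] * (bg$axes[2] - ax[2] - 2))
      sp <- phantom_spec(size = size, with_tumor = with_tumor,
                        tumor_center = ctr, tumor_axes = ax,
                        contrast = stats::runif(1, 40, 90),
                        noise_sd = stats::runif(1, 6, 12), seed = seed)
      ok <- tryCatch({ check_tumor_inside(H, W, sp); TRUE },
                     brainseg_spec_error = function(e) FALSE)
      if (ok) return(sp)
    }
  })
}

ellipse_mask <- function(H, W, center, axes) {
  r <- matrix(seq_len(H), H, W)
  c2 <- matrix(seq_len(W), H, W, byrow = TRUE)
  ((r - center[1]) / axes[1])^2 + ((c2 - center[2]) / axes[2])^2 <= 1
}

brain_geometry <- function(H, W) {
  list(center = c(H / 2, W / 2), axes = c(H * 0.42, W * 0.38))
}

check_tumor_inside <- function(H, W, spec) {
  bg <- brain_geometry(H, W)
  # tumor ellipse bounding points must satisfy the brain ellipse equation
  tc <- spec$tumor_center; ta <- spec$tumor_axes
  pts <- rbind(tc + c(ta[1], 0), tc - c(ta[1], 0),
               tc + c(0, ta[2]), tc - c(0, ta[2]))
  ok <- ((pts[, 1] - bg$center[1]) / bg$axes[1])^2 +
    ((pts[, 2] - bg$center[2]) / bg$axes[2])^2 <= 1
  if (!all(ok)) stop_spec("phantom: tumor ellipse extends outside the brain")
}

#' Generate a 2-D phantom image with exact tumor mask
#'
#' Background level 20, brain ellipse level 110, tumor ellipse at
#' 110 + contrast; Gaussian noise added everywhere, then clipped to the
#' byte range. The returned mask marks exactly the tumor ellipse pixels.
#'
#' @param spec a [phantom_spec()] with 2-D `size`.
#' @return `list(image = gray_image, mask = binary matrix, label = 0|1)`.
#' @export
make_phantom2d <- function(spec) {
  H <- spec$size[1]; W <- spec$size[2]
  bg <- brain_geometry(H, W)
  brain <- ellipse_mask(H, W, bg$center, bg$axes)
  px <- matrix(20, H, W)
  px[brain] <- 110
  mask <- matrix(0, H, W)
  if (spec$with_tumor) {
    check_tumor_inside(H, W, spec)
    tum <- ellipse_mask(H, W, spec$tumor_center, spec$tumor_axes)
    px[tum] <- 110 + spec$contrast
    mask[tum] <- 1
  }
  px <- with_seed(spec$seed,
                  px + matrix(stats::rnorm(H * W, 0, spec$noise_sd), H, W))
  px <- pmin(pmax(px, 0), 255)
  list(image = gray_image(px, "byte", source = "synthetic"),
       mask = mask, label = as.integer(spec$with_tumor))
}

#' Generate a four-modality phantom volume with labelled tumor mask
#'
#' All modalities share one anatomy; modality-specific multiplicative gains
#' (T1 1.0, T2 0.8, T1ce 1.2, FLAIR 0.9) and offsets make the channels
#' distinguishable. The tumor occupies a contiguous axial slice band placed
#' wholly inside the middle-slice window [60, 130), so a window-selection
#' bug collapses the observable Dice instead of passing silently. The mask
#' volume uses the labels 1, 2 and 4 on concentric tumor shells to exercise
#' label binarization.
#'
#' @param spec a [phantom_spec()] with `size = (H, W, D)`, `D >= 131`.
#' @param tumor_slices 0-based slice band holding the tumor (default
#'   75..114).
#' @return a [multimodal_volume()] with mask.
#' @export
make_multimodal_phantom <- function(spec = phantom_spec(size = c(240, 240, 155)),
                                    tumor_slices = 75:114) {
  if (length(spec$size) != 3) stop_spec("make_multimodal_phantom: 3-D size required")
  H <- spec$size[1]; W <- spec$size[2]; D <- spec$size[3]
  if (D < 131) stop_spec("make_multimodal_phantom: depth must be >= 131")
  if (spec$with_tumor && (min(tumor_slices) < 60 || max(tumor_slices) >= 130))
    stop_spec("make_multimodal_phantom: tumor slice band outside the [60,130) window")
  bg <- brain_geometry(H, W)
  brain <- ellipse_mask(H, W, bg$center, bg$axes)
  base <- matrix(20, H, W)
  base[brain] <- 110
  gains <- c(t1 = 1.0, t2 = 0.8, t1ce = 1.2, flair = 0.9)
  offs <- c(t1 = 0, t2 = 5, t1ce = -5, flair = 10)
  mask <- array(0L, c(H, W, D))
  vol_base <- array(rep(base, D), c(H, W, D))
  if (spec$with_tumor) {
    check_tumor_inside(H, W, spec)
    core <- ellipse_mask(H, W, spec$tumor_center, spec$tumor_axes * 0.5)
    mid <- ellipse_mask(H, W, spec$tumor_center, spec$tumor_axes * 0.8)
    full <- ellipse_mask(H, W, spec$tumor_center, spec$tumor_axes)
    lab <- matrix(0L, H, W)
    lab[full] <- 2L   # edema shell
    lab[mid] <- 1L    # necrotic core shell
    lab[core] <- 4L   # enhancing core
    for (s in tumor_slices + 1) {
      mask[, , s] <- lab
      sl <- vol_base[, , s]
      sl[full] <- sl[full] + spec$contrast
      vol_base[, , s] <- sl
    }
  }
  vols <- with_seed(spec$seed, {
    lapply(seq_along(gains), function(m) {
      vol_base * gains[m] + offs[m] +
        array(stats::rnorm(H * W * D, 0, spec$noise_sd), c(H, W, D))
    })
  })
  multimodal_volume(vols[[1]], vols[[2]], vols[[3]], vols[[4]], mask,
                    case_id = sprintf("phantom_seed%d", spec$seed))
}

#' Write a detection phantom dataset of named PNG files
#'
#' Writes `round(n * tumor_fraction)` tumor phantoms named `Y1..Yk` and the
#' rest named `N1..Nm`, plus a `manifest.csv` (name, label, seed). The
#' generation label of every file is recoverable through
#' [label_from_name()].
#'
#' @param n number of images (>= 2).
#' @param tumor_fraction proportion with tumors, in (0, 1).
#' @param seed base seed; file i uses `seed + i`.
#' @param out_dir output directory (created if needed).
#' @param size image size.
#' @return data frame manifest, invisibly.
#' @export
make_detection_dataset <- function(n, tumor_fraction = 0.5, seed = 1L,
                                   out_dir, size = c(128, 128)) {
  if (n < 2 || tumor_fraction <= 0 || tumor_fraction >= 1)
    stop_spec("make_detection_dataset: need n >= 2 and 0 < tumor_fraction < 1")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop_io(sprintf("cannot create directory %s", out_dir))
  k <- round(n * tumor_fraction)
  labels <- c(rep(1L, k), rep(0L, n - k))
  names_out <- c(sprintf("Y%d.png", seq_len(k)),
                 sprintf("N%d.png", seq_len(n - k)))
  for (i in seq_len(n)) {
    sp <- random_phantom_spec(size = size, with_tumor = labels[i] == 1,
                              seed = seed + i)
    ph <- make_phantom2d(sp)
    png::writePNG(ph$image$pixels / 255, file.path(out_dir, names_out[i]))
  }
  manifest <- data.frame(name = names_out, label = labels,
                         seed = seed + seq_len(n))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Write a CjData-style phantom record
#'
#' A 512x512 phantom with tumor, stored as an HDF5 container with the
#' `cjdata/image`, `cjdata/tumorMask` and `cjdata/label` datasets that
#' [read_cjdata_record()] expects.
#'
#' @param spec a [phantom_spec()]; the size is forced to 512x512.
#' @param path output file (conventionally `.mat`).
#' @return `path` invisibly.
#' @export
make_cjdata_fixture <- function(spec = phantom_spec(), path) {
  sp <- phantom_spec(size = c(512, 512), with_tumor = TRUE,
                     contrast = spec$contrast, noise_sd = spec$noise_sd,
                     seed = spec$seed)
  ph <- make_phantom2d(sp)
  write_cjdata_record(ph$image$pixels, ph$mask, 1, path)
  invisible(path)
}

#' Write a four-modality phantom case as NIfTI files
#'
#' @param volume a [multimodal_volume()] (e.g. from
#'   [make_multimodal_phantom()]).
#' @param out_dir output directory.
#' @return named character vector of the five written paths (t1, t2, t1ce,
#'   flair, mask).
#' @export
write_multimodal_case <- function(volume, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop_io(sprintf("cannot create directory %s", out_dir))
  paths <- c(t1 = "t1.nii.gz", t2 = "t2.nii.gz", t1ce = "t1ce.nii.gz",
             flair = "flair.nii.gz", mask = "seg.nii.gz")
  paths <- vapply(paths, function(p) file.path(out_dir, p), "")
  RNifti::writeNifti(volume$t1, paths["t1"])
  RNifti::writeNifti(volume$t2, paths["t2"])
  RNifti::writeNifti(volume$t1ce, paths["t1ce"])
  RNifti::writeNifti(volume$flair, paths["flair"])
  if (!is.null(volume$mask)) RNifti::writeNifti(volume$mask, paths["mask"])
  paths
}
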