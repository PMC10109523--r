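#' Grayscale 2-D image container
#'
#' Thin value class around a numeric matrix of pixel intensities with a
#' declared value range and provenance. The range tag travels with the image
#' so preprocessing can normalize correctly: `"byte"` means `[0, 255]`,
#' `"unit"` means `[0, 1]`, `"raw"` is unconstrained finite data (e.g.
#' 16-bit DICOM before rescaling) and `"zscore"` is standardized data.
#'
#' @param pixels numeric matrix (height x width).
#' @param value_range one of `"raw"`, `"byte"`, `"unit"`, `"zscore"`.
#' @param source file path or `"synthetic"`.
#' @return object of class `gray_image`.
#' @export
gray_image <- function(pixels, value_range = "raw", source = "synthetic") {
  if (!is.matrix(pixels) || nrow(pixels) < 1 || ncol(pixels) < 1)
    stop_shape("gray_image: pixels must be a non-empty matrix")
  if (!all(is.finite(pixels)))
    stop_format("gray_image: non-finite pixel values")
  value_range <- match.arg(value_range, c("raw", "byte", "unit", "zscore"))
  if (value_range == "byte" && (min(pixels) < 0 || max(pixels) > 255))
    stop_format("gray_image: byte range violated")
  if (value_range == "unit" && (min(pixels) < 0 || max(pixels) > 1))
    stop_format("gray_image: unit range violated")
  structure(list(pixels = pixels, value_range = value_range, source = source),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %dx%d, range %s [%.3g, %.3g], source %s\n",
              nrow(x$pixels), ncol(x$pixels), x$value_range,
              min(x$pixels), max(x$pixels), x$source))
  invisible(x)
}

#' Derive the tumor class label from a file name
#'
#' Detection datasets name files `Yxx` (tumor) or `Nxx` (no tumor); the
#' first character carries the label. Matching is case-insensitive.
#'
#' @param name file name (base name or path).
#' @return `1L` for tumor (`Y*`), `0L` for non-tumor (`N*`).
#' @examples
#' label_from_name("Y12.jpg")  # 1
#' label_from_name("N3.png")   # 0
#' @export
label_from_name <- function(name) {
  if (!is.character(name) || length(name) != 1 || nchar(name) == 0)
    stop_unlabeled("label_from_name: empty name")
  ch <- toupper(substr(basename(name), 1, 1))
  if (ch == "Y") return(1L)
  if (ch == "N") return(0L)
  stop_unlabeled(sprintf(
    "file name '%s' does not follow the Yxx/Nxx labeling convention", name))
}

rgb_to_gray <- function(arr) {
  # standard luminance weights; alpha channel (if any) ignored
  if (length(dim(arr)) == 2) return(arr)
  arr[, , 1] * 0.299 + arr[, , 2] * 0.587 + arr[, , 3] * 0.114
}

#' Read a 2-D grayscale image from PNG, JPEG or DICOM
#'
#' Color images are collapsed to grayscale by luminance weighting
#' (0.299 R + 0.587 G + 0.114 B). PNG/JPEG pixels are returned on the byte
#' scale. DICOM pixel data has any rescale slope/intercept applied and is
#' then mapped to `[0, 255]` by min-max rescaling (a constant frame maps
#' to 0).
#'
#' @param path image file (`.png`, `.jpg`/`.jpeg`, `.dcm`).
#' @return a [gray_image()] with `value_range = "byte"`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("no such file: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png", "jpg", "jpeg")) {
    arr <- tryCatch(
      if (ext == "png") png::readPNG(path) else jpeg::readJPEG(path),
      error = function(e) stop_format(sprintf("unreadable image %s: %s",
                                              path, conditionMessage(e))))
    g <- rgb_to_gray(arr) * 255
  } else if (ext %in% c("dcm", "dicom")) {
    d <- read_dicom(path)
    px <- d$pixels * d$slope + d$intercept
    rng <- range(px)
    g <- if (rng[2] > rng[1]) (px - rng[1]) / (rng[2] - rng[1]) * 255
         else px * 0
  } else stop_format(sprintf("unsupported image format: .%s", ext))
  if (length(g) == 0) stop_format("empty raster")
  gray_image(as.matrix(g), "byte", source = path)
}

# ---- minimal single-frame DICOM (Explicit VR Little Endian) ------------
# Covers exactly what the pipeline needs: Rows, Columns, BitsAllocated,
# PixelRepresentation, RescaleSlope/Intercept and PixelData of monochrome
# secondary-capture files, such as those the phantom generator writes.

dcm_tag <- function(group, elem) sprintf("%04X%04X", group, elem)

read_dicom <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 132 || rawToChar(raw[129:132]) != "DICM")
    stop_format(sprintf("%s: not a DICOM part-10 file", path))
  pos <- 133L
  u16 <- function(at) sum(as.integer(raw[at:(at + 1)]) * c(1L, 256L))
  u32 <- function(at) sum(as.numeric(raw[at:(at + 3)]) * 256^(0:3))
  fields <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7 <= length(raw)) {
    grp <- u16(pos); ele <- u16(pos + 2)
    vr <- rawToChar(raw[(pos + 4):(pos + 5)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop_format(sprintf("%s: implicit VR or corrupt element at %d",
                          path, pos))
    if (vr %in% long_vrs) {
      len <- u32(pos + 8); data_at <- pos + 12L
    } else {
      len <- u16(pos + 6); data_at <- pos + 8L
    }
    tag <- dcm_tag(grp, ele)
    if (tag %in% c("00280010", "00280011", "00280100", "00280103")) {
      fields[[tag]] <- u16(data_at)
    } else if (tag %in% c("00281052", "00281053")) {
      fields[[tag]] <- as.numeric(rawToChar(raw[data_at:(data_at + len - 1)]))
    } else if (tag == "7FE00010") {
      fields[["pixeldata"]] <- raw[data_at:(data_at + len - 1)]
    }
    pos <- data_at + len
  }
  rows <- fields[["00280010"]]; cols <- fields[["00280011"]]
  bits <- fields[["00280100"]] %||% 16
  if (is.null(rows) || is.null(cols) || is.null(fields$pixeldata))
    stop_format(sprintf("%s: missing Rows/Columns/PixelData", path))
  signed <- (fields[["00280103"]] %||% 0) == 1
  v <- readBin(fields$pixeldata, "integer", n = rows * cols,
               size = bits / 8, signed = if (bits == 8) signed else signed,
               endian = "little")
  if (bits == 16 && !signed) v <- ifelse(v < 0, v + 65536, v)
  list(pixels = matrix(v, nrow = rows, ncol = cols, byrow = TRUE),
       slope = fields[["00281053"]] %||% 1,
       intercept = fields[["00281052"]] %||% 0)
}

# Writer used by the phantom generator to produce DICOM fixtures.
write_dicom <- function(pixels, path, bits = 16L) {
  pixels <- round(pixels)
  if (any(pixels < 0)) stop_io("write_dicom: unsigned pixel data required")
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  elem <- function(group, el, vr, payload) {
    w16(group); w16(el)
    writeChar(vr, con, eos = NULL)
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      w16(0)
      writeBin(as.integer(length(payload)), con, size = 4, endian = "little")
    } else w16(length(payload))
    writeBin(payload, con)
  }
  str_pad <- function(s) {
    r <- charToRaw(s)
    if (length(r) %% 2 == 1) r <- c(r, as.raw(0))
    r
  }
  us <- function(x) writeBin(as.integer(x), raw(), size = 2,
                             endian = "little")
  writeBin(raw(128), con)
  writeChar("DICM", con, eos = NULL)
  # file meta group (group 2): transfer syntax = Explicit VR Little Endian
  ts <- str_pad("1.2.840.10008.1.2.1")
  meta_len <- 8 + length(ts)  # the single (0002,0010) element that follows
  elem(0x0002, 0x0000, "UL", writeBin(as.integer(meta_len), raw(), size = 4,
                                      endian = "little"))
  elem(0x0002, 0x0010, "UI", ts)
  elem(0x0008, 0x0016, "UI", str_pad("1.2.840.10008.5.1.4.1.1.7"))
  elem(0x0008, 0x0018, "UI", str_pad("1.2.826.0.1.3680043.9999.1"))
  elem(0x0028, 0x0002, "US", us(1))
  elem(0x0028, 0x0004, "CS", str_pad("MONOCHROME2"))
  elem(0x0028, 0x0010, "US", us(nrow(pixels)))
  elem(0x0028, 0x0011, "US", us(ncol(pixels)))
  elem(0x0028, 0x0100, "US", us(bits))
  elem(0x0028, 0x0101, "US", us(bits))
  elem(0x0028, 0x0102, "US", us(bits - 1))
  elem(0x0028, 0x0103, "US", us(0))
  px <- as.integer(t(pixels))  # DICOM stores rows consecutively
  pd <- writeBin(px, raw(), size = bits / 8, endian = "little")
  elem(0x7FE0, 0x0010, "OW", pd)
  invisible(path)
}

#' Read a CjData-style record (image + tumor mask + label)
#'
#' CjData records are HDF5 containers (MATLAB v7.3-style layout) holding a
#' T1-contrast MRI, its binary tumor mask and a tumor-type label under a
#' `cjdata` group. Every record contains a tumor, so the binary presence
#' label is 1.
#'
#' @param path HDF5 container with datasets `image`, `tumorMask`, `label`
#'   (under group `cjdata`, or at the file root).
#' @return `list(image, mask, label = 1L, name)` of class `labeled_record`,
#'   where `image` is a [gray_image()] and `mask` a binary matrix of the
#'   same shape.
#' @export
read_cjdata_record <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("no such file: %s", path))
  objs <- tryCatch(rhdf5::h5ls(path),
                   error = function(e) stop_format(sprintf(
                     "%s: not an HDF5 container", path)))
  avail <- sub("^/+", "", file.path(objs$group, objs$name))
  root <- if (any(objs$name == "cjdata" & objs$otype == "H5I_GROUP"))
    "cjdata/" else ""
  get <- function(nm) {
    full <- paste0(root, nm)
    if (!full %in% avail)
      stop_format(sprintf("%s: missing field '%s'", path, nm))
    rhdf5::h5read(path, full)
  }
  img <- drop(get("image")); msk <- drop(get("tumorMask"))
  on.exit(rhdf5::H5close(), add = TRUE)
  if (!identical(dim(img), dim(msk)))
    stop_format(sprintf("%s: image and tumorMask shapes differ", path))
  structure(list(image = gray_image(as.matrix(img), "raw", source = path),
                 mask = (as.matrix(msk) != 0) * 1,
                 label = 1L,
                 name = basename(path)),
            class = "labeled_record")
}

write_cjdata_record <- function(image, mask, label, path) {
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "cjdata")
  rhdf5::h5write(image, path, "cjdata/image")
  rhdf5::h5write(mask, path, "cjdata/tumorMask")
  rhdf5::h5write(as.numeric(label), path, "cjdata/label")
  rhdf5::H5close()
  invisible(path)
}

#' Read a co-registered four-modality NIfTI case
#'
#' Loads T1, T2, T1ce and FLAIR volumes (and optionally the labelled tumor
#' mask volume) and verifies they share one shape. Modality order is fixed
#' and never permuted: slot i of the result corresponds to path i in the
#' order T1, T2, T1ce, FLAIR.
#'
#' @param paths character vector of exactly four NIfTI files, in the order
#'   T1, T2, T1ce, FLAIR.
#' @param mask_path optional NIfTI file with integer tumor labels.
#' @param case_id identifier stored with the volume.
#' @return `list(t1, t2, t1ce, flair, mask, case_id)` of class
#'   `multimodal_volume`; each volume is a 3-D array (height, width, depth).
#' @export
read_multimodal_case <- function(paths, mask_path = NULL, case_id = "case") {
  if (length(paths) != 4)
    stop_arity(sprintf("expected 4 modality files (T1, T2, T1ce, FLAIR), got %d",
                       length(paths)))
  vols <- lapply(paths, function(p) {
    v <- tryCatch(as.array(RNifti::readNifti(p)),
                  error = function(e) stop_format(sprintf(
                    "unreadable NIfTI %s: %s", p, conditionMessage(e))))
    if (length(dim(v)) != 3) stop_shape(sprintf("%s: expected 3-D volume", p))
    v
  })
  d1 <- dim(vols[[1]])
  for (i in 2:4)
    if (!identical(dim(vols[[i]]), d1))
      stop_shape(sprintf("modality %d shape (%s) differs from T1 (%s)", i,
                         paste(dim(vols[[i]]), collapse = "x"),
                         paste(d1, collapse = "x")))
  mask <- NULL
  if (!is.null(mask_path)) {
    mask <- as.array(RNifti::readNifti(mask_path))
    if (!identical(dim(mask), d1))
      stop_shape("mask volume shape differs from modalities")
  }
  multimodal_volume(vols[[1]], vols[[2]], vols[[3]], vols[[4]], mask, case_id)
}

#' Construct a multimodal volume in memory
#'
#' @param t1,t2,t1ce,flair 3-D arrays of identical shape.
#' @param mask optional integer-labelled 3-D array of the same shape.
#' @param case_id identifier string.
#' @return object of class `multimodal_volume`.
#' @export
multimodal_volume <- function(t1, t2, t1ce, flair, mask = NULL,
                              case_id = "case") {
  d <- dim(t1)
  for (v in list(t2, t1ce, flair))
    if (!identical(dim(v), d)) stop_shape("modality shapes differ")
  if (!is.null(mask) && !identical(dim(mask), d))
    stop_shape("mask shape differs from modalities")
  structure(list(t1 = t1, t2 = t2, t1ce = t1ce, flair = flair,
                 mask = mask, case_id = case_id),
            class = "multimodal_volume")
}

#' @export
print.multimodal_volume <- function(x, ...) {
  cat(sprintf("<multimodal_volume> %s: %s%s\n", x$case_id,
              paste(dim(x$t1), collapse = "x"),
              if (is.null(x$mask)) "" else " (+mask)"))
  invisible(x)
}

#' Write a red tumor overlay PNG
#'
#' Renders the grayscale image as RGB with mask-positive pixels blended
#' toward red (alpha 0.5), the standard review rendering for segmentation
#' output. An empty mask reproduces the grayscale image exactly.
#'
#' @param image a [gray_image()] (or numeric matrix).
#' @param mask binary matrix aligned to the image.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(image, mask, path) {
  px <- if (inherits(image, "gray_image")) image$pixels else image
  vr <- if (inherits(image, "gray_image")) image$value_range else "raw"
  if (!identical(dim(px), dim(mask)))
    stop_shape("write_overlay: mask shape differs from image")
  g <- switch(vr,
              byte = px / 255,
              unit = px,
              { rng <- range(px)
                if (rng[2] > rng[1]) (px - rng[1]) / (rng[2] - rng[1])
                else px * 0 })
  pos <- mask > 0.5
  r <- g; gg <- g; b <- g
  r[pos] <- 0.5 * g[pos] + 0.5
  gg[pos] <- 0.5 * g[pos]
  b[pos] <- 0.5 * g[pos]
  arr <- array(c(r, gg, b), dim = c(nrow(g), ncol(g), 3))
  png::writePNG(arr, path)
  invisible(path)
}
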