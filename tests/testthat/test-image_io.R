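test_that("label_from_name follows the Y/N convention and rejects others", {
  expect_identical(label_from_name("Y12.jpg"), 1L)
  expect_identical(label_from_name("N3.png"), 0L)
  expect_identical(label_from_name("y7.png"), 1L)
  expect_identical(label_from_name("n1.dcm"), 0L)
  expect_identical(label_from_name("/some/dir/Y1.png"), 1L)
  expect_error(label_from_name("brain.png"),
               class = "brainseg_unlabeled_name_error")
  expect_error(label_from_name(""), class = "brainseg_unlabeled_name_error")
})

test_that("PNG write/read round-trips byte rasters exactly", {
  px <- matrix(sample(0:255, 64 * 48, replace = TRUE), 64, 48)
  f <- withr::local_tempfile(fileext = ".png")
  png::writePNG(px / 255, f)
  img <- read_image(f)
  expect_s3_class(img, "gray_image")
  expect_identical(img$value_range, "byte")
  expect_equal(img$pixels, px, tolerance = 1e-12)
})

test_that("color images collapse to luminance grayscale", {
  arr <- array(50 / 255, c(10, 12, 3))
  f <- withr::local_tempfile(fileext = ".png")
  png::writePNG(arr, f)
  img <- read_image(f)
  expect_equal(img$pixels, matrix(50, 10, 12), tolerance = 1e-9)
})

test_that("DICOM pixel data is min-max rescaled to the byte range", {
  set.seed(11)
  px <- matrix(sample(0:4000, 32 * 32, replace = TRUE), 32, 32)
  px[1, 1] <- 0; px[2, 2] <- 4000  # pin the range
  f <- withr::local_tempfile(fileext = ".dcm")
  brainseg:::write_dicom(px, f)
  img <- read_image(f)
  expect_equal(min(img$pixels), 0)
  expect_equal(max(img$pixels), 255)
  # independent oracle: direct min-max rescale of the same array
  expect_equal(img$pixels, (px - 0) / 4000 * 255, tolerance = 1e-9)
})

test_that("constant PNG reads back constant, corrupt file errors", {
  f <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(100 / 255, 20, 20), f)
  expect_true(all(read_image(f)$pixels == 100))
  bad <- withr::local_tempfile(fileext = ".png")
  writeLines("not a png", bad)
  expect_error(read_image(bad), class = "brainseg_format_error")
  expect_error(read_image("does_not_exist.png"),
               class = "brainseg_format_error")
})

test_that("CjData records round-trip and validate their fields", {
  f <- withr::local_tempfile(fileext = ".mat")
  make_cjdata_fixture(phantom_spec(seed = 42), f)
  rec <- read_cjdata_record(f)
  expect_s3_class(rec, "labeled_record")
  expect_identical(rec$label, 1L)
  expect_identical(dim(rec$image$pixels), c(512L, 512L))
  expect_identical(dim(rec$mask), dim(rec$image$pixels))
  expect_true(all(rec$mask %in% c(0, 1)))
  expect_gt(sum(rec$mask), 0)

  # regenerating the same phantom reproduces the stored mask exactly
  ph <- make_phantom2d(phantom_spec(size = c(512, 512), with_tumor = TRUE,
                                    seed = 42))
  expect_equal(rec$mask, ph$mask)

  # container missing the mask is rejected
  g <- withr::local_tempfile(fileext = ".mat")
  rhdf5::h5createFile(g)
  rhdf5::h5write(ph$image$pixels, g, "image")
  rhdf5::H5close()
  expect_error(read_cjdata_record(g), class = "brainseg_format_error")
})

test_that("multimodal cases read back in fixed modality order", {
  d <- withr::local_tempdir()
  vol <- make_multimodal_phantom(
    phantom_spec(size = c(40, 40, 155), noise_sd = 2, seed = 9),
    tumor_slices = 80:95)
  paths <- write_multimodal_case(vol, d)
  back <- read_multimodal_case(paths[1:4], mask_path = paths["mask"])
  expect_equal(dim(back$t1), c(40L, 40L, 155L))
  # order preserved: T1 has the highest gain after FLAIR offsets removed
  expect_equal(mean(back$t1), mean(vol$t1), tolerance = 1e-4)
  expect_equal(mean(back$flair), mean(vol$flair), tolerance = 1e-4)
  expect_error(read_multimodal_case(paths[1:3]),
               class = "brainseg_arity_error")
  # shape mismatch across modalities is rejected
  small <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(vol$t2[, , 1:154], small)
  expect_error(read_multimodal_case(c(paths[1], small, paths[3], paths[4])),
               class = "brainseg_shape_error")
})

test_that("overlay renders mask pixels red and empty masks are no-ops", {
  img <- gray_image(matrix(128, 16, 16), "byte")
  f <- withr::local_tempfile(fileext = ".png")
  write_overlay(img, matrix(0, 16, 16), f)
  arr <- png::readPNG(f)
  expect_equal(arr[, , 1], arr[, , 2])
  expect_equal(arr[, , 1], matrix(128 / 255, 16, 16), tolerance = 1e-2)

  m <- matrix(0, 16, 16); m[5, 7] <- 1
  write_overlay(img, m, f)
  arr <- png::readPNG(f)
  red <- arr[, , 1] > arr[, , 2] & arr[, , 1] > arr[, , 3]
  expect_identical(sum(red), 1L)
  expect_true(red[5, 7])

  write_overlay(img, matrix(1, 16, 16), f)
  arr <- png::readPNG(f)
  expect_true(all(arr[, , 1] > arr[, , 2]))

  expect_error(write_overlay(img, matrix(0, 8, 8), f),
               class = "brainseg_shape_error")
})
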