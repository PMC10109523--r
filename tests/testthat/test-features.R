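test_that("intensity moments match direct formulas", {
  m <- matrix(0:8, 3, 3, byrow = TRUE)
  f <- intensity_features(m)
  expect_equal(unname(f["int_mean"]), 4)
  expect_equal(unname(f["int_var"]), 60 / 9)

  expect_equal(unname(intensity_features(matrix(5, 7, 7))),
               c(5, 0, 0, 0))

  half <- matrix(c(rep(0, 32), rep(255, 32)), 8, 8)
  expect_equal(unname(intensity_features(half)["int_skew"]), 0)

  set.seed(21)
  for (i in 1:20) {
    x <- matrix(runif(100, 0, 255), 10, 10)
    f <- intensity_features(x)
    n <- length(x); mu <- mean(x); v <- sum((x - mu)^2) / n
    expect_equal(unname(f["int_mean"]), mu, tolerance = 1e-10)
    expect_equal(unname(f["int_var"]), v, tolerance = 1e-10)
    expect_equal(unname(f["int_skew"]), sum((x - mu)^3) / n / v^1.5,
                 tolerance = 1e-10)
    expect_equal(unname(f["int_kurt"]), sum((x - mu)^4) / n / v^2 - 3,
                 tolerance = 1e-10)
  }
})

test_that("GLCM features match brute-force pair counting", {
  # exhaustive: every 2x2 image over 4 gray levels
  for (code in 0:255) {
    q <- matrix(c(code %% 4, code %/% 4 %% 4, code %/% 16 %% 4,
                  code %/% 64 %% 4), 2, 2)
    img <- spread_levels(q)
    got <- unname(glcm_features(img))
    want <- unname(oracle_glcm_features(img))
    expect_equal(got, want, tolerance = 1e-12)
  }
  # randomized: 4x4 images over 4 gray levels
  set.seed(77)
  for (i in 1:500) {
    img <- spread_levels(matrix(sample(0:3, 16, TRUE), 4, 4))
    expect_equal(unname(glcm_features(img)),
                 unname(oracle_glcm_features(img)), tolerance = 1e-12)
  }
})

test_that("GLCM limits and symmetries hold", {
  f <- glcm_features(matrix(9, 6, 6))
  expect_equal(unname(f[c("glcm_contrast", "glcm_dissimilarity")]), c(0, 0))
  expect_equal(unname(f[c("glcm_homogeneity", "glcm_asm", "glcm_energy",
                          "glcm_correlation")]), c(1, 1, 1, 1))

  # [[0,1],[0,1]]: both horizontal pairs differ by one gray level
  expect_equal(unname(glcm_features(matrix(c(0, 0, 1, 1), 2, 2))
                      ["glcm_contrast"]), 1)

  set.seed(3)
  img <- matrix(sample(0:255, 15 * 17, TRUE), 15, 17)
  expect_equal(glcm_features(img), glcm_features(img[, ncol(img):1]),
               tolerance = 1e-12)

  expect_error(glcm_features(matrix(1, 5, 1)), class = "brainseg_shape_error")
})

test_that("Haar sub-band features behave like the hand-computed transform", {
  # constant image: all detail bands zero, LL coefficient = 2c
  f <- dwt_features(matrix(3, 2, 2))
  expect_equal(unname(f["dwt_ll_mean"]), 6)
  expect_equal(unname(f[c("dwt_lh_mean", "dwt_lh_energy", "dwt_hl_mean",
                          "dwt_hl_energy", "dwt_hh_mean", "dwt_hh_energy")]),
               rep(0, 6))

  # vertical step placed off the dyadic grid (a step between pair columns
  # is invisible to a single Haar level): column-direction detail only;
  # pins the LH/HL naming convention
  step <- cbind(matrix(0, 8, 3), matrix(255, 8, 5))
  f <- dwt_features(step)
  expect_gt(unname(f["dwt_lh_energy"]), 0)
  expect_equal(unname(f["dwt_hl_energy"]), 0)
  expect_equal(unname(f["dwt_hh_energy"]), 0)
  # horizontal step: the orthogonal band
  f2 <- dwt_features(t(step))
  expect_gt(unname(f2["dwt_hl_energy"]), 0)
  expect_equal(unname(f2["dwt_lh_energy"]), 0)

  # odd sizes are edge-padded, not an error
  expect_length(dwt_features(matrix(runif(35), 5, 7)), 8)

  # orthonormality: energy conservation against a direct 2x2 block formula
  set.seed(9)
  x <- matrix(rnorm(16 * 16), 16, 16)
  f3 <- dwt_features(x)
  total <- (f3["dwt_ll_energy"] + f3["dwt_lh_energy"] +
            f3["dwt_hl_energy"] + f3["dwt_hh_energy"]) * (8 * 8)
  expect_equal(unname(total), sum(x^2), tolerance = 1e-9)
})

test_that("entropy, LBP and Haralick blocks satisfy their contracts", {
  tex <- texture_features(matrix(42, 9, 9))
  expect_equal(unname(tex$entropy), 0)
  expect_equal(sum(tex$lbp), 1)
  expect_length(tex$haralick, 13)

  half <- matrix(c(rep(0, 32), rep(255, 32)), 8, 8)
  expect_equal(unname(texture_features(half)$entropy), 1)

  set.seed(5)
  img <- matrix(sample(0:255, 400, TRUE), 20, 20)
  tex <- texture_features(img)
  expect_equal(sum(tex$lbp), 1)
  expect_true(all(is.finite(c(tex$entropy, tex$lbp, tex$haralick))))
  # Haralick ASM/entropy consistency with the single-direction GLCM limits
  expect_gt(tex$haralick[9], 0)   # entropy of a noisy image is positive
  expect_lt(tex$haralick[1], 1)   # ASM of a noisy image is below 1
})

test_that("extract_all produces the fixed-order 42-vector deterministically", {
  ph <- make_phantom2d(phantom_spec(size = c(64, 64), seed = 30))
  v1 <- extract_all(ph$image, name = "p1", label = 1L)
  expect_s3_class(v1, "feature_vector")
  expect_length(v1$values, 42)
  expect_identical(names(v1$values), feature_block_names("all"))
  expect_identical(v1$values, extract_all(ph$image, "p1", 1L)$values)

  # single-pixel change must perturb at least one coordinate
  img2 <- ph$image
  img2$pixels[10, 10] <- (img2$pixels[10, 10] + 128) %% 255
  v2 <- extract_all(img2, "p2", 1L)
  expect_gt(sum(v1$values != v2$values), 0)

  # block lengths: 4 + 6 + 8 + 1 + 10 + 13
  expect_length(feature_block_names("intensity"), 4)
  expect_length(feature_block_names("glcm"), 6)
  expect_length(feature_block_names("dwt"), 8)
  expect_length(feature_block_names("other"), 24)
})

test_that("feature tables round-trip through CSV", {
  ph <- make_phantom2d(phantom_spec(size = c(64, 64), seed = 31))
  vecs <- list(extract_all(ph$image, "Y1.png", 1L),
               extract_all(ph$image, "N1.png", 0L))
  f <- withr::local_tempfile(fileext = ".csv")
  df <- write_feature_table(vecs, f)
  back <- read_feature_table(f)
  expect_identical(colnames(back), c("name", "label", feature_block_names()))
  expect_equal(as.numeric(back[1, -(1:2)]), unname(vecs[[1]]$values),
               tolerance = 1e-9)
})
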