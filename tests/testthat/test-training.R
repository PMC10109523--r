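test_that("splits are disjoint, exhaustive and sized by the nested 80:20 rule", {
  sp <- split_dataset(100, seed = 1)
  expect_length(sp$train, 64)
  expect_length(sp$validation, 16)
  expect_length(sp$test, 20)
  expect_setequal(c(sp$train, sp$validation, sp$test), 1:100)

  # property over sizes and seeds
  for (n in c(5, 17, 83, 250)) for (seed in c(1, 7)) {
    sp <- split_dataset(n, seed)
    all_ix <- c(sp$train, sp$validation, sp$test)
    expect_identical(sort(all_ix), 1:n)
    expect_identical(anyDuplicated(all_ix), 0L)
    expect_length(sp$test, round(0.2 * n))
    expect_length(sp$validation, round(0.2 * (n - round(0.2 * n))))
  }

  expect_identical(split_dataset(40, 9), split_dataset(40, 9))
  expect_false(identical(split_dataset(100, 1)$train,
                         split_dataset(100, 2)$train))
  expect_error(split_dataset(4), class = "brainseg_size_error")
})

test_that("flip augmentation triples the set with exact mirror geometry", {
  m <- matrix(0, 10, 12); m[3, 4] <- 1
  img <- matrix(runif(120), 10, 12)
  out <- augment_flips(list(list(image = img, mask = m)))
  expect_length(out, 3)
  expect_identical(out[[1]]$image, img)
  # horizontal mirror: column c -> W - 1 - c (0-based index arithmetic)
  expect_equal(sum(out[[2]]$mask), 1)
  expect_equal(out[[2]]$mask[3, 12 - 4 + 1], 1)
  # vertical mirror: row r -> H - 1 - r
  expect_equal(out[[3]]$mask[10 - 3 + 1, 4], 1)
  # involution: mirroring twice restores the original
  expect_identical(brainseg:::flip_h(brainseg:::flip_h(img)), img)
  expect_identical(brainseg:::flip_v(brainseg:::flip_v(img)), img)

  expect_error(augment_flips(list(list(image = img, mask = matrix(0, 2, 2)))),
               class = "brainseg_shape_error")
})

test_that("random augmentation is seeded, binary-preserving and identity at unit factors", {
  ph <- make_phantom2d(phantom_spec(size = c(64, 64), seed = 12))
  pairs <- list(list(image = ph$image$pixels / 255, mask = ph$mask))
  g1 <- random_augment(pairs, seed = 5)
  g2 <- random_augment(pairs, seed = 5)
  for (i in 1:5) {
    a <- g1(); b <- g2()
    expect_identical(a$image, b$image)
    expect_identical(a$mask, b$mask)
    expect_true(all(a$mask %in% c(0, 1)))
    expect_true(max(a$image) <= 1 && min(a$image) >= 0)
  }
  # forced unit factors leave the pair untouched
  id <- brainseg:::perturb_pair(pairs[[1]]$image, pairs[[1]]$mask, 1, 1)
  expect_equal(id$image, pairs[[1]]$image, tolerance = 1e-12)
  expect_identical(id$mask, pairs[[1]]$mask)
  # masks stay binary over many draws
  g3 <- random_augment(pairs, seed = 99)
  for (i in 1:100) expect_true(all(g3()$mask %in% c(0, 1)))
})

test_that("task configurations carry the published hyperparameters", {
  cd <- train_config("detect_image")
  expect_equal(cd$epochs, 50L)
  expect_equal(cd$optimizer, "rmsprop")
  expect_equal(cd$learning_rate, 1e-4)
  cf <- train_config("detect_features")
  expect_equal(cf$epochs, 100L)
  expect_equal(cf$optimizer, "adam")
  c2 <- train_config("seg2d_unet")
  expect_equal(c2$epochs, 60L)
  expect_equal(c2$batch_size, 8L)
  expect_equal(c2$learning_rate, 1e-3)
  expect_equal(c2$loss, "hybrid")
  c3 <- train_config("seg3d_unetpp")
  expect_equal(c3$epochs, 50L)
  expect_equal(c3$learning_rate, 1e-4)
  expect_equal(c3$loss, "dice")
})

test_that("degenerate training sets are rejected", {
  recs <- tiny_detection_records(12)
  for (r in seq_along(recs)) recs[[r]]$label <- 1L
  expect_error(train_detection(recs, train_config("detect_image", seed = 1)),
               class = "brainseg_degenerate_data_error")

  s <- tiny_seg2d_samples(6)
  s$y[] <- 0
  expect_error(train_segmentation(s, train_config("seg2d_unet", seed = 1)),
               class = "brainseg_degenerate_data_error")
})

test_that("feature-mode detection trains end to end on separable phantoms", {
  recs <- tiny_detection_records(30, seed = 700)
  vecs <- lapply(recs, function(r)
    extract_all(r$image, name = r$name, label = r$label))
  f <- withr::local_tempfile(fileext = ".csv")
  tab <- write_feature_table(vecs, f)
  cfg <- train_config("detect_features", epochs = 30, seed = 2)
  fit <- train_detection(tab, cfg, input_mode = "features",
                         feature_block = "intensity")
  expect_s3_class(fit$model, "nn_model")
  expect_equal(nrow(fit$history), 30)
  expect_lt(tail(fit$history$train_loss, 1), fit$history$train_loss[1])
  expect_equal(nrow(fit$test$results), length(fit$split$test))
})

test_that("multimodal segmentation trains end to end with the Dice loss", {
  vol <- make_multimodal_phantom(
    phantom_spec(size = c(64, 64, 155), noise_sd = 4, seed = 31),
    tumor_slices = 70:120)
  pr <- prep_seg3d_training(vol)
  cfg <- train_config("seg3d_unet", epochs = 1, seed = 2,
                      width_multiplier = 0.0625)
  fit <- train_segmentation(list(x = pr$x, y = pr$y), cfg)
  expect_s3_class(fit$model, "nn_model")
  expect_identical(fit$model$graph$name, "unet_multimodal")
  expect_true(is.finite(fit$test$mean_dice))
  expect_equal(nrow(fit$history), 1)
  # prediction shape contract for the 4-channel input
  p <- nn_predict(fit$model, pr$x[, , , 1:2, drop = FALSE])
  expect_identical(dim(p), c(128L, 128L, 1L, 2L))
})
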