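# A small graph exercising every layer kind used by the 2-D networks;
# no dropout so the training-mode forward pass is deterministic.
tiny_graph <- function() {
  model_graph("tiny", list(
    brainseg:::layer("input", "in", shape = c(8L, 8L, 2L)),
    brainseg:::layer("conv", "c1", "in", filters = 3L, kernel = c(3L, 3L),
                     padding = "same", activation = "relu"),
    brainseg:::layer("maxpool", "p1", "c1", pool = 2L),
    brainseg:::layer("batchnorm", "bn1", "p1", momentum = 0.8),
    brainseg:::layer("tconv", "t1", "bn1", filters = 2L, kernel = c(3L, 3L),
                     stride = 2L),
    brainseg:::layer("concat", "cc", c("t1", "c1")),
    brainseg:::layer("conv", "c2", "cc", filters = 1L, kernel = c(1L, 1L),
                     padding = "same", activation = "sigmoid")))
}

test_that("analytic gradients match finite differences through all layers", {
  ns <- asNamespace("brainseg")
  set.seed(42)
  m <- nn_compile(tiny_graph(), seed = 7)
  x <- array(rnorm(8 * 8 * 2 * 3), c(8, 8, 2, 3))
  y <- array((runif(8 * 8 * 3) > 0.5) * 1, c(8, 8, 1, 3))
  lf <- ns$loss_fn("hybrid")
  lossfun <- function(model) {
    fw <- ns$nn_forward(model, x, training = TRUE)
    lf(fw$out, y)$value
  }
  fw <- ns$nn_forward(m, x, training = TRUE)
  lv <- lf(fw$out, y)
  g <- lv$grad; dim(g) <- dim(fw$out)
  pg <- ns$nn_backward(m, fw, g)
  eps <- 5e-4
  for (lnm in names(pg)) for (pnm in names(pg[[lnm]])) {
    if (pnm %in% c("mmean", "mvar")) next
    garr <- pg[[lnm]][[pnm]]
    for (i in sample(length(garr), min(4, length(garr)))) {
      m2 <- m; m2$weights[[lnm]][[pnm]][i] <- m2$weights[[lnm]][[pnm]][i] + eps
      m3 <- m; m3$weights[[lnm]][[pnm]][i] <- m3$weights[[lnm]][[pnm]][i] - eps
      num <- (lossfun(m2) - lossfun(m3)) / (2 * eps)
      expect_lt(abs(num - garr[i]) / max(1e-4, abs(num) + abs(garr[i])),
                5e-3)
    }
  }
})

test_that("loss functions satisfy their closed-form identities", {
  # perfect overlap and empty-empty conventions
  expect_equal(dice_loss(array(1, c(4, 4)), array(1, c(4, 4))), 0,
               tolerance = 1e-12)
  expect_equal(dice_loss(array(0, c(4, 4)), array(0, c(4, 4))), 0)
  # pred all 1 on a half-covered raster: 1 - (2(N/2)+1)/(N + N/2 + 1)
  for (n in c(4, 16, 64)) {
    t <- c(rep(1, n / 2), rep(0, n / 2))
    expect_equal(dice_loss(rep(1, n), t),
                 1 - (2 * (n / 2) + 1) / (n + n / 2 + 1), tolerance = 1e-12)
  }
  # BCE closed form: constant 0.5 prediction on all-ones truth is ln 2
  p <- array(0.5, c(3, 3)); t <- array(1, c(3, 3))
  expect_equal(hybrid_loss(p, t) - 0.5 * dice_loss(p, t), 0.5 * log(2),
               tolerance = 1e-12)
  # hybrid decomposes into its two halves on random rasters
  set.seed(8)
  for (i in 1:10) {
    p <- array(runif(36, 0.01, 0.99), c(6, 6))
    t <- array((runif(36) > 0.5) * 1, c(6, 6))
    bce <- -mean(t * log(p) + (1 - t) * log(1 - p))
    expect_equal(hybrid_loss(p, t), 0.5 * dice_loss(p, t) + 0.5 * bce,
                 tolerance = 1e-9)
  }
  # perfect binary prediction scores (near) zero under clipping
  t <- array((runif(64) > 0.5) * 1, c(8, 8))
  expect_lt(hybrid_loss(t * (1 - 1e-7) + (1 - t) * 1e-7, t), 1e-5)
  expect_error(dice_loss(array(1, c(2, 2)), array(1, c(3, 3))),
               class = "brainseg_shape_error")
})

test_that("every architecture maps a zero input into finite [0,1] output", {
  for (g in list(build_detection_cnn(), build_feature_cnn(4),
                 build_unet2d(0.125), build_unetpp2d(0.125),
                 build_unet_multimodal(0.125),
                 build_unetpp_multimodal(0.125))) {
    m <- nn_compile(g, seed = 2)
    in_shape <- m$shapes[["in"]]
    x <- array(0, c(in_shape, 1))
    p <- nn_predict(m, x)
    expect_true(all(is.finite(p)))
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("checkpoints round-trip to identical predictions", {
  m <- nn_compile(build_feature_cnn(6), seed = 3)
  x <- array(rnorm(6 * 1 * 5), c(6, 1, 5))
  f <- withr::local_tempfile(fileext = ".rds")
  nn_save(m, f)
  m2 <- nn_load(f)
  expect_identical(nn_predict(m, x), nn_predict(m2, x))
})

test_that("compilation is seed-deterministic and seed-sensitive", {
  g <- build_feature_cnn(4)
  expect_identical(nn_compile(g, seed = 5)$weights,
                   nn_compile(g, seed = 5)$weights)
  expect_false(identical(nn_compile(g, seed = 5)$weights$conv1$W,
                         nn_compile(g, seed = 6)$weights$conv1$W))
})

test_that("a short fit reduces the training loss on separable data", {
  set.seed(1)
  n <- 24
  # class means 0 vs 3 on all six features
  x <- array(0, c(6, 1, n))
  y <- matrix(rep(c(0, 1), n / 2), nrow = 1)
  for (i in seq_len(n)) x[, 1, i] <- rnorm(6, mean = 3 * y[1, i])
  m <- nn_compile(build_feature_cnn(6), seed = 4)
  fit <- nn_fit(m, x, y, epochs = 30, batch_size = 8, optimizer = "adam",
                lr = 1e-2, loss = "bce", seed = 4, metric = "accuracy")
  expect_lt(tail(fit$history$train_loss, 1), fit$history$train_loss[1])
})
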