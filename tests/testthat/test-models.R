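test_that("parameter bookkeeping primitives are exact", {
  g <- model_graph("d", list(
    brainseg:::layer("input", "in", shape = c(10L)),
    brainseg:::layer("dense", "out", "in", units = 1L)))
  expect_equal(count_parameters(g)$total, 11)

  g2 <- model_graph("c", list(
    brainseg:::layer("input", "in", shape = c(64L, 64L, 3L)),
    brainseg:::layer("conv", "c", "in", filters = 32L, kernel = c(8L, 8L),
                     padding = "valid", activation = "relu")))
  expect_equal(count_parameters(g2)$total, 32 * (64 * 3 + 1))

  g3 <- model_graph("b", list(
    brainseg:::layer("input", "in", shape = c(8L, 8L, 64L)),
    brainseg:::layer("batchnorm", "bn", "in", momentum = 0.8)))
  pc <- count_parameters(g3)
  expect_equal(pc$total, 256)
  expect_equal(pc$non_trainable, 128)
  expect_equal(pc$total, pc$trainable + pc$non_trainable)
})

test_that("detection CNN reproduces its published audit and shape trace", {
  g <- build_detection_cnn()
  pc <- count_parameters(g)
  expect_identical(pc$total, 352609)
  expect_identical(pc$non_trainable, 0)
  s <- infer_shapes(g)
  expect_identical(s$conv1, c(249L, 249L, 32L))
  expect_identical(s$pool1, c(124L, 124L, 32L))
  expect_identical(s$conv2, c(117L, 117L, 64L))
  expect_identical(s$pool2, c(58L, 58L, 64L))
  expect_identical(s$flat, 215296L)
})

test_that("feature CNN audits to 2,817 parameters at 4 inputs", {
  g <- build_feature_cnn(4)
  expect_identical(count_parameters(g)$total, 2817)
  s <- infer_shapes(g)
  expect_identical(s$conv1, c(3L, 64L))
  expect_identical(s$flat, 16L)
  # valid kernel-2 convolution shortens any input by one
  for (k in c(2, 7, 42))
    expect_identical(infer_shapes(build_feature_cnn(k))$conv1[1],
                     as.integer(k - 1))
  expect_error(build_feature_cnn(1), class = "brainseg_shape_error")
})

test_that("2D U-Net audits to its published totals", {
  g <- build_unet2d()
  pc <- count_parameters(g)
  expect_identical(pc$total, 22718529)
  expect_identical(pc$non_trainable, 1920)
  s <- infer_shapes(g)
  expect_identical(s$enc4_pool, c(8L, 8L, 512L))
  expect_identical(s$bridge_conv2, c(8L, 8L, 512L))
  expect_identical(s$dec1_cat, c(16L, 16L, 1024L))
  expect_identical(s$out, c(128L, 128L, 1L))
})

test_that("2D U-Net++ audits to its published totals and concat widths", {
  g <- build_unetpp2d()
  pc <- count_parameters(g)
  expect_identical(pc$total, 22498881)
  expect_identical(pc$non_trainable, 1920)
  s <- infer_shapes(g)
  expect_identical(s$cat02[3], 256L)
  expect_identical(s$cat31[3], 768L)
  expect_identical(s$cat22[3], 768L)
  expect_identical(s$cat13[3], 512L)
  expect_identical(s$cat04[3], 320L)
  expect_identical(s$head_cat, c(128L, 128L, 256L))
  expect_identical(s$out, c(128L, 128L, 1L))
})

test_that("multimodal U-Net audits to its published totals", {
  g <- build_unet_multimodal()
  pc <- count_parameters(g)
  expect_identical(pc$total, 31055873)
  expect_identical(pc$non_trainable, 11776)
  s <- infer_shapes(g)
  expect_identical(s$bridge_bn2, c(8L, 8L, 1024L))
  expect_identical(s[["in"]], c(128L, 128L, 4L))
  expect_identical(s$out, c(128L, 128L, 1L))
})

test_that("multimodal U-Net++ matches its table shapes and encoder audit", {
  g <- build_unetpp_multimodal()
  s <- infer_shapes(g)
  expect_identical(s[["in"]], c(128L, 128L, 4L))
  expect_identical(s$out, c(128L, 128L, 1L))
  # encoder batch-norm bookkeeping: non-trainable = 2 * (64+128+256+512)
  expect_identical(count_parameters(g)$non_trainable, 2L * (64 + 128 + 256 + 512))
})

test_that("width multiplier 1.0 is the identity and scaling shrinks audits", {
  expect_identical(count_parameters(build_unet2d(1.0))$total,
                   count_parameters(build_unet2d())$total)
  expect_lt(count_parameters(build_unet2d(0.25))$total,
            count_parameters(build_unet2d())$total / 10)
  expect_identical(count_parameters(build_detection_cnn(1.0))$total, 352609)
})

test_that("graph validation rejects broken wiring", {
  expect_error(model_graph("bad", list(
    brainseg:::layer("input", "in", shape = c(8L, 8L, 1L)),
    brainseg:::layer("conv", "c", "nope", filters = 1L, kernel = c(3L, 3L),
                     padding = "same"))), class = "brainseg_spec_error")
  # concat of mismatched spatial dims
  expect_error(model_graph("bad2", list(
    brainseg:::layer("input", "in", shape = c(8L, 8L, 1L)),
    brainseg:::layer("maxpool", "p", "in", pool = 2L),
    brainseg:::layer("concat", "cc", c("in", "p")))),
    class = "brainseg_shape_error")
})

test_that("model summaries export per-layer audits as JSON", {
  g <- build_feature_cnn(4)
  js <- jsonlite::fromJSON(model_graph_summary(g))
  expect_equal(js$parameters$total, 2817)
  expect_equal(sum(js$layers$parameters), 2817)
  expect_equal(nrow(js$layers), length(g$layers))
})
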