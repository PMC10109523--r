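test_that("detection applies the strict 0.5 decision rule", {
  for (p in c(0.7, 0.2, 0.5)) {
    m <- constant_prob_model(p)
    r <- detect(m, rnorm(4))
    expect_equal(r$probability, p, tolerance = 1e-6)
    expect_identical(r$label, as.integer(r$probability > 0.5))
  }
  expect_identical(detect(constant_prob_model(0.5), rnorm(4))$label, 0L)
  expect_error(detect(constant_prob_model(0.5, 4), rnorm(7)),
               class = "brainseg_shape_error")
})

test_that("accuracy is the plain fraction of matches", {
  expect_equal(accuracy(c(1, 1, 0, 0, 1, 0, 1, 1, 0, 1),
                        c(1, 1, 0, 0, 1, 0, 1, 0, 1, 0)), 0.7)
  expect_equal(accuracy(1:5, 1:5), 1)
  expect_equal(accuracy(c(0, 1, 0), c(1, 0, 1)), 0)
  set.seed(13)
  for (i in 1:20) {
    t <- sample(0:1, 50, TRUE); p <- sample(0:1, 50, TRUE)
    expect_equal(accuracy(t, p), sum(t == p) / 50)
  }
  expect_error(accuracy(integer(0), integer(0)),
               class = "brainseg_size_error")
  expect_error(accuracy(c(1, 0), c(1)), class = "brainseg_size_error")
})

test_that("dice_score equals the set formula on sampled 3x3 mask pairs", {
  set.seed(31)
  for (i in 1:500) {
    P <- matrix(sample(0:1, 9, TRUE), 3, 3)
    Q <- matrix(sample(0:1, 9, TRUE), 3, 3)
    denom <- sum(P) + sum(Q)
    want <- if (denom == 0) 1 else 2 * sum(P & Q) / denom
    expect_equal(dice_score(P, Q), want, tolerance = 1e-15)
  }
  # symmetry and permutation invariance
  set.seed(2)
  P <- matrix(sample(0:1, 64, TRUE), 8, 8)
  Q <- matrix(sample(0:1, 64, TRUE), 8, 8)
  expect_equal(dice_score(P, Q), dice_score(Q, P))
  perm <- sample(64)
  expect_equal(dice_score(P, Q),
               dice_score(matrix(P[perm], 8, 8), matrix(Q[perm], 8, 8)))
  expect_error(dice_score(P, matrix(0, 4, 4)),
               class = "brainseg_shape_error")
})

test_that("segmentation post-processing derives area, ratio and confidence", {
  brain <- matrix(0, 40, 40)
  brain[6:35, 6:35] <- 100  # 900 brain pixels
  pm <- matrix(0, 40, 40)
  pm[10:14, 10:29] <- 0.9   # 100 positive pixels at probability 0.9
  r <- postprocess_segmentation(pm, brain)
  expect_identical(r$tumor_area, 100L)
  expect_equal(r$tumor_ratio, 100 / 900)
  expect_equal(r$confidence, 0.9)
  expect_identical(r$mask, (pm > 0.5) * 1)

  r0 <- postprocess_segmentation(matrix(0, 40, 40), brain)
  expect_identical(r0$tumor_area, 0L)
  expect_equal(r0$tumor_ratio, 0)
  expect_equal(r0$confidence, 0)

  # empty brain guard
  rb <- postprocess_segmentation(matrix(0.4, 8, 8), matrix(0, 8, 8))
  expect_equal(rb$tumor_ratio, 0)

  expect_error(postprocess_segmentation(matrix(0.5, 3, 3), matrix(0, 4, 4)),
               class = "brainseg_shape_error")
})

test_that("tumor area never exceeds brain area on contained phantoms", {
  for (seed in 1:5) {
    ph <- make_phantom2d(random_phantom_spec(size = c(96, 96), seed = seed))
    r <- postprocess_segmentation(ph$mask * 0.99, ph$image$pixels)
    expect_lte(r$tumor_area, sum(ph$image$pixels > 0.05 * max(ph$image$pixels)))
    expect_lte(r$tumor_ratio, 1)
  }
})

test_that("detection evaluation reports accuracy with one row per record", {
  m <- constant_prob_model(0.9)
  x <- array(rnorm(4 * 1 * 6), c(4, 1, 6))
  labels <- c(1, 1, 1, 0, 0, 0)
  ev <- evaluate_detection(m, x, labels)
  expect_equal(ev$accuracy, 0.5)  # constant tumor vote on a balanced set
  expect_equal(nrow(ev$results), 6)
  expect_true(all(ev$results$prediction == 1))
  expect_error(evaluate_detection(m, x, labels[1:3]),
               class = "brainseg_size_error")
})

test_that("segmentation evaluation averages per-sample Dice", {
  # rig a constant-probability segmentation net: zero conv weights with a
  # bias put every pixel on one side of the threshold
  g <- model_graph("flat", list(
    brainseg:::layer("input", "in", shape = c(16L, 16L, 1L)),
    brainseg:::layer("conv", "out", "in", filters = 1L, kernel = c(1L, 1L),
                     padding = "same", activation = "sigmoid")))
  m <- nn_compile(g, seed = 1)
  m$weights$out$W[] <- 0
  m$weights$out$b[] <- 4  # sigmoid(4) > 0.5 everywhere
  x <- array(runif(16 * 16 * 2), c(16, 16, 1, 2))
  masks <- array(1, c(16, 16, 1, 2))
  ev <- evaluate_segmentation(m, x, masks)
  expect_equal(ev$mean_dice, 1)
  m$weights$out$b[] <- -4  # all-background prediction
  ev0 <- evaluate_segmentation(m, x, masks)
  expect_equal(ev0$mean_dice, 0)
  expect_equal(mean(ev0$dice), ev0$mean_dice)
})
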