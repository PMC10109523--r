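# Shared fixture builders: everything is generated in code at test time.

# small labelled phantom set for detection-style tests
tiny_detection_records <- function(n = 12, size = c(96, 96), seed = 500) {
  lapply(seq_len(n), function(i) {
    ph <- make_phantom2d(phantom_spec(size = size, with_tumor = i %% 2 == 0,
                                      seed = seed + i))
    list(image = ph$image, label = ph$label,
         name = paste0(if (ph$label == 1) "Y" else "N", i, ".png"))
  })
}

# stacked 2-D segmentation tensors from n tumor phantoms
tiny_seg2d_samples <- function(n = 12, seed = 900) {
  xs <- vector("list", n); ys <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- make_phantom2d(phantom_spec(size = c(128, 128), with_tumor = TRUE,
                                      seed = seed + i))
    pr <- prep_seg2d_training(ph$image, ph$mask)
    xs[[i]] <- pr$x; ys[[i]] <- pr$y
  }
  list(x = brainseg:::stack4(xs), y = brainseg:::stack4(ys))
}

# a network whose output probability is a constant: zero weights, bias set
# to the logit of p (single dense sigmoid head over any input)
constant_prob_model <- function(p, n_features = 4) {
  m <- nn_compile(build_feature_cnn(n_features), seed = 1)
  for (nm in names(m$weights)) {
    m$weights[[nm]]$W[] <- 0
    m$weights[[nm]]$b[] <- 0
  }
  m$weights$out$b[] <- log(p / (1 - p))
  m
}

# brute-force co-occurrence oracle: count horizontal neighbour pairs both
# ways and normalize, then evaluate the six statistics directly over the
# full 256-level gray scale
oracle_glcm_features <- function(q, levels = 256) {
  H <- nrow(q); W <- ncol(q)
  P <- matrix(0, levels, levels)
  for (r in seq_len(H)) for (cc in seq_len(W - 1)) {
    a <- q[r, cc] + 1; b <- q[r, cc + 1] + 1
    P[a, b] <- P[a, b] + 1
    P[b, a] <- P[b, a] + 1
  }
  P <- P / sum(P)
  i <- row(P) - 1; j <- col(P) - 1
  mi <- sum(i * P); mj <- sum(j * P)
  si <- sqrt(sum((i - mi)^2 * P)); sj <- sqrt(sum((j - mj)^2 * P))
  c(contrast = sum(P * (i - j)^2),
    dissimilarity = sum(P * abs(i - j)),
    homogeneity = sum(P / (1 + (i - j)^2)),
    asm = sum(P^2),
    energy = sqrt(sum(P^2)),
    correlation = if (si > 0 && sj > 0)
      sum((i - mi) * (j - mj) * P) / (si * sj) else 1)
}

# spread L gray levels 0..L-1 onto the byte scale (distinct byte values)
spread_levels <- function(q, levels = 4) {
  round(q * 255 / (levels - 1))
}
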