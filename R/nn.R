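#' @title Seeded CPU training engine
#' @description The package trains its networks with a small built-in engine:
#'   every [model_graph()] compiles to a set of weight arrays, and training
#'   runs explicit forward/backward passes (im2col + BLAS gemm convolutions
#'   in compiled code, batch normalization / dropout / dense / concat in R).
#'   All randomness — weight initialization, shuffling, dropout masks,
#'   augmentation draws — flows from one seed, so runs are reproducible
#'   bit-for-bit on a fixed BLAS.
#' @name brainseg-engine
#' @keywords internal
NULL

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

conv_pads <- function(kernel, padding) {
  if (identical(padding, "same")) {
    ph0 <- (kernel[1] - 1L) %/% 2L
    pw0 <- (kernel[2] - 1L) %/% 2L
    c(ph0, kernel[1] - 1L - ph0, pw0, kernel[2] - 1L - pw0)
  } else c(0L, 0L, 0L, 0L)
}

glorot <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

#' Compile a model graph into a trainable network
#'
#' Allocates and initializes all weights (Glorot-uniform convolutions and
#' dense layers, unit-scale batch normalization) under the given seed. The
#' output layer's weights start at zero, so every network begins at
#' probability 0.5 everywhere: with unnormalized (byte-scale) inputs a
#' randomly initialized sigmoid head would start deeply saturated on half
#' the samples, which destabilizes the first optimizer steps.
#'
#' @param graph a [model_graph()].
#' @param seed integer seed for weight initialization.
#' @return An object of class `nn_model` holding the graph, inferred shapes
#'   and a named list of per-layer weight arrays.
#' @export
nn_compile <- function(graph, seed = 1L) {
  shapes <- infer_shapes(graph)
  weights <- with_seed(seed, {
    w <- list()
    for (ly in graph$layers) {
      if (length(ly$inbound) == 0) next
      inshp <- shapes[[ly$inbound[1]]]
      cin <- inshp[length(inshp)]
      w[[ly$name]] <- switch(ly$kind,
        conv = ,
        tconv = {
          k <- ly$kernel
          if (length(k) == 1L) k <- c(k, 1L)  # 1-D conv as (k,1)
          list(W = glorot(c(k[1], k[2], cin, ly$filters),
                          prod(k) * cin, prod(k) * ly$filters),
               b = numeric(ly$filters))
        },
        dense = list(W = glorot(c(cin, ly$units), cin, ly$units),
                     b = numeric(ly$units)),
        batchnorm = list(gamma = rep(1, cin), beta = numeric(cin),
                         mmean = numeric(cin), mvar = rep(1, cin)),
        NULL)
    }
    # zero-init the output layer: training starts at p = 0.5 everywhere
    last <- names(graph$layers)[length(graph$layers)]
    if (!is.null(w[[last]]$W)) w[[last]]$W[] <- 0
    w
  })
  # consumers: which layers read each layer's output (for gradient fan-in)
  consumers <- stats::setNames(vector("list", length(graph$layers)),
                               names(graph$layers))
  for (ly in graph$layers)
    for (nm in ly$inbound) consumers[[nm]] <- c(consumers[[nm]], ly$name)
  structure(list(graph = graph, shapes = shapes, weights = weights,
                 consumers = consumers),
            class = "nn_model")
}

#' @export
print.nn_model <- function(x, ...) {
  pc <- count_parameters(x$graph)
  cat(sprintf("<nn_model> %s: %s parameters\n", x$graph$name,
              format(pc$total, big.mark = ",")))
  invisible(x)
}

act_code <- function(act) {
  switch(act %||% "linear", relu = 1L, sigmoid = 2L, 0L)
}

apply_act <- function(y, act) {
  switch(act %||% "linear",
         relu = { y[y < 0] <- 0; y },
         sigmoid = pmin(pmax(1 / (1 + exp(-y)), 1e-7), 1 - 1e-7),
         y)
}

# gradient through the activation given the *post-activation* output
act_grad <- function(g, y, act) {
  switch(act %||% "linear",
         relu = g * (y > 0),
         sigmoid = g * y * (1 - y),
         g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as4d <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d[1], 1L, d[2], d[3])  # (L,C,N) -> (L,1,C,N)
  x
}

# ---- per-layer forward -------------------------------------------------

nn_forward_layer <- function(ly, w, inputs, training) {
  cache <- NULL
  y <- switch(ly$kind,
    input = inputs[[1]],
    conv = {
      x <- as4d(inputs[[1]])
      k <- dim(w$W)[1:2]
      cpp_conv_fwd(x, w$W, w$b, conv_pads(k, ly$padding %||% "valid"),
                   act_code(ly$activation))
    },
    tconv = {
      x <- as4d(inputs[[1]])
      cpp_tconv_fwd(x, w$W, w$b, as.integer(ly$stride),
                    act_code(ly$activation))
    },
    maxpool = {
      x <- as4d(inputs[[1]])
      d <- dim(x)
      if (d[2] == 1L) {  # 1-D pooling over the length axis
        OH <- d[1] %/% ly$pool
        keep <- seq_len(OH * ly$pool)  # trailing remainder is dropped
        xr <- array(x[keep, 1, , , drop = FALSE],
                    c(ly$pool, OH, d[3], d[4]))
        y <- apply(xr, 2:4, max)
        cache <- list(xr = xr, OH = OH, d = d)
        dim(y) <- c(OH, 1L, d[3], d[4])
        y
      } else {
        r <- cpp_maxpool_fwd(x, as.integer(ly$pool))
        cache <- list(idx = r$idx, xdim = dim(x))
        r$y
      }
    },
    batchnorm = {
      x <- as4d(inputs[[1]])
      d <- dim(x)
      C <- d[3]; m <- prod(d) / C
      xp <- aperm(x, c(1, 2, 4, 3))
      dim(xp) <- c(m, C)
      if (training) {
        mu <- colMeans(xp)
        xc <- xp - rep(mu, each = m)
        v <- colMeans(xc * xc)
        w$mmean <- ly$momentum * w$mmean + (1 - ly$momentum) * mu
        w$mvar <- ly$momentum * w$mvar + (1 - ly$momentum) * v
      } else {
        mu <- w$mmean; v <- w$mvar
        xc <- xp - rep(mu, each = m)
      }
      istd <- 1 / sqrt(v + 1e-5)
      xhat <- xc * rep(istd, each = m)
      yp <- xhat * rep(w$gamma, each = m) + rep(w$beta, each = m)
      if (training) cache <- list(xhat = xhat, istd = istd, d = d, m = m)
      dim(yp) <- c(d[1], d[2], d[4], d[3])
      aperm(yp, c(1, 2, 4, 3))
    },
    dropout = {
      x <- inputs[[1]]
      if (training && ly$rate > 0) {
        r <- cpp_dropout_fwd(x, ly$rate)
        cache <- list(mask = r$mask, rate = ly$rate)
        r$y
      } else x
    },
    activation = apply_act(inputs[[1]], ly$activation),
    flatten = {
      x <- inputs[[1]]
      d <- dim(x)
      n <- d[length(d)]
      dim(x) <- c(prod(d) / n, n)
      x
    },
    dense = {
      x <- inputs[[1]]
      if (is.matrix(x)) {
        y <- crossprod(w$W, x) + w$b
        apply_act(y, ly$activation)
      } else {  # positional dense over the channel axis of (L,1,C,N)
        x <- as4d(x)
        d <- dim(x)
        xp <- aperm(x, c(1, 2, 4, 3))
        dim(xp) <- c(d[1] * d[2] * d[4], d[3])
        yp <- xp %*% w$W + rep(w$b, each = nrow(xp))
        dim(yp) <- c(d[1], d[2], d[4], ly$units)
        apply_act(aperm(yp, c(1, 2, 4, 3)), ly$activation)
      }
    },
    concat = {
      xs <- lapply(inputs, as4d)
      cs <- vapply(xs, function(a) dim(a)[3], 0L)
      cache <- list(cs = cs)
      cpp_concat4(xs)
    },
    stop_spec(sprintf("unknown layer kind '%s'", ly$kind)))
  list(y = y, cache = cache, w = w)
}

# ---- per-layer backward ------------------------------------------------
# Returns list(dins = list of gradients w.r.t. each inbound, dw = param grads)

nn_backward_layer <- function(ly, w, inputs, y, cache, g, need_dx = TRUE) {
  switch(ly$kind,
    conv = {
      x <- as4d(inputs[[1]])
      k <- dim(w$W)[1:2]
      r <- cpp_conv_bwd(x, w$W, g, y, conv_pads(k, ly$padding %||% "valid"),
                        act_code(ly$activation), need_dx)
      dx <- r$dx
      if (need_dx && length(dim(inputs[[1]])) == 3L) dim(dx) <- dim(inputs[[1]])
      list(dins = list(if (need_dx) dx else NULL),
           dw = list(W = r$dw, b = r$db))
    },
    tconv = {
      x <- as4d(inputs[[1]])
      r <- cpp_tconv_bwd(x, w$W, g, y, as.integer(ly$stride),
                         act_code(ly$activation))
      list(dins = list(r$dx), dw = list(W = r$dw, b = r$db))
    },
    maxpool = {
      if (!is.null(cache$idx)) {
        list(dins = list(cpp_maxpool_bwd(cache$idx, g, cache$xdim)), dw = NULL)
      } else {  # 1-D pooling backward: route to argmax within each window
        xr <- cache$xr; d <- cache$d; OH <- cache$OH
        pool <- d[1] %/% OH
        dxr <- array(0, dim(xr))
        gm <- array(g, c(OH, d[3], d[4]))
        am <- apply(xr, 2:4, which.max)
        for (i in seq_len(OH)) for (c3 in seq_len(d[3])) for (n in seq_len(d[4]))
          dxr[am[i, c3, n], i, c3, n] <- gm[i, c3, n]
        dx <- array(0, d)
        dx[seq_len(OH * dim(xr)[1]), 1, , ] <-
          array(dxr, c(OH * dim(xr)[1], 1, d[3], d[4]))
        if (length(dim(inputs[[1]])) == 3L) dim(dx) <- dim(inputs[[1]])
        list(dins = list(dx), dw = NULL)
      }
    },
    batchnorm = {
      d <- cache$d; m <- cache$m; C <- d[3]
      gp <- aperm(as4d(g), c(1, 2, 4, 3))
      dim(gp) <- c(m, C)
      xhat <- cache$xhat
      dgamma <- colSums(gp * xhat)
      dbeta <- colSums(gp)
      dxhat <- gp * rep(w$gamma, each = m)
      t1 <- colSums(dxhat)
      t2 <- colSums(dxhat * xhat)
      dxp <- (dxhat - rep(t1 / m, each = m) - xhat * rep(t2 / m, each = m)) *
        rep(cache$istd, each = m)
      dim(dxp) <- c(d[1], d[2], d[4], d[3])
      dx <- aperm(dxp, c(1, 2, 4, 3))
      if (length(dim(inputs[[1]])) == 3L) dim(dx) <- dim(inputs[[1]])
      list(dins = list(dx),
           dw = list(gamma = dgamma, beta = dbeta, mmean = 0, mvar = 0))
    },
    dropout = {
      dx <- if (is.null(cache$mask)) g
            else cpp_dropout_bwd(g, cache$mask, cache$rate)
      list(dins = list(dx), dw = NULL)
    },
    activation = list(dins = list(act_grad(g, y, ly$activation)), dw = NULL),
    flatten = {
      dx <- g
      dim(dx) <- dim(inputs[[1]])
      list(dins = list(dx), dw = NULL)
    },
    dense = {
      g <- act_grad(g, y, ly$activation)
      x <- inputs[[1]]
      if (is.matrix(x)) {
        list(dins = list(w$W %*% g),
             dw = list(W = tcrossprod(x, g), b = rowSums(g)))
      } else {
        x4 <- as4d(x); d <- dim(x4)
        xp <- aperm(x4, c(1, 2, 4, 3)); dim(xp) <- c(d[1] * d[2] * d[4], d[3])
        gp <- aperm(as4d(g), c(1, 2, 4, 3))
        dim(gp) <- c(d[1] * d[2] * d[4], ly$units)
        dxp <- gp %*% t(w$W)
        dim(dxp) <- c(d[1], d[2], d[4], d[3])
        dx <- aperm(dxp, c(1, 2, 4, 3))
        if (length(dim(x)) == 3L) dim(dx) <- dim(x)
        list(dins = list(dx),
             dw = list(W = crossprod(xp, gp), b = colSums(gp)))
      }
    },
    concat = {
      list(dins = cpp_split4(as4d(g), cache$cs), dw = NULL)
    },
    list(dins = list(NULL), dw = NULL))
}

# Full forward pass. Returns the output; with training=TRUE also all layer
# activations and caches (and applies dropout + batch statistics, updating
# the moving averages in place on the returned model).
nn_forward <- function(model, x, training = FALSE) {
  acts <- list(); caches <- list()
  for (ly in model$graph$layers) {
    inputs <- if (ly$kind == "input") list(x)
              else lapply(ly$inbound, function(nm) acts[[nm]])
    w <- model$weights[[ly$name]]
    r <- nn_forward_layer(ly, w, inputs, training)
    if (!is.null(w)) model$weights[[ly$name]] <- r$w
    acts[[ly$name]] <- r$y
    caches[[ly$name]] <- r$cache
  }
  out_name <- names(model$graph$layers)[length(model$graph$layers)]
  list(out = acts[[out_name]], acts = acts, caches = caches, model = model)
}

# Backward pass from the gradient of the loss w.r.t. the network output.
nn_backward <- function(model, fw, dout) {
  lys <- model$graph$layers
  grads <- list(); pgrads <- list()
  grads[[names(lys)[length(lys)]]] <- dout
  for (i in rev(seq_along(lys))) {
    ly <- lys[[i]]
    g <- grads[[ly$name]]
    if (is.null(g) || ly$kind == "input") next
    inputs <- lapply(ly$inbound, function(nm) fw$acts[[nm]])
    need_dx <- !identical(lys[[ly$inbound[1]]]$kind, "input")
    r <- nn_backward_layer(ly, model$weights[[ly$name]], inputs,
                           fw$acts[[ly$name]], fw$caches[[ly$name]], g,
                           need_dx)
    if (!is.null(r$dw)) pgrads[[ly$name]] <- r$dw
    for (j in seq_along(ly$inbound)) {
      nm <- ly$inbound[j]
      di <- r$dins[[j]]
      if (is.null(di)) next
      tgt <- fw$acts[[nm]]
      if (!is.null(dim(tgt)) && !identical(dim(di), dim(tgt)))
        dim(di) <- dim(tgt)
      grads[[nm]] <- if (is.null(grads[[nm]])) di else grads[[nm]] + di
    }
  }
  pgrads
}

# ---- losses ------------------------------------------------------------

#' Soft Dice loss
#'
#' `1 - (2 * sum(pred * truth) + 1) / (sum(pred) + sum(truth) + 1)`, the
#' smoothed complement of the Dice coefficient evaluated over the whole
#' raster (or batch). The unit smoothing constant makes the empty-vs-empty
#' case a perfect score instead of 0/0.
#'
#' @param pred probability raster in `[0,1]`.
#' @param truth binary mask of the same shape.
#' @return scalar loss in `[0,1)`.
#' @export
dice_loss <- function(pred, truth) {
  if (!identical(dim(pred) %||% length(pred), dim(truth) %||% length(truth)))
    stop_shape("dice_loss: prediction and truth shapes differ")
  1 - (2 * sum(pred * truth) + 1) / (sum(pred) + sum(truth) + 1)
}

bce_value <- function(pred, truth) {
  p <- pmin(pmax(pred, 1e-7), 1 - 1e-7)
  -mean(truth * log(p) + (1 - truth) * log(1 - p))
}

#' Hybrid Dice + binary cross-entropy loss
#'
#' Equal-weight sum `0.5 * dice_loss + 0.5 * BCE`, where the cross-entropy
#' is the pixel-mean with probabilities clipped to `[1e-7, 1 - 1e-7]`. Used
#' for the 2D segmentation models.
#'
#' @inheritParams dice_loss
#' @return scalar loss.
#' @export
hybrid_loss <- function(pred, truth) {
  if (!identical(dim(pred) %||% length(pred), dim(truth) %||% length(truth)))
    stop_shape("hybrid_loss: prediction and truth shapes differ")
  0.5 * dice_loss(pred, truth) + 0.5 * bce_value(pred, truth)
}

# value + gradient pairs used by the trainer
loss_fn <- function(name) {
  switch(name,
    bce = function(p, t) {
      pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
      # Written so that composing with the sigmoid derivative p(1-p) of a
      # clamped output layer yields exactly (p - t)/N, the logit-space
      # form: a saturated sigmoid still receives a full-strength error
      # signal instead of a clipped-to-zero one.
      list(value = -mean(t * log(pc) + (1 - t) * log(1 - pc)),
           grad = (pc - t) / (pc * (1 - pc)) / length(p))
    },
    dice = function(p, t) {
      num <- 2 * sum(p * t) + 1
      den <- sum(p) + sum(t) + 1
      list(value = 1 - num / den, grad = num / den^2 - 2 * t / den)
    },
    hybrid = {
      fd <- loss_fn("dice"); fb <- loss_fn("bce")
      function(p, t) {
        d <- fd(p, t); b <- fb(p, t)
        list(value = 0.5 * d$value + 0.5 * b$value,
             grad = 0.5 * d$grad + 0.5 * b$grad)
      }
    },
    stop_spec(sprintf("unknown loss '%s'", name)))
}

# ---- optimizers --------------------------------------------------------

make_optimizer <- function(name, lr) {
  state <- list()
  step <- 0
  if (name == "adam") {
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-7
    function(weights, grads) {
      step <<- step + 1
      for (lnm in names(grads)) for (pnm in names(grads[[lnm]])) {
        if (pnm %in% c("mmean", "mvar")) next
        g <- grads[[lnm]][[pnm]]
        key <- paste0(lnm, ".", pnm)
        if (is.null(state[[key]]))
          state[[key]] <<- list(m = 0 * g, v = 0 * g)
        s <- state[[key]]
        s$m <- b1 * s$m + (1 - b1) * g
        s$v <- b2 * s$v + (1 - b2) * g * g
        state[[key]] <<- s
        mh <- s$m / (1 - b1^step)
        vh <- s$v / (1 - b2^step)
        weights[[lnm]][[pnm]] <- weights[[lnm]][[pnm]] -
          lr * mh / (sqrt(vh) + eps)
      }
      weights
    }
  } else if (name == "rmsprop") {
    rho <- 0.9; eps <- 1e-7
    function(weights, grads) {
      step <<- step + 1
      for (lnm in names(grads)) for (pnm in names(grads[[lnm]])) {
        if (pnm %in% c("mmean", "mvar")) next
        g <- grads[[lnm]][[pnm]]
        key <- paste0(lnm, ".", pnm)
        if (is.null(state[[key]])) state[[key]] <<- 0 * g
        state[[key]] <<- rho * state[[key]] + (1 - rho) * g * g
        weights[[lnm]][[pnm]] <- weights[[lnm]][[pnm]] -
          lr * g / (sqrt(state[[key]]) + eps)
      }
      weights
    }
  } else stop_spec(sprintf("unknown optimizer '%s'", name))
}

# ---- fit / predict -----------------------------------------------------

# Scale the whole gradient set so its global L2 norm is at most `maxnorm`.
clip_global_norm <- function(grads, maxnorm) {
  ss <- 0
  for (l in grads) for (gname in c("W", "b", "gamma", "beta"))
    if (!is.null(l[[gname]])) ss <- ss + sum(l[[gname]]^2)
  nrm <- sqrt(ss)
  if (!is.finite(nrm) || nrm <= maxnorm) return(grads)
  sc <- maxnorm / nrm
  for (lnm in names(grads)) for (gname in c("W", "b", "gamma", "beta"))
    if (!is.null(grads[[lnm]][[gname]]))
      grads[[lnm]][[gname]] <- grads[[lnm]][[gname]] * sc
  grads
}

batch_slice <- function(x, ix) {
  d <- dim(x)
  if (length(d) == 2L) x[, ix, drop = FALSE]
  else if (length(d) == 3L) x[, , ix, drop = FALSE]
  else x[, , , ix, drop = FALSE]
}

#' Train a compiled network
#'
#' Plain minibatch SGD loop: shuffle per epoch, optional on-the-fly
#' augmentation, forward/backward, optimizer update; after each epoch the
#' validation set (if given) is scored with the loss and the task metric.
#' All randomness is governed by `seed`.
#'
#' @param model an [nn_compile()]d network.
#' @param x input array with the batch as last dimension.
#' @param y target array (matching spatial shape for segmentation, a
#'   `1 x N` matrix of 0/1 labels for detection).
#' @param epochs,batch_size training budget.
#' @param optimizer `"adam"` or `"rmsprop"`.
#' @param lr learning rate.
#' @param loss `"bce"`, `"dice"` or `"hybrid"`.
#' @param seed integer; fixes shuffling, dropout and augmentation.
#' @param validation optional `list(x =, y =)` scored after each epoch.
#' @param metric `"accuracy"` or `"dice"` for the validation metric.
#' @param augment optional `function(xb, yb)` returning a perturbed
#'   `list(x, y)`; draws from the governing RNG stream.
#' @param clipnorm global gradient-norm ceiling applied before each update
#'   (an engine numerical safeguard: architectures without decoder
#'   normalization can enter high-gain regimes on easy data where raw
#'   updates destabilize training); `Inf` disables.
#' @param verbose print per-epoch progress.
#' @return `list(model, history)`; history is a data frame with one row per
#'   epoch (`epoch`, `train_loss`, `val_loss`, `val_metric`).
#' @export
nn_fit <- function(model, x, y, epochs, batch_size = 8L,
                   optimizer = "adam", lr = 1e-3, loss = "bce", seed = 1L,
                   validation = NULL, metric = c("dice", "accuracy"),
                   augment = NULL, clipnorm = 5, verbose = FALSE) {
  metric <- match.arg(metric)
  lf <- loss_fn(loss)
  opt <- make_optimizer(optimizer, lr)
  dN <- dim(x)
  N <- dN[length(dN)]
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), val_metric = numeric())
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      perm <- sample.int(N)
      losses <- c()
      for (start in seq(1, N, by = batch_size)) {
        ix <- perm[start:min(start + batch_size - 1, N)]
        xb <- batch_slice(x, ix); yb <- batch_slice(y, ix)
        if (!is.null(augment)) {
          ab <- augment(xb, yb)
          xb <- ab$x; yb <- ab$y
        }
        fw <- nn_forward(model, xb, training = TRUE)
        model <- fw$model  # batchnorm moving statistics advanced
        lv <- lf(fw$out, yb)
        g <- lv$grad
        dim(g) <- dim(fw$out)
        pg <- nn_backward(model, fw, g)
        if (is.finite(clipnorm)) pg <- clip_global_norm(pg, clipnorm)
        model$weights <- opt(model$weights, pg)
        losses <- c(losses, lv$value)
      }
      vl <- NA_real_; vm <- NA_real_
      if (!is.null(validation)) {
        pv <- nn_predict(model, validation$x, batch_size)
        vl <- lf(pv, validation$y)$value
        vm <- if (metric == "accuracy") {
          mean((pv > 0.5) == (validation$y > 0.5))
        } else {
          dv <- dim(validation$y)
          nv <- dv[length(dv)]
          mean(vapply(seq_len(nv), function(i) {
            dice_score(batch_slice(pv, i) > 0.5, batch_slice(validation$y, i) > 0.5)
          }, 0))
        }
      }
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = mean(losses),
                                     val_loss = vl, val_metric = vm))
      if (verbose)
        message(sprintf("epoch %d/%d  loss %.4f  val_loss %.4f  val_%s %.4f",
                        ep, epochs, mean(losses), vl, metric, vm))
    }
  })
  list(model = model, history = hist)
}

#' Predict with a trained network (inference mode)
#'
#' @param model an `nn_model`.
#' @param x input array, batch last.
#' @param batch_size chunk size.
#' @return output array with the same batch dimension.
#' @export
nn_predict <- function(model, x, batch_size = 8L) {
  d <- dim(x)
  N <- d[length(d)]
  outs <- NULL
  for (start in seq(1, N, by = batch_size)) {
    ix <- start:min(start + batch_size - 1, N)
    o <- nn_forward(model, batch_slice(x, ix), training = FALSE)$out
    outs <- if (is.null(outs)) list(o) else c(outs, list(o))
  }
  od <- dim(outs[[1]])
  k <- length(od)
  tot <- sum(vapply(outs, function(o) dim(o)[k], 0))
  res <- array(0, c(od[-k], tot))
  off <- 0L
  for (o in outs) {
    nn <- dim(o)[k]
    if (k == 2L) res[, off + seq_len(nn)] <- o
    else if (k == 3L) res[, , off + seq_len(nn)] <- o
    else res[, , , off + seq_len(nn)] <- o
    off <- off + nn
  }
  res
}

#' Save / load a trained network
#'
#' Checkpoints hold the graph and all weight arrays (including batch-norm
#' moving statistics) in R's native serialization.
#'
#' @param model an `nn_model`.
#' @param path checkpoint file.
#' @return `nn_save` returns `path` invisibly; `nn_load` returns the model.
#' @export
nn_save <- function(model, path) {
  saveRDS(list(graph = model$graph, weights = model$weights), path)
  invisible(path)
}

#' @rdname nn_save
#' @export
nn_load <- function(path) {
  obj <- readRDS(path)
  m <- nn_compile(obj$graph, seed = 0L)
  m$weights <- obj$weights
  m
}
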