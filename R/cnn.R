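#' Specification of the two-tower convolutional network
#'
#' One subnetwork (tower) per input image -- e.g. a cell-line expression
#' image paired with a drug descriptor image. Each tower stacks three
#' convolution layers with square kernels, each followed by batch
#' normalization, ReLU and 2 x 2 max pooling (valid padding throughout).
#' The tower outputs are flattened, concatenated and passed through a fully
#' connected head ending in a single regression output (e.g. the area under
#' the dose-response curve), with dropout between the dense layers.
#'
#' The default widths (towers 32-64-64 filters, head 1000-385-256-1) are the
#' configuration whose trainable-parameter count is 1,307,218 for two
#' 50 x 50 inputs at convolution stride 1 and 2,715,218 for 227 x 387 and
#' 380 x 387 inputs at stride 2; [count_trainable_parameters] is the guard
#' on that reading. All widths are configurable.
#'
#' @param input_shapes list of two integer pairs c(rows, cols), one per
#'   tower input image (single channel each).
#' @param conv_filters integer vector of filter counts, one per convolution
#'   layer in each tower.
#' @param kernel_size convolution kernel side length (square kernels).
#' @param conv_stride stride of every convolution layer (1 for the compact
#'   50 x 50 images; 2 for large inputs).
#' @param pool_size max-pooling window and stride (non-overlapping).
#' @param dense_units widths of the fully connected hidden layers.
#' @param dropout_rate dropout probability between dense layers, in \[0, 1).
#' @return An object of class `igtd_cnn_spec`.
#' @export
cnn_spec <- function(input_shapes = list(c(50L, 50L), c(50L, 50L)),
                     conv_filters = c(32L, 64L, 64L),
                     kernel_size = 5L,
                     conv_stride = 1L,
                     pool_size = 2L,
                     dense_units = c(1000L, 385L, 256L),
                     dropout_rate = 0.25) {
  if (length(input_shapes) != 2L) stop("exactly two tower inputs are expected")
  input_shapes <- lapply(input_shapes, function(s) {
    s <- as.integer(s)
    if (length(s) != 2L || any(s < 1L)) stop("each input shape must be c(rows, cols)")
    s
  })
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  structure(list(input_shapes = input_shapes,
                 conv_filters = as.integer(conv_filters),
                 kernel_size = as.integer(kernel_size),
                 conv_stride = as.integer(conv_stride),
                 pool_size = as.integer(pool_size),
                 dense_units = as.integer(dense_units),
                 dropout_rate = dropout_rate),
            class = "igtd_cnn_spec")
}

conv_out_dim <- function(n, k, s) (n - k) %/% s + 1L
pool_out_dim <- function(n, k) (n - k) %/% k + 1L

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

#' Build the two-tower network
#'
#' Lays out the full layer graph of [cnn_spec], checks that every
#' convolution and pooling layer receives a large enough input (the failing
#' layer is named otherwise), and initialises all weights (He-scaled
#' normals; batch-norm scale 1 / shift 0). Layer shapes are a pure function
#' of the spec; only the weight values depend on the seed.
#'
#' @param spec an [igtd_cnn_spec].
#' @param seed integer seed for weight initialisation.
#' @return An object of class `igtd_cnn` holding the layer graph, a named
#'   list of trainable parameter tensors, and batch-norm running statistics
#'   (not trainable).
#' @export
build_two_tower_cnn <- function(spec = cnn_spec(), seed = 1L) {
  stopifnot(inherits(spec, "igtd_cnn_spec"))
  params <- list()
  state <- list()
  k <- spec$kernel_size
  build_tower <- function(ti) {
    h <- spec$input_shapes[[ti]][1L]
    w <- spec$input_shapes[[ti]][2L]
    cin <- 1L
    layers <- list()
    for (ci in seq_along(spec$conv_filters)) {
      cout <- spec$conv_filters[ci]
      if (h < k || w < k) {
        stop("tower ", ti, ", convolution layer ", ci, ": input ",
             h, "x", w, " is smaller than the ", k, "x", k, " kernel")
      }
      h <- conv_out_dim(h, k, spec$conv_stride)
      w <- conv_out_dim(w, k, spec$conv_stride)
      nm <- sprintf("t%d_conv%d", ti, ci)
      params[[paste0(nm, "_w")]] <<- he_init(c(k, k, cin, cout), k * k * cin)
      params[[paste0(nm, "_b")]] <<- numeric(cout)
      layers[[length(layers) + 1L]] <- list(type = "conv", name = nm,
                                            stride = spec$conv_stride,
                                            kernel = k)
      nb <- sprintf("t%d_bn%d", ti, ci)
      params[[paste0(nb, "_gamma")]] <<- rep(1, cout)
      params[[paste0(nb, "_beta")]] <<- numeric(cout)
      state[[paste0(nb, "_mean")]] <<- numeric(cout)
      state[[paste0(nb, "_var")]] <<- rep(1, cout)
      layers[[length(layers) + 1L]] <- list(type = "batchnorm", name = nb)
      layers[[length(layers) + 1L]] <- list(type = "relu")
      if (h < spec$pool_size || w < spec$pool_size) {
        stop("tower ", ti, ", pooling layer ", ci, ": feature map ",
             h, "x", w, " is smaller than the ", spec$pool_size, "x",
             spec$pool_size, " pooling window")
      }
      h <- pool_out_dim(h, spec$pool_size)
      w <- pool_out_dim(w, spec$pool_size)
      layers[[length(layers) + 1L]] <- list(type = "maxpool",
                                            size = spec$pool_size)
      cin <- cout
    }
    list(layers = layers, out_shape = c(h, w, cin), flat = h * w * cin)
  }
  towers <- with_seed(seed, {
    t1 <- build_tower(1L)
    t2 <- build_tower(2L)
    concat <- t1$flat + t2$flat
    head_layers <- list()
    prev <- concat
    for (di in seq_along(spec$dense_units)) {
      d <- spec$dense_units[di]
      nm <- sprintf("dense%d", di)
      params[[paste0(nm, "_w")]] <- he_init(c(prev, d), prev)
      params[[paste0(nm, "_b")]] <- numeric(d)
      head_layers[[length(head_layers) + 1L]] <- list(type = "dense", name = nm)
      head_layers[[length(head_layers) + 1L]] <- list(type = "relu")
      if (spec$dropout_rate > 0) {
        head_layers[[length(head_layers) + 1L]] <-
          list(type = "dropout", rate = spec$dropout_rate)
      }
      prev <- d
    }
    params[["out_w"]] <- he_init(c(prev, 1L), prev)
    params[["out_b"]] <- numeric(1L)
    head_layers[[length(head_layers) + 1L]] <- list(type = "dense",
                                                    name = "out")
    list(t1 = t1, t2 = t2, head = head_layers, concat = concat)
  })
  structure(list(spec = spec,
                 tower1 = towers$t1$layers,
                 tower2 = towers$t2$layers,
                 tower_shapes = list(towers$t1$out_shape, towers$t2$out_shape),
                 head = towers$head,
                 concat_units = towers$concat,
                 params = params,
                 state = state),
            class = "igtd_cnn")
}

#' @export
print.igtd_cnn <- function(x, ...) {
  s1 <- x$tower_shapes[[1L]]
  s2 <- x$tower_shapes[[2L]]
  cat("igtd_cnn: two towers (", length(x$spec$conv_filters),
      " conv blocks each), head ", paste(x$spec$dense_units, collapse = "-"),
      "-1\n", sep = "")
  cat("  tower outputs: ", paste(s1, collapse = "x"), " and ",
      paste(s2, collapse = "x"), "; concat ", x$concat_units, " units\n",
      sep = "")
  cat("  trainable parameters:",
      format(count_trainable_parameters(x), big.mark = ","), "\n")
  invisible(x)
}

#' Count trainable parameters of a built network
#'
#' Sums the element counts of every trainable tensor: convolution kernels
#' and biases, batch-norm scale/shift, dense weights and biases. Batch-norm
#' moving statistics are excluded (non-trainable). The count is a pure
#' function of the spec, identical across seeds.
#'
#' @param model an `igtd_cnn` from [build_two_tower_cnn].
#' @return Integer parameter count.
#' @export
count_trainable_parameters <- function(model) {
  stopifnot(inherits(model, "igtd_cnn"))
  sum(vapply(model$params, length, numeric(1L)))
}

# ---- layer forward/backward kernels (arrays are batch x H x W x C) -------

conv_forward <- function(x, w, b, stride) {
  dms <- dim(x)
  n <- dms[1L]; h <- dms[2L]; wd <- dms[3L]; cin <- dms[4L]
  k <- dim(w)[1L]; cout <- dim(w)[4L]
  oh <- conv_out_dim(h, k, stride)
  ow <- conv_out_dim(wd, k, stride)
  out <- matrix(rep(b, each = n * oh * ow), n * oh * ow, cout)
  for (kh in seq_len(k)) {
    rows <- seq.int(kh, by = stride, length.out = oh)
    for (kw in seq_len(k)) {
      cols <- seq.int(kw, by = stride, length.out = ow)
      xs <- x[, rows, cols, , drop = FALSE]
      dim(xs) <- c(n * oh * ow, cin)
      out <- out + xs %*% matrix(w[kh, kw, , ], cin, cout)
    }
  }
  dim(out) <- c(n, oh, ow, cout)
  out
}

conv_backward <- function(dout, x, w, stride) {
  dms <- dim(x)
  n <- dms[1L]; cin <- dms[4L]
  od <- dim(dout)
  oh <- od[2L]; ow <- od[3L]; cout <- od[4L]
  k <- dim(w)[1L]
  dout_m <- dout
  dim(dout_m) <- c(n * oh * ow, cout)
  dw <- array(0, dim(w))
  dx <- array(0, dms)
  for (kh in seq_len(k)) {
    rows <- seq.int(kh, by = stride, length.out = oh)
    for (kw in seq_len(k)) {
      cols <- seq.int(kw, by = stride, length.out = ow)
      xs <- x[, rows, cols, , drop = FALSE]
      dim(xs) <- c(n * oh * ow, cin)
      dw[kh, kw, , ] <- crossprod(xs, dout_m)
      dxs <- dout_m %*% t(matrix(w[kh, kw, , ], cin, cout))
      dim(dxs) <- c(n, oh, ow, cin)
      dx[, rows, cols, ] <- dx[, rows, cols, , drop = FALSE] + dxs
    }
  }
  list(dx = dx, dw = dw, db = colSums(dout_m))
}

bn_forward <- function(x, gamma, beta, run_mean, run_var, training,
                       momentum = 0.9, eps = 1e-5) {
  dms <- dim(x)
  cc <- dms[4L]
  xm <- x
  dim(xm) <- c(prod(dms[1:3]), cc)
  if (training) {
    mu <- colMeans(xm)
    centred <- sweep(xm, 2L, mu, "-")
    v <- colMeans(centred^2)
    run_mean <- momentum * run_mean + (1 - momentum) * mu
    run_var <- momentum * run_var + (1 - momentum) * v
  } else {
    mu <- run_mean
    v <- run_var
    centred <- sweep(xm, 2L, mu, "-")
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(centred, 2L, invstd, "*")
  out <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  dim(out) <- dms
  list(out = out, xhat = xhat, invstd = invstd,
       run_mean = run_mean, run_var = run_var)
}

bn_backward <- function(dout, cache, gamma) {
  dms <- dim(dout)
  cc <- dms[4L]
  dm <- dout
  dim(dm) <- c(prod(dms[1:3]), cc)
  m <- nrow(dm)
  dgamma <- colSums(dm * cache$xhat)
  dbeta <- colSums(dm)
  dxhat <- sweep(dm, 2L, gamma, "*")
  t1 <- sweep(dxhat, 2L, colMeans(dxhat), "-")
  t2 <- sweep(cache$xhat, 2L, colMeans(dxhat * cache$xhat), "*")
  dx <- sweep(t1 - t2, 2L, cache$invstd, "*")
  dim(dx) <- dms
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

maxpool_forward <- function(x, size) {
  dms <- dim(x)
  n <- dms[1L]; h <- dms[2L]; wd <- dms[3L]; cc <- dms[4L]
  oh <- pool_out_dim(h, size)
  ow <- pool_out_dim(wd, size)
  best <- NULL
  which_slab <- NULL
  slab <- 0L
  for (kh in seq_len(size)) {
    rows <- seq.int(kh, by = size, length.out = oh)
    for (kw in seq_len(size)) {
      cols <- seq.int(kw, by = size, length.out = ow)
      slab <- slab + 1L
      cand <- x[, rows, cols, , drop = FALSE]
      if (is.null(best)) {
        best <- cand
        which_slab <- array(1L, dim(cand))
      } else {
        upd <- cand > best
        best[upd] <- cand[upd]
        which_slab[upd] <- slab
      }
    }
  }
  list(out = best, which_slab = which_slab)
}

maxpool_backward <- function(dout, cache, in_dim, size) {
  dx <- array(0, in_dim)
  oh <- dim(dout)[2L]; ow <- dim(dout)[3L]
  slab <- 0L
  for (kh in seq_len(size)) {
    rows <- seq.int(kh, by = size, length.out = oh)
    for (kw in seq_len(size)) {
      cols <- seq.int(kw, by = size, length.out = ow)
      slab <- slab + 1L
      dx[, rows, cols, ] <- dout * (cache$which_slab == slab)
    }
  }
  dx
}

# Forward through one tower or the dense head. `x` is an array for towers
# and a matrix for the head. Returns output, per-layer caches, and updated
# batch-norm state.
forward_layers <- function(layers, x, params, state, training) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      w <- params[[paste0(ly$name, "_w")]]
      b <- params[[paste0(ly$name, "_b")]]
      caches[[i]] <- list(x = x)
      x <- conv_forward(x, w, b, ly$stride)
    } else if (ly$type == "batchnorm") {
      g <- params[[paste0(ly$name, "_gamma")]]
      bt <- params[[paste0(ly$name, "_beta")]]
      res <- bn_forward(x, g, bt,
                        state[[paste0(ly$name, "_mean")]],
                        state[[paste0(ly$name, "_var")]],
                        training)
      if (training) {
        state[[paste0(ly$name, "_mean")]] <- res$run_mean
        state[[paste0(ly$name, "_var")]] <- res$run_var
      }
      caches[[i]] <- res[c("xhat", "invstd")]
      x <- res$out
    } else if (ly$type == "relu") {
      caches[[i]] <- list(mask = x > 0)
      x <- x * caches[[i]]$mask
    } else if (ly$type == "maxpool") {
      res <- maxpool_forward(x, ly$size)
      caches[[i]] <- list(which_slab = res$which_slab, in_dim = dim(x))
      x <- res$out
    } else if (ly$type == "dense") {
      w <- params[[paste0(ly$name, "_w")]]
      b <- params[[paste0(ly$name, "_b")]]
      caches[[i]] <- list(x = x)
      x <- sweep(x %*% w, 2L, b, "+")
    } else if (ly$type == "dropout") {
      if (training) {
        keep <- 1 - ly$rate
        mask <- (matrix(stats::runif(length(x)), nrow(x)) < keep) / keep
        caches[[i]] <- list(mask = mask)
        x <- x * mask
      } else {
        caches[[i]] <- list(mask = NULL)
      }
    } else {
      stop("unknown layer type: ", ly$type)
    }
  }
  list(out = x, caches = caches, state = state)
}

backward_layers <- function(layers, caches, dout, params) {
  grads <- list()
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    ca <- caches[[i]]
    if (ly$type == "conv") {
      w <- params[[paste0(ly$name, "_w")]]
      res <- conv_backward(dout, ca$x, w, ly$stride)
      grads[[paste0(ly$name, "_w")]] <- res$dw
      grads[[paste0(ly$name, "_b")]] <- res$db
      dout <- res$dx
    } else if (ly$type == "batchnorm") {
      g <- params[[paste0(ly$name, "_gamma")]]
      res <- bn_backward(dout, ca, g)
      grads[[paste0(ly$name, "_gamma")]] <- res$dgamma
      grads[[paste0(ly$name, "_beta")]] <- res$dbeta
      dout <- res$dx
    } else if (ly$type == "relu") {
      dout <- dout * ca$mask
    } else if (ly$type == "maxpool") {
      dout <- maxpool_backward(dout, ca, ca$in_dim, ly$size)
    } else if (ly$type == "dense") {
      w <- params[[paste0(ly$name, "_w")]]
      grads[[paste0(ly$name, "_w")]] <- crossprod(ca$x, dout)
      grads[[paste0(ly$name, "_b")]] <- colSums(dout)
      dout <- dout %*% t(w)
    } else if (ly$type == "dropout") {
      if (!is.null(ca$mask)) dout <- dout * ca$mask
    }
  }
  list(dx = dout, grads = grads)
}

as_nhwc <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("image batch must be n x rows x cols (x 1)")
  x
}

cnn_forward <- function(model, x1, x2, training = FALSE) {
  x1 <- as_nhwc(x1)
  x2 <- as_nhwc(x2)
  n <- dim(x1)[1L]
  f1 <- forward_layers(model$tower1, x1, model$params, model$state, training)
  f2 <- forward_layers(model$tower2, x2, model$params, f1$state, training)
  o1 <- f1$out; dim(o1) <- c(n, prod(dim(f1$out)[-1L]))
  o2 <- f2$out; dim(o2) <- c(n, prod(dim(f2$out)[-1L]))
  xh <- cbind(o1, o2)
  fh <- forward_layers(model$head, xh, model$params, f2$state, training)
  list(pred = as.numeric(fh$out), f1 = f1, f2 = f2, fh = fh,
       split = ncol(o1), state = fh$state)
}

#' Predict with a built (or trained) network
#'
#' Runs the forward pass in inference mode (batch norm uses its running
#' statistics; dropout is disabled).
#'
#' @param model an `igtd_cnn`.
#' @param x1,x2 image batches, arrays of dim `n x rows x cols`, one per tower.
#' @return Numeric vector of n predictions.
#' @export
cnn_predict <- function(model, x1, x2) {
  cnn_forward(model, x1, x2, training = FALSE)$pred
}

adam_step <- function(params, grads, m, v, t, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * g
    v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * g^2
    mhat <- m[[nm]] / (1 - beta1^t)
    vhat <- v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, m = m, v = v)
}

#' Desk-scale smoke training of the two-tower network
#'
#' Trains the network with mean squared error loss and the Adam optimiser on
#' paired synthetic images (see [generate_paired_image_response]), holding
#' out a validation split for early stopping, and compares the best
#' validation MSE against the mean predictor (predicting the training-set
#' mean response for every sample). This is a learning-capability check,
#' not a benchmark: a model trained on a planted signal must beat the mean
#' predictor, and one trained on pure noise must not beat it materially.
#'
#' @param model an `igtd_cnn` whose input shapes match the data.
#' @param data list with arrays `x1`, `x2` and response `y`.
#' @param epochs maximum training epochs.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param val_fraction fraction of pairs held out for validation.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param seed integer seed driving the split, shuffling and dropout.
#' @return An object of class `igtd_fit`: per-epoch `train_loss` and
#'   `val_loss`, `best_epoch`, `best_val_mse`, `baseline_mse` (mean
#'   predictor), `beats_baseline`, `n_parameters`, and the trained `model`.
#' @export
smoke_train <- function(model, data, epochs = 20L, batch_size = 32L,
                        lr = 1e-3, val_fraction = 0.2, patience = 5L,
                        seed = 1L) {
  stopifnot(inherits(model, "igtd_cnn"))
  x1 <- as_nhwc(data$x1)
  x2 <- as_nhwc(data$x2)
  y <- as.numeric(data$y)
  n <- dim(x1)[1L]
  if (dim(x2)[1L] != n || length(y) != n) stop("x1, x2 and y sizes disagree")
  with_seed(seed, {
    idx <- sample.int(n)
    n_val <- max(1L, round(val_fraction * n))
    val_idx <- idx[seq_len(n_val)]
    tr_idx <- idx[-seq_len(n_val)]
    x1_tr <- x1[tr_idx, , , , drop = FALSE]
    x2_tr <- x2[tr_idx, , , , drop = FALSE]
    y_tr <- y[tr_idx]
    x1_va <- x1[val_idx, , , , drop = FALSE]
    x2_va <- x2[val_idx, , , , drop = FALSE]
    y_va <- y[val_idx]
    baseline_mse <- mean((y_va - mean(y_tr))^2)

    params <- model$params
    m <- lapply(params, function(p) array(0, dim(p) %||% length(p)))
    v <- lapply(params, function(p) array(0, dim(p) %||% length(p)))
    t_step <- 0L
    best_val <- Inf
    best_params <- params
    best_state <- model$state
    best_epoch <- 0L
    train_loss <- numeric(0L)
    val_loss <- numeric(0L)
    stall <- 0L
    n_tr <- length(tr_idx)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n_tr)
      batch_losses <- numeric(0L)
      for (b0 in seq(1L, n_tr, by = batch_size)) {
        bi <- ord[b0:min(b0 + batch_size - 1L, n_tr)]
        if (length(bi) < 2L) next  # batch norm needs > 1 sample
        model$params <- params
        fw <- cnn_forward(model, x1_tr[bi, , , , drop = FALSE],
                          x2_tr[bi, , , , drop = FALSE], training = TRUE)
        model$state <- fw$state
        resid <- fw$pred - y_tr[bi]
        if (any(!is.finite(resid))) {
          stop("training diverged (non-finite loss) with lr = ", lr,
               ", batch_size = ", batch_size, ", epoch = ", ep)
        }
        batch_losses <- c(batch_losses, mean(resid^2))
        dpred <- matrix(2 * resid / length(resid), ncol = 1L)
        bh <- backward_layers(model$head, fw$fh$caches, dpred, params)
        d1 <- bh$dx[, seq_len(fw$split), drop = FALSE]
        d2 <- bh$dx[, -seq_len(fw$split), drop = FALSE]
        dim(d1) <- dim(fw$f1$out)
        dim(d2) <- dim(fw$f2$out)
        b1 <- backward_layers(model$tower1, fw$f1$caches, d1, params)
        b2 <- backward_layers(model$tower2, fw$f2$caches, d2, params)
        grads <- c(bh$grads, b1$grads, b2$grads)
        t_step <- t_step + 1L
        upd <- adam_step(params, grads, m, v, t_step, lr)
        params <- upd$params
        m <- upd$m
        v <- upd$v
      }
      model$params <- params
      val_pred <- cnn_forward(model, x1_va, x2_va, training = FALSE)$pred
      vmse <- mean((val_pred - y_va)^2)
      train_loss <- c(train_loss, mean(batch_losses))
      val_loss <- c(val_loss, vmse)
      if (vmse < best_val) {
        best_val <- vmse
        best_params <- params
        best_state <- model$state
        best_epoch <- ep
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= patience) break
      }
    }
    model$params <- best_params
    model$state <- best_state
    structure(list(train_loss = train_loss, val_loss = val_loss,
                   best_epoch = best_epoch, best_val_mse = best_val,
                   baseline_mse = baseline_mse,
                   beats_baseline = best_val < baseline_mse,
                   n_parameters = count_trainable_parameters(model),
                   model = model),
              class = "igtd_fit")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.igtd_fit <- function(x, ...) {
  cat("igtd_fit:", length(x$val_loss), "epochs; best epoch", x$best_epoch, "\n")
  cat("  validation MSE:", signif(x$best_val_mse, 5L),
      "vs mean predictor", signif(x$baseline_mse, 5L),
      if (x$beats_baseline) "(beats baseline)" else "(does not beat baseline)",
      "\n")
  invisible(x)
}
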