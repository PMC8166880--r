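test_that("parameter counting matches closed forms for single layers", {
  # dense 10 -> 1 with bias
  m <- build_two_tower_cnn(cnn_spec(input_shapes = list(c(7, 7), c(7, 7)),
                                    conv_filters = 8L, kernel_size = 5L,
                                    dense_units = integer(0),
                                    dropout_rate = 0))
  # per tower: conv 5*5*1*8 + 8 = 208, batch norm 16; towers doubled;
  # head: flatten 1x1x8 each -> concat 16 -> out dense 17
  expect_equal(count_trainable_parameters(m), 2 * (208 + 16) + 17)
})

test_that("tower feature-map shapes follow the conv/pool arithmetic", {
  m <- build_two_tower_cnn(cnn_spec())
  # 50 -> conv5 46 -> pool 23 -> conv5 19 -> pool 9 -> conv5 5 -> pool 2
  expect_equal(m$tower_shapes[[1]], c(2L, 2L, 64L))
  expect_equal(m$concat_units, 2 * 2 * 2 * 64)
  m2 <- build_two_tower_cnn(cnn_spec(input_shapes = list(c(227L, 387L),
                                                         c(380L, 387L)),
                                     conv_stride = 2L))
  # 227 -> 112 -> 56 -> 26 -> 13 -> 5 -> 2 ; 387 -> 192 -> 96 -> 46 -> 23 -> 10 -> 5
  expect_equal(m2$tower_shapes[[1]], c(2L, 5L, 64L))
  expect_equal(m2$tower_shapes[[2]], c(4L, 5L, 64L))
})

test_that("the default architecture reproduces both reference parameter counts", {
  m50 <- build_two_tower_cnn(cnn_spec())
  expect_identical(count_trainable_parameters(m50), 1307218)
  mbig <- build_two_tower_cnn(cnn_spec(input_shapes = list(c(227L, 387L),
                                                           c(380L, 387L)),
                                       conv_stride = 2L))
  expect_identical(count_trainable_parameters(mbig), 2715218)
  # the count is a pure function of the spec, not of the weights
  expect_identical(count_trainable_parameters(build_two_tower_cnn(cnn_spec(),
                                                                  seed = 99L)),
                   1307218)
})

test_that("undersized inputs fail with the offending layer named", {
  expect_error(build_two_tower_cnn(cnn_spec(input_shapes = list(c(20, 20),
                                                                c(20, 20)))),
               "convolution layer 3")
  expect_error(build_two_tower_cnn(cnn_spec(input_shapes = list(c(4, 40),
                                                                c(40, 40)))),
               "tower 1, convolution layer 1")
})

test_that("backpropagated gradients match numerical differentiation", {
  sp <- cnn_spec(input_shapes = list(c(14, 14), c(12, 12)),
                 conv_filters = c(3L, 4L), kernel_size = 3L,
                 dense_units = 7L, dropout_rate = 0)
  model <- build_two_tower_cnn(sp, seed = 5)
  set.seed(9)
  n <- 4
  x1 <- array(runif(n * 14 * 14), c(n, 14, 14))
  x2 <- array(runif(n * 12 * 12), c(n, 12, 12))
  y <- rnorm(n)
  loss_of <- function(params) {
    model$params <- params
    fw <- igtd:::cnn_forward(model, x1, x2, training = TRUE)
    mean((fw$pred - y)^2)
  }
  fw <- igtd:::cnn_forward(model, x1, x2, training = TRUE)
  dpred <- matrix(2 * (fw$pred - y) / n, ncol = 1)
  bh <- igtd:::backward_layers(model$head, fw$fh$caches, dpred, model$params)
  d1 <- bh$dx[, seq_len(fw$split), drop = FALSE]
  d2 <- bh$dx[, -seq_len(fw$split), drop = FALSE]
  dim(d1) <- dim(fw$f1$out)
  dim(d2) <- dim(fw$f2$out)
  b1 <- igtd:::backward_layers(model$tower1, fw$f1$caches, d1, model$params)
  b2 <- igtd:::backward_layers(model$tower2, fw$f2$caches, d2, model$params)
  grads <- c(bh$grads, b1$grads, b2$grads)
  eps <- 1e-5
  for (nm in names(grads)) {
    g <- grads[[nm]]
    for (trial in 1:2) {
      i <- sample(length(g), 1)
      pp <- model$params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- model$params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (loss_of(pp) - loss_of(pm)) / (2 * eps)
      # conv biases sit before batch norm, so both gradients are ~0 there;
      # compare on an absolute + relative scale
      expect_lt(abs(num - g[i]), 1e-4 + 1e-3 * (abs(num) + abs(g[i])))
    }
  }
})

test_that("prediction is deterministic and matches layer-count bookkeeping", {
  sp <- cnn_spec(input_shapes = list(c(14, 14), c(14, 14)),
                 conv_filters = c(3L, 4L), kernel_size = 3L,
                 dense_units = 7L, dropout_rate = 0.3)
  model <- build_two_tower_cnn(sp, seed = 6)
  set.seed(10)
  x1 <- array(runif(3 * 14 * 14), c(3, 14, 14))
  x2 <- array(runif(3 * 14 * 14), c(3, 14, 14))
  p1 <- cnn_predict(model, x1, x2)
  p2 <- cnn_predict(model, x1, x2)
  expect_identical(p1, p2)   # inference mode: no dropout randomness
  expect_length(p1, 3L)
})

test_that("smoke training beats the mean predictor on a planted signal", {
  pairs <- generate_paired_image_response(240, seed = 81)
  model <- build_two_tower_cnn(
    cnn_spec(input_shapes = list(c(38L, 38L), c(38L, 38L)),
             conv_filters = c(8L, 8L, 8L), dense_units = c(32L, 16L)),
    seed = 81)
  fit <- smoke_train(model, pairs, epochs = 12L, seed = 81)
  expect_true(fit$beats_baseline)
  expect_lt(fit$best_val_mse, 0.5 * fit$baseline_mse)
  # reproducibility of the loss curve under the same seed
  model_b <- build_two_tower_cnn(
    cnn_spec(input_shapes = list(c(38L, 38L), c(38L, 38L)),
             conv_filters = c(8L, 8L, 8L), dense_units = c(32L, 16L)),
    seed = 81)
  fit_b <- smoke_train(model_b, pairs, epochs = 2L, seed = 81)
  expect_identical(fit$train_loss[1:2], fit_b$train_loss[1:2])
})

test_that("smoke training does not beat the mean predictor on pure noise", {
  pairs <- generate_paired_image_response(240, alpha = 0, beta = 0,
                                          noise_sd = 0.1, seed = 82)
  model <- build_two_tower_cnn(
    cnn_spec(input_shapes = list(c(38L, 38L), c(38L, 38L)),
             conv_filters = c(8L, 8L, 8L), dense_units = c(32L, 16L)),
    seed = 82)
  fit <- smoke_train(model, pairs, epochs = 8L, seed = 82)
  expect_gt(fit$best_val_mse, 0.8 * fit$baseline_mse)
})
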