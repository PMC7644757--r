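test_that("grid enumeration is the deduplicated Cartesian product", {
  grid <- enumerate_grid(conv = list(n_kernels = c(3, 5), n_layers = c(1, 2)),
                         dense = list(n_layers = 1))
  expect_length(grid, 4)
  expect_true(all(vapply(grid, inherits, logical(1), "model_spec")))

  dup <- enumerate_grid(conv = list(n_kernels = c(3, 3)), dense = list(n_layers = 1))
  expect_length(dup, 1)

  expect_error(enumerate_grid(conv = list(n_kernels = numeric(0)),
                              dense = list(n_layers = 1)), "empty grid")
})

test_that("the published best architectures are expressible in the grammar", {
  # best RNN: two bidirectional LSTMs, two FC layers with two dropouts
  rnn <- model_spec(recurrent_block(n_layers = 2, hidden_size = 64, bidirectional = TRUE),
                    dense_block(n_layers = 2, dropout = 0.5))
  expect_s3_class(rnn, "model_spec")
  expect_true(zdnascan:::spec_has_recurrent(rnn))

  # best CNN: one conv layer with 3 kernels, one FC layer
  cnn <- model_spec(conv_block(n_layers = 1, n_kernels = 3, kernel_size = 5),
                    dense_block(n_layers = 1))
  expect_s3_class(cnn, "model_spec")
  expect_true(zdnascan:::spec_is_cnn_only(cnn))

  # invalid orders are rejected
  expect_error(model_spec(dense_block(1), conv_block(1)), "last")
  expect_error(model_spec(recurrent_block(1), conv_block(1), dense_block(1)), "order")
})

test_that("receptive field follows 1 + sum(kernel - 1) and rejects recurrent models", {
  expect_identical(receptive_field(model_spec(conv_block(2, 8, 5), dense_block(1))), 9L)
  expect_identical(receptive_field(model_spec(conv_block(1, 4, 3), dense_block(1))), 3L)
  expect_identical(receptive_field(model_spec(conv_block(2, 2, 17), dense_block(1))), 33L)
  expect_identical(receptive_field(model_spec(dense_block(1))), 1L)
  expect_error(receptive_field(model_spec(recurrent_block(1), dense_block(1))),
               "unbounded")
})

test_that("backpropagated gradients match finite differences on the full hybrid stack", {
  set.seed(7)
  spec <- model_spec(conv_block(2, c(4, 3), c(3, 5)),
                     recurrent_block(1, 5, bidirectional = TRUE),
                     dense_block(2, 6, dropout = 0))
  layers <- zdnascan:::init_layers(spec, 3)
  X <- matrix(rnorm(36), 12, 3)
  y <- rbinom(12, 1, 0.4)
  fwd <- zdnascan:::nn_forward(layers, X)
  cl <- zdnascan:::ce_loss(fwd$logits, y)
  bk <- zdnascan:::nn_backward(layers, fwd, cl$dLogits)
  eps <- 1e-6
  for (i in seq_along(layers)) {
    for (nm in names(layers[[i]]$par)) {
      P <- layers[[i]]$par[[nm]]
      for (j in sample(length(P), min(4, length(P)))) {
        l2 <- layers
        l2[[i]]$par[[nm]][j] <- P[j] + eps
        lp <- zdnascan:::ce_loss(zdnascan:::nn_forward(l2, X)$logits, y)$loss
        l2[[i]]$par[[nm]][j] <- P[j] - eps
        lm <- zdnascan:::ce_loss(zdnascan:::nn_forward(l2, X)$logits, y)$loss
        expect_equal(as.numeric(bk$grads[[i]][[nm]][j]),
                     as.numeric((lp - lm) / (2 * eps)), tolerance = 1e-4)
      }
    }
  }
  # gradient with respect to the input (used by input maximisation)
  for (j in sample(length(X), 6)) {
    X2 <- X; X2[j] <- X[j] + eps
    lp <- zdnascan:::ce_loss(zdnascan:::nn_forward(layers, X2)$logits, y)$loss
    X2[j] <- X[j] - eps
    lm <- zdnascan:::ce_loss(zdnascan:::nn_forward(layers, X2)$logits, y)$loss
    expect_equal(as.numeric(bk$dInput[j]),
                 as.numeric((lp - lm) / (2 * eps)), tolerance = 1e-4)
  }
})

test_that("the two output units are softmax-normalised at every position", {
  set.seed(8)
  layers <- zdnascan:::init_layers(model_spec(conv_block(1, 3, 5), dense_block(1)), 4)
  P <- zdnascan:::softmax_rows(zdnascan:::nn_forward(layers, matrix(rnorm(80), 20, 4))$logits)
  expect_equal(rowSums(P), rep(1, 20))
  expect_true(all(P >= 0 & P <= 1))
})

test_that("a one-layer CNN separates a fixture whose channel equals the label", {
  set.seed(10)
  L <- 400
  labels <- list(chrA = as.numeric(rbinom(L, 1, 0.3)))
  genome <- c(chrA = paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = ""))
  markers <- NULL
  store <- build_feature_store(genome, markers, energy_table = NULL)
  # graft a channel identical to the label onto the store
  store$chroms$chrA$channels$oracle <- as_sparse_track(labels$chrA)
  store$chroms$chrA$classes <- c(store$chroms$chrA$classes, oracle = "marker")
  store$channel_names <- c(store$channel_names, "oracle")
  store$classes <- c(store$classes, oracle = "marker")
  ws <- structure(
    data.frame(chrom = "chrA", start = seq(0, 300, 100), end = seq(100, 400, 100),
               contains_z = TRUE, split = NA_character_, fold = NA_integer_),
    class = c("window_set", "data.frame"), window_length = 100, seed = 1)
  spec <- model_spec(conv_block(1, 2, 3), dense_block(1))
  fit <- zdna_fit(spec, ws, store, labels,
                  control = zdna_control(epochs = 150, batch_size = 1,
                                         learning_rate = 5e-3), seed = 4)
  p <- predict(fit, store, "chrA")
  expect_gt(zdnascan:::f1_score(p > 0.5, labels$chrA), 0.95)
  # training loss decreases in moving average
  lo <- fit$training_log$loss
  expect_lt(mean(tail(lo, 5)), mean(head(lo, 5)))
})

test_that("training is deterministic under the seed and rejects empty splits", {
  fx <- tiny_fixture()
  ws <- head(fx$ws, 6)
  spec <- model_spec(conv_block(1, 2, 3), dense_block(1))
  ctrl <- zdna_control(epochs = 3, batch_size = 2)
  f1 <- zdna_fit(spec, ws, fx$store, fx$labels, control = ctrl, seed = 99)
  f2 <- zdna_fit(spec, ws, fx$store, fx$labels, control = ctrl, seed = 99)
  expect_identical(f1$training_log$loss, f2$training_log$loss)
  expect_identical(f1$layers, f2$layers)

  ws_empty <- ws
  ws_empty$split <- "test"
  expect_error(zdna_fit(spec, ws_empty, fx$store, fx$labels, control = ctrl),
               "empty training split")
})

test_that("chunked CNN prediction stitches without seams and respects bounds", {
  fx <- tiny_fixture()
  fit <- tiny_cnn_fit()
  full <- predict(fit, fx$store, "chr1", 0, 3000)
  chunked <- predict(fit, fx$store, "chr1", 0, 3000, chunk_size = 500)
  expect_identical(full, chunked)
  expect_length(full, 3000)
  expect_true(all(full >= 0 & full <= 1))
  expect_identical(predict(fit, fx$store, "chr1", 10, 10), numeric(0))

  bad_store <- fx$store
  bad_store$channel_names <- setdiff(bad_store$channel_names, "inf_01")
  expect_error(predict(fit, bad_store, "chr1", 0, 100), "lacks model channels")
})

test_that("an all-zero input yields a constant probability (translation invariance)", {
  set.seed(11)
  layers <- zdnascan:::init_layers(model_spec(conv_block(2, 4, 5), dense_block(1)), 6)
  p <- zdnascan:::nn_probs(layers, matrix(0, 50, 6))
  expect_equal(p, rep(p[1], 50))
})

test_that("inputs beyond the receptive-field half-width cannot touch an output", {
  set.seed(12)
  spec <- model_spec(conv_block(2, 8, 5), dense_block(1))
  rf <- receptive_field(spec)            # 9 nt
  half <- (rf - 1) / 2
  layers <- zdnascan:::init_layers(spec, 5)
  X <- matrix(rnorm(61 * 5), 61, 5)
  centre <- 31
  p0 <- zdnascan:::nn_probs(layers, X)[centre]
  for (rep in 1:5) {
    X2 <- X
    far <- c(seq_len(centre - half - 1), seq(centre + half + 1, 61))
    X2[far, ] <- matrix(rnorm(length(far) * 5), length(far), 5)
    expect_identical(zdnascan:::nn_probs(layers, X2)[centre], p0)
    # while perturbation inside the window does change it
    X3 <- X; X3[centre + half, ] <- X3[centre + half, ] + 1
    expect_false(zdnascan:::nn_probs(layers, X3)[centre] == p0)
  }
})

test_that("model methods print, summarise, plot and expose coefficients", {
  fit <- tiny_cnn_fit()
  expect_output(print(fit), "segmentation model")
  expect_output(summary(fit), "Receptive field")
  w <- coef(fit)
  expect_named(w, fit$channel_names)
  path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(path); plot(fit); grDevices::dev.off()
  expect_true(file.exists(path))
  fx <- tiny_fixture()
  r <- residuals(fit, fx$store, fx$labels, head(fx$ws, 3))
  expect_length(r, 3000)
  expect_true(all(abs(r) <= 1))
})
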