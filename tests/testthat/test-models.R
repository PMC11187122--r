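test_that("the autoencoder reconstructs input shape and the encoder compresses time by the stride product", {
  set.seed(1)
  cfg <- dcae_config(enc_filters = c(4L, 4L, 8L, 8L, 16L, 16L))
  m <- build_dcae(cfg, n_channels = 19L, input_len = 2560L)
  x <- array(rnorm(19 * 2560 * 2), c(19, 2560, 2))
  out <- seizecast:::nn_forward(m, x)$out
  expect_identical(dim(out), dim(x))

  # encoder output temporal length = input / product of strides = 2560/64
  enc_only <- m
  enc_only$layers <- Filter(function(l) identical(l$scope, "encoder"),
                            m$layers)
  z <- seizecast:::nn_forward(enc_only, x)$out
  expect_identical(dim(z), c(16L, 40L, 2L))

  expect_error(dcae_config(enc_filters = c(4L, 4L), strides = c(2L, 2L),
                           dec_filters = c(4L, NA), upsample = c(2L, 4L)),
               "stride product")
  expect_error(build_dcae(tiny_dcae_cfg(), n_channels = 2L, input_len = 10L),
               "divisible")
})

test_that("swish matches its closed form", {
  expect_equal(swish(0), 0)
  expect_equal(swish(1), 1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(swish(1), 0.7310586, tolerance = 1e-6)
  expect_equal(swish(-50), -50 / (1 + exp(50)), tolerance = 1e-12)
})

test_that("predictor outputs are probabilities and inference is deterministic", {
  set.seed(2)
  pc <- predictor_config(tiny_dcae_cfg(dropout = 0.3), bilstm_units = 3L)
  m <- build_predictor(pc, n_channels = 2L, input_len = 16L)
  x <- array(rnorm(2 * 16 * 5), c(2, 16, 5))
  p <- predict_windows(m, x)
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(p, predict_windows(m, x))
  # identical inputs give identical outputs
  x2 <- x
  x2[, , 2] <- x[, , 1]
  p2 <- predict_windows(m, x2)
  expect_equal(p2[1, ], p2[2, ], tolerance = 1e-12)
})

test_that("backpropagated gradients match finite differences on a tiny predictor", {
  set.seed(3)
  pc <- predictor_config(tiny_dcae_cfg(), bilstm_units = 3L)
  m <- build_predictor(pc, n_channels = 2L, input_len = 16L)
  x <- array(rnorm(2 * 16 * 4), c(2, 16, 4))
  y <- c(1L, 2L, 1L, 2L)
  fw <- seizecast:::nn_forward(m, x, training = TRUE)
  l <- seizecast:::softmax_xent(fw$out, y)
  bk <- seizecast:::nn_backward(fw$net, fw$caches, l$grad)

  loss_at <- function(model) {
    f <- seizecast:::nn_forward(model, x, training = TRUE)
    seizecast:::softmax_xent(f$out, y)$loss
  }
  # check a representative tensor of every trainable layer type (conv bias
  # feeding BatchNorm has true gradient 0, so W is checked for conv layers)
  checks <- list(c(1, "W"), c(2, "gamma"), c(9, "Wf"), c(9, "Ub"),
                 c(10, "W"), c(10, "b"))
  for (ck in checks) {
    i <- as.integer(ck[1]); nm <- ck[2]
    theta <- m$layers[[i]]$params[[nm]]
    num <- theta * 0
    for (j in seq_along(theta)) {
      mp <- m; mp$layers[[i]]$params[[nm]][j] <- theta[j] + 1e-5
      mm <- m; mm$layers[[i]]$params[[nm]][j] <- theta[j] - 1e-5
      num[j] <- (loss_at(mp) - loss_at(mm)) / 2e-5
    }
    rel <- max(abs(num - bk$grads[[i]][[nm]])) /
      max(1e-8, max(abs(num)), max(abs(bk$grads[[i]][[nm]])))
    expect_lt(rel, 1e-5)
  }
})

test_that("encoder transfer copies tensors exactly and freezing controls trainability", {
  set.seed(4)
  cfg <- tiny_dcae_cfg()
  dcae <- build_dcae(cfg, n_channels = 2L, input_len = 16L)
  bundle <- weight_bundle(dcae, provenance = list(dataset = "src"))
  pc <- predictor_config(cfg, bilstm_units = 3L)
  pred <- build_predictor(pc, n_channels = 2L, input_len = 16L)
  moved <- transfer_encoder(bundle, pred, freeze = TRUE)

  enc_after <- seizecast:::model_params(moved, scope = "encoder")
  expect_identical(enc_after[names(bundle$params)], bundle$params)
  expect_identical(moved$provenance$dataset, "src")

  # trainable parameter count strictly smaller when frozen
  count_trainable <- function(m) {
    sum(vapply(m$layers, function(l) {
      if (isTRUE(l$trainable) && !is.null(l$params)) {
        sum(vapply(l$params, length, 1L))
      } else 0L
    }, 1L))
  }
  expect_lt(count_trainable(moved), count_trainable(pred))

  # a shape-incompatible bundle is rejected naming the problem
  other <- build_dcae(dcae_config(enc_filters = c(5L, 4L), kernel = 3L,
                                  strides = c(2L, 2L),
                                  dec_filters = c(3L, NA),
                                  upsample = c(2L, 2L)),
                      n_channels = 2L, input_len = 16L)
  expect_error(transfer_encoder(weight_bundle(other), pred, freeze = TRUE),
               "hash")

  # a tensor-level shape mismatch is rejected naming the tensor
  tampered <- bundle
  tampered$params[["L01.W"]] <- matrix(0, 2, 2)
  expect_error(transfer_encoder(tampered, pred, freeze = TRUE), "L01.W")
})

test_that("one optimisation step reaches the encoder iff it is unfrozen", {
  set.seed(5)
  cfg <- tiny_dcae_cfg()
  dcae <- build_dcae(cfg, n_channels = 2L, input_len = 16L)
  bundle <- weight_bundle(dcae)
  x <- array(rnorm(2 * 16 * 8), c(2, 16, 8))
  y <- rep(1:2, 4)

  step_once <- function(freeze) {
    pred <- build_predictor(predictor_config(cfg, bilstm_units = 3L),
                            n_channels = 2L, input_len = 16L)
    pred <- transfer_encoder(bundle, pred, freeze = freeze)
    fw <- seizecast:::nn_forward(pred, x, training = TRUE)
    l <- seizecast:::softmax_xent(fw$out, y)
    bk <- seizecast:::nn_backward(fw$net, fw$caches, l$grad)
    st <- seizecast:::adam_step(fw$net, bk$grads, seizecast:::adam_init(),
                                lr = 1e-2)
    st$model
  }
  conv_w <- function(m) m$layers[[1]]$params$W

  frozen <- step_once(TRUE)
  expect_identical(conv_w(frozen), conv_w(dcae))
  free <- step_once(FALSE)
  expect_false(identical(conv_w(free), conv_w(dcae)))
  expect_gt(max(abs(conv_w(free) - conv_w(dcae))), 0)
})

test_that("weight bundles save and load byte-stably", {
  set.seed(6)
  dcae <- build_dcae(tiny_dcae_cfg(), n_channels = 2L, input_len = 16L)
  b <- weight_bundle(dcae, provenance = list(run = "r1"))
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "b1.bundle")
  p2 <- file.path(dir, "b2.bundle")
  save_weight_bundle(b, p1)
  b2 <- load_weight_bundle(p1)
  expect_identical(b2$params, b$params)
  save_weight_bundle(b2, p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})

test_that("a trained autoencoder reconstructs held-out windows better than an untrained one", {
  ws <- tiny_corpus(80, n_channels = 2L, len = 64L, seed = 7)
  hold <- tiny_corpus(20, n_channels = 2L, len = 64L, seed = 8)
  cfg <- tiny_dcae_cfg()
  losses <- vapply(1:3, function(s) {
    fit <- train_dcae(ws, train_protocol("dcae", batch_size = 16L,
                                         max_epochs = 8L, patience = 7L,
                                         seed = s), cfg)
    untrained <- {
      set.seed(s + 100)
      build_dcae(cfg, n_channels = 2L, input_len = 64L)
    }
    rec_t <- seizecast:::nn_forward(fit$model, hold$data)$out
    rec_u <- seizecast:::nn_forward(untrained, hold$data)$out
    mean((rec_t - hold$data)^2) / mean((rec_u - hold$data)^2)
  }, 0)
  expect_lt(stats::median(losses), 1)
})
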