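# Training regimes: DCAE pretraining on the source corpus (MSE, batch 2048,
# up to 2000 epochs, patience 200) and patient-specific predictor fits
# (binary cross-entropy over balanced 32/32 batches of 64, up to 500 epochs,
# patience 50), both with Adam at learning rate 3e-4 and best-validation
# weight restoration. Predictor fits are repeated (5 by default) with
# distinct recorded seeds.

#' Training protocol
#'
#' Defaults follow the published optimisation protocol; tests and desk-scale
#' runs shrink `max_epochs`/`patience`/`batch_size` through this object.
#'
#' @param mode `"dcae"`, `"standard"` or `"transfer"`.
#' @param batch_size Samples per batch (predictor batches are balanced:
#'   half interictal, half preictal).
#' @param max_epochs,patience Early-stopping protocol; `patience` epochs
#'   without validation improvement stop training and the best-validation
#'   weights are restored.
#' @param lr Adam learning rate.
#' @param n_repeats Independent predictor fits (ignored for `"dcae"`).
#' @param seed Base RNG seed; repeat `r` uses `seed + r`.
#' @return A `train_protocol`.
#' @export
train_protocol <- function(mode = c("dcae", "standard", "transfer"),
                           batch_size = NULL, max_epochs = NULL,
                           patience = NULL, lr = 3e-4, n_repeats = 5L,
                           seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(batch_size)) batch_size <- if (mode == "dcae") 2048L else 64L
  if (is.null(max_epochs)) max_epochs <- if (mode == "dcae") 2000L else 500L
  if (is.null(patience)) patience <- if (mode == "dcae") 200L else 50L
  stopifnot(patience < max_epochs, lr > 0, batch_size >= 2)
  structure(list(mode = mode, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), lr = lr,
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed)),
            class = "train_protocol")
}

# snapshot/restore of all parameters incl. BatchNorm running stats
snapshot_params <- function(model) model_params(model)

#' Pretrain the DCAE on a source window corpus
#'
#' Minimises the mean squared reconstruction error over a random 80/20
#' train/validation holdout of the (already standardized) windows, with
#' early stopping on validation loss and best-weight restoration.
#'
#' @param ws A standardized `window_set` from the source corpus.
#' @param proto A [train_protocol()] with mode `"dcae"`.
#' @param cfg A [dcae_config()].
#' @param val_frac Validation fraction of the holdout.
#' @return A `fit_result`: `model`, `train_loss`/`val_loss` per epoch,
#'   `stopped_epoch`, `best_epoch`, `seed`, `mode`. The encoder is
#'   extractable with [weight_bundle()].
#' @export
train_dcae <- function(ws, proto = train_protocol("dcae"),
                       cfg = dcae_config(), val_frac = 0.2) {
  stopifnot(inherits(ws, "window_set"), proto$mode == "dcae")
  idx <- which(ws$valid)
  if (!length(idx)) stop("no valid windows to train on")
  set.seed(proto$seed)
  n_val <- max(1L, round(val_frac * length(idx)))
  val_idx <- sort(idx[sample.int(length(idx), n_val)])
  tr_idx <- setdiff(idx, val_idx)
  if (!length(tr_idx)) stop("training split is empty")

  d <- dim(ws$data)
  model <- build_dcae(cfg, n_channels = d[1], input_len = d[2])
  opt <- adam_init()
  xval <- ws$data[, , val_idx, drop = FALSE]

  best_val <- Inf; best_params <- NULL; best_epoch <- 0L; wait <- 0L
  tl <- vl <- numeric()
  for (epoch in seq_len(proto$max_epochs)) {
    ord <- tr_idx[sample.int(length(tr_idx))]
    eloss <- 0; nb <- 0L
    for (s in seq(1L, length(ord), by = proto$batch_size)) {
      b <- ord[s:min(s + proto$batch_size - 1L, length(ord))]
      xb <- ws$data[, , b, drop = FALSE]
      fw <- nn_forward(model, xb, training = TRUE)
      model <- fw$net
      loss <- mse_loss(fw$out, xb)
      bk <- nn_backward(model, fw$caches, loss$grad)
      st <- adam_step(model, bk$grads, opt, lr = proto$lr)
      model <- st$model; opt <- st$state
      eloss <- eloss + loss$loss; nb <- nb + 1L
    }
    tl[epoch] <- eloss / nb
    vout <- nn_forward(model, xval, training = FALSE)$out
    vl[epoch] <- mse_loss(vout, xval)$loss
    if (vl[epoch] < best_val - 1e-9) {
      best_val <- vl[epoch]; best_params <- snapshot_params(model)
      best_epoch <- epoch; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= proto$patience) break
    }
  }
  if (!is.null(best_params)) model <- model_set_params(model, best_params)
  structure(list(model = model, train_loss = tl, val_loss = vl,
                 stopped_epoch = length(tl), best_epoch = best_epoch,
                 seed = proto$seed, mode = "dcae"),
            class = "fit_result")
}

balanced_batches <- function(y, batch_size) {
  half <- batch_size %/% 2L
  cls <- split(seq_along(y), y)
  if (length(cls) < 2L || any(!lengths(cls))) {
    stop("both classes must be present in the training selection")
  }
  sizes <- lengths(cls)
  maj <- which.max(sizes); mnr <- setdiff(1:2, maj)
  maj_idx <- cls[[maj]][sample.int(length(cls[[maj]]))]  # one majority pass
  mnr_idx <- cls[[mnr]]
  batches <- list()
  for (s in seq(1L, length(maj_idx), by = half)) {
    a <- maj_idx[s:min(s + half - 1L, length(maj_idx))]
    b <- mnr_idx[sample.int(length(mnr_idx), length(a), replace = TRUE)]
    batches[[length(batches) + 1L]] <- c(a, b)
  }
  batches
}

predictor_val_loss <- function(model, x, y, batch = 256L) {
  n <- dim(x)[3]
  tot <- 0
  for (s in seq(1L, n, by = batch)) {
    e <- min(s + batch - 1L, n)
    out <- nn_forward(model, x[, , s:e, drop = FALSE], training = FALSE)$out
    tot <- tot + softmax_xent(out, y[s:e])$loss * (e - s + 1L)
  }
  tot / n
}

#' Fit patient-specific seizure predictors
#'
#' Trains `proto$n_repeats` independent predictors on the supplied
#' selection. In `"standard"` mode all weights start random and everything
#' trains; in `"transfer"` mode the encoder comes from `bundle` and is
#' frozen (bit-identical before and after the fit). Binary cross-entropy is
#' minimised over balanced batches: each batch holds `batch_size/2`
#' majority-class windows and the same number of minority-class windows
#' oversampled with replacement; one epoch is one pass over the majority
#' class.
#'
#' @param x_train,y_train Standardized training windows
#'   `(channels, samples, n)` and labels (1 = interictal, 2 = preictal).
#' @param x_val,y_val Validation windows/labels for early stopping.
#' @param mode `"standard"` or `"transfer"`.
#' @param proto A [train_protocol()].
#' @param pcfg A [predictor_config()].
#' @param bundle Encoder `weight_bundle` (required for `"transfer"`).
#' @return List of `fit_result` objects, one per repeat, each with its
#'   recorded seed.
#' @export
train_predictor <- function(x_train, y_train, x_val, y_val,
                            mode = c("standard", "transfer"),
                            proto = train_protocol(mode),
                            pcfg = predictor_config(), bundle = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(y_train) == dim(x_train)[3],
            length(y_val) == dim(x_val)[3])
  if (length(unique(y_train)) < 2L) {
    stop("both classes must be present in the training selection")
  }
  if (mode == "transfer" && is.null(bundle)) {
    stop("transfer mode requires an encoder weight bundle")
  }
  d <- dim(x_train)
  fits <- vector("list", proto$n_repeats)
  for (r in seq_len(proto$n_repeats)) {
    seed_r <- proto$seed + r
    set.seed(seed_r)
    model <- build_predictor(pcfg, n_channels = d[1], input_len = d[2])
    if (mode == "transfer") {
      model <- transfer_encoder(bundle, model, freeze = TRUE)
    }
    opt <- adam_init()
    best_val <- Inf; best_params <- NULL; best_epoch <- 0L; wait <- 0L
    tl <- vl <- numeric()
    for (epoch in seq_len(proto$max_epochs)) {
      eloss <- 0; nb <- 0L
      for (b in balanced_batches(y_train, proto$batch_size)) {
        xb <- x_train[, , b, drop = FALSE]
        fw <- nn_forward(model, xb, training = TRUE)
        model <- fw$net
        loss <- softmax_xent(fw$out, y_train[b])
        bk <- nn_backward(model, fw$caches, loss$grad)
        st <- adam_step(model, bk$grads, opt, lr = proto$lr)
        model <- st$model; opt <- st$state
        eloss <- eloss + loss$loss; nb <- nb + 1L
      }
      tl[epoch] <- eloss / nb
      vl[epoch] <- predictor_val_loss(model, x_val, y_val)
      if (vl[epoch] < best_val - 1e-9) {
        best_val <- vl[epoch]; best_params <- snapshot_params(model)
        best_epoch <- epoch; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= proto$patience) break
      }
    }
    if (!is.null(best_params)) model <- model_set_params(model, best_params)
    fits[[r]] <- structure(list(model = model, train_loss = tl,
                                val_loss = vl, stopped_epoch = length(tl),
                                best_epoch = best_epoch, seed = seed_r,
                                mode = mode),
                           class = "fit_result")
  }
  fits
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result %s> %d epoch(s), best val %.5f @ epoch %d (seed %d)\n",
              x$mode, x$stopped_epoch,
              if (x$best_epoch > 0) x$val_loss[x$best_epoch] else NA,
              x$best_epoch, x$seed))
  invisible(x)
}
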