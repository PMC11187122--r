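# Model architectures: the deep convolutional autoencoder (DCAE) and the
# encoder + BiLSTM + softmax seizure predictor, plus weight-transfer and
# freezing mechanics.

#' Deep convolutional autoencoder configuration
#'
#' The encoder is a stack of strided `Conv1D -> BatchNorm -> swish ->
#' SpatialDropout` blocks; the decoder alternates nearest-neighbour
#' upsampling with convolutions and restores the input length exactly
#' (the product of encoder strides must equal the product of decoder
#' upsampling factors). The final decoder convolution is linear, since it
#' reconstructs standardized (unbounded) signals.
#'
#' @param enc_filters Integer vector: filters per encoder convolution.
#' @param kernel Convolution kernel length in samples.
#' @param strides Integer vector of per-layer encoder strides (same length
#'   as `enc_filters`).
#' @param dec_filters Filters per decoder convolution (the last entry is
#'   replaced by the channel count at build time).
#' @param upsample Integer vector of decoder upsampling factors.
#' @param spatial_dropout Spatial dropout rate in `[0, 1)`.
#' @return A `dcae_config` list.
#' @export
dcae_config <- function(enc_filters = c(32L, 32L, 64L, 64L, 128L, 128L),
                        kernel = 5L,
                        strides = rep(2L, length(enc_filters)),
                        dec_filters = c(64L, 32L, NA_integer_),
                        upsample = c(4L, 4L, 4L),
                        spatial_dropout = 0.2) {
  stopifnot(length(strides) == length(enc_filters),
            length(upsample) == length(dec_filters),
            spatial_dropout >= 0, spatial_dropout < 1)
  if (prod(strides) != prod(upsample)) {
    stop("encoder stride product (", prod(strides),
         ") must equal decoder upsample product (", prod(upsample),
         ") so the reconstruction has the input length")
  }
  structure(list(enc_filters = as.integer(enc_filters),
                 kernel = as.integer(kernel),
                 strides = as.integer(strides),
                 dec_filters = as.integer(dec_filters),
                 upsample = as.integer(upsample),
                 spatial_dropout = spatial_dropout),
            class = "dcae_config")
}

#' Seizure-predictor configuration
#'
#' @param dcae A [dcae_config()]; only its encoder half is used.
#' @param bilstm_units Hidden units per BiLSTM direction.
#' @param encoder_frozen Logical: if `TRUE` the encoder is a fixed feature
#'   extractor (its weights never change during a fit and its BatchNorm
#'   layers use stored running statistics).
#' @return A `predictor_config` list.
#' @export
predictor_config <- function(dcae = dcae_config(), bilstm_units = 64L,
                             encoder_frozen = FALSE) {
  structure(list(dcae = dcae, bilstm_units = as.integer(bilstm_units),
                 encoder_frozen = isTRUE(encoder_frozen)),
            class = "predictor_config")
}

encoder_layers <- function(cfg, n_channels) {
  layers <- list()
  cin <- n_channels
  for (i in seq_along(cfg$enc_filters)) {
    f <- cfg$enc_filters[i]
    layers <- c(layers, list(
      layer_conv1d(cin, f, kernel = cfg$kernel, stride = cfg$strides[i]),
      layer_batchnorm(f),
      layer_swish(),
      layer_spatial_dropout(cfg$spatial_dropout)
    ))
    cin <- f
  }
  lapply(layers, function(ly) { ly$scope <- "encoder"; ly })
}

#' Build a DCAE model
#'
#' @param cfg A [dcae_config()].
#' @param n_channels Number of input channels.
#' @param input_len Window length in samples (must be divisible by the
#'   stride product).
#' @return A model object (list of layers) mapping
#'   `(n_channels, input_len, batch)` to a reconstruction of the same shape.
#' @export
build_dcae <- function(cfg, n_channels = 19L, input_len = 2560L) {
  down <- prod(cfg$strides)
  if (input_len %% down != 0) {
    stop("input_len must be divisible by the total stride product ", down)
  }
  enc <- encoder_layers(cfg, n_channels)
  dec <- list()
  cin <- cfg$enc_filters[length(cfg$enc_filters)]
  nd <- length(cfg$dec_filters)
  for (i in seq_len(nd)) {
    f <- cfg$dec_filters[i]
    if (is.na(f) || i == nd) f <- n_channels
    dec <- c(dec, list(layer_upsample(cfg$upsample[i]),
                       layer_conv1d(cin, f, kernel = cfg$kernel, stride = 1L)))
    if (i < nd) {
      dec <- c(dec, list(layer_batchnorm(f), layer_swish()))
    }
    cin <- f
  }
  dec <- lapply(dec, function(ly) { ly$scope <- "decoder"; ly })
  structure(list(layers = c(enc, dec), cfg = cfg,
                 n_channels = as.integer(n_channels),
                 input_len = as.integer(input_len), kind = "dcae"),
            class = "seizecast_model")
}

#' Build a seizure-predictor model
#'
#' Encoder blocks (as in the DCAE) feed their temporal feature-map sequence
#' into a BiLSTM; the concatenated final states of both directions pass
#' through one fully connected layer with a two-way softmax
#' (interictal, preictal).
#'
#' @param cfg A [predictor_config()].
#' @inheritParams build_dcae
#' @return A model object; [predict_windows()] yields probability pairs
#'   summing to one.
#' @export
build_predictor <- function(cfg, n_channels = 19L, input_len = 2560L) {
  enc <- encoder_layers(cfg$dcae, n_channels)
  f_last <- cfg$dcae$enc_filters[length(cfg$dcae$enc_filters)]
  head <- list(layer_bilstm(f_last, cfg$bilstm_units),
               layer_dense(2L * cfg$bilstm_units, 2L))
  head <- lapply(head, function(ly) { ly$scope <- "head"; ly })
  model <- structure(list(layers = c(enc, head), cfg = cfg,
                          n_channels = as.integer(n_channels),
                          input_len = as.integer(input_len),
                          kind = "predictor"),
                     class = "seizecast_model")
  if (cfg$encoder_frozen) model <- set_encoder_frozen(model, TRUE)
  model
}

set_encoder_frozen <- function(model, frozen) {
  model$layers <- lapply(model$layers, function(ly) {
    if (identical(ly$scope, "encoder")) {
      ly$trainable <- if (frozen) FALSE else !is.null(ly$params)
      ly$inference_only <- frozen
    }
    ly
  })
  model$cfg$encoder_frozen <- frozen
  model
}

## ---- parameter plumbing -------------------------------------------------

# flat named list "L<i>.<name>" -> array; optionally restricted by scope
model_params <- function(model, scope = NULL) {
  out <- list()
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    if (is.null(ly$params)) next
    if (!is.null(scope) && !identical(ly$scope, scope)) next
    for (nm in names(ly$params)) {
      out[[sprintf("L%02d.%s", i, nm)]] <- ly$params[[nm]]
    }
    if (ly$type == "batchnorm") {
      out[[sprintf("L%02d.running_mean", i)]] <- ly$running_mean
      out[[sprintf("L%02d.running_var", i)]] <- ly$running_var
    }
  }
  out
}

model_set_params <- function(model, params) {
  for (nm in names(params)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    i <- as.integer(sub("^L", "", parts[1]))
    field <- parts[2]
    if (field %in% c("running_mean", "running_var")) {
      model$layers[[i]][[field]] <- params[[nm]]
    } else {
      cur <- model$layers[[i]]$params[[field]]
      if (is.null(cur) || !identical(dim2(cur), dim2(params[[nm]]))) {
        stop("parameter shape mismatch at ", nm)
      }
      model$layers[[i]]$params[[field]] <- params[[nm]]
    }
  }
  model
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

## ---- weight bundles -----------------------------------------------------

# deterministic polynomial rolling hash of a serialised configuration
config_hash <- function(cfg) {
  bytes <- as.integer(serialize(cfg, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Extract a weight bundle
#'
#' A weight bundle packages named parameter tensors with a configuration
#' hash and provenance, so encoder weights can be shared and loaded only
#' into a compatible architecture.
#'
#' @param model A model object.
#' @param scope `"encoder"` (default) or `NULL` for all parameters.
#' @param provenance Named list (e.g. source dataset id, training run id).
#' @return A `weight_bundle`.
#' @export
weight_bundle <- function(model, scope = "encoder", provenance = list()) {
  enc_cfg <- if (inherits(model$cfg, "predictor_config")) model$cfg$dcae else model$cfg
  structure(list(
    params = model_params(model, scope = scope),
    scope = scope,
    config_hash = config_hash(list(enc_cfg[c("enc_filters", "kernel", "strides")],
                                   model$n_channels, model$input_len)),
    provenance = provenance
  ), class = "weight_bundle")
}

#' Save / load a weight bundle
#'
#' Serialisation is byte-stable: saving, loading and saving again produces
#' identical files.
#'
#' @param bundle A `weight_bundle`.
#' @param path File path.
#' @return `load_weight_bundle` returns the bundle; `save_weight_bundle`
#'   returns `path` invisibly.
#' @export
save_weight_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "weight_bundle"))
  con <- file(path, "wb")
  on.exit(close(con))
  serialize(bundle, con, version = 2, xdr = TRUE)
  invisible(path)
}

#' @rdname save_weight_bundle
#' @export
load_weight_bundle <- function(path) {
  b <- readRDS2(path)
  if (!inherits(b, "weight_bundle")) stop("not a weight bundle: ", path)
  b
}

readRDS2 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  unserialize(con)
}

#' Transfer encoder weights into a predictor
#'
#' Copies every encoder tensor from `bundle` into `model` exactly; any shape
#' mismatch aborts listing the offending tensors (never a silent partial
#' load). With `freeze = TRUE` the encoder becomes a fixed feature extractor.
#'
#' @param bundle A `weight_bundle` with encoder scope.
#' @param model A predictor from [build_predictor()].
#' @param freeze Logical.
#' @return The model with transferred (and optionally frozen) encoder.
#' @export
transfer_encoder <- function(bundle, model, freeze = TRUE) {
  stopifnot(inherits(bundle, "weight_bundle"))
  enc_cfg <- model$cfg$dcae
  want <- config_hash(list(enc_cfg[c("enc_filters", "kernel", "strides")],
                           model$n_channels, model$input_len))
  if (!identical(bundle$config_hash, want)) {
    stop("weight bundle configuration hash ", bundle$config_hash,
         " does not match predictor encoder hash ", want)
  }
  have <- model_params(model, scope = "encoder")
  bad <- character()
  for (nm in names(bundle$params)) {
    if (is.null(have[[nm]]) ||
        !identical(dim2(have[[nm]]), dim2(bundle$params[[nm]]))) {
      bad <- c(bad, nm)
    }
  }
  if (length(bad)) {
    stop("encoder tensor shape mismatch: ", paste(bad, collapse = ", "))
  }
  model <- model_set_params(model, bundle$params)
  model <- set_encoder_frozen(model, freeze)
  model$provenance <- bundle$provenance
  model
}

#' Classify standardized windows
#'
#' @param model A predictor model.
#' @param x Array `(channels, samples, n_windows)` of standardized windows.
#' @return Matrix `n_windows x 2` of (interictal, preictal) probabilities,
#'   rows summing to one. Inference is deterministic (dropout off, BatchNorm
#'   running statistics).
#' @export
predict_windows <- function(model, x, batch = 256L) {
  stopifnot(model$kind == "predictor")
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  n <- dim(x)[3]
  out <- matrix(NA_real_, n, 2,
                dimnames = list(NULL, c("interictal", "preictal")))
  for (s in seq(1L, n, by = batch)) {
    e <- min(s + batch - 1L, n)
    logits <- nn_forward(model, x[, , s:e, drop = FALSE], training = FALSE)$out
    m <- apply(logits, 2, max)
    ex <- exp(sweep(logits, 2, m))
    out[s:e, ] <- t(sweep(ex, 2, colSums(ex), "/"))
  }
  out
}

#' @export
print.seizecast_model <- function(x, ...) {
  np <- sum(vapply(model_params(x), length, 1L))
  ntr <- sum(vapply(x$layers, function(ly) {
    if (isTRUE(ly$trainable) && !is.null(ly$params)) {
      sum(vapply(ly$params, length, 1L))
    } else 0L
  }, 1L))
  cat(sprintf("<seizecast %s model> %d channels x %d samples; %d parameters (%d trainable)\n",
              x$kind, x$n_channels, x$input_len, np, ntr))
  invisible(x)
}

## ---- optimiser ----------------------------------------------------------

adam_init <- function() list(t = 0L, m = list(), v = list())

# grads: per-layer list parallel to model$layers (NULL where frozen)
adam_step <- function(model, grads, state, lr = 3e-4,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(model$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (nm in names(g)) {
      key <- sprintf("L%02d.%s", i, nm)
      if (is.null(state$m[[key]])) {
        state$m[[key]] <- g[[nm]] * 0
        state$v[[key]] <- g[[nm]] * 0
      }
      state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * g[[nm]]
      state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * g[[nm]]^2
      upd <- lr * (state$m[[key]] / bc1) / (sqrt(state$v[[key]] / bc2) + eps)
      model$layers[[i]]$params[[nm]] <- model$layers[[i]]$params[[nm]] - upd
    }
  }
  list(model = model, state = state)
}
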