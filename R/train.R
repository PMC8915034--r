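#' Training configuration
#'
#' Defaults: six epochs with batch size 32, Adam at learning rate 1e-3,
#' binary cross-entropy loss.
#'
#' @param epochs Number of passes over the training data.
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam step size.
#' @param beta1,beta2,epsilon Adam moment decay rates and stabilizer.
#' @param seed Seed for weight initialization, shuffling and dropout.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 6L, batch_size = 32L, learning_rate = 1e-3,
                         beta1 = 0.9, beta2 = 0.999, epsilon = 1e-7,
                         seed = 1L) {
  if (epochs < 1L || batch_size < 1L) {
    ecg_abort("epochs and batch_size must be >= 1", "ecgkit_invalid_config")
  }
  structure(
    list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         optimizer = "adam", learning_rate = learning_rate,
         beta1 = beta1, beta2 = beta2, epsilon = epsilon,
         loss = "binary_crossentropy", seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Build and train a 1-D CNN beat classifier
#'
#' Constructs the network described by `spec` in the package's C++ engine
#' and trains it on the dataset's training partition. As a transcription
#' guard, the engine's allocated parameter total must equal the analytic
#' [count_trainable_parameters()]; a mismatch is a hard error. Training is
#' deterministic given the seed.
#'
#' @param spec An [architecture_spec()].
#' @param dataset An `ecg_dataset` from [split_dataset()], or a beats
#'   tibble with `samples` and `label` columns (used whole for training).
#' @param config A [train_config()].
#' @return An `ecg_cnn_fit`: the spec, trained weights, per-epoch training
#'   `history` tibble (`epoch`, `loss`, `accuracy`) and parameter count.
#' @export
build_and_train <- function(spec, dataset, config = train_config()) {
  stopifnot(inherits(spec, "architecture_spec"), inherits(config, "train_config"))
  beats <- if (inherits(dataset, "ecg_dataset")) dataset$train else dataset
  if (nrow(beats) == 0L) ecg_abort("training set is empty", "ecgkit_invalid_input")
  if (length(unique(beats$label)) < 2L) {
    ecg_abort("training set must contain both classes", "ecgkit_invalid_input")
  }
  X <- beats_matrix(beats)
  if (nrow(X) != spec$input_length * spec$input_channels) {
    ecg_abort(sprintf("beat windows (%d samples) do not match the architecture input (%d)",
                      nrow(X), spec$input_length * spec$input_channels),
              "ecgkit_invalid_input")
  }
  analytic <- count_trainable_parameters(spec)
  enc <- encode_layers(spec)
  backend_total <- cpp_cnn_param_count(enc, spec$input_length, spec$input_channels)
  if (backend_total != analytic) {
    ecg_abort(sprintf(
      "engine allocated %s parameters but the analytic count is %s: architecture transcription bug",
      format(backend_total, big.mark = ","), format(analytic, big.mark = ",")
    ), "ecgkit_param_mismatch")
  }
  res <- cpp_cnn_train(
    enc, X, as.integer(beats$label), spec$input_channels,
    config$epochs, config$batch_size, config$learning_rate,
    config$beta1, config$beta2, config$epsilon, config$seed
  )
  if (res$n_params != analytic) {
    ecg_abort("engine parameter total diverged from the analytic count", "ecgkit_param_mismatch")
  }
  structure(
    list(
      spec = spec,
      weights = res$weights,
      history = tibble(epoch = seq_len(config$epochs),
                       loss = as.numeric(res$loss),
                       accuracy = as.numeric(res$accuracy)),
      n_params = as.integer(res$n_params),
      config = config
    ),
    class = "ecg_cnn_fit"
  )
}

#' @export
print.ecg_cnn_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf(
    "<ecg_cnn_fit '%s'> %s parameters; %d epochs (final training loss %.4f, accuracy %.4f)\n",
    x$spec$name, format(x$n_params, big.mark = ","), nrow(x$history),
    last$loss, last$accuracy
  ))
  invisible(x)
}

#' Predict abnormality probabilities for beat segments
#'
#' Runs the trained network forward (no dropout); outputs are sigmoid
#' probabilities in `[0, 1]`. Thresholding at 0.5 gives hard labels.
#'
#' @param fit An `ecg_cnn_fit`.
#' @param segments A beats tibble with a `samples` list-column, or a
#'   numeric matrix with one column per beat.
#' @return Numeric vector of probabilities.
#' @export
predict_scores <- function(fit, segments) {
  stopifnot(inherits(fit, "ecg_cnn_fit"))
  X <- if (is.matrix(segments)) segments else beats_matrix(segments)
  expected <- fit$spec$input_length * fit$spec$input_channels
  if (nrow(X) != expected) {
    ecg_abort(sprintf("segments have %d samples, expected %d", nrow(X), expected),
              "ecgkit_invalid_input")
  }
  as.numeric(cpp_cnn_predict(encode_layers(fit$spec), fit$weights, X,
                             fit$spec$input_channels))
}

#' @export
#' @rdname build_and_train
#' @param x An `ecg_cnn_fit`.
#' @param ... Unused.
tidy.ecg_cnn_fit <- function(x, ...) x$history

#' @export
#' @rdname build_and_train
glance.ecg_cnn_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble(
    model = x$spec$name,
    n_params = x$n_params,
    epochs = nrow(x$history),
    final_loss = last$loss,
    final_accuracy = last$accuracy
  )
}

#' @export
#' @rdname build_and_train
#' @param object An `ecg_cnn_fit`.
autoplot.ecg_cnn_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, c("loss", "accuracy"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(title = sprintf("Training history: %s", object$spec$name),
                  x = "Epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' Save / load a trained classifier as JSON
#'
#' Weights are stored as plain JSON arrays next to the architecture
#' description and the analytic parameter count, so a saved model is a
#' text artifact.
#'
#' @param fit An `ecg_cnn_fit`.
#' @param path Output file.
#' @export
save_model <- function(fit, path) {
  stopifnot(inherits(fit, "ecg_cnn_fit"))
  spec <- fit$spec
  obj <- list(
    name = spec$name,
    input_length = spec$input_length,
    input_channels = spec$input_channels,
    layers = spec$layers,
    n_params = fit$n_params,
    history = fit$history,
    weights = lapply(fit$weights, function(w) {
      if (is.matrix(w)) list(dim = dim(w), data = as.numeric(w))
      else list(dim = length(w), data = as.numeric(w))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  layers <- lapply(obj$layers, function(l) {
    l$type <- as.character(l$type)
    for (f in intersect(names(l), c("filters", "kernel", "units", "pool", "stride"))) {
      l[[f]] <- as.integer(l[[f]])
    }
    if (!is.null(l$rate)) l$rate <- as.numeric(l$rate)
    if (!is.null(l$activation)) l$activation <- as.character(l$activation)
    l
  })
  spec <- architecture_spec(obj$name, layers, as.integer(obj$input_length),
                            as.integer(obj$input_channels))
  weights <- lapply(obj$weights, function(w) {
    dim <- unlist(w$dim)
    data <- unlist(w$data)
    if (length(dim) == 2L) matrix(data, dim[1], dim[2]) else as.numeric(data)
  })
  history <- tibble(
    epoch = vapply(obj$history, function(h) as.integer(h$epoch), integer(1)),
    loss = vapply(obj$history, function(h) as.numeric(h$loss), numeric(1)),
    accuracy = vapply(obj$history, function(h) as.numeric(h$accuracy), numeric(1))
  )
  structure(
    list(spec = spec, weights = weights, history = history,
         n_params = as.integer(obj$n_params), config = NULL),
    class = "ecg_cnn_fit"
  )
}
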