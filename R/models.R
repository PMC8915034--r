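#' Layer descriptors for 1-D convolutional networks
#'
#' Building blocks for [architecture_spec()]: valid (unpadded) 1-D
#' convolutions with ReLU activation, length-halving max pooling
#' (pool 2, stride 2, floor), dropout, flatten, and dense layers.
#'
#' @param filters Number of convolution filters.
#' @param kernel Kernel length in samples.
#' @param rate Dropout rate in (0, 1).
#' @param units Dense layer width.
#' @param activation `"relu"` or `"sigmoid"`.
#' @return A list describing the layer.
#' @name layer_specs
NULL

#' @rdname layer_specs
#' @export
conv1d <- function(filters, kernel) {
  stopifnot(filters >= 1, kernel >= 1)
  list(type = "conv1d", filters = as.integer(filters), kernel = as.integer(kernel))
}

#' @rdname layer_specs
#' @export
max_pool1d <- function() list(type = "max_pool1d", pool = 2L, stride = 2L)

#' @rdname layer_specs
#' @export
dropout <- function(rate) {
  stopifnot(rate > 0, rate < 1)
  list(type = "dropout", rate = rate)
}

#' @rdname layer_specs
#' @export
flatten <- function() list(type = "flatten")

#' @rdname layer_specs
#' @export
dense <- function(units, activation = c("relu", "sigmoid")) {
  stopifnot(units >= 1)
  list(type = "dense", units = as.integer(units), activation = match.arg(activation))
}

#' Assemble a 1-D CNN architecture
#'
#' Validates that the network ends in a single-unit sigmoid dense layer
#' (binary output) and that a flatten layer precedes the first dense
#' layer.
#'
#' @param name Architecture name.
#' @param layers List of layer descriptors (see [layer_specs]).
#' @param input_length Input window length in samples.
#' @param input_channels Number of input channels.
#' @return A list of class `architecture_spec`.
#' @export
architecture_spec <- function(name, layers, input_length = 2160L, input_channels = 1L) {
  types <- vapply(layers, `[[`, "", "type")
  last <- layers[[length(layers)]]
  if (last$type != "dense" || last$units != 1L || last$activation != "sigmoid") {
    ecg_abort("architecture must end in a single-unit sigmoid dense layer",
              "ecgkit_invalid_spec")
  }
  first_dense <- which(types == "dense")[1L]
  if (!any(types[seq_len(first_dense - 1L)] == "flatten")) {
    ecg_abort("a flatten layer must precede the first dense layer", "ecgkit_invalid_spec")
  }
  structure(
    list(name = name, input_length = as.integer(input_length),
         input_channels = as.integer(input_channels), layers = layers),
    class = "architecture_spec"
  )
}

#' @export
print.architecture_spec <- function(x, ...) {
  cat(sprintf("<architecture_spec '%s'> input (%d, %d)\n",
              x$name, x$input_length, x$input_channels))
  shapes <- propagate_shapes(x)
  for (i in seq_along(x$layers)) {
    l <- x$layers[[i]]
    desc <- switch(l$type,
      conv1d = sprintf("conv1d(filters=%d, kernel=%d, relu)", l$filters, l$kernel),
      max_pool1d = "max_pool1d(2, 2)",
      dropout = sprintf("dropout(%.2f)", l$rate),
      flatten = "flatten",
      dense = sprintf("dense(%d, %s)", l$units, l$activation)
    )
    cat(sprintf("  %2d. %-36s -> %s\n", i, desc, shapes[[i]]))
  }
  cat(sprintf("  trainable parameters: %s\n",
              format(count_trainable_parameters(x), big.mark = ",")))
  invisible(x)
}

# Shape bookkeeping shared by printing and counting: valid convolution
# shrinks length by kernel - 1; pooling floor-halves it.
propagate_shapes <- function(spec) {
  len <- spec$input_length; ch <- spec$input_channels; flat <- NA_integer_
  out <- character(length(spec$layers))
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    if (l$type == "conv1d") {
      len <- len - l$kernel + 1L
      if (len < 1L) {
        ecg_abort(sprintf("layer %d (conv1d kernel %d) leaves a non-positive length",
                          i, l$kernel), "ecgkit_invalid_spec")
      }
      ch <- l$filters
      out[i] <- sprintf("(%d, %d)", len, ch)
    } else if (l$type == "max_pool1d") {
      len <- len %/% 2L
      if (len < 1L) {
        ecg_abort(sprintf("layer %d (max_pool1d) leaves a non-positive length", i),
                  "ecgkit_invalid_spec")
      }
      out[i] <- sprintf("(%d, %d)", len, ch)
    } else if (l$type == "flatten") {
      flat <- len * ch
      out[i] <- sprintf("(%d)", flat)
    } else if (l$type == "dense") {
      flat <- l$units
      out[i] <- sprintf("(%d)", flat)
    } else {
      out[i] <- if (is.na(flat)) sprintf("(%d, %d)", len, ch) else sprintf("(%d)", flat)
    }
  }
  out
}

#' Analytic trainable-parameter count
#'
#' Counts parameters without any tensor backend: a convolution with kernel
#' `K`, input depth `D` and `L` filters adds `(K * D + 1) * L`; a dense
#' layer adds `(fan_in + 1) * units`; pooling, dropout and flatten add
#' none. Lengths propagate as `length - K + 1` after a valid convolution
#' and `floor(length / 2)` after pooling.
#'
#' @param spec An [architecture_spec()].
#' @return Integer parameter total.
#' @export
count_trainable_parameters <- function(spec) {
  stopifnot(inherits(spec, "architecture_spec"))
  len <- spec$input_length; ch <- spec$input_channels
  flat <- NA_integer_; total <- 0
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    switch(l$type,
      conv1d = {
        total <- total + (l$kernel * ch + 1) * l$filters
        len <- len - l$kernel + 1L
        if (len < 1L) {
          ecg_abort(sprintf("layer %d (conv1d) leaves a non-positive length", i),
                    "ecgkit_invalid_spec")
        }
        ch <- l$filters
      },
      max_pool1d = {
        len <- len %/% 2L
        if (len < 1L) {
          ecg_abort(sprintf("layer %d (max_pool1d) leaves a non-positive length", i),
                    "ecgkit_invalid_spec")
        }
      },
      flatten = flat <- len * ch,
      dense = {
        total <- total + (flat + 1) * l$units
        flat <- l$units
      },
      dropout = NULL
    )
  }
  as.integer(total)
}

# conv/dropout/pool block repeated throughout the three architectures
conv_block <- function(filters, kernel, rate) {
  list(conv1d(filters, kernel), dropout(rate), max_pool1d())
}

#' The three custom CNN beat classifiers
#'
#' Model 1: five conv/dropout/pool blocks (filters 400, 256, 178, 88, 44;
#' kernels 20, 15, 7, 5, 3; dropout 0.5 for the first three blocks, 0.25
#' for the last two) and a single sigmoid output — 1,956,651 parameters.
#'
#' Model 2: five blocks (filters 600, 400, 256, 178, 88; kernels 20, 15,
#' 10, 7, 20; dropout 0.25 throughout) and a sigmoid output — 5,274,443
#' parameters.
#'
#' Model 3: four blocks (filters 256, 128, 72, 36; kernel 5 everywhere;
#' dropout 0.5) and dense layers of 50, 32 and 1 units — 462,167
#' parameters.
#'
#' All take a z-scored window of shape (2160, 1), use valid convolutions,
#' ReLU activations, and pool-2/stride-2 max pooling with floor division.
#'
#' @return An [architecture_spec()].
#' @name model_specs
NULL

#' @rdname model_specs
#' @export
model1_spec <- function() {
  architecture_spec("model1", c(
    conv_block(400, 20, 0.5),
    conv_block(256, 15, 0.5),
    conv_block(178, 7, 0.5),
    conv_block(88, 5, 0.25),
    conv_block(44, 3, 0.25),
    list(flatten(), dense(1, "sigmoid"))
  ))
}

#' @rdname model_specs
#' @export
model2_spec <- function() {
  architecture_spec("model2", c(
    conv_block(600, 20, 0.25),
    conv_block(400, 15, 0.25),
    conv_block(256, 10, 0.25),
    conv_block(178, 7, 0.25),
    conv_block(88, 20, 0.25),
    list(flatten(), dense(1, "sigmoid"))
  ))
}

#' @rdname model_specs
#' @export
model3_spec <- function() {
  architecture_spec("model3", c(
    conv_block(256, 5, 0.5),
    conv_block(128, 5, 0.5),
    conv_block(72, 5, 0.5),
    conv_block(36, 5, 0.5),
    list(flatten(), dense(50, "relu"), dense(32, "relu"), dense(1, "sigmoid"))
  ))
}

#' Per-layer multiply count for the convolutional stack
#'
#' For each convolution, the number of multiplications is
#' `K * N_out * D * L` (kernel length times output length times input
#' depth times filter count), the dominant cost term of these networks.
#'
#' @param spec An [architecture_spec()].
#' @return Tibble with one row per convolution layer: `layer`, `kernel`,
#'   `depth`, `filters`, `out_length`, `multiplies`.
#' @export
conv_multiply_counts <- function(spec) {
  len <- spec$input_length; ch <- spec$input_channels
  rows <- list()
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    if (l$type == "conv1d") {
      out_len <- len - l$kernel + 1L
      rows[[length(rows) + 1L]] <- tibble(
        layer = i, kernel = l$kernel, depth = ch, filters = l$filters,
        out_length = out_len,
        multiplies = as.numeric(l$kernel) * out_len * ch * l$filters
      )
      len <- out_len; ch <- l$filters
    } else if (l$type == "max_pool1d") {
      len <- len %/% 2L
    }
  }
  bind_rows(rows)
}

# Encode an architecture_spec as the integer matrix the C++ engine takes.
# Columns: type (1 conv, 2 pool, 3 dropout, 4 flatten, 5 dense), p1, p2.
# conv: p1 = kernel, p2 = filters; dropout: p1 = rate in per-mille;
# dense: p1 = units, p2 = 1 for sigmoid else 0.
encode_layers <- function(spec) {
  enc <- t(vapply(spec$layers, function(l) {
    switch(l$type,
      conv1d = c(1L, l$kernel, l$filters),
      max_pool1d = c(2L, 0L, 0L),
      dropout = c(3L, as.integer(round(l$rate * 1000)), 0L),
      flatten = c(4L, 0L, 0L),
      dense = c(5L, l$units, as.integer(l$activation == "sigmoid"))
    )
  }, integer(3)))
  storage.mode(enc) <- "integer"
  enc
}
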