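test_that("parameter counting follows the closed-form layer rules", {
  # single conv: (K*D + 1) * L
  s <- architecture_spec("toy", list(conv1d(8, 5), flatten(), dense(1, "sigmoid")),
                         input_length = 32L)
  # conv: (5*1+1)*8 = 48; dense: (28*8 + 1)*1 = 225
  expect_identical(count_trainable_parameters(s), 48L + 225L)
  # pooling and dropout add nothing but pooling halves the flatten length
  s2 <- architecture_spec("toy2",
                          list(conv1d(8, 5), dropout(0.5), max_pool1d(),
                               flatten(), dense(1, "sigmoid")),
                          input_length = 32L)
  expect_identical(count_trainable_parameters(s2), 48L + (14L * 8L + 1L))
  # stacked dense layers chain fan-in
  s3 <- architecture_spec("toy3",
                          list(flatten(), dense(4), dense(1, "sigmoid")),
                          input_length = 10L)
  expect_identical(count_trainable_parameters(s3), (10L + 1L) * 4L + 5L)
})

test_that("the three beat classifiers have their exact parameter totals", {
  expect_identical(count_trainable_parameters(model1_spec()), 1956651L)
  expect_identical(count_trainable_parameters(model2_spec()), 5274443L)
  expect_identical(count_trainable_parameters(model3_spec()), 462167L)
})

test_that("engine-side parameter allocation matches the analytic count", {
  for (spec in list(model1_spec(), model2_spec(), model3_spec())) {
    expect_identical(
      as.integer(cpp_cnn_param_count(encode_layers(spec), spec$input_length,
                                     spec$input_channels)),
      count_trainable_parameters(spec)
    )
  }
})

test_that("flatten widths propagate through valid convolutions and floor pooling", {
  flatten_width <- function(spec) {
    len <- spec$input_length; ch <- spec$input_channels
    for (l in spec$layers) {
      if (l$type == "conv1d") { len <- len - l$kernel + 1L; ch <- l$filters }
      if (l$type == "max_pool1d") len <- len %/% 2L
      if (l$type == "flatten") return(len * ch)
    }
  }
  expect_identical(flatten_width(model1_spec()), 63L * 44L)   # 2772
  expect_identical(flatten_width(model2_spec()), 53L * 88L)   # 4664
  expect_identical(flatten_width(model3_spec()), 131L * 36L)  # 4716
})

test_that("convolution multiply counts follow K * N * D * L", {
  s <- architecture_spec("toy",
                         list(conv1d(4, 3), max_pool1d(), conv1d(6, 3),
                              flatten(), dense(1, "sigmoid")),
                         input_length = 20L)
  mc <- conv_multiply_counts(s)
  expect_equal(nrow(mc), 2L)
  # layer 1: K=3, N=18, D=1, L=4; layer 3: K=3, N=7 (from 9), D=4, L=6
  expect_equal(mc$multiplies, c(3 * 18 * 1 * 4, 3 * 7 * 4 * 6))
  mc3 <- conv_multiply_counts(model3_spec())
  expect_equal(nrow(mc3), 4L)
  expect_equal(mc3$multiplies[1], 5 * 2156 * 1 * 256)
})

test_that("invalid architectures are rejected with classed errors", {
  expect_error(architecture_spec("bad", list(flatten(), dense(2, "sigmoid"))),
               class = "ecgkit_invalid_spec")
  expect_error(architecture_spec("bad", list(flatten(), dense(1, "relu"))),
               class = "ecgkit_invalid_spec")
  expect_error(architecture_spec("bad", list(dense(1, "sigmoid"))),
               class = "ecgkit_invalid_spec")
  shrunk <- architecture_spec("bad", list(conv1d(2, 50), flatten(), dense(1, "sigmoid")),
                              input_length = 40L)
  expect_error(count_trainable_parameters(shrunk), class = "ecgkit_invalid_spec")
})

# a tiny architecture + separable dataset reused by the training tests
tiny_spec <- function(input_length = 64L) {
  architecture_spec("tiny",
                    c(conv_block(4, 5, 0.25), conv_block(8, 3, 0.25),
                      list(flatten(), dense(8), dense(1, "sigmoid"))),
                    input_length = input_length)
}

tiny_beats <- function(n = 60, len = 64L, seed = 61) {
  set.seed(seed)
  label <- rep(0:1, length.out = n)
  samples <- lapply(label, function(l) {
    base <- if (l == 1) sin(seq_len(len) / 3) else numeric(len)
    zscore_raw <- base + rnorm(len, sd = 0.3)
    (zscore_raw - mean(zscore_raw)) / stats::sd(zscore_raw)
  })
  tibble::tibble(source_index = seq_len(n), symbol = ifelse(label == 1, "V", "N"),
                 label = as.integer(label), samples = samples)
}

test_that("training learns a separable problem and is deterministic in the seed", {
  beats <- tiny_beats()
  cfg <- train_config(epochs = 8L, batch_size = 8L, seed = 7L)
  fit <- build_and_train(tiny_spec(), beats, cfg)
  expect_s3_class(fit, "ecg_cnn_fit")
  expect_equal(nrow(fit$history), 8L)
  expect_lt(fit$history$loss[8], fit$history$loss[1])
  scores <- predict_scores(fit, beats)
  expect_true(all(scores >= 0 & scores <= 1))
  acc <- mean((scores > 0.5) == beats$label)
  expect_gte(acc, 0.9)
  # same seed, identical weights and history
  fit2 <- build_and_train(tiny_spec(), beats, cfg)
  expect_identical(fit$weights, fit2$weights)
  expect_identical(fit$history, fit2$history)
  # different seed, different weights
  fit3 <- build_and_train(tiny_spec(), beats, train_config(epochs = 8L, batch_size = 8L, seed = 8L))
  expect_false(identical(fit$weights, fit3$weights))
})

test_that("prediction is deterministic and batch-order invariant", {
  beats <- tiny_beats(n = 20)
  fit <- build_and_train(tiny_spec(), beats, train_config(epochs = 2L, batch_size = 8L, seed = 3L))
  s1 <- predict_scores(fit, beats)
  s2 <- predict_scores(fit, beats)
  expect_identical(s1, s2)
  perm <- rev(seq_len(nrow(beats)))
  expect_equal(predict_scores(fit, beats[perm, ]), s1[perm], tolerance = 1e-6)
})

test_that("training rejects degenerate inputs", {
  beats <- tiny_beats(n = 10)
  one_class <- beats[beats$label == 0, ]
  expect_error(build_and_train(tiny_spec(), one_class), class = "ecgkit_invalid_input")
  expect_error(build_and_train(tiny_spec(), beats[0, ]), class = "ecgkit_invalid_input")
  wrong_len <- beats
  wrong_len$samples <- lapply(wrong_len$samples, function(s) s[1:32])
  expect_error(build_and_train(tiny_spec(), wrong_len), class = "ecgkit_invalid_input")
})

test_that("a saved model reloads to identical predictions", {
  beats <- tiny_beats(n = 24)
  fit <- build_and_train(tiny_spec(), beats, train_config(epochs = 2L, batch_size = 8L, seed = 5L))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(fit, path)
  back <- load_model(path)
  expect_identical(back$n_params, fit$n_params)
  expect_equal(back$weights, fit$weights, tolerance = 1e-12)
  expect_equal(predict_scores(back, beats), predict_scores(fit, beats), tolerance = 1e-12)
  expect_equal(back$history, fit$history)
})

test_that("tidy, glance and print summarize a fit", {
  beats <- tiny_beats(n = 16)
  fit <- build_and_train(tiny_spec(), beats, train_config(epochs = 3L, batch_size = 8L, seed = 2L))
  expect_identical(tidy(fit), fit$history)
  g <- glance(fit)
  expect_equal(g$model, "tiny")
  expect_equal(g$epochs, 3L)
  expect_equal(g$n_params, count_trainable_parameters(tiny_spec()))
  expect_output(print(fit), "ecg_cnn_fit")
  expect_output(print(model3_spec()), "462,167")
})
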