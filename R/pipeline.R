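#' Benchmark denoising filters by PSNR
#'
#' For each record: takes the clean channel as reference, adds noise,
#' applies every filter, and scores PSNR against the clean original. A
#' `"none"` baseline row (the noisy signal itself, no filtering) is
#' included so each filter's gain over doing nothing is visible. Per-record
#' noise realizations differ (seed offset by record position) while
#' remaining fully reproducible.
#'
#' @param records List of [ecg_record()] objects (or a single record).
#' @param noise A [noise_spec()].
#' @param filters Named list of [filter_config()]s
#'   (default [default_filter_set()]).
#' @param channel 0-based channel used as the clean reference.
#' @param include_baseline Include the no-op `"none"` row.
#' @return Tibble with one row per filter — `filter`, `mean_psnr_db`,
#'   `sd_psnr_db`, `n_records`, `n_failed` — sorted by ascending mean
#'   PSNR. The per-record long table is attached as attribute
#'   `"per_record"`.
#' @export
run_benchmark <- function(records, noise, filters = default_filter_set(),
                          channel = 0L, include_baseline = TRUE) {
  if (inherits(records, "ecg_record")) records <- list(records)
  if (length(records) == 0L) ecg_abort("need at least one record", "ecgkit_invalid_input")
  stopifnot(inherits(noise, "noise_spec"))
  if (include_baseline && !"none" %in% names(filters)) {
    filters <- c(filters, list(none = filter_config("none")))
  }
  rows <- list()
  for (r in seq_along(records)) {
    rec <- records[[r]]
    clean <- record_channel(rec, channel)
    spec_r <- noise
    spec_r$seed <- noise$seed + r - 1L
    noisy <- add_noise(clean, spec_r, rec$header$sampling_rate)
    for (f in names(filters)) {
      value <- tryCatch(
        psnr(clean, apply_filter(noisy, filters[[f]], rec$header$sampling_rate)),
        error = function(e) {
          ecg_warn(sprintf("filter '%s' failed on record %d: %s",
                           f, r, conditionMessage(e)), "ecgkit_filter_failure")
          NA_real_
        }
      )
      rows[[length(rows) + 1L]] <- tibble(record = r, filter = f, psnr_db = value)
    }
  }
  per_record <- bind_rows(rows)
  out <- per_record %>%
    group_by(.data$filter) %>%
    summarise(
      mean_psnr_db = mean(.data$psnr_db, na.rm = TRUE),
      sd_psnr_db = stats::sd(.data$psnr_db, na.rm = TRUE),
      n_records = sum(!is.na(.data$psnr_db)),
      n_failed = sum(is.na(.data$psnr_db)),
      .groups = "drop"
    ) %>%
    arrange(.data$mean_psnr_db)
  attr(out, "per_record") <- per_record
  out
}

#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end run: simulation, noise, the
#' denoising filter (the median filter by default — robust, cheap, and
#' artifact-tolerant), segmentation, split and training. One seed propagates
#' to every stochastic stage (offset per stage so realizations differ but
#' remain reproducible).
#'
#' @param seed Master seed.
#' @param sim A [sim_config()]; by default a 5-minute two-class recording.
#' @param noise A [noise_spec()] (`NULL` skips noise injection).
#' @param filter A [filter_config()] for the denoising stage
#'   (`NULL` skips denoising).
#' @param segment_length Beat window length in samples.
#' @param channel 0-based channel fed to segmentation.
#' @param ratio Training fraction of the split.
#' @param model `"model1"`, `"model2"` or `"model3"`.
#' @param train A [train_config()] (its seed is overridden by `seed`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            sim = sim_config(duration = 300, fraction_abnormal = 0.3,
                                             seed = seed),
                            noise = noise_spec(snr_db = 10, seed = seed + 1L),
                            filter = filter_config("median"),
                            segment_length = 2160L,
                            channel = 0L,
                            ratio = 0.8,
                            model = c("model3", "model1", "model2"),
                            train = train_config(seed = seed + 3L)) {
  model <- match.arg(model)
  structure(
    list(seed = as.integer(seed), sim = sim, noise = noise, filter = filter,
         segment_length = as.integer(segment_length), channel = as.integer(channel),
         ratio = ratio, model = model, train = train),
    class = "pipeline_config"
  )
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    ecg_abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
              paste0("ecgkit_stage_", name))
  })
}

#' Run the full classification pipeline
#'
#' Simulate (or take a provided record), add noise, denoise with the
#' configured filter, segment into z-scored beat windows, split, train the
#' selected network, and evaluate on the held-out test beats. All
#' artifacts — metrics JSON, ROC and confusion CSVs, training history,
#' model weights and a manifest with every seed — are written under
#' `out_dir`. Two runs with the same configuration produce identical
#' manifests and metrics.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Artifact directory (created if needed), or `NULL` to
#'   skip writing files.
#' @param record Optional [ecg_record()] to use instead of simulating.
#' @return A list of class `pipeline_result`: `record`, `denoised`,
#'   `dataset`, `fit`, `report`, `manifest`, `paths`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL, record = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  paths <- character(0)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  clean <- pipeline_stage("simulate", {
    if (is.null(record)) generate_clean_ecg(config$sim) else record
  })

  noisy_signal <- pipeline_stage("noise", {
    x <- record_channel(clean, config$channel)
    if (is.null(config$noise)) x
    else add_noise(x, config$noise, clean$header$sampling_rate)
  })

  denoised_signal <- pipeline_stage("denoise", {
    if (is.null(config$filter)) noisy_signal
    else apply_filter(noisy_signal, config$filter, clean$header$sampling_rate)
  })
  denoised <- ecg_record(denoised_signal, clean$header$sampling_rate,
                         annotations = clean$annotations,
                         record_name = paste0(clean$header$record_name, "_dn"))

  dataset <- pipeline_stage("segment", {
    beats <- make_beats(denoised, length = config$segment_length, channel = 0L)
    split_dataset(beats, ratio = config$ratio, seed = config$seed + 2L)
  })

  fit <- pipeline_stage("train", {
    spec <- switch(config$model,
                   model1 = model1_spec(), model2 = model2_spec(), model3 = model3_spec())
    build_and_train(spec, dataset, config$train)
  })

  report <- pipeline_stage("evaluate", {
    scores <- predict_scores(fit, dataset$test)
    evaluate_predictions(dataset$test$label, scores)
  })

  manifest <- list(
    tool = "ecgkit",
    version = as.character(utils::packageVersion("ecgkit")),
    seed = config$seed,
    stage_seeds = list(simulate = config$sim$seed,
                       noise = if (is.null(config$noise)) NULL else config$noise$seed,
                       split = config$seed + 2L,
                       train = config$train$seed),
    sampling_rate = clean$header$sampling_rate,
    duration_s = clean$header$n_samples / clean$header$sampling_rate,
    filter = if (is.null(config$filter)) "none" else config$filter$type,
    segment_length = config$segment_length,
    split = list(ratio = config$ratio,
                 n_train = nrow(dataset$train), n_test = nrow(dataset$test)),
    model = config$model,
    n_params = fit$n_params,
    train = list(epochs = fit$config$epochs, batch_size = fit$config$batch_size,
                 optimizer = fit$config$optimizer,
                 learning_rate = fit$config$learning_rate),
    metrics = as.list(report$metrics)
  )

  if (!is.null(out_dir)) {
    paths <- c(
      manifest = file.path(out_dir, "manifest.json"),
      metrics = file.path(out_dir, "metrics.json"),
      roc = file.path(out_dir, "roc.csv"),
      confusion = file.path(out_dir, "confusion.csv"),
      history = file.path(out_dir, "history.csv"),
      model = file.path(out_dir, "model.json")
    )
    jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(as.list(report$metrics), paths[["metrics"]],
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(report$roc$points, paths[["roc"]], row.names = FALSE)
    utils::write.csv(
      data.frame(TP = report$counts$TP, FP = report$counts$FP,
                 TN = report$counts$TN, FN = report$counts$FN),
      paths[["confusion"]], row.names = FALSE
    )
    utils::write.csv(fit$history, paths[["history"]], row.names = FALSE)
    save_model(fit, paths[["model"]])
  }

  structure(
    list(record = clean, denoised = denoised, dataset = dataset, fit = fit,
         report = report, manifest = manifest, paths = paths),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> model %s on %d train / %d test beats\n",
              x$manifest$model, x$manifest$split$n_train, x$manifest$split$n_test))
  print(x$report$metrics)
  invisible(x)
}

#' Plot a stretch of an ECG record with its annotations
#'
#' @param object An [ecg_record()].
#' @param channel 0-based channel.
#' @param from,to Time window in seconds.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ecg_record <- function(object, channel = 0L, from = 0,
                                to = min(10, object$header$n_samples /
                                           object$header$sampling_rate), ...) {
  fs <- object$header$sampling_rate
  x <- record_channel(object, channel)
  idx <- which((seq_along(x) - 1) / fs >= from & (seq_along(x) - 1) / fs <= to)
  df <- tibble(time_s = (idx - 1) / fs, mV = x[idx])
  ann <- object$annotations
  ann <- ann[ann$sample_index / fs >= from & ann$sample_index / fs <= to, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$mV)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (s)", y = "Amplitude (mV)",
                  title = object$header$record_name) +
    ggplot2::theme_minimal()
  if (nrow(ann) > 0) {
    p <- p + ggplot2::annotate("text", x = ann$sample_index / fs,
                               y = max(df$mV) * 1.05, label = ann$symbol,
                               size = 3, colour = "firebrick")
  }
  p
}

#' Compare clean, noisy and denoised signals in one plot
#'
#' @param clean,noisy,denoised Numeric signals of equal length.
#' @param sampling_rate Hz.
#' @param from,to Time window in seconds.
#' @return A ggplot faceted by signal version.
#' @export
plot_denoising <- function(clean, noisy, denoised, sampling_rate = 360,
                           from = 0, to = 5) {
  n <- length(clean)
  t <- (seq_len(n) - 1) / sampling_rate
  keep <- t >= from & t <= to
  df <- bind_rows(
    tibble(time_s = t[keep], mV = clean[keep], signal = "1 clean"),
    tibble(time_s = t[keep], mV = noisy[keep], signal = "2 noisy"),
    tibble(time_s = t[keep], mV = denoised[keep], signal = "3 denoised")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$mV)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~signal, ncol = 1) +
    ggplot2::labs(x = "Time (s)", y = "Amplitude (mV)") +
    ggplot2::theme_minimal()
}
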