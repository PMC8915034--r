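#' Construct an ECG record
#'
#' The central container of the toolkit: a multi-channel sampled waveform in
#' millivolts together with its acquisition metadata and per-beat
#' annotations. MIT-BIH-style records are two-channel at 360 Hz; synthetic
#' records from [generate_clean_ecg()] are single-channel.
#'
#' @param signal Numeric matrix (`n_samples x n_channels`) of amplitudes in
#'   mV, or a numeric vector for a single channel.
#' @param sampling_rate Sampling rate in Hz.
#' @param annotations Tibble/data frame with columns `sample_index`
#'   (0-based) and `symbol` (single-character beat code such as `"N"` or
#'   `"V"`), or `NULL`.
#' @param record_name Record identifier used in file names.
#' @param gain ADC units per mV, one per channel (recycled).
#' @param baseline ADC baseline offset, one per channel (recycled).
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(signal, sampling_rate, annotations = NULL,
                       record_name = "rec", gain = 200, baseline = 0) {
  if (is.vector(signal)) signal <- matrix(as.numeric(signal), ncol = 1L)
  storage.mode(signal) <- "double"
  n_channels <- ncol(signal)
  gain <- rep_len(as.numeric(gain), n_channels)
  baseline <- rep_len(as.numeric(baseline), n_channels)
  if (sampling_rate <= 0) ecg_abort("sampling_rate must be > 0", "ecgkit_invalid_record")
  if (any(gain <= 0)) ecg_abort("gains must be > 0", "ecgkit_invalid_record")
  annotations <- normalize_annotations(annotations, nrow(signal))
  structure(
    list(
      header = list(
        record_name = record_name,
        n_channels = n_channels,
        sampling_rate = as.numeric(sampling_rate),
        n_samples = nrow(signal),
        gain = gain,
        baseline = baseline
      ),
      signal = signal,
      annotations = annotations
    ),
    class = "ecg_record"
  )
}

normalize_annotations <- function(annotations, n_samples) {
  if (is.null(annotations) || nrow(annotations) == 0L) {
    return(tibble(sample_index = integer(0), symbol = character(0)))
  }
  ann <- as_tibble(annotations)[, c("sample_index", "symbol")]
  ann$sample_index <- as.integer(ann$sample_index)
  ann$symbol <- as.character(ann$symbol)
  if (any(!nzchar(ann$symbol))) ecg_abort("annotation symbols must be non-empty", "ecgkit_invalid_record")
  if (any(ann$sample_index < 0L | ann$sample_index >= n_samples)) {
    ecg_abort("annotation sample_index out of range [0, n_samples)", "ecgkit_invalid_record")
  }
  ann <- ann[order(ann$sample_index), ]
  if (anyDuplicated(ann$sample_index)) {
    ecg_abort("annotation sample_index values must be unique", "ecgkit_invalid_record")
  }
  ann
}

#' @export
print.ecg_record <- function(x, ...) {
  h <- x$header
  cat(sprintf(
    "<ecg_record '%s'> %d channel(s), %d samples @ %g Hz (%.1f s), %d annotations\n",
    h$record_name, h$n_channels, h$n_samples, h$sampling_rate,
    h$n_samples / h$sampling_rate, nrow(x$annotations)
  ))
  invisible(x)
}

#' Extract one channel of an ECG record as a numeric vector
#'
#' @param record An `ecg_record`.
#' @param channel 0-based channel index (default 0, the MLII convention for
#'   MIT-BIH records).
#' @return Numeric vector of amplitudes in mV.
#' @export
record_channel <- function(record, channel = 0L) {
  stopifnot(inherits(record, "ecg_record"))
  ch <- as.integer(channel) + 1L
  if (ch < 1L || ch > record$header$n_channels) {
    ecg_abort(sprintf("channel %d not present (record has %d)", channel,
                      record$header$n_channels), "ecgkit_invalid_record")
  }
  record$signal[, ch]
}

# ---- WFDB-style header ------------------------------------------------------

parse_header <- function(header_path) {
  lines <- readLines(header_path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 1L) ecg_abort("empty header file", "ecgkit_parse_error")
  top <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  if (length(top) < 4L) ecg_abort("header first line needs: name n_channels fs n_samples", "ecgkit_parse_error")
  if (length(top) > 4L) {
    ecg_warn(sprintf("ignoring %d unknown token(s) on header record line", length(top) - 4L),
             "ecgkit_header_warning")
  }
  n_channels <- as.integer(top[[2L]])
  if (length(lines) < 1L + n_channels) {
    ecg_abort("header has fewer signal lines than channels", "ecgkit_parse_error")
  }
  gain <- numeric(n_channels); baseline <- numeric(n_channels)
  signal_file <- character(n_channels)
  for (i in seq_len(n_channels)) {
    tok <- strsplit(trimws(lines[[1L + i]]), "\\s+")[[1L]]
    if (length(tok) < 4L) ecg_abort("header signal line needs: file format gain baseline", "ecgkit_parse_error")
    if (tok[[2L]] != "212") ecg_abort(sprintf("unsupported signal format '%s' (only 212)", tok[[2L]]), "ecgkit_parse_error")
    if (length(tok) > 4L) {
      ecg_warn(sprintf("ignoring %d unknown token(s) on signal line %d", length(tok) - 4L, i),
               "ecgkit_header_warning")
    }
    signal_file[i] <- tok[[1L]]
    gain[i] <- as.numeric(tok[[3L]])
    baseline[i] <- as.numeric(tok[[4L]])
  }
  list(
    record_name = top[[1L]], n_channels = n_channels,
    sampling_rate = as.numeric(top[[3L]]), n_samples = as.integer(top[[4L]]),
    gain = gain, baseline = baseline, signal_file = signal_file
  )
}

write_header <- function(header, path, signal_file) {
  lines <- c(
    sprintf("%s %d %g %d", header$record_name, header$n_channels,
            header$sampling_rate, header$n_samples),
    sprintf("%s 212 %g %g", signal_file, header$gain, header$baseline)
  )
  writeLines(lines, path)
}

# ---- record reading / writing ----------------------------------------------

#' Read an ECG record from WFDB-style files
#'
#' Reads a text header (`.hea`), a format-212 packed signal (`.dat`) and an
#' optional annotation CSV (columns `sample_index,symbol`). ADC values are
#' converted to mV as `(adc - baseline) / gain`. Channels are interleaved
#' sample-by-sample in the signal file, the MIT-BIH convention.
#'
#' @param header_path Path to the header file.
#' @param signal_path Path to the packed signal file; defaults to the file
#'   named in the header, resolved relative to the header's directory.
#' @param annotation_path Optional path to an annotation CSV.
#' @return An [ecg_record()].
#' @export
read_record <- function(header_path, signal_path = NULL, annotation_path = NULL) {
  h <- parse_header(header_path)
  if (is.null(signal_path)) {
    signal_path <- file.path(dirname(header_path), h$signal_file[[1L]])
  }
  n_values <- h$n_samples * h$n_channels
  bytes <- readBin(signal_path, "raw", n = file.info(signal_path)$size)
  if (length(bytes) < ceiling(n_values * 3 / 2)) {
    ecg_abort(sprintf(
      "signal file holds fewer samples than header declares (%d needed)", n_values
    ), "ecgkit_length_mismatch")
  }
  adc <- decode_format212(bytes, n_values)
  sig <- matrix(adc, ncol = h$n_channels, byrow = TRUE)
  sig <- sweep(sweep(sig, 2L, h$baseline, "-"), 2L, h$gain, "/")
  ann <- if (!is.null(annotation_path)) read_annotations(annotation_path) else NULL
  ecg_record(sig, h$sampling_rate, annotations = ann,
             record_name = h$record_name, gain = h$gain, baseline = h$baseline)
}

#' Write an ECG record as WFDB-style files
#'
#' Emits `<name>.hea`, `<name>.dat` (format 212) and `<name>_ann.csv` into
#' `dir`. mV amplitudes are quantized as `round(mV * gain + baseline)`;
#' values outside the signed 12-bit ADC range raise an overflow error.
#' [read_record()] inverts this up to half an ADC step per sample.
#'
#' @param record An [ecg_record()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths
#'   (`header`, `signal`, `annotations`), invisibly.
#' @export
write_record <- function(record, dir) {
  stopifnot(inherits(record, "ecg_record"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  h <- record$header
  adc <- round(sweep(sweep(record$signal, 2L, h$gain, "*"), 2L, h$baseline, "+"))
  if (length(adc) && (max(adc) > 2047 || min(adc) < -2048)) {
    ecg_abort("scaled amplitudes exceed the signed 12-bit ADC range [-2048, 2047]",
              "ecgkit_overflow_error")
  }
  dat_name <- paste0(h$record_name, ".dat")
  paths <- c(
    header = file.path(dir, paste0(h$record_name, ".hea")),
    signal = file.path(dir, dat_name),
    annotations = file.path(dir, paste0(h$record_name, "_ann.csv"))
  )
  write_header(h, paths[["header"]], dat_name)
  interleaved <- as.integer(t(adc))  # sample-major channel interleave
  writeBin(encode_format212(interleaved), paths[["signal"]])
  write_annotations(record$annotations, paths[["annotations"]])
  invisible(paths)
}

#' Read beat annotations from CSV
#'
#' @param path CSV with header row `sample_index,symbol`.
#' @return Tibble with integer `sample_index` and character `symbol`,
#'   sorted by `sample_index`.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, colClasses = c("integer", "character"))
  if (!all(c("sample_index", "symbol") %in% names(df))) {
    ecg_abort("annotation CSV must have columns sample_index,symbol", "ecgkit_parse_error")
  }
  out <- as_tibble(df[order(df$sample_index), c("sample_index", "symbol")])
  out
}

#' Write beat annotations to CSV
#'
#' @param annotations Tibble with `sample_index` and `symbol`.
#' @param path Output path.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.csv(annotations[, c("sample_index", "symbol")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a single-channel signal from CSV
#'
#' @param path CSV with header row `sample_index,amplitude_mV`.
#' @param sampling_rate Sampling rate in Hz to attach to the record.
#' @param annotation_path Optional annotation CSV.
#' @return An [ecg_record()] with one channel.
#' @export
read_signal_csv <- function(path, sampling_rate = 360, annotation_path = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("sample_index", "amplitude_mV") %in% names(df))) {
    ecg_abort("signal CSV must have columns sample_index,amplitude_mV", "ecgkit_parse_error")
  }
  df <- df[order(df$sample_index), ]
  ann <- if (!is.null(annotation_path)) read_annotations(annotation_path) else NULL
  ecg_record(df$amplitude_mV, sampling_rate, annotations = ann,
             record_name = tools::file_path_sans_ext(basename(path)))
}

#' Write one channel of a record as a signal CSV
#'
#' @param record An [ecg_record()].
#' @param path Output path.
#' @param channel 0-based channel index.
#' @export
write_signal_csv <- function(record, path, channel = 0L) {
  x <- record_channel(record, channel)
  utils::write.csv(
    data.frame(sample_index = seq_along(x) - 1L, amplitude_mV = x),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
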