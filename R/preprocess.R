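# MIT-BIH beat-level annotation codes. Everything else ("+", "~", "|", ...)
# is a rhythm/signal-quality marker, not a beat.
BEAT_SYMBOLS <- c("N", "L", "R", "e", "j", "A", "a", "J", "S", "V", "E",
                  "F", "/", "f", "Q", "B", "n", "r", "?")

#' Z-score normalize a segment
#'
#' Centers and scales by the population standard deviation, removing
#' amplitude scaling and offset effects: `zscore(a * x + b)` equals
#' `zscore(x)` for any `a > 0`. Constant segments (SD below `1e-12`) map
#' to all zeros with a warning.
#'
#' @param x Non-empty numeric vector.
#' @return Numeric vector with mean 0 and population SD 1.
#' @export
zscore <- function(x) {
  if (length(x) == 0L) ecg_abort("cannot z-score an empty segment", "ecgkit_invalid_input")
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  if (s < 1e-12) {
    ecg_warn("constant segment mapped to zeros by z-score", "ecgkit_degenerate_segment")
    return(numeric(length(x)))
  }
  (x - mu) / s
}

#' Segment a record into fixed-length beat windows
#'
#' For each annotation at 0-based sample `i`, extracts the window
#' `[i - length/2, i + length/2)`. Annotations whose window would cross a
#' record boundary are dropped; the count of dropped beats is stored in
#' the `n_dropped` attribute and reported via a message.
#'
#' @param record An [ecg_record()].
#' @param length Window length in samples (even; default 2160, i.e. 6 s
#'   at 360 Hz).
#' @param channel 0-based channel to segment.
#' @return Tibble with columns `source_index` (annotation sample),
#'   `symbol`, and `samples` (list-column of numeric windows), plus
#'   attribute `n_dropped`.
#' @export
segment_beats <- function(record, length = 2160L, channel = 0L) {
  stopifnot(inherits(record, "ecg_record"))
  length <- as.integer(length)
  if (length %% 2L != 0L) ecg_abort("segment length must be even", "ecgkit_invalid_config")
  x <- record_channel(record, channel)
  n <- base::length(x)
  ann <- record$annotations
  if (n < length) {
    ecg_warn(sprintf("record (%d samples) shorter than one segment (%d)", n, length),
             "ecgkit_short_record")
    out <- tibble(source_index = integer(0), symbol = character(0), samples = list())
    attr(out, "n_dropped") <- nrow(ann)
    return(out)
  }
  half <- length %/% 2L
  keep <- ann$sample_index - half >= 0L & ann$sample_index + half - 1L <= n - 1L
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    rlang::inform(sprintf("dropped %d beat(s) whose window crosses the record boundary",
                          n_dropped))
  }
  kept <- ann[keep, ]
  out <- tibble(
    source_index = kept$sample_index,
    symbol = kept$symbol,
    samples = lapply(kept$sample_index, function(i) x[(i - half + 1L):(i + half)])
  )
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Map beat symbols to binary labels
#'
#' `"N"` maps to 0 (normal); every other beat-level symbol maps to 1
#' (abnormal). Non-beat annotations (rhythm or signal-quality markers such
#' as `"+"` or `"~"`) are excluded. Unknown symbols are excluded with a
#' warning, or raise an error in strict mode.
#'
#' @param symbols Character vector of annotation symbols.
#' @param strict Error on symbols outside the known alphabet.
#' @return Integer vector of 0/1 labels for the retained symbols, with a
#'   logical attribute `kept` marking which inputs were retained.
#' @export
label_beats <- function(symbols, strict = FALSE) {
  known_nonbeat <- c("+", "~", "|", "!", "[", "]", "x", "\"", "s", "T", "*", "=", "@")
  is_beat <- symbols %in% BEAT_SYMBOLS
  unknown <- !is_beat & !(symbols %in% known_nonbeat)
  if (any(unknown)) {
    msg <- sprintf("unknown annotation symbol(s): %s",
                   paste(unique(symbols[unknown]), collapse = ", "))
    if (strict) ecg_abort(msg, "ecgkit_unknown_symbol")
    ecg_warn(paste0(msg, " (excluded)"), "ecgkit_unknown_symbol")
  }
  n_excluded <- sum(!is_beat)
  if (n_excluded > 0L) {
    rlang::inform(sprintf("excluded %d non-beat annotation(s)", n_excluded))
  }
  labels <- as.integer(symbols[is_beat] != "N")
  attr(labels, "kept") <- is_beat
  labels
}

#' Build a normalized, labelled beat table from a record
#'
#' Segments ([segment_beats()]), drops non-beat annotations
#' ([label_beats()]) and z-scores each window ([zscore()]).
#'
#' @inheritParams segment_beats
#' @param strict Passed to [label_beats()].
#' @return Tibble with `source_index`, `symbol`, `label` (0/1) and
#'   `samples` (list-column of z-scored windows of the requested length).
#' @export
make_beats <- function(record, length = 2160L, channel = 0L, strict = FALSE) {
  seg <- segment_beats(record, length = length, channel = channel)
  if (nrow(seg) == 0L) {
    return(tibble(source_index = integer(0), symbol = character(0),
                  label = integer(0), samples = list()))
  }
  labels <- label_beats(seg$symbol, strict = strict)
  seg <- seg[attr(labels, "kept"), ]
  tibble(
    source_index = seg$source_index,
    symbol = seg$symbol,
    label = as.integer(labels),
    samples = lapply(seg$samples, zscore)
  )
}

#' Randomized stratified train/test split
#'
#' Shuffles the beats with the given seed and splits each class stratum
#' 80/20 (or the requested ratio). With a single class present, stratified
#' mode falls back to a plain shuffle with a warning.
#'
#' @param beats Tibble from [make_beats()] (needs a `label` column).
#' @param ratio Training fraction.
#' @param seed RNG seed; the same seed always yields the same partition.
#' @param stratify Stratify by `label` (default).
#' @return An `ecg_dataset`: list with `train` and `test` tibbles, `seed`,
#'   `ratio` and the label map.
#' @export
split_dataset <- function(beats, ratio = 0.8, seed = 1L, stratify = TRUE) {
  if (nrow(beats) < 2L) ecg_abort("need at least 2 segments to split", "ecgkit_invalid_input")
  if (ratio <= 0 || ratio >= 1) ecg_abort("ratio must lie in (0, 1)", "ecgkit_invalid_config")
  classes <- sort(unique(beats$label))
  if (stratify && length(classes) < 2L) {
    ecg_warn("single-class input: falling back to unstratified shuffle",
             "ecgkit_single_class")
    stratify <- FALSE
  }
  with_seed(seed, {
    take_train <- logical(nrow(beats))
    if (stratify) {
      for (cl in classes) {
        idx <- which(beats$label == cl)
        idx <- sample(idx)
        take_train[idx[seq_len(round(ratio * length(idx)))]] <- TRUE
      }
    } else {
      idx <- sample(nrow(beats))
      take_train[idx[seq_len(round(ratio * nrow(beats)))]] <- TRUE
    }
    structure(
      list(
        train = beats[take_train, ],
        test = beats[!take_train, ],
        seed = as.integer(seed),
        ratio = ratio,
        label_map = c(N = 0L, other = 1L)
      ),
      class = "ecg_dataset"
    )
  })
}

#' @export
print.ecg_dataset <- function(x, ...) {
  cat(sprintf(
    "<ecg_dataset> %d train / %d test beats (ratio %.2f, seed %d); abnormal: %d train, %d test\n",
    nrow(x$train), nrow(x$test), x$ratio, x$seed,
    sum(x$train$label), sum(x$test$label)
  ))
  invisible(x)
}

#' Stack a beat table's windows into a samples-by-beats matrix
#'
#' @param beats Tibble with a `samples` list-column.
#' @return Numeric matrix, one column per beat.
#' @export
beats_matrix <- function(beats) {
  if (nrow(beats) == 0L) return(matrix(numeric(0), nrow = 0L, ncol = 0L))
  lens <- lengths(beats$samples)
  if (length(unique(lens)) != 1L) {
    ecg_abort("beat windows have inconsistent lengths", "ecgkit_invalid_input")
  }
  matrix(unlist(beats$samples, use.names = FALSE), nrow = lens[[1L]])
}
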