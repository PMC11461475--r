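# Corpus and configuration I/O: WAV + transcript + token-inventory corpora,
# YAML pipeline configs, and JSON-lines training logs.

#' Write a corpus to disk
#'
#' Writes one 16-bit PCM WAV per utterance, a `transcripts.txt` with one
#' `<id> <tok> <tok> ...` line per utterance, and a `tokens.txt` inventory
#' mapping tokens to integer indices with the CTC blank reserved at index 0.
#'
#' @param corpus List of utterances `list(id, wave, tokens, ...)`, e.g. from
#'   [gen_tone_corpus()].
#' @param dir Output directory (created if missing).
#' @param fs Sampling rate of the waveforms, Hz.
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir, fs = 16000) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tokens <- attr(corpus, "tokens")
  if (is.null(tokens)) tokens <- sort(unique(unlist(lapply(corpus,
                                                           `[[`, "tokens"))))
  writeLines(c("<blank> 0",
               paste(tokens, seq_along(tokens))),
             file.path(dir, "tokens.txt"))
  lines <- vapply(corpus, function(u)
    paste(c(u$id, u$tokens), collapse = " "), "")
  writeLines(lines, file.path(dir, "transcripts.txt"))
  for (u in corpus) write_wav(u$wave, fs, file.path(dir,
                                                    paste0(u$id, ".wav")))
  invisible(dir)
}

#' Read a corpus directory
#'
#' Reads the token inventory, transcripts and WAV files written by
#' [write_corpus()]. Tokens map to internal class indices as inventory
#' index + 1 (so the blank, index 0 in the file, is class 1).
#'
#' @param dir Corpus directory.
#' @return List of utterances `list(id, wave, tokens, labels)` with
#'   attribute `tokens`.
#' @export
read_corpus <- function(dir) {
  inv <- utils::read.table(file.path(dir, "tokens.txt"),
                           col.names = c("token", "index"),
                           stringsAsFactors = FALSE)
  idx_map <- stats::setNames(inv$index, inv$token)
  lines <- readLines(file.path(dir, "transcripts.txt"))
  corpus <- lapply(lines, function(line) {
    parts <- strsplit(trimws(line), "\\s+")[[1]]
    id <- parts[1]
    toks <- parts[-1]
    if (!all(toks %in% inv$token))
      stop("unknown token(s) in transcript for ", id)
    wav <- read_wav(file.path(dir, paste0(id, ".wav")))
    list(id = id, wave = wav$samples, tokens = toks,
         labels = as.integer(idx_map[toks]) + 1L)
  })
  attr(corpus, "tokens") <- inv$token[inv$index > 0]
  corpus
}

#' Write a pipeline configuration as YAML
#'
#' @param cfg A [pipeline_config()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$snn_layers <- lapply(x$snn_layers, unclass)
  x$reg <- unclass(x$reg)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file written by [write_config()] (or hand-authored with
#'   the same keys).
#' @return A [pipeline_config()].
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  layers <- lapply(x$snn_layers, function(l)
    layer_spec(l$n_neurons, l$ff_connectivity, l$rec_connectivity,
               l$sfa_fraction, isTRUE(l$dale),
               if (is.null(l$ei_ratio)) 1 else l$ei_ratio,
               if (is.null(l$mask_seed)) 1L else l$mask_seed))
  reg <- if (is.null(x$reg)) reg_config()
         else reg_config(x$reg$f_min, x$reg$f_max, x$reg$weight)
  pipeline_config(
    n_classes = x$n_classes, n_mels = x$n_mels, win_ms = x$win_ms,
    hop_ms = x$hop_ms, cnn_channels = x$cnn_channels,
    cnn_kernel = unlist(x$cnn_kernel), snn_layers = layers,
    n_phoneme_features = x$n_phoneme_features, dropout = x$dropout,
    reg = reg, reg_include_nerve = isTRUE(x$reg_include_nerve),
    fs = x$fs, seed = x$seed)
}

#' Append a structured record to a JSON-lines log
#'
#' @param record Named list (e.g. epoch, loss, per, mean rates).
#' @param path Log file; created on first use.
#' @return `path`, invisibly.
#' @export
log_jsonl <- function(record, path) {
  line <- jsonlite::toJSON(record, auto_unbox = TRUE, digits = NA)
  cat(line, "\n", sep = "", file = path, append = TRUE)
  invisible(path)
}
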