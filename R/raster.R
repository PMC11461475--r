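#' Binary spike raster
#'
#' Container for binary spike trains over (utterance, time step, neuron),
#' together with the simulation step and the true utterance durations used
#' for firing-rate computations (padded steps beyond an utterance's true
#' length must be zero).
#'
#' @param values Binary array of dim `c(B, T, N)`, or a `T x N` matrix for a
#'   single utterance.
#' @param dt Simulation step, ms.
#' @param layer_id Label of the producing layer.
#' @param duration_s True duration of each utterance in seconds; defaults to
#'   `T * dt / 1000` for all utterances.
#' @return An object of class `spike_raster`.
#' @export
spike_raster <- function(values, dt, layer_id = "layer", duration_s = NULL) {
  if (is.matrix(values)) values <- array(values, dim = c(1L, dim(values)))
  stopifnot(length(dim(values)) == 3L)
  if (!all(values %in% c(0, 1))) stop("raster entries must be binary")
  if (is.null(duration_s)) duration_s <- rep(dim(values)[2] * dt / 1000,
                                             dim(values)[1])
  stopifnot(length(duration_s) == dim(values)[1], all(duration_s > 0))
  structure(list(values = values, dt = dt, layer_id = layer_id,
                 duration_s = duration_s), class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<spike_raster '%s'> %d utterance(s) x %d steps x %d neurons, dt = %g ms\n",
              x$layer_id, d[1], d[2], d[3], x$dt))
  invisible(x)
}

#' Per-neuron firing rates in Hz
#'
#' Rate of neuron n on utterance b is its spike count divided by the true
#' utterance duration in seconds.
#'
#' @param raster A [spike_raster()].
#' @return A `B x N` matrix of rates, Hz.
#' @export
firing_rates <- function(raster) {
  stopifnot(inherits(raster, "spike_raster"))
  if (any(raster$duration_s <= 0)) stop("non-positive utterance duration")
  counts <- apply(raster$values, c(1, 3), sum)
  counts <- matrix(counts, nrow = dim(raster$values)[1])
  sweep(counts, 1, raster$duration_s, "/")
}

#' Firing-rate regularization configuration
#'
#' Defaults follow the convention of keeping every neuron's rate between
#' `f_min = 0.5` Hz and the Nyquist frequency of the simulation
#' (`1000 / (2 * dt_ms)` Hz).
#'
#' @param f_min Lower rate bound, Hz.
#' @param f_max Upper rate bound, Hz; `NULL` means the Nyquist frequency,
#'   resolved once `dt` is known.
#' @param weight Multiplier applied when the penalty is combined with a task
#'   loss.
#' @return A list of class `reg_config`.
#' @export
reg_config <- function(f_min = 0.5, f_max = NULL, weight = 1) {
  structure(list(f_min = f_min, f_max = f_max, weight = weight),
            class = "reg_config")
}

resolve_f_max <- function(cfg, dt) {
  if (is.null(cfg$f_max)) 1000 / (2 * dt) else cfg$f_max
}

#' Firing-rate regularization penalty
#'
#' Hinge penalty discouraging silent neurons and neurons firing above the
#' Nyquist frequency: the mean over utterances and layers of the layer-mean of
#' `ReLU(f_min - f) + ReLU(f - f_max)` (outer normalization `1/(B*L)`, inner
#' `1/N_l`).
#'
#' @param rates A `B x N` rate matrix (one layer) or a list of such matrices
#'   (one per layer), as returned by [firing_rates()].
#' @param cfg A [reg_config()]; `f_max` must be resolved (numeric).
#' @return Scalar penalty (Hz).
#' @export
regularization_loss <- function(rates, cfg = reg_config(f_max = 250)) {
  if (is.matrix(rates)) rates <- list(rates)
  if (is.null(cfg$f_max)) stop("f_max unresolved; pass dt-resolved config")
  stopifnot(all(vapply(rates, function(r) all(r >= 0), logical(1))))
  per_layer <- vapply(rates, function(r) {
    pen <- pmax(cfg$f_min - r, 0) + pmax(r - cfg$f_max, 0)
    mean(rowMeans(matrix(pen, nrow = nrow(r))))  # mean over B of layer mean
  }, numeric(1))
  mean(per_layer)
}

#' Histogram of single-neuron firing rates
#'
#' Supports activity comparisons between inputs (speech-like vs noise) and
#' between trained and untrained networks.
#'
#' @param raster A [spike_raster()].
#' @param bin_edges Increasing vector of rate bin edges, Hz. Rates above the
#'   last edge are counted in the last bin.
#' @return List with `counts` (per bin, summed over utterances), `mids` and
#'   `edges`.
#' @export
rate_distribution <- function(raster,
                              bin_edges = seq(0, 1000 / (2 * raster$dt),
                                              length.out = 26)) {
  r <- as.numeric(firing_rates(raster))
  r <- pmin(r, max(bin_edges))
  h <- hist(r, breaks = bin_edges, plot = FALSE)
  list(counts = h$counts, mids = h$mids, edges = bin_edges)
}

#' Write a spike raster as a sparse event list
#'
#' Plain-text format: header lines (`dt_ms`, `layer_id`, `n_utterances`,
#' `n_steps`, `n_neurons`, per-utterance `duration_s`), then one
#' `b t n` line per spike (1-based indices). The round trip through
#' [read_raster_events()] is lossless.
#'
#' @param raster A [spike_raster()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_raster_events <- function(raster, path) {
  d <- dim(raster$values)
  hdr <- c(
    "# spikeosc raster v1",
    paste("dt_ms", format(raster$dt, digits = 17)),
    paste("layer_id", raster$layer_id),
    paste("n_utterances", d[1]), paste("n_steps", d[2]),
    paste("n_neurons", d[3]),
    paste("duration_s", paste(format(raster$duration_s, digits = 17),
                              collapse = " ")))
  idx <- which(raster$values != 0, arr.ind = TRUE)
  lines <- if (nrow(idx)) paste(idx[, 1], idx[, 2], idx[, 3]) else character(0)
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a spike raster written by [write_raster_events()]
#'
#' @param path File path.
#' @return A [spike_raster()].
#' @export
read_raster_events <- function(path) {
  lines <- readLines(path)
  stopifnot(lines[1] == "# spikeosc raster v1")
  hdr <- lines[2:7]
  kv <- strsplit(hdr, " ")
  key <- vapply(kv, `[`, "", 1)
  val <- lapply(kv, function(x) x[-1])
  names(val) <- key
  d <- c(as.integer(val$n_utterances), as.integer(val$n_steps),
         as.integer(val$n_neurons))
  values <- array(0, dim = d)
  body <- lines[-(1:7)]
  body <- body[nzchar(body)]
  if (length(body)) {
    ev <- matrix(as.integer(unlist(strsplit(body, " "))), ncol = 3,
                 byrow = TRUE)
    values[ev] <- 1
  }
  spike_raster(values, dt = as.numeric(val$dt_ms[1]),
               layer_id = paste(val$layer_id, collapse = " "),
               duration_s = as.numeric(val$duration_s))
}
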