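#' EEG-like population signal from a spike raster
#'
#' Sums the binary spike trains of all neurons in a layer at each time step
#' (the model's analog of an EEG trace), then z-scores the series over time
#' (mean 0, standard deviation 1).
#'
#' @param raster A [spike_raster()] holding a single utterance, or a
#'   `T x N` binary matrix.
#' @param utterance Utterance index when the raster holds several.
#' @return An object of class `population_signal` with fields `raw`
#'   (integer counts), `normalized`, `mu`, `sigma`, `dt` (ms), `fs` (Hz),
#'   `layer_id` and `utterance_id`.
#' @export
aggregate_population <- function(raster, utterance = 1L) {
  if (inherits(raster, "spike_raster")) {
    v <- raster$values[utterance, , ]
    dt <- raster$dt
    layer_id <- raster$layer_id
  } else {
    v <- raster
    dt <- 1
    layer_id <- "layer"
  }
  raw <- rowSums(matrix(v, nrow = nrow(v)))
  mu <- mean(raw)
  sigma <- sqrt(mean((raw - mu)^2))  # population sd: z-scored series has sd 1
  if (!is.finite(sigma) || sigma == 0)
    stop("degenerate signal: constant population activity cannot be normalized")
  structure(list(raw = raw, normalized = (raw - mu) / sigma, mu = mu,
                 sigma = sigma, dt = dt, fs = 1000 / dt,
                 layer_id = layer_id, utterance_id = utterance),
            class = "population_signal")
}

#' Canonical EEG frequency bands
#'
#' Delta (0.5--4 Hz), theta (4--8), alpha (8--13) and beta (13--30) serve as
#' low-frequency modulating (phase) bands; low-gamma (30--80) and high-gamma
#' (80--150) as high-frequency modulated (amplitude) bands.
#'
#' @return A data frame with `name`, `lo`, `hi` (Hz) and `role`.
#' @export
frequency_bands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta", "low_gamma", "high_gamma"),
    lo = c(0.5, 4, 8, 13, 30, 80),
    hi = c(4, 8, 13, 30, 80, 150),
    role = c(rep("modulating", 4), rep("modulated", 2)),
    stringsAsFactors = FALSE)
}

band_by_name <- function(name) {
  fb <- frequency_bands()
  row <- fb[fb$name == name, ]
  if (nrow(row) != 1) stop("unknown band: ", name)
  row
}

#' Zero-phase FIR band-pass filtering
#'
#' Windowed-sinc (Hamming) FIR design via `signal::fir1`, applied
#' forward-backward (`signal::filtfilt`) for zero phase distortion. The
#' filter order is chosen so that the Hamming transition width is at most a
#' quarter of the band's width (so adjacent canonical bands do not leak into
#' each other) and covers at least three cycles of the band's low edge; it
#' is capped at a third of the signal length when the signal is short.
#'
#' @param x Numeric series, or a `population_signal` (its normalized series
#'   is filtered).
#' @param band Band name (see [frequency_bands()]) or a list/row with `lo`
#'   and `hi` in Hz.
#' @param fs Sampling rate, Hz (taken from a `population_signal` input).
#' @return Filtered numeric series with attribute `half_span` (samples), the
#'   edge region a metric computation should trim.
#' @export
bandpass <- function(x, band, fs = NULL) {
  if (inherits(x, "population_signal")) {
    if (is.null(fs)) fs <- x$fs
    x <- x$normalized
  }
  if (is.null(fs)) stop("fs required for plain numeric input")
  if (is.character(band)) band <- band_by_name(band)
  if (band$hi >= fs / 2)
    stop(sprintf("band edge %g Hz at or above Nyquist (%g Hz)", band$hi,
                 fs / 2))
  trans <- (band$hi - band$lo) / 4
  n_want <- ceiling(max(3 * fs / band$lo, 3.3 * fs / trans))
  n_max <- floor(length(x) / 3) - 1
  if (n_max < 8) stop("signal shorter than the minimal filter span")
  n <- min(n_want, n_max)
  n <- n - n %% 2  # even order -> odd tap count, symmetric type-I FIR
  h <- signal::fir1(n, c(band$lo, band$hi) / (fs / 2), type = "pass")
  y <- signal::filtfilt(h, x)
  attr(y, "half_span") <- n %/% 2
  y
}

#' Analytic signal via the frequency domain
#'
#' Standard FFT construction: negative frequencies are zeroed, positive ones
#' doubled, yielding `x + i * H(x)` with `H` the Hilbert transform.
#'
#' @param x Real numeric series.
#' @return Complex series of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase and amplitude envelope
#'
#' Extracts the phase series of the low-band (modulating) signal and the
#' amplitude envelope of the high-band (modulated) signal from their
#' analytic signals.
#'
#' @param filtered_low Band-passed low-frequency series.
#' @param filtered_high Band-passed high-frequency series, same length.
#' @return List with `phase` (radians in (-pi, pi\]) and `amplitude`.
#' @export
phase_and_envelope <- function(filtered_low, filtered_high) {
  stopifnot(length(filtered_low) == length(filtered_high))
  list(phase = Arg(analytic_signal(as.numeric(filtered_low))),
       amplitude = Mod(analytic_signal(as.numeric(filtered_high))))
}
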