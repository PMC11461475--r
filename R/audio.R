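#' Read a mono PCM WAV file
#'
#' Minimal RIFF/WAVE reader for the corpus format used throughout the
#' package: uncompressed PCM, 16-bit, mono. Samples are returned scaled to
#' \[-1, 1\].
#'
#' @param path File path.
#' @return List with `samples` (numeric vector in \[-1, 1\]) and `fs` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fs <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, 2, endian = "little", signed = FALSE)
      channels <- fmt[2]
      fs <- readBin(con, "integer", 1, 4, endian = "little")
      invisible(readBin(con, "integer", 1, 4, endian = "little"))
      ba <- readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      bits <- readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      if (size > 16) invisible(readBin(con, "raw", size - 16))
      if (fmt[1] != 1 || bits != 16) stop("only 16-bit PCM supported")
      if (channels != 1) stop("only mono supported")
    } else if (identical(id, "data")) {
      samples <- readBin(con, "integer", size / 2, 2, endian = "little",
                         signed = TRUE)
      break
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
  }
  if (is.null(samples)) stop("no data chunk found")
  list(samples = samples / 32768, fs = fs)
}

#' Write a mono PCM WAV file
#'
#' @param samples Numeric vector in \[-1, 1\] (clipped if outside).
#' @param fs Sampling rate, Hz.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, fs, path) {
  x <- as.integer(round(pmin(pmax(samples, -1), 32767 / 32768) * 32768))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(x) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(c(1L, 1L), con, size = 2, endian = "little")         # PCM, mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 2L), con, size = 4, endian = "little")
  writeBin(c(2L, 16L), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(x, con, size = 2, endian = "little")
  invisible(path)
}

# frequency (Hz) <-> Mel scale
hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Triangular Mel filterbank matrix
#'
#' @param n_mels Number of filters.
#' @param n_fft FFT length.
#' @param fs Sampling rate, Hz.
#' @param f_min,f_max Frequency span of the filterbank, Hz.
#' @return `n_mels x (n_fft/2 + 1)` matrix of filter weights.
#' @export
mel_filterbank <- function(n_mels, n_fft, fs, f_min = 0, f_max = fs / 2) {
  mel_pts <- seq(hz_to_mel(f_min), hz_to_mel(f_max), length.out = n_mels + 2)
  hz_pts <- mel_to_hz(mel_pts)
  bins <- hz_pts / fs * n_fft
  freqs <- seq(0, n_fft / 2)
  fb <- matrix(0, n_mels, n_fft / 2 + 1)
  for (m in seq_len(n_mels)) {
    lo <- bins[m]; ce <- bins[m + 1]; hi <- bins[m + 2]
    up <- (freqs - lo) / max(ce - lo, 1e-12)
    down <- (hi - freqs) / max(hi - ce, 1e-12)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

#' Log-Mel filterbank features
#'
#' Frames the waveform with a Hamming window of `win_ms` every `hop_ms`,
#' takes the power spectrum, applies a triangular Mel filterbank spanning
#' 0 to `fs/2`, and log-compresses. With a 25 ms window and 2 ms hop a
#' 16 kHz signal becomes a 500 Hz spectrogram.
#'
#' @param waveform Numeric vector of mono samples.
#' @param fs Sampling rate, Hz.
#' @param n_mels Number of Mel filters.
#' @param win_ms Analysis window, ms.
#' @param hop_ms Window shift, ms; sets the frame rate `1000/hop_ms` Hz.
#' @return `frames x n_mels` matrix of log-Mel energies, with attributes
#'   `frame_rate_hz` and `hop_ms`.
#' @export
extract_features <- function(waveform, fs = 16000, n_mels = 80, win_ms = 25,
                             hop_ms = 2) {
  win <- round(win_ms * fs / 1000)
  hop <- round(hop_ms * fs / 1000)
  if (length(waveform) < win)
    stop(sprintf("waveform too short: %d samples < one %d ms window",
                 length(waveform), win_ms))
  n_fft <- 2^ceiling(log2(win))
  n_frames <- floor((length(waveform) - win) / hop) + 1
  starts <- (seq_len(n_frames) - 1) * hop
  hamming <- 0.54 - 0.46 * cos(2 * pi * seq(0, win - 1) / (win - 1))
  frames <- matrix(0, n_fft, n_frames)
  for (i in seq_len(n_frames))
    frames[seq_len(win), i] <- waveform[starts[i] + seq_len(win)] * hamming
  spec <- stats::mvfft(frames)
  power <- Mod(spec[seq_len(n_fft / 2 + 1), , drop = FALSE])^2
  fb <- mel_filterbank(n_mels, n_fft, fs)
  feats <- t(fb %*% power)
  feats <- log(feats + 1e-10)
  attr(feats, "frame_rate_hz") <- 1000 / hop_ms
  attr(feats, "hop_ms") <- hop_ms
  feats
}
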