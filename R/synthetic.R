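# Synthetic inputs for the whole stack: coupled-oscillation signals with
# known phase-amplitude coupling, Poisson spike rasters, a tone-sequence
# corpus standing in for phoneme-labeled speech, and noise inputs.

#' Specification for a synthetic phase-amplitude-coupled signal
#'
#' @param f_phase Modulating (phase) frequency, Hz.
#' @param f_amp Carrier (amplitude) frequency, Hz; must exceed `f_phase` and
#'   stay below `fs/2`.
#' @param depth Modulation depth in \[0, 1\]; 0 plants no coupling.
#' @param snr_db Signal-to-noise ratio of the additive Gaussian noise, dB.
#' @param fs Sampling rate, Hz.
#' @param duration Duration, seconds.
#' @param freq_jitter_sd Stationary standard deviation (Hz) of the slow
#'   Ornstein-Uhlenbeck wander added to the modulating frequency.
#'   Physiological low-frequency rhythms are quasi-periodic, not clock-like;
#'   a strictly periodic phase would also make cut-and-swap surrogates blind
#'   to the planted coupling (rotating a periodic envelope merely
#'   phase-shifts it, leaving both coupling metrics unchanged). The wander
#'   is smooth (correlation time `jitter_tau`), so the modulating line stays
#'   inside its band without heavy spectral tails.
#' @param jitter_tau Correlation time of the frequency wander, seconds.
#' @param seed Integer seed.
#' @return A list of class `pac_gen_spec`.
#' @export
pac_gen_spec <- function(f_phase = 6, f_amp = 55, depth = 1, snr_db = 10,
                         fs = 500, duration = 5, freq_jitter_sd = 0.4,
                         jitter_tau = 0.3, seed = 1L) {
  stopifnot(f_amp > f_phase, f_amp < fs / 2, depth >= 0, depth <= 1,
            duration > 0, freq_jitter_sd >= 0, jitter_tau > 0)
  structure(list(f_phase = f_phase, f_amp = f_amp, depth = depth,
                 snr_db = snr_db, fs = fs, duration = duration,
                 freq_jitter_sd = freq_jitter_sd, jitter_tau = jitter_tau,
                 seed = as.integer(seed)),
            class = "pac_gen_spec")
}

#' Generate a coupled-oscillation signal with known ground truth
#'
#' The signal is an amplitude-modulated carrier plus its low-frequency
#' modulating component and Gaussian noise:
#' `x_t = (1 + depth * cos(phi_t)) * cos(2 pi f_amp t) + cos(phi_t) + noise`,
#' with `phi_t = 2 pi f_phase t`. The returned ground-truth phase and
#' envelope let the analysis stack be validated against a known coupling.
#'
#' @param spec A [pac_gen_spec()].
#' @return List with `x`, `phase` (wrapped to (-pi, pi\]), `envelope`
#'   (`1 + depth * cos(phi)`), `t` (s) and `fs`.
#' @export
gen_pac_signal <- function(spec = pac_gen_spec()) {
  n <- round(spec$fs * spec$duration)
  t <- (seq_len(n) - 1) / spec$fs
  with_seed(spec$seed, {
    # smooth frequency wander: AR(1)/Ornstein-Uhlenbeck, stationary sd
    # freq_jitter_sd Hz, correlation time jitter_tau s
    rho <- exp(-1 / (spec$jitter_tau * spec$fs))
    g <- stats::filter(stats::rnorm(n, sd = spec$freq_jitter_sd *
                                      sqrt(1 - rho^2)),
                       rho, method = "recursive")
    phi <- cumsum(2 * pi * (spec$f_phase + as.numeric(g)) / spec$fs)
    envelope <- 1 + spec$depth * cos(phi)
    clean <- envelope * cos(2 * pi * spec$f_amp * t) + cos(phi)
    noise_sd <- sqrt(stats::var(clean) / 10^(spec$snr_db / 10))
    x <- clean + stats::rnorm(n, sd = noise_sd)
    list(x = x, phase = atan2(sin(phi), cos(phi)), envelope = envelope,
         t = t, fs = spec$fs)
  })
}

#' Generate a homogeneous-Poisson spike raster
#'
#' Independent Bernoulli(`rate * dt / 1000`) spikes per step and neuron
#' (at most one spike per step, so the rate may not exceed `1000/dt` Hz).
#'
#' @param rate Target rate, Hz.
#' @param n_neurons Number of neurons.
#' @param duration Duration, seconds.
#' @param dt Step, ms.
#' @param seed Integer seed.
#' @return A [spike_raster()] with one utterance.
#' @export
gen_poisson_raster <- function(rate, n_neurons, duration, dt = 2,
                               seed = 1L) {
  p <- rate * dt / 1000
  if (p > 1) stop("rate exceeds one spike per step (1000/dt Hz)")
  T_ <- round(1000 * duration / dt)
  v <- with_seed(seed, stats::rbinom(T_ * n_neurons, 1, p))
  spike_raster(array(v, c(1L, T_, n_neurons)), dt = dt,
               layer_id = "poisson")
}

#' Specification for the tone-sequence corpus
#'
#' A desk-scale stand-in for phoneme-labeled speech: each utterance
#' concatenates pure tones (one per symbol of its transcript) with jittered
#' durations, short silent gaps, amplitude ramps and a white noise floor.
#'
#' @param n_symbols Alphabet size.
#' @param tone_freqs One frequency per symbol, Hz (distinct, < `fs/2`).
#' @param seq_len_range Min/max transcript length, tokens.
#' @param tone_dur_range Min/max tone duration, ms.
#' @param gap_dur_range Min/max inter-tone silence, ms.
#' @param noise_floor_db Noise floor relative to tone RMS, dB.
#' @param fs Sampling rate, Hz.
#' @param n_utterances Corpus size.
#' @param seed Integer seed.
#' @return A list of class `tone_task_spec`.
#' @export
tone_task_spec <- function(n_symbols = 4,
                           tone_freqs = c(400, 800, 1600, 3200),
                           seq_len_range = c(2, 5),
                           tone_dur_range = c(100, 160),
                           gap_dur_range = c(20, 50),
                           noise_floor_db = -30, fs = 16000,
                           n_utterances = 200, seed = 1L) {
  stopifnot(length(tone_freqs) == n_symbols,
            !anyDuplicated(tone_freqs), all(tone_freqs < fs / 2))
  structure(list(n_symbols = n_symbols, tone_freqs = tone_freqs,
                 seq_len_range = seq_len_range,
                 tone_dur_range = tone_dur_range,
                 gap_dur_range = gap_dur_range,
                 noise_floor_db = noise_floor_db, fs = fs,
                 n_utterances = n_utterances, seed = as.integer(seed)),
            class = "tone_task_spec")
}

tone_symbols <- function(spec) letters[seq_len(spec$n_symbols)]

#' Generate the tone-sequence corpus
#'
#' Deterministic given `spec$seed`. Each utterance's transcript equals its
#' generating symbol sequence; label class indices reserve 1 for the CTC
#' blank, so symbol k maps to class k + 1.
#'
#' @param spec A [tone_task_spec()].
#' @param out_dir If non-`NULL`, the corpus is also written there as WAV
#'   files plus `transcripts.txt` (one `<id> <tok> <tok> ...` line per
#'   utterance) and `tokens.txt` (the token inventory, blank at index 0).
#' @return List of utterances `list(id, wave, tokens, labels)` with
#'   attribute `tokens` (the symbol inventory).
#' @export
gen_tone_corpus <- function(spec = tone_task_spec(), out_dir = NULL) {
  syms <- tone_symbols(spec)
  corpus <- with_seed(spec$seed, {
    lapply(seq_len(spec$n_utterances), function(i) {
      len <- sample(spec$seq_len_range[1]:spec$seq_len_range[2], 1)
      seq_idx <- sample.int(spec$n_symbols, len, replace = TRUE)
      pieces <- list()
      for (k in seq_idx) {
        gap_ms <- stats::runif(1, spec$gap_dur_range[1],
                               spec$gap_dur_range[2])
        dur_ms <- stats::runif(1, spec$tone_dur_range[1],
                               spec$tone_dur_range[2])
        n_gap <- round(gap_ms * spec$fs / 1000)
        n_tone <- round(dur_ms * spec$fs / 1000)
        tt <- seq_len(n_tone) / spec$fs
        tone <- 0.3 * sin(2 * pi * spec$tone_freqs[k] * tt)
        ramp <- round(0.005 * spec$fs)
        win <- rep(1, n_tone)
        win[seq_len(ramp)] <- (1 - cos(pi * seq_len(ramp) / ramp)) / 2
        win[n_tone + 1 - seq_len(ramp)] <- win[seq_len(ramp)]
        pieces[[length(pieces) + 1]] <- numeric(n_gap)
        pieces[[length(pieces) + 1]] <- tone * win
      }
      pieces[[length(pieces) + 1]] <-
        numeric(round(spec$gap_dur_range[2] * spec$fs / 1000))
      wave <- unlist(pieces)
      noise_sd <- 0.3 / sqrt(2) * 10^(spec$noise_floor_db / 20)
      wave <- wave + stats::rnorm(length(wave), sd = noise_sd)
      list(id = sprintf("utt-%04d", i), wave = wave,
           tokens = syms[seq_idx], labels = seq_idx + 1L)
    })
  })
  attr(corpus, "tokens") <- syms
  if (!is.null(out_dir)) write_corpus(corpus, out_dir, fs = spec$fs)
  corpus
}

#' Generate noise input waveforms
#'
#' `uniform` is white noise; `babble` emulates speech-like temporal
#' structure as a sum of independent narrowband (voiced-range) noise
#' processes, each amplitude-modulated at a syllabic rate (2--6 Hz).
#'
#' @param kind `"uniform"` or `"babble"`.
#' @param duration Duration, seconds.
#' @param fs Sampling rate, Hz.
#' @param seed Integer seed.
#' @return Numeric waveform with RMS ~0.1.
#' @export
gen_noise_inputs <- function(kind = c("uniform", "babble"), duration = 1,
                             fs = 16000, seed = 1L) {
  kind <- match.arg(kind)
  n <- round(duration * fs)
  with_seed(seed, {
    if (kind == "uniform") {
      x <- stats::runif(n, -1, 1)
    } else {
      bands <- cbind(lo = c(300, 600, 1200, 2400),
                     hi = c(600, 1200, 2400, 3400))
      x <- numeric(n)
      t <- seq_len(n) / fs
      for (i in seq_len(nrow(bands))) {
        h <- signal::fir1(128, bands[i, ] / (fs / 2), type = "pass")
        nb <- signal::filter(h, stats::rnorm(n))
        f_mod <- stats::runif(1, 2, 6)
        env <- (1 + sin(2 * pi * f_mod * t + stats::runif(1, 0, 2 * pi))) / 2
        x <- x + as.numeric(nb) * env
      }
    }
    x / sqrt(mean(x^2)) * 0.1
  })
}
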