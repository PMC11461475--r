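test_that("every generator is deterministic given its seed", {
  s1 <- gen_pac_signal(pac_gen_spec(seed = 5))
  s2 <- gen_pac_signal(pac_gen_spec(seed = 5))
  expect_identical(s1$x, s2$x)
  expect_false(identical(s1$x, gen_pac_signal(pac_gen_spec(seed = 6))$x))
  r1 <- gen_poisson_raster(30, 20, 1, dt = 2, seed = 3)
  r2 <- gen_poisson_raster(30, 20, 1, dt = 2, seed = 3)
  expect_identical(r1$values, r2$values)
  c1 <- gen_tone_corpus(tone_task_spec(n_utterances = 2, seed = 4))
  c2 <- gen_tone_corpus(tone_task_spec(n_utterances = 2, seed = 4))
  expect_identical(c1[[1]]$wave, c2[[1]]$wave)
  expect_identical(c1[[2]]$tokens, c2[[2]]$tokens)
  n1 <- gen_noise_inputs("babble", 0.5, seed = 8)
  expect_identical(n1, gen_noise_inputs("babble", 0.5, seed = 8))
})

test_that("coupled-signal ground truth is recovered by the analysis stack", {
  spec <- pac_gen_spec(f_phase = 6, f_amp = 55, depth = 1, snr_db = 10,
                       duration = 5, seed = 2)
  sig <- gen_pac_signal(spec)
  lo <- bandpass(sig$x, "theta", sig$fs)
  hi <- bandpass(sig$x, "low_gamma", sig$fs)
  tr <- max(attr(lo, "half_span"), attr(hi, "half_span"))
  keep <- (tr + 1):(length(lo) - tr)
  pe <- phase_and_envelope(lo[keep], hi[keep])
  expect_gt(stats::cor(pe$amplitude, sig$envelope[keep]), 0.95)
  expect_gt(stats::cor(cos(pe$phase), cos(sig$phase[keep])), 0.95)
})

test_that("Poisson rasters hit their target rate", {
  ras <- gen_poisson_raster(60, n_neurons = 512, duration = 10, dt = 2,
                            seed = 1)
  expect_equal(mean(firing_rates(ras)), 60, tolerance = 2 / 60 * 60)
  expect_lt(abs(mean(firing_rates(ras)) - 60), 2)
  expect_true(all(gen_poisson_raster(0, 5, 1, 2, 1)$values == 0))
  expect_error(gen_poisson_raster(600, 5, 1, dt = 2), "exceeds")
})

test_that("tone corpus transcripts equal their generating sequences", {
  spec <- tone_task_spec(n_utterances = 5, seed = 6)
  corpus <- gen_tone_corpus(spec)
  expect_length(corpus, 5)
  for (u in corpus) {
    expect_true(all(u$tokens %in% letters[1:4]))
    expect_identical(u$labels, match(u$tokens, letters) + 1L)
    expect_gte(length(u$tokens), spec$seq_len_range[1])
    expect_lte(length(u$tokens), spec$seq_len_range[2])
  }
  # single-symbol degenerate utterances still decode through the collapse rule
  one <- gen_tone_corpus(tone_task_spec(n_utterances = 1,
                                        seq_len_range = c(1, 1), seed = 1))
  expect_length(one[[1]]$tokens, 1)
})

test_that("babble-like noise has more low-frequency envelope power than uniform", {
  env_lf_power <- function(x, fs = 16000) {
    env <- Mod(analytic_signal(x))
    env <- env - mean(env)
    spec <- Mod(stats::fft(env))^2
    freqs <- (seq_along(env) - 1) * fs / length(env)
    sum(spec[freqs > 0.5 & freqs < 16]) / sum(spec[freqs > 0.5 & freqs < fs / 2])
  }
  set.seed(1)
  bab <- gen_noise_inputs("babble", 2, seed = 3)
  uni <- gen_noise_inputs("uniform", 2, seed = 3)
  expect_gt(env_lf_power(bab), env_lf_power(uni))
  expect_error(gen_noise_inputs("brown", 1), "arg")
})
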