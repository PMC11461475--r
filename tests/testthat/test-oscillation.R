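test_that("population signal sums spikes and z-scores over time", {
  v <- array(0, c(1, 6, 4))
  v[1, c(2, 4), ] <- 1  # all neurons spike at steps 2 and 4
  ps <- aggregate_population(spike_raster(v, dt = 2))
  expect_equal(ps$raw, c(0, 4, 0, 4, 0, 0))
  expect_lt(abs(mean(ps$normalized)), 1e-12)
  expect_equal(sqrt(mean(ps$normalized^2)), 1, tolerance = 1e-12)
  # alternating all-spike/all-silent normalizes to +/-1
  alt <- array(rep(c(1, 0), 10 * 3), c(1, 20, 3))
  psa <- aggregate_population(spike_raster(alt, dt = 2))
  expect_equal(sort(unique(round(psa$normalized, 10))), c(-1, 1))
  expect_error(aggregate_population(spike_raster(array(0, c(1, 10, 3)),
                                                 dt = 2)),
               "degenerate")
})

test_that("canonical band table and FIR band-pass behave", {
  fb <- frequency_bands()
  expect_equal(fb$lo[fb$name == "theta"], 4)
  expect_equal(fb$hi[fb$name == "high_gamma"], 150)
  fs <- 500
  t <- seq_len(4000) / fs
  in_band <- sin(2 * pi * 6 * t)
  y <- bandpass(in_band, "theta", fs)
  tr <- attr(y, "half_span")
  keep <- (tr + 1):(length(y) - tr)
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(abs(rms(y[keep]) / rms(in_band[keep]) - 1), 0.05)
  out_band <- sin(2 * pi * 50 * t)
  y2 <- bandpass(out_band, "theta", fs)
  expect_lt(20 * log10(rms(y2[keep]) / rms(out_band[keep])), -20)
  # white noise: filtered spectrum concentrates inside the passband
  set.seed(1)
  wn <- rnorm(4000)
  y3 <- bandpass(wn, "low_gamma", fs)[keep]
  spec <- Mod(stats::fft(y3))^2
  freqs <- (seq_along(y3) - 1) * fs / length(y3)
  half <- freqs <= fs / 2
  mass_in <- sum(spec[half & freqs >= 30 & freqs <= 80]) /
    sum(spec[half])
  expect_gt(mass_in, 0.9)
  expect_error(bandpass(wn, list(lo = 200, hi = 300), fs), "Nyquist")
})

test_that("analytic signal recovers phase and envelope", {
  fs <- 500
  t <- seq_len(5000) / fs
  x <- cos(2 * pi * 8 * t)
  pe <- phase_and_envelope(x, x)
  inner <- 100:4900
  # phase advances linearly and wraps in (-pi, pi]
  dphi <- diff(pe$phase[inner]) %% (2 * pi)
  expect_lt(max(abs(dphi - 2 * pi * 8 / fs)), 1e-3)
  expect_true(all(pe$phase <= pi + 1e-12 & pe$phase > -pi - 1e-12))
  # constant-amplitude sinusoid: flat envelope away from edges
  expect_lt(max(abs(pe$amplitude[inner] - 1)), 0.02)
  # AM carrier: recovered envelope tracks the modulator
  m <- 0.6
  am <- (1 + m * cos(2 * pi * 5 * t)) * cos(2 * pi * 60 * t)
  env <- phase_and_envelope(am, am)$amplitude
  expect_gt(stats::cor(env[inner], (1 + m * cos(2 * pi * 5 * t))[inner]),
            0.99)
})

test_that("modulation index spans [0, 1] and matches the binned-KL oracle", {
  set.seed(2)
  phi <- runif(20000, -pi, pi)
  expect_equal(modulation_index(phi, rep(2, length(phi))), 0,
               tolerance = 1e-12)
  # all amplitude in one bin -> maximal index
  phi1 <- runif(500, -pi, -pi + 2 * pi / 18)
  expect_equal(modulation_index(phi1, rep(1, 500)), 1, tolerance = 1e-12)
  # cosine-modulated amplitude vs direct numerical KL
  A <- 1 + cos(phi)
  expect_equal(modulation_index(phi, A), oracle_mi(phi, A),
               tolerance = 1e-12)
  expect_error(modulation_index(phi, A, n_bins = 1), "n_bins")
  expect_error(modulation_index(numeric(0), numeric(0)), "empty")
  expect_error(modulation_index(phi1, rep(0, 500)), "zero")
})

test_that("mean vector length takes its analytic limits", {
  set.seed(3)
  T_ <- 10000
  phi <- (seq_len(T_) - 0.5) / T_ * 2 * pi - pi  # uniform whole cycles
  expect_lt(mean_vector_length(phi, rep(1, T_)), 1e-10)
  # envelope 1 + cos(phi): circular mean -> 0.5
  expect_equal(mean_vector_length(phi, 1 + cos(phi)), 0.5,
               tolerance = 0.02)
  # point mass at one phase with amplitude c -> mvl = c
  expect_equal(mean_vector_length(rep(0.7, 100), rep(2.5, 100)), 2.5)
})

test_that("cut-and-swap surrogates permute amplitudes and are seeded", {
  set.seed(4)
  phi <- runif(300, -pi, pi)
  A <- abs(rnorm(300)) + 0.1
  s1 <- surrogate_distribution(phi, A, n = 50, rng_seed = 42)
  s2 <- surrogate_distribution(phi, A, n = 50, rng_seed = 42)
  expect_identical(s1, s2)
  s3 <- surrogate_distribution(phi, A, n = 50, rng_seed = 43)
  expect_false(identical(s1$mvl, s3$mvl))
  # rotation preserves the amplitude multiset: check via a manual surrogate
  cut <- 120
  A_rot <- c(A[(cut + 1):300], A[1:cut])
  expect_equal(sort(A_rot), sort(A))
  mvl_manual <- Mod(mean(A_rot * exp(1i * phi)))
  mi_manual <- modulation_index(phi, A_rot)
  cuts_all <- surrogate_distribution(phi, A, n = 299, rng_seed = 1)
  # the manual value must appear among all possible single-cut surrogates
  all_mvl <- vapply(1:299, function(ct)
    Mod(mean(c(A[(ct + 1):300], A[1:ct]) * exp(1i * phi))), numeric(1))
  expect_true(any(abs(all_mvl - mvl_manual) < 1e-12))
  # every drawn surrogate equals one of the T-1 possible rotations
  expect_true(all(round(cuts_all$mvl, 12) %in% round(all_mvl, 12)))
  expect_equal(mi_manual, oracle_mi(phi, A_rot), tolerance = 1e-12)
})

test_that("Gaussian-fit p-values follow the normal upper tail", {
  set.seed(5)
  sur <- rnorm(5000, mean = 2, sd = 0.5)
  expect_equal(gaussian_p_value(mean(sur), sur), 0.5, tolerance = 1e-6)
  expect_equal(gaussian_p_value(mean(sur) + 1.6449 * sd(sur), sur), 0.05,
               tolerance = 1e-3)
  expect_gt(gaussian_p_value(mean(sur) - 5 * sd(sur), sur), 0.999)
  expect_error(gaussian_p_value(1, rep(2, 10)), "zero spread")
})

test_that("scenario enumeration matches the closed-form counts", {
  sc <- enumerate_scenarios(4, utterance_ids = 1:64)
  expect_equal(nrow(sc), 5120)
  expect_equal(sum(sc$relation == "intra"), 4 * 8 * 64)
  one_utt <- enumerate_scenarios(4)
  expect_equal(nrow(one_utt), 10 * 8)  # 10 relations x 8 band pairs
  # brute-force comparison of relation counts for 2..6 populations
  for (np in 2:6) {
    sc_np <- enumerate_scenarios(np, low_bands = "theta",
                                 high_bands = "low_gamma")
    expect_equal(sum(sc_np$relation == "intra"), np)
    expect_equal(sum(sc_np$relation == "inter"), np * (np - 1) / 2)
    # inter relations always point downstream
    ord <- match(sc_np$phase_layer, paste0("pop", 1:np))
    ord2 <- match(sc_np$amplitude_layer, paste0("pop", 1:np))
    expect_true(all(ord[sc_np$relation == "inter"] <
                      ord2[sc_np$relation == "inter"]))
  }
})

test_that("planted coupling is detected and the result is deterministic", {
  sig <- gen_pac_signal(pac_gen_spec(depth = 1, snr_db = 10, duration = 5,
                                     seed = 11))
  ps <- structure(list(raw = sig$x, normalized = scale(sig$x)[, 1],
                       dt = 1000 / sig$fs, fs = sig$fs, layer_id = "syn",
                       utterance_id = 1L), class = "population_signal")
  r1 <- pac_test(ps, ps, "theta", "low_gamma", n_surrogates = 500,
                 rng_seed = 3)
  expect_true(r1$significant)
  expect_lt(r1$p_mi, 0.05)
  expect_lt(r1$p_mvl, 0.05)
  r2 <- pac_test(ps, ps, "theta", "low_gamma", n_surrogates = 500,
                 rng_seed = 3)
  expect_identical(r1, r2)
})

test_that("coupling reports tabulate significance by relation type", {
  sc <- enumerate_scenarios(c("nerve", "snn1", "snn2", "snn3"))[1:3, ]
  mk <- function(sig) structure(list(mi = 0.1, mvl = 0.1, p_mi = 0.01,
                                     p_mvl = if (sig) 0.01 else 0.5,
                                     n_surrogates = 10, significant = sig,
                                     rng_seed = 1), class = "pac_result")
  rep0 <- coupling_report(sc, list(mk(FALSE), mk(FALSE), mk(FALSE)))
  expect_equal(rep0$n_intra + rep0$n_inter, 0)
  sc2 <- enumerate_scenarios(c("nerve", "snn1", "snn2", "snn3"))
  inter_idx <- which(sc2$relation == "inter" & sc2$phase_band == "theta" &
                       sc2$amplitude_band == "low_gamma" &
                       sc2$phase_layer == "nerve" &
                       sc2$amplitude_layer == "snn3")[1]
  res <- lapply(seq_len(nrow(sc2)), function(i) mk(i == inter_idx))
  rep1 <- coupling_report(sc2, res)
  expect_equal(rep1$n_inter, 1)
  expect_equal(rep1$n_intra, 0)
})

test_that("rate histograms conserve neurons and locate the Poisson mode", {
  v <- array(0, c(1, 1000, 6))
  v[1, seq(1, 1000, by = 100), ] <- 1  # all neurons at 5 Hz (dt = 2 ms)
  rd <- rate_distribution(spike_raster(v, dt = 2),
                          bin_edges = seq(0, 250, by = 10))
  expect_equal(sum(rd$counts > 0), 1)
  expect_equal(sum(rd$counts), 6)
  pois <- gen_poisson_raster(60, n_neurons = 400, duration = 10, dt = 2,
                             seed = 3)
  rdp <- rate_distribution(pois, bin_edges = seq(0, 250, by = 10))
  expect_equal(sum(rdp$counts), 400)
  expect_equal(rdp$mids[which.max(rdp$counts)], 65, tolerance = 10)
})
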