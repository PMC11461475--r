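test_that("zero state with zero input is a fixed point", {
  p <- neuron_params(tau_u = 10, tau_w = 100, a = 1, b = 1)
  out <- simulate_neuron(rep(0, 50), p, dt = 2)
  expect_true(all(out$u == 0) && all(out$w == 0) && all(out$s == 0))
})

test_that("subthreshold LIF converges to the input fixed point", {
  p <- neuron_params(tau_u = 10, sfa_enabled = FALSE)
  out <- simulate_neuron(rep(0.9, 400), p, dt = 2)
  expect_equal(tail(out$u, 1), 0.9, tolerance = 1e-8)
  expect_true(all(out$s == 0))
  expect_true(all(out$w == 0))
})

test_that("single-step LIF update matches the hand-evaluated recurrence", {
  p <- neuron_params(tau_u = 5, sfa_enabled = FALSE)
  out <- simulate_neuron(2.0, p, dt = 1)
  expect_equal(out$u, (1 - exp(-1 / 5)) * 2, tolerance = 1e-12)
  expect_equal(out$s, 0)
})

test_that("adlif_step reads only previous-step values", {
  p <- neuron_params(tau_u = 5, tau_w = 30, a = 0.5, b = 1.5)
  co <- decay_coefficients(p, 1)
  st <- list(u = 1.2, w = 0.3, s = 1)
  nx <- adlif_step(st, 0.7, p, co)
  expect_equal(nx$u, co$alpha * (1.2 - 1) + (1 - co$alpha) * (0.7 - 0.3))
  expect_equal(nx$w, co$beta * (0.3 + p$b * 1) + (1 - co$beta) * p$a * 1.2)
  expect_equal(nx$s, as.numeric(nx$u >= 1))
  expect_error(adlif_step(st, NaN, p, co), "non-finite")
  expect_error(decay_coefficients(p, -1), "positive")
})

test_that("simulation equals an independently coded loop over the recurrence", {
  for (seed in 1:20) {
    pars <- draw_box_params(seed)
    T_ <- sample(5:200, 1)
    I <- rnorm(T_, mean = 0.6, sd = 0.8)
    p <- neuron_params(pars$tau_u, pars$tau_w, pars$a, pars$b)
    got <- simulate_neuron(I, p, dt = 2)
    ref <- oracle_adlif(I, pars$tau_u, pars$tau_w, pars$a, pars$b, dt = 2)
    expect_lt(max(abs(got$u - ref$u)), 1e-10)
    expect_lt(max(abs(got$w - ref$w)), 1e-10)
    expect_identical(got$s, ref$s)
  }
})

test_that("subthreshold trace matches the analytic linear-map solution", {
  p <- neuron_params(tau_u = 8, tau_w = 60, a = 1.2, b = 0.7)
  dt <- 2
  co <- decay_coefficients(p, dt)
  T_ <- 150
  I <- 0.3 * sin(seq_len(T_) / 9)  # stays far below threshold
  out <- simulate_neuron(I, p, dt)
  expect_true(all(out$s == 0))
  A <- matrix(c(co$alpha, (1 - co$beta) * p$a,
                -(1 - co$alpha), co$beta), 2, 2)
  x <- c(0, 0)
  u_ref <- numeric(T_)
  for (t in seq_len(T_)) {
    x <- as.numeric(A %*% x + c((1 - co$alpha) * I[t], 0))
    u_ref[t] <- x[1]
  }
  expect_lt(max(abs(out$u - u_ref)), 1e-8)
})

test_that("pulse response matches a fine-step reference integration", {
  # Input-pulse response of the two-variable neuron: positive peak followed
  # by an adaptation undershoot below zero.
  p <- neuron_params(tau_u = 5, tau_w = 30, a = 0.5, b = 1.5)
  dt <- 1
  horizon <- 120
  pulse_ms <- 1
  amp <- 0.5
  I <- c(rep(0, 9), rep(amp, pulse_ms / dt), rep(0, horizon - 10))
  coarse <- simulate_neuron(I, p, dt)
  fine_dt <- dt / 10
  I_fine <- rep(I, each = dt / fine_dt)
  fine <- oracle_adlif(I_fine, p$tau_u, p$tau_w, p$a, p$b, fine_dt)
  u_fine_sampled <- fine$u[seq(10, length(I_fine), by = dt / fine_dt)]
  expect_lt(max(abs(coarse$u - u_fine_sampled)), 0.02)
  expect_gt(max(coarse$u), 0)
  expect_lt(min(coarse$u), 0)  # undershoot
})

test_that("boxcar surrogate takes its printed values", {
  expect_equal(boxcar_surrogate(1.0), 0.5)
  expect_equal(boxcar_surrogate(0.5), 0.5)  # boundary |u-1| = 0.5
  expect_equal(boxcar_surrogate(1.5), 0.5)
  expect_equal(boxcar_surrogate(1.6), 0)
  expect_equal(boxcar_surrogate(c(0.4, 2)), c(0, 0))
})

test_that("parameter projection clips to the admissible box and is idempotent", {
  p <- neuron_params(tau_u = 10, tau_w = 100, a = 0.5, b = 0.5)
  p$tau_u <- 1; p$a <- -2; p$tau_w <- 500; p$b <- 3
  q <- clamp_parameters(p)
  expect_equal(q$tau_u, 3)
  expect_equal(q$a, -0.5)
  expect_equal(q$tau_w, 350)
  expect_equal(q$b, 2)
  expect_identical(clamp_parameters(q), q)
  r <- neuron_params(tau_u = 12, tau_w = 80, a = 1, b = 1)
  expect_identical(clamp_parameters(r), r)
  # SFA mask forces a = b = 0 and hence w = 0 throughout
  lif <- neuron_params(tau_u = 12, tau_w = 80, a = 1, b = 1,
                       sfa_enabled = FALSE)
  expect_equal(lif$a, 0)
  expect_equal(lif$b, 0)
  out <- simulate_neuron(runif(100, 0, 2), lif, dt = 2)
  expect_true(all(out$w == 0))
})

test_that("admissible parameters give a stable subthreshold map", {
  set.seed(1)
  for (i in 1:50) {
    p <- neuron_params(runif(1, 3, 25), runif(1, 30, 350),
                       runif(1, -0.5, 5), runif(1, 0, 2))
    expect_true(all(subthreshold_stable(p)))
  }
})

test_that("spike-frequency adaptation slows sustained firing", {
  base <- list(tau_u = 8, tau_w = 100, a = 0)
  I <- rep(1.6, 500)
  no_sfa <- simulate_neuron(I, neuron_params(base$tau_u, base$tau_w, 0, 0),
                            dt = 2)
  sfa <- simulate_neuron(I, neuron_params(base$tau_u, base$tau_w, 0, 1.5),
                         dt = 2)
  isi <- function(s) diff(which(s == 1))
  expect_gt(mean(isi(sfa$s)), mean(isi(no_sfa$s)))
  # adaptation also lengthens intervals over time within the b > 0 run
  iv <- isi(sfa$s)
  expect_gte(mean(tail(iv, 3)), mean(head(iv, 3)))
})

test_that("SRM kernels have the expected shapes", {
  # LIF: pure exponential decay with ratio alpha between samples
  lif <- neuron_params(tau_u = 5, sfa_enabled = FALSE)
  k <- srm_kernels(lif, dt = 1, horizon = 60)
  ratios <- k$input_kernel[-1] / k$input_kernel[-length(k$input_kernel)]
  expect_equal(ratios, rep(exp(-1 / 5), length(ratios)), tolerance = 1e-10)
  # adaptation undershoot: exactly one zero crossing after the peak
  ad <- neuron_params(tau_u = 5, tau_w = 30, a = 0.5, b = 1.5)
  k2 <- srm_kernels(ad, dt = 1, horizon = 200)
  pk <- which.max(k2$input_kernel)
  crossings <- sum(diff(sign(k2$input_kernel[pk:length(k2$input_kernel)])) != 0)
  expect_equal(crossings, 1)
  # spike-response kernel starts with the negative reset deflection
  expect_lt(k2$spike_kernel[1], 0)
  expect_equal(k2$spike_kernel[1], -exp(-1 / 5), tolerance = 1e-10)
  expect_error(srm_kernels(ad, dt = 1, horizon = 4), "horizon")
})

test_that("larger membrane time constant never decays a pulse faster", {
  k_fast <- srm_kernels(neuron_params(tau_u = 5, sfa_enabled = FALSE),
                        dt = 1, horizon = 80)
  k_slow <- srm_kernels(neuron_params(tau_u = 15, sfa_enabled = FALSE),
                        dt = 1, horizon = 80)
  n_f <- k_fast$input_kernel / max(k_fast$input_kernel)
  n_s <- k_slow$input_kernel / max(k_slow$input_kernel)
  expect_true(all(n_s >= n_f - 1e-12))
})
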