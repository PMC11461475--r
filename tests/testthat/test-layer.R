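test_that("layer stimulus is the masked linear drive", {
  set.seed(3)
  W <- matrix(rnorm(64), 8, 8)
  V <- matrix(rnorm(64), 8, 8); diag(V) <- 0
  s_prev <- rbinom(8, 1, 0.4)
  s_own <- rbinom(8, 1, 0.4)
  got <- layer_stimulus(s_prev, s_own, W, V)
  # brute-force double loop
  ref <- numeric(8)
  for (n in 1:8) {
    for (j in 1:8) ref[n] <- ref[n] + W[n, j] * s_prev[j] + V[n, j] * s_own[j]
  }
  expect_equal(got, ref, tolerance = 1e-12)
  expect_equal(layer_stimulus(rep(0, 8), rep(0, 8), W, V), rep(0, 8))
  expect_equal(layer_stimulus(s_prev, s_own, W, V * 0),
               as.numeric(W %*% s_prev))
  expect_error(layer_stimulus(s_prev[1:3], s_own, W, V), "shape")
  Vd <- V; Vd[1, 1] <- 1
  expect_error(layer_stimulus(s_prev, s_own, W, Vd), "diagonal")
})

test_that("layer forward equals a hand-rolled loop oracle (B=1, T=50, N=4)", {
  spec <- layer_spec(4, ff_connectivity = 0.8, rec_connectivity = 0.7,
                     sfa_fraction = 0.5, mask_seed = 9, w_gain = 6)
  layer <- init_layer(spec, n_inputs = 6)
  set.seed(21)
  s_in <- matrix(rbinom(50 * 6, 1, 0.3), 50, 6)
  ras_in <- spike_raster(s_in, dt = 2, layer_id = "in")
  out <- layer_forward(ras_in, layer, dt = 2)
  ew <- spikeosc:::effective_weights(layer)
  ref <- oracle_layer(s_in, ew$W, ew$V, layer$params$tau_u,
                      layer$params$tau_w, layer$params$a, layer$params$b,
                      dt = 2)
  expect_lt(max(abs(out$values[1, , ] - ref$s)), 1e-10)
  expect_gt(sum(ref$s), 0)  # the case actually spikes
})

test_that("zero input through a fresh layer stays silent", {
  layer <- init_layer(layer_spec(5, mask_seed = 2), n_inputs = 3)
  ras <- spike_raster(matrix(0, 40, 3), dt = 2)
  out <- layer_forward(ras, layer, dt = 2)
  expect_true(all(out$values == 0))
})

test_that("an identity single-neuron layer reduces to simulate_neuron", {
  spec <- layer_spec(1, rec_connectivity = 0, sfa_fraction = 1, mask_seed = 4)
  layer <- init_layer(spec, n_inputs = 1)
  layer$W <- matrix(1, 1, 1)
  layer$mask_W <- matrix(1, 1, 1)
  s_in <- matrix(rep(c(1, 1, 0, 1, 0), 8), ncol = 1)
  out <- layer_forward(spike_raster(s_in, dt = 2), layer, dt = 2)
  ref <- simulate_neuron(as.numeric(s_in), layer$params, dt = 2)
  expect_equal(as.numeric(out$values[1, , 1]), ref$s)
})

test_that("dt mismatch between raster and layer is rejected", {
  layer <- init_layer(layer_spec(3, mask_seed = 5), n_inputs = 3)
  ras <- spike_raster(matrix(0, 10, 3), dt = 1)
  expect_error(layer_forward(ras, layer, dt = 2), "dt mismatch")
})

test_that("Dale's law signs outgoing weights per presynaptic neuron", {
  set.seed(8)
  W <- matrix(rnorm(30), 3, 10)
  expect_equal(apply_dale(W, rep(1, 10)), abs(W))
  signs10 <- dale_signs(10, ei_ratio = 1, seed = 1)
  expect_equal(sum(signs10 == 1), 5)
  signs12 <- dale_signs(12, ei_ratio = 0.33, seed = 1)
  expect_equal(sum(signs12 == 1), 3)
  Wd <- apply_dale(W, c(rep(1, 4), rep(-1, 6)))
  expect_true(all(Wd[, 1:4] >= 0) && all(Wd[, 5:10] <= 0))
  expect_equal(abs(Wd), abs(W))
})

test_that("firing rates follow spike count over true duration", {
  v <- array(0, c(1, 1000, 2))
  v[1, seq_len(10), 1] <- 1
  ras <- spike_raster(v, dt = 2, duration_s = 2)
  r <- firing_rates(ras)
  expect_equal(r[1, 1], 5)   # 10 spikes over 2 s
  expect_equal(r[1, 2], 0)   # silent neuron
  all_on <- spike_raster(array(1, c(1, 500, 3)), dt = 2)
  expect_equal(as.numeric(firing_rates(all_on)), rep(500, 3))
  bad <- all_on; bad$duration_s <- 0
  expect_error(firing_rates(bad), "duration")
})

test_that("rate regularization matches the nested-normalization hand value", {
  cfg <- reg_config(f_min = 0.5, f_max = 250)
  expect_equal(regularization_loss(matrix(c(100, 7), 1), cfg), 0)
  expect_equal(regularization_loss(matrix(0, 1, 1), cfg), 0.5)
  rates <- list(matrix(c(0, 1), 1), matrix(c(300, 260), 1))
  expect_equal(regularization_loss(rates, cfg),
               0.5 * ((0.5 + 0) / 2 + (50 + 10) / 2))
  expect_equal(regularization_loss(rates, cfg), 15.125)
})

test_that("layers without SFA produce no adaptation current", {
  spec <- layer_spec(6, sfa_fraction = 0, mask_seed = 3, w_gain = 6)
  layer <- init_layer(spec, n_inputs = 4)
  set.seed(2)
  ras <- spike_raster(matrix(rbinom(120, 1, 0.5), 30, 4), dt = 2)
  out <- layer_forward(ras, layer, dt = 2, return_cache = TRUE)
  expect_true(all(attr(out, "cache")$w == 0))
})

test_that("raster event-list serialization round-trips losslessly", {
  set.seed(11)
  v <- array(rbinom(2 * 40 * 5, 1, 0.2), c(2, 40, 5))
  ras <- spike_raster(v, dt = 2, layer_id = "snn1",
                      duration_s = c(0.08, 0.061))
  path <- tempfile(fileext = ".events")
  write_raster_events(ras, path)
  back <- read_raster_events(path)
  expect_identical(back$values, ras$values * 1)
  expect_equal(back$dt, ras$dt)
  expect_equal(back$duration_s, ras$duration_s)
  expect_equal(back$layer_id, ras$layer_id)
  # empty raster round-trips too
  empty <- spike_raster(array(0, c(1, 10, 3)), dt = 1)
  write_raster_events(empty, path)
  expect_identical(read_raster_events(path)$values, empty$values * 1)
})

test_that("surrogate gradients reach layer weights and time constants", {
  spec <- layer_spec(4, rec_connectivity = 0.8, sfa_fraction = 1,
                     mask_seed = 6, w_gain = 6)
  layer <- init_layer(spec, n_inputs = 4)
  set.seed(5)
  ras <- spike_raster(matrix(rbinom(200, 1, 0.4), 50, 4), dt = 2)
  out <- layer_forward(ras, layer, dt = 2, return_cache = TRUE)
  expect_gt(sum(out$values), 0)
  cache <- attr(out, "cache")
  gs_ext <- array(1, dim(out$values))  # loss = total spike count
  bk <- spikeosc:::adlif_backward_cpp(
    gs_ext, out$values, cache$u, cache$w, t(cache$ew$V),
    cache$coeffs$alpha, cache$coeffs$beta, layer$params$a, layer$params$b,
    1L, 50L, 4L, TRUE)
  gff <- bk$g_ff; dim(gff) <- c(50, 4)
  sp <- matrix(ras$values[1, , ], 50, 4)
  gW <- t(crossprod(sp, gff))
  expect_gt(sum(abs(gW)), 0)
  expect_gt(sum(abs(bk$gVt)), 0)
  expect_gt(sum(abs(bk$g_alpha)), 0)
})
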