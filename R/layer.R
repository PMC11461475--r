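#' Spiking layer specification
#'
#' Describes one layer of AdLIF/LIF neurons: its width, the fractions of
#' nonzero feedforward and recurrent connections (enforced through fixed
#' random binary masks), the fraction of neurons with spike-frequency
#' adaptation, and optional Dale's-law sign constraints.
#'
#' `ei_ratio` is the excitatory:inhibitory count ratio — 1 means half the
#' neurons are excitatory and half inhibitory, 0.33 means one excitatory for
#' every three inhibitory neurons.
#'
#' @param n_neurons Layer width.
#' @param ff_connectivity Fraction of nonzero feedforward weights, in \[0,1\].
#' @param rec_connectivity Fraction of nonzero recurrent weights, in \[0,1\];
#'   0 disables recurrence.
#' @param sfa_fraction Fraction of AdLIF (adapting) neurons, in \[0,1\].
#' @param dale Logical; enforce Dale's law on outgoing weights.
#' @param ei_ratio Excitatory:inhibitory ratio used when `dale = TRUE`.
#' @param mask_seed Integer seed fixing masks, sign assignment and parameter
#'   initialization.
#' @param w_gain Feedforward init gain: weights are drawn with standard
#'   deviation `w_gain / sqrt(n_inputs)`. Spiking layers need a gain above 1
#'   because their binary inputs are sparse; the default targets membrane
#'   fluctuations of order the threshold at typical input rates.
#' @return A list of class `layer_spec`.
#' @export
layer_spec <- function(n_neurons, ff_connectivity = 1, rec_connectivity = 1,
                       sfa_fraction = 0.5, dale = FALSE, ei_ratio = 1,
                       mask_seed = 1L, w_gain = 4) {
  stopifnot(n_neurons >= 1,
            ff_connectivity >= 0, ff_connectivity <= 1,
            rec_connectivity >= 0, rec_connectivity <= 1,
            sfa_fraction >= 0, sfa_fraction <= 1, ei_ratio > 0)
  structure(list(n_neurons = as.integer(n_neurons),
                 ff_connectivity = ff_connectivity,
                 rec_connectivity = rec_connectivity,
                 sfa_fraction = sfa_fraction, dale = dale,
                 ei_ratio = ei_ratio, mask_seed = as.integer(mask_seed),
                 w_gain = w_gain),
            class = "layer_spec")
}

# evaluate expr under a private RNG stream, restoring the caller's stream
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# binary mask with approximately `fraction` nonzero entries, fixed count
random_mask <- function(n_out, n_in, fraction) {
  m <- matrix(0, n_out, n_in)
  k <- round(fraction * n_out * n_in)
  if (k > 0) m[sample.int(n_out * n_in, k)] <- 1
  m
}

#' Dale's-law sign assignment for a layer
#'
#' Assigns each neuron an outgoing sign (+1 excitatory, -1 inhibitory) under
#' a seeded permutation. For E/I ratio r the excitatory count is
#' `ceiling(N * r / (1 + r))`: a ratio of 1 gives half excitatory, 0.33
#' gives one excitatory neuron per three inhibitory ones.
#'
#' @param n Number of neurons.
#' @param ei_ratio Excitatory:inhibitory count ratio.
#' @param seed Integer seed for the permutation.
#' @return Vector of +/-1 of length `n`.
#' @export
dale_signs <- function(n, ei_ratio, seed = 1L) {
  n_exc <- ceiling(n * ei_ratio / (1 + ei_ratio))
  signs <- c(rep(1, n_exc), rep(-1, n - n_exc))
  with_seed(seed, sample(signs))
}

#' Impose Dale's law on a weight matrix
#'
#' Every presynaptic neuron's outgoing weights share one sign: column j of
#' the result (presynaptic index, for `W %*% s` stimulus convention) equals
#' `signs[j] * |W_raw[, j]|`.
#'
#' @param W_raw Unconstrained weight matrix, postsynaptic x presynaptic.
#' @param presynaptic_signs Vector of +/-1, one per presynaptic neuron.
#' @return Signed weight matrix of the same shape.
#' @export
apply_dale <- function(W_raw, presynaptic_signs) {
  stopifnot(ncol(W_raw) == length(presynaptic_signs))
  sweep(abs(W_raw), 2, presynaptic_signs, "*")
}

#' Initialize a spiking layer
#'
#' Draws the feedforward and recurrent weights (zero-mean normal scaled by
#' fan-in), the fixed binary connectivity masks, the SFA mask, Dale signs and
#' heterogeneous neuron parameters (uniform over their admissible ranges),
#' all from `spec$mask_seed`. The recurrent matrix diagonal is forced to zero
#' (no autapses; the after-spike reset already provides self-inhibition).
#'
#' @param spec A [layer_spec()].
#' @param n_inputs Number of presynaptic (previous-layer) neurons.
#' @param in_signs Presynaptic sign vector for Dale's law on the feedforward
#'   weights (`NULL` when the previous layer is unsigned).
#' @return A list of class `snn_layer` with raw weights, masks, signs and
#'   `neuron_params`.
#' @export
init_layer <- function(spec, n_inputs, in_signs = NULL) {
  with_seed(spec$mask_seed, {
    N <- spec$n_neurons
    W <- matrix(rnorm(N * n_inputs, sd = spec$w_gain / sqrt(max(1, n_inputs))),
                N, n_inputs)
    V <- matrix(rnorm(N * N, sd = 1 / sqrt(N)), N, N)
    mask_W <- random_mask(N, n_inputs, spec$ff_connectivity)
    mask_V <- random_mask(N, N, spec$rec_connectivity)
    diag(mask_V) <- 0
    sfa <- rep(FALSE, N)
    n_sfa <- round(spec$sfa_fraction * N)
    if (n_sfa > 0) sfa[sample.int(N, n_sfa)] <- TRUE
    params <- neuron_params(tau_u = runif(N, 3, 25),
                            tau_w = runif(N, 30, 350),
                            a = runif(N, 0, 2), b = runif(N, 0, 2),
                            sfa_enabled = sfa)
    signs <- if (spec$dale) dale_signs(N, spec$ei_ratio, spec$mask_seed) else NULL
    structure(list(spec = spec, n_inputs = n_inputs, W = W, V = V,
                   mask_W = mask_W, mask_V = mask_V, params = params,
                   signs = signs, in_signs = in_signs),
              class = "snn_layer")
  })
}

# effective (masked, signed) weight matrices of a layer
effective_weights <- function(layer) {
  W <- layer$W * layer$mask_W
  V <- layer$V * layer$mask_V
  if (layer$spec$dale) {
    if (!is.null(layer$in_signs)) W <- apply_dale(W, layer$in_signs)
    V <- apply_dale(V, layer$signs)
  }
  diag(V) <- 0
  list(W = W, V = V)
}

#' Layer stimulus from feedforward and recurrent spikes
#'
#' Computes `I_t = W %*% s_prev_t + V %*% s_own_tm1`, the linear drive of one
#' layer at one time step.
#'
#' @param prev_layer_spikes_t Binary vector: previous layer's spikes at t.
#' @param own_spikes_tminus1 Binary vector: this layer's spikes at t-1.
#' @param W Feedforward weights (postsynaptic x presynaptic), masks applied.
#' @param V Recurrent weights with zero diagonal, masks applied.
#' @return Stimulus vector I_t.
#' @export
layer_stimulus <- function(prev_layer_spikes_t, own_spikes_tminus1, W, V) {
  if (ncol(W) != length(prev_layer_spikes_t) ||
      ncol(V) != length(own_spikes_tminus1) || nrow(W) != nrow(V))
    stop("shape mismatch between spikes and weights")
  if (any(diag(V) != 0)) stop("recurrent diagonal must be zero")
  as.numeric(W %*% prev_layer_spikes_t + V %*% own_spikes_tminus1)
}

#' Run a spiking layer over an input raster
#'
#' Evolves every neuron by the discrete AdLIF update, with stimulus
#' `I_t = W s^{l-1}_t + V s^l_{t-1}` (masked weights, zero recurrent
#' diagonal, optional Dale signs). Real-valued input (a `B x T x n_inputs`
#' array) is also accepted and is then fed directly as stimulus without a
#' weight matrix — the auditory-nerve case.
#'
#' @param input A [spike_raster()] (spiking input through `W`) or a numeric
#'   `B x T x N` array of direct stimuli (then the layer must have
#'   `n_inputs == spec$n_neurons` and `W` is unused).
#' @param layer An [init_layer()] result.
#' @param dt Simulation step, ms; must match a raster input's `dt`.
#' @param return_cache Keep membrane traces for a backward pass.
#' @return A [spike_raster()]; with `return_cache = TRUE`, attribute `cache`
#'   holds `u`, `w` and the feedforward drive.
#' @export
layer_forward <- function(input, layer, dt, return_cache = FALSE) {
  direct <- !inherits(input, "spike_raster")
  if (!direct && abs(input$dt - dt) > 1e-12)
    stop("dt mismatch between raster and coefficients")
  x <- if (direct) input else input$values
  stopifnot(length(dim(x)) == 3L)
  B <- dim(x)[1]; T_ <- dim(x)[2]
  N <- layer$spec$n_neurons
  ew <- effective_weights(layer)
  if (direct) {
    ff <- x
    stopifnot(dim(x)[3] == N)
  } else {
    xm <- x; dim(xm) <- c(B * T_, dim(x)[3])
    ff <- xm %*% t(ew$W)
    dim(ff) <- c(B, T_, N)
  }
  co <- decay_coefficients(layer$params, dt)
  recurrent <- layer$spec$rec_connectivity > 0
  out <- adlif_forward_cpp(ff, t(ew$V), co$alpha, co$beta, layer$params$a,
                           layer$params$b, B, T_, N, recurrent)
  dur <- if (direct) rep(T_ * dt / 1000, B) else input$duration_s
  ras <- spike_raster(out$s, dt = dt, layer_id = "layer", duration_s = dur)
  if (return_cache)
    attr(ras, "cache") <- list(u = out$u, w = out$w, ff = ff, ew = ew,
                               coeffs = co, recurrent = recurrent)
  ras
}
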