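#' Adaptive leaky integrate-and-fire neuron parameters
#'
#' Bundles the four constants of the dimensionless AdLIF neuron (threshold 1,
#' rest 0): the membrane time constant `tau_u`, the adaptation time constant
#' `tau_w`, the subthreshold coupling strength `a` and the spike-triggered
#' adaptation increment `b`. When `sfa_enabled` is `FALSE` the neuron has no
#' spike-frequency adaptation: `a` and `b` are forced to 0 and the model
#' reduces to a plain LIF neuron.
#'
#' All fields may be vectors (one entry per neuron); scalar fields are
#' recycled. Values are projected into their biologically plausible ranges:
#' tau_u in \[3, 25\] ms, tau_w in \[30, 350\] ms, a in \[-0.5, 5\],
#' b in \[0, 2\].
#'
#' @param tau_u Membrane time constant, ms.
#' @param tau_w Adaptation time constant, ms.
#' @param a Subthreshold coupling strength, dimensionless.
#' @param b Spike-triggered adaptation increment, dimensionless.
#' @param sfa_enabled Logical; per-neuron spike-frequency-adaptation flag.
#' @return An object of class `neuron_params`.
#' @examples
#' p <- neuron_params(tau_u = 5, tau_w = 30, a = 0.5, b = 1.5)
#' @export
neuron_params <- function(tau_u = 10, tau_w = 100, a = 0, b = 0,
                          sfa_enabled = TRUE) {
  n <- max(length(tau_u), length(tau_w), length(a), length(b),
           length(sfa_enabled))
  p <- structure(list(
    tau_u = rep_len(as.numeric(tau_u), n),
    tau_w = rep_len(as.numeric(tau_w), n),
    a = rep_len(as.numeric(a), n),
    b = rep_len(as.numeric(b), n),
    sfa_enabled = rep_len(as.logical(sfa_enabled), n)
  ), class = "neuron_params")
  clamp_parameters(p)
}

#' Project neuron parameters into their plausible ranges
#'
#' Each field is clipped into its admissible interval (tau_u 3--25 ms,
#' tau_w 30--350 ms, a -0.5--5, b 0--2), the SFA mask is re-applied
#' (`a = b = 0` where disabled), and the subthreshold stability of the
#' resulting two-variable linear map is verified. The projection is total and
#' idempotent; it is meant to be applied after every optimizer step.
#'
#' @param params A `neuron_params` object (possibly with out-of-range values,
#'   e.g. after a gradient update).
#' @return A `neuron_params` object with every invariant restored.
#' @export
clamp_parameters <- function(params) {
  params$tau_u <- pmin(pmax(params$tau_u, 3), 25)
  params$tau_w <- pmin(pmax(params$tau_w, 30), 350)
  params$a <- pmin(pmax(params$a, -0.5), 5)
  params$b <- pmin(pmax(params$b, 0), 2)
  off <- !params$sfa_enabled
  params$a[off] <- 0
  params$b[off] <- 0
  stopifnot(all(subthreshold_stable(params)))
  params
}

#' Decay coefficients for a given simulation step
#'
#' Computes `alpha = exp(-dt/tau_u)` and `beta = exp(-dt/tau_w)`; both lie
#' strictly in (0, 1). Recompute whenever the time constants or the step
#' change.
#'
#' @param params A `neuron_params` object.
#' @param dt Simulation step, ms (> 0).
#' @return A list with `alpha`, `beta` and `dt`.
#' @export
decay_coefficients <- function(params, dt) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a positive scalar (ms)")
  list(alpha = exp(-dt / params$tau_u), beta = exp(-dt / params$tau_w),
       dt = dt)
}

#' Spectral-radius stability check of the subthreshold dynamics
#'
#' With spiking suppressed, (u, w) follows the linear map
#' `u_t = alpha*u_{t-1} - (1-alpha)*w_{t-1}`,
#' `w_t = (1-beta)*a*u_{t-1} + beta*w_{t-1}`. The map is stable when the
#' spectral radius of its 2x2 transition matrix is below 1. The check is
#' evaluated at the most permissive admissible step (dt = 1 ms is used; the
#' radius shrinks with larger dt for admissible parameters).
#'
#' @param params A `neuron_params` object.
#' @param dt Simulation step used to form the transition matrix, ms.
#' @return Logical vector, one entry per neuron.
#' @export
subthreshold_stable <- function(params, dt = 1) {
  alpha <- exp(-dt / params$tau_u)
  beta <- exp(-dt / params$tau_w)
  # closed-form spectral radius of [[alpha, -(1-alpha)], [(1-beta)a, beta]]
  tr <- alpha + beta
  dt2 <- alpha * beta + (1 - alpha) * (1 - beta) * params$a
  disc <- tr^2 - 4 * dt2
  rho <- ifelse(disc < 0, sqrt(pmax(dt2, 0)),
                pmax(abs(tr + sqrt(pmax(disc, 0))),
                     abs(tr - sqrt(pmax(disc, 0)))) / 2)
  rho < 1
}

#' One discrete AdLIF update step
#'
#' Applies the exponential-integrator update from the previous state, reading
#' only previous-step values:
#' `u_t = alpha*(u_{t-1} - s_{t-1}) + (1-alpha)*(I_t - w_{t-1})`,
#' `w_t = beta*(w_{t-1} + b*s_{t-1}) + (1-beta)*a*u_{t-1}`,
#' `s_t = [u_t >= 1]`.
#'
#' @param state List with numeric `u`, `w` and binary `s` (use
#'   `list(u = 0, w = 0, s = 0)` for the rest state).
#' @param stimulus Dimensionless input current I_t (finite).
#' @param params A `neuron_params` object (scalar fields).
#' @param coeffs Output of [decay_coefficients()] for `params`.
#' @return The next state, same shape as `state`.
#' @export
adlif_step <- function(state, stimulus, params, coeffs) {
  if (!all(is.finite(stimulus))) stop("non-finite stimulus")
  if (!all(is.finite(c(state$u, state$w, state$s)))) stop("non-finite state")
  u <- coeffs$alpha * (state$u - state$s) +
    (1 - coeffs$alpha) * (stimulus - state$w)
  w <- coeffs$beta * (state$w + params$b * state$s) +
    (1 - coeffs$beta) * params$a * state$u
  list(u = u, w = w, s = as.numeric(u >= 1))
}

#' Simulate a single neuron over a stimulus series
#'
#' Repeats [adlif_step()] from the zero initial state `u0 = w0 = s0 = 0` over
#' the whole stimulus.
#'
#' @param stimulus_series Numeric vector of dimensionless inputs I_t.
#' @param params A `neuron_params` object (scalar fields).
#' @param dt Simulation step, ms.
#' @return List with numeric vectors `u`, `w` and binary `s`, each of length
#'   `length(stimulus_series)`.
#' @export
simulate_neuron <- function(stimulus_series, params, dt) {
  if (length(stimulus_series) < 1L) stop("empty stimulus")
  if (!all(is.finite(stimulus_series))) stop("non-finite stimulus")
  co <- decay_coefficients(params, dt)
  T_ <- length(stimulus_series)
  ff <- array(stimulus_series, dim = c(1L, T_, 1L))
  out <- adlif_forward_cpp(ff, matrix(0, 1, 1), co$alpha, co$beta,
                           params$a, params$b, 1L, T_, 1L, FALSE)
  list(u = as.numeric(out$u), w = as.numeric(out$w), s = as.numeric(out$s))
}

#' Boxcar surrogate derivative of the spike threshold
#'
#' The threshold nonlinearity `s = [u >= 1]` has a derivative of zero almost
#' everywhere; during reverse-mode gradient accumulation it is replaced by the
#' boxcar function: 0.5 where `|u - 1| <= 0.5`, 0 otherwise.
#'
#' @param u_t Membrane potential value(s), dimensionless.
#' @return Surrogate derivative, same shape as `u_t`.
#' @export
boxcar_surrogate <- function(u_t) {
  if (!all(is.finite(u_t))) stop("non-finite membrane potential")
  0.5 * (abs(u_t - 1) <= 0.5)
}

#' Spike-response-model kernels of an AdLIF neuron
#'
#' The AdLIF neuron is equivalent to a spike response model characterized by
#' two kernels: the membrane response to a unit input pulse and the response
#' to an emitted spike. Both are obtained by direct simulation from rest with
#' spiking suppressed (the input pulse is scaled so the trace stays
#' subthreshold; kernels are reported up to input scaling).
#'
#' @param params A `neuron_params` object (scalar fields).
#' @param dt Simulation step, ms.
#' @param horizon Kernel duration, ms; must exceed `tau_u` and should cover
#'   several `tau_w` for the adaptation undershoot to resolve.
#' @return List with `time` (ms) and numeric vectors `input_kernel` and
#'   `spike_kernel`.
#' @export
srm_kernels <- function(params, dt, horizon) {
  if (horizon <= params$tau_u) stop("horizon shorter than tau_u")
  T_ <- ceiling(horizon / dt)
  co <- decay_coefficients(params, dt)
  # input kernel: unit input pulse at t = 1, free subthreshold evolution
  u <- 0; w <- 0
  input_kernel <- numeric(T_)
  for (t in seq_len(T_)) {
    I_t <- if (t == 1L) 1 else 0
    u_new <- co$alpha * u + (1 - co$alpha) * (I_t - w)
    w_new <- co$beta * w + (1 - co$beta) * params$a * u
    u <- u_new; w <- w_new
    input_kernel[t] <- u
  }
  # spike kernel: force an emitted spike at t = 0 (s_0 = 1), no input
  u <- 0; w <- 0; s <- 1
  spike_kernel <- numeric(T_)
  for (t in seq_len(T_)) {
    u_new <- co$alpha * (u - s) + (1 - co$alpha) * (0 - w)
    w_new <- co$beta * (w + params$b * s) + (1 - co$beta) * params$a * u
    u <- u_new; w <- w_new; s <- 0
    spike_kernel[t] <- u
  }
  list(time = seq_len(T_) * dt, input_kernel = input_kernel,
       spike_kernel = spike_kernel)
}
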