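# Independent oracles, deliberately written as naive scalar loops so they
# share no code path with the package implementation.

# AdLIF recurrence, one neuron, plain R loop
oracle_adlif <- function(I, tau_u, tau_w, a, b, dt) {
  alpha <- exp(-dt / tau_u)
  beta <- exp(-dt / tau_w)
  T_ <- length(I)
  u <- numeric(T_); w <- numeric(T_); s <- numeric(T_)
  up <- 0; wp <- 0; sp <- 0
  for (t in seq_len(T_)) {
    u[t] <- alpha * (up - sp) + (1 - alpha) * (I[t] - wp)
    w[t] <- beta * (wp + b * sp) + (1 - beta) * a * up
    s[t] <- as.numeric(u[t] >= 1)
    up <- u[t]; wp <- w[t]; sp <- s[t]
  }
  list(u = u, w = w, s = s)
}

# layer of AdLIF neurons with feedforward + recurrent drive, double loops
oracle_layer <- function(spikes_in, W, V, tau_u, tau_w, a, b, dt) {
  T_ <- nrow(spikes_in)
  N <- nrow(W)
  alpha <- exp(-dt / tau_u); beta <- exp(-dt / tau_w)
  u <- matrix(0, T_, N); w <- matrix(0, T_, N); s <- matrix(0, T_, N)
  up <- numeric(N); wp <- numeric(N); sp <- numeric(N)
  for (t in seq_len(T_)) {
    for (n in seq_len(N)) {
      I_tn <- 0
      for (j in seq_len(ncol(W))) I_tn <- I_tn + W[n, j] * spikes_in[t, j]
      for (j in seq_len(N)) I_tn <- I_tn + V[n, j] * sp[j]
      u[t, n] <- alpha[n] * (up[n] - sp[n]) + (1 - alpha[n]) * (I_tn - wp[n])
      w[t, n] <- beta[n] * (wp[n] + b[n] * sp[n]) +
        (1 - beta[n]) * a[n] * up[n]
      s[t, n] <- as.numeric(u[t, n] >= 1)
    }
    up <- u[t, ]; wp <- w[t, ]; sp <- s[t, ]
  }
  list(u = u, w = w, s = s)
}

# CTC likelihood by exhaustive enumeration of all frame-label paths
oracle_ctc_nll <- function(log_probs, labels) {
  T_ <- nrow(log_probs); C <- ncol(log_probs)
  collapse <- function(path) {
    r <- rle(path)$values
    r[r != 1L]
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(C)), T_)))
  total <- 0
  for (i in seq_len(nrow(paths))) {
    p <- paths[i, ]
    if (identical(as.integer(collapse(p)), as.integer(labels)))
      total <- total + exp(sum(log_probs[cbind(seq_len(T_), p)]))
  }
  -log(total)
}

# modulation index by direct binned-KL computation
oracle_mi <- function(phase, amplitude, n_bins = 18) {
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  means <- numeric(n_bins)
  for (k in seq_len(n_bins)) {
    inbin <- phase > edges[k] & phase <= edges[k + 1]
    means[k] <- if (any(inbin)) mean(amplitude[inbin]) else 0
  }
  p <- means / sum(means)
  H <- -sum(p[p > 0] * log(p[p > 0]))
  (log(n_bins) - H) / log(n_bins)
}

# deterministic parameters drawn inside the admissible box
draw_box_params <- function(seed) {
  set.seed(seed)
  list(tau_u = runif(1, 3, 25), tau_w = runif(1, 30, 350),
       a = runif(1, -0.5, 5), b = runif(1, 0, 2))
}
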