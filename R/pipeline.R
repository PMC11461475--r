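#' End-to-end pipeline configuration
#'
#' Collects every architecture hyperparameter of the waveform-to-symbol
#' pipeline: Mel frontend, auditory CNN, LIF nerve fibers, multi-layered
#' recurrent SNN, and the pooling/projection readout head. The simulation
#' step equals the frontend hop (`hop_ms`, one of 1, 2 or 5 ms), the nerve
#' fiber count is `cnn_channels * (n_mels - 7 + 1)`, and the average-pooling
#' kernel is `40 / dt` steps so the readout always runs at 25 Hz.
#'
#' @param n_classes Number of output classes including the blank (40 for a
#'   39-phoneme inventory).
#' @param n_mels Number of Mel bins.
#' @param win_ms Mel analysis window, ms.
#' @param hop_ms Frontend hop = simulation step, ms (1, 2 or 5).
#' @param cnn_channels Auditory CNN channels.
#' @param cnn_kernel CNN kernel `(time, feature)`.
#' @param snn_layers List of [layer_spec()]s for the central SNN.
#' @param n_phoneme_features Width of the readout's hidden FC layers.
#' @param dropout Dropout probability (CNN channel dropout).
#' @param reg A [reg_config()] for firing-rate regularization.
#' @param reg_include_nerve Include the nerve fibers in the regularized
#'   layers.
#' @param fs Waveform sampling rate, Hz.
#' @param seed Integer seed for parameter initialization.
#' @return A list of class `pipeline_config` with derived fields `dt`
#'   (ms), `n_fibers`, `pool_kernel`, `frame_rate_hz`, `nyquist_hz` and
#'   `pooled_rate_hz`.
#' @export
pipeline_config <- function(n_classes = 40, n_mels = 80, win_ms = 25,
                            hop_ms = 2, cnn_channels = 16,
                            cnn_kernel = c(7, 7),
                            snn_layers = list(layer_spec(512, mask_seed = 1),
                                              layer_spec(512, mask_seed = 2),
                                              layer_spec(512, mask_seed = 3)),
                            n_phoneme_features = 512, dropout = 0.15,
                            reg = reg_config(), reg_include_nerve = TRUE,
                            fs = 16000, seed = 1L) {
  stopifnot(hop_ms %in% c(1, 2, 5))
  dt <- hop_ms
  pool_kernel <- 40 / dt
  stopifnot(pool_kernel == round(pool_kernel))
  cfg <- list(n_classes = n_classes, n_mels = n_mels, win_ms = win_ms,
              hop_ms = hop_ms, cnn_channels = cnn_channels,
              cnn_kernel = cnn_kernel, snn_layers = snn_layers,
              n_phoneme_features = n_phoneme_features, dropout = dropout,
              reg = reg, reg_include_nerve = reg_include_nerve, fs = fs,
              seed = as.integer(seed), dt = dt,
              n_fibers = cnn_channels * (n_mels - cnn_kernel[2] + 1),
              pool_kernel = as.integer(pool_kernel),
              frame_rate_hz = 1000 / hop_ms, nyquist_hz = 1000 / (2 * dt),
              pooled_rate_hz = 1000 / hop_ms / (40 / dt))
  structure(cfg, class = "pipeline_config")
}

#' Initialize the full pipeline model
#'
#' Creates CNN parameters, one membrane time constant per auditory nerve
#' fiber (uniform over 3--25 ms), the SNN layers with their masks, Dale
#' signs and neuron parameters, and the readout head. Under Dale's law the
#' nerve fibers are all excitatory, so the first SNN layer sees all-positive
#' input signs.
#'
#' @param cfg A [pipeline_config()].
#' @return A list of class `snn_model`.
#' @export
model_init <- function(cfg) {
  with_seed(cfg$seed, {
    cnn <- cnn_init(cfg$cnn_channels, cfg$cnn_kernel, cfg$n_mels,
                    seed = sample.int(.Machine$integer.max, 1))
    nerve <- list(tau_u = runif(cfg$n_fibers, 3, 25))
    layers <- list()
    n_in <- cfg$n_fibers
    in_signs <- NULL
    for (l in seq_along(cfg$snn_layers)) {
      spec <- cfg$snn_layers[[l]]
      if (spec$dale && l == 1) in_signs <- rep(1, cfg$n_fibers)
      layers[[l]] <- init_layer(spec, n_in, in_signs)
      n_in <- spec$n_neurons
      in_signs <- layers[[l]]$signs
    }
    n_last <- cfg$snn_layers[[length(cfg$snn_layers)]]$n_neurons
    Fh <- cfg$n_phoneme_features
    head <- list(
      W1 = matrix(rnorm(n_last * Fh, sd = 1 / sqrt(n_last)), n_last, Fh),
      b1 = numeric(Fh),
      W2 = matrix(rnorm(Fh * Fh, sd = 1 / sqrt(Fh)), Fh, Fh),
      b2 = numeric(Fh),
      W3 = matrix(rnorm(Fh * cfg$n_classes, sd = 1 / sqrt(Fh)), Fh,
                  cfg$n_classes),
      b3 = numeric(cfg$n_classes))
    structure(list(cfg = cfg, cnn = cnn, nerve = nerve, layers = layers,
                   head = head), class = "snn_model")
  })
}

#' Encode nerve stimuli into spike trains
#'
#' The auditory nerve fibers are LIF neurons (no adaptation, no recurrence)
#' with one trainable membrane time constant each; every CNN output signal
#' drives exactly one fiber.
#'
#' @param stimuli `B x T x n_fibers` array (or `T x n_fibers` matrix) of
#'   real-valued drive signals.
#' @param tau_u Per-fiber membrane time constants, ms (in \[3, 25\]).
#' @param dt Simulation step, ms.
#' @param duration_s Per-utterance true durations, seconds.
#' @return A [spike_raster()] with attribute `cache` (membrane traces).
#' @export
auditory_nerve <- function(stimuli, tau_u, dt, duration_s = NULL) {
  if (is.matrix(stimuli)) stimuli <- array(stimuli, c(1L, dim(stimuli)))
  B <- dim(stimuli)[1]; T_ <- dim(stimuli)[2]; N <- dim(stimuli)[3]
  stopifnot(length(tau_u) == N, all(tau_u >= 3 - 1e-9), all(tau_u <= 25 + 1e-9))
  alpha <- exp(-dt / tau_u)
  out <- adlif_forward_cpp(stimuli, matrix(0, 1, 1), alpha, alpha * 0 + 0.5,
                           numeric(N), numeric(N), B, T_, N, FALSE)
  ras <- spike_raster(out$s, dt = dt, layer_id = "nerve",
                      duration_s = duration_s)
  attr(ras, "cache") <- list(u = out$u, w = out$w)
  ras
}

# average-pool a (B, T, N) array over time by integer kernel K
pool_time <- function(x, K) {
  B <- dim(x)[1]; T_ <- dim(x)[2]; N <- dim(x)[3]
  Tp <- T_ %/% K
  if (Tp < 1) stop("sequence shorter than the pooling kernel")
  xt <- x[, seq_len(Tp * K), , drop = FALSE]
  dim(xt) <- c(B, K, Tp * N)
  pooled <- colMeans(aperm(xt, c(2, 1, 3)))
  dim(pooled) <- c(B, Tp, N)
  pooled
}

log_softmax_rows <- function(x) {
  m <- apply(x, 1, max)
  z <- x - m
  z - log(rowSums(exp(z)))
}

#' Readout head: spikes to per-frame log probabilities
#'
#' Average-pools the final spike raster down to 25 Hz (`40/dt`-step kernel),
#' applies two fully connected layers with Leaky-ReLU to the phoneme feature
#' width, then a final projection with log-softmax over the classes (blank
#' included).
#'
#' @param final_raster A [spike_raster()] from the last SNN layer.
#' @param head Head parameter list from [model_init()].
#' @param cfg A [pipeline_config()].
#' @param return_cache Keep intermediates for the backward pass.
#' @return `B x T_pooled x n_classes` array of log probabilities (attribute
#'   `cache` when requested).
#' @export
head_forward <- function(final_raster, head, cfg, return_cache = FALSE) {
  S <- if (inherits(final_raster, "spike_raster")) final_raster$values
       else final_raster
  K <- cfg$pool_kernel
  P <- pool_time(S, K)
  B <- dim(P)[1]; Tp <- dim(P)[2]; N <- dim(P)[3]
  Pm <- P; dim(Pm) <- c(B * Tp, N)
  A1 <- sweep(Pm %*% head$W1, 2, head$b1, "+")
  H1 <- leaky_relu(A1)
  A2 <- sweep(H1 %*% head$W2, 2, head$b2, "+")
  H2 <- leaky_relu(A2)
  logits <- sweep(H2 %*% head$W3, 2, head$b3, "+")
  lp <- log_softmax_rows(logits)
  out <- array(lp, c(B, Tp, cfg$n_classes))
  if (return_cache)
    attr(out, "cache") <- list(Pm = Pm, A1 = A1, H1 = H1, A2 = A2, H2 = H2,
                               B = B, Tp = Tp, N = N, K = K,
                               T_in = dim(S)[2])
  out
}

# full forward pass over a batch of feature matrices (list of T_b x n_mels)
model_forward <- function(model, feats, cfg, training = FALSE,
                          return_cache = FALSE) {
  B <- length(feats)
  T_b <- vapply(feats, nrow, integer(1))
  T_max <- max(T_b)
  dur <- T_b * cfg$dt / 1000
  stim <- array(0, c(B, T_max, cfg$n_fibers))
  cnn_caches <- vector("list", B)
  for (b in seq_len(B)) {
    cf <- cnn_forward(feats[[b]], model$cnn, cfg$dropout, training)
    stim[b, seq_len(T_b[b]), ] <- cf$out
    if (return_cache) cnn_caches[[b]] <- cf$cache
  }
  nerve_ras <- auditory_nerve(stim, model$nerve$tau_u, cfg$dt,
                              duration_s = dur)
  rasters <- list(nerve = nerve_ras)
  x <- nerve_ras
  layer_caches <- vector("list", length(model$layers))
  for (l in seq_along(model$layers)) {
    x <- layer_forward(x, model$layers[[l]], cfg$dt,
                       return_cache = return_cache)
    x$layer_id <- paste0("snn", l)
    rasters[[paste0("snn", l)]] <- x
    if (return_cache) layer_caches[[l]] <- attr(x, "cache")
  }
  lp <- head_forward(x, model$head, cfg, return_cache = return_cache)
  list(log_probs = lp, rasters = rasters, T_b = T_b,
       cnn_caches = cnn_caches, layer_caches = layer_caches,
       head_cache = attr(lp, "cache"), stim = stim)
}

# rates over true utterance lengths only (padded steps carry no spikes for
# the nerve but recurrent layers can ring into the padding)
masked_rates <- function(raster, T_b) {
  v <- raster$values
  B <- dim(v)[1]; N <- dim(v)[3]
  r <- matrix(0, B, N)
  for (b in seq_len(B))
    r[b, ] <- colSums(matrix(v[b, seq_len(T_b[b]), ], ncol = N)) /
      raster$duration_s[b]
  r
}

#' Combined training loss: CTC + firing-rate regularization
#'
#' Mean CTC negative log-likelihood over the batch plus
#' `reg$weight` times the firing-rate penalty over all spiking layers
#' (nerve fibers included by default).
#'
#' @param log_probs `B x T x n_classes` array of per-frame log probabilities
#'   (or `T x n_classes` matrix for a single utterance).
#' @param label_sequences List of integer label vectors (class indices > 1).
#' @param all_rasters List of [spike_raster()]s for every spiking layer.
#' @param cfg A [pipeline_config()].
#' @param T_pooled Optional per-utterance count of valid (unpadded) pooled
#'   frames.
#' @return List with `total`, `ctc` and `reg` components.
#' @export
training_loss <- function(log_probs, label_sequences, all_rasters, cfg,
                          T_pooled = NULL) {
  if (is.matrix(log_probs)) log_probs <- array(log_probs,
                                               c(1L, dim(log_probs)))
  B <- dim(log_probs)[1]
  if (is.null(T_pooled)) T_pooled <- rep(dim(log_probs)[2], B)
  nll <- numeric(B)
  for (b in seq_len(B)) {
    lp <- matrix(log_probs[b, seq_len(T_pooled[b]), ],
                 ncol = dim(log_probs)[3])
    nll[b] <- ctc_loss(lp, label_sequences[[b]])$nll
  }
  rates <- lapply(all_rasters, firing_rates)
  rc <- cfg$reg
  rc$f_max <- resolve_f_max(rc, cfg$dt)
  reg <- regularization_loss(rates, rc)
  list(total = mean(nll) + rc$weight * reg, ctc = mean(nll), reg = reg)
}

# backward pass; returns gradient tree aligned with get_params(model)
model_backward <- function(model, fwd, labels, cfg) {
  B <- length(labels)
  hc <- fwd$head_cache
  Tp <- hc$Tp
  K <- hc$K
  Tp_b <- pmin(Tp, fwd$T_b %/% K)
  n_layers <- length(model$layers)
  L_reg <- n_layers + as.integer(cfg$reg_include_nerve)
  rc <- cfg$reg
  rc$f_max <- resolve_f_max(rc, cfg$dt)

  # CTC gradient on logits, averaged over the batch
  g_logits <- array(0, c(B, Tp, cfg$n_classes))
  nll <- numeric(B)
  for (b in seq_len(B)) {
    lp <- matrix(fwd$log_probs[b, seq_len(Tp_b[b]), ], ncol = cfg$n_classes)
    cl <- ctc_loss(lp, labels[[b]], grad = TRUE)
    nll[b] <- cl$nll
    g_logits[b, seq_len(Tp_b[b]), ] <- cl$grad_logits / B
  }

  # head backward
  gl <- g_logits; dim(gl) <- c(B * Tp, cfg$n_classes)
  gW3 <- crossprod(hc$H2, gl); gb3 <- colSums(gl)
  gH2 <- gl %*% t(model$head$W3) * leaky_relu_grad(hc$A2)
  gW2 <- crossprod(hc$H1, gH2); gb2 <- colSums(gH2)
  gH1 <- gH2 %*% t(model$head$W2) * leaky_relu_grad(hc$A1)
  gW1 <- crossprod(hc$Pm, gH1); gb1 <- colSums(gH1)
  gP <- gH1 %*% t(model$head$W1)
  dim(gP) <- c(B, Tp, hc$N)

  # un-pool: each raster step in window j receives gP[, j, ] / K
  T_in <- hc$T_in
  gS <- array(0, c(B, T_in, hc$N))
  gPk <- gP[, rep(seq_len(Tp), each = K), , drop = FALSE] / K
  gS[, seq_len(Tp * K), ] <- gPk

  # firing-rate regularization gradient on each layer's spikes (rates over
  # true utterance lengths only)
  add_reg <- function(gs_ext, raster, T_b) {
    N_l <- dim(raster$values)[3]
    r <- masked_rates(raster, T_b)
    dh <- (-(r < rc$f_min) + (r > rc$f_max)) * rc$weight / (B * L_reg * N_l)
    dh <- sweep(dh, 1, raster$duration_s, "/")
    for (b in seq_len(B))
      gs_ext[b, seq_len(T_b[b]), ] <-
        sweep(gs_ext[b, seq_len(T_b[b]), , drop = FALSE], 3, dh[b, ], "+")
    gs_ext
  }

  grads <- list(cnn = NULL, nerve = NULL, layers = vector("list", n_layers),
                head = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                            W3 = gW3, b3 = gb3))

  gs_ext <- gS
  for (l in rev(seq_len(n_layers))) {
    layer <- model$layers[[l]]
    cache <- fwd$layer_caches[[l]]
    ras <- fwd$rasters[[paste0("snn", l)]]
    gs_ext <- add_reg(gs_ext, ras, fwd$T_b)
    dims <- dim(ras$values)
    bk <- adlif_backward_cpp(gs_ext, ras$values, cache$u, cache$w,
                             t(cache$ew$V), cache$coeffs$alpha,
                             cache$coeffs$beta, layer$params$a,
                             layer$params$b, dims[1], dims[2], dims[3],
                             cache$recurrent)
    prev_ras <- if (l == 1) fwd$rasters$nerve
                else fwd$rasters[[paste0("snn", l - 1)]]
    sp <- prev_ras$values; dim(sp) <- c(dims[1] * dims[2], dim(sp)[3])
    gff <- bk$g_ff; dim(gff) <- c(dims[1] * dims[2], dims[3])
    gW_eff <- t(crossprod(sp, gff))             # N x N_prev
    gV_eff <- t(bk$gVt)
    # chain through masks (and Dale's |.|*sign reparameterization)
    gW <- gW_eff * layer$mask_W
    gV <- gV_eff * layer$mask_V
    if (layer$spec$dale) {
      if (!is.null(layer$in_signs))
        gW <- sweep(gW, 2, layer$in_signs, "*") * sign(layer$W)
      gV <- sweep(gV, 2, layer$signs, "*") * sign(layer$V)
    }
    diag(gV) <- 0
    al <- cache$coeffs$alpha; be <- cache$coeffs$beta
    g_tau_u <- bk$g_alpha * al * cfg$dt / layer$params$tau_u^2
    g_tau_w <- bk$g_beta * be * cfg$dt / layer$params$tau_w^2
    sfa <- layer$params$sfa_enabled
    g_tau_w[!sfa] <- 0
    g_a <- bk$g_a; g_a[!sfa] <- 0
    g_b <- bk$g_b; g_b[!sfa] <- 0
    grads$layers[[l]] <- list(W = gW, V = gV, tau_u = g_tau_u,
                              tau_w = g_tau_w, a = g_a, b = g_b)
    gs_prev <- gff %*% cache$ew$W               # (B*T) x N_prev
    dim(gs_prev) <- c(dims[1], dims[2], ncol(cache$ew$W))
    gs_ext <- gs_prev
  }

  # nerve fibers (LIF, no recurrence): gradient reaches tau_u and the CNN
  nerve_ras <- fwd$rasters$nerve
  if (cfg$reg_include_nerve) gs_ext <- add_reg(gs_ext, nerve_ras, fwd$T_b)
  nc <- attr(nerve_ras, "cache")
  dims <- dim(nerve_ras$values)
  alpha_n <- exp(-cfg$dt / model$nerve$tau_u)
  bk <- adlif_backward_cpp(gs_ext, nerve_ras$values, nc$u, nc$w,
                           matrix(0, 1, 1), alpha_n, alpha_n * 0 + 0.5,
                           numeric(dims[3]), numeric(dims[3]),
                           dims[1], dims[2], dims[3], FALSE)
  grads$nerve <- list(tau_u = bk$g_alpha * alpha_n * cfg$dt /
                        model$nerve$tau_u^2)

  # CNN backward per utterance on the true-length slices
  gc_acc <- list(K = model$cnn$K * 0, bias = model$cnn$bias * 0,
                 gamma = model$cnn$gamma * 0, delta = model$cnn$delta * 0)
  for (b in seq_len(B)) {
    gsig <- matrix(bk$g_ff[b, seq_len(fwd$T_b[b]), ], ncol = dims[3])
    gb <- cnn_backward(gsig, fwd$cnn_caches[[b]], model$cnn)
    gc_acc <- tree_map2(`+`, gc_acc, gb)
  }
  grads$cnn <- gc_acc
  list(grads = grads, nll = mean(nll))
}

get_params <- function(model) {
  list(cnn = model$cnn[c("K", "bias", "gamma", "delta")],
       nerve = list(tau_u = model$nerve$tau_u),
       layers = lapply(model$layers, function(l)
         list(W = l$W, V = l$V, tau_u = l$params$tau_u,
              tau_w = l$params$tau_w, a = l$params$a, b = l$params$b)),
       head = model$head)
}

set_params <- function(model, p) {
  model$cnn[c("K", "bias", "gamma", "delta")] <- p$cnn
  model$nerve$tau_u <- pmin(pmax(p$nerve$tau_u, 3), 25)
  for (l in seq_along(model$layers)) {
    model$layers[[l]]$W <- p$layers[[l]]$W
    model$layers[[l]]$V <- p$layers[[l]]$V
    pl <- model$layers[[l]]$params
    pl$tau_u <- p$layers[[l]]$tau_u
    pl$tau_w <- p$layers[[l]]$tau_w
    pl$a <- p$layers[[l]]$a
    pl$b <- p$layers[[l]]$b
    model$layers[[l]]$params <- clamp_parameters(pl)
  }
  model$head <- p$head
  model
}

#' Train the pipeline on a labeled corpus
#'
#' Runs stochastic gradient training (Adam) of the complete architecture:
#' CTC loss on the decoded symbol sequences plus firing-rate regularization,
#' with the boxcar surrogate standing in for the threshold derivative during
#' backpropagation through time. After every step the neuron parameters are
#' projected back into their admissible ranges; connectivity masks, Dale
#' signs and the zero recurrent diagonal are structural and never change.
#'
#' @param dataset List of utterances, each `list(wave = numeric samples,
#'   labels = integer class indices > 1)`, or a corpus directory readable by
#'   [read_corpus()].
#' @param cfg A [pipeline_config()].
#' @param epochs Number of passes over the data.
#' @param batch_size Utterances per gradient step.
#' @param lr Adam learning rate.
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout; a fixed seed makes the whole run deterministic.
#' @param verbose Print per-epoch progress.
#' @param model Optional pre-initialized model (resume training).
#' @return List of class `snn_fit` with the trained `model`, the `log`
#'   data frame (epoch, loss, ctc, reg, ser, mean rates per layer) and `cfg`.
#' @export
train_pipeline <- function(dataset, cfg, epochs = 10, batch_size = 8,
                           lr = 5e-3, seed = 1L, verbose = interactive(),
                           model = NULL) {
  if (is.character(dataset)) dataset <- read_corpus(dataset)
  set.seed(seed)
  if (is.null(model)) model <- model_init(cfg)
  feats <- lapply(dataset, function(u)
    extract_features(u$wave, cfg$fs, cfg$n_mels, cfg$win_ms, cfg$hop_ms))
  labels <- lapply(dataset, function(u) as.integer(u$labels))
  n <- length(dataset)
  params <- get_params(model)
  state <- adam_init(params)
  log_rows <- list()
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_ctc <- 0; ep_reg <- 0; nb <- 0
    err_n <- 0; err_d <- 0
    rate_acc <- NULL
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      fwd <- model_forward(model, feats[idx], cfg, training = TRUE,
                           return_cache = TRUE)
      bwd <- model_backward(model, fwd, labels[idx], cfg)
      rates <- lapply(fwd$rasters, masked_rates, T_b = fwd$T_b)
      rc <- cfg$reg; rc$f_max <- resolve_f_max(rc, cfg$dt)
      reg_rasters <- if (cfg$reg_include_nerve) rates else rates[-1]
      reg <- regularization_loss(reg_rasters, rc)
      loss <- bwd$nll + rc$weight * reg
      if (!is.finite(loss)) stop("divergent loss (non-finite); aborting")
      ep_loss <- ep_loss + loss; ep_ctc <- ep_ctc + bwd$nll
      ep_reg <- ep_reg + reg; nb <- nb + 1
      mr <- vapply(rates, mean, numeric(1))
      rate_acc <- if (is.null(rate_acc)) mr else rate_acc + mr
      # greedy decode of this batch for a running symbol error rate
      K <- cfg$pool_kernel
      for (j in seq_along(idx)) {
        Tpj <- min(dim(fwd$log_probs)[2], fwd$T_b[j] %/% K)
        lp <- matrix(fwd$log_probs[j, seq_len(Tpj), ], ncol = cfg$n_classes)
        hyp <- greedy_ctc_decode(lp)
        ref <- labels[[idx[j]]]
        err_n <- err_n + phoneme_error_rate(ref, hyp) * length(ref) / 100
        err_d <- err_d + length(ref)
      }
      st <- adam_step(params, bwd$grads, state, lr = lr)
      params <- st$params; state <- st$state
      model <- set_params(model, params)
      params <- get_params(model)  # pick up clamped neuron parameters
    }
    row <- data.frame(epoch = ep, loss = ep_loss / nb, ctc = ep_ctc / nb,
                      reg = ep_reg / nb, ser = 100 * err_n / err_d)
    mr <- rate_acc / nb
    for (k in seq_along(mr)) row[[paste0("rate_", names(mr)[k])]] <- mr[k]
    log_rows[[ep]] <- row
    if (verbose)
      message(sprintf("epoch %d: loss %.3f (ctc %.3f, reg %.3f), SER %.1f%%",
                      ep, row$loss, row$ctc, row$reg, row$ser))
  }
  structure(list(model = model, log = do.call(rbind, log_rows), cfg = cfg),
            class = "snn_fit")
}

#' Evaluate a trained model on a labeled corpus
#'
#' Greedy-decodes every utterance and scores the symbol error rate
#' (edit distance over reference length, in percent).
#'
#' @param fit An `snn_fit` (or a bare model list with `cfg` supplied).
#' @param dataset As in [train_pipeline()].
#' @param cfg Optional [pipeline_config()] override.
#' @return List with `ser` (percent), `decoded` and `references`.
#' @export
evaluate_pipeline <- function(fit, dataset, cfg = NULL) {
  model <- if (inherits(fit, "snn_fit")) fit$model else fit
  if (is.null(cfg)) cfg <- if (inherits(fit, "snn_fit")) fit$cfg else model$cfg
  if (is.character(dataset)) dataset <- read_corpus(dataset)
  err_n <- 0; err_d <- 0
  decoded <- vector("list", length(dataset))
  for (i in seq_along(dataset)) {
    u <- dataset[[i]]
    feats <- extract_features(u$wave, cfg$fs, cfg$n_mels, cfg$win_ms,
                              cfg$hop_ms)
    fwd <- model_forward(model, list(feats), cfg, training = FALSE)
    lp <- matrix(fwd$log_probs[1, , ], ncol = cfg$n_classes)
    hyp <- greedy_ctc_decode(lp)
    ref <- as.integer(u$labels)
    decoded[[i]] <- hyp
    err_n <- err_n + phoneme_error_rate(ref, hyp) * length(ref) / 100
    err_d <- err_d + length(ref)
  }
  list(ser = 100 * err_n / err_d, decoded = decoded,
       references = lapply(dataset, function(u) as.integer(u$labels)))
}

#' Run a waveform through the pipeline and collect spike rasters
#'
#' @param fit An `snn_fit` or model.
#' @param wave Numeric vector of mono samples at `cfg$fs`.
#' @param cfg Optional [pipeline_config()] override.
#' @param dump_dir If non-`NULL`, every layer's raster is written there as a
#'   sparse event list (see [write_raster_events()]).
#' @return Named list of [spike_raster()]s (`nerve`, `snn1`, ...), with the
#'   per-frame log probabilities as attribute `log_probs`.
#' @export
simulate_pipeline <- function(fit, wave, cfg = NULL, dump_dir = NULL) {
  model <- if (inherits(fit, "snn_fit")) fit$model else fit
  if (is.null(cfg)) cfg <- if (inherits(fit, "snn_fit")) fit$cfg else model$cfg
  feats <- extract_features(wave, cfg$fs, cfg$n_mels, cfg$win_ms, cfg$hop_ms)
  fwd <- model_forward(model, list(feats), cfg, training = FALSE)
  rasters <- fwd$rasters
  for (nm in names(rasters)) rasters[[nm]]$layer_id <- nm
  if (!is.null(dump_dir)) {
    dir.create(dump_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(rasters))
      write_raster_events(rasters[[nm]], file.path(dump_dir,
                                                   paste0(nm, ".events")))
  }
  attr(rasters, "log_probs") <- fwd$log_probs
  rasters
}

#' Desk-scale configuration for the synthetic tone task
#'
#' A compact preset of the full architecture sized for CPU training on the
#' 4-symbol tone corpus: 5 ms step (100 Hz Nyquist), 40 Mel bins, 8 CNN
#' channels (272 nerve fibers), two recurrent SNN layers of 128 neurons with
#' 50% adaptation and 50% recurrent connectivity, and a 128-wide readout.
#' All structural conventions (pooling to 25 Hz, blank-augmented classes,
#' firing-rate regularization) match the full-scale default.
#'
#' @param n_symbols Alphabet size of the tone task.
#' @param dale Enforce Dale's law in the SNN layers.
#' @param reg_weight Multiplier of the firing-rate penalty (0 disables).
#' @param seed Integer seed for initialization.
#' @return A [pipeline_config()].
#' @export
tone_task_config <- function(n_symbols = 4, dale = FALSE, reg_weight = 1,
                             seed = 1L) {
  pipeline_config(
    n_classes = n_symbols + 1, n_mels = 40, hop_ms = 5, cnn_channels = 8,
    snn_layers = list(
      layer_spec(128, rec_connectivity = 0.5, sfa_fraction = 0.5,
                 dale = dale, mask_seed = 101),
      layer_spec(128, rec_connectivity = 0.5, sfa_fraction = 0.5,
                 dale = dale, mask_seed = 102)),
    n_phoneme_features = 128, dropout = 0.15,
    reg = reg_config(weight = reg_weight), seed = seed)
}
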