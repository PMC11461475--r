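# Auditory CNN: a single 2-D convolution over (time, Mel) with "same" time
# padding and no feature padding, followed by layer normalization (per time
# frame, trainable gain/offset), channel dropout and a Leaky-ReLU activation.
# With 16 channels and a (7, 7) kernel on 80 Mel bins this yields
# 16 * (80 - 7 + 1) = 1184 output signals at an unchanged frame rate, each
# summarizing the energy evolution across seven adjacent Mel bins.

leaky_relu <- function(x, slope = 0.01) ifelse(x > 0, x, slope * x)
leaky_relu_grad <- function(x, slope = 0.01) ifelse(x > 0, 1, slope)

#' Initialize auditory CNN parameters
#'
#' @param cnn_channels Number of convolution channels.
#' @param cnn_kernel Kernel size `(time, feature)`.
#' @param n_mels Number of Mel bins in the input features.
#' @param seed Integer seed for weight initialization.
#' @return List with kernel weights `K` (`kt x kf x channels`), `bias`, and
#'   layer-norm gain `gamma` / offset `delta` (per output signal).
#' @export
cnn_init <- function(cnn_channels = 16, cnn_kernel = c(7, 7), n_mels = 80,
                     seed = 1L) {
  kt <- cnn_kernel[1]; kf <- cnn_kernel[2]
  f_out <- n_mels - kf + 1
  with_seed(seed, {
    K <- array(rnorm(kt * kf * cnn_channels, sd = 1 / sqrt(kt * kf)),
               dim = c(kt, kf, cnn_channels))
    list(K = K, bias = numeric(cnn_channels),
         gamma = rep(1, f_out * cnn_channels),
         delta = numeric(f_out * cnn_channels),
         kt = kt, kf = kf, n_mels = n_mels, channels = cnn_channels,
         f_out = f_out)
  })
}

# im2col patch matrix for one utterance: (T * f_out) x (kt * kf)
cnn_im2col <- function(x, kt, kf, f_out) {
  T_ <- nrow(x)
  pt <- (kt - 1) %/% 2  # "same" time padding keeps the frame count unchanged
  xp <- rbind(matrix(0, pt, ncol(x)), x, matrix(0, kt - 1 - pt, ncol(x)))
  P <- matrix(0, T_ * f_out, kt * kf)
  col <- 1L
  for (j in seq_len(kf)) {
    for (i in seq_len(kt)) {
      P[, col] <- as.vector(xp[i:(i + T_ - 1), j:(j + f_out - 1)])
      col <- col + 1L
    }
  }
  P
}

#' Auditory CNN forward pass (one utterance)
#'
#' @param features `T x n_mels` log-Mel matrix from [extract_features()].
#' @param p Parameters from [cnn_init()].
#' @param dropout Channel-dropout probability (active when `training`).
#' @param training Logical; enables dropout.
#' @return List with `out` (`T x (f_out * channels)` nerve stimuli, channel
#'   fastest-varying last) and a `cache` for the backward pass.
#' @export
cnn_forward <- function(features, p, dropout = 0.15, training = FALSE) {
  if (ncol(features) != p$n_mels)
    stop(sprintf("expected %d Mel bins, got %d", p$n_mels, ncol(features)))
  T_ <- nrow(features)
  P <- cnn_im2col(features, p$kt, p$kf, p$f_out)
  Kmat <- matrix(p$K, p$kt * p$kf, p$channels)
  conv <- P %*% Kmat                      # (T * f_out) x channels
  conv <- sweep(conv, 2, p$bias, "+")
  z <- matrix(conv, T_, p$f_out * p$channels)  # (t, f) x c flattened
  # layer normalization per time frame across all signals
  mu <- rowMeans(z)
  zc <- z - mu
  v <- rowMeans(zc^2)
  inv_sd <- 1 / sqrt(v + 1e-5)
  zhat <- zc * inv_sd
  y <- sweep(sweep(zhat, 2, p$gamma, "*"), 2, p$delta, "+")
  # channel dropout
  keep <- rep(1, p$channels)
  if (training && dropout > 0) {
    keep <- stats::rbinom(p$channels, 1, 1 - dropout) / (1 - dropout)
  }
  keep_full <- rep(keep, each = p$f_out)
  yd <- sweep(y, 2, keep_full, "*")
  out <- leaky_relu(yd)
  list(out = out,
       cache = list(P = P, zhat = zhat, inv_sd = inv_sd, keep = keep_full,
                    pre_act = yd, T_ = T_))
}

#' Auditory CNN backward pass (one utterance)
#'
#' @param g_out Gradient on the CNN output, `T x (f_out * channels)`.
#' @param cache Cache from [cnn_forward()].
#' @param p Parameters from [cnn_init()].
#' @return List of gradients `K`, `bias`, `gamma`, `delta`.
#' @export
cnn_backward <- function(g_out, cache, p) {
  g <- g_out * leaky_relu_grad(cache$pre_act)
  g <- sweep(g, 2, cache$keep, "*")
  g_gamma <- colSums(g * cache$zhat)
  g_delta <- colSums(g)
  gzh <- sweep(g, 2, p$gamma, "*")
  # layer-norm backward (per row, D features)
  D <- ncol(gzh)
  gz <- cache$inv_sd *
    (gzh - rowMeans(gzh) - cache$zhat * rowMeans(gzh * cache$zhat))
  gconv <- matrix(gz, cache$T_ * p$f_out, p$channels)
  gK <- crossprod(cache$P, gconv)
  g_bias <- colSums(gconv)
  list(K = array(gK, dim = dim(p$K)), bias = g_bias, gamma = g_gamma,
       delta = g_delta)
}

#' Auditory CNN as a user-facing operation
#'
#' Applies the convolution frontend to a log-Mel feature matrix, producing
#' one real-valued stimulus signal per auditory nerve fiber
#' (`channels * (n_mels - 7 + 1)` signals, frame count unchanged).
#'
#' @param features `T x n_mels` matrix from [extract_features()].
#' @param p Parameters from [cnn_init()]; created on the fly if `NULL`.
#' @param dropout,training Passed to [cnn_forward()].
#' @return `T x n_fibers` matrix of nerve stimuli.
#' @export
auditory_cnn <- function(features, p = NULL, dropout = 0.15,
                         training = FALSE) {
  if (is.null(p)) p <- cnn_init(n_mels = ncol(features))
  cnn_forward(features, p, dropout, training)$out
}
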