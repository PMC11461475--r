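# Connectionist temporal classification: forward-backward loss on log
# probabilities, its gradient with respect to the pre-softmax logits, greedy
# decoding, and the edit-distance error rate.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' CTC negative log-likelihood and gradient
#'
#' Sums over all alignments of the label sequence to the frame sequence via
#' the blank token (class index 1), using the standard forward-backward
#' recursion in log space.
#'
#' @param log_probs `T x n_classes` matrix of per-frame log probabilities
#'   (rows log-sum-exp to 0); class 1 is the blank.
#' @param labels Integer vector of label class indices (> 1, no blanks).
#' @param grad Logical; also return the gradient with respect to the
#'   pre-softmax logits.
#' @return List with `nll` and (if requested) `grad_logits` (`T x n_classes`).
#' @export
ctc_loss <- function(log_probs, labels, grad = FALSE) {
  T_ <- nrow(log_probs)
  U <- length(labels)
  if (any(labels <= 1)) stop("labels must not contain the blank (class 1)")
  n_rep <- if (U > 1) sum(labels[-1] == labels[-U]) else 0
  if (T_ < U + n_rep)
    stop(sprintf("label sequence infeasible: %d labels (+%d repeats) for %d frames",
                 U, n_rep, T_))
  ext <- integer(2 * U + 1)
  ext[seq(1, 2 * U + 1, by = 2)] <- 1L
  if (U > 0) ext[seq(2, 2 * U, by = 2)] <- labels
  S <- length(ext)

  la <- matrix(-Inf, T_, S)
  la[1, 1] <- log_probs[1, 1]
  if (S > 1) la[1, 2] <- log_probs[1, ext[2]]
  for (t in 2:max(T_, 2)) {
    if (t > T_) break
    for (s in seq_len(S)) {
      acc <- la[t - 1, s]
      if (s > 1) acc <- max2_lse(acc, la[t - 1, s - 1])
      if (s > 2 && ext[s] != 1L && ext[s] != ext[s - 2])
        acc <- max2_lse(acc, la[t - 1, s - 2])
      la[t, s] <- acc + log_probs[t, ext[s]]
    }
  }
  logP <- if (S > 1) max2_lse(la[T_, S], la[T_, S - 1]) else la[T_, S]
  out <- list(nll = -logP)
  if (!grad) return(out)

  lb <- matrix(-Inf, T_, S)
  lb[T_, S] <- log_probs[T_, ext[S]]
  if (S > 1) lb[T_, S - 1] <- log_probs[T_, ext[S - 1]]
  if (T_ > 1) for (t in (T_ - 1):1) {
    for (s in seq_len(S)) {
      acc <- lb[t + 1, s]
      if (s < S) acc <- max2_lse(acc, lb[t + 1, s + 1])
      if (s < S - 1 && ext[s] != 1L && ext[s] != ext[s + 2])
        acc <- max2_lse(acc, lb[t + 1, s + 2])
      lb[t, s] <- acc + log_probs[t, ext[s]]
    }
  }
  # occupancy gamma_{t,k}: posterior probability of emitting class k at t
  gam <- matrix(0, T_, ncol(log_probs))
  for (s in seq_len(S)) {
    contrib <- exp(la[, s] + lb[, s] - log_probs[, ext[s]] - logP)
    gam[, ext[s]] <- gam[, ext[s]] + contrib
  }
  out$grad_logits <- exp(log_probs) - gam
  out
}

max2_lse <- function(x, y) {
  m <- pmax(x, y)
  ifelse(is.finite(m), m + log(exp(x - m) + exp(y - m)), m)
}

#' Greedy CTC decoding
#'
#' Takes the per-frame argmax, collapses consecutive repeats, and removes
#' blanks (class 1). A blank between two identical labels separates them.
#'
#' @param log_probs `T x n_classes` matrix of log probabilities.
#' @return Integer vector of decoded class indices (> 1), possibly empty.
#' @export
greedy_ctc_decode <- function(log_probs) {
  path <- max.col(log_probs, ties.method = "first")
  collapsed <- rle(path)$values
  collapsed[collapsed != 1L]
}

#' Token error rate (phoneme error rate)
#'
#' Levenshtein distance (substitutions + insertions + deletions) between the
#' hypothesis and the reference, divided by the reference length, in percent.
#' Can exceed 100% when the hypothesis is much longer than the reference.
#'
#' @param reference Reference token sequence (character or integer vector).
#' @param hypothesis Hypothesis token sequence.
#' @return Error rate in percent.
#' @export
phoneme_error_rate <- function(reference, hypothesis) {
  if (length(reference) == 0) stop("empty reference")
  nr <- length(reference); nh <- length(hypothesis)
  d <- matrix(0L, nr + 1, nh + 1)
  d[, 1] <- 0:nr
  d[1, ] <- 0:nh
  for (i in seq_len(nr)) {
    for (j in seq_len(nh)) {
      cost <- if (reference[i] == hypothesis[j]) 0L else 1L
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + cost)
    }
  }
  100 * d[nr + 1, nh + 1] / nr
}
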