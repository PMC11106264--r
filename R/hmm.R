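# Hidden-Markov-model smoothing primitives (log-space Viterbi).

#' Viterbi decoding
#'
#' Most-likely state path of a hidden Markov model, computed in log space.
#'
#' @param log_init length-K log initial state probabilities.
#' @param log_trans K x K log transition matrix (rows = from-state).
#' @param log_emit T x K matrix of per-step log emission likelihoods.
#' @return integer vector of length T with the decoded state indices
#'   (1-based). Ties break toward the lower state index.
#' @export
viterbi <- function(log_init, log_trans, log_emit) {
  log_emit <- as.matrix(log_emit)
  K <- length(log_init)
  Tn <- nrow(log_emit)
  if (ncol(log_emit) != K || nrow(log_trans) != K || ncol(log_trans) != K) {
    stop("dimension mismatch between init, transition and emission inputs")
  }
  if (Tn == 0L) return(integer(0))
  delta <- matrix(-Inf, Tn, K)
  psi <- matrix(1L, Tn, K)
  delta[1, ] <- log_init + log_emit[1, ]
  if (Tn > 1L) {
    for (t in 2:Tn) {
      cand <- delta[t - 1, ] + log_trans # K x K: from x to
      psi[t, ] <- apply(cand, 2, which.max)
      delta[t, ] <- cand[cbind(psi[t, ], seq_len(K))] + log_emit[t, ]
    }
  }
  path <- integer(Tn)
  path[Tn] <- which.max(delta[Tn, ])
  if (Tn > 1L) {
    for (t in (Tn - 1L):1L) path[t] <- psi[t + 1L, path[t + 1L]]
  }
  path
}
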