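#' Brute-force CRF computations by exhaustive enumeration
#'
#' Enumerates all `L^T` tag sequences of a sentence and computes the log
#' partition function, per-position marginals, and the argmax sequence by
#' direct summation over [score_sequence]. Exponential in sentence length --
#' intended as the independent oracle against which the dynamic-programming
#' routines ([log_partition], [crf_marginals], [crf_viterbi]) are validated
#' on short sentences.
#'
#' @inheritParams score_sequence
#' @return List with elements `log_partition`, `marginals` (`T x L` matrix),
#'   `best_tags`, `best_score`.
#' @export
crf_enumerate <- function(model, feats) {
  L <- length(model$labels)
  T_ <- length(feats)
  stopifnot(T_ >= 1L)
  grid <- as.matrix(expand.grid(rep(list(seq_len(L)), T_)))
  E <- sentence_emissions(model, feats)
  tr <- eff_trans(model); b <- eff_bos(model)
  scores <- b[grid[, 1L]] + model$eos[grid[, T_]]
  for (t in seq_len(T_)) {
    scores <- scores + E[cbind(rep(t, nrow(grid)), grid[, t])]
    if (t > 1L) scores <- scores + tr[cbind(grid[, t - 1L], grid[, t])]
  }
  lse <- function(x) {
    m <- max(x)
    if (!is.finite(m)) return(m)
    m + log(sum(exp(x - m)))
  }
  logZ <- lse(scores)
  marg <- matrix(0, T_, L, dimnames = list(NULL, model$labels))
  for (t in seq_len(T_)) {
    for (l in seq_len(L)) {
      sel <- scores[grid[, t] == l]
      marg[t, l] <- if (length(sel) > 0L) exp(lse(sel) - logZ) else 0
    }
  }
  best <- which.max(scores)
  list(log_partition = logZ,
       marginals = marg,
       best_tags = model$labels[grid[best, ]],
       best_score = scores[best])
}
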