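# Markov background models over structural letters: fitting, sampling,
# and analytic expected word counts.

#' Fit a Markov background on letter sequences
#'
#' Maximum-likelihood estimation (optionally with an additive
#' pseudocount) of a homogeneous Markov model of order 0 or 1.  The
#' initial distribution is the empirical distribution of first letters.
#' Contexts never observed receive the uniform conditional distribution.
#'
#' @param sequences character vector of letter strings (non-empty).
#' @param order Markov order, 0 or 1 (default 1).
#' @param pseudocount additive smoothing count (default 0).
#' @param letters alphabet; defaults to the sorted set of letters seen in
#'   `sequences`.  Supply explicitly to include letters that may not occur.
#' @return a [MarkovBackground-class].
#' @examples
#' bg <- fitBackground(c("ABAB", "ABBA"), order = 1)
#' transitionMatrix(bg)
#' @export
fitBackground <- function(sequences, order = 1L, pseudocount = 0,
                          letters = NULL) {
  stopifnot(length(sequences) >= 1L, order >= 0L, pseudocount >= 0)
  if (order > 1L)
    stop("only background orders 0 and 1 are supported")
  chars <- strsplit(sequences, "")
  if (is.null(letters)) letters <- sort(unique(unlist(chars)))
  K <- length(letters)
  idx <- lapply(chars, function(x) match(x, letters))
  if (anyNA(unlist(idx)))
    stop("sequences contain letters outside the supplied alphabet")

  firsts <- vapply(idx, `[`, 1L, 1L)
  initial <- tabulate(firsts, K) + pseudocount
  if (sum(initial) == 0) initial <- rep(1, K)
  initial <- initial / sum(initial)

  if (order == 0L) {
    cnt <- tabulate(unlist(idx), K) + pseudocount
    if (sum(cnt) == 0) cnt <- rep(1, K)
    trans <- matrix(cnt / sum(cnt), 1L, K)
  } else {
    cnt <- matrix(pseudocount, K, K)
    for (s in idx) {
      if (length(s) < 2L) next
      from <- s[-length(s)]
      to <- s[-1L]
      for (i in seq_along(from)) cnt[from[i], to[i]] <- cnt[from[i], to[i]] + 1
    }
    rs <- rowSums(cnt)
    trans <- cnt / ifelse(rs > 0, rs, 1)
    trans[rs == 0, ] <- 1 / K       # unseen context -> uniform
  }
  MarkovBackground(letters, trans, initial = initial, order = order)
}

#' Sample letter sequences from a Markov background
#'
#' First letters are drawn from the background's initial distribution,
#' subsequent letters from the conditional distributions.  Vectorised
#' across sequences.
#'
#' @param bg a [MarkovBackground-class].
#' @param lengths integer vector of sequence lengths (>= 1).
#' @param seed optional integer; when supplied the caller's RNG stream is
#'   left untouched.
#' @return character vector of sampled sequences.
#' @export
sampleFromBackground <- function(bg, lengths, seed = NULL) {
  run <- function() {
    n <- length(lengths)
    maxLen <- max(lengths)
    K <- length(bg@letters)
    M <- matrix(0L, n, maxLen)
    cumInit <- cumsum(bg@initial)
    M[, 1L] <- findInterval(runif(n), cumInit, left.open = TRUE) + 1L
    if (maxLen > 1L) {
      TC <- t(apply(bg@transition, 1L, cumsum))   # rows cumulative
      if (bg@order == 0L) TC <- TC[rep(1L, K), , drop = FALSE]
      for (t in 2:maxLen) {
        act <- lengths >= t
        if (!any(act)) next
        u <- runif(sum(act))
        prev <- M[act, t - 1L]
        M[act, t] <- rowSums(u > TC[prev, , drop = FALSE]) + 1L
      }
    }
    vapply(seq_len(n), function(i)
      paste(bg@letters[M[i, seq_len(lengths[i])]], collapse = ""), "")
  }
  if (is.null(seed)) run() else .withSeed(seed, run())
}

#' Expected occurrence count of a word under the background
#'
#' Computes `E[N]` exactly by linearity: the sum over all sequence
#' positions of the probability that the word starts there, with the
#' marginal letter distribution at each position propagated from the
#' initial distribution.
#'
#' @param seq_lengths integer vector of sequence lengths.
#' @param word the pattern.
#' @param bg a [MarkovBackground-class].
#' @return the expected total count over the sequence set.
#' @export
expectedCount <- function(seq_lengths, word, bg) {
  w <- match(strsplit(word, "")[[1]], bg@letters)
  if (anyNA(w)) stop("word contains letters outside the background alphabet")
  L <- length(w)
  maxLen <- max(seq_lengths, 0L)
  if (maxLen < L) return(0)
  K <- length(bg@letters)
  trans <- if (bg@order == 0L)
    matrix(bg@transition[1L, ], K, K, byrow = TRUE) else bg@transition
  # inner factor: P(w2..wL | w1)
  innerP <- 1
  if (L > 1L) for (j in 2:L) innerP <- innerP * trans[w[j - 1L], w[j]]
  # marginal distribution of the letter at each start position
  marg <- bg@initial
  pStart <- numeric(maxLen - L + 1L)
  for (t in seq_len(maxLen - L + 1L)) {
    pStart[t] <- marg[w[1L]] * innerP
    marg <- as.numeric(marg %*% trans)
  }
  cum <- cumsum(pStart)
  ns <- seq_lengths - L + 1L
  sum(cum[ns[ns >= 1L]])
}
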