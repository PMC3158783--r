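# Exact distribution of the total occurrence count of a word in a set of
# sequences under a Markov background, via the Markov-chain embedding of
# the word's counting DFA.  The generating-function formulation is
# replaced by an equivalent dynamic program over (DFA state, previous
# letter, saturated count), which yields the identical exact distribution.

# Capped convolution of two count distributions (vectors over counts
# 0..cap, last cell aggregating >= cap mass).
.convolveCapped <- function(a, b) {
  C <- length(a)
  if (sum(b > 0) > sum(a > 0)) { tmp <- a; a <- b; b <- tmp }
  res <- numeric(C)
  for (j in which(b > 0)) {
    jc <- j - 1L
    if (jc == 0L) {
      res <- res + a * b[j]
    } else if (jc >= C - 1L) {
      res[C] <- res[C] + sum(a) * b[j]
    } else {
      res[(jc + 1L):C] <- res[(jc + 1L):C] + a[seq_len(C - jc)] * b[j]
      res[C] <- res[C] + sum(a[(C - jc + 1L):C]) * b[j]
    }
  }
  res
}

# One DP sweep to maxLen; returns a (maxLen x cap+1) matrix whose row t is
# the count distribution for a single sequence of length t.
.dpCountByLength <- function(dfa, bg, cap, maxLen) {
  K <- length(bg@letters)
  if (!identical(dfa@letters, bg@letters))
    stop("DFA and background alphabets differ")
  Q <- nrow(dfa@delta)
  C <- cap + 1L
  trans <- if (bg@order == 0L)
    matrix(bg@transition[1L, ], K, K, byrow = TRUE) else bg@transition
  snapshots <- matrix(0, maxLen, C)

  # M[q, a, c]: DFA state q, previous letter a, saturated count c-1
  M <- array(0, c(Q, K, C))
  for (a in seq_len(K)) {
    q2 <- dfa@delta[1L, a]
    c2 <- if (dfa@counting[1L, a]) min(1L, cap) else 0L
    M[q2, a, c2 + 1L] <- M[q2, a, c2 + 1L] + bg@initial[a]
  }
  snapshots[1L, ] <- apply(M, 3L, sum)

  if (maxLen > 1L) for (t in 2:maxLen) {
    Mn <- array(0, c(Q, K, C))
    for (b in seq_len(K)) {
      # A[q, c] = sum_a M[q, a, c] * P(b | a)
      A <- matrix(0, Q, C)
      for (a in seq_len(K)) {
        if (trans[a, b] == 0) next
        A <- A + M[, a, ] * trans[a, b]
      }
      for (q in seq_len(Q)) {
        q2 <- dfa@delta[q, b]
        if (dfa@counting[q, b]) {
          # shift counts by one, saturating at cap
          Mn[q2, b, 2:C] <- Mn[q2, b, 2:C] + A[q, seq_len(C - 1L)]
          Mn[q2, b, C] <- Mn[q2, b, C] + A[q, C]
        } else {
          Mn[q2, b, ] <- Mn[q2, b, ] + A[q, ]
        }
      }
    }
    M <- Mn
    snapshots[t, ] <- apply(M, 3L, sum)
  }
  snapshots
}

#' Exact count distribution of a word over a sequence set
#'
#' Computes the exact distribution (up to floating point) of the total
#' number of overlapping occurrences of a word in a set of independent
#' sequences drawn from a Markov background of order 0 or 1.  Counts are
#' saturated at `cap`: the returned vector gives `P(N = k)` for
#' `k = 0 .. cap - 1` and the aggregated tail `P(N >= cap)` in the last
#' cell, which is all that is needed for the inclusive tail p-value at
#' any observed count `<= cap`.  Per-sequence distributions are obtained
#' by a dynamic program over (DFA state, previous letter, saturated
#' count) and convolved across sequences.
#'
#' @param seq_lengths integer vector of sequence lengths.
#' @param dfa the word's [WordDFA-class] (see [buildWordDFA()]); its
#'   alphabet must equal the background's.
#' @param bg a [MarkovBackground-class] (order 0 or 1).
#' @param cap saturation count (>= 1); use the observed count when the
#'   goal is its tail p-value.
#' @return an object of class `"CountDistribution"`: a numeric vector of
#'   length `cap + 1` named `"0" ... ">=cap"`, summing to 1.
#' @examples
#' bg <- MarkovBackground(c("A", "B"), matrix(0.5, 1, 2))
#' dfa <- buildWordDFA("AA", c("A", "B"))
#' countDistribution(3, dfa, bg, cap = 2)  # 5/8, 2/8, 1/8
#' @export
countDistribution <- function(seq_lengths, dfa, bg, cap) {
  stopifnot(cap >= 1L, length(seq_lengths) >= 1L, all(seq_lengths >= 1L))
  cap <- as.integer(cap)
  maxLen <- max(seq_lengths)
  snap <- .dpCountByLength(dfa, bg, cap, maxLen)
  lens <- table(seq_lengths)
  total <- c(1, numeric(cap))
  for (i in seq_along(lens)) {
    d <- snap[as.integer(names(lens))[i], ]
    m <- as.integer(lens[[i]])
    # repeated capped self-convolution by binary exponentiation
    pw <- d
    while (m > 0L) {
      if (m %% 2L == 1L) total <- .convolveCapped(total, pw)
      m <- m %/% 2L
      if (m > 0L) pw <- .convolveCapped(pw, pw)
    }
  }
  names(total) <- c(as.character(seq_len(cap) - 1L), paste0(">=", cap))
  structure(total, class = "CountDistribution", cap = cap)
}

#' @export
print.CountDistribution <- function(x, ...) {
  cat(sprintf("CountDistribution (cap %d):\n", attr(x, "cap")))
  print(unclass(x)[seq_len(min(length(x), 10L))], ...)
  invisible(x)
}

#' Inclusive tail p-value of an observed count
#'
#' Returns `P(N >= N_obs)` under the background model from a
#' [countDistribution()] object; `N_obs = 0` gives 1 by definition.
#'
#' @param dist a `"CountDistribution"`.
#' @param N_obs observed occurrence count (0 <= N_obs <= cap).
#' @return the exact tail probability in (0, 1].
#' @export
pvalueGE <- function(dist, N_obs) {
  stopifnot(N_obs >= 0L)
  cap <- attr(dist, "cap")
  if (N_obs == 0L) return(1)
  if (N_obs > cap)
    stop("N_obs exceeds the distribution cap; recompute with cap >= N_obs")
  sum(dist[(N_obs + 1L):(cap + 1L)])
}

#' Over-representation score
#'
#' `Lp = -log10(p)`: a score of 3 means the word is over-represented
#' with a p-value of 1e-3.
#'
#' @param p p-value in (0, 1].
#' @return the Lp score (>= 0).
#' @examples
#' lpScore(1e-3)  # 3
#' @export
lpScore <- function(p) {
  if (any(p <= 0)) stop("p must be in (0, 1]")
  -log10(p)
}
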