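# Word-counting automata: KMP failure-link DFA construction and
# occurrence counting (overlapping occurrences are always counted).

#' Build the counting DFA of a word
#'
#' Constructs the deterministic finite automaton whose states are the
#' prefixes of `word` (|word| + 1 states).  Transitions follow the
#' Knuth-Morris-Pratt failure structure, so after a match the automaton
#' resumes from the longest proper suffix of the word that is also a
#' prefix — overlapping occurrences are therefore counted.  Transitions
#' entering the match state are flagged as counting transitions.
#'
#' @param word non-empty pattern over `letters`.
#' @param letters the alphabet (character vector of single letters).
#' @return a [WordDFA-class].
#' @examples
#' dfa <- buildWordDFA("AAAA", c("A", "B"))
#' dfa@delta     # from the match state, 'A' re-enters the match state
#' @export
buildWordDFA <- function(word, letters) {
  stopifnot(nchar(word) >= 1L)
  w <- match(strsplit(word, "")[[1]], letters)
  if (anyNA(w)) stop("word contains letters outside the alphabet")
  L <- length(w)
  K <- length(letters)
  # delta in 0-based matched-length states 0..L; classic O(L K)
  # construction carrying the border (failure) state along
  delta0 <- matrix(0L, L + 1L, K)
  delta0[1L, w[1L]] <- 1L
  border <- 1L    # 1-based row index of state 0
  for (q in seq_len(L)) {
    row <- q + 1L
    delta0[row, ] <- delta0[border, ]
    if (q < L) {
      border <- delta0[border, w[q + 1L]] + 1L
      delta0[row, w[q + 1L]] <- q + 1L
    }
  }
  delta <- delta0 + 1L    # to 1-based state indices
  counting <- delta == (L + 1L)
  dimnames(delta) <- dimnames(counting) <- list(NULL, letters)
  new("WordDFA", word = word, letters = as.character(letters),
      delta = delta, counting = counting)
}

#' Count word occurrences by running the DFA
#'
#' Feeds a sequence through a [WordDFA-class] and counts the number of
#' counting transitions taken.  Equals the naive overlapping substring
#' count; used as the automaton-side cross-check of [countOccurrences()].
#'
#' @param dfa a [WordDFA-class].
#' @param sequence a letter string.
#' @return integer occurrence count.
#' @export
dfaCountOccurrences <- function(dfa, sequence) {
  s <- match(strsplit(sequence, "")[[1]], dfa@letters)
  if (anyNA(s)) stop("sequence contains letters outside the DFA alphabet")
  q <- 1L
  n <- 0L
  for (c in s) {
    if (dfa@counting[q, c]) n <- n + 1L
    q <- dfa@delta[q, c]
  }
  n
}

#' Count overlapping word occurrences
#'
#' Overlapping occurrences of `word` in each sequence, via a
#' lookahead-regex scan.  Vectorised over `sequences`.
#'
#' @param sequences character vector of letter strings.
#' @param word the pattern.
#' @return integer vector of counts, one per sequence.
#' @examples
#' countOccurrences("AAAAAA", "AAAA")  # 3
#' @export
countOccurrences <- function(sequences, word) {
  pat <- paste0("(?=\\Q", word, "\\E)")
  vapply(sequences, function(s) {
    m <- gregexpr(pat, s, perl = TRUE)[[1]]
    if (m[1L] == -1L) 0L else length(m)
  }, integer(1L), USE.NAMES = FALSE)
}
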