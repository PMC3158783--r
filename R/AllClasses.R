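#' Structural-alphabet model
#'
#' An `AlphabetModel` holds a structural alphabet: `K` structural letters,
#' each a Gaussian prototype of the 4-D geometric descriptor of a
#' four-residue backbone fragment, together with the Markov transition
#' matrix between letters, the initial letter distribution, and a
#' secondary-structure class (`helix`, `strand` or `loop`) per letter.
#'
#' @slot letters character vector of unique single-character letter names
#'   (conventionally `a`, `A`-`Z` for K = 27).
#' @slot emissionMean K x 4 matrix; row k is the descriptor mean of letter k.
#' @slot emissionCov 4 x 4 x K array of symmetric positive-definite
#'   emission covariances.
#' @slot transition K x K row-stochastic transition matrix.
#' @slot initial length-K initial distribution.
#' @slot letterClass character vector, one of `"helix"`, `"strand"`,
#'   `"loop"` per letter.
#' @slot representative optional list of 4 x 3 coordinate matrices, one
#'   representative four-residue fragment per letter (may be empty).
#'
#' @seealso [AlphabetModel()] for the user-facing constructor,
#'   [trainAlphabet()], [readAlphabet()].
#' @name AlphabetModel-class
#' @rdname AlphabetModel-class
#' @exportClass AlphabetModel
setClass("AlphabetModel",
  representation(
    letters        = "character",
    emissionMean   = "matrix",
    emissionCov    = "array",
    transition     = "matrix",
    initial        = "numeric",
    letterClass    = "character",
    representative = "list"
  )
)

.validAlphabetModel <- function(object) {
  msg <- character(0)
  K <- length(object@letters)
  if (K < 1L) msg <- c(msg, "model must contain at least one letter")
  if (anyDuplicated(object@letters)) msg <- c(msg, "letter names must be unique")
  if (!all(dim(object@emissionMean) == c(K, 4L)))
    msg <- c(msg, "emissionMean must be a K x 4 matrix")
  if (!all(dim(object@emissionCov) == c(4L, 4L, K)))
    msg <- c(msg, "emissionCov must be a 4 x 4 x K array")
  if (!all(dim(object@transition) == c(K, K)))
    msg <- c(msg, "transition must be a K x K matrix")
  if (length(object@initial) != K)
    msg <- c(msg, "initial must have one entry per letter")
  if (length(object@letterClass) != K)
    msg <- c(msg, "letterClass must have one entry per letter")
  if (!all(object@letterClass %in% c("helix", "strand", "loop")))
    msg <- c(msg, "letterClass entries must be 'helix', 'strand' or 'loop'")
  if (length(msg) == 0L) {
    if (any(object@transition < 0) || any(abs(rowSums(object@transition) - 1) > 1e-9))
      msg <- c(msg, "transition rows must be non-negative and sum to 1 (tol 1e-9)")
    if (any(object@initial < 0) || abs(sum(object@initial) - 1) > 1e-9)
      msg <- c(msg, "initial must be non-negative and sum to 1 (tol 1e-9)")
    for (k in seq_len(K)) {
      S <- object@emissionCov[, , k]
      if (max(abs(S - t(S))) > 1e-8) {
        msg <- c(msg, sprintf("emission covariance of letter '%s' is not symmetric",
                              object@letters[k]))
        break
      }
      ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) <= 0) {
        msg <- c(msg, sprintf("emission covariance of letter '%s' is not positive-definite",
                              object@letters[k]))
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
}
setValidity("AlphabetModel", .validAlphabetModel)

#' Construct a structural-alphabet model
#'
#' @param letters character vector of unique letter names.
#' @param emissionMean K x 4 matrix of descriptor means.
#' @param emissionCov 4 x 4 x K array (or list of K 4 x 4 matrices) of
#'   emission covariances.
#' @param transition K x K row-stochastic matrix.
#' @param initial length-K probability vector.
#' @param letterClass per-letter class in `helix`, `strand`, `loop`
#'   (default all `loop`).
#' @param representative optional list of per-letter 4 x 3 representative
#'   fragments.
#' @return a validated [AlphabetModel-class] object.
#' @examples
#' m <- AlphabetModel(
#'   letters = c("A", "B"),
#'   emissionMean = rbind(c(5, 5, 5, 1), c(6, 9, 6, -2)),
#'   emissionCov = array(diag(4), c(4, 4, 2)),
#'   transition = rbind(c(.8, .2), c(.4, .6)),
#'   initial = c(.5, .5)
#' )
#' alphabetSize(m)
#' @export
AlphabetModel <- function(letters, emissionMean, emissionCov, transition,
                          initial, letterClass = rep("loop", length(letters)),
                          representative = list()) {
  if (is.list(emissionCov)) {
    emissionCov <- array(unlist(emissionCov), c(4L, 4L, length(emissionCov)))
  }
  emissionMean <- as.matrix(emissionMean)
  dimnames(emissionMean) <- list(letters, c("d13", "d14", "d24", "h"))
  dimnames(emissionCov) <- list(NULL, NULL, letters)
  transition <- as.matrix(transition)
  dimnames(transition) <- list(letters, letters)
  new("AlphabetModel",
      letters = as.character(letters),
      emissionMean = emissionMean,
      emissionCov = emissionCov,
      transition = transition,
      initial = setNames(as.numeric(initial), letters),
      letterClass = setNames(as.character(letterClass), letters),
      representative = representative)
}

setMethod("show", "AlphabetModel", function(object) {
  K <- length(object@letters)
  cls <- table(factor(object@letterClass, c("helix", "strand", "loop")))
  cat(sprintf("AlphabetModel with %d structural letters\n", K))
  cat("  letters: ", paste(object@letters, collapse = " "), "\n", sep = "")
  cat(sprintf("  classes: %d helix, %d strand, %d loop\n",
              cls[["helix"]], cls[["strand"]], cls[["loop"]]))
  invisible(NULL)
})

#' Markov background model over structural letters
#'
#' A homogeneous Markov model of order 0 or 1 over a letter alphabet, used
#' as the reference model when testing words for over-representation.  For
#' order 0 the `transition` matrix has a single row (the letter
#' probabilities); for order 1 row `a` is the conditional distribution of
#' the next letter given current letter `a`.  `initial` is the distribution
#' of the first letter of a sequence.
#'
#' @slot order integer, 0 or 1.
#' @slot letters character vector of letter names.
#' @slot transition conditional probability matrix (1 x K or K x K).
#' @slot initial length-K distribution of the first letter.
#' @seealso [fitBackground()]
#' @name MarkovBackground-class
#' @rdname MarkovBackground-class
#' @exportClass MarkovBackground
setClass("MarkovBackground",
  representation(
    order      = "integer",
    letters    = "character",
    transition = "matrix",
    initial    = "numeric"
  )
)

.validMarkovBackground <- function(object) {
  msg <- character(0)
  K <- length(object@letters)
  if (!object@order %in% c(0L, 1L))
    msg <- c(msg, "only background orders 0 and 1 are supported")
  if (anyDuplicated(object@letters)) msg <- c(msg, "letters must be unique")
  expRows <- if (object@order == 0L) 1L else K
  if (!all(dim(object@transition) == c(expRows, K)))
    msg <- c(msg, sprintf("transition must be %d x %d", expRows, K))
  if (length(object@initial) != K)
    msg <- c(msg, "initial must have one entry per letter")
  if (length(msg) == 0L) {
    if (any(object@transition < 0) ||
        any(abs(rowSums(object@transition) - 1) > 1e-9))
      msg <- c(msg, "conditional distributions must sum to 1 (tol 1e-9)")
    if (any(object@initial < 0) || abs(sum(object@initial) - 1) > 1e-9)
      msg <- c(msg, "initial must sum to 1 (tol 1e-9)")
  }
  if (length(msg)) msg else TRUE
}
setValidity("MarkovBackground", .validMarkovBackground)

#' Construct a Markov background
#'
#' @param letters character vector of letter names.
#' @param transition 1 x K (order 0) or K x K (order 1) conditional
#'   probability matrix.
#' @param initial length-K first-letter distribution; defaults to the
#'   order-0 marginal (order 0) or the uniform distribution (order 1).
#' @param order 0 or 1; inferred from `transition` when missing.
#' @return a [MarkovBackground-class] object.
#' @export
MarkovBackground <- function(letters, transition, initial = NULL, order = NULL) {
  transition <- as.matrix(transition)
  if (is.null(order)) order <- if (nrow(transition) == 1L) 0L else 1L
  if (is.null(initial)) {
    initial <- if (order == 0L) as.numeric(transition[1L, ])
               else rep(1 / length(letters), length(letters))
  }
  dimnames(transition) <- if (order == 0L) list(NULL, letters)
                          else list(letters, letters)
  new("MarkovBackground", order = as.integer(order),
      letters = as.character(letters), transition = transition,
      initial = setNames(as.numeric(initial), letters))
}

setMethod("show", "MarkovBackground", function(object) {
  cat(sprintf("MarkovBackground of order %d over %d letters (%s)\n",
              object@order, length(object@letters),
              paste(head(object@letters, 8), collapse = "")))
  invisible(NULL)
})

#' Word-counting deterministic finite automaton
#'
#' The DFA that recognises overlapping occurrences of one word: states are
#' the proper prefixes of the word plus the full word (`nchar(word) + 1`
#' states), transitions follow the Knuth-Morris-Pratt failure structure so
#' that after a match the automaton resumes from the longest proper suffix
#' of the word that is also a prefix.  Transitions entering the final state
#' emit one occurrence (`counting`).
#'
#' @slot word the pattern.
#' @slot letters the alphabet.
#' @slot delta (L+1) x K integer transition table, 1-based state indices;
#'   state 1 is the empty prefix, state L+1 the match state.
#' @slot counting (L+1) x K logical table, TRUE where the transition emits
#'   an occurrence.
#' @seealso [buildWordDFA()], [dfaCountOccurrences()]
#' @name WordDFA-class
#' @rdname WordDFA-class
#' @exportClass WordDFA
setClass("WordDFA",
  representation(
    word     = "character",
    letters  = "character",
    delta    = "matrix",
    counting = "matrix"
  )
)

setValidity("WordDFA", function(object) {
  msg <- character(0)
  L <- nchar(object@word)
  K <- length(object@letters)
  if (!all(dim(object@delta) == c(L + 1L, K)))
    msg <- c(msg, "delta must be (L+1) x K")
  if (!all(dim(object@counting) == dim(object@delta)))
    msg <- c(msg, "counting must match delta in shape")
  if (length(msg) == 0L &&
      (any(object@delta < 1L) || any(object@delta > L + 1L)))
    msg <- c(msg, "delta entries must be valid state indices")
  if (length(msg)) msg else TRUE
})

setMethod("show", "WordDFA", function(object) {
  cat(sprintf("WordDFA for '%s' over {%s}: %d states\n", object@word,
              paste(object@letters, collapse = ""), nrow(object@delta)))
  invisible(NULL)
})
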