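#' Exact word over-representation within groups
#'
#' For every structural word and every group (e.g. SCOP superfamily),
#' compares the observed overlapping occurrence count of the word in the
#' group's loops with its exact distribution under a Markov background,
#' and reports the inclusive tail p-value and `Lp = -log10(p)` score.
#' Only (word, group) pairs in which the word is observed at least
#' `minCountGroup` times (default 5) are tested; pairs with fewer (but at
#' least one) occurrences are reported with `tested = FALSE` and no
#' score.  The count distribution is computed with the saturation cap set
#' to the observed count, which is exactly what the tail
#' `P(N >= N_obs)` requires.
#'
#' The background is fitted by maximum likelihood on the whole loop
#' corpus by default (`bgScope = "corpus"`), so group-specific excesses
#' remain detectable, or per group (`bgScope = "group"`).  A
#' pre-fitted [MarkovBackground-class] can be supplied instead.
#'
#' @param loops loop table (see [extractLoops()]); only `loop_id` and
#'   `letters` are required.
#' @param groups loop-to-group assignment: a data.frame with columns
#'   `loop_id` and `group_id`, or a vector of group labels named by (or
#'   parallel to) `loops$loop_id`.
#' @param words character vector of word types to test; when `NULL`, all
#'   word types of length `wordLength` seen at least `minCountCorpus`
#'   times in the corpus.
#' @param bgScope `"corpus"` (default) or `"group"`.
#' @param order Markov order of the background (0 or 1, default 1).
#' @param pseudocount additive smoothing for the background fit.
#' @param minCountGroup minimum in-group occurrence count for a word to
#'   be tested in that group (default 5).
#' @param minCountCorpus corpus-wide minimum used when `words = NULL`
#'   (default 5).
#' @param wordLength word length used when `words = NULL` (default 4).
#' @param background optional [MarkovBackground-class] overriding the fit.
#' @return a data.frame with one row per (word, group) pair in which the
#'   word occurs: `word`, `group_id`, `N_obs`, `expected`, `p_value`,
#'   `Lp`, `tested`.
#' @seealso [summarizeWords()], [bonferroniThreshold()]
#' @export
enrichWords <- function(loops, groups, words = NULL,
                        bgScope = c("corpus", "group"), order = 1L,
                        pseudocount = 0, minCountGroup = 5L,
                        minCountCorpus = 5L, wordLength = 4L,
                        background = NULL) {
  bgScope <- match.arg(bgScope)
  if (nrow(loops) == 0L) stop("empty loop table")
  if (is.data.frame(groups)) {
    g <- groups$group_id[match(loops$loop_id, groups$loop_id)]
  } else if (!is.null(names(groups))) {
    g <- unname(groups[as.character(loops$loop_id)])
  } else {
    stopifnot(length(groups) == nrow(loops))
    g <- groups
  }
  if (anyNA(g)) stop("every loop must be assigned to a group")
  if (length(unique(g)) == 0L) stop("empty group table")

  letters <- sort(unique(unlist(strsplit(loops$letters, ""))))
  if (is.null(words)) {
    occ <- extractWords(loops, L = wordLength)
    counts <- table(occ$word)
    words <- names(counts)[counts >= minCountCorpus]
  } else {
    occ <- extractWords(loops, L = nchar(words[1L]))
  }
  if (length(words) == 0L) stop("no words to test")
  stopifnot(length(unique(nchar(words))) == 1L)
  occ <- occ[occ$word %in% words, , drop = FALSE]
  occ$group_id <- g[match(occ$loop_id, loops$loop_id)]

  corpusBg <- if (!is.null(background)) background
              else if (bgScope == "corpus")
                fitBackground(loops$letters, order = order,
                              pseudocount = pseudocount, letters = letters)
              else NULL

  dfaCache <- new.env(parent = emptyenv())
  getDFA <- function(word) {
    if (is.null(dfaCache[[word]]))
      dfaCache[[word]] <- buildWordDFA(word, letters)
    dfaCache[[word]]
  }

  rows <- list()
  for (grp in sort(unique(g))) {
    inGrp <- g == grp
    lens <- nchar(loops$letters[inGrp])
    bg <- if (!is.null(corpusBg)) corpusBg
          else fitBackground(loops$letters[inGrp], order = order,
                             pseudocount = pseudocount, letters = letters)
    cnt <- table(occ$word[occ$group_id == grp])
    if (length(cnt) == 0L) next
    word <- names(cnt)
    N <- as.integer(cnt)
    testable <- N >= minCountGroup & max(lens) >= nchar(word[1L])
    expct <- vapply(word, function(wd) expectedCount(lens, wd, bg), 0)
    p <- rep(NA_real_, length(word))
    for (i in which(testable)) {
      dist <- countDistribution(lens, getDFA(word[i]), bg, cap = N[i])
      p[i] <- pvalueGE(dist, N[i])
    }
    rows[[grp]] <- data.frame(word = word, group_id = grp, N_obs = N,
                              expected = unname(expct), p_value = p,
                              Lp = ifelse(is.na(p), NA_real_, -log10(p)),
                              tested = testable, stringsAsFactors = FALSE)
  }
  out <- .rbindRows(rows)
  if (is.null(out)) stop("no word occurrences in any group")
  out
}
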