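# Word taxonomy: aggregate per-group scores into Lp_max / nb_sf*,
# categorise words, and compute coverage rates of word subsets.

#' Bonferroni significance threshold on the Lp scale
#'
#' `-log10(alpha / n_tests)`, with `n_tests` the number of (word, group)
#' pairs actually tested.  Large published loop-corpus analyses with the
#' 27-letter alphabet used a threshold of 5.97 on this scale; the
#' constant [legacyLpThreshold] is provided for runs mimicking that
#' setting, but the default everywhere in this package is the threshold
#' computed from the actual number of tests.
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param n_tests number of tests performed (>= 1).
#' @return the Lp significance threshold.
#' @examples
#' bonferroniThreshold(0.05, 1)    # 1.3010
#' bonferroniThreshold(0.05, 100)  # 3.3010
#' @export
bonferroniThreshold <- function(alpha = 0.05, n_tests) {
  stopifnot(alpha > 0, alpha < 1)
  if (n_tests < 1L) stop("n_tests must be >= 1")
  -log10(alpha / n_tests)
}

#' Legacy Lp significance threshold
#'
#' The Bonferroni-corrected threshold (5.97) used by large-scale loop
#' analyses with the published 27-letter structural alphabet, kept as a
#' documented constant for runs that mimic that setting.  New analyses
#' should compute their own threshold with [bonferroniThreshold()].
#' @export
legacyLpThreshold <- 5.97

#' Taxonomy thresholds
#'
#' Bundles the cut-offs of the word taxonomy: significance threshold
#' `lpSig`, minimum number of significant groups for a ubiquitous word
#' (`ubiqMinSf`, default 5), the `Lp_max` cut-offs for extreme ubiquitous
#' (10), moderately group-specific (10) and extreme group-specific (50)
#' words, and the precision threshold for functional words (0.40).  A
#' warning is issued when the cut-offs are not ordered
#' `extremeSpecLp >= moderateLp >= lpSig`.
#'
#' @param lpSig significance threshold on the Lp scale.
#' @param ubiqMinSf,extremeUbiqLp,moderateLp,extremeSpecLp,functionalPrecision
#'   taxonomy cut-offs (see Description).
#' @return a list of class `"wordThresholds"`.
#' @export
wordThresholds <- function(lpSig, ubiqMinSf = 5L, extremeUbiqLp = 10,
                           moderateLp = 10, extremeSpecLp = 50,
                           functionalPrecision = 0.40) {
  if (extremeSpecLp < moderateLp || moderateLp < lpSig)
    warning("taxonomy cut-offs are not ordered extremeSpecLp >= moderateLp >= lpSig")
  structure(list(lpSig = lpSig, ubiqMinSf = ubiqMinSf,
                 extremeUbiqLp = extremeUbiqLp, moderateLp = moderateLp,
                 extremeSpecLp = extremeSpecLp,
                 functionalPrecision = functionalPrecision),
            class = "wordThresholds")
}

#' Summarise per-group enrichment into per-word statistics
#'
#' For every word: `Lp_max`, the maximal Lp score among tested groups (0
#' when no group was tested); `nb_sf_star`, the number of groups in which
#' the word is significantly over-represented (`Lp >= lpSig` among tested
#' groups); and `nb_sf`, the number of groups in which the word is seen
#' at all (`N_obs >= 1`).  The summary is invariant to the order of the
#' enrichment rows.
#'
#' @param results an enrichment table from [enrichWords()].
#' @param lpSig significance threshold on the Lp scale (e.g. the output
#'   of [bonferroniThreshold()] for the number of tested pairs).
#' @return a data.frame with one row per word: `word`, `Lp_max`,
#'   `nb_sf_star`, `nb_sf`.
#' @export
summarizeWords <- function(results, lpSig) {
  split_ <- split(results, results$word)
  out <- lapply(split_, function(r) {
    lp <- r$Lp[r$tested]
    data.frame(word = r$word[1L],
               Lp_max = if (length(lp)) max(lp) else 0,
               nb_sf_star = sum(lp >= lpSig),
               nb_sf = sum(r$N_obs >= 1L),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res[order(res$word), , drop = FALSE]
}

#' Categorise words from their summary statistics
#'
#' Applies the word taxonomy: a word is over-represented when
#' `Lp_max >= lpSig`; over-represented words with `nb_sf_star >= 5` are
#' ubiquitous (extreme when `Lp_max >= 10`), those with `nb_sf_star < 5`
#' are group-specific (moderately so when `Lp_max >= 10`, extreme when
#' `Lp_max >= 50`).  The `functional` category is assigned downstream by
#' [callFunctionalWords()] from annotation precision.
#'
#' @param summaries output of [summarizeWords()].
#' @param thr a [wordThresholds()] object.
#' @return `summaries` with an added `category` column.
#' @export
categorizeWords <- function(summaries, thr) {
  stopifnot(inherits(thr, "wordThresholds"))
  cat_ <- character(nrow(summaries))
  over <- summaries$Lp_max >= thr$lpSig
  ubiq <- over & summaries$nb_sf_star >= thr$ubiqMinSf
  spec <- over & summaries$nb_sf_star < thr$ubiqMinSf
  cat_[!over] <- "not_over_represented"
  cat_[ubiq] <- ifelse(summaries$Lp_max[ubiq] >= thr$extremeUbiqLp,
                       "extreme_ubiquitous", "ubiquitous")
  cat_[spec] <- ifelse(summaries$Lp_max[spec] >= thr$extremeSpecLp,
                       "extreme_superfamily_specific",
                       ifelse(summaries$Lp_max[spec] >= thr$moderateLp,
                              "moderately_superfamily_specific",
                              "superfamily_specific"))
  summaries$category <- cat_
  summaries
}

#' Coverage rates of a word subset
#'
#' Four complementary coverage measures of a word subset over a corpus,
#' all in percent: `word_cov`, the fraction of word types in the subset;
#' `fragment_cov`, the fraction of fragments (word occurrences) encoded
#' by subset words; `loop_length_cov`, the fraction of loop residues
#' covered by at least one subset-word fragment (union of residue spans,
#' overlaps counted once); and `protein_cov`, the fraction of proteins
#' containing at least one subset occurrence.
#'
#' @param subset character vector of words (must be a subset of the word
#'   types in `occurrences`).
#' @param occurrences full word-occurrence table of the corpus
#'   ([extractWords()] output, possibly filtered).
#' @param loops the loop table the occurrences were extracted from.
#' @param proteins optional character vector of all protein ids (defaults
#'   to the proteins in `loops`).
#' @return named numeric vector with components `word_cov`,
#'   `fragment_cov`, `loop_length_cov`, `protein_cov` (percent).
#' @export
coverageRates <- function(subset, occurrences, loops, proteins = NULL) {
  types <- unique(occurrences$word)
  if (!all(subset %in% types))
    stop("subset contains words absent from the occurrence table")
  if (is.null(proteins)) proteins <- unique(loops$protein_id)
  inSub <- occurrences$word %in% subset

  wordCov <- 100 * length(unique(subset)) / length(types)
  fragCov <- if (nrow(occurrences)) 100 * sum(inSub) / nrow(occurrences) else 0

  totalLoopRes <- sum(nchar(loops$letters) + 3L)
  sub <- occurrences[inSub, , drop = FALSE]
  covered <- 0L
  if (nrow(sub)) {
    L <- nchar(sub$word[1L])
    ir <- IRanges::reduce(S4Vectors::split(
      IRanges::IRanges(start = sub$start_letter, end = sub$start_letter + L + 2L),
      factor(sub$loop_id)))
    covered <- sum(sum(IRanges::width(ir)))
  }
  loopCov <- if (totalLoopRes > 0) 100 * covered / totalLoopRes else 0

  protCov <- 100 * length(unique(sub$protein_id)) / length(proteins)
  c(word_cov = wordCov, fragment_cov = fragCov,
    loop_length_cov = loopCov, protein_cov = protCov)
}
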