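# Correspondence between structural words and interval annotations:
# fragment/annotation overlap, precision, sensitivity, functional calls.

.normalizeLabel <- function(x) gsub("\\s+", " ", trimws(x))

.annoLabels <- function(annotations, level) {
  if (level == "feature") annotations$feature_key
  else .normalizeLabel(annotations$description)
}

.keyedRanges <- function(protein, chain, start, end) {
  GenomicRanges::GRanges(
    seqnames = paste(protein, chain, sep = "\r"),
    ranges = IRanges::IRanges(start = start, end = end))
}

# occurrence x annotation overlap pairs with >= minOverlap shared residues
.overlapPairs <- function(occurrences, annotations, minOverlap = 1L) {
  if (nrow(occurrences) == 0L || nrow(annotations) == 0L)
    return(data.frame(occ = integer(0), anno = integer(0)))
  q <- .keyedRanges(occurrences$protein_id, occurrences$chain_id,
                    occurrences$residue_start, occurrences$residue_end)
  s <- .keyedRanges(annotations$protein_id, annotations$chain_id,
                    annotations$residue_start, annotations$residue_end)
  GenomeInfoDb::seqlevels(q) <- GenomeInfoDb::seqlevels(s) <-
    union(GenomeInfoDb::seqlevels(q), GenomeInfoDb::seqlevels(s))
  hits <- GenomicRanges::findOverlaps(q, s, minoverlap = minOverlap)
  data.frame(occ = S4Vectors::queryHits(hits),
             anno = S4Vectors::subjectHits(hits))
}

#' Read an interval annotation table
#'
#' Tab-separated file with columns `protein_id`, `chain_id`,
#' `residue_start`, `residue_end` (1-based inclusive), `feature_key`
#' (first annotation level, e.g. `NP_BIND`, `CA_BIND`, `Binding`,
#' `Repeat`, `Active site`) and `description` (second level, e.g. the
#' ligand type).
#'
#' @param file path to the TSV.
#' @return a data.frame of annotation records.
#' @export
readAnnotations <- function(file) {
  a <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("protein_id", "chain_id", "residue_start", "residue_end",
            "feature_key", "description")
  missing <- setdiff(need, names(a))
  if (length(missing))
    stop("annotation table lacks column(s): ", paste(missing, collapse = ", "))
  stopifnot(all(a$residue_start <= a$residue_end))
  a
}

#' Annotation labels matched by one fragment
#'
#' A fragment matches an annotation when at least `minOverlap` residues
#' of its residue span intersect the annotation interval on the same
#' protein and chain.
#'
#' @param occ a single-row word-occurrence data.frame (with
#'   `protein_id`, `chain_id`, `residue_start`, `residue_end`).
#' @param annotations an annotation table (see [readAnnotations()]).
#' @param level `"feature"` (feature key) or `"description"`
#'   (whitespace-normalised description).
#' @param minOverlap minimum number of shared residues (default 1).
#' @return character vector of distinct matched labels.
#' @export
fragmentMatches <- function(occ, annotations, level = c("feature", "description"),
                            minOverlap = 1L) {
  level <- match.arg(level)
  stopifnot(minOverlap >= 1L, nrow(occ) == 1L)
  pairs <- .overlapPairs(occ, annotations, minOverlap)
  unique(.annoLabels(annotations, level)[pairs$anno])
}

#' Precision of a word for an annotation label
#'
#' The proportion of fragments encoded by a structural word that carry a
#' given annotation: matched fragments / all fragments of the word.
#' A word with no occurrences has undefined precision (`NA`).
#'
#' @param word the structural word.
#' @param occurrences the corpus word-occurrence table.
#' @inheritParams fragmentMatches
#' @param label the annotation label (at the given level).
#' @return a fraction in `[0, 1]`, or `NA` if the word has no fragment.
#' @export
wordPrecision <- function(word, occurrences, annotations, label,
                          level = c("feature", "description"),
                          minOverlap = 1L) {
  level <- match.arg(level)
  occ <- occurrences[occurrences$word == word, , drop = FALSE]
  if (nrow(occ) == 0L) return(NA_real_)
  keep <- .annoLabels(annotations, level) == label
  pairs <- .overlapPairs(occ, annotations[keep, , drop = FALSE], minOverlap)
  length(unique(pairs$occ)) / nrow(occ)
}

#' Sensitivity of a word for an annotation label
#'
#' The proportion of loop-located instances of an annotation that are
#' covered by the word: the denominator counts annotation records (one
#' interval = one instance) with at least one residue inside a loop
#' region; the numerator counts those overlapped by at least one
#' occurrence of the word (with the same `minOverlap` rule as
#' [fragmentMatches()]).  Annotations lying entirely within regular
#' secondary structures are discarded from the denominator.
#'
#' @inheritParams wordPrecision
#' @param loops the loop table defining loop regions.
#' @return a fraction in `[0, 1]`, or `NA` when no instance of the label
#'   touches a loop.
#' @export
wordSensitivity <- function(word, occurrences, annotations, label,
                            level = c("feature", "description"), loops,
                            minOverlap = 1L) {
  level <- match.arg(level)
  keep <- .annoLabels(annotations, level) == label
  anno <- annotations[keep, , drop = FALSE]
  if (nrow(anno) == 0L) return(NA_real_)
  loopRegions <- data.frame(protein_id = loops$protein_id,
                            chain_id = loops$chain_id,
                            residue_start = loops$residue_start,
                            residue_end = loops$residue_end)
  inLoop <- unique(.overlapPairs(anno, loopRegions, 1L)$occ)
  if (length(inLoop) == 0L) return(NA_real_)
  anno <- anno[inLoop, , drop = FALSE]
  occ <- occurrences[occurrences$word == word, , drop = FALSE]
  if (nrow(occ) == 0L) return(0)
  hit <- unique(.overlapPairs(anno, occ, minOverlap)$occ)
  length(hit) / nrow(anno)
}

#' Per-word precision table
#'
#' Precision of every word for every annotation label it touches, at one
#' or both annotation levels.  Pairs with no matched fragment are
#' omitted (their precision is 0).
#'
#' @inheritParams wordPrecision
#' @param levels annotation levels to scan (default both).
#' @return a data.frame: `word`, `level`, `label`, `n_fragments`,
#'   `n_matched`, `precision`.
#' @export
precisionTable <- function(occurrences, annotations,
                           levels = c("feature", "description"),
                           minOverlap = 1L) {
  nFrag <- table(occurrences$word)
  pairs <- .overlapPairs(occurrences, annotations, minOverlap)
  out <- list()
  for (lv in levels) {
    if (nrow(pairs) == 0L) next
    lab <- .annoLabels(annotations, lv)[pairs$anno]
    key <- data.frame(word = occurrences$word[pairs$occ], label = lab,
                      occ = pairs$occ)
    key <- unique(key)
    agg <- aggregate(occ ~ word + label, key, FUN = function(x) length(unique(x)))
    agg$level <- lv
    out[[lv]] <- agg
  }
  if (length(out) == 0L)
    return(data.frame(word = character(0), level = character(0),
                      label = character(0), n_fragments = integer(0),
                      n_matched = integer(0), precision = numeric(0)))
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  data.frame(word = res$word, level = res$level, label = res$label,
             n_fragments = as.integer(nFrag[res$word]),
             n_matched = res$occ,
             precision = res$occ / as.integer(nFrag[res$word]),
             stringsAsFactors = FALSE)
}

#' Call functional words
#'
#' A word is functional when its category is
#' `extreme_superfamily_specific` and its best precision over all
#' annotation labels (both levels) reaches the precision threshold
#' (default 0.40).
#'
#' @param summaries categorised word summaries ([categorizeWords()]).
#' @param precision_table output of [precisionTable()].
#' @param thrPrecision precision threshold (default 0.40).
#' @return `summaries` with added columns `precision_max` (0 for words
#'   absent from the precision table) and `functional`; the category of
#'   functional words is set to `"functional"`.
#' @export
callFunctionalWords <- function(summaries, precision_table,
                                thrPrecision = 0.40) {
  stopifnot(!is.null(summaries$category))
  best <- if (nrow(precision_table))
    tapply(precision_table$precision, precision_table$word, max)
  else numeric(0)
  pmax_ <- as.numeric(best[summaries$word])
  pmax_[is.na(pmax_)] <- 0
  summaries$precision_max <- pmax_
  summaries$functional <- summaries$category == "extreme_superfamily_specific" &
    pmax_ >= thrPrecision
  summaries$category[summaries$functional] <- "functional"
  summaries
}
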