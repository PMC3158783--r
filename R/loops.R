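# Loop extraction and decomposition of loops into overlapping structural
# words.  Letter-sequence tables carry a `residue_offset` column: letter i
# of a sequence covers residues residue_offset + i .. residue_offset + i + 3
# (1-based inclusive in all I/O).

# rbind a list of data.frames, tolerating NULLs and the empty case
.rbindRows <- function(rows) {
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

.asLetterTable <- function(seqs) {
  if (is.character(seqs))
    seqs <- data.frame(protein_id = sprintf("seq%04d", seq_along(seqs)),
                       chain_id = "A", segment = 1L, letters = seqs,
                       stringsAsFactors = FALSE)
  if (is.null(seqs$segment)) seqs$segment <- 1L
  if (is.null(seqs$residue_offset)) {
    seqs$residue_offset <- if (!is.null(seqs$resno_start))
      seqs$resno_start - 1L else 0L
  }
  seqs
}

#' Extract loops from structural-letter sequences
#'
#' Removes regular secondary structures using the letter classes of the
#' alphabet: a loop is a maximal run of loop-class letters, so helix-class
#' and strand-class letters never appear inside a loop.  No minimum loop
#' length is imposed (loops shorter than the word length simply yield no
#' words).
#'
#' @param seqs a letter-sequence data.frame (from [encodeStructure()], the
#'   synthetic generator or [readLetterFasta()]) with columns
#'   `protein_id`, `chain_id`, `letters` and optionally `segment`,
#'   `residue_offset`; or a plain character vector of letter strings.
#' @param model the [AlphabetModel-class] providing letter classes; every
#'   letter occurring in `seqs` must be classed.
#' @return a data.frame with one row per loop: `loop_id` (unique integer),
#'   `protein_id`, `chain_id`, `segment`, `letters`, `start_letter`
#'   (1-based position of the loop's first letter in its parent sequence),
#'   `residue_start`, `residue_end` (1-based inclusive; a loop of m
#'   letters spans m + 3 residues).
#' @examples
#' \dontrun{
#' loops <- extractLoops(seqs, model)
#' }
#' @export
extractLoops <- function(seqs, model) {
  seqs <- .asLetterTable(seqs)
  cls <- letterClasses(model)
  rows <- vector("list", nrow(seqs))
  for (i in seq_len(nrow(seqs))) {
    ls <- strsplit(seqs$letters[i], "")[[1]]
    unknown <- setdiff(ls, names(cls))
    if (length(unknown))
      stop("letters not classed in the model: ", paste(unknown, collapse = ", "))
    isLoop <- cls[ls] == "loop"
    if (!any(isLoop)) next
    r <- rle(isLoop)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    off <- seqs$residue_offset[i]
    rows[[i]] <- data.frame(
      protein_id = seqs$protein_id[i], chain_id = seqs$chain_id[i],
      segment = seqs$segment[i],
      letters = vapply(keep, function(k)
        paste(ls[starts[k]:ends[k]], collapse = ""), ""),
      start_letter = starts[keep],
      residue_start = off + starts[keep],
      residue_end = off + ends[keep] + 3L,
      stringsAsFactors = FALSE)
  }
  out <- .rbindRows(rows)
  if (is.null(out))
    out <- data.frame(protein_id = character(0), chain_id = character(0),
                      segment = integer(0), letters = character(0),
                      start_letter = integer(0), residue_start = integer(0),
                      residue_end = integer(0))
  cbind(loop_id = seq_len(nrow(out)), out)
}

#' Split loops into overlapping structural words
#'
#' Each loop of `m` letters yields `max(0, m - L + 1)` overlapping words
#' of `L` consecutive letters, in order.  A word of `L` letters spans
#' `L + 3` residues (seven for the default `L = 4`).
#'
#' @param loops a loop table from [extractLoops()] (or any data.frame with
#'   `loop_id`, `protein_id`, `chain_id`, `letters`, `residue_start`).
#' @param L word length in structural letters (default 4).
#' @return a data.frame of word occurrences: `word`, `protein_id`,
#'   `chain_id`, `loop_id`, `start_letter` (1-based within the loop),
#'   `residue_start`, `residue_end`.
#' @examples
#' loops <- data.frame(loop_id = 1L, protein_id = "p", chain_id = "A",
#'                     letters = "SPBDRPI", residue_start = 1L)
#' extractWords(loops)$word   # SPBD PBDR BDRP DRPI
#' @export
extractWords <- function(loops, L = 4L) {
  stopifnot(L >= 1L)
  m <- nchar(loops$letters)
  nw <- pmax(0L, m - L + 1L)
  idx <- rep.int(seq_len(nrow(loops)), nw)
  if (length(idx) == 0L)
    return(data.frame(word = character(0), protein_id = character(0),
                      chain_id = character(0), loop_id = integer(0),
                      start_letter = integer(0), residue_start = integer(0),
                      residue_end = integer(0)))
  start <- unlist(lapply(nw, seq_len), use.names = FALSE)
  resStart <- loops$residue_start[idx] + start - 1L
  data.frame(word = substr(rep(loops$letters, nw), start, start + L - 1L),
             protein_id = loops$protein_id[idx],
             chain_id = loops$chain_id[idx],
             loop_id = loops$loop_id[idx],
             start_letter = start,
             residue_start = resStart,
             residue_end = resStart + L + 2L,
             stringsAsFactors = FALSE)
}

#' Filter out rare word types
#'
#' Removes occurrences of word types seen fewer than `min_count` times in
#' the corpus (rare words track flexible or poorly determined regions).
#' The per-group minimum (a word must be seen at least 5 times in a group
#' to be tested there) is applied separately by [enrichWords()].
#'
#' @param occurrences a word-occurrence table from [extractWords()].
#' @param min_count minimum corpus-wide occurrence count (default 5).
#' @return the filtered occurrence table, with the full corpus word-count
#'   table attached as attribute `wordCounts`.
#' @export
filterWords <- function(occurrences, min_count = 5L) {
  stopifnot(min_count >= 1L)
  counts <- table(occurrences$word)
  keep <- names(counts)[counts >= min_count]
  out <- occurrences[occurrences$word %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "wordCounts") <- counts
  out
}

#' Write and read structural-letter sequences as FASTA-like records
#'
#' Records use the header convention
#' `>{protein_id}_{chain_id}/{segment_index}`.
#'
#' @param seqs a letter-sequence data.frame (see [extractLoops()] for the
#'   expected columns).
#' @param file path to write to / read from.
#' @return `writeLetterFasta` returns `file` invisibly; `readLetterFasta`
#'   returns a letter-sequence data.frame (`residue_offset` of 0).
#' @export
writeLetterFasta <- function(seqs, file) {
  seqs <- .asLetterTable(seqs)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(rbind(sprintf(">%s_%s/%d", seqs$protein_id, seqs$chain_id,
                           seqs$segment),
                   seqs$letters), con)
  invisible(file)
}

#' @rdname writeLetterFasta
#' @export
readLetterFasta <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  hd <- grepl("^>", lines)
  if (!any(hd)) stop("no FASTA headers in ", file)
  id <- sub("^>", "", lines[hd])
  seqGroup <- cumsum(hd)
  letters <- vapply(split(lines[!hd], seqGroup[!hd]), paste, "", collapse = "")
  segment <- as.integer(sub(".*/", "", id))
  rest <- sub("/[0-9]+$", "", id)
  chain <- sub(".*_", "", rest)
  protein <- sub("_[^_]*$", "", rest)
  data.frame(protein_id = protein, chain_id = chain, segment = segment,
             letters = unname(letters), residue_offset = 0L,
             stringsAsFactors = FALSE)
}
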