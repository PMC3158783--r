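#' Build a C-alpha trace
#'
#' A `CaTrace` is a plain data.frame with one row per residue and columns
#' `protein_id`, `chain_id`, `resno` (author residue number), `ins`
#' (insertion code, `""` when absent) and `x`, `y`, `z` coordinates in
#' Angstrom.  All geometry functions in the package consume this layout.
#'
#' @param coords n x 3 numeric matrix of C-alpha coordinates (Angstrom).
#' @param protein_id,chain_id identifiers stored on every row.
#' @param resno integer author residue numbers (default `1:n`).
#' @param ins insertion codes (default empty).
#' @return a data.frame with class `c("CaTrace", "data.frame")`.
#' @examples
#' tr <- caTrace(matrix(rnorm(30), ncol = 3), "prot1", "A")
#' nrow(tr)
#' @export
caTrace <- function(coords, protein_id = "protein", chain_id = "A",
                    resno = seq_len(nrow(coords)), ins = "") {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3L, nrow(coords) >= 1L,
            length(resno) == nrow(coords))
  out <- data.frame(protein_id = protein_id, chain_id = chain_id,
                    resno = as.integer(resno), ins = ins,
                    x = coords[, 1], y = coords[, 2], z = coords[, 3],
                    stringsAsFactors = FALSE)
  class(out) <- c("CaTrace", "data.frame")
  out
}

.traceCoords <- function(trace) {
  as.matrix(trace[, c("x", "y", "z"), drop = FALSE])
}

# Segment a trace at chain breaks: consecutive Ca-Ca distance above
# maxCaGap, or a jump in author residue numbering (difference outside
# {0, 1}; 0 accommodates insertion codes).
.traceSegments <- function(trace, maxCaGap = 4.5) {
  xyz <- .traceCoords(trace)
  n <- nrow(xyz)
  if (n == 1L) return(rep(1L, 1L))
  d <- sqrt(rowSums((xyz[-1L, , drop = FALSE] - xyz[-n, , drop = FALSE])^2))
  dres <- diff(trace$resno)
  brk <- d > maxCaGap | dres > 1L | dres < 0L
  cumsum(c(TRUE, brk))
}

#' Geometric descriptors of four-residue fragments
#'
#' Slides a four-residue window along a C-alpha trace and computes, for
#' every window that does not span a chain break, the 4-D descriptor
#' `(d13, d14, d24, h)`: the three distances between non-successive
#' C-alphas and the signed out-of-plane component of the fourth C-alpha
#' relative to the plane of the first three.  `h` is signed along the
#' right-handed normal `(p2 - p1) x (p3 - p1)`, so it flips sign under a
#' mirror reflection of the coordinates and captures fragment chirality.
#'
#' Chain breaks (consecutive C-alpha distance above `maxCaGap`, or
#' non-consecutive author residue numbering) split the trace; windows that
#' would span a break yield no descriptor and start a new segment, so the
#' downstream letter sequence is split as well.  Windows whose first three
#' points are collinear (plane undefined) are dropped with a warning and
#' also split the segment.
#'
#' @param trace a [caTrace()] data.frame with at least 4 residues.
#' @param maxCaGap maximum consecutive C-alpha distance (Angstrom) treated
#'   as a bonded neighbour; default 4.5.
#' @return a data.frame with one row per valid window: `segment` (index of
#'   the contiguous descriptor run), `anchor` (row index in `trace` of the
#'   window's first residue), `resno` (author number of that residue) and
#'   the descriptor columns `d13`, `d14`, `d24`, `h`.
#' @examples
#' p <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(3.8, 3.8, 0), c(0, 3.8, 2))
#' computeDescriptors(caTrace(p))
#' @export
computeDescriptors <- function(trace, maxCaGap = 4.5) {
  stopifnot(nrow(trace) >= 4L, maxCaGap > 0)
  xyz <- .traceCoords(trace)
  if (any(!is.finite(xyz)))
    stop("trace contains non-finite coordinates")
  seg <- .traceSegments(trace, maxCaGap)
  n <- nrow(xyz)
  anchors <- seq_len(n - 3L)
  inSeg <- seg[anchors] == seg[anchors + 3L]

  p1 <- xyz[anchors, , drop = FALSE]
  p2 <- xyz[anchors + 1L, , drop = FALSE]
  p3 <- xyz[anchors + 2L, , drop = FALSE]
  p4 <- xyz[anchors + 3L, , drop = FALSE]
  d13 <- sqrt(rowSums((p3 - p1)^2))
  d14 <- sqrt(rowSums((p4 - p1)^2))
  d24 <- sqrt(rowSums((p4 - p2)^2))
  u <- p2 - p1
  v <- p3 - p1
  nrm <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
               u[, 3] * v[, 1] - u[, 1] * v[, 3],
               u[, 1] * v[, 2] - u[, 2] * v[, 1])
  nlen <- sqrt(rowSums(nrm^2))
  degenerate <- inSeg & nlen < 1e-9
  if (any(degenerate))
    warning(sprintf("dropping %d degenerate window(s) (collinear points) at anchor(s) %s",
                    sum(degenerate),
                    paste(anchors[degenerate], collapse = ", ")))
  keep <- inSeg & !degenerate
  h <- rowSums(nrm / pmax(nlen, 1e-300) * (p4 - p1))

  anchors <- anchors[keep]
  if (length(anchors) == 0L) {
    return(data.frame(segment = integer(0), anchor = integer(0),
                      resno = integer(0), d13 = numeric(0), d14 = numeric(0),
                      d24 = numeric(0), h = numeric(0)))
  }
  # a run breaks when anchors are not consecutive or cross a trace segment
  newRun <- c(TRUE, diff(anchors) != 1L | diff(seg[anchors]) != 0L)
  data.frame(segment = cumsum(newRun), anchor = anchors,
             resno = trace$resno[anchors],
             d13 = d13[keep], d14 = d14[keep], d24 = d24[keep], h = h[keep],
             row.names = NULL)
}

#' Residue span of a word occurrence
#'
#' A word of `L` structural letters starting at letter position `i`
#' (1-based within its loop or sequence) covers residues `i` to
#' `i + L + 2`: each letter describes a four-residue fragment and
#' consecutive letters overlap by three residues, so `L` letters span
#' `L + 3` residues (seven residues for the default `L = 4`).
#'
#' @param startLetter 1-based position of the word's first letter.
#' @param L word length in letters (default 4).
#' @return integer vector `c(start, end)` of the 1-based inclusive residue
#'   span.
#' @examples
#' fragmentResidueSpan(1)      # residues 1..7
#' fragmentResidueSpan(3, 5)   # residues 3..10 (eight residues)
#' @export
fragmentResidueSpan <- function(startLetter, L = 4L) {
  stopifnot(startLetter >= 1L, L >= 1L)
  c(start = as.integer(startLetter), end = as.integer(startLetter + L + 2L))
}
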