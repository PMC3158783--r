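# Rigid-body fragment superposition (Kabsch) and the sampled word-pair
# RMSD protocol used to compare the geometry of two structural words.

#' Optimal-superposition RMSD of two fragments
#'
#' Root-mean-square deviation of two equal-length C-alpha fragments
#' after the optimal rigid-body superposition (Kabsch algorithm: SVD of
#' the cross-covariance with determinant correction, so only proper
#' rotations are allowed — fragments are chiral and mirror images must
#' not superpose).  Symmetric in its arguments and invariant to rigid
#' transforms of either one.  If either point set is fully degenerate
#' (all points identical) the rotation is the identity and the RMSD of
#' the centred sets is returned.
#'
#' @param X,Y n x 3 coordinate matrices (n >= 3), same n.
#' @return the minimal RMSD in Angstrom.
#' @examples
#' sq <- rbind(c(1, 1, 0), c(-1, 1, 0), c(-1, -1, 0), c(1, -1, 0))
#' rc <- rbind(c(1.5, 1, 0), c(-1.5, 1, 0), c(-1.5, -1, 0), c(1.5, -1, 0))
#' kabschRMSD(sq, rc)  # 0.5
#' @export
kabschRMSD <- function(X, Y) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  stopifnot(ncol(X) == 3L, ncol(Y) == 3L, nrow(X) == nrow(Y), nrow(X) >= 3L,
            all(is.finite(X)), all(is.finite(Y)))
  Xc <- sweep(X, 2L, colMeans(X))
  Yc <- sweep(Y, 2L, colMeans(Y))
  if (sum(Xc^2) < 1e-20 || sum(Yc^2) < 1e-20) {
    # degenerate: no rotation is identifiable, use the identity
    return(sqrt(mean(rowSums((Xc - Yc)^2))))
  }
  H <- crossprod(Xc, Yc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sqrt(mean(rowSums((Yc - Xc %*% t(R))^2)))
}

#' Mean RMSD between sampled fragment pairs of two words
#'
#' The structural distance between two words is measured by the average
#' (and standard deviation) of the superposition RMSD over `nPairs`
#' fragment pairs sampled from the cross product of the two words'
#' fragment sets — without replacement when enough distinct pairs exist,
#' with replacement otherwise.  Reproducible given `seed`; the caller's
#' RNG stream is left untouched.
#'
#' @param fragsA,fragsB non-empty lists of n x 3 coordinate matrices
#'   (all fragments the same length).
#' @param nPairs number of sampled cross pairs (default 30).
#' @param seed integer seed for the pair sampling.
#' @return named numeric vector `c(mean, sd)` in Angstrom, with the
#'   sampled per-pair RMSDs attached as attribute `rmsds`.
#' @export
wordPairRMSD <- function(fragsA, fragsB, nPairs = 30L, seed = 1L) {
  stopifnot(length(fragsA) >= 1L, length(fragsB) >= 1L, nPairs >= 1L)
  nA <- length(fragsA)
  nB <- length(fragsB)
  total <- nA * nB
  pairIdx <- .withSeed(seed, {
    if (total >= nPairs) sample.int(total, nPairs, replace = FALSE)
    else sample.int(total, nPairs, replace = TRUE)
  })
  i <- ((pairIdx - 1L) %% nA) + 1L
  j <- ((pairIdx - 1L) %/% nA) + 1L
  r <- vapply(seq_along(pairIdx), function(k)
    kabschRMSD(fragsA[[i[k]]], fragsB[[j[k]]]), 0)
  out <- c(mean = mean(r), sd = if (length(r) > 1L) sd(r) else 0)
  attr(out, "rmsds") <- r
  out
}

#' Extract fragment coordinates for word occurrences
#'
#' Looks up, for each occurrence, the C-alpha coordinates of its residue
#' span in the matching trace (by protein, chain and residue number).
#' Occurrences whose span is not fully resolvable are dropped with a
#' warning.
#'
#' @param occurrences a word-occurrence table ([extractWords()]).
#' @param traces a list of [caTrace()] data.frames.
#' @return a list of (L + 3) x 3 coordinate matrices, one per resolved
#'   occurrence, named by occurrence row index.
#' @export
fragmentCoords <- function(occurrences, traces) {
  key <- vapply(traces, function(tr)
    paste(tr$protein_id[1L], tr$chain_id[1L], sep = "\r"), "")
  out <- list()
  dropped <- 0L
  for (r in seq_len(nrow(occurrences))) {
    k <- paste(occurrences$protein_id[r], occurrences$chain_id[r], sep = "\r")
    tr <- traces[[match(k, key)]]
    if (is.null(tr)) { dropped <- dropped + 1L; next }
    rows <- match(occurrences$residue_start[r]:occurrences$residue_end[r],
                  tr$resno)
    if (anyNA(rows)) { dropped <- dropped + 1L; next }
    out[[as.character(r)]] <- .traceCoords(tr)[rows, , drop = FALSE]
  }
  if (dropped > 0L)
    warning(sprintf("%d occurrence(s) could not be mapped to coordinates", dropped))
  out
}

#' @importFrom stats sd
NULL
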