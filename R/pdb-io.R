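#' Read C-alpha traces from a PDB file
#'
#' Parses `ATOM` records (via `bio3d`), keeps C-alpha atoms with blank or
#' `'A'` alternate-location indicator, and returns one [caTrace()] per
#' chain.  Insertion codes are preserved in the `ins` column and
#' participate in chain-break detection only through the coordinates.
#'
#' @param file path to a PDB-format file.
#' @param protein_id identifier stored on the traces; defaults to the file
#'   name without extension.
#' @return a named list of `CaTrace` data.frames, one per chain.
#' @export
readCaTraces <- function(file, protein_id = NULL) {
  if (is.null(protein_id))
    protein_id <- sub("\\.(pdb|ent)(\\.gz)?$", "", basename(file))
  pdb <- bio3d::read.pdb(file, verbose = FALSE)
  at <- pdb$atom
  keep <- at$type == "ATOM" & at$elety == "CA" &
    (is.na(at$alt) | at$alt %in% c("", "A"))
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0L) stop("no C-alpha ATOM records in ", file)
  chains <- unique(at$chain)
  out <- lapply(chains, function(ch) {
    a <- at[at$chain == ch, , drop = FALSE]
    ins <- ifelse(is.na(a$insert), "", a$insert)
    caTrace(cbind(a$x, a$y, a$z), protein_id = protein_id,
            chain_id = ch, resno = a$resno, ins = ins)
  })
  names(out) <- chains
  out
}

#' Write a C-alpha trace as minimal PDB ATOM records
#'
#' Emits one `ATOM` record per residue (atom name `CA`, residue `GLY`).
#' Mainly used to materialise synthetic backbones for tools that consume
#' PDB files, and to round-trip traces in tests.
#'
#' @param trace a [caTrace()] data.frame.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeCaPDB <- function(trace, file) {
  lines <- sprintf(
    "ATOM  %5d  CA  GLY %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(trace)), substr(trace$chain_id, 1, 1), trace$resno,
    ifelse(trace$ins == "", " ", trace$ins), trace$x, trace$y, trace$z)
  writeLines(c(lines, "END"), file)
  invisible(file)
}

#' Read and write structural-alphabet model files
#'
#' Alphabet models are stored as structured text (JSON, or YAML when the
#' file extension is `.yml`/`.yaml`) with fields `letters`, `means`,
#' `covariances`, `transition`, `initial` and `classes`.  JSON files are
#' written at full double precision so a write/read cycle is bit-stable.
#'
#' @param model an [AlphabetModel-class].
#' @param file path to the model file.
#' @return `readAlphabet` returns an [AlphabetModel-class];
#'   `writeAlphabet` returns `file` invisibly.
#' @examples
#' \dontrun{
#' writeAlphabet(model, "alphabet.json")
#' model2 <- readAlphabet("alphabet.json")
#' }
#' @export
writeAlphabet <- function(model, file) {
  validObject(model)
  K <- length(model@letters)
  obj <- list(
    letters = model@letters,
    means = unname(asplit(model@emissionMean, 1L)),
    covariances = lapply(seq_len(K), function(k)
      unname(asplit(model@emissionCov[, , k], 1L))),
    transition = unname(asplit(model@transition, 1L)),
    initial = unname(model@initial),
    classes = unname(model@letterClass)
  )
  if (grepl("\\.ya?ml$", file)) {
    yaml::write_yaml(obj, file, precision = 17L)
  } else {
    # 17 significant digits round-trip IEEE doubles exactly
    jsonlite::write_json(obj, file, digits = I(17), auto_unbox = FALSE,
                         pretty = TRUE)
  }
  invisible(file)
}

#' @rdname writeAlphabet
#' @export
readAlphabet <- function(file) {
  obj <- if (grepl("\\.ya?ml$", file)) yaml::read_yaml(file)
         else jsonlite::read_json(file, simplifyVector = TRUE)
  lets <- as.character(obj$letters)
  K <- length(lets)
  toMat <- function(x, nr, nc) {
    if (is.matrix(x)) return(matrix(as.numeric(x), nr, nc, byrow = FALSE))
    matrix(as.numeric(unlist(x)), nr, nc, byrow = TRUE)
  }
  means <- toMat(obj$means, K, 4L)
  covs <- array(0, c(4L, 4L, K))
  cv <- obj$covariances
  for (k in seq_len(K)) {
    covs[, , k] <- if (is.array(cv) && length(dim(cv)) == 3L)
      matrix(as.numeric(cv[k, , ]), 4L, 4L)   # simplified K x 4 x 4 array
    else toMat(cv[[k]], 4L, 4L)
  }
  classes <- if (!is.null(obj$classes)) as.character(obj$classes)
             else rep("loop", K)
  AlphabetModel(lets, means, covs, toMat(obj$transition, K, K),
                as.numeric(obj$initial), classes)
}
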