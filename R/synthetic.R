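# Synthetic-data generators: idealised backbones, planted structural
# alphabets, letter corpora with controlled group-specific word
# enrichment and co-located annotations.  Every generator is a pure
# function of its arguments and seed.

.idealHelixCoords <- function(n, radius = 2.3, rise = 1.5, twist = 100) {
  ang <- (seq_len(n) - 1L) * twist * pi / 180
  cbind(radius * cos(ang), radius * sin(ang), rise * (seq_len(n) - 1L))
}

.idealStrandCoords <- function(n, rise = 3.4) {
  # zigzag in the xy plane with exact 3.8 A steps
  half <- sqrt(3.8^2 - rise^2) / 2
  cbind(rise * (seq_len(n) - 1L), half * (-1)^(seq_len(n) - 1L), 0)
}

.randomUnit <- function() {
  repeat {
    v <- rnorm(3L)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

.selfAvoidingWalk <- function(n, start, step = 3.8, minSep = 3.5,
                              tries = 50L) {
  pts <- matrix(0, n, 3L)
  pts[1L, ] <- start
  for (i in seq_len(n - 1L)) {
    best <- NULL
    bestMin <- -Inf
    for (k in seq_len(tries)) {
      cand <- pts[i, ] + step * .randomUnit()
      dmin <- if (i >= 2L)
        min(sqrt(rowSums((pts[seq_len(i - 1L), , drop = FALSE] -
                            rep(cand, each = i - 1L))^2)))
      else Inf
      if (dmin >= minSep) { best <- cand; break }
      if (dmin > bestMin) { bestMin <- dmin; best <- cand }
    }
    pts[i + 1L, ] <- best
  }
  pts
}

.randomRotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  qr_ <- qr(matrix(rnorm(9L), 3L))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

#' Generate a synthetic C-alpha backbone
#'
#' Concatenates idealised secondary-structure segments: an alpha-helix
#' (radius 2.3 A, rise 1.5 A/residue, 100 degrees/residue), an extended
#' strand (zigzag with 3.4 A rise and exact 3.8 A C-alpha steps), and
#' loops as self-avoiding random walks with 3.8 A steps.  Segments are
#' joined with a 3.8 A step in a random (seeded) direction and random
#' orientation, then i.i.d. Gaussian noise of standard deviation
#' `noise_sd` is added to every coordinate.
#'
#' @param segments a data.frame with columns `kind` (`"helix"`,
#'   `"strand"` or `"loop"`) and `length` (residues, >= 1), or a list of
#'   `list(kind, length)` pairs.
#' @param noise_sd coordinate noise (Angstrom, default 0).
#' @param seed integer seed; the caller's RNG stream is left untouched.
#' @param protein_id,chain_id identifiers for the returned trace.
#' @return a [caTrace()] data.frame of the concatenated backbone.
#' @examples
#' tr <- generateBackbone(data.frame(kind = "helix", length = 12))
#' computeDescriptors(tr)  # identical descriptors along the helix
#' @export
generateBackbone <- function(segments, noise_sd = 0, seed = 1L,
                             protein_id = "synthetic", chain_id = "A") {
  if (is.data.frame(segments))
    segments <- lapply(seq_len(nrow(segments)), function(i)
      list(kind = segments$kind[i], length = segments$length[i]))
  stopifnot(length(segments) >= 1L,
            all(vapply(segments, function(s) s$length >= 1L, TRUE)))
  coords <- .withSeed(seed, {
    pts <- NULL
    for (s in segments) {
      n <- as.integer(s$length)
      start <- if (is.null(pts)) c(0, 0, 0) else pts[nrow(pts), ] + 3.8 * .randomUnit()
      seg <- switch(as.character(s$kind),
        helix = .idealHelixCoords(n),
        strand = .idealStrandCoords(n),
        loop = .selfAvoidingWalk(n, c(0, 0, 0)),
        stop("unknown segment kind: ", s$kind))
      seg <- sweep(seg, 2L, seg[1L, ])          # local origin
      if (!is.null(pts)) seg <- seg %*% .randomRotation()
      seg <- sweep(seg, 2L, start, "+")
      pts <- rbind(pts, seg)
    }
    if (noise_sd > 0) pts <- pts + rnorm(length(pts), sd = noise_sd)
    pts
  })
  caTrace(coords, protein_id = protein_id, chain_id = chain_id)
}

#' Reference descriptors of ideal secondary structures
#'
#' The 4-D fragment descriptor of an ideal alpha-helix or extended
#' strand, as produced by [generateBackbone()] without noise.  Used as
#' the default references of [assignLetterClasses()].
#'
#' @return named length-4 numeric vector (`d13`, `d14`, `d24`, `h`).
#' @export
helixReferenceDescriptor <- function() {
  d <- computeDescriptors(caTrace(.idealHelixCoords(4L)))
  c(d13 = d$d13, d14 = d$d14, d24 = d$d24, h = d$h)
}

#' @rdname helixReferenceDescriptor
#' @export
strandReferenceDescriptor <- function() {
  d <- computeDescriptors(caTrace(.idealStrandCoords(4L)))
  c(d13 = d$d13, d14 = d$d14, d24 = d$d24, h = d$h)
}

#' Generate a planted structural alphabet
#'
#' Builds an [AlphabetModel-class] with well-separated Gaussian emission
#' prototypes and generator-assigned letter classes: helix and strand
#' letters get the ideal reference descriptors as means, loop letters
#' get means drawn (seeded, with rejection) so every pair of letters is
#' at least `separation` times the maximal marginal standard deviation
#' apart.  Transitions are random sparse row-stochastic draws with a
#' guaranteed floor so every letter remains reachable.
#'
#' @param K number of letters (>= 2).
#' @param separation minimal pairwise mean distance in units of the
#'   maximal marginal standard deviation (default 4).
#' @param seed integer seed.
#' @param nHelix,nStrand number of helix/strand letters (defaults scale
#'   with `K` like the 4/27 and 5/27 proportions of the 27-letter
#'   alphabet).
#' @param sdEmission marginal emission standard deviation (default 0.3).
#' @return an [AlphabetModel-class] with classes set by construction.
#' @export
generateAlphabet <- function(K, separation = 4, seed = 1L,
                             nHelix = max(1L, round(K * 4 / 27)),
                             nStrand = max(1L, round(K * 5 / 27)),
                             sdEmission = 0.3) {
  stopifnot(K >= 2L, nHelix + nStrand < K)
  .withSeed(seed, {
    minDist <- separation * sdEmission
    means <- rbind(
      matrix(rep(helixReferenceDescriptor(), nHelix), nHelix, byrow = TRUE),
      matrix(rep(strandReferenceDescriptor(), nStrand), nStrand, byrow = TRUE))
    # spread same-class letters slightly so they stay distinct
    if (nrow(means) > 1L)
      means <- means + matrix(rnorm(length(means), sd = minDist / 6),
                              nrow(means))
    while (nrow(means) < K) {
      cand <- c(runif(3L, 4, 11), runif(1L, -4, 4))
      d <- sqrt(rowSums(sweep(means, 2L, cand)^2))
      if (min(d) >= minDist) means <- rbind(means, cand)
    }
    covs <- array(diag(sdEmission^2, 4L), c(4L, 4L, K))
    trans <- matrix(rgamma(K * K, shape = 0.5) + 0.02, K, K)
    trans <- trans / rowSums(trans)
    classes <- c(rep("helix", nHelix), rep("strand", nStrand),
                 rep("loop", K - nHelix - nStrand))
    AlphabetModel(.defaultLetterNames(K), means, covs, trans,
                  rep(1 / K, K), classes)
  })
}

#' Specification of a synthetic loop corpus
#'
#' Collects the study conditions for [sampleCorpus()]: the number of
#' groups and loops per group, the loop-length distribution, the
#' background Markov model the loops are drawn from, the planted words
#' (with their target group and enrichment factor) and the annotation
#' rate of planted words.
#'
#' @param nGroups number of groups (default 20).
#' @param loopsPerGroup loops per group (default 150).
#' @param loopLengthSampler function(n) returning n loop lengths in
#'   letters; the default, `1 + rnbinom(n, size = 2, mu = 5)`, gives a
#'   mean of about 6 letters (9 residues) with many loops shorter than
#'   one word, mirroring the short-loop-dominated length profile of
#'   real loop corpora.
#' @param background a [MarkovBackground-class] over the loop letters;
#'   default: order-1 model with Dirichlet(0.6) rows over 8 letters.
#' @param plants data.frame with columns `word`, `group` (a group label,
#'   or `"ALL"`) and `factor` (enrichment factor >= 1); may be empty.
#' @param annotationRate probability q that an occurrence of a planted
#'   word is annotated (default 0.5).
#' @param featureKey feature key written on generated annotations.
#' @param seed integer seed.
#' @return a list of class `"CorpusSpec"`.
#' @export
corpusSpec <- function(nGroups = 20L, loopsPerGroup = 150L,
                       loopLengthSampler = function(n)
                         1L + rnbinom(n, size = 2, mu = 5),
                       background = NULL,
                       plants = data.frame(word = character(0),
                                           group = character(0),
                                           factor = numeric(0)),
                       annotationRate = 0.5, featureKey = "Binding",
                       seed = 1L) {
  if (is.null(background))
    background <- randomBackground(LETTERS[2:9], seed = seed)
  stopifnot(nGroups >= 1L, loopsPerGroup >= 1L,
            all(plants$factor >= 1), annotationRate >= 0, annotationRate <= 1)
  structure(list(nGroups = as.integer(nGroups),
                 loopsPerGroup = as.integer(loopsPerGroup),
                 loopLengthSampler = loopLengthSampler,
                 background = background, plants = plants,
                 annotationRate = annotationRate, featureKey = featureKey,
                 seed = as.integer(seed)),
            class = "CorpusSpec")
}

#' Random Markov background
#'
#' Order-0 or order-1 background with Dirichlet-distributed rows
#' (concentration `conc`), reproducible given `seed`.
#'
#' @param letters the alphabet.
#' @param order 0 or 1 (default 1).
#' @param conc Dirichlet concentration per entry (default 0.6; smaller
#'   values give more skewed letter preferences).
#' @param seed integer seed.
#' @return a [MarkovBackground-class].
#' @export
randomBackground <- function(letters, order = 1L, conc = 0.6, seed = 1L) {
  K <- length(letters)
  .withSeed(seed, {
    rows <- if (order == 0L) 1L else K
    tr <- matrix(rgamma(rows * K, shape = conc) + 1e-6, rows, K)
    tr <- tr / rowSums(tr)
    init <- rgamma(K, shape = conc) + 1e-6
    MarkovBackground(letters, tr, initial = init / sum(init), order = order)
  })
}

#' Sample a grouped loop corpus with planted words
#'
#' Draws loop letter sequences from the background, assigns them to
#' groups, and injects occurrences of each planted word so that the
#' in-group occurrence rate is about `factor` times the background
#' expectation: the number of extra occurrences is Poisson with mean
#' `(factor - 1) * E`, where `E` is the exact background expectation of
#' the word's count in the group, and each injection overwrites a
#' random window of a distinct loop (loop lengths are preserved).
#' Every occurrence of a planted word in the final corpus (injected or
#' arising from the background) is then annotated with probability
#' `annotationRate`, the annotation interval being its residue span.
#'
#' Each loop is carried by its own pseudo-protein (`P00001`, ... chain
#' `A`) with residues numbered from 1, so annotation and coverage
#' machinery apply unchanged.
#'
#' @param spec a [corpusSpec()] object.
#' @return a list with components `loops` (a loop table as produced by
#'   [extractLoops()]), `groups` (data.frame `loop_id`, `group_id`),
#'   `annotations` (annotation records) and `truth` (one row per
#'   (plant, group): `word`, `group_id`, `factor`, `expected_bg`,
#'   `n_injected`, `q`).
#' @export
sampleCorpus <- function(spec) {
  stopifnot(inherits(spec, "CorpusSpec"))
  bg <- spec$background
  plantWords <- unique(spec$plants$word)
  for (w in plantWords)
    if (anyNA(match(strsplit(w, "")[[1]], bg@letters)))
      stop("planted word '", w, "' is incompatible with the corpus alphabet")
  .withSeed(spec$seed, {
    nLoops <- spec$nGroups * spec$loopsPerGroup
    lens <- pmax(1L, as.integer(spec$loopLengthSampler(nLoops)))
    seqs <- sampleFromBackground(bg, lens)
    groupId <- sprintf("G%02d", rep(seq_len(spec$nGroups),
                                    each = spec$loopsPerGroup))
    injected <- rep(FALSE, nLoops)
    truth <- list()
    for (r in seq_len(nrow(spec$plants))) {
      w <- spec$plants$word[r]
      f <- spec$plants$factor[r]
      Lw <- nchar(w)
      targets <- if (identical(spec$plants$group[r], "ALL"))
        unique(groupId) else spec$plants$group[r]
      for (tg in targets) {
        inG <- which(groupId == tg)
        E <- expectedCount(lens[inG], w, bg)
        nInj <- if (f > 1) rpois(1L, (f - 1) * E) else 0L
        eligible <- inG[lens[inG] >= Lw & !injected[inG]]
        nInj <- min(nInj, length(eligible))
        if (nInj > 0L) {
          pick <- if (length(eligible) == 1L) eligible
                  else sample(eligible, nInj)
          for (i in pick) {
            pos <- sample.int(lens[i] - Lw + 1L, 1L)
            substr(seqs[i], pos, pos + Lw - 1L) <- w
          }
          injected[pick] <- TRUE
        }
        truth[[length(truth) + 1L]] <- data.frame(
          word = w, group_id = tg, factor = f, expected_bg = E,
          n_injected = nInj, q = spec$annotationRate,
          stringsAsFactors = FALSE)
      }
    }
    loops <- data.frame(loop_id = seq_len(nLoops),
                        protein_id = sprintf("P%05d", seq_len(nLoops)),
                        chain_id = "A", segment = 1L, letters = seqs,
                        start_letter = 1L, residue_start = 1L,
                        residue_end = lens + 3L, stringsAsFactors = FALSE)
    annotations <- list()
    for (w in plantWords) {
      Lw <- nchar(w)
      for (i in seq_len(nLoops)) {
        m <- gregexpr(paste0("(?=\\Q", w, "\\E)"), seqs[i], perl = TRUE)[[1]]
        if (m[1L] == -1L) next
        for (pos in as.integer(m)) {
          if (runif(1L) <= spec$annotationRate) {
            annotations[[length(annotations) + 1L]] <- data.frame(
              protein_id = loops$protein_id[i], chain_id = "A",
              residue_start = pos, residue_end = pos + Lw + 2L,
              feature_key = spec$featureKey,
              description = paste("SITE", w), stringsAsFactors = FALSE)
          }
        }
      }
    }
    annotations <- if (length(annotations))
      do.call(rbind, c(annotations, list(make.row.names = FALSE)))
    else data.frame(protein_id = character(0), chain_id = character(0),
                    residue_start = integer(0), residue_end = integer(0),
                    feature_key = character(0), description = character(0))
    list(loops = loops,
         groups = data.frame(loop_id = loops$loop_id, group_id = groupId,
                             stringsAsFactors = FALSE),
         annotations = annotations,
         truth = if (length(truth))
           do.call(rbind, c(truth, list(make.row.names = FALSE)))
         else data.frame(word = character(0), group_id = character(0),
                         factor = numeric(0), expected_bg = numeric(0),
                         n_injected = integer(0), q = numeric(0)))
  })
}

#' Shuffle loop-to-group labels
#'
#' Uniform random permutation of the group labels over loops: the label
#' multiset is preserved exactly.  Used as the randomised control that
#' collapses group-specific over-representation.
#'
#' @param groups data.frame with columns `loop_id` and `group_id` (or a
#'   vector of labels).
#' @param seed integer seed.
#' @return the same structure with permuted labels.
#' @export
shuffleGroupLabels <- function(groups, seed = 1L) {
  .withSeed(seed, {
    if (is.data.frame(groups)) {
      groups$group_id <- sample(groups$group_id)
      groups
    } else {
      out <- sample(unname(groups))
      names(out) <- names(groups)
      out
    }
  })
}

#' Most and mid-probability words under a background
#'
#' Enumerates all words of length `L` over the background alphabet and
#' returns them ordered by their expected start-position probability
#' (stationary single-window probability).  Convenient for choosing
#' plant words whose background expectation has a desired magnitude.
#'
#' @param bg a [MarkovBackground-class].
#' @param L word length (default 4).
#' @param n number of top words to return (default all).
#' @return data.frame `word`, `prob`, ordered by decreasing probability.
#' @export
rankWordsByProbability <- function(bg, L = 4L, n = NULL) {
  K <- length(bg@letters)
  grid <- do.call(expand.grid, rep(list(seq_len(K)), L))
  trans <- if (bg@order == 0L)
    matrix(bg@transition[1L, ], K, K, byrow = TRUE) else bg@transition
  # stationary marginal of the chain
  ev <- Re(eigen(t(trans))$vectors[, 1L])
  statn <- abs(ev) / sum(abs(ev))
  p <- statn[grid[, 1L]]
  for (j in 2:L) p <- p * trans[cbind(grid[, j - 1L], grid[, j])]
  word <- do.call(paste0, lapply(grid, function(col) bg@letters[col]))
  out <- data.frame(word = word, prob = p, stringsAsFactors = FALSE)
  out <- out[order(-out$prob), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(n)) head(out, n) else out
}
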