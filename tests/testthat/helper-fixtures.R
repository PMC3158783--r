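# Shared fixtures and independent oracles used across the test files.

# Letter classes of the canonical 27-letter structural alphabet:
# helix {A, a, W, V}, strand {L, M, N, T, X}, the rest loop.
hmmsaClasses <- function() {
  lets <- c("a", LETTERS)
  cls <- rep("loop", 27L)
  names(cls) <- lets
  cls[c("A", "a", "W", "V")] <- "helix"
  cls[c("L", "M", "N", "T", "X")] <- "strand"
  cls
}

# A valid alphabet model whose only meaningful content is its classes.
classOnlyModel <- function(classes = hmmsaClasses()) {
  K <- length(classes)
  means <- cbind(seq(4, 10, length.out = K), seq(5, 11, length.out = K),
                 seq(4, 10, length.out = K), seq(-3, 3, length.out = K))
  AlphabetModel(names(classes), means, array(diag(4), c(4, 4, K)),
                matrix(1 / K, K, K), rep(1 / K, K), unname(classes))
}

# Random small Gaussian-emission HMM for Viterbi cross-checks.
randomToyModel <- function(K) {
  means <- matrix(runif(K * 4, 3, 10), K)
  covs <- array(0, c(4, 4, K))
  for (k in seq_len(K)) covs[, , k] <- diag(runif(4, 0.2, 1))
  tr <- matrix(rgamma(K * K, 1), K)
  ini <- rgamma(K, 1)
  AlphabetModel(LETTERS[seq_len(K)], means, covs, tr / rowSums(tr),
                ini / sum(ini))
}

# Joint log probability of a letter path given descriptors and a model.
pathLogProb <- function(X, model, path) {
  p <- match(strsplit(path, "")[[1]], alphabetLetters(model))
  K <- alphabetSize(model)
  logB <- vapply(seq_len(K), function(k)
    loopmotifs:::.mvnLogDensity(X, emissionMeans(model)[k, ],
                                emissionCovs(model)[, , k]),
    numeric(nrow(X)))
  if (nrow(X) == 1L) logB <- matrix(logB, 1L)
  s <- log(initialProbs(model)[p[1L]]) + logB[1L, p[1L]]
  if (nrow(X) > 1L) for (t in 2:nrow(X))
    s <- s + log(transitionMatrix(model)[p[t - 1L], p[t]]) + logB[t, p[t]]
  unname(s)
}

# Best path log probability by exhaustive enumeration over K^n paths
# (vectorised over the path grid; independent of the Viterbi recursion).
bruteBestPathLogProb <- function(X, model) {
  K <- alphabetSize(model)
  n <- nrow(X)
  logB <- vapply(seq_len(K), function(k)
    loopmotifs:::.mvnLogDensity(X, emissionMeans(model)[k, ],
                                emissionCovs(model)[, , k]),
    numeric(n))
  if (n == 1L) logB <- matrix(logB, 1L)
  logA <- log(transitionMatrix(model))
  paths <- as.matrix(do.call(expand.grid, rep(list(seq_len(K)), n)))
  sc <- log(initialProbs(model))[paths[, 1L]] + logB[1L, paths[, 1L]]
  if (n > 1L) for (t in 2:n)
    sc <- sc + logA[cbind(paths[, t - 1L], paths[, t])] +
      logB[t, paths[, t]]
  max(sc)
}

# Exact count distribution by exhaustive enumeration: every sequence of
# each length is enumerated with its probability, per-sequence count
# distributions are convolved exactly (no cap) and the result is capped
# only at the end.  Independent of the DFA/DP implementation.
enumCountDist <- function(lens, word, bg, cap) {
  K <- alphabetSize(bg)
  lets <- alphabetLetters(bg)
  tr <- transitionMatrix(bg)
  if (backgroundOrder(bg) == 0L)
    tr <- matrix(tr[1L, ], K, K, byrow = TRUE)
  perSeq <- lapply(lens, function(L) {
    grid <- do.call(expand.grid, rep(list(seq_len(K)), L))
    pr <- initialProbs(bg)[grid[, 1L]]
    if (L > 1L) for (t in 2:L)
      pr <- pr * tr[cbind(grid[, t - 1L], grid[, t])]
    ss <- do.call(paste0, lapply(grid, function(col) lets[col]))
    # naive overlapping substring count
    Lw <- nchar(word)
    cnt <- vapply(ss, function(s) {
      n <- nchar(s) - Lw + 1L
      if (n < 1L) return(0L)
      sum(vapply(seq_len(n), function(t) substr(s, t, t + Lw - 1L) == word,
                 TRUE))
    }, 0L, USE.NAMES = FALSE)
    tapply(pr, cnt, sum)
  })
  full <- 1
  for (d in perSeq) {
    v <- numeric(max(as.integer(names(d))) + 1L)
    v[as.integer(names(d)) + 1L] <- d
    res <- numeric(length(full) + length(v) - 1L)
    for (j in seq_along(v))
      res[j:(j + length(full) - 1L)] <- res[j:(j + length(full) - 1L)] +
        full * v[j]
    full <- res
  }
  out <- numeric(cap + 1L)
  m <- min(cap, length(full) - 1L)
  out[seq_len(m + 1L) - 1L + 1L] <- full[seq_len(m + 1L)]
  if (length(full) - 1L > cap) out[cap + 1L] <- sum(full[(cap + 1L):length(full)])
  out
}

# Descriptor sequences sampled from a planted Gaussian-emission HMM.
sampleHMMDescriptors <- function(model, nSeq, len, sdNoise = 0.4) {
  K <- alphabetSize(model)
  lapply(seq_len(nSeq), function(i) {
    s <- integer(len)
    s[1L] <- sample.int(K, 1L, prob = initialProbs(model))
    if (len > 1L) for (t in 2:len)
      s[t] <- sample.int(K, 1L, prob = transitionMatrix(model)[s[t - 1L], ])
    emissionMeans(model)[s, , drop = FALSE] +
      matrix(rnorm(len * 4L, sd = sdNoise), len)
  })
}

# Planted 3-state model reused by the training-recovery tests.
plantedThreeStateModel <- function() {
  AlphabetModel(c("A", "B", "C"),
                rbind(c(5, 5, 5, 2), c(8, 9, 8, -2), c(6, 11, 6, 0)),
                array(diag(0.16, 4L), c(4L, 4L, 3L)),
                rbind(c(.7, .2, .1), c(.15, .7, .15), c(.1, .3, .6)),
                c(1, 1, 1) / 3)
}

# Match fitted states to planted states by nearest emission means.
matchStates <- function(truth, fit) {
  K <- alphabetSize(truth)
  D <- as.matrix(dist(rbind(emissionMeans(truth), emissionMeans(fit))))
  apply(D[seq_len(K), K + seq_len(K), drop = FALSE], 1L, which.min)
}

# The planted-corpus design shared by the enrichment recovery tests and
# the acceptance script: an 8-letter order-1 background, one word planted
# at 10x in one group, one word planted at 3x in ten groups, two further
# specific plants.  Plant words are chosen from the background alone:
# words with four distinct letters (so occurrences do not clump), the
# ubiquitous plant the most probable such word, the specific plants those
# whose expected per-group count is closest to 1.5.
plantedCorpusDesign <- function(seed) {
  bg <- randomBackground(LETTERS[2:9], order = 1L, conc = 0.3,
                         seed = 42L)
  rk <- rankWordsByProbability(bg, 4L)
  distinct <- vapply(rk$word, function(w)
    length(unique(strsplit(w, "")[[1]])) == 4L, TRUE)
  rkd <- rk[distinct, , drop = FALSE]
  positions <- 500 * 3.25   # loops per group x mean word positions per loop
  ubiqWord <- rkd$word[1L]
  ordSpec <- order(abs(rkd$prob - 1.5 / positions))
  specWords <- setdiff(rkd$word[ordSpec], ubiqWord)[1:3]
  plants <- data.frame(
    word = c(specWords, rep(ubiqWord, 10L)),
    group = c("G01", "G03", "G05", sprintf("G%02d", 11:20)),
    factor = c(10, 10, 10, rep(3, 10L)),
    stringsAsFactors = FALSE)
  spec <- corpusSpec(nGroups = 20L, loopsPerGroup = 500L, background = bg,
                     plants = plants, seed = seed)
  list(spec = spec, bg = bg, ubiqWord = ubiqWord, specWords = specWords)
}
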