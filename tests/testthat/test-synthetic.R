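test_that("noise-free helices are perfectly regular with constant chirality", {
  tr <- generateBackbone(data.frame(kind = "helix", length = 12))
  xyz <- as.matrix(tr[, c("x", "y", "z")])
  steps <- sqrt(rowSums(diff(xyz)^2))
  expect_lt(max(steps) - min(steps), 1e-6)
  expect_lt(abs(mean(steps) - 3.8), 0.1)
  d <- computeDescriptors(tr)
  expect_lt(max(apply(d[, c("d13", "d14", "d24", "h")], 2, sd)), 1e-9)
  expect_true(all(d$h > 0) || all(d$h < 0))
})

test_that("backbone generation is a pure function of its seed", {
  segs <- data.frame(kind = c("helix", "loop", "strand"), length = c(6, 8, 5))
  t1 <- generateBackbone(segs, noise_sd = 0.1, seed = 61)
  t2 <- generateBackbone(segs, noise_sd = 0.1, seed = 61)
  expect_identical(t1, t2)
  t3 <- generateBackbone(segs, noise_sd = 0.1, seed = 62)
  expect_false(identical(t1, t3))
  # noise respects the consecutive-distance envelope
  xyz <- as.matrix(t1[, c("x", "y", "z")])
  expect_lt(max(abs(sqrt(rowSums(diff(xyz)^2)) - 3.8)), 3 * 0.1 + 0.1)
})

test_that("planted alphabets are valid, reproducible, and recoverable by training", {
  m1 <- generateAlphabet(8, seed = 63)
  m2 <- generateAlphabet(8, seed = 63)
  expect_identical(emissionMeans(m1), emissionMeans(m2))
  expect_false(anyDuplicated(alphabetLetters(m1)) > 0)
  expect_equal(unname(rowSums(transitionMatrix(m1))), rep(1, 8),
               tolerance = 1e-9)
  expect_true(all(c("helix", "strand", "loop") %in% letterClasses(m1)))

  # a 3-letter planted alphabet is recovered from sampled descriptors
  set.seed(64)
  truth <- plantedThreeStateModel()
  corpus <- sampleHMMDescriptors(truth, 400, 40)
  fit <- trainAlphabet(corpus, 3, seed = 5, restarts = 2)
  perm <- matchStates(truth, fit)
  expect_lt(max(abs(transitionMatrix(fit)[perm, perm] -
                      transitionMatrix(truth))), 0.05)
})

test_that("unplanted corpora match the background expectation", {
  bg <- randomBackground(LETTERS[2:9], conc = 0.3, seed = 42)
  rk <- rankWordsByProbability(bg, 4, n = 40)
  corp <- sampleCorpus(corpusSpec(nGroups = 5, loopsPerGroup = 300,
                                  background = bg, seed = 65))
  lens <- nchar(corp$loops$letters)
  for (w in rk$word[c(1, 5, 20)]) {
    E <- expectedCount(lens, w, bg)
    N <- sum(countOccurrences(corp$loops$letters, w))
    # Poisson-scale tolerance (clumping inflates the variance a little)
    expect_lt(abs(N - E), 4 * sqrt(E) + 5)
  }
  # letter frequencies match the marginal distribution propagated from
  # the initial letters (short loops have not mixed to stationarity)
  lets2 <- strsplit(paste(corp$loops$letters, collapse = ""), "")[[1]]
  freq <- table(factor(lets2, alphabetLetters(bg))) / length(lets2)
  tr <- transitionMatrix(bg)
  marg <- initialProbs(bg)
  expectedCounts <- 0
  for (t in seq_len(max(lens))) {
    expectedCounts <- expectedCounts + marg * sum(lens >= t)
    marg <- as.numeric(marg %*% tr)
  }
  expect_lt(max(abs(as.numeric(freq) -
                      expectedCounts / sum(expectedCounts))), 0.02)
})

test_that("planted corpora are seed-reproducible with truthful bookkeeping", {
  bg <- randomBackground(LETTERS[2:9], conc = 0.3, seed = 42)
  plants <- data.frame(word = "BCGF", group = "G02", factor = 8)
  spec <- corpusSpec(nGroups = 3, loopsPerGroup = 100, background = bg,
                     plants = plants, seed = 66)
  c1 <- sampleCorpus(spec)
  c2 <- sampleCorpus(spec)
  expect_identical(c1$loops$letters, c2$loops$letters)
  expect_identical(c1$annotations, c2$annotations)
  expect_equal(c1$truth$word, "BCGF")
  expect_equal(c1$truth$group_id, "G02")
  expect_gte(c1$truth$n_injected, 1)
  # injected occurrences really are in the corpus
  inG2 <- c1$loops$loop_id[c1$groups$group_id == "G02"]
  n <- sum(countOccurrences(c1$loops$letters[inG2], "BCGF"))
  expect_gte(n, c1$truth$n_injected)
  expect_error(sampleCorpus(corpusSpec(background = bg,
                                       plants = data.frame(word = "QQQQ",
                                                           group = "G01",
                                                           factor = 2))),
               "incompatible")
})

test_that("label shuffles preserve the group multiset and are seeded", {
  groups <- data.frame(loop_id = 1:50,
                       group_id = rep(c("G1", "G2", "G3"), c(20, 20, 10)))
  s1 <- shuffleGroupLabels(groups, seed = 67)
  s2 <- shuffleGroupLabels(groups, seed = 67)
  expect_identical(s1, s2)
  expect_equal(table(s1$group_id), table(groups$group_id))
  expect_false(all(s1$group_id == groups$group_id))
})
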