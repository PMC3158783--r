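test_that("model constructor enforces the validity contract", {
  m <- classOnlyModel()
  expect_s4_class(m, "AlphabetModel")
  expect_equal(alphabetSize(m), 27)
  expect_error(AlphabetModel(c("A", "A"),
                             matrix(1, 2, 4), array(diag(4), c(4, 4, 2)),
                             matrix(0.5, 2, 2), c(0.5, 0.5)),
               "unique")
  expect_error(AlphabetModel(c("A", "B"),
                             matrix(1, 2, 4), array(diag(4), c(4, 4, 2)),
                             matrix(c(0.5, 0.5, 0.2, 0.7), 2, byrow = TRUE),
                             c(0.5, 0.5)),
               "sum to 1")
})

test_that("encoding yields n - 3 letters and one-step decoding is the MAP letter", {
  m <- generateAlphabet(8, seed = 21)
  tr <- generateBackbone(data.frame(kind = "loop", length = 10), seed = 22)
  seqs <- encodeStructure(tr, m)
  expect_equal(sum(nchar(seqs$letters)), 10 - 3)

  # single descriptor: the letter maximising initial x emission density
  x <- matrix(c(6, 7, 6, 1), 1)
  one <- encodeDescriptors(x, m)
  dens <- vapply(seq_len(alphabetSize(m)), function(k)
    log(initialProbs(m)[k]) +
      loopmotifs:::.mvnLogDensity(x, emissionMeans(m)[k, ],
                                  emissionCovs(m)[, , k]), 0)
  expect_equal(one, alphabetLetters(m)[which.max(dens)])
})

test_that("Viterbi equals exhaustive best-path enumeration on small instances", {
  set.seed(23)
  for (i in 1:25) {
    K <- sample(2:4, 1)
    n <- sample(1:5, 1)
    m <- randomToyModel(K)
    X <- matrix(runif(n * 4, 3, 10), n)
    v <- encodeDescriptors(X, m)
    expect_equal(pathLogProb(X, m, v), bruteBestPathLogProb(X, m),
                 tolerance = 1e-9)
  }
})

test_that("non-finite descriptors are rejected with the window identified", {
  m <- generateAlphabet(6, seed = 24)
  X <- matrix(5, 3, 4)
  X[2, 3] <- NA
  expect_error(encodeDescriptors(X, m), "window\\(s\\) 2")
})

test_that("single-letter training recovers the pooled closed form", {
  set.seed(25)
  corpus <- list(matrix(rnorm(80, mean = 6), 20), matrix(rnorm(60, mean = 6), 15))
  reg <- 1e-6
  fit <- trainAlphabet(corpus, K = 1, seed = 1, restarts = 1, reg = reg)
  X <- do.call(rbind, corpus)
  expect_equal(unname(emissionMeans(fit)[1, ]), unname(colMeans(X)),
               tolerance = 1e-8)
  expect_equal(emissionCovs(fit)[, , 1],
               cov(X) * (nrow(X) - 1) / nrow(X) + diag(reg, 4),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(unname(transitionMatrix(fit)[1, 1]), 1)

  # BIC closed form at K = 1: -2 logL + 14 log N with the Gaussian MLE
  sel <- selectAlphabetSize(corpus, K_values = 1, seed = 1, restarts = 1,
                            reg = reg)
  expect_equal(sel$bestK, 1)
  ll <- sum(loopmotifs:::.mvnLogDensity(X, colMeans(X),
                                        cov(X) * (nrow(X) - 1) / nrow(X) +
                                          diag(reg, 4)))
  expect_equal(sel$table$BIC, -2 * ll + 14 * log(nrow(X)), tolerance = 1e-6)
})

test_that("training is deterministic given the seed and monotone in likelihood", {
  set.seed(26)
  truth <- plantedThreeStateModel()
  corpus <- sampleHMMDescriptors(truth, 60, 20)
  f1 <- trainAlphabet(corpus, 3, seed = 4, restarts = 2)
  f2 <- trainAlphabet(corpus, 3, seed = 4, restarts = 2)
  expect_identical(emissionMeans(f1), emissionMeans(f2))
  expect_identical(transitionMatrix(f1), transitionMatrix(f2))
  expect_true(all(diff(attr(f1, "logLikTrace")) > -1e-6))
})

test_that("letter classes follow the reference descriptors", {
  m <- generateAlphabet(10, seed = 27)
  relabelled <- assignLetterClasses(m)
  expect_gte(mean(letterClasses(relabelled) == letterClasses(m)), 0.9)

  # a letter whose mean equals the helix reference is classed helix,
  # one far from both references is classed loop
  means <- rbind(helixReferenceDescriptor(), c(9, 14, 9, -3))
  toy <- AlphabetModel(c("A", "B"), means, array(diag(0.09, 4), c(4, 4, 2)),
                       matrix(0.5, 2, 2), c(0.5, 0.5))
  toy <- assignLetterClasses(toy)
  expect_equal(unname(letterClasses(toy)), c("helix", "loop"))
})

test_that("alphabet model files round-trip bit-stably", {
  m <- generateAlphabet(6, seed = 28)
  f <- withr::local_tempfile(fileext = ".json")
  writeAlphabet(m, f)
  back <- readAlphabet(f)
  expect_identical(unname(emissionMeans(back)), unname(emissionMeans(m)))
  expect_identical(unname(emissionCovs(back)), unname(emissionCovs(m)))
  expect_identical(unname(transitionMatrix(back)), unname(transitionMatrix(m)))
  expect_identical(unname(initialProbs(back)), unname(initialProbs(m)))
  expect_identical(unname(letterClasses(back)), unname(letterClasses(m)))

  fy <- withr::local_tempfile(fileext = ".yaml")
  writeAlphabet(m, fy)
  backY <- readAlphabet(fy)
  expect_equal(unname(transitionMatrix(backY)), unname(transitionMatrix(m)),
               tolerance = 1e-12)
})
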