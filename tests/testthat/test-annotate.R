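mkOcc <- function(word, starts, protein = "p1", chain = "A") {
  L <- nchar(word)
  data.frame(word = word, protein_id = protein, chain_id = chain,
             loop_id = seq_along(starts), start_letter = 1L,
             residue_start = starts, residue_end = starts + L + 2L,
             stringsAsFactors = FALSE)
}
mkAnno <- function(start, end, key = "Binding", desc = "ATP/GTP",
                   protein = "p1", chain = "A") {
  data.frame(protein_id = protein, chain_id = chain,
             residue_start = start, residue_end = end,
             feature_key = key, description = desc, stringsAsFactors = FALSE)
}

test_that("fragment/annotation matching is interval intersection with min overlap", {
  occ <- mkOcc("WXYZ", 10)                      # residues 10-16
  expect_equal(fragmentMatches(occ, mkAnno(14, 20)), "Binding")
  expect_equal(length(fragmentMatches(occ, mkAnno(17, 20))), 0)
  expect_equal(length(fragmentMatches(occ, mkAnno(12, 14), minOverlap = 7)), 0)
  expect_equal(fragmentMatches(occ, mkAnno(10, 16), minOverlap = 7), "Binding")
  # different chain never matches
  expect_equal(length(fragmentMatches(occ, mkAnno(10, 16, chain = "B"))), 0)
  # description level is whitespace-normalised
  expect_equal(fragmentMatches(occ, mkAnno(12, 14, desc = "  ATP/GTP "),
                               level = "description"), "ATP/GTP")
})

test_that("precision is the annotated fraction of a word's fragments", {
  occ <- mkOcc("WXYZ", seq(1, by = 20, length.out = 10))
  anno <- do.call(rbind, lapply(occ$residue_start[1:4], function(s)
    mkAnno(s, s + 6)))
  expect_equal(wordPrecision("WXYZ", occ, anno, "Binding"), 0.4)
  expect_equal(wordPrecision("WXYZ", occ, anno[0, ], "Binding"), 0)
  annoAll <- do.call(rbind, lapply(occ$residue_start, function(s)
    mkAnno(s, s + 6)))
  expect_equal(wordPrecision("WXYZ", occ, annoAll, "Binding"), 1)
  expect_true(is.na(wordPrecision("ABCD", occ, anno, "Binding")))
})

test_that("sensitivity counts loop-located annotation instances covered by the word", {
  loops <- data.frame(loop_id = 1:20, protein_id = "p1", chain_id = "A",
                      letters = "BCDEFG",
                      residue_start = seq(1, by = 50, length.out = 20),
                      stringsAsFactors = FALSE)
  loops$residue_end <- loops$residue_start + 8
  # 20 annotation instances inside loops, 8 covered by the word
  anno <- do.call(rbind, lapply(loops$residue_start, function(s)
    mkAnno(s + 1, s + 4)))
  occ <- mkOcc("BCDE", loops$residue_start[1:8])
  expect_equal(wordSensitivity("BCDE", occ, anno, "Binding", loops = loops),
               0.4)
  # an annotation outside any loop is excluded from the denominator
  annoHelix <- rbind(anno, mkAnno(2000, 2004))
  expect_equal(wordSensitivity("BCDE", occ, annoHelix, "Binding",
                               loops = loops), 0.4)
  # a word with no occurrence has sensitivity 0
  expect_equal(wordSensitivity("ZZZZ", occ, anno, "Binding", loops = loops), 0)
  # no instance of the label in any loop: undefined
  expect_true(is.na(wordSensitivity("BCDE", occ,
                                    mkAnno(2000, 2004), "Binding",
                                    loops = loops)))
})

test_that("the functional gate requires extreme specificity and 40% precision", {
  summ <- data.frame(
    word = c("RUDO", "UGRU", "PZCD", "ZDOD"),
    Lp_max = c(55, 60, 26, 91), nb_sf_star = c(1, 1, 10, 1),
    nb_sf = c(4, 8, 211, 13),
    category = c("extreme_superfamily_specific",
                 "extreme_superfamily_specific",
                 "extreme_ubiquitous",
                 "extreme_superfamily_specific"),
    stringsAsFactors = FALSE)
  prec <- data.frame(word = c("RUDO", "UGRU", "PZCD"),
                     level = "feature",
                     label = c("Binding", "Binding", "Binding"),
                     n_fragments = c(10, 12, 10),
                     n_matched = c(5, 4, 9),
                     precision = c(0.50, 0.33, 0.90))
  out <- callFunctionalWords(summ, prec)
  expect_true(out$functional[out$word == "RUDO"])        # 50% precision
  expect_false(out$functional[out$word == "UGRU"])       # 33% precision
  expect_false(out$functional[out$word == "PZCD"])       # category gate
  expect_false(out$functional[out$word == "ZDOD"])       # no annotation
  expect_equal(out$category[out$word == "RUDO"], "functional")
  expect_equal(out$category[out$word == "PZCD"], "extreme_ubiquitous")
})

test_that("planted annotations recover the annotation rate within binomial error", {
  bg <- randomBackground(LETTERS[2:9], conc = 0.3, seed = 42)
  plants <- data.frame(word = "BCGF", group = "ALL", factor = 3)
  corp <- sampleCorpus(corpusSpec(nGroups = 4, loopsPerGroup = 200,
                                  background = bg, plants = plants,
                                  annotationRate = 0.5, seed = 8))
  occ <- extractWords(corp$loops)
  n <- sum(occ$word == "BCGF")
  pr <- wordPrecision("BCGF", occ, corp$annotations, "Binding")
  expect_gt(n, 20)
  expect_lt(abs(pr - 0.5), 3 * sqrt(0.25 / n) + 0.05)
})
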