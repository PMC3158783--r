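test_that("loops are maximal loop-class runs between regular secondary structures", {
  m <- classOnlyModel()
  loops <- extractLoops("AAAABDSPIAAAA", m)
  expect_equal(loops$letters, "BDSPI")
  expect_equal(loops$start_letter, 5)
  expect_equal(loops$residue_start, 5)
  expect_equal(loops$residue_end, 5 + 5 + 2)

  expect_equal(nrow(extractLoops("AAAAWWaa", m)), 0)

  all_ <- extractLoops("BDSPI", m)
  expect_equal(all_$letters, "BDSPI")
  expect_equal(all_$start_letter, 1)

  expect_error(extractLoops("AA0B", m), "not classed")
})

test_that("loop and non-loop runs reconstruct the parent sequence", {
  m <- classOnlyModel()
  set.seed(31)
  cls <- letterClasses(m)
  for (i in 1:20) {
    s <- paste(sample(names(cls), sample(5:40, 1), TRUE), collapse = "")
    loops <- extractLoops(s, m)
    # rebuild by writing loop letters back over a masked template
    mask <- strsplit(s, "")[[1]]
    isLoop <- cls[mask] == "loop"
    rebuilt <- mask
    rebuilt[isLoop] <- NA
    for (r in seq_len(nrow(loops))) {
      idx <- loops$start_letter[r] + seq_len(nchar(loops$letters[r])) - 1L
      rebuilt[idx] <- strsplit(loops$letters[r], "")[[1]]
    }
    expect_false(anyNA(rebuilt))
    expect_equal(paste(rebuilt, collapse = ""), s)
  }
})

test_that("loops split into overlapping words in order", {
  loops <- data.frame(loop_id = 1L, protein_id = "p", chain_id = "A",
                      letters = "SPBDRPI", residue_start = 1L)
  w <- extractWords(loops, L = 4)
  expect_equal(w$word, c("SPBD", "PBDR", "BDRP", "DRPI"))
  expect_equal(w$residue_start, 1:4)
  expect_equal(w$residue_end, 7:10)

  short <- data.frame(loop_id = 1L, protein_id = "p", chain_id = "A",
                      letters = "SPB", residue_start = 1L)
  expect_equal(nrow(extractWords(short, L = 4)), 0)
})

test_that("word counts equal the sliding-window enumeration over a random corpus", {
  set.seed(32)
  lets <- LETTERS[2:9]
  loops <- data.frame(loop_id = 1:50, protein_id = sprintf("p%02d", 1:50),
                      chain_id = "A",
                      letters = vapply(1:50, function(i)
                        paste(sample(lets, sample(1:12, 1), TRUE),
                              collapse = ""), ""),
                      residue_start = 1L)
  for (L in c(1, 4, 5)) {
    w <- extractWords(loops, L = L)
    expect_equal(nrow(w), sum(pmax(0, nchar(loops$letters) - L + 1)))
    # each reported word really sits where claimed
    ok <- vapply(seq_len(nrow(w)), function(r) {
      s <- loops$letters[loops$loop_id == w$loop_id[r]]
      substr(s, w$start_letter[r], w$start_letter[r] + L - 1) == w$word[r]
    }, TRUE)
    expect_true(all(ok))
  }
})

test_that("rare word types are filtered by corpus count", {
  occ <- data.frame(word = rep(c("AAAA", "BBBB"), c(4, 5)),
                    protein_id = "p", chain_id = "A", loop_id = 1L,
                    start_letter = 1L, residue_start = 1L, residue_end = 7L)
  kept <- filterWords(occ, min_count = 5)
  expect_equal(unique(kept$word), "BBBB")
  expect_equal(nrow(kept), 5)
  expect_equal(nrow(filterWords(occ, min_count = 1)), nrow(occ))
  expect_equal(as.integer(attr(kept, "wordCounts")["AAAA"]), 4)
})

test_that("letter sequences round-trip through FASTA-like records", {
  seqs <- data.frame(protein_id = c("1abc", "1abc", "2xyz_x"),
                     chain_id = c("A", "A", "B"), segment = c(1L, 2L, 1L),
                     letters = c("BDSPI", "QRST", "ZZZ"))
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLetterFasta(seqs, f)
  back <- readLetterFasta(f)
  expect_equal(back$protein_id, seqs$protein_id)
  expect_equal(back$chain_id, seqs$chain_id)
  expect_equal(back$segment, seqs$segment)
  expect_equal(back$letters, seqs$letters)
})
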