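test_that("background fitting matches forced and Laplace-smoothed MLEs", {
  bg <- fitBackground("ABAB", order = 1)
  expect_equal(transitionMatrix(bg)["A", "B"], 1)
  expect_equal(transitionMatrix(bg)["B", "A"], 1)

  bgL <- fitBackground("AA", order = 1, pseudocount = 1,
                       letters = c("A", "B"))
  expect_equal(transitionMatrix(bgL)["A", "A"], 2 / 3)
  expect_equal(transitionMatrix(bgL)["A", "B"], 1 / 3)

  set.seed(41)
  seqs <- vapply(1:20, function(i)
    paste(sample(c("A", "B", "C"), sample(2:10, 1), TRUE), collapse = ""), "")
  for (ord in 0:1) {
    bgr <- fitBackground(seqs, order = ord, pseudocount = 0.5)
    expect_equal(unname(rowSums(transitionMatrix(bgr))),
                 rep(1, nrow(transitionMatrix(bgr))), tolerance = 1e-12)
    expect_equal(sum(initialProbs(bgr)), 1, tolerance = 1e-12)
  }
  expect_error(fitBackground(seqs, order = 2), "orders 0 and 1")
})

test_that("the counting DFA has the failure-link structure and counts overlaps", {
  dfa <- buildWordDFA("PZCD", c("P", "Z", "C", "D", "S"))
  expect_equal(nrow(dfa@delta), 5)
  # after a match, a non-matching letter returns toward the start
  expect_equal(unname(dfa@delta[5, "S"]), 1)
  expect_equal(unname(dfa@delta[5, "P"]), 2)

  # a self-overlapping word re-enters the match state and counts again
  dfaA <- buildWordDFA("AAAA", c("A", "B"))
  expect_equal(unname(dfaA@delta[5, "A"]), 5)
  expect_true(dfaA@counting[5, "A"])
  expect_equal(dfaCountOccurrences(dfaA, "AAAAAA"), 3)

  expect_error(buildWordDFA("AXZ", c("A", "B")), "outside the alphabet")
})

test_that("DFA counting equals the naive overlapping scan on random strings", {
  set.seed(42)
  lets <- c("A", "B", "C")
  for (i in 1:300) {
    s <- paste(sample(lets, sample(1:15, 1), TRUE), collapse = "")
    w <- paste(sample(lets, sample(1:4, 1), TRUE), collapse = "")
    naive <- {
      Lw <- nchar(w)
      n <- nchar(s) - Lw + 1L
      if (n < 1L) 0L
      else sum(vapply(seq_len(n), function(t)
        substr(s, t, t + Lw - 1L) == w, TRUE))
    }
    expect_equal(dfaCountOccurrences(buildWordDFA(w, lets), s), naive)
    expect_equal(countOccurrences(s, w), naive)
  }
  expect_equal(countOccurrences("SPZCDS", "PZCD"), 1L)
  expect_equal(countOccurrences("AB", "ABBA"), 0L)
})

test_that("the exact count distribution matches enumeration on the worked example", {
  bg <- MarkovBackground(c("A", "B"), matrix(0.5, 1, 2))
  dfa <- buildWordDFA("AA", c("A", "B"))
  d <- countDistribution(3, dfa, bg, cap = 2)
  expect_equal(as.numeric(d), c(5, 2, 1) / 8, tolerance = 1e-14)
  expect_equal(sum(d), 1, tolerance = 1e-12)

  # word longer than every sequence: all mass at zero
  dfa4 <- buildWordDFA("AAAA", c("A", "B"))
  d0 <- countDistribution(c(2, 3), dfa4, bg, cap = 1)
  expect_equal(as.numeric(d0), c(1, 0))
})

test_that("the DP distribution equals exhaustive enumeration on random small instances", {
  set.seed(43)
  for (i in 1:10) {
    K <- sample(2:3, 1)
    lets <- LETTERS[seq_len(K)]
    bg <- randomBackground(lets, order = sample(0:1, 1), conc = 0.8,
                           seed = 100 + i)
    lens <- sample(2:7, sample(1:3, 1), TRUE)
    w <- paste(sample(lets, sample(2:3, 1), TRUE), collapse = "")
    cap <- sample(1:4, 1)
    got <- as.numeric(countDistribution(lens, buildWordDFA(w, lets), bg, cap))
    want <- enumCountDist(lens, w, bg, cap)
    expect_lt(max(abs(got - want)), 1e-12)
  }
})

test_that("p-values are inclusive tails, monotone, and order-invariant", {
  bg <- randomBackground(c("A", "B", "C"), order = 1, seed = 7)
  dfa <- buildWordDFA("AB", c("A", "B", "C"))
  lens <- c(4, 6, 8)
  d <- countDistribution(lens, dfa, bg, cap = 6)
  expect_equal(pvalueGE(d, 0), 1)
  pv <- vapply(0:6, function(n) pvalueGE(d, n), 0)
  expect_true(all(diff(pv) <= 1e-15))
  # convolution commutativity: sequence order is irrelevant
  d2 <- countDistribution(rev(lens), dfa, bg, cap = 6)
  expect_equal(as.numeric(d), as.numeric(d2), tolerance = 1e-14)
  expect_error(pvalueGE(d, 9), "cap")
})

test_that("the Lp transform is -log10", {
  expect_equal(lpScore(1e-3), 3)
  expect_equal(lpScore(1), 0)
  expect_equal(lpScore(0.375), 0.4260, tolerance = 1e-4)
  expect_error(lpScore(0), "p must be")
})

test_that("expected counts match the iid closed form for order-0 backgrounds", {
  bg <- MarkovBackground(c("A", "B"), matrix(c(0.3, 0.7), 1, 2))
  expect_equal(expectedCount(10, "AB", bg), 9 * 0.3 * 0.7, tolerance = 1e-12)
  expect_equal(expectedCount(c(10, 5, 3), "AB", bg),
               (9 + 4 + 2) * 0.21, tolerance = 1e-12)
  expect_equal(expectedCount(3, "ABABA", bg), 0)
  # and the DP's mean matches the analytic expectation (uncapped regime)
  dfa <- buildWordDFA("AB", c("A", "B"))
  d <- countDistribution(8, dfa, bg, cap = 7)
  expect_equal(sum(as.numeric(d) * 0:7), expectedCount(8, "AB", bg),
               tolerance = 1e-12)
})

test_that("words below the in-group minimum are reported untested", {
  set.seed(44)
  lets <- c("A", "B", "C")
  loops <- data.frame(loop_id = 1:40,
                      protein_id = sprintf("p%02d", 1:40), chain_id = "A",
                      letters = sampleFromBackground(
                        randomBackground(lets, seed = 9), rep(8, 40)),
                      residue_start = 1L)
  # force one group to hold exactly 4 occurrences of a word
  loops$letters[1:4] <- c("AABCABCC", "CABCBBAC", "ABCABBBC", "BCABCCCA")
  groups <- data.frame(loop_id = 1:40,
                       group_id = rep(c("G1", "G2"), each = 20))
  enr <- enrichWords(loops, groups, words = "ABC", minCountGroup = 5,
                     order = 0)
  g1 <- enr[enr$group_id == "G1" & enr$word == "ABC", ]
  if (nrow(g1) == 1 && g1$N_obs < 5) {
    expect_false(g1$tested)
    expect_true(is.na(g1$Lp))
  }
  expect_true(all(enr$tested == (enr$N_obs >= 5)))
  expect_true(all(is.na(enr$Lp) | enr$Lp >= 0))
})
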