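---
title: "Methods: exact over-representation of structural words in protein loops"
author: "loopmotifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exact over-representation of structural words in protein loops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopmotifs)
```

## The problem

Protein loops — the backbone regions outside alpha-helices and
beta-strands — are structurally variable but not random: recurrent
seven-residue conformations exist, and some of them sit in functional
sites such as ligand-binding loops.  `loopmotifs` implements a pipeline
that finds such motifs without any pairwise structure comparison:

1. backbones are simplified into one-dimensional strings over a
   *structural alphabet* (a set of four-residue fragment prototypes plus
   transition rules, fitted as a hidden Markov model);
2. letters specific to regular secondary structures are removed, and
   the remaining maximal loop runs are cut into overlapping
   *structural words* of four letters (seven residues);
3. each word is tested for over-representation inside each protein
   group (e.g. a SCOP superfamily) with an **exact** p-value under a
   Markov background, computed through the word's counting automaton;
4. words are classified as *ubiquitous* (over-represented in many
   groups — structural building blocks) or *group-specific*
   (over-represented in few groups — functional-site candidates), and
   group-specific words are confronted with interval annotations via
   precision and sensitivity.

## Geometry and encoding

Each four-residue window of a C-alpha trace is described by four
numbers: the three distances between non-successive C-alphas
(`d13`, `d14`, `d24`) and `h`, the out-of-plane component of the fourth
C-alpha relative to the plane of the first three.  `h` is *signed*
along the right-handed normal `(p2 - p1) x (p3 - p1)`.  The sign
convention is a deliberate design choice: an unsigned projection would
conflate a fragment with its mirror image, and backbone fragments are
chiral (an ideal right-handed helix has constant `h` of one sign).
Descriptors are invariant to rotations and translations and flip the
sign of `h` under reflection; both properties are asserted in the test
suite.

Chain breaks split a trace before encoding: a consecutive C-alpha
distance above `maxCaGap` (default 4.5 Å — above any plausible bonded
Cα–Cα distance, below typical gap artefacts) or a jump in author
residue numbering starts a new segment, and windows never span a
break.  Windows whose first three points are collinear have no defined
plane; they are dropped with a warning and also split the segment.

The alphabet itself is a hidden Markov model with one state per letter
and full-covariance Gaussian emissions over the 4-D descriptors.  Full
(rather than diagonal) covariance was chosen because the three
distances of real fragments are strongly correlated; the ridge
`reg * I` (default `1e-6`) keeps M-step covariances invertible.
Training is Baum-Welch from k-means initialisations (5 restarts by
default, best log-likelihood wins, per-iteration monotonicity is
asserted in tests); the alphabet size is selected by BIC with
`p = (K - 1) + K(K - 1) + 14K` free parameters.  Encoding is the joint
maximum a posteriori state path (Viterbi in log space, ties broken
towards the lowest letter index so encoding is deterministic).  An
unbroken trace of `n` residues always yields `n - 3` letters.

The package does not ship the published 27-letter alphabet: its
numeric parameters are not public.  The default alphabet objects
produced by `generateAlphabet()` are documented synthetic constructs,
and user-supplied alphabet model files (JSON/YAML, written with 17
significant digits so a write/read cycle is bit-stable) are
first-class; letter classes stored in a model file are authoritative,
`assignLetterClasses()` only fills them in from reference descriptors
(Mahalanobis distance below 3 marginal standard deviations) when they
are absent.

## Loops, words and counts

A loop is a *maximal run of loop-class letters*; no minimum length is
imposed — loops shorter than the word length simply yield no words,
which keeps counts conservative.  A loop of `m` letters yields
`max(0, m - 3)` overlapping four-letter words; a word of `L` letters
spans `L + 3` residues.  Word types seen fewer than 5 times in the
corpus are discarded (rare words track flexible or poorly determined
regions); independently, a word must be seen at least 5 times *within
a group* to be tested there.  Residue coordinates are 1-based
inclusive in every file the package reads or writes; 0-based
conversions happen only internally.

## Exact statistics

Over-representation of word `w` in a group is scored by

    Lp = -log10( P(N >= N_obs) )

where `N` is the total overlapping occurrence count of `w` in the
group's loops under a homogeneous Markov background, and `N_obs` the
observed count.  The tail probability is exact, not asymptotic: the
word's counting DFA (prefix states with Knuth-Morris-Pratt failure
links, so overlapping occurrences are counted) is embedded in a Markov
chain, and a dynamic program over (DFA state, previous letter,
saturated count) yields the per-sequence count distribution; the
per-sequence distributions are convolved across the group's loops.
The generating-function formulation of the same embedding is replaced
by this dynamic program on purpose: it has the identical contract (the
exact distribution of `N`) and is verified against exhaustive
enumeration over all sequence tuples to below `1e-12` in the tests.

Numerical choices worth recording:

* **Counts are saturated at `cap = N_obs`.**  Only the inclusive tail
  `P(N >= N_obs)` is needed, and saturating the count coordinate makes
  the DP and the convolutions linear in `N_obs` instead of quadratic
  in the full support.  The saturation cell is exact for the tail.
* **The background is order 1 by default**, fitted by maximum
  likelihood on the *whole loop corpus* and applied within each group
  (`bgScope = "corpus"`).  Fitting per group is available, but a
  corpus-wide background is what makes group-specific excesses
  detectable.  Orders above 1 are not supported: the DP carries one
  letter of history, which is exact for orders 0 and 1.
* **First letters are drawn from the empirical initial distribution**,
  not the stationary one — loops are short (the mean loop in the
  synthetic corpus is about 6 letters), so the difference is material
  and tests account for it.
* The expected count reported alongside each p-value is computed
  analytically by linearity, propagating the marginal letter
  distribution along positions.

Multiple testing uses Bonferroni on the number of (word, group) pairs
actually tested: `lp_sig = -log10(alpha / n_tests)`.  The constant
`legacyLpThreshold = 5.97` is kept for runs mimicking published
large-scale analyses, but every run of this package computes its own
threshold — the number of tests behind 5.97 is not recoverable and is
never hard-coded into a computation.

## The word taxonomy

From the per-group results each word gets `Lp_max` (maximal Lp over
tested groups), `nb_sf_star` (tested groups with `Lp >= lp_sig`) and
`nb_sf` (groups where the word occurs at all).  The taxonomy is:
over-represented iff `Lp_max >= lp_sig`; ubiquitous iff additionally
`nb_sf_star >= 5` (extreme when `Lp_max >= 10`); group-specific iff
`nb_sf_star < 5` (moderately specific when `Lp_max >= 10`, extreme
when `Lp_max >= 50`); *functional* iff extreme group-specific **and**
best annotation precision `>= 40%`.  Coverage of a word subset is
reported four ways — word types, fragments, loop residues (union of
residue spans, overlaps counted once; the union rule is a design
choice, double counting would overstate coverage), and proteins.

## Annotations

A fragment matches an annotation when at least `minOverlap` residues
(default 1) of its span intersect the annotation interval on the same
protein and chain; the overlap rule is configurable because no single
convention is canonical.  Precision of a word for a label is the
fraction of its fragments matched; sensitivity is the fraction of
loop-located annotation *instances* (one interval record = one
instance) covered by the word, annotations lying entirely in regular
secondary structures being discarded from the denominator.
Description-level labels are compared after whitespace normalisation.

## Fragment superposition

`kabschRMSD()` uses the SVD form of the Kabsch algorithm with the
determinant correction, so only proper rotations are allowed —
fragments are chiral and a mirror image must not superpose.  The
distance between two words is the mean RMSD over 30 fragment pairs
sampled from the cross product of their fragment sets, without
replacement when enough distinct pairs exist (with replacement
otherwise; the choice is a convention and is documented rather than
load-bearing), reproducibly from a seed.

## What the synthetic generator emulates — and what it does not

`sampleCorpus()` draws loop letter strings from a configurable Markov
background, groups them (each loop on its own pseudo-protein), injects
planted words and plants annotations on their occurrences.  The
defaults are the study conditions used throughout the tests and are
chosen once:

* **20 groups** with **150 loops each** (the enrichment-recovery
  experiments use 500 per group; see below), mirroring a corpus where
  groups have tens-to-hundreds of loops;
* **loop lengths** `1 + NegBin(size 2, mu 5)` letters — a mean of
  about 6 letters / 9 residues and many loops shorter than one word,
  matching the short-loop-dominated profile of real loop corpora
  (about 2.6 words per loop on average);
* **background**: order-1 Markov with Dirichlet(0.6) rows over 8 loop
  letters (the enrichment experiments sharpen this to
  Dirichlet(0.3), giving realistic skewed letter preferences);
* **plant injection replaces a window** of a background-sampled loop
  rather than appending, so loop lengths are preserved; the number of
  injections is Poisson with mean `(factor - 1) * E`, `E` being the
  exact background expectation of the word in the group, which makes
  the realised in-group rate `factor` times the background rate in
  expectation;
* **annotations** are planted on every occurrence of a planted word
  with probability `q` (default 0.5), the interval being exactly the
  occurrence's residue span.

The enrichment-recovery experiment (in the test suite and mirrored in
the pipeline tests) plants one word at 10x background in 1 of 20
groups and one word at 3x in 10 groups, with 500 loops per group.
The plant words are chosen from the background alone by a fixed rule:
words of four *distinct* letters (self-overlapping words clump, which
the exact statistic rightly discounts — planting a homopolymer is the
weakest possible signal), the most probable such word for the
ubiquitous plant and words with per-group expectation near 1.5 for the
specific plants.  A power calculation fixes these sizes: a Poisson
approximation gives `Lp ≈ E (f ln f - f + 1) / ln 10`, so the 10x
plant at `E ≈ 1.5` yields `Lp ≈ 9` and the 3x plant at `E ≈ 14`
yields `Lp ≈ 8`, both comfortably above a Bonferroni threshold near
4.6 — the experiment is designed to have power, not tuned to a test
outcome.

What the generator does **not** emulate: amino-acid sequences, real
loop geometry ensembles (loops are self-avoiding random walks), group
size imbalance, letter-uncertainty near chain termini, and annotation
noise (planted intervals are exact).  Passing tests therefore
demonstrate the correctness and calibration of the statistical
machinery under its own model assumptions — not that any particular
biological corpus contains functional motifs.

## Problem sizes used by the test suite

The suite runs at deliberately modest sizes, chosen as the smallest
that make each statistical assertion sharp: exhaustive-enumeration
cross-checks use alphabets of 2–3 letters, up to 3 sequences of
length ≤ 8; Monte-Carlo calibration uses 1e5 simulated sequence sets
with agreement required within 3 binomial standard errors; HMM
recovery uses 1e5 observations from a planted 3-state model (transition
error < 0.05, BIC selection over K ∈ {2..5}); the enrichment
experiment uses the 20 × 500 corpus described above.

## Known limitations

* Backgrounds above order 1 are unsupported (by design of the DP).
* Insertion codes are preserved in traces but residue-span arithmetic
  assumes locally consecutive numbering within an unbroken segment.
* Precision measured with `minOverlap = 1` can be slightly inflated
  when occurrences of the same word overlap (a neighbour's annotation
  may touch a fragment); full-containment matching
  (`minOverlap = L + 3`) removes the effect and is what the
  annotation-recovery test uses.
* `enrichWords()` reports only (word, group) pairs with at least one
  occurrence; absent pairs carry no evidence either way under the
  tail test.
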