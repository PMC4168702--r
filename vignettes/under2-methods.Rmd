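---
title: "Assembly-free read-set comparison with underlying patterns: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembly-free read-set comparison with underlying patterns: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(under2)
```

## The problem

When sequencing reads cannot be assembled or mapped — no reference, short
reads, distant organisms — evolutionary relationships must be estimated
directly from the unassembled read sets.  Fixed-*k* word statistics (the D2
family) do this by correlating k-mer count vectors, but their behavior
depends strongly on the choice of *k*, and every sequence position
contributes to *k* different words.  The Under2 dissimilarity implemented
here instead uses *variable-length* patterns shared between two read sets,
filtered so that each read position contributes to the score at most once.

A read set \(R\) is \(M\) reads of nominal length \(\beta\) over
\(\{A,C,G,T\}\).  By default patterns are also matched on the reverse,
complement and reverse-complement string of every read, to model the two
DNA strands and inverted transfers of genetic material.

## From shared words to underlying patterns

**Irredundant common patterns.**  A word is *shared* when it occurs in both
read sets (possibly on a transform string).  Most shared words are
redundant: an occurrence completely contained — on the same read and
transform — inside an occurrence of a longer shared word adds no
information.  A shared word is *irredundant* when at least one of its
occurrences is not covered in this sense.  The package extracts exactly
this set on a generalized suffix array with LCP support built over all
reads of both sets (transform strings appended as extra documents,
per-position unique sentinels preventing cross-read matches).  For every
position the matching statistic against the *other* set gives the longest
shared word starting there; within a document the end-reach of these
maximal occurrences is non-decreasing, and an occurrence is uncovered
exactly when its reach strictly exceeds every earlier reach.  This yields
all uncovered occurrences in linear scans, and the distinct words via LCP
range queries.  The count of irredundant patterns is bounded by the total
length of the searched text (the classic \(|R_1|+|R_2|\) bound for the
forward strings; four times that when all four transforms are searched).

**Underlying patterns.**  To make each position count once, patterns are
ranked by the *priority rule* — longer first; among equal lengths the word
with smaller null-model probability (rarer) first; then the word whose
first occurrence appears earlier in the canonical read concatenation; a
final lexicographic tie-break makes the order strict — and consumed
greedily over a location vector \(\Gamma\) spanning every position of both
sets (transform strings included).  An occurrence is *untied* when all of
its cells are free; claims are made progressively in position order, so
accepted claims are pairwise disjoint even between overlapping occurrences
of the same word.  A pattern is accepted when it retains at least one
untied occurrence in *each* set, and then all its untied occurrences claim
their cells.  The same greedy pass runs in compiled code for the full
statistic and in R (`extract_underlying()`) as a readable reference; both
are tested against a literal brute-force implementation of the definitions.

## The score and the dissimilarity

With the underlying set \(U\), the directional score is

\[ Score(R_1, R_2) \;=\; \frac{1}{|R_1|} \sum_{w \in U} |w|\,
   \mathrm{untied}^1_w\, \frac{occ_w}{E[occ_w]} \]

where \(\mathrm{untied}^1_w\) counts the untied occurrences of \(w\) in
\(R_1\), \(occ_w\) its total occurrences in \(R_1\) across the enabled
transforms, and \(E[occ_w] = p_w\, M\, (\beta - |w| + 1)\) the expected
count under a first-order Markov model fitted on \(R_1\) (pseudocount 1,
initial distribution from symbol frequencies, pair counts never crossing
read boundaries).  When reads have unequal lengths the possible-positions
factor generalizes to \(\sum_r \max(0, \mathrm{len}_r - |w| + 1)\), and
when \(t\) transform strings are searched the factor is scaled by \(t\),
so possible match sites scale with the searched text.  The mean of
\(occ_w/E[occ_w]\) under the generating model is exactly 1, which the test
suite verifies by Monte-Carlo simulation (the generator uses the
stationary initial law so the closed form is exact at every position).

The directional statistic and the symmetric dissimilarity are

\[ Under^2(R_1,R_2) = \frac{\log_4 |R_2|}{Score(R_1,R_2)} - \log_4 |R_1|,
   \qquad
   \overline{Under_2} = \tfrac12\left(Under^2(R_1,R_2) + Under^2(R_2,R_1)\right). \]

Identical read multisets short-circuit to exactly 0: the claimed identity
\(Score(R,R)=1\) does not hold under the printed occurrence/expectation
ratio, so the implementation enforces the intended fixed point directly and
documents it here.  When the two sets share no pattern at all the score is
0 and the statistic returns \(+\infty\) with a warning.

### Numerical behavior and a practical limitation

Because \(p_w \approx 4^{-|w|}\), the ratio \(occ_w/E[occ_w]\) grows like
\(4^{|w|}\): the score is dominated exponentially by the longest underlying
patterns.  Two consequences matter in practice.  First, read sets from
nearly identical genomes share patterns as long as the reads themselves,
the score exceeds \(10^{15}\), and the directional statistic collapses to
\(-\log_4 |R|\) at double precision — all such pairs tie.  Under2 is
therefore a tool for comparing *diverged* genomes (species level, roughly
\(>20\%\) substitution divergence for 50-kb inputs), which is also the
regime of the phylogeny benchmark below.  Second, weak localized signals
(short implanted motifs at low intensity) sit exponentially below the
noise floor set by the longest background coincidence; the centered
fixed-k statistics, which integrate count excesses over all words, can be
more sensitive in that regime.  The benchmark suite reports both.

For phylogeny benchmarks these two effects bracket an *informative window*
of divergences.  Between 50-kb genomes the longest purely coincidental
shared word is about 17 bp (\(\log_4\) of the number of position pairs
across the searched strings), so clades whose homologous shared runs are
shorter than roughly 23 bp are indistinguishable from unrelated pairs;
conversely runs beyond about 38 bp drive the score past \(10^{13}\) and
the distances collapse onto the floor.  In substitution terms the window
is pairwise divergence of roughly 0.2–0.4 per site.  The shipped
end-to-end benchmark places its generating-tree tiers inside that window.
A second consequence: the distances carry heavy-tailed, decidedly
non-additive noise (a single chance long pattern shifts one pair by orders
of magnitude in score).  Average-linkage reconstruction (UPGMA), which
matches the ultrametric generating tree and averages over tiers, recovers
the topology reliably; neighbor joining, whose Q-criterion assumes
near-additivity, frequently does not.  The shipped end-to-end benchmark
therefore requires exact recovery from UPGMA and only bounds the NJ score.

## Comparator statistics

`dtype_dissimilarity()` implements the D2 family on pooled k-mer counts
(default \(k = 5\), the standard choice for this benchmark; counts never
span read boundaries; reverse-complement merging on by default to account
for double strands).  D2 is the plain inner product; D2\(^*\) and D2S
center the counts at \(\tilde A_w = A_w - m_A p_w\) (with \(m_A\) the
pooled word-start count and \(p_w\) from an order-0 null fitted per set,
pseudocount 1) and standardize by
\(\sqrt{m_A p^A_w\, m_B p^B_w}\) and \(\sqrt{\tilde A_w^2 + \tilde B_w^2}\)
respectively.  Each statistic is converted to a bounded dissimilarity
\(d = \tfrac12(1 - S/\nu)\in[0,1]\), with \(\nu\) the geometric mean of the
corresponding self-normalizers, so identical inputs give 0.  These
read-set adaptations follow the published approach in spirit; they are not
claimed to be bit-compatible with the original d2-NGS software, and the
pooled (rather than per-read) centering constant is this package's
documented choice.

## The simulator

`build_experiment()` reproduces the standard motif-implantation benchmark:

* **Backgrounds** — i.i.d. uniform; i.i.d. GC-rich
  (\(p_A=p_T=1/6,\ p_C=p_G=1/3\)); or a uniformly placed window of a
  supplied FASTA record, which stands in for sampling windows of a real
  genome.
* **Correlation models** — a left-to-right scan implants a motif variant
  at each position with probability \(\lambda\) (default 0.001),
  overwriting in place (length preserved) and jumping past the implant so
  implants never overlap; a variant that does not fit the remaining suffix
  is skipped.  CM uses one fixed length-5 word; SMM draws uniformly from
  five motifs (lengths 5,4,5,6,6) and their reverse-complements (10
  variants); FMM adds the plain reverses (15 variants — the plain
  complement is deliberately not included).  The motif strings are
  arbitrary documented constants, not ground truth.  The scan is
  implemented with geometric jumps, which is distributionally identical to
  the per-position Bernoulli scan and fast at any \(\lambda\).
* **Sequencing** — \(M = \lceil \gamma N / \beta \rceil\) reads of length
  \(\beta\) (defaults \(\gamma = 5\), \(\beta = 200\)) with uniform start
  positions; optional strand flipping; optional per-base substitution
  errors (default 0, i.e. exact sequencing).  Platform-specific error
  structure (homopolymer indels etc.) is out of scope.
* **Determinism** — all sub-seeds derive from the configuration seed, so
  the same configuration reproduces bit-identical read sets.

`simulate_genome_family()` evolves a uniform root genome down a given tree
with per-edge substitution probabilities, providing genomes with a known
generating topology.

What the simulator does *not* emulate: real genomic repeat structure and
composition bias (except through the FASTA-window background), indels,
coverage bias, and read-quality artifacts.  Green tests on simulated data
therefore establish the internal correctness and calibration of the
statistics, not their field performance on real libraries.

## Evaluation protocol

`ppv()` merges all within-positive and within-negative pair scores, ranks
them with "better = more similar", and reports the fraction of the best
\(\lfloor n/2 \rfloor\) entries that are positive pairs: 1 is perfect
separation, 0.5 is no power.  Tie groups straddling the cut contribute
proportionally, so the value is deterministic under ties.  `benchmark_ppv()`
runs the protocol for Under2 and the d-type statistics; the command-line
`benchmark` subcommand averages over five independently seeded replicates
by default.

`pairwise_matrix()`, `nj_tree()`, `upgma_tree()` and `robinson_foulds()`
cover the phylogeny workflow (square-PHYLIP and Newick IO included);
neighbor joining, UPGMA and the Robinson–Foulds bipartition distance
delegate to the standard implementations in `ape`, `stats::hclust` and
`phangorn`, with a brute-force bipartition oracle in the test suite.

## Problem sizes and seeds used by the shipped checks

The test suite and `scripts/acceptance.R` run entirely on simulated data:
self-comparison at 25 reads × 200 bp; expectation calibration over 10,000
read sets of 50 × 200 bp; the null-PPV calibration at \(N = 2000\),
\(\gamma = 5\), \(\beta = 200\), 20 positive + 20 negative sequences and 20
replicates; definition-oracle equivalence on 200 random instances of up to
10 reads × 30 bp per set; and the end-to-end phylogeny benchmark on six
50-kb genomes at species-level divergences.  Every stochastic run is
seeded, and all randomness in the acceptance script derives from its
`--seed` argument.

## Known limitations

* The saturation behavior described above: no resolution between
  near-identical genome-scale inputs, and low sensitivity to sparse short
  motifs relative to the centered fixed-k statistics.
* The \(O(L^2)\)-worst-case greedy location-vector pass is used (in
  practice it is far from quadratic on read data); the asymptotically
  faster underlying-extraction algorithm is not implemented.
* Quality values are parsed and discarded; quality-aware weighting is
  future work.
* `common_patterns_bruteforce()` is an oracle for testing, guarded to
  2,000 total symbols.
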