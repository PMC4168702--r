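# under2

Assembly-free comparison of sequencing read sets with variable-length
underlying patterns.

## What this is for

When reads cannot be assembled or mapped — no reference genome, short
reads, distantly related organisms — the evolutionary relationship of the
underlying genomes must be estimated directly from the unassembled read
sets.  This package implements **Under2**, an alignment-free, assembly-free
dissimilarity between two read sets built from *variable-length* shared
patterns, together with the fixed-*k* **D2 family** of comparator
statistics (d2, d2\*, d2S), the standard **motif-implantation simulation
benchmark** (CM / SMM / FMM correlation models), **PPV** scoring of
statistics, and distance-based **phylogeny reconstruction** (NJ, UPGMA)
scored with the Robinson–Foulds distance.

## The statistic

For read sets `R1`, `R2` (each `M` reads of length `β` over `{A,C,G,T}`,
searched by default also as reverses, complements and reverse-complements):

1. **Irredundant common patterns** — shared words with at least one
   occurrence not contained in a longer shared word's occurrence —
   are extracted on a generalized suffix array with LCP support
   (compiled code; count bounded by the searched text length).
2. **Underlying patterns** are selected greedily by the priority rule
   (longer, then rarer under the null, then earliest first occurrence)
   over a location vector spanning every read position, so accepted
   *untied* occurrences are pairwise disjoint: each position contributes
   to the score at most once.
3. The directional score weighs each underlying pattern by its
   observed-to-expected occurrence ratio under a first-order Markov
   background fitted on the scored set:

   ```
   Score(R1,R2) = (1/|R1|) Σ_{w∈U} |w| · untied¹_w · occ_w / E[occ_w],
   E[occ_w] = p_w · M · (β − |w| + 1)
   ```

4. The dissimilarity is the symmetrized log statistic

   ```
   Under²(R1,R2) = log4|R2| / Score(R1,R2) − log4|R1|
   Under2(R1,R2) = (Under²(R1,R2) + Under²(R2,R1)) / 2
   ```

   It is exactly 0 for identical inputs and smaller (more negative) for
   more similar pairs.

See `vignettes/under2-methods.Rmd` for the full model description, design
decisions and known limitations.

## Worked example

```r
library(under2)
set.seed(1)
genome_a <- paste(sample(c("A","C","G","T"), 5000, TRUE), collapse = "")
genome_b <- paste(sample(c("A","C","G","T"), 5000, TRUE), collapse = "")
cfg <- simulation_config(N = 5000, gamma = 5, beta = 200)  # 125 reads/set
r_a1 <- sample_reads(genome_a, cfg, label = "a1")
r_a2 <- sample_reads(genome_a, cfg, label = "a2")   # same genome, new reads
r_b  <- sample_reads(genome_b, cfg, label = "b")    # unrelated genome

under2(r_a1, r_a2)
#> under2 comparison
#>   score 1->2: 5.17023e+116   score 2->1: 6.38776e+116
#>   under2 1->2: -7.30482  under2 2->1: -7.30482
#>   symmetric under2: -7.30482

under2(r_a1, r_b)
#> under2 comparison
#>   score 1->2: 95.2841   score 2->1: 98.2048
#>   under2 1->2: -7.22816  under2 2->1: -7.23044
#>   symmetric under2: -7.2293
```

Reads from the *same* genome share long patterns, so the score is huge and
the statistic sits at its similarity floor `−log4|R| = −7.3048`; the
unrelated pair shares only short coincidental patterns and scores higher
(less similar).  The fixed-k comparators behave analogously:

```r
dtype_dissimilarity(r_a1, r_a2, "d2s")   # 0.1356902
dtype_dissimilarity(r_a1, r_b,  "d2s")   # 0.4688005
```

A command-line interface is installed as `exec/under2` with subcommands
`simulate`, `compare`, `benchmark` and `phylogeny`, e.g.

```sh
Rscript exec/under2 compare setA.fasta setB.fasta --stat under2
Rscript exec/under2 benchmark --model FMM --lambda 0.001 --n 2000 --seed 1 --out ppv.tsv
Rscript exec/under2 phylogeny --matrix dist.phylip --method nj --reference ref.nwk
```

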