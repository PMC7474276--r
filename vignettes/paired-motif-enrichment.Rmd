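---
title: "Paired motif enrichment in promoters: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired motif enrichment in promoters: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifpairs)
```

## The problem

Single transcription factor (TF) binding motifs are short and degenerate,
so almost every promoter contains a passable match to almost every motif;
single-motif enrichment in a gene set is correspondingly weak evidence.
Combinatorial regulation — two TFs whose sites co-occur in the same
promoter — is both more specific and closer to how cell-type- and
stimulus-specific expression is actually encoded. `motifpairs` asks, for
every pair of motifs in a library, whether promoters containing *both*
motifs are over-represented among a gene set of interest (say, the genes a
cell type induces after an immune elicitor), against the background of all
nuclear promoters.

The pipeline has four stages, each with a deliberately simple statistical
model.

## 1. Scanning: exact hit p-values under a 0-order background

A motif is a letter-probability matrix $f_{b,i}$ (probability of base $b$
at position $i$). Every window of every promoter, on both strands, is
scored by the log-odds $\sum_i \log_2 (f'_{x_i,i} / q_{x_i})$ against a
0-order background $q$; $f'$ carries a small additive pseudocount
(default 0.001, scanning only). Scores are discretized to a grid
(default $10^{-3}$ log2-odds units) and the exact null distribution of the
window score is built by dynamic-programming convolution of the
per-position score distributions, position by position. The hit p-value is
the exact upper tail $P(S \ge s)$ on that grid; the window scorer uses the
same integer grid, so lookup involves no additional rounding. For motifs
of small width this is verifiably identical to enumerating all $4^w$
windows (the test suite does exactly that).

Two details worth knowing:

* the background is symmetrized ($q_A = q_T$, $q_C = q_G$), so one null
  distribution serves both strands and scanning a promoter or its reverse
  complement gives identical p-values. The default background is uniform;
  a 0-order background estimated from the promoter set is available
  (`run_config(background = "promoters")`).
* a base with matrix frequency exactly 0 (possible only with pseudocount
  0) can never match: such windows get p-value 1, as do windows containing
  `N`.

## 2. Promoter score: binomial tail over the top $k \le 5$ hits

TFs often bind in clusters, so one best hit is not the right summary. For
each promoter the non-overlapping hits are selected greedily in order of
increasing p-value (ties: position, then strand), up to five. For each
$k$, let $p_k$ be the geometric mean of the $k$ best p-values; the
promoter's score for the motif is

$$\min_{1 \le k \le 5} P\!\left(X \ge k\right),
  \qquad X \sim \mathrm{Binomial}(N, p_k),$$

and the minimizing $k$ is the estimated number of binding sites (smallest
$k$ on ties; no hits gives score 1). $N$ is the number of candidate
placements actually scanned, $(L - w + 1)$ per strand, which adapts
correctly to promoters truncated at chromosome ends; a fixed $N$ (e.g.
1000 for a literal 1 kb reading) can be configured.

## 3. The motif index: top $n$ promoters and a recorded threshold

For each motif, promoters are ranked by increasing score and the top
$n = 5000$ (default) are taken to *contain* the motif; the $n$-th score is
recorded as that motif's threshold. A single $n$ for all motifs makes pair
statistics comparable between specific and degenerate motifs, and a
generous $n$ favors sensitivity — stringency comes from requiring the
*pair*. Boundary ties are broken by gene id so the index is reproducible
to the byte.

## 4. Pairs: IC-based overlap resolution and the hypergeometric test

Two hits that overlap on the promoter may be one physical site matched by
two motifs rather than two sites. Whether the overlap is disqualifying is
decided by information content: each motif's total IC over its overlapped
positions, $\sum_{i \in I} (2 + \sum_b f_{b,i} \log_2 f_{b,i})$ bits (no
pseudocount). If either motif's overlap IC exceeds 4 bits — conserved
bases fall inside the overlap — both participating hits are removed and
both promoters' scores are recomputed from the remaining hits ($k$
re-optimized, $N$ unchanged). The decision depends only on IC, never on
overlap length; an overlap of exactly 4 bits is retained. A promoter on
which both motifs still score at or below their recorded thresholds after
this resolution is *colocalized* for the pair. Removing both hits (rather
than one) keeps the colocalization decision symmetric in the pair; a motif
left hitless rescores to 1 and cannot pass.

Enrichment of a pair in a gene set of size $K$ is the upper-tail
hypergeometric probability of drawing at least the observed number of
colocalized promoters when $K$ promoters are drawn from the universe, and
is Bonferroni-corrected by the number of pairs tested for that gene set
(corrected $P < 0.05$ is called significant). When several conditions are
compared, gene sets should be equalized first
(`equalize_gene_sets()`, or `equalize = TRUE` in `run_pair_tests()`):
each larger set is truncated to its top $K$ genes, $K$ the smallest set's
size, so p-values are comparable.

## Defaults and their provenance

| parameter | default | meaning |
|---|---|---|
| `promoter_length` | 1000 bp | upstream window from the TSS |
| `n` | 5000 | index size per motif |
| `max_k` | 5 | hits considered per promoter |
| `ic_cutoff` | 4 bits | overlap removal threshold |
| `alpha` | 0.05 | significance on corrected p |
| `pseudocount` | 0.001 | scanning log-odds only |
| `granularity` | 1e-3 | score grid (log2-odds units) |
| `strands` | both | scanning strands |
| `trials` | auto | binomial $N$ = placements scanned |

The first five are the method's standard operating point; the scanning
knobs are implementation choices exposed for reproducibility. Promoter
extraction takes the gene-level 5' end as the TSS (one promoter per gene),
keeps fixed windows without trimming overlaps with neighboring genes,
retains `N` bases, and excludes organellar chromosomes by name.

Two deliberate non-filters: no p-value cutoff is applied to hits before
top-$k$ selection (selection alone provides stringency), and homotypic
(self) pairs are excluded by default (`include_self = TRUE` tests them,
requiring two non-overlapping instances).

## The synthetic benchmark: what it emulates, and what it does not

`make_benchmark_scenario()` builds the study conditions used by the test
suite and by `scripts/acceptance.R`: a universe of 5000 i.i.d. uniform
promoters of 1000 bp; a library of 16 random width-8 motifs, each column
having one dominant base with frequency drawn from 0.85–0.97 (the sharp
column profile of specific plant TF motifs); the first two motifs planted
together — instances sampled from the matrices, random strands, 10 bp
apart — in 200 promoters; and a ranked gene set of 300 genes, 150 of them
planted promoters. Indexing uses $n = 900$, keeping the index fraction at
18% of the universe, the same fraction as $n = 5000$ against the ~27,000
nuclear genes of a plant genome.

Design notes, decided once while specifying the scenario:

* *Library size 16.* The planted motifs' genuine single-motif enrichment
  (half the gene set carries them) bleeds into every pair that contains
  one planted motif; those pairs can legitimately reach significance.
  A library of 14 decoys ensures the specificity control — pairs of two
  *unplanted* motifs — is measured over 91 pure-null pairs, and the per-set
  Bonferroni over 120 pairs is realistic. The planted pair must still rank
  first.
* *Instances sampled from the matrix*, not consensus, so planted hit
  p-values vary over orders of magnitude as real sites do; roughly
  10–20% of planted promoters end up below index rank and are lost, which
  the gene set's hypergeometric test must tolerate.
* *What is not emulated:* nucleotide autocorrelation, CpG/TA periodicity,
  shared promoter architecture between co-regulated genes, and motif
  correlations within a real library. Passing the benchmark shows the
  statistics and bookkeeping are right at genome-like scale, not that any
  particular biological pair will validate.

The negative control mirrors the method's published sanity check: 100
random gene sets of 300 genes drawn from an unplanted universe (2000
promoters, 4 motifs, the same 18% index fraction) are tested; raw
p-values should be super-uniform (checked with a one-sided
Kolmogorov–Smirnov test — hypergeometric p-values are conservative, so a
two-sided test against the uniform would reject for the *right* reason).
Note the exact count of corrected-significant pairs over 100 sets is a
binomial random variable with expectation of order $100\alpha$ times the
discreteness factor of the hypergeometric; observing a literal zero
depends on how coarse the colocalization counts are.

## Numerical choices and degenerate inputs

* Tie-breaking is total everywhere — hits by (p-value, start, strand),
  index membership by (score, gene id), pairs by lexicographic motif id —
  so the whole pipeline is byte-reproducible; rerunning `run_index()` +
  `run_pair_tests()` on identical inputs yields identical files, and the
  manifest records parameter and input checksums to enforce index/config
  consistency.
* Geometric means are clamped away from 0 before `pbinom`; scores are
  floored at the smallest normal double, so $-\log_{10}$ heatmap values
  stay finite (capped at 300).
* Promoters shorter than the motif contribute no candidates and score 1;
  a promoter of length 0 is dropped at extraction.
* Problem sizes in the test suite (and above) were chosen so the whole
  suite and the acceptance script each complete comfortably on a single
  CPU; the statistical conclusions do not depend on these sizes.

## Known limitations

* Only 0-order backgrounds; no higher-order Markov correction for
  dinucleotide composition.
* One promoter per gene (gene-level TSS); alternative TSSs are ignored.
* Bonferroni is the only correction offered, by design — the method's
  published decision rule is corrected $P < 0.05$ — so results are
  conservative.
* No distance or orientation constraints between paired sites beyond
  overlap resolution: a pair colocalized at opposite ends of the promoter
  counts as much as an adjacent pair.
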