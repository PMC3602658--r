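---
title: "Detecting locally enriched transcription factor binding sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting locally enriched transcription factor binding sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(localmotif)
```

## The problem

Transcription factor binding sites (TFBSs) are not placed uniformly across
promoters: some motifs work only in a narrow window relative to the
transcription start site (TSS) — the TATA box around −30 to −25 bp is the
classic case — while others prefer broader neighbourhoods.  A standard
over-representation test, which only counts sites, misses motifs whose
signal is *positional* rather than *numerical*.  `localmotif` asks the
complementary question: given a set *S* of *N* co-regulated promoters, is
there a region, at some position relative to the TSS, in which a motif's
predicted sites are significantly concentrated?

## The enrichment score

All coordinates are TSS-relative: position 0 is the first transcribed
base, upstream is negative, and sequences are read 5'→3' on the gene's
strand.  Spans are half-open integer windows `[start, end)`; by default
sequences cover `[-3000, +2000)` and scores are evaluated on the inclusive
grid `[-2000, +1000]`, so that sites outside the scored region but inside
the scanned span still contribute near the boundary and no edge artifact
appears.

For sequence *s* with predicted site positions
$l_{s,1}, \dots, l_{s,m_s}$, the contribution to position $x$ is a Parzen
window sum

$$p_s(x) = \sum_{i=1}^{m_s} \phi(x, l_{s,i}, h),$$

with a Gaussian window function

$$\phi(x, l, h) = \frac{1}{\sqrt{2\pi}\,(h/2)}
  \exp\!\left(-\frac{(l - x)^2}{2 (h/2)^2}\right),$$

where $h/2$ plays the role of the kernel standard deviation.  A uniform
("sliding window") kernel $\phi = 1/h$ for $|x - l| \le h/2$ is also
provided; with ZOOPS normalization disabled it reduces exactly to a
sliding-window site count divided by $h$, which is the independent oracle
the test suite checks against.

The set-level local enrichment score is

$$S_{\mathrm{local}}(x) = \sum_{s=1}^{N} \frac{p_s(x)}{Z_s},
\qquad Z_s = \max\!\Big(1, \sum_{x = x_{start}}^{x_{stop}} p_s(x)\Big),$$

the sum in $Z_s$ running over the integer scoring grid.  This
zero-or-one-occurrence-per-sequence (ZOOPS) normalization caps any single
sequence's total contribution at about 1, so a repeat-rich sequence with
dozens of spurious sites cannot dominate the profile.  $S_{\mathrm{local}}$
is evaluated at 1-bp resolution and is deliberately *not* a probability
density: more contributing sequences mean a higher score.

Kernel widths $h/2 \in \{10, 20, 50, 100, 200\}$ bp are used side by side:
narrow kernels resolve tightly positioned elements, wide ones detect loose
positional preferences.  Gaussian tails are truncated at $6\,(h/2)$, which
discards less than $10^{-8}$ of a site's mass and makes the per-site cost
independent of the grid length; the truncation multiple is an argument for
users who want to tighten it.

## Significance by GC-matched resampling

Motif hit rates track GC content, and GC content varies systematically
between promoter classes (CpG-island promoters are GC-rich, particularly
near the TSS).  Comparing an input set against arbitrary promoters
therefore produces false local enrichment of AT- or GC-rich motifs.  The
null model here resamples sets of $N$ promoters from the genomic universe
*with matched GC profiles*:

1. every genomic promoter is summarized by 20 GC fractions in 100-bp bins
   over `[-1000, +1000)` (N bases excluded from numerator and denominator;
   an all-N bin is imputed with the bin's genomic mean);
2. profiles are scaled per bin to mean 0 / sd 1 and clustered by k-means
   (Hartigan-Wong; $k = 2..10$; 100 random restarts of up to 100
   iterations each, keeping the best total within-cluster sum of squares);
3. for each $k$, 1000 stratified samples matching the input's cluster
   counts $c_i$ are drawn, and the RMSD between sampled and input mean GC
   bins is recorded; $k^\ast$ is the smallest $k$ with
   $\mathrm{RMSD}_k \le \mathrm{RMSD}_{k+1} + \mathrm{SD}_{k+1}$ — a
   Gap-statistic-like elbow rule.  $k = 1$ is never considered, because
   the split into GC-rich and GC-poor promoters is biologically
   established; when no $k$ below 10 qualifies, $k^\ast = 10$ (RMSD tends
   to decrease with $k$, so the largest considered value is the natural
   fallback — the rule's inputs make this case rare).

Sampling at $k^\ast$ then draws $c_i$ sequences per cluster without
replacement within a set (and with replacement across sets; the package
treats this as its own convention, stated here because either choice is
defensible).  Input genes stay in the pool.  Two empirical p-values are
computed per position from `n_samples` resampled profiles:

* $P_{dep}(x)$ — the proportion of sampled sets with
  $S^{sampled}(x) \ge S_{\mathrm{local}}(x)$: is the observed enrichment
  unusual *at this position*?
* $P_{ind}(x)$ — the proportion of sampled sets whose profile *maximum*
  reaches $S_{\mathrm{local}}(x)$: is it unusual *at any position*?  This
  gate removes calls that only reflect a globally flat profile crossed by
  sampling noise.

P-values are plain proportions, following the estimator's definition; the
conservative $(r+1)/(n+1)$ variant is available behind a flag for users
who prefer never to report 0.

## Region calling

A position is significant when $P_{dep}(x)$ falls below a width-dependent
threshold — 1e-3, 5e-4, 2e-4, 1e-4, 5e-5 for $h/2$ = 200, 100, 50, 20, 10
(stricter for narrow kernels, which test more independent positions) —
and $P_{ind}(x) < 0.01$.  Maximal runs of significant positions
$[x_1, x_2]$ are expanded to $[x_1 - h/2,\; x_2 + h/2]$.  Overlapping
regions of the same width are unioned; runs separated by even one
non-significant bp are kept apart at first, because the expansion already
bridges small gaps.  Across widths, overlapping regions are grouped
transitively and each group keeps its largest member (by bp span) —
unless a smaller member contains *strictly more than* 2/3 of the largest
member's sites, in which case the smallest such member wins, preferring
narrow regions dense in sites.  Ties on span resolve to the member with
more sites, then the smaller start; the tie-break is a package decision
(the rule itself does not define one) and is asserted deterministic in the
tests.

Default sampling depths are 25000 sets for local enrichment — the
strictest threshold, 5e-5, needs resolution finer than 1/20000 — and
10000 for the global index below.  These defaults are deliberately above
the minimum; the worked examples and tests use smaller values where only
the machinery, not a 5e-5 threshold, is being exercised.

## Global statistics

For comparison with plain over-representation, the Over-Representation
Index over the 1 kb upstream of the TSS (half-open `[-1000, 0)`):

$$ORI = \frac{\mathrm{Density}_S}{\mathrm{Density}_{genomic}} \times
        \frac{\mathrm{Proportion}_S}{\mathrm{Proportion}_{genomic}},$$

with Density = sites per sequence and Proportion = fraction of sequences
with at least one site.  $P_{ORI}$ is the proportion of GC-matched sampled
sets with *strictly higher* ORI (an asymmetry with $P_{dep}$'s $\ge$ that
follows the index's definition), thresholded at 0.01.  A motif with no
upstream genomic sites has an undefined ORI and is reported as an error
rather than a number.

Two follow-up tests characterize called regions.  The weak-site test
counts the motif's weak hits (relative score in the weak band, excluding
weak hits overlapping a strong hit of the same motif) inside a region and
compares with GC-matched sets.  The conservation test averages a
user-supplied per-base score track (PhastCons, phyloP, or synthetic — the
interface is just gene, TSS-relative position, score) over the bases
covered by the region's sites and standardizes it against draws of the
same number of bases at identical TSS-relative offsets in uniformly
sampled promoters — uniform, not GC-stratified, because conservation
scores are not a GC artifact being corrected for.  It is intended for
regions with at least 10 sites; fewer triggers a warning, and a constant
track (null SD 0) is an error.

## Motif scanning

Sites are predicted by log-odds scanning of both strands with
position weight matrices read from JASPAR PFM or TRANSFAC flat files.
Column probabilities use a total pseudocount of 0.8 split by the
background composition (uniform by default, configurable); relative
scores $(score - min)/(max - min)$ classify hits as strong
($\ge 0.85$) or weak ($[0.70, 0.85)$) — the MATCH-style convention; the
two fractions are configuration, not biology.  The site anchor is the
floor of the match midpoint, so implanted or genuine sites produce
symmetric Gaussian peaks; windows containing N never score.  All
overlapping hits are kept: the ZOOPS factor, not a greedy filter, handles
multiplicity, and strong/weak overlap is recorded as a flag so the
weak-site test can apply its exclusion.  Strong sites are the substrate
of $S_{\mathrm{local}}$ and the ORI; weak sites exist only for the
weak-site test.

## The synthetic promoter universe

Because the method's claims are distributional, the package ships a
generator rather than fixture files.  `generate_universe()` draws each
base independently with a position-dependent GC probability
$p_{GC}(x) = b + a\,e^{-x^2/(2w^2)}$, giving GC-profile classes with an
optional TSS-proximal GC bump — the structure the GC-matched null exists
to handle.  `implant_motifs()` overwrites a fraction of sequences
(without replacement) with words sampled column-wise from a motif's
probability matrix, at midpoints drawn around a chosen center.

This emulates what matters for the statistics — GC class structure,
controlled signal position and insertion rate — and deliberately omits
dinucleotide structure, repeats, CpG islands as discrete elements, and
inter-promoter homology.  Passing tests therefore demonstrate
correctness and calibration of the machinery on i.i.d. backgrounds, not
performance on real genomes.

The validation conditions used in the test suite and the acceptance
script: universes of 800–5000 promoters over `[-1000, +1000)` with two GC
classes (baselines 0.45 + 0.20 TSS bump vs. 0.38); input sets of 60–100
promoters; implants at −30 ± 5 bp at insertion rate 0.5; scoring on
`[-500, 500]`; 400–5000 resampled sets depending on the check.  Those
sizes keep a full run at desk scale while leaving every statistical
property (calibration of $P_{dep}$ and $P_{ORI}$, false-positive budget,
$\ge 90\%$ implant recovery, $k^\ast = 2$ on a two-class universe)
testable; they are stated here so that a reader can scale them up.

## Numerical and design notes

* Determinism: every sampling routine takes a seed and restores the RNG
  state afterwards; reruns are byte-identical, including written TSVs.
* The per-gene normalized profile matrix (`site_profiles()`) is the
  workhorse: a sampled set's profile is a column sum over member rows, so
  the genomic universe is scanned and profiled once regardless of
  `n_samples`.  `null_pvalues()` accepts it as an explicit cache.
* Empty clusters in a k-means restart are re-initialized rather than
  accepted; the contract is "best within-SS over 100 restarts", not a
  particular updater.
* `gc_profile` imputation uses the genomic bin mean so that an all-N bin
  is GC-neutral for clustering instead of dragging a profile to 0.
* Degenerate inputs fail loudly: empty promoter sets, matrices whose max
  score does not exceed their min, motifs without genomic upstream sites
  (ORI), constant conservation tracks, stratified requests exceeding a
  cluster's size.
* Known limitations: the background model is zeroth-order; scanning is
  plain log-odds without a dinucleotide correction; P_ind is based on the
  profile maximum only, so two genuine peaks in one profile share one
  gate; and the 2/3 redundancy rule compares site *counts*, not site
  identity, which can in principle keep a small region whose sites are
  disjoint from the large region's.
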