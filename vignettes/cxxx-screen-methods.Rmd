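---
title: "Methods: scoring the CXXX farnesylation screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring the CXXX farnesylation screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cxxxscreen)
```

## The screen and its readout

Protein farnesyltransferase (FTase) attaches a C15 isoprenoid to the cysteine
of a C-terminal four-residue motif, classically written CaaX
(cysteine - aliphatic - aliphatic - variable). The yeast Hsp40 co-chaperone
Ydj1 requires farnesylation, and nothing downstream of it, for growth at
elevated temperature. That makes a Ydj1 reporter carrying an arbitrary
C-terminal CXXX motif a clean in vivo sensor of farnesylation alone: a pooled
library of all 20^3 = 8,000 motifs grown competitively at a permissive (25°C)
and a selective (37°C) temperature enriches, at 37°C, exactly the variants
whose motif supports modification.

`cxxxscreen` implements the full quantitative path from that experiment's
sequencing reads to interpretable specificity rules, plus a generative
simulator of the whole screen so each stage can be validated against a known
ground truth.

## From reads to counts

Amplicon reads carry a fixed 21-nt anchor that ends with the library's Cys
codon (TGT); the 9 nt that follow are the three variable codons, one fixed
codon per amino acid (a trimer-phosphoramidite design, so no stops and no
synonym bookkeeping). Extraction (`count_replicate()`):

* locates the first exact anchor occurrence (reverse complement searched as
  a fallback; read orientation is not guaranteed). Matching is exact by
  default — the amplicon context gives no reason to absorb mismatches, and a
  1-mismatch mode exists but is off;
* rejects reads whose 9-nt insert has mean Phred below
  `min_insert_quality` (default 20), or whose insert is truncated, or whose
  codons contain a stop or a non-ACGT character;
* tallies every read as either one motif count or one rejection reason —
  assigned plus rejected always equals the total.

Replicate-level QC mirrors sequencing practice: a replicate is dropped when
fewer than `replicate_q30_fraction_min` (default 80%) of its reads have mean
Phred ≥ 30. The per-read Q30 statistic is the only quality summary the
original assay reports (≈96% of reads at Q30+, with one selective-condition
replicate excluded); the replicate-level gate value is this package's choice
and is always written into the QC report.

## Enrichment factors

Counts are pooled across the retained replicates of a condition *before*
normalization, then converted to frequencies. The enrichment factor of motif
$m$ is

$$\mathrm{EF}(m) = \frac{v_{37}(m) + c}{v_{25}(m) + c},$$

with pseudocount $c = 1$ so motifs unobserved at 25°C stay finite and motifs
absent everywhere sit at exactly 1. The abundance scale for $v$ matters: a
literal +1 on frequencies in $[0,1]$ would crush every ratio toward 1, which
is incompatible with screens of this kind spanning two orders of magnitude in
EF. The default scale is therefore counts-per-million of the pooled
condition (typical motif abundance 125 cpm, so the pseudocount is a gentle
5-10% regularizer at realistic depth and EFs are depth-invariant); raw-count
and literal-fraction modes are selectable, and the mode is recorded in the
EF table metadata and all downstream outputs.

Two estimator properties worth knowing:

* EF is a ratio of noisy abundances, so it carries a convexity bias:
  $E[\mathrm{EF}] \approx 1 + \mathrm{CV}^2(v_{25})$ per motif under no
  selection. At the screen's depth (8 replicates × 5×10^5 reads per
  condition, ≈500 reads per motif) the bias of the mean EF is
  ≈ $e^{\sigma^2} M / N \approx 2.4\times10^{-3}$ for $M = 8000$ motifs,
  $N = 4\times10^6$ pooled reads and library-imbalance lognormal
  $\sigma = 0.447$. That is the same order as three standard errors of the
  mean over 8,000 motifs, so exact mean-EF-equals-1 null checks at this
  depth sit on a knife edge by construction; rank-based and pattern-based
  summaries are unaffected.
* Quartiles are assigned by EF rank with lexicographic tie-breaks, so the
  full space splits into exactly 2,000 motifs per quartile.

## Contextual heatmaps and pattern calls

For each ordered position pair — a1×a2, a1×X, a2×X — motifs sharing the two
residues form 400 groups of exactly 20; each heatmap cell is the group's mean
EF. Because each heatmap partitions the space, the unweighted mean of its
400 cells equals the grand mean EF (asserted to 1e-9 in the tests).

Pattern detection summarizes a row (or column) as positively selected or
restrictive when at least 18 of its 20 cells lie strictly beyond a cutoff
around the grand mean; cells exactly at a cutoff never count. The cutoff is
built from the standard deviation of the 20 row (or column) means. Two
constructions are offered:

* `cutoff_type = "ci_mean"` (default): grand mean ± $z \cdot SD/\sqrt{20}$,
  a 95% confidence interval of the grand mean at $z = 1.96$ (a
  t-quantile variant is available via `use_t`).
* `cutoff_type = "sd"`: grand mean ± $z \cdot SD$.

The default is a deliberate design decision. When a block of $k$ rows is
uniformly depressed by $d$ (the situation the screen actually produces:
charged residues at a2), those rows themselves inflate the row-mean SD to at
least $\sqrt{5/19}\,|d| \approx 0.51|d|$ for $k = 4$, so $1.96\,SD > |d|$
*always* — the raw-SD cutoff is structurally unable to call a four-residue
restriction no matter how strong it is. The CI-of-the-mean form does not
have this degeneracy, and in simulations with planted restrictions it
recovers them in 20 of 20 seeded runs while calling zero patterns in null
(no-selection) screens in ≥19 of 20 runs. The pattern report always records
which construction and critical value produced it.

## The HM score

The HM score of a motif sums its three heatmap cells: the mean EF of the 20
motifs sharing its (a1, a2) pair, plus the (a1, X) mean, plus the (a2, X)
mean. Averaging 20-member groups buffers single-motif outliers while keeping
position-pair context; a score above 3 predicts prenylation-proficiency. On
the packaged 48-motif gel-shift reference set this cutoff classifies 45 of
48 motifs correctly (2 false positives among 39 predicted positive, 1 false
negative among 9 predicted negative), against 30, 38 and 17 correct for the
PrePS (> −2), SVM (> 0) and Ras-reporter-EF (> 3) predictors run through the
same classify/confusion path. Reported percentages round halves upward at
one decimal; machine outputs keep the raw fractions.

Increasing one motif's EF by $\delta$ moves its own HM score by exactly
$3\delta/20$ — the score is deliberately insensitive to single-motif noise.

## The decision tree

To turn the EF landscape into explicit rules, motifs are labelled enriched
(EF > 1) versus depleted — the threshold is a required, logged parameter;
1.0 separates growth-supported from growth-disadvantaged variants and is the
natural default for a competitive screen — and fitted with a depth-limited
binary decision tree over set-membership features: for each variable
position and each residue set of size ≤ 5, "is the motif's residue in this
set". That is 3 × Σ_{k=1..5} C(20,k) = 65,097 features; size-1 sets are
ordinary one-hot features.

The tree is grown greedily on information gain (entropy in bits), depth ≤ 3,
with every node (internal and leaf) holding ≥ 50 motifs, and deterministic
tie-breaks by feature enumeration order (position-major, then set size, then
lexicographic). The fitting contract is pinned down this tightly so results
reproduce bit-for-bit across platforms; an off-the-shelf learner cannot see
the implicit 8,000 × 65,097 feature space without materializing ~4 GB, so
`fit_caax_tree()` computes each feature's split counts from per-position
residue tallies instead (a residue-set count is the sum of its members'
tallies), and the tests verify it is node-for-node identical to the explicit
matrix fit and to an exhaustive-search oracle for root splits.

On screens simulated from the planted rules the fitted tree reads, from the
root down: restriction of D/E/K/R at a2; then restriction of K/P/R at X;
then rescue of the X restriction by I/L/M/V at a2 — with ~100% training
accuracy at realistic depth.

## Top-set logos and absence analysis

`top_fraction()` takes the highest-EF 5% (exactly 400 motifs of 8,000; ties
broken lexicographically), `pfm()` turns any motif set into per-position
residue counts and frequencies for a frequency-logo renderer, and
`absent_residues()` reports residues never observed at a position, optionally
conditioning on a residue at another position (the way one reads a 3D
projection of the enrichment space along one axis). Logo rendering itself is
delegated: the package exports matrices plus the screen's color-group
annotation (Cys blue; D/E/H/K/R green; N/Q/S/T/Y black; I/L/V red; the rest
purple).

## The synthetic screen

The simulator exists so that every pipeline stage has a testable ground
truth. It emulates, with defaults fixed at the study conditions:

* **Library**: all 8,000 motifs with lognormal abundance imbalance,
  $\sigma = 0.447$, putting the 99.5th/0.5th percentile ratio at ~10×.
* **Ground truth**: rule-based prenylation propensities — D/K/R at a2
  abolish modification (0.02); E at a2 is milder (0.15), matching its
  weaker, context-dependent restriction in heatmap calls; K/P/R at X drop
  propensity to 0.15 unless a2 carries a rescuing I/L/M/V; everything else
  sits at 0.95 with a +0.05 bonus for Q at X; truncated Gaussian noise
  (sd 0.03) on top.
* **Selection**: multiplicative growth over $G = 8$ generations,
  $w \propto (1 + s\,p)^G$ with $s = 0.3$ at 37°C and $s = 0$ at 25°C. The
  closed form keeps expected EFs analytically predictable for tests.
  Saturation of the culture is not modelled; selection strength lives
  entirely in $s$ and $G$.
* **Sequencing**: 8 replicates per condition, 5×10^5 reads each, drawn
  multinomially; the exact draw is the emitted truth table. Optional FASTQ
  emission wraps each motif's fixed codons in the 100-nt amplicon scaffold
  with per-read constant Phred qualities from N(37, 4) clipped to [25, 40]
  (≈96-97% of reads at Q30+), plus 2% junk reads (half anchor-free, half
  Q10) to exercise the QC paths. Junk reads are not in the truth table;
  clean-read qualities never fall below the insert gate, so re-counting the
  emitted FASTQ reproduces the truth table exactly.

All randomness flows from one seed; identical seeds give byte-identical
outputs, and the truth counts are drawn before (and independently of) read
emission so counts-only and FASTQ-emitting runs agree.

What the simulator does *not* emulate — PCR jackpotting, base-call errors
beyond the quality model, GGTase-I cross-modification, plasmid copy-number
variation, fitness effects unrelated to prenylation — bounds what a passing
recovery test shows: the pipeline recovers rules from data generated under
its own noise model at realistic depth, not that the original screen was
free of those artifacts.

## Problem sizes and numerical choices

The test suite and the acceptance script run the simulation batteries at the
full study scale (8,000 motifs, 8+8 replicates, 5×10^5 reads per replicate)
for 20 seeds per battery; the FASTQ round-trip uses 2+2 replicates at 10^5
reads and the byte-reproducibility check 2+2 at 2×10^4, sizes chosen to
exercise the read path thoroughly while keeping a full run in minutes on one
core. Floating-point identities (heatmap partition, HM-score oracle) are
asserted at 1e-9; split-gain ties use a 1e-12 guard; strict inequalities
everywhere follow the conventions above (classification cutoffs, pattern
cutoffs, EF label threshold).

## Known limitations

* The published screen's exact abundance scale for the pseudocount is not
  recoverable from its description; the cpm default reproduces the *shape*
  of the reported EF landscape but individual published EF values can only
  be checked against the original supplementary tables, which are not
  packaged.
* The mean-EF convexity bias above means "mean EF = 1" null checks at
  realistic depth are only approximate; prefer the pattern-based null
  calibration.
* With selection modelled as $(1+sp)^G$ at $s=0.3$, simulated EFs span
  roughly 0.1-2; the extreme published EFs (≈0.04 and ≈14) arise from
  near-zero denominators under library imbalance, which the simulator only
  produces at lower depth.
* `encode()` materializes its feature matrix; use it for subsets, and
  `fit_caax_tree()` for the full space.
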