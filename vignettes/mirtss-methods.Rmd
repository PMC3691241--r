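---
title: "Predicting brain-specific miRNA transcription start sites: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting brain-specific miRNA transcription start sites: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirtss)
```

## The problem

Primary transcripts of microRNAs are poorly annotated: the mature miRNA and
its hairpin precursor are catalogued, but the transcription start site (TSS)
of the primary transcript — often tens of kilobases upstream — usually is
not. `mirtss` frames TSS recognition as binary classification of 1 kb
genomic windows: does this window contain a (brain-expressed) miRNA TSS or
not? The signal comes from two sources: genetic sequence composition
(promoters are CpG-island-rich and carry characteristic motifs) and
epigenetic state (promoter CpG islands of active genes are hypomethylated,
and DNA methylation is tissue-specific, so brain methylomes carry
brain-specific information).

## Feature families

All sequence statistics are computed on the *valid* part of a window only:
maximal runs of uppercase `A/C/G/T`. Lowercase (soft-masked, repeat-derived)
bases and `N` both terminate runs and are excluded from every numerator and
denominator. This matters because repeat elements such as Alu are CpG-rich
and would otherwise mimic promoter islands; the package's tests verify that
soft-masking a block and hard-masking it to `N` give bit-identical features.

* **NM (340):** overlapping counts of every word of length $k = 1,\dots,4$,
  normalised by the total valid length $L$ of the window. For any $k$ the
  340-feature block satisfies $\sum_w \mathrm{NM}_w = \sum_s
  \max(\ell_s - k + 1, 0) / L$ over segments $s$ of length $\ell_s$, which
  the tests assert.
* **PL (20):** reverse-complement palindromes. Sixteen per-pattern
  frequencies, one for each length-4 palindrome (determined by its first two
  bases), plus one aggregate count of all palindromic windows for each half
  length $h \in \{2,3,4,5\}$. The 16 per-pattern values sum to the $h=2$
  aggregate by construction; the tests assert this identity as a guard
  against counting-mode drift.
* **S (3):** the promoter-associated wildcard motifs `G**G`, `G**G**G` and
  `GC**GC**GC` (`*` = any base), counted overlapping and normalised by $L$.
* **CI (8):** CpG-island statistics. For each tiling length
  $w \in \{125, 250, 500, 1000\}$ bp the window is cut into non-overlapping
  tiles and per tile we compute the observed/expected CpG ratio
  $\mathrm{O/E} = N_{CpG} \cdot L / (N_C \cdot N_G)$ and the G+C content
  $(N_C + N_G)/L$, on unmasked bases. The feature per length is the
  **maximum** over tiles: a promoter island is a localized peak, and a mean
  would dilute a 250 bp island inside a 1 kb window (the mean is available
  by configuration). Degenerate tiles ($L = 0$, or no C or no G) score 0
  rather than raising a division error.
* **MT (one per methylome):** for each methylation track, with sites $s$ in
  the window carrying methylation probability $p_s$ and read coverage
  $r_s$,
  $$\mathrm{MT} = \frac{1}{\max(n, 1)} \sum_{s} p_s \frac{r_s}{r_s + c},$$
  where $n$ is the number of CpG islands in the window (maximal runs of
  125 bp tiles passing the Gardiner-Garden thresholds O/E ≥ 0.6 and
  G+C ≥ 0.5) and $c$ is a coverage half-saturation constant (default 10
  reads). The saturating weight $r/(r+c)$ rewards high methylation
  probability while discounting low-coverage calls, and the island-count
  normalisation ties the score to promoter-island structure. The exact
  functional form is a design choice of this package realising that
  rationale; it is isolated behind `methylation_score()` so an alternative
  can be swapped in.

With 14 methylome tracks the default space is $340+20+3+8+14 = 385$
features, or 371 without the MT block.

### Window extraction

Coordinates are 0-based half-open throughout; BED input is native and
methylation tracks (1-based, MethylomeDB-style) are shifted on read. A
window is `total_len` bp (default 1000) with `upstream` bp (default 500)
preceding the TSS *in transcript orientation*: on the minus strand the
genomic span is mirrored around the TSS base and the reverse complement is
returned, preserving soft-mask case base-wise. Windows that would cross a
chromosome end are rejected rather than clipped — a partial window would
silently shrink every length-normalised feature. The upstream/downstream
split is configurable because there is no single canonical choice.

## Feature ranking and selection

**F-score.** For feature $i$ with class means $\bar x_i^{+}, \bar x_i^{-}$,
grand mean $\bar x_i$ and $n_\pm$ samples per class,
$$F_i = \frac{(\bar x_i^{+}-\bar x_i)^2 + (\bar x_i^{-}-\bar x_i)^2}
  {\tfrac{1}{n_+-1}\sum_k (x^{+}_{k,i}-\bar x_i^{+})^2 +
   \tfrac{1}{n_--1}\sum_k (x^{-}_{k,i}-\bar x_i^{-})^2}.$$
It is shift- and scale-invariant (tested). A perfect separator with zero
within-class variance returns `Inf`, which sorts ahead of all finite
scores; ties, including between several `Inf` sentinels, fall through to
lexicographic feature-name order so rankings are bitwise reproducible.

**Normalised mutual information.** Features are discretised into three
equal-frequency bins (quantile cut points; boundary ties go to the lower
bin; constant features collapse to one state). Equal-frequency binning is
used because most k-mer features are heavily zero-inflated and
equal-width bins would put nearly all mass in one bin. Mutual information
is the empirical plug-in estimate with natural logs, normalised as
$\mathrm{NI}(X;Y) = I(X;Y)/\sqrt{H(X)H(Y)} \in [0,1]$, defined as 0 when
either variable is constant.

**VWMRmR.** Greedy forward selection. The first feature maximises
$\mathrm{NI}(f; c)$ against the class $c$; with $m$ features already in
$S$, the next maximises
$$J(f) = \mathrm{NI}(f;c) - w(m)\,\frac{1}{m}\sum_{g \in S}\mathrm{NI}(f;g).$$
The class-relevance weight is fixed while the redundancy weight grows with
the selected set; the default schedule $w(m) = m/(m+1)$ starts at the
classic mRMR balance of ½ and approaches parity. It is a function-valued
argument: $w \equiv 0$ recovers pure relevance ranking and $w \equiv 1$
mRMR-with-NMI, both used as test limits. One numerical subtlety: $J$ is
compared after rounding to 10 decimals, so candidates whose criteria are
equal up to floating-point summation order tie exactly and fall through to
the name-order tie-break — without this, selection order would depend on
the summation order inside the MI sum. The package's tests check every
greedy step against an independently written brute-force implementation on
hundreds of small random matrices.

**Rank summaries.** Rankings are summarised per feature family (min, max
and mean 1-based rank) for the ten categories NM, NM-CG (words containing
`CG`), NM-1..NM-4, CI, PL, S and MT, derived mechanically from the
feature-name scheme; the categories overlap by design.

## Classifier and evaluation

A random forest (the `randomForest` package) with `num_trees` = 100 and
`num_features` = ⌈√d⌉ tried per split, both configurable;
`rf_sensitivity_scan()` cross-validates a grid when those defaults need
revisiting for a new dataset. Evaluation is stratified k-fold
cross-validation (default 5 folds) repeated (default 10 times) with folds
re-randomised per repeat from `seed + repeat`; stratification matters
because at ~26% positives an unstratified fold can lose the positive class
entirely. Per-fold confusion matrices yield accuracy, sensitivity,
specificity and precision (as percentages) and the Matthews correlation
coefficient, pooled into a mean and standard deviation per criterion. Zero
denominators map to 0 (with a warning for Sn/Sp/Pr; silently for MCC, the
usual convention). MCC is invariant under swapping the two classes and
negates under label flip — both asserted as tests.

## The synthetic study

Real training data for this problem requires a reference genome and brain
methylome tracks; the package instead ships a generator whose outputs have
the statistical structure the pipeline assumes, so every stage is testable
offline. Defaults: 52 positive and 148 negative 1 kb windows (26%
positives) and 14 methylome tracks.

* **Background** is i.i.d. mildly AT-rich sequence (A/T 30%, C/G 20%) with
  CpG dinucleotides thinned to 25% of their chance rate — genomic
  background is CpG-poor.
* **Positives** carry a centred 250 bp island block targeting G+C = 0.6 and
  CpG O/E = 0.9 in expectation, and the three S motifs planted in the
  flanks at `motif_boost` (default 3) times their background rate.
  Planting is CpG-neutral: a background `C` that would abut a planted `G`
  is rewritten, so the motif family does not leak into the CpG family (the
  generator's tests check that the central island out-scores the flanks and
  that `motif_boost = 1` plants nothing detectable).
* **Negatives** are background; half of them (configurable) receive a
  300 bp soft-masked CpG-rich Alu-like decoy that a correct extractor must
  ignore.
* **Methylomes**: every unmasked CpG site gets
  $p \sim \mathrm{Beta}(1, 9)$ in positives (hypomethylated promoters) or
  $\mathrm{Beta}(9, 1)$ in negatives, and coverage
  $r \sim 1 + \mathrm{Poisson}(19)$.
* Windows are embedded, strand-randomised (minus-strand windows as reverse
  complements), into one synthetic chromosome with `N` spacers, so the
  FASTA + BED + track file path is exercised end to end. All output is a
  pure function of the configuration seed.

`null_sim_config()` removes every planted difference and balances the
classes, giving a negative control whose cross-validated accuracy sits at
chance.

What passing on this data shows — and what it does not. The generator
validates the machinery: coordinate conventions, mask handling,
normalisations, selection and evaluation logic, and that planted signal of
each family is recoverable (cross-validated accuracy at the defaults is
effectively 100%, and the CI and MT families appear in the VWMRmR top 30
across seeds). It does not emulate real genome composition (isochores,
repeat taxonomy, motif grammar), assay noise structure, or the much weaker
class separation of real promoter data, so performance numbers on
synthetic data say nothing quantitative about performance on a real
genome.

## Problem sizes and reproducibility

The shipped tests and the acceptance script use the generator's default
study (200 windows, 14 tracks), 5-fold × 5-repeat cross-validation,
oracle comparisons on matrices up to 8 features × 40 samples (100 seeded
trials), and mask-equivalence over 100 random 1 kb windows — sizes chosen
so the whole suite re-runs in a few minutes on one CPU while still
exercising every code path at the defaults. Every stochastic step takes an
explicit integer seed, and repeated runs are byte-identical.

## Known limitations

* The MT score is one reasonable realisation of "reward methylation
  probability, discount low coverage, normalise by island count"; other
  forms (e.g. coverage-weighted means) are plausible and can be swapped in
  behind `methylation_score()`.
* Equal-frequency discretisation with 3 bins is a robust default but
  discards within-bin ordering; very finely structured features may prefer
  more bins (`n_bins` is exposed).
* The island count `n` uses fixed 125 bp tiles, not a segmentation
  algorithm; islands shorter than a tile or split across a tile boundary
  can be merged or missed.
* `randomForest` holds the full matrix in memory; at 385 features and
  thousands of windows this is trivial, but genome-wide scanning would
  need a streaming design.
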