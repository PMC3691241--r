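# mirtss

Prediction of microRNA transcription start sites (TSSs) expressed in brain
tissue, from genetic **and** epigenetic signals.

Most miRNA primary transcripts are unannotated: the hairpin is catalogued,
the promoter is not. `mirtss` treats TSS recognition as binary
classification of 1 kb genomic windows and implements the full pipeline:

1. **Feature extraction** from soft-masked sequence and per-sample DNA
   methylation tracks — five families, computed only on the non-repetitive
   (uppercase) part of each window:
   * `NM` — 340 normalised k-mer frequencies (k = 1..4),
   * `PL` — 20 reverse-complement palindrome features (16 length-4
     patterns + aggregates for half-lengths 2–5),
   * `S` — the promoter motifs `G**G`, `G**G**G`, `GC**GC**GC`,
   * `CI` — max CpG observed/expected ratio
     `O/E = N_CpG · L / (N_C · N_G)` and G+C content over non-overlapping
     tiles of 125/250/500/1000 bp,
   * `MT` — one score per brain methylome:
     `(1/max(n,1)) · Σ_s p_s · r_s/(r_s + c)` over methylation sites
     (probability `p`, coverage `r`, island count `n`),

   giving 371 features, or 385 with 14 methylome tracks.
2. **Feature ranking/selection** by the two-class F-score and by VWMRmR —
   greedy maximal-relevance / minimal-redundancy selection on normalised
   mutual information, `J(f) = NI(f;c) − w(m)·mean_{g∈S} NI(f;g)` with a
   redundancy weight `w(m) = m/(m+1)` that grows as features accumulate.
3. **Classification** by random forest, evaluated with repeated stratified
   cross-validation and reported as accuracy, sensitivity, specificity,
   precision and Matthews correlation coefficient.

A seeded synthetic-data generator (promoter-like positives with CpG
islands and motifs, repeat-decoy negatives, beta-distributed methylomes)
makes the whole pipeline testable without any genome download. See
`vignettes/mirtss-methods.Rmd` for models, assumptions and design choices.

## Worked example

Simulate a study, extract features through the file formats (FASTA + BED +
methylome TSVs), cross-validate, and select features:

```r
library(mirtss)

dir <- tempfile()
cfg <- load_config()                       # defaults; YAML-overridable
ds  <- cmd_simulate(cfg, dir)              # genome.fa, loci.bed, 14 tracks
fm  <- cmd_extract(ds$genome, ds$bed, ds$tracks, cfg,
                   file.path(dir, "matrix.tsv"), labels_path = ds$truth)
fm
#> feature_matrix: 200 samples x 385 features (52 positive, 148 negative)

cross_validate(fm, folds = 5, repeats = 5, rf_config(seed = 1))
#>   criterion  mu sigma
#> 1       Acc 100     0
#> 2        Sn 100     0
#> 3        Sp 100     0
#> 4        Pr 100     0
#> 5       MCC   1     0

head(as.data.frame(vwmrmr_select(fm, 30)), 5)
#>   rank    feature score
#> 1    1 NM_k4_GTGG 0.602
#> 2    2  S_G**G**G 0.399
#> 3    3  NM_k3_GGG 0.323
#> 4    4 NM_k4_GGTG 0.308
#> 5    5   NM_k2_CG 0.289
```

The synthetic study is strongly separated by construction, so
cross-validated accuracy saturates at 100% and the selected list is led by
CpG/G-rich words, the planted `S` motif and (further down) `CI` and `MT`
features — the `score` column is the selection criterion `J` at the step
each feature was picked. `category_rank_summary()` condenses a ranking
into per-family min/max/mean ranks (NM, NM-CG, NM-1..4, CI, PL, S, MT).

A shell entry point wrapping the same commands
(`simulate | extract | select | train | evaluate | predict`) is installed
at `system.file("cli", "mirtss.R", package = "mirtss")`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","mirtss.R",package="mirtss"))')" \
    simulate --out /tmp/study --seed 1
```

Exit codes: 0 ok, 2 validation/usage error, 1 runtime error.

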