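# aflpdelimit

Delimiting genetic clusters from dominant AFLP markers — with the scoring
error made explicit — plus the companion sequence-character analyses
(indel coding, Fitch parsimony, bootstrap).

## The problem

Automated scoring of AFLP electropherograms produces many polymorphisms but
poor reproducibility: duplicate amplifications of the same DNA can disagree
at 5–20% of markers, mostly because peaks near a bin edge or an intensity
threshold flip between runs. Left uncorrected, this inflates apparent
within-cluster variation and blurs the between/within contrast that
species-delimitation studies depend on. `aflpdelimit` implements the whole
analysis as a tested pipeline:

* **Binning and three-state scoring.** Peaks are filtered (window
  `[100, 500)` bp, threshold 30 RFU, max width 1.5 bp), binned at 0.5 bp,
  per-sample signal is normalised by total intensity, and each bin is
  called against its maximum intensity *M* over samples:
  state = `0` if *r* < 0.10, `?` if 0.10 ≤ *r* ≤ 0.20, `1` if *r* > 0.20,
  where *r* = intensity / *M*.
* **Replicate QC.** For replicate profiles *x*, *y* the difference rate is
  *e* = #{bins: {x,y} = {0,1}} / #{bins: both determinate}. A two-step
  filter deletes (1) every bin containing a `?`, then (2) every bin at
  which any replicate pair disagrees; afterwards *e* = 0 for every pair by
  construction.
* **Split network.** p-distances *d(i,j)* (pairwise-complete over
  determinate calls) are decomposed by NeighborNet: an agglomerative
  circular ordering, then non-negative least squares
  min‖A·w − d‖², w ≥ 0, over the ordering's n(n−1)/2 interval splits
  (A the split-metric incidence). Output is SplitsTree-compatible NEXUS.
  Groups are delineated by single-linkage at a chosen *k*.
* **Sequence track.** Simple indel coding (each positionally distinct gap
  becomes one binary character; longer covering gaps score `?`),
  variable / parsimony-informative counts, Fitch parsimony (exact
  branch-and-bound ≤ 14 taxa, or random-addition + NNI heuristic),
  zero-length-branch condensation, strict consensus, and column bootstrap.
* **Synthetic truth.** Seeded generators emit AFLP peak tables with known
  cluster structure and replicate noise from binning/threshold effects
  (calibrated so replicate error lands in the empirically observed
  6.1–17.2% band), and alignments evolved on known trees — so every stage
  is testable without external data.

## Worked example

```r
library(aflpdelimit)
cfg <- run_config(simulate = paper_like_config(seed = 1),
                  out_dir = "aflp-run", k_groups = 3, seed = 1)
report <- run_pipeline(cfg)

c(fragments = report$fragments_total, step1 = report$bins_step1_removed,
  step2 = report$bins_step2_removed, retained = report$bins_retained)
#> fragments     step1     step2  retained
#>      1195       725       318       152

round(100 * report$replicate_error_range, 1)   # replicate error, %
#> [1]  8.5 13.1
```

1195 scoreable fragments were called across the two simulated primer-pair
channels; the pre-filter replicate difference rates (8.5–13.1%) sit in the
range typical of automated AFLP scoring. Step 1 removes the 725 bins with
any ambiguous (10–20%-band) call and step 2 the 318 bins discordant between
replicates, leaving 152 reproducible characters. The reduced matrix still
recovers the three simulated clusters perfectly (and its NeighborNet
explains 99.99% of the squared distances):

```r
grp <- unlist(report$networks$reduced$groups)
table(grp, sub("_.*$", "", names(grp)))
#>    
#> grp C1 C2 C3
#>   1  8  0  0
#>   2  0  8  0
#>   3  0  0  8
```

Artifacts written under `out_dir`: binned matrices, call matrices
(CSV + NEXUS), replicate-error table, filter trace, PHYLIP distances,
splits NEXUS per variant, group assignments, a JSON report and a
reproducibility manifest. A thin CLI wrapper lives in
`inst/scripts/aflp-delimit` (`run`, `simulate` subcommands).

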