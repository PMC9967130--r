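# ionframes

MS1 ion-current frame quantification for label-free DDA proteomics, with
the downstream statistics of a metastasis-marker exosome study: altered-
protein gating, six-pattern classification, a median-split Kaplan-Meier
survival screen, and gene-set over-representation.

## The problem

In data-dependent acquisition (DDA) LC-MS, MS2 identification scans are
triggered stochastically, so a peptide identified in one run often lacks
an identification in another even though its MS1 ion current is present
in every run. Pipelines that quantify only identified features produce
matrices riddled with run-level missing values. `ionframes` takes the
MS1 ion-current route instead: identifications from *any* run define
**frames** — fixed m/z x retention-time windows (10 ppm, 1 min by
default) on a common aligned timescale — and the ion current inside every
frame is integrated in **every** run. The protein matrix has a value in
every cell by construction.

The pipeline, per run cohort:

1. **Alignment** — base peak chromatograms, banded dynamic time warping
   with local cross-correlation refinement, monotone piecewise-linear
   warps; reference chosen by rank-combining pairwise alignment scores
   and total BPC intensity.
2. **Frames** — MS2 precursor events of the same peptide/charge merged
   within 10 ppm and 1 min (single linkage); per-run extracted-ion traces
   (most intense in-window peak per scan) integrated by trapezoid.
3. **Quantification** — dataset-wide median-of-ratios normalization,
   principal-component-based peptide outlier removal, protein roll-up
   with a >= 2 unique-peptide rule and zero-flooring.
4. **Differential gates** — one-way ANOVA on log2 abundances across all
   groups; *altered* = p < 0.05 and a tumor/control ratio > 1.5 or
   < 0.67 in >= 1 comparison; *metastasis-specific* = altered and the
   same ratio band in >= 1 metastatic/non-metastatic comparison.
5. **Patterns** — z-scored 4-group profiles (non-metastatic, primary,
   kidney, lung) classified by a deterministic cascade into six abundance
   patterns; the non-metastatic pattern is excluded from the marker set.
6. **Survival screen** — median-split Kaplan-Meier + log-rank per marker,
   with an abundance/hazard concordance call.
7. **Enrichment** — one-sided Fisher exact tests against user-supplied
   gene sets (GMT), BH-adjusted.

A synthetic LC-MS cohort generator with full ground truth (fold changes,
RT drifts, intensity biases, outlier peptides, stochastic MS2 sampling)
drives calibration and parameter-recovery testing; see the methods
vignette (`vignettes/ionframes-methods.Rmd`) for the model and every
tunable.

## Worked example

```r
library(ionframes)

# a 5-group x 4-replicate cohort: control EpH4, non-metastatic 116,
# metastatic 1424 and its kidney (1424.1) / lung (1424.2) derivatives
design <- cohort_design(seed = 3)          # 200 proteins, 5 peptides each
sim    <- simulate_cohort(design)

cfg <- pipeline_config(design$run_group, design$control_group,
                       design$non_metastatic_group,
                       design$metastatic_groups, seed = 3)
res <- run_pipeline(sim$runs, sim$psm_table, cfg)
res
#> pipeline_result (config 378b36a3, seed 3)
#>   reference run: EpH4_4
#>   frames: 1000   proteins: 200
#>   altered: 20   metastasis-specific: 18 (17 after pattern exclusion)

round(res$cv, 1)    # mean intra-group CV (%), one per group
#>   EpH4    116   1424 1424.1 1424.2
#>   14.2   14.1   14.3   14.6   13.7

truth <- sim$truth$true_altered
length(intersect(res$altered, truth)) / length(truth)   # sensitivity
#> [1] 1
```

The run prints: a reference run picked for alignment, 1000 frames built
from ~14,000 PSMs (one frame per simulated peptide), a complete 200 x 20
protein matrix, exactly the 20 planted proteins passing the altered gate
(sensitivity 1, no false calls at this seed), and intra-group CVs of
~14%, matching the generator's 15% biological noise. `res$patterns`
holds the six-pattern labels for the metastasis-specific set;
`write_pipeline_outputs(res, "out/")` writes the CSV artifacts.

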