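---
title: "MS1 ion-current frame quantification: models, parameters, and design choices"
author: "ionframes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MS1 ion-current frame quantification: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Data-dependent acquisition (DDA) LC-MS proteomics triggers MS2
identification scans stochastically: a peptide confidently identified in
one run may simply never receive an MS2 scan in another, even though its
MS1 ion current is present in every run. Identification-driven
quantification therefore produces ragged matrices with run-level missing
values. `ionframes` implements the alternative that MS1 ion-current
pipelines use: identifications from *any* run define quantification
*frames* — fixed m/z-by-retention-time windows on a common, aligned
timescale — and the ion current inside each frame is integrated in *every*
run, identified or not. Missingness is removed structurally, not imputed.

The downstream analysis mirrors a five-cell-line exosome proteomics
design: a non-tumorigenic control, a tumorigenic non-metastatic line, a
primary-site metastatic line, and its kidney- and lung-metastasis
derivatives (four replicates each). On top of the protein matrix the
package provides the differential gates (one-way ANOVA plus fold-change
thresholds), a six-pattern classification of metastasis-specific
proteins, a median-split Kaplan-Meier/log-rank marker screen, and Fisher
over-representation statistics.

# Pipeline stages and their models

## Retention-time alignment

Each run is summarized by its base peak chromatogram (BPC): the maximum
centroided peak intensity per MS1 scan. BPCs are max-binned at
`bin_s = 5` s, log-transformed, and z-normalized — the z-normalization
matters, because per-run global intensity bias otherwise makes dynamic
time warping (DTW) distort time to explain amplitude. A banded DTW
(Sakoe-Chiba band `band_s = 240` s — wide enough that two runs drifting
±60 s in opposite directions, plus slope divergence, stay inside the
band) yields a coarse monotone path, which is summarized into anchors
every `anchor_s = 60` s (median matched time per window). Because the
integer-bin DTW path wanders by a few bins on busy chromatograms, every
anchor is then refined by local cross-correlation: the shift of the
reference signal (within ±30 s, 1 s steps, parabolic sub-step
interpolation) that maximizes the correlation with the run signal in a
±60 s window around the anchor. Anchors whose best local correlation
stays below 0.5 keep the DTW estimate, and a running median over the
anchor offsets replaces any isolated anchor that locked onto a spurious
correlation peak with its neighborhood consensus (LC drift is locally
smooth, so a single anchor disagreeing with its neighbors by tens of
seconds is an artifact, not signal). The final warp is strictly
monotone piecewise-linear; on simulated cohorts with
linear drifts up to ±60 s it recovers the injected drift to within a few
seconds over the central 80% of the gradient (the acceptance suite
asserts ≤ 6 s).

The alignment reference is chosen by a scale-free rank combination: the
rank of each run's mean pairwise alignment score (Pearson correlation of
DTW-matched signals, quantized to 3 decimals so floating-point noise
cannot separate effectively identical alignments) plus the rank of its
total BPC intensity; ties break to the lexicographically smallest run id.
Ranks rather than raw values are combined because no weighting of the two
criteria is canonically defined.

The choice to align on BPCs (not full ion maps) is a declared
simplification: it reproduces the required contract — a monotone RT
correction with an alignment score — at a fraction of the cost, and its
recovery error is measured directly in the tests.

## Frame generation and extraction

MS2 events of the same peptide and charge are merged into one frame
target when their precursor m/z agree within 10 ppm and their aligned RTs
within 60 s (single linkage). The frame center is the
precursor-intensity-weighted mean m/z and the median aligned RT. Both
window constants are the package defaults and are configurable.

Extraction is deliberately simple and auditable: per MS1 scan within
±30 s of the frame center, the single most intense peak within ±10 ppm of
the frame m/z (robust to neighboring isotopes entering the window), zero
if none; the frame area is the trapezoidal integral of that trace. A
window holding a single scan uses area = intensity × cycle time. Whether
an ion-current pipeline should integrate apex intensity or full peak area
is not uniquely defined; trapezoidal area is the declared choice here, and
the brute-force oracle in the tests pins its exact semantics. Charge
states are extracted as separate frames and summed at peptide roll-up.

## Normalization

Dataset-wide median-of-ratios at the frame level: each run's factor is
the median over frames of the log-ratio to the frame's geometric-mean
"reference run", renormalized to mean zero in log space. This is the
standard robust choice when most frames are unchanged; it recovers
injected per-run biases in [0.5, 2] with Pearson r ≥ 0.99 under 10-15%
measurement noise, and is exactly idempotent.

## Peptide outlier removal

Peptides of one protein should move in parallel; contaminated or
mis-assigned peptides do not. The detector scores each peptide against
the first principal component of the *other* peptides' row-centered
log2 profiles — the leave-one-out consensus, oriented towards the
majority of the remaining peptides. A peptide's residual is its
distance to the *positive half-line* of that component: a concordant
peptide keeps only orthogonal noise, while an anti-correlated peptide
keeps its full norm (plain orthogonal residuals would pass it, since a
sign-flipped profile lies on the same line). The leave-one-out
construction matters for a second failure mode: in a protein with no
real group signal, a single contaminated peptide *is* the direction of
largest variance, so a component fitted on all peptides would absorb it
and report a near-zero residual; fitted on the others only, the
contaminated profile sticks out.
Peptides with residual above median + 3 × MAD are flagged, with two
guards: proteins with fewer than 3 peptides are never flagged, and at
least 2 peptides always survive. On simulation the detector catches an
injected anti-correlated peptide among five concordant ones in ≥ 95% of
seeds while falsely flagging ≤ 5% of clean peptides.

## Protein roll-up

Surviving unique peptides are summed per protein and sample (sum, not
mean or top-3, preserves the linearity proven at the frame level;
configurable in principle but the tested contract). Proteins with fewer
than two surviving unique peptides are dropped, mirroring the
two-unique-peptide identification contract of the upstream search.
Remaining zero cells — a frame window genuinely empty in some run — are
floored to half the smallest positive value of the matrix so every ratio
is computable; the result is a matrix with no missing cells by
construction.

## Differential gates

One-way fixed-effects ANOVA (via `stats::oneway.test`, equal variances)
on log2 abundances across all five groups, plus linear-scale ratios of
arithmetic group means. A protein is *altered* when p < 0.05 (strict) and
at least one tumor-vs-control ratio is > 1.5 or < 0.67 (strict); it is
*metastasis-specific* when additionally at least one
metastatic-vs-non-metastatic ratio passes the same band. No
multiple-testing correction is applied by default — the raw-p gate is the
analysis being reproduced — but a BH option exists. Log2 transformation
before ANOVA is a declared choice (the transform is not uniquely
specified for this kind of gate); ratios are computed on the linear scale
with a geometric-mean option.

## Pattern classification

Metastasis-specific proteins are summarized by their mean log2 abundance
in the four tumorigenic groups (non-metastatic NM, primary site P, kidney
metastasis K, lung metastasis L), z-scored per protein across the four
groups (sample sd). Rather than reading patterns off a dendrogram by
eye, assignment is a deterministic cascade with margin `delta = 0.5`
z-units: NON_METASTATIC when NM leads all others by ≥ delta; METASTATIC
when all of P, K, L exceed NM by ≥ delta; PRIMARY_SITE when P leads;
KIDNEY_LUNG when K and L both clear NM and P; then KIDNEY or LUNG when
one leads alone; otherwise the argmax group's label with a fixed
NM → P → K → L tie-break. The margin is not canonically defined by the
underlying analysis; 0.5 is the default and the tests exercise the
cascade against an independently coded rule table across random
profiles. Hierarchical clustering (average linkage, 1 − Pearson distance
on the z-scores) is retained for ordering and visualization; the
NON_METASTATIC pattern is excluded from the final marker set, since by
definition it does not represent a metastasis-driven change.

## Survival screen

For each marker, the cohort is split at the median expression (ties to
the low arm, making the split deterministic), Kaplan-Meier curves are
estimated, and a standard two-group log-rank test (1 df) is computed,
both implemented directly in the package (the `survival` package serves
as an independent cross-check in the tests). The hazard direction is +1
when the high-expression arm has more observed than expected events. A
marker is *concordant* when abundance up in metastatic cells coincides
with high expression being hazardous, or abundance down with low
expression being hazardous. P-values are tiered at raw p < 0.05
(significant) and p < 0.1 (suggestive), again mirroring a raw-p screen
with a BH option off by default. Under the null the empirical type-I
error at α = 0.05 sits within [3.5%, 6.5%] (1000-cohort simulation in
the acceptance suite).

## Over-representation

One-sided Fisher exact tests per gene set against a background universe
defaulting to all quantified proteins (standard ORA practice), BH
adjustment across sets. Exact Fisher is the declared statistic (some
popular web tools use an EASE-penalized variant).

# The synthetic cohort generator

The generator is first-class, tested code: it defines the conditions
under which every statistical claim in the test suite is measured.

Each peptide receives a random m/z in [400, 1500] Th, a reference RT
uniform over the gradient (default 300-3000 s), and a base intensity
drawn log-normal (meanlog 20, sdlog 1.5 on the natural-log scale), giving
the several-orders-of-magnitude dynamic range real exosome proteomes
show. Peptides elute as Gaussians (sigma = 6 s) sampled on a 2 s MS1
cycle, so a whole peak fits comfortably inside a 1-min frame window.
Per run, scan times follow a linear drift `rt_run = slope * rt_ref +
offset` (slope in [0.99, 1.01], offset in [-60, 60] s by default) and all
intensities carry a global bias factor (log-uniform in [0.5, 2]). MS2
events are placed at the peak apex of each run where the precursor is
"sampled" (probability `ms2_sampling_rate`, default 0.7 — a realistic DDA
identification rate; the value is not dictated by the emulated study), so
runs genuinely differ in which peptides carry identifications.

Noise has two multiplicative log-normal components. `noise_cv`
(default 0.15) acts per protein and run, shared by all peptides of the
protein — biological replicate variability — so the protein-level
intra-group CV tracks `noise_cv` itself rather than averaging away over
peptides; the default brackets the 13-18% intra-group CVs typical of
replicated exosome preparations. `peptide_noise_cv` (default
`noise_cv / 3`) acts per peptide and run — measurement jitter — and is
what the outlier detector sees as its noise floor. Tying its default to
`noise_cv` keeps `noise_cv = 0` an exactly noise-free cohort, which the
exactness tests rely on. Outlier peptides (default 1%) receive an
independent random group profile (log2 fold changes uniform in [-2, 2]),
decoupling them from their protein. Small Gaussian m/z errors (1.5 ppm,
1 sd) are applied to peak and precursor m/z.

The default design *is* the acceptance condition: 5 groups × 4
replicates, 200 proteins × 5 peptides, 20 proteins planted at
|log2 FC| = 1 in a random non-empty subset of tumor groups. Ground truth
(true fold-change matrix, outlier set, drift/bias parameters, and the
implied altered / metastasis-specific sets) is derived deterministically
from the design.

What the generator does **not** emulate: isotope envelopes, charge-state
coelution, chimeric spectra, peak-shape asymmetry, nonlinear (non-affine)
RT distortions, missing-not-at-random identification bias, and shared
(non-unique) peptides (these exist in the data model and tests, but the
generator emits unique peptides only). Passing tests therefore certify
the pipeline's contracts — alignment recovery, extraction exactness,
normalization, gating calibration — under a clean, controllable model of
DDA data, not performance on any real instrument's quirks.

# Numerical choices and degenerate inputs

* All RTs are in seconds, m/z in Thomson; groups are referenced by label.
* Extraction windows are closed intervals; the m/z window is relative to
  the frame center.
* Warps are strictly monotone by construction (`cummax` plus a 1e-6 s
  perturbation where anchors tie); evaluation outside the anchor span
  clamps with a warning.
* A single-scan extraction window uses area = intensity × cycle time
  (a trapezoid needs two points).
* An all-censored survival arm yields a flat Kaplan-Meier curve at 1; a
  log-rank with zero variance returns chi-square 0, p = 1.
* Proteins with zero variance everywhere get ANOVA p = 1; constant
  4-group profiles get z = 0 with a warning.
* Normalization refuses runs with no nonzero frame and warns below 10
  frames.
* Determinism: all simulation flows through one seeded RNG scope that
  restores the caller's RNG state; the pipeline itself is
  deterministic, and outputs carry a config hash and seed.

# Problem sizes used by the test and acceptance suites

Unit tests run on 12-40-protein cohorts with a 300-900 s gradient;
the end-to-end acceptance checks run the full 200-protein, 20-run default
cohort for 50 seeds, 1000 null proteins for ANOVA calibration, and 1000
simulated cohorts (n = 200) for log-rank calibration. These sizes were
chosen so the whole suite exercises every stage at the study's design
scale while remaining comfortable to run on a laptop; they are stated
here so results are reproducible at exactly these sizes.

# Known limitations

* BPC-based alignment cannot separate co-eluting content changes from RT
  drift; severely dissimilar runs will align on the strongest shared
  features only (the alignment score makes this visible).
* The frame model quantifies the most intense in-window peak; heavy
  interference inside 10 ppm × 1 min would be integrated as signal.
* The pattern cascade is a determinization of an interpretive step; near
  the margin delta the label is sensitive to noise in the group means
  (by design, the fallback is the argmax label).
* The survival screen is a marginal, median-split screen — not a
  proportional-hazards model — and inherits the multiplicity behavior of
  a raw-p screen.
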