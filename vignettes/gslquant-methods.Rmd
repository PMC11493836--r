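---
title: "Methods: multiplexed MRM quantification of serum glycosphingolipids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiplexed MRM quantification of serum glycosphingolipids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gslquant)
```

## The measurement problem

Gangliosides (sialylated glycosphingolipids) and their neutral precursors
share a common architecture: a ceramide (sphingoid base + N-acyl chain)
carrying a glycan headgroup built from hexose (Hex), N-acetylhexosamine
(HexNAc) and N-acetylneuraminic acid (NeuAc) residues. In GM2-gangliosidosis
(Tay-Sachs and Sandhoff disease), deficient beta-hexosaminidase A blocks the
GM2 -> GM3 step, so serum GM2 accumulates while GM3 falls; Sandhoff disease
additionally accumulates GA2. A single scheduled, polarity-switching MRM run
can monitor the whole pathway: 84 analyte transitions over 10 ganglioside
classes (negative mode) and 4 neutral glycosphingolipid classes (positive
mode), in a 15-min gradient with 1-min retention-time windows.

This package implements that pipeline end to end: compositional m/z
calculation, panel construction, chromatogram quantification with
internal-standard calibration, the bioanalytical validation metrics, and the
cohort biomarker statistics — plus a synthetic chromatogram generator that
provides every input the analysis needs.

## Mass and m/z calculation

Every mass is assembled from elemental compositions and monoisotopic
CODATA/IUPAC atomic masses (`atomic_masses()`); nothing is hard-coded.

* Ceramide `d<base C>:<base DB>/<acyl C>:<acyl DB>` = dihydroxy sphingoid
  base (CnH(2n+3-2k)NO2) + fatty acid (CmH(2m-2j)O2) − H2O. Deuterium labels
  (`-d3`, `-d5`) replace acyl hydrogens one-for-one. The summed shorthand
  (`d36:1`) is resolved against a fixed d18:1 base — the base every
  commercial standard in the panel uses; this is an assumption, recorded
  here, not a chemical fact.
* Species = ceramide + nHex × C6H10O5 + nHexNAc × C8H13NO5 + nNeuAc ×
  C11H17NO8 (residues are dehydrated: one water per glycosidic bond).
* m/z = (M ± z·1.00727646)/|z| using the proton mass, not the H-atom mass:
  an [M−H]⁻ ion keeps its electron.
* Quantifier fragments are computed the same way: the dehydrated sialic acid
  anion [NeuAc − H2O − H]⁻ (rounds to m/z 290.1) for all gangliosides, and
  the dehydrated sphingosine cation [d18:1 + H − 2H2O]⁺ (rounds to 264.3)
  for the neutral classes.

Default charge states are +1 for neutral classes, −1 for monosialo and −2
for di-/tri-/tetrasialo classes; both charges and retention times are
per-species overridable in the panel configuration, because the true
instrument values belong to the acquisition method, not to this code.

## Panel construction

The published method names 84 targets but not the per-class roster, so the
default configuration reconstructs it as six ceramides (d34:1, d36:1,
d38:1, d40:1, d41:1, d42:1) in each of the 14 classes. The roster is plain
configuration data (`default_panel_config()`); a laboratory's actual species
list can replace it without touching code.

Scheduling uses a deliberately minimal linear retention model: class base
time + 0.05 min per ceramide carbon beyond 36 − 0.05 min per double bond.
The base times only encode the observed elution ordering on a phenyl-hexyl
column (more sialic acids elute earlier: GQ1 first, the monosialo classes
last among gangliosides, neutral classes after), and chain length separates
species within a class. The absolute values are scheduling inputs with no
predictive claim.

## The synthetic-data generator

The generator emulates what the analysis needs from a triple-quadrupole
acquisition, no more:

* points only inside each transition's 1-min scheduled window, spaced by the
  cycle time (default 1 s);
* Gaussian peaks (sigma 3 s; an exponentially modified Gaussian tail is
  available) whose areas are `amount × response factor × matrix factor ×
  extraction efficiency`, exactly linear below a saturation cap;
* additive point noise (sd 20 counts on a baseline of 50) plus a 1%
  signal-proportional term;
* a per-injection log-normal amplitude factor (sdlog 0.02). This term, not
  the point noise, dominates replicate-to-replicate area CVs — point noise
  averages out on integration — and it was chosen once to put intra-assay
  CVs in the 2–6% range typical of a validated targeted assay;
* retention-time jitter (sd 0.02 min) derived from the *sample identity*
  rather than the noise seed, so that re-seeding changes noise realizations
  but never peak locations;
* per-day batch factors (sdlog 0.04) in the QC-replicate generator, so
  inter-assay variability exceeds intra-assay variability.

Cohort simulation draws control amounts log-normally per class, with
location/scale fitted by log-moment matching to the packaged reference
cohort (amounts there are positive and right-skewed). Patients multiply the
control draw by per-class fold factors — GM2 ×10, GM1 ×6, GM3 ×0.57 in both
phenotypes, GA2 ×2.4 in Sandhoff only; classes without a published factor
default to ×1 and are placeholders. The default design is 36 controls, 2
Tay-Sachs, 1 Sandhoff.

What the generator does **not** emulate: isotope interference, carryover,
retention drift between runs, heteroscedastic matrix effects per species, or
non-Gaussian peak pathology beyond EMG tailing. Tests passing on this
generator therefore demonstrate the correctness of the pipeline's
arithmetic and its statistical behaviour under the stated model — not
instrument-grade performance on real serum.

## Peak integration and calibration

The integration algorithm is fixed and testable against closed-form areas:

1. 3-point median smoothing; the apex is the smoothed maximum.
2. Baseline and noise come from the quietest quarter of the window:
   baseline = median, noise = scaled MAD of the smoothed points at or below
   the 25th percentile.
3. A peak is detected only if the smoothed apex exceeds baseline + 3×noise;
   otherwise the result is "not detected" with area 0 (never an error).
4. Boundaries are the nearest points on each side where the smoothed trace
   returns to baseline + 1×noise; the area is the trapezoidal integral of
   the raw trace above baseline between them.

This detector is conservative on blanks (the quietest-quartile MAD
underestimates full-trace noise, so pure-noise windows occasionally pass the
3×noise gate); consumers therefore select species explicitly, and
calibration marks fits `usable` only with a positive slope.

Calibration is ordinary least squares of response ratio (analyte area / IS
area) on amount, with Sy the residual SD on n−2 degrees of freedom, r² from
the same fit, and LOD = 3.3·Sy/S. Two deliberate choices:

* **Sy scope.** By default Sy uses the full curve; `lod_levels = k`
  restricts it to the k lowest levels (the levels approximating the LOD),
  which is the stricter reading of the usual formula. Both are exposed
  because the convention is genuinely ambiguous.
* **Weighting.** The default fit is unweighted. With signal-proportional
  noise over the default 1.2–5000 fmol range, however, the unweighted
  intercept is estimated almost entirely from the top levels and its
  sampling noise corresponds to several fmol — enough to bias
  back-calculation by >20% at the bottom of the range. The cohort workflow
  therefore back-calculates against the `weighting = "1/x"` fit, the
  standard bioanalytical remedy for wide dynamic ranges. The unweighted
  default is kept for the LOD/linearity reporting where it is conventional.

Internal standards are matched by structural proximity among the four
spiked standards: same class where available (GM3-d5, Gb3-d3, GlcCer-d3),
otherwise shared headgroup series (GM3-d5 covers GD3/GT3; GM1 d18:1/17:0
covers the GalNAc-bearing gangliosides and GA2; GlcCer-d3 covers LacCer).
The map is data (`default_is_map()`) and fully overridable.

## Validation metrics

* Precision: CV% = 100·SD/mean per standard per QC level. Intra-assay uses
  same-day replicates. Inter-assay defaults to pooling all measurements
  (5/day × 5 days = 25) because the published design ("five times daily
  over 5 days") does not specify nesting; a day-means variant is exposed.
* Extraction yield = 100 × (amount spiked before extraction)/(amount spiked
  after); matrix factor = 100 × (area in matrix)/(area in neat solvent).
  Both are exact paired ratios.
* Stability: per-class sums of IS-normalized response ratios (not
  back-calculated fmol) against the day-0 baseline; a class is unstable at
  a time point iff its recovery changes by strictly more than 15% — a
  114.9% recovery is still stable, 115.1% is not.

## Cohort statistics

* **Outliers.** Iterative two-sided Grubbs at alpha 0.05, applied per
  species independently within the control and patient groups; the critical
  value is ((n−1)/sqrt(n))·sqrt(t²/(n−2+t²)) with t the upper alpha/(2n)
  t-quantile on n−2 df, which reproduces the published tables (e.g. 2.290
  at n = 10, alpha 0.05). Groups with n < 3 are left unfiltered with a
  warning.
* **Group tests.** Two-tailed Student's (pooled-variance) t-test per
  species, as in the source protocol, despite the 36-vs-3 imbalance; Welch
  is available (`var_equal = FALSE`). Benjamini–Hochberg adjustment across
  species by default, Bonferroni as an option.
* **Fold-changes.** Both mean-based and median-based fold-changes are
  always reported: published per-species figures match mean arithmetic
  while the class-total figures are described as median fold-changes, and
  the two differ noticeably on 3-patient groups.
* **GM2/GM3 ratio.** Computed per sample; the group fold-change of the
  ratio is reported both ways (mean-based 16.4 and median-based 21.1 on the
  reference cohort). The reference table holds only d18:1/18:0 species, so
  these numbers validate single-species arithmetic, not the all-species
  totals.
* **PCA.** Column autoscaling then SVD (`prcomp`); each loading vector is
  oriented so its largest-magnitude element is positive, making score signs
  reproducible. On the reference cohort the three patients separate from
  all 36 controls along PC1.

## Problem sizes and numerical checks in the test suite

The suite exercises: a 7-point 1:4 calibration (3 replicates) and a
50-sample simulated cohort for round-trip recovery (median error per class
~2%, bound 5%); 5 × 2 QC replicates for the CV bound; 5,000 null cohorts
(multipliers 1) for the t-test type-I rate (0.05 ± 0.01); Grubbs agreement
with published critical values and a step-by-step oracle over n = 3..50;
and PCA reconstruction to < 1e−8. Mass arithmetic is verified against a
flat atom-list oracle to < 1e−6 u for all 88 panel species. These sizes
were chosen as the smallest that make the statistical assertions stable
across seeds.

## Known limitations

* The 84-species roster is a reconstruction; laboratories should substitute
  their instrument's list (the configuration is data).
* Linkage isomers (GD1a/GD1b, GT1b) are treated as one compositional class;
  the panel cannot and does not claim to separate them.
* The retention model is ordinal, not predictive.
* LOD magnitudes from simulated calibrations reflect the simulator's noise
  model, not instrument sensitivity; they are orders of magnitude away from
  attomole-level instrument LODs and are reported only to exercise the
  formula.
* The pooled t-test on 36-vs-3 log-normal amounts is the protocol's choice,
  not the statistically ideal one; its type-I behaviour under the simulated
  null is verified, but small patient groups make the patient-side Grubbs
  step (n = 3) nearly powerless by construction.
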