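Package: gslquant
Title: Multiplexed Targeted Quantification of Serum Gangliosides and
    Glycosphingolipids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and quantifies a scheduled, polarity-switching
    multiple-reaction-monitoring (MRM) panel for 84 ganglioside and
    glycosphingolipid species spanning 14 lipid classes. Computes elemental
    compositions and monoisotopic precursor/quantifier m/z values from
    ceramide shorthand and class glycan compositions, constructs scheduled
    transition lists with retention-time windows, integrates extracted ion
    chromatograms, normalizes to internal standards, fits calibration curves
    with limit-of-detection estimation, and derives bioanalytical
    validation metrics (precision, extraction yield, matrix factor, storage
    stability). Includes a synthetic chromatogram generator for calibration
    series, QC replicates, stability series and case-control serum cohorts,
    and the biomarker statistics used for GM2-gangliosidosis serum profiling
    (Grubbs outlier filtering, group comparisons with multiplicity
    adjustment, GM2/GM3 ratios, PCA, and heatmap z-scores), together with a
    packaged reference cohort of quantified serum ganglioside amounts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
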