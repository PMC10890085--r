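---
title: "Methods: targeted LC-MS quantification of thyroid hormones and polar metabolites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: targeted LC-MS quantification of thyroid hormones and polar metabolites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thquant)
```

## The problem

Cerebrospinal fluid (CSF) is available only in microliter volumes, yet
its thyroid hormone content — triiodothyronine (T3) and thyroxine (T4)
— and its polar metabolome carry physiologically important signals
(developmental stage, pregnancy, sample handling). `thquant`
re-implements, as a tested and reusable pipeline, the data-processing
chain used for targeted Orbitrap LC-MS assays of such samples: targeted
extraction at ppm mass tolerance, stable-isotope-dilution
normalization, pooled-QC filtering, limit-of-detection calibration, and
profiling statistics. Every stage can be exercised end to end on
synthetic data with known ground truth, so correctness claims are
testable without instrument data.

## Theoretical masses and adduct m/z

Target m/z values derive from elemental composition: monoisotopic
element masses (IUPAC/AME values embedded as a static table — no
network dependency) are summed and the adduct delta applied, e.g.
`(M + 1.007276) / 1` for `[M+H]+`. The protonation delta is the
*proton* mass, not the hydrogen atom mass: the electron's 0.00055 Da
matters at the fourth decimal place for ions in the 600–800 m/z range
where the thyroid hormones sit. Only single-charge adducts are
exercised; the formula supports |z| > 1 but the assay uses z = 1
species exclusively.

```{r mz}
adduct_mz(monoisotopic_mass("C15H12I3NO4"), "[M+H]+")  # T3
adduct_mz(monoisotopic_mass("C15H11I4NO4"), "[M+H]+")  # T4
```

## Targeted quantification

An extracted ion chromatogram (XIC) sums, per MS1 scan, all centroid
intensities within a symmetric, inclusive window of `ppm_tol` (default
5 ppm, the assay's setting) around the target m/z; membership is
computed against the target, not the centroid. Peaks are located
within `expected_rt ± rt_tol` (minutes are the RT unit everywhere):
the window maximum is the apex, ties resolve toward the expected RT
and then to the earlier scan, and integration bounds extend from the
apex to the nearest local minima or the window edges. The area is the
trapezoidal integral of intensity over RT with **no baseline
subtraction** — the vendor tool's integration algorithm is
undisclosed, and any constant response offset is absorbed by the
normalization stages downstream.

MS2 identity checks use a greedy one-to-one fragment matching within
`frag_tol` Da, pairs accepted in order of decreasing intensity product
(ties by smaller mass difference), followed by the cosine of the
matched intensity vectors with unmatched fragments zero-paired. This
choice is deterministic and symmetric by construction.

## Normalization and quality control

The chain runs in a fixed, logged order: (1) peak-table assembly, (2)
internal-standard (IS) normalization, (3) pooled-QC filtering, (4)
total-signal normalization. Missing values are encoded as empty CSV
cells; literal zeros survive I/O but are treated as missing by every
analysis step, never as true zeros.

**IS normalization.** For IS *s* and sample *j*, the mean-centered
area is `r_sj = area_sj / mean_s` where `mean_s` is taken over study
plus undiluted pool samples; the per-sample factor `f_j` is the
*arithmetic* mean of `r_sj` over the usable IS panel. The source
procedure does not state whether the average is arithmetic or
geometric, nor exactly which samples enter the centering mean; the
arithmetic mean over study + pool samples is this package's documented
choice. IS with any missing value are dropped with a warning; blanks
and mocks neither receive factors (blanks carry no IS by construction)
nor contribute to the means. If every sample's signal is distorted by
a multiplicative matrix factor, `f_j` recovers it exactly up to one
global constant — a property the tests assert at 1e-10.

**Pooled-QC filtering.** Precision is the percent CV (unbiased sd /
mean) over undiluted pool reinjections; response linearity is the
R-squared of ordinary least squares (with intercept) of area on
relative concentration across pool and pool-dilution samples (1, 1/3,
1/10 — the concentration axis, not the fold-dilution axis). Both
metrics are computed on IS-normalized areas, mirroring the stated step
order. A compound passes only when `CV < 30` **and** `R² > 0.95`,
strict inequalities exactly as the cutoffs are written; undefined
metrics fail. IS are retained through the filter for bookkeeping but
flagged.

**Total-signal normalization.** Per-sample totals over the kept non-IS
compounds are equalized by `mean(t) / t_j`. This is applied to study
samples only (a function argument widens it): rescaling pool dilutions
to equal totals would erase the very dilution response the QC metrics
measure.

**Isotope-dilution TH quantification.** T3 and T4 are reported as
`area(analyte) / area(paired 13C IS)` per sample on raw areas, which
cancels per-sample multiplicative matrix effects exactly; an
equal-volume comparison is enforced, and a zero or missing IS flags
the ratio as undefined rather than producing a spurious 0.

## Calibration

From a standard dilution series, the linear dynamic range is the
longest contiguous run of concentration levels, anchored at the top,
whose OLS fit of mean area versus concentration reaches `R² ≥ 0.99`
(at least 4 levels). "Linear limit of detection" is ambiguous in
common usage, so both readings are reported: the LOD proper is the
conventional blank + 3σ crossing constrained to the linear segment
(requiring ≥ 2 blank replicates for the σ estimate), and the lowest
linear level is available as the bottom of `linear_range`. Fits use
mean area per level (replicate scatter is reported as per-level CV);
both LOD and range are invariant under global rescaling of areas.
Instrument LODs from any specific chromatography are hardware facts,
not reproduction targets; the simulator-recovery property (planted LOD
recovered within one 2-fold step in ≥ 95% of 500 seeded series) is the
acceptance surface instead.

## Profiling statistics

The processed tables historically feed a MetaboAnalyst-style workflow,
so its defaults are adopted and documented rather than reinvented:
zeros/missing are imputed as half the compound's minimum positive
value, areas are log10-transformed, and each compound is Pareto scaled
— `(x − mean)/sqrt(sd)` with the unbiased sd, the intermediate between
no scaling and unit variance. A useful identity follows directly: the
variance of a Pareto-scaled column equals the sd of its logged column,
which the tests assert at 1e-8. PCA is the column-centered SVD with a
deterministic sign convention (largest-magnitude loading positive).
Group comparisons use Welch's unequal-variance t-test on logged values
(the source does not name its test; Welch is the robust default), fold
changes on unlogged means, and Benjamini–Hochberg adjustment. Rankings
("top 25 changed") sort by ascending p — one-way ANOVA when more than
two groups — with ties broken by |log2FC| and then compound id so the
ordering is reproducible.

## What the simulator emulates — and what it does not

`simulate_study()` generates peak areas as
`true_concentration × dilution × matrix_factor × lognormal_noise +
baseline`, with IS spiked at sample-independent levels sharing the
sample's matrix factor (that is what makes IS normalization work), a
pool averaged from all study samples and rediluted 3- and 10-fold,
IS-free blanks, metabolite-free mocks, and sporadic missing values.

Default parameter choices, made once on field-typical grounds:

| parameter | default | rationale |
|---|---|---|
| group sizes | 6/5/5/4 | matches the reference study's cohort scale (≥ 5 CSF, 4 paired serum) |
| panel | 200 metabolites + 40 IS | mirrors the 266-compound (40 IS + 226) routine library |
| `noise_cv` | 0.05 | technical reinjection CV of an abundant compound on an Orbitrap (field-typical 3–7%) |
| `matrix_sdlog` | 0.2 | per-sample prep/matrix variability, the distortion IS normalization corrects |
| `noise_cv_bad` | 1.0 | near-LOD variability for planted high-CV compounds, far beyond the 30% cutoff |
| dilutions | 1, 1/3, 1/10 | the stated QC design |
| T3 effects | embryo 4×, pregnant 1.5×, female 0.8× | qualitative embryo-elevated T3 direction; magnitudes are free parameters, shown only graphically in the source |
| T4 effects | pregnant 3×, embryo 1.5×, female 0.8× | qualitative pregnancy-elevated T4 direction |
| labile set | 10 nucleotide-salvage compounds, 2.5× in frozen embryo CSF | fresh-vs-frozen lability of salvage-pathway metabolites |

Non-compliant compounds are planted two independent ways, exercising
each QC cutoff separately: high-CV noise, and a saturating
Michaelis-Menten-style detector response (`V·x/(K + x)` with K at 5%
of the pool concentration) that flattens the dilution series.

The dilution-series simulator puts mean signal at `slope ×
concentration` at and above the planted LOD and at the blank level
below it, with additive Gaussian noise. The default blank level is a
nonzero instrument background (100 area units): with a zero blank, the
non-negativity floor truncates the noise distribution, biasing the
blank σ estimate downward and sub-LOD level means upward — a generator
defect caught and fixed during development, not a tuning knob.

The raw-run writer places Gaussian elution profiles on a uniform scan
grid so that XIC trapezoids reproduce requested areas within ~2% when
the scan spacing is at most the peak σ, with optional per-centroid
mass jitter (±1 ppm), noise centroids, and paired MS2 spectra at two
collision energies.

What a green test does **not** establish: the simulator draws
multiplicative lognormal noise with no RT drift, no chromatographic
tailing or co-elution beyond the planted isomer stress test, no
isotope envelopes, no vendor-specific noise spectra, and
missingness-completely-at-random rather than intensity-dependent
dropout. Recovery claims therefore validate the *algorithms*, not
instrument performance.

## Numerical and degenerate-input choices

* ppm windows are inclusive at both edges; a centroid exactly at the
  boundary counts.
* An all-zero or empty RT window yields a missing peak (`NULL` /
  `NA`), never an area of 0.
* CV and R² that cannot be computed (fewer than 2 pool values, mean 0,
  constant areas, fewer than 3 dilution levels) are `NA` and fail the
  filter rather than defaulting to a passing value.
* Constant compounds Pareto-scale to all-zero columns with a warning;
  compounds with no observed values are dropped with a warning.
* Zero-total samples in total-signal normalization are flagged and
  left unscaled rather than producing infinities.
* All simulation entry points take a seed and use it for every source
  of randomness; identical seeds give byte-identical outputs, which
  the pipeline tests assert on written CSVs.

## Known limitations

mzML support is a deliberately minimal PSI subset (centroided,
uncompressed 64-bit float arrays) because no general mzML reader is
available in the target toolchain; vendor formats, mzXML and
profile-mode data are out of scope, as are untargeted peak picking,
PLS-DA, free-versus-bound hormone speciation, and absolute
concentration calibration of study samples (the assay reports relative
abundances).
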