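---
title: "Compartmentalized quantification of stromal Cav-1: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartmentalized quantification of stromal Cav-1: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stromacav)
```

## The problem

Loss of caveolin-1 (Cav-1) in tumor-adjacent fibroblasts marks an
aggressive cancer-associated-fibroblast (CAF) phenotype. Measuring it on a
tissue microarray (TMA) requires separating two cell populations that are
interleaved at pixel scale — the desmoplastic stroma and the tumor
epithelium — and then producing an expression measure that is comparable
across cores acquired at different exposure settings. `stromacav`
implements that pipeline for four-channel multiplex immunofluorescence
(DAPI, vimentin, pancytokeratin, Cav-1), together with the semi-quantitative
IHC H-score used when only chromogenic staining is available, the clinical
definitions needed downstream (response to platinum therapy, overall
survival, long/short survivor groups), and the association statistics.

## Compartment model

Compartments are *pixel sets defined by marker logic*, not segmented
cells:

* **Epithelium** = pancytokeratin (panCK)–positive pixels.
* **Stroma** = vimentin-positive pixels that are panCK-negative **and**
  lie within a configurable radius of a DAPI-positive nucleus.

Two rules deserve comment. First, vimentin is a ubiquitous mesenchymal
marker that can also stain tumor cells; pixels positive for both vimentin
and panCK are therefore assigned to the epithelium and excluded from the
stroma, which also makes the two masks disjoint by construction. Second,
DAPI is nuclear while vimentin is cytoplasmic, so demanding strict
per-pixel coincidence of the two signals would leave the stroma empty. We
read "vimentin with a nucleus" as *vimentin within
`nucleus_association_radius` (default 10 px, about one cell diameter at
TMA scan resolution) of a DAPI-positive component*, implemented as a
disc dilation of the DAPI mask. Whether the original instrument associated
nuclei per-pixel or per-object is not public; the radius rule is this
package's reading, and the radius is a tunable parameter.

Positivity thresholds are not published either. The default is Otsu's
method per channel (reproducible and data-driven, and exact on the
bimodal synthetic images); a fixed per-channel threshold override is
available and the thresholds actually used are returned with the masks.
Connected components smaller than `min_region_px` can be dropped to
suppress speckle; the default (0) leaves the masks untouched.

## The intensity-per-area score

For a compartment mask $M$ with area $|M|$ (pixels), Cav-1 channel $I$,
exposure time $e$ (ms) and reference exposure $e_0$:

$$\mathrm{score} = s \cdot \frac{\sum_{p \in M} I_p}{|M|} \cdot \frac{e_0}{e}$$

This is the AQUA-style "total target intensity over compartment area,
normalized for exposure" — proportional to protein molecules per unit
area, in arbitrary units. The scale $s$ (default 1000) and reference
exposure $e_0$ (default 100 ms) are free constants chosen so that
noise-free simulated cores at the default concentrations land on the
familiar hundreds scale; scores are comparable within a run, not across
instruments. Only the whole-cell ("overall") score is computed; nuclear
and cytoplasmic sub-compartment scores are out of scope.

Duplicate cores from the same subject and region are combined by the
arithmetic mean of their non-missing scores; a core with an empty
compartment contributes a *missing* score, never a zero, and a subject
whose duplicates are all missing stays missing. IF expression is
dichotomized at the median of the non-missing values with ties at the
median labelled *high*.

## IHC H-score

The chromogenic arm multiplies a pathologist's intensity category
(0 negative, 1 weak, 2 moderate, 3 strong) by a percent-positive category
(0 = 0%, 1 = 1–33%, 2 = 34–66%, 3 = 67–100%), giving values in
{0, 1, 2, 3, 4, 6, 9}. The printed bins are integers; fractional
percentages fall into half-open intervals (0, 33], (33, 66], (66, 100],
which reproduces the integer bins exactly and is unambiguous in between.
Only integer categories are accepted — a fractional "mean intensity" is
rejected rather than silently rounded. H-scores are dichotomized as
presence (> 0) versus absence (= 0).

## Clinical definitions

* **Analysis set**: serous histology, chemo-naive (no neoadjuvant
  therapy), primary (non-recurrent) tissue. The three filters commute.
* **Response**: complete responders had complete disappearance of all
  measurable disease sustained ≥ 4 weeks after first-line platinum
  therapy or, absent measurable lesions, CA-125 normalization ≥ 4 weeks;
  partial response, stable disease, a > 50% CA-125 drop without
  normalization, or progression on therapy are incomplete responders.
* **Overall survival**: months from diagnosis to death or last contact,
  at 30.4375 days/month (registry convention; the source does not state
  one). Censored if alive.
* **Survivor groups**: long-term > 60 months (vital status not required —
  an alive patient with 70 months of follow-up is a long-term survivor),
  short-term = died ≤ 36 months; alive cases with < 36 months of
  follow-up and deaths between 36 and 60 months belong to neither group.
* **Age dichotomy**: ≤ 65 vs > 65 years.

## Statistics

Two-group expression comparisons use the Wilcoxon rank-sum test (exact
for small tie-free samples, normal approximation with tie correction
otherwise); three or more groups use Kruskal-Wallis. Paired
stroma-minus-epithelium differences use one-sample t; subgroup mean
differences use Student's t or one-way ANOVA. Survival uses the
product-limit estimator with the median defined as the smallest $t$ with
$\hat S(t) \le 0.5$ (the `survfit` summary interpolates ties at exactly
0.5; we keep the textbook convention since it is what printed medians
follow), log-rank tests across groups, and Cox proportional-hazards
models with Efron tie handling (Breslow available; note that "duplicate
every record" leaves the estimate invariant only under Breslow, since
Efron treats the induced ties differently). Response models use logistic
regression with Wald intervals; separation is flagged, not silently
reported. All tests are two-sided, missing data are removed per analysis
with post-removal group sizes reported, and no multiple-testing
correction is applied.

## What the simulator emulates — and what it does not

`generate_core_image()` renders disk nuclei and blob-union epithelial
nests, with fibroblast cell bodies (vimentin) surrounding every stromal
nucleus, channel intensity linear in concentration × exposure
(gain 0.005 per concentration-unit·ms on a 0–1 intensity scale, clipped
at saturation), additive Gaussian noise (default SD 0.01), optional
Poisson shot noise, and optional panCK→vimentin bleed-through. Ground
truth (masks and concentrations) is exact, so the score contract can be
tested to machine precision: on a noise-free core,
score = $s \cdot c \cdot g \cdot e_0$ exactly.

It does **not** emulate point-spread blur, autofluorescence spectra,
staining gradients, tissue folds, or out-of-focus cores. Passing the
recovery tests therefore demonstrates that the *score algebra and mask
logic* are correct and robust to pixel noise — not that segmentation
would survive real-slide artifacts, which is an instrument-calibration
question outside this package.

`generate_cohort()` draws subject-level compartment means from gamma
distributions (CV `dispersion`, default 0.28, which reproduces a
between-subject SD near 43 at a mean of 152.6) around configurable
compartment levels — defaults 308.9 (benign stroma), 152.6 (tumor
stroma), 124.0 (tumor epithelium), i.e. the benign stroma roughly
twice the tumor stroma — with lognormal duplicate-core replicates
(CV 0.08, two cores per region). Survival is exponential with the
lymphovascular-invasion (LVI) flag as the *only* systematic effect
(default HR 3.56 at 77% prevalence; the baseline LVI-negative median of
160 months puts the marginal median near 50 months), and censoring is
independent exponential calibrated so the expected censored fraction
equals `censoring_rate` (default 0.11). All other covariates are
generated independent of both expression and survival, so any
association the analysis finds in them is a false positive by
construction — which is exactly what the null-calibration tests exploit.

## Numerical choices and degenerate inputs

* Intensities live on a 0–1 nominal scale; 16-bit TIFF export scales by
  65535, so a round trip is lossless to 1/65535.
* An all-zero marker channel produces a warning and an empty mask, not an
  error; an empty compartment produces a missing score, not a zero.
* Zero-variance inputs to t-tests return `p = NA` with a warning (except
  all-zero paired deltas, where t = 0, p = 1 by convention).
* Dichotomization ties go *high* (≥ median) for IF and *present* (> 0)
  for IHC.
* All randomness flows from one explicit integer seed per call
  (`withr::with_seed`), so identical configurations are bit-identical.

## Problem sizes used in the checks

The packaged checks run the imaging recovery on 128–192 px cores (50
cores for the recovery sweep), cohorts of 105 tumor + 30 benign subjects
(500 for model-recovery checks), and 10,000 null replicates for rank-sum
type-I calibration at n = 30 per group. These sizes give standard errors
comfortably below the effects being recovered while keeping a full run in
minutes on one CPU.

## Known limitations

* Scores are in arbitrary units; cross-instrument comparability is not
  claimed (the vendor's normalization constant and scanner bit depth are
  proprietary).
* The published per-case supplementary table is not redistributable here;
  the reproduction driver accepts it (or any mapped CSV/XLS) but the
  package ships only the synthetic route.
* Compartmentalization is pixel-logic, not cell segmentation: nuclear vs
  cytoplasmic sub-scores, spectral unmixing and whole-slide ROI detection
  are out of scope.

## A worked run

```{r example, eval = FALSE}
report <- end_to_end_synthetic(seed = 1)
print(report)
```

The report carries the per-core recovery table (`report$imaging`), the
full association analysis (`report$analysis`, a `cav_reproduction`
object with the summary table, benign-vs-tumor tests, KM and Cox fits),
and the headline recovered quantities (`report$recovered`).
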