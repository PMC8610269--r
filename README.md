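# stromacav

Digital-pathology quantification of **stromal caveolin-1 (Cav-1)** in
tissue microarrays, and the clinical association analysis built on it.

Loss of Cav-1 in tumor-adjacent fibroblasts marks an aggressive
cancer-associated-fibroblast phenotype. Quantifying it on a multiplex
immunofluorescence TMA means (1) separating stroma from tumor epithelium
at pixel level by marker logic, and (2) turning the Cav-1 channel into an
expression measure that survives exposure differences between cores.
`stromacav` implements both, alongside the semi-quantitative IHC H-score,
the clinical definitions (chemotherapy response, overall survival,
long/short-term survivor groups), the association statistics
(rank tests, Kaplan-Meier/log-rank, Cox, logistic), and a synthetic-data
generator with exact ground truth so the whole pipeline is testable
without any external images.

## The model

Compartments are pixel sets defined by marker logic on the four channels
(DAPI, vimentin, pancytokeratin (panCK), Cav-1):

* **epithelium** — panCK⁺ pixels;
* **stroma** — vimentin⁺ ∧ panCK⁻ pixels within a configurable radius of
  a DAPI⁺ nucleus. Vimentin⁺panCK⁺ pixels are assigned to epithelium, so
  the masks are disjoint by construction.

The expression score for compartment mask *M*, Cav-1 image *I*, exposure
*e* and reference exposure *e₀* is the exposure-normalized intensity per
unit area (AQUA-style, proportional to molecules per unit area):

```
score = s · ( Σ_{p∈M} I_p / |M| ) · ( e₀ / e )
```

Duplicate cores per subject are averaged (missing scores excluded, never
zeroed); IF scores are dichotomized at the median (ties high). The IHC arm
computes H-score = intensity category (0–3) × percent-positive category
(0–3) and dichotomizes at zero (presence/absence).

## Worked example

```r
library(stromacav)

# one synthetic core, segmented and scored
sim   <- generate_core_image(image_sim_config(noise_sd = 0.01, seed = 1))
masks <- build_compartment_masks(sim$image)
masks
#> compartment masks: stroma 13102 px, epithelium 11442 px
compute_aqua_score(sim$image, masks, "stroma")
#> AQUA score [stroma, core core01]: 152.3714 over 13102 px

# full pipeline on synthetic data
report <- end_to_end_synthetic(seed = 1, quiet = TRUE)
report
#> end-to-end synthetic run (seed 1 )
#>  score~concentration Spearman: 1.000
#>  mask Jaccard vs truth:        1.000
#>  benign / tumor stroma median: 290.6 / 140.9 (ratio 2.06, p = 1.92e-14)
#>  tumor epithelium median:      125.3
#>  LVI hazard ratio:             4.06
#>  KM median OS (months):        45.7
```

Reading the numbers: the simulated ground-truth tumor-stroma
concentration (0.305 at the default gain and scale) maps to a score of
152.5 noise-free, and the segmented, noisy core recovers 152.4. At cohort
level the generator's configured benign:tumor stroma contrast (308.9 vs
152.6, a 2.0× loss of stromal Cav-1 in tumors) is recovered as
290.6/140.9 with a rank-sum p ≈ 10⁻¹⁴, the Spearman correlation between
recovered score and true concentration across cores is 1.0, and the Cox
model recovers the configured lymphovascular-invasion hazard ratio
(true 3.56; 4.06 estimated at n = 105 with ~0.45 SE on the log scale).

Real data enter through the same surface: `quantify_cores()` on images
read with `read_core_image()` (multichannel TIFF + exposure sidecar), and
`reproduce_tables()` on a per-case clinical/expression table (CSV/TSV or
XLS with a column mapping), which rebuilds the expression-by-subgroup
summary tables, the benign-vs-tumor comparisons, and the KM/Cox/logistic
analyses.

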