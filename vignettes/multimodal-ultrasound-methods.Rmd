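---
title: "Methods: multimodal ultrasound diagnostics for small liver cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal ultrasound diagnostics for small liver cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonodx)
library(dplyr)
```

# Scope and model

`sonodx` implements the quantitative machinery around multimodal ultrasound
diagnosis of small hepatocellular carcinoma (lesions no larger than 3 cm):

1. **Image conditioning** — an adaptive median filter for the impulse
   ("long-tail") component of ultrasound noise, plus simple augmentation
   operators (crop, zoom, rotate, brightness, contrast).
2. **Segmentation agreement and evaluation** — volumetric overlap error
   (VOE, one minus the Jaccard overlap) between annotator masks, selection
   of a gold-standard annotation, pixelwise confusion counts, and average
   precision (AP) as the trapezoidal area under an explicit
   precision–recall point list.
3. **Rule-based diagnosis** — per-modality benign/malignant calls (Doppler
   blood-flow grade, elastography stiffness score, CEUS enhancement and
   washout) fused by a logical AND on malignancy.
4. **Diagnostic statistics** — sensitivity, specificity, accuracy and
   Cohen's kappa from 2×2 diagnosis-versus-pathology tables, chi-square and
   Fisher's exact tests for categorical association.
5. **Immunohistochemistry scoring** — the semiquantitative product rule for
   EZH2 and p57 positivity and group/grade-stratified expression rates.
6. **Synthetic data** — phantoms, annotator panels, a four-arm patient
   cohort and marker expression cohorts whose defaults reproduce the
   reference study's printed marginals, so everything above runs end to end
   without clinical data.

Deliberately out of scope: any learned feature extraction or network
segmentation, physically realistic B-mode acoustics or CEUS time–intensity
curves, and histology image simulation. Segmentation metrics are validated
on synthetic masks; no claim is made about network-level segmentation
performance.

# The adaptive median filter

For each pixel a square window of odd size starts at `initial_size` and may
grow to `s_max`. With window minimum $Z_{min}$, median $Z_{med}$, maximum
$Z_{max}$ and centre value $Z_{xy}$:

* **Level A** passes when $Z_{med}-Z_{min} > 0$ **and**
  $Z_{max}-Z_{med} > 0$ — the median is strictly interior and therefore not
  itself an impulse. Otherwise the window grows by 2 per side; if it cannot
  grow past `s_max`, the centre value is output unchanged.
* **Level B** then outputs $Z_{xy}$ when $Z_{xy}-Z_{min} > 0$ **and**
  $Z_{max}-Z_{xy} > 0$ (the centre is not an extreme), else $Z_{med}$.

Design choices, made where the procedure's written form left room:

* The two second differences are taken as $Z_{max}-Z_{med}$ and
  $Z_{max}-Z_{xy}$; the algebraically impossible sign variants (which would
  make both branches unreachable for non-negative intensities) are treated
  as typographical and corrected to the standard adaptive median filter,
  whose control flow matches the written procedure exactly.
* Strict inequalities throughout ("greater than 0"): ties trigger window
  enlargement. A consequence worth knowing: on an *exactly constant*
  background the window median equals the window minimum at every size, so
  Level A never passes and an isolated impulse survives via the exhaustion
  rule. Real speckled images never have exactly constant windows, and on
  impulse-corrupted phantoms the filter strictly reduces mean absolute
  error (a property the test suite checks at densities 0.05–0.2).
* Windows are square, growing by +2 per side; defaults `initial_size = 3`,
  `s_max = 7` (no sizes are stated in the source; these are the customary
  choices at these image scales).
* Borders use edge-replication padding so every pixel has a full window.
* The filter reads only the original image, never its own partial output,
  making the result independent of scan order — and bit-identical to a
  naive per-pixel re-implementation, which the tests verify on random
  images.

# Segmentation agreement

VOE is $1-|A\cap B|/|A\cup B|$: 0 for identical masks, 1 for disjoint
non-empty masks, symmetric. Two empty masks have an empty union; we define
their VOE as 0 (identical emptiness) and warn, since the ratio is formally
undefined. "Highest reliability" among $k$ annotators is operationalised as
**minimal mean pairwise VOE** against the other members, ties broken by the
lowest annotator index; the selected gold standard is always a member of
the panel. AP is computed exactly as the trapezoidal sum
$\tfrac12\sum_i (R_{i+1}-R_i)(P_{i+1}+P_i)$ over a supplied point list with
non-decreasing recall; producing the curve (threshold sweeping) is the
caller's job. Confusion metrics are pixel-level; a lesion-level reading of
"accuracy" would need object matching that the source never describes.

# Diagnostic rules and statistics

The modality rules are thresholds on ordinal scales — Doppler flow grade
≤ 1 benign, ≥ 2 malignant; elastography score ≤ 3 benign, ≥ 4 malignant —
and, for CEUS, "nothing malignant observed": a lesion is negative only
when arterial-phase enhancement is absent **and** washout is absent.
Noncharacteristic enhancement/washout findings are grouped with "not
observed" (the benign side) by default, because the source lists them
among the non-positive features; the opposite grouping is one flag away
(`noncharacteristic_benign = FALSE`) since the written rule is genuinely
ambiguous on this cell. Multimodal fusion is the AND rule on malignancy:
one benign call makes the fused call benign.

Performance statistics come from 2×2 call-versus-pathology tables with
malignant as the positive class. Percentages are rounded half-up to two
decimals, matching how the reference tables print; raw fractions are
always returned alongside. Cohen's kappa uses the margin-based chance
agreement, banded as satisfactory (≥ 0.70), good (0.45–0.70) or poor
(< 0.45). Chi-square is Pearson's without continuity correction (the
source does not use Yates); Fisher's exact test is the two-sided
hypergeometric test. Both delegate to the standard R implementations and
are cross-checked in the tests against direct $\sum(O-E)^2/E$ and
enumeration oracles.

## The packaged reference tables

The printed contingency and expression tables of the reference study ship
inside the package (`reference_diagnosis_tables()`,
`reference_expression_tables()`), and `replay_reference_tables()` recomputes
every derivable statistic from the cells, printing it beside the printed
value and flagging disagreements at the printed precision. Several printed
values are **not** arithmetically consistent with their own cells — the
Doppler sensitivity (printed 57.69% vs 16/26 = 61.54%), the multimodal
sensitivity (88.87% vs 24/27 = 88.89%), all four kappas, and the p57
lesional rate (whose row also sums to 83 against a stated group size of
79). The package treats the cells as the reproducible surface: consistent
statistics must replay exactly, inconsistent ones must be flagged, never
"reconciled".

# The synthetic cohort generator

The generator's defaults *are* the reference study conditions; they are not
tuning knobs.

* **Cohort**: 100 patients split evenly across four examination arms.
  26% of patients carry multiple lesions; multiple means exactly three,
  which simultaneously matches the printed 74/26 single/multiple split and
  the expected 152 lesions. Pathology is a patient-level label with
  malignancy prevalence 0.79 (expected 110 vs 42 lesions); malignant
  lesions draw a differentiation grade with probabilities 49/110, 40/110,
  21/110 (poor/moderate/high). Lesion diameters are uniform on 0.8–3.0 cm.
* **Imaging features**: per-grade probabilities are the published
  frequencies (e.g. irregular shape 79.59% in poorly differentiated
  lesions); features with no dominant published category in the
  well-differentiated stratum default to 0.5. Benign-lesion frequencies
  are published nowhere, so the benign row is this package's stated
  assumption — the complementary benign-looking pattern (20% for each
  malignant-leaning binary feature, 5% fast-in-fast-out) — and is fully
  overridable. Ordinal scores are sampled consistently with the binary
  high/low draw (e.g. a "rich flow" lesion draws grade 2 or 3).
* **Phantoms**: a two-level ellipse or radially perturbed blob (default
  hypoechoic lesion, 60 on a 120 background), corrupted by mean-one
  log-normal speckle (`speckle_scale` = log-sd, default 0.2) then
  salt-and-pepper impulses at `impulse_density` (default 0.05, equal
  salt/pepper split). These are the simplest standard models of
  multiplicative and long-tail noise; no attempt is made at acoustically
  realistic speckle correlation, attenuation or shadowing, so passing
  denoising tests show impulse-noise behaviour, not clinical image quality.
* **Annotators**: ordinary readers are integer translations (sd
  `boundary_jitter` per axis) plus random boundary-pixel flips; outliers
  translate the lesion half a frame away. This produces controllable
  disagreement with a known outlier structure; it does not model real
  inter-reader bias.
* **IHC cohorts**: 79 lesional / 79 perilesional / 39 normal specimens.
  Group-level positivity defaults are EZH2 0.7595/0.1519/0.1026 and p57
  0.4304/0.7975/0.9487 (the p57 lesional value is 34/79, the only reading
  of the printed row compatible with the stated group size). Per-grade
  positivity defaults (EZH2 ≈ 0.54 in every grade; p57 0.1683/0.2059/
  0.8079) serve the grade-stratified analysis. The two sets are kept
  independent because the published group-level and grade-level rates are
  mutually inconsistent (no grade mixture of ≈54% rates can produce a
  75.95% group rate); `stratify_lesional_by_grade = TRUE` switches the
  lesional specimens to grade-conditional sampling.

Every generator validates its configuration, is bit-reproducible under a
fixed config and seed, and recovers each configured probability within
three binomial standard errors at around 10,000 sampling units — a property
the test suite checks at that scale (≈ 6,600 patients for the cohort,
≈ 20,000 specimens for the IHC module; both run in seconds).

# Numerical conventions and degenerate inputs

* Undefined ratios (zero denominators) are returned as `NA` and never
  silently coerced to 0; kappa with degenerate margins ($p_e = 1$) is `NA`
  with band `"undefined"`.
* Percentages round half-up at two decimals; all raw fractions are
  retained.
* Masks are strictly binary matrices; images are numeric matrices in
  [0, 255], stored on disk as 8-bit PNG/TIFF with masks at {0, 255}.
* The pipeline derives per-stage child seeds deterministically from one
  global seed, so stages re-run independently with identical results, and
  every CSV bundle carries the seed and a configuration hash.

# Known limitations

* The IHC per-field counting protocol (five high-power fields, 120 cells
  each) is metadata only; specimens carry a single score pair.
* Two-reader adjudication of discordant images is a human process; the
  pipeline takes one findings record per lesion.
* The synthetic cohort samples features independently given the stratum;
  real imaging features are correlated within a lesion, so fused-call
  performance on synthetic cohorts should not be read as a clinical
  estimate.
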