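---
title: "Methods: quantifying radiation-induced DNA damage in uveal melanoma histology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying radiation-induced DNA damage in uveal melanoma histology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uvealrad)
```

# The problem

Uveal melanoma is usually treated eye-sparingly with radiotherapy, delivered
either as a single high dose or in several fractions of stereotactic
photon irradiation. How much DNA damage the tumor actually sustains — and
whether tumors carrying monosomy 3, the dominant cytogenetic risk factor for
metastasis, respond differently — can be read off enucleation or resection
specimens: a chromogenic TUNEL assay marks DNA strand breaks in situ, and the
stained area fraction quantifies the damage burden. `uvealrad` implements the
full computational side of that workflow: colour deconvolution of the
brightfield images, thresholding and pooled area quantification, a
cohort-relative monosomy 3 classifier from FISH signal counts,
histopathological marker quantification, and the nonparametric statistics
used to compare treatment groups and metastasis-free survival.

# Stain separation

Brightfield absorption follows the Beer–Lambert law. With background
intensity $I_0$ and pixel intensity $I_c$ in channel $c$, the optical
density is $OD_c = \log_{10}(I_0 / I_c)$, and $OD$ is linear in stain
concentration. Each of the three stains — nuclear fast red counterstain,
the HRP-green TUNEL chromogen, and brown melanin pigmentation — absorbs
along a fixed unit direction in $(R,G,B)$ OD space. Writing those
directions as the rows of a matrix $M$, a pixel with stain concentrations
$c = (c_1, c_2, c_3)$ has $OD = c\,M$, so concentrations are recovered as
$c = OD\,M^{-1}$ (stains-as-rows convention throughout; pixels are row
vectors and $M^{-1}$ multiplies on the right). The calibrated matrix is

```{r}
stain_matrix_default()
```

Defaults that the source data do not pin down are declared, not inferred:
$I_0 = 255$ (8-bit acquisition; configurable for 16-bit), and
$\varepsilon = 1$ intensity unit as the floor inside the logarithm. Negative
concentrations — OD vectors outside the cone spanned by the stains, as
produced by noise — are deliberately *retained* by `deconvolve()` so that
composition and deconvolution are exact inverses; they are clipped only at
the thresholding stage, and their prevalence is reported as the
`negative_fraction` diagnostic.

**Numerical limits.** With the calibrated matrix, $M^{-1}$ has column
$\ell_1$-norms around 6–8. Half-count 8-bit quantisation perturbs a channel's
OD by about $0.5/(I \ln 10)$, so quantisation noise alone exceeds 0.02
concentration units for pixels darker than roughly 120 counts, and recovery
degrades without bound as composed intensities approach zero (concentration
triples near $(2,2,2)$ quantise to 0 counts). The test suite therefore checks
the unquantised round-trip at $10^{-4}$ and checks the quantised round-trip
against the exact per-pixel error-propagation bound rather than a fixed
constant.

# TUNEL-positive area

The TUNEL concentration plane is thresholded into a positive mask. The
automatic mode maximises between-class variance on a 256-bin histogram
(Otsu's criterion) — a deterministic, documented stand-in for the manual
"threshold adjustment" of an interactive image program — with a fixed-value
mode to reproduce manual choices. Ties across an empty histogram gap are
broken at the gap's midpoint. A constant plane has no bimodal structure and
is rejected with instructions to use the fixed mode.

Within the pipeline wrapper `quantify_tunel_field()`, the automatic
threshold is additionally floored at `threshold_floor = 0.1` concentration
units: in a field with essentially no positive signal the histogram is
unimodal and an unconstrained between-class split would label acquisition
noise as positive (up to half the field). The floor is well below the
typical positive-signal concentration (≈0.9 in the generator) and well
above deconvolved noise; setting it to 0 restores bare Otsu behaviour.
Whether thresholds should be per-field or fixed per-tumor is not
determined by the source protocol; per-field is the default and a fixed
per-tumor threshold is available through the configuration.

Per field, the analysed region is the tumor mask minus the vessel exclusion
mask; necrotic areas are *included* by design (necrotic DNA degradation is
part of the damage signal). The per-tumor statistic is the pooled ratio

$$\mathrm{TUNEL\%} = 100 \times \frac{\sum_f \text{positive px}_f}
{\sum_f \text{analysed px}_f},$$

not the mean of per-field percentages; pooling is invariant to how fields
are split, which the suite tests as a property. Twenty representative
fields are targeted per tumor; smaller tumors are quantified entirely.
Because a human "representative" selection cannot be reproduced, field
selection is a seeded uniform sample without replacement.

# Chromosome 3 classification

From per-cell centromeric FISH counts in marker-positive (Melan-A/HMB45)
regions, two statistics are computed per tumor: the percentage of cells
with exactly one signal (`pct_monosomy`) and the chromosome 3 index (total
signals per evaluated nucleus, ≈2 for diploid tissue). Fewer than 203
evaluated nuclei triggers a warning, not an error — one historical tumor
was profiled from 88 nuclei.

Because no absolute monosomy cutoff is established, both statistics are
binarised at their *cohort* median (medians computed per clinic, since
specimen storage time affects hybridisation quality): score 1 means
`pct ≥ median` and `index ≤ median`, ties scoring 1 exactly as written.
Concordant scores decide the call; discordant ("mixed") tumors are called
monosomy 3 when `pct > 40` (strict) or when the index is at least one SD
below the mean of the *entire* reference cohort (inclusive,
`index ≤ mean − SD`), else disomy 3. The reference set defaults to all
profiles passed in, and by default includes the tumor being classified —
the alternative is not determined by the source description and the
difference is negligible at cohort size.

Two consequences are worth understanding: at least half of each cohort
scores 1 on each parameter by construction, and the same tumor profile can
receive different calls in different cohort contexts — both are covered by
tests, the latter with an explicit two-cohort construction. Zero-signal
nuclei (hybridisation failures) stay in both denominators by default
(`drop_zero_signal = TRUE` for sensitivity analyses); nuclei with three or
more signals enter the index fully and never count as monosomic.

# Histopathological markers

Vessel area is the vWF-positive fraction of the tumor mask (normal choroid
excluded by the mask itself); macrophage density converts a CD68 cell count
and a pixel area to cells/mm² via the supplied µm-per-pixel scale, which is
configuration, never inferred from files. Morphology uses the strict
90 percent dominance rule (exactly 90 percent epithelioid is `mixed`);
necrosis bins are `0–10%` (10 inclusive), `>10–33%`, and an out-of-range
flag above 33. Mitotic figures are identified manually in 40 high-power
fields; only the count's storage is implemented, as no detection algorithm
is defined.

# Cohort statistics

All tests are implemented from their defining formulas; `stats::` and
`survival::` equivalents appear only as oracles in the test suite.

* **Mann–Whitney U** from midranks with the tie-corrected variance
  $\sigma^2 = \frac{n_1 n_2}{12}\left(N + 1 - \frac{\sum(t^3 - t)}{N(N-1)}\right)$
  and a two-sided normal p. The 0.5 continuity correction is applied when
  ties are present (the reporting convention of the source tables), and both
  behaviours are exposed (`continuity = "auto"/"on"/"off"`). At $n = m = 4$
  the corrected approximation stays within 0.031 of the exact permutation
  p-value over all 70 splits of a tie-free pool; the uncorrected one
  deviates by up to 0.12, which is why the oracle tests compare the
  corrected variant.
* **Fisher's exact test** (2×2, two-sided) enumerates all tables with the
  observed margins and sums hypergeometric probabilities at most as large
  as the observed one — the probability-ordering criterion, with relative
  tolerance $10^{-7}$ guarding floating-point ties. This variant reproduces
  all five hand-verified published p-values (0.004, 0.049, 0.41, 1.00,
  0.032).
* **Kaplan–Meier** with Greenwood variance; 95 percent intervals on the
  plain survival scale clipped to $[0,1]$ by default (the interval
  construction used in the source is unstated), with a log-log option.
  Patients without observed metastasis are censored at the end of
  follow-up.
* **Log-rank** as the standard one-degree-of-freedom observed-minus-expected
  chi-square; degenerate cases (no events, groups never concurrently at
  risk) return p = 1 with a note instead of failing.
* Significance is fixed at 0.05 with no multiple-testing correction,
  matching the reporting it reproduces.

`build_report()` assembles the per-group mean ± SD/median/min/max columns
with Mann–Whitney p-values and categorical counts with Fisher p-values,
excluding missing values pairwise and reporting them in `n_missing`.

# The synthetic-data generator

The generator is a stated world, not a tuning knob. Its defaults are the
published cohort structure: group sizes 31/8/15 (no RT, single-dose,
fractionated), TUNEL means ± SD of 4.9 ± 4.0, 7.6 ± 5.5 and 15.9 ± 6.6
percent, monosomy prevalences 16/31, 5/8 and 6/15, and a 144-month
follow-up horizon. Choices the publication does not determine are made
once, on realism grounds:

* TUNEL percentages are drawn from a normal left-truncated at 0 (simple,
  bounded, matches the reported means/SDs to within the truncation shift of
  under one percentage point); a moment-matched lognormal is available as
  an option.
* Metastasis times are exponential with monthly hazards 0.012 (monosomy 3)
  and 0.004 (disomy 3) — free parameters chosen so that monosomy tumors
  metastasise earlier and the overall event fraction lands near the
  published 56 percent; no claim is made of reproducing the published
  5-year rates, which derive from unpublished per-patient data.
* Synthetic images place TUNEL-positive disks (nuclei-scale, radius ≤ 4 px)
  until the planted pixel fraction is met within 0.5 percent, with a
  single-pixel fill for the last gap; counterstain concentration 0.35
  everywhere, TUNEL 0.9 in positive regions, pigment 0.3 in patches
  covering ≈10 percent, Gaussian acquisition noise of SD 2 intensity
  counts, 8-bit quantisation.
* FISH cells are monosomic with the planted per-tumor probability, and
  every true signal drops out independently (default 2 percent), giving
  the closed-form expected index $(2 - m)(1 - d)$ used as a test oracle.

What a green test does *not* establish: real sections have spatially
correlated staining, out-of-focus blur, vessel and necrosis structure,
touching nuclei and scanner-dependent stain vectors — none of which the
generator emulates. The recovery tests certify the computational chain, not
the histology.

# End-to-end power check

`run_synthetic_study()` runs the full loop per seed — cohort, one rendered
field per tumor, deconvolution, thresholding, FISH classification, report —
and the acceptance suite requires the planted group ordering
(fSRT > sdSRT > noRT in mean estimated TUNEL percent) together with
Mann–Whitney p < 0.05 for fSRT vs noRT in at least 95 of 100 seeds.
Success is dominated by the sdSRT-vs-noRT mean ordering: with the published
moments (difference ≈ 2.8 points, SE ≈ 1.8 at $n = 8$ vs 31) the ordering
holds with probability only ≈0.94–0.97, so the criterion sits close to its
threshold by the cohort's own design, not by any tunable of this package.
Fields are rendered at 64 px for the replicated check (estimation error
under 1 TUNEL percentage point, far below the group differences); the
single-image recovery tests use 256 px.

# Known limitations

* File I/O is NetPBM (PPM/PGM) rather than TIFF/PNG; in-memory arrays are
  the canonical representation and conversion is a one-liner in any image
  tool. No whole-slide pyramids.
* Stain vectors are inputs; there is no automatic stain estimation.
* No spot detection from FISH images and no CD68/vessel segmentation —
  counts and masks are inputs, matching the scope of the computation being
  reproduced.
* The quantised deconvolution accuracy is bounded by quantisation noise
  amplified by $M^{-1}$ (see above); 16-bit acquisition or brighter
  exposure, not software, is the remedy.
* No Cox regression or multivariable modelling; the source analysis used
  none.
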