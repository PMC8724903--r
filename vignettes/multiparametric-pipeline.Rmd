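---
title: "Mapping proliferation, vasculature, and hypoxia against contrast enhancement: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping proliferation, vasculature, and hypoxia against contrast enhancement: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(perivox)
```

## The problem

Glioblastoma treatment — surgery and radiotherapy alike — is planned on the
contrast-enhancement (CE) region of gadolinium-enhanced T1-weighted MRI. But
biologically active tumor is not confined to CE: proliferating cells (seen as
¹⁸F-FLT PET uptake), hypervascularized tissue (seen as elevated relative
cerebral blood volume, rCBV, from DSC-MRI) and hypoxic tissue (¹⁸F-FMISO PET
uptake) can all extend into non-enhancing brain. `perivox` quantifies that
extension per patient: it segments a tumor volume and a high-uptake "hot
spot" on each modality's map and reports, for each, the **peripheral
volume** — the part of the segmented volume lying outside CE, expressed as a
percentage of the CE volume:

$$\text{peripheral volume (\%)} =
  100 \cdot \frac{\lvert \mathrm{ROI}_{\text{modality}} \setminus
  \mathrm{ROI}_{\text{CE}}\rvert}{\lvert \mathrm{ROI}_{\text{CE}}\rvert}.$$

Because the denominator is the CE volume, values above 100% are meaningful
(a modality volume far larger than CE) and do occur. The same Boolean
statistic applied to the hot-spot mask gives the **peripheral hot spot**.

Patient images for this kind of study are generally not shareable, so the
package pairs the analysis chain with a digital phantom generator
(`make_phantom()`) that produces cases with complete ground truth; every
stage is validated closed-loop against that truth.

## From DSC signal to rCBV

The DSC acquisition is a dynamic T2\*-weighted echo-planar series during a
gadolinium bolus (defaults: 35 frames, TR 2.28 s, TE 60 ms, 20 s injection
delay so the pre-bolus baseline is well estimated). Per voxel:

1. **Concentration.** The baseline signal $S_0$ is the mean over the
   baseline frames — all frames before the injection delay, discarding the
   first (steady-state transient) when more than three are available. The
   concentration-proportional quantity is
   $\Delta R_2^*(t) = -\ln(S(t)/S_0)/TE$ in ms⁻¹
   (`signal_to_deltaR2star()`). Voxels outside the brain mask or with
   non-positive signal are flagged invalid and zeroed, never propagated as
   NaN.
2. **First-pass model.** A gamma-variate
   $C(t) = K (t-t_0)^{\alpha} e^{-(t-t_0)/\beta}$ is fitted to the first
   pass only (`fit_gamma_variate()`), which removes the recirculation bump
   by construction. CBV is the area under the fitted curve; the closed form
   $K\beta^{\alpha+1}\Gamma(\alpha+1)$ is the default and agrees with
   numerical quadrature of the fitted model to better than 1e-6 relative
   (both are implemented; `compute_cbv(integration =)`).
3. **Normalization.** rCBV = CBV divided by the mean CBV of the
   normal-appearing contralateral tissue (`normalize_rcbv()`), realized as
   the mirrored tumor-free hemisphere: brain ∧ mirrored hemisphere ∧ ¬
   mirrored FLAIR (`contralateral_reference()`). The rCBV mean over that
   mask is 1 by construction.

### Numerical choices in the fit

The fit window runs from bolus arrival to the first post-peak sample below
20% of peak. Arrival is found by walking *backwards* from the peak to the
last sample below 10% of peak — walking forwards would let a single
pre-bolus noise spike drag the window open many frames early. Initialization
is by log-linearization of the model over the high-signal part of the
window, with a moment-based fallback; a fixed multi-start schedule (two
arrival candidates plus three deterministic perturbations) guards against
local minima without consuming the random-number stream, so the whole
pipeline is bit-reproducible. Convergence tolerance is 1e-10 on parameters.

Three bounds keep the closed-form area anchored to the observed data, and
all three are satisfied by any genuine first-pass bolus: $\beta$ may not
exceed the fit-window span (a tail slower than the observed washout is an
extrapolation artifact), $t_0$ may not precede the window start by more than
three frames, and $\alpha \ge 0.1$ (below that the model degenerates into a
decaying exponential whose area lies almost entirely outside the data). We
added the bounds after observing exactly this failure mode on noisy
background voxels: rare degenerate fits with $\alpha$ at the boundary whose
extrapolated area was tens of times the truth, inflating the contralateral
SD and thereby the rCBV segmentation threshold. With the bounds in place,
background fits at the default noise level show ~2% relative AUC spread and
no convergence failures.

Failed fits are reported explicitly (flag plus per-map count in the QC
attribute) and enter the CBV map as 0, never NaN, because downstream
thresholding needs finite maps. Voxels whose curve never exceeds a noise
floor (default 1e-4 ms⁻¹) are skipped. Identical curves are fitted once and
the result reused — on noise-free phantom data with a handful of tissue
classes this reduces tens of thousands of fits to four.

## Tumor-volume segmentation

Contrast-to-background differs so much between the three maps that a single
rule does not work; each modality gets the method that suits it, all exposed
individually:

* **FLT** — `flab_seg()`: a fuzzy locally adaptive Bayesian class model.
  Intensities inside an operator ROI (default: the FLAIR bounding box
  dilated by 2 voxels, `bbox_roi()`) are modelled as 2 or 3 Gaussian
  classes. Voxels hold fuzzy memberships; each voxel's class prior blends
  the global class proportions with the average membership of its
  6-neighbourhood (weight 0.3), which is the locally adaptive part and
  regularizes the boundary. The tumor is the highest-mean class after hard
  assignment. Initialization is intensity-quantile-free: class centers
  equally spaced over the intensity range, refined by deterministic Lloyd
  k-means — robust to the tumor being a small mass fraction, which makes a
  mass-quantile initialization collapse two classes onto the background. A
  constant ROI is a hard error, not an arbitrary split. The class count is
  a per-case choice, exactly as in semiautomated practice: a faint
  infiltrative margin needs the third class or it is absorbed into the
  broad high-uptake class (see `analysis/02_run_cases.R`).
* **FMISO** — `stat_threshold_seg()` at mean + 3.3 SD of the contralateral
  statistics (`contralateral_stats()`), restricted to the FLAIR
  hypersignal. The 3.3-SD rule corresponds to a one-sided Gaussian false
  positive rate of $\bar\Phi(3.3) \approx 4.8\times10^{-4}$; the test suite
  verifies the realized selection rate against that tail on 10⁶ background
  voxels. The 1.2 tissue-to-blood alternative is available as
  `ratio_seg()`.
* **rCBV** — the same statistical rule at mean + 1.96 SD
  ($\bar\Phi(1.96) = 0.025$), restricted to FLAIR; the 2–3× normal-appearing
  white matter alternative is `ratio_seg()` with the NAWM mean as
  reference.
* **Percent-of-maximum** (`percent_max_seg()`, e.g. 40% of SUVmax) is
  provided for comparison.

Thresholding conventions: statistical and ratio rules use strict `>`;
percentile and percent-of-max rules use `≥`, so a constant FLAIR region
yields a full (not empty) hot spot — the less surprising reading of a
histogram percentile. Non-finite voxels are excluded from all statistics and
never selected. Every `SegmentationResult` records its realized threshold
and parameters, so the mask is reproducible from its own metadata.

## Hot spots and peripheral metrics

The hot spot of a modality is the subvolume at or above the 95th percentile
(linear interpolation between order statistics, the common histogram
convention) of the map's values within the FLAIR hypersignal
(`hotspot_seg()`); it is a subset of FLAIR by construction. Peripheral
percentages are computed by exact Boolean voxel counting on the shared grid
(`peripheral_volume_pct()`, `peripheral_hotspot_pct()`,
`overlap_summary()`); volumes in mL are reported alongside
(voxel count × voxel volume). An empty CE mask is a hard error — a
percentage relative to nothing is meaningless and should fail loudly.

All mask algebra requires bit-identical geometry (same dimensions, spacing
within 1e-6 mm); inputs on different grids must be resampled explicitly with
`resample_to_reference()` (trilinear for maps, nearest for masks, identity
spatial transform — the package assumes co-registered inputs and does not
estimate registrations). Silent implicit resampling is deliberately absent.

## The digital phantom

`phantom_config()` / `make_phantom()` build a two-hemisphere ellipsoidal
brain with a three-compartment tumor — necrotic core, enhancing rim,
infiltrative margin, as nested spheres voxelized by center-of-voxel
inclusion (analytic volumes then bound the voxelization error in tests). CE
is the enhancing rim; the FLAIR hypersignal is rim + margin; a
normal-appearing white-matter sphere sits at the mirror image of the tumor.
Defaults encode the intended acquisition and biology:

| parameter | default | meaning |
|---|---|---|
| grid / spacing | 44×44×20 at 1.95×1.95×3.27 mm | PET reconstruction grid, shared by all maps |
| DSC timing | 35 frames, TR 2.28 s, TE 60 ms, delay 20 s | baseline well sampled before the bolus |
| FLT SUV (bg/core/rim/margin) | 0.4 / 0.3 / 2.5 / 1.5 g/mL | proliferation in rim and margin, cold necrosis, low normal-brain uptake |
| FMISO SUV | 1.0 / 0.8 / 2.2 / 1.45 g/mL | average background uptake with large SD (0.15); hypoxic rim, moderately hypoxic margin |
| bolus scale (core/rim/margin) | 0.3 / 3.0 / 1.0 | angiogenesis in the enhancing rim only; the infiltrative margin is not hypervascular |
| PSF FWHM | 5 mm | PET resolution, applied to the mean image before noise |
| DSC noise SD | 6 (signal units, S0 = 600) | ~1% signal noise |

The margin's unit bolus scale is a deliberate biological statement:
infiltration without angiogenesis. We initially set it to 1.1 ("mildly
vascular"), but once the rCBV chain reached its ~3% per-voxel precision that
became a reliably detectable elevation — i.e. a hypervascular margin, which
is a different phantom (it exists in the simulated cohort as the
`hypoxic_margin` case, scale 1.6). DSC signal is generated by the forward
model $S(t) = S_0 e^{-TE\,\Delta R_2^*(t)}$ with each compartment scaling
the background gamma-variate curve, so the analysis chain can be checked as
the exact inverse of the generator at zero noise. PET maps are compartment
means, PSF-smoothed, then Gaussian noise — resolution before counting
noise. One integer seed makes a case bit-reproducible; per-modality noise
substreams are derived from it deterministically.

The truth record stores pre-noise means, the generating ΔR2\* curves,
spacing-exact volumes, and peripheral percentages recomputed through the
same `spatial_metrics` code path that analyses the case — so truth
bookkeeping and pipeline disagreements cannot hide in a second
implementation.

**What the phantom does not emulate:** anatomy (no template brain, no
cortex/white-matter structure), MR artifacts and field inhomogeneity, PET
sinogram/reconstruction effects beyond a Gaussian PSF, tracer kinetics
beyond static SUV means, leakage effects in DSC (no leakage correction is
implemented, matching the intended analysis). Passing closed-loop tests
therefore demonstrates correctness of the computational chain under its own
model assumptions, not clinical performance on patient data.

## Workflow shape and problem sizes

The package is organised as an analysis workflow: `analysis/01…03` simulate
a six-case cohort spanning compact to extensively infiltrative tumors
(including a metabolically bland margin and a hypoxic, hypervascular
margin), run the full per-case analysis from NIfTI files on disk, and
summarize the cohort with the 0–20% / 20–40% / >40% peripheral-volume
binning. Images land under `scratch/`, tables under `results/`. All
computation lives in package functions (`run_case()`,
`summarize_cohort()`), which is also what the tests and
`scripts/acceptance.R` call.

Test and acceptance runs use a coarser 26×26×12 grid at 3×3×5 mm with
noise-free DSC where the check is a closed loop (identical compartment
curves then collapse to four unique fits), and the default noisy conditions
where spread matters (threshold calibration, the nested-volume scenario).
These sizes are the package's choice of a fast, fully converged test bed;
the cohort scripts run the full default grid.

## Known limitations

* The FLAB implementation follows the published idea (Bayesian class
  models, fuzzy memberships, local adaptation) but is not the original
  software; agreement is behavioural (Dice against truth and against the
  3.3-SD threshold), not bit-level.
* Registration is out of scope; inputs must be co-registered. Only grid
  resampling under an identity transform is provided.
* The gamma-variate fit needs ≥6 usable samples and a peak above the noise
  floor; extremely narrow boluses (washout within ~2 frames) push against
  the window heuristics.
* Hot-spot percentiles are computed on raw map values within FLAIR; no
  inter-modality normalization is attempted, and voxelwise inter-modality
  correlation is deliberately not part of the package.
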