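---
title: "Methods: pixel-ratio cell-fate scoring in 3D stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pixel-ratio cell-fate scoring in 3D stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement model

`cellfate3d` quantifies cell fate in 3D cultures **without segmenting
cells**. Each fluorescence channel of a z-stack is reduced to its total
foreground pixel area, summed slice by slice, and all readouts are
ratios of such areas. The ratiometric design is deliberate: nuclear
overlap, polyploidy, and irregular nuclear shapes bias cell *counting*,
but affect the numerator and denominator of a pixel ratio
symmetrically. The corresponding assumptions are that staining is bright
and uniform enough that foreground area tracks the amount of stained
material, and that nuclear morphology does not change drastically
across conditions.

Per position the pipeline computes

* viability $= \ln(\mathrm{Hoechst\ px} / \mathrm{dead\ px} + 1)$, with
  $\mathrm{dead} = \mathrm{EtHd} + \mathrm{apopxin} -
  \mathrm{EtHd}\cap\mathrm{apopxin}$ (cells positive for both death
  markers are counted once), and
* proliferation $= \ln(\mathrm{EdU\ px} / \mathrm{Hoechst\ px} + 1)$.

Per-image log ratios are averaged per treatment and divided by the
vehicle-control (DMSO) mean, so the control scores exactly 1.

## Choice of the proliferation orientation

A literal reading of the assay description would put Hoechst over EdU.
We default to **EdU over Hoechst** because the resulting normalized
score then *falls* as S-phase is suppressed, matching the downward dose
trends of proliferation read-outs; the literal orientation is available
as `orientation = "hoechst_over_edu"` and is recorded in the run
config. This is the single most consequential configuration switch in
the pipeline, which is why both the config snapshot and `images.csv`
make the orientation auditable.

## Normalization and dispersion

"Normalized to the control" is implemented as the ratio of treatment
mean to control mean (not per-image normalization before averaging);
the two agree in the mean but differ in dispersion. The SEM reported is
the per-image SD over $\sqrt n$, scaled by the control mean, treating
the control mean as a constant. Per-repeat aggregation is available by
scoring each repeat separately and comparing with `compare_groups()`.

A zero denominator is floored at an integer pseudocount of 1 px, which
keeps the logarithm finite and is negligible against realistic areas
($10^3$–$10^6$ px). Images whose *nuclear* channel fails the signal
rule are excluded from scoring (no cells found there); zero signal on a
marker channel legitimately contributes zero pixels.

# Preprocessing and thresholding

## Illumination correction

Widefield images carry a smooth, center-bright illumination bias. Each
plane is corrected as $\mathrm{plane} - G_\sigma * \mathrm{plane}$ with
negatives clamped to zero. $\sigma$ defaults to 50 px, chosen to sit
far above the nucleus scale (radius 5–10 px) so nuclei survive the
subtraction; a warning fires if $\sigma$ is within twice the expected
nucleus radius. The blur uses symmetric (edge-repeating) boundary
padding, which avoids the dark rims that zero-padding would read as
signal loss at the plane edges. Correction is strictly per plane: the
pipeline's contract is slice-by-slice analysis throughout.

Note what subtraction can and cannot fix: an *additive* center-bright
pedestal (stray light, autofluorescence haze) is removed almost
entirely; a *multiplicative* shading of the signal itself survives at
its original contrast. The threshold therefore still has to clear the
dimmest corner nuclei, which is part of why thresholds land well below
the nucleus intensity mode.

## Yen's threshold from central slices

One threshold is estimated per (position, channel) stack — never per
slice, because per-slice thresholds on empty edge slices hallucinate
foreground from noise. The estimate pools the histogram of the central
`ceiling(central_fraction * n_slices)` slices (default fraction 0.2,
minimum one slice) and maximizes Yen's entropic-correlation criterion
over all interior cuts, breaking ties toward the lower threshold. The
criterion is exactly constant across runs of empty bins, so the
implementation snaps to the lowest cut within $10^{-10}$ relative
rounding noise; cut validity is decided on integer counts (each class
must hold at least one pixel), not on floating cumulative
probabilities.

Two numerical choices deviate from the most naive construction, both
forced by observed degeneracies:

* **Histogram range.** 256 equal-width bins span
  $[0, q_{0.9999}(\mathrm{pixels})]$ rather than $[0, \max]$, with
  brighter pixels pooled into the top bin. A single freak-bright pixel
  (two nuclei overlapping in a summed widefield projection) otherwise
  stretches the range so far that the noise and halo structure collapse
  into one or two bins, and the criterion develops a second, spurious
  maximum above the nucleus mode. The quantile is an order statistic
  (type 1), so intensity rescaling rescales the bin edges exactly and
  masks are scale-invariant.
* **Central pooling on short stacks.** The 0.2 default is calibrated to
  production-scale stacks (251 slices: ~50 slices pooled). On 10–20
  slice test fixtures it pools only 2–4 slices, and the thresholds
  acquire visible seed-to-seed variance; the test fixtures therefore
  pool 5 of 10–12 slices (`central_fraction = 0.42`). The knob is
  exposed on the command line as `--central-fraction`.

Whether to pool central slices or to take a median of per-slice
thresholds was genuinely open; pooling was chosen as the variant that
uses all central pixels in one estimate, and the fraction knob makes
the block size explicit.

## The ten-fold signal-absence rule

A stack whose threshold is less than ten-fold its background mean is
declared devoid of biological signal (`has_signal = FALSE`) and
contributes an empty mask. "Background" is the mean of the pooled
central-slice pixels strictly below the threshold — self-contained, no
extra image pass. "Less than ten-fold" is strict: exactly ten-fold
passes. On corrected blank fields the threshold lands at roughly 1.5
noise SD and the background mean near 0.3 noise SD, a fold of ~5, so
blanks fail the rule with a wide margin; stacks with real nuclei show
folds of 30–100+.

## Co-culture arithmetic

Melanoma/fibroblast co-cultures tag the fibroblasts with H2B-eGFP.
Target-cell (melanoma) areas subtract the mask **intersection** with
GFP — not the raw GFP area — from the Hoechst and EtHd totals:
intersection subtraction is non-negative by construction, whereas
raw-area subtraction goes negative whenever GFP bleeds outside Hoechst
and double-penalizes misregistration. The raw-area variant remains
available (`coculture_areas(..., raw_subtraction = TRUE)`) for parity
studies. Apopxin is not used in co-culture runs (the green channel is
taken by GFP); `dead_area()` treats a single configured death channel
as a configuration, not an error.

# The synthetic world

The generator exists so that every pipeline stage can be validated
against ground truth. It emulates what a widefield microscope sees in a
3D collagen culture, at test scale:

* **Geometry.** Default 16 slices of 256×256 px holding 30 cells,
  nucleus radius 6 px, z-step half a radius (2 µm steps on ~4 µm-radius
  nuclei). That is ~1.9 in-focus nuclei per slice — denser than the
  production acquisitions (100–300 cells across 251 slices is ~0.4–1.2
  per slice). Crowding is the stability limit: at several-fold higher
  density, summed-overlap pixels reshape the histogram until Yen's
  criterion becomes bistable, which is no longer the assay's operating
  regime.
* **Light adds.** Every slice is the *sum* of contributions: in-focus
  nucleus cross-sections (flat-top discs with a soft 0.4 px edge and a
  1.4× chromatin-core boost, per-cell brightness lognormal with CV
  0.10, chord-length dimming toward the nucleus edge) plus the
  defocused halos of cells centered elsewhere, attenuated as
  $h^{(dz/r)^2}$ with $h = 0.3$ pinned at one nucleus radius of
  defocus, and blurred wider with defocus. This defocus continuum is
  load-bearing: it is exactly the histogram mass that makes Yen's
  criterion settle just above the haze and below the in-focus mode —
  the mechanism that rejects halos.
* **Camera.** A centered Gaussian vignetting field (1 at center,
  1 − 0.15 at the corners), a background offset of 100 counts and
  Gaussian noise of SD 15 (read noise and collagen autofluorescence
  lumped), rounded and clipped to 16 bits. Pure Gaussian noise (no
  Poisson term) keeps the thresholding behavior analytically
  tractable; photon statistics are not what is under test.
* **Fates.** One multinomial draw per cell over alive / EtHd-only /
  apopxin-only / both-marked, S-phase among survivors, and an optional
  GFP lineage tag; GFP-tagged cells are drug-protected by default
  (the drug-insensitive-fibroblast situation). Apopxin renders as a
  membrane ring overlapping the nucleus edge by 1 px, so dual-marker
  overlap subtraction is exercised with nonzero, non-total
  intersections.
* **Ground truth.** Per channel, the voxels of the noiseless,
  unvignetted render at or above half the nominal nucleus intensity —
  the in-focus marker footprint; defocus halos fall below that level by
  construction.

Scene, fates, rendering and plate layout are bit-reproducible functions
of a single integer seed.

## What a green test does and does not establish

The synthetic world shares the real assay's failure modes by
construction — halos, vignetting, blank wells, marker overlap, channel
crosstalk through co-culture arithmetic — so green tests establish that
the *pipeline logic* (correction, threshold estimation, signal rule,
area bookkeeping, normalization, parallel orchestration) behaves as
specified under those stresses. They do not establish performance on
real microscope data: real point-spread functions, collagen fiber
autofluorescence, spectral bleed-through, staining heterogeneity
beyond a lognormal, and focus drift are all outside the model. The
apopxin ring channel in particular is rendered with soft edges whose
thresholded masks run 1.4–1.9× the geometric ring footprint; pixel
areas on thin membrane structures should be read as relative, not
absolute, quantities — which the ratio-and-normalize design assumes
anyway.

## Test-fixture sizing

The dose-recovery fixtures use 4 px nuclei in 12-slice (recovery: 10)
stacks of 256² with 70 cells: the same areal density as the default
world, but ~2.3× the cells per CPU second, which is what makes strict
20/20-seed monotonicity of the proliferation score statistically
comfortable at test runtimes (the binding noise source is the
multinomial draw of S-phase cells at the 0.05 top-dose fraction). The
co-culture acceptance comparison is *paired*: one scene rendered with
and without its fibroblasts, isolating the deconvolution error from
sampling noise. Control wells carry 15% baseline death — spontaneous
death is realistic in 3D collagen, and a nonzero control denominator
makes the control log-ratio independent of absolute cell number, which
an all-alive control (denominator = pseudocount) is not.

# Statistics

Row-wise condition comparisons use Welch's unequal-variance t statistic
with Welch–Satterthwaite degrees of freedom (both groups constant and
equal gives $p = 1$ by convention). Families of rows are corrected with
the Holm–Šidák step-down: sort ascending, adjust
$1-(1-p_{(i)})^{m-i+1}$, enforce monotonicity with a running maximum,
and stop at the first non-rejection. Stars follow $p<0.05$ (*),
$p<0.005$ (**), $p<0.0005$ (***) on adjusted values. Comparisons are
meant to run on per-repeat treatment scores (n = independent repeats),
not per-image ratios.

# Numerical conventions, in one place

| Quantity | Convention |
|---|---|
| Segmentation | strictly greater than the threshold; a plane equal to the threshold everywhere is background |
| Threshold reported | upper edge of the selected cut bin |
| Tie-break | lowest cut within $10^{-10}$ relative criterion noise |
| Histogram | 256 bins over $[0, q_{0.9999}]$, overflow in the top bin |
| Cut validity | both classes hold ≥ 1 pixel (integer counts) |
| Signal rule | threshold ≥ 10 × mean of sub-threshold central pixels; equality passes |
| Degenerate stack | `has_signal = FALSE`, threshold $+\infty$, empty mask, logged — not an error |
| Pseudocount | denominator floored at 1 px |
| Blur boundary | symmetric (edge-repeating) reflection |
| Z-order | ascending z parsed as the last integer run in the file name |
| Intersections | slice-wise in 2D, never via z-projection |

# Known limitations

* Pixel areas are not cell counts; all conclusions are ratio-level.
* The threshold is global per stack; strong within-stack depth
  attenuation (deep 3D samples) would bias deep slices toward
  under-detection. The central-slice rule mitigates but does not remove
  this.
* The signal-absence rule is a heuristic with a knife edge near
  ten-fold; stacks with one dim cell over noise can fall on either
  side. The per-stack fold is logged in `decisions.csv` precisely so
  such calls are auditable.
* `robust_background_threshold()` is provided as the alternative
  backend for parity with CellProfiler-style pipelines but is not the
  validated default.
* Proprietary microscope container formats (ND2, CZI, LIF) and OME-XML
  metadata are out of scope; the expected input is one grayscale TIFF
  per slice with a channel token in the file name.
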