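---
title: "Quantifying mitophagy reporters and cytosolic mtDNA: methods and design"
author: "mitoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitophagy reporters and cytosolic mtDNA: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoquant)
```

## The assays

**mito-QC mitolysosome counting.** The mito-QC reporter is a
mitochondria-targeted mCherry-GFP tandem protein. In the neutral
cytoplasm both fluorophores emit, so mitochondria are mCherry+GFP+; in
the acidic lysosome lumen GFP is quenched, so a mitochondrion being
degraded (a *mitolysosome*) appears mCherry+GFP−. The countable unit of
mitophagy is therefore the set of mCherry-only puncta. The pipeline:

1. per-channel rolling-ball background subtraction (25 px radius),
2. per-channel Gaussian blur (sigma 1 px),
3. one *batch-frozen* global threshold per channel,
4. mitolysosome mask = mCherry+ mask minus GFP+ mask,
5. 3D connected-component counting of the difference mask.

The calibrated volume of the GFP+ mask is reported as mitochondrial
mass. All filtering is applied per 2D z-slice (the convention of the
tools these procedures come from) while object counting is fully 3D,
matching stacks acquired with a 0.5 µm z-step.

**Cytosolic DNA focus calling.** mtDNA escaping damaged mitochondria
into the cytosol is a cGAS/STING trigger. Anti-DNA immunostaining shows
nuclear DNA, intramitochondrial nucleoids, and — the signal of interest
— DNA puncta outside both organelles. After preprocessing (rolling ball
25 px, blur 0.75 px), TOMM20 and DAPI are thresholded, their union
forms the organelle exclusion mask, the DNA intensity is zeroed inside
it, and prominence-based maxima are counted per cell ROI on the maximal
projection of the residual. The subtraction is done at the signal level
(zeroing intensities) rather than as binary mask arithmetic because
maxima are detected on intensities; the mitolysosome case, which counts
mask components, uses binary subtraction as written above.

**Colocalization and intensity readouts.** Colocalization uses the
Manders overlap coefficient
\[
r = \frac{\sum_i A_i B_i}{\sqrt{\sum_i A_i^2 \sum_i B_i^2}} \in [0, 1],
\]
computed over the union of the two channel masks; it is symmetric and
invariant to rescaling either channel, and equals 1 exactly when the
channels are proportional on the evaluation region. Mean fluorescence
intensities (pUb-Ser65, NAO, p62, ubiquitin) are measured on maximal
projections, per cell ROI or as thresholded area fractions.

**Fraction-resolved qPCR.** For each sample, cytosolic and
mitochondrial Ct values of mtDNA-encoded genes (mt-Nd2, mt-Co1,
mt-Cytb) are transformed to relative levels \(2^{-\Delta Ct}\) against
nuclear 18S, and the cytosolic/mitochondrial ratio
\(R = 2^{-(Ct_{cyto} - Ct_{mito})}\) is formed per gene. The 18S term
cancels algebraically in \(R\) but both normalized levels are
reported. Amplification efficiency is fixed at 2 (no efficiency
correction), technical replicates are averaged on the Ct scale before
transformation, and undetermined Cts are treated as missing, never
imputed. A global Ct shift applied to one sample (e.g. a loading or
dilution effect) cancels in every ratio.

**Statistics policy.** Group data are screened per group with
Shapiro-Wilk (alpha 0.05) and for variance homogeneity with
median-centred Levene. Two groups: both normal → two-tailed Student's
t (Welch when Levene rejects); otherwise two-tailed Mann-Whitney U,
exact by full enumeration when min(n1, n2) ≤ 8 and by normal
approximation with tie and continuity correction otherwise. More
groups: fixed-effects one- or two-way ANOVA with Tukey HSD or
Šidák-corrected pairwise post-hoc comparisons. Spearman's rho uses
midranks, with exact permutation p for n ≤ 8 and the t approximation
beyond. Results always carry mean ± s.e.m. (sd/√n) and record which
route the policy took. Requiring *both* groups to pass normality for
the parametric route is the conservative reading of the policy; a
degenerate zero-variance pair falls back to the rank route, flagged.

## The synthetic scenes

The raw images behind these procedures are not deposited, so the
package ships a scene generator whose outputs carry a registry of every
planted object — the ground truth every pipeline is tested against.

A reporter scene renders (defaults in parentheses, all configurable via
`sceneParams()`):

- a 16 × 256 × 256 voxel stack at (0.5, 0.2, 0.2) µm — the confocal
  geometry of the emulated acquisition;
- the mitochondrial network as 3D random-walk tubes (6 segments,
  dilation radius 2 px in-plane, 1 slice in z), present in both
  channels at 1.2× the spot peak: network morphology is unspecified in
  the source procedures, and dilated random walks give realistic mask
  topology cheaply;
- mitolysosomes (30) as isotropic Gaussian puncta truncated at
  3 sigma with sigma = punctaRadius/2 (radius 3 px), present in
  mCherry only — the diffraction-limited spot model;
- an optional per-slice linear background ramp (amplitude 0 by
  default) to exercise background subtraction;
- Poisson noise (scale 1 photon per intensity unit) followed by
  Gaussian noise (sd 10, i.e. 10% of the spot peak of 100).

Placement enforces a minimum centre separation (default
4 × punctaRadius) and a clearance margin around the network so planted
puncta are resolvable; placement failure after bounded retries signals
over-dense parameters rather than silently overlapping objects. One
random stream per stack is split into substreams per object class, so
switching noise on or off never moves an object. Identical parameters
(including the seed) give bit-identical scenes.

DNA scenes add ellipsoidal nuclei (DAPI), a network avoiding the
nuclei (TOMM20), nucleoids confined to the network interior, and
cytosolic foci planted strictly outside both organelle footprints, in
cells defined by the Voronoi tiles of the nucleus centres. Planted
foci also keep one truncation radius plus 2 px away from ROI
boundaries: the emulated cells are delineated by hand, and a human
would not draw an outline through a focus — a focus cut by an ROI
border would otherwise be legitimately counted once per ROI by the
per-ROI maxima search.

**What the simulator does not model.** No optical PSF or
deconvolution, no axial blur (filtering is per-slice by design), no
photobleaching, drift, or tiling, no autofluorescence texture, and
mitochondrial networks are geometric tubes rather than segmented real
morphology. Passing ground-truth recovery here shows the *composition
of operators* is correct and robust to the modelled noise; it does not
certify thresholds or tolerances for any particular real microscope or
staining, which practitioners must calibrate on reference images as
they would in the original tools.

## Numerical choices

**Rolling ball.** The background is the grayscale opening with a
non-flat ball (spherical-cap) structuring element of the stated pixel
radius: erosion then dilation with height
\(h(d) = \sqrt{r^2 - |d|^2}\), out-of-bounds neighbours skipped. This
makes the background an idempotent, pointwise lower envelope; a
constant image yields an all-zero residual, and an unbounded linear
ramp is reproduced exactly (removed from the residual) away from the
borders. Within one ball radius of the image border the envelope is
weaker (the footprint is truncated) — identical to the exhaustive
definition, and visible as a small residual at the high edge of a
ramp.

**Thresholding.** Membership is intensity strictly greater than the
threshold. The threshold is a batch-level constant: either supplied,
or computed by Otsu's method (exhaustive between-class-variance
maximisation over a 256-bin histogram) on one designated reference
image and then frozen for the batch — mirroring the convention that
the same threshold is applied to every image of an experiment. Masks
record their threshold and its origin in their provenance.

**Object counting.** 26-connectivity by default (configurable to 6),
labels renumbered in first-encounter order. The primitive's default
size filter is minVoxels = 2 (suppress single-voxel speckle). The
*counting procedures* default to minVoxels = 8: at this calibration a
diffraction-limited punctum thresholded near half peak spans well over
10 voxels, while threshold flicker along organelle mask edges under
shot noise produces fragments of at most ~6 voxels, so the floor
separates noise from puncta with margin on both sides. Both values are
exposed in every signature and config.

**Maxima.** A candidate is a connected equal-value plateau with no
strictly higher neighbour inside the region; it is rejected if it
connects to a strictly higher pixel through pixels above (value −
tolerance). Equal-value maxima within tolerance of each other merge to
a single reported point (deterministic tie-break: the plateau with the
smallest linear index wins); plateaus report their centroid; maxima
whose value does not exceed the tolerance — in particular anything in
an all-zero region — are not reported, treating the tolerance as a
noise floor against the zero baseline.

**The focus-calling tolerance.** Zeroing the DNA signal inside the
exclusion mask leaves residual *halos* around organelles, bounded
above by the organelle threshold that cut the mask (any brighter voxel
would itself have been excluded). A tolerance expressed relative to
the image dynamic range sits below this bound and would report halo
fragments as foci even on noise-free scenes. The procedure therefore
defaults its tolerance to the larger of the two frozen TOMM20/DAPI
thresholds: every halo is silenced by construction, while genuine
cytosolic foci — whose peak after preprocessing is well above the
organelle cut — survive. The tolerance remains an explicit, overridable
parameter.

**TIFF round trips.** Stacks travel as multi-page TIFF, channel-major,
with voxel size, channel roles and the intensity scale in a JSON
sidecar. Integer-valued intensities up to 65535 (the realistic
acquisition bit depth) are stored as 16-bit samples and round-trip
bit-exactly; other values use 32-bit samples and return to within one
part in 2^31 of full scale. Reading fails with a named field when no
sidecar and no override supplies the voxel size.

**Exact small-sample inference.** The exact Mann-Whitney p enumerates
all C(n, n1) group assignments on midranks and counts two-sided tail
mass symmetrically about n1·n2/2 (the permutation distribution of U is
symmetric there, ties included). The Spearman permutation p enumerates
all n! rank permutations. Both switch to their large-sample
approximations above min(n) = 8 and n = 8 respectively, the largest
sizes where enumeration stays immediate.

## Problem sizes in the shipped tests

The unit tests run the pipelines on 96 × 96 × 10 scenes; the
acceptance suite uses the full default 16 × 256 × 256 geometry: 20
noise-free and 20 noisy reporter stacks (10-50 planted mitolysosomes),
6 noise-free and 20 noisy DNA scenes, 100 random 16³ masks for the
labelling oracle, 50 random 64² images × 3 tolerances for the maxima
oracle, 200 random small-sample datasets for the exact U oracle, and
500 null simulations per distribution for the policy's type-I error.
These sizes were chosen to make each property statistically meaningful
while keeping a complete run on a single CPU comfortable.

## Known limitations

- Per-slice (2.5D) filtering plus 3D counting is the emulated tool's
  convention, not an optimal 3D denoiser.
- Otsu-frozen thresholds inherit Otsu's bias on heavily unbalanced
  histograms; mitochondrial-mass volumes are threshold-sensitive
  (a half-peak threshold reproduces rendered volumes closely, a lower
  Otsu cut inflates them by several percent).
- The qPCR module models no fractionation cross-contamination and no
  amplification-efficiency estimation; dilution factors cancel in the
  ratios and are not corrected for.
- The test-selection policy is a documented convention (Shapiro-Wilk +
  median-centred Levene at alpha 0.05); the original analyses named
  the tests applied but not the screening procedure.
- No multiplicity correction is applied across independent endpoints;
  corrections live only inside post-hoc families.
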