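---
title: "Voxelwise atlas rating: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxelwise atlas rating: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxar)
```

## The diagnostic model

`voxar` implements atlas-based computer-aided diagnosis for conditions that
alter organ morphology, with congenital heart disease after d-TGA repair as
the motivating application. The central assumption is that an atlas image is
morphologically more similar to the target image when both share the same
clinical condition. Instead of suppressing the registration errors that
morphological differences cause, the method measures the residual
dissimilarity and reads the diagnosis out of it. No labelled (annotated)
images are needed — only intensity images grouped by condition, each with a
rough binary mask of the organ.

Given atlas databases $D_\omega = \{(J_n^\omega, M_n^\omega)\}_{n=1}^{N_\omega}$
for each condition $\omega \in \Omega$, and a target image $I$, the pipeline
is:

1. **Mapping.** Every atlas pair is mapped into target space. A two-stage
   scheme is standard: an affine stage whose mapped masks are fused by simple
   majority (threshold 0.5) into a rough organ mask, then a non-rigid stage
   with the target restricted to that mask. The deformable engine sits
   behind an adapter (`registration_config()`): `identity` for cohorts
   already on a common grid, `builtin_affine` for a 12-parameter NCC-driven
   affine, `external` for a full free-form-deformation tool via a subprocess
   contract (coarse-to-fine levels 3, rigid/affine iteration caps 5/8,
   non-rigid iterations 300, bending energy 0.005, NMI metric are carried in
   the config).
2. **ROI.** The mapped masks of each database are fused by majority voting
   at threshold 0.8 into $M_\omega$, and the analysis ROI is their
   intersection $M = \bigcap_\omega M_\omega$, so every database contributes
   information at every analysed voxel.
3. **Local similarity.** For every mapped atlas, the local normalised
   correlation coefficient
   $\mathrm{LNCC}_n^\omega(x) = \frac{\langle I, J_n^\omega\rangle(x)}
   {\sigma_I(x)\,\sigma_{J_n^\omega}(x)}$
   is computed, with all local moments obtained by Gaussian convolution with
   $\sigma_G = 2$ voxels.
4. **VoxAR rating.** The LNCC values of *all* atlases from *all* databases
   are ranked per voxel. With $L_n^\omega(x)$ indicating membership of the
   top $T$ (default $T = 7$), the per-condition count is
   $A^\omega(x) = \#\{n : L_n^\omega(x) = 1\}$. The rating map assigns
   $R(x) = \arg\max_\omega A^\omega(x)$ only when the winning count reaches
   the absolute-majority guard $\lceil T/2 + 1\rceil$; otherwise the voxel
   stays UNASSIGNED. The rating histogram is the percentage of assigned
   voxels per condition; its mode is the diagnosis and the gap between the
   top two bins (the *separation*) is a confidence proxy.
5. **ISA baseline.** The predecessor image-synthesis approach ranks LNCC
   within each database, converts ranks to weights
   $\alpha_n^\omega(x) = e^{-\beta r_n^\omega(x)}$ with $\beta = 0.5$, fuses
   the z-scored atlas intensities into a synthetic image per condition, and
   diagnoses by the global NCC between each synthetic image and the
   (z-scored) target.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `sigma_g` | 2 | voxels | Gaussian window of the local moments; smaller windows see finer morphological differences |
| `T` | 7 | atlases | pooled top size per voxel; larger T smooths the rating but dilutes local evidence |
| majority guard | `ceil(T/2+1)` (5 for T = 7) | count | minimum winning count for a voxel to be assigned |
| `beta` | 0.5 | — | exponential rank decay of the ISA fusion weights |
| fusion threshold | 0.8 | fraction | refined majority-vote mask fusion per database |
| affine fusion threshold | 0.5 | fraction | rough-mask fusion after the affine stage |

Two readings of the guard coexist in the method's description: the printed
formula $\lceil T/2+1\rceil$ (5 of 7) and the verbal "absolute majority"
(4 of 7). The package implements the printed formula exactly and exposes the
guard as an explicit override (`threshold =`), so either reading is one
argument away. Because the guard exceeds $T/2$, an assigned voxel's winning
count is always a strict unique maximum — argmax ties can never be assigned.
A corollary the tests pin down: for $T \le 3$ combined with small databases
the guard can be unreachable and every voxel stays UNASSIGNED, in which case
the diagnosis is explicitly refused rather than guessed.

Rank origin: the best atlas receives rank 0 (weight $e^0 = 1$). Starting
ranks at 1 would scale every weight by $e^{-\beta}$, which cancels in the
normalised fusion — the choice is provably diagnosis-neutral, so it is fixed
once here.

## Numerical choices

* **Convolution boundary.** Local moments use zero padding renormalised by
  the convolved all-ones volume, so the effective weights at every voxel sum
  to one and edge voxels inside the ROI are not attenuated. The kernel is
  truncated at $4\sigma$ (relative error < 1e-4). The test suite checks the
  convolution path against a direct full-grid weighted-summation oracle to
  1e-5.
* **Flat regions.** Where $\sigma_I \sigma_J$ falls below
  $10^{-6} \cdot s_I s_J$ (the ROI-wide intensity scales), the LNCC is 0/0
  and the voxel is flagged undefined; undefined entries never enter any
  ranking. Per-voxel ranking is over the defined atlases only.
* **Ties.** All rankings are stable: ties keep (condition name, atlas index)
  order. Exact global-NCC ties in ISA are broken by condition-name order and
  flagged in the report.
* **Vote fractions.** Mask fusion evaluates `count/N >= threshold` as a
  fraction with a 1e-12 guard, so the boundary case 16/20 at threshold 0.8
  is foreground.
* **z-scores** use the population standard deviation over the ROI; voxels
  outside the ROI are transformed with the same affine map.

## What the phantom generator emulates — and what it does not

No public cohort exists for the original clinical application, so the
package ships a synthetic-phantom module that reproduces the *statistical
structure* the rating method relies on: several morphologically distinct
condition classes whose differences are local (vessel arrangement) while the
bulk anatomy is shared, within-condition anatomical variability, intensity
inhomogeneity, and noise on a textured nonzero background.

Each subject is a condition template — a shared body ellipsoid plus two
tube-like vessels: parallel (`normal`), crossed (`switch_a`, emulating the
translocation of an arterial-switch repair), anteriorly displaced with a
connecting baffle slab (`switch_b`, emulating an atrial-switch repair), or a
single widened displaced vessel (`fallot`, the novel-morphology probe) —
warped by a random smooth displacement field, modulated by a smooth
multiplicative bias field, plus Gaussian noise.

Defaults and why:

* grid $48^3$, spacing 1.5 mm isotropic — a heart-sized ROI at whole-heart
  MR angiography resolution, small enough that a full leave-one-out
  experiment runs on one CPU in minutes;
* deformation amplitude 1 voxel RMS per component, smoothness 5 voxels —
  the experiments run with the `identity` registration backend, so the
  per-subject warp stands for the *residual* misalignment left after
  non-rigid inter-subject registration, which is of voxel order;
* noise sd 8 against a structure/background contrast of 80 (SNR 10), bias
  amplitude 10% — ordinary angiographic image quality;
* condition differences are carried by structures occupying a modest
  fraction of the mask, so most ROI voxels are condition-neutral — the
  regime in which pooled ranking (and its sensitivity to database
  imbalance) is actually exercised.

What passing phantom experiments do **not** show: performance under real
registration error fields (which are correlated with anatomy, not
synthetically smooth), under pathologies that alter intensity rather than
shape, or at clinical effect sizes. The phantom results demonstrate the
machinery's correctness and its qualitative behaviours (size sensitivity,
imbalance bias, reduced confidence on unknown morphology), not clinical
accuracy.

## Experiment harnesses and their problem sizes

All experiments run on common-grid cohorts with identity registration, so
diagnosis quality is attributable to the rating machinery rather than to a
registration engine. Because the LNCC is symmetric in its two images, the
harnesses precompute one pairwise LNCC map per unordered subject pair
(`build_lncc_cache()`) and re-rank cached values per experiment; a test
asserts exact agreement between the cached path and the direct
`voxar_diagnose()` pipeline.

* Leave-one-out comparison: 3 conditions × 10 subjects, $48^3$.
* Size sweep: 3 × 11 subjects; balanced subsamples of 3/5/7/10 atlases per
  database, 10 repeats. The sweep's resampling is stratified random
  subsampling without replacement per repeat — a pragmatic reading of
  "balanced repeated K-fold generalisation"; at size 3 the majority guard is
  unreachable (3 × 3 = 9 atlases cannot give 5 of 7 to one condition when no
  database holds 5) and the refused diagnoses score as failures, which is
  the faithful behaviour of the printed rule.
* Imbalance study: correct-database minority 5 vs 10/10 and majority 10 vs
  5/5, against balanced-5 and balanced-10 baselines, 10 repeats. This is the
  published unbalanced design (10 vs 19/19 and 19 vs 10/10) at a scale that
  keeps the cohort at 33 subjects.
* Missing-pathology probe: 4 novel-morphology targets against the three
  known databases, with known-condition leave-one-out separations as the
  baseline.

A refused diagnosis (empty rating histogram, or empty ROI intersection)
counts as incorrect in every accuracy and as wrong-for-both-classes in the
binary (pathological-vs-normal) metrics.

## Known limitations

* The deformable registration engine is deliberately out of scope; the
  `external` backend carries the standard parameter block verbatim but the
  package itself only provides identity and affine mappings.
* The rating histogram is a confidence *proxy*, not a calibrated posterior;
  turning it into one is future work in the method's own framing.
* Conditions absent from the databases cannot be identified — the probe
  harness quantifies the reduced separation such targets produce, which is a
  flag, not a detection.
* The affine search is gradient-free (Nelder-Mead over 12 parameters,
  multi-resolution); it is adequate for the rough alignment the pipeline
  needs, not a general-purpose registration.
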