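---
title: "Regional lung mechanics from serial inspiratory CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional lung mechanics from serial inspiratory CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Two inspiratory CT scans of the same subject, both acquired near total lung
capacity (TLC) but months apart, differ subtly: regions of the lung may have
become relatively hyper-expanded — through air trapping, local compliance
change, or tissue remodelling around a growing lesion — even when the global
lung volume is essentially unchanged. `lungmech` quantifies such changes
voxel by voxel. It registers the two scans with a mass-preserving similarity
metric, converts the local volume change into indices normalized for global
volume differences, and summarizes the fraction of lung that is
hyper-expanded.

Throughout, the *floating* image is the earlier scan (Time 0) and the
*reference* image the later scan (Time 1). The warp $T(x)$ maps reference
positions into the floating image.

## Density decomposition

CT intensity in Hounsfield units is treated as a linear mixture of air and
"tissue" — where tissue means every non-air component: parenchymal tissue,
blood, extravascular water, inflammatory cells, contrast medium. With
anchors $HU_{air} = -1000$ and $HU_{tissue} = +55$, a voxel of geometric
volume $v$ decomposes as

$$ v_{tissue}(x) \;=\; v(x)\,
   \frac{\mathrm{clamp}(I(x)) - HU_{air}}{HU_{tissue} - HU_{air}},
   \qquad v_{air} = v - v_{tissue}, $$

with intensities clamped to $[-1000, 55]$ so fractions stay in $[0,1]$.
Because scanners drift and clinical protocols vary, volumes should first be
calibrated with `calibrate_hu()`: a global affine intensity map fitted so
the mean of a mid-tracheal ROI is exactly $-1000$ and the mean of an aortic
ROI exactly $+55$. A single affine map (rather than two independent shifts)
was chosen because it preserves intensity ordering, is idempotent, and is
determined exactly by the two anchors; no nonlinear HU correction is
attempted.

## The SSTVD registration

Matching raw intensities between inspiratory scans is unreliable: a region
that expands becomes darker without any tissue change. The registration
therefore minimizes the sum of squared **tissue volume** differences
(SSTVD),

$$ E(T) \;=\; \sum_{x \in \Omega}
   \big( v^r_{tissue}(x) - v^f_{tissue}(T(x)) \big)^2 , $$

over the reference region of interest $\Omega$ (the union of lung, airway
and vessel masks). When tissue density is approximately constant, driving
$E$ down preserves the tissue mass of the lung.

The floating-side term needs a discretization choice the cost's definition
leaves open: which volume multiplies the interpolated floating tissue
fraction. This package uses the mass-preserving form

$$ v^f_{tissue}(T(x)) \;=\; v_r \,\det\!\big(\partial T/\partial x\big)\,
   \mathrm{frac}\big(I^f(T(x))\big), $$

i.e. the reference voxel volume scaled by the local volume ratio, so a
voxel is compared against the floating volume it actually matches. The
intensity clamp is applied inside the cost, before the fraction, and images
are interpolated trilinearly.

### Transform model and optimization

$T(x) = x + \sum_\ell u_\ell(x)$ is an additive stack of cubic B-spline
free-form deformation levels, optimized coarse to fine. Per level the image
pyramid is block-averaged (factors 4/2/1 by default) and the control
spacing halves. Each level's coefficients are optimized with L-BFGS-B using
the analytic gradient of $E$, which involves both the interpolated image
gradient and the cofactor matrix of $\partial T/\partial x$ (for the
determinant factor). Defaults: 3 levels, finest control spacing
$4\times$ the largest voxel dimension, 200 iterations per level,
convergence when the relative cost decrease stays below $10^{-6}$.

No explicit smoothness regularization term is used; instead each
coefficient is box-bounded to $0.4\times$ its level's control spacing — a
classical sufficient condition for a single cubic FFD level to remain
diffeomorphic — and the fraction of lung voxels with non-positive Jacobian
is always computed and reported (a fraction above 1% triggers a warning).
Registration is deterministic given its inputs: there is no stochastic
sampling in the cost.

For sharp, localized expansion (lesion-like phantoms) the recommended
setting is a 4-level stack with image factors 4/2/1/1 and a finest control
spacing of about two voxels, e.g.
`reg_control(levels = 4, downsample = c(4, 2, 1, 1), control_spacing = 4,
maxit = 400)`; the default 3-level stack is adequate for smooth global
deformations and roughly twice as fast.

### Jacobian conventions

`jacobian_field()` returns $\det(\partial T/\partial x)$ — the floating
volume matched to one unit of reference volume (uniform scaling by 1.1
gives 1.331). The mechanics maps use the reciprocal **volume ratio**
$J = v^r/v^f = 1/\det$, so that local expansion from Time 0 to Time 1
gives $J > 1$. Both conventions are exact for affine and radial transforms
and use analytic basis derivatives for B-spline stacks; sampled
displacement fields fall back to central differences.

## Normalized fractional change maps

With global lung volumes $V^r$, $V^f$ (geometric volume of each image's own
lung mask), the normalized fractional volume change is

$$ \Delta^* \;=\; J\,\frac{V^f}{V^r} - 1 . $$

Uniform global inflation leaves $\Delta^*$ at zero everywhere; $\Delta^* =
0.5$ means the region's contribution to the global lung volume grew by
50%. The air and tissue analogues replace $J$ by the ratio of per-voxel
component volumes at matched points:

$$ \Delta^*_{air} = \frac{v^r_{air}}{v^f_{air}}\frac{V^f}{V^r} - 1,
   \qquad
   \Delta^*_{tissue} = \frac{v^r_{tissue}}{v^f_{tissue}}\frac{V^f}{V^r} - 1. $$

The floating-side per-voxel volumes use the same matched volume
$v^f = v_r \det(\partial T/\partial x)$ as the cost, split into components
by the interpolated floating tissue fraction. This choice makes the
additive identity

$$ (1+\Delta^*)\,v^f \;=\; (1+\Delta^*_{air})\,v^f_{air} +
   (1+\Delta^*_{tissue})\,v^f_{tissue} $$

hold to machine precision wherever all three maps are defined, which the
test suite asserts at $10^{-9}$ relative tolerance on every computed pair.
Voxels whose floating air or tissue volume falls below $10^{-6} v_r$ are
excluded from the respective map (and counted) to avoid division blow-ups;
voxels mapping outside the floating extent or with non-positive
determinant are likewise excluded and counted.

Summaries report, for each threshold $t$ (defaults 0.2, 0.5, 1.0), the
percent of lung volume with $\Delta^* \ge t$ and with
$\Delta^*_{tissue} \ge t$. The 50% index drives the pair-level
hyperinflation flag at lung-volume cutoffs of 0.1, 0.5, 1 and 2 percent.
Hyper-expanded voxels are additionally classified by the sign of their
normalized air-content change. An optional interior erosion of the lung
domain discounts the boundary, where large apparent deformations
concentrate; it defaults to off, and per-voxel validation statistics in
the tests are evaluated at least two voxels inside the boundary.

## The digital phantom

`generate_phantom()` builds seeded serial pairs with exactly known answers:

* **Anatomy (Time 0):** a soft-tissue body at $+55$ HU; an ellipsoidal
  lung (semi-axes 0.33/0.28/0.40 of the grid extent) of parenchyma at
  $-860$ HU with a smooth Gaussian-random-field texture (SD 30 HU,
  correlation length 8 mm); a tracheal air column of radius 5 mm; six
  bright vessel-like chords of radius 1.2 mm. The composed anatomy is
  filtered with a scanner-like Gaussian PSF ($\sigma$ = 0.6 voxel), since
  real CT boundaries are band-limited — a crisp synthetic boundary would
  be inconsistent with any interpolated evaluation of the image. Defaults
  emulate inspiratory-CT parenchyma; the texture and vessels give the
  registration local structure, as vasculature and septa do in real
  lungs.
* **Deformation:** analytic and invertible — affine scalings, random
  B-spline fields, or a radial "lesion" map that expands a spherical core
  with a $C^1$ monotone falloff shell (width one quarter of the core
  radius). The generator verifies $\det > 0$ on the whole grid and refuses
  non-invertible requests. Because the radial map is identity outside its
  shell, the global lung volume is unchanged: the shell compresses to
  balance the expanding core, exactly how a locally hyper-expanding region
  redistributes volume in a lung held at TLC. The core volume ratio is
  therefore simply $J_{core} = 1 + \Delta^*_{target}$, and the core radius
  is set from the requested fraction of the lung volume.
* **Time 1 synthesis:** the Time 1 image is the warp-resampled Time 0
  with the mass-preserving intensity update
  $\mathrm{frac}_1(x) = \det(\partial T/\partial x)\,
  \mathrm{frac}_0(T(x))$ (capped at 1), so hyper-expanded regions become
  darker exactly as conservation requires, and both time points share one
  band-limited sampling process — as two acquisitions of one subject do.
  An optional tissue lesion multiplies the floating tissue fraction
  inside a sphere before warping, emulating tissue gain. Independent
  Gaussian noise (SD 20 HU) added to each time point afterwards
  decorrelates the pair.
* **Ground truth:** the analytic Jacobian gives exact $J$ maps;
  $\Delta^*$ truth combines them with the voxel-counted global volumes, so
  the truth satisfies the $\Delta^*$ identity exactly. `oracle_summary()`
  turns the truth into the same summary the pipeline produces, with no
  registration involved.

What the phantom does **not** emulate: airway-tree morphology, scanner and
reconstruction-kernel differences, contrast enhancement, cardiac or
breathing motion, and segmentation errors. Passing the phantom suite shows
the estimator recovers known deformations under realistic noise and
texture; it does not bound errors on clinical scans, where protocol
variability adds further uncertainty.

## Group statistics

Per-pair indices are compared between groups with Welch's unequal-variance
two-sample $t$ test (Welch–Satterthwaite degrees of freedom). Two-sided
$p$ values are reported — the conservative default where sidedness is not
specified — and no multiple-testing correction is applied; raw $p$ values
are printed. Pairs are treated as independent records even when a subject
contributes several; `group_table(per_subject = TRUE)` averages within
subject first as a sensitivity analysis. Identical constant samples return
$t = 0$, $p = 1$ by convention.

## Problem sizes and runtime

The shipped validation suite works at the sizes a single CPU handles
comfortably: $64^3$ phantoms (2 mm voxels) for identity and
lesion-recovery checks — a lesioned registration with the 4-level stack
takes about two minutes — and $48^3$ (2.6 mm) for the synthetic two-group
cohort (7 identity controls vs 10 lesioned cases), where each pair
registers in about ten seconds with the default stack. Clinical-resolution
volumes are larger by two orders of magnitude; the algorithms are the
same, with runtime scaling linearly in the number of lung voxels times
optimizer iterations.

## Known limitations

* No regularization term beyond coefficient bounds: very large or sliding
  deformations may fold; the negative-Jacobian fraction is the guard.
* The SSTVD cost does not vanish when true tissue change exists between
  scans (a growing nodule); it minimizes, not removes, the discrepancy,
  and the fitted det field smooths sharp expansion edges at the scale of
  the finest control spacing.
* $\Delta^*_{tissue}$ is noticeably more sensitive than $\Delta^*$ —
  tissue occupies a small fraction of a parenchymal voxel, so small HU
  errors move the ratio strongly.
* Contrast agent inflates the apparent tissue fraction; excluding
  vessel-mask voxels (`exclude_vessels = TRUE`) limits, but does not
  remove, the effect.
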