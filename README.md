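# lungmech

Quantitative CT (QCT) assessment of **regional lung mechanics** from pairs
of serial inspiratory CT scans, for imaging scientists and pulmonary
researchers who want to quantify where a lung has become relatively
hyper-expanded between two time points — e.g. while monitoring oncology
patients for early regional changes that precede visible lung metastases.

Two scans of the same subject near total lung capacity are registered with
a mass-preserving non-rigid method, and the local volume change is turned
into indices that are insensitive to global inflation differences.

## Method

**Density decomposition.** Each voxel of volume $v$ splits into air and
"tissue" (all non-air components) linearly in Hounsfield units between
$HU_{air}=-1000$ and $HU_{tissue}=+55$:

$$ v_{tissue}(x) = v(x)\,\frac{I(x) - HU_{air}}{HU_{tissue} - HU_{air}},
   \qquad v_{air} = v - v_{tissue} . $$

Volumes are first calibrated (`calibrate_hu()`) so a tracheal ROI averages
−1000 HU and an aortic ROI +55 HU.

**Registration.** The warp $T(x)$ from the reference (later, Time 1) grid
into the floating (earlier, Time 0) image minimizes the sum of squared
tissue volume differences (SSTVD),

$$ E = \sum_{x\in\Omega}\big(v^r_{tissue}(x) - v^f_{tissue}(T(x))\big)^2 , $$

which matches local tissue *mass* rather than raw intensity. $T$ is a
multilevel cubic B-spline free-form deformation optimized coarse-to-fine
(L-BFGS-B, analytic gradients including the Jacobian-determinant factor).

**Normalized fractional volume change.** With local volume ratio
$J = v^r/v^f$ and global lung volumes $V^r, V^f$:

$$ \Delta^* = J\,\frac{V^f}{V^r} - 1 , $$

so uniform inflation gives 0 and $\Delta^*=0.5$ means the region's
contribution to the global lung volume grew by 50%. Air and tissue
analogues $\Delta^*_{air}$, $\Delta^*_{tissue}$ use the matched component
volumes. The headline index $\Delta^*_{50\%}$ is the percent of lung
volume with $\Delta^* \ge 0.5$; pairs are flagged hyperinflated at
configurable lung-volume cutoffs (0.1–2%), and groups of pairs are
compared with Welch two-sample t tests.

A seeded digital phantom generator (`generate_phantom()`) produces serial
pairs with analytically known deformations and exact ground-truth
$\Delta^*$ maps for end-to-end validation; see the methods vignette
(`vignettes/regional-lung-mechanics.Rmd`) for the model and all numerical
choices.

## Worked example

Generate a 64³ phantom whose lung carries a hyper-expanding region
(target $\Delta^*$ = 0.8 over 15% of the lung), recover it by
registration, and summarize:

```r
library(lungmech)

spec <- phantom_spec(hyper_region = list(lung_fraction = 0.15,
                                         target_delta = 0.8),
                     seed = 101)
pair <- generate_phantom(spec)
oracle_summary(pair)$pct_hyper_at_50   # ground truth, no registration
#> [1] 15.22571

fit <- run_pair(pair$time1, pair$time0, pair$masks1, pair$masks0,
                control = reg_control(levels = 4, downsample = c(4, 2, 1, 1),
                                      control_spacing = 4, maxit = 400))
fit$summary
#> Hyper-expansion summary (% of lung volume at or above threshold)
#>  threshold pct_lung_hyper pct_lung_tissue_exp
#>        0.2         19.390             9.47400
#>        0.5         12.970             0.80280
#>        1.0          2.881             0.02501
#> pair hyperinflated (Delta50%* = 13%): 0.1%:yes 0.5%:yes 1%:yes 2%:yes
#> air content in hyper-expanded voxels: 5186 increased, 0 decreased
```

The recovered percent of hyper-expanded lung (13.0%) sits within the
voxelization/smoothing error of the 15.2% ground truth; the per-voxel
$\Delta^*$ map correlates with the truth at r = 0.92 in the lung interior.
`plot(fit$registration)` draws the per-level cost convergence;
`welch_t()` / `group_table()` compare groups of such per-pair records.

A command-line interface wraps the same pipeline:

```sh
exec/lungmech phantom --seed 17 --out-dir phantom17/
exec/lungmech pair --ref t1.nii.gz --flt t0.nii.gz \
    --ref-mask m1.nii.gz --flt-mask m0.nii.gz --out-dir out/
exec/lungmech group-stats --records pairs.csv --reference control
```

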