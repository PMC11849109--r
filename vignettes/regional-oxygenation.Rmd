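---
title: "Regional brain oxygenation from multi-delay pCASL and QSM"
author: "oxflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional brain oxygenation from multi-delay pCASL and QSM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxflow)
```

# The measurement problem

Cerebral tissue viability depends on the balance between oxygen delivery
and consumption. Three quantities describe it regionally:

* **CBF** (cerebral blood flow, ml blood /100 ml tissue /min) and **ATT**
  (arterial transit time, ms), estimated from multi-delay
  pseudo-continuous arterial spin labelling (pCASL);
* **OEF** (oxygen extraction fraction), the fraction of arterial oxygen
  removed by the tissue,
  $\mathrm{OEF} = (S_aO_2 - S_vO_2)/S_aO_2$, where the venous saturation
  comes from quantitative susceptibility mapping (QSM) of large draining
  veins and the arterial saturation from the exhaled-oxygen trace;
* **CMRO~2~** (µmol O~2~ /100 ml tissue /min), their product
  $\mathrm{CMRO_2} = \mathrm{CBF} \cdot [O_2]_a \cdot \mathrm{OEF}$ with
  $[O_2]_a$ the arterial oxygen content.

`oxflow` implements this measurement chain end to end, together with
synthetic phantom generators that emulate its inputs, Bland-Altman
test-retest statistics, and a thin linear mixed-model group stage.
Because venous saturation is only measurable in a handful of large veins,
all quantities are reported per *venous drainage territory*: the brain
regions whose blood drains into the superior sagittal sinus (vertical and
horizontal segments), straight sinus, basal veins and internal cerebral
veins.

# The kinetic model

The pCASL label-control difference signal under a single blood
compartment (no exchange of label into tissue; decay at the T1 of blood
throughout) at readout time $t = \tau + w$ from label onset, with label
duration $\tau$ and post-label delay $w$, is

$$
\Delta M(t) =
\begin{cases}
0 & t < \mathrm{ATT}\\[2pt]
A\,(1 - e^{-(t-\mathrm{ATT})/T_{1b}}) & \mathrm{ATT} \le t < \mathrm{ATT}+\tau\\[2pt]
A\,(1 - e^{-\tau/T_{1b}})\, e^{-(t-\mathrm{ATT}-\tau)/T_{1b}} & t \ge \mathrm{ATT}+\tau
\end{cases}
$$

with amplitude
$A = 2\,\alpha\,(M_0/\lambda)\,f\,T_{1b}\,e^{-\mathrm{ATT}/T_{1b}}$,
$f = \mathrm{CBF}/6000$ in ml/ml/s and $T_{1b}$ in seconds inside the
prefactor. The function is continuous at both regime boundaries and
linear in CBF and in $M_0$; in the late regime it reduces exactly to the
standard single-delay quantification formula.

Parameters and defaults:

| parameter | meaning | default | why |
|---|---|---|---|
| $\alpha$ | labelling efficiency | 0.85 | standard pCASL value; vascular crushing and background suppression are treated as absorbed into it |
| $\lambda$ | blood-brain partition coefficient | 0.9 ml/ml | scales the voxel-wise $M_0$ to blood $M_0$ as $M_0/\lambda$; the measurement protocol uses voxel-wise calibration, so this is a stated convention rather than an empirical choice |
| $T_{1b}$ | blood T1 | per subject | from haematocrit via $1/T_1\,[\mathrm{s^{-1}}] = 0.52\,\mathrm{Hct} + 0.38$ |
| schedule | $(\tau, w)$ pairs, ms | six pairs | union of two 3-delay acquisitions, PLDs (700, 1297, 2158) and (1000, 1573, 2024) ms with label durations (573, 885, 2024) ms paired index-wise ascending, fitted jointly |

## Estimation

`fitVoxel()` minimises the sum of squared deviations of the
$M_0$-normalised signals from the forward model, bounded to CBF
$\in [0, 200]$ ml/100 ml/min and ATT $\in [100, 3500]$ ms (physiology
plus schedule support). The piecewise model has local minima, so the fit
is restarted from ATT $\in \{800, 1200, 1600, 2000\}$ ms with CBF
started at 50; the candidate with the smallest residual wins and ties go
to the smallest ATT, which makes the fit deterministic. Negative measured
signals are kept, not clipped: under zero-mean noise this is unbiased.
All-zero input is detected up front and reported as CBF = 0 with ATT
pinned at the lower bound and `converged = FALSE`, since ATT is then
meaningless.

## A structural identifiability limit

In the late regime the ATT factors cancel:
$e^{-\mathrm{ATT}/T_{1b}}\,e^{-(t-\mathrm{ATT}-\tau)/T_{1b}} =
e^{-(t-\tau)/T_{1b}}$. Consequently, **when every delay of the schedule
samples the late regime — i.e. whenever ATT is at or below the minimum
PLD (700 ms for the default schedule) — the data contain no information
about ATT at all**, while CBF is still exactly identifiable. Two ATT
values below that floor produce bit-identical signals. No optimiser can
recover ATT there; ours converges to the edge of the flat region. Tests
and phantom comparisons therefore treat ATT as meaningful only above the
minimum PLD, and the acceptance script reports the noiseless recovery
error separately for the identifiable part of the parameter grid and for
the degenerate 600 ms edge, where the error is irreducible.

## Estimator behaviour at very low SNR

The peak difference signal at CBF = 50, ATT = 1400 is about 0.55% of
$M_0$. With per-delay noise of 0.5% of $M_0$ — single-average SNR of
order 1 — the bounded least-squares estimator is markedly skewed: the
acceptance script measures the median CBF over 2000 such voxels at
roughly +15% of truth, and an exhaustive grid-search oracle shows the
same effect, so it is a property of the estimator in that noise regime,
not of the optimiser. Real acquisitions average many label-control pairs
and operate at substantially higher effective SNR; quantitative use of
single-average fits at SNR ≈ 1 is outside the method's intended regime.

# Venous oximetry

Vein ROIs drawn (or simulated) around each vein are refined by keeping
only voxels whose susceptibility lies in [130, 1000] ppb (inclusive;
1 ppm = 1000 ppb), removing tissue below and artefacts above. The vein
value is the 90th percentile of the non-zero refined voxels — linear
interpolation between order statistics, chosen for reproducibility — a
high percentile countering partial-volume dilution at the vessel edge.
The CSF-referenced susceptibility difference then inverts to venous
saturation through

$$
\Delta\chi_{vein-CSF} = (1 - S_vO_2)\,\Delta\chi_0\,\mathrm{Hct}
 + \Delta\chi_{Hb-H_2O}\,\mathrm{Hct},
$$

with $\Delta\chi_0 = 0.27$ ppm per unit haematocrit and
$\Delta\chi_{Hb-H_2O} = -0.03$ ppm in cgs units.

**Unit convention.** The package works in SI ppm internally, with
constants $4\pi$ times the cgs values. The rationale: a venous
$\Delta\chi$ at typical saturations is ≈ 0.03–0.05 ppm in cgs units —
which would *never* pass the 130 ppb refinement floor — but ≈ 0.3–0.6 ppm
in SI units, which is exactly the range the thresholds select. The
thresholds are therefore only coherent with SI-convention maps. Both
conventions are supported (`oximetryConstants("cgs")`), and the chain
produces identical saturations when the map units match the constants.
Out-of-range inversions are clamped to [0, 1] with a `clamped` flag
rather than silently accepted.

Before refinement the brain mask is eroded by one 6-connected pass,
dropping the outermost voxel layer where background-field removal is
unreliable.

# Arterial oxygenation

End-tidal O~2~ values are the end-expiratory extrema of the exhaled
trace. Physiologically these are local *minima* of the O~2~ concentration
(expiration carries alveolar gas), so the detector runs peak finding on
the negated trace, with a minimum breath spacing (default 1.5 s) and a
minimum prominence (default 1 percentage point) to reject ramp jitter; a
`mode = "peaks"` switch runs the raw-maxima variant for auditing against
pipelines that fed the unnegated signal to a generic peak finder. The
median end-tidal percentage is bridged to a partial pressure as
$P_{ET}O_2 = (EtO_2/100)(P_B - P_{H_2O})$ with defaults 760 and 47 mmHg
(both configurable), then converted through the Severinghaus dissociation
curve

$$ S_aO_2 = \left(1 + \frac{23400}{P O_2^3 + 150\,PO_2}\right)^{-1}. $$

The percent-to-mmHg bridge is stated explicitly because feeding raw
percentages to the Severinghaus form is a plausible alternative reading
of common practice; both paths are reachable, the bridge is the default.

Arterial oxygen content uses $[\mathrm{Hb}] = \mathrm{Hct}/3$ (g/100 ml,
Hct in percent) and 55.6 µmol O~2~ per gram of haemoglobin; dissolved
oxygen is neglected (negligible in veins). Negative OEF values — possible
under noise when the vein estimate exceeds arterial saturation — are
flagged and *not* clamped, preserving the noise structure that the
repeatability statistics measure.

# Territories and aggregation

Each vein has an exclusive drainage territory (a set of parcellation
labels). Because upstream veins empty into downstream ones, the
saturation measured in a large vein samples the pooled territory, so CBF
and ATT are harmonised to the same support by composition: the straight
sinus pools its exclusive territory with the internal cerebral and basal
veins; the vertical superior sagittal segment pools with the horizontal
one. Composite values use the pooled-voxel median over the label union —
consistent with the exclusive-territory statistic — with a
volume-weighted mean of per-label medians available as the alternative
combiner. The shipped Destrieux-style label table is a synthetic
approximation (the published allocation is pictorial); it is data, not
code, and is meant to be edited.

# Repeatability and the group stage

Test-retest precision per territory and parameter uses the Bland-Altman
within-subject standard deviation
$\sigma_{inter} = \sqrt{\sum_i (x_{1i} - x_{2i})^2 / 2n}$ and the
coefficient of variation $100\,\sigma_{inter}/\bar{x}$, with $\bar{x}$
the grand mean of both sessions (per-subject means average to the same
number, so the reading of "mean across participants" is inert).

The group stage is deliberately thin glue over `lme4`:
`outcome ~ predictor * territory + (1 | subject)`. Two degenerate cases
are handled explicitly. If the fixed effects alone fit the data exactly
(noiseless synthetic input), the variance components sit on the boundary
and the mixed-model deviance is numerically degenerate, so the exact
least-squares solution is returned instead (flagged `method = "ols"`).
If a subject random intercept is unidentifiable (one observation per
subject), the model likewise falls back to least squares. Singular mixed
fits are reported with their flag, never promoted to errors. Inference
(type-III ANOVA tables, p-values) is intentionally out of scope: the
package's substance is the measurement pipeline, and coefficient recovery
is what the synthetic studies can validate.

# What the generators emulate — and what they do not

`makeCohort()` draws subjects with QRisk uniform on [5.1, 45.4], Hct
$\sim N(0.42, 0.034)$ truncated to [0.30, 0.55], MoCA 17–30, amyloid
positivity at rate 7/24, and an end-tidal O~2~ level uniform on [14, 17]%.
Territory means for OEF, CBF and ATT are seeded from the regional
reference table built into the generator; per-parameter subject offsets
are Gaussian with sd equal to the reference standard error × √24 (for
ATT, reduced by the variance the QRisk term itself contributes, so the
total between-subject spread stays at the reference scale). Ground-truth
ATT is `baseline + 13.2 ms × QRisk + offset` by default, with baselines
centred so expected territory means match the reference values. No
subject-level variance components are reported for the source cohort;
these constants are the package's own documented choices of plausible
scale, fixed once, and `offsetScale = 0` switches all random components
off for exact-recovery tests.

`simulateAslVolume()` evaluates the forward model on a slab parcellation
and adds independent Gaussian noise on the difference signal — not Rician,
because difference images are approximately Gaussian-distributed.
`simulateSusceptibilityPhantom()` builds a cylinder whose core carries
the forward susceptibility of the generating saturation, with linear
partial-volume blending at the edge (the simplest testable model) and
optional field noise. `simulateRespTrace()` builds trapezoidal breaths
whose end-expiratory plateau samples equal the requested value exactly,
with seeded jitter confined to the ramps — so end-tidal extraction has an
exact target. Session tables add measurement noise at the scale of the
reference test-retest CoVs, which is what makes the simulated study's
repeatability land in a realistic range.

None of the generators simulate MRI physics: no k-space, no background
fields, no phase, no dipole inversion, no motion, no registration error.
Passing tests therefore validate the *estimation chain* — model
inversion, thresholds, percentiles, composition, statistics — under the
model's own assumptions, not the upstream reconstruction steps, which
are consumed as finished products.

# Numerical choices and degenerate inputs

* Percentiles and medians use linear interpolation between order
  statistics (R type 7); even-count medians average the central pair.
* The optimiser is `minpack.lm` Levenberg-Marquardt with box bounds,
  `ftol = ptol = 1e-14`, 500 iterations, multi-start as above; residual
  ties within a relative 1e-9 resolve to the smallest ATT.
* Empty refined ROIs, empty territories, all-missing maps, constant
  respiratory traces, out-of-range haematocrit and non-positive pressures
  are all explicit errors with descriptive messages; a failing territory
  inside `runSubject()` yields an `NA` row plus a logged reason and the
  run continues.
* Every generator is a pure function of its arguments including the
  seed; the per-subject pipeline is fully deterministic given inputs and
  configuration.

Problem sizes used by the shipped validation (chosen to exercise every
code path at desk scale): phantoms of 10–30 voxels per side, 2000-voxel
noise studies, 24-subject cohorts with 100 replicates for slope recovery,
and 100 random tables for the repeatability oracle.

# Known limitations

* ATT is structurally unidentifiable at or below the schedule's minimum
  PLD (see above); reported ATT values near 700 ms for the default
  schedule should be read as "at or below the identifiability floor".
* Voxel-wise bounded least squares is a skewed estimator at
  single-average SNR; territory medians of multi-average data are the
  intended operating point.
* The vein-territory label table is an editable approximation.
* One- and two-compartment dispersion effects, partial-volume correction
  of ASL, and CO~2~/dissolved-oxygen terms are out of scope.
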