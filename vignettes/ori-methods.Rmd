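---
title: "Quantifying junction robustness in multi-isocenter VMAT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying junction robustness in multi-isocenter VMAT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oriqa)
```

## The problem

Craniospinal irradiation (CSI) with volumetric modulated arc therapy
(VMAT) needs several isocenters, because the target — the whole brain
and spinal axis — is longer than a single field. Adjacent arc sets are
joined in *overlap* (junction) regions where their doses superimpose to
form the prescribed total. How the two falloffs share that region
decides how the plan responds to longitudinal setup errors: if each arc
set ramps down linearly across the whole overlap, a few millimetres of
isocenter misalignment shifts dose between arcs almost uniformly; if
the falloff is concentrated in a steep transition, the same
misalignment carves hot and cold bands into the junction.

`oriqa` quantifies this vulnerability from quantities a physicist can
export from any treatment planning system: the cumulative dose–volume
histograms (DVHs) of the two adjacent arc sets inside the overlap
structure, the overlap length $h$, and the prescription dose $D_{pr}$.

## The Overlap Robustness Index

For each arc set $i \in \{1, 2\}$ the cumulative DVH
$V_i(D)$ (% volume receiving at least dose $D$) is summarised three
ways over its falling branch:

* an ordinary least-squares line $V_i(D) = m_i D + b_i$ with slope
  $m_i$ (`fit_linear()`),
* the coefficient of determination $R_i^2$ of that line,
* the median $\tilde{m}_i$ of the per-bin finite-difference slopes
  $\mathrm{d}V/\mathrm{d}D$ (`slope_distribution()`).

The **linear coefficient** of the arc set is

$$f_{lin,i} = R_i^2 \, \frac{\tilde{m}_i}{m_i}, \qquad
  f_{lin} = \tfrac{1}{2}(f_{lin,1} + f_{lin,2}),$$

equal to 1 exactly when the DVH is a perfect linear ramp (then the
median slope equals the fitted slope and $R^2 = 1$) and below 1 when
shallow- and steep-sloped DVH regions coexist, as in conventional
fixed-overlap junctions.

The **gradient coefficient** compares the junction's average dose
gradient with that of an idealised reference overlap: a cylinder of
length $L_{ref} = 9$ cm whose arc-set DVHs ramp from zero to the
prescription. Reading the per-arc dose span as $D2\%_i - D98\%_i$,

$$f_{grad} = \frac{h \, D_{pr}}{2 L_{ref}}
  \sum_{i=1}^{2} \frac{1}{D2\%_i - D98\%_i}.$$

It grows linearly with the overlap length and shrinks as the per-arc
dose spans widen. The **Overlap Robustness Index** is the product

$$\mathrm{ORI} = f_{lin} \times f_{grad}.$$

Both unit systems (Gy, or % of prescription) give identical results
because $D_{pr}$ and the spans rescale together.

```{r worked}
bench <- make_benchmark_pair(h = 4, prescription_gy = 36)
compute_ori(bench$static)
compute_ori(bench$dynamic)
```

The benchmark pair reproduces the two clinical regimes on matched
geometry: a conventional (sigmoid-DVH) junction near
$f_{lin} \approx 0.5$, ORI $\approx 0.29$, and a staggered (ramp-DVH)
junction at $f_{lin} = 1$, ORI $\approx 0.46$.

### Numerical conventions

* **Dx% read-out.** Dose is interpolated linearly as a function of
  cumulative volume on the falling segment that brackets the level; a
  level attained on a plateau returns the plateau's highest dose
  (conservative for hot-spot metrics). A cliff sampled on a discrete
  grid resolves the read-out only to within one bin.
* **Fit/median support.** By default only bins with
  $0.1\% < V < 99.9\%$ (plus one flanking bin) enter the fit and the
  slope distribution: including the 100% plateau and the zero tail
  biases the fitted slope toward zero. `support = "full"` or an
  explicit dose range are available; published per-arc summaries can be
  re-evaluated without curves through `f_lin_from_summary()`.
* **Resampling.** Slopes assume uniform dose bins; curves are resampled
  at 0.05 Gy by default, finer than any gradient feature the junction
  simulator produces.
* **Monotonicity repair.** Volume increases up to 0.01 %-points
  (rounding noise in text exports) are repaired by running-minimum
  enforcement; anything larger is rejected as corrupt.
* **Degenerate cliffs.** A bin-to-bin volume drop above 50 %-points
  (a step DVH of a uniform dose) has no resolvable slope and raises an
  error instead of returning a discretisation artefact.
* **Normalisation.** $f_{grad}$ can exceed 1 for $h > L_{ref}$; values
  are reported as-is with a warning, since the index is deliberately
  not clamped. ORI values are only comparable at equal $L_{ref}$.
* **Full-range ramps.** An exact ramp DVH spanning $[0, D_{pr}]$ has
  $D2\% - D98\% = 0.96\,D_{pr}$, so a 9 cm ramp-pair overlap evaluates
  to $f_{grad} = 25/24$, not exactly 1; the theoretical reference in
  the denominator uses the full $0..D_{pr}$ range by construction.

## The junction simulator

No public DVH or junction-dose data exist for this setting, so the
package ships a parametric one-dimensional model of the two-arc
junction (`make_junction()`): dose along the patient's cranial–caudal
axis, with the overlap occupying $z \in [0, h]$ and the two arcs
summing exactly to $D_{pr}$ at zero shift and zero noise. The overlap
volume is treated as a cylinder of uniform cross-section, so volume
fractions equal length fractions and `profile_to_dvh()` converts
profiles to DVHs exactly (piecewise-linear crossing lengths, no
grid-counting quantisation).

Two techniques are modelled:

* **static** (conventional fixed overlap): the delivered per-arc
  falloff is a logit-in-position curve spanning the whole overlap —
  steep near the overlap boundaries, shallow at mid-overlap. Its DVH is
  sigmoid in dose with an 80–20% width of `sigmoid_width` (default
  10 Gy). This width, not a fluence penumbra, parameterises the static
  technique: the composite of many optimised segments is best specified
  directly in delivered dose, and a 10 Gy width reproduces the
  clinically observed static regime (fitted slope steeper than the
  ideal ramp, median/fit ratio near 0.55, $R^2 \approx 0.95$).
* **staggered**: field edges staggered in `n_steps` equal sub-steps
  (3, 4 or 6; by default 3 for $h \le 4$ cm, 4 up to 6 cm, 6 beyond,
  i.e. shorter steps for longer overlaps), each sub-field contributing
  through its own logistic beam-edge penumbra (80–20% width
  `penumbra_width`, default 0.8 cm, a typical 6 MV longitudinal
  penumbra). The superposition approaches a linear ramp as steps
  refine. Sub-field weights are jittered by 15% relative
  (`step_weight_jitter`), because optimised plans do not deliver
  exactly $D_{pr}/n$ per sub-field; set it to 0 for the ideal
  construction.

The grid step is 0.1 mm so that 3 mm shifts are exact grid
translations; optional Gaussian profile noise is seeded and clipped to
$[0, 2D_{pr}]$.

### Shift simulation and the Inhomogeneity Ratio

`apply_shift()` translates one arc set (the shared isocenter moves; the
overlap stays fixed in the patient frame) with linear interpolation and
constant extension at the plateaus. `inhomogeneity_ratio()` evaluates
the total-dose D2%/D98% ratio in the overlap at shifts
$\{-\delta, 0, +\delta\}$ (default $\delta = 3$ mm, a realistic couch
sag / intrafraction error) and reports each shifted ratio divided by
the unshifted one. The headline `ir_worst` is the worse of the two
signs; both are retained, since convergence (hot band) and divergence
(cold band) degrade differently.

```{r ir}
ms <- make_junction("static", h = 6)
md <- make_junction("staggered", h = 6)
inhomogeneity_ratio(ms)$ir_worst
inhomogeneity_ratio(md)$ir_worst
```

### The synthetic cohort

`cohort_generate()` emulates a small clinical cohort: by default 5
patients, each with an upper and a lower junction, each planned with
both techniques — 20 overlaps. Overlap lengths are drawn from 3–9 cm
(the clinical range for these junctions), per-patient penumbra widths
from 0.6–1.0 cm, and per-overlap static sigmoid widths from 8–12 Gy
(plan-to-plan variation in how well the conventional optimisation
spreads the gradient). These defaults were fixed once from the
physical reasoning above; on them the built-in relationship gives a
Spearman rank correlation between ORI and IR of about $-0.85$ to
$-0.95$ across seeds, static-technique IR medians near 1.2 and
staggered near 1.04, with the staggered junction never less robust
than the static one on matched geometry.

What the simulator does **not** contain: three-dimensional dose,
lateral profile variation, MLC sequencing, couch-sag time dependence,
anatomical deformation, or the residual in-field inhomogeneity of real
plans (the model's unshifted junctions are homogeneous to ~0.1%,
clinical ones to ~10%). Passing the cohort-level tests therefore shows
that the index orders *this family* of junction shapes correctly, not
that any specific clinical plan will reproduce the same correlation
strength. In particular the simulated relationship is somewhat noisier
than a clinical power-law fit (natural-scale $R^2 \approx 0.6$–$0.8$),
precisely because ideal ramps are cleaner and short ideal ramps more
robust than their clinical counterparts.

## Tolerance and action limits

QA limits for the index are derived in two steps
(`ir_thresholds()`, `fit_power()`, `ori_limit()`):

1. Dose-ratio tolerances are converted to IR thresholds. With the
   nominal unshifted D2%/D98% ratio taken as 105%/95%, a tolerated
   shifted ratio of 110%/90% (the accepted 5% delivery accuracy) gives
   an IR tolerance of $\frac{110/90}{105/95} = 1.11$, and an
   actionable 125%/90% (spinal-cord D2% at the 125% isodose) gives
   1.26.
2. A power law $\mathrm{ORI} = a \cdot \mathrm{IR}^b$ is fitted to
   paired (IR, ORI) observations by untransformed nonlinear least
   squares, initialised from the log–log linear fit (the log-scale
   objective is exposed via `objective = "log"`). The ORI limit is the
   fitted curve evaluated at an IR threshold, rounded half away from
   zero to one decimal — the reporting precision of QA limits.

```{r limits}
cal <- power_calibration(a = 1.45, b = -6.02)
calibrate_limits(cal)
```

The recovery experiment used in the tests — 50 calibration points
evenly spaced over IR 1.05–1.40, 5% relative noise on ORI, 100 seeded
replicates — recovers $b$ to within $\pm 0.5$ in every replicate;
fewer than ~40 points leave too little leverage for that bound at this
noise level. Cohort statistics (`cohort_statistics()`) use Spearman
rank correlation, the paired two-sided Wilcoxon signed-rank test
(exact distribution for $n \le 25$, zero differences dropped and
flagged), and a Lilliefors-corrected Kolmogorov–Smirnov normality
check, the correct KS variant when mean and variance are estimated
from the sample.

## Dose verification analytics

For junction dose verification the package compares a calculated
reference distribution with an evaluated (measured) one on 1D or 2D
uniform grids:

* `gamma_index()` implements the global gamma test: per evaluated
  point, the minimum over reference positions within `3 * dta` of
  $\sqrt{(\Delta d / \delta_{dose})^2 + (\Delta r / \delta_{DTA})^2}$,
  with the dose tolerance a percentage of a global normalisation dose
  (reference maximum by default; a prescription-dose normalisation can
  be supplied via `normalization_gy`). The reference is interpolated at
  `dta / 10`; halving that step changes passing rates by well under
  0.5% on smooth fixtures. The low-dose cutoff defaults to 0 because
  junction analyses evaluate points inside the overlap PTV only, where
  everything is clinically relevant; 10% is conventional for
  whole-field comparisons. The reference/evaluated roles are asymmetric
  and fixed by the caller.
* `profile_difference()` reports local percentage differences
  $100(\mathrm{ref}/\mathrm{eval} - 1)$ and their median, the
  convention for calculated-vs-measured boundary profiles.
* `degrade_resolution()` point-samples a grid at a coarser pitch
  (no averaging), emulating the contrast between ~1 mm film sampling
  and a ~5 mm diode array: a 2 mm dose feature is flagged by a 3%/1 mm
  gamma only at the fine pitch.

Because no measured junction data can ship with the package, this
module is validated by closed forms (identical grids give 100%; a
uniform offset of exactly the dose tolerance on flat fields gives
$\gamma = 1$ everywhere) and by invariance properties
(anti-monotonicity in the criteria, interpolation-refinement
stability), not by reproducing any specific measurement.

## Problem sizes and determinism

The shipped tests and the acceptance script run on deliberately modest
problem sizes — 0.1 mm junction grids over at most ~15 cm, 20-overlap
cohorts, 40–60-point dose grids — chosen so the full analysis chain
(profile, DVH, index, shift simulation, calibration) is exercised end
to end in seconds per case. Every stochastic component (profile noise,
sub-field weights, cohort draws) is driven by an explicit integer seed
and reproduces byte-identically under the same seed.

## Known limitations

* The 1D cylinder geometry ignores cross-sectional dose variation; ORI
  from real DVHs is unaffected (DVHs already integrate the volume),
  but simulated IR values should be read as orderings, not absolute
  clinical predictions.
* The falling-branch support rule is a convention; published per-arc
  summaries may have used the full curve. Both options are exposed,
  and the per-arc ratio $\tilde{m}_i / m_i$ is only mildly sensitive
  on the shapes studied here.
* Limits derived from a 20-point synthetic cohort inherit its
  assumptions; the published tolerance/action values (0.8 / 0.4) come
  from evaluating the reported clinical fit, which the package
  reproduces, not from the simulator.
* Only two-arc overlaps are supported; multi-arc junctions and
  non-rigid error modes are out of scope.
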