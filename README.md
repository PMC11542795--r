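# oriqa — Overlap Robustness Index and junction QA for multi-isocenter VMAT

Craniospinal irradiation (CSI) delivered with volumetric modulated arc
therapy needs several isocenters, and the adjacent arc sets must be
joined in *overlap* (junction) regions where their doses sum to the
prescription. A junction whose per-arc falloffs are gentle linear ramps
tolerates millimetre setup errors; one with a concentrated transition
develops hot and cold bands from the same error. `oriqa` gives medical
physicists a single, TPS-agnostic number for that vulnerability — the
**Overlap Robustness Index (ORI)** — computed from quantities any
planning system can export: the cumulative DVHs of the two adjacent arc
sets inside the overlap structure, the overlap length *h* (cm) and the
prescription dose *D*<sub>pr</sub> (Gy).

For each arc set *i*, a straight line `V(D) = m_i D + b_i` is fitted to
the cumulative DVH, and the per-bin slope distribution dV/dD is
summarised by its median `med_i`. The index is

    f_lin,i = R_i^2 * med_i / m_i          (1 for a perfect ramp DVH)
    f_lin   = (f_lin,1 + f_lin,2) / 2
    f_grad  = h * Dpr / (2 * 9 cm) * sum_i 1 / (D2%_i - D98%_i)
    ORI     = f_lin * f_grad

`f_grad` normalises the junction dose gradient to an ideal 9 cm
reference overlap with full-range ramp DVHs. Higher ORI means a more
robust junction; on the recommended scale, values above 0.8 are within
tolerance and values below 0.4 call for action.

The package also ships:

* a parametric 1D two-arc junction simulator (`make_junction`,
  `apply_shift`, `profile_to_dvh`) for conventional (fixed-overlap) and
  staggered (stepped-edge) techniques, and the **Inhomogeneity Ratio**
  `IR = (D2%/D98%)_shift / (D2%/D98%)_0` under ±3 mm isocenter shifts
  (`inhomogeneity_ratio`, `cohort_generate`);
* power-law calibration of ORI tolerance/action limits against IR
  thresholds and cohort rank statistics (`ir_thresholds`, `fit_power`,
  `ori_limit`, `cohort_statistics`);
* global gamma-index and boundary-profile comparison of 1D/2D dose
  grids for junction dose verification (`gamma_index`,
  `profile_difference`, `degrade_resolution`);
* deterministic synthetic DVH/junction fixtures so everything is
  testable without clinical data (`make_dvh_fixture`,
  `make_benchmark_pair`).

## Worked example

Two benchmark junctions on the same geometry (h = 4 cm, 36 Gy), one
with sigmoid-in-dose arc DVHs (conventional overlap), one with exact
ramps (staggered overlap):

```r
library(oriqa)
bench <- make_benchmark_pair(h = 4, prescription_gy = 36)
compute_ori(bench$static)
#> <ori_result> benchmark_static (h = 4 cm, 36 Gy)
#>   arc US   fit  -3.640 %/Gy  R^2 0.948  median  -1.951  f_lin_i 0.508  D2 32.04  D98 3.96
#>   arc MS   fit  -3.640 %/Gy  R^2 0.948  median  -1.951  f_lin_i 0.508  D2 32.04  D98 3.96
#>   f_lin = 0.508   f_grad = 0.570   ORI = 0.290
compute_ori(bench$dynamic)
#> <ori_result> benchmark_dynamic (h = 4 cm, 36 Gy)
#>   arc UD   fit  -2.778 %/Gy  R^2 1.000  median  -2.778  f_lin_i 1.000  D2 35.28  D98 0.72
#>   arc MD   fit  -2.778 %/Gy  R^2 1.000  median  -2.778  f_lin_i 1.000  D2 35.28  D98 0.72
#>   f_lin = 1.000   f_grad = 0.463   ORI = 0.463
```

The conventional junction mixes shallow and steep DVH slopes
(median/fit ≈ 0.54, so f_lin ≈ 0.51) while the staggered junction is an
ideal ramp (f_lin = 1); both spread dose over most of the prescription
range, so their gradient coefficients are comparable and the linear
coefficient dominates the ORI difference (0.29 vs 0.46).

Simulating a 3 mm shift of the shared isocenter of a staggered 6 cm
junction:

```r
m <- make_junction("staggered", h = 6, seed = 42)
inhomogeneity_ratio(m, delta_mm = 3)
#> <ir_result> +/-3 mm shift
#>   D2/D98: unshifted 1.0013, +shift 1.0587, -shift 1.0552
#>   IR: + 1.0573, - 1.0538, worst 1.0573
```

— the junction's D2%/D98% degrades by ~6% in the worst shift
direction. Converting IR thresholds into ORI limits with a fitted power
relationship `ORI = a * IR^b`:

```r
calibrate_limits(power_calibration(a = 1.45, b = -6.02))
#>   IR tolerance 1.11 -> ORI tolerance 0.8
#>   IR action    1.26 -> ORI action    0.4
```

DVH files are plain TSV with a small self-describing header
(`read_dvh`/`write_dvh`); a command-line front-end for shell use is in
`inst/scripts/ori-cli.R` (subcommands `metrics`, `compute`, `simulate`,
`calibrate`, `gamma`, `fixtures`).

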