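---
title: "The tracer-bolus method for whole-body glutamine kinetics: models, choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The tracer-bolus method for whole-body glutamine kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glnbolus)
```

## The estimator

After an intravenous bolus of `Dose` µmol/kg of [1-13C]glutamine, arterial
plasma enrichment rises at once and decays as the tracer is diluted by
endogenous glutamine production and cleared with the glutamine flux. Under
the single-pool idealization — instantaneous mixing into one well-stirred
pool at tracee steady state — the enrichment decays mono-exponentially and
the whole-body rate of appearance is

$$R_a = \frac{\mathrm{Dose}}{\mathrm{AUC}/100},$$

with AUC the time integral of atom percent excess (APE, %). The identity
needs no knowledge of the pool size: integrating the tracer mass balance
shows the full-time AUC of the tracer-to-tracee ratio equals
`Dose / Ra` whenever irreversible loss occurs from the sampled pool.
When glutamine is delivered exogenously (an alanyl-glutamine infusion at
rate $r$ mg/kg/h delivers $r / 217.22 \cdot 1000/60$ µmol/kg/min of
glutamine), that rate is subtracted:
$\mathrm{endo}R_a = R_a - R_{exo}$. The bolus tracer itself is not part of
$R_{exo}$: it is the numerator of the estimator, not a steady infusion.

### Which APE?

A GC-MS measurement yields the labeled/unlabeled ion-intensity ratio
$r_t$ (m/z 432/431). Two enrichment conventions are in use:

- **ratio difference** (default): $\mathrm{APE} = 100\,(r_t - r_b)$,
  where $r_b$ is the mean pre-bolus baseline ratio;
- **mole-fraction difference**:
  $100\,\bigl(\tfrac{r_t}{1+r_t} - \tfrac{r_b}{1+r_b}\bigr)$.

At trace enrichment the two agree; they do not here. The 3 mg/kg bolus
(≈ 20.4 µmol/kg) produces peak excess ratios of roughly 10–15%, where the
mole-fraction form is compressed by up to ~10% relative to the ratio
form. Since the mass-balance identity behind $R_a = \mathrm{Dose/AUC}$ is
exact on the tracer/tracee-ratio scale (the tracee denominator is the
constant plasma pool), the ratio difference is the correct default: with
the mole-fraction convention the same pipeline overestimates a known
simulated Ra by several percent, an avoidable method bias. Both
conventions are implemented and selected by one `ape_method` switch shared
by the analysis and the simulators, so mixed conventions cannot occur.
The background-shift tests document the exact mole-fraction behaviour.

### AUC: observed area, tail, head

- **Observed area**: linear trapezoid between the first (0.5 min) and last
  (90 min) sample, by default. On the dense default schedule the trapezoid
  excess for a convex decay is a few parts in $10^4$ — far below the 4.1%
  analytical CV — so the simpler rule is preferred; a log-trapezoid (exact
  for exponential segments, falling back to linear where an endpoint is
  non-positive or the segment is flat) is available.
- **Tail**: the curve is still positive at 90 min. By default the terminal
  mono-exponential is fitted by OLS of log(APE) on time over the last
  `n_tail = 10` quantifiable points and the area `amplitude / k` beyond
  the last quantifiable time is added. Points below the limit of
  quantification (default `loq_ape = 0.01`%) are excluded from the fit but
  retained in the observed integral — clamping sub-LOQ noise would bias
  the area upward. A non-negative fitted slope raises a
  `no_valid_tail` error rather than extrapolating nonsense.
- **Head**: no area is added before the first sample. One cannot sample at
  the instant of peak enrichment, so the observed AUC is always slightly
  smaller than the ideal one and $R_a$ is a small, acknowledged
  overestimate; on the default schedule with the default generator the
  noiseless bias is +1.9%. Keeping the estimator definition fixed across
  protocols is worth more than chasing this bias; an optional triangular
  head (`add_head = TRUE`) exists for sensitivity analyses only.

### Key parameters

| parameter | default | units | why |
|---|---|---|---|
| dose | 3 | mg/kg | keeps enrichment quantifiable ~60 min with only a transient concentration rise |
| tracer molar mass | 147.14 | g/mol | [1-13C]glutamine |
| isotopic purity | 1.0 | – | supplier-grade tracer; overridable |
| Ala-Gln molar mass | 217.22 | g/mol | Ala 89.09 + Gln 146.15 − H₂O 18.02 |
| `loq_ape` | 0.01 | % APE | delimits tail fitting once enrichment becomes unquantifiable |
| `n_tail` | 10 | points | enough leverage on the terminal slope without reaching into the mixing phase |
| `auc_method` | linear | – | error ≪ analytical CV on the default grid |
| `extrapolate` | TRUE | – | truncation-vs-extrapolation differences are small but must be explicit |

## The synthetic generators

The generators exist so that every estimator property is testable with
known ground truth; they emulate the study conditions, not any particular
subject.

**Single pool.** APE(t) on the ratio scale is
$100\,(\mathrm{dose}/Q)\,e^{-(R_a/Q)t}$. Defaults: true Ra 6.1 µmol/kg/min
(the post-absorptive control mean) and a rapidly mixing pool
$Q = 160$ µmol/kg — approximately the extracellular-water dilution volume
(~0.26 L/kg at ~0.6 mM plasma glutamine). These give a peak enrichment of
12.7%, a terminal rate constant of 0.038/min, and enrichment of ~1.3% at
60 min and ~0.4% at 90 min, i.e. the observed quantifiability horizon.

**Two pool.** A small plasma pool (20.7 µmol/kg, sized so the bolus
transiently doubles plasma glutamine) exchanges bidirectionally with a
large, slow tissue pool (defaults 500 µmol/kg, exchange 0.25/min —
illustrative values; free glutamine in skeletal muscle dominates the
whole-body pool but exchanges slowly). The closed bi-exponential solution
is cross-checked in the tests against an independent ODE integration at
1e-8 and against exact mass conservation at 1e-9. Because irreversible
loss occurs only from plasma, the full-time plasma AUC still equals
`100·dose/Ra`: a single-pool analysis of a two-pool curve estimates
plasma-pool *throughput*, and what a finite 90-min study misses is the
slow tail, increasingly so the faster the exchange.

**Noise.** Measurement error is multiplicative lognormal with median 1
and a total per-measurement CV of 4.1% (the analytical CV of duplicate
GC-MS analyses). The variance is split 80/20 between a run-level factor
shared by all points of one analytical run and independent per-point
factors. The split is the package's own modelling choice, made on one
ground: purely independent point noise would average out almost entirely
in a 60-point AUC (propagating only ~0.5% to endoRa), whereas repeat
studies of the same subject show endoRa variability of the same order as
the analytical CV — so most of the analytical error must move the whole
curve together, as calibration drift does. Defaults keep the stated 4.1%
per-measurement CV; with the 80% run share, replicate-visit simulations
give pooled within-subject endoRa CVs around 4–5%, consistent with the
observed 5.5% once day-to-day biology (not simulated) is allowed for.

What the generators do **not** emulate: the finite injection/mixing phase
(real curves are not mono-exponential in the first minutes), baseline
drift, tracee non-steady state during feeding, or between-visit biological
variation in Ra. Passing recovery tests therefore demonstrate estimator
correctness under the model's assumptions, not robustness to their
violation.

## Protocol sensitivity

The default schedule (30-s sampling to 10 min, 1-min to 30 min, 3-min to
90 min; 60 samples) is compared against alternatives along the axes that
matter for a bolus study: peak frequency (`peak_1min`, `peak_2min`), tail
frequency (`tail_6min`), and tail duration (`trunc_60`, `trunc_30`). All
are subsets of the default grid, so measured default-protocol curves can
be subsampled to each. The analysis runs **without** tail extrapolation by
default: the question is what each schedule's observed samples alone
support, and extrapolating would mask the cost of a truncated tail.

The noiseless deviations follow segment-exact closed-form integrals and
their signs are instructive: truncation discards tail area and inflates
Ra strongly; a coarser *peak* moves the first sample later and also
inflates Ra (the missed leading edge outweighs the opposing
trapezoid-excess gain); a coarser tail grid alone deflates Ra slightly.
In noisy cohorts the paired t-tests single out the truncation schedules
as significantly different from the default.

## Statistics

- Repeatability: the pooled within-subject CV is the root mean square of
  per-subject CVs. (With two visits per subject, a simple CV of
  differences is an alternative reading; the pooled form is the default
  because it generalizes to more than two occasions.)
- Paired comparisons use Student's paired t (two-sided, α = 0.05);
  zero-variance differences are flagged degenerate instead of erroring.
- Group comparisons use one-way ANOVA followed by Dunnett many-to-one
  contrasts against the named control. Adjusted p-values are computed
  from the multivariate-t distribution of the comparison statistics with
  correlation $\sqrt{n_i n_j / ((n_i+n_c)(n_j+n_c))}$ (1/2 when
  balanced), by deterministic Genz–Bretz quadrature (abs. error 1e-6,
  fixed internal stream). The implementation is cross-checked against
  `multcomp::glht` in the tests, and its familywise type-I error under
  the global null is verified by simulation.

## Numerical and degenerate-input choices

- Schedule time matching uses a 1e-6 min tolerance: schedules address
  exact grid points, and both simulated and parsed times are
  decimal-exact on these grids.
- Baselines: the mean of all pre-bolus samples; a single baseline is
  accepted with a warning, none is an error.
- Negative post-baseline APE (noise around zero) is retained for the
  AUC, flagged below LOQ, and excluded from tail fitting; non-positive
  points inside the tail window shrink it with a warning, and fewer than
  three surviving points, or a non-negative slope, abort the tail fit.
- An all-baseline record reaches the Ra stage with a non-positive AUC and
  fails there with a stage-labelled domain error; cohort drivers can
  convert per-subject failures into flagged rows instead.
- All stochastic outputs (noise, cohorts, CSV fixtures) are reproducible
  bit-for-bit under a fixed seed; the Dunnett quadrature preserves the
  caller's RNG stream.

## Validation problem sizes

The test-suite and acceptance checks run at desk scale, chosen as the
smallest sizes that make the brackets stable: noiseless recovery on the
60-sample default schedule; six 5-subject noisy cohorts (true Ra uniform
on 4–8 µmol/kg/min) for the bias bracket; twelve subjects × two visits
for the repeatability CV bracket (twenty-four in the reproduction
script's steadier estimate); 5-subject cohorts for protocol sensitivity; and
10⁴ simulated null studies (3 × 5 subjects) for the Dunnett type-I rate.

## Known limitations

- The single-pool reading of a bolus study estimates plasma-pool
  throughput; with substantial slow-pool exchange it does not equal
  whole-body production, and the package's two-pool simulator exists
  precisely to quantify that gap.
- Group-level values from real cohorts depend on per-subject data that
  ships with no public study; the acceptance script therefore validates
  against simulated cohorts with known truth, not against archived
  subject tables.
- Fitting multi-compartment models to measured data, continuous-infusion
  steady-state estimation, and clearance modelling are out of scope.
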