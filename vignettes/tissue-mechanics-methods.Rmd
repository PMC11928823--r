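---
title: "Methods: tensile, viscoelastic and AFM nano-mechanical analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tensile, viscoelastic and AFM nano-mechanical analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissuemech)
```

tissuemech implements the quantitative analysis layer for mechanical
characterization of soft biological membranes — the kind of decellularized,
basement-membrane-containing scaffold used as an epithelial culture
substrate. Three instrument modalities are covered: uniaxial tensile tests
to failure, ramp-and-hold stress-relaxation tests, and AFM colloidal-probe
measurements (friction loops and nano-indentation). Because raw instrument
exports for such studies are rarely deposited, the package ships seeded
generators for every input type; the test suite validates each analysis
stage by recovering known generating parameters.

All internal units are strictly SI (m, N, Pa, s, V, rad). Units declared in
a column map are converted once, at the I/O boundary, and never downstream;
this prevents the silent errors that arise when µm, mN, MPa and nN coexist
in one pipeline.

## Tensile analysis

A test record is time, force and displacement plus the dog-bone geometry
(width, thickness, gauge length). Processing follows the standard protocol
for soft-tissue testing:

1. **Preload zero-referencing.** A small preload (default 40 mN) defines
   the reference state: the first sample whose force reaches it becomes the
   origin, its displacement is subtracted, and earlier samples are dropped.
   The force offset is *not* subtracted — the preloaded specimen is the
   mechanical reference, not an artefact. A consequence worth knowing: with
   preload stress $\sigma_p = F_{pre}/A$, a specimen that is linear from
   zero load appears as $\sigma = \sigma_p + E\,\varepsilon$ after
   zero-referencing, so the apparent failure strain is
   $(\sigma_f - \sigma_p)/E$ rather than $\sigma_f/E$; the two coincide as
   the preload vanishes. The slope (Young's modulus) and the failure stress
   are unaffected.
2. **Conventions.** Engineering stress/strain is force over original
   cross-section and displacement over gauge length. True values
   ($\sigma_t = \sigma(1+\varepsilon)$,
   $\varepsilon_t = \ln(1+\varepsilon)$) are available via `to_true()`,
   which refuses to convert twice. Conversions are tagged so the two
   conventions can never be mixed.
3. **Failure point.** These scaffolds fail in a brittle manner, so the
   failure point is the global stress maximum (ties break to the earliest
   sample). If the curve never drops by more than 5% of its peak after the
   maximum, it looks like a truncated ramp rather than a rupture and the
   result carries a `no_post_failure_drop` flag.
4. **Young's modulus.** The OLS slope of stress against strain over the
   window between 40% and 60% of the failure strain — the central linear
   region. The window is a parameter (`window = c(0.40, 0.60)`), since some
   labs prefer a stress-fraction window; for near-linear curves the two
   readings coincide.
5. **Stress relaxation percentage.**
   $100\,[\sigma(t_0) - \sigma(t_0 + 200\,\mathrm{s})]/\sigma(t_0)$, with
   $t_0$ the first hold sample. Because acquisition rates vary, the stress
   at the horizon is read at the nearest sample, with linear interpolation
   when the horizon falls between samples. The hold start on real traces is
   detected as the first sample within 0.5% (relative, configurable) of the
   nominal hold strain.

## Generalized Maxwell model

The relaxation stress of an $n$-element generalized Maxwell (Prony series)
solid is

$$\sigma(t) = \sum_{i=1}^{n} E_i\, e^{-t/\tau_i},$$

with element stiffnesses $E_i$, relaxation times $\tau_i = \eta_i/E_i$
(dashpot viscosity $\eta_i$), and relative importances
$RI_i = 100\,E_i/\sum_j E_j$. No separate equilibrium spring is included:
an element with $\tau$ far beyond the observation window is
indistinguishable from one and plays the quasi-equilibrium role.

**Fit target.** The fit runs on the raw hold-segment stress (Pa), time
re-origined to the hold start. Dividing by the constant hold strain (the
relaxation-modulus convention) is a pure rescaling that changes neither
$\tau_i$ nor $RI_i$; `as_modulus = TRUE` reports stiffnesses as moduli.

**Objective.** $\chi^2 = \sum_k (\sigma_k - \hat\sigma_k)^2/\hat\sigma_k$
(Pearson-weighted, consistent with the name; `weighting = "rss"` switches
to a plain residual sum of squares). The model stress in the denominator is
floored at $10^{-12}\max|\sigma|$ purely to avoid division blow-ups on
degenerate iterates.

**Optimization.** Multi-exponential fitting is notoriously ill-conditioned,
so: positivity is enforced by optimizing $\log E_i$ and $\log \tau_i$
(no box constraints to stick to); Levenberg–Marquardt with an analytic
Jacobian does the local work; and the optimizer is multi-started (default
8 restarts) from relaxation times log-spaced over $[\Delta t,\,100\,T_{hold}]$
— the resolvable window — with seeded log-normal jitter and stiffnesses
initialized by a linear solve given the trial times. Ties between restarts
break to the lowest $\chi^2$, then the earliest restart. The seed is a
mandatory argument of every fitting entry point; there is no hidden global
state. Non-convergence never throws: the best-effort parameters are
returned with `converged = FALSE`.

**Order selection.** `select_order()` fits $n = 1, 2, \dots$ and selects
the smallest $n$ for which the next element no longer buys at least a 5%
(configurable) relative drop in $\chi^2$:
$(\chi^2_n - \chi^2_{n+1})/\chi^2_n < 0.05$. Each order is warm-started
from the previous solution padded with a near-zero element, which makes the
$\chi^2$ path non-increasing by construction; fitting stops as soon as the
criterion is met, so at most $n^\ast + 1$ orders are ever fitted.

### Identifiability over a finite hold

Two facts about a 200 s hold window deserve emphasis, because they bound
what any fitting procedure can deliver.

First, for $\tau \gg T_{hold}$ the exponential is locally linear
($e^{-t/\tau} \approx 1 - t/\tau$), so only the element's amplitude — and
hence its relative importance — is well determined; its $\tau$ is known
only to be "long". Tests therefore assert recovery of the slow element's
$RI$, not its $\tau$.

Second, and more stringently: for the reference 4-element solid used
throughout the package ($\tau = 0.5/20/300/4000$ s, $RI = 10/10/10/70\%$),
the best *3*-element series reproduces the 4-element curve on a 200 s
window to a maximum relative deviation of about $8\times10^{-4}$. At 1%
multiplicative noise (10 Hz, 200 s, ~2000 samples) the $\chi^2$ gained by
the fourth element is therefore roughly 0.1% — far below the 5% selection
threshold — and the selector settles on $n = 3$, with the slowest fitted
element absorbing both slow components ($RI \approx 80 = 10 + 70$,
$\tau \approx 2000$ s). Resolving the $\tau = 300$ s and $\tau = 4000$ s
components separately on this window requires noise below roughly 0.15%,
or a substantially longer hold. Simulation at the reference conditions
consequently reports three elements; studies that report four elements
from comparable holds are extracting the extra component from information
(lower noise, longer or repeated holds, averaging across specimens) that a
single synthetic 200 s trace at 1% noise does not contain. The selection
machinery itself is exercised and verified on problems where the order
*is* identifiable (1- and 2-element solids with decade-separated times).

## AFM nano-mechanics

**Force calibration.** Normal force: $F_n = \Delta V_n\,\alpha\,K_n$
(deflection sensitivity $\alpha$ in m/V, spring constant $K_n$ in N/m).
Friction force from a loop width:
$F_f = \Delta V_l\,K_t\,\delta\,/\,[2(d + t/2)]$, where $\delta$ (rad/V)
converts lateral voltage to torsion angle, $K_t$ (N·m/rad) converts angle
to torque, and the moment arm is the tip height $d$ plus half the
cantilever thickness $t$. The factor 2 is there because the loop width
(trace minus retrace) is twice the friction signal. This is the standard
colloidal-probe lateral-force calibration; a sensitivity quoted in V/rad
instead of rad/V is accommodated by inverting it before building the
calibration object. The tip height has no default — it is probe-specific
and must be supplied.

**Friction loops.** The loop width is the mean of trace-minus-retrace over
the central 80% of scan positions; the outer 10% on each side is excluded
because scan-turnaround spikes live there. At each normal force the widths
of all loops (16 per load in the emulated protocol) are averaged, converted
to force, and the coefficient of friction is the OLS slope of friction
force against normal force across the load sweep (up to 60 nN). The
intercept is left free and reported as an adhesion offset — hydrated tissue
shows adhesion hysteresis, and forcing the line through the origin would
bias the slope. Per-load $F_f/F_n$ ratios are reported as diagnostics.

**Hertz fit.** Sphere-on-flat contact:
$F = \tfrac{4}{3}\,\frac{E}{1-\nu^2}\,\sqrt{R}\,\delta^{3/2}$, with probe
radius $R$ (default 10.25 µm, a colloidal sphere) and Poisson ratio $\nu$
(default 0.45, nearly incompressible hydrated tissue). The approach curve
is baseline-corrected by the mean force over its first 25% of samples
(assumed pre-contact), and the modulus and contact point are then fitted
*jointly* by least squares over the samples up to the trigger force
(default 5 nN). Joint fitting is deliberate: kPa-soft samples have no
sharp contact kink, so threshold detection of the contact point is
unreliable. Indentations beyond $0.3R$ trigger a small-strain warning.

## Synthetic data

Each generator is a pure function of its parameters and a seed
(bit-identical reruns), and emulates one specimen at a time:

- `gen_relaxation()`: strain ramps at 0.34 s⁻¹ (the emulated protocol's
  rate) to the hold strain, then holds for 200 s. The hold stress is the
  idealized step response (hold strain × Prony curve), so closed-form
  expressions hold exactly on the segment the analysis actually uses; the
  ramp uses the analytic constant-rate response of each element,
  $E_i \tau_i \dot\varepsilon\,(1 - e^{-t/\tau_i})$, verified against
  numerical convolution to $10^{-4}$. The two conventions disagree slightly
  at the junction for elements with $\tau$ comparable to the ramp time
  (fractions of a second); the hold-only fit never sees this.
- `gen_tensile()`: stress linear in strain up to the failure stress, then a
  3-sample collapse to 5% of the peak, converted to force/displacement
  through the geometry; the early ramp (below the preload) is what
  zero-referencing later discards.
- `gen_hertz_curve()`: flat baseline, Hertz branch, truncated exactly at
  the trigger; by default a third of the sweep is pre-contact baseline so
  the fitter's 25% baseline assumption holds.
- `gen_friction_loops()`: loop widths built by inverting the lateral
  calibration so processing recovers $F_f = \mu F_n + F_{adh}$ exactly in
  the noiseless limit; optional turnaround spikes in the outer 10% exercise
  the central-80% rule.

Default noise is multiplicative Gaussian (load-cell noise scales with
signal); additive Gaussian is available for photodiode-style noise, with
`sd` either absolute or relative to the peak signal.

What the generators do *not* model: biological variability across animals
and specimens, toe regions and J-shaped nonlinearity (the emulated scaffold
curves are near-linear because the tissue lacks elastin), viscoelastic
coupling between the ramp and the hold, drift, and instrument-specific
artefacts beyond scan-turnaround spikes. Passing recovery tests therefore
demonstrates that the *analysis* is correct and stable, not that real
tissue obeys these models.

### A note on noisy maxima

The failure point is defined as the global stress maximum. On a noisy
curve the observed maximum is biased upward by the expected maximum of the
near-peak noise. For a steeply rising line only a handful of samples
compete for the maximum, so the typical bias is about one noise standard
deviation (~1% at 1% noise), but individual realizations reach 3%. The
modulus, by contrast, is an unbiased OLS slope with ~1% sampling error at
these settings. Both effects mean that noisy-data recovery is meaningfully
assessed only in aggregate — the tests check the mean absolute recovery
error over 20 seeded replicates, not a per-replicate band, which no
correct estimator could guarantee below its own sampling error.

## Problem sizes and tolerances

The shipped tests and the acceptance script use: 500-sample tensile ramps;
10 Hz × 200 s relaxation holds (~2000 samples); 400-sample force curves;
16 loops × 6 loads × 128 positions for friction; 20–50 seeded replicates
for the statistical checks. Closed-form equivalences are asserted at
$10^{-9}$ relative; noiseless in-class recovery at $10^{-4}$ relative
(Maxwell) and 1% (Hertz, which must also locate the contact point);
noisy-recovery bands follow from the error analysis above. Levenberg–
Marquardt runs with `ftol = ptol = 1e-13` and at most 400 iterations per
start.

## Statistics

Only descriptive group summaries (mean, sample SD, n, CV%) are provided.
Normality tests, ANOVA and post-hoc corrections are deliberately out of
scope: the package emits tidy per-sample tables that drop directly into
any statistics environment, mirroring how such studies typically run
inference in dedicated software.
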