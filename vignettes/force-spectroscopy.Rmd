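---
title: "Models and methods: simulating and analysing polyprotein pulling experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: simulating and analysing polyprotein pulling experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smfstools)
```

# Scope

`smfstools` analyses atomic-force-microscope (AFM) single-molecule force
spectroscopy (SMFS) experiments on tandem polyproteins — engineered chains
of repeated protein domains pulled between a cantilever tip and a surface —
and simulates such experiments so that every stage of the analysis can be
tested against known ground truth. The motivating systems are octameric
constructs of bacterial adhesin extender domains (calcium-dependent
immunoglobulin-like β-sandwich repeats), with GFP and titin I27 as
reference fingerprints, but nothing in the package is specific to them:
domains are described by a residue count, a folded end-to-end distance, an
unfolded contour length and Bell kinetics.

Units are fixed package-wide: nanometres, piconewtons, seconds, and
piconewton-nanometres for energy. Spring constants are accepted in N/m at
user-facing boundaries and carried internally in pN/nm (1 N/m =
1000 pN/nm). Temperature defaults to 298 K everywhere (thermal energy
$k_BT = 4.114$ pN nm) and is overridable in every constructor; AFM pulling
experiments of this kind are performed at room temperature and the data
formats carry a `temperature_K` field.

# The physical models

## Worm-like-chain elasticity

The stretched protein chain is described by the interpolation formula of
the worm-like chain (WLC),
$$
F(x) = \frac{k_B T}{L_p}\left[\frac{1}{4}\Bigl(1-\frac{x}{L_c}\Bigr)^{-2}
 - \frac{1}{4} + \frac{x}{L_c}\right],
$$
with persistence length $L_p$ and contour length $L_c$. `wlc_force()`
evaluates it; `wlc_extension()` inverts it by bracketed root finding on
the fractional extension (round-trip error below $10^{-6}$ pN across the
working range). Unfolding of one domain releases a contour-length
increment $\Delta L_c$; per residue the released length is
$$
L_{aa} = \frac{\Delta L_c + d_{N;C}}{N_{aa}},
$$
where $d_{N;C}$ is the folded N-to-C distance (`contour_per_aa()`), with
values near 0.36–0.40 nm/aa expected for fully stretched polypeptides.

## Bell kinetics and the Evans loading-rate relation

Domain unfolding under force is a thermally activated barrier crossing
with rate
$$
k_u(F) = k_u^0\, e^{F x_u / k_B T},
$$
parameterised by the zero-force rate $k_u^0$ and the distance to the
transition state $x_u$; all prefactors are absorbed into $k_u^0$
(`bell_rate()`). Under a constant loading rate $r$ the most probable
rupture force is
$$
F^*(r) = \frac{k_B T}{x_u}\ln\!\frac{r\,x_u}{k_B T\,k_u^0},
$$
linear in $\ln r$ with slope $k_B T/x_u$ (`evans_force()`). When the
logarithm's argument is at or below one the model predicts no positive
most-probable force; the function returns 0 and flags the value out of
regime rather than reporting a negative force. The full rupture-force
distribution has the closed-form survival
$$
S(F) = \exp\!\left[-\frac{k_u^0 k_B T}{x_u r}
 \left(e^{F x_u/k_B T}-1\right)\right],
$$
implemented with its density, CDF and analytic quantile function in
`rupture_force_distribution()`; the quantile function makes exact
inverse-CDF sampling possible and serves as the oracle for every Monte
Carlo check in the test suite.

`fit_bell_evans()` estimates $(x_u, k_u^0)$ by ordinary least squares of
the representative force on $\ln r$, with the *nominal* loading rate
$r = k_c v$ (cantilever stiffness times pulling speed). This is a
deliberate fidelity choice: the true instantaneous loading rate of a WLC
tether is lower and extension-dependent, but the nominal estimator is the
convention of the experimental literature this package mirrors, so the
recovered parameters are comparable to published ones. The representative
force defaults to the histogram mode for loading-rate fits (the Evans
relation describes the most probable force) and to the mean for condition
comparisons (matching mean ± sd reporting conventions).

## Thermal-tune calibration

The cantilever spring constant is calibrated from its thermal-noise power
spectrum. The resonance is fitted with the damped simple-harmonic
oscillator response
$$
A(\nu) = A_0 + \frac{A_{DC}\,\nu_0^4}
 {(\nu_0^2-\nu^2)^2 + \nu_0^2 \nu^2 / Q^2},
$$
(`fit_resonance()`); the power under the resonance term alone — the
baseline $A_0$ is excluded — equals the mean-square deflection and gives
the spring constant by equipartition, $k = k_B T / P$
(`peak_power()`, `spring_constant()`). The integral has the closed form
$P = (\pi/2) A_{DC} \nu_0 Q$, used by default, with adaptive quadrature
(relative tolerance $10^{-6}$, split at $3\nu_0$ with the analytic tail)
available as a cross-check. Fit initialisation is data-driven: $\nu_0$
from the spectrum argmax, $A_0$ from the high-frequency median, $Q = 2$
(appropriate for soft levers in liquid), $A_{DC}$ from the peak height. A
spectrum whose maximum is not prominent above the baseline is refused
rather than silently fitted, and a resonance at the edge of the frequency
window is flagged. No mode-shape or optical-lever corrections are applied.
Repeated calibrations are averaged arithmetically with their relative
spread (`aggregate_calibrations()`).

# The simulator

`simulate_pull()` performs a quasi-static Monte Carlo pull: at each time
step the piezo advances by $v\,\Delta t$, the series force balance
$z = x + F/k_c$ (WLC tether in series with a Hookean cantilever) is solved
by Newton iteration with a bisection fallback, and each still-folded
domain — and the tip–protein attachment — ruptures with Bell hazard
$1-\exp(-k_u(F)\Delta t)$. An unfolding event moves the domain's
contribution to the tether contour from its folded spacer $d_{N;C}$ to its
unfolded contour $L$ (so the observable increment is
$\Delta L_c = L - d_{N;C}$) and the force relaxes through the same
balance; attachment rupture terminates the trace. When the total per-step
hazard exceeds 0.1 the step is subdivided so at most one event occurs per
substep, bounding discretisation bias; halving the sampling interval
changes rupture statistics by less than sampling error (tested). The
default sampling interval tracks the pulling speed (0.5 nm of piezo
travel per sample, 2000 samples per 1 µm ramp).

The simulator was validated against an independent first-passage oracle:
for a single domain, the survival probability along the deterministic
force ramp can be obtained by direct quadrature of the Bell hazard, and
the Monte Carlo mean rupture force agrees with it to within Monte Carlo
error (≈275 pN for the RII preset pulled at 1 µm/s on a 33.6 nm linker).
Two systematic effects make simulated mean forces lower than the
single-bond Evans value at the nominal loading rate: with $m$ identical
folded domains the first rupture is the minimum of $m$ races (a downshift
of $(k_B T/x_u)\ln m$), and the WLC compliance makes the true loading
rate fall below $k_c v$ as released contour accumulates. Both effects are
genuine consequences of the modelled mechanism, and both are also present
in the experiments the simulator emulates; they are why the loading-rate
fit applied to fully simulated experiments recovers the generative $x_u$
only within ~25 %, while the idealised constant-loading sampler recovers
it within a few percent.

## What the generator emulates, and what it does not

`simulate_experiment()` reproduces the nuisance structure of real
experiments: per-ramp molecule pickup (default probability 0.03, matching
the 1–5 % of ramps that show sawtooth patterns), a uniformly random
contiguous C-terminal sub-construct on pickup (the chain is anchored at
its C-terminus, the tip grabs anywhere), Gaussian force noise (10 pN sd),
a nonspecific tip–substrate adhesion bump at small extensions
(exponential decay, mean amplitude 150 pN over 15 nm, with per-curve
amplitude variation), optional linear baseline drift, and Bell-model
detachment of the tip–protein attachment. A GFP domain placed mid-chain
is misfolded from the start with probability 0.5 (contributing unfolded
contour and no peak), emulating the observed fractions of curves in which
the GFP fingerprint is present, absent, or masked by adhesion.

Not emulated: cantilever and fluid dynamics (the analysis operates on the
same quasi-static models, so this omission cannot hide analysis errors),
refolding during the ramp, multiple parallel tethers, instrument drift
beyond a linear baseline, and digitisation artifacts. Passing the
end-to-end tests therefore demonstrates correctness of the analysis
pipeline under the modelled physics, not robustness to every artifact of
real instrument data.

## Domain presets

Preset geometry uses the structure-derived values: RII
($N_{aa}=104$, $d_{N;C}=4.8$ nm, unfolded contour 38.0 nm, hence
$\Delta L_c = 33.2$ nm), MhLap RII (97, 3.38, 36.98), GFP (239, 3.0,
77.4) and I27 (89, 4.3, 31.6). Bell kinetics for RII are the
loading-rate-fit estimates $x_u = 0.2$ nm, $k_u^0 = 0.003\ \mathrm{s^{-1}}$;
the other three have no published Bell parameters in the source data, so
their kinetics are package presets calibrated once so that the Evans
force at the nominal 1 µm/s loading rate (0.15 N/m lever) matches the
reported mean unfolding forces (≈306, 88 and 218 pN respectively). The
MhLap octamer additionally carries a fixed symmetric spread of
$\ln k_u^0$ across its eight repeats (sd 1.9) emulating their imperfect
sequence identity; this raises the within-curve force heterogeneity
(cv) above the homogeneous-repeat case, which is the qualitative contrast
the per-curve cv statistic is designed to detect.

# Curve analysis

The analysis chain mirrors manual SMFS practice:

* **Baseline** (`estimate_baseline()`): median force over the final 10 %
  of the extension range (the post-detachment tail); when that tail is
  not flat relative to the point-to-point noise, the fallback is the mode
  of the force histogram of the whole trace. The baseline estimator is a
  package choice — conventions differ between laboratories.
* **Peak calling** (`detect_peaks()`): local maxima of a 5-sample
  moving-average force, at least `min_force` above baseline, followed
  within `min_separation` by a drop of at least `min_drop`; taller peaks
  suppress neighbours within `min_separation`. Defaults 50 pN, 50 pN,
  10 nm — chosen so the weakest expected fingerprint (GFP at ~88 pN)
  clears the threshold above the default 10 pN noise while pure-noise
  traces yield no calls. The unfolding force of a call is defined as raw
  peak force minus baseline, exactly.
* **Per-peak WLC fits** (`fit_wlc_peak()`): Levenberg–Marquardt least
  squares of the WLC over the rising edge from the force minimum after
  the previous rupture to the peak, with both $L_c$ and $L_p$ free
  ($L_p$ is fitted per peak because its empirical distribution is itself
  a result of interest). Windows with fewer than 8 points, failed
  convergence, or $L_c$ not exceeding the peak extension are flagged and
  excluded, never imputed.
* **Event table and classification** (`event_table()`,
  `classify_peaks()`): $\Delta L_c$ as successive differences of fitted
  contour lengths, $\Delta L$ as successive differences of peak
  extensions; the final peak of each curve is the detachment, peaks near
  the surface (within 1.5 × the adhesion range) without a WLC-consistent
  rising edge are adhesion artifacts, low-force peaks whose unfolding
  length to the next peak falls in the 60–90 nm band are GFP, and the
  rest are repeat-domain ("RII") unfoldings.
* **Sawtooth filter** (`sawtooth_filter()`): per-curve statistics are
  restricted to curves with at least five repeat peaks, the convention
  for the cv statistic $c_v = \sigma/\mu$ computed by `cv_per_curve()`.

Note that $\Delta L$ is an operational proxy for $\Delta L_c$: each
rupture happens below full contour extension, so on average
$\Delta L < \Delta L_c$, but an individual pair can invert when the later
rupture occurs at a higher force. The per-event invariant the package
guarantees is that every peak extension lies below its fitted contour
length.

# Numerical choices and degenerate inputs

Root finding uses Newton iteration seeded from the previous sample with a
guarded bisection fallback (`uniroot`, tolerance $10^{-12}$ on the
fractional extension). Nonlinear fits use `minpack.lm::nls.lm`; residuals
that are exactly zero (noiseless fixtures) are handled without error. The
histogram-mode estimator fits a Gaussian to the contiguous
Freedman–Diaconis bins above 40 % of the modal count, a local
approximation that avoids the bias a whole-histogram Gaussian incurs on
the left-skewed rupture distribution; it requires at least 20
observations. Degenerate inputs fail loudly: spectra without a resonance,
configurations with unknown keys or a missing seed, piezo-coordinate
files without a spring constant, non-positive Bell–Evans slopes.

All randomness flows from explicit integer seeds. `simulate_experiment()`
seeds once and draws every ramp from the same stream, so a single
configuration seed reproduces the full output tree byte for byte (tested
through the command-line interface).

# Problem sizes used in the tests

The shipped suite works at desk scale, chosen to make every stochastic
assertion comfortably stable under its fixed seed: 200 simulated curves
for the end-to-end detection/recovery checks (sensitivity and precision
≥ 95 %, mean $\Delta L_c$ within 5 % of the generative 33.2 nm, mean
$L_p$ inside 0.1–0.5 nm when generated at 0.3 nm), 2000 inverse-CDF
rupture draws per speed at the four experimental pulling speeds (50, 200,
1000, 4880 nm/s) for Bell-parameter recovery ($x_u$ within 15 %,
$k_u^0$ within a factor of 2), 50 seeds for the thermal-tune round trip
(spring constants in 0.12–0.22 N/m recovered within 10 % at 5 %
spectral noise), and $10^4$ draws for distribution-level
Kolmogorov–Smirnov checks (D < 0.02).

# Known limitations

* The quasi-static force balance ignores cantilever inertia and
  hydrodynamics; at the highest experimental speeds this is a mild
  approximation.
* Loading-rate fits use the nominal $r = k_c v$; parameters recovered
  from fully simulated experiments inherit the corresponding bias, which
  is intrinsic to the estimator, not the implementation.
* Classification is rule-based; pathological curves (two fingerprint
  domains, strong drift) may need threshold changes via the configuration
  block.
* The calcium dependence of domain stability enters only through the
  kinetics chosen for a scenario (weaker `bell_params` and larger spread
  emulate a low-calcium condition); the package does not model calcium
  binding itself beyond the stoichiometric free-calcium bookkeeping of
  `free_calcium()`.
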