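---
title: "Methods: multifractal release dynamics and their calibration"
author: "mfrelease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multifractal release dynamics and their calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfrelease)
```

## Scope and assumptions

`mfrelease` models the release of a covalently bound drug from a polymer
matrix — the motivating system is an antifungal aldehyde held on
imino-chitosan by reversible imine bonds — as dynamics of a multifractal
object analysed at varying resolution. Two synchronous descriptions
coexist: one in *scale space* (resolution `s = ln(ε/ε₀)`), associated with
the fungicidal action, and one in *usual space* (laboratory time),
associated with the cumulative release. Both reduce to Riccati-type
first-order equations, which is what makes the machinery below uniform.

The package deliberately excludes: estimation of singularity spectra from
data, any claim of genuine chaos (no Lyapunov estimation — the taxonomy
below tops out at "quasi-chaotic" by design), mechanistic Fickian
diffusion solvers, and any wet-lab image or swelling analysis.

## The scale-space gauge

The gauge is

$$\frac{dw}{ds} = \frac{w^2}{M} - \frac{2R}{M}\,w + K,$$

with dimensionless constants `(M, R, K)`, `M ≠ 0`. Its stationary points
are `w₀ = R + iMΩ` and `w̄₀ = R − iMΩ` with `Ω² = K/M − (R/M)²`.

*A sign convention had to be fixed here.* Both signs of the quadratic
term appear in the literature on Riccati-type gauges; the form above is
the unique choice whose stationary points are `R ± iMΩ` with the stated
`Ω²`. The test suite verifies the closed form against adaptive numerical
integration of exactly this ODE, so the convention is checked
operationally, not assumed.

The general solution

$$w(s) = \frac{w_0 + r\,e^{2i\Omega s}\,\bar w_0}{1 + r\,e^{2i\Omega s}}$$

has an integration constant `r` setting the modulation depth. For real
`Ω` and real `r` it separates into the real form implemented by
`riccati_real_form()`; the two forms agree to machine precision (the
suite asserts 1e−12), and the denominator `1 + r² + 2r cos 2Ωs` exposes
the genuine poles at `|r| = 1`, `cos 2Ωs = −1`.

**Numerical conventions.** `Ω` is stored complex under a principal branch
(`Re Ω ≥ 0`, and `Im Ω ≥ 0` on the imaginary axis). Purely imaginary `Ω`
(when `K/M < (R/M)²`) is admitted and produces hyperbolically damped
solutions. Evaluations where the solution denominator has modulus below
1e−9 raise an error listing the offending `s`; below 1e−3 the sample is
flagged but returned. These two thresholds are the package's singularity
policy throughout.

## Regime taxonomy and the bifurcation-style scan

The regime names (period doubling, damping, strong modulation,
quasi-chaos, intermittency) describe qualitatively distinct modes of
scale symmetry breaking; no quantitative thresholds are standard, so the
classifier's decision rules are a package design choice, rationalised by
the monotone growth of the modulation depth with `|r|`:

| condition | label |
|---|---|
| `r = 0` (or `Ω = 0`) | `fixed_point` |
| `Ω` non-real | `damped` |
| real-form denominator min `< 1e−3` | `intermittent` |
| `0 < |r| ≤ 0.3` | `harmonic_modulation` |
| `0.3 < |r| ≤ 0.7` | `period_doubled` |
| `0.7 < |r| ≤ 0.95` | `strongly_modulated` |
| `|r| > 0.95` | `quasi_chaotic` |

No `chaotic` label exists: the closed-form solution is periodic for real
`Ω`, so the system approaches but never reaches chaos, and the classifier
reflects that structurally.

`bifurcation_scan()` sweeps `Ω` (reconstructing `K` for each value so `M`
and `R` stay fixed), discards the first 20 % of the grid as transient,
detects local extrema of `Re w` with three-point parabolic refinement, and
clusters extremum levels with tolerance `1e−4 × range`. The number of
distinct levels is reported as the *pseudo-chaos index*. For this solution
family the orbit has exactly one maximum and one minimum per period, so
the index is 1 at `r = 0` and 2 for `0 < |r| < 1`; the refinement step
exists to keep that count stable against grid sampling error near the
spiky `|r| → 1` limit, where naive sampled extrema would scatter into
spurious levels.

## Phase parameter

The large-scale parametrisation
`h(s) = (−i cosh μ + r e^{2iΩs} sinh μ)/(cosh μ + r e^{2iΩs} sinh μ)`
is implemented with `μ` and `r` independent, plus a convenience
constructor enforcing the coupling `r = coth μ`. The coupling and the
real-form solution are *not* mutually consistent as a pointwise identity
(`R + MΩh` with `r = coth μ` does not reproduce the real form — a
numerical check is easy to run), so the implementation exposes the
object itself and asserts only the properties that do hold: `h ≡ −i` at
`μ = 0`, the large-`μ` limit, boundedness away from poles, and the shared
singularity policy. The invariant-side conversion `ρ = tanh μ`
(`rho_from_mu()`, `mu_from_rho()`) is kept as the documented link between
the hyperbolic parameter and the joint invariant.

## Kink, antikink and logistic laws

Rewriting the gauge with `M = 2μ`, `R = ±c`, `K/M = −d` gives
`2μ w′ = w² − 2cw − d`, which under `d + c² > 0` admits the bounded fronts
`w(s) = c ± A tanh(As/2μ)`, `A = √(d + c²)`. Sign bookkeeping for the two branches is delicate (only one branch can
solve the equation as written), so the package fixes the convention
*antikink solves the equation as written; kink solves its s-reversed
form* and verifies both by residual
(the suite asserts `< 1e−8` on `[−10, 10]`). The logistic specialisation
(`M = −1/f`, `R = ½`, `K = 0`) is implemented directly through its exact
solution `w(s) = 1/(1 − (1 − 1/w₀)e^{−fs})`, which satisfies
`dw/ds = f w(1−w)` identically. (The reciprocal substitution `n = 1/w`
obeys `dn/ds = −f n(1−n)`, with a sign flip, so the package works with
the exact solution directly rather than through that transform.)
Kink–antikink pairs carry no canonical closed form; the package uses the
additive superposition with baseline subtraction

$$w(s) = c + A\left[\tanh\frac{A(s+s_0)}{2\mu} - \tanh\frac{A(s-s_0)}{2\mu}\right],$$

chosen as the simplest form that is even, baseline-preserving at both
infinities, and reproduces the observed pulse morphology with amplitude
`2A tanh(As₀/2μ)`.

## The SL(2,R) machinery and joint invariants

Usual-space dynamics are invariant under homographies
`t ↦ (αt + β)/(γt + δ)`; `mobius_apply()`/`mobius_compose()` implement the
action and its group law. The left-invariant coframe `(ω₁, ω₂, ω₃)` of a
parameter step and the metric `ds² = ¼(ω₂² − 4ω₁ω₃)` are implemented with
both the coframe and the direct expression, which agree to 1e−12 (dual
formula test). Along geodesics the dynamics reduce to
`dt/dτ = a₁t² + 2a₂t + a₃`, which `geodesic_riccati_solve()` maps back to
the scale gauge (`M = 1/a₁`, `R = −a₂/a₁`, `K = a₃`) with the modulation
constant chosen from the initial condition — reusing the closed form
rather than re-deriving one.

The two operator algebras are
`Â₁ = ∂_h + ∂_h̄`, `Â₂ = h∂_h + h̄∂_h̄`,
`Â₃ = h²∂_h + h̄²∂_h̄ + (h − h̄)k∂_k` and the `B̂` copy in `(z, z̄)` without
a `k` term. Commutators are verified *exactly* on all monomials to total
degree 3 using an in-package polynomial type (complex coefficients,
five variables), not by finite differences.

Both joint invariants are determined *operationally*: a candidate is
accepted only if the Stoka system `(Âᵢ + B̂ᵢ)f = 0` annihilates it (the suite asserts
residuals `< 1e−8` at 100 random points in the five independent
coordinates). The primary invariant is the cross-ratio

$$\rho^2 = \frac{(h-z)(\bar h-\bar z)}{(h-\bar z)(\bar h - z)},$$

which is translation-invariant, scaling-degree-0 and Möbius-invariant.
For the second, `k`-dependent invariant, the candidate
`(h − z)(h̄ − z̄)/k` fails annihilation under both `Â₂ + B̂₂` and
`Â₃ + B̂₃`; requiring translation invariance, homogeneity balanced by the
`k` weight, and annihilation including the `(h − h̄)k∂_k` term determines

$$f_2 = k^2\,\frac{(\bar h - z)(\bar h - \bar z)}{(h - z)(h - \bar z)}$$

uniquely up to functions of `ρ²`, and this is what `joint_invariant()`
returns as `aux`. The finite-difference residual check uses a
fourth-order central stencil (step 1e−4) and draws test points with all
pairwise coordinate separations at least 0.4, keeping truncation and
cancellation error two orders below the 1e−8 assertion.

## From scale space to laboratory observables

The largest genuinely open design choice is how the scale variable meets
laboratory time. The package adopts

$$s = (t/\tau)^c \quad\Rightarrow\quad F(t) = F_\infty \tanh\left[(t/\tau)^c\right],$$

because it preserves the kink's saturation morphology, reduces to a pure
tanh law at `c = 1`, and gives the fitted exponent `c` the role of the
sample's *fractality degree* — the scalar by which two differently loaded
samples are compared. The mapping lives in one place (`model_curve()`), so
alternates can be swapped without touching the fitter. The kill observable
is the antikink analogue `V(t) = V_{res} + (1 − V_{res})(1 − \tanh[(t/\tau)^c])`,
with `V(0) = 1` by construction. The classical comparators (zero-order,
first-order, Higuchi, Hixson–Crowell with clipping at complete
dissolution, Korsmeyer–Peppas) use their standard forms.

## Calibration

`release_fit()` minimises (optionally 1/F-weighted) squared residuals by
Levenberg–Marquardt with box bounds (`τ ∈ (0, 10 t_max]`, `c ∈ (0, 10]`,
`F∞ ∈ (0, 110]` — the 110 allows measurement overshoot above 100 %),
from 16 seeded Latin-hypercube starting points (log-uniform over the box)
plus one deterministic data-driven start. Identical data and seed give
bitwise-identical estimates. Standard errors come from the residual
curvature (`σ̂²(JᵀJ)⁻¹`); model ranking uses the small-sample corrected
information criterion AICc, appropriate for release curves of 10–25
points. Fits report a convergence flag (Levenberg–Marquardt termination
codes for the ftol/ptol/gtol criteria) and downstream reporting refuses
non-converged inputs rather than passing them through silently.

One caveat on the information criterion: for nested models the AICc
difference is invariant under rescaling the noise, and the larger model
always gains a chi-square-distributed residual improvement, so "the
smaller model always wins on data it generated" is not a theorem. The
suite asserts the defensible version — the smaller model wins in the
clear majority of seeded replicates and on the median score difference.

## What the synthetic generators emulate — and what they do not

`generate_release()` draws `F(tᵢ) = F_∞\tanh[(tᵢ/τ)^c] + N(0, σ)`,
clipped below at 0 only (no upper clip, so fits must cope with small
overshoot, as real UV-Vis readings require). Defaults encode the study
conditions: `F∞ = 100`, `τ = 4` h (the burst completes in the first four
hours), `c = 1.7` (the canonical fractality degree of the higher-loading
sample), 25 points over 24 h with 8 of them front-loaded into `[0, 4]` h,
and noise sd 2 % — the last a package convention chosen once as a
realistic UV-Vis measurement error. `generate_kill()` uses
`V_res = 0.02` (near-complete extinction), `τ = 6` h, `c = 1.7` and noise
sd 0.02 in viable-fraction units, likewise a convention.
`generate_two_sample_study()` encodes the two-loading design — the
higher-loading sample must dominate in release and kill faster — and
refuses truths that violate the domination.

What this does *not* emulate: correlated or heteroscedastic measurement
error, calibration-curve (absorbance) chemistry, inter-batch variability,
or curves whose true law is none of the implemented families. Passing
recovery tests therefore demonstrate the fitter's correctness and
precision *under the stated error model*, not robustness to real-world
misspecification.

## Problem sizes and tolerances used by the checks

The packaged checks run 100 random gauges for the closed-form/ODE
comparison (tolerance 1e−6 against integration at rtol 1e−12), 50 for the
complex/real equivalence (1e−12), 100 random points for the Stoka
residuals (1e−8), 100 random steps for the metric identity (1e−12), 100
pairs for the composition law (1e−10), 200 noisy replicates for the
recovery medians (assertion: < 5 % on `τ` and `c`), and 100 replicate
studies for the ordering rate (assertion: ≥ 95 %). These sizes make the
whole suite run in well under a minute while keeping every Monte-Carlo
assertion far from its boundary.

## Known limitations

- The phase-parameter coupling `r = coth μ` and the real-form solution
  do not cohere as a pointwise identity; the package exposes both
  objects and their individually verified properties instead of an
  identity that does not hold.
- The time mapping `s = (t/τ)^c` is a declared convention, not a derived
  result; fractality degrees from differently conventioned analyses are
  not directly comparable.
- The fitter's bounds make estimates at a bound (`τ` at `10 t_max`, say)
  formally "converged"; inspect the flag and the standard errors, which
  blow up in such cases.
- `ρ² ≥ 0` is guaranteed only for `z` and `h` in the same half-plane
  configuration; the implementation returns the real part and leaves
  interpretation of mixed configurations to the caller.
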