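# mfrelease

Multifractal release kinetics for polymer–drug systems in R.

## The problem

Hydrogels that bind a drug covalently — here the motivating system is an
imino-chitosan hydrogel carrying an antifungal aldehyde through reversible
imine (C=N) bonds — release that drug when a pH stimulus shifts the imination
equilibrium. The observed curves have a characteristic shape: a burst over
the first few hours, then a prolonged approach to a plateau at or below
100 %, mirrored by a monotone decline of the viable fungal population the
drug attacks. `mfrelease` implements a scale-relativity description of these
dynamics, treating the polymer–drug system as a multifractal object, and
turns it into a practical curve-fitting toolkit for pharmaceutics work.

The package is aimed at modellers of controlled drug delivery who want both
the theoretical machinery (closed forms, regime taxonomy, group invariants)
and a conventional calibration workflow (fit, compare, report) in one place.

## The model

Scale-space dynamics are governed by a Riccati-type gauge in the
logarithmic resolution variable `s = ln(ε/ε₀)`:

    dw/ds = w²/M − (2R/M) w + K,

with multifractal constants `(M, R, K)`, characteristic frequency
`Ω² = K/M − (R/M)²` and stationary roots `R ± iMΩ`. Its general solution

    w(s) = (w₀ + r e^{2iΩs} w̄₀) / (1 + r e^{2iΩs})

displays, as the modulation constant `r` grows, the full ladder of
scale-symmetry-breaking regimes (harmonic modulation, period doubling,
strong modulation, quasi-chaos, intermittency — never true chaos), which
`mode_classify()` labels and `bifurcation_scan()` quantifies by a
pseudo-chaos index.

In hyperbolic form the same gauge yields bounded kink/antikink fronts
`w(s) = c ± A tanh(As/2μ)` with `A = √(d + c²)`, and with a different
constant choice the logistic law `dw/ds = f w(1−w)`. The rising kink is the
release observable; the falling antikink is the kill observable. Two
isomorphic SL(2,R) operator algebras (one per space) and their joint
invariants — verified operationally through the Stoka system
`(Âᵢ + B̂ᵢ)f = 0` — tie the scale-space dynamics to laboratory coordinates.

Laboratory time enters through the mapping `s = (t/τ)^c`, giving the
release law

    F(t) = F∞ · tanh((t/τ)^c),

where the exponent `c` acts as the sample's fractality degree. `release_fit()`
calibrates this (or the logistic law, or any of the classical zero-order,
first-order, Higuchi, Hixson–Crowell and Korsmeyer–Peppas models) by
bounded Levenberg–Marquardt least squares with a seeded Latin-hypercube
multi-start, and `kill_fit()` does the same for the antikink kill law
`V(t) = V_res + (1−V_res)(1 − tanh((t/τ)^c))`.

## Worked example

```r
library(mfrelease)

curve <- generate_release(seed = 7)   # synthetic burst-release curve
fit <- release_fit(curve)
summary(fit)
#> Model: mf_kink (release observable), n = 25
#>      Estimate Std. Error
#> Finf  101.478      0.565
#> tau     4.023      0.075
#> c       1.802      0.082
#> R-squared 0.9965, residual sigma 2.216, AICc 43.73
```

The generating truth was `F∞ = 100`, `τ = 4` h, `c = 1.7` with Gaussian
noise of sd 2 %: the fit recovers the plateau, burst time-scale and
fractality degree within one to two standard errors. Ranking against
classical dissolution models shows why a plateauing curve defeats the
straight-line and square-root laws:

```r
compare_release_models(curve, models = c("mf_kink", "first_order",
                                         "higuchi", "zero_order"))
#>         model  r_squared      aicc rank
#> 1     mf_kink 0.99648610  43.73483    1
#> 2 first_order 0.93929265 112.37091    2
#> 3     higuchi 0.70947848 149.13969    3
#> 4  zero_order 0.04323227 178.93676    4
```

A two-sample comparison reports fractality degrees and their ratio:

```r
hi <- generate_release(truth = list(model = "mf_kink",
                                    theta = c(Finf = 100, tau = 4, c = 5.44)),
                       seed = 8)
fractality_report(release_fit(hi), fit)
#> Fractality-degree report
#>   exponent a: 5.167   exponent b: 1.802   ratio: 2.868
#>   higher fractality: sample a; faster release at 4 h: sample b
```

The scale-space side is equally direct:

```r
g <- scale_gauge(M = 1, R = 0, K = 1)
mode_classify(g, r = 0.5)
#> [1] "period_doubled"
joint_invariant(z = 1i, h = 2i, k = 1)$rho2
#> [1] 0.1111111
```

## Command line

A thin Rscript wrapper is installed at `inst/cli/mfrelease`:

    mfrelease synth --kind release --out data/ --seed 5
    mfrelease fit --input data/release.csv --model mf_kink --seed 5 --out fit.json
    mfrelease invariants-check --report report.txt

Subcommands: `simulate`, `scan`, `synth`, `fit`, `compare`,
`invariants-check`. Every flag can instead be given in a flat YAML config
(`--config run.yaml`; command-line flags win), and every run writes a
`.manifest.json` (inputs, config hash, seed, package version) beside its
outputs.

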