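# colecole

Time- and frequency-domain tools for the **Cole-Cole dielectric relaxation
model** and its relatives (Debye, Cole-Davidson, Havriliak-Negami), written
for people who measure and model impedance spectra — bioimpedance in
particular — and for anyone who needs reliable numerics for the
Mittag-Leffler relaxation functions behind them.

## The science in one page

A dielectric-filled capacitor answers a voltage step with a current
transient and a charge build-up. The Debye model (one relaxation time τ)
makes both exponential. Real dielectrics relax more broadly; the Cole-Cole
model captures this with a single extra exponent α ∈ (0, 1]:

    ε_r(ω) = ε_∞ + (ε_s − ε_∞) / (1 + (jωτ)^α)

In the time domain the normalized step responses are Mittag-Leffler
functions — φ(t) = (1/τ)(t/τ)^(α−1) E_{α,α}(−(t/τ)^α) for the current
(response function) and ψ(t) = E_α(−(t/τ)^α) for the charge (relaxation
function) — whose asymptotes are the two classical empirical laws of
imperfect capacitors:

* **small times**: the Curie-von Schweidler power-law current
  t^(α−1)/(τ Γ(α)) and the Kohlrausch-Williams-Watts stretched
  exponential exp[−(t/τ)^α/Γ(1+α)] for the charge, with
  τ* = τ Γ(1+α)^(1/α);
* **large times**: power-law tails t^(−α−1) and t^(−α).

The same model is a *fractional Zener* constitutive law,
D + τ^α d^α D/dt^α = ε₀ε_s E + τ^α ε₀ε_∞ d^α E/dt^α, and in the limit
(ωτ)^α ≫ 1 with ε_∞ = 0 its capacitance becomes a constant-phase element
with phase −απ/2 at all frequencies.

The package provides:

* `mittag_leffler()` — a guarded multi-regime evaluator of E_{α,β}(−x)
  (series / spectral integral / Talbot / asymptotic), validated against a
  frozen 50-digit arbitrary-precision reference table;
* `permittivity()`, `capacitance()`, `impedance()`, `step_spectra()`,
  `cpe_limit_capacitance()`, `cpe_onset_omega_tau()` — frequency domain;
* `cc_response_function()`, `cc_relaxation_function()`,
  `response_asymptote()`, `relaxation_asymptote()`, `kww_from_cole()`,
  `assemble_step_current()`, `assemble_step_charge()` — time domain;
* `gl_fractional_derivative()`, `caputo_derivative()`,
  `fields_from_step()`, `constitutive_residual()` — discrete fractional
  calculus and verification of the fractional Zener law;
* `invert_normalized_model()` (fixed Talbot and epsilon-accelerated
  Fourier series) and `complete_monotonicity_check()` — independent
  numerical cross-checks;
* `cole_fit()` — bounded nonlinear least-squares estimation from complex
  permittivity spectra or relaxation records, returning a classed model
  object with `print`, `summary`, `coef`, `predict`, `plot`, `simulate`,
  `residuals` methods, plus seeded generators `synth_spectrum()` /
  `synth_relaxation()`;
* a command-line tool (`inst/cli/colecole`) with subcommands `spectrum`,
  `response`, `relaxation`, `fit`, `verify`, `simulate`.

## Worked example

Fit a Cole-Cole model to a noisy synthetic spectrum (50 frequencies over
six decades, 1% proportional noise):

```r
library(colecole)
p   <- dielectric_params("cole_cole", eps_s = 100, eps_inf = 10,
                         tau = 1e-6, alpha = 0.7)
sp  <- synth_spectrum(p, log_grid(1e3, 1e9, 50),
                      noise_model("proportional_gaussian", 0.01, seed = 42))
fit <- cole_fit(sp)
fit
#> Dielectric relaxation fit (cole_cole, frequency domain)
#>   eps_s = 100.232  eps_inf = 9.91105  tau = 1.00512e-06 s  alpha = 0.6965  beta = 1
#>   residual RMS 0.5263, 2 iterations, converged: TRUE
```

All four generating parameters come back within a fraction of a percent:
ε_s within 0.23, ε_∞ within 0.09, τ within 0.5%, and the fractional order
α̂ = 0.6965 within 0.0035 of the true 0.7. The residual RMS (0.53
permittivity units) matches the injected 1% noise on |ε| ≈ 40-100.

Verify that the model's own step fields satisfy the fractional Zener
constitutive law on a uniform grid (h = τ/1000, window 0.1τ-5τ):

```r
res <- constitutive_residual(fields_from_step(p, seq(0, 5e-6, by = 1e-9)),
                             p, window = c(0.1, 5) * 1e-6)
res
#> <zener_residual: max 3.761e-04, rms 7.352e-05 over 4900 samples (h = 1e-09 s)>
```

The normalized residual is ~4×10⁻⁴ and halves when h halves (a first-order
discrete fractional derivative); replacing ψ by its large-time asymptote
inflates it by six orders of magnitude.

One number worth remembering: a nearly ideal capacitor with α = 0.01
reaches CPE factor (ωτ)^α = 10 only at

```r
cpe_onset_omega_tau(0.01, 10, log10 = TRUE)
#> [1] 100
```

i.e. ωτ = 10¹⁰⁰ — which is why real capacitors can follow the
Curie-von Schweidler law for days.

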