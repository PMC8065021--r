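# oscillab

Hopf-bifurcation analysis of genetic negative-feedback oscillators and
their coupled-cell collectives.

Cellular clocks — circadian oscillators, the vertebrate segmentation clock —
are built from a transcriptional negative-feedback loop (mRNA → protein →
repressor ⊣ transcription) and synchronise across cells through a released
signal sensed as a population mean field. `oscillab` answers two questions
about such systems quantitatively: *where in parameter space does a stable
oscillation appear*, and *how does the collective frequency of coupled cells
compare with the average of their intrinsic frequencies* — and how both
answers depend on whether transcription is repressed by cooperative
promoter binding (Hill type, `f(x) = 1/(1+(x/k_H)^n)`) or by protein
sequestration of an activator pool.

## Method

The core primitive is the degenerate Routh–Hurwitz criterion: for the
characteristic polynomial `λ^m + b1 λ^(m−1) + … + bm` of the equilibrium
Jacobian, the system has exactly one purely imaginary eigenvalue pair (all
other roots stable) iff

    b_m > 0,   D_i > 0 (i ≤ m−2),   D_{m−1} = 0,

with `D_i` the Hurwitz-matrix determinants. A simple Hopf bifurcation sits
where `D_{m−1}(α)` crosses zero transversally; the imaginary pair's
magnitude ω\* is the frequency of the emergent cycle. On top of this the
package provides:

- closed-form locators — single cell (`α0 = 8/γ`, `γ = −f'(x̄)`, frequency
  exactly √3 for *any* repression function) and identical coupled pair
  (quartic factorisation: explicit `α*(γ, c, s)` and collective frequency
  `ω_c*(γ, c, s)`);
- a numeric `D_{m−1} = 0` locator for nonidentical pairs and the
  segmentation-clock model, plus two-parameter bifurcation-curve
  continuation;
- matched eigenvalue-branch tracing between the decoupled and coupled
  bifurcation points, classifying how the equilibrium's stable/unstable
  manifolds reorganise;
- high-accuracy limit-cycle extraction (lsoda at rtol 1e−12, Hermite-refined
  Poincaré sections, geometric-tail extrapolation of return times) giving
  periods, frequencies, amplitudes and inter-cell phase differences;
- Hopf normal-form coefficients (`g20, g11, g02, g21, C1, p2, ζ2, T2`) for
  super/subcriticality, cycle stability and the leading period trend;
- collective-vs-average frequency comparisons, including the coupling
  strength at which they match.

## Worked example

```r
library(oscillab)
ht <- hill_repression(n = 11, k_H = 0.136)

single_cell_hb(ht)
#> <hopf_point>
#>   parameters: alpha=0.54517354
#>   omega* = 1.73205081, crossing derivative = -4.891
```

The single Hill cell (n = 11) destabilises at α0 ≈ 0.5452; the cycle is born
with frequency √3 ≈ 1.732 — a value independent of the repression mechanism.
Coupling two such cells (strength c = 0.05, signal timescale s = 20) moves
the bifurcation down and the frequency below √3:

```r
coupled_identical_hb(ht, coupling = 0.05, s = 20)
#> <hopf_point>
#>   parameters: alpha=0.4741627, coupling=0.05
#>   omega* = 1.72122893, crossing derivative = -4.752e+04
```

The bifurcation is supercritical with a stable cycle whose period grows
with α:

```r
hp <- single_cell_hb(ht)
hopf_coefficients(single_cell_model(ht, hp$parameter_values$alpha), hp)
#> <normal_form> supercritical_stable
#>   C1 = -20.207-42.5797i,  p2 = 99.1467,  zeta2 = -40.4139,  T2 = 4.37646
```

Simulation well beyond the bifurcation confirms and refines the picture
(α = 0.60139, the drive at which the Hill and sequestration waveforms
nearly coincide):

```r
extract_cycle(single_cell_model(ht, 0.60139), x0 = c(0.1, 0.1, 0.1))
#> <cycle_summary> T = 3.637283901, omega = 1.7274388 (converged to 6e-10)
#>   amplitude: 0.0408637, 0.0204191, 0.0102123
```

The period is converged to 10 digits (two independent integrators agree);
the frequency has dropped from √3 as the theory's positive `T2` predicts.
See `vignettes/hopf-methods.Rmd` for the full methodology, numerical
choices and known limitations.

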