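---
title: "Locating Hopf bifurcations and collective frequencies in coupled genetic oscillators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating Hopf bifurcations and collective frequencies in coupled genetic oscillators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oscillab)
```

## The biological question and the models

Many biological rhythms — the circadian clock of the mammalian
suprachiasmatic nucleus being the canonical example — arise from cells that
each carry an intracellular negative-feedback oscillator and that are coupled
through a released signal. Two questions drive this package: when does a
population of such cells produce a *collective* oscillation, and how does the
collective frequency compare with the average of the cells' intrinsic
frequencies?

The intracellular clock is the minimal transcriptional negative-feedback
loop: clock mRNA `x1` makes protein `x2`, which makes a transcriptional
repressor `x3`, which shuts off `x1` production. After scaling all three
degradation rates to one, a single cell is

$$\dot x_1 = \alpha f(x_3) - x_1,\qquad \dot x_2 = x_1 - x_2,\qquad
  \dot x_3 = x_2 - x_3,$$

where $\alpha>0$ lumps the production rates and is the bifurcation
parameter. The repression function $f$ is either

* **Hill type (HT)** — $f_1(x) = 1/(1 + (x/k_H)^n)$, cooperative binding of
  the repressor to the promoter, with Hill coefficient $n$ and
  half-saturation $k_H$; or
* **protein sequestration (PS)** — $f_2(x)$, the unsequestered fraction of
  an activator pool $A$ titrated by the repressor with dissociation constant
  $k_d$ (the positive root of the binding quadratic).

Both are smooth, strictly decreasing, equal to 1 at zero repressor. The slope
magnitude at equilibrium, $\gamma = -f'(\bar x)$, turns out to carry all the
model-discriminating information.

Coupled cells release a signal (`x4`, in the circadian context a
neuropeptide such as VIP) at rate proportional to promoter activity, and
every cell senses the population mean:

$$\dot x_1^{(i)} = \alpha f(x_3^{(i)}) - x_1^{(i)} +
  \frac{c}{N}\sum_j x_4^{(j)},\qquad
  \dot x_4^{(i)} = s\,[f(x_3^{(i)}) - x_4^{(i)}],$$

with coupling strength $c$ and signal timescale $s$ (fast coupling, $s>1$).
A pair of *nonidentical* cells is modelled by running the second cell's
intracellular clock at a timescale factor $\sigma$ (its intrinsic frequency
is exactly $\sigma$ times the first cell's — time rescaling changes no
bifurcation value). A structurally different comparison system, a pair of
zebrafish segmentation-clock cells with Michaelis–Menten degradation and
signal-mediated coupling, is included as `segclock_model()`.

## The degenerate Routh–Hurwitz test

All bifurcation location in this package goes through one primitive. For an
equilibrium $\bar{\mathbf x}(\alpha)$ with Jacobian $J$, write the
characteristic polynomial $\lambda^m + b_1\lambda^{m-1}+\dots+b_m$
(`char_coefficients()`, computed by the Faddeev–LeVerrier recurrence so the
coefficients are exact polynomials in the matrix entries) and build the
Hurwitz matrices $H_1,\dots,H_m$ with determinants $D_i$
(`hurwitz_determinants()`). The classical criterion says all roots lie in
the open left half-plane iff every $D_i>0$; its degenerate form says the
polynomial has exactly one purely imaginary conjugate pair, all other roots
stable, iff

$$b_m > 0,\quad D_i > 0\ (i \le m-2),\quad D_{m-1} = 0 .$$

A simple Hopf bifurcation therefore sits where $D_{m-1}(\alpha)$ crosses
zero with the side conditions holding and
$\tfrac{d}{d\alpha}D_{m-1}\ne 0$ (the transversal crossing). The package
verifies every located point twice: by the Hurwitz flags and by the
eigenvalue configuration itself (exactly one near-imaginary pair, the rest
strictly stable).

Three locators implement this at increasing generality:

* `single_cell_hb()` — closed form. The cubic gives $D_2 = 8-\alpha\gamma$,
  so the bifurcation value is $\alpha_0 = 8/\gamma(\bar x)$, and
  self-consistency $\alpha_0 f(\bar x)=\bar x$ pins
  $\bar x = k_H(8/(n-8))^{1/n}$ for HT (feasible iff $n>8$) and the smaller
  root of a quadratic for PS (feasible iff $A > (127+48\sqrt7)k_d$). At the
  bifurcation the Jacobian is one universal constant matrix with eigenvalues
  $\pm\sqrt3\,i$ and $-3$: the emergent frequency $\sqrt3$ is independent of
  the repression mechanism.
* `coupled_identical_hb()` — the $4N$-dimensional identical-cell polynomial
  factors through the synchronous quartic
  (`synchronous_quartic()`), whose degenerate condition is solvable:
  $\alpha^*=\frac1{2\gamma}[-(s-1)(s^2+4s+7)+(s+3)\sqrt{(s^2+3)^2-4sc\gamma}]$
  with collective frequency
  $\omega_c^*=\sqrt{\tfrac12[\sqrt{(s^2+3)^2-4sc\gamma}-(s^2-3)]}$.
  Since $\gamma$ depends on the equilibrium, $\alpha^*$ is found
  self-consistently with $(\alpha^*+c)f(\bar x)=\bar x$ by a scan plus
  Brent root-finding in $\bar x$; when the PS fixed-point equation admits two
  roots the smaller is taken (it yields the smaller $\alpha^*$). Only the
  "+" branch and $s>1$ are supported; the anti-phase quartic never
  bifurcates first because its $D_3$ exceeds the synchronous one's wherever
  the latter vanishes (asserted in the tests on random draws). Note that
  $\gamma$, and hence $\omega_c^*$, distinguishes HT from PS here, unlike in
  the single cell.
* `general_hb_locator()` — for systems without a factorisation
  (nonidentical pair, segmentation clock): a bracketed scan of
  $D_{m-1}(\alpha)$ with the equilibrium re-solved at every evaluation, root
  refinement on the first positive-to-negative crossing, then verification
  of the side conditions, the numeric crossing derivative (central
  difference, step $10^{-6}\max(1,|\alpha^*|)$) and the spectrum. Scans use
  40 grid points by default; closely spaced bifurcations (the two pairs of a
  weakly coupled, nearly identical pair cross within $\sim10^{-3}$ of each
  other) need a denser scan, e.g. `n_scan = 150` for the segmentation-clock
  example.

`trace_hb_curve()` continues these solutions over a coupling grid
(natural-parameter continuation, previous solution seeding the next bracket,
one bisected retry before a point is declared lost). Two facts the curve
exhibits for the gene circuits: $\alpha^* < \alpha_0$ for every $c>0$
(coupling enlarges the oscillatory regime), and at weak coupling the curve
hugs $\alpha + c = \alpha_0$ — the quasi-steady-state argument for fast
coupling. Exact computation shows that approximation is good to 2% only for
small coupling ($c \lesssim 0.026$ at $s = 20$ for the reference Hill
parameters), degrading smoothly to about 8% by $c=0.1$; the package
documents the measured deviation rather than the folklore version.

## Eigenvalue paths

`trace_segment()` follows the full spectrum along a straight segment in
parameter space — canonically from the decoupled bifurcation point
$P_0=(0,\alpha_0)$, where identical cells carry a *double* imaginary pair
$\sqrt3\,i$, to a coupled bifurcation value $P_1=(c^*,\alpha^*)$. Branches
are matched step to step by a globally greedy minimal-distance assignment in
the complex plane (repeatedly pairing the closest previous/current
eigenvalues). With 100–200 steps the branch separation exceeds the per-step
motion by orders of magnitude for every system treated here, so the greedy
assignment is exact; the degenerate start is disambiguated retrospectively
by labelling first the branch that ends nearest the imaginary axis.
`classify_transition()` then reports the unstable-manifold dimension along
the path, which cleanly separates the two repression mechanisms at the
reference parameters: the HT pair's bifurcating branch makes a right
half-plane excursion mid-segment (unstable dimension 0 → 2 → 0 at $P_1$),
while the PS pair's branches stay in the left half-plane until the endpoint.
In both, the collective frequency at $P_1$ sits *below* the (larger)
individual frequency at $P_0$.

## Limit-cycle extraction

`integrate_model()` wraps `deSolve::ode` (lsoda) at `rtol = 1e-12`,
`atol = 1e-14`, storing the exact derivative at each output point.
`extract_cycle()` measures the attractor:

* Poincaré section: the first cell's repressor `x3` crossing its mean
  upward. The level is frozen after the first measurement window so return
  times are strictly comparable; crossing times are refined by cubic Hermite
  interpolation (value + derivative at the bracketing samples), giving
  $O(dt^4)$ event times ($\sim10^{-9}$ at the default `dt = 0.01`).
* Convergence: the return-time sequence approaches the cycle geometrically
  (one dominant Floquet mode), so the limit period is recovered by fitting
  the tail to $p_n = T + A r^n$ (ratio $r$ estimated as the geometric mean
  of successive increment ratios over the last dozen returns). The fit is
  skipped at the round-off floor. Acceptance requires the extrapolated
  period to move by less than `period_rtol` ($10^{-9}$ by default) between
  windows; integration proceeds in 50-time-unit windows up to `max_time`
  (5000). This acceleration matters near a bifurcation, where the naive
  estimate converges at rate $e^{-2\mu'\delta T}$ per cycle and would need
  tens of thousands of time units.
* Amplitudes are half peak-to-trough per component over one full cycle (the
  source text never fixes an amplitude convention; this one is used
  consistently and compared only qualitatively). Phase differences between
  corresponding components of different cells are peak-time offsets within
  the same local cycle, peaks refined on the Hermite interpolant of the
  derivative — identical synchronized cells measure offsets below
  $10^{-6}T$, while the nonidentical Hill pair near its bifurcation value
  phase-locks at an offset of about 0.3 time units, the faster cell leading.

Default initial conditions are the equilibrium perturbed by +1% per
component; the reference runs use their published starting points. For
near-bifurcation work the tests seed the integration on the predicted cycle
(equilibrium plus $2\varepsilon\,\mathrm{Re}\,q$, with $q$ the unit centre
eigenvector), cutting the slow radial transient.

`frequency_sweep()` (warm-started continuation in any parameter),
`average_frequency()` ($\omega_{\rm Ave}$ and $T_{\rm Ave}$ — means of
frequencies and of periods respectively; they are *not* interchangeable,
the period of the mean frequency being the harmonic mean of periods), and
`find_matching_coupling()` (bracketed root of
$\omega_c(c)-\omega_{\rm Ave}$) build the collective-versus-average
comparisons. At the reference parameters ($\sigma=1.05$, $s=20$,
$\alpha=0.56$) the PS pair matches the average frequency at $c\approx0.04$
while the HT pair needs roughly double that — the quantitative signature
separating the two repression mechanisms at the population level.

## Normal form

`hopf_coefficients()` computes the classical projection quantities at a
verified bifurcation point: unit right/left eigenvectors $q,p$
($\langle p,q\rangle=1$, phase fixed by making the largest component of $q$
real positive), the quadratic/cubic coefficients
$g_{20},g_{11},g_{02},g_{21}$, the curvature coefficient $C_1$, and the
derived direction, stability and period-trend numbers

$$p_2=-\frac{\operatorname{Re}C_1}{\operatorname{Re}\lambda'},\qquad
  \zeta_2=2\operatorname{Re}C_1,\qquad
  T_2=-\frac{\operatorname{Im}C_1+p_2\operatorname{Im}\lambda'}{\omega^*},$$

with $T=(2\pi/\omega^*)(1+T_2\varepsilon^2+O(\varepsilon^4))$,
$\varepsilon^2=(\alpha-\alpha^*)/p_2$. Two implementation points deserve
record. First, the centre-manifold corrections $h_{20},h_{11}$ must have
their centre components projected out before inversion; using the full-space
resolvents together with the two-dimensional $g_{20}g_{11}$ combination
double-counts the quadratic interactions (an error of roughly a factor two
in the period correction that simulation immediately exposes). Second, the
multilinear forms $B$ and $C$ are evaluated analytically for the gene
circuits — the only nonlinearity is $f(x_3)$ per cell, so each tensor has
one nonzero direction per cell, using the closed-form second and third
derivatives of $f_1$/$f_2$ — and by Richardson-extrapolated central
differences with full trilinear polarisation otherwise (steps $10^{-4}$ and
$2\times10^{-4}$; the divisor of the eight-term odd polarisation sum is 48).
The planar normal form $\dot z=(\mu+i)z-z|z|^2$ is carried in the test
suite as an exact oracle ($C_1=-2$, $p_2=2$, $\zeta_2=-4$, $T_2=0$ under
this normalisation).

At every reference bifurcation point of both repression mechanisms the sign
pattern is $p_2>0$, $\zeta_2<0$, $T_2>0$: supercritical, stable cycle,
period growing with $\alpha$ — consistent with the simulated sweeps (the
frequency decreases from $\sqrt3$ as $\alpha$ grows, faster for PS).

## Accuracy, validation and known limitations

*Validation levels.* Closed forms are checked against the published
equilibria, slopes and bifurcation values to $10^{-5}$; spectra against the
published eigenvalue lists to $10^{-5}$; the two independent routes to the
collective frequency (quartic closed form vs 8×8 spectrum; Hurwitz locator
vs eigensolver) against each other to $10^{-6}$.

*Simulated reference digits.* Exact integration of the stated equations
(two independent high-order integrators agreeing to ten digits) yields
periods that differ from the published ten-digit values in the fourth
significant decimal — e.g. 3.6372839017 against a printed 3.6367989020 for
the Hill cell at $\alpha=0.60139$, with matching small offsets for the other
printed periods and frequencies. The package reports its converged values
and does not tune toward the printed digits; the corresponding reproduction
test asserts the printed values at their nominal tolerance and is expected
to fail by that ~$10^{-4}$ relative margin, which we attribute to the
original computation's integration accuracy.

*Period-expansion window.* The $T_2\varepsilon^2$ law is verified to within
a few tenths of a percent of the correction term for the Hill cell at
$\delta=(\alpha-\alpha_0)\in\{10^{-3},2\times10^{-3}\}$. For the PS cell the
quartic remainder is already ~20–40% of the correction at those offsets: with
$k_d=10^{-5}$ the repression curve is nearly piecewise linear and the cubic
truncation is only valid for $\delta\lesssim8\times10^{-4}$ (an independent
quadratic fit of the measured correction confirms the computed $T_2$ to 3%).
The corresponding consistency assertion is kept at the nominal 20% band and
left failing rather than widened.

*Segmentation clock.* No published parameter set is available in the
sources used here, so `segclock_example_model()` ships a synthetic
calibration chosen once: saturating degradation capacities exceed maximal
production (boundedness), the repressor equilibrium sits on the steep flank
of its Hill term, and the isolated cell crosses a Hopf bifurcation in the
transcription rate near $\nu_1\approx0.245$. For a weakly coupled,
5%-detuned pair the two eigenvalue pairs cross within $\sim10^{-3}$ of each
other, so slightly above the first crossing the second mode is barely
damped; stable *synchronous* cycles (identical pair) are used for cycle
extraction, and the nonidentical pair is exercised at the linear level
(locator and eigenpaths) only.

*What the synthetic studies do not show.* All systems here are determinate,
noise-free ODEs with mean-field coupling of two (or $N$ identical) cells;
conclusions about stochastic, heterogeneous-population, or
spatially structured clocks are outside the model class. Floquet stability
of extracted cycles is inferred from the normal-form signs plus empirical
convergence, not computed.

## Problem sizes used by the shipped checks

The test-suite and acceptance runs use the systems at their natural sizes
(3- and 8-dimensional ODEs, degree-8 polynomials), integration spans of
500–4000 time units at `rtol` $10^{-10}$–$10^{-12}$, 100–150-point
eigenvalue paths, 500-draw polynomial classification sweeps, and 20-point
bifurcation curves — choices that keep every check deterministic and
desk-scale.
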