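---
title: "Stem cell dynamics from VAF spectra and single-cell mutational burdens"
author: "vafdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stem cell dynamics from VAF spectra and single-cell mutational burdens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vafdyn)
```

## The model

`vafdyn` models the accumulation of neutral somatic mutations in a
tissue-specific stem cell pool across a lifetime.  The population starts
from a single unmutated founder cell and passes through three demographic
phases:

1. **Early development** — the pool expands by symmetric growth divisions
   at per-cell rate $\gamma$; the mean trajectory is $N(t) = e^{\gamma t}$
   with $\gamma = \log(N_M)/t_M$, so the mature size $N_M$ is reached at
   age $t_M$.
2. **Mixed phase** — once the pool exceeds $N_H$ cells, homeostatic
   turnover runs alongside growth: *Moran events* (a symmetric division
   paired with a uniform cell removal, keeping the running size unchanged)
   at per-cell rate $\rho$, and *asymmetric divisions* (one stem daughter,
   one differentiated daughter) at rate $\phi$.
3. **Maturity** — from $t_M$ on, the pool size is constant and only the
   homeostatic events continue.

Every daughter cell retained in the pool acquires a
$\mathrm{Poisson}(\mu)$ number of new mutations at birth, each unique
(infinite-sites assumption).  Only symmetric divisions move variants in
frequency; both division types inject new variants.  Users supply the
total homeostatic rate $\lambda = \rho + \phi$ and the asymmetric fraction
$p = \phi/\lambda$, because the inference problem lives naturally in
$(N, p)$ space.

The package provides two independent realizations of this model — an
exact Gillespie simulation at single-cell resolution
(`simulate_population()`) and a deterministic solver for the expected
variant-allele-frequency (VAF) spectrum (`evolve_expected_vaf()`) — plus
the estimators that invert observed spectra and single-cell mutational
burdens into $(\mu, \lambda, N_M, p)$.

## The expected VAF spectrum

Writing $\kappa = fN(t)$ for the number of cells carrying a variant, the
expected spectrum $V(\kappa, t)$ (variants per unit abundance) obeys an
advection–diffusion equation with a point source at $\kappa = 1$:

$$\partial_t V = -\partial_\kappa\!\left[A V\right]
  + \partial_\kappa^2\!\left[B V\right] + C\,\delta(\kappa - 1),$$

with $A = \gamma\kappa$, $B = \kappa(1 - \kappa/N)\rho + \gamma\kappa/2$
and $C = 2\mu N (\rho + \gamma + \phi/2)$.  Growth advects variants to
larger $\kappa$, Moran turnover diffuses them, and each division injects
new variants: a symmetric division contributes two mutated daughters
($2\mu$ variants), an asymmetric one a single daughter, hence the
half-weight of $\phi$ in $C$.

We work in absolute abundance $\kappa$, not frequency, because the influx
point then stays fixed while the population grows.  Two closed-form
limits anchor the numerics:

* a **constant population** approaches the Moran equilibrium
  $V^*(k) = \mu_e N/k$, where $\mu_e$ is the mutation supply *per
  division event*; since every Moran event produces two mutated
  daughters, $\mu_e = 2\mu$ in the per-daughter units of the model, and
  the equilibrium is $2\mu N/k$ (a $1/f$ spectrum);
* a **purely growing population** follows the pure-birth expectation
  $V_k(t) = 2\mu(t+1)/(k(k+1))$ (a $1/f^2$ spectrum), available exactly
  through `pure_birth_recursion()` / `pure_birth_closed()` and proved
  stationary in shape from the very first division.

The distinction between per-daughter and per-event mutation units matters
only for the constant-population amplitude and is handled explicitly
wherever the two meet (`moran_equilibrium()` is expressed per event;
`reference_spectrum()` supplies the $2\mu$ conversion).

After maturity the spectrum relaxes from the $1/f^2$ to the $1/f$ shape
as a wave travelling from low to high frequency, and the relaxation slows
with age — `transition_profile()` exposes this, and the synthetic bulk
cohort reproduces the resulting age ordering of donor spectra.

### Numerics

The solver discretizes the equation by the method of lines on a
variable-step grid (`build_grid()`): steps grow linearly with index,
$\Delta\kappa_i = 1 + (i-1)\alpha$, with unit spacing at the influx point
and $\alpha$ fixed by the requirement that the $n-1$ steps span $[1, N]$
exactly, i.e. $\alpha = 2(N-n)/((n-1)(n-2))$.  The delta source is a step
of height $2/(\Delta\kappa_1 + \Delta\kappa_2)$ at the $\kappa = 1$ node.
Fluxes use central differences in conservative form; the boundaries at
$\kappa = 0$ and $\kappa = N$ are absorbing (variant loss and fixation),
with a purely diffusive flux across the extinction edge.  Time stepping
is adaptive implicit `lsoda` with a tridiagonal (banded) Jacobian,
relative tolerance $10^{-6}$, split at the phase-switch times so the
solver never steps across a rate discontinuity.  The default $n = 400$
changes the lowest-node value by well under 1% when doubled; the test
suite pins this refinement check, positivity, stationarity of the
equilibrium under the mature-phase flow, and agreement with
ensemble-averaged Gillespie runs (within 5% for $\kappa \le 20$ at
$N = 100$ over 2000 replicates).

One genuine continuum limitation is worth knowing: during *pure growth*
the Kramers–Moyal diffusion term $\gamma\kappa/2$ lets singleton mass
leak below $\kappa = 1$, where the discrete birth-only process loses
nothing.  The solver therefore reproduces the pure-birth *shape*
faithfully but sits at roughly three quarters of its absolute level while
growth lasts.  Homeostatic-phase amplitudes, which drive all inferences
in this package, are unaffected (the Moran equilibrium is matched to
within 1%).

### Simulator conventions

The Gillespie implementation stores the genealogy on branches (parent
link plus per-branch mutation count), so memory scales with divisions
rather than cells × mutations; burdens, spectra and sampled spectra are
recovered by tree traversal.  Two conventions are deliberate:

* **Growth is size-capped.** Growth divisions run while $N < N_M$ rather
  than while $t < t_M$.  A time-capped pure-birth phase would leave
  $N(t_M)$ geometrically distributed (coefficient of variation near 1),
  whereas the size cap lets every realization mature at exactly $N_M$,
  with the maturation *age* concentrated at $t_M$ (standard deviation
  $\approx 1.28/\gamma$).  The deterministic `rates_at()` /
  `population_size()` pair used by the PDE keeps the time-based
  three-phase schedule.
* **Moran self-replacement is allowed.** The divider and the removed cell
  are drawn independently and uniformly; with probability $1/N$ they
  coincide and the division leaves a single surviving daughter.  This
  matches the $1/N$ correction in the expected division accrual below and
  affects only $O(1/N)$ terms.

## Sampling

Sequencing a handful of cells reshapes the spectrum.  For a uniform
sample of $S$ of $N$ cells the expected sampled spectrum is the
hypergeometric mixture
$\tilde V(i) = \sum_j V(j)\,P_{\mathrm{hyp}}(i; j, N-j, S)$,
implemented stably for $N$ up to $\sim 10^6$
(`expected_sampled_vaf()`).  Sampling preserves each variant's expected
frequency but, conditional on detection, shifts it upward — ignoring the
transform inflates population-size estimates.  The mutational *burden*
distribution, by contrast, is sampling-robust: its expectation is
unchanged by subsampling, which is why burden-based estimators work with
~100 cells.

## Estimators

**Burden route.**  A cell's burden is $m = \sum_i^{y} u_i$ over the $y$
divisions in its past, so $E(m) = E(y)\,\mu$ and
$\mathrm{Var}(m) = E(y)\mathrm{Var}(u) + E(u)^2\mathrm{Var}(y)$.  With
Poisson mutations these give

* `estimate_divisions()`: $E(y) = E(m)/\mu$;
* `estimate_mu()`: $\mu = (\mathrm{Var}(m)/E(m) - 1)\cdot E(y)/\mathrm{Var}(y)$,
  with the divisions-per-lineage dispersion $\mathrm{Var}(y)/E(y) = 1$
  (Poisson divisions) as the default assumption.  Under-dispersed samples
  yield negative estimates, which are reported with a warning rather than
  clamped — they are diagnostic.

The expected divisions per lineage accrue at phase-dependent rates: both
Moran daughters stay in the pool, so Moran events add
$2\rho(1 - 1/2N)$ divisions per lineage-year and growth divisions
$2\gamma(1 - 1/(N+1))$, while asymmetric divisions add $\phi$ singly.
`expected_divisions()` integrates this by quadrature (relative tolerance
$10^{-10}$), split at the phase switches; `solve_lambda()` inverts it for
$\lambda$ by bracketed root finding ($y$ is monotone — in fact linear —
in $\lambda$), and `sweep_lambda()` propagates the unidentified geometry
$(t_M, N_H, N_M, p)$ into an interval, reported separately from the
statistical error on $E(m)$.  A printed closed form of this inversion
exists but is typographically corrupted in its source; the quadrature
plus root-find is authoritative here, and the test suite pins the
round-trip and the mature-phase limit
$\lambda \to R/((2-p)(t - t_H))$ instead.

A caveat the package tests rather than hides: within a *single*
population, shared ancestry makes burdens positively correlated and
shrinks the sample variance, biasing per-population $\hat\mu$ downward —
noticeably so at desk scales ($N_M \sim 10^3$), negligibly at
$N_M \gtrsim 10^4$.  Across independently evolved populations the pooled
burden distribution is exactly the compound Poisson
(`compound_poisson_pmf()`), and the estimator applied to pooled burdens
is unbiased; the acceptance suite uses that construction.  The burden
dispersion ratio $\theta = \mathrm{Var}(m)/E(m)$ has expectation
$1 + \mu$ under the compound model; `dispersion_probability()` measures
how often simulated populations land in an observed $\theta$ interval,
e.g. showing that $\theta \in (3, 5)$ is essentially unreachable at
$\mu = 1.3$ but common at $\mu = 3$.

**VAF route.**  `regress_mu()` estimates $\mu$ as
$\mathrm{Cov}(V_d, V_r)/\mathrm{Var}(V_r)$ against a unit-rate reference
shape; the references are the *discrete expected sampled* spectra of the
two limiting demographies (`reference_spectrum()`), not raw power laws,
so data and reference share the same support of sample frequencies and no
binning choice intrudes.  The regression support excludes frequencies
above one half and the fixed class by default.

`lattice_fit()` performs the population-size inference: for candidate
$(N_M, p)$ on a lattice it predicts the expected number of variants at
the lowest sample frequency $1/S$ (PDE $\to$ sampling transform $\to$
singleton class) and records the error against the observed count.  The
lowest-frequency class is the fitting observable because its
across-replicate coefficient of variation is the smallest of all sampled
classes (a property the test suite checks).  `zero_contour()`
interpolates the zero crossing along $\log N_M$ per $p$ (monotone spline
plus root bracketing); the crossing is unique because the predicted
singleton count increases with $N_M$.  The $p = 0$ intercept
(`max_population()`) is the largest population able to produce the data;
larger asymmetric fractions trade off against smaller pools along the
contour.  Lattice resolution, spline details and the $p$ grid are
configurable; defaults (7 log-spaced $N_M$ values, $p \in \{0, 0.25,
0.5, 0.75, 0.9\}$) recover a generating $N_M = 10^4$ within a few
percent in self-recovery runs.

## Synthetic data

`make_single_cell_dataset()` emulates the single-cell design the burden
estimators target: a population simulated to the donor age, 89 cells
sampled by default from a 59-year-old donor, written as a burden list, a
binary cell×variant matrix and a sample VAF table, with the generating
truth in a JSON manifest.  The desk-scale defaults used throughout the
tests ($N_M = 10^3$, $t_M = 5$, $\lambda = 5$, $p = 0.4$, $\mu = 1.2$)
keep runtimes in seconds while preserving every qualitative feature; the
only quantitative casualty of the reduced $N_M$ is the shared-ancestry
bias discussed above.

`make_bulk_cohort()` emulates a bulk-sequenced multi-donor cohort:
per-donor expected spectra from the PDE, realized variant counts drawn
Poisson per abundance class (independent-sites approximation — the
genealogical correlations present in real tissue are available only
through the simulator route, which is also provided), and binomial
read-depth noise.  The cohort defaults describe a fast-turnover
epithelium — maturity at 18 years, $\lambda = 10$ divisions per cell per
year — because the age ordering of spectra (young donors near $1/f^2$,
old near $1/f$ at bulk-detectable frequencies) requires homeostatic
relaxation to outpace the donors' age span; with slow turnover even old
donors retain the growth shape at measurable frequencies.

What passing tests on these synthetic data do **not** show: robustness to
sequencing artefacts beyond binomial depth noise, to copy-number or
selection effects (the model is strictly neutral), or to mutation-rate
heterogeneity across cells; real-data inferences inherit those caveats.

## Degenerate inputs and tie-breaks

Zero mutation rates, zero homeostatic rates ($\lambda = 0$), all- or
no-asymmetric splits ($p \in \{0, 1\}$) and single-donor "cohorts" are
all legal and tested.  Burden samples with zero mean have undefined
$\theta$ and count as outside any dispersion interval.  Lattice rows
whose error never changes sign yield `NA` contour points and an explicit
no-fit warning; `max_population()` falls back to linear extrapolation in
$(p, \log N_M)$ when $p = 0$ is not a lattice row.  The simulator
enforces a configurable event cap (default $10^8$) and warns when it
truncates.

## Reproducibility

All randomness flows through R's generator: every simulating function
takes a `seed` argument, identical seeds give bit-identical outputs
(including written files), and each dataset directory carries a manifest
with the resolved parameters, seed and package version.
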