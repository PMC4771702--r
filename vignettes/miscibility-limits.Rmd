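---
title: "Locating miscibility limits of chaperone-client lattice mixtures"
author: "latmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating miscibility limits of chaperone-client lattice mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(latmix)
```

## The model

`latmix` implements a minimal coarse-grained model of a protein solution
containing two explicitly modelled species: an aggregation-prone **client**
and a passive **molecular chaperone** of the small-heat-shock-protein kind
(ATP-independent, reversibly binding).  Monomers occupy sites of an
$L \times L \times L$ simple-cubic lattice with periodic boundaries; empty
sites are implicit solvent.  Each monomer is a rigid cube in one of the 24
proper rotations of the cubic group and interacts only with its six nearest
neighbours:

* every adjacent occupied pair shares an orientationally averaged
  *nonspecific* contact of dimensionless free energy $-\beta\epsilon$
  (any sign: positive $\beta\epsilon$ is attractive, negative is
  repulsive), representing screened, transient associations in a crowded
  cytosol;
* a *directional* bond of free energy $-\beta\epsilon_{xy}$ forms in
  addition when both partners present a binding patch on the shared pair of
  faces, with $xy \in \{\text{s-s}, \text{c-s}, \text{c-c}\}$ by species
  pair.  Directional interactions are always attractive
  ($\beta\epsilon_{xy} \ge 0$).

Clients carry three patches; in the reference orientation they sit on the
three mutually orthogonal faces $+x, +y, +z$.  The corner arrangement is a
package constant (swappable through `model_spec()`): the model geometry
requires *some* choice of three faces, and the orthogonal one maximizes the
client's ability to form percolating bonded networks, which is what makes
the client aggregation-prone through directional interactions alone.
Chaperones carry a single patch ($+x$ in the reference orientation),
modelling the passivation of client binding sites by burial of a
hydrophobic surface.  Any chaperone patch binds any client patch: patches
are species-typed, not site-typed.

Six dimensionless thermodynamic fields define a state point
(`field_vector()`): $\beta\epsilon$, $\beta\epsilon_{s\text{-}s}$,
$\beta\epsilon_{c\text{-}s}$, $\beta\epsilon_{c\text{-}c}$ and the two
chemical potentials $\beta\mu_s, \beta\mu_c$.  The critical surface of a
fluid with $d$ independent fields has dimension $d-2$
(`critical_surface_dimension()`), here 4.  The **miscibility limit**
$\beta\epsilon^*$ is the critical value of the nonspecific interaction at
fixed directional energies and fixed chaperone stoichiometric fraction
$x_c = \rho_c/(\rho_s+\rho_c)$: beyond it the well-mixed solution is
unstable against demixing/aggregation.

The chemical-potential convention is *activity per site per discrete
species-orientation state*: an ideal solution has site occupancy
$z\Omega/(1+z\Omega)$ with $z = e^{\beta\mu}$ and $\Omega$ the number of
orientation states.  This shifts $\beta\mu$ by a constant relative to other
conventions and leaves every quantity on the $\epsilon$ axes unchanged.

## Sampling: flat-histogram biased GCMC

Near a demixing critical point the two incipient phases are separated by a
free-energy barrier in the total density.  `build_bias()` constructs a bias
$\eta(N)$ over the total particle number $N = N_s + N_c$ by Wang-Landau
iteration (modification factor halved on flatness, default terminal
$\ln f = 10^{-4}$) followed by fixed-weight refinement passes, so that the
sampled $N$-histogram is flat and both phases are visited.  The biased
measure is $\pi \propto \exp(-E + \beta\mu_s N_s + \beta\mu_c N_c +
\eta(N))$, and every snapshot records $\eta$ so the bias cancels exactly on
reweighting.  The biasing variable is $N$ rather than the ordering operator
itself: the ordering operator is a linear combination of observables that
is recovered afterwards by reweighting, while a density-like variable is
what bridges the two phases.

Two numerical points deserve emphasis:

* **Refinement length.**  The multicanonical random walk needs
  $\mathcal{O}(W^2/D)$ sweeps to traverse a biased range of width $W$
  ($D$ accepted insert/delete events per sweep).  A refinement pass shorter
  than several traversals feeds on a single noisy excursion and *degrades*
  the weights; the default refinement length therefore scales as
  $W^2/V$, and only visited bins are updated.
* **Snapshot spacing.**  The global autocorrelation time of $N$ is of the
  order of a traversal (thousands of sweeps at $L = 12$), which is not an
  affordable snapshot spacing.  Spacing (default 40 sweeps) is instead
  chosen well above the *local* decorrelation scale: per-bin occupancy
  indicators decorrelate as soon as the walker leaves the bin
  neighbourhood, which takes a few sweeps.  The measured integrated
  autocorrelation time of $N$ is recorded in the table metadata, and the
  uncertainty on $\beta\epsilon^*$ is obtained by bootstrap over snapshots,
  not from per-sample error formulas.

Moves are paired insertion/deletion (equal probability, exact detailed
balance against the proposal measure: uniform site $\times$ species ratio
$\times$ uniform orientation for insertion, uniform occupied site for
deletion), nonlocal translation (uniform destination, which decorrelates
dilute configurations quickly) and rotation, in a 40/40/20 mix.  The
compiled inner loop draws from an internal xoshiro256+ generator seeded
from R's RNG stream, so `set.seed()` fixes the complete seed chain.

Snapshots store the particle numbers and the four contact counts
$(n_{\rm iso}, n_{ss}, n_{cs}, n_{cc})$, from which the energy is exactly
reconstructible at *any* field vector; `reweight()` therefore maps a single
run to nearby state points with per-snapshot weights
$w_v \propto \exp[\Delta\beta\epsilon\, n_{{\rm iso},v} + \dots +
\Delta\beta\mu_s N_{s,v} + \Delta\beta\mu_c N_{c,v} - \eta_v]$ and reports
the effective sample size $\mathrm{ESS} = (\sum w)^2 / \sum w^2$.

## Locating the critical point

The mixed-field finite-size-scaling ansatz defines the ordering operator

$$ \mathcal{M} = \nu_s \rho_s + \nu_c \rho_c - s\,u, $$

a linear combination of the two number densities and the energy density
$u = U/V$.  At a critical point the distribution of
$\delta\mathcal{M} = \Lambda(\mathcal{M} - \mathcal{M}^*)$ collapses onto
the universal ordering distribution $p^*$ of the 3D Ising class.  The
package ships $p^*$ as the exponential-of-quartic parametric form
$p(y) \propto \exp[-(y^2-1)^2(a y^2 + c)]$ with $a = 0.158$, $c = 0.776$,
rescaled by quadrature to unit integral and unit variance
(`ising_ordering_density()`); its normalization, symmetry and bimodality
are asserted in the test suite.

`find_critical_point()` solves the self-consistency by iterating

1. build/refresh the bias at the trial fields and collect a biased sample;
2. minimize the matching objective over
   $(\beta\epsilon, \beta\mu_s, \beta\mu_c, \hat\nu, s)$ by reweighting;
3. move the fields to the optimum and re-simulate,

until $\beta\epsilon^*$ moves by less than `tol` (default 0.005) between
outer iterations.  Within step 2 the fit is staged for robustness:
the ordering distribution is first *symmetrized* by root-finding the zero
of its skewness along the chemical-potential direction; a bracketed 1-D
search in $\beta\epsilon$ (nested over the symmetrization) then finds the
matching coupling; a constrained simplex finally releases the remaining
mixing freedom ($\hat\nu$ direction, $s$, composition offset
$\beta\mu_c - \beta\mu_s$).  Three safeguards matter:

* $\Lambda$ is not a free parameter: it is profiled out self-consistently
  as the inverse weighted standard deviation of $\mathcal{M}$ (the value
  that maps the sampled fluctuations onto the unit-variance universal
  form).  Leaving it free is degenerate -- the scale trades off against the
  histogram support.
* the fit is confined to an ESS trust region (at least half the ESS at the
  generating fields): outside it the error bars inflate until *any* shape
  is consistent with $p^*$ and the objective is pure noise.  Long-distance
  travel through field space is the outer loop's job, one re-simulation at
  a time.
* the $\hat\nu$ gauge is fixed to unit Euclidean length with
  $\nu_s \ge 0$; the scale freedom of $\hat\nu$ is absorbed by $\Lambda$
  and the joint sign flip $(\hat\nu, s) \to (-\hat\nu, -s)$ leaves the
  distribution invariant.

**Histogram convention.**  Bins of width $L^{-3}$ are laid in
$m = \mathcal{M} - \mathcal{M}^*$ -- the natural granularity of the
density-like part of $\mathcal{M}$ -- centred on the weighted mean, and the
bin masses are normalized to unit total; the universal prediction for a bin
is $p^*(\Lambda m_k)\,\Lambda L^{-3}$.  $\Lambda$ thus enters exactly twice
(argument scale and Jacobian).  The per-bin error estimate is the printed
formula $\sigma_k^2 = [\sum_v w_v^2 1_{k,v} - (\sum_v w_v 1_{k,v})^2/n] /
\sum_v w_v$ (`histogram_error()`); with weights normalized to unit sum it
is exactly the sampling variance of the bin mass, which is the
normalization `chi_squared()` uses.

**Objective vs. reported statistic.**  The reported matching statistic is
the chi-squared sum $\sum_k [p_k - p^*_k]^2/\sigma_k^2$ over well-sampled
bins (effective occupancy at least `n_eff_min = 8`; near-empty bins are
excluded as sampling-limited, and their count reported) plus the
composition constraint $\sum_i [\langle\rho_i\rangle/\phi - x_i]^2 /
\sigma_i^2$ with $\sigma_i^2$ the printed quadratic form of the density
covariance (`composition_error()`).  The *numerical minimization*, however,
uses a Poisson-deviance $G$-statistic on effective counts
($O_k = \mathrm{mass}_k \cdot \mathrm{ESS}$ against
$E_k = q_k \cdot \mathrm{ESS}$).  The two agree asymptotically where both
are valid, but the chi-squared form is unusable as an objective: in bins
with few effective samples the estimated $\sigma_k^2$ is itself noise and
single terms can dominate by twelve orders of magnitude, while bins whose
weights underflow to zero drop out silently -- which would let a deep
two-phase trial point match only its two peaks and hide the valley.  The
deviance charges an interior hole its full expected count ($2E_k$) and
remains smooth everywhere, and the minimization uses its per-dof reduction
because the occupied-bin count varies with the trial mixing parameters.

**Composition control.**  For mixtures the printed composition-error
variance is a population quantity and far too permissive to steer a fit,
so the solver enforces the target $x_c$ actively: the chemical-potential
difference $\beta\mu_c - \beta\mu_s$ is root-found against the target
inside the staged fit, the fitting objective charges composition error on
a fixed 0.02 scale (which also rejects branches of the critical line whose
composition cannot be brought on target), and the outer loop applies a
mass-action correction to $\beta\mu_c$ between simulations.  The
*reported* statistics keep the printed forms, and the solved point is
checked to sit within $2\sigma_i$ of the target composition.  Surface
scans are seeded from the client-only instability (the calibration end
point): a blind start at the $\beta\epsilon_{c\text{-}s}=0$ corner can
land on the ordinary condensation branch instead of the bond-driven
demixing branch.

Non-converged solves (the outer loop oscillating at its resolution limit
rather than meeting the tolerance) report the mean of the last few outer
iterations with the full tail scatter folded into the quoted error; at
small $L$ this is the better estimator and the more honest uncertainty.
Even so, repeated solves of the same $L = 6$ mixture cell across seeds
scatter by roughly 0.1 in $\beta\epsilon^*$ -- between-run
bias-construction noise that no single run can estimate from within --
so comparisons between such cells should not trust per-cell errors below
that scale.

Single-species systems (the lattice-gas limit used for calibration and
validation) fix $\hat\nu$ to the density axis and drop the composition
term.  The solved point is returned with a bootstrap standard error on
$\beta\epsilon^*$, the achieved composition and its $\sigma_i$, the final
chi-squared per degree of freedom (flagged non-converged above
`chi2_dof_max`), the skewness of the matched distribution, and full
provenance (seed, schedules, package version).

## Observables and scans

`chaperone_dimer_probability()` computes the critical-ensemble average
$\langle p_{c\text{-}c}\rangle^* = \langle 2 n_{cc}/N_c \rangle^*$, the
probability that a chaperone binding interface is buried in a
chaperone-only dimer.  Snapshots with $N_c = 0$ are excluded (the ratio is
undefined) and their weight fraction reported.

`scan_critical_surface()` maps $\beta\epsilon^*(x_c,
\beta\epsilon_{c\text{-}s})$ with warm starts between neighbouring cells
and per-cell checkpointing; the chaperone-interaction mode is either
promiscuous ($\beta\epsilon_{c\text{-}c} = \beta\epsilon_{c\text{-}s}$,
chaperones treat their own binding interfaces like client surfaces) or
disabled ($\beta\epsilon_{c\text{-}c} = 0$).  `response_function()` forms
the finite-difference response maps $\partial\beta\epsilon^*/\partial x_c$
and $\partial\beta\epsilon^*/\partial\beta\epsilon_{c\text{-}s}$ (central
differences in the interior, one-sided at edges, errors propagated), and
`design_window()` operationalizes the optimal-chaperone criterion: per
$x_c$, the interval of binding strengths where both response functions
exceed 80% of their column maximum, compared against the interval where
$\langle p_{c\text{-}c}\rangle^*$ exceeds the same quantile.

The client-client bond strength for mixture scans is not a free guess: the
model is meant to describe clients that aggregate through directional
interactions alone, i.e. $\beta\epsilon^* < 0$ for the client-only
solution.  `calibrate_ss()` scans $\beta\epsilon_{s\text{-}s}$ upward and
returns the first value that drives the client-only miscibility limit
negative; that calibrated value is the default operating point for the
surface scans.

## Validation oracle

`enumerate_grand_partition()` enumerates the truncated grand-canonical
ensemble exactly on tiny open-boundary lattices (every placement of at most
$N_{\max}$ monomers $\times$ 24 orientations $\times$ species), sharing the
compiled energy kernel with the engine so that agreement tests isolate
sampling correctness.  Open boundaries avoid the double-bond artifact of
periodic $L \le 2$ lattices.  The neglected tail mass is bounded by an
ideal-gas estimate and reported.  `validate_sampler()` runs the engine on
the identical capped system and compares $\langle N_s\rangle$,
$\langle N_c\rangle$, $\langle U\rangle$, $\langle n_{cc}\rangle$ and the
full $p(N)$ within three batch-means standard errors.  Because the engine
is capped at the same $N_{\max}$, both sides sample exactly the same
truncated ensemble and the comparison is unbiased by truncation.

## Problem sizes and defaults

Production solves use $L = 12$ (a single size in the scaling regime; no
multi-$L$ extrapolation, no corrections-to-scaling terms).  The default
biased range covers $N \in [0.02V, 0.98V]$; the default production
schedule per outer iteration is 12,000 snapshots at 40-sweep spacing after
2,000 sweeps of burn-in, and the bias build runs Wang-Landau to
$\ln f = 10^{-4}$ plus two refinement passes of $\sim 50 W^2/V$ sweeps.
Scaled-down studies of the full mixture surface (the qualitative
miscibility-limit and design-window trends) run at $L = 6$-$8$ with
proportionally lighter schedules: the trends are robust to size at the
qualitative level, while quantitative values at these sizes carry visible
finite-size corrections -- which is also why the matched chi-squared per
dof grows above 1 as $L$ shrinks (corrections to scaling deform the
finite-$L$ ordering distribution away from the asymptotic universal form).

## Known limitations

* Single lattice size: apparent critical couplings carry an $L$-dependent
  shift; the package reports apparent values at the requested $L$.
* The parametric $p^*$ is a fit to the universal distribution, not an
  exact function; its parameter uncertainty is negligible against the
  Monte Carlo error at these problem sizes.
* Bootstrap uncertainties treat snapshots as exchangeable; residual
  correlation at the chosen spacing makes them mildly optimistic.
* No cluster moves and no parallel tempering: deeply bonded networks
  (very large $\beta\epsilon_{s\text{-}s}$) relax slowly, and the
  calibration utility is the intended way to choose a workable bond
  strength.
* No kinetics: Monte Carlo trajectories carry no dynamical meaning; the
  package addresses thermodynamic stability only.
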