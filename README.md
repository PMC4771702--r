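# latmix

Miscibility limits of chaperone–client lattice mixtures.

## The problem

Passive molecular chaperones — small heat-shock proteins and their
relatives — bind aggregation-prone client proteins reversibly, without ATP,
and keep the cytosol soluble even at strongly sub-stoichiometric
concentrations.  `latmix` implements a minimal statistical-mechanical model
of this situation and the machinery to compute its central quantity: the
**miscibility limit** βϵ\*, the critical strength of nonspecific
protein–protein attraction beyond which a well-mixed chaperone–client
solution becomes thermodynamically unstable and demixes/aggregates.  The
package is for computational biophysicists who want a working, tested
implementation of grand-canonical lattice criticality located by
finite-size scaling — applied here to chaperone design questions: how does
βϵ\* respond to the chaperone–client binding strength βϵ<sub>c-s</sub> and
the chaperone stoichiometric fraction x<sub>c</sub>, and where is the
binding-strength "design window" that maximizes both responses?

## The model and method

Two species on an L×L×L periodic cubic lattice, each in one of the 24 cube
orientations: three-patch **clients** (directional bond −βϵ<sub>s-s</sub>
between facing patches) and single-patch **chaperones**
(−βϵ<sub>c-s</sub> to client patches, −βϵ<sub>c-c</sub> to other
chaperones).  Every adjacent pair also shares an orientationally averaged
nonspecific contact −βϵ of either sign.  The six thermodynamic fields are
(βϵ, βϵ<sub>s-s</sub>, βϵ<sub>c-s</sub>, βϵ<sub>c-c</sub>, βμ<sub>s</sub>,
βμ<sub>c</sub>); the critical surface has dimension 6 − 2 = 4.

Criticality is located by Wilding–Bruce mixed-field finite-size scaling:
flat-histogram (Wang–Landau + refinement) biased grand-canonical Monte
Carlo samples both incipient phases; the ordering operator

    M = ν_s ρ_s + ν_c ρ_c − s·u

mixes the number densities and energy density, and the fields and mixing
parameters (ν̂, s, Λ) are tuned — by histogram reweighting inside a
simulate → fit → re-simulate loop — until the scaled distribution of
δM = Λ(M − M\*) matches the universal 3D-Ising ordering distribution
p\*(δM) under a composition constraint on x<sub>c</sub>.  A brute-force
truncated grand-canonical enumeration oracle on tiny open lattices
validates energies, sampling, and reweighting exactly.

## Worked example

Locate the miscibility limit of the fully passivated limit of the model —
the single-species, patch-free lattice gas — at L = 8, then compare with
the known simple-cubic lattice-gas critical coupling 4·K<sub>c</sub> ≈
0.8867:

```r
library(latmix)
set.seed(42)
cp <- find_critical_point(
  fixed = list(beta_eps_ss = 0, beta_eps_cs = 0, beta_eps_cc = 0),
  L = 8, species = "client",
  schedule = list(burnin = 2000, n_samples = 8000, spacing = 40))
print(cp)
```

```
critical point (L = 8, species = client)
  beta_eps* = +0.8838 +/- 0.0011
  nu = (1.000, 0.000), s = +0.0029, Lambda = 4.95
  chi2/dof = 0.82 (307 bins, 189 excluded), ESS = 5132 of 8000
```

`beta_eps*` is the apparent critical nonspecific attraction at this
lattice size (dimensionless, in units of k<sub>B</sub>T), a few parts per
thousand from the known infinite-volume value; the energy-mixing
parameter s is consistent with zero (particle-hole symmetry of the
lattice gas), the matched ordering distribution is symmetric (skewness
0.005), and the fit residual against the universal Ising form is
χ²/dof ≈ 0.8.  The `excluded` count is near-empty tail bins outside the
matching sum.

A mixture point works the same way through `fixed = list(beta_eps_ss =
…, beta_eps_cs = …, beta_eps_cc = …, x_c = …)` with `species = "both"`;
`scan_critical_surface()` maps βϵ\*(x<sub>c</sub>, βϵ<sub>c-s</sub>) grids
with warm starts, `response_function()` and `design_window()` derive the
chaperone-design readouts, and `chaperone_dimer_probability()` gives the
critical-ensemble probability ⟨p<sub>c-c</sub>⟩\* = ⟨2n<sub>cc</sub>/N<sub>c</sub>⟩\*
that a chaperone interface is buried in a chaperone dimer.
`calibrate_ss()` chooses the client–client bond strength so that the
client-only solution aggregates at negative βϵ, the regime the model is
meant to describe.  See the vignette in `vignettes/` for the method,
conventions, parameter defaults and limitations.

A thin command-line front end is installed at
`system.file("cli", "latmix", package = "latmix")` with subcommands
`simulate`, `critical`, `scan`, `validate` and `calibrate-ss`, driven by
strictly validated YAML configurations.

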