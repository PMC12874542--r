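---
title: "Effective-medium analysis of holographic binding assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effective-medium analysis of holographic binding assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holoassay)
```

## The measurement problem

Holographic particle characterization reports, for every colloidal bead
that transits the instrument, a diameter $d_p$ (with nanometer-scale
precision) and a refractive index $n_p$. When macromolecules bind to a
bead's surface they form a molecular coating a few nanometers thick, and
the bead's *apparent* diameter grows. The growth is not simply twice the
layer thickness, because the layer is mostly solvent: its optical
contrast is diluted. holoassay implements the chain of models that turns
measured diameter shifts into physically meaningful coating properties,
and the population-level workflow that turns per-particle tables into
binding calls with honest uncertainties.

## Optical model of a thin molecular coating

A substrate bead of index $n_0$ in a medium of index $n_m$ carries a
coating of thickness $a_c$ whose effective index is $n_c$. For thin
coatings the apparent diameter change is

$$\Delta d_p = 2 a_c \, \frac{n_c - n_m}{n_0 - n_m}.$$

An index-matched layer ($n_c = n_m$) is invisible; a layer on a
low-contrast substrate (small $n_0 - n_m$) produces a *larger* apparent
shift, which is why silica-core probe beads respond more strongly than
polystyrene ones to the same analyte.

The coating is a two-phase mixture of macromolecules (intrinsic index
$n_1$, volume fraction $\phi_c$) and medium. Maxwell Garnett
effective-medium theory links them through the Lorentz–Lorenz
polarizability-contrast function $L(m) = (m^2-1)/(m^2+2)$:

$$L\!\left(\frac{n_c}{n_m}\right) = \phi_c\, L\!\left(\frac{n_1}{n_m}\right)
\quad\Longleftrightarrow\quad
n_c = n_m\sqrt{\frac{1 + 2\phi_c L_1}{1 - \phi_c L_1}},$$

with $L_1 = L(n_1/n_m)$. The explicit square-root form is the exact
inverse of the mixing rule: `mg_effective_index()` and
`mg_volume_fraction()` are mutual inverses to machine precision, which
the test suite asserts at $10^{-12}$ across the full range of $\phi$.

For a *grafted* coating the volume fraction is tied to the grafting
density $\Gamma_c$ (chains per nm$^2$) by mass conservation,
$\phi_c = v_s \Gamma_c / a_c$, where $v_s$ is the optical specific
volume of one chain (nm$^3$). Eliminating $n_c$ and $\phi_c$ yields a
closed-form constraint on $(\Gamma_c, a_c)$ given a measured shift:

$$\Gamma_c(a_c \mid \Delta d_p) = \frac{x}{v_s L_1}\,
\frac{a_c^2 + x a_c}{\tfrac{3}{4} a_c^2 + x a_c + x^2},
\qquad x = \frac{1}{4}\left(\frac{n_0}{n_m} - 1\right)\Delta d_p.$$

This is an exact algebraic identity, not an approximation: the tests
verify agreement with a brute-force numerical inversion of the three
underlying relations to better than $10^{-9}$ relative error over a
$20\times20$ grid of $(a_c, \Delta d)$, excluding corners where the
implied $\phi_c$ exceeds 1 (there both the closed form and the oracle
are flagged infeasible — the measured shift cannot be produced by any
physical coating of that thickness).

## Closing the system: brush scaling and the anchor correction

One measured shift cannot fix two unknowns. For a polymer brush the
second relation is the Gaussian-brush scaling law

$$a_c(\Gamma_c) = \left(\tfrac{1}{6}\, l^2 v_s \Gamma_c\right)^{1/3},$$

where $l$ is the chain contour length (incremental length per monomer
times monomer count). `solve_grafting()` returns the intersection of the
two curves.

Diblock-anchored brushes add a subtlety: each chain buries an anchor
block (mass $m_{PS}$, bulk density $\rho_{PS}$) *inside* the substrate
bead, swelling its diameter by
$\Delta d_0 = 2 \Gamma_c\, m_{PS}/\rho_{PS}$ (thin-shell volume
conservation, with the mass-to-volume conversion handled by a single
unit helper). The optical inversion must therefore run on
$\Delta d_p - \Delta d_0(\Gamma_c)$, which depends on the answer. The
solver iterates: correct the shift with the current $\Gamma_c$, re-solve
the intersection by bracketing + Brent root search on
$a_c \in [0.01, 1000]$ nm (tolerance $10^{-12}$ nm), and repeat until
$\Gamma_c$ moves by less than $10^{-12}$ nm$^{-2}$ (at most 100
iterations; in practice the correction is ~20% of the signal and the
fixed point converges in a handful of steps). Parameter-recovery tests
confirm that forward-modeling any ground truth
$\Gamma_c \in [0.01, 0.2]$ nm$^{-2}$ and re-solving recovers it to
$10^{-6}$ relative error.

```{r graft}
constants <- optical_constants(n0 = 1.6019, nm = 1.340, n1 = 1.470)
brush <- brush_parameters(mw_coat = 34, monomer_mass = 44,
                          increment = 0.28, r_g = 9.1,
                          m_ps = 3.8, rho_ps = 1.05, v_s = 44.5)
solve_grafting(3.3, constants, brush)
```

### Uncertainty propagation

The curve-intersection construction does not come with an analytic
error estimate, so `propagate_uncertainty()` resamples the measured
shift, both relevant indices, and the specific volume from independent
normals (a stated modeling choice — correlations between the inputs are
not modeled), re-solves for each draw, and reports sample standard
deviations. The seed is an explicit argument and the output records the
method, so reports remain audit-able. Infeasible draws are dropped and
counted.

### Brush diagnostics

The mean in-plane spacing between grafting points is
$\Gamma_c^{-1/2}$. When it is strictly smaller than the coil's radius
of gyration $R_g$ the chains stretch into a brush; at equality or above
they remain isolated mushrooms. The tie goes to "mushroom" — when
claiming a coating is protective, the conservative label is the safer
error. $R_g$ is a supplied parameter (default 9.1 nm for a 34 kDa PEO
coil), not computed from a model.

## Optical specific volume from refractometry

$v_s$ enters every grafting result, and is itself measurable optically.
For a polymer solution the same mixing rule applies with the solution
index $n$ in place of $n_c$ and $\phi = c\,v_s$, $c$ being the
*molecular number density*. The package converts mass concentrations
(g/cm$^3$ or % w/v) to molecules/nm$^3$ in one unit helper, inverts each
reading to $\phi$, and fits $\phi$ against $c$ by least squares
*through the origin* — zero concentration forces $\phi = 0$ physically,
so a free intercept would only absorb noise. A free-intercept refit runs
as a diagnostic and warns when its intercept strays beyond two standard
errors (with seven-point series this trips occasionally by chance; it is
a flag, not a failure). Readings above the pure-polymer index $n_1$ are
physically impossible and are excluded with a message; readings slightly
below $n_m$ (refractometer noise near zero concentration) clamp to
$\phi = 0$.

Across molecular weights, $v_s$ grows linearly; a weighted fit
(weights $1/\mathrm{se}^2$) of $v_s$ on $m_w$ gives the differential
specific volume $dv_s/dm_w$ (nm$^3$/kDa), from which
`specific_volume_at()` predicts $v_s$ for any chain length. The
synthetic generator mirrors the laboratory design — stock at 40% w/v,
serial two-fold dilutions, five molecular weights from 1.5 to 20 kDa —
and noiseless end-to-end recovery of the generating slope to $10^{-9}$
relative error is part of the acceptance suite.

## The multi-population assay workflow

A test kit mixes several optically distinguishable bead types: probe
beads functionalized with binding sites and inert, brush-passivated
reference beads. One holographic measurement characterizes all of them
at once; populations are separated afterwards in the $(d_p, n_p)$ plane.

- **Gating.** Axis-aligned rectangles (closed lower edge, open upper
  edge) assign each particle to at most one population; gates must be
  pairwise disjoint, so gating is a partition and counts are conserved.
  Rectangles mirror laboratory practice; no density-based clustering is
  attempted.
- **Drift correction.** Run-to-run instrumental offsets (up to ~5 nm in
  diameter) are shared by every bead in a run. The deviation
  $\delta d_p$ of the reference population's mean from its pooled
  ground-truth value is subtracted from all diameters in that run. The
  reference lands exactly on its ground truth by construction; every
  *other* population inherits the reference's sampling noise, which is
  propagated into the pooled standard error in quadrature with run-size
  weights. Runs without a reference population cannot be corrected and
  are dropped with a message.
- **Replicate consistency.** Two-sample Kolmogorov–Smirnov tests run on
  every pair of replicates; a replicate is discarded only when it
  rejects against a strict majority of its peers, so one bad run cannot
  poison the tests among good ones. When drift correction is active the
  replicates are mean-centered first: residual sub-nanometer mean jitter
  is already accounted for in the propagated error, and letting the KS
  test re-detect it would double-count the same noise and discard
  healthy runs. Without a reference the raw diameters are compared, so
  uncorrected drift is caught.
- **Pooling and calls.** Retained replicates are concatenated at the
  particle level; $\Delta d_p$ is the difference of pooled means
  (reported in nm) with quadrature errors. The binding call uses a
  $k\sigma$ rule ($k = 3$ by default): positive above $+k\,\mathrm{se}$,
  negative within $\pm k\,\mathrm{se}$, and *indeterminate* below
  $-k\,\mathrm{se}$ — apparent shrinkage is unphysical for binding and
  deserves a QC flag rather than a call.
- **Layer thickness.** When an effective index for the bound-analyte
  layer is configured, the shift inverts to a thickness through the
  coated-sphere relation. That index is generally not measured; treating
  it as a config parameter makes the assumption explicit.

## What the synthetic generator does and does not emulate

`generate_run()` draws each population's diameters and indices from
normals (means, 2% diameter polydispersity, index spread 0.005 by
default), applies one uniform-law offset per run (bounded by 5 nm in
diameter and 0.003 in index), and stamps per-particle uncertainty
columns. `generate_assay_experiment()` adds binding shifts to targeted
populations through the coated-sphere forward model and records every
truth in a manifest. Defaults place three populations at diameters
0.9920, 1.0436 and 1.3476 µm; the silica index default of 1.43 is a
typical colloidal-silica value chosen for the generator, not a measured
property. Distributions are normal because population summaries are
reported as mean/sd/sem; no lognormal option is provided.

The generator is forward-only and shares no code path with any
inversion, so recovery tests are genuine. It does **not** emulate:
non-Gaussian diameter tails, aggregates and doublets, flow- or
size-dependent detection efficiency, per-particle measurement-error
correlation with size, or buffer-composition effects on $n_m$. Passing
tests therefore demonstrate correctness of the *analysis* under the
stated statistical model, not robustness to every artifact of real
instrument data.

## Numerical and design choices

- All module-internal lengths are nm, volumes nm$^3$; particle tables
  carry µm and convert at the reporting boundary, in one place.
- Constants are taken as given at the instrument wavelength; no
  dispersion modeling. The specific volume is assumed transferable
  across wavelengths.
- The thickness root is bracketed in $[0.01, 1000]$ nm; the grafting
  constraint is evaluated in an unchecked form at bracket endpoints
  (where implied $\phi_c$ may legitimately exceed 1) and feasibility is
  enforced at the solution.
- The joint-solve convergence criteria ($10^{-12}$ on both the root and
  the fixed point) are far below measurement noise; they cost a few
  iterations and make the determinism tests exact.
- Test problem sizes: coverage properties use 100 seeded experiments of
  3 pre + 3 post runs with 3000 particles each; KS type-I control uses
  200 null simulations of three 1000-particle replicates; Monte-Carlo
  checks use 1500–2000 draws. These sizes give stable pass/fail margins
  for the properties being asserted.

## Known limitations

- The effective-medium coating model ignores the radial density
  gradient of a real brush and therefore tends to underestimate the
  physical brush extent; orthogonal (e.g. electrokinetic) estimates of
  brush thickness can come out larger for that reason.
- The Gaussian-brush scaling law is a scaling relation; its $1/6$
  prefactor is part of the model definition here, validated against the
  reference working point rather than derived from first principles.
- Uncertainty propagation assumes independent normal input errors.
- The analyte-layer effective index used for thickness conversion is a
  configuration input; reported thicknesses inherit its uncertainty
  without quantifying it.
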