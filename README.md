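# holoassay

Effective-medium analysis for label-free, bead-based molecular binding
assays read out by holographic particle characterization.

Holographic microscopy measures the diameter d<sub>p</sub> and refractive
index n<sub>p</sub> of every colloidal bead in a sample with nanometer and
part-per-thousand precision. When analyte molecules bind to a
functionalized probe bead they form a molecular coating that increases
the bead's apparent diameter by a few nanometers. This package is for
people who run or develop such assays and need to turn per-particle
characterization tables into physical coating properties and defensible
binding calls: assay developers characterizing polymer-brush-passivated
reference beads, and analysts processing multi-population immunoassay
kits with internal negative controls.

## The models at the core

A coating of thickness a<sub>c</sub> and effective index n<sub>c</sub> on
a substrate of index n<sub>0</sub> in a medium of index n<sub>m</sub>
shifts the apparent diameter by

    Δd_p = 2 a_c (n_c − n_m) / (n_0 − n_m)

The coating is macromolecules (intrinsic index n<sub>1</sub>) at volume
fraction φ<sub>c</sub> mixed with medium; Maxwell Garnett theory gives
L(n<sub>c</sub>/n<sub>m</sub>) = φ<sub>c</sub> L(n<sub>1</sub>/n<sub>m</sub>)
with the Lorentz–Lorenz factor L(m) = (m² − 1)/(m² + 2). For a grafted
brush, φ<sub>c</sub> = v<sub>s</sub> Γ<sub>c</sub>/a<sub>c</sub> ties the
optics to the grafting density Γ<sub>c</sub> and per-chain specific
volume v<sub>s</sub>. One measured shift then constrains
Γ<sub>c</sub>(a<sub>c</sub>), and intersecting that constraint with the
Gaussian-brush scaling law
a<sub>c</sub> = ((1/6) l² v<sub>s</sub> Γ<sub>c</sub>)<sup>1/3</sup>
(contour length l) pins both unknowns — after a self-consistent
correction for the diblock anchor volume buried in the substrate,
Δd<sub>0</sub> = 2 Γ<sub>c</sub> m<sub>PS</sub>/ρ<sub>PS</sub>.

The package also estimates v<sub>s</sub> and its molecular-weight slope
dv<sub>s</sub>/dm<sub>w</sub> from refractometer dilution series (same
mixing rule, φ = c v<sub>s</sub>), and implements the population
workflow: rectangular gating in the (d<sub>p</sub>, n<sub>p</sub>) plane,
Kolmogorov–Smirnov replicate-consistency checks, particle-level pooling,
reference-bead drift correction with full error propagation, kσ binding
calls, and a forward-only synthetic-data generator for validation.

## Worked example

Characterize a PEO-grafted polystyrene reference bead from its measured
3.3 nm diameter increase after functionalization:

```r
library(holoassay)

constants <- optical_constants(n0 = 1.6019, nm = 1.340, n1 = 1.470,
                               sigma_nm = 0.001, sigma_n1 = 0.005)
brush <- brush_parameters(mw_coat = 34, monomer_mass = 44, increment = 0.28,
                          r_g = 9.1, m_ps = 3.8, rho_ps = 1.05, v_s = 44.5)
sol <- propagate_uncertainty(3.3, 0.3, constants, brush, sigma_v_s = 0.1,
                             n_draws = 2000, seed = 1)
sol
#> Coating solution (effective-medium + brush scaling):
#>   grafting density Gamma_c = 0.0595 +/- 0.0059 nm^-2
#>   coating thickness a_c    = 27.44 +/- 0.9 nm
#>   volume fraction phi_c    = 0.0965
#>   effective index n_c      = 1.3523
#>   anchor shift delta_d0    = 0.715 nm (of 3.300 nm measured)
```

About 0.06 chains per nm² form a 27 nm layer that is 90% solvent; its
effective index (1.352) barely exceeds the medium's, which is why a
27 nm brush reads as only a ~2.6 nm optical shift (plus 0.7 nm of
substrate swelling from the embedded anchors). The chain spacing
confirms a true brush:

```r
brush_diagnostics(sol$gamma_c, brush)
#> mean chain separation: 4.10 nm (brush regime)
```

Run a synthetic three-population immunoassay — probe beads receive a
forward-modeled 13 nm analyte layer, reference beads stay inert, and
every run gets an instrumental drift offset up to 5 nm:

```r
kit_exp <- generate_assay_experiment(
  default_kit(), run_drift_spec(),
  binding = list(binding_spec("ps_probe",
    optical_constants(1.6019, 1.340, 1.54), a_c = 13, n_c = 1.50)),
  n_particles = 3000, seed = 42)
res <- run_assay(kit_exp$pre, kit_exp$post, default_gates(),
                 reference = "reference", ground_truth_d = 1.3476)
res
#> Holographic binding assay result (call threshold 3 se, KS alpha 0.01):
#>    population     d0_um        delta_dp     call
#>      ps_probe 0.9914798 16.3 +/- 0.9 nm positive
#>  silica_probe 1.0429062  0.7 +/- 0.9 nm negative
#>     reference 1.3476000  0.0 +/- 0.7 nm negative
#> Reference drift correction applied to 6 run(s).
```

The injected ground-truth shift is 15.9 nm; the pipeline recovers
16.3 ± 0.9 nm and calls it positive, the untargeted silica population
and the reference are negative, and the reference-corrected baseline
sits exactly on its ground truth.

A thin command-line wrapper over these functions is installed at
`inst/cli/holoassay.R` with subcommands `simulate`, `graft`, `dvdm` and
`assay` (see the script header for usage).

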