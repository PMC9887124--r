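# khmd — coarse-grained Kim–Hummer dynamics for protein binding ensembles

`khmd` is an R package for simulating how folded protein domains find and
bind each other, at the resolution structural biologists use when the
question is *where does it bind and how strongly — not what happens to every
side chain*.  It was built for branch-junction-style problems — a ligand
helix searching a large rigid complex, actin-like subunits stacking on a
filament stub, disordered linkers delivering cargo — but the machinery is
generic: any mix of rigid domains and flexible chains at Cα resolution.

## The model

Each residue is one bead at its Cα position.  Non-bonded beads interact
through a signed Lennard-Jones-type potential with strengths rescaled from
the Miyazawa–Jernigan contact-energy matrix in the Kim–Hummer model-A
convention,

    ε_ij = λ (e_ij − e0),   λ = 0.159,  e0 = −1.36 kcal/mol,

(negative ε = attractive LJ well of depth |ε|; positive ε = purely
repulsive branch), plus Debye–Hückel electrostatics
`u = C q_i q_j exp(−r/ℓ_D) / (D r)` with dielectric D = 80 and screening
length ℓ_D = 10 Å, truncated at 3σ and 35 Å respectively.  Flexible
residues are joined by stiff springs `u = k (r − r0)²` with r0 = 3.81 Å and
k = 189 kcal/(mol Å²); folded domains are quaternion rigid bodies whose
internal interactions are excluded.  Dynamics is BAOAB Langevin (dt 10 fs,
damping time 1,000 fs) with temperature replica exchange over a geometric
ladder (28 rungs, 180–540 K by default, swaps every 100 steps).  Binding
ensembles are analysed with interface-pair dRMS against a reference
complex (pairs within 10 Å of the reference interface), cross-group
binding energies, 2D occupancy histograms and hotspot summaries.

## Worked example

Two rigid α-helices with a designed complementary interface (the shipped
synthetic binding-pair fixture), simulated for a short stretch at 300 K
from the bound dock:

```r
library(khmd)

bp <- make_binding_pair()                  # topology + bound reference
pairs <- select_interface_pairs(bp$reference, "A", "B")
nrow(pairs)                                # interface pairs within 10 Å
#> [1] 40
binding_energy(bp$topology, bp$bound_positions, "A", "B")
#> # A tibble: 1 × 3
#>     vdw   elec total
#>   <dbl>  <dbl> <dbl>
#> 1 -15.4 -0.416 -15.8

st <- init_state(bp$topology, positions = bp$bound_positions,
                 temperature = 300, seed = 1)
tr <- run_dynamics(bp$topology, st, nsteps = 20000,
                   integrator_params(temperature = 300, seed = 1),
                   output_every = 200)
ds <- drms_series(tr, pairs)
round(c(median(ds$drms), mean(ds$drms < 3)), 2)
#> [1] 1.64 0.87
```

The binding energy is the cross-helix sum of contact and screened-charge
terms in kcal/mol — about −16 for the designed dock, dominated by the
leucine/methionine face.  At 300 K the complex rattles inside its binding
site: the median dRMS from the bound reference is 1.6 Å and 87% of frames
stay below 3 Å, with occasional partial excursions.  `run_remd()` runs the same system over the default
temperature ladder; `cold_ensemble()`, `hist2d()` and `hotspot_summary()`
then recover the bound-cold/unbound-hot contrast, and `autoplot()` methods
plot histograms, energy logs and replica traces.

## Package layout

| Area | Functions |
|---|---|
| Force field | `kh_params`, `load_contact_matrix`, `build_pair_table`, `pair_energy`, `electrostatic_energy`, `bond_energy`, `assign_charge` |
| Topology | `read_calpha_structure`, `build_system`, `kabsch_superpose`, `make_reference`, `add_capping_beads`, `set_mass_scaling` |
| Dynamics | `init_state`, `run_dynamics`, `nve_run`, `compute_forces`, `write_xyz`, `write_calpha_pdb` |
| Replica exchange | `geometric_ladder`, `exchange_attempt`, `run_remd`, `dwell_time_distribution` |
| Analysis | `select_interface_pairs`, `drms`, `drms_series`, `binding_energy`, `hist2d`, `cold_ensemble`, `hotspot_summary` |
| Fixtures | `make_alpha_helix`, `make_binding_pair`, `make_tailed_domain`, `make_filament_stub` |
| Workflow | `default_config`, `read_config`, `cmd_build`, `cmd_run`, `cmd_remd`, `cmd_analyze` (CLI wrapper in `inst/cli/khmd.R`) |

The methods vignette (`vignettes/coarse-grained-binding.Rmd`) documents the
model assumptions, numerical choices, fixture design and known limitations.
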