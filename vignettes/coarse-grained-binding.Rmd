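---
title: "Coarse-grained simulation of protein binding ensembles with khmd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained simulation of protein binding ensembles with khmd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(khmd)
```

## The model

`khmd` implements a residue-level implicit-solvent model for simulating how
folded protein domains associate: the Kim–Hummer "model A" flavour of the
Miyazawa–Jernigan statistical potential.  Each residue is a single bead at
its C\eqn{\alpha} position.  Non-bonded beads interact through a signed
Lennard-Jones-type potential whose strength is a linear rescaling of a
20×20 residue contact-energy matrix \(e_{ij}\),

\[
\epsilon_{ij} \;=\; \lambda\,(e_{ij} - e_0),
\qquad \lambda = 0.159,\; e_0 = -1.36\ \mathrm{kcal/mol},
\]

so that statistically favourable contacts (hydrophobic pairs such as
Leu–Leu, \(\epsilon \approx -0.96\) kcal/mol) become attractive LJ wells of
depth \(|\epsilon_{ij}|\), while unfavourable pairs become purely repulsive:
below the LJ minimum the repulsive branch is the LJ core shifted up by
\(2\epsilon\), and beyond it the mirrored tail \(-4\epsilon[(\sigma/r)^{12} -
(\sigma/r)^6]\), which decays to zero from above and is continuous at
\(2^{1/6}\sigma\).  Pair diameters are arithmetic means of per-residue van
der Waals diameters (4.5–6.8 Å).  Charged side chains (Asp/Glu −1, Lys/Arg
+1, His +0.5) interact through Debye–Hückel electrostatics with uniform
dielectric 80 and screening length 10 Å, corresponding to roughly 100 mM
monovalent salt.  All LJ-like terms truncate at \(3\sigma\) and
electrostatics at 35 Å; truncation is plain (no shift), which leaves a
discontinuity of at most \(\approx 0.0055\,|\epsilon|\) at the LJ cutoff —
negligible against thermal energy and matching common practice for this
model family.

Folded domains with known structures are treated as rigid bodies: their
internal geometry is frozen and intra-body interactions are excluded
entirely.  Disordered linkers, tails and loops are flexible bead-spring
chains: consecutive residues are joined by stiff harmonic springs with
equilibrium length 3.81 Å and spring constant 189 kcal/(mol Å²).  The
printed constant multiplies the squared displacement directly
(\(u = k(r-r_0)^2\), the harmonic-bond convention of the MD engines this
parameterisation comes from); `kh_params(bond_half_convention = TRUE)`
selects the \(\tfrac12 k\) convention instead.  Bonds also join
rigid–flexible junction residues, with the same spring.  Bonded (1–2) pairs
are excluded from non-bonded terms: at \(r_0 = 3.81\) Å, well inside
\(\sigma_{ij}\) for most pairs, including them would strain every bond.

## Dynamics

The integrator is a BAOAB-splitting Langevin scheme.  Flexible beads are
Langevin particles with friction \(\gamma = m/\tau\) where \(\tau\) is the
damping *time* (default 1,000 fs — the semantics of the engine the value is
taken from).  Rigid groups move as quaternion rigid bodies: aggregated
force and body-frame torque drive centre-of-mass translation and rotation
about principal axes, with the same Langevin damping time applied to both
(the source protocol does not state a separate rotational damping; sharing
it is the simplest consistent choice and does not affect equilibrium
ensembles).  With damping set to zero the scheme reduces to symplectic
velocity Verlet, which the tests use for energy-conservation checks.

The production time step is 10 fs.  For a 189 kcal/(mol Å²) bond this is a
coarse step (\(\omega\,\Delta t \approx 0.53\)); BAOAB remains stable and
configurationally accurate to a few percent there, but *fluctuation-based
metrology* — recovering the spring constant from bond-length variance, or
checking equipartition — is done in the tests at 2–5 fs, where the
\(O((\omega \Delta t)^2)\) discretisation bias of the sampled variance
(about 7% at 10 fs for the stiffest mode) becomes negligible.  Kinetic
temperature is reported from the velocities at full steps.

Randomness comes from a counter-based generator hashed over (seed, replica,
step, slot): every replica has an independent stream, trajectories are
bit-reproducible for a given seed, and a run sliced into segments — as
replica exchange requires — is bit-identical to the same run in one piece.

Non-bonded interactions use a Verlet neighbour list with a 4 Å skin,
rebuilt every 1,000 steps and additionally whenever any bead has moved more
than half the skin since the last build, so the list can never silently
miss a pair.  Boxes are cubic and periodic with minimum image; the
reference protocol does not state its boundary treatment, and periodic
boundaries are the default of the engine family it used.

## Replica exchange

Temperature replica exchange uses a geometric ladder, by default 28 rungs
from 180 K to 540 K (the spacing is not stated in the source protocol;
geometric spacing gives near-uniform neighbour acceptance when heat
capacity varies slowly).  Swaps are attempted every 100 steps, alternating
even and odd neighbour pairings, with Metropolis probability
\(\min(1, \exp[(\beta_i-\beta_j)(E_i-E_j)])\); on acceptance the two
replicas exchange temperatures and velocities are rescaled by
\(\sqrt{T_{new}/T_{old}}\).  Pair strengths are independent of temperature.
Mixing diagnostics (replica traces, dwell-time distributions) and the
cold-ensemble extractor (`cold_ensemble()`) reproduce the standard
bookkeeping: frames are attributed to the rung their replica occupied when
recorded.

## Binding-ensemble analysis

Similarity to a reference complex is measured with the distance RMS over
interface pairs: all cross-component residue pairs within 10 Å
(inclusive) in the reference,

\[
\mathrm{dRMS} = \sqrt{\tfrac1N \sum_{(i,j)} (d_{ij} - d^{ref}_{ij})^2 },
\]

which is invariant to rigid motion of the whole frame.  The inclusive
boundary is a convention; it is measure-zero for real coordinates and a
dedicated test documents it.  In periodic boxes pair distances use minimum
image, since molecules are free to associate through a periodic image.
Pair selection is restricted to inter-component pairs (intra-component
geometry is rigid anyway), and sub-region selections are expressible by
passing component labels per bead.  Binding energies are cross-group sums
of the non-bonded terms, additive over partitions of either group, so
per-subunit decompositions sum to the whole.  2D occupancy histograms use
half-open bins (edge samples go up) with 0.5 Å default widths on dRMS axes
and 0.1 kcal/mol on energy axes; for signed energy axes the origin should
be floored to the bin width.  `hotspot_summary()` lists bins above a
fraction of the maximal occupancy, ties broken by bin index.

## Synthetic fixtures and what they do (and do not) show

The package ships deterministic generators for three toy system classes
that mirror the structural motifs of branch-junction simulations without
requiring any structure download:

* `make_binding_pair()` — two rigid α-helices with a designed interface:
  five leucines plus two methionines on the facing side, framed by a
  complementary Glu/Lys pair at either end that selects a unique docking
  registry.  The bound reference is found by a deterministic grid scan plus
  6-degree-of-freedom local minimisation of the cross energy *using the
  shipped pair table itself*, so the fixture exercises the production
  force-field path.  The initial state is separated by 60 Å, beyond every
  cutoff.
* `make_tailed_domain()` — a rigid helical core with a flexible Gly/Ser
  tail, the motif of a folded domain carrying a disordered linker.
* `make_filament_stub()` — rigid subunits stacked with fixed rise and
  twist, all in one rigid group, each carrying a flexible loop bonded at
  both ends into its subunit (loops are the only mobile beads).

Fixture scale was chosen for desk-scale statistics: the binding pair lives
in a 100 Å periodic box (its 60 Å initial separation stays beyond all
cutoffs under minimum image) and both bodies carry a mass scaling of 100 —
the standard fast-diffusion device for fully rigid objects, which divides
dynamical masses without touching the potential and therefore leaves every
equilibrium average unchanged (a property the tests verify).  The
interface strength (≈ −16 kcal/mol at the dock) was set so that at 180 K
the bound basin overwhelms the translational entropy of the box while at
540 K it does not; that is the bound-cold/unbound-hot contrast the
scenario test asserts.  What passing fixtures show is that the force
field, integrator, replica exchange and analysis chain are internally
consistent at equilibrium; they say nothing about the accuracy of the
contact-energy matrix for real protein surfaces, about association
kinetics at experimental concentrations, or about systems whose binding
involves conformational change — rigid bodies cannot capture the latter at
all.

## Numerical choices and degenerate inputs

* Units: Å, fs, kcal/mol, amu, K; \(k_B = 0.0019872\) kcal/(mol K),
  Coulomb constant 332.0637 kcal Å/(mol e²).
* Rigid groups need at least three non-collinear members; collinear or
  smaller groups are rejected at build time (no orientable frame).
* Beads closer than 0.1 Å are flagged as a numerical hazard in the log but
  are not fatal; non-finite coordinates abort the run with the offending
  step and bead.
* An empty interface-pair selection warns and makes dRMS undefined
  (an error when evaluated) rather than returning 0.
* Zero-step runs return an empty trajectory with the initial energies
  logged, so pipelines can be smoke-tested cheaply.
* Capping beads (immobile, uncharged, purely repulsive, user-chosen large
  σ) are available to block sticky surfaces such as the open ends of a
  filament stub; fixed–fixed pairs are excluded from the energy so caps do
  not add constants to binding energies.

## Problem sizes used by the test-suite

The statistical tests run at sizes chosen for tight yet fast statistics:
bond metrology and Boltzmann histograms use \(10^6\) steps of a two-bead
chain; equipartition and mass-scaling invariance use \(2\times10^5\) to
\(5\times10^5\) steps of one-bead traps; the replica-exchange scenario runs
3,000 sweeps × 100 steps of the binding pair over the default 28-rung
ladder, discarding the first half as the association transient.  These
sizes give sampling errors several times smaller than each asserted
tolerance.

## Known limitations

Rigid bodies exclude conformational activation; there are no nucleotides,
ions beyond implicit screening, or explicit solvent; no barostat or
constraint algorithms; dissociation constants are deliberately out of
scope (truncation choices shift absolute binding strengths, as the model
literature documents); and the DCD trajectory format is not written —
XYZ and multi-model PDB cover the analysis path.
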