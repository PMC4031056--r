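---
title: "Methods: aggregation analysis of multi-copy protein simulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aggregation analysis of multi-copy protein simulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggtraj)
```

## Scope and model

`aggtraj` analyzes the self-association of identical protein molecules
simulated with multiple copies in a periodic cubic box, at the millimolar
concentrations where crowding and aggregation artifacts become visible.
The pipeline takes multi-frame coordinate trajectories plus a topology
(molecules, residues, atoms, optional charges and Lennard-Jones
parameters) and derives, stage by stage:

1. **Contacts** — an intermolecular atomic contact exists whenever two
   eligible atoms (heavy atoms, or hydrogens bonded to them) of
   *different* protein molecules come within 0.4 nm under the
   minimum-image convention. The rule is boundary-inclusive
   (distance ≤ cutoff); at double precision the distinction from a strict
   inequality is immaterial. Solvent and ions never participate.
2. **Oligomer states** — molecules are nodes, contacting pairs are edges;
   species (monomer, dimer, trimer, tetramer, ≥5) are the connected
   components, and species fractions count *molecules*, not assemblies,
   so they sum to 1 at every frame. "Free monomer" uses this
   instantaneous graph, not the persistence rule below: the kinetic
   complex definition exists to coarse-grain recrossings in waiting-time
   statistics, while the time-resolved monomer-fraction curve is a purely
   structural observable.
3. **Kinetics** — a *complex* is a molecule pair in continuous atomic
   contact for at least 1 ns (a run of consecutive frames with ≥ 1
   contact; one contact-free frame ends the run; the gap tolerance is
   deliberately zero and the threshold is configurable). Runs reaching
   the final frame are censored — their true lifetime is unobserved — and
   are excluded from the dissociation mean but reported as the
   never-dissociate fraction, which equals the survival curve at the
   longest observable lifetime. Association waiting times are measured
   per molecule from the trajectory start or the end of its previous
   bound interval. The diffusion-limited reference is the Smoluchowski
   rate $k_{on} = 4\pi R D$ with $R$ twice the monomer radius of gyration
   and $D$ the relative diffusion coefficient; the package computes both
   from the trajectory itself (`radius_of_gyration()`,
   `diffusion_coefficient_msd()`).
4. **Interaction propensity** — per residue group $g$ (side chains pooled
   by sequence position across the identical molecules, plus one
   collective backbone group) and frame $t$,
   $p_g(t) = \frac{c_g(t)/\sum_g c_g(t)}{s_g(t)/\sum_g s_g(t)}$, the
   contact share normalized by the SASA share. Frames without contacts
   are skipped; per-trajectory time averages are averaged over
   trajectories without weighting. Contacts distributed exactly
   proportionally to exposure give $p \equiv 1$, and the profile is
   invariant under any uniform rescaling of the SASA values.
5. **Foldedness** — backbone RMSD after Kabsch superposition (proper
   rotation enforced), the number of α-helical residues by the
   Kabsch–Sander hydrogen-bond energy
   $E = 0.084 \cdot 332\,(1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})$
   kcal/mol (bond when $E < -0.5$; amide H rebuilt 1 Å from N opposite
   the preceding C=O; label `H` from two consecutive i→i+4 turns; 3₁₀ and
   π helices are deliberately not counted), and the summed distances
   between the side-chain centers of mass of the three core
   phenylalanines (positions 7, 11, 18 of the 36-mer; the C-terminal Phe
   35 is not part of the buried core). The center of mass uses all
   side-chain heavy atoms including Cβ, mass-weighted — the atom set
   behind the published native value of 18.0 Å is not stated, which is
   why the validation tolerance on that number is ±0.5 Å.
6. **Energetics** — cutoff Lennard-Jones (geometric combination) plus
   Coulomb electrostatics, either plain-truncated or reaction-field
   corrected: $E_C = f q_i q_j (1/r + k_{rf} r^2 - c_{rf})$ with
   $k_{rf} = (\varepsilon_{rf} - \varepsilon_1)/((2\varepsilon_{rf} +
   \varepsilon_1) r_c^3)$, which vanishes exactly at the 1.4 nm cutoff
   (defaults $\varepsilon_{rf} = 65$, $\varepsilon_1 = 1$). Every pair is
   assigned to protein–protein, protein–solvent or solvent–solvent by its
   atoms' group labels (ions count as solvent), so the decomposition
   closes exactly: $E_{pp} + E_{ps} + E_{ss} = E_{total}$. Pairs one or
   two bonds apart are excluded; no 1–4 scaling is applied — a documented
   simplification, because the energetics here is validated against the
   package's own synthetic Hamiltonian, never against a published force
   field. Particle-mesh Ewald is out of scope. The ΔE estimator takes,
   per trajectory, the mean energy of fully aggregated frames (all
   molecules in one component) minus the mean of fully monomeric frames
   (all singletons), requires strictly more than 20 snapshots of each
   state, and averages qualifying trajectories with the sample (n−1)
   standard deviation. Output headers state that only nonbonded terms are
   decomposed.

Setup arithmetic mirrors the study conditions: the cubic box side from
concentration is $(n / (c N_A))^{1/3}$ (10.34 nm for 4 copies at 6 mM,
11.30 nm for 8 at 9.2 mM), the counter-ion excess equals the magnitude of
the net formal charge per molecule (K/R +1, D/E −1, H neutral,
zwitterionic termini net zero; carbonylated K/R/P contribute nothing, as
their semialdehyde products are neutral aldehydes) — +2 for the wild-type
sequence, hence 2 Cl⁻ per molecule, and −4 when all seven carbonylatable
positions are converted, hence 4 Na⁺. The neutral-pH charge model is
inferred from those printed ion counts; no pKa calculation is attempted.
Starting-structure ensembles are filtered to backbone RMSDs within one
standard deviation of the ensemble mean, boundaries inclusive.

## The synthetic-data generator

Because the analyses need ground truth, the package ships a
Brownian-dynamics simulator of sticky bead-molecules
(`simulate_aggregation()`): overdamped Langevin updates
$\Delta x = (D/k_BT) F \Delta t + \sqrt{2 D \Delta t}\,\xi$, linear bead
chains joined by harmonic bonds, and an intermolecular pair potential
with a harmonic core repulsion below bead contact, a flat attractive
bottom of depth ε, and a cosine switch to zero. Inertia is deliberately
absent: only diffusion and binding statistics matter to the analyses
under test. Defaults emulate the study conditions — 4 molecules at 6 mM
(10.34 nm box), 100-ps frame spacing, a monomer diffusion coefficient of
1.2 × 10⁻¹⁰ m²/s (typical for a compact 4-kDa mini-protein), kT = 2.494
kJ/mol (300 K), and a dissociation rate near 2.2 × 10⁷/s, i.e. a 45-ns
mean bound time.

Dissociation is controlled in one of two ways. In **well mode** unbinding
is purely thermal escape from the well, and the matching ground truth is
the radial mean-first-passage quadrature
(`mfpt_dissociation_time()`; `well_depth_for_koff()` inverts it to
calibrate a depth for a target rate — a first-passage refinement of the
Kramers-style estimate). In **markov mode** a bound pair loses its
attraction at exactly the Poisson rate `k_off_target`, making the planted
lifetime distribution exponential by construction; the attraction stays
off until the pair has separated well beyond the contact shell
(`r_release`, default 1 nm past the outer well edge), so that a fired
dissociation is committed rather than instantly recrossed. Markov mode is
the primary oracle for rate recovery because its planted rate is exact;
well mode is the oracle for equilibrium energy statistics.

Numerical choices that matter: the integration step must resolve the
switching region — `sim_params()` warns when the drift from the maximal
well force, or the per-step diffusive displacement, approaches the switch
width. The default switch width is 0.25 nm for that reason. The planted
bound-state energy gap is computed independently of any trajectory as the
radial Boltzmann average of the pair potential over the bound region
(`planted_energy_gap()`), so the ΔE validation compares simulation
statistics against quadrature, not against itself. Initial configurations
place molecule centers on the exact best lattice (simple cubic, bcc or
fcc) when the molecule count fits one — for 4 molecules in a cubic box
the fcc arrangement attains the optimal minimal periodic center distance
$L\sqrt{2}/2$ — and otherwise fall back to a maximin relaxation of random
points; orientations are drawn from the seeded generator and re-drawn on
overlap. A third simulator mode (`ljc`) drives the dynamics with the same
Lennard-Jones + reaction-field Hamiltonian the analysis module evaluates,
with optional explicit solvent beads; its independently accumulated
per-frame energy log is the central cross-module oracle for
`frame_energy_decomposition()`.

What the generator does *not* emulate: internal protein structure and
folding, sequence-specific chemistry, hydrodynamic interactions, and
explicit water at realistic density. Passing the recovery tests therefore
demonstrates that the *analysis* stages measure what they claim on data
with known statistical structure — not that any particular force field or
real protein behaves this way.

## Validation design and problem sizes

Every non-trivial operation has an independent oracle in the test suite:
cell-list contact detection against an all-pairs scan on random periodic
frames; connected components against an independent graph library;
Shrake–Rupley areas against a 10×-refined quadrature and the closed-form
single-sphere area; Kabsch RMSD against a grid-plus-refinement search of
rotation space; the α-helix assignment against a reference DSSP
implementation run on an ideal poly-alanine helix during development,
with the resulting labels frozen into the test; reaction-field and
Lennard-Jones terms against their closed forms; and the simulator against
the Einstein relation, the Smoluchowski rate, its own Poisson unbinding
clock, and the Boltzmann quadrature of its Hamiltonian.

Statistical recovery runs are sized to finish on one CPU in a few
minutes while leaving comfortable margins at the stated tolerances:
diffusion from 27 non-interacting molecules over 10⁴ steps (10%
tolerance); association from 100 replicate two-molecule irreversible
runs in a 12-nm box, estimated with the censoring-aware exponential mean
(20%); lifetimes from 5 replicate dimer systems totaling ≥ 200 events,
compared as mean-above-threshold against 1/k_off (15%); the energy gap
from 5 well-mode dimer trajectories (within 2 between-trajectory
standard deviations); and the sticky-residue ranking from a 4-chain,
4-bead system. Two-molecule systems are used for rate recovery because
in larger clusters a pair whose bond has dissolved is still held inside
the contact shell by shared neighbors, which floods the detector with
sub-nanosecond flicker runs — precisely the phenomenon the 1-ns
persistence rule exists to remove.

Degenerate inputs are contracts, not corner cases: non-monotone frame
times, atom-count mismatches, triclinic boxes, atoms without molecule
assignment, collinear superposition sets, carbonylation positions not
holding K/R/P, zero total SASA, and non-uniform frame spacing in
kinetics all raise explicit errors. Zero-count residue pairs in the
log-rescaled contact map receive a 0.5 pseudo-count before the
logarithm, whose handling at zero the transform itself leaves undefined;
the map is shifted so the most-contacted pair sits at zero and scarcer
pairs grow positively.

## Open design points, resolved

- **Hydrogen eligibility** without bond records falls back to attaching
  each hydrogen to the nearest heavy atom of its residue within 0.12 nm
  in the first frame (`assign_bonded_heavy()`); unattachable hydrogens
  are excluded with a warning.
- **Censored complexes** are excluded from the dissociation mean; both
  the mean and the censored fraction are always reported, so the
  alternative estimator (counting censored lifetimes at their observed
  values) can be formed from the event table if wanted.
- **SASA normalization** pools residues of the identical molecules by
  sequence position before normalizing; for identical chains this is
  proportional to any per-molecule variant and cancels in the ratio.
- **Radii and probe** for SASA are the Bondi van der Waals table with a
  0.14-nm water probe — standard choices, stated because the source
  analysis names neither.
- **Backbone definition** covers N, CA, C, O (plus OXT and the amide and
  α hydrogens) by PDB v3 naming; everything else is side chain.
- **Sample vs population SD**: trajectory averages report the sample
  (n−1) standard deviation.
- **Coordinate conventions**: nm and ps internally (Å converted on PDB
  I/O), energies in kJ/mol, residue numbering 1-based per molecule; atom
  indices are 1-based throughout, the natural R convention.

## Known limitations

Absolute energies of real systems are out of reach by design: no
published force-field parameter sets ship with the package, PME is not
implemented, and bonded terms beyond the simulator's own springs are not
evaluated — the ΔE machinery is validated on the synthetic Hamiltonian
only. The α-helix assignment implements only the `H` state of the
Kabsch–Sander scheme. Trajectory I/O handles orthorhombic cells only and
does not read compressed formats. The Smoluchowski comparison inherits
finite-box corrections of order R/L; the validation keeps R/L ≈ 0.12,
where the bias is within the stated 20% band.
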