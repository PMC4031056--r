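# aggtraj

Analysis of protein self-association in multi-copy molecular simulation
trajectories, for people who simulate several identical protein molecules
in one periodic box at millimolar concentration and need to quantify
whether, how fast, and through which residues they aggregate — and for
people validating whether a simulation protocol *spuriously* aggregates a
protein that is experimentally soluble.

## What it computes

Given trajectories (multi-MODEL PDB, GRO, or the package's plain-text
dialect) plus a topology:

- **Intermolecular contacts** under periodic boundaries: two heavy atoms
  (or hydrogens bonded to them) of different protein molecules within
  0.4 nm, via a cell list verified against an all-pairs scan.
- **Oligomeric state**: connected components of the molecule contact
  graph; species fractions (monomer, dimer, trimer, tetramer, ≥5) count
  molecules and sum to 1 per frame.
- **Association/dissociation kinetics**: a *complex* is a pair in
  continuous contact for ≥ 1 ns; censored (never-dissociating) complexes
  are tracked separately; waiting times are compared against the
  Smoluchowski diffusion limit
  `k_on = 4πRD`, with `R` (= 2 R_g) and `D` measured from the trajectory
  itself (MSD fit with periodic unwrapping).
- **Interaction propensity** per residue: contact share normalized by
  solvent-accessibility share at each time point
  (`p_g = (c_g/Σc) / (s_g/Σs)`), with Shrake–Rupley SASA and the backbone
  as one collective group.
- **Foldedness**: backbone RMSD (Kabsch superposition), α-helical residue
  count (Kabsch–Sander hydrogen-bond rules), and the summed distances
  between core phenylalanine side-chain centers of mass (ΣdPHEs, 18.0 Å
  in the native villin headpiece structure).
- **Energy decomposition**: cutoff Lennard-Jones + Coulomb (plain or
  reaction-field, ε_rf = 65, 1.4 nm), split exactly into
  protein–protein, protein–solvent and solvent–solvent terms, and the
  aggregated-minus-monomeric ΔE estimator with the >20-snapshot filter.
- **Setup arithmetic**: box side from concentration, net formal charge
  and counter-ion plans (including carbonylated K/R/P variants), and the
  mean ± sd starting-ensemble RMSD filter.

A Brownian-dynamics generator (`simulate_aggregation()`) produces
trajectories of diffusing sticky molecules with *known* association and
dissociation rates, planted sticky residues, optional explicit solvent,
and ground-truth event and energy logs — every analysis stage is tested
against it.

## Worked example

Four sticky molecules at 6 mM (a 10.34 nm box), 200 ns of Brownian
dynamics with a planted dissociation rate of 2.2 × 10⁷/s:

```r
library(aggtraj)

params <- sim_params(n_molecules = 4, conc_mM = 6, D_target = 1.2e-10,
                     k_off_target = 2.2e7, n_frames = 2001, seed = 42)
sim    <- simulate_aggregation(params)

series  <- contact_timeseries(sim$trajectory, cutoff = params$contact_radius)
species <- species_fraction_timeseries(oligomer_timeseries(series))
round(species[c(1, 500, 1000, 2001), ], 2)
#>      time_ps monomer dimer trimer tetramer larger
#> 1          0    1.00   0.0   0.00        0      0
#> 500    49900    0.50   0.5   0.00        0      0
#> 1000   99900    0.25   0.0   0.75        0      0
#> 2001  200000    0.25   0.0   0.75        0      0

events <- detect_complexes(series, min_lifetime_ns = 1)
ks <- kinetics_summary(events, 0, 200000, molecules = series$molecules)
ks$n_events                      # 17 complexes
round(ks$mean_association_ns, 1)  # 27.4
round(ks$mean_dissociation_ns, 1) # 12.1
round(ks$censored_fraction, 2)    # 0.12  (complexes that never dissociate)

smoluchowski_association_time(params$contact_radius, 2 * 1.2e-10, 6e-3)
#> 63.3 ns
```

Reading: monomers pair up and grow to a trimer. The planted mean bound
time is 1/k_off = 45 ns; the observed dissociation mean (12.1 ns) is
smaller because it averages only complexes that dissociated within the
run — the long-lived ones are censored, which is exactly what the 12%
never-dissociate fraction flags. The measured association waiting time
(27.4 ns)
is shorter than the well-mixed Smoluchowski estimate (63.3 ns) because
dissociated pairs re-associate from spatially correlated positions — the
same reason the reference is a sanity bound, not a fit.

Setup arithmetic for the study conditions:

```r
box_side_from_concentration(4, 6e-3)          # 10.34 nm
net_formal_charge("MLSDEDFKAVFGMTRSAFANLPLWKQQNLKKEKGLF")  # +2  -> 2 Cl-
```

`run_pipeline()` chains all stages over one or many trajectories from a
config list or YAML file and writes tidy TSVs per stage.

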