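# mdfinger

Interaction fingerprints for protein–glycosaminoglycan trajectories.

`mdfinger` analyses multi-model PDB trajectories of a protein ("receptor")
bound to a polysaccharide ligand — the motivating system is human serum
albumin (HSA) with hyaluronate (HA) in electrolyte solution — and answers
the structural questions such simulations are run for: which residues form
hydrogen bonds to which ligand oxygens, where water molecules bridge the two
solutes, where lysines contact the ligand carboxylates directly, where
Ca²⁺/Mg²⁺ ions bridge both partners, which carbons make hydrophobic
contacts, and how a binding-energy decomposition evolves over the
trajectory.

## The scoring and detection rules

**Hydrogen bonds** are scored by an explicit distance–angle energy
(kJ/mol, distances in Å):

    E_HB = 25 · (2.6 − max(d_HA, 2.1)) / 0.5 · s_DHA · s_HAX

where `d_HA` is the hydrogen–acceptor distance and the two factors are
piecewise-linear angular ramps

    S(α) = 0              α ≤ θ1
         = (α−θ1)/(θ2−θ1) θ1 < α ≤ θ2
         = 1              α > θ2

with (θ1, θ2) = (75°, 85°) for the donor–H–acceptor angle (taken at the
hydrogen) and (85°, 95°) when the acceptor-attached atom X is a heavy atom.
A contact is reported when `E_HB` strictly exceeds 6.25 kJ/mol. The energy
plateaus at 25 kJ/mol for `d_HA` ≤ 2.1 Å and vanishes at 2.6 Å.

**Water bridges**: a water donating one hydrogen to a receptor N/O and the
other to a ligand N/O, both H···acceptor legs within 3.0 Å.

**Ionic contacts**: opposite formal-charge centres (LYS NZ, ARG CZ,
carboxylate oxygen midpoints, monatomic ions) whose raw separation minus
the two hydrogen-bond radii lies in \[0, 1.5\] Å. **Cation bridges** are
cations (Ca²⁺/Mg²⁺ by default) in simultaneous ionic contact with a
receptor anionic centre and the ligand carboxylate.

**Hydrophobic contacts** pair carbons of the three classes — CH₃, CH₂/CH,
aromatic CH — within 4.5 Å, excluding α-carbons (except glycine).

**Binding energy** per frame, with a pluggable potential/solvation backend:

    E_bind = E_pot1 + E_pot2 + E_sol1 + E_sol2 − (E_pot,comp + E_sol,comp)

positive values meaning affinity; windowed statistics exclude the leading
40 % of the trajectory as equilibration. Aggregation produces per-frame
counts, amino-acid × ligand-oxygen-class (O1–O10, N) matrices, HSA
subdomain labels (IA 5–107, IB 108–197, IIA 198–296, IIB 297–382, IIIA
383–494, IIIB 495–569), and complex rankings.

## Worked example

Every detector is testable without any external data: the synthetic module
plants interactions at exactly known geometry.

```r
library(mdfinger)

pc   <- make_planted_complex(n_hbond = 2, n_water_bridge = 1, n_ionic = 1,
                             n_cation_bridge = 1, cation_species = "CA",
                             n_hydrophobic = 1, n_decoys = 2, seed = 42)
traj <- make_trajectory(pc, n_frames = 20, jitter_sd = 0.04, seed = 42)
summary(interaction_fingerprint(traj))
```

```
Interaction fingerprint over 20 frame(s); 12 in analysis window
  window means: H-bonds 2.00 | water bridges 1.00 | ionic 1.00 | cation bridges 1.00 | hydrophobic 1.00

H-bond amino-acid x ligand-class matrix (window totals):
      O7
  SER 24

Water-bridge amino-acid x ligand-class matrix (window totals):
      O7
  SER 12

Hydrophobic contacts by amino acid (window totals):
ALA 
 12 
```

The window means recover the planted ground truth (2, 1, 1, 1, 1) in every
analysed frame, the decoys are never detected, and the matrices show the
planted serine–ring-oxygen (class O7) geometry. Individual contacts carry
their full geometry:

```r
detect_hbonds(traj)[, c("donor_resname", "acceptor_resname", "dist_HA", "energy")]
#>   donor_resname acceptor_resname  dist_HA   energy
#> 1           SER              NAG 2.198406 20.07971
#> 2           SER              NAG 2.216265 19.18675
```

Binding-energy traces use the reference backend (12-6 van der Waals +
Coulomb with distance-dependent dielectric + surface-area solvation):

```r
sys  <- assign_charges(plant_ionic_system())
traj <- assign_charges(make_trajectory(sys, n_frames = 10,
                                       jitter_sd = 0.03, seed = 1))
binding_energy_trace(traj, reference_backend())
#> Binding-energy trace: 10 frame(s), time 0..0.9
#>   windowed mean 20.227 kJ/mol (sd 0.351, n 6)
```

A positive mean: pulling the lysine off the carboxylate costs energy. A
thin CLI covering the same operations ships in `inst/cli/mdfinger`
(`fingerprint`, `energy`, `synth` subcommands).

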