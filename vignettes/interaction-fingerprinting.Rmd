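---
title: "Interaction fingerprinting of protein-glycosaminoglycan trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interaction fingerprinting of protein-glycosaminoglycan trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdfinger)
```

## Scope and model

`mdfinger` post-processes molecular-dynamics trajectories of a
protein-polysaccharide complex, stored as multi-model PDB, into interaction
fingerprints. The motivating system is human serum albumin (HSA) binding
hyaluronate (HA) — the deprotonated polysaccharide of repeating
D-glucuronate (GCU) and N-acetyl-D-glucosamine (NAG) units — in water with
Na⁺, Mg²⁺ or Ca²⁺ ions. The package deliberately stops short of running or
re-scoring dynamics: force fields, integrators and electrostatics solvers
are out of scope. What it owns is the geometric detection layer and the
aggregation on top of it.

Assumptions baked into the design:

* **Explicit hydrogens.** The hydrogen-bond energy is defined on the
  hydrogen atom, so structures must carry at least their polar hydrogens.
  Hydrogen-free systems parse fine, but hydrogen-dependent detectors raise
  a typed error (`mf_missing_hydrogens`) rather than invent hydrogen
  positions — placement heuristics would add unvalidated geometry to a
  quantity that is exponentially sensitive to it.
* **Fixed-column multi-model PDB as the trajectory format.** Text-only,
  diff-able, and testable from fixtures built in code; no binary trajectory
  reader. MODEL/ENDMDL blocks are frames; the atom inventory must be
  identical across frames.
* **Bulk protonation at pH 7.4.** Aspartate/glutamate and the GCU
  carboxylate (pKa ≈ 3) are deprotonated (−1), lysine and arginine are
  +1, histidine is neutral by default. The delocalized carboxylate charge
  is carried as −0.5 on each oxygen so residue totals stay integral, while
  the ionic detector works from the oxygen-midpoint pseudo-centre.

## The hydrogen-bond score

A candidate donor-H···acceptor triple is scored (kJ/mol, Å)

$$E_{HB} = 25\cdot\frac{2.6-\max(d_{HA},\,2.1)}{0.5}\cdot s_{DHA}\cdot s_{HAX}$$

and reported iff $E_{HB} > 6.25$ strictly. Each $s$ is a piecewise-linear
ramp $S(\alpha)$: zero at or below $\theta_1$, one above $\theta_2$, linear
between. Two parameter tables exist: $(85°, 95°)$ for heavy atoms and
$(75°, 85°)$ for hydrogens.

Design choices the source conventions leave open, and what this package
does:

* **Ramp orientation.** A decreasing numerator
  $(\theta_2-\alpha)/(\theta_2-\theta_1)$ between the plateaus contradicts
  the stated limits (0 below $\theta_1$, 1 above $\theta_2$) and physical
  intuition (straighter bonds are stronger). The default is therefore the
  increasing ramp $(\alpha-\theta_1)/(\theta_2-\theta_1)$, which meets both
  plateaus continuously; the decreasing variant remains available as
  `ramp_orientation = "printed"` for comparability.
* **Angle vertices and table dispatch.** $s_{DHA}$ is evaluated at the
  hydrogen vertex (the D–H···A angle) through the hydrogen table — the
  convention under which a 75°/85° table is sensible. $s_{HAX}$ is
  evaluated at the acceptor vertex against each covalently attached atom X,
  through the heavy-atom table when X is heavy and the hydrogen table when
  X is a hydrogen.
* **Several acceptor neighbours.** $s_{HAX}$ combines over neighbours with
  the maximum (most permissive) by default; `hax_rule = "min"` switches to
  the strictest. Acceptors with no attached atom get a factor of 1.
* **Strictness at the threshold.** Equality is not a contact. The test
  suite pins this with an exact-arithmetic geometry whose energy evaluates
  to exactly 6.25.
* **Covalent perception.** Donor hydrogens are hydrogens of the same
  residue within 1.2 Å of an N/O; acceptor neighbours are group atoms
  within 1.8 Å (heavy) or 1.2 Å (H). Distance-based perception keeps the
  detectors total over arbitrary fragments, including the deliberately
  minimal synthetic sites.
* **Speed.** A prefilter keeps only pairs with $d_{HA} \le 2.6 - 0.5\cdot
  E_{min}/25$ (2.475 Å at the default threshold). Since both angular
  factors are at most 1, no reportable contact can be lost: the prefilter
  is provably lossless, and correctness is always defined by the formula.

## The other detectors

* **Water bridges** use the pure leg-distance criterion: one water
  hydrogen within 3.0 Å (inclusive) of a receptor N/O, the other within
  3.0 Å of a ligand N/O. No angular term is applied — the source
  convention for bridges specifies the distance only, and adding the full
  energy machinery would silently change counts. Water acts strictly as a
  double donor (a compatibility flag `water_as_acceptor` exists but is off
  by default); a (water, receptor atom, ligand atom) triple counts once
  regardless of which hydrogen serves which side.
* **Ionic contacts** measure centre-to-centre distance minus the two
  hydrogen-bond radii and accept the inclusive range \[0, 1.5\] Å. The
  radii are not printed in any source and are shipped as package defaults
  (N 1.75, O 1.70, C 1.80, Cl 1.70, Na 1.00, Mg 0.85, Ca 1.10, K 1.33 Å),
  editable in the config; pseudo-centres use the element of their defining
  atoms. Receptor-ligand, ion-receptor and ion-ligand pairings are all
  reported with labels. Arginine and (optionally protonated) histidine
  centres are scanned like any other: the empirical observation that only
  lysine forms direct contacts in real HSA-HA trajectories is something
  the detector can reproduce, not something it enforces.
* **Cation bridges** are cations in simultaneous ionic contact with both
  partners; the default species filter is {Ca, Mg} with Na available on
  request. Every (cation, receptor centre, ligand centre) pair is a
  separate bridge, and each bridge decomposes into two reported ionic
  contacts by construction.
* **Hydrophobic contacts** use template-assigned carbon classes (methyl;
  CH₂ or CH with three carbon neighbours; hydrogen-carrying aromatic ring
  carbons) with α-carbons excluded except glycine, and a distance cutoff
  that no source prints: the default 4.5 Å between qualifying carbons is a
  package choice, exposed in the config and echoed in outputs.

## Binding-energy decomposition

$E_{bind} = E_{pot1}+E_{pot2}+E_{sol1}+E_{sol2}-(E_{pot,comp}+E_{sol,comp})$,
positive = affinity. The six terms come from a pluggable backend evaluated
on receptor, ligand, and complex. Reproducing a production force field is a
non-goal; the shipped reference backend is a transparent desk-scale model:

* 12-6 van der Waals with geometric-mean well depths and summed
  half-minima, over inter-residue pairs (intra-residue pairs cancel
  exactly in the decomposition and are skipped);
* Coulomb on the formal charges with distance-dependent dielectric
  $\varepsilon(r)=4r$, i.e. $1389.35\,q_iq_j/(4r^2)$ kJ/mol;
* solvation $\gamma\cdot$SASA with $\gamma = 0.025$ kJ/mol/Å², the surface
  computed on a deterministic 240-point golden spiral per atom
  (Shrake-Rupley style). The point set is fixed in the laboratory frame,
  so solvation is exactly translation-invariant and rotation-invariant
  only to sampling resolution (relative deviations around $10^{-3}$ at the
  default point count) — the tests assert exactly that.

What the package warrants about energies is the algebra and its limits —
zero for null or non-interacting backends, positive for a planted salt
bridge, closed forms for isolated pairs and spheres — not agreement with
any force-field number.

**Windowing.** All trajectory statistics exclude the leading fraction
(default 0.4, matching a 40-of-100-ns equilibration split) of the simulated
time span. The window is closed on the left: a frame exactly at
$t_0 + 0.4\,(t_1-t_0)$ is included. The spread reported alongside the mean
is the population standard deviation of the per-frame values: it describes
the fluctuation range, not the standard error of the mean, and no block
averaging is applied.

## Fingerprints and reports

Per-frame counts of the five contact types are aggregated into window
means *and* window totals — figure-style count summaries in the literature
rarely state their normalization, so both are always reported side by side.
Direct hydrogen bonds and water bridges additionally fill amino-acid ×
ligand-class matrices. The ligand classes O1–O10 and N follow a shipped
map over the GCU-NAG repeat unit; since no text source fixes which
physical oxygen carries which class number, the assignment is a documented
package convention (glucuronate hydroxyls O1–O3, carboxylate O4, ring and
glycosidic oxygens O5/O6, NAG ring/hydroxymethyl/carbonyl/remaining
hydroxyls O7–O10, amide nitrogen N) and every output carries
`map_version = "mdfinger-map-1"` so that downstream comparisons can detect
a convention change. A user map is accepted, with a strict mode that
refuses unmapped ligand N/O atoms.

Contacted receptor residues map onto the HSA subdomain ranges IA 5–107,
IB 108–197, IIA 198–296, IIB 297–382, IIIA 383–494, IIIB 495–569; labels
are emitted hyphen-joined in that canonical order, residues outside all
ranges labelling `other` with a warning. Complex ranking orders
binding-energy traces by descending windowed mean with input-order
tie-breaking.

## The synthetic generator: what it does and does not show

Real trajectories are large, binary and force-field-dependent, so the test
bed is synthetic: `make_planted_complex()` builds systems in which each
interaction exists *by construction* at mid-criterion geometry:

| event | planted geometry | criterion margin |
|---|---|---|
| hydrogen bond | $d_{HA}$ = 2.2 Å, linear, ideal X angle | 0.275 Å to the 2.475 Å boundary |
| water bridge | both legs 2.8 Å | 0.2 Å |
| ionic contact | adjusted 0.75 Å | 0.75 Å |
| cation bridge | both legs adjusted 0.75 Å | 0.75 Å |
| hydrophobic | 4.0 Å methyl-methyl | 0.5 Å |

Decoys use the same motifs pushed well outside the criteria (2.9 Å
hydrogen bonds, 3.5 Å legs, adjusted 2.0 Å, one-sided bridges, 5.5 Å
carbon pairs). Every event occupies its own site of a 20 Å grid, so sites
cannot interact and the ground-truth inventory is provable rather than
asserted; sites receive seed-derived rigid rotations, which leave internal
geometry — and hence detection outcomes — bit-for-bit intact. Planted
receptor fragments carry only the atoms their interaction needs (a lysine
site is just the NZ centre); full-residue chemistry is covered by the
typing templates and their tests instead. The ligand copy at each site is
an idealized GCU-NAG unit: regular hexagon rings, radial substituents,
rigid water (O-H 0.957 Å, H-O-H 104.5°), heavy atoms plus polar
hydrogens.

`make_trajectory()` adds independent per-coordinate Gaussian jitter.
With `jitter_sd` at most a quarter of the smallest margin (≤ 0.05 Å),
planted counts survive in at least 95 % of frames — a property the suite
checks at `jitter_sd = 0.04` over 100 frames.

What passing these tests shows: the detectors implement their criteria
exactly (boundary bisections recover 3.0 Å and 1.5 Å to 10⁻⁶, a
10,000-geometry randomized sweep agrees with an independent closed-form
oracle contact-for-contact). What it does not show: behaviour on crowded,
correlated real interfaces — bifurcated hydrogen bonds, shared waters,
competing centres within one cutoff — where detection is still
well-defined (all qualifying pairs are reported; nothing is pruned) but no
synthetic ground truth certifies completeness, and physical realism of the
idealized geometry, which is not attempted.

## Problem sizes and numerics

The shipped suites run at desk scale by design: 10⁴ randomized
hydrogen-bond geometries for the detector-oracle equivalence, 50 seeded
planted complexes with up to five events per type for inventory recovery,
100-frame jittered trajectories for the stability property, and boundary
bisections to 10⁻⁶ Å (10⁻⁹ degrees for the ramp saturation angles).
Floating-point ties are resolved by the criteria themselves: strict `>` at
the hydrogen-bond threshold, inclusive `≤`/`≥` at the water-bridge and
ionic range ends. Degenerate inputs fail loudly with typed conditions
(`mf_missing_hydrogens`, `mf_packing_error`, `mf_statistics_error`, ...)
rather than silently returning empty results, with the one documented
exception that unknown carbons classify as `none`.

## Known limitations

* No π-hydrogen bonds, π-cation interactions or halogen bonds.
* Water-as-acceptor bridges are not counted by default (flag available).
* Aromatic rings are recognized from residue templates, not perceived from
  geometry; ligand parametrization covers GCU/NAG.
* The reference energy backend is illustrative, not predictive: no PME, no
  entropy, no force-field fidelity.
* mmCIF and compressed/binary trajectory formats are not read.
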