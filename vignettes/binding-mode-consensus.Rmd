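---
title: "Consensus binding-mode inference: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus binding-mode inference: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindmode)
```

## The problem

Protein–protein docking engines disagree. Given a receptor (for example a
GAP domain such as the TSC2 GAP) and a smaller ligand protein (such as the
GTPase Rheb), each engine returns a ranked list of rigid placements
("poses") of the ligand, and different engines often place the ligand on
different faces of the receptor. A practical remedy is *consensus*: pool
the top poses from many engines, discard poses that violate known
interface restraints, cluster the pool by ligand RMSD in a common receptor
frame, and take the pose nearest the centroid of the most populated
cluster as the working binding mode. If several independent methods pile
their poses onto the same patch of receptor surface, that patch is far
more credible than any single engine's top score.

`bindmode` implements that pipeline, together with the downstream analyses
that are usually run on the chosen mode: typed interface-interaction
detection, contact occupancy over trajectories, RMSD/RMSF/trajectory
clustering, a surrogate end-point binding free energy with per-frame
averaging, computational alanine scanning, and spatial grouping of
hotspots into hot regions.

## The consensus model

**Restraints.** An interface restraint names receptor-side and ligand-side
residues believed to interact. For each restrained residue the minimum
heavy-atom distance to the partner's restrained set must fall within
`[lower, upper]`, by default 2–10 Å. The bounds are applied to minimum
heavy-atom distances because the atom convention behind published
restraint bounds is rarely stated; minimum heavy-atom distance is the
least surprising choice and is what docking servers typically enforce.

**Superposition.** Poses arriving in per-engine frames are fitted onto one
reference receptor by least squares (Kabsch, SVD with the determinant sign
correction); the same rigid transform is applied to the ligand. After
this, the receptor is common to all poses, so plain coordinate RMSD over
*ligand heavy atoms, with no per-pair refitting*, measures exactly what
distinguishes binding modes: where the ligand sits. An `all-heavy` option
includes the (shared) receptor atoms, reproducing the literal
"all heavy atoms" reading; it only rescales the matrix, since the receptor
contributes zero displacement. Ligand-heavy is the default because it is
the standard discriminator in docking-pose clustering.

**Cluster-count selection (Kelley–Gardner–Sutcliffe).** Agglomerative
clustering (average linkage by default; the linkage used by the original
panel tools is undisclosed, so it is configurable) yields a dendrogram.
For every level $k \in [2, N-1]$ the average spread — the mean pairwise
RMSD within non-singleton clusters, with all-singleton levels assigned
spread 0 — is min–max normalised onto $[1, N-1]$ and penalised by the
cluster count:

$$\mathrm{pen}(k) = \tilde{s}(k) + k, \qquad k^\* = \arg\min_k \mathrm{pen}(k).$$

Two numerical guards matter in practice. When the spread range across
levels is at numerical-noise level (duplicate poses), normalisation is
skipped and all levels take $\tilde{s}=1$; otherwise $10^{-15}$ jitter
would be amplified across the full $[1, N-1]$ band and the argmin would be
arbitrary. Ties in the argmin go to the smallest $k$, and every other tie
in the pipeline (most-populated cluster, centroid) is broken
deterministically — smaller mean intra-cluster RMSD, then
lexicographically smallest pose label — so reruns are reproducible without
any seed.

**Consensus pose.** The most populated cluster wins; its centroid is the
member pose minimising the sum of squared RMSD to all members (an
exhaustive argmin — cluster sizes here are tens, not thousands). Engine
contributions are the engine shares of that cluster in percent.

## Interaction fingerprints

The geometric criteria are declared surrogates for the undisclosed
defaults of commercial interaction panels, chosen so that the distance
ranges typical of published GAP–GTPase interface tables (2.2–5.7 Å
across H-bonds, aromatic H-bonds and π-stacks) are all classifiable:

| type | rule | default |
|---|---|---|
| hbond | donor–acceptor heavy-atom distance; D–H–A angle ≥ 120° when H present, distance-only otherwise | ≤ 3.5 Å |
| salt_bridge | protonated-N group atom (Lys NZ, Arg NH/NE, doubly protonated His ND1/NE2) to carboxylate/phosphate O | ≤ 4.0 Å |
| pi_stacking | ring-centroid distance with inter-plane angle ≤ 30° (parallel) or 60–120° (T-shaped) | ≤ 6.0 Å |
| aromatic_hbond | donor heavy atom to ring centroid | ≤ 4.0 Å |

A salt-bridge pair that also passes the H-bond rule yields both records;
occupancy analysis collapses atom-level variants to (type, residue pair),
because stability discussions are residue-level. Occupancy over a
trajectory is the fraction of frames in which a key is present; ≥ 50 %
(inclusive) is flagged *stable*. Histidine is treated as charged only when
both ring nitrogens carry explicit protons — no protonation engine is in
scope, so the input structure decides.

## Trajectory metrics

RMSD series superpose each frame on the reference (first frame by
default) over Cα — the usual convention for complex-stability plots —
and the selection is configurable. Convergence, usually called by visual
inspection, is formalised as a declared surrogate rule: the earliest time
from which every subsequent sliding-window mean (window 20 ns) stays
within 0.5 Å of the others through the end; the trailing window alone is
excluded because a single window is trivially flat.

RMSF uses the mean structure after two rounds of iterative superposition
as its reference (the panel default in the original tooling is
undocumented). Note a small systematic effect: superposition absorbs six
rigid degrees of freedom, so on an $N$-atom Cα selection the measured RMSF
of pure isotropic jitter with per-coordinate sd $\sigma$ converges to
slightly below $\sigma\sqrt{3}$ — about $\sigma\sqrt{3}\,(1 - 2/N)^{1/2}$.
At the default toy sizes this is a ~4 % deflation, within the 5 % band the
tests assert at 2000 frames.

Trajectory clustering samples every `stride`-th frame (the "frequency"
setting of panel tools; an every-10th-ns protocol maps to a frame stride
through the frame spacing, which such protocols rarely print),
builds a per-pair-refit heavy-atom RMSD matrix, cuts the dendrogram at
`min(max_clusters, Kelley optimum)` and reports the medoid of the largest
cluster.

## The surrogate binding energy

Commercial MM-GBSA implementations (Prime with VSGB solvation) are
closed and cannot be reimplemented from their documentation, so
`bindmode` substitutes a *declared* surrogate with the same end-point
structure,
$\Delta G_\mathrm{bind} = G_\mathrm{complex} - G_\mathrm{receptor} - G_\mathrm{ligand}$
under the single-trajectory convention (separated partners keep the
complex geometry; cross-interface terms are dropped, nothing is
re-minimised). Components, all configurable:

* **vdW** — 12-6 Lennard-Jones with per-element parameters
  (Lorentz–Berthelot combination), 10 Å cutoff;
* **electrostatics** — Coulomb between per-residue formal-charge centres
  (Arg/Lys +1, Asp/Glu −1, His +1 only if doubly protonated, nucleotides
  −3/−4 on the phosphates) with distance-dependent dielectric
  $\varepsilon(r) = 4r$, 12 Å cutoff;
* **H-bond** — −1.0 kcal/mol per detected cross-interface hydrogen bond;
* **lipophilic** — −0.1 kcal/mol per apolar (C/S) cross-interface
  heavy-atom pair within 4.5 Å.

Because floating-point addition is not associative, computing the G terms
first and subtracting would leave the two identities the decomposition
promises ($\Delta G = G_c - G_r - G_l$ and $\Delta G = \sum$ components)
agreeing only to rounding. The implementation therefore computes the
cross-interface component sums directly, *defines*
$\Delta G_\mathrm{bind}$ as their sum, and defines
$G_\mathrm{complex} := G_r + G_l + \Delta G_\mathrm{bind}$; both
identities then hold to machine precision by construction. The intra-
partner G terms are reported for scale only (non-bonded pairs from
different residues at ≥ 2.5 Å) and cancel exactly in the difference.
Absolute magnitudes of this surrogate are *not* comparable to published
MM-GBSA tables, and the package makes no such claim.

**Alanine scanning** truncates a residue's side chain to Cβ on the
unrelaxed geometry and recomputes the surrogate energy;
$\Delta\Delta G = \Delta G_\mathrm{mut} - \Delta G_\mathrm{wt}$, positive
meaning weakened binding. Glycine is flagged and skipped; alanine
truncates to itself, so its $\Delta\Delta G$ is exactly zero, as is that
of any residue whose atoms touch no cross-interface term within the
cutoffs. The hotspot threshold is 1.0 kcal/mol, a conventional value:
published alanine-scan analyses rarely state their cutoff for a
"significant decrease" in binding. Consensus over multiple scanner tables (the package's own, or
externally supplied ones) is a Borda rank sum with ties broken by residue
number, and a residue is a consensus hotspot when flagged in at least half
the tables. Hot regions are single-linkage groups of hotspots at 12 Å Cα
cutoff — roughly two helix diameters, matching the intuition that hot
regions are contiguous surface patches.

## The synthetic world

All tests and the acceptance studies run on generated inputs; what the
generators emulate, and what they do not, bounds what a green test
establishes.

**Toy complexes** are two short chains in idealised extended geometry
facing each other across an 11 Å backbone separation, alanine filler plus
typed residues at planted contacts: a Lys–Glu salt bridge at 3.0 Å, a
Ser–Asn hydrogen bond at 2.9 Å and a Leu–Leu hydrophobic pair at 4.0 Å,
placed exactly (backbone jitter sd 0.02 Å decorates everything else).
Side chains are reduced to Cβ plus one functional pseudo-atom bearing the
residue's real functional atom name — enough for every detection rule and
the surrogate energy, while full rotamer geometry stays out of scope. A
toy therefore validates the *logic* of detection, energetics and scanning;
it says nothing about performance on real side-chain geometry, crystal
contacts or waters.

**Pose ensembles** default to 9 engines × 5 poses with near-native
fraction 0.6, noise sd 1 Å and decoys at ≥ 15 Å ligand-RMSD — the regime
in which a consensus strategy is expected to work. The noise parameter is
read as the pose-level RMSD scale: translations use per-component sd
$\sigma/\sqrt{3}$ (expected displacement magnitude $\sigma$) and rotation
angles sd $\sigma / r_\mathrm{gyr}$ (rms atom displacement about
$\sigma$), fixed a priori. Decoys are uniformly rotated and displaced in a
random direction, resampled on steric clash (< 2 Å cross contact) or
insufficient displacement. With near-native fraction 0, recovery is not
expected — that negative control is part of the test suite.

**Trajectories** are isotropic Gaussian jitter about a start structure,
optionally with a sinusoidal rigid displacement of a residue range to
emulate a breathing helix. They have no physics: no correlations, no
conformational substates (unless planted), no solvent. They validate the
estimators (RMSD, RMSF, occupancy, per-frame energy averaging), not any
claim about real dynamics.

All generators restore the caller's RNG state and are bit-reproducible
given their seed; the end-to-end pipeline writes byte-identical artifacts
on same-seed reruns.

## Degenerate inputs and numerical choices

* Duplicate poses / identical frames: flat-spread guard in the Kelley
  normalisation (tolerance $\max(10^{-9}, 10^{-9}\,s_{max})$); trajectory
  clustering returns a single cluster when the whole RMSD matrix is at
  noise level.
* Kabsch on fewer than 3 or collinear correspondence atoms errors rather
  than returning a degenerate rotation.
* Alternate locations resolve to the highest occupancy (ties: first
  record); insertion codes are part of residue identity and residue ranges
  exclude inserted residues unless listed explicitly.
* Waters are dropped on read by default; cofactors (GTP and friends) are
  kept and counted on the ligand side of the interface, since
  nucleotide-proximal distances are part of the downstream analyses.
  Whether cofactors accompanied the ligand during the original docking is
  unstated there; the flag exists for the other choice.
* "Standard error" in end-point energy tables is ambiguous (sd vs
  sd/√n); both are reported, with sd/√n labelled primary.

## Worked example

```{r example}
toy <- build_toy_complex(toy_spec(seed = 3))
gen <- generate_pose_ensemble(toy, ensemble_spec(seed = 7))
ens <- superpose_on_receptor(gen$ensemble)
cl <- consensus_pose(ens, kelley_optimal_k(rmsd_matrix(ens)))
cl

lh <- select_atoms(ens$ligand_template, heavy = TRUE)
coord_rmsd(cl$centroid_pose$ligand_coords[lh, ], gen$truth_coords[lh, ])

detect_interactions(complex_from_pose(ens, cl$centroid_label))[, c(1, 3, 7, 10)]
```

## Known limitations

* The surrogate energy ranks and classifies; it does not predict
  measurable affinities, and no comparison against published MM-GBSA
  magnitudes is intended or valid.
* Reduced side chains mean rotamer-dependent effects (bifurcated H-bonds,
  buried salt bridges) are outside the tested world.
* π-stacking and aromatic H-bond definitions are declared, not claimed
  identical to any commercial panel's unpublished geometry.
* Cluster counts and cluster sizes published for real consensus-docking
  campaigns depend on their (unreleased) pose sets and are not
  reproduction targets; the package's acceptance surfaces are the
  property-based recovery studies in `tests/testthat/test-acceptance.R`
  and `scripts/acceptance.R`.
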