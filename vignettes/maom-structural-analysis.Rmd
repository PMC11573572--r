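---
title: "Structural analysis of mineral-associated organic matter with maomtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural analysis of mineral-associated organic matter with maomtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maomtools)
```

## The problem

Mineral-associated organic matter (MAOM) is soil organic matter (SOM)
stabilized by association with mineral surfaces — smectite clays with
permanent negative layer charge, or neutral Fe-oxyhydroxides such as
goethite. Molecular simulation of these systems produces configurations
of thousands of atoms: a mineral slab, dozens of small organic
molecules (~70–300 Da), charge-balancing cations (Na⁺ or Ca²⁺),
explicit water, and a vapor gap above the liquid. The scientific
questions are structural: which molecules aggregate into a hydrophobic
cluster, which are sorbed to the mineral and through which mechanism
(direct contact, cation bridging, or attachment through auxiliary SOM
molecules), how much of the mineral surface is actually covered by
organics versus water and ions, and which chemical features of a
molecule predict its clustering and bridging behavior.

`maomtools` implements this post-processing pipeline as a tested R
package. Because public trajectory data for such systems are generally
not deposited, the package also ships a synthetic-scene generator that
plants configurations with *known* sorption labels and cluster
memberships, so that every stage of the pipeline can be validated
exactly at desk scale.

## The classification model

Every SOM molecule in a frame receives exactly one sorption label, by
priority:

1. **VAPOR** — molecule centroid above `z* + 2·s`, where `z*` is the
   liquid surface and `s` the interfacial shell half-width;
2. **DIRECT** — any heavy atom within `d_direct` of a mineral atom;
3. **CATION_BRIDGED** — some cation within `d_cat_surf` of the mineral
   *and* within `d_cat_som` of the molecule's O/N atoms;
4. **SOM_BRIDGED** — same contact-graph component as a DIRECT or
   CATION_BRIDGED molecule;
5. **INTERFACE** — centroid within `±s` of `z*`;
6. **FREE** — otherwise.

DIRECT outranks CATION_BRIDGED for molecules satisfying both, because a
cation-bridged monomer is the distinguishing case only when no direct
contact exists. A single label per molecule keeps mode percentages an
exact partition (they sum to 100 by construction); the full bonding
detail remains available in the graph.

The contact graph joins molecules whose heavy atoms approach within
`r_c` under the minimum-image convention; hydrogens are excluded
throughout (consistent with the SASA convention below). An optional
edge kind records divalent-cation bridges: a +2 cation within `r_ion`
of O/N atoms of two different molecules. Whether such bridges should
count toward the "hydrophobic cluster" is genuinely ambiguous in the
literature this follows, so both behaviors are exposed
(`include_divalent_bridges`), with plain contacts as the default.

A *bridging* molecule is a sorbed one (DIRECT or CATION_BRIDGED) with
at least one graph edge to a non-sorbed neighbor — the molecules that
anchor the hydrophobic cluster to the surface.

### Parameters and defaults

| parameter | default | units | meaning |
|---|---|---|---|
| `r_c` | 3.5 | Å | heavy-atom SOM–SOM contact cutoff |
| `d_direct` | 3.5 | Å | SOM–mineral contact cutoff |
| `d_cat_surf`, `d_cat_som` | 3.0 | Å | cation–mineral and cation–O/N cutoffs |
| `r_ion` | 3.0 | Å | divalent-bridge coordination cutoff |
| `interface_shell` | 3.0 | Å | half-width of the interfacial band |
| `density_bin` | 0.2 | Å | water density-profile bin |
| `d_fe_o` | 2.6 | Å | metal–O coordination ceiling (ligand exchange) |
| `probe_radius` | 1.4 | Å | water-probe radius for SASA |
| `n_sphere_points` | 960 | — | Fibonacci points per atom |

3.5 Å is the conventional heavy-atom contact criterion; 3.0 Å is a
typical first-shell cation–oxygen distance ceiling; 2.6 Å bounds the
Fe–O first coordination shell. Published MAOM analyses rarely state
their exact cutoffs, so all of them are configurable here and the
defaults are pinned in the test suite.

## The liquid surface

`locate_liquid_surface()` bins water-oxygen z-coordinates, estimates
the bulk plateau as the median bin count over the central liquid region
(10th–60th percentile of water z), and reports the upper edge of the
highest bin still reaching 50% of that plateau. Taking the *highest*
crossing makes the estimate immune to interior Poisson dips; only water
above the surface could mislead it, and there is none. This is a global
density-profile definition, not an intrinsic-surface construction: it
is the simplest contract that operationalizes the interface/vapor
distinction, and it is what the interfacial-shell margins in the
generator are sized against. A capillary-wave-resolving intrinsic
surface would be the natural extension.

## Surface layers and Voronoi coverage

`assign_layers()` bins the z-density of non-mineral heavy atoms above
the top mineral plane and places layer boundaries at resolvable minima:
a smoothed local minimum below half the peak since the previous
boundary, below half the tallest remaining peak (or the trailing decay
after the last peak), and below half the typical occupied level. The
last clause prevents Poisson noise in an unstructured fluid from faking
layers; when fewer than the requested minima resolve, fixed 3.0 Å bands
are used and flagged. The synthetic scenes place water uniformly (no
layering physics), so generated scenes exercise the fallback path by
design; the minima path is exercised by banded fixtures.

`layer_coverage()` projects a layer to the x–y plane, replicates the
sites in the 3×3 periodic images, and clips each central site's Voronoi
cell by perpendicular bisectors. First-ring image bisectors bound every
cell within half a box length per axis, so 3×3 replication is exact and
the cell areas sum to `lx·ly` (asserted to 1e-9 relative in tests).
Sites that project to the same point — vertically stacked atoms —
share one cell, split evenly. Coverage is area-weighted (every layer
atom owns its cell); count-weighted fractions are emitted alongside,
since either weighting is defensible and published analyses rarely say
which they used.
A radius-weighted power diagram would be the refinement.

## SASA

`shrake_rupley_sasa()` is a deterministic Shrake–Rupley: per heavy
atom, the fraction of golden-angle Fibonacci points on the
probe-expanded sphere not inside any other heavy atom's expanded
sphere. Polar area is the O/N-attributed part, apolar the rest;
hydrogens neither contribute nor occlude. SASA is computed per molecule
in isolation (no neighbors, no periodic images) because it feeds a
per-species descriptor table, not a buried-interface analysis.

One numerical subtlety: a sample point lying exactly *on* another
atom's expanded sphere is a measure-zero tie, but it is the generic
situation for exactly coincident atoms. The implementation resolves
boundary ties (within 1e-8 Å) by atom index — lower-index atoms occlude
— so two coincident identical atoms yield exactly the single-atom area
rather than 0 (both occluded) or double (both exposed). For
non-degenerate geometry the tie shell is irrelevant.

## Statistics

Spearman coefficients are computed as Pearson correlation of
average-tied ranks, validated against a naive rank-then-Pearson oracle
to 1e-12 including ties. Correlations are species-level: copies and
frames pool into one clustering (and one bridging) probability per
species before ranking, matching a per-molecule-type analysis; no
p-values are attached by default. Missing descriptor values (logP is an
optional pass-through, never computed) drop pairwise with `n` reported.
The sub-200 Da mass trend is an ordinary least-squares fit on the
strictly-sub-threshold species only. Replica (temperature-ladder)
averaging is unweighted, since the systems this mirrors showed no
qualitative temperature dependence, with across-replica SD reported.

## The synthetic-scene generator

`build_scene()` constructs an orthorhombic box (default 120×120×100 Å,
periodic in x and y) containing:

- a three-plane lattice slab (O/Si/O, 2.6 Å spacing) — SMECTITE_LIKE
  marks a fraction (default 5%) of mid-plane sites charged −1;
  OXIDE_LIKE is neutral with Fe sites on every second top-plane node,
  each paired with a ligand-water oxygen 2.0 Å above it;
- 84 SOM molecules (20 species, 8 peptide copies) with per-label
  counts (default 8 direct / 6 cation-bridged / 12 SOM-bridged /
  42 free / 10 interface / 6 vapor);
- counterions balancing the total charge exactly (bridging cations
  placed geometrically, the rest by seeded rejection sampling ≥6 Å from
  any SOM atom);
- water oxygens by seeded rejection sampling at ≥2.4 Å spacing up to
  the nominal liquid height (60% of the box), with a vapor gap above.

Molecules are rigid "blob" templates: deterministic self-avoiding
walks, 1.5 Å steps, ≥1.2 Å pair spacing, radius capped at 4.3 Å.
Chemistry (element counts, charges, ring/COOH/amine counts, logP) lives
in the species records; the geometry carries shape only. This is the
central honesty point of the package: a green label-recovery test
establishes that the *classifier* implements its stated geometric
contract exactly — it does not establish anything about force-field
energetics, water structure, or the real-world values of cluster
fractions, which require full replica-exchange sampling of the actual
systems.

Placement margins: every planted distance sits well inside its
classifying cutoff (direct anchors at 2.8 vs 3.5 Å; cation bridges at
2.3 vs 3.0 Å; chain contacts at 2.8 vs 3.5 Å; separations ≥ ~5 Å
against spurious contacts at 4.1 Å). With jitter σ = 0.1 Å the standard
deviation of a pair distance is ≈0.14 Å, so the effective margins are
≈5σ; the stated rule `3σ < δ` (δ = 0.5 Å) is therefore conservative in
expectation but, Gaussian tails being unbounded, recovery is
*near*-exact rather than literally exact — the per-pair violation
probability is ~1e-7, and all tests fix their seeds. Cross-unit
separations are additionally enforced by an explicit post-placement
verification (no SOM–SOM proximity ≤4.2 Å across planted clusters, no
non-DIRECT molecule within 4.2 Å of the slab) with up to 25
deterministic re-rotation attempts.

The default water fill (3,500 molecules) is far below liquid-water
density; it exists to give the surface locator a clean plateau, not to
model solvation. Water plays no role in any label. Evaporated (VAPOR)
molecules are always drawn from neutral species, mirroring the physical
observation that charged molecules do not evaporate (no artificial
dipole across the cell).

Ligand-exchange plants (OXIDE_LIKE): a donor molecule's oxygen replaces
a displaced ligand water 2.0 Å above an Fe site; detection is purely
geometric (SOM oxygen within `d_fe_o` while the paired ligand oxygen is
farther) and makes no bond-order claim.

## Degenerate inputs and tie-breaks

- Largest-cluster ties resolve to the component containing the smallest
  molecule id; component ids *are* their smallest molecule id.
- Coincident Voronoi sites share one cell, split evenly.
- Constant vectors give `NA` Spearman coefficients (an undefined-result
  signal), never an error or a crash.
- An empty coverage layer returns a flagged all-zero row.
- Triclinic boxes, non-periodic x/y, and cutoffs ≥ half a periodic box
  length are rejected with explicit errors.

## Known limitations

- No trajectory formats requiring binary decoders (XTC/DCD); GRO, XYZ
  and PDB only, with a JSON topology sidecar.
- The species library is a statistically analogous stand-in for the
  (non-public) 20-molecule dissolved-organic-matter model: masses,
  charges and functional-group counts mirror the stated ranges, but the
  structures are abstract.
- Layer detection is density-profile based, not probe-sphere intrinsic.
- No kinetics, residence times, or energetics anywhere; percentages and
  probabilities are purely occupancy statistics of the supplied frames.
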