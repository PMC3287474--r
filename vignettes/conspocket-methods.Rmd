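---
title: "conspocket: methods, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{conspocket: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`conspocket` predicts ligand binding sites by intersecting two independent
signals:

* **Geometry.** Binding sites sit in concave crevices. We mark an atom as
  a *cleft* atom when it is solvent-exposed (per-atom SASA > 1 Å²) yet not
  part of the protein's convex "outside" — the convex-hull vertex atoms
  expanded by 6.5 Å. A perfectly convex body has an empty cleft set; every
  invagination deeper than the expansion horizon survives.
* **Evolution.** Functional residues are conserved. Residues with a
  ConSurf-style colour grade ≥ 7 (on the ordinal 1–9 scale, 9 = most
  conserved) contribute their atoms to the conserved set; the *potential*
  set is the intersection of cleft and conserved atoms.

Potential atoms are clustered by single linkage (threshold cut), cluster
centres closer than 8 Å are merged with centre recomputation iterated to a
fixpoint, and pockets are ranked by the summed conservation grade of their
distinct member residues (volume ranking is available as an alternative).
The final assumption — standard in this family of methods — is that the
geometric centre of a correct pocket lands within 4 Å of the bound ligand.

Conservation grades are treated strictly ordinally and are only ever
compared or summed *within* one structure; grades are not comparable across
protein families, which is why the pipeline never mixes them between
structures.

## Parameters

| parameter | default | unit | status |
|---|---|---|---|
| SASA probe radius | 1.4 | Å | water probe, standard |
| SASA lattice points | 960 | – | implementation choice (see below) |
| surface threshold | 1.0 (strict >) | Å² | published procedure |
| hull expansion | 6.5 | Å | published procedure |
| conservation cutoff | 7 (≥, or none) | grade | published procedure |
| atom linkage cut | 4.5 | Å | implementation choice |
| centre merge distance | 8.0 | Å | published procedure |
| min pocket atoms | 3 | – | implementation choice |
| hit cutoff | 4.0 (inclusive ≤) | Å | published criterion |
| volume voxel | 1.0 | Å | implementation choice |

Notes on the choices that were genuinely open:

* **Surface threshold units.** The source procedure states the SASA
  threshold as "over 1 Å"; an area must be meant, so we read 1 Å² and use a
  strict inequality to match "over".
* **Atom-level linkage cut (4.5 Å).** Only the centre-merge distance (8 Å)
  is published. Single linkage with a threshold cut is the one
  "simple hierarchical clustering according to spatial distances" that
  needs no extra criterion; 4.5 Å is roughly a heavy-atom contact distance
  plus slack, and both it and the possibility of reusing 8 Å are exposed as
  flags (`--atom-link-dist`). The parameter sweep harness is the place to
  study sensitivity.
* **Score aggregation (sum, not mean).** "Conservation score of all
  residues in the cluster" is aggregated by summation over distinct
  residues: a large conserved pocket should outrank a tiny equally
  conserved one, and the contrast with volume ranking only makes sense if
  size contributes. Each residue counts once however many of its atoms are
  members; `aggregate = "mean"` is available.
* **Pocket volume.** No volume definition is published. We use the volume
  of the union of probe-inflated member-atom spheres (r_vdw + 1.4 Å),
  estimated by counting voxel centres on a grid anchored at global
  multiples of the step — deterministic, monotone in pocket size,
  translation-consistent to one voxel shell, and convergent to the analytic
  union volume as the step shrinks. Volume-ranked numbers are therefore a
  reimplementation proxy, not comparable in absolute terms to any other
  tool's volumes.
* **Expansion from hull vertices only**, centre-to-centre, inclusive ≤.
  The alternative (all atoms of hull facets) is not distinguishable from
  the text; vertices-only is cheaper and well-defined.
* **Ties.** Pockets are ordered by (score desc, member count desc, smallest
  member serial asc); clusters before ranking by (size desc, smallest
  serial asc). All output is bit-deterministic; there is no RNG anywhere in
  the prediction path.

## Numerical choices

* **SASA** is Shrake–Rupley with a golden-spiral lattice — deterministic,
  no seed. 960 points give ≲ 0.5 % error on an isolated sphere (exactly 0
  for a free atom, since all points are unoccluded) and ≤ 2 % against the
  two-sphere spherical-cap closed form in the tests. The lattice is
  oriented per atom in a frame built from its two nearest neighbours, so it
  co-rotates with the structure: SASA, and everything downstream, is
  rigid-motion equivariant to floating point, not merely
  translation-invariant. Isolated atoms and collinear neighbourhoods fall
  back to the global axes.
* **Convex hull** is an incremental 3-D hull (compiled) with a visibility
  tolerance of 1e-9 of the coordinate range — far below the 1e-3 Å
  precision of PDB coordinates. Inputs with fewer than 4 atoms, or
  collinear/coplanar inputs, raise a geometry error. The hull vertex set is
  verified in the tests against a linear-programming membership oracle
  (a point is a vertex iff it is not in the convex hull of the others).
* **Clustering** delegates to `stats::hclust(method = "single")` with
  `cutree(h = d)`, which keeps merges at height ≤ d — the inclusive
  contract; an independent union-find over all pairs serves as the test
  oracle.
* **Degenerate inputs.** An empty potential set is a "no pocket found"
  outcome (empty list, CLI exit status 3), never a crash; clusters smaller
  than `min_pocket_atoms` are dropped to suppress single-atom noise
  pockets; structures without any ligand are reported as *skipped* in
  benchmarks, separately from evaluated misses, so TOP-N denominators are
  auditable.

## The synthetic fixture generator

Real benchmark corpora for this task are assembled from external structure
databases plus per-chain conservation profiles; the package instead ships a
generator whose ground truth is known by construction:

* a ball of carbon pseudo-atoms on a jittered cubic grid (spacing 3 Å,
  jitter ±0.75 Å, shell radius 18–21 Å — roughly a small single-domain
  protein);
* per pocket, a cylindrical invagination carved along a chosen direction
  (mouth radius 6.5–7.5 Å, depth 10–11 Å) with a 3–8 atom ligand seated
  just above the pocket floor;
* singleton residues (or 3-atom residues in a variant that exercises
  residue-level score aggregation) with conserved grades (7–9) on pocket
  linings with probability 0.9 and background grades drawn from a fixed
  distribution (~20 % of background residues reach grade ≥ 7) elsewhere;
* optionally a *decoy* pocket: carved like a real one, slightly larger, but
  with background-graded lining and no ligand.

Geometric constraints worth recording: mouths must be wider than ~6.5 Å so
that walls of 1.87 Å united atoms still admit the 1.4 Å probe to the lining
(narrower mouths produce linings with SASA ≈ 0 and no detectable cleft);
depths of 10–11 Å put the pocket floor well below the 6.5 Å expansion
horizon; and pocket directions are placed 120° apart in a randomly oriented
plane so the lining bands of distinct pockets stay more than one linkage
cut apart — deep antipodal pockets on a small ball otherwise chain through
the core into a single merged cluster centred at the origin.

Decoys are what make the no-conservation control informative: without them,
switching the filter off barely changes a suite in which every carved cleft
carries a ligand. With decoys, the geometry-only pipeline regularly ranks a
large unconserved cleft first, while the filtered pipeline rejects it — the
package's benchmark reproduces that contrast (the filtered TOP-1 rate is an
upper bound for the unfiltered one on these suites by construction, since
decoys carry no ligand).

What the fixtures do **not** emulate: real backbone chemistry and packing
density, heteroatom diversity, mixed radii, partially conserved patches,
conservation-map coverage gaps, crystal-contact artefacts. Passing the
synthetic benchmark therefore demonstrates internal correctness of the
pipeline and the informativeness of the conservation filter under
controlled conditions — not field accuracy on crystal structures, which
depends on external data quality (notably ConSurf coverage and chain-ID
agreement).

All randomness in the generator flows from one integer seed; per-fixture
seeds are `1000 * master + index`, so any fixture regenerates in isolation,
and fixture files are byte-identical across runs.

## Problem sizes

The shipped tests run the full pipeline on fixtures of ~800–1500 atoms; the
end-to-end benchmark uses 50 fixtures (about half a minute in total), the
hull oracle 20 instances of 200 points, and the clustering oracle 20
instances of 100 points at cuts of 2, 4 and 8 Å. These sizes were chosen to
exercise every code path with comfortable statistical margins while keeping
the default check fast.

## Known limitations

* HETATM entities are all treated as ligands for evaluation (with an
  optional exclusion list); crystallographic additives like glycerol or
  sulfate will count as binding sites unless excluded.
* Grade files must use the PDB's chain identifiers (a `chain_map` argument
  handles renamed chains); residues missing from the grade map are treated
  as unconserved, with a warning once more than 10 % of residues are
  unmapped.
* The cleft definition cannot see fully enclosed cavities' mouths or
  distinguish adjacent sub-pockets closer than the merge distance.
* Only the first MODEL of multi-model files is read; mmCIF is not
  supported.
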