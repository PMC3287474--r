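# conspocket

Predicting where a small-molecule ligand binds on a protein structure, by
combining surface **geometry** with residue **evolutionary conservation**.

Purely geometric pocket detectors (SURFNET, PASS, PocketPicker, LIGSITE and
relatives) find every concavity on a protein surface, but a concavity is not
necessarily a functional site. Functional sites are under selective
pressure, so their residues tend to be conserved. `conspocket` implements a
simple, grid-free predictor that uses conservation both to *filter*
candidate cleft atoms and to *rank* the resulting pockets.

## Method

For a protein with heavy atoms `A` (ligands and waters removed):

1. **Surface set `S`** — per-atom solvent-accessible surface area (SASA) by
   the Shrake–Rupley method (probe 1.4 Å, deterministic golden-spiral
   lattice, 960 points/atom); an atom is surface if SASA > 1 Å².
2. **Expanded hull set `Q`** — the vertices of the 3-D convex hull of all
   atom centres, plus every atom within 6.5 Å of a hull vertex atom. `Q`
   approximates the convex "outside" of the protein.
3. **Cleft set** — `S \ Q`: surface atoms that are *not* part of the convex
   outside, i.e. atoms lining crevices.
4. **Conserved set `C`** — atoms of residues whose ConSurf-style
   conservation grade (1 = variable … 9 = conserved) is ≥ 7.
   **Potential set `P`** = cleft ∩ `C`.
5. **Pockets** — single-linkage clustering of `P` cut at 4.5 Å; cluster
   centres within 8 Å are merged (iterated to a fixpoint, centres
   recomputed as the mean over member atoms).
6. **Ranking** — pockets are ordered by the sum of conservation grades over
   their distinct member residues (or, alternatively, by an estimated
   pocket volume: the union of probe-inflated atom spheres on a 1 Å voxel
   grid).

A prediction is evaluated with the PocketPicker criterion: a ranked centre
is a **hit** if it lies within 4 Å of any ligand atom; TOP-*N* is the
fraction of structures with a hit among the *N* best-ranked pockets.

Because hull, distances and linkage are all coordinate-frame free — and the
SASA lattice is oriented in a per-atom neighbour frame — predictions are
equivariant under rotation/translation of the input, unlike grid-based
detectors.

## Worked example

No downloads are needed: the package ships a deterministic generator of
pseudo-protein fixtures with planted, conserved, ligand-bearing pockets.

```r
library(conspocket)

fix <- make_pocketed_structure(fixture_spec(seed = 7))
fix$complex
#> <protein_complex> synthetic_seed7: 845 protein atoms, 8 ligand atoms (1 ligand group), 0 water(s) removed

pockets <- predict_pockets(fix$complex, fix$cmap)
attr(pockets, "stats")
#>        n_S        n_Q    n_cleft        n_C        n_P n_clusters  n_pockets
#>        354        636         19        229         18          1          1

pred <- rank_pockets(pockets, "conservation", cmap = fix$cmap,
                     atoms = fix$complex$protein, structure_id = "demo")
pred
#> <ranked_prediction> demo: 1 pocket(s) ranked by conservation
#> <pocket> 18 atoms / 18 residues, centre (5.97, 0.35, -0.04), rank 1 score 141.0

evaluate_structure(pred, fix$complex)$top1_hit
#> [1] TRUE
```

Reading: of 845 protein atoms, 354 are surface (`S`), 636 belong to the
expanded convex hull (`Q`), 19 line crevices (cleft), 18 of those are
conserved (`P`), and they form one pocket whose centre falls within 4 Å of
the planted ligand — a TOP-1 hit. The score 141 is the summed grade of the
18 pocket residues.

For real structures: `read_pdb("xxxx.pdb")` + `parse_grades("grades.tsv")`
(ConSurf-DB grades tables and a plain `chain/resno/grade` TSV are both
supported), then the same calls as above.

## Command line

```sh
Rscript inst/cli/conspocket.R predict protein.pdb grades.tsv --out-dir out/
Rscript inst/cli/conspocket.R fixtures --n 50 --seed 1 --out-dir suite/
Rscript inst/cli/conspocket.R eval suite/manifest.tsv --out-dir eval/
Rscript inst/cli/conspocket.R sweep suite/manifest.tsv \
    --expand-dists 5.5,6.5,7.5 --cutoffs none,7,8 --out-dir sweep/
```

All reports embed the full parameter set and carry no timestamps, so
identical invocations are byte-identical.

## Scope

Conservation grades are consumed precomputed (ConSurf-DB files or TSV);
computing conservation from an alignment, mmCIF input, NMR ensembles and
druggability scoring are out of scope. See the methods vignette
(`vignettes/conspocket-methods.Rmd`) for the model, parameter rationale and
limitations.
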