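---
title: "Methods: mesh volumetrics and tissue composition for a virtual worm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mesh volumetrics and tissue composition for a virtual worm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormvolumes)
```

## The measurement model

A cell in a mesh-based anatomy model is a closed triangle surface. For a
watertight, consistently outward-oriented surface the enclosed volume is the
divergence-theorem sum of signed origin-anchored tetrahedra,

$$V = \frac{1}{6}\sum_{\text{faces}} \det[\,v_0\; v_1\; v_2\,],$$

which is exact for polyhedra up to floating-point accumulation and
independent of where the origin sits. The assumptions are explicit and
checked, not hoped for:

* **Watertight** — every edge shared by exactly two faces. `validate_mesh()`
  counts boundary edges (one face) and non-manifold edges (three or more);
  either kind voids the volume's meaning.
* **Consistently oriented** — every shared edge traversed in opposite
  directions by its two faces. A consistently *inward* surface merely
  negates the sign, which is why measured volumes are reported as absolute
  values and the sign is kept as a diagnostic.
* **Polyhedral exactness** — no quadrature error; the only numerical error
  source is summation, handled by computing per-face contributions
  vectorised and reducing with `sum()`, which accumulates in extended
  (long-double) precision — a compensated reduction in effect. Equality
  tests throughout the package use a 1e-9 relative tolerance.

Self-intersecting or mutually nested meshes are measured as-is (the
divergence sum then reports outer-minus-inner for a nested shell, which is
exactly what a cuticle-like structure wants); adjacent-cell overlap is a
modelling artefact this package measures faithfully rather than arbitrates.

## Calibration

Model files carry arbitrary "model units". Following the convention of the
workflow this package reimplements, a reference object of known physical
size — the `100um_cube`, defined as 100 × 100 × 100 = 1,000,000 µm³ — is
measured in model units and the ratio becomes a single volumetric factor
(µm³ per model-unit³). We deliberately calibrate volume-to-volume with one
division rather than deriving a linear scale factor and cubing it back: the
root/cube round trip adds nothing but rounding.

## Orientation repair and the defective-mesh policy

`repair_orientation()` propagates a reference winding breadth-first across
shared edges within each connected component, then flips any closed
component whose signed volume is negative, so all shells end up outward.
For the common single-component mesh this is exactly "make windings
consistent, then flip everything if the volume is negative"; doing the sign
fix per component keeps multi-shell input correct, where a single global
flip could turn one shell inward.

The default measurement policy is **exclude, don't repair**: a mesh that
fails validation is carried through the output with `excluded = TRUE` and
`NA` volumes, because the source workflow defines no repair protocol and an
audited hole in the table beats a silently invented surface. `policy =
"repair"` opts into orientation repair for watertight meshes; punctured
meshes are never repairable here. Duplicate vertices are counted but never
merged (merging changes topology; the count is a smell detector).

## Anatomy: syncytia, ploidy, genome equivalents

The worm's cytology breaks the naive cell ↔ nucleus ↔ genome equivalences:
hyp7 is one cell with 139 nuclei, pharyngeal muscle pm1 has 6, and
young-adult intestinal cells are 32C polyploid. The anatomy table stores
`nuclei` per cell and `ploidy_c` as a **per-nucleus C-value**, and
`genome_equivalents() = nuclei × ploidy_c / 2` is always computed, never
stored — so a binucleate intestinal variant is expressible as
`nuclei = 2, ploidy_c = 32` without double bookkeeping. Whether published
"16 diploid genomes (32C)" figures are per nucleus or per cell is genuinely
ambiguous for binucleate cells; the bundled fixture adopts the cell-level
reading (`nuclei = 1, ploidy_c = 32` → 16 genome equivalents) and documents
the convention in its header so either choice can be expressed explicitly.

The bundled `inst/extdata/celegans_anatomy.csv` is deliberately **partial**:
it carries the well-attested records (hyp7, pm1–pm8, the 20 intestinal
cells, cuticle, a germline pseudo-record) with provenance comments, not a
fabricated census of all 959 somatic cells. The germline nuclei count is an
approximate literature point value (~1000 germ nuclei plus ~300 stored
sperm); it is flagged `somatic = FALSE` and is toggled as a unit.

Regrouping (`regroup()`) rewrites tissue labels only — separating cuticle
from hypodermis collections, rachis/germ cells from somatic gonad — and is
required to be total over the observed collections so a forgotten mapping
fails loudly. Total volume is conserved exactly because nothing numeric is
touched.

## Aggregation conventions

* Volume, nuclei and genome fractions are normalised over the tissues that
  remain after the exclusion set (default: cuticle) is removed.
* "Fraction below a threshold" uses **strict** inequality (`value <
  threshold`), matching the phrasing "below 1,000 µm³"; the non-strict
  variant is reported alongside since the two can differ on real data with
  ties.
* Percentages are rounded only at print time; raw fractions are retained.
* For ranking, `somatic gonad` and `germline` merge into `gonads` when the
  germline is included — the convention under which the published ordering
  *intestine > hypodermis > gonads > body wall muscle > pharynx > neurons*
  is stated. Ties break lexicographically and are flagged.
* Neuron volumes deserve a standing caveat rather than a correction: fine
  axonal structure is underrepresented in mesh models, so neuron totals are
  best treated as lower bounds.

## The synthetic worm: what it emulates, what it does not

`generate_worm()` writes a complete stated world: 60 cells across six
tissues (intestine 9, hypodermis 6, body wall muscle 12, pharynx 8,
neurons 20, somatic gonad 5), one hyp7-like syncytium fixed at 60% of the
hypodermis (139 nuclei, 2C), 32C intestinal cells, a nested-box cuticle
shell with zero nuclei, a germline capsule (`somatic = FALSE`, 1300
nuclei) and the 100-unit calibration cube. Tissue totals are fixed targets
(in µm³: intestine 340k, hypodermis 300k, body wall muscle 250k, germline
175k, cuticle 120k, somatic gonad 110k, pharynx 65k, neurons 40k; total
1.4e6) chosen once so the constructed composition reproduces the published
tissue ordering, puts the germline near 1/8 of the total, and sums to the
order of magnitude a whole-worm model reports. Within a tissue, cell sizes
are log-normal draws (sdlog 0.6, echoing the long-tailed empirical size
distribution) renormalised to hit the tissue target exactly; shapes cycle
through boxes, icospheres, brute-force convex hulls and capsules.

Ground truth discipline: the manifest stores **mesh-exact** volumes computed
by `convex_volume_oracle()` — centroid-anchored, winding-independent
tetrahedra, a deliberately different route from `signed_volume()`'s
origin-anchored signed sum — so end-to-end recovery tests compare two
computations, not a function with itself, and pass at 1e-9 relative without
tolerance tuning. Smooth closed forms (sphere, capsule) are kept for
convergence checks only, since an inscribed polyhedron is strictly smaller.
Expected aggregates in the manifest are computed with plain inline
arithmetic, not by calling the aggregation module.

What a green synthetic run does **not** establish: realistic cell shapes or
packing (geometry is schematic and non-overlapping by construction),
EM-fixation shrinkage (real models likely underestimate live volumes),
segmentation error, or the fidelity of any particular anatomy table. It
establishes that meshes are read, validated, measured, calibrated, joined
and aggregated correctly — the parts a download cannot be allowed to break.

## Numerical and design choices

* Faces are stored 1-based internally (R convention); the 1-based OBJ and
  0-based PLY/STL conventions are converted at the I/O boundary only.
* OBJ: only `v`/`f` records are interpreted; negative indices resolve
  against the vertex count at point of use; n-gons fan-triangulate from the
  first vertex (the common exporter behaviour).
* STL carries no vertex indexing, so reads weld vertices at exact
  coordinate equality to recover connectivity; binary STL is float32 and
  therefore lossy — round trips are exact only for float32-representable
  coordinates. PLY is written with double-precision coordinates in both
  ASCII and binary little-endian.
* The brute-force hull constructor tests all point triples (O(n⁴)) and is
  intended for the ≤ ~50-point clouds the generator uses; it requires
  general position, which continuous random clouds satisfy almost surely.
* Determinism: one global seed governs all generator randomness; report
  CSVs omit timestamps by default so identical inputs give byte-identical
  outputs.
* Translation invariance of the signed volume is a 1e-9 relative property
  at mesh-scale offsets; no floating-point implementation can hold that
  bound for origins arbitrarily far from a small mesh, and tests respect
  this.

## Limitations

Volumes inherit every bias of the source model: EM fixation shrinkage,
schematic neuron processes, unmodelled extracellular spaces (pseudocoelom,
uterine lumen). No inference across animals is attempted — one model, no
variance — and no correction maps model totals onto live-animal estimates.
The optional reproduction workflow against a full Virtual Worm OBJ export
and a published per-cell table (thresholds at 200 and 1,000 µm³ per diploid
genome, largest-cell and muscle-per-genome ratios) requires external
downloads and is documented in the README rather than run in the test
suite.
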