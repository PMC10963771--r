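---
title: "Face-based topological indices: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Face-based topological indices: models, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nfindex)
```

## The model

`nfindex` works on hydrogen-suppressed molecular graphs: vertices are heavy
atoms (here, carbons), edges are bonds, and hydrogens are never added — the
benzene skeleton has six vertices, all of degree 2. A graph on its own does
not have faces; a *plane* graph does. The package therefore stores, with
every graph, a combinatorial embedding: for each vertex the
counterclockwise cyclic order of its neighbours, derived from 2D
coordinates (`build_embedding()`). Faces are recovered purely
combinatorially as the orbits of directed edges under the traversal rule
"from (u, v), continue along (v, w) where w immediately precedes u in the
rotation at v". Every directed edge then lies in exactly one closed walk,
the total walk length is 2|E|, and Euler's relation V − E + F = 2 holds;
the test suite asserts all three on every constructed graph, including
randomly grown benzenoids.

With faces available, the descriptors are sums over faces: the face degree
d(£) adds vertex degrees over the vertices incident to £, its
neighbourhood version d\_n(£) adds neighbourhood degrees (degree sums of
open neighbourhoods), and the neighborhood face index is NFI(G) = Σ\_£
d\_n(£) over *all* faces, the unbounded one included. Including the
external face is not optional: the worked perylene example (304) and the
benzene value (48) both require it. For a 2-connected plane graph each
vertex is incident to exactly d(v) faces, giving the identity

NFI(G) = Σ\_v d(v)·d\_n(v) = 2 Σ\_{uv∈E} d(u)d(v),

i.e. twice the second Zagreb index. The package never uses this shortcut
in production code — indices are computed from the actual face
enumeration — but the tests use it as an independent oracle on hundreds of
structures, and it has a useful corollary: NFI is always even. That
corollary settles at least one defect in the published reference data (see
below).

Two conventions deserve explicit statement. First, the external face is
identified as the unique orbit whose boundary polygon has negative signed
area under the traversal above (internal faces come out counterclockwise);
if a degenerate drawing yields no negative orbit the largest-area orbit is
taken. Second, face degrees sum over *distinct* incident vertices. For
2-connected graphs — every structure treated here — boundary walks are
simple cycles and the distinction is vacuous; for other inputs the walk
revisits cut vertices, the operation counts each vertex once and emits a
warning, since no published value constrains that case.

## Exact lattice coordinates

Benzenoids are specified by hexagon cells in axial coordinates on the
pointy-top honeycomb lattice (`hexspec()`). Corners live on an integer
"doubled" grid: cell (q, r) has centre (u, y) = (2q + r, 3r) and corners
(u, y ± 2), (u ± 1, y ± 1). Fusing cells therefore deduplicates corners by
exact integer comparison — no floating-point tolerance is involved. The
true cartesian drawing scales x by √3/2 per unit; since a uniform positive
scaling of one axis preserves the angular *order* around every vertex, the
rotation system computed from the integer coordinates is the correct one.
Floating-point inputs (2D MOL/SDF files, `read_mol()`) use a relative
merge tolerance of 1e-6 of the median bond length instead. The nanosheet
builders use analogous integer schemes for the square-octagon and 4-6-8
lattices. Coordinates follow the mathematical convention: y grows upward,
angles are measured counterclockwise from +x.

## The 21-compound catalog

`benzenoid_catalog()` ships 21 benzenoid hydrocarbons with their published
NFI, Randić index, edge-connectivity index, π-electron energy and boiling
point. The property columns are stored exactly as printed and are data,
not derived quantities. The hexagon specifications were reconstructed from
the standard fusion structures and pinned by requiring each skeleton to
reproduce its published NFI; where a name abbreviates several isomers the
connectivity indices arbitrate when they can. Three naming decisions could
not be settled by the printed numbers alone and are recorded here: the
(a,h)- and (a,i)-dibenzanthracene entries share NFI and Randić values with
every candidate angular–linear–angular pentahex chain (the cis and trans
chains are index-isomorphic), so the trans chain was assigned to (a,h) and
the cis chain to (a,i) on structural grounds; the two dibenzopyrenes are
the centrosymmetric and non-centrosymmetric pyrene-plus-two-benzo
hexahexes, in that order.

`validate_catalog()` recomputes everything and compares: NFI exactly,
Randić at two decimals, ECI at four (half-away-from-zero rounding, the
convention used for every printed-value comparison in the package).
Twenty of 21 NFI values reproduce exactly. The 21st, triphenylene, is
printed as 255 — an odd number, which the parity corollary above rules out
for any molecular graph; the skeleton's value is 252. The connectivity
columns are less reliable still: several entries are truncations rather
than roundings (coronene 11.89 for a computed 11.899), the picene ECI is a
digit transposition (printed 12.6860, computed 12.8680), the chrysene ECI
matches no tetrahex at all, and the Randić entries of both dibenzopyrenes
are inconsistent with any C24 hexahex. The validation report flags each of
these rather than silently "correcting" either side, and the test suite
freezes the exact sets of matching and non-matching rows so that any
change in behaviour surfaces.

## Nanosheet families

Four periodic families are generated parametrically, with `a` rows and `b`
unit cells per row; published results give a piecewise closed form for
NFI and a face-frequency table for each. The structures themselves are
published only as figures, so the lattices were reconstructed from the
standard constructions and pinned by the face censuses:

* **graphene** — a brick-wall rectangle: `a` rows of `b` hexagons, rows
  offset by half a hexagon alternately. This reproduces the published
  four-row census *exactly*, including its odd face class of degree 43,
  which is strong evidence for the convention. Degenerate sheets
  (`a = 1` or `b = 1`) are linear polyacene chains, matching the published
  single-row census; its printed closed form "14b − 18" is a typo for
  66b − 18, the value its own face data (and benzene, b = 1) give.
* **H-naphthalenic** — rows of vertically fused hexagon pairs joined by
  squares, consecutive rows linked by vertical bonds; hexagonal and
  octagonal inter-row rings close automatically. The reconstruction
  reproduces the published face table *exactly for every a, b ≥ 2*.
* **C₄C₈(S)** and **C₄C₈(R)** — two rectangular cuts of the same
  truncated-square (square–octagon) tiling: (S) stacks `a` anti-diagonal
  rows of `b` diagonally chained octagons; (R) is an (a+1) × (b+1) grid of
  rhombic squares joined by bridge bonds with a × b octagonal holes. (R)
  reproduces its published face table exactly for all a, b ≥ 2 and the
  published single-row census; (S) reproduces every class except the
  interior octagons, which the published table undercounts by exactly one.

Because the published *tables* are (nearly) exact while the published
*formulas* were evidently derived from them with algebraic slips, the
package keeps both quantities and names them honestly:
`closed_form_nfi()` evaluates the published piecewise formulas verbatim —
they reproduce the published square-dimension growth table (`table6()`)
for all 36 entries — while `lattice_nfi()` gives the face-census value of
the generated lattice in closed form. The two agree only on parts of the
parameter plane:

| family | published general branch | lattice value (a, b ≥ 2) | agree when |
|---|---|---|---|
| graphene | 54ab − 30a + 12b + 142 | 54ab + 14a + 12b − 34 | a = 4 (and a = 1, b = 1) |
| H-naphthalenic | 270ab − 80a + 60b − 280 | 270ab − 80a − 84b + 8 | b ≤ 2 (and a = 1) |
| C₄C₈(S) | 216ab − 80(a+b) − 64 | 216ab − 80(a+b) + 8 | a = 1 or b = 1 only |
| C₄C₈(R) | 108ab + 66a + 246b − 472 | 108ab + 66a + 66b + 32 | a = 1 or b = 1 only |

The graphene difference is the boundary class of degree 44 (count a − 4)
that the published general row omits; the C₄C₈(S) difference is the single
undercounted octagon (72 = one face); the C₄C₈(R) published branch is
asymmetric in a and b although the lattice — and the published face table
itself — is symmetric, so it can only be a transcription slip of the
symmetric 108ab + 66a + 66b + 32. `verify_closed_form()` checks the
published table-row sums against the published formulas symbolically (the
graphene and C₄C₈(S) pairs are internally consistent; the other two are
not), and `check_sheet()` generates the lattice and reports every
class-by-class discrepancy with both values. No discrepancy is ever
absorbed silently; the acceptance tests assert both the matches on the
stated domains and the presence of the reports off them.

An exhaustive search over small patches of the square–octagon tiling (all
octagon placements in a 4 × 4 window with every boundary-square
completion) found no patch whose face census matches the published
C₄C₈(S) two-row values, confirming that those rows are extrapolation
artifacts rather than a different convention we failed to find.

## Regression models

`ols()` wraps `stats::lm()` and reports the statistics conventional in
QSPR work, fixed to R = √(1 − RSS/TSS), adjusted R² =
1 − (1 − R²)(n−1)/(n−p−1), SEE = √(RSS/(n−p−1)) and F =
(R²/p)/((1−R²)/(n−p−1)); these definitions reproduce the internally
consistent published triples (for the ECI model, R = 0.994, SEE = 0.3438
and F = 1538.095 all match to every printed digit). Degenerate designs
error out: constant response (zero total sum of squares), rank-deficient
predictors, or n ≤ p + 1. `reproduce_models()` refits all six published
models on the catalog's printed columns — the printed columns, not the
recomputed indices, since the models were fitted to those — and compares
all 40 printed statistics at their printed precision. The gated
reproductions hold (the ECI and energy models' R, and the energy and
boiling-point slopes); the report also flags the known print
inconsistencies: the boiling-point model's R is printed as 0.9994, which
contradicts its own printed adjusted R² = 0.969 and F = 631.678 (both of
which we reproduce), and the energy model's printed F = 987.512 is the
computed 978.512 with two digits transposed.

## What the generators do and do not emulate

The lattices are idealized: all-carbon, strictly planar, defect-free, with
integer unit-cell counts. They do not model 3D relaxation (nanotubes and
nanotori are out of scope), heteroatoms, substituents, Clar structure or
any electronic effect; π-electron energies and boiling points enter only
as published data for the 21 molecular compounds. Passing tests therefore
certify the combinatorics of the indices and the faithfulness of the
reconstructions — not any chemical prediction about real materials beyond
what the regression report states.

## Problem sizes and numerical choices

The test suite exercises generators on the full grid a, b ≤ 8 for all four
families (the largest sheet has 640 atoms), validates the oracle identity
on 200 randomly grown benzenoids of up to 10 cells under a fixed seed, and
checks the symbolic table/formula identities up to a = b = 10; the whole
suite runs in under two minutes on one core. Random benzenoid growth can
produce holed (coronoid) structures, which is deliberate: the identities
under test hold for any 2-connected plane graph. All printed-value
comparisons round half away from zero at the printed number of decimals.
Ties in the rotation system cannot occur on the lattices (neighbour
angles are distinct by construction); for arbitrary coordinate input the
angular sort order at exact ties follows the stable sort of the underlying
`order()` call.

## Known limitations

MOL input is 2D V2000 only, first record, bond orders ignored. The
external-face heuristic assumes the drawing is not self-overlapping.
Catalog isomer assignment for the two dibenzanthracene chains is by
structure, not by index (none distinguishes them). The published-value
comparisons are frozen to the shipped reference table; users with a
corrected data source can rerun `validate_catalog()` and
`reproduce_models()` on their own tibbles.
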