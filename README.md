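# nfindex

Face-based topological indices for planar molecular graphs of polycyclic
compounds.

Topological indices map a molecular graph to a number that correlates with
physicochemical properties (boiling point, π-electron energy, ...), which is
how QSPR models screen compounds before anything is synthesized. Most
classical indices use only vertex degrees or edges. `nfindex` implements the
*neighborhood face index* (NFI), a descriptor that also uses the faces of
the planar embedding: for a plane molecular graph *G* with face set *F(G)*,

```
d(v)    = degree of vertex v
d_n(v)  = Σ_{u ~ v} d(u)                  (neighborhood degree)
d_n(£)  = Σ_{v incident to £} d_n(v)      (neighborhood face degree)
NFI(G)  = Σ_{£ ∈ F(G)} d_n(£)             (external face included)
```

together with its companions: the face index FI(G) = Σ d(£), the Randić
(vertex-connectivity) index RCI(G) = Σ_{uv∈E} (d_u d_v)^(−1/2), and the
edge-connectivity index ECI(G) = Σ_{e~f} (d_e d_f)^(−1/2) with line-graph
edge degree d_e = d_u + d_v − 2. For every 2-connected plane graph the
identity NFI(G) = Σ_v d(v)·d_n(v) holds (each vertex lies on exactly d(v)
faces), which the test suite uses as a brute-force oracle throughout.

The package is aimed at people working on degree- and face-based graph
invariants of benzenoid hydrocarbons and nanostructures: it provides

* a planar-graph data model with an explicit rotation system, face
  enumeration by directed-edge orbits, and exact integer hexagonal-lattice
  coordinates (`build_embedding()`, `enumerate_faces()`, `build_benzenoid()`);
* a 21-compound benzenoid reference catalog with published NFI/RCI/ECI,
  π-electron energies and boiling points, plus a validation report that
  recomputes every index and flags each transcription defect of the
  published table instead of hiding it (`benzenoid_catalog()`,
  `validate_catalog()`);
* parametric generators, closed-form NFI formulas and symbolic
  face-frequency tables for four nanosheet families — graphene,
  H-naphthalenic, C₄C₈(S) and C₄C₈(R) — with a cross-validation report
  that compares lattice, formula and table on every parameter pair
  (`generate_sheet()`, `closed_form_nfi()`, `face_spec()`, `check_sheet()`);
* OLS machinery that refits the six published structure–property
  regressions (RI, ECI, π-energy and boiling point on NFI) and compares
  every statistic to its printed value (`ols()`, `reproduce_models()`,
  with broom-style `tidy()`/`glance()` methods);
* readers/writers for hexspec JSON, graph-dump JSON and 2D MOL/SDF V2000,
  and a command-line tool (`inst/cli/nfitool.R`).

## Worked example

Perylene (five peri-fused hexagons, 20 carbons):

```r
library(nfindex)
perylene <- build_benzenoid(catalog_hexspec("Perylene"))
index_report(perylene, "Perylene")
#> # A tibble: 1 × 9
#>   name     n_vertices n_edges n_faces   nfi face_index randic   eci external_nfd
#> 1 Perylene         20      24       6   304        120   9.93  11.9          102

face_histogram(perylene)
#> $internal
#> 38 50
#>  4  1
#> $external
#> [1] 102
```

The five internal hexagons have neighborhood face degrees 38, 38, 38, 38
and 50, the external face 102, so NFI = 4·38 + 50 + 102 = 304. The Randić
and edge-connectivity values round to the published 9.93 and 11.897.

Nanosheets and regressions:

```r
closed_form_nfi("graphene", 6, 6)   # 1978
check_sheet("c4c8_r", 3, 3)$ok      # TRUE: published face table is exact here
glance(reproduce_models()$fits[["ECI~NFI"]])
#>       R r.squared adj.r.squared   SEE     F     n     p
#> 1 0.994     0.988         0.987 0.344 1538.    21     1
```

`validate_catalog()` recomputes all 21 catalog compounds; 20 of 21
published NFI values reproduce exactly. The single failure is a defect of
the published table, not of the reconstruction: the printed value 255 for
triphenylene is odd, and NFI is always even on these skeletons (it equals
twice the second Zagreb index). The vignette
(`vignettes/face-indices.Rmd`) documents this and every other place where
published numbers and recomputed ones differ, including where the
published nanosheet formulas deviate from their own lattices.

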