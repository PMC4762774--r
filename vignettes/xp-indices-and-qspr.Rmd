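---
title: "Quantum-topological XP indices and QSPR models for polybrominated xanthones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantum-topological XP indices and QSPR models for polybrominated xanthones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xpqspr)
```

## The problem

Xanthone (dibenzo-gamma-pyrone, C13H8O2) carries eight substitutable ring
positions.  Brominating any subset of them produces a polybrominated
xanthone congener; because the scaffold has a mirror symmetry mapping
positions 1<->8, 2<->7, 3<->6 and 4<->5, the 255 non-empty substitution
subsets collapse into exactly 135 distinct congeners.  Measuring or
computing thermodynamic properties (entropy, Gibbs energy of formation)
for each one individually is expensive, which motivates a quantitative
structure-property relationship (QSPR): compute cheap structural
descriptors, regress the property of interest on them, and predict the
rest of the family.

This package implements one such descriptor pair, here called XP1 and
XP2, together with the regression and cross-validation machinery around
it, and ships the reference data table for the full congener family.

## The descriptor construction

For a hydrogen-suppressed molecular graph with `n` heavy atoms the
pipeline combines three ingredients:

1. **Spatial distance matrix** `D`.  Entry `(i, j)` is the shortest-path
   distance through the bond network with each bond weighted by its real
   Euclidean length in Angstrom (computed with Dijkstra's algorithm via
   igraph).  This replaces the classical unit-edge graph distance with a
   physically scaled analogue.  A through-space Euclidean mode is also
   available (`mode = "euclidean"`); bond-path is the default because it
   is the direct generalization of the topological distance matrix that
   this family of descriptors descends from.

2. **Equilibrium electronegativity vector** `e`.  For each atom,
   `chi_i = (chi_iA + sum(chi_G)) / (1 + l)` where `chi_iA` is the
   atom's Pauling electronegativity, one group electronegativity
   `chi_G` is contributed by each attached group, and `l` is the number
   of attached groups (heavy neighbours plus implicit hydrogens).  A
   group's electronegativity is the equal-weight recursive average over
   its structure tree: a lone atom contributes its Pauling value, and an
   anchor atom with `k` substituent groups contributes
   `(chi_anchor + sum of the k group values) / (1 + k)`.  Every result
   is therefore a convex combination of Pauling values, which gives the
   bounds asserted in the test suite.

3. **Branching degree vector** `v`, with `v_i = z_i - h_i + 1` from the
   valence-electron count `z_i` and the implicit-hydrogen count `h_i`.
   In this congener family only four values occur: 4 (aromatic CH), 5
   (substituted, fusion or carbonyl carbon), 7 (oxygen), 8 (bromine).

These are combined into the extension matrix `S`, the correction matrix
`Q = S %*% t(S)`, and finally

```
XP1 = |smallest eigenvalue of Q|,   XP2 = |largest eigenvalue of Q|
```

with eigenvalues sorted ascending.

### Why two extension-matrix strategies

The defining product "S = D x E x V" admits more than one reading, and
the readings differ materially.  Read literally as chained matrix
products of an `n x n` matrix, a column vector and a row vector, `S`
becomes the outer product `(D e) v^T`, which has rank 1; its Gram matrix
`Q` then has a single nonzero eigenvalue, so XP1 is numerically zero for
every molecule and cannot carry information.  The package therefore
defaults to the `"diagonal"` strategy, `S_ij = D_ij * e_j * v_j`, i.e.
the two atomic vectors act as diagonal column scalings — the standard
pattern for electronegativity- and valence-weighted distance matrices in
this descriptor family.  The literal reading stays available as
`strategy = "literal"` and the test suite pins down its rank-1 behaviour
so the difference is documented executable knowledge rather than prose.

A related inconsistency affects the one worked example available for the
construction: the published 17 x 17 correction matrix for the
2,8-dibromo congener is not symmetric as printed, and its published
eigenvalue list contains negative values — both impossible for a true
Gram matrix `S %*% t(S)`.  The package therefore ships that matrix and
eigenvalue list verbatim as *reference fixtures* (`fixture_q_matrix()`,
`fixture_spectrum()`): they exercise the spectrum and index-extraction
operations, but the pipeline is not expected to regenerate them, and no
test asserts that it does.

### Geometry

The original congener geometries came from quantum-chemical optimization
and are not available.  The package instead generates idealized planar
geometries: the central pyranone ring is built mirror-symmetrically from
exact bond lengths (aromatic C–C 1.39 Å, aromatic C–O 1.36 Å, C=O
1.22 Å), the two benzo rings are regular hexagons of side 1.39 Å fused
onto it, and bromines sit on the exocyclic bisector at 1.89 Å.  Every
bonded distance equals its table value exactly by construction, and
mirror-image substitution patterns give congruent coordinate sets.

This generator exists so the whole pipeline — geometry, distances,
electronegativities, eigenvalues — runs end to end and its structural
invariants can be tested on all 136 molecules.  What it does *not* do is
reproduce the bundled XP1/XP2 reference values, which were derived from
optimized geometries by a construction that (per the previous section)
cannot be fully reverse-engineered.  Tests never assert that the
generated indices match the bundled ones.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `strategy` | `"diagonal"` | extension-matrix reading (see above) |
| `mode` | `"bond-path"` | distance definition: bond-length-weighted shortest path vs through-space |
| `depth_limit` | 3 | levels in each group tree grown from a neighbour atom; cycles are truncated by never revisiting an atom on the current path.  On this rigid polycyclic scaffold the choice shifts all chi values slightly and uniformly; increments shrink monotonically with depth (tested on chains) |
| `tol` | 1e-8 | relative tolerance for symmetry detection and imaginary-part rejection in the eigensolver |
| `en_table` | built-in | Pauling electronegativities: H 2.20, C 2.55, N 3.04, I 2.66 (the values used in the worked examples), O 3.44 and Br 2.96 from the standard Pauling scale; overridable per element via `en_table = c(O = 3.5)` or a key-value config file |

The group-electronegativity recursion is defined for trees while
xanthone is polycyclic; the tree-growth rule (breadth-first away from the
central atom, no atom revisited on the current root path, truncation at
`depth_limit`) is this package's documented convention, chosen because
the available worked examples are all acyclic and some explicit
termination rule is required.

## The QSPR layer

`fit_mlr()` fits `P = a1 + a2*XP1 + a3*XP2` by ordinary least squares
(through `stats::lm`) and reports the statistics conventional in QSPR
work: the multiple correlation coefficient in square-root form
`R = sqrt(1 - SSE/SST)`, adjusted R, standard error of estimate, Fisher
F, PRESS and the guarded average relative error.  `loo_cv()` performs
leave-one-out cross-validation through the hat-matrix identity
`e_(-i) = e_i / (1 - h_ii)` (with an explicit-refit fallback when a
leverage equals 1); the test suite verifies the shortcut against
brute-force refits to 1e-8.  The cross-validated coefficient is likewise
reported in square-root form, `r_cv = sqrt(max(0, 1 - PRESS/SST))`,
because the published cross-validation values (about 0.997) track `R`
rather than `R^2`; the `q2` value is exposed alongside.  The published
formula for the cross-validated coefficient (a `1 - SS/DD` form without
the root) is inconsistent with the magnitudes published next to it; the
square-root form is the reading consistent with those magnitudes.

`relative_property()` re-expresses a property within each
bromination-count group relative to the group's most stable member
(`y - min(y)`); singleton groups (the parent compound, the fully
substituted congener) get `NA`, matching the undefined cells in the
reference table.

## Data curation

The bundled table (`load_table1()`) is a verbatim transcription guarded
by an MD5 checksum.  Curation happens in code and is visible in the
`flags` column:

- Reference ("cal") columns are **never** modified — refitting the
  models requires them untouched.
- Two predicted-column cells with dropped decimal points are repaired
  (`2079 -> 20.79`, `5305 -> 53.05`), flagged, originals kept.
- Two internally inconsistent reference cells are flagged but not
  altered: congener "2" (its relative Gibbs value conflicts with its
  formation Gibbs value) and "2,3,6,7" (its formation Gibbs value is
  about 82 kJ/mol below every consistency reconstruction for its group).
- Rows where XP1 or XP2 breaks the otherwise monotone ordering of the
  printed table are flagged rather than silently reordered or edited.

The consistency reconstruction itself is a tested invariant: within each
bromination-count group, `dfg_cal - drg_cal` is constant to ±0.02 for
132 of the 134 defined rows, and the two failures are exactly the two
flagged anomalies.

## Reproducibility findings

Refitting the three models on the bundled table as published (two
descriptors, OLS, n = 136/136/134) yields

```{r}
t1 <- load_table1()
c(S = fit_mlr(t1, "s_cal")$r,
  dfG = fit_mlr(t1, "dfg_cal")$r,
  dRG = fit_mlr(t1, "drg_cal")$r,
  r_cv_S = loo_cv(t1, "s_cal")$r_cv)
```

against published values of 0.9971, 0.9965, 0.9982 and 0.9970.  The
mismatch is not a numerical issue: the bundled predicted columns sit
within about 0.1 % of the reference columns (far closer than any
two-descriptor model on the bundled XP columns can reach), and the
published coefficient sets do not map the bundled descriptors onto the
bundled predictions either (`reference_models()` documents this: the
entropy equation applied to the parent compound's tabled descriptors
gives 456.05 against a tabled prediction of 416.32).  The descriptor
columns, the coefficient sets and the prediction columns of the source
table are mutually inconsistent, so the published correlation statistics
cannot be regenerated from the published data.  The package reports the
honestly refitted statistics and keeps the published ones as reference
constants; the corresponding acceptance test records the disagreement
rather than papering over it.

The published average relative errors (0.85 %, 1.19 %, 0.79 %) are
likewise not recoverable: the averaging rule is undefined for the
zero-valued relative-Gibbs rows.  `average_relative_error()` implements
the guarded definition (rows with `|reference| < eps` excluded and
counted) and makes no claim of matching those numbers.

## Problem sizes and runtime

All property suites run on every one of the 136 congeners (15–23 heavy
atoms each); eigendecompositions at this size are microseconds, so the
full test suite completes in well under two minutes on a single CPU.
The LOO shortcut-vs-oracle checks use random tables of 10–30 rows, where
the brute-force oracle (n explicit refits) is exact and cheap.

## Known limitations

- The idealized geometry is planar and strain-free; steric crowding of
  adjacent bromines (e.g. the peri positions 1 and 8) is not modelled,
  so generated descriptors underestimate congestion effects.
- Bond perception for XYZ input uses a covalent-radius cutoff (factor
  1.25); it is reliable for rigid aromatic scaffolds but is not a
  general-purpose perception algorithm, which is out of scope.
- The electronegativity scheme is topology-only; charge- or
  geometry-dependent equalization schemes (EEM, QEq) are out of scope.
- Descriptor selection, regularized regression and external test-set
  schemes beyond leave-one-out are out of scope; the model family is
  fixed at two descriptors.
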