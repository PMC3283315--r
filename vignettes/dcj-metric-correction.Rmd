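---
title: "Genomic distances with unequal content and the surcharge that makes them metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic distances with unequal content and the surcharge that makes them metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcjmetric)
```

## The problem

Classical genome rearrangement distances assume two genomes with identical
marker content and count organizational operations — inversions,
translocations, fusions, fissions, all subsumed by the double cut and join
(DCJ) — needed to transform one into the other.  Real genome pairs differ in
content, so hybrid models add content-modifying operations: insertion or
deletion of a contiguous block of markers (an *indel*), or replacement of one
contiguous block by another (a *substitution*, which subsumes indels).  When
all operations weigh 1, the resulting distances are computable in polynomial
time but are **not metrics**: the triangle inequality can fail, because a
genome can reach a third genome (in the extreme, the empty genome) with a
handful of whole-chromosome indels, undercutting the direct route.  That
matters whenever the distance feeds a median computation or a distance-based
phylogeny.

This package implements the machinery around that observation for genomes of
signed, unique markers organized in linear and circular chromosomes:

* the labeled **adjacency graph** `AG(A, B)` and its decomposition into
  cycles, AB/AA/BB-paths and singletons;
* the classical DCJ distance `d_DCJ = n - (c + b/2)`;
* run counts and the **indel-** and **substitution-potentials** per component,
  giving tight upper bounds for the DCJ-indel and DCJ-substitution distances;
* the **weight framework** `w(rho) = p + k*m(rho)` for content-modifying
  operations and its a-posteriori form `m(A,B) = d(A,B) + k*u(A,B)`;
* triangle-inequality **audits**, exhaustive tiny-universe scans and a grid
  search recovering the minimal surcharge `k` on constructed families;
* brute-force **oracles** that validate every closed form at small scale.

## Distances as component-wise bounds

Every common marker contributes one head and one tail extremity on each
genome side; consecutive extremities form adjacencies, and unique markers
between them become adjacency *labels*.  Connecting equal extremities across
genomes decomposes the graph into components, and the whole distance theory
is component-local.

Concatenating the labels along a component `P` and reading maximal
same-genome blocks gives its *runs*; `Lambda(P)` denotes their number
(`Lambda(P) <= |P|`).  DCJ-sorting a component can accumulate and merge runs;
after sorting `P` with its minimal number of optimal DCJs, at least

* `lambda(P) = floor(Lambda/2) + 1` runs remain (one indel each), and
* `sigma(P) = ceiling((Lambda + 1)/4)` substitutions are needed,

for `Lambda >= 1`, and zero otherwise.  The headline functions
`dcj_indel_bound()` and `dcj_substitution_bound()` return
`d_DCJ + sum(lambda(P))` and `d_DCJ + sum(sigma(P))`, flagged
`exactness = "bound"`: the exact linear-time distances additionally require
path-recombination corrections that are deliberately out of scope here.  Two
safeguards keep the bounds honest:

1. the closed forms of `lambda` and `sigma` (whose printed bodies we had to
   reconstruct from the worst-case table and the per-case inequalities of the
   diameter proofs) are validated against `component_sorting_search()`, an
   exhaustive search over optimal-DCJ sorting sequences of realized
   components, across **all** labeling patterns up to size 5 and the
   all-labeled size-7 fixture;
2. `exact_distance_search()` (uniform-cost search over the full operation
   model) never exceeds the bound on any enumerable instance, with equality
   on ≈99% of tiny pairs for the indel model.

The same reconstruction applies to the DCJ-indel diameter
`2n + L_A + S_A + L_B + S_B` (`diameter_bound()`), assembled from the
per-component inequalities `d + lambda <= |P|` and the vertex-count identity
`|AG(A,B)| = 2n + L_A + S_A + L_B + S_B`.

## The weight framework and the minimal surcharge

Organizational operations weigh 1; a content-modifying operation affecting
`m` markers weighs `p + k*m`.  For `p = 1`, the weighted distance decomposes
as `d_{1,k}(A,B) = d_{1,0}(A,B) + k*u(A,B)` where `u` counts the markers
private to either genome: in a parsimonious sequence each unique marker is
touched by exactly one content-modifying operation.  The correction is
therefore *a posteriori* — no distance algorithm needs to change.

On which triples does the corrected distance satisfy the triangle
inequality?  The binding family (`make_tightness_family()`) consists of pairs
`A_n = (g1 x1 ... gn xn)`, `B_n = (g1 y1 -g2 y2 ... -gn yn)` — one circular
chromosome each, chosen so that `AG(A_n, B_n)` is a single cycle with all
`2n` vertices labeled — together with the empty genome `C`.  Then
`m(A_n,B_n) = 2n + 2nk` while the detour through `C` costs `2 + 4nk`, so the
inequality is violated exactly when `n(1 - k) > 1`.  As `n` grows the
threshold `1 - 1/n` approaches 1 for the DCJ-indel distance (and `3/4 - 1/n`
approaches 3/4 with substitutions), so a 0.01-spaced grid over the family up
to `n = 200` recovers the minimal constants exactly:

```r
fam <- make_tightness_family(200)
min_k_grid(fam, "dcj-indel")          # 1.00
min_k_grid(fam, "dcj-substitution")   # 0.75
```

The constructor verifies its single-all-labeled-cycle invariant rather than
trusting the sign pattern.  (The "n common plus n unique markers per genome"
profile of the family is itself reconstructed from the violation algebra
`2n + 2nk > 2 + 4nk`; the printed condition was lost in extraction.)

Audits are exact: `k` is carried as a rational `num/den` and every violation
test is an integer comparison on denominator-scaled values, so `k = 0.99`
versus `k = 1.00` can never be blurred by floating point.
`min_k_grid()` also verifies upward closure — once a grid value passes, all
larger audited values must pass — which is the monotonicity property that
makes "minimal k" well defined.

`audit_triple()` additionally reports a *reduced* quantity
`d(A,B) - d(A,C') - d(B,C') - 2k*|G_AB|`, where `C'` drops the markers
private to `C` and `G_AB` collects markers common to exactly `A` and `B`.
Under the seven-set partition of a triple's markers this equals
`m(A,B) - m(A,C) - m(B,C)` whenever `C` has no private markers; the displayed
form of the source inequality was stripped, so this reconstruction is tested
as an identity rather than assumed.  When `G_AB` is empty — every marker
shared by `A` and `B` also occurs in `C` — no surcharge is needed at all
(`shared_content_triangle_check()`): concatenating optimal sequences through
`C` bounds the direct distance.

## What the oracle model is, precisely

The search oracles implement the operation semantics the distances are
defined over:

* **DCJ**: cut two adjacencies (a telomere counts as an open end; fissions
  and fusions are the degenerate cases) and rejoin the four ends differently.
* **Deletion / insertion**: one contiguous block within one chromosome, or a
  whole chromosome; an insertion may not create duplicates.
* **Substitution**: replace one contiguous (possibly empty) block by another
  (possibly empty) at the same location, counted once with
  `m = deleted + inserted`.  We allow a whole chromosome to be replaced in
  one substitution ("at most one chromosome at once"); this is a generous
  reading, and it only ever lowers oracle distances, keeping the
  oracle-below-bound validation conservative.

One restriction is essential and easy to miss: **content-modifying
operations act on unique markers only**.  If a deletion could remove markers
shared with the target (to be reinserted later), every distance would
collapse to "delete everything, insert the target" — two operations — and
the decomposition `d_{1,k} = d_{1,0} + k*u` would fail, as would the entire
run-based theory.  The restriction is exactly what makes the empty-genome
detour a *triangle* phenomenon rather than a property of the direct
distance.  In the state-graph oracle this becomes a per-edge validity test
against the target's marker content (each edge stores the content mask of
its intermediate state, so a substitution that internally touches shared
markers is rejected for that target).

Three oracle entry points matter:

* `exact_distance_search(A, B, model, p, k)`: uniform-cost search with
  canonical-form deduplication; insertions are restricted to target markers
  absent from the state (a consequence of the each-marker-once property)
  and to blocks of at most 3 markers — ample for the enumerable universes.
* `oracle_state_graph(markers, model)` + `graph_distance()`: all canonical
  genomes over a 4-marker universe (1137 states) with every operation edge
  precomputed.  At `p = 1, k = 0` all weights equal 1, so breadth-first
  search gives exact distances in milliseconds, which is what makes
  `exhaustive_triple_scan()` — 1.4 million audited triples over the
  2-common/1-unique universe — affordable.
* `component_sorting_search(A, B)`: level-wise exhaustive search over
  *optimal* DCJs applied within the one non-trivial component of
  `AG(A, B)`, cutting either genome and anywhere inside a label.  Cuts on
  both genomes are necessary: merging B-side runs requires B-side cuts, and
  restricting to one side overestimates the substitution minimum (the
  all-labeled size-6 cycle needs 2 substitutions, not 3).

## What the generators emulate — and what they do not

`random_genome_pair(n_common, n_unique_each, ...)` draws a content profile
(shared and private marker counts), arranges each genome's markers uniformly
at random with random orientations, splits them into up to
`max_chromosomes` chromosomes and makes each circular with probability
`circular_prob` (default 0.3, linear-dominated as in most published marker
sets).  Defaults are chosen for the property tests, where the relevant
conditions are structural (vertex-count identity, parity, symmetry,
metric axioms) and uniform randomness is the right null.  The generator does
**not** emulate biological realism — no rearrangement hotspots, no length
distributions, no phylogenetic correlation between the two genomes — so a
green property test certifies combinatorial correctness of the
implementation, not fit to any organism.  The tightness family and the
7-vertex fixture are not random at all: they are the worst-case constructions
that drive the minimal-k and worst-component results, verified at
construction.

## Numerical and representational choices

* **Canonical forms.**  A circular chromosome is equal to any rotation and to
  its reflected complement; a linear chromosome to its reflected complement;
  chromosomes are unordered.  `canonical_form()` picks the lexicographically
  minimal representative (marker name before orientation, radix order, so
  `a b` beats `-b -a`) and is idempotent; canonical keys are the state
  identity of every search.
* **Exact arithmetic.**  Audits and the grid search compare
  denominator-scaled integers; the oracle's weighted searches use dyadic
  `k` (0.5, 0.75) where doubles are exact.
* **Deterministic traversal.**  Components order their vertices canonically
  (AB-paths start on the A side, other paths and cycles at the smallest
  vertex key); run counting is invariant under rotation and reversal of the
  traversal, and the tests recompute it from shuffled traversals.
* **Degenerate inputs.**  The empty genome is first-class (it is the
  worst-case third genome); single-marker chromosomes are legal in both
  topologies; `b` (AB-path count) is asserted even before halving.

## Limitations

* The headline distances are the tight component-wise **bounds**, not the
  exact DCJ-indel/DCJ-substitution distances; all metric conclusions drawn
  from them are cross-validated against the exact oracle at tiny scale
  (where the indel bound coincides with the exact distance on ≈99% of
  pairs), but for large unequal-content pairs the bound can exceed the exact
  distance.
* The minimal-constant theory implemented here is for `p = 1`; for other
  `p` the underlying distances are open, and the package only exposes the
  generic framework.
* Oracles are limited to ~5-marker universes by design; they are validators,
  not production distance algorithms.
* Genomes with duplicated markers are rejected, matching the model.
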