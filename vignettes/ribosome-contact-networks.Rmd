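---
title: "Coarse-grained contact networks of the bacterial ribosome: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained contact networks of the bacterial ribosome: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribonet)
```

## The model

The ribosome is treated as a network of coarse-grained *elements*: every
ribosomal protein, every tRNA, the mRNA and any bound elongation factor is
one node, and the 16S and 23S rRNAs — molecules an order of magnitude
larger than any protein — are split into their secondary-structure domains
(16S 5', central, 3'-major, 3'-minor; 23S domains, plus 5S as its own
node) so that their connectivity is resolved on a comparable scale. An
edge is drawn between two elements when they are in physical contact in
the deposited structure.

Contact is defined through solvent-accessible surface area (SASA). For a
pair of elements A and B the *buried area* is

$$\Delta \mathrm{SASA} = \mathrm{SASA}(A) + \mathrm{SASA}(B) -
  \mathrm{SASA}(A \cup B),$$

the surface each element hides from a water-sized probe by the presence of
the other. A positive burial means the solvent-expanded surfaces overlap,
i.e. the elements touch. This criterion needs no contact-distance cutoff
tuned per atom type and is symmetric by construction. Multiple atomic
contacts between the same pair still give a single unweighted edge: the
analysis targets the topology of communication, not interface sizes.

Assumptions inherited from this construction: the deposited coordinates
are taken at face value (no refinement or completion of missing chains —
elements absent from a deposition are simply absent from that network);
hydrogens, waters and monoatomic ions are excluded, as crystallographic
and cryo-EM depositions rarely resolve hydrogens reliably; only the first
model of a multi-model file is used; and residue ranges in element maps
use author numbering, which is how domain boundaries are published.

## Parameters that matter

* **Probe radius** (`probe_radius`, Å, default 1.4): the water-probe
  convention. Larger probes would additionally capture weaker,
  solvent-mediated proximities; the default captures direct contacts.
* **Quadrature points** (`n_sphere_points`, default 960): each atom's
  expanded sphere is sampled with a deterministic golden-section spiral.
  960 points put the single-sphere quadrature error well under 1% while
  keeping a full pairwise scan of a toy assembly below a second; the
  point set is identical across runs, so SASA values are bit-stable.
* **Burial threshold** (`min_buried_area`, Å², default 0.1): the contact
  criterion is "any positive burial"; the small positive floor only
  absorbs quadrature noise, since a genuine atomic contact buries tens of
  Å². Whether the original analyses used a strict zero or a small floor
  is not documented; the parameter is exposed for that reason.
* **Van der Waals radii**: heavy-atom Bondi-style values (C 1.70, N 1.55,
  O 1.52, P 1.80, S 1.80 Å), configurable via `default_vdw_radii()`;
  unknown element symbols fall back to 1.70 Å with a warning.
* **Null-model ensemble** (`reps`, default 5000; `seed`): number of
  Erdős–Rényi replicates averaged in the random reference column.
* **Decomposition threshold** (`min_size`, default 9): communities with
  at least this many members are decomposed further. The source material
  states the bound both as "9 or more" and "more than 9"; this package
  uses ≥ 9 and leaves the value a parameter.

An exact speed-up: pairs whose bounding spheres (centroid plus maximal
atom reach including van der Waals radius) are separated by more than one
probe diameter cannot bury any area, so they are called non-interacting
without SASA evaluation. This prunes most of the quadratic pair scan on
real assemblies and provably never changes a call.

## Edge classes and bridges

Contact classes partition the edge set with an explicit precedence: any
edge touching a tRNA or mRNA node is a ligand contact (`mrna_trna`);
otherwise two rRNA-domain endpoints give `rrna_rrna`; two protein
endpoints — ribosomal proteins and elongation factors both count as
proteins — give `rprot_rprot`; everything else is `rrna_rprot`. The
precedence makes the four counts sum exactly to the edge count, which is
what lets class tables be read as a decomposition of the network. An
edge between an elongation factor and a tRNA is therefore a ligand
contact, not a protein contact; this is this package's convention and is
flagged here because the original tabulation does not state one.

Inter-subunit bridges are edges whose endpoints are ribosomal elements
(rRNA domain or r-protein) on opposite subunits; tRNA, mRNA and factor
contacts span the subunit interface by function rather than by
architecture and are excluded from the bridge count.

When two networks (states or species) are compared, the percent
difference is 100 × (changed edges)/(all edges): an edge counts as
changed only if both its endpoints exist in both networks, while the
denominator is the union of all edges of both networks. Contacts of an
element present in only one deposition therefore dilute, never inflate,
the difference — a deliberately conservative estimate.

## Descriptive statistics

`summarize_network()` reports node count ("Size" in the source tables),
edge count ("Order" — note both terms are used in their non-standard
table sense and kept here for recognisability), isolated and pendant
counts, average and maximum degree, diameter, average path length
$L = \sum_{s,t} d(s,t) / n(n-1)$ over ordered pairs, Watts–Strogatz mean
local clustering (nodes of degree < 2 contribute 0), density
$m/\binom{n}{2}$ and the degree assortativity (Pearson correlation of
endpoint degrees over the symmetrised edge list). On disconnected graphs
— which arise for the protein-only subnetworks — distance-based
quantities are computed on the largest connected component, with $n$ in
the denominator replaced by that component's size. Assortativity of a
degree-regular graph has zero variance in the correlation and is
reported as `NaN` with a warning rather than an arbitrary number; for
the same reason the regular-lattice reference column leaves that cell
undefined.

## Null models and small-world statistics

The random reference is the mean over 5000 Erdős–Rényi graphs
$G(n, p)$ with $p = m/\binom{n}{2}$, so node count and expected edge
count match the observed network; path lengths and diameters are taken
on each replicate's largest component, and replicate assortativity is
averaged where defined. The regular reference is a deterministic
periodic lattice: nodes on a ring, edges added in rounds of increasing
circular neighbour distance (all distance-1 edges, then distance-2, …),
within a round in ascending node index, stopping at exactly m edges.
This construction formalises "connect each node to its nearest
unconnected neighbour with periodic boundaries"; for (n = 68, m = 235)
it terminates partway through the distance-4 round, giving degrees 6–8
and the published maximum degree 8.

The two small-world statistics are
$\sigma = (C/C_{rand})/(L/L_{rand})$ (> 1 indicates small-world) and
$\omega = L_{rand}/L - C/C_{reg}$ (near 0 small-world, −1 lattice-like,
+1 random-like).

## Centralities

Degree centrality is degree/(n−1). Eigenvector centrality solves
$Ax = \lambda x$ for the principal eigenvector by power iteration
(tolerance 1e-8 on the maximal score change, 1000 iterations, error on
non-convergence); the iteration uses the shifted matrix $A + I$, which
has the same principal eigenvector but is immune to the sign-flip
oscillation of bipartite spectra, and reports non-negative scores of
unit Euclidean norm. On disconnected graphs the dominant component
carries the mass and other components decay to zero. Closeness is the
within-component definition scaled by the component fraction
(reachable−1)²/((n−1)·Σd), so scores remain comparable across
components. Betweenness follows Brandes' accumulation, excludes
endpoints, and is reported normalised by (n−1)(n−2)/2; the source does
not state either convention, so both choices are documented here. Hub
tables order nodes per measure with ties broken lexicographically by
element name — again this package's convention, not the original's.

## Modularity

Modularity is evaluated exactly as
$Q = \frac{1}{2m}\sum_{ij}\left(A_{ij} - \frac{k_i k_j}{2m}\right)
\delta_{g_i g_j}$. Maximization uses Clauset–Newman–Moore greedy
agglomeration as implemented in igraph; the cut along the merge
sequence is then chosen by this package as the step of maximal Q with
ties resolved toward the later step, so zero-gain merges are still
applied and a complete graph remains one block. Determinism comes from
the implementation's fixed merge order rather than an explicit
lexicographic tie-break on block labels; the result is reproducible
run-to-run, which is the property the analyses need. Recursive
decomposition reruns the optimisation on the induced subgraph of every
block with ≥ `min_size` nodes — edges leaving a block are ignored at
deeper levels, matching the idea of decomposing each community as its
own network — and stops where a block yields a single child.

## What the synthetic generators emulate

`generate_toy_structure()` plants a known contact graph in 3D: each
element is a compact blob of carbon atoms, touching pairs are placed
with a surface gap below one probe diameter (plus one dedicated
facing atom per partner, making the burial unambiguous at the default
threshold), and all other pairs at least `apart_gap` apart, beyond any
possible burial. Planted adjacencies must form a forest: trees embed by
breadth-first placement with well-separated directions, while cyclic
contact patterns would require solving a distance-geometry problem and
are rejected as infeasible. The generator verifies the realised
geometry before returning, so a successful call guarantees the planted
edge set is the unique correct answer for the detection stage.

`generate_ribosome_like_network()` is a statistical stand-in for the
element network: a configuration-model simple graph whose degree
sequence has ~12 high-degree hubs (the rRNA-domain role) over a
low-degree periphery, reproducing the printed global shape — 68 nodes,
235 edges, hub degrees up to the 20s — and the negative degree
assortativity that hub-periphery wiring forces. It does not reproduce
the real contact map, the real clustering level (random wiring gives
C ≈ 0.26 versus ≈ 0.44 observed, so its ω lands above the small-world
band even though σ > 1), or any biological adjacency; conclusions about
real ribosomes require real structures. `generate_planted_partition()`
wraps a stochastic block model and returns the planted labels for
community-recovery benchmarks.

What passing tests show, and what they do not: exact recovery of
planted contacts demonstrates the structure → SASA → network path is
correct; it does not validate domain boundary choices or radius tables
against real depositions, where boundary curation dominates the
residual error in node and edge counts.

## Numerical choices and degenerate inputs

Deterministic quadrature (golden spiral) makes SASA reproducible to the
bit; all stochastic steps (ensembles, generators) take explicit integer
seeds and are bit-reproducible given one. Degenerate cases are defined
rather than left to chance: an edgeless graph has Q = 0 and singleton
communities; eigenvector centrality on an edgeless graph is an error
(no principal direction); assortativity without degree variance is
`NaN` with a warning; a single element yields an empty interaction
table; metrics of graphs whose largest component is a single node
return `NaN` path length and diameter 0.

Problem sizes used by the test suite were chosen to keep the full run
under a minute: toy assemblies of 5–11 elements with 15–40 atoms each,
brute-force oracle graphs of ≤ 16 nodes, 20-seed recovery sweeps at 480
quadrature points, and the full 5000-replicate ensemble at (68, 235)
run once. The analysis scripts under `analysis/` use the same sizes.

## Known limitations

* Reproducing the published per-structure tables end-to-end requires
  downloading the five deposited 70S structures and curating their
  element maps (chain assignments and domain boundaries); the shipped
  map is an approximate template, and the discontinuous 23S domain 0
  must be assigned by hand if distinguished.
* The lattice reference's pendant count and assortativity as published
  are not reproducible from any ring construction matching the stated
  recipe; those two reference cells are left undefined here.
* Buried area is computed on the pair in isolation (matching the
  pair-versus-individuals definition), so a third element cannot mask a
  contact; this is the intended semantics but differs from whole-
  assembly SASA.
* Only unweighted, binary contacts are represented; interface area is
  reported per pair but never used as an edge weight.
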