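# ribonet

Coarse-grained contact network analysis of bacterial ribosome structures.

## What problem this solves, and for whom

High-resolution structures of the 70S ribosome capture snapshots of the
elongation cycle, but how the ~70 components — ribosomal proteins, rRNAs,
tRNAs, mRNA, elongation factors — function *together* is hard to read off
coordinates. `ribonet` turns a deposited structure into an element-level
contact network and analyses it with the standard toolkit of network
science: is the topology small-world, which elements are the
communication hubs, and which groups of elements form modular
communities. It is aimed at structural and systems biologists who want a
reproducible, scriptable version of that analysis for ribosomes (or any
multi-chain assembly with a sensible coarse-graining).

## The method in brief

1. **Coarse-graining.** Every protein, tRNA, mRNA and factor is one node;
   16S/23S rRNA are split into their secondary-structure domains via a
   user-editable element map (YAML; an approximate *E. coli* template
   ships in `inst/extdata/`).
2. **Contact calling.** Two elements interact when pairing them buries
   solvent-accessible surface area:
   ΔSASA = SASA(A) + SASA(B) − SASA(A∪B) > 0, with SASA computed by a
   deterministic Shrake–Rupley quadrature (probe 1.4 Å, 960 golden-spiral
   points per atom). Edges are simple and unweighted.
3. **Descriptive statistics.** Node/edge counts, edge classes
   (rRNA–rRNA, rprotein–rprotein, rRNA–rprotein, tRNA/mRNA contacts),
   inter-subunit bridges, average path length
   L = Σ d(s,t)/n(n−1), Watts–Strogatz clustering CC, density
   m/C(n,2), degree assortativity r.
4. **Small-world assessment.** Against a 5000-replicate Erdős–Rényi
   ensemble matched in n and p = m/C(n,2) and a deterministic periodic
   nearest-neighbour ring lattice with the same n, m:
   σ = (CC/CC_rand)/(L/L_rand) and ω = L_rand/L − CC/CC_reg.
5. **Centrality.** Degree, eigenvector (power iteration on Ax = λx),
   closeness and betweenness, with top-k hub tables.
6. **Modularity.** Q = (1/2m) Σ (A_ij − k_i k_j/2m) δ(g_i, g_j),
   maximised by Clauset–Newman–Moore greedy agglomeration, applied
   recursively to every community with ≥ 9 members.
7. **Synthetic validation.** Generators for toy structures with planted
   contacts, ribosome-like hub-periphery networks (68 nodes, 235 edges)
   and planted-partition graphs make every stage testable without
   downloading structures.

## Worked example

Build a five-element assembly around the peptidyl transferase centre with
four planted contacts, call interfaces from geometry alone, and analyse
the network:

```r
library(ribonet)

els <- data.frame(
  name     = c("23S-D5", "L16", "L27", "tRNA-A", "mRNA"),
  category = c("rRNA_domain", "rprotein", "rprotein", "tRNA", "mRNA"),
  subunit  = c("50S", "50S", "50S", "none", "none"),
  n_atoms  = c(40, 20, 20, 25, 15))
adj <- rbind(c("23S-D5", "L16"), c("23S-D5", "L27"),
             c("23S-D5", "tRNA-A"), c("tRNA-A", "mRNA"))

toy      <- generate_toy_structure(els, adj, seed = 1, path = "ptc.pdb")
model    <- parse_structure("ptc.pdb")
elements <- assign_elements(model, toy$element_map)
calls    <- detect_interactions(elements)
subset(calls, is_interaction)
#>  element_a element_b buried_area is_interaction
#>     23S-D5       L16    35.47408           TRUE
#>     23S-D5       L27    40.88325           TRUE
#>     23S-D5    tRNA-A    35.47408           TRUE
#>     tRNA-A      mRNA    36.73202           TRUE
```

The four called contacts are exactly the four planted ones — each buries
35–41 Å² of accessible surface, far above the 0.1 Å² noise floor.

```r
net <- build_network(elements, calls, source_id = "ptc-toy")
summarize_network(net)
#>  size order isolated pendant ave_degree max_degree diameter
#>     5     4        0       3        1.6          3        3
#>  largest_cc_fraction ave_path_length cluster_coef density assortativity
#>                    1             1.8            0     0.4    -0.6666667
classify_edges(net)
#>   rrna_rrna rprot_rprot  rrna_rprot   mrna_trna
#>           0           0           2           2
greedy_communities(net)
#> community_partition: 2 blocks, Q = 0.2188
```

The 23S-D5 domain is the hub (degree 3 of a possible 4); the network is
dis-assortative (r = −0.67) because the hub connects to degree-1 leaves;
the two rRNA–protein contacts and the two ligand contacts partition the
edge set; and modularity maximisation separates the protein lobe from the
ligand lobe. The scripts under `analysis/` run the same workflow at full
scale (ribosome-sized synthetic networks, 5000-replicate null ensembles,
recursive community decomposition), writing tables under `results/`; run
them in order, `Rscript analysis/01_simulate.R` through
`06_communities.R`.

To analyse a real deposition, point `run_pipeline()` at the structure
file and a curated element map:

```r
run_pipeline(list(
  inputs = list(list(id = "5we4", structure = "5we4.cif",
                     element_map = "5we4_map.yaml")),
  out_dir = "results/5we4"))
```

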