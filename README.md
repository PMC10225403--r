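# ppimod

Phenotype-module discovery in scored protein–protein interaction (PPI)
networks.

`ppimod` is for researchers who have (a) a STRING-style scored interaction
network for their organism and (b) a list of *seed proteins* already known
to be involved in a phenotype of interest (for example root development in
rice), and who want to know which other proteins most likely belong to the
same phenotype module, how that module decomposes into dense functional
sub-modules, and which proteins hold it together.

## What it computes

**Candidate prioritization (guilt by association).** After filtering the
network to combined score > 400 and collapsing duplicate records, every
non-seed protein *u* is scored with the Hishigaki neighborhood chi-square
statistic. With *n*<sub>f</sub>(*u*) seed proteins among the *n*(*u*)
immediate neighbors of *u*, tot<sub>f</sub> seeds in the network and
tot<sub>n</sub> proteins in total,

    e_f      = tot_f · n(u) / tot_n
    score(u) = (n_f(u) − e_f)² / e_f

and candidates are ranked by decreasing score. Because the raw chi-square
also rewards seed-*depleted* neighborhoods, neighborhoods with
*n*<sub>f</sub>(*u*) ≤ *e*<sub>f</sub> score 0 by default (the
`overrepresented_only` guard; disable with `allow_depletion` in the
pipeline config).

**Module extraction.** The phenotype module is the induced subgraph on the
in-network seeds plus the top-*k* candidates (default *k* = 75, with a
20/50/75/100 seed-retention report to justify the choice of *k*).

**Sub-modules.** A from-scratch reimplementation of the MCODE
molecular-complex detection algorithm (vertex weighting by the
core-clustering coefficient, greedy seeded growth, 2-core filter, haircut)
at degree cutoff 2, node score cutoff 0.6, k-core 2, max depth 100.

**Hubs.** Intramodular hubs are the top decile of the module degree
distribution with boundary ties included; intermodular hubs are proteins
whose neighbors span at least 3 distinct sub-modules.

**Enrichment.** Hypergeometric over-representation of annotation terms
(flat GO/KEGG-style sets, GMT or two-column TSV) in any protein set against
the network background, with Benjamini–Hochberg adjusted p-values reported
alongside the raw ones.

**Synthetic benchmark networks.** `generate_synthetic()` emits a
STRING-dialect scored edge list with planted, seed-enriched communities,
symmetric duplicate records, a score distribution straddling the 400
cutoff and controlled seed dropout, plus a ground-truth table — so the
whole pipeline is testable end to end without any database download.

## Worked example

```r
library(ppimod)

gen     <- generate_synthetic(synth_config(), dir = tempfile())
edges   <- deduplicate(filter_by_score(parse_string_links(gen$paths$links), 400))
network <- build_graph(edges)
seeds   <- load_seed_list(gen$paths$seeds, igraph::V(network)$name)
seeds
#> Seed set: 51 protein(s), 6 missing from network

scores <- score_all_candidates(network, seeds)
head(as.data.frame(scores), 3)
#>   protein n_f_u n_u      e_f     score rank
#> 1   P0065    19  27 2.124126 134.07639    1
#> 2   P0004    17  23 1.809441 127.52731    2
#> 3   P0041    14  21 1.652098  92.28913    3

seed_retention_report(network, seeds, scores, c(20, 50, 75, 100))
#>     k present absent
#> 1  20      45      6
#> 2  50      45      6
#> 3  75      45      6
#> 4 100      45      6

module <- extract_module(network, seeds, select_top_k(scores, 75))
module
#> PPI module: 120 proteins (45 seed, 75 predicted), 740 interactions

cx  <- find_complexes(module$graph)
cx
#> MCODE: 2 sub-module(s)
#>   [1] 62 members, score 14.131 (seed P0024)
#>   [2] 16 members, score 4.533 (seed P0014)

hubs <- hub_report(module, assign_submodules(module, cx))
hubs
#> Hub report: 17 intramodular (degree >= 23), 0 intermodular

ground_truth_metrics(select_top_k(scores, 30), gen$truth)$precision
#> [1] 0.9666667
```

Reading the output: of the 51 listed seeds, 3 never appear in the raw edge
file and 3 survive only in sub-cutoff records, so 45 reach the module at
every *k* — the module is 45 seeds + 75 candidates = 120 proteins. The
Hishigaki ranking is driven by `n_f_u` far exceeding its expectation `e_f`
(e.g. 19 seed neighbors where 2.1 were expected). MCODE splits the module
into a dominant dense cluster and a smaller one, and 29 of the top 30
candidates fall inside the planted community (precision 0.967). On this
dense synthetic community the intramodular degree cutoff (top decile with
ties) lands at 23; on sparser real modules it is correspondingly lower.

A full run with all outputs (TSV/SIF/GraphML tables, hub report, JSON run
report) is one call:

```r
cfg <- run_config(links = gen$paths$links, seeds = gen$paths$seeds,
                  annotations = gen$paths$annotations, out_dir = "results/run1")
run <- run_pipeline(cfg)
```

or from the shell via the thin wrapper `inst/cli/ppimod.R`
(`run-all <config.yaml>`, `simulate --out <dir> [--rng-seed <int>]`,
`--version`).

The package also bundles the published hub tables of a 120-protein rice
root-development module as example data (`example_hub_degrees()`,
`example_submodule_rosters()`, `example_hub_module()`,
`example_intermodular_fixture()`) for demonstrating the hub rules on real
reported values.

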