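---
title: "Phenotype module discovery in PPI networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype module discovery in PPI networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppimod)
```

## The problem

A developmental phenotype such as root architecture is rarely the product
of one gene: it emerges from a module of interacting proteins. Given a
confidence-scored protein–protein interaction (PPI) network and a set of
*seed proteins* with established roles in the phenotype, `ppimod`
prioritizes further candidate proteins by guilt by association, extracts
the phenotype module, decomposes it into dense sub-modules, and identifies
the hub proteins that hold the module together and bridge its sub-modules.
Every stage is deterministic given its inputs; the only randomness in the
package lives in the synthetic-network generator, which is fully
reproducible from its `rng_seed`.

## Preprocessing scored edge lists

STRING-style files carry one record per ordered pair with an integer
*combined score* on a 0–1000 scale that aggregates the evidence channels.
Preprocessing has three steps, each logged in the provenance record:

* **Score filtering.** Default: keep records with score strictly greater
  than 400, the conventional medium-confidence mark. Strict `>` is the
  package default; `strict = FALSE` switches to `>=` for users who follow
  the convention that 400 itself is medium confidence. On any concrete
  input the two differ only for records scoring exactly 400.
* **Deduplication.** Each unordered pair is kept once, in lexicographic
  endpoint order. When duplicate records disagree on the score (possible
  when files are concatenated) the *maximum* is kept — conservative
  retention, and visible in the provenance counts. Self-loops are dropped
  silently from analysis but counted: they carry no information for any
  neighborhood statistic used here.
* **Identifier aliasing.** Optional, applied at parse time. Unmappable IDs
  are kept verbatim rather than dropped, so an incomplete alias table can
  never change the network topology, only its labels.

After `build_graph()` edge scores are deliberately discarded: every
downstream statistic (degree, neighborhood seed counts, MCODE weighting,
hub span) is purely topological. Scores stay available in the `edge_list`
for export.

## The Hishigaki statistic

For candidate *u* with $n(u)$ immediate neighbors, of which $n_f(u)$ are
seeds, the expected seed frequency under random placement is

$$ e_f = \frac{\mathrm{tot}_f \cdot n(u)}{\mathrm{tot}_n}, $$

and the prediction score is the chi-square-style deviation

$$ s(u) = \frac{(n_f(u) - e_f)^2}{e_f}. $$

Design choices, each a package decision where the method description is
open:

* **Enrichment guard (default on).** The raw statistic is symmetric: a
  neighborhood with *fewer* seeds than expected scores just as high as an
  equally enriched one. Since the ranking is meant to find
  phenotype-associated proteins, neighborhoods with $n_f(u) \le e_f$ score
  0 by default; `overrepresented_only = FALSE` restores the raw statistic.
  Under the guard, the score is monotone non-decreasing in $n_f(u)$ at
  fixed $n(u)$, $\mathrm{tot}_f$, $\mathrm{tot}_n$ (a property test).
* **$\mathrm{tot}_f$ counts in-network seeds only.** Seeds absent after
  preprocessing cannot contribute neighbors, so counting them would
  deflate $e_f$ and inflate every score.
* **Radius 1 by default.** The expectation formula is calibrated to the
  immediate neighborhood; larger radii are available (`radius`) but change
  the meaning of $n(u)$, not the formula.
* **Determinism.** Ties in score are broken by lexicographic protein ID,
  and seeds are never scored or selectable as candidates.
* **Zero-score candidates are never selected** by `select_top_k()`, even
  when fewer than *k* candidates score positively — padding a module with
  unsupported proteins would only dilute later stages.

The module is the induced subgraph on in-network seeds plus the selected
candidates; members with no within-module edge are retained at degree 0,
and the seed-retention report counts, for each *k* in a grid, the listed
seeds with at least one within-module interaction.

## MCODE sub-module detection

The package reimplements the MCODE algorithm rather than wrapping a GUI
plugin, with the numeric parameters fixed to the values used throughout
the analyses: degree cutoff 2, node score cutoff 0.6, k-core 2, max depth
100.

1. **Vertex weighting.** Each vertex $v$ with degree at least the degree
   cutoff gets weight $k_{\max} \times \mathrm{density}$ of the *highest
   k-core* of the subgraph induced on its closed neighborhood; density is
   the simple-graph form $2e / (n(n-1))$ (preprocessed networks are
   loop-free). Vertices below the cutoff weigh 0.
2. **Greedy growth.** The highest-weight unassigned vertex seeds a
   complex; unassigned neighbors with weight $\ge$ seed weight $\times$
   $(1 - \text{node score cutoff})$ join breadth-first up to the depth
   limit. Inclusion is `>=` (ties at the threshold join). All choice
   points break ties lexicographically, so output is invariant to edge
   ordering (tested).
3. **Post-processing.** Complexes without a 2-core are discarded; haircut
   (on by default, the plugin's default) iteratively strips members with
   fewer than two within-complex interactions; fluff is available but off
   by default. Complexes are scored density × size and numbered in
   descending score order.

A structural note documented here because it is easy to trip over: when
two cliques are joined by a single *direct* edge, every vertex weight in
both cliques is equal, so the growth threshold (at node score cutoff 0.6)
always admits the far endpoint and the cliques merge into one complex —
the same behavior as the original algorithm. Separation requires a
low-weight intermediary (e.g. a bridge *node*), whose weight falls below
the threshold. The unit tests exercise both configurations.

Manual "cluster expansion by inspecting the drawing" is not reproducible;
`assign_submodules(attach_satellites = TRUE)` provides a deterministic
substitute: one pass in which each unassigned node adjacent to members of
exactly one sub-module joins it, and ambiguous nodes stay unassigned. It
is off by default because it changes sub-module membership relative to
plain MCODE output.

## Hub identification

**Intramodular hubs** are the top decile of the *module* degree
distribution (not global network degree — hub status here means centrality
within the phenotype neighborhood). The cutoff is the degree of the
$(\lfloor 0.10\,n \rfloor + 1)$-th node in descending order — equivalently
the type-1 empirical 90th percentile — and *every* node at or above the
cutoff is a hub, so boundary ties can push the list past 10%. With the
bundled example degree table (120 proteins, top degrees 22, 19, 17, 17,
13, 12, 11, 11, 10, 10, 10, 9, then eight proteins at 8), the 13th-highest
degree is 8 and the rule returns exactly the 20 reported hubs. An
alternative convention, "cutoff = degree of the $\lceil 0.10\,n
\rceil$-th node", would land on the single degree-9 protein and return
only 12 hubs on the same table; the percentile form was chosen because it
reproduces the reported table and behaves identically on the boundary
cases covered by the tests (an all-tied degree distribution saturates the
list with a warning).

**Intermodular hubs** are proteins whose neighbors span at least 3
distinct sub-modules. A node's own sub-module counts towards its span
exactly when it has a same-sub-module neighbor — this is what makes a
protein sitting inside sub-module 4 with neighbor sub-modules {4, 2, 3}
span three, matching the bundled example fixture. Unassigned neighbors
contribute nothing. Raising the span threshold can only shrink the hub
list (tested), and a module whose sub-modules are separate components has
no intermodular hubs.

## Over-representation analysis

`enrich()` tests each annotation term for over-representation in a query
set (typically the predicted candidates or one sub-module) with the
hypergeometric upper tail $P(X \ge k)$, term by term. Decisions:

* **Background** defaults to all proteins of the preprocessed network —
  the natural population from which candidates were drawn. Web-service
  backgrounds of annotation tools are not recoverable offline; users can
  pass any background explicitly.
* **Significance flag** uses the raw p-value at `alpha = 0.05`;
  BH-adjusted values are always emitted alongside so stricter control is a
  filter away, not a re-run.
* **EASE variant** (`ease = TRUE`) discounts one query hit before taking
  the tail, giving the more conservative score some annotation servers
  report. It is offered as an option without any claim of numerical
  equivalence to a specific service.
* Annotations are flat sets; no ontology-graph propagation is performed.

## The synthetic benchmark generator

`generate_synthetic()` emulates exactly the input features the pipeline
must cope with, at a desk scale chosen once as the package's reference
condition:

| parameter | default | why |
|---|---|---|
| `n_nodes` | 600 | large enough for a stable Hishigaki null, small enough for seconds-scale runs |
| `background_edge_prob` | 0.01 | sparse background (mean background degree ≈ 6) |
| planted community | 80 nodes, intra-prob 0.25 | a dense phenotype community (mean intra-degree ≈ 20) clearly above background |
| `seed_count` | 51 | reference seed-list size |
| `seeds_missing_from_raw` | 3 | seeds absent from the raw edge file |
| `seeds_below_cutoff` | 3 | seeds whose every record is rescored below 400, so score filtering removes them |
| background scores | uniform 100–800 | ≈43% of background records fall below the 400 cutoff, so filtering bites |
| community scores | uniform 401–1000 | planted structure survives filtering |
| `emit_symmetric_duplicates` | on | STRING distributes both orientations; deduplication must halve the records |

With these defaults, preprocessing retains 45 of the 51 listed seeds by
construction, and the 120-protein module (45 seeds + 75 candidates)
reproduces the reference module arithmetic. Seeds are drawn from the
planted community so that guilt-by-association recovery is well-posed; the
`noise_seeds` option plants seeds outside it to stress the method.

What the generator does *not* emulate — and therefore what passing tests
do not show about real data: degree heterogeneity (real PPI networks are
roughly scale-free; Erdős–Rényi backgrounds are not, and degree
heterogeneity changes the Hishigaki null behavior), STRING's empirical
score distribution (only position relative to the 400 cutoff matters to
any tested behavior), overlapping communities, and correlated annotation
structure. Results on synthetic data certify the *implementation*, not
biological performance.

## Numerical and degenerate-input choices

* Score comparisons use exact integer arithmetic; the Hishigaki and MCODE
  statistics are plain double arithmetic with no tolerance tricks — the
  oracle-equivalence tests run at `1e-12`.
* Empty edge lists, edgeless graphs, header-only files, all-zero score
  vectors, queries without annotated members, and modules with fully tied
  degree distributions all have defined behavior (empty results or errors
  with informative messages), each covered by a test.
* Problem sizes used by the test suite — 200 random graphs of up to 50
  nodes for scoring-oracle equivalence, 20 graphs of up to 40 nodes for
  MCODE weight oracles, exhaustive hypergeometric enumeration up to
  N = 12, 20 replicate generator seeds for the community-recovery check —
  were chosen as the smallest sizes at which the properties are
  non-trivial; the full suite runs in well under a minute.

## Known limitations

* Degree-corrected or scale-free synthetic generators are future work;
  see above for why this matters to the null model.
* MCODE complexes are grown disjointly (a node joins at most one
  complex); the original plugin's fluff option can create overlaps and is
  implemented but off by default.
* The hypergeometric test treats annotations as independent flat sets;
  hierarchical ontologies violate this and BH control is approximate
  under term overlap.
* No weighted or directed graph semantics: the combined score is used
  only as a filter, never as an edge weight in the statistics.
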