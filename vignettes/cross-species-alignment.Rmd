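---
title: "Cross-species PPI network alignment and interolog discovery: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species PPI network alignment and interolog discovery: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(interolign)
```

## The problem

Protein–protein interactions (PPIs) conserved between a model organism and
human — *interologs* — let experimental findings travel between species: an
interaction between two proteins in one species whose orthologs also
interact in the other species is strong evidence for a conserved functional
module. `interolign` implements the full comparative workflow around that
idea: building species-specific PPI networks from STRING-style scored edge
tables (confidence cutoffs, experimental-evidence filtering, seeded
subnetwork extraction), computing cross-species protein sequence similarity
by global alignment, producing a one-to-one *global network alignment*
(GNA) between the two networks, scoring it against a predicted-ortholog
gold standard, and extracting the *unified* and *common* conserved
networks that summarize what the alignment found.

The package ships a duplication–divergence simulator of paired species
networks with planted ortholog truth, so every stage is testable end to end
without any database download.

## Network model and filtering

A network is an undirected graph whose edges carry a STRING-style combined
confidence score (integer 0–1000) plus per-channel evidence scores. Two
filtering decisions follow STRING conventions:

* **Confidence cutoff.** User-facing cutoffs are fractions of the combined
  score (0.7 = high confidence, 0.9 = highest, 0.5 = medium); an edge
  passes when `combined_score >= round(min_combined * 1000)`. Duplicate
  rows for an unordered pair are collapsed (keeping the maximum score)
  *before* filtering, so reciprocal rows cannot rescue an edge.
* **Experimental evidence.** `require_experimental` keeps only edges whose
  direct `experiments` channel is positive. Evidence transferred by
  homology from another organism (`experiments_transferred`) is excluded
  unless explicitly allowed — transferred evidence is circular when the
  goal is to *discover* cross-species conservation.

Nodes left without edges after filtering are retained (they are real
proteins of the dataset, merely without reliable PPIs); a prune flag drops
them. Seeded extraction returns the subgraph induced on the seed proteins,
their direct partners, and all edges among that set, including
partner–partner edges.

## Sequence similarity

The biological input to alignment is a dense source × target matrix of
global (Needleman–Wunsch) percent similarity, divided by 100. Choices, all
configurable and echoed into output metadata:

* **Scoring**: BLOSUM62, gap open 10, gap extend 0.5 — the de facto
  standard for needle-style global protein alignment. A gap of length
  $L$ costs $\mathrm{open} + L\cdot\mathrm{extend}$; end gaps are
  penalized, so the alignment spans the entire length of both proteins.
* **"Similar"**: a column counts as matched when both positions are
  residues and their substitution score is strictly positive (the EMBOSS
  similarity convention); `X` scores 0 against everything and therefore
  never matches. The denominator is the full alignment length including
  gap columns.
* Proteins without a sequence get similarity 0 everywhere (with a
  warning), and the dynamic programming itself is delegated to
  `Biostrings::pairwiseAlignment`; an independently coded Gotoh recursion
  serves as the test oracle. Tie-breaking among co-optimal alignments is
  deterministic (same inputs, same output) but the specific traceback
  preference is the library's; scores and, in practice, percent similarity
  are unaffected.

## The alignment objective

An alignment $f$ maps every node of the smaller (source) network $G$
injectively into the target network $H$. Its quality is

$$\mathrm{obj}(f) = \alpha \cdot \mathrm{S3}(f) + (1 - \alpha) \cdot
\frac{1}{|V_G|}\sum_{u \in V_G} \mathrm{sim}(u, f(u)),$$

where S3 (symmetric substructure score) is
$C / (|E_G| + I - C)$ with $C$ the conserved edges and $I$ the target
edges induced on the image. S3 penalizes both unconserved source edges and
spurious induced target edges; plain edge conservation $C/|E_G|$ (EC) is
selectable. When both edge sets on the mapped region are empty the score is
defined as 0 and flagged degenerate. $\alpha = 1$ is topology-only
alignment; $\alpha = 0.5$ is the default for combined
topological+biological runs. Neither the measure nor the weight is
canonical in the GNA literature, which is why both are explicit,
recorded parameters rather than hidden constants.

## Aligners

**Genetic algorithm (`ga_align`).** A population of injective
target-index arrays evolves by tournament selection (size 2), position-wise
crossover with conflict repair (a source whose inherited target is already
taken receives the free target of highest sequence similarity), and
random-transposition mutation; elitism keeps the best `elite_count`
alignments, so the best objective is non-decreasing across generations. A
run stops after `generations` generations or `patience` generations
without improvement, and `restarts` independent runs keep the best
result. The initial population contains the greedy solution plus random
injections — memetic seeding that costs one greedy run and reliably
anchors the search; the GA must still escape the greedy solution when it is
suboptimal, which the exhaustive-oracle tests verify. All randomness flows
from one explicit seed via labeled, independent streams
(`derive_seed`), so adding a stage never perturbs another stage's draws.

**Greedy baseline (`greedy_align`).** Repeatedly matches the unmatched
pair $(u, w)$ maximizing $\alpha T(u,w) + (1-\alpha)\mathrm{sim}(u,w)$,
where $T$ is the fraction of $u$'s already-aligned neighbors mapped onto
neighbors of $w$ — the topological information is renewed after every
match. Ties break lexicographically by (source id, target id), making the
baseline fully deterministic.

**Exhaustive oracle (`exhaustive_align`).** Complete enumeration of
injective mappings, guarded to $|V_G| \le 7$, $|V_H| \le 8$; ties resolve
to the lexicographically least mapping tuple. It exists to certify the
stochastic aligner on tiny instances and is checked against a second,
independently coded enumerator in the tests.

## Evaluation against predicted orthologs

The gold standard is a many-to-many ortholog map (OrthoList2-style,
two-column TSV). Because several proteins can share a predicted ortholog, a
perfect one-to-one alignment is generally impossible; a mapped pair is
therefore *correct* when the target is **any** of the source's predicted
orthologs. Only source proteins with at least one ortholog present in the
target network are evaluable — the rest are reported separately, so the
correct + incorrect accounting runs over evaluable pairs only. *Aligned
interactions* are the conserved source edges; *interologs identified* are
the conserved edges whose both endpoint pairs are correct.

The *reference alignment* emulates a manual, ortholog-guided alignment:
candidate pairs (ortholog pairs present in both networks) are assigned
greedily by marginal conserved-edge gain with lexicographic tie-breaks,
under the constraint that no assignment may reduce the number of
ortholog-bearing proteins that can still be matched (checked with a
maximum bipartite matching). It therefore maximizes correct node
alignments while resolving one-to-many choices toward conserved
interactions, and it is partial by design: proteins without in-network
orthologs stay unmapped.

## Unified and common networks

The *unified network* merges the two species: nodes are aligned protein
pairs, edges are conserved interactions. Membership defaults to pairs
incident to at least one conserved edge — the published pair counts of
this kind of analysis are strict subsets of all aligned pairs, and
conserved-edge incidence is the natural formalization; `orthologous_pairs`
and `all_pairs` are selectable alternatives since no canonical rule
exists. Pairs that are also predicted orthologs are flagged
interolog-confirmed. The *common network* intersects two unified networks:
pairs aligned identically in both analyses and conserved interactions
present in both — a commutative, associative, idempotent operation whose
output is contained in both inputs.

## The synthetic benchmark generator

`make_benchmark` emulates exactly the structure the comparative analysis
exploits:

* an ancestral PPI network grown by **duplication–divergence** (each new
  protein copies a random template's interactions with retention
  probability `dd_retention = 0.4` and links to the template with
  probability `dd_parent_link = 0.7`, from a 3-clique) — chosen over
  Erdős–Rényi because duplication-born redundancy (similar neighborhoods,
  network automorphisms) is precisely what defeats topology-only
  alignment of real interactomes;
* two descendants that independently lose nodes (`node_loss_rate`) and
  edges (`edge_loss_rate`), gain spurious edges (`edge_gain_rate` as a
  fraction of $|E|$), duplicate surviving genes (`duplication_rate`,
  creating the one-to-many rows of the ortholog map), and accumulate
  per-site substitutions (`mutation_rate`) in initially random
  length-`seq_length` protein sequences.

The planted truth is closed-form: orthologs are descendants sharing an
ancestor; interologs are edge pairs, one per species, whose endpoints share
ancestors. Ortholog sequence similarity is controlled solely by
`mutation_rate`, with unrelated proteins at whatever random sequences give
(about 0.25 mean similarity under the default scoring) — emulating the
clear ortholog signal that real cross-species sequence comparison shows.
What the generator does **not** emulate: indels and realistic
substitution-model sequence evolution, correlated evidence noise in
confidence scores, study-bias in which interactions get tested, and
assortative degree structure beyond what duplication–divergence produces.
Passing recovery tests therefore demonstrate correctness of the machinery
and the qualitative behavior of the objective, not performance guarantees
on any particular real interactome.

## Study conditions and numerical choices

The package's desk-scale studies (test suite and `scripts/acceptance.R`)
use these conditions, chosen once as realistic for the regime they probe:

* *GA optimality*: 20 random instances with 4–6 source nodes, population
  200, up to 500 generations, patience 30, 5 restarts, compared to the
  exhaustive optimum at tolerance $10^{-9}$.
* *Sequence alignment*: 200 random pairs of length ≤ 12 against the
  independent Gotoh recursion, exact equality.
* *Planted recovery*: zero-divergence benchmarks with 20 ancestral
  proteins recover 100% of orthologs and all planted interologs; the
  degradation sweep fixes `mutation_rate = 0.15`, `duplication_rate =
  0.1`, `node_loss_rate = 0.05`, `edge_gain_rate = 0.05`, sequence length
  60, and varies `edge_loss_rate` over {0, 0.15, 0.3, 0.45} with 30 seeds
  per level (trend assessed by the sign and significance of a linear fit).
* *Topology-vs-combined contrast*: `duplication_rate = 0.25`,
  `edge_loss_rate = 0.15`, `mutation_rate = 0.05`, 30 paired seeds,
  $\alpha = 0.5$ versus $\alpha = 1$ with identical GA settings
  (population 60, ≤ 80 generations, patience 15).

Numerical conventions throughout: objective comparisons use absolute
tolerance $10^{-9}$; degenerate denominators (edgeless regions) score 0
with a flag rather than `NaN`; all ties (greedy candidate choice,
exhaustive enumeration, duplicate-edge collapse) break lexicographically so
every deterministic path is bit-reproducible; seeds are 32-bit safe.

## Limitations

The GA is a stochastic maximizer certified only at desk scale; on large
networks its result depends on the budget (population, generations,
restarts) and should be treated as a lower bound on the attainable
objective. The evaluation inherits every bias of the predicted ortholog
map used as gold standard. Identifier translation between resources is out
of scope — inputs must share one namespace per species. Directed, signed,
or weighted-topology alignment is not supported, and no statistical
enrichment is performed on the resulting conserved networks.
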