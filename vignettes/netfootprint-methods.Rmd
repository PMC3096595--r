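---
title: "Phylogenetic network footprinting: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic network footprinting: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netfootprint)
library(dplyr)
```

## The problem

Transcription factor (TF) interaction networks are experimentally mapped in
only a handful of species — large mammalian two-hybrid screens exist for
human and mouse, and curated databases hold a modest set of fly
interactions. For most marine invertebrates, including reef-building
corals, no interaction data exist at all. Phylogenetic network footprinting
sidesteps this gap: if two proteins interact in one species, their orthologs
in another species are expected to interact as well. Transferring
experimentally verified TF–TF interactions along orthology relations yields
*interologs* — inferred interactions — in species that have never been
assayed, and aligning the resulting per-species networks exposes which
regulatory interactions are ancient and conserved, which are restricted to
particular lineages, and where networks have expanded by gene duplication.

netfootprint implements this pipeline end to end, together with a
ground-truthed synthetic-data generator so that every stage can be validated
without any external downloads.

## TF classification

A protein is regarded as a TF when it carries at least one Pfam domain from
a curated catalog of domains that bind DNA in a sequence-specific manner
(`read_dbd_catalog()` + `classify_tfs()`). This is deliberately a
high-precision rule: co-factors and chromatin proteins without a
sequence-specific DNA-binding domain (DBD) are excluded. The package ships
no catalog of its own — the catalog is an input, one accession per line —
and `validate_against_known()` quantifies the rule against a curated known
TF set via the positive predictive value, PPV = 100·TP/(TP+FP), reported to
two decimals with half-up rounding.

For transcriptome assemblies without gene models, `find_orfs()` /
`find_all_orfs()` implement six-frame ORF finding and `select_cds()` the
two-tier CDS choice: an ORF with a protein-database best hit wins (highest
bitscore, then lowest e-value, then longest peptide, then smallest start);
contigs with no hit fall back to the longest ORF (ties: smallest start, then
lowest absolute frame). These tie-breaks are the package's own convention —
"best hit" alone does not pin down an order. Two ORF conventions are
supported because ORF-finder defaults differ between tools and versions:
`atg_to_stop` (default, first ATG of every maximal stop-free codon run, 30
aa minimum) and `stop_to_stop`. Coordinates are 1-based inclusive on the
forward strand and exclude the stop codon; a run truncated by the contig end
is reported without a stop; codons containing `N` translate to `X`. Only
the standard genetic code is used (nuclear transcripts).

## Interolog inference

For each experimentally verified source interaction (A, B) of species *s*
and each target species *i*, the orthologs of A in *i* (A<sub>i1</sub> …
A<sub>iP</sub>) and of B (B<sub>i1</sub> … B<sub>iQ</sub>) are read from
pairwise ortholog groups, and **all** P×Q pairs are taken as candidate
interologs (`infer_interlogs()`). Ortholog groups follow the Inparanoid
layout: a seed pair of mutual best hits plus same-species *inparalogs* —
co-orthologs created by duplication after the speciation. Inparalogs
generally retain the interactions of their duplication partner, which is
exactly why the cross product, rather than a one-to-one mapping, is the
right transfer rule; a one-to-many ortholog relation then expands a single
source interaction into several interologs (a *network expansion*).

Design choices worth stating explicitly:

* **DBD filter.** A candidate interolog is retained only when **both**
  endpoints are TFs of the target species. Filtering on one endpoint only is
  available as `dbd_filter = "either"` for sensitivity analysis, but the
  default matches the rule that proteins without any sequence-specific DBD
  are excluded from the networks altogether.
* **Homodimers.** A homodimeric source (A, A) with k ortholog copies
  expands, under the literal all-pairs reading, to all k(k+1)/2 unordered
  pairs (`homodimer_mode = "full"`, the default). The `"diagonal"` mode
  keeps only the k self-pairs — the "redundant system of homodimers"
  reading. Both are implemented and tested; the choice changes expansion
  multiplicities (3 vs 2 for k = 2) but not presence/absence.
* **No transitive chaining.** Interologs are inferred directly from source
  edges only, never through an intermediate species: transfer is
  source-species → target species in one hop.
* Inparalog confidences are carried through but never thresholded.

Edges are stored as unordered pairs canonicalized by lexicographic endpoint
order; duplicates collapse on ingest, and an interolog reachable from
several source edges is stored once with the originating edge ids merged
(`collapse_interlogs()`, `merge_networks()`).

## Conservation, TRIs and expansions

Every source edge defines an *interaction class*: the edge plus its
interolog sets in every species (`build_interaction_classes()`).
Conservation is decided at the class level — one surviving interolog per
species suffices — because paralog counts legitimately differ across
species while the interaction itself is the conserved object. A class
present in every analyzed species (configurable via `required_species`) is
conserved (`conserved_classes()`); the connected components of the
conserved classes projected onto a reference species form conserved
subnetworks (`conserved_subnetworks()`), reported with per-species edges
and orthology links between display-adjacent species.

A class whose presence pattern is a proper non-empty subset of the analyzed
species is a **taxonomically restricted interaction** (TRI,
`detect_tris()`) — the interaction-level analogue of taxonomically
restricted genes. The definition is deliberately operational (proper-subset
pattern); a class present only in its source species is a TRI with a
pattern of size 1, so conserved/TRI is an exact partition of the classes.
When the ortholog maps and TF sets are supplied, each missing species is
diagnosed from the actual inputs: `ortholog_loss` when an endpoint has no
ortholog there, `dbd_loss` when orthologs exist but none passes the DBD
filter, `mixed` when different missing species disagree. Classes with a
species multiplicity ≥ 2 are reported as expansions (`detect_expansions()`).

## Domain-composition phylogeny

`composition_profile()` counts, per species, how many TFs contain each
domain type. Counting is presence-per-TF (a TF with three zinc fingers
contributes 1 to the zinc-finger count) because the question is what
fraction of the repertoire uses a domain, not how often the domain is
copied; `count_copies = TRUE` switches to hit counting, in which case the
"proportion" is an average copy number and is capped at 1 before the
transform. Proportions are variance-stabilized with the arcsine-square-root
transform, asin(√p), which makes repertoires of very different sizes
comparable (the package checks the stabilization property itself: across
binomial proportions 0.1–0.9 at n = 100 the transformed variance varies by
less than a factor 1.6 while the raw variance varies more than twofold).

Species are compared two ways. A species × domain contingency table over
the union of per-species top-10 domains (`top_k_domains()`,
`domain_contingency()`) feeds Fisher's test
(`fisher_species_test()`): exact for 2×2, and the Freeman–Halton
generalization estimated by Monte-Carlo (default 10⁵ draws, seeded, with
the standard error of the p-value reported) for larger tables, where exact
enumeration is infeasible — a chi-square fallback is available. Second,
Euclidean distances between the arcsine-transformed proportion vectors
(`species_distance_matrix()`) are clustered into a tree
(`build_domain_tree()`): UPGMA by default, neighbour joining as an option,
both deterministic for a given matrix. Neither the distance nor the linkage
is forced by theory; Euclidean-on-transformed-proportions with UPGMA is the
package's default and NJ is provided because it is the standard choice when
clock-likeness is in doubt.

## Degree structure

`degree_distribution()` counts distinct interaction partners; under the
default `partner_count` policy a homodimer loop contributes 1 (the TF is
its own partner), under `graph_degree` it contributes 2 so that the
handshake identity Σdeg = 2|E| holds. `fit_power_law()` fits
p(k) ∝ k^(−α) for k ≥ xmin by discrete maximum likelihood: α maximizes the
Hurwitz-zeta likelihood (direct summation plus an Euler–Maclaurin tail
correction), and xmin is chosen by Kolmogorov–Smirnov minimization over
candidate cutoffs retaining at least `min_tail` (default 10) observations.
The historical least-squares fit of the log–log histogram is available as
`method = "ols"` and is flagged as biased in its own method string.
Degree-0 nodes are excluded from fits and included in summaries.

## The synthetic-data generator

`simulate_dataset()` produces every input the pipeline reads, plus the
ground truth to score it against, from one seeded RNG stream:

* **Species and families.** Five species on the tree
  `((((HS,MM),SP),DM),AM)`. Each of `n_families` (default 500) ancestral
  families survives a lineage with probability 1 − `loss_rate` (default
  0.05) and holds 1 + Poisson(`duplication_rate`) copies there (default
  0.3) — pure inparalogs, duplications after the terminal speciation;
  outparalogs are out of scope, matching the Inparanoid semantics the
  transfer rule relies on. A fraction `dbd_fraction` (default 0.35) of
  families carries a catalog DBD inherited by every member. Protein
  sequences are random residue strings of length 100–1500 aa: nothing
  downstream of TF classification reads sequence, so placeholders suffice.
* **Source network.** `n_source_edges` (default 300) edges among the
  DBD-bearing proteins of the assayed species (default HS and MM, mirroring
  the mammalian-assay-plus-fly regime), grown by preferential attachment:
  nodes activate one at a time, attaching with probability proportional to
  degree^`attachment_exponent` (linear kernel, default exponent 1), a
  process whose degree sequence is heavy-tailed; `homodimer_fraction`
  (default 0.05) of edges are self-loops.
* **Planted losses.** With probability `tri_loss_rate` a family is knocked
  out in one lineage drawn from the *non-assayed* species (so a planted
  loss can never invalidate a source edge): either its members there are
  deleted (`ortholog_loss`) or only their DBD annotations stripped
  (`dbd_loss`), 50/50. Every source edge touching a knocked-out family
  becomes a TRI with a known pattern and cause.
* **Ground truth.** Expected interolog sets are computed by a plain
  nested-loop brute force over family members — deliberately sharing no
  code with the join-based `infer_interlogs()` — along with expected
  presence patterns, planted TRIs and expected expansion multiplicities.
  The same seed is byte-identical on disk (`emit_dataset()`).

What the generator does **not** emulate: sequence similarity (ortholog
groups are derived from family membership, not alignment scores), noisy or
incomplete domain annotation, assay false positives/negatives in the source
network, and outparalogy. Passing tests therefore demonstrate that the
machinery is correct — the cross product, the filters, the alignment, the
bookkeeping — not that interolog transfer is biologically error-free on
real data, where annotation noise and ortholog misassignment add error
modes the generator excludes by construction.

`simulate_domain_profiles()` separately evolves arcsine-transformed domain
proportions by Brownian motion along a supplied tree (increment variance
proportional to branch length, values clipped to [0, π/2]); on an
ultrametric input tree the expected distance matrix is ultrametric with the
generating topology, which is what makes topology-recovery testing
well-posed.

## Numerical conventions and degenerate inputs

* Text I/O is UTF-8; numeric text output uses a fixed 6-significant-digit
  format; all string orderings use C-locale (radix) sorting, so outputs are
  byte-stable across locales.
* PPV is rounded half-up to 2 decimals (base R's `round()` is
  banker's rounding and is not used there). An empty predicted set flags
  PPV as undefined rather than reporting 0.
* An empty DBD catalog is an error (a TF census against it is meaningless);
  an InterProScan file with zero retained rows is a warning, not an error.
* Fisher tables with zero-margin rows/columns have them dropped with a
  warning; tables smaller than 2×2 after dropping are an error.
* `fit_power_law()` refuses constant degree sequences (no exponent is
  identifiable) and sequences shorter than `min_tail`.
* Distance matrices with 2 taxa yield a degenerate single-split tree with a
  warning; UPGMA/NJ ties resolve by the (lexicographic) leaf order of the
  input matrix.
* Top-k ties resolve lexicographically by accession.

## Problem sizes used by the test-suite

The package's own checks run at deliberately modest sizes chosen to make
the statistical assertions sharp rather than to stress throughput: oracle
equivalence on 200+ randomized small instances (≤ 8 source proteins, ≤ 4
orthologs per protein); planted-TRI recovery on datasets of 500 families
and 300 source edges across multiple seeds; exponent recovery at n = 10⁴
degree draws; tree recovery with 60 domain coordinates, where the relative
sampling error of a pairwise distance, ≈ √(2/m), is small against the
internal branch lengths of the generating tree.

## Known limitations

* Orthology is consumed, not computed: the bundled `infer_orthologs_bbh()`
  is a deliberately simple mutual-best-hit + inparalog caller for testing
  and small studies; real analyses should ingest Inparanoid (or comparable)
  output via `read_inparanoid_sqltable()`.
* Interolog transfer inherits every limitation of its inputs: incomplete
  source networks, missing ortholog calls and annotation gaps all surface
  as apparent taxonomic restriction. TRI calls on real data are hypotheses
  ranked by the cause diagnosis, not proofs of loss.
* The Monte-Carlo Fisher p-value is an estimate; its standard error is
  reported and the draw count is configurable.
* No graph-alignment heuristics: classes are aligned exactly through
  source-edge provenance, which is correct here by construction but does
  not generalize to networks without such provenance.
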