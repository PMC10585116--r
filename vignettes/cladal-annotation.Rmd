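---
title: "Cladal taxonomic annotation: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cladal taxonomic annotation: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladetax)
```

## The problem

Amplicon surveys of poorly charted environments routinely produce ASVs that
a k-mer based naive Bayesian classifier cannot place: the nearest database
records are either too distant or are themselves unannotated environmental
sequences. Yet the same ASVs, aligned and placed in a phylogeny together
with curated type-strain references, often fall squarely inside clades
whose reference members agree on their taxonomy. Cladal taxonomic
annotation (CTA) exploits that agreement: it pushes reference labels
rootward onto internal nodes, and lets each unknown tip inherit the lineage
of its nearest labeled ancestor. The result is merged with the classifier
table so that tree-derived labels only ever *fill gaps*, never replace a
classifier call — the classifier remains the higher-confidence source and
the provenance of every rank is recorded.

## The node-labeling model

A ranked lineage is a vector of labels over an ordered rank set (default
kingdom, phylum, class, order, family, genus) in which assigned ranks form
a contiguous prefix. Given a rooted tree and the lineages of its reference
tips, every node is assigned, rank by rank from kingdom downward, the label
whose support among its reference descendants reaches the threshold $f$:

$$\mathrm{support}_r(L) \;=\;
\frac{\#\{\text{ref.\ descendants assigned } L \text{ at } r\}}
     {\#\{\text{ref.\ descendants assigned at } r\}} \;\ge\; f,
\qquad f \in (0.5, 1].$$

Three rules complete the definition:

* **Missing knowledge does not veto.** References unassigned at $r$ leave
  the denominator. A clade of one fully-annotated and one kingdom-only
  reference is still labeled to genus.
* **Conflicts are excluded onward.** A reference that disagrees with an
  adopted label no longer contributes at deeper ranks (it is not evidence
  about the inside of a clade it does not belong to, taxonomically).
* **Stop at failure.** The first rank where no label reaches $f$ (or no
  reference is assigned) terminates the lineage; deeper ranks stay
  unassigned, which keeps every node annotation prefix-contiguous.

Because $f > 0.5$, the adopted label is always unique; ties are
impossible. $f = 1$ demands congruence of all known labels and is the
default; lowering $f$ toward 0.5 gives a majority-rule relaxation that
tolerates isolated misannotated references at the cost of occasionally
overruling a genuine minority. The support fraction of every adopted label
is reported (to 3 decimals in file output) but plays no further role — only
$f$ gates labeling.

Only reference tips contribute. Query ASVs never feed back into node
labels, so annotating one query can never contaminate another; labeling a
tree twice is bit-identical.

## Query annotation and the merge

Each query tip walks parent-by-parent toward the root and adopts the *full*
lineage of the first node carrying any assigned rank (the `to_rank` option
instead continues until a node assigned at a chosen rank, for users who
want e.g. a genus hypothesis or nothing). A query that reaches the root
unanswered is reported all-unassigned — the expected outcome for lineages
with no curated relatives.

The merge with the classifier table is deliberately asymmetric. Per rank:
a classifier-assigned label is kept verbatim (source `NBC`); a
classifier-unassigned rank takes the tree label (source `CTA`) only if the
tree lineage agrees with the classifier at every classifier-assigned rank.
A disagreement is a *conflict*: under the default `keep-nbc` policy nothing
is filled and the conflicting ranks are flagged; the `prefer-cta` policy
(off by default) lets the tree override from the first conflicting rank
down, still flagged. Merged lineages are re-checked for prefix contiguity.
A row is tagged `CTA` when at least one rank was filled from the tree —
the "reclassified" count in the summary.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `threshold` ($f$) | 1.0 | support a label needs at a node; unitless fraction in (0.5, 1] |
| `ranks` | kingdom…genus | ordered rank set; any non-empty unique list works |
| `gap_policy` | `truncate` | lineages with a label below an unassigned rank are truncated at the first gap (warning); `error` aborts instead |
| `conflict_policy` | `keep-nbc` | see above |
| `to_rank` | none | traverse until this rank is assigned rather than any rank |
| sentinels | `""`, `NA`, `Unassigned`, `unclassified` | table fields read as "unassigned" |

Labels are compared case-sensitively after whitespace trimming. Homotypic
synonyms (the same taxon under two nomenclatures, e.g. phylum
"Planctomycetes" vs. "Planctomycetota") must be unified before congruence
testing; `normalize_lineage()` applies a user-supplied rank-scoped
alias → canonical map, validated to be idempotent.

## Tree handling and numerical choices

Trees are `ape::phylo` objects; Newick I/O, tip pruning with unifurcation
suppression and rerooting are delegated to `ape`/`phytools`. Choices where
upstream conventions are silent:

* **Midpoint rooting** places the root on the longest tip-to-tip path at
  half its length, which provably minimizes the maximum root-to-tip
  distance. When several pairs realize the diameter the lexicographically
  smallest label pair is used, so rooting is deterministic. When the
  midpoint coincides with an existing node, the tree is rooted at that
  node's position as a bifurcation with one zero-length child edge: ape's
  rooted-tree convention is a binary root, and a basal polytomy would make
  the tree "unrooted" to every downstream check. Metric properties are
  unaffected. Node-landing comparisons use a relative tolerance of 1e-9.
* **Branch lengths** must be present and non-negative for metric
  operations (rooting, distance checks); node labeling itself is
  topology-only, which the test suite verifies by perturbing lengths and
  demanding identical labels. Negative lengths are rejected at parse;
  zero lengths are allowed.
* **Node identifiers** are ape node numbers, a deterministic function of
  the Newick string. The pipeline canonicalizes the rooted tree through a
  write/re-parse round-trip before labeling, so the node ids written to
  `node_annotations.tsv` are exactly the ids a consumer obtains by
  re-reading the emitted `rooted_tree.nwk`.
* **Outputs** are fully deterministic: fixed-format support values,
  tab-separated tables, no randomness anywhere in the pipeline itself.

Collapsing nested labels (for visualization or per-clade summaries) keeps,
for each (rank, label), only the bearers with no same-labeled ancestor.
The output is an antichain in the ancestor order; a polyphyletic label
keeps one representative per disjoint occurrence rather than being forced
to a single node.

## The planted-clade simulator

Real reference trees and classifications are large and external, so
validation uses a simulator whose outputs carry ground truth by
construction. `planted_scenario()` fixes the generating conditions; a
single integer seed determines everything.

* **Taxonomy**: branching factors per rank, default two children per taxon
  from kingdom to genus — 64 genus clades, a size comparable to one
  family-level neighbourhood of a reference tree while keeping node
  labeling and the brute-force oracles fast (a few hundred tips per tree).
* **Tree**: each genus is a clade of 2–3 reference tips with 1–2 query
  ASVs grafted inside (random coalescent-style joins); genera nest into
  families and upward mirroring the taxonomy. Branch lengths are
  exponential with mean 0.05 — the scale of 16S V4 within-family
  divergence — though labeling ignores them.
* **Outgroups**: 2 query tips attach at the base on long (1.5) pendant
  edges, outside every labeled clade. They model novel deep lineages and
  double as a rooting control: carrying the tree diameter, they force the
  midpoint onto their attachment point, so midpoint rooting reconstructs
  the planted rooted topology from the unrooted emission.
* **Reference dropout**: a configurable fraction of reference lineages is
  truncated at a random rank, emulating incompletely curated references
  (default 0 — the clean condition).
* **NBC failure**: per-rank failure probabilities, default (0, 0.02, 0.05,
  0.1, 0.2, 0.4) kingdom → genus; once a rank fails all deeper ranks fail,
  mimicking the geometric depth profile of a real classifier at V4
  resolution. Outgroup queries get an all-unassigned classifier row.

What the simulator does **not** emulate: sequence evolution, alignment
error, tree-inference error (misplaced tips), chimeras, or rank structure
disagreeing with the tree. Trees are perfectly concordant with the planted
taxonomy, so passing tests demonstrate the correctness of the annotation
machinery — not robustness of the upstream tree to real data. The
`corrupt_tree()` helpers (tip shuffling, length perturbation) probe
sensitivity to exactly those violations in negative tests.

## Validation and problem sizes

The acceptance suite checks, at sizes chosen to run in seconds to a couple
of minutes on one CPU: node-by-node equality with a brute-force consensus
oracle on 50 simulated trees (~260 tips; dropout 0–0.3 crossed with
$f \in \{1.0, 0.9, 0.75\}$); exact recovery of >1,000 planted in-clade
query lineages and all-unassigned outgroups under noiseless references;
a 10,000-pair audit that the merge never alters a classifier label;
midpoint depth against an exact per-edge envelope minimization on 100
random trees; distance conservation under pruning and Newick round-trips;
byte-level determinism of two identical end-to-end runs; and the worked
micro-example of classifier-gap filling (family known, genus rescued from
the clade vs. fully-classified "no change").

## Known limitations

* **Ancestor consistency degrades with reference dropout.** At $f = 1$
  and fully annotated references, the lineage of an ancestor is always a
  rank-prefix of any labeled descendant's. With partially annotated
  references this directional guarantee is provably unattainable for any
  consensus of this family: a clade whose references are all truncated at,
  say, kingdom is labeled to kingdom even when its ancestor — informed by
  better-annotated relatives — carries a genus. What always survives, at
  $f = 1$, is comparability: nested labeled nodes never conflict at
  mutually assigned ranks. The acceptance suite asserts the directional
  property both on clean trees (holds) and on the mixed-dropout pool
  (fails by design of the condition, reported as a violation count).
* A query whose nearest labeled ancestor is wrong — misplaced tips,
  misannotated references — inherits the error; `f < 1` mitigates single
  bad references at the node-labeling stage only.
* Support fractions quantify reference agreement, not placement
  confidence; no bootstrap or posterior weighting is used.
* Which ASVs deserve tree-based rescue is the caller's decision; the
  package annotates whatever query set it is given.
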