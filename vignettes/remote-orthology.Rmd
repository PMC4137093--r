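---
title: "Detecting remote orthologs by conservation-pattern clustering and reciprocal-best-hit networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting remote orthologs by conservation-pattern clustering and reciprocal-best-hit networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Some proteins — "sequence orphans" — have orthologs in distant species that
no standard similarity search will surface: every candidate scores far below
significance (E-values of 1 to 100), buried among hundreds of equally
unimpressive chance hits. Yet true family members often remain recognisable
by a different signal: a short, family-specific set of query positions that
stays identical-or-conserved across *all* true members, while chance hits
scatter their matches arbitrarily. remort operationalises this idea: collect
everything a relaxed search returns, cluster the hits by the *pattern* of
their conservation rather than by score, and then let the candidates verify
each other through reciprocal searches.

The pipeline has five stages, each exposed as ordinary functions and
orchestrated by `run_pipeline()`:

1. **Relaxed search** (`backend_search()`): all subjects with E ≤ 100.
2. **Binarization** (`binarize()`, `alignment_profiles()`): each alignment
   becomes a 0/1 vector over the query.
3. **Consensus clustering + climbing-rate cut** (`consensus_linkage()`,
   `cut_dendrogram()`): profiles sharing a conserved consensus group
   together; the query's cluster seeds the candidate set.
4. **Iterative reciprocal verification** (`run_engine()`): candidates are
   accepted or rejected by reciprocal-best-hit rules against the growing
   set of verified orthologs.
5. **Network scoring** (`build_network()`, `network_centrality()`): verified
   orthologs are ranked by an E-value-independent eigenvector-centrality
   score on a typed orthology network.

## Binarization and the meaning of "conserved"

A pairwise local alignment is transformed into a profile of length equal to
the full query: position *p* is 1 iff it lies inside the aligned region,
neither column is a gap, and the residues are identical or conserved. We
define *conserved* as a positive substitution-matrix score (BLOSUM62 by
default); the matrix is configurable. `X` residues never count. Only the
lowest-E-value HSP per subject is kept, so each database subject contributes
exactly one profile and the cluster consensus stays well defined.

## Position weights

A conserved tryptophan says more than a conserved leucine. Position *p* is
weighted by the rarity of the query residue it carries. The default scheme
is `log_rarity`: w(a) = −log2 f(a) with Robinson–Robinson background
frequencies, i.e. the information content of observing residue *a*
(W ≈ 6.2 bits, L ≈ 3.5 bits). A second scheme, `optima`, loads diagonal
weights of the OPTIMA substitution matrix from a user-supplied table; the
package does not bundle those values, so without a table the scheme errors.

## Profile similarity and consensus linkage

Two profiles are compared by weighted Jaccard similarity over conserved
positions,

S(p_i, p_j) = Σ_p w(q_p) p_i[p] p_j[p] / Σ_p w(q_p) max(p_i[p], p_j[p]),

which is 1 exactly for identical non-empty supports, 0 for disjoint ones,
and comparable across alignment lengths — the normalisation the distance
transform d = 1 − S needs. Clustering is agglomerative, but the distance
between clusters is computed between their **conserved consensus** vectors
(elementwise AND of members), not as the average of pairwise distances:
a cluster is represented by what *all* its members conserve, which is
precisely the family pattern of interest. Ties in the minimum distance are
broken by the lexicographically smallest pair of cluster representative
ids, so runs are bit-reproducible.

Two properties of this linkage are worth knowing. Consensus vectors shrink
monotonically up the tree (the parent consensus is a subset of each
child's). And merge heights can *invert*: collapsing two clusters to their
AND can move the merged cluster closer to a third one, so a later merge may
sit below an earlier one — the same behaviour `hclust`'s centroid-type
linkages document. The cut (below) sorts heights, so it is unaffected. On
groups of mutually identical profiles the linkage reduces to classical
average linkage for within-group merges and the first cross-group
comparison; past that point the AND-consensus deliberately deviates from
the pairwise average — that deviation *is* the modification.

## Cutting the tree at the climbing rate

Sorted merge heights of a family dendrogram typically show a long flat
stretch (mutually similar alignments) followed by a steep climb (merges
joining unrelated clusters); an exponential y = a·exp(b·x) over the height
ranks x = 1..m describes this shape well. The cut is placed where the
climbing rate turns from flat to steep: the first rank x\* at which the
fitted instantaneous slope a·b·exp(b·x) exceeds the mean chord slope
(y_m − y_1)/(m − 1). Clusters are the connected components over merges
strictly below the fitted height a·exp(b·x\*).

Two numerical choices matter here, both visible in degenerate inputs:

* **Zero heights.** Identical profiles merge at height 0, and log-least
  squares cannot take log 0. Clamping zeros to a fixed tiny constant puts
  them ~20 log-units below the data and the lever arm destroys the fitted
  slope; we instead clamp to *half the smallest positive height*, which
  keeps the flatness information without distorting b.
* **No crossing.** On flat-plus-jump data the log-scale fit can
  underestimate b enough that the fitted slope never reaches the mean
  chord slope; the acceleration point then lies beyond the last rank and
  we cut at the top of the fitted curve (x\* = m).

Fewer than 3 merges, all-equal heights, or a non-increasing fit yield a
single cluster. The cut is global (a single height for the whole tree);
per-branch cutting would be a different algorithm.

## Reciprocal verification rules

Candidates are selected and judged by a small set of rules whose constants
are the method's operating point (`engine_params()`):

| parameter | default | role |
|---|---|---|
| `identity_select` | 80 % | hits *above* this identity are candidates regardless of cluster |
| `strict_e` | 1e-5 | below this E-value to the query, the strict RBH rule applies |
| `reject_fraction` | 1/3 | rejection vote threshold (strictly greater rejects) |
| `acceptable_ranks` | 2–3 | reciprocal ranks within a species still counted as support |
| `multi_support_select` | 2 | subjects found as RBH by *more than* this many verified orthologs are selected |

The engine starts from the hits with > 80 % identity plus the query's whole
cluster, and iterates: each candidate (in ascending order of its E-value to
the query, ties by id — the order is part of the contract, making runs
deterministic) is searched against the source database; for every currently
verified ortholog *o* in species *s* the rank of *o* among the candidate's
hits from *s* gives a relation — `best` (rank 1), `acceptable` (rank 2–3;
for weak similarities the second or third hit in a species may well be the
true ortholog), else `rejected`. Candidates with a reliable E-value to the
query (< 1e-5) must have the query as their reciprocal best hit in the
query's species. All others fail only if more than a third of the verified
set rejects them; the denominator is the verified-set size at decision
time, and verification is accretive (no retraction — late rejections are
visible in the audit log instead). After each pass the candidate set grows
by cluster co-membership and by subjects that more than two verified
orthologs find as their species-best hit; one-directional support is used
here because the subject's own reciprocal search does not exist until it is
selected. Candidates are bounded by the initial hit table, so the loop
terminates. Finally, any verified candidate whose supporters are the query
alone is dropped: a lone reciprocal link to the query is exactly the
signature of an unrelated sequence that happens to align.

## Network scoring

Verified orthologs plus the query form an undirected typed graph. For each
pair, the two directed relations (how each ranks the other in its search;
the query contributes its original relaxed search) classify the edge:
best–best `bb` (weight 1), best–acceptable `ba` (0.5),
acceptable–acceptable `aa` (0.25), and the one-sided `b` (0.125) and `a`
(0.0625). The weights are fixed constants carrying the score semantics, not
tunables. Each node's network score is its entry in the principal
eigenvector of the edge-weighted adjacency matrix, computed per connected
component by power iteration from a uniform positive start, L2-normalised
every step, to a 1e-10 max-change tolerance (1000-iteration cap). The
iteration runs on W + I: the shift leaves the principal eigenvector
unchanged but converges on bipartite components (a bare two-node component
oscillates under plain power iteration). Scores are non-negative, unit-norm
per component; an isolated node scores 1 by convention. Per-component
normalisation is deliberate: global centrality on a disconnected graph
concentrates all mass on one component, whereas real result networks can
contain several tight clusters.

The score is a *confidence read-out*, not a filter: true members attached
to only a few family members legitimately score low, so no exclusion logic
reads the score — the ranked table simply sorts by it.

## The synthetic generator

`generate_family()` builds seeded ground-truth worlds: one ortholog per
species carrying a 20-residue motif embedded at a random position in
150 residues of Robinson–Robinson background, with each motif position
mutated with probability 1 − `motif_identity`; per-species paralogs whose
motif copy is *scrambled* (they still align, exercising the rejection
path); and pure-background decoys that reach only weak, high-E-value
alignments. Defaults — 20 species, 3 paralogs per species, 50 decoys,
motif identity 0.8 — model a small remotely conserved protein whose family
signal lives in one short pattern.

What the generator does *not* emulate: indel evolution along a phylogeny,
domain shuffling, compositional bias, database-scale hit counts, and
realistic E-value statistics (the internal backend's E-value is a
Karlin–Altschul-shaped monotone transform of the Smith–Waterman score,
sufficient because every pipeline rule depends only on E-value order plus
two absolute, configurable cutoffs). Passing tests on these worlds
demonstrate the pipeline's logic, determinism and separation behaviour —
not performance on real databases, which depends on database composition
and search statistics.

## Problem sizes and test design

The test suite verifies the two algorithmic cores against independent
oracles — consensus linkage against a brute-force agglomerator that
recomputes AND-consensus and weighted-Jaccard distances from scratch at
every step (100 random sets, up to 12 profiles), and centrality against a
dense eigen-decomposition (100 random typed networks, up to 8 nodes).
Engine rules are pinned by hand-derived fixture scenarios at their
boundaries (80.0 vs 80.1 % identity; 2/6 vs 3/6 rejectors; 2 vs 3 RBH
supporters; strict-RBH failure; query-alone exclusion). Full-pipeline
behaviour is measured on planted families at motif identities 0.7/0.8/0.9,
20 seeds each, and the climbing-rate cut on 100 seeded 3-cluster profile
sets; `scripts/acceptance.R` recomputes seed-averaged precision, recall and
F1, the cut recovery rate, and reference arithmetic from scratch on every
run. These sizes keep the whole suite at a few minutes on one CPU while
averaging over enough seeds for the stochastic checks to be stable.

## Limitations

* The pipeline sees only what the initial relaxed search returns; an
  ortholog absent from the hit table cannot be recovered.
* Orthologs and close paralogs are not always distinguishable; the
  rejection vote is deliberately permissive (raising it loses true
  positives), and phylogenetic follow-up remains the arbiter.
* Near-identical database duplicates can exclude each other through the
  strict RBH rule.
* Searches returning more than `max_hits` (default 1500) abort by design:
  such families have enough similarity for phylogenetic methods.
* Results depend on the query chosen; running several family members as
  queries and comparing verified sets is the recommended practice.
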