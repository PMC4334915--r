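---
title: "Methods: cross-species orthology and developmental time-course comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species orthology and developmental time-course comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dictyComp)
```

`dictyComp` compares the gene repertoires and developmental expression
programs of social amoebae. This vignette is the package's own account of
its methods: the models and rules implemented, the parameters that matter,
the numerical decisions taken where the customary description of this
analysis leaves room,
and what the synthetic validation data do and do not demonstrate.

## Orthology by reciprocal best hits

Orthologous gene pairs between two species are inferred from directed
protein-alignment hit tables (BLAST outfmt 6) by the reciprocal
(bidirectional) best-hit criterion: after discarding hits with e-value
above `max_evalue` (default `1e-10`), gene *a* pairs with gene *b* iff *b*
is *a*'s best surviving hit and *a* is *b*'s. Genes that retain hits but
join no pair are recorded as paralogs of their species.

"Best" needs a total order to be reproducible. We use lowest e-value, then
highest bitscore, then the lexicographically smallest subject id, and keep
exactly one best subject per query even under full ties. Any deterministic
convention would do; this one matches common reciprocal-best practice and
is exercised against an exhaustive enumeration oracle in the tests.

Orthology is evaluated independently per species pair — no transitive
closure — so a four-species comparison uses six pairwise maps. Each gene is
then labelled by the set of other species in which it has at least one
ortholog: no orthologs makes it species-specific, otherwise it falls into
one of the 11 shared regions of the four-set Venn diagram. Only two letters
of the customary labelling are externally anchored (`K` = shared by all
four; `G` = the region absent from the second roster species); the
remaining letters follow a fixed package convention (pairwise regions `A`–`F`
in `combn` order, triple regions `G`–`J` ordered by the excluded roster
position 2, 4, 3, 1). Because letters beyond `K` and `G` are conventions,
every output also carries the explicit presence bitmask, and downstream
code should key on bitmasks, not letters.

## Gene families and lineage-dependent expansion

Family assignment propagates reference-species seed families (e.g. OG-style
ids from an external clustering) outward: a non-reference gene orthologous
to a seeded reference gene inherits that family, and genes with no ortholog
assignment inherit through within-species homolog links, processed in order
of increasing e-value so the strongest link decides first. A gene reachable
from two families keeps the stronger link's family; link cycles cannot loop
because each pass assigns only currently unassigned genes.

For expansion calling the package needs a rule, not just examples. The rule
implemented: for a family with per-species sizes $s_1,\dots,s_m$, take the
baseline $b=\max(\min_i s_i, 1)$ and call species $i$ expanded when

$$ s_i \ge \rho\, b \quad\text{and}\quad s_i \ge n_{\min}, $$

with defaults $\rho = 3$ and $n_{\min} = 4$. The expanded set is reported
as such when it is one species or matches a declared lineage grouping
(e.g. a phylogenetic group); when it covers all species but one it is
reported as the excluded lineage's *lack of expansion* (a contraction),
which is the same structural pattern seen from the other side. Measuring
against the smallest lineage rather than the median is what lets a family
that has grown in three of four lineages be recognized as such — a
median-referenced test can never flag more than half the species at once.
The $n_{\min}$ floor keeps 1-vs-2 jitter in small families from counting
as expansion. Both knobs are exposed; at the defaults the rule reproduces the
qualitative lineage categories of the six reference family-size vectors
the test suite carries (expansions confined to one lineage, to a declared
phylogenetic group, or to all lineages but one).

## Normalization of developmental time courses

The expression pipeline has a fixed order, and every stage tags its output
so running stages out of order is an error rather than a silent contract
change:

1. **RPKM**: $x = c \cdot 10^9 / (L \cdot N)$ for count $c$, transcript
   length $L$ (bp) and mapped-read total $N$ per (timepoint, replicate).
2. **Replicate means** per timepoint (replicate counts may differ across
   timepoints, e.g. 6 for one species and 2 for the other).
3. **Scaling**: each species × timepoint column is multiplied by
   $10^7/\text{column sum}$, putting both species on a common per-timepoint
   total (the `scaling_total` default of $10^7$ is the conventional value).
4. **Filtering**: genes at or below `epsilon` (default 0) at *every*
   timepoint are removed as unexpressed. Filtering after scaling means the
   removed mass does not perturb the column totals used for scaling;
   the stage tags make this order testable.
5. **Standardization**: per-gene z-scores across timepoints, using the
   sample (n−1) standard deviation — with only 4 timepoints the n vs n−1
   choice is material, so it is fixed, documented, and applied consistently
   to data and centroids. Constant rows have no defined Pearson
   correlation and are diverted to an `excluded` list, not clustered.
   Standardization happens per species *before* combining; the scaling
   step has already made the species comparable, and z-scores are
   invariant to the residual per-gene factors.
6. **Combining**: the two standardized matrices are row-stacked with
   species-namespaced gene ids.

Numerically, z-scoring large-magnitude rows (post-scaling values reach
$10^6$–$10^7$) leaves a relative centering residue, so the z-scores get one
refinement pass (re-center, re-scale); row means and sample SDs then sit at
machine epsilon, and the package tests them at $|m| < 10^{-12}$ and
$|s - 1| < 10^{-9}$.

## K-means under Pearson correlation distance

The combined matrix is clustered collectively with K-means under
$d(x,y) = 1 - r(x,y)$, k = 8, 100 random restarts, which mirrors the
standard configuration for this analysis (k chosen after trying larger and
smaller values; restarts with random initialization). For rows z-scored to
mean 0 and sample SD 1 over $T$ timepoints,

$$ 1 - r(x, y) \;=\; \frac{\lVert x - y\rVert^2}{2\,(T-1)}, $$

so Pearson-distance K-means is Euclidean K-means on the z-scored sphere.
The centroid update is the member mean followed by re-standardization —
exactly the z-scored profile maximizing the summed correlation with the
members — which makes each Lloyd step provably non-increasing in the
objective (asserted per iteration in the tests). Convergence is an exact
label fixpoint, capped at `max_iter = 300`.

Two degeneracies are handled by the same deterministic rule, reseeding from
the row farthest from its current centroid: clusters that empty out, and
centroids that become (near-)duplicates, detected at Pearson distance
$< 10^{-10}$. Duplicate reseeding matters in the exact-replication limit:
identical rows always co-assign, so a local optimum that merges two
archetypes while splitting a block of identical profiles necessarily
produces a duplicated or empty centroid, and reseeding it escapes the
optimum without ever increasing the objective (the abandoned duplicate's
members fall back to its twin at the same distance). With noisy data the
rule is essentially never triggered. The restart with the lowest total
within-cluster distance wins; ties keep the earliest restart.

The k centroids are then split into two super-groups. Rather than cutting
an agglomerative average-linkage tree, `group_clusters()` solves the
two-group problem exactly: with $k \le 8$ there are only $2^{k-1}-1$
2-partitions, and the one maximizing the mean between-group Pearson
distance is found by enumeration. On well-separated centroids this
coincides with the average-linkage cut (asserted in tests); on ambiguous
configurations the exact optimum is better defined than a greedy merge
order. Groups are labelled *down*/*up* by whether the group-mean centroid
falls or rises from the first to the last timepoint; if both groups trend
the same way the relative trend decides, with a warning. Clusters are
finally renumbered so the down group takes the lowest indices ordered by
time of peak — cosmetic, but it makes reports stable across runs.

## Concordance classes and alteration calls

Each ortholog pair is classified from its two cluster assignments:
**match** (same cluster), **similar** (different clusters, same group),
otherwise **precocious** or **retarded**; pairs with a filtered gene are
**unclassified**, and the five classes partition every submitted pair.

The orientation of *precocious* is a convention, and the two ways this
analysis gets described disagree: one phrasing reads "focal gene in the
up-regulated group, reference ortholog in the down-regulated group =
precocious", while the worked gene-level examples and the developmental
biology point the other way — a focal species that makes its spore
materials soon after aggregation runs *ahead*, and its early genes have
already switched off by later timepoints, i.e. they sit in the *down*
group. The package default (`convention = "down_in_a"`) therefore calls a
pair precocious when the focal-species gene is in the down group with its
reference ortholog in the up group; the literal alternative reading stays
available as `convention = "caption"`. Flipping the convention swaps
precocious and retarded exactly, leaving match/similar untouched, and the
package asserts that bijection as a property test.

Expression-level alterations compare post-scaling per-gene means $\ell_a,
\ell_d$: `no_expression` when $\ell_a \le$ `trace_threshold` (default 1 on
the $10^7$ scale), `increased` when $\ell_a \ge 4\,\ell_d$, `depressed`
when $\ell_d \ge 4\,\ell_a$, else `comparable`. Such genes are customarily marked
without explicit numeric criteria, so the fold (4) and trace (1)
thresholds are package choices, config-exposed, chosen as a conventional
"clearly different" fold change and a level indistinguishable from noise
after scaling.

## The synthetic study conditions

The generator defines the conditions the package is validated under; its
defaults are fixed once and are not tuned to test outcomes.

**Temporal archetypes.** `make_archetypes()` builds k = 8 z-scored
profiles over 4 timepoints, 3 falling and 5 rising, mirroring the
down/up cluster split. Profiles are combinations of orthonormal polynomial
trend contrasts: the pure falling/rising ramps sit on the linear axis and
the others sit 50° off it at spread azimuths in the quadratic/cubic plane,
staggering peak times and guaranteeing pairwise Pearson distance ≥ 0.3 at
the defaults (checked at construction).

**Time courses.** Each gene follows one archetype $z$ with expected count
$\text{base} \cdot (3 + z_t) \cdot (L/1000) \cdot (N/10^6)$ — base
abundance log-uniform over three decades, lengths uniform on 300–6000 bp,
per-replicate depths around $5 \times 10^6$ — times multiplicative
log-normal noise with sdlog `noise_sd` (default 0.1). Counts are continuous
expected-coverage values rather than integers: that choice makes the
zero-noise limit exact (z-scoring a replicate-mean RPKM profile returns the
archetype bit for bit), which the generator contracts rely on. Replicate
counts default to 6 for the focal species and 2 for the reference, and 5%
of genes are planted all-zero to exercise the expression filter.

**Planted classes and marginals.** `plant_ortholog_pairs()` draws each
pair's class from (match, similar, precocious, retarded) =
(0.18, 0.32, 0.30, 0.20) — a fixture-design choice mirroring the kind of
landscape such cross-species comparisons report (a small matched fraction,
about half the pairs in opposite groups), not a claim of reproduction — and picks archetypes
realizing the class. Per-species down-group occupancies default to 0.55
(focal) and 0.18 (reference). These marginals interact with the pair
classes: if every gene were paired, the two marginals' difference would be
pinned by the class mix, so by default only half the genes are paired
(`n_pairs = n_genes/2`) and the unpaired genes absorb the remainder.
All-zero genes are planted only among unpaired genes so planted classes
stay classifiable.

**Hit tables.** `simulate_hit_tables()` plants ortholog groups (one gene
per member species, mutual best hits at $e \le 10^{-20}$, plus strictly
worse decoy hits), paralog-only genes (surviving one-directional hits at
$10^{-15}$–$10^{-11}$ that fail the reciprocal test), and species-specific
genes (no hits, or hits weaker than the $10^{-10}$ threshold). Default
region weights put 45% of genes in all-four groups, 4% per triple region
and 2% per pairwise region, with 5% paralog-only genes.

**What passing tests do and do not show.** The generator emulates the
structure of the real analysis — archetype-driven profiles, heteroscedastic
positive noise, unequal replicate counts, planted presence/absence — but
not everything real data bring: no read-level artifacts, no
mapping/annotation errors, no genuinely novel expression shapes outside the
archetype set, no correlated noise across genes, and hit tables whose
score structure is cleaner than real alignment output. Recovery of planted
truth therefore validates the implementation (the algorithms do what they
claim under their assumptions), not the biological robustness of the
method on arbitrary real data.

## Problem sizes and determinism

The validation suite runs reciprocal-best-hit enumeration oracles on 200
random instances of up to 50 genes per species, Venn recovery on 4 × 200
genes, clustering recovery on 2 × 2000 genes with 100 restarts, and the
full file-based pipeline twice to confirm byte-identical artifacts; the
whole suite completes in well under a minute on one CPU. All randomness
flows through explicit seeds (`with_seed` restores the caller's RNG
state), pipeline artifacts contain no timestamps, and provenance files
record input checksums, parameters, seed and package version, so any run
can be reproduced exactly.

## Known limitations

- Family propagation crosses only reference-species orthology and
  within-species links; orthology between two non-reference species never
  transfers family ids, matching the seeded-propagation design.
- The exact two-group search is exponential in k; it is instant for the
  k ≤ 8 regime this analysis uses but would need the agglomerative
  fallback for k beyond ~20.
- The expansion rule is deliberately simple (ratio to the smallest
  lineage); it does not model birth–death processes or correct for
  phylogenetic non-independence.
- Venn letters beyond the anchored `K` and `G` are package conventions;
  cross-study comparisons should use the emitted bitmasks.
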