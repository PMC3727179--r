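---
title: "Subnetwork marker discovery with netmark: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subnetwork marker discovery with netmark: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netmark)
```

## The problem

Expression-only marker discovery ranks genes one at a time and returns long,
unstable lists. netmark implements the network-integrated alternative: it
overlays a two-class expression matrix on a protein--protein interaction
graph and searches for *subnetworks* — connected sets of genes whose joint
expression summary discriminates the two phenotype classes. A subnetwork can
contain members that are not differentially expressed at all ("connectors")
yet hold the discriminative members together in the graph; such genes are
invisible to per-gene statistics but can matter biologically (for example
when a loss-of-function variant leaves transcript levels unchanged).

The package covers the full analysis: data ingestion, the greedy
seed-expansion search, three permutation significance filters, a
patient-half resampling consensus, cross-validated classification of
subnetwork activity, and a conventional differential-expression /
hierarchical-clustering comparator, plus a synthetic-data generator with
planted ground truth used to validate every stage end to end.

## Data model and preprocessing

An `ExpressionDataset` is a genes-by-samples matrix of finite values with a
`case`/`control` label per sample. Values are assumed already summarized and
quantile normalized; `quantile_normalize()` (classical sort/average-rank,
ties averaged, via limma) is available for inputs that are not, but nothing
calls it implicitly. Probe-level matrices are collapsed with
`collapse_probes()`: each gene row is the arithmetic mean of its probes' rows
on the provided scale — averaging is done post-normalization, not in log
space, because the inputs are already on their final scale. Probes without
an annotation entry, and genes absent from the interaction network, are
dropped with logged counts rather than imputed; published analyses of this
kind rarely document how such genes are handled, so the package takes the
conservative option and makes it visible.

Gene identifiers are opaque, case-sensitive strings. All tie-breaking that
involves identifiers uses byte-order (C-locale) sorting, so results do not
depend on the platform's collation.

## The search

For a z-scored dataset (each gene centred and scaled across all samples;
constant genes are zeroed and flagged), the **activity** of a member set is
the per-sample arithmetic mean of member z-scores. The discriminative score
is the plug-in **mutual information** (bits) between the activity,
discretized into equal-width bins over its observed range, and the class
label. The bin count defaults to Sturges' rule, `floor(log2(n_samples)) + 1`.
MI is scale- and shift-invariant in the activity, non-negative, and bounded
by the label entropy; a constant activity scores exactly 0.

`greedy_search()` starts from every seed gene and repeatedly adds the
neighbouring gene (adjacent to the current member set, within
`max_distance_from_seed` of the seed, default 2) with the largest MI gain,
stopping when the best relative gain falls below `min_improvement_rate`
(default 5%), the set reaches `max_subnetwork_size` (default 10, matching
the 1--10-gene range marker modules are expected to span), or no candidates
remain. Ties are broken toward the lexicographically smallest gene id, and
candidates are evaluated in sorted order, so the search is fully
deterministic. When the current score is exactly 0 (a seed whose activity is
constant), any strictly positive gain is accepted, since a relative
threshold is undefined there.

### Significance filtering

Every candidate is tested against three nulls, each with `n_permutations`
draws (default 100) and the add-one estimator
`p = (1 + #{null >= observed}) / (1 + n_permutations)`, which cannot return
zero:

* **gene-null** — the assignment of expression rows to network nodes is
  permuted and the greedy search is re-run from the same seed;
* **label-null** — class labels are permuted and the search is re-run;
* **random-subnetwork-null** — connected subgraphs of the same size are
  sampled (uniform frontier growth from a uniform start node) and scored on
  the unpermuted data.

A candidate is retained only if all three p-values are at or below `alpha`
(default 0.05).

The first two nulls *re-run the search* by default (`research_nulls = TRUE`)
rather than re-scoring the fixed member set. This is deliberate: the
observed score is a maximum over many greedy expansions, so comparing it to
an unoptimized null draw is anti-conservative — on pure-noise data a
score-level label-null retains far more than the nominal 5% of candidates,
because every candidate was optimized against the very labels being
permuted. Re-running the search under the permuted data puts the same
selection pressure into the null distribution, and the package's calibration
tests confirm the retained fraction then stays within the binomial band
around alpha. The cheaper score-level variant remains available for
exploratory work. The third null is kept score-level by construction (it
randomizes the topology, not the data).

The frontier-growth sampler for the third null is not exactly uniform over
connected subgraphs (no practical sampler is); it favours subgraphs around
high-degree nodes, which is the relevant reference family here since the
greedy search also expands through hubs.

## Resampling consensus

With many more cases than controls, each resampling round splits the cases
into halves of `ceiling(n/2)` and `floor(n/2)` and merges **every** control
into both halves, equating class sizes without discarding any control;
`R` rounds times two halves times `K` repeated runs gives `2*R*K` runs
(a cohort of 173 cases and 74 controls, say, yields merged runs of 87+74 and
86+74 samples, and R = 5 with K = 4 gives a 40-run design). The search itself is
deterministic given a dataset, so repeated runs on the same half differ only
through the permutation filter's seed; both interpretations of "repeated
runs" are representable by setting `K` and the per-run seeds, which the plan
generator derives from one master seed by a counter scheme (adding runs
never reshuffles earlier ones).

Runs are then aggregated by `group_and_rank()`. Two identity notions are
supported. The strict one — groups are exact member sets — turned out to be
degenerate in validation: a recurrent module whose recovered boundary
wobbles by a single gene across halves splinters into several low-frequency
variants, and perfectly stable one- and two-gene cores then dominate the
frequency ranking. The default is therefore the Jaccard identity: exact
groups are clustered (visited in frequency/score order, absorbed when the
Jaccard index with a cluster's representative set reaches 0.8), a cluster's
frequency is the number of runs containing any variant, and its reported
member set is the best-scoring variant's. Groups are ranked by frequency,
then mean score, then member list, and selection takes either the `top_k`
groups or all groups above a frequency floor; there is no principled
universal cutoff, so both modes are exposed and reported.

## Classification evaluation

Selected subnetworks become features (their activity per sample);
gene lists become per-gene z-score features. Accuracy is estimated by
k-fold cross-validation (default 10 folds, sizes differing by at most one,
unstratified by default with a stratified option) with two deliberately
dissimilar classifiers:

* `tree` — a recursive-partitioning decision tree (rpart);
* `rbf` — a radial-basis-function network built in the package: k-means
  centres on the training folds (centre count `min(10, floor(sqrt(n)))`),
  Gaussian hidden units with a shared width equal to the mean inter-centre
  distance, and a logistic output layer.

The contract is "two dissimilar classifier families with fixed seeds", not
byte-compatibility with any particular third-party binary; analyses of this
kind have historically leaned on off-the-shelf C4.5 and RBF-network
implementations.
Reported accuracy is the mean of the fold accuracies (the pooled rate over
all held-out predictions is also returned; with near-equal folds they differ
by well under a point).

`cross_test()` trains on all of one dataset and evaluates on another —
typically the two case halves, each merged with the shared controls. Z-score
parameters are learned on the training set only and applied unchanged to the
test set; a construction test shifts the whole test matrix far outside the
training range and checks that accuracy collapses to the majority rate,
which would be impossible if test statistics leaked into standardization.

## The expression-based comparator

`t_test_rank()` runs a per-gene two-tailed Welch t-test (the
unequal-variance form is the safer default when no variance assumption is
justified; a pooled option exists) and flags raw `p < 0.05` without multiple-testing
correction — that is the comparator being reproduced, not a recommendation.
Genes are ranked by p, then |t|, then id. The top-k genes feed
complete-linkage hierarchical clustering on `1 - Pearson` distances, genes
correlated across all samples and samples across the selected genes only.
Misclassification is counted by cutting the sample dendrogram into exactly
two clusters at the highest merge and labelling each cluster by majority
(ties resolved toward "case" for the cluster holding more cases) — the
minimal formalization of reading misassigned samples off a two-way heat map.
`overlap_genes()` reports the intersection of the subnetwork gene union with
the top-k DE list, the quantity behind the observation that network markers
and top-DE lists barely overlap.

## The synthetic generator

`synthetic_config()` describes the validation conditions: a scale-free
(preferential-attachment) or Erdos--Renyi interactome, two sample classes,
per-gene baselines `mu_g ~ N(0,1)`, additive Gaussian noise (microarray-like
continuous intensities, not counts), and `n_modules` vertex-disjoint
connected modules of `module_size` genes planted by random frontier growth.
`ceiling(connector_fraction * module_size)` members per module get effect
exactly 0 (connectors); the rest are mean-shifted by `effect_size` in
noise-SD units. Disjointness keeps recovery scoring unambiguous. Everything
is bit-reproducible from the config seed.

Effect direction is controlled by `sign_scheme`. The default is
`per_module`: all differential members of a module shift the same (random)
way. The alternative `per_gene` draws a sign per member and so produces
mixed up/down modules — but a module whose directions cancel (two up, two
down) has *identically zero* class signal in its mean activity, making the
planted set unrecoverable by the statistic under test; with random per-gene
signs that happens to roughly a third of four-member modules. Recovery
benchmarks therefore use the coherent scheme, and the mixed scheme is kept
for studying exactly that failure mode.

Default conditions (300 genes, mean degree 4, 50 cases / 50 controls, one
5-gene module with one connector, effect 2 SD, unit noise) are the
desk-scale conditions used throughout the package's validation; the classification checks raise the effect to 3 SD, and the
calibration checks set it to 0. What the generator does **not** emulate:
batch and laboratory effects, probe-level structure, correlated background
expression, dependence between network topology and expression, or realistic
interactome noise (false/missing edges). Passing the bundled validation
therefore demonstrates correctness of the machinery under its stated
assumptions, not performance on real cohorts.

## Numerical and degenerate-input conventions

* Binning: `bin = floor((x - min) / range * n_bins)`, clamped to the last
  bin at the maximum; a zero range (constant activity) scores 0 directly.
* The add-one p-value estimator never returns 0; configurations whose
  minimal attainable p exceeds alpha (fewer than `1/alpha - 1` permutations)
  are rejected at the door.
* Constant genes: zeroed and flagged by `zscore_normalize()`; assigned
  `t = 0, p = 1` by `t_test_rank()`; rejected by name in clustering, where
  a Pearson distance is undefined.
* An unsampleable random-subnetwork size (no component large enough) counts
  as a null tie, which can only make the test more conservative.
* All readers reject NA/NaN/Inf with located errors instead of propagating
  them.

## Validation problem sizes

The shipped test suite validates the MI estimator by exhaustive enumeration
of all small joint tables, the greedy search against exhaustive
connected-subgraph enumeration on 200 random graphs of up to 12 nodes,
filter calibration on three 200-gene null datasets (600 candidates), module
recovery on twenty 300-gene replicates of the default conditions,
classification behaviour at effect 3 SD with label-permutation nulls over 20
seeds, and the clustering stage against a naive cubic-time re-implementation.
These sizes were chosen so the full suite exercises every claim in minutes
on a single core while keeping each check's statistical band meaningful.

## Known limitations

* The greedy search cannot pass through a zero-signal connector unless the
  connector is the seed's own neighbourhood hub; modules whose informative
  members are separated by several uninformative hops are recovered as
  fragments reachable from their best seed.
* Plug-in MI is upward-biased at small sample counts, and the bias grows
  with the number of candidates compared, so chance-correlated genes can
  edge out true members in finite samples; the consensus stage mitigates
  but does not eliminate this.
* Frequency has coarse resolution when `K` repeats are deterministic
  duplicates (they differ only in filter randomness).
* Two-class phenotypes only; unweighted networks only; accuracy is the only
  classification metric (matching the comparator being reproduced).
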