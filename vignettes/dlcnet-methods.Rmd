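---
title: "Methods: ceRNA network inference and lncRNA diagnostic signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ceRNA network inference and lncRNA diagnostic signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

The ceRNA (competing endogenous RNA) hypothesis holds that transcripts
sharing miRNA response elements compete for a limited pool of those miRNAs:
when a lncRNA that sponges a miRNA is over-expressed, the miRNA's mRNA
targets are de-repressed. In expression data this predicts a characteristic
correlation signature for a functional (miRNA, lncRNA, mRNA) trio:

* lncRNA and mRNA positively co-expressed,
* miRNA negatively co-expressed with both,
* both the lncRNA and the mRNA documented targets of the miRNA.

`dlcnet` operationalizes this on matched tumor/normal cohorts in four
stages: (1) differential expression restricts attention to dysregulated
features; (2) triplet detection applies the correlation-plus-targeting
predicate; (3) network analysis asks whether the assembled network is
organized rather than random; (4) the ceRNA-active lncRNAs are evaluated as
a diagnostic signature. All stages assume expression is already normalized
and log2-scaled; the package never re-normalizes.

## Differential expression

Each feature is scored with a variance-stabilized two-class statistic
`d = (mean_tumor - mean_normal) / (s + s0)`, where `s` is the pooled
standard error of the mean difference. The fudge constant `s0` damps
statistics of low-variance features; we default to the median of all
per-feature pooled standard errors — a single robust scale choice in the
spirit of the original percentile-search procedure, exposed as the `s0`
argument for users who want the full search or another constant.

Significance comes from permuting class labels: two-sided
`p = (1 + #{|d*| >= |d|}) / (1 + P)` over `P` distinct label assignments.
When the number of distinct tumor/normal assignments is at most `n_perm`
they are enumerated completely (exact test); otherwise distinct assignments
are sampled uniformly without replacement. The add-one correction keeps p
strictly positive. FDR control is Benjamini–Hochberg on the permutation
p-values, matching the convention of reporting an FDR-adjusted p. The
selection gate — linear fold change `>= 1.5` or `<= 0.67` (computed from
log2 means, i.e. a ratio of geometric means) and `q <= 0.1` — treats its
boundaries as inclusive, following the `>=`/`<=` convention those
thresholds are usually quoted with.

## Triplet detection and network assembly

Candidate (lncRNA, mRNA) pairs are restricted to differentially expressed
features and kept when Pearson `r > 0.5` with `p < 0.05` (strict
inequalities, since these cutoffs are conventionally quoted with strict
comparison operators; p-values use the exact t transform
`t = r * sqrt((n-2)/(1-r^2))` with `n - 2` degrees of freedom).
Zero-variance features make the correlation undefined; such records are
excluded explicitly rather than propagating `NaN`.

For each surviving pair, every differentially expressed miRNA that targets
both members in the interaction table is tested for negative co-expression
with each member. The negative gate defaults to `r < 0` and `p < 0.05`,
mirroring the positive gate; both the correlation bound (`neg_r`) and the
p bound (`neg_p`) are exposed because "negatively co-expressed" does not by
itself fix a threshold. Interaction records naming features absent from the
expression matrices are filtered (with a count) at detection time, not at
load time, so one interaction table can serve several cohorts.

Accepted triplets are assembled into an undirected typed graph. Two edge
policies are implemented: `mirna_only` (each triplet contributes its
miRNA–lncRNA and miRNA–mRNA edges; the default) and `full` (adds the
lncRNA–mRNA competing edge). The published node/edge censuses of networks
of this kind do not disambiguate which convention was used, so both are
available; the default is the sparser, regulation-only view. Edges are
deduplicated across triplets and carry the contributing triplet indices as
provenance.

## Topology and null models

Degree, unnormalized shortest-path betweenness, mean local clustering
coefficient (nodes of degree < 2 contribute 0), and characteristic path
length (mean geodesic over connected pairs only; cross-component pairs are
excluded rather than imputed) are computed on the undirected, unweighted
graph via igraph. The degree distribution's power-law fit is a least-squares
line on `(log10 k, log10 P(k))` using the raw frequency at each observed
degree — no logarithmic binning — because that is the regression whose R²
is conventionally reported alongside the slope.

Null networks are generated by attempted double-edge swaps (default
`10 * |E|` attempts per replicate) constrained to pairs of edges of the
same type. Because every edge type connects two distinct node classes,
orienting edges by class makes the swap class-safe: degree sequence, node
classes and per-type edge counts are all invariant, and biologically
impossible edges (e.g. mRNA–mRNA) can never appear. Unconstrained rewiring
would not preserve this structure, which is why the package implements the
swap itself instead of using a generic rewiring routine. Empirical p-values
use the add-one rule `(1 + #{null >= obs}) / (1 + n_null)` and are therefore
never zero. Class differences in degree and betweenness use the
tie-corrected Kruskal–Wallis test.

## The diagnostic signature

The classifier is a sigmoid-kernel SVM (`tanh(gamma * <x, x'> + coef0)`),
with defaults `cost = 1`, `gamma = 1/n_features`, `coef0 = 0` — the common
defaults for kernel SVMs when no tuning protocol is specified; all three
are exposed. Features are z-scored per training fold, with the fold's
parameters applied to the held-out sample, so no information leaks from the
test sample into standardization (kernel SVMs are scale-sensitive).

Evaluation is leave-one-out cross-validation. Pooled LOOCV decision scores
have a known pathology: removing a sample tilts the training fold's class
balance against the held-out class, which depresses that sample's score and
biases null AUC below 0.5. We therefore fold-centre each score — subtract
the mean decision value of the fold's own training samples — which cancels
the fold-level shift while leaving the between-sample ordering, and hence
any real signal, intact. The package's calibration test verifies that with
permuted labels on a signal-free cohort the mean LOOCV AUC over 20
replicates stays within 0.05 of 0.5.

AUC is computed in the rank-sum form (ties count one half), identical to
the trapezoidal area over all thresholds. The diagnostic odds ratio is
`(Sens * Spec) / ((1 - Sens) * (1 - Spec))`, algebraically `(TP*TN)/(FN*FP)`
from a confusion matrix. Permutation p-values for AUC and DOR re-run the
entire LOOCV per label permutation with
`p = (1 + #{null >= obs}) / (1 + n_perm)`; permuting labels is an
equivalent, cheaper realization of the null than shuffling the expression
values themselves, since either breaks the feature–label association while
keeping the feature joint distribution. Permutation replicates with a zero
confusion cell would give an infinite DOR; those replicates use the
Haldane–Anscombe correction (0.5 added to all four cells, flagged on the
result) so the null distribution stays finite.

Unsupervised structure is assessed by average-linkage agglomerative
clustering on `1 - r` correlation distance between sample profiles, cut at
k = 2 (hclust's deterministic lowest-index merge order breaks ties). The
cluster-by-status 2x2 table is tested with the two-sided Fisher exact test
when any expected count is below 5 and with the Yates-corrected chi-square
otherwise — the standard small-count decision rule, which also matches how
such tables are typically tested at n ≈ 30 vs n ≈ 70.

## Over-representation analysis

The hypergeometric upper tail `P(X >= k)` is exact (`phyper`), with fold
enrichment `(k/m)/(K/N)` as the effect size — the usual reading of an
"enrichment score" filter — and default filters `p < 0.05`,
`fold enrichment > 3` (raw p by design; BH is available via `adjust = TRUE`
but is not applied by the default filter, which mirrors common practice for
exploratory GO screens). The default universe is the union of the
collection's members and the query — the annotation universe — since a
"whole genome" background is not well defined for an arbitrary GMT; a
custom universe can be passed. The enrichment map links surviving sets
whose overlap coefficient `|A∩B|/min(|A|,|B|)` reaches 0.5 (inclusive).

## The synthetic cohort generator

`generate_cohort()` emulates what the analysis assumes about real cohorts:

* log2 intensities with per-feature baselines from N(7, 1), matching the
  location/scale of RMA-style log2 microarray data;
* a tumor/normal design of 25 vs 7 samples by default, the size and
  imbalance of a small discovery cohort;
* per-class feature counts (300 mRNA, 80 miRNA, 100 lncRNA by default)
  small enough for fast tests but large enough that BH multiplicity is
  non-trivial;
* planted differential expression: `n_de_per_class = 30` features per class
  shifted by `log2_effect = 2` in tumors. With residual sd 0.5 this is a
  four-fold change of roughly two total standard deviations — a strong but
  realistic cancer-microarray effect, and the regime in which the DE gate
  should operate at high recall;
* planted triplets coupled through one latent factor per triplet: with
  loading `s = triplet_strength` and residual scale `noise_sd`, each
  member's residual is `noise_sd * (±s*f + sqrt(1-s^2)*z)`. The factor
  explains a share `s^2` of the residual variance instead of adding to it,
  so planted and background features are exchangeable in marginal
  distribution — planted structure is visible only through correlations,
  never through variance. Signs give the ceRNA signature (members
  positively coupled, miRNA negatively). Triplet DE directions alternate
  (lncRNA/mRNA up with miRNA down, then the reverse), because a signature
  whose members all shift one way is invisible to shift-invariant
  correlation-distance clustering and unlike real mixed-direction
  signatures;
* interaction tables containing every planted miRNA–lncRNA and miRNA–mRNA
  edge plus `n_decoy_interactions = 100` uniform random decoys over
  non-planted pairs;
* a ground-truth ledger (planted DE features with directions, planted
  triplets, labels) that round-trips through TSV.

Triplets never share a member: requesting more triplets than any feature
class supports is an error rather than an ambiguity in the truth ledger.
Seeds are mandatory; a fixed configuration is bitwise-reproducible.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: probe-level artifacts, batch effects,
heavy-tailed or heteroscedastic noise, correlated background features
(co-expression modules unrelated to ceRNA activity), partial or condition-
specific targeting, and miRNAs shared across triplets. In particular,
because all planted DE features shift by the same magnitude, same-direction
DE features acquire a class-driven mutual correlation; with an unlucky
decoy interaction such a pair can satisfy the full triplet predicate. These
are genuine statistical false positives of correlation-based ceRNA
inference, visible in the recovery test as precision slightly below 1.

## Problem sizes and numerical conventions in the test suite

The suite validates recovery on the default cohort (32 samples, 20 planted
triplets, strength 0.9, noise sd 0.5, 1000 DE permutations), classifier
null calibration on a signal-free cohort (20 permuted-label replicates),
DE-gate specificity on 20 pure-noise cohorts (200 permutations each), and
null-model soundness over 200 rewiring replicates; brute-force oracles
(path enumeration for betweenness, pair counting for AUC, hypergeometric
enumeration for Fisher and over-representation, rank-sum arithmetic for
Kruskal–Wallis) are checked on instances of at most a few hundred cells.
These sizes keep the whole suite under a minute while leaving every
statistical mechanism exercised at non-toy multiplicity.

Throughout the package: permutation and randomization p-values use the
add-one rule; correlation p-values are exact t-tail transforms; undefined
correlations (zero variance) are excluded records, not NaNs; DE-gate
boundaries are inclusive while correlation-gate boundaries are strict; and
every stochastic routine takes an explicit seed.

## Known limitations

Correlation-based triplet detection cannot distinguish miRNA-mediated
coupling from other sources of co-expression (here, the shared class
shift; in real data, co-regulation or tumor purity). Conditional or
partial-correlation scores and sensitivity-correlation variants are out of
scope. The power-law fit is the conventional log-log regression, not a
maximum-likelihood tail fit, and is reported for comparability rather than
as a rigorous scale-free test. LOOCV on three dozen samples has high
variance regardless of centring; external validation remains the only
reliable assessment of a diagnostic signature.
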