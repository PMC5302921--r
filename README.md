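# dlcnet

Competing endogenous RNA (ceRNA) analysis for matched tumor/normal
transcriptome cohorts: `dlcnet` builds a dysregulated lncRNA-associated
ceRNA network from sample-matched mRNA, miRNA and lncRNA expression
profiles, characterizes its topology against degree-preserving null models,
and evaluates an lncRNA-based diagnostic signature. It is aimed at
computational biologists studying post-transcriptional regulation — lncRNAs
that sequester shared miRNAs and thereby de-repress the miRNAs' mRNA
targets — and at anyone who needs a fully synthetic, ground-truthed test bed
for this class of pipeline.

## What it computes

**Differential expression.** A SAM-style variance-stabilized statistic per
feature,

d = (x̄_tumor − x̄_normal) / (s + s₀),

where s is the pooled standard error of the mean difference and s₀ a fudge
constant (default: the median of all per-feature pooled standard errors).
Two-sided p-values come from label permutations (complete enumeration when
feasible), are BH-adjusted, and features pass the gate when fold change
≥ 1.5 or ≤ 0.67 and q ≤ 0.1.

**Competing triplets.** For differentially expressed features, every
(lncRNA, mRNA) pair with Pearson r > 0.5 and p < 0.05 is screened against a
miRNA-target interaction table: a (miRNA, lncRNA, mRNA) competing triplet is
reported when a differentially expressed miRNA targets both members and
correlates negatively with each (r < 0, p < 0.05). Accepted triplets are
assembled into an undirected typed network.

**Topology.** Degree, betweenness centrality, mean local clustering
coefficient (CC), characteristic path length (CPL), a log₁₀–log₁₀
least-squares power-law fit of the degree distribution, randomization tests
of CC and CPL against degree-preserving double-edge-swap nulls that rewire
only within an edge type, and Kruskal–Wallis comparisons of degree and
betweenness across the three node classes.

**Diagnostic signature.** A sigmoid-kernel SVM over a chosen lncRNA panel,
evaluated by leave-one-out cross-validation with per-fold z-score
standardization and fold-centred decision scores. Reported: confusion
matrix, sensitivity, specificity, accuracy, ROC/AUC (rank-sum form), the
diagnostic odds ratio

DOR = (Sens × Spec) / ((1 − Sens) × (1 − Spec)) = (TP·TN)/(FN·FP),

and permutation p-values for AUC and DOR. Unsupervised average-linkage
clustering on correlation distance, with Fisher-exact or Yates chi-square
association between clusters and tumor status, is also provided.

**Enrichment.** Hypergeometric over-representation of a gene list against
GMT collections with fold-enrichment filtering, and an enrichment map
linking surviving sets by overlap coefficient |A∩B|/min(|A|,|B|).

**Synthetic cohorts.** `generate_cohort()` simulates log2 expression for the
three RNA classes over a shared tumor/normal sample set, plants
differentially expressed features and latent-factor-coupled competing
triplets, emits interaction tables (planted edges plus random decoys) and a
ground-truth ledger, so the entire pipeline can be validated end to end
without any external data.

## Worked example

```r
library(dlcnet)

co  <- generate_cohort(cohort_config(seed = 1))   # 25 tumor / 7 normal
res <- run_cerna_pipeline(co, n_perm = 1000, seed = 1)
res$network
#> ceRNA network: 42 edges among 20 miRNAs, 21 lncRNAs and 20 mRNAs (policy: mirna_only)

ts <- topology_summary(res$network, n_null = 200, seed = 1)
ts$kw_degree
#> H = 55.27, p = 9.95e-13   (degree differs strongly across node classes)

sig <- unique(res$triplets$lncrna)                # ceRNA-active lncRNAs
report <- evaluate_signature(unclass(co$lncrna)[sig, ], co$pheno,
                             n_perm = 200, seed = 1)
report
#> LOOCV: 32/32 correct (accuracy 1.000)
#>   sensitivity 1.000  specificity 1.000  AUC 1.000  DOR Inf
#>   permutation p: AUC 0.004975, DOR 0.004975

cl <- cluster_samples(unclass(co$lncrna)[sig, ])
cluster_association(cl$clusters, co$pheno)$p
#> 2.97e-07   (Fisher exact: clusters align with tumor status)

truth <- with(co$truth$planted_triplets, paste(mirna, lncrna, mrna))
found <- with(res$triplets, paste(mirna, lncrna, mrna))
c(precision = mean(found %in% truth), recall = mean(truth %in% found))
#> precision 0.909  recall 1.000
```

The pipeline recovers every planted triplet; the two extra triplets are
genuine co-dysregulation patterns created by the shared class shift plus a
decoy interaction — the kind of statistical false positive inherent to
correlation-based ceRNA inference (see the methods vignette). On this
separable synthetic cohort the signature classifies all 32 samples
correctly, so the permutation p-value sits at its add-one lower bound for
201 tests.

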