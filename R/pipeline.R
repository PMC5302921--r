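#' Run the full ceRNA-network discovery pipeline on an aligned cohort
#'
#' Performs permutation differential expression on the mRNA, miRNA and lncRNA
#' matrices, applies the fold-change/FDR gate, screens DE lncRNA-mRNA pairs
#' for positive co-expression, detects miRNA-mediated competing triplets over
#' the interaction tables, and assembles the dysregulated ceRNA network.
#'
#' @param cohort An `aligned_cohort` (see [align_cohort()]) or a
#'   `synthetic_cohort` from [generate_cohort()].
#' @param interactions Interaction table covering miRNA-mRNA and miRNA-lncRNA
#'   records (rbind of both tables is fine). Defaults to the cohort's own
#'   tables for a `synthetic_cohort`.
#' @param n_perm Label permutations for the DE step.
#' @param seed Integer seed.
#' @param fc_up,fc_down,fdr DE gate thresholds.
#' @param r_min,p_max Positive-correlation gate for lncRNA-mRNA pairs.
#' @param neg_p,neg_r Negative-correlation gate for the shared miRNA.
#' @param edge_policy Passed to [assemble_network()].
#' @return list with `de` (per-class DE tables), `de_ids` (per-class selected
#'   feature ids), `pairs`, `triplets`, `network` (`NULL` when no triplet
#'   passes).
#' @export
run_cerna_pipeline <- function(cohort, interactions = NULL, n_perm = 1000,
                               seed = 1, fc_up = 1.5, fc_down = 0.67,
                               fdr = 0.1, r_min = 0.5, p_max = 0.05,
                               neg_p = 0.05, neg_r = 0,
                               edge_policy = "mirna_only") {
  if (is.null(interactions)) {
    if (!inherits(cohort, "synthetic_cohort")) {
      stop("an interaction table is required")
    }
    interactions <- rbind(cohort$interactions_mrna, cohort$interactions_lncrna)
  }
  de <- list(
    mrna = run_sam(cohort$mrna, cohort$pheno, n_perm, seed,
                   fc_up = fc_up, fc_down = fc_down, fdr = fdr),
    mirna = run_sam(cohort$mirna, cohort$pheno, n_perm, seed + 1L,
                    fc_up = fc_up, fc_down = fc_down, fdr = fdr),
    lncrna = run_sam(cohort$lncrna, cohort$pheno, n_perm, seed + 2L,
                     fc_up = fc_up, fc_down = fc_down, fdr = fdr)
  )
  de_ids <- lapply(de, function(d) d$feature[d$selected])
  pairs <- if (length(de_ids$lncrna) && length(de_ids$mrna)) {
    codysregulated_pairs(de_ids$lncrna, de_ids$mrna, cohort,
                         r_min = r_min, p_max = p_max)
  } else {
    data.frame(lncrna = character(), mrna = character(),
               r_lm = numeric(), p_lm = numeric())
  }
  triplets <- detect_triplets(pairs, interactions, cohort, de_ids$mirna,
                              neg_p = neg_p, neg_r = neg_r)
  network <- if (nrow(triplets) > 0L) {
    assemble_network(triplets, edge_policy)
  } else NULL
  list(de = de, de_ids = de_ids, pairs = pairs, triplets = triplets,
       network = network)
}
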