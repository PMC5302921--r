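# two-sided p for a Pearson r at sample size n, via t = r sqrt((n-2)/(1-r^2))
# with n-2 degrees of freedom. |r| = 1 gives p = 0 exactly.
cor_pvalue <- function(r, n) {
  p <- numeric(length(r))
  one <- abs(r) >= 1 - 1e-15
  p[one] <- 0
  tt <- abs(r[!one]) * sqrt((n - 2) / (1 - r[!one]^2))
  p[!one] <- 2 * stats::pt(tt, df = n - 2, lower.tail = FALSE)
  p
}

#' Pearson correlation with a two-sided p-value
#'
#' @param x,y Numeric vectors of equal length n >= 3 with finite values.
#' @return A list with `r`, `p`, `n` and `excluded`. A zero-variance vector
#'   makes the correlation undefined; the record is then flagged
#'   `excluded = TRUE` with `r` and `p` set to `NA` (no NaN propagation).
#' @export
pearson_with_p <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L) stop("need n >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n, excluded = TRUE))
  }
  r <- stats::cor(x, y)
  list(r = r, p = cor_pvalue(r, n), n = n, excluded = FALSE)
}

# all pairwise correlations between rows of two matrices plus p-values;
# rows with zero variance yield NA (excluded downstream).
cross_cor <- function(a, b) {
  ta <- t(a); tb <- t(b)
  sda <- apply(ta, 2, stats::sd); sdb <- apply(tb, 2, stats::sd)
  r <- suppressWarnings(stats::cor(ta, tb))
  r[sda == 0, ] <- NA
  r[, sdb == 0] <- NA
  r
}

#' Co-dysregulated lncRNA-mRNA pairs
#'
#' Screens every (lncRNA, mRNA) combination over the supplied DE feature
#' lists and retains pairs with Pearson r > `r_min` and p < `p_max`
#' (strict inequalities). Zero-variance features are excluded.
#'
#' @param de_lncrnas,de_mrnas Character vectors of differentially expressed
#'   feature ids present in the cohort matrices.
#' @param cohort An `aligned_cohort` (or any list with `lncrna` and `mrna`
#'   expression matrices sharing sample columns).
#' @param r_min Positive-correlation threshold (default 0.5, exclusive).
#' @param p_max p-value threshold (default 0.05, exclusive).
#' @return data.frame with columns `lncrna`, `mrna`, `r_lm`, `p_lm`.
#' @export
codysregulated_pairs <- function(de_lncrnas, de_mrnas, cohort,
                                 r_min = 0.5, p_max = 0.05) {
  if (length(de_lncrnas) == 0L || length(de_mrnas) == 0L) {
    stop("DE lncRNA and mRNA lists must be non-empty")
  }
  lm <- unclass(cohort$lncrna)[intersect(de_lncrnas, rownames(cohort$lncrna)), , drop = FALSE]
  gm <- unclass(cohort$mrna)[intersect(de_mrnas, rownames(cohort$mrna)), , drop = FALSE]
  n <- ncol(lm)
  r <- cross_cor(lm, gm)
  p <- matrix(NA_real_, nrow(r), ncol(r))
  ok <- !is.na(r)
  p[ok] <- cor_pvalue(r[ok], n)
  keep <- which(ok & r > r_min & p < p_max, arr.ind = TRUE)
  out <- data.frame(lncrna = rownames(r)[keep[, 1L]],
                    mrna = colnames(r)[keep[, 2L]],
                    r_lm = r[keep], p_lm = p[keep],
                    stringsAsFactors = FALSE)
  out[order(out$lncrna, out$mrna), , drop = FALSE]
}

#' Detect dysregulated competing triplets
#'
#' For each co-dysregulated (lncRNA, mRNA) pair and each candidate miRNA that
#' targets both members according to the interaction table, a competing
#' triplet is emitted when the miRNA is negatively co-expressed with both:
#' r < `neg_r` and p < `neg_p` for the miRNA-lncRNA and miRNA-mRNA
#' correlations. Candidate miRNAs are restricted to `de_mirnas`. Interaction
#' records whose ids are absent from the cohort matrices are filtered with a
#' message.
#'
#' @param pairs Output of [codysregulated_pairs()].
#' @param interactions Interaction table(s) as returned by
#'   [load_interactions()] (miRNA-mRNA and miRNA-lncRNA records may be mixed;
#'   pass `rbind()` of both).
#' @param cohort An `aligned_cohort` (or compatible list).
#' @param de_mirnas Character vector of DE miRNA ids eligible as the shared
#'   miRNA.
#' @param neg_p p-value threshold for the negative correlations (exclusive).
#' @param neg_r Correlation threshold; miRNA correlations must be strictly
#'   below it (default 0).
#' @return data.frame with one row per (mirna, lncrna, mrna) triplet and the
#'   six correlation statistics `r_lm`, `p_lm`, `r_ml`, `p_ml`, `r_mg`,
#'   `p_mg`.
#' @export
detect_triplets <- function(pairs, interactions, cohort, de_mirnas,
                            neg_p = 0.05, neg_r = 0) {
  if (nrow(interactions) == 0L) stop("interaction table is empty: shared miRNAs undefined")
  empty <- data.frame(mirna = character(), lncrna = character(), mrna = character(),
                      r_lm = numeric(), p_lm = numeric(), r_ml = numeric(),
                      p_ml = numeric(), r_mg = numeric(), p_mg = numeric())
  if (nrow(pairs) == 0L || length(de_mirnas) == 0L) return(empty)

  known <- c(rownames(cohort$mrna), rownames(cohort$mirna), rownames(cohort$lncrna))
  present <- interactions$mirna %in% rownames(cohort$mirna) &
    interactions$target %in% known
  if (any(!present)) {
    message(sum(!present), " interaction record(s) referencing unknown features filtered")
  }
  interactions <- interactions[present, , drop = FALSE]

  mi_ids <- intersect(de_mirnas, rownames(cohort$mirna))
  mi_ids <- intersect(mi_ids, unique(interactions$mirna))
  if (length(mi_ids) == 0L) return(empty)
  targets_of <- split(interactions$target, interactions$mirna)

  mim <- unclass(cohort$mirna)[mi_ids, , drop = FALSE]
  n <- ncol(mim)
  lnc_ids <- unique(pairs$lncrna)
  g_ids <- unique(pairs$mrna)
  r_ml <- cross_cor(mim, unclass(cohort$lncrna)[lnc_ids, , drop = FALSE])
  r_mg <- cross_cor(mim, unclass(cohort$mrna)[g_ids, , drop = FALSE])

  res <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    l <- pairs$lncrna[i]; g <- pairs$mrna[i]
    shared <- mi_ids[vapply(mi_ids, function(m) {
      tg <- targets_of[[m]]
      !is.null(tg) && l %in% tg && g %in% tg
    }, logical(1))]
    if (length(shared) == 0L) next
    rml <- r_ml[shared, l]; rmg <- r_mg[shared, g]
    ok <- !is.na(rml) & !is.na(rmg) & rml < neg_r & rmg < neg_r
    if (!any(ok)) next
    pml <- cor_pvalue(rml[ok], n); pmg <- cor_pvalue(rmg[ok], n)
    pass <- pml < neg_p & pmg < neg_p
    if (!any(pass)) next
    res[[i]] <- data.frame(mirna = shared[ok][pass], lncrna = l, mrna = g,
                           r_lm = pairs$r_lm[i], p_lm = pairs$p_lm[i],
                           r_ml = rml[ok][pass], p_ml = pml[pass],
                           r_mg = rmg[ok][pass], p_mg = pmg[pass],
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) return(empty)
  out <- out[order(out$mirna, out$lncrna, out$mrna), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble the dysregulated lncRNA-associated ceRNA network
#'
#' Builds an undirected typed graph from accepted competing triplets. Under
#' the `mirna_only` policy each triplet contributes its miRNA-lncRNA and
#' miRNA-mRNA edges; `full` adds the lncRNA-mRNA competing edge. Edges are
#' deduplicated across triplets and carry the number (and row indices) of
#' contributing triplets as provenance.
#'
#' @param triplets data.frame from [detect_triplets()] (>= 1 row).
#' @param edge_policy `"mirna_only"` (default) or `"full"`.
#' @return A list of class `cerna_network` with elements `graph` (igraph with
#'   vertex attribute `class` and edge attributes `type`, `n_triplets`,
#'   `triplet_ids`), `edges` (data.frame `node_a`, `node_b`, `edge_type`,
#'   `n_triplets`) and `triplets`.
#' @export
assemble_network <- function(triplets, edge_policy = c("mirna_only", "full")) {
  edge_policy <- match.arg(edge_policy)
  if (is.null(triplets) || nrow(triplets) == 0L) {
    stop("cannot assemble a network from an empty triplet list")
  }
  mk <- function(a, b, type) {
    data.frame(node_a = a, node_b = b, edge_type = type,
               triplet = seq_len(nrow(triplets)), stringsAsFactors = FALSE)
  }
  ed <- rbind(mk(triplets$mirna, triplets$lncrna, "miRNA-lncRNA"),
              mk(triplets$mirna, triplets$mrna, "miRNA-mRNA"))
  if (edge_policy == "full") {
    ed <- rbind(ed, mk(triplets$lncrna, triplets$mrna, "lncRNA-mRNA"))
  }
  key <- paste(ed$node_a, ed$node_b, ed$edge_type, sep = "\r")
  prov <- split(ed$triplet, key)
  uniq <- ed[!duplicated(key), , drop = FALSE]
  uniq_key <- key[!duplicated(key)]
  uniq$n_triplets <- lengths(prov)[uniq_key]
  uniq$triplet <- NULL
  rownames(uniq) <- NULL

  classes <- c(stats::setNames(rep("miRNA", nrow(triplets)), triplets$mirna),
               stats::setNames(rep("lncRNA", nrow(triplets)), triplets$lncrna),
               stats::setNames(rep("mRNA", nrow(triplets)), triplets$mrna))
  classes <- classes[!duplicated(names(classes))]

  g <- igraph::graph_from_data_frame(
    data.frame(from = uniq$node_a, to = uniq$node_b),
    directed = FALSE,
    vertices = data.frame(name = names(classes), class = unname(classes)))
  igraph::E(g)$type <- uniq$edge_type
  igraph::E(g)$n_triplets <- uniq$n_triplets
  igraph::E(g)$triplet_ids <- unname(prov[uniq_key])

  out <- list(graph = g,
              edges = uniq[, c("node_a", "node_b", "edge_type", "n_triplets")],
              triplets = triplets, edge_policy = edge_policy)
  class(out) <- "cerna_network"
  out
}

#' @export
print.cerna_network <- function(x, ...) {
  cls <- igraph::V(x$graph)$class
  cat("ceRNA network:", nrow(x$edges), "edges among",
      sum(cls == "miRNA"), "miRNAs,", sum(cls == "lncRNA"), "lncRNAs and",
      sum(cls == "mRNA"), "mRNAs (policy:", x$edge_policy, ")\n")
  invisible(x)
}

#' Write a ceRNA network edge list as TSV
#' @param net A `cerna_network`.
#' @param path Output path.
#' @export
write_network <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
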