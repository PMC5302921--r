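#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation in a query gene list with the
#' exact hypergeometric upper tail P(X >= k), where k is the overlap between
#' query and set, m the query size, K the set size within the universe and N
#' the universe size. Fold enrichment is the observed/expected overlap ratio
#' (k/m)/(K/N). A set passes the default filter when p < `p_cut` and fold
#' enrichment > `fe_cut` (both strict).
#'
#' @param query Character vector of gene ids. Ids outside the universe are
#'   dropped with a message.
#' @param collection Named list of gene sets (see [load_gmt()]).
#' @param universe Background id vector; default is the union of all
#'   collection members and the query.
#' @param p_cut,fe_cut Filter thresholds (default 0.05 and 3.0).
#' @param adjust If `TRUE`, adds a BH-adjusted `q` column (the filter still
#'   uses the raw p, as is conventional for this style of analysis).
#' @return data.frame with one row per set: `set`, `k`, `m`, `K`, `N`, `p`,
#'   `fold_enrichment`, `passes_filter` (and `q` when `adjust = TRUE`),
#'   ordered by p.
#' @export
overrepresentation <- function(query, collection, universe = NULL,
                               p_cut = 0.05, fe_cut = 3.0, adjust = FALSE) {
  if (length(query) == 0L) stop("empty query gene list")
  if (length(collection) == 0L) stop("empty gene-set collection")
  if (is.null(universe)) {
    universe <- union(unlist(collection, use.names = FALSE), query)
  }
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside) > 0L) {
    message(length(outside), " query id(s) outside the universe dropped")
    query <- setdiff(query, outside)
  }
  if (length(query) == 0L) stop("no query genes remain inside the universe")
  m <- length(query)
  N <- length(universe)
  rows <- lapply(names(collection), function(nm) {
    members <- intersect(collection[[nm]], universe)
    K <- length(members)
    k <- length(intersect(query, members))
    p <- stats::phyper(k - 1, K, N - K, m, lower.tail = FALSE)
    fe <- if (K == 0L) 0 else (k / m) / (K / N)
    data.frame(set = nm, k = k, m = m, K = K, N = N, p = p,
               fold_enrichment = fe, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$passes_filter <- out$p < p_cut & out$fold_enrichment > fe_cut
  if (adjust) out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build an enrichment map from filtered over-representation results
#'
#' Nodes are the gene sets passing the p-value and fold-enrichment filters;
#' an edge connects two sets whose overlap coefficient
#' |A intersect B| / min(|A|, |B|) is at least `overlap_cut`.
#'
#' @param results Output of [overrepresentation()].
#' @param collection The gene-set collection the results came from.
#' @param p_cut,fe_cut Filters re-applied to `results` (strict inequalities).
#' @param overlap_cut Overlap-coefficient cutoff for drawing an edge
#'   (default 0.5, inclusive).
#' @return list with `nodes` (filtered results) and `edges` (data.frame
#'   `set_a`, `set_b`, `overlap_coefficient`); both may be empty.
#' @export
filter_and_map <- function(results, collection, p_cut = 0.05, fe_cut = 3.0,
                           overlap_cut = 0.5) {
  keep <- results[results$p < p_cut & results$fold_enrichment > fe_cut, , drop = FALSE]
  edges <- data.frame(set_a = character(), set_b = character(),
                      overlap_coefficient = numeric())
  if (nrow(keep) >= 2L) {
    nms <- keep$set
    combs <- utils::combn(nms, 2L)
    oc <- apply(combs, 2L, function(pr) {
      a <- collection[[pr[1L]]]; b <- collection[[pr[2L]]]
      length(intersect(a, b)) / min(length(a), length(b))
    })
    sel <- oc >= overlap_cut
    edges <- data.frame(set_a = combs[1L, sel], set_b = combs[2L, sel],
                        overlap_coefficient = oc[sel],
                        stringsAsFactors = FALSE)
  }
  rownames(keep) <- rownames(edges) <- NULL
  list(nodes = keep, edges = edges)
}
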