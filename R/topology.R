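# accept a cerna_network or a bare igraph
as_igraph_net <- function(net) {
  if (inherits(net, "cerna_network")) net$graph
  else if (igraph::is_igraph(net)) net
  else stop("expected a cerna_network or igraph object")
}

#' Per-node degree and betweenness centrality
#'
#' Degree is the incident edge count; betweenness is standard unnormalized
#' shortest-path betweenness on the undirected, unweighted graph.
#'
#' @param net A `cerna_network` or igraph object.
#' @return data.frame with columns `node`, `class` (NA when absent),
#'   `degree`, `betweenness`.
#' @export
degree_and_betweenness <- function(net) {
  g <- as_igraph_net(net)
  if (igraph::vcount(g) == 0L) stop("empty network")
  cls <- igraph::vertex_attr(g, "class")
  if (is.null(cls)) cls <- NA_character_
  data.frame(node = igraph::V(g)$name,
             class = cls,
             degree = as.numeric(igraph::degree(g)),
             betweenness = as.numeric(igraph::betweenness(g, directed = FALSE,
                                                          weights = NA)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Global clustering coefficient (mean of local coefficients)
#'
#' Mean over all nodes of the fraction of neighbour pairs that are themselves
#' connected; nodes of degree < 2 contribute 0.
#'
#' @param net A `cerna_network` or igraph object.
#' @return Value in [0, 1].
#' @export
clustering_coefficient <- function(net) {
  g <- as_igraph_net(net)
  if (igraph::vcount(g) == 0L) stop("empty network")
  loc <- igraph::transitivity(g, type = "local", isolates = "zero")
  loc[is.nan(loc)] <- 0
  mean(loc)
}

#' Characteristic path length
#'
#' Mean shortest-path length over all unordered connected node pairs;
#' disconnected pairs are excluded from the mean.
#'
#' @param net A `cerna_network` or igraph object with >= 1 edge.
#' @return Mean geodesic length (>= 1).
#' @export
characteristic_path_length <- function(net) {
  g <- as_igraph_net(net)
  if (igraph::ecount(g) == 0L) stop("network has no edges")
  igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
}

#' Fit a power law to a degree distribution by log-log regression
#'
#' Computes the empirical degree distribution P(k) at each observed degree k
#' with P(k) > 0 and fits a least-squares line on (log10 k, log10 P(k)).
#'
#' @param degrees Integer vector of node degrees (>= 3 distinct positive
#'   values required).
#' @return list with `slope` and `r_squared`.
#' @export
power_law_fit <- function(degrees) {
  degrees <- degrees[degrees > 0]
  tab <- table(degrees)
  k <- as.numeric(names(tab))
  if (length(k) < 3L) stop("need >= 3 distinct positive degrees for a power-law fit")
  pk <- as.numeric(tab) / length(degrees)
  fit <- stats::lm(log10(pk) ~ log10(k))
  rss <- sum(stats::resid(fit)^2)
  tss <- sum((log10(pk) - mean(log10(pk)))^2)
  list(slope = unname(stats::coef(fit)[2L]),
       r_squared = 1 - rss / tss)
}

# one degree-preserving randomization replicate: double-edge swaps restricted
# to edges of the same type, so class-impossible edges (e.g. mRNA-mRNA) can
# never appear. Edges of each type are oriented by endpoint class, making the
# swap (a1,b1),(a2,b2) -> (a1,b2),(a2,b1) class-safe; a swap is rejected if
# it would duplicate an existing edge of that type.
swap_edges_once <- function(edges_by_type, n_attempts) {
  counts <- vapply(edges_by_type, nrow, integer(1))
  types <- sample(names(edges_by_type), n_attempts, replace = TRUE,
                  prob = counts / sum(counts))
  for (ty in types) {
    ed <- edges_by_type[[ty]]
    i <- sample.int(nrow(ed), 2L)
    a1 <- ed$a[i[1L]]; b1 <- ed$b[i[1L]]
    a2 <- ed$a[i[2L]]; b2 <- ed$b[i[2L]]
    if (b1 == b2 || a1 == a2) next
    k1 <- paste(a1, b2); k2 <- paste(a2, b1)
    keys <- paste(ed$a, ed$b)
    if (k1 %in% keys || k2 %in% keys) next
    ed$b[i[1L]] <- b2; ed$b[i[2L]] <- b1
    edges_by_type[[ty]] <- ed
  }
  edges_by_type
}

split_edges_by_type <- function(g) {
  el <- igraph::as_edgelist(g, names = TRUE)
  ty <- igraph::edge_attr(g, "type")
  if (is.null(ty)) ty <- rep("edge", nrow(el))
  cls <- stats::setNames(igraph::vertex_attr(g, "class"), igraph::V(g)$name)
  if (all(is.na(cls)) || is.null(igraph::vertex_attr(g, "class"))) {
    cls <- stats::setNames(rep("node", igraph::vcount(g)), igraph::V(g)$name)
  }
  # orient each edge so endpoint classes appear in a fixed order per type
  a <- el[, 1L]; b <- el[, 2L]
  flip <- cls[a] > cls[b]
  flip[is.na(flip)] <- FALSE
  tmp <- a[flip]; a[flip] <- b[flip]; b[flip] <- tmp
  lapply(split(seq_along(ty), ty), function(ix) {
    data.frame(a = a[ix], b = b[ix], stringsAsFactors = FALSE)
  })
}

#' Degree-preserving randomization of a typed network
#'
#' Generates one null network by attempted double-edge swaps (default
#' 10 x |E| attempts) constrained to pairs of edges of the same type, which
#' preserves every node's degree, every node's class and the per-type edge
#' counts.
#'
#' @param net A `cerna_network` or igraph object.
#' @param n_attempts Number of attempted swaps; default `10 * ecount`.
#' @return An igraph object with the same vertices (and `class` attribute)
#'   and rewired edges carrying their `type`.
#' @export
rewire_network <- function(net, n_attempts = NULL) {
  g <- as_igraph_net(net)
  ebt <- split_edges_by_type(g)
  if (any(vapply(ebt, nrow, integer(1)) < 2L)) {
    stop("network too small to rewire: an edge type has fewer than 2 edges")
  }
  if (is.null(n_attempts)) n_attempts <- 10L * igraph::ecount(g)
  ebt <- swap_edges_once(ebt, n_attempts)
  ed <- do.call(rbind, lapply(names(ebt), function(ty) {
    cbind(ebt[[ty]], type = ty)
  }))
  vert <- data.frame(name = igraph::V(g)$name)
  cls <- igraph::vertex_attr(g, "class")
  if (!is.null(cls)) vert$class <- cls
  gg <- igraph::graph_from_data_frame(data.frame(from = ed$a, to = ed$b),
                                      directed = FALSE, vertices = vert)
  igraph::E(gg)$type <- ed$type
  gg
}

#' Randomization test of a global network statistic
#'
#' Compares an observed statistic (clustering coefficient or characteristic
#' path length) with its distribution over degree-preserving, type-preserving
#' null networks. Empirical p-values use the add-one rule
#' p = (1 + #{null >= observed}) / (1 + n_null) for the upper tail (the lower
#' tail is symmetric), so p is never 0.
#'
#' @param net A `cerna_network` or igraph object.
#' @param statistic `"CC"` (clustering coefficient) or `"CPL"`
#'   (characteristic path length).
#' @param n_null Number of null networks (>= 100).
#' @param seed Integer seed.
#' @param tail `"upper"` (default; is the observed value high?) or
#'   `"lower"`.
#' @return list with `observed`, `null` (numeric vector of length `n_null`),
#'   `p` (for the requested tail), `p_upper`, `p_lower`.
#' @export
randomization_test <- function(net, statistic = c("CC", "CPL"), n_null = 1000,
                               seed = 1, tail = c("upper", "lower")) {
  statistic <- match.arg(statistic)
  tail <- match.arg(tail)
  if (n_null < 100) stop("n_null must be >= 100")
  stat_fn <- if (statistic == "CC") clustering_coefficient else characteristic_path_length
  obs <- stat_fn(net)
  set.seed(seed)
  nulls <- vapply(seq_len(n_null), function(i) stat_fn(rewire_network(net)),
                  numeric(1))
  p_up <- (1 + sum(nulls >= obs)) / (1 + n_null)
  p_lo <- (1 + sum(nulls <= obs)) / (1 + n_null)
  list(observed = obs, null = nulls,
       p = if (tail == "upper") p_up else p_lo,
       p_upper = p_up, p_lower = p_lo)
}

#' Kruskal-Wallis comparison of node statistics across node classes
#'
#' @param values Numeric vector of per-node values (e.g. degree).
#' @param classes Character/factor vector of node classes aligned with
#'   `values` (>= 2 classes, each non-empty).
#' @return list with `H` (tie-corrected statistic) and `p` (chi-square,
#'   classes - 1 df).
#' @export
class_comparison <- function(values, classes) {
  classes <- as.character(classes)
  if (length(values) != length(classes)) stop("values and classes must align")
  tab <- table(classes)
  if (length(tab) < 2L) stop("need >= 2 node classes")
  if (any(tab == 0L)) stop("every class must be non-empty")
  kt <- stats::kruskal.test(values, factor(classes))
  list(H = unname(kt$statistic), p = kt$p.value)
}

#' Full topology summary of a ceRNA network
#'
#' Convenience wrapper computing per-node degree and betweenness, the global
#' clustering coefficient, the characteristic path length, the log-log
#' power-law fit of the degree distribution, randomization tests for CC and
#' CPL, and Kruskal-Wallis class comparisons of degree and betweenness.
#'
#' @param net A `cerna_network`.
#' @param n_null Null networks per randomization test.
#' @param seed Integer seed.
#' @return list with `nodes`, `cc`, `cpl`, `power_law`, `cc_test`,
#'   `cpl_test`, `kw_degree`, `kw_betweenness`.
#' @export
topology_summary <- function(net, n_null = 1000, seed = 1) {
  nodes <- degree_and_betweenness(net)
  pl <- tryCatch(power_law_fit(nodes$degree), error = function(e) NULL)
  list(nodes = nodes,
       cc = clustering_coefficient(net),
       cpl = characteristic_path_length(net),
       power_law = pl,
       cc_test = randomization_test(net, "CC", n_null, seed),
       cpl_test = randomization_test(net, "CPL", n_null, seed + 1L),
       kw_degree = class_comparison(nodes$degree, nodes$class),
       kw_betweenness = class_comparison(nodes$betweenness, nodes$class))
}
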