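# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities from first principles (path enumeration, pair
# counting, hypergeometric summation) so they share no code with the package
# implementations they check.

# all shortest paths between s and t in an adjacency list, by DFS restricted
# to the BFS distance layers
all_shortest_paths_bf <- function(adj, s, t) {
  n <- length(adj)
  dist <- rep(Inf, n); dist[s] <- 0
  queue <- s
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) if (dist[w] > dist[v] + 1) {
      dist[w] <- dist[v] + 1; queue <- c(queue, w)
    }
  }
  if (!is.finite(dist[t])) return(list())
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) { paths[[length(paths) + 1L]] <<- path; return(invisible()) }
    for (w in adj[[v]]) if (dist[w] == dist[v] + 1) walk(c(path, w))
  }
  walk(s)
  paths
}

# unnormalized shortest-path betweenness by explicit path enumeration
brute_betweenness <- function(adj) {
  n <- length(adj)
  btw <- numeric(n)
  for (s in seq_len(n - 1L)) for (t in (s + 1L):n) {
    paths <- all_shortest_paths_bf(adj, s, t)
    if (length(paths) == 0L) next
    inner <- unlist(lapply(paths, function(p) p[-c(1L, length(p))]))
    if (length(inner)) {
      cnt <- table(inner)
      btw[as.integer(names(cnt))] <- btw[as.integer(names(cnt))] +
        as.numeric(cnt) / length(paths)
    }
  }
  btw
}

# mean local clustering coefficient by explicit neighbour-pair counting
brute_clustering <- function(adj) {
  n <- length(adj)
  loc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- adj[[v]]
    if (length(nb) < 2L) { loc[v] <- 0; next }
    pairs <- utils::combn(nb, 2L)
    linked <- sum(apply(pairs, 2L, function(pr) pr[2L] %in% adj[[pr[1L]]]))
    loc[v] <- linked / ncol(pairs)
  }
  mean(loc)
}

# AUC by counting concordant positive/negative score pairs, half for ties
brute_auc <- function(scores, truth) {
  sp <- scores[truth == "tumor"]; sn <- scores[truth == "normal"]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# two-sided Fisher exact p by full hypergeometric enumeration (the standard
# convention: sum the probabilities of all tables no more probable than the
# observed one, with a small relative tolerance)
brute_fisher <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, c1, n - c1, r1)
  obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-07)])
}

# upper-tail hypergeometric p by direct summation
brute_hyper_upper <- function(k, K, N, m) {
  kk <- k:min(m, K)
  sum(stats::dhyper(kk, K, N - K, m))
}

# Kruskal-Wallis H with tie correction, from the rank-sum definition
brute_kruskal_h <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(x) sum(x)^2 / length(x))) - 3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# igraph -> integer adjacency list for the brute-force graph oracles
graph_to_adj <- function(g) {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  adj <- vector("list", n)
  for (i in seq_len(nrow(el))) {
    adj[[el[i, 1L]]] <- c(adj[[el[i, 1L]]], el[i, 2L])
    adj[[el[i, 2L]]] <- c(adj[[el[i, 2L]]], el[i, 1L])
  }
  adj
}

# small typed test networks -------------------------------------------------

# triplet table with given ids (correlation columns filled with valid values)
toy_triplets <- function(mirna, lncrna, mrna) {
  k <- length(mirna)
  data.frame(mirna = mirna, lncrna = lncrna, mrna = mrna,
             r_lm = rep(0.8, k), p_lm = rep(0.001, k),
             r_ml = rep(-0.7, k), p_ml = rep(0.002, k),
             r_mg = rep(-0.6, k), p_mg = rep(0.003, k),
             stringsAsFactors = FALSE)
}

# decimal (half-up) rounding with a tiny tolerance, so values that are exact
# rationals but sit a few ulp below a .5 boundary round as their true value
round_half_up <- function(x, digits) {
  floor(x * 10^digits + 0.5 + 1e-8) / 10^digits
}

# a dense typed network with many triangles (full edge policy), for
# randomization tests with planted clustering
clustered_test_network <- function(n_m = 6, n_l = 6, n_g = 6, n_trip = 40,
                                   seed = 11) {
  set.seed(seed)
  tr <- unique(data.frame(
    mirna = sprintf("m%d", sample.int(n_m, n_trip, replace = TRUE)),
    lncrna = sprintf("l%d", sample.int(n_l, n_trip, replace = TRUE)),
    mrna = sprintf("g%d", sample.int(n_g, n_trip, replace = TRUE)),
    stringsAsFactors = FALSE))
  assemble_network(toy_triplets(tr$mirna, tr$lncrna, tr$mrna), "full")
}
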