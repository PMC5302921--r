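test_that("pearson_with_p matches the t-distribution and handles degeneracy", {
  expect_equal(pearson_with_p(c(1, 2, 3, 4), c(2, 4, 6, 8))$r, 1.0)
  expect_equal(pearson_with_p(1:5, -(1:5))$r, -1.0)
  # p for r = 0.5 at n = 32 equals the two-sided t(30) tail
  set.seed(4)
  x <- rnorm(32)
  y <- 0.5 * scale(x)[, 1] + sqrt(0.75) * scale(resid(lm(rnorm(32) ~ x)))[, 1]
  rec <- pearson_with_p(x, y)
  t_exp <- abs(rec$r) * sqrt(30 / (1 - rec$r^2))
  expect_equal(rec$p, 2 * pt(t_exp, 30, lower.tail = FALSE))
  expect_equal(rec$r, 0.5, tolerance = 1e-6)
  # zero variance: excluded, never NaN
  z <- pearson_with_p(rep(1, 5), rnorm(5))
  expect_true(z$excluded)
  expect_true(is.na(z$r) && is.na(z$p))
  expect_error(pearson_with_p(1:3, 1:4), "equal length")
})

test_that("co-dysregulation screening applies strict r and p thresholds", {
  x <- c(1, -1, 0, 0, 1, -1, 0, 0)
  z <- c(0, 0, 1, -1, 0, 0, 1, -1)
  samples <- sprintf("S%d", 1:8)
  lnc <- matrix(x, 1, 8, dimnames = list("l1", samples))
  mr <- rbind(x + 0.1 * z, -2 * x + 0.01 * z)
  dimnames(mr) <- list(c("g_pos", "g_neg"), samples)
  cohort <- list(lncrna = expression_matrix(lnc, "lncRNA"),
                 mrna = expression_matrix(mr, "mRNA"))
  got <- codysregulated_pairs("l1", c("g_pos", "g_neg"), cohort)
  expect_equal(got$mrna, "g_pos")  # negative correlation is dropped
  expect_gt(got$r_lm, 0.5)
  expect_lt(got$p_lm, 0.05)
  # the r threshold is strict: a pair at exactly the threshold is excluded
  at_thr <- codysregulated_pairs("l1", "g_pos", cohort, r_min = got$r_lm)
  expect_equal(nrow(at_thr), 0L)
  # the p threshold is strict too
  at_p <- codysregulated_pairs("l1", "g_pos", cohort, p_max = got$p_lm)
  expect_equal(nrow(at_p), 0L)
  # tiny n with high r but weak evidence is rejected by the p gate
  s3 <- sprintf("S%d", 1:4)
  lnc3 <- matrix(c(1, 2, 3, 3.5), 1, 4, dimnames = list("l1", s3))
  mr3 <- matrix(c(1, 1.5, 2, 4), 1, 4, dimnames = list("g1", s3))
  got3 <- codysregulated_pairs("l1", "g1",
                               list(lncrna = expression_matrix(lnc3, "lncRNA"),
                                    mrna = expression_matrix(mr3, "mRNA")))
  expect_equal(nrow(got3), 0L)
})

test_that("triplet detection agrees with a brute-force predicate oracle", {
  co <- generate_cohort(cohort_config(n_tumor = 14, n_normal = 10,
                                      n_mrna = 15, n_mirna = 8, n_lncrna = 10,
                                      n_de_per_class = 8, n_triplets = 5,
                                      n_decoy_interactions = 40, seed = 77))
  inter <- rbind(co$interactions_mrna, co$interactions_lncrna)
  de_l <- rownames(co$lncrna)  # treat everything as DE: stresses the gates
  de_g <- rownames(co$mrna)
  de_m <- rownames(co$mirna)
  pairs <- codysregulated_pairs(de_l, de_g, co)
  got <- detect_triplets(pairs, inter, co, de_m)

  # oracle: enumerate every combination and apply the predicate directly
  n <- ncol(co$mrna)
  keys <- paste(inter$mirna, inter$target)
  expected <- list()
  for (mi in de_m) for (l in de_l) for (g in de_g) {
    if (!(paste(mi, l) %in% keys) || !(paste(mi, g) %in% keys)) next
    r_lm <- cor(unclass(co$lncrna)[l, ], unclass(co$mrna)[g, ])
    r_ml <- cor(unclass(co$mirna)[mi, ], unclass(co$lncrna)[l, ])
    r_mg <- cor(unclass(co$mirna)[mi, ], unclass(co$mrna)[g, ])
    p_of <- function(r) 2 * pt(abs(r) * sqrt((n - 2) / (1 - r^2)), n - 2,
                               lower.tail = FALSE)
    if (r_lm > 0.5 && p_of(r_lm) < 0.05 &&
        r_ml < 0 && p_of(r_ml) < 0.05 &&
        r_mg < 0 && p_of(r_mg) < 0.05) {
      expected[[length(expected) + 1L]] <- c(mi, l, g)
    }
  }
  exp_keys <- sort(vapply(expected, paste, character(1), collapse = " "))
  got_keys <- sort(paste(got$mirna, got$lncrna, got$mrna))
  expect_identical(got_keys, exp_keys)
  expect_gt(length(got_keys), 0L)  # the instance is non-trivial
})

test_that("triplets require a shared targeting miRNA and negative correlations", {
  co <- generate_cohort(cohort_config(n_tumor = 12, n_normal = 8, n_mrna = 6,
                                      n_mirna = 4, n_lncrna = 5,
                                      n_de_per_class = 3, n_triplets = 3,
                                      n_decoy_interactions = 0, seed = 13))
  inter <- rbind(co$interactions_mrna, co$interactions_lncrna)
  tr <- co$truth$planted_triplets
  pairs <- codysregulated_pairs(tr$lncrna, tr$mrna, co)
  expect_gt(nrow(pairs), 0L)
  # interaction table lacking the lncRNA edge: no triplet possible
  only_mrna <- co$interactions_mrna
  got <- detect_triplets(pairs, only_mrna, co, tr$mirna)
  expect_equal(nrow(got), 0L)
  # positively correlated miRNA is excluded: flip the miRNA rows
  flipped <- unclass(co$mirna)
  flipped[tr$mirna, ] <- 14 - flipped[tr$mirna, ]  # reflect -> correlations flip sign
  co2 <- co
  co2$mirna <- expression_matrix(flipped, "miRNA")
  got2 <- detect_triplets(pairs, inter, co2, tr$mirna)
  expect_equal(nrow(got2), 0L)
  expect_error(detect_triplets(pairs, inter[0, ], co, tr$mirna), "empty")
})

test_that("network assembly deduplicates edges and records provenance", {
  tr1 <- toy_triplets("m1", "l1", "g1")
  net_m <- assemble_network(tr1, "mirna_only")
  expect_equal(nrow(net_m$edges), 2L)
  expect_equal(igraph::vcount(net_m$graph), 3L)
  net_f <- assemble_network(tr1, "full")
  expect_equal(nrow(net_f$edges), 3L)
  expect_setequal(net_f$edges$edge_type,
                  c("miRNA-lncRNA", "miRNA-mRNA", "lncRNA-mRNA"))

  # two triplets sharing the miRNA-lncRNA pair: that edge appears once with
  # both triplets as provenance
  tr2 <- toy_triplets(c("m1", "m1"), c("l1", "l1"), c("g1", "g2"))
  net2 <- assemble_network(tr2, "mirna_only")
  expect_equal(nrow(net2$edges), 3L)
  ml <- net2$edges[net2$edges$edge_type == "miRNA-lncRNA", ]
  expect_equal(ml$n_triplets, 2L)
  expect_true(all(net2$edges$node_a != net2$edges$node_b))  # no self-loops
  # edge count bound
  expect_lte(nrow(net2$edges), 2L * nrow(tr2))
  expect_error(assemble_network(toy_triplets(character(), character(), character())),
               "empty")
})
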