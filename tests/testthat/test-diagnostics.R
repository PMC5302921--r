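# small two-class expression fixture: k features x (n1 tumor + n2 normal),
# tumor shifted by delta standard deviations
two_class_matrix <- function(n1, n2, k = 5, delta = 0, sd = 1, seed = 1) {
  set.seed(seed)
  n <- n1 + n2
  m <- matrix(rnorm(k * n, sd = sd), k, n,
              dimnames = list(sprintf("f%d", 1:k), sprintf("S%02d", 1:n)))
  m[, 1:n1] <- m[, 1:n1] + delta * sd
  list(mat = m, pheno = phenotype_table(colnames(m),
                                        c(rep("tumor", n1), rep("normal", n2))))
}

test_that("LOOCV separates well-separated classes perfectly and leaks nothing", {
  fx <- two_class_matrix(15, 15, delta = 3, seed = 2)
  res <- loocv_svm(fx$mat, fx$pheno)
  expect_equal(mean(res$predicted == res$truth), 1.0)
  expect_equal(roc_auc(res$score, res$truth), 1.0)
  # determinism
  expect_identical(res, loocv_svm(fx$mat, fx$pheno))
  # standardization is fitted on the training fold only: an extreme held-out
  # sample cannot shift its own z-scores
  std <- dlcnet:::fold_standardize(fx$mat[, -1], fx$mat[, 1, drop = FALSE] * 1000)
  mu_train <- rowMeans(fx$mat[, -1])
  sd_train <- apply(fx$mat[, -1], 1, sd)
  expect_equal(std$test[, 1],
               (fx$mat[, 1] * 1000 - mu_train) / sd_train, tolerance = 1e-12)
  expect_equal(rowMeans(std$train), rep(0, 5), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("duplicated samples receive identical predictions", {
  fx <- two_class_matrix(6, 6, delta = 1.5, seed = 3)
  dup <- cbind(fx$mat, fx$mat)
  colnames(dup) <- c(colnames(fx$mat), paste0(colnames(fx$mat), "_bis"))
  ph <- phenotype_table(colnames(dup), rep(as.character(fx$pheno$status), 2))
  res <- loocv_svm(dup, ph)
  first <- res[1:12, ]; second <- res[13:24, ]
  expect_equal(first$predicted, second$predicted)
  # training multisets are identical for twin folds; scores agree up to the
  # SVM optimizer's numerical tolerance
  expect_equal(first$score, second$score, tolerance = 1e-3)
})

test_that("confusion metrics reproduce the published worked examples", {
  # discovery-style cohort: 24 of 32 correct, sensitivity 84%
  pred <- c(rep("tumor", 21), rep("normal", 4), rep("normal", 3), rep("tumor", 4))
  truth <- c(rep("tumor", 25), rep("normal", 7))
  cm <- confusion_metrics(pred, truth)
  expect_equal(cm$confusion, c(TP = 21, FN = 4, TN = 3, FP = 4))
  expect_equal(cm$accuracy, 0.75)
  expect_equal(cm$sensitivity, 0.84)

  # validation-style cohort: 26/36 tumors and 24/36 controls correct
  pred2 <- c(rep("tumor", 26), rep("normal", 10), rep("normal", 24), rep("tumor", 12))
  truth2 <- c(rep("tumor", 36), rep("normal", 36))
  cm2 <- confusion_metrics(pred2, truth2)
  expect_equal(cm2$accuracy, 50 / 72)
  expect_equal(cm2$sensitivity, 26 / 36)
  expect_equal(cm2$specificity, 24 / 36)

  cm3 <- confusion_metrics(truth2, truth2)
  expect_equal(cm3$accuracy, 1.0)
  expect_equal(cm3$sensitivity, 1.0)
})

test_that("the diagnostic odds ratio follows its defining formula", {
  expect_equal(diagnostic_odds_ratio(0.84, 3 / 7), 63 / 16)  # = 3.9375
  expect_equal(diagnostic_odds_ratio(26 / 36, 24 / 36), 5.2)
  expect_equal(diagnostic_odds_ratio(0.5, 0.5), 1.0)
  expect_equal(diagnostic_odds_ratio(1, 0.3), Inf)
  # equality of the two routes on random confusion matrices
  set.seed(9)
  for (i in 1:25) {
    cm <- c(TP = sample(1:40, 1), FN = sample(1:40, 1),
            TN = sample(1:40, 1), FP = sample(1:40, 1))
    sens <- cm["TP"] / (cm["TP"] + cm["FN"])
    spec <- cm["TN"] / (cm["TN"] + cm["FP"])
    expect_equal(unname(dor_from_confusion(cm)),
                 unname(diagnostic_odds_ratio(sens, spec)), tolerance = 1e-12)
  }
  # Haldane-Anscombe correction keeps zero-cell replicates finite
  z <- dor_from_confusion(c(TP = 10, FN = 0, TN = 5, FP = 5), correction = TRUE)
  expect_true(is.finite(z))
  expect_true(attr(z, "corrected"))
})

test_that("AUC equals the pair-counting oracle, including ties", {
  truth <- c(rep("tumor", 4), rep("normal", 4))
  expect_equal(roc_auc(c(4, 3.5, 3, 2.5, 2, 1, 0.5, 0), truth), 1.0)
  expect_equal(roc_auc(rep(1, 8), truth), 0.5)
  set.seed(10)
  for (i in 1:20) {
    sc <- sample(seq(0, 2, by = 0.25), 8, replace = TRUE)  # many ties
    expect_equal(roc_auc(sc, truth), brute_auc(sc, truth))
  }
  pts <- roc_points(c(3, 2, 1, 0, 2.5, 1.5, 0.5, -1), truth)
  expect_equal(pts$fpr[1], 0); expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1); expect_equal(pts$tpr[nrow(pts)], 1)
})

test_that("permutation p-values behave at their extremes and under signal", {
  fx <- two_class_matrix(10, 10, delta = 3, seed = 4)
  pv <- permutation_pvalue(fx$mat, fx$pheno, "auc", n_perm = 200, seed = 1)
  expect_equal(pv$observed, 1.0)
  expect_lte(pv$p, 0.01)
  expect_gte(pv$p, 1 / 201)  # add-one lower bound
  pv_dor <- permutation_pvalue(fx$mat, fx$pheno, "dor", n_perm = 100, seed = 2)
  expect_true(all(is.finite(pv_dor$null)))  # corrected nulls never infinite
  expect_lte(pv_dor$p, 0.05)
})

test_that("null permutation p-values are not anti-conservative", {
  # small signal-free cohorts: p should look super-uniform on average
  set.seed(20)
  ps <- vapply(1:6, function(i) {
    fx <- two_class_matrix(6, 6, delta = 0, seed = 100 + i)
    permutation_pvalue(fx$mat, fx$pheno, "auc", n_perm = 100, seed = i)$p
  }, numeric(1))
  expect_gte(mean(ps), 0.3)
  expect_true(all(ps > 0 & ps <= 1))
})

test_that("signature evaluation assembles a coherent report", {
  fx <- two_class_matrix(12, 8, delta = 2.5, seed = 5)
  rep <- evaluate_signature(fx$mat, fx$pheno, n_perm = 100, seed = 1)
  cm <- rep$confusion
  expect_equal(unname(cm["TP"] + cm["FN"]), 12)
  expect_equal(unname(cm["TN"] + cm["FP"]), 8)
  expect_equal(rep$accuracy, unname((cm["TP"] + cm["TN"]) / 20))
  expect_equal(rep$auc, roc_auc(rep$loocv$score, rep$loocv$truth))
  expect_lte(rep$p_auc, 0.05)
  expect_output(print(rep), "LOOCV")
})

test_that("hierarchical clustering recovers structure and associates with status", {
  # two groups of near-identical profiles
  base1 <- rnorm(6); base2 <- base1 + 5
  m <- cbind(sapply(1:5, function(i) base1 + rnorm(6, sd = 0.01)),
             sapply(1:5, function(i) base2 + rnorm(6, sd = 0.01)))
  dimnames(m) <- list(sprintf("f%d", 1:6), sprintf("S%02d", 1:10))
  # correlation distance is shift-invariant, so separate by profile shape
  m[1:3, 6:10] <- -m[1:3, 6:10]
  cl <- cluster_samples(m, k = 2)
  expect_equal(length(unique(cl$clusters[1:5])), 1L)
  expect_equal(length(unique(cl$clusters[6:10])), 1L)
  expect_false(cl$clusters[1] == cl$clusters[6])

  # permuting sample order permutes but does not change the partition
  perm <- c(7, 2, 9, 4, 1, 6, 3, 8, 5, 10)
  cl2 <- cluster_samples(m[, perm], k = 2)
  agree <- outer(cl$clusters[colnames(m)[perm]], cl$clusters[colnames(m)[perm]], "==") ==
    outer(cl2$clusters, cl2$clusters, "==")
  expect_true(all(agree))

  expect_error(cluster_samples(cbind(m, const = rep(1, 6)), 2), "constant")

  ph <- phenotype_table(colnames(m), c(rep("tumor", 5), rep("normal", 5)))
  assoc <- cluster_association(cl$clusters, ph)
  expect_equal(assoc$test, "fisher")
  expect_lt(assoc$p, 0.05)
})

test_that("association test reproduces published contingency p-values", {
  fisher_tab <- matrix(c(7, 4, 0, 21), 2, byrow = TRUE)
  out <- association_test(fisher_tab)
  expect_equal(out$test, "fisher")
  expect_equal(out$p, 9.804e-05, tolerance = 1e-4)

  chisq_tab <- matrix(c(30, 6, 8, 28), 2, byrow = TRUE)
  out2 <- association_test(chisq_tab)
  expect_equal(out2$test, "chi2_yates")
  expect_equal(out2$p, 7.144e-07, tolerance = 1e-4)

  expect_equal(association_test(matrix(5, 2, 2))$p, 1.0)
  expect_error(association_test(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margin")
})

test_that("Fisher exact agrees with hypergeometric enumeration on small tables", {
  set.seed(14)
  for (i in 1:30) {
    tab <- matrix(sample(0:7, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher.test(tab)$p.value, brute_fisher(tab), tolerance = 1e-10)
  }
})
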