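# z-score columns (samples) of a feature x sample matrix using training-fold
# statistics only; zero-sd features map to 0.
fold_standardize <- function(train, test) {
  mu <- rowMeans(train)
  sd <- apply(train, 1, stats::sd)
  sd[sd == 0] <- Inf  # constant feature carries no information in this fold
  list(train = (train - mu) / sd, test = (test - mu) / sd)
}

# decision scores from an e1071 sigmoid-kernel SVM, oriented so that larger
# scores favour the tumor class regardless of internal label order.
svm_decision <- function(model, newx) {
  pr <- stats::predict(model, newx, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  score <- as.numeric(dv[, 1L])
  pos_first <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1L]][1L]
  if (pos_first != "tumor") score <- -score
  list(label = as.character(pr), score = score)
}

# Pooled leave-one-out decision scores are systematically shifted against the
# held-out class: removing a sample tilts the training-fold class balance the
# other way, which biases null AUC below 0.5. Centring each held-out score on
# the mean decision value of that fold's own training samples cancels the
# fold-level shift and leaves between-sample ordering (and hence any real
# signal) intact.
fold_centered_score <- function(model, train_x, test_x) {
  te <- svm_decision(model, test_x)
  tr <- svm_decision(model, train_x)
  list(label = te$label, score = te$score - mean(tr$score))
}

#' Leave-one-out cross-validated sigmoid-kernel SVM
#'
#' Each sample is predicted by a support vector machine trained on the other
#' n - 1 samples. Feature standardization (z-score) is fitted on the training
#' fold only and applied to the held-out sample, so no information leaks from
#' the test sample. Decision scores are fold-centred: the mean decision value
#' of the fold's training samples is subtracted from the held-out score,
#' cancelling the systematic shift that pooled leave-one-out scores otherwise
#' show against the held-out class. The procedure is fully deterministic for
#' a given configuration.
#'
#' @param sig_mat Numeric matrix, signature features x samples (log2 scale).
#' @param pheno Phenotype table covering the samples.
#' @param cost SVM soft-margin cost C (default 1).
#' @param gamma Sigmoid kernel coefficient; default `1 / n_features`.
#' @param coef0 Sigmoid kernel offset (default 0).
#' @return data.frame with columns `sample`, `truth`, `predicted`, `score`
#'   (real-valued decision score, larger = more tumor-like).
#' @export
loocv_svm <- function(sig_mat, pheno, cost = 1, gamma = NULL, coef0 = 0) {
  m <- unclass(sig_mat)
  ph <- pheno[match(colnames(m), pheno$sample), ]
  if (anyNA(ph$sample)) stop("phenotype table does not cover all samples")
  y <- factor(as.character(ph$status), levels = c("normal", "tumor"))
  if (any(table(y) < 2L)) stop("need >= 2 samples per class for LOOCV")
  if (is.null(gamma)) gamma <- 1 / nrow(m)
  n <- ncol(m)
  pred <- character(n); score <- numeric(n)
  for (i in seq_len(n)) {
    tr <- m[, -i, drop = FALSE]
    ytr <- y[-i]
    if (length(unique(ytr)) < 2L) stop("single-class training fold")
    std <- fold_standardize(tr, m[, i, drop = FALSE])
    fit <- e1071::svm(x = t(std$train), y = ytr, kernel = "sigmoid",
                      cost = cost, gamma = gamma, coef0 = coef0,
                      scale = FALSE)
    out <- fold_centered_score(fit, t(std$train), t(std$test))
    pred[i] <- out$label
    score[i] <- out$score
  }
  data.frame(sample = colnames(m), truth = as.character(y),
             predicted = pred, score = score,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Confusion matrix and derived classification metrics
#'
#' Tumor is the positive class: sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP), accuracy = (TP+TN)/total.
#'
#' @param predicted Character vector of predicted labels
#'   (`tumor`/`normal`).
#' @param truth Character vector of true labels, aligned with `predicted`.
#' @return list with `confusion` (named vector TP, FN, TN, FP),
#'   `sensitivity`, `specificity`, `accuracy`.
#' @export
confusion_metrics <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stop("predicted and truth must align")
  if (!any(truth == "tumor") || !any(truth == "normal")) {
    stop("both classes must be present in truth")
  }
  tp <- sum(predicted == "tumor" & truth == "tumor")
  fn <- sum(predicted == "normal" & truth == "tumor")
  tn <- sum(predicted == "normal" & truth == "normal")
  fp <- sum(predicted == "tumor" & truth == "normal")
  list(confusion = c(TP = tp, FN = fn, TN = tn, FP = fp),
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       accuracy = (tp + tn) / length(truth))
}

#' Diagnostic odds ratio
#'
#' DOR = (Sensitivity x Specificity) / ((1 - Sensitivity) x
#' (1 - Specificity)); equal to (TP x TN)/(FN x FP) when computed from a
#' confusion matrix. Perfect sensitivity or specificity yields +Inf unless
#' the Haldane-Anscombe continuity correction is requested.
#'
#' @param sensitivity,specificity Values in [0, 1].
#' @return Positive real, possibly `Inf`.
#' @export
diagnostic_odds_ratio <- function(sensitivity, specificity) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  den <- (1 - sensitivity) * (1 - specificity)
  num <- sensitivity * specificity
  if (den == 0) return(Inf)
  num / den
}

#' Diagnostic odds ratio from a confusion matrix
#'
#' @param confusion Named vector or list with TP, FN, TN, FP counts.
#' @param correction If `TRUE` and any cell is zero, the Haldane-Anscombe
#'   correction adds 0.5 to all four cells (the result carries attribute
#'   `corrected = TRUE`).
#' @return Positive real (Inf when a zero denominator cell occurs and
#'   `correction = FALSE`).
#' @export
dor_from_confusion <- function(confusion, correction = FALSE) {
  cm <- as.numeric(confusion[c("TP", "FN", "TN", "FP")])
  if (correction && any(cm == 0)) {
    cm <- cm + 0.5
    out <- (cm[1L] * cm[3L]) / (cm[2L] * cm[4L])
    attr(out, "corrected") <- TRUE
    return(out)
  }
  if (cm[2L] * cm[4L] == 0) return(Inf)
  (cm[1L] * cm[3L]) / (cm[2L] * cm[4L])
}

#' Area under the ROC curve from decision scores
#'
#' Computed by the rank-sum (Mann-Whitney) formulation, which equals the
#' trapezoidal area over all score thresholds with tied pairs contributing
#' one half.
#'
#' @param scores Real-valued decision scores (larger = more tumor-like).
#' @param truth Character vector of true labels (`tumor` = positive).
#' @return AUC in [0, 1]; constant scores give 0.5.
#' @export
roc_auc <- function(scores, truth) {
  pos <- truth == "tumor"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' True positive rate vs false positive rate across all score thresholds.
#'
#' @inheritParams roc_auc
#' @return data.frame with `threshold`, `fpr`, `tpr` (one row per distinct
#'   score, plus the (0,0) and (1,1) endpoints).
#' @export
roc_points <- function(scores, truth) {
  pos <- truth == "tumor"
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Permutation p-value for a LOOCV performance statistic
#'
#' Class labels are permuted uniformly and the whole LOOCV pipeline is re-run
#' per permutation; p = (1 + #{null >= observed}) / (1 + n_perm). For the
#' DOR statistic, permutation replicates with a zero confusion cell use the
#' Haldane-Anscombe correction so the null distribution stays finite.
#'
#' @param sig_mat Signature matrix (features x samples).
#' @param pheno Phenotype table.
#' @param statistic `"auc"` or `"dor"`.
#' @param n_perm Number of label permutations (>= 100).
#' @param seed Integer seed.
#' @param ... Passed to [loocv_svm()].
#' @return list with `observed`, `null`, `p`.
#' @export
permutation_pvalue <- function(sig_mat, pheno, statistic = c("auc", "dor"),
                               n_perm = 1000, seed = 1, ...) {
  statistic <- match.arg(statistic)
  if (n_perm < 100) stop("n_perm must be >= 100")
  stat_of <- function(res) {
    if (statistic == "auc") {
      roc_auc(res$score, res$truth)
    } else {
      cm <- confusion_metrics(res$predicted, res$truth)
      as.numeric(dor_from_confusion(cm$confusion, correction = TRUE))
    }
  }
  obs <- stat_of(loocv_svm(sig_mat, pheno, ...))
  set.seed(seed)
  nulls <- vapply(seq_len(n_perm), function(i) {
    ph <- pheno
    ph$status <- ph$status[sample.int(nrow(ph))]
    stat_of(loocv_svm(sig_mat, ph, ...))
  }, numeric(1))
  list(observed = obs, null = nulls,
       p = (1 + sum(nulls >= obs)) / (1 + n_perm))
}

#' Evaluate a diagnostic signature end to end
#'
#' Runs LOOCV, derives the confusion matrix and metrics, the ROC AUC and the
#' diagnostic odds ratio, and (optionally) permutation p-values for AUC and
#' DOR.
#'
#' @param sig_mat Signature matrix (selected features x samples).
#' @param pheno Phenotype table.
#' @param n_perm Permutations for the p-values; 0 skips them.
#' @param seed Integer seed for the permutations.
#' @param ... Passed to [loocv_svm()].
#' @return list of class `classifier_report`: `loocv`, `confusion`,
#'   `sensitivity`, `specificity`, `accuracy`, `auc`, `dor`, `roc`,
#'   `p_auc`, `p_dor`.
#' @export
evaluate_signature <- function(sig_mat, pheno, n_perm = 0, seed = 1, ...) {
  res <- loocv_svm(sig_mat, pheno, ...)
  cm <- confusion_metrics(res$predicted, res$truth)
  rep <- list(loocv = res, confusion = cm$confusion,
              sensitivity = cm$sensitivity, specificity = cm$specificity,
              accuracy = cm$accuracy,
              auc = roc_auc(res$score, res$truth),
              dor = diagnostic_odds_ratio(cm$sensitivity, cm$specificity),
              roc = roc_points(res$score, res$truth),
              p_auc = NA_real_, p_dor = NA_real_)
  if (n_perm > 0) {
    rep$p_auc <- permutation_pvalue(sig_mat, pheno, "auc", n_perm, seed, ...)$p
    rep$p_dor <- permutation_pvalue(sig_mat, pheno, "dor", n_perm, seed + 1L, ...)$p
  }
  class(rep) <- "classifier_report"
  rep
}

#' @export
print.classifier_report <- function(x, ...) {
  cm <- x$confusion
  cat(sprintf("LOOCV: %d/%d correct (accuracy %.3f)\n",
              cm["TP"] + cm["TN"], sum(cm), x$accuracy))
  cat(sprintf("  sensitivity %.3f  specificity %.3f  AUC %.3f  DOR %.3f\n",
              x$sensitivity, x$specificity, x$auc, x$dor))
  if (!is.na(x$p_auc)) {
    cat(sprintf("  permutation p: AUC %.4g, DOR %.4g\n", x$p_auc, x$p_dor))
  }
  invisible(x)
}

#' Unsupervised hierarchical clustering of samples on a signature
#'
#' Agglomerative clustering with distance 1 - Pearson correlation between
#' sample expression profiles and average linkage, cut into `k` clusters.
#'
#' @param sig_mat Signature matrix (features x samples).
#' @param k Number of clusters (default 2).
#' @return list with `tree` (hclust), `clusters` (named integer vector).
#' @export
cluster_samples <- function(sig_mat, k = 2) {
  m <- unclass(sig_mat)
  if (ncol(m) < k) stop("fewer samples than clusters")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant sample profile(s): correlation distance undefined for ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  }
  d <- stats::as.dist(1 - stats::cor(m))
  tree <- stats::hclust(d, method = "average")
  list(tree = tree, clusters = stats::cutree(tree, k = k))
}

#' Association between a 2-level partition and a 2 x 2 contingency table
#'
#' Applies the two-sided Fisher exact test when any expected count is below
#' 5, otherwise the chi-square test with Yates continuity correction (1 df).
#'
#' @param table A 2 x 2 matrix of nonnegative counts with positive margins.
#' @return list with `test` (`"fisher"` or `"chi2_yates"`), `p`, `expected`.
#' @export
association_test <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("need a 2 x 2 table")
  if (any(table < 0)) stop("counts must be nonnegative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero margin: association undefined")
  }
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected < 5)) {
    list(test = "fisher", p = stats::fisher.test(table)$p.value,
         expected = expected)
  } else {
    list(test = "chi2_yates",
         p = stats::chisq.test(table, correct = TRUE)$p.value,
         expected = expected)
  }
}

#' Association between sample clusters and tumor status
#'
#' @param clusters Named integer vector from [cluster_samples()] (2 clusters).
#' @param pheno Phenotype table covering the clustered samples.
#' @return list with `table` (cluster x status), plus the fields of
#'   [association_test()].
#' @export
cluster_association <- function(clusters, pheno) {
  st <- pheno$status[match(names(clusters), pheno$sample)]
  if (anyNA(st)) stop("phenotype table does not cover all clustered samples")
  tab <- table(cluster = clusters, status = st)
  if (!all(dim(tab) == c(2L, 2L))) stop("need exactly 2 clusters and 2 statuses")
  c(list(table = tab), association_test(as.matrix(tab)))
}
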