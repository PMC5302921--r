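#' Linear-scale fold change from log2 expression
#'
#' Computed as 2^(mean log2 tumor - mean log2 normal), i.e. the ratio of
#' geometric means on the linear scale.
#'
#' @param row Numeric vector of log2 expression values.
#' @param labels Factor or character vector with values `tumor`/`normal`,
#'   aligned with `row`.
#' @return Positive fold change (tumor relative to normal).
#' @export
fold_change <- function(row, labels) {
  labels <- as.character(labels)
  t_idx <- labels == "tumor"
  n_idx <- labels == "normal"
  if (!any(t_idx) || !any(n_idx)) stop("both classes must be non-empty")
  2^(mean(row[t_idx]) - mean(row[n_idx]))
}

# Pooled standard error of the two-class mean difference, the denominator of
# the variance-stabilized t-like statistic.
pooled_se <- function(row, t_idx, n_idx) {
  n1 <- sum(t_idx); n2 <- sum(n_idx)
  sp2 <- ((n1 - 1) * stats::var(row[t_idx]) + (n2 - 1) * stats::var(row[n_idx])) /
    (n1 + n2 - 2)
  sqrt(sp2 * (1 / n1 + 1 / n2))
}

#' SAM-style variance-stabilized test statistic
#'
#' d = (mean tumor - mean normal) / (s + s0), where s is the pooled standard
#' error of the mean difference and s0 a small positive "fudge" constant that
#' damps the statistic for low-variance features.
#'
#' @param row Numeric log2 expression vector.
#' @param labels `tumor`/`normal` labels aligned with `row`.
#' @param s0 Exchangeability constant, >= 0. With `s0 = 0` and zero pooled
#'   variance but a nonzero mean difference, an error is raised rather than
#'   dividing by zero.
#' @return The statistic (finite real; sign matches the mean difference).
#' @export
sam_statistic <- function(row, labels, s0 = 0) {
  labels <- as.character(labels)
  t_idx <- labels == "tumor"
  n_idx <- labels == "normal"
  if (sum(t_idx) < 2L || sum(n_idx) < 2L) stop("need >= 2 samples per class")
  num <- mean(row[t_idx]) - mean(row[n_idx])
  den <- pooled_se(row, t_idx, n_idx) + s0
  if (den == 0) {
    if (num == 0) return(0)
    stop("zero pooled variance with s0 = 0 and a nonzero mean difference")
  }
  num / den
}

# pooled SE of the mean difference for all rows, under an arbitrary tumor
# indicator; vectorized over features so that label permutations stay cheap.
pooled_se_matrix <- function(mat, t_idx) {
  n1 <- sum(t_idx); n2 <- sum(!t_idx)
  m1 <- rowMeans(mat[, t_idx, drop = FALSE])
  m2 <- rowMeans(mat[, !t_idx, drop = FALSE])
  v1 <- rowSums((mat[, t_idx, drop = FALSE] - m1)^2)
  v2 <- rowSums((mat[, !t_idx, drop = FALSE] - m2)^2)
  sp2 <- (v1 + v2) / (n1 + n2 - 2)
  list(diff = m1 - m2, se = sqrt(sp2 * (1 / n1 + 1 / n2)))
}

sam_statistic_matrix <- function(mat, t_idx, s0) {
  ps <- pooled_se_matrix(mat, t_idx)
  ps$diff / (ps$se + s0)
}

# distinct tumor-index sets for the permutation null: complete enumeration
# when feasible, otherwise uniform sampling of distinct assignments.
permutation_sets <- function(n, n_tumor, n_perm) {
  total <- choose(n, n_tumor)
  if (total <= n_perm) {
    cmb <- utils::combn(n, n_tumor)
    lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
  } else {
    seen <- new.env(hash = TRUE)
    out <- vector("list", n_perm)
    got <- 0L
    while (got < n_perm) {
      cand <- sort(sample.int(n, n_tumor))
      key <- paste(cand, collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        got <- got + 1L
        out[[got]] <- cand
      }
    }
    out
  }
}

#' Two-class permutation differential expression
#'
#' Computes a SAM-style d statistic per feature, a two-sided permutation
#' p-value (proportion of label permutations with |d*| >= |d|, add-one
#' corrected), a Benjamini-Hochberg q-value, the linear fold change, and the
#' up/down call under the fold-change + FDR gate.
#'
#' @param mat Expression matrix (features x samples, log2 scale).
#' @param pheno Phenotype table covering the matrix samples.
#' @param n_perm Number of label permutations (>= 100). When the number of
#'   distinct tumor/normal assignments is at most `n_perm` they are
#'   enumerated completely; otherwise distinct assignments are sampled
#'   uniformly without replacement.
#' @param seed Integer seed for the permutation draw.
#' @param s0 Fudge constant; `NULL` (default) uses the median per-feature
#'   pooled standard error.
#' @param fc_up,fc_down,fdr Selection gate passed to [select_de()].
#' @return data.frame with one row per feature: `feature`, `mean_tumor`,
#'   `mean_normal`, `fold_change`, `d_stat`, `p_perm`, `q_value`,
#'   `direction`, `selected`.
#' @export
run_sam <- function(mat, pheno, n_perm = 1000, seed = 1, s0 = NULL,
                    fc_up = 1.5, fc_down = 0.67, fdr = 0.1) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  m <- unclass(mat)
  ph <- pheno[match(colnames(m), pheno$sample), ]
  if (anyNA(ph$sample)) stop("phenotype table does not cover all samples")
  t_idx <- ph$status == "tumor"
  n <- ncol(m)
  if (sum(t_idx) < 2L || sum(!t_idx) < 2L) stop("need >= 2 samples per class")
  if (choose(n, sum(t_idx)) < 20) {
    stop("fewer than 20 distinct label permutations; permutation p-values would be meaningless")
  }

  ps <- pooled_se_matrix(m, t_idx)
  if (is.null(s0)) s0 <- stats::median(ps$se)
  d_obs <- ps$diff / (ps$se + s0)

  set.seed(seed)
  perms <- permutation_sets(n, sum(t_idx), n_perm)
  exceed <- integer(nrow(m))
  abs_obs <- abs(d_obs)
  for (p in perms) {
    ti <- rep(FALSE, n); ti[p] <- TRUE
    d_null <- sam_statistic_matrix(m, ti, s0)
    exceed <- exceed + (abs(d_null) >= abs_obs)
  }
  p_perm <- (1 + exceed) / (1 + length(perms))
  q <- stats::p.adjust(p_perm, method = "BH")

  mt <- rowMeans(m[, t_idx, drop = FALSE])
  mn <- rowMeans(m[, !t_idx, drop = FALSE])
  res <- data.frame(feature = rownames(m), mean_tumor = mt, mean_normal = mn,
                    fold_change = 2^(mt - mn), d_stat = d_obs,
                    p_perm = p_perm, q_value = q,
                    stringsAsFactors = FALSE, row.names = NULL)
  select_de(res, fc_up = fc_up, fc_down = fc_down, fdr = fdr)
}

#' Apply the fold-change / FDR selection gate
#'
#' A feature is selected when its q-value is at most `fdr` and its fold
#' change is at least `fc_up` (called `up`) or at most `fc_down` (called
#' `down`). All three boundaries are inclusive.
#'
#' @param results data.frame with columns `fold_change` and `q_value` (as
#'   produced by [run_sam()]).
#' @param fc_up,fc_down,fdr Gate thresholds.
#' @return `results` with `direction` (`up`/`down`/`none`) and `selected`
#'   columns (re)computed.
#' @export
select_de <- function(results, fc_up = 1.5, fc_down = 0.67, fdr = 0.1) {
  dir <- ifelse(results$fold_change >= fc_up, "up",
                ifelse(results$fold_change <= fc_down, "down", "none"))
  sel <- dir != "none" & results$q_value <= fdr
  results$direction <- ifelse(sel, dir, "none")
  results$selected <- sel
  results
}
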