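#' Configuration for a synthetic tumor/normal cohort
#'
#' Parameters of the generative model used by [generate_cohort()]. Defaults
#' emulate a small discovery cohort of 25 tumor and 7 normal samples with a
#' modest transcriptome and a planted ceRNA architecture strong enough to be
#' recoverable by the pipeline.
#'
#' @param n_tumor,n_normal Sample counts per class.
#' @param n_mrna,n_mirna,n_lncrna Feature counts per RNA class.
#' @param n_de_per_class Number of differentially expressed features planted
#'   in each RNA class (planted triplet members count towards this number).
#' @param log2_effect Planted log2 mean shift of DE features in tumor
#'   samples (log2-intensity units).
#' @param n_triplets Number of planted competing triplets; each uses a
#'   distinct miRNA, lncRNA and mRNA, so it may not exceed any class count.
#' @param triplet_strength Latent-factor loading in [0, 1]: the shared
#'   factor explains a fraction `triplet_strength^2` of each planted
#'   member's residual variance, so planted pairwise correlations have
#'   magnitude about `triplet_strength^2` (0 = no shared factor).
#' @param noise_sd Residual log2-intensity noise standard deviation (> 0),
#'   identical for planted and background features.
#' @param n_decoy_interactions Number of random miRNA-target interaction
#'   records added on top of the planted ones.
#' @param seed Integer seed; mandatory, cohorts are fully reproducible.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_tumor = 25, n_normal = 7,
                          n_mrna = 300, n_mirna = 80, n_lncrna = 100,
                          n_de_per_class = 30, log2_effect = 2,
                          n_triplets = 20, triplet_strength = 0.9,
                          noise_sd = 0.5, n_decoy_interactions = 100,
                          seed = NULL) {
  if (is.null(seed)) stop("a seed is mandatory: synthetic cohorts must be reproducible")
  cfg <- list(n_tumor = as.integer(n_tumor), n_normal = as.integer(n_normal),
              n_mrna = as.integer(n_mrna), n_mirna = as.integer(n_mirna),
              n_lncrna = as.integer(n_lncrna),
              n_de_per_class = as.integer(n_de_per_class),
              log2_effect = log2_effect, n_triplets = as.integer(n_triplets),
              triplet_strength = triplet_strength, noise_sd = noise_sd,
              n_decoy_interactions = as.integer(n_decoy_interactions),
              seed = as.integer(seed))
  counts <- c("n_tumor", "n_normal", "n_mrna", "n_mirna", "n_lncrna",
              "n_de_per_class", "n_triplets", "n_decoy_interactions")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 0L) stop(nm, " must be a nonnegative count")
  }
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0")
  if (cfg$triplet_strength < 0 || cfg$triplet_strength > 1) {
    stop("triplet_strength must lie in [0, 1]")
  }
  if (cfg$n_triplets > min(cfg$n_mrna, cfg$n_mirna, cfg$n_lncrna)) {
    stop("n_triplets exceeds a feature-class count; triplets may not share members")
  }
  class(cfg) <- "cohort_config"
  cfg
}

#' Generate a synthetic sample-matched cohort with planted ceRNA structure
#'
#' Simulates log2-scale expression for mRNAs, miRNAs and lncRNAs over a
#' shared set of tumor and normal samples. Baseline expression is drawn per
#' feature from N(7, 1), matching typical log2 microarray intensities. Each
#' planted competing triplet shares a per-sample latent factor f ~ N(0, 1):
#' with s = `triplet_strength` and residual scale `noise_sd`, the miRNA's
#' residual is `noise_sd * (s * f + sqrt(1 - s^2) * z)` while its lncRNA and
#' mRNA partners load on -f the same way (z iid noise), so the miRNA
#' correlates negatively with both partners, the partners correlate
#' positively with each other, and every feature keeps the same marginal
#' noise scale.
#' Differentially expressed features receive a +/- `log2_effect` mean shift
#' in tumor samples; triplet members are always DE in a consistent direction
#' (lncRNA and mRNA shifted together, the miRNA oppositely; the orientation
#' alternates between triplets) so they pass the downstream DE gate.
#' Planted miRNA-lncRNA and miRNA-mRNA interactions are emitted in the
#' interaction tables together with `n_decoy_interactions` random decoy
#' records connecting non-planted pairs.
#'
#' @param config A [cohort_config()].
#' @return A list of class `synthetic_cohort` with elements `mrna`, `mirna`,
#'   `lncrna` (expression matrices), `pheno` (phenotype table),
#'   `interactions_mrna`, `interactions_lncrna` (interaction tables) and
#'   `truth` (ground-truth ledger: `de_features`, `planted_triplets`,
#'   `labels`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_tumor + config$n_normal
  if (n < 1L) stop("cohort must contain at least one sample")
  samples <- sprintf("S%03d", seq_len(n))
  status <- c(rep("tumor", config$n_tumor), rep("normal", config$n_normal))
  tumor <- status == "tumor"

  ids <- list(mRNA = sprintf("mRNA_%04d", seq_len(config$n_mrna)),
              miRNA = sprintf("miR_%03d", seq_len(config$n_mirna)),
              lncRNA = sprintf("lnc_%03d", seq_len(config$n_lncrna)))

  nt <- config$n_triplets
  s <- config$triplet_strength
  fac <- if (nt > 0L) matrix(stats::rnorm(nt * n), nt, n) else matrix(0, 0, n)

  # DE plan per class: triplet members first, then extra independent DE
  # features with alternating direction. Triplet directions alternate too
  # (odd triplets: lncRNA/mRNA up with miRNA down; even triplets reversed),
  # so a planted signature mixes over- and under-expressed members as real
  # dysregulated signatures do.
  de_plan <- lapply(c(mRNA = "mRNA", miRNA = "miRNA", lncRNA = "lncRNA"), function(cl) {
    n_feat <- length(ids[[cl]])
    dir <- rep("none", n_feat)
    if (nt > 0L) {
      dir[seq_len(nt)] <- if (cl == "miRNA") {
        rep(c("down", "up"), length.out = nt)
      } else {
        rep(c("up", "down"), length.out = nt)
      }
    }
    extra <- min(config$n_de_per_class - nt, n_feat - nt)
    if (extra > 0L) {
      idx <- nt + seq_len(extra)
      dir[idx] <- rep(c("up", "down"), length.out = extra)
    }
    dir
  })

  build <- function(cl) {
    n_feat <- length(ids[[cl]])
    base <- stats::rnorm(n_feat, mean = 7, sd = 1)
    noise <- matrix(stats::rnorm(n_feat * n, sd = config$noise_sd), n_feat, n)
    if (nt > 0L) {
      # the latent factor explains a share s^2 of the member's residual
      # variance rather than adding to it, so planted and background
      # features have identical marginal noise scale
      load <- if (cl == "miRNA") s else -s
      noise[seq_len(nt), ] <- sqrt(1 - s^2) * noise[seq_len(nt), , drop = FALSE] +
        load * config$noise_sd * fac
    }
    m <- matrix(base, n_feat, n) + noise
    dir <- de_plan[[cl]]
    shift <- ifelse(dir == "up", config$log2_effect,
                    ifelse(dir == "down", -config$log2_effect, 0))
    m[, tumor] <- m[, tumor] + shift
    dimnames(m) <- list(ids[[cl]], samples)
    expression_matrix(m, cl)
  }
  mats <- list(mrna = build("mRNA"), mirna = build("miRNA"), lncrna = build("lncRNA"))

  planted <- if (nt > 0L) {
    data.frame(mirna = ids$miRNA[seq_len(nt)], lncrna = ids$lncRNA[seq_len(nt)],
               mrna = ids$mRNA[seq_len(nt)], stringsAsFactors = FALSE)
  } else {
    data.frame(mirna = character(), lncrna = character(), mrna = character())
  }

  inter <- rbind(
    if (nt > 0L) data.frame(mirna = planted$mirna, target = planted$mrna,
                            target_class = "mRNA", source = "planted") else NULL,
    if (nt > 0L) data.frame(mirna = planted$mirna, target = planted$lncrna,
                            target_class = "lncRNA", source = "planted") else NULL
  )
  # decoys: uniform over non-planted (miRNA, target) pairs, no replacement
  all_targets <- c(ids$mRNA, ids$lncRNA)
  n_pairs <- length(ids$miRNA) * length(all_targets)
  planted_keys <- if (nt > 0L) paste(inter$mirna, inter$target) else character()
  n_decoy <- min(config$n_decoy_interactions, n_pairs - length(planted_keys))
  if (n_decoy > 0L) {
    picked <- character(0)
    while (length(picked) < n_decoy) {
      cand <- paste(sample(ids$miRNA, n_decoy, replace = TRUE),
                    sample(all_targets, n_decoy, replace = TRUE))
      picked <- unique(c(picked, setdiff(cand, planted_keys)))
    }
    picked <- picked[seq_len(n_decoy)]
    parts <- do.call(rbind, strsplit(picked, " ", fixed = TRUE))
    decoys <- data.frame(mirna = parts[, 1L], target = parts[, 2L],
                         target_class = ifelse(parts[, 2L] %in% ids$mRNA, "mRNA", "lncRNA"),
                         source = "decoy", stringsAsFactors = FALSE)
    inter <- rbind(inter, decoys)
  }
  if (is.null(inter)) {
    inter <- data.frame(mirna = character(), target = character(),
                        target_class = character(), source = character())
  }
  rownames(inter) <- NULL

  de_features <- do.call(rbind, lapply(names(de_plan), function(cl) {
    dir <- de_plan[[cl]]
    sel <- dir != "none"
    if (!any(sel)) return(NULL)
    data.frame(feature = ids[[cl]][sel], class = cl, direction = dir[sel],
               stringsAsFactors = FALSE)
  }))
  if (is.null(de_features)) {
    de_features <- data.frame(feature = character(), class = character(),
                              direction = character())
  }

  truth <- list(de_features = de_features, planted_triplets = planted,
                labels = data.frame(sample = samples, status = status,
                                    stringsAsFactors = FALSE))
  class(truth) <- "synthetic_truth"

  out <- list(mrna = mats$mrna, mirna = mats$mirna, lncrna = mats$lncrna,
              pheno = phenotype_table(samples, status),
              interactions_mrna = inter[inter$target_class == "mRNA", , drop = FALSE],
              interactions_lncrna = inter[inter$target_class == "lncRNA", , drop = FALSE],
              truth = truth)
  rownames(out$interactions_mrna) <- rownames(out$interactions_lncrna) <- NULL
  class(out) <- "synthetic_cohort"
  out
}

#' Write a ground-truth ledger to delimited text
#'
#' The ledger is stored as a single TSV with a `record_type` column
#' (`de_feature`, `triplet` or `label`) and three value columns; it
#' round-trips losslessly through [read_truth()].
#'
#' @param truth A `synthetic_truth` object (see [generate_cohort()]).
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  rows <- rbind(
    if (nrow(truth$de_features)) data.frame(record_type = "de_feature",
                                            f1 = truth$de_features$feature,
                                            f2 = truth$de_features$class,
                                            f3 = truth$de_features$direction),
    if (nrow(truth$planted_triplets)) data.frame(record_type = "triplet",
                                                 f1 = truth$planted_triplets$mirna,
                                                 f2 = truth$planted_triplets$lncrna,
                                                 f3 = truth$planted_triplets$mrna),
    if (nrow(truth$labels)) data.frame(record_type = "label",
                                       f1 = truth$labels$sample,
                                       f2 = truth$labels$status,
                                       f3 = "")
  )
  if (is.null(rows)) {
    rows <- data.frame(record_type = character(), f1 = character(),
                       f2 = character(), f3 = character())
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ground-truth ledger written by [write_truth()]
#'
#' @param path Ledger TSV path.
#' @return A `synthetic_truth` object.
#' @export
read_truth <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "", fill = TRUE,
                          na.strings = NULL)
  pick <- function(type) df[df$record_type == type, , drop = FALSE]
  de <- pick("de_feature"); tr <- pick("triplet"); lb <- pick("label")
  truth <- list(
    de_features = data.frame(feature = de$f1, class = de$f2, direction = de$f3,
                             stringsAsFactors = FALSE),
    planted_triplets = data.frame(mirna = tr$f1, lncrna = tr$f2, mrna = tr$f3,
                                  stringsAsFactors = FALSE),
    labels = data.frame(sample = lb$f1, status = lb$f2, stringsAsFactors = FALSE)
  )
  rownames(truth$de_features) <- rownames(truth$planted_triplets) <-
    rownames(truth$labels) <- NULL
  class(truth) <- "synthetic_truth"
  truth
}

#' Write a full synthetic cohort to a directory
#'
#' Emits the three expression matrices, the phenotype table, the two
#' interaction tables and the truth ledger as TSV files.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(mrna = file.path(dir, "mrna.tsv"),
             mirna = file.path(dir, "mirna.tsv"),
             lncrna = file.path(dir, "lncrna.tsv"),
             pheno = file.path(dir, "pheno.tsv"),
             interactions_mrna = file.path(dir, "interactions_mrna.tsv"),
             interactions_lncrna = file.path(dir, "interactions_lncrna.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_expression(cohort$mrna, paths["mrna"])
  write_expression(cohort$mirna, paths["mirna"])
  write_expression(cohort$lncrna, paths["lncrna"])
  write_phenotype(cohort$pheno, paths["pheno"])
  utils::write.table(cohort$interactions_mrna, paths["interactions_mrna"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$interactions_lncrna, paths["interactions_lncrna"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_truth(cohort$truth, paths["truth"])
  invisible(paths)
}
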