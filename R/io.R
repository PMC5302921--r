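#' Read an expression matrix from delimited text
#'
#' Reads a features x samples matrix of log2-scale expression values from a
#' tab-separated file whose first column holds feature identifiers and whose
#' header row holds sample identifiers. Values are assumed to be already
#' normalized and log2-transformed; no re-normalization is performed.
#' Duplicate feature identifiers are collapsed by retaining the row with the
#' largest mean expression (a warning reports how many rows were dropped).
#'
#' @param path Path to a TSV file (first column feature id, header of sample
#'   ids).
#' @param feature_class One of `"mRNA"`, `"miRNA"`, `"lncRNA"`; stored as the
#'   `feature_class` attribute of the returned matrix.
#' @param sep Field separator, default tab.
#' @return A numeric matrix with feature ids as rownames, sample ids as
#'   colnames and a `feature_class` attribute.
#' @export
load_expression <- function(path, feature_class = c("mRNA", "miRNA", "lncRNA"),
                            sep = "\t") {
  feature_class <- match.arg(feature_class)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  if (ncol(raw) < 2L) stop("expression file must have a feature id column and >= 1 sample column")
  ids <- raw[[1L]]
  samples <- colnames(raw)[-1L]
  if (anyDuplicated(samples)) {
    stop("duplicate sample id(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) | !is.finite(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric or non-finite value '%s' at row %d (feature '%s'), column '%s'",
                 vals[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L],
                 ids[bad[1L, 1L]], samples[bad[1L, 2L]]))
  }
  dimnames(num) <- list(ids, samples)
  if (anyDuplicated(ids)) {
    means <- rowMeans(num)
    keep <- unlist(lapply(split(seq_along(ids), ids), function(ix) ix[which.max(means[ix])]),
                   use.names = FALSE)
    keep <- sort(keep)
    warning(sprintf("%d duplicated feature id row(s) collapsed (kept row with maximal mean)",
                    nrow(num) - length(keep)))
    num <- num[keep, , drop = FALSE]
  }
  expression_matrix(num, feature_class)
}

#' Construct an expression matrix object
#'
#' @param values Numeric matrix, features in rows (rownames), samples in
#'   columns (colnames), log2 scale.
#' @param feature_class One of `"mRNA"`, `"miRNA"`, `"lncRNA"`.
#' @return The matrix with class tag and `feature_class` attribute.
#' @export
expression_matrix <- function(values, feature_class = c("mRNA", "miRNA", "lncRNA")) {
  feature_class <- match.arg(feature_class)
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs feature rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate feature ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (any(!is.finite(values))) stop("expression values must be finite")
  attr(values, "feature_class") <- feature_class
  class(values) <- c("expression_matrix", class(values))
  values
}

#' Write an expression matrix as TSV
#'
#' @param x Expression matrix (see [expression_matrix()]).
#' @param path Output path.
#' @param id_col Name of the feature id column in the written header.
#' @export
write_expression <- function(x, path, id_col = "feature_id") {
  df <- data.frame(rownames(x), as.data.frame(unclass(x)), check.names = FALSE)
  colnames(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' @param path TSV with header columns `sample` and `status`
#'   (`tumor`/`normal`).
#' @return A data.frame with columns `sample`, `status` (factor with levels
#'   normal, tumor).
#' @export
load_phenotype <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  phenotype_table(df$sample, df$status)
}

#' Construct a phenotype table
#'
#' @param sample Character vector of sample ids.
#' @param status Character vector, `"tumor"` or `"normal"` per sample.
#' @return Validated data.frame with `sample` and `status` columns.
#' @export
phenotype_table <- function(sample, status) {
  if (is.null(sample) || is.null(status) || length(sample) != length(status)) {
    stop("phenotype table needs matched sample and status vectors")
  }
  if (anyDuplicated(sample)) stop("duplicate sample ids in phenotype table")
  if (!all(status %in% c("tumor", "normal"))) {
    stop("status must be 'tumor' or 'normal'")
  }
  data.frame(sample = as.character(sample),
             status = factor(status, levels = c("normal", "tumor")),
             stringsAsFactors = FALSE)
}

#' Write a phenotype table as TSV
#' @param pheno Phenotype table.
#' @param path Output path.
#' @export
write_phenotype <- function(pheno, path) {
  utils::write.table(data.frame(sample = pheno$sample,
                                status = as.character(pheno$status)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load miRNA-target interaction tables
#'
#' Reads one or more TSV files with header
#' `mirna  target  target_class  source` and returns their union with
#' duplicate (mirna, target) pairs removed (first occurrence wins).
#' Interactions referencing features absent from any expression matrix are
#' retained at load time; they are filtered during triplet detection.
#'
#' @param ... Paths to interaction TSV files.
#' @return data.frame with columns `mirna`, `target`, `target_class`,
#'   `source`.
#' @export
load_interactions <- function(...) {
  paths <- c(...)
  if (length(paths) == 0L) stop("no interaction files given")
  tabs <- lapply(paths, function(p) {
    df <- utils::read.table(p, header = TRUE, sep = "\t",
                            colClasses = "character", quote = "")
    need <- c("mirna", "target")
    if (!all(need %in% colnames(df))) {
      stop("interaction file ", p, " must have columns 'mirna' and 'target'")
    }
    if (is.null(df$target_class)) df$target_class <- NA_character_
    if (is.null(df$source)) df$source <- basename(p)
    df[, c("mirna", "target", "target_class", "source")]
  })
  out <- do.call(rbind, tabs)
  if (any(!nzchar(out$mirna)) || any(!nzchar(out$target))) {
    stop("empty interaction ids")
  }
  out <- out[!duplicated(out[, c("mirna", "target")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a GMT gene-set collection
#'
#' Standard tab-separated GMT: set name, description, then member gene ids.
#' Duplicate members within a set are dropped.
#'
#' @param path GMT file path.
#' @return Named list of character vectors of member ids, with a
#'   `descriptions` attribute (named character vector).
#' @export
load_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  desc <- character(length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) {
      stop(sprintf("malformed GMT line %d: fewer than 3 tab-separated fields", i))
    }
    nms[i] <- parts[1L]
    desc[i] <- parts[2L]
    sets[[i]] <- unique(parts[-(1:2)][nzchar(parts[-(1:2)])])
    if (length(sets[[i]]) == 0L) stop(sprintf("GMT line %d: set '%s' has no members", i, parts[1L]))
  }
  names(sets) <- nms
  names(desc) <- nms
  attr(sets, "descriptions") <- desc
  sets
}

#' Align the three expression matrices and the phenotype table
#'
#' Restricts the mRNA, miRNA and lncRNA matrices to the intersection of their
#' sample ids (exact string match) in a common column order, and subsets the
#' phenotype table to match. Samples missing from any matrix are dropped from
#' all with a message.
#'
#' @param mrna,mirna,lncrna Expression matrices (see [expression_matrix()]).
#' @param pheno Phenotype table covering all retained samples.
#' @return A list of class `aligned_cohort` with elements `mrna`, `mirna`,
#'   `lncrna` (matrices with identical colnames) and `pheno`.
#' @export
align_cohort <- function(mrna, mirna, lncrna, pheno) {
  mats <- list(mrna = mrna, mirna = mirna, lncrna = lncrna)
  common <- Reduce(intersect, lapply(mats, colnames))
  all_ids <- unique(unlist(lapply(mats, colnames)))
  dropped <- setdiff(all_ids, common)
  if (length(common) < 3L) {
    stop("fewer than 3 samples shared across the three matrices")
  }
  if (length(dropped) > 0L) {
    message(length(dropped), " sample(s) absent from at least one matrix dropped: ",
            paste(dropped, collapse = ", "))
  }
  missing_ph <- setdiff(common, pheno$sample)
  if (length(missing_ph) > 0L) {
    stop("samples missing from phenotype table: ", paste(missing_ph, collapse = ", "))
  }
  ph <- pheno[match(common, pheno$sample), , drop = FALSE]
  rownames(ph) <- NULL
  if (length(unique(ph$status)) < 2L) {
    stop("aligned cohort must contain both tumor and normal samples")
  }
  out <- list(
    mrna = expression_matrix(unclass(mats$mrna)[, common, drop = FALSE], "mRNA"),
    mirna = expression_matrix(unclass(mats$mirna)[, common, drop = FALSE], "miRNA"),
    lncrna = expression_matrix(unclass(mats$lncrna)[, common, drop = FALSE], "lncRNA"),
    pheno = ph
  )
  class(out) <- "aligned_cohort"
  out
}

#' @export
print.aligned_cohort <- function(x, ...) {
  cat("aligned cohort:", ncol(x$mrna), "samples (",
      sum(x$pheno$status == "tumor"), "tumor /",
      sum(x$pheno$status == "normal"), "normal )\n")
  cat("  mRNA:", nrow(x$mrna), " miRNA:", nrow(x$mirna),
      " lncRNA:", nrow(x$lncrna), "features\n")
  invisible(x)
}
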