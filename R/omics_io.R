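#' Feature-by-sample omics matrix
#'
#' The container consumed by every stage of the pipeline: a numeric matrix
#' with features in rows and samples in columns, plus a tag saying which kind
#' of data it holds.  Methylation matrices carry beta values and must lie in
#' \[0, 1\].
#'
#' @param values Numeric matrix (features x samples) with rownames (feature
#'   ids) and colnames (sample ids).
#' @param omic_kind Either `"expression"` or `"methylation"`.
#'
#' @return An object of class `omics_matrix` (the matrix itself with an
#'   `omic_kind` attribute).
#' @examples
#' m <- matrix(rnorm(6), 2, 3,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' omics_matrix(m, "expression")
#' @export
omics_matrix <- function(values, omic_kind = c("expression", "methylation")) {
  omic_kind <- match.arg(omic_kind)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("omics matrix must be numeric")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("omics matrix needs feature rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate feature ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (omic_kind == "methylation") {
    bad <- which(values < 0 | values > 1, arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf(
        "methylation beta values must lie in [0,1]; first offender: feature '%s', sample '%s' (value %g)",
        rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]],
        values[bad[1, , drop = FALSE]]))
    }
  }
  structure(values, omic_kind = omic_kind, class = c("omics_matrix", "matrix"))
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("%s omics matrix: %d features x %d samples\n",
              omic_kind(x), nrow(x), ncol(x)))
  invisible(x)
}

#' Omic kind of a matrix
#' @param x An [omics_matrix].
#' @return `"expression"` or `"methylation"`.
#' @export
omic_kind <- function(x) attr(x, "omic_kind")

# keep attributes when subsetting
#' @export
`[.omics_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    out <- structure(out, omic_kind = attr(x, "omic_kind"),
                     class = c("omics_matrix", "matrix"))
  }
  out
}

#' Read / write a feature-by-sample matrix as tab-delimited text
#'
#' Files have a header row of sample ids and a first column of feature ids.
#' Parsing failures and out-of-range methylation values are reported with the
#' offending coordinates.
#'
#' @param path File path.
#' @param omic_kind `"expression"` or `"methylation"`.
#' @param x An [omics_matrix].
#' @return `read_omics_matrix` returns a validated [omics_matrix];
#'   `write_omics_matrix` returns `path` invisibly.
#' @export
read_omics_matrix <- function(path, omic_kind = c("expression", "methylation")) {
  omic_kind <- match.arg(omic_kind)
  d <- read.delim(path, header = TRUE, check.names = FALSE,
                  stringsAsFactors = FALSE, row.names = NULL)
  if (ncol(d) < 2) stop("matrix file needs a feature-id column plus samples")
  feat <- as.character(d[[1]])
  vals <- d[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad)) {
        stop(sprintf("non-numeric value '%s' at feature '%s', sample '%s'",
                     v[bad[1]], feat[bad[1]], colnames(vals)[j]))
      }
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- feat
  omics_matrix(m, omic_kind)
}

#' @rdname read_omics_matrix
#' @export
write_omics_matrix <- function(x, path) {
  stopifnot(inherits(x, "omics_matrix"))
  d <- data.frame(feature_id = rownames(x), unclass(x), check.names = FALSE,
                  stringsAsFactors = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the per-sample clinical table
#'
#' A CSV with one row per sample.  The only required column is `sample_id`;
#' the conventional clinical columns are `copd_status` (0/1), `age`, `sex`,
#' `race`, `bmi`, `pack_years`, `months_quit`, `fev1pp`, `fev1_fvc`,
#' `pct_laa950`, `perc15` and `pi10`.  Missing values stay `NA`; nothing is
#' imputed at I/O time.
#'
#' @param path File path.
#' @param clinical A data frame with a `sample_id` column.
#' @return `read_cohort_table` returns the validated data frame.
#' @export
read_cohort_table <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  validate_cohort_table(d)
}

#' @rdname read_cohort_table
#' @export
write_cohort_table <- function(clinical, path) {
  validate_cohort_table(clinical)
  write.csv(clinical, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_cohort_table <- function(d) {
  if (!"sample_id" %in% names(d)) stop("clinical table needs a 'sample_id' column")
  d$sample_id <- as.character(d$sample_id)
  if (anyDuplicated(d$sample_id)) stop("duplicate sample ids in clinical table")
  if ("fev1_fvc" %in% names(d)) {
    v <- d$fev1_fvc
    if (any(!is.na(v) & (v < 0 | v > 1))) stop("fev1_fvc must lie in [0,1]")
  }
  d
}

#' Read / write a per-feature association statistics table
#'
#' Fixed-header CSV (`feature_id, effect, t_stat, p_value, fdr`) holding one
#' row per feature: the model coefficient, moderated t, raw p and BH-adjusted
#' FDR.  This is the output of [moderate()] and the input to [filter_by_fdr()].
#'
#' @param path File path.
#' @param stats A data frame with the columns above.
#' @return `read_stat_table` returns the validated data frame.
#' @export
read_stat_table <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  validate_stat_table(d)
}

#' @rdname read_stat_table
#' @export
write_stat_table <- function(stats, path) {
  validate_stat_table(stats)
  write.csv(stats[, c("feature_id", "effect", "t_stat", "p_value", "fdr")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_stat_table <- function(d) {
  need <- c("feature_id", "effect", "t_stat", "p_value", "fdr")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("stat table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (any(d$p_value < 0 | d$p_value > 1, na.rm = TRUE) ||
      any(d$fdr < 0 | d$fdr > 1, na.rm = TRUE)) {
    stop("p_value and fdr must lie in [0,1]")
  }
  d
}

#' Read gene sets in GMT format
#'
#' One set per line: set name, description, then member gene ids, all
#' tab-separated.
#'
#' @param path File path.
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(l, 1, 60))
    unique(parts[-(1:2)])
  })
  names(out) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1))
  if (anyDuplicated(names(out))) stop("duplicate gene-set names in GMT file")
  out
}

#' Restrict multi-omics matrices and the clinical table to shared samples
#'
#' Each matrix and the clinical table are cut down to the intersection of
#' their sample ids and put into one canonical order: the order of appearance
#' in the clinical table.  Dropped ids are reported via message.
#'
#' @param matrices A list of [omics_matrix] objects.
#' @param clinical A clinical data frame with a `sample_id` column.
#' @return A list with elements `matrices` (list of aligned matrices) and
#'   `clinical` (aligned data frame), plus `dropped` (ids removed from any
#'   input).
#' @export
align_on_samples <- function(matrices, clinical) {
  clinical <- validate_cohort_table(clinical)
  sample_sets <- c(lapply(matrices, colnames), list(clinical$sample_id))
  shared <- Reduce(intersect, sample_sets)
  if (length(shared) == 0) stop("no samples shared across all inputs")
  keep <- clinical$sample_id[clinical$sample_id %in% shared]
  dropped <- unique(unlist(lapply(sample_sets, setdiff, keep)))
  if (length(dropped)) {
    message(sprintf("align_on_samples: dropped %d sample(s): %s",
                    length(dropped),
                    paste(head(dropped, 10), collapse = ", ")))
  }
  list(
    matrices = lapply(matrices, function(m) m[, keep, drop = FALSE]),
    clinical = clinical[match(keep, clinical$sample_id), , drop = FALSE],
    dropped = dropped
  )
}

#' Keep only features below an association FDR threshold
#'
#' Retains exactly the features of `matrix` whose `fdr` in `stats` is strictly
#' below `threshold`.  Features absent from `stats` are treated as
#' non-significant.  `threshold = 1` keeps every feature, i.e. the genome-wide
#' run.
#'
#' @param matrix An [omics_matrix].
#' @param stats A stat table (see [read_stat_table()]) covering the features.
#' @param threshold FDR cutoff in (0, 1].
#' @return The filtered [omics_matrix].
#' @export
filter_by_fdr <- function(matrix, stats, threshold) {
  stopifnot(inherits(matrix, "omics_matrix"))
  stats <- validate_stat_table(stats)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1) {
    stop("threshold must lie in (0, 1]")
  }
  if (threshold == 1) return(matrix)
  fdr <- stats$fdr[match(rownames(matrix), stats$feature_id)]
  fdr[is.na(fdr)] <- 1   # unscored features are non-significant
  keep <- fdr < threshold
  if (!any(keep)) stop(sprintf("no features survive FDR < %g", threshold))
  matrix[keep, , drop = FALSE]
}
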