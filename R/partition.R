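#' Cluster partition of a sample set
#'
#' A `partition` assigns each sample to exactly one of `k` clusters.  It is
#' the common currency of both clustering engines and of all evaluation
#' statistics.
#'
#' @param labels Integer vector of cluster labels in `1..k`, one per sample.
#' @param sample_ids Character vector of sample identifiers; defaults to
#'   `names(labels)`.
#' @param k Number of clusters; defaults to `max(labels)`.
#'
#' @return An object of class `partition`: a list with elements `sample_ids`,
#'   `labels` (integer, named by sample) and `k`.
#' @examples
#' p <- partition(c(a = 1, b = 1, c = 2))
#' cluster_sizes(p)
#' @export
partition <- function(labels, sample_ids = names(labels), k = max(labels)) {
  force(sample_ids)   # capture names before integer coercion strips them
  k <- as.integer(k)
  labels <- as.integer(labels)
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("S%03d", seq_along(labels))
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != length(labels)) {
    stop("'labels' and 'sample_ids' must have equal length")
  }
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids in partition")
  if (any(!is.finite(labels)) || any(labels < 1L)) {
    stop("labels must be positive integers")
  }
  if (any(labels > k)) stop("label exceeds declared number of clusters k")
  names(labels) <- sample_ids
  structure(list(sample_ids = sample_ids, labels = labels, k = k),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  sz <- cluster_sizes(x)
  cat(sprintf("partition of %d samples into %d clusters\n",
              length(x$labels), x$k))
  cat("sizes:", paste(sprintf("%d:%d", seq_len(x$k), sz), collapse = " "), "\n")
  invisible(x)
}

#' Cluster sizes of a partition
#'
#' @param p A [partition].
#' @return Integer vector of length `p$k` with the number of samples per
#'   cluster.
#' @export
cluster_sizes <- function(p) {
  stopifnot(inherits(p, "partition"))
  tabulate(p$labels, p$k)
}

#' Renumber clusters so that cluster 1 is the largest
#'
#' Reported solutions list the larger cluster first; ties are broken by the
#' lowest original label so the mapping is deterministic.
#'
#' @param p A [partition].
#' @return A [partition] with relabelled clusters.
#' @export
relabel_largest_first <- function(p) {
  stopifnot(inherits(p, "partition"))
  sz <- cluster_sizes(p)
  ord <- order(-sz, seq_len(p$k))   # original labels in new-label order
  partition(match(p$labels, ord), p$sample_ids, k = p$k)
}

# Coerce a labelled vector / factor / partition to a partition over given ids.
as_partition <- function(x, sample_ids = NULL) {
  if (inherits(x, "partition")) return(x)
  if (is.factor(x)) x <- as.integer(x)
  if (is.null(sample_ids)) sample_ids <- names(x)
  partition(x, sample_ids)
}

check_same_samples <- function(a, b, what = "partitions") {
  if (length(a$sample_ids) != length(b$sample_ids) ||
      !all(a$sample_ids == b$sample_ids)) {
    if (setequal(a$sample_ids, b$sample_ids)) {
      stop(sprintf("%s cover the same samples but in different order; align first",
                   what))
    }
    stop(sprintf("%s do not cover the same samples", what))
  }
  invisible(TRUE)
}

#' Write / read a partition as a two-column CSV
#'
#' Files have columns `sample_id,cluster`, one row per sample.
#'
#' @param p A [partition].
#' @param path File path.
#' @return `read_partition` returns a [partition]; `write_partition` returns
#'   `path` invisibly.
#' @export
write_partition <- function(p, path) {
  stopifnot(inherits(p, "partition"))
  write.csv(data.frame(sample_id = p$sample_ids, cluster = p$labels),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "cluster") %in% names(d))) {
    stop("partition file needs columns 'sample_id' and 'cluster'")
  }
  partition(as.integer(d$cluster), d$sample_id)
}
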