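#' Generate an ensemble of basic partitions from one omic block
#'
#' Each basic partition is produced by (1) drawing a cluster count uniformly
#' from `bp_k_range`, (2) drawing a random feature subspace containing a
#' fraction `bp_feature_fraction` of the features, and (3) running seeded
#' k-means on the standardized subspace.  Every draw is reproducible from
#' `(seed, draw index)`: a single stream seeded by `seed` yields one
#' sub-seed per draw.
#'
#' @param matrix An [omics_matrix] (features x samples).
#' @param n_bp Number of basic partitions to generate.
#' @param bp_k_range Integer range (length-2 vector) of cluster counts;
#'   default `c(2, ceiling(sqrt(n_samples)))`.
#' @param bp_feature_fraction Fraction of features per random subspace.
#' @param seed Integer seed.
#' @param view_tag Label attached to every partition (e.g. the omic kind).
#' @return An object of class `basic_partitions`: list with `sample_ids`,
#'   `labels` (n_samples x n_bp integer matrix), `k` (per-partition cluster
#'   count) and `view` (per-partition tag).
#' @export
ecc_basic_partitions <- function(matrix, n_bp,
                                 bp_k_range = NULL,
                                 bp_feature_fraction = 0.05,
                                 seed = 1L,
                                 view_tag = omic_kind(matrix) %||% "view") {
  x <- unclass(standardize_features(matrix))
  n <- ncol(x)
  if (is.null(bp_k_range)) bp_k_range <- c(2L, max(2L, ceiling(sqrt(n))))
  bp_k_range <- as.integer(bp_k_range)
  if (length(bp_k_range) != 2 || bp_k_range[1] < 2 ||
      bp_k_range[2] < bp_k_range[1]) {
    stop("bp_k_range must be an integer range with lower bound >= 2")
  }
  if (n < bp_k_range[2]) stop("fewer samples than the largest basic-partition k")
  if (n_bp < 1) stop("n_bp must be >= 1")
  n_feat <- max(1L, floor(bp_feature_fraction * nrow(x)))
  if (bp_feature_fraction <= 0) stop("bp_feature_fraction must yield >= 1 feature")
  labels <- matrix(0L, n, n_bp)
  ks <- integer(n_bp)
  draw_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_bp))
  for (b in seq_len(n_bp)) {
    labels[, b] <- with_seed(draw_seeds[b], {
      k_b <- sample(seq(bp_k_range[1], bp_k_range[2]), 1)
      idx <- sample.int(nrow(x), n_feat)
      cl <- kmeans(t(x[idx, , drop = FALSE]), centers = k_b, nstart = 1,
                   iter.max = 30)$cluster
      ks[b] <- k_b
      as.integer(cl)
    })
  }
  structure(list(sample_ids = colnames(x), labels = labels, k = ks,
                 view = rep(view_tag, n_bp)),
            class = "basic_partitions")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.basic_partitions <- function(x, ...) {
  cat(sprintf("%d basic partitions over %d samples (k in %d..%d; views: %s)\n",
              ncol(x$labels), nrow(x$labels), min(x$k), max(x$k),
              paste(unique(x$view), collapse = ", ")))
  invisible(x)
}

#' Concatenate basic-partition ensembles from several views
#'
#' @param ... `basic_partitions` objects over the same samples (empty sets,
#'   i.e. zero partitions, are allowed).
#' @return A merged `basic_partitions` object preserving view tags.
#' @export
merge_basic_partitions <- function(...) {
  sets <- list(...)
  sets <- Filter(function(s) ncol(s$labels) > 0, sets)
  if (length(sets) == 0) stop("nothing to merge")
  ids <- sets[[1]]$sample_ids
  for (s in sets) {
    if (!identical(s$sample_ids, ids)) {
      stop("basic-partition sets cover different samples")
    }
  }
  structure(list(sample_ids = ids,
                 labels = do.call(cbind, lapply(sets, `[[`, "labels")),
                 k = unlist(lapply(sets, `[[`, "k"), use.names = FALSE),
                 view = unlist(lapply(sets, `[[`, "view"), use.names = FALSE)),
            class = "basic_partitions")
}

# one-hot block encoding of the ensemble: n x (sum of k_i), each block of
# columns holds one basic partition, each row has a single 1 per block,
# scaled by 1/r so rows sum to 1 (a probability vector per sample)
bp_onehot <- function(bps) {
  n <- nrow(bps$labels)
  r <- ncol(bps$labels)
  offs <- c(0L, cumsum(bps$k))
  b <- matrix(0, n, offs[r + 1L])
  for (i in seq_len(r)) {
    b[cbind(seq_len(n), offs[i] + bps$labels[, i])] <- 1 / r
  }
  b
}

#' Mean entropy utility of a candidate partition against an ensemble
#'
#' For each basic partition the Shannon-entropy utility of the contingency
#' between candidate and basic partition equals their mutual information
#' \eqn{I(\pi, \pi_i) = H(\pi_i) - H(\pi_i \mid \pi)} (in nats); the returned
#' value is its mean over the ensemble.  Higher means more agreement; the
#' value is invariant to relabelling of either side, and for candidates with
#' a fixed number of clusters it is maximised when the candidate reproduces
#' the ensemble exactly.
#'
#' @param candidate A [partition] (or label vector) over the ensemble samples.
#' @param bps A `basic_partitions` object.
#' @return A single non-negative number.
#' @export
ecc_utility <- function(candidate, bps) {
  candidate <- as_partition(candidate, bps$sample_ids)
  if (!identical(candidate$sample_ids, bps$sample_ids)) {
    stop("candidate and basic partitions must cover the same samples")
  }
  if (any(tabulate(candidate$labels, candidate$k) == 0)) {
    stop("candidate partition has an empty cluster")
  }
  mean(vapply(seq_len(ncol(bps$labels)), function(i) {
    mutual_information(candidate$labels, bps$labels[, i])
  }, numeric(1)))
}

mutual_information <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  pa <- rowSums(p); pb <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / (pa[row(p)[nz]] * pb[col(p)[nz]])))
}

#' Entropy-based consensus over an ensemble of basic partitions
#'
#' Finds the `k`-cluster partition maximizing the mean entropy utility
#' ([ecc_utility()]) over the ensemble.  Each sample is encoded by its
#' one-hot membership across all basic partitions (rows scaled to
#' probability vectors) and the utility maximization is carried out as
#' k-means under the KL divergence: assignment moves each sample to the
#' centroid minimizing \eqn{D_{KL}(x \| m_k)}, the centroid update takes
#' cluster means, and each full iteration cannot decrease the utility.
#' Several seeded restarts are run and the best-utility solution returned
#' with labels renumbered largest-first.  An empty cluster is repaired
#' deterministically by reseeding it at the sample with the worst divergence
#' from its current centroid.
#'
#' @param bps A `basic_partitions` object.
#' @param k Number of consensus clusters.
#' @param n_restarts Seeded restarts (default 5).
#' @param max_iterations Iteration cap per restart (default 100).
#' @param seed Integer seed.
#' @return A list of class `ecc_consensus` with `partition`, `utility`
#'   (mean entropy utility of the returned partition), `utility_trace`
#'   (per-iteration utility of the winning restart), `restart_utilities`.
#' @export
ecc_consensus <- function(bps, k = 2, n_restarts = 5, max_iterations = 100,
                          seed = 1L) {
  n <- nrow(bps$labels)
  r <- ncol(bps$labels)
  if (r < 1) stop("empty basic-partition set")
  if (k > n) stop("k cannot exceed the number of samples")
  b <- bp_onehot(bps)
  # affine link between the k-means cross term and the mean entropy utility:
  # mean_i I(pi, pi_i) = mean_i H(pi_i) + log r + (1/n) sum_l b_l . log m_{c(l)}
  mean_h <- mean(apply(bps$labels, 2, function(l) {
    p <- tabulate(l) / length(l); p <- p[p > 0]; -sum(p * log(p))
  }))
  log_clamp <- function(m) log(pmax(m, 1e-9))
  restart_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                              n_restarts))
  best <- NULL
  restart_utilities <- numeric(n_restarts)
  for (s in seq_len(n_restarts)) {
    # random balanced label initialization keeps the initial centroids dense,
    # which avoids the sharp log-zero penalties of single-sample centroids
    init_labels <- with_seed(restart_seeds[s], sample(rep_len(seq_len(k), n)))
    m <- t(vapply(seq_len(k), function(kk) {
      colMeans(b[init_labels == kk, , drop = FALSE])
    }, numeric(ncol(b))))
    labels <- integer(n)
    trace <- numeric(0)
    for (it in seq_len(max_iterations)) {
      scores <- b %*% t(log_clamp(m))         # n x k cross terms
      new_labels <- max.col(scores, ties.method = "first")
      # deterministic empty-cluster repair: reseed at the worst-fitting sample
      empties <- which(tabulate(new_labels, k) == 0)
      if (length(empties)) {
        fit <- scores[cbind(seq_len(n), new_labels)]
        for (kk in empties) {
          sizes <- tabulate(new_labels, k)
          movable <- which(sizes[new_labels] > 1)
          worst <- movable[which.min(fit[movable])]
          new_labels[worst] <- kk
          fit[worst] <- Inf   # a repaired sample is not moved twice
        }
      }
      converged <- it > 1 && all(new_labels == labels)
      labels <- new_labels
      m <- t(vapply(seq_len(k), function(kk) {
        colMeans(b[labels == kk, , drop = FALSE])
      }, numeric(ncol(b))))
      cross <- sum(b * log_clamp(m)[labels, , drop = FALSE]) / n
      trace <- c(trace, mean_h + log(r) + cross)
      if (converged) break
    }
    u <- trace[length(trace)]
    restart_utilities[s] <- u
    if (is.null(best) || u > best$utility + 1e-12) {
      best <- list(labels = labels, utility = u, trace = trace)
    }
  }
  part <- relabel_largest_first(partition(best$labels, bps$sample_ids, k = k))
  structure(list(partition = part, utility = best$utility,
                 utility_trace = best$trace,
                 restart_utilities = restart_utilities),
            class = "ecc_consensus")
}

#' @export
print.ecc_consensus <- function(x, ...) {
  cat(sprintf("entropy consensus: clusters %s, utility %.4f (%d restarts)\n",
              paste(cluster_sizes(x$partition), collapse = "/"),
              x$utility, length(x$restart_utilities)))
  invisible(x)
}

#' Fit entropy-based consensus clustering on one or two omic blocks
#'
#' The end-to-end consensus engine: generates `n_bp` basic partitions per
#' view ([ecc_basic_partitions()]), merges the ensembles, and computes the
#' entropy consensus ([ecc_consensus()]).  The default ensemble size of
#' 15000 per view matches the scale needed for a stable solution on noisy
#' tissue data; pass a smaller `n_bp` for quick runs.
#'
#' @param expr,meth Omics matrices over the same samples; `meth` may be
#'   `NULL` for a single-view fit.
#' @param n_bp Basic partitions per view (default 15000).
#' @param k Number of consensus clusters (default 2).
#' @param bp_k_range,bp_feature_fraction Passed to [ecc_basic_partitions()].
#' @param n_restarts,max_iterations Passed to [ecc_consensus()].
#' @param seed Integer seed (sub-seeds per view are derived from it).
#' @return An object of class `ecc_fit`: list with `partition`, `utility`,
#'   `utility_trace`, `restart_utilities`, `basic_partitions` and the call
#'   parameters.
#' @seealso [snf_fit()] for the network-fusion engine.
#' @export
ecc_fit <- function(expr, meth = NULL, n_bp = 15000, k = 2,
                    bp_k_range = NULL, bp_feature_fraction = 0.05,
                    n_restarts = 5, max_iterations = 100, seed = 1L) {
  if (!is.null(meth) && !identical(colnames(expr), colnames(meth))) {
    stop("expression and methylation must cover identical samples; see align_on_samples()")
  }
  bps <- ecc_basic_partitions(expr, n_bp = n_bp, bp_k_range = bp_k_range,
                              bp_feature_fraction = bp_feature_fraction,
                              seed = seed, view_tag = "expression")
  if (!is.null(meth)) {
    bps_m <- ecc_basic_partitions(meth, n_bp = n_bp, bp_k_range = bp_k_range,
                                  bp_feature_fraction = bp_feature_fraction,
                                  seed = seed + 1L, view_tag = "methylation")
    bps <- merge_basic_partitions(bps, bps_m)
  }
  cons <- ecc_consensus(bps, k = k, n_restarts = n_restarts,
                        max_iterations = max_iterations, seed = seed + 2L)
  structure(list(partition = cons$partition, utility = cons$utility,
                 utility_trace = cons$utility_trace,
                 restart_utilities = cons$restart_utilities,
                 basic_partitions = bps,
                 params = list(n_bp = n_bp, k = k,
                               bp_feature_fraction = bp_feature_fraction,
                               n_restarts = n_restarts, seed = seed)),
            class = "ecc_fit")
}

#' @export
print.ecc_fit <- function(x, ...) {
  cat("Entropy-based consensus clustering fit\n")
  cat(sprintf("  %d basic partitions (%s)\n", ncol(x$basic_partitions$labels),
              paste(sprintf("%s: %d", names(table(x$basic_partitions$view)),
                            table(x$basic_partitions$view)), collapse = ", ")))
  cat(sprintf("  k = %d, cluster sizes: %s, utility %.4f\n", x$params$k,
              paste(cluster_sizes(x$partition), collapse = "/"), x$utility))
  invisible(x)
}

#' @export
summary.ecc_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  restart utilities: %s\n",
              paste(sprintf("%.4f", object$restart_utilities), collapse = " ")))
  cat(sprintf("  iterations to converge: %d\n", length(object$utility_trace)))
  invisible(object)
}

#' @export
plot.ecc_fit <- function(x, ...) {
  plot(seq_along(x$utility_trace), x$utility_trace, type = "b",
       xlab = "iteration", ylab = "mean entropy utility",
       main = "consensus utility trace", ...)
  invisible(x)
}
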