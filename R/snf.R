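#' Standardize features of an omics matrix
#'
#' Centres each feature to mean 0 and scales it to standard deviation 1
#' across samples, using the population SD (denominator `n`); the convention
#' is fixed so that downstream kernel values are exactly reproducible.
#' Zero-variance features cannot be scaled and are dropped with a warning.
#'
#' @param matrix An [omics_matrix] (or plain numeric matrix, features x
#'   samples).
#' @return The standardized matrix of the same class.
#' @export
standardize_features <- function(matrix) {
  x <- unclass(matrix)
  if (ncol(x) < 2) stop("standardization needs at least 2 samples")
  mu <- rowMeans(x)
  sdev <- sqrt(rowMeans((x - mu)^2))   # population SD
  zero <- sdev == 0 | !is.finite(sdev)
  if (any(zero)) {
    warning(sprintf("dropping %d zero-variance feature(s)", sum(zero)))
    x <- x[!zero, , drop = FALSE]
    mu <- mu[!zero]; sdev <- sdev[!zero]
    if (nrow(x) == 0) stop("all features have zero variance")
  }
  z <- (x - mu) / sdev
  if (inherits(matrix, "omics_matrix")) {
    # standardized methylation is no longer a beta value; tag as expression-like
    z <- structure(z, omic_kind = attr(matrix, "omic_kind"),
                   class = c("omics_matrix", "matrix"))
  }
  z
}

# squared Euclidean distances between sample columns
sample_dist2 <- function(x) {
  g <- crossprod(x)                     # samples x samples
  n2 <- diag(g)
  d2 <- outer(n2, rep(1, length(n2))) + outer(rep(1, length(n2)), n2) - 2 * g
  d2[d2 < 0] <- 0
  diag(d2) <- 0
  (d2 + t(d2)) / 2
}

#' Sample affinity matrix from one omic block
#'
#' Converts squared Euclidean distances between sample columns into
#' similarities with the scaled exponential kernel of the network-fusion
#' method: for samples i and j,
#' \deqn{W_{ij} = \exp\!\left(-\frac{d_{ij}}{\alpha\,\varepsilon_{ij}}\right),\quad
#'   \varepsilon_{ij} = \frac{\bar d_i + \bar d_j + d_{ij}}{3},}
#' where \eqn{d_{ij}} is the squared distance and \eqn{\bar d_i} is the mean
#' squared distance from i to its `n_neighbors` nearest samples.  The local
#' bandwidth adapts the kernel to each pair's neighbourhood density.
#'
#' @param matrix An [omics_matrix] or numeric matrix (features x samples),
#'   typically standardized with [standardize_features()].
#' @param n_neighbors Neighbourhood size used for the local bandwidth.
#' @param alpha Kernel scaling parameter (> 0).
#' @return A symmetric positive `n x n` matrix of class `affinity_matrix`
#'   with unit diagonal, rownames/colnames the sample ids.
#' @export
snf_affinity <- function(matrix, n_neighbors = 30, alpha = 0.8) {
  x <- unclass(matrix)
  n <- ncol(x)
  if (n_neighbors >= n) stop("n_neighbors must be smaller than the number of samples")
  if (alpha <= 0) stop("alpha must be positive")
  d2 <- sample_dist2(x)
  if (any(!is.finite(d2))) stop("non-finite distances between samples")
  # mean squared distance to the n_neighbors nearest other samples
  mu <- vapply(seq_len(n), function(i) {
    mean(sort(d2[i, -i])[seq_len(n_neighbors)])
  }, numeric(1))
  eps <- (outer(mu, mu, `+`) + d2) / 3 + .Machine$double.eps
  w <- exp(-d2 / (alpha * eps))
  w <- (w + t(w)) / 2
  dimnames(w) <- dimnames(d2)
  if (!is.null(colnames(x))) rownames(w) <- colnames(w) <- colnames(x)
  structure(w, class = c("affinity_matrix", "matrix"))
}

#' @export
print.affinity_matrix <- function(x, ...) {
  cat(sprintf("affinity matrix over %d samples (off-diagonal range %.3g - %.3g)\n",
              nrow(x), min(x[upper.tri(x)]), max(x[upper.tri(x)])))
  invisible(x)
}

# Full-kernel normalization: off-diagonal mass scaled to 1/2 per row, diagonal
# set to 1/2, so every row sums to 1.  This is the diffusion "status" matrix.
snf_status <- function(w) {
  off <- rowSums(w) - diag(w)
  p <- w / (2 * off)
  diag(p) <- 0.5
  p
}

# Sparse local kernel: each row keeps its n_neighbors largest affinities
# (which include self, since the diagonal is maximal) renormalized to sum 1.
snf_local_kernel <- function(w, n_neighbors) {
  n <- nrow(w)
  s <- matrix(0, n, n, dimnames = dimnames(w))
  for (i in seq_len(n)) {
    idx <- order(w[i, ], decreasing = TRUE)[seq_len(n_neighbors)]
    s[i, idx] <- w[i, idx] / sum(w[i, idx])
  }
  s
}

#' Fuse per-omic affinity networks by iterative cross-diffusion
#'
#' Each view keeps a row-stochastic full status matrix and a sparse local
#' kernel restricted to the `n_neighbors` strongest similarities.  At every
#' iteration each view's status matrix is propagated through its own local
#' kernel applied to the average of the other views' status matrices
#' (`P_v <- S_v (mean of other P) S_v'`), then renormalized and symmetrized.
#' After `iterations` rounds the fused network is the symmetrized average of
#' the final status matrices.  With a single view fusion is a no-op: the
#' normalized status matrix of that view is returned.
#'
#' @param affinities A list of [snf_affinity()] matrices over identical
#'   samples.
#' @param n_neighbors Local-kernel neighbourhood size.
#' @param iterations Number of diffusion rounds.
#' @return A fused `affinity_matrix`.
#' @export
snf_fuse <- function(affinities, n_neighbors = 30, iterations = 15) {
  if (!is.list(affinities) || length(affinities) < 1) {
    stop("need at least one affinity matrix")
  }
  ids <- colnames(affinities[[1]])
  for (w in affinities) {
    if (nrow(w) != nrow(affinities[[1]]) ||
        !identical(colnames(w), ids)) {
      stop("affinity matrices must cover identical samples in the same order")
    }
  }
  if (iterations < 1) stop("iterations must be >= 1")
  m <- length(affinities)
  status <- lapply(affinities, function(w) {
    p <- snf_status(w)
    (p + t(p)) / 2
  })
  if (m == 1) {
    return(structure(status[[1]], class = c("affinity_matrix", "matrix")))
  }
  local <- lapply(affinities, snf_local_kernel, n_neighbors = n_neighbors)
  for (it in seq_len(iterations)) {
    nxt <- vector("list", m)
    for (v in seq_len(m)) {
      others <- Reduce(`+`, status[-v]) / (m - 1)
      nxt[[v]] <- local[[v]] %*% others %*% t(local[[v]])
    }
    status <- lapply(nxt, function(p) {
      p <- snf_status(p)
      (p + t(p)) / 2
    })
  }
  fused <- Reduce(`+`, status) / m
  fused <- (fused + t(fused)) / 2
  dimnames(fused) <- list(ids, ids)
  structure(fused, class = c("affinity_matrix", "matrix"))
}

#' Spectral clustering of an affinity matrix
#'
#' Embeds the samples with the top `k` eigenvectors of the symmetric
#' normalized adjacency \eqn{D^{-1/2} W D^{-1/2}} (equivalently the bottom
#' eigenvectors of the normalized Laplacian), row-normalizes the embedding,
#' and partitions it with seeded k-means using `nstart` internal restarts.
#' With a fixed seed the result is deterministic.  Labels are renumbered so
#' cluster 1 is the largest.
#'
#' @param affinity An `affinity_matrix` (or symmetric positive matrix with
#'   sample dimnames).
#' @param k Number of clusters (>= 2).
#' @param seed Integer seed for the k-means step.
#' @param nstart Internal k-means restarts.
#' @return A [partition].
#' @export
spectral_cluster <- function(affinity, k = 2, seed = 1L, nstart = 10) {
  w <- unclass(affinity)
  n <- nrow(w)
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop("k cannot exceed the number of samples")
  ids <- colnames(w)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(n))
  if (k == n) return(partition(seq_len(n), ids, k = n))
  d <- rowSums(w)
  dm <- 1 / sqrt(pmax(d, .Machine$double.eps))
  a <- t(w * dm) * dm                   # D^-1/2 W D^-1/2
  a <- (a + t(a)) / 2
  u <- eigen(a, symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE]
  rn <- sqrt(rowSums(u^2))
  u <- u / pmax(rn, .Machine$double.eps)
  labels <- with_seed(seed, kmeans(u, centers = k, nstart = nstart,
                                   iter.max = 100)$cluster)
  relabel_largest_first(partition(labels, ids, k = k))
}

# run code under a temporary RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Choose kernel hyperparameters maximizing affinity variance
#'
#' Scores every `(n_neighbors, alpha)` grid point by the mean, over the two
#' omic blocks, of the variance of the off-diagonal affinities, and returns
#' the point with the largest score.  A near-constant affinity matrix carries
#' no contrast between samples, so higher off-diagonal variance indicates a
#' more informative similarity network.  Ties and equal scores resolve to the
#' earliest grid point.
#'
#' @param expr,meth Omics matrices (standardized internally).
#' @param grid Data frame with columns `n_neighbors` and `alpha`.
#' @return A list with `n_neighbors`, `alpha`, `score`, and the scored `grid`.
#' @export
select_snf_hyperparameters <- function(expr, meth, grid) {
  if (!is.data.frame(grid) || !all(c("n_neighbors", "alpha") %in% names(grid)) ||
      nrow(grid) == 0) {
    stop("grid must be a non-empty data frame with columns n_neighbors, alpha")
  }
  zs <- list(standardize_features(expr), standardize_features(meth))
  n <- ncol(zs[[1]])
  score <- rep(NA_real_, nrow(grid))
  for (g in seq_len(nrow(grid))) {
    kn <- grid$n_neighbors[g]
    if (kn >= n || kn < 1 || grid$alpha[g] <= 0) next  # infeasible point
    score[g] <- mean(vapply(zs, function(z) {
      w <- snf_affinity(z, n_neighbors = kn, alpha = grid$alpha[g])
      var(w[upper.tri(w)])
    }, numeric(1)))
  }
  if (all(is.na(score))) stop("no feasible grid point")
  best <- which.max(score)   # first maximum wins
  list(n_neighbors = grid$n_neighbors[best], alpha = grid$alpha[best],
       score = score[best], grid = cbind(grid, score = score))
}

#' Fit similarity network fusion with spectral clustering
#'
#' The end-to-end network-fusion engine: standardizes each omic block, builds
#' per-block affinity networks with the scaled exponential kernel, fuses them
#' by cross-diffusion, and clusters the fused network spectrally into `k`
#' clusters.  Cluster stability is assessed by repeating the seeded spectral
#' step `n_stability_repeats` times with different seeds and recording
#' whether memberships agree across repeats.
#'
#' @param expr,meth Omics matrices over the same samples (features x
#'   samples).  `meth` may be `NULL` for a single-view fit.
#' @param n_neighbors Neighbourhood size (default 30).
#' @param alpha Kernel scaling (default 0.8).
#' @param iterations Diffusion rounds (default 15).
#' @param k Number of clusters (default 2).
#' @param n_stability_repeats Spectral-clustering repeats for the stability
#'   check (default 10).
#' @param seed Integer seed.
#' @return An object of class `snf_fit`: list with `partition`, `fused`
#'   (affinity matrix), `affinities` (per view), `stability`
#'   (`n_repeats`, `all_identical`, `pairwise_nmi_min`), and the call
#'   parameters.
#' @seealso [ecc_fit()] for the consensus-clustering engine.
#' @export
snf_fit <- function(expr, meth = NULL, n_neighbors = 30, alpha = 0.8,
                    iterations = 15, k = 2, n_stability_repeats = 10,
                    seed = 1L) {
  views <- Filter(Negate(is.null), list(expression = expr, methylation = meth))
  if (!is.null(meth) && !identical(colnames(expr), colnames(meth))) {
    stop("expression and methylation must cover identical samples; see align_on_samples()")
  }
  affinities <- lapply(views, function(v) {
    snf_affinity(standardize_features(v), n_neighbors = n_neighbors,
                 alpha = alpha)
  })
  fused <- snf_fuse(affinities, n_neighbors = n_neighbors,
                    iterations = iterations)
  part <- spectral_cluster(fused, k = k, seed = seed)
  reps <- lapply(seq_len(n_stability_repeats), function(r) {
    spectral_cluster(fused, k = k, seed = seed + r)
  })
  same <- vapply(reps, function(p) identical(p$labels, part$labels), logical(1))
  min_nmi <- min(vapply(reps, function(p) nmi(part, p), numeric(1)), 1)
  structure(list(
    partition = part, fused = fused, affinities = affinities,
    stability = list(n_repeats = n_stability_repeats,
                     all_identical = all(same), pairwise_nmi_min = min_nmi),
    params = list(n_neighbors = n_neighbors, alpha = alpha,
                  iterations = iterations, k = k, seed = seed)
  ), class = "snf_fit")
}

#' @export
print.snf_fit <- function(x, ...) {
  cat("Similarity network fusion fit\n")
  cat(sprintf("  views: %s\n", paste(names(x$affinities), collapse = " + ")))
  cat(sprintf("  n_neighbors = %d, alpha = %g, iterations = %d, k = %d\n",
              x$params$n_neighbors, x$params$alpha, x$params$iterations,
              x$params$k))
  cat(sprintf("  cluster sizes: %s\n",
              paste(cluster_sizes(x$partition), collapse = "/")))
  cat(sprintf("  stability: %d repeats, %s (min NMI %.3f)\n",
              x$stability$n_repeats,
              if (x$stability$all_identical) "identical memberships"
              else "memberships varied",
              x$stability$pairwise_nmi_min))
  invisible(x)
}

#' @export
summary.snf_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  fused off-diagonal affinity: mean %.4g, var %.4g\n",
              mean(object$fused[upper.tri(object$fused)]),
              var(object$fused[upper.tri(object$fused)])))
  invisible(object)
}

#' @export
plot.snf_fit <- function(x, ...) {
  ord <- order(x$partition$labels)
  w <- unclass(x$fused)[ord, ord]
  image(seq_len(nrow(w)), seq_len(ncol(w)), w,
        xlab = "samples (ordered by cluster)", ylab = "samples",
        main = "fused similarity network", ...)
  invisible(x)
}
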