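#' Deterministic seed for one cell of the sensitivity grid
#'
#' Every `(threshold, view)` cell of [run_sensitivity()] runs the consensus
#' engine with its own seed derived from the base seed and the cell index,
#' so the effect of feature filtering is isolated from Monte-Carlo noise and
#' any cell can be reproduced standalone.
#'
#' @param seed Base integer seed.
#' @param threshold_index 1-based index of the threshold in the grid.
#' @param view_index 1-based index of the view (1 expression, 2 methylation,
#'   3 merged).
#' @return An integer seed.
#' @export
sensitivity_cell_seed <- function(seed, threshold_index, view_index) {
  as.integer(seed) + 101L * (as.integer(threshold_index) - 1L) +
    7L * (as.integer(view_index) - 1L)
}

#' COPD classification accuracy across association-FDR feature filters
#'
#' Re-runs entropy-based consensus clustering on feature sets filtered at a
#' series of association-FDR thresholds, separately for the expression view,
#' the methylation view and the merged two-view ensemble, and records the
#' case-enrichment classification accuracy of each solution against the
#' phenotype.  A threshold of 1 keeps all features (the genome-wide run).
#' Cells where no feature survives the filter are recorded as missing rather
#' than failing the grid.
#'
#' @param expr,meth Omics matrices over the same samples.
#' @param expr_stats,meth_stats Per-feature association stat tables (e.g.
#'   from [reference_association_table()]) covering the two matrices.
#' @param phenotype Binary labels over the same samples (1 = case).
#' @param thresholds FDR thresholds in (0, 1]; default
#'   `c(0.05, 0.1, 0.25, 0.5, 1)`.
#' @param n_bp Basic partitions per view and cell (default 1000, a
#'   desk-scale grid; raise towards 15000 for the full-scale ensemble).
#' @param k,bp_k_range,bp_feature_fraction,n_restarts Passed to the
#'   consensus engine.
#' @param seed Base seed; per-cell seeds come from [sensitivity_cell_seed()].
#' @return An object of class `accuracy_curve`: data frame with columns
#'   `threshold, view, accuracy, n_features`.
#' @export
run_sensitivity <- function(expr, meth, expr_stats, meth_stats, phenotype,
                            thresholds = c(0.05, 0.1, 0.25, 0.5, 1),
                            n_bp = 1000, k = 2, bp_k_range = NULL,
                            bp_feature_fraction = 0.05, n_restarts = 5,
                            seed = 1L) {
  if (!identical(colnames(expr), colnames(meth))) {
    stop("expression and methylation must cover identical samples")
  }
  if (any(thresholds <= 0 | thresholds > 1)) stop("thresholds must lie in (0,1]")
  y <- as_case_indicator(phenotype)
  views <- c("expression", "methylation", "merged")
  rows <- list()
  for (ti in seq_along(thresholds)) {
    th <- thresholds[ti]
    fe <- tryCatch(filter_by_fdr(expr, expr_stats, th), error = function(e) NULL)
    fm <- tryCatch(filter_by_fdr(meth, meth_stats, th), error = function(e) NULL)
    for (vi in seq_along(views)) {
      v <- views[vi]
      cell_seed <- sensitivity_cell_seed(seed, ti, vi)
      inputs <- switch(v,
                       expression = list(fe, NULL),
                       methylation = list(fm, NULL),
                       merged = list(fe, fm))
      nfeat <- sum(vapply(inputs, function(m) if (is.null(m)) 0L else nrow(m),
                          integer(1)))
      acc <- NA_real_
      missing_input <- (v == "expression" && is.null(fe)) ||
        (v == "methylation" && is.null(fm)) ||
        (v == "merged" && (is.null(fe) || is.null(fm)))
      if (!missing_input) {
        fit <- ecc_fit(inputs[[1]], inputs[[2]], n_bp = n_bp, k = k,
                       bp_k_range = bp_k_range,
                       bp_feature_fraction = bp_feature_fraction,
                       n_restarts = n_restarts, seed = cell_seed)
        acc <- classification_accuracy(fit$partition, y)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        threshold = th, view = v, accuracy = acc,
        n_features = if (missing_input) NA_integer_ else nfeat,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("accuracy_curve", "data.frame")
  attr(out, "seed") <- seed
  out
}

#' Rank views and tabulate accuracy deltas per threshold
#'
#' @param curve An `accuracy_curve` from [run_sensitivity()].
#' @return A data frame with one row per threshold: accuracy per view, the
#'   best view, and the merged-minus-best-single-view delta.
#' @export
summarize_curve <- function(curve) {
  stopifnot(inherits(curve, "accuracy_curve"))
  if (all(is.na(curve$accuracy))) stop("curve has no computed cells")
  rows <- lapply(split(curve, curve$threshold), function(d) {
    acc <- setNames(d$accuracy, d$view)
    get <- function(nm) if (nm %in% names(acc)) acc[[nm]] else NA_real_
    single <- acc[setdiff(names(acc), "merged")]
    best_single <- if (length(single) == 0 || all(is.na(single))) NA_real_
                   else max(single, na.rm = TRUE)
    data.frame(threshold = d$threshold[1],
               expression = get("expression"),
               methylation = get("methylation"),
               merged = get("merged"),
               best_view = d$view[which.max(replace(d$accuracy,
                                                    is.na(d$accuracy), -Inf))],
               merged_minus_best_single =
                 if (is.na(best_single) || is.na(get("merged"))) NA_real_
                 else get("merged") - best_single,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$threshold), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.accuracy_curve <- function(x, ...) {
  cat("classification accuracy by association-FDR filter:\n")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' @export
plot.accuracy_curve <- function(x, ...) {
  d <- as.data.frame(x)
  ths <- sort(unique(d$threshold))
  views <- c("expression", "methylation", "merged")
  acc <- sapply(views, function(v) {
    d$accuracy[match(paste(ths, v), paste(d$threshold, d$view))]
  })
  matplot(seq_along(ths), acc, type = "b", pch = 1:3, lty = 1:3,
          xaxt = "n", xlab = "association FDR threshold",
          ylab = "COPD classification accuracy", ylim = c(0, 1), ...)
  axis(1, at = seq_along(ths), labels = ths)
  legend("bottomleft", legend = views, pch = 1:3, lty = 1:3, bty = "n")
  invisible(x)
}
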