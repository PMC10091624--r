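#' Run the end-to-end analysis pipeline from one structured config
#'
#' Orchestrates the stages simulate -> snf -> ecc -> evaluate -> diffexp ->
#' enrich -> sensitivity in dependency order, writing each stage's outputs
#' under a run directory together with a manifest (config snapshot, seeds,
#' input digests, output paths, package version).  Identical config plus
#' seed reproduces byte-identical outputs.
#'
#' The config is a named list (or path to a YAML file) with elements:
#' \describe{
#'   \item{out_dir}{run directory (required).}
#'   \item{stages}{character vector of stages to run.}
#'   \item{seed}{integer base seed.}
#'   \item{simulate}{[simulation_config()] fields; alternatively
#'     `inputs: list(expression=, methylation=, clinical=)` file paths.}
#'   \item{snf / ecc}{engine parameters ([snf_fit()] / [ecc_fit()]).}
#'   \item{diffexp}{`list(partition = "snf"|"ecc", covariates = ...)`.}
#'   \item{enrich}{`list(gmt = path, fdr = 0.10)` gene-set file and the
#'     significance cutoff applied to the diffexp table.}
#'   \item{sensitivity}{[run_sensitivity()] parameters (`thresholds`,
#'     `n_bp`).}
#' }
#'
#' @param config Named list or YAML file path.
#' @return The run manifest (list), invisibly; also written to
#'   `out_dir/manifest.yaml`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) stop("config needs an 'out_dir'")
  stages <- config$stages %||% c("simulate", "snf", "ecc", "evaluate")
  known <- c("simulate", "snf", "ecc", "evaluate", "diffexp", "enrich",
             "sensitivity")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  seed <- as.integer(config$seed %||% 1L)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  manifest <- list(package = "copdclust",
                   version = as.character(utils::packageVersion("copdclust")),
                   seed = seed, stages = stages, config = config,
                   outputs = list(), inputs = list())
  log_line <- function(...) {
    msg <- sprintf(...)
    message("[copdclust] ", msg)
    cat(format(Sys.time(), "%H:%M:%S "), msg, "\n",
        file = out("run.log"), append = TRUE, sep = "")
  }

  # --- inputs: simulate or load ---------------------------------------
  expr <- meth <- clinical <- NULL
  if ("simulate" %in% stages) {
    sim_args <- config$simulate %||% list()
    sim_args$seed <- sim_args$seed %||% seed
    cohort <- simulate_cohort(do.call(simulation_config, sim_args))
    write_cohort(cohort, config$out_dir)
    expr <- cohort$expression; meth <- cohort$methylation
    clinical <- cohort$clinical
    manifest$outputs$simulate <- out(c("expression.tsv", "methylation.tsv",
                                       "clinical.csv"))
    log_line("simulate: %d samples, %d/%d features", ncol(expr),
             nrow(expr), nrow(meth))
  } else if (!is.null(config$inputs)) {
    expr <- read_omics_matrix(config$inputs$expression, "expression")
    meth <- read_omics_matrix(config$inputs$methylation, "methylation")
    clinical <- read_cohort_table(config$inputs$clinical)
    al <- align_on_samples(list(expr, meth), clinical)
    expr <- al$matrices[[1]]; meth <- al$matrices[[2]]; clinical <- al$clinical
    manifest$inputs <- lapply(config$inputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    })
  }
  need_data <- function(stage) {
    if (is.null(expr) || is.null(clinical)) {
      stop(sprintf("stage '%s' needs data from 'simulate' or config$inputs",
                   stage))
    }
  }

  partitions <- list()
  if ("snf" %in% stages) {
    need_data("snf")
    args <- config$snf %||% list()
    fit <- snf_fit(expr, meth,
                   n_neighbors = args$n_neighbors %||% 30,
                   alpha = args$alpha %||% 0.8,
                   iterations = args$iterations %||% 15,
                   k = args$k %||% 2,
                   n_stability_repeats = args$n_stability_repeats %||% 10,
                   seed = seed)
    partitions$snf <- fit$partition
    write_partition(fit$partition, out("snf_partition.csv"))
    fused <- data.frame(sample_id = rownames(fit$fused), unclass(fit$fused),
                        check.names = FALSE)
    write.table(fused, out("snf_fused_affinity.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    manifest$outputs$snf <- out(c("snf_partition.csv", "snf_fused_affinity.tsv"))
    log_line("snf: clusters %s, stable = %s",
             paste(cluster_sizes(fit$partition), collapse = "/"),
             fit$stability$all_identical)
  }
  if ("ecc" %in% stages) {
    need_data("ecc")
    args <- config$ecc %||% list()
    fit <- ecc_fit(expr, meth,
                   n_bp = args$n_bp %||% 1000,
                   k = args$k %||% 2,
                   bp_feature_fraction = args$bp_feature_fraction %||% 0.05,
                   n_restarts = args$n_restarts %||% 5,
                   seed = seed)
    partitions$ecc <- fit$partition
    write_partition(fit$partition, out("ecc_partition.csv"))
    write.csv(data.frame(iteration = seq_along(fit$utility_trace),
                         utility = fit$utility_trace),
              out("ecc_utility_trace.csv"), row.names = FALSE)
    manifest$outputs$ecc <- out(c("ecc_partition.csv", "ecc_utility_trace.csv"))
    log_line("ecc: clusters %s, utility %.4f",
             paste(cluster_sizes(fit$partition), collapse = "/"), fit$utility)
  }
  if ("evaluate" %in% stages) {
    need_data("evaluate")
    if (length(partitions) == 0) {
      stop("stage 'evaluate' needs a partition from stage 'snf' or 'ecc'")
    }
    for (nm in names(partitions)) {
      cmp <- compare_clusters(clinical, partitions[[nm]])
      write.csv(as.data.frame(cmp), out(sprintf("%s_comparison.csv", nm)),
                row.names = FALSE)
    }
    evalsum <- list()
    if (!is.null(clinical$copd_status)) {
      for (nm in names(partitions)) {
        evalsum[[paste0(nm, "_accuracy")]] <-
          classification_accuracy(partitions[[nm]], clinical$copd_status)
      }
    }
    if (length(partitions) == 2) {
      evalsum$nmi_snf_ecc <- nmi(partitions$snf, partitions$ecc)
      ov <- overlap_table(partitions$snf, partitions$ecc, clinical$copd_status)
      write.csv(as.data.frame(ov$table), out("overlap_counts.csv"),
                row.names = FALSE)
    }
    yaml::write_yaml(evalsum, out("evaluation.yaml"))
    manifest$outputs$evaluate <- out("evaluation.yaml")
    log_line("evaluate: %s",
             paste(names(evalsum), sprintf("%.3f", unlist(evalsum)),
                   sep = " = ", collapse = ", "))
  }
  stat_tab <- NULL
  if ("diffexp" %in% stages) {
    need_data("diffexp")
    args <- config$diffexp %||% list()
    which_p <- args$partition %||%
      (if (length(partitions)) names(partitions)[1] else NULL)
    if (is.null(which_p) || is.null(partitions[[which_p]])) {
      stop("stage 'diffexp' needs a partition from stage 'snf' or 'ecc'")
    }
    stat_tab <- moderated_diffexp(expr, clinical, partitions[[which_p]],
                                  covariates = args$covariates %||%
                                    c("age", "sex", "race", "pack_years"))
    write_stat_table(stat_tab, out("diffexp.csv"))
    # volcano-ready coordinates: effect vs -log10 FDR
    write.csv(data.frame(feature_id = stat_tab$feature_id,
                         logFC = stat_tab$effect,
                         neg_log10_fdr = -log10(pmax(stat_tab$fdr, 1e-300))),
              out("volcano.csv"), row.names = FALSE)
    manifest$outputs$diffexp <- out(c("diffexp.csv", "volcano.csv"))
    log_line("diffexp (%s): %d features at FDR < 0.05, %d with |logFC| > 1",
             which_p, sum(stat_tab$fdr < 0.05), sum(stat_tab$abs_lfc_gt1))
  }
  if ("enrich" %in% stages) {
    if (is.null(stat_tab)) stop("stage 'enrich' needs stage 'diffexp'")
    args <- config$enrich %||% list()
    if (is.null(args$gmt)) stop("stage 'enrich' needs a 'gmt' file in config")
    sets <- read_gmt(args$gmt)
    cutoff <- args$fdr %||% 0.10
    sig <- stat_tab$feature_id[stat_tab$fdr < cutoff]
    if (length(sig) == 0) {
      log_line("enrich: no features at FDR < %g, skipping", cutoff)
    } else {
      enr <- ora(sig, stat_tab$feature_id, sets, id_map = NULL)
      write.csv(enr, out("enrichment.csv"), row.names = FALSE)
      manifest$outputs$enrich <- out("enrichment.csv")
      log_line("enrich: %d/%d sets at FDR < 0.05", sum(enr$fdr < 0.05),
               nrow(enr))
    }
  }
  if ("sensitivity" %in% stages) {
    need_data("sensitivity")
    args <- config$sensitivity %||% list()
    es <- reference_association_table(
      structure(list(expression = expr, methylation = meth,
                     clinical = clinical), class = "synthetic_cohort"),
      "expression")
    ms <- reference_association_table(
      structure(list(expression = expr, methylation = meth,
                     clinical = clinical), class = "synthetic_cohort"),
      "methylation")
    curve <- run_sensitivity(expr, meth, es, ms, clinical$copd_status,
                             thresholds = args$thresholds %||%
                               c(0.05, 0.1, 0.25, 0.5, 1),
                             n_bp = args$n_bp %||% 1000, seed = seed)
    write.csv(as.data.frame(curve), out("sensitivity_curve.csv"),
              row.names = FALSE)
    write.csv(summarize_curve(curve), out("sensitivity_summary.csv"),
              row.names = FALSE)
    manifest$outputs$sensitivity <- out(c("sensitivity_curve.csv",
                                          "sensitivity_summary.csv"))
    log_line("sensitivity: %d cells computed", sum(!is.na(curve$accuracy)))
  }
  yaml::write_yaml(manifest, out("manifest.yaml"))
  invisible(manifest)
}
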