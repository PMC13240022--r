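#' Pipeline configuration
#'
#' Collects every tunable constant of the workflow with the defaults used
#' throughout: 30 embedding neighbours for the integration metrics, a 5%
#' AUC ranking window, z > 1.5 with rank-sum p < 0.05 for state-specific
#' regulons, FDR < 0.05 for fate drivers, 7 regulon modules, and a top-30%
#' CoreScore cut for core regulatory nodes.
#'
#' @param inputs optional named list of input paths for [load_inputs()].
#' @param synthetic optional [synthetic_design()]; when given, inputs are
#'   generated rather than read.
#' @param k_neighbors neighbours for the integration QC metrics.
#' @param aucell_top_fraction ranking-window fraction for activity scoring.
#' @param z_threshold z cut for state-specific regulon selection.
#' @param z_mode "cellwise" or "states" (see [state_mean_zscore()]).
#' @param wilcoxon_alpha rank-sum significance level.
#' @param fdr_threshold fate-driver FDR cut.
#' @param n_modules regulon modules to cut from the CSI clustering.
#' @param core_fraction fraction of network nodes flagged core.
#' @param sqrt_jsd use the `1 - sqrt(JSD)` specificity variant.
#' @param degree_mode CoreScore degree handling (see [core_score()]).
#' @param signature_fate fate whose core TFs form the survival signature.
#' @param signature_genes optional explicit signature gene list (overrides
#'   `signature_fate` derivation).
#' @param outdir output directory (`NULL` = no export).
#' @param seed integer master seed.
#' @return validated `pipeline_config` list.
#' @export
pipeline_config <- function(inputs = NULL, synthetic = NULL,
                            k_neighbors = 30L,
                            aucell_top_fraction = 0.05,
                            z_threshold = 1.5,
                            z_mode = c("cellwise", "states"),
                            wilcoxon_alpha = 0.05,
                            fdr_threshold = 0.05,
                            n_modules = 7L,
                            core_fraction = 0.30,
                            sqrt_jsd = FALSE,
                            degree_mode = c("in_out", "total"),
                            signature_fate = "fate2",
                            signature_genes = NULL,
                            outdir = NULL,
                            seed = 1L) {
  cfg <- list(
    inputs = inputs, synthetic = synthetic,
    k_neighbors = check_count(k_neighbors, "k_neighbors"),
    aucell_top_fraction = check_fraction(aucell_top_fraction,
                                         "aucell_top_fraction"),
    z_threshold = z_threshold,
    z_mode = match.arg(z_mode),
    wilcoxon_alpha = check_fraction(wilcoxon_alpha, "wilcoxon_alpha"),
    fdr_threshold = fdr_threshold,
    n_modules = check_count(n_modules, "n_modules"),
    core_fraction = check_fraction(core_fraction, "core_fraction"),
    sqrt_jsd = isTRUE(sqrt_jsd),
    degree_mode = match.arg(degree_mode),
    signature_fate = signature_fate,
    signature_genes = signature_genes,
    outdir = outdir,
    seed = as.integer(seed)
  )
  if (cfg$aucell_top_fraction <= 0)
    stop_param("aucell_top_fraction", "must be in (0, 1]")
  if (!is.finite(cfg$z_threshold)) stop_param("z_threshold", "must be finite")
  if (!is.finite(cfg$fdr_threshold))
    stop_param("fdr_threshold", "must be finite")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys map to [pipeline_config()] arguments; an `inputs:` block
#' carries file paths and a `synthetic:` block carries
#' [synthetic_design()] arguments.
#'
#' @param path YAML file.
#' @return `pipeline_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synthetic)) y$synthetic <- do.call(synthetic_design,
                                                    y$synthetic)
  do.call(pipeline_config, y)
}

#' Run the full analysis workflow
#'
#' Executes the stages in order: input generation or loading, integration
#' QC metrics, per-cell activity scoring of all regulons, specificity
#' scores and CSI-based module clustering, state-specific regulon
#' selection, fate-driver-intersected network construction with CoreScore
#' hub calling, and (when a cohort is available) signature scoring with
#' survival association. Stage progress and shapes are logged via
#' `message()`; results are exported to `config$outdir` when set.
#'
#' @param config a [pipeline_config()].
#' @return results bundle (list), invisibly when exporting.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, code) {
    message(sprintf("[regfate] stage: %s", name))
    tryCatch(code, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  res <- list(config = config)

  dat <- stage("inputs", {
    if (!is.null(config$synthetic)) {
      d <- config$synthetic
      sc <- generate_single_cell_dataset(d)
      sc$drivers <- generate_fate_drivers(
        sc$truth, sc$regulons,
        overlap_fraction = d$driver_overlap_fraction,
        seed = d$seed + 1L)
      sc$cohort <- {
        sig <- sc$truth$state_specific_regulons[[config$signature_fate]] %||%
          names(sc$regulons)[1:5]
        generate_survival_cohort(400L, sig, beta = 0.6,
                                 seed = d$seed + 2L)
      }
      sc
    } else if (!is.null(config$inputs)) {
      do.call(load_inputs, config$inputs)
    } else stop("no inputs: set 'inputs' or 'synthetic'")
  })
  message(sprintf("[regfate]   expression %d cells x %d genes; %d regulons",
                  nrow(dat$expression), ncol(dat$expression),
                  length(dat$regulons)))

  cells <- dat$cells
  res$cells <- stage("integration_qc", {
    if (all(c("emb1", "emb2") %in% names(cells))) {
      g <- knn_neighbors(as.matrix(cells[, c("emb1", "emb2")]),
                         k = config$k_neighbors)
      cells$batch_mixing <- batch_mixing_score(g, cells$sample)
      cells$tissue_separation <- tissue_separation_score(g, cells$tissue)
    } else message("[regfate]   no embedding columns; QC metrics skipped")
    cells
  })

  activity <- stage("activity_scoring", {
    ranking <- rank_genes_per_cell(dat$expression, seed = config$seed)
    score_gene_sets(ranking, dat$regulons,
                    top_fraction = config$aucell_top_fraction)
  })
  res$activity <- activity

  scoreable <- apply(activity, 2, function(a)
    !anyNA(a) && sum(a) > 0 && stats::var(a) > 0)
  if (any(!scoreable))
    message(sprintf("[regfate]   %d unscoreable/constant regulon column(s) %s",
                    sum(!scoreable),
                    "excluded from specificity and clustering"))
  act_ok <- activity[, scoreable, drop = FALSE]

  res$rss <- stage("regulon_specificity",
                   compute_rss_matrix(act_ok, cells$state,
                                      sqrt_jsd = config$sqrt_jsd))
  res$csi <- stage("csi", compute_csi(act_ok))
  res$modules <- stage("module_clustering",
                       cluster_modules(res$csi,
                                       min(config$n_modules, ncol(act_ok))))

  res$state_calls <- stage("state_regulons",
    identify_state_regulons(act_ok, cells$state,
                            z_threshold = config$z_threshold,
                            alpha = config$wilcoxon_alpha,
                            z_mode = config$z_mode))
  if (!any(res$state_calls$selected))
    warning("no state-specific regulons selected under the configured thresholds")

  if (!is.null(dat$drivers)) {
    res$networks <- stage("fate_networks", {
      cores <- intersect_core_genes(res$state_calls, dat$regulons,
                                    dat$drivers, config$fdr_threshold)
      sel <- res$state_calls[res$state_calls$selected, ]
      nets <- lapply(names(cores), function(f)
        fate_network(cores[[f]], sel$regulon[sel$state == f], dat$regulons,
                     modules = res$modules,
                     core_fraction = config$core_fraction,
                     degree_mode = config$degree_mode))
      names(nets) <- names(cores)
      nets
    })
  } else message("[regfate] stage fate_networks skipped: no driver table")

  if (!is.null(dat$cohort)) {
    stage("clinical_signature", {
      sig_genes <- config$signature_genes
      if (is.null(sig_genes) && !is.null(res$networks)) {
        nw <- res$networks[[config$signature_fate]]
        if (!is.null(nw) && nrow(nw$nodes) > 0)
          sig_genes <- nw$nodes$node[nw$nodes$kind == "TF"]
      }
      if (is.null(sig_genes) || length(sig_genes) == 0) {
        sel <- res$state_calls[res$state_calls$selected, ]
        sig_genes <- sel$regulon[sel$state == config$signature_fate]
      }
      sig_genes <- intersect(sig_genes, rownames(dat$cohort$expression))
      if (length(sig_genes) == 0) {
        message("[regfate]   no signature gene present in cohort; skipped")
      } else {
        sc <- signature_score(dat$cohort$expression, sig_genes)
        surv <- dat$cohort$survival
        qt <- stratify_quartiles(sc)
        q41 <- qt %in% c("Q1", "Q4")
        lr <- logrank_test(surv$time[q41], surv$event[q41],
                           droplevels(qt[q41]))
        zsig <- zscore_pop(sc)
        uni <- cox_ph_fit(surv$time, surv$event,
                          data.frame(signature = zsig))
        multi <- cox_ph_fit(surv$time, surv$event,
                            data.frame(signature = zsig,
                                       stage = factor(surv$stage),
                                       age = surv$age))
        ka <- stage_association(sc, surv$stage)
        res$signature <- list(genes = sig_genes, scores = sc,
                              quartiles = qt, logrank = lr,
                              stage_association = ka)
        res$survival_summary <- rbind(
          data.frame(endpoint = "OS", model = "Univariate", uni),
          data.frame(endpoint = "OS", model = "Multivariate", multi))
      }
      NULL
    })
  } else message("[regfate] stage clinical_signature skipped: no cohort")

  if (!is.null(config$outdir)) {
    stage("export", export_results(res, config$outdir))
    return(invisible(res))
  }
  res
}
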