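# Orchestration: one configuration object drives the full per-region
# analysis (QC -> DMS -> DMR -> modules -> clock -> DE -> network
# integration -> TF regulatory network -> cohort table), with deterministic
# seeding and a JSON run manifest of per-stage counts.

#' Build and validate a run configuration
#'
#' Every threshold is checked against its domain before any computation.
#'
#' @param detp_threshold Detection-p cutoff for QC.
#' @param dms_adj_p Adjusted-p threshold defining DMSs.
#' @param dms_export_p Raw-p threshold for the exported candidate-site table.
#' @param lambda,min_cpgs,dmr_fdr,min_delta_beta DMR-calling parameters
#'   (see [dmr_params()]).
#' @param min_conf Minimum PPI edge confidence.
#' @param percentile Hub-selection percentile.
#' @param enrich_min_size,enrich_fdr Over-representation parameters.
#' @param deg_p DEG export p threshold.
#' @param min_cpm,min_frac Expression filter parameters.
#' @param covariates Sample-sheet columns used as model covariates.
#' @param fem_max_modules,fem_max_size,fem_n_perm Module-search parameters.
#' @param fem_emp_p Permutation-p threshold for modules feeding integration.
#' @param seed Integer seed for all stochastic stages.
#' @return A validated `run_config` list.
#' @export
run_config <- function(detp_threshold = 0.05, dms_adj_p = 0.05,
                       dms_export_p = 5e-4, lambda = 1000, min_cpgs = 2,
                       dmr_fdr = 0.05, min_delta_beta = 0.10,
                       min_conf = 0.7, percentile = 95,
                       enrich_min_size = 5, enrich_fdr = 0.05,
                       deg_p = 0.01, min_cpm = 0.3, min_frac = 0.5,
                       covariates = "age", fem_max_modules = 10,
                       fem_max_size = 100, fem_n_perm = 200,
                       fem_emp_p = 0.05, seed = 1) {
  in01 <- function(x) is.numeric(x) && length(x) == 1 && x > 0 && x < 1
  checks <- list(detp_threshold = in01(detp_threshold),
                 dms_adj_p = in01(dms_adj_p),
                 dms_export_p = in01(dms_export_p),
                 dmr_fdr = in01(dmr_fdr),
                 min_delta_beta = in01(min_delta_beta),
                 min_conf = in01(min_conf),
                 enrich_fdr = in01(enrich_fdr),
                 deg_p = in01(deg_p),
                 min_cpm = min_cpm > 0,
                 min_frac = in01(min_frac),
                 lambda = lambda > 0,
                 percentile = percentile > 0 && percentile < 100,
                 fem_n_perm = fem_n_perm >= 1)
  bad <- names(checks)[!unlist(checks)]
  if (length(bad)) {
    abort(paste("config values out of domain:", paste(bad, collapse = ", ")),
          class = "invalid_config")
  }
  structure(list(
    detp_threshold = detp_threshold, dms_adj_p = dms_adj_p,
    dms_export_p = dms_export_p, lambda = lambda, min_cpgs = min_cpgs,
    dmr_fdr = dmr_fdr, min_delta_beta = min_delta_beta,
    min_conf = min_conf, percentile = percentile,
    enrich_min_size = enrich_min_size, enrich_fdr = enrich_fdr,
    deg_p = deg_p, min_cpm = min_cpm, min_frac = min_frac,
    covariates = covariates, fem_max_modules = fem_max_modules,
    fem_max_size = fem_max_size, fem_n_perm = fem_n_perm,
    fem_emp_p = fem_emp_p, seed = seed), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys match the [run_config()] arguments.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Run the full integrative analysis
#'
#' Executes QC, M-value conversion, per-CpG differential methylation, DMR
#' calling and gene mapping, methylation-module detection on the PPI graph,
#' epigenetic-clock age acceleration, expression filtering and differential
#' expression, cross-source network integration with centralities and hub
#' selection, and the DMR-anchored TF regulatory network. Identical inputs,
#' config and seed give identical outputs.
#'
#' @param inputs Named list as produced by [simulate_study()] (`manifest`,
#'   `sheet`, `beta`, `detp`, `counts`, `ppi`, `clock`, `tf_clusters`,
#'   `tf_targets`; `clock` may be `NULL` to skip the clock stage).
#' @param config A [run_config()].
#' @param out_dir Optional directory: stage outputs are written as TSV and
#'   the run manifest as JSON.
#' @return A list of stage outputs plus `manifest_counts`.
#' @export
run_pipeline <- function(inputs, config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  need <- c("manifest", "sheet", "beta", "detp", "counts", "ppi",
            "tf_clusters", "tf_targets")
  missing_in <- setdiff(need, names(inputs))
  if (length(missing_in)) {
    abort(paste("missing inputs:", paste(missing_in, collapse = ", ")),
          class = "missing_input")
  }
  covars <- intersect(config$covariates, names(inputs$sheet))

  qc <- filter_probes(inputs$beta, inputs$detp, inputs$manifest,
                      detp_threshold = config$detp_threshold)
  m <- beta_to_m(qc$beta)
  dms <- fit_dms(m, qc$beta, inputs$sheet, inputs$manifest,
                 covariates = covars)
  dms_export <- filter(dms, .data$p < config$dms_export_p)
  dmrs <- call_dmrs(dms, dmr_params(
    lambda = config$lambda, min_cpgs = config$min_cpgs,
    site_fdr = config$dms_adj_p, region_fdr = config$dmr_fdr,
    min_delta_beta = config$min_delta_beta))
  dmr_genes <- map_dmrs_to_genes(dmrs, inputs$manifest)

  gstats <- gene_stats(dms, inputs$manifest)
  modules <- detect_modules(gstats, inputs$ppi,
                            max_modules = config$fem_max_modules,
                            max_size = config$fem_max_size,
                            n_perm = config$fem_n_perm,
                            seed = config$seed)
  fem_genes <- unique(unlist(modules$members[modules$emp_p <= config$fem_emp_p]))

  ages <- NULL
  if (!is.null(inputs$clock)) {
    pred <- predict_age(qc$beta, inputs$clock, missing = "mean_impute")
    aa <- age_acceleration(pred, inputs$sheet)
    ages <- list(aa = aa, comparison = compare_groups_aa(aa, inputs$sheet))
  }

  counts_f <- cpm_filter(inputs$counts, inputs$sheet,
                         min_cpm = config$min_cpm,
                         min_frac = config$min_frac)
  de <- simple_de(counts_f, inputs$sheet, covariates = covars)
  degs <- deg_export(de, p_cut = config$deg_p)

  network <- NULL; centralities <- NULL; hubs <- character()
  net_try <- tryCatch(
    build_integrated_network(inputs$ppi, degs$gene, unique(dmr_genes$gene),
                             fem_genes, min_conf = config$min_conf),
    error = function(e) e)
  if (!inherits(net_try, "error")) {
    network <- net_try
    centralities <- select_hubs(compute_centralities(network),
                                percentile = config$percentile)
    hubs <- centralities$node[centralities$selected]
  }

  tf_support <- annotate_dmrs_to_tfs(dmrs, inputs$tf_clusters)
  regnet <- build_regulatory_network(tf_support, inputs$tf_targets, degs)

  cohort <- cohort_table(inputs$sheet,
                         vars = intersect(c("age", "sex"),
                                          names(inputs$sheet)))

  counts_tbl <- tibble(
    stage = c("qc_remaining", "dms_sites", "dms_export", "dmrs",
              "dmr_genes", "modules", "fem_genes", "degs",
              "network_nodes", "hubs", "regnet_edges"),
    n = c(qc$report$remaining, sum(dms$adj_p <= config$dms_adj_p),
          nrow(dms_export), nrow(dmrs), length(unique(dmr_genes$gene)),
          nrow(modules), length(fem_genes), nrow(degs),
          if (is.null(network)) 0L else nrow(network$nodes),
          length(hubs), nrow(regnet)))

  result <- list(qc = qc, dms = dms, dms_export = dms_export, dmrs = dmrs,
                 dmr_genes = dmr_genes, modules = modules,
                 fem_genes = fem_genes, ages = ages, de = de, degs = degs,
                 network = network, centralities = centralities,
                 hubs = hubs, tf_support = tf_support, regnet = regnet,
                 cohort = cohort, manifest_counts = counts_tbl,
                 config = config)
  if (!is.null(out_dir)) write_run_dir(result, out_dir)
  result
}

write_run_dir <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) {
    if (!is.null(x) && is.data.frame(x)) {
      write_table_tsv(x, file.path(out_dir, paste0(name, ".tsv")))
    }
  }
  w(result$dms_export, "dms_candidates")
  w(result$dmrs, "dmrs")
  if (nrow(result$dmrs)) write_dmr_bed(result$dmrs,
                                       file.path(out_dir, "dmrs.bed"))
  w(result$dmr_genes, "dmr_genes")
  w(tidy(result$modules), "modules")
  if (!is.null(result$ages)) {
    w(result$ages$aa, "age_acceleration")
    w(result$ages$comparison, "age_comparison")
  }
  w(result$degs, "degs")
  if (!is.null(result$network)) {
    w(result$network$edges, "network_edges")
    w(result$centralities, "centralities")
  }
  w(tidy(result$regnet), "regulatory_network")
  w(result$cohort, "cohort_table")
  manifest <- list(
    package = "methnet",
    version = as.character(utils::packageVersion("methnet")),
    seed = result$config$seed,
    counts = setNames(as.list(result$manifest_counts$n),
                      result$manifest_counts$stage))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
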