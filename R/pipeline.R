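#' Pipeline configuration
#'
#' Collects the thresholds and switches of the end-to-end analysis. The
#' defaults mirror the printed parameters of the source protocol at full
#' scale (module minimum size 100, scale-free fit target 0.8, seed-gene
#' flagging r > 0.9, top 50 memberships, TF enrichment p < 0.05,
#' eigengene correlation classes at |r| > 0.7, survival clusters > 10
#' patients); `desk_scale = TRUE` switches the module size and top-k to
#' values suited to the bundled synthetic preset (min_size 30,
#' top_k = module size).
#'
#' @param min_size minimum module size.
#' @param soft_power fixed soft power (NULL to select by scale-free fit).
#' @param target_fit scale-free fit target.
#' @param mode network mode, `"signed"` or `"unsigned"`.
#' @param kme_threshold membership threshold of the refinement pass.
#' @param r_emt EMT-module flagging threshold.
#' @param top_k membership genes taken per flagged module.
#' @param p_tf TF enrichment retention threshold.
#' @param r_tf TF classification threshold.
#' @param min_cluster strict minimum PEP cluster size for survival.
#' @param reference_cluster reference PEP cluster for hazard ratios.
#' @param seed RNG seed for the stochastic steps.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(min_size = 100L, soft_power = 6L,
                            target_fit = 0.8,
                            mode = c("signed", "unsigned"),
                            kme_threshold = 0.75,
                            r_emt = 0.9, top_k = 50L,
                            p_tf = 0.05, r_tf = 0.7,
                            min_cluster = 10L,
                            reference_cluster = "h0-8",
                            seed = 1L) {
  structure(list(min_size = check_count(min_size, "min_size"),
                 soft_power = soft_power,
                 target_fit = check_prob(target_fit, "target_fit"),
                 mode = match.arg(mode),
                 kme_threshold = check_prob(kme_threshold, "kme_threshold"),
                 r_emt = check_prob(r_emt, "r_emt"),
                 top_k = check_count(top_k, "top_k"),
                 p_tf = check_prob(p_tf, "p_tf"),
                 r_tf = check_prob(r_tf, "r_tf"),
                 min_cluster = check_count(min_cluster, "min_cluster"),
                 reference_cluster = reference_cluster,
                 seed = check_count(seed, "seed", min = 0L)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes module detection on both time courses, EMT-module flagging and
#' cross-dataset signature extraction, TF regulator inference with hub
#' scoring, PEP staging of the cohort, and survival stratification.
#' Inputs can be supplied as in-memory objects (e.g. from the synthetic
#' generator) or file paths readable by the package's TSV adapters.
#' All numeric outputs are deterministic given the config.
#'
#' @param expr_a,expr_b the two time courses ([ts_matrix()] or TSV paths).
#' @param seed_genes seed EMT gene IDs (vector or file path).
#' @param regnet reference TF-target edge list (data.frame or TSV path);
#'   `NULL` skips the regulator stage.
#' @param cohort gene x sample FPKM matrix (matrix or TSV path); `NULL`
#'   skips staging and survival.
#' @param surv survival records (data.frame or TSV path); `NULL` skips
#'   the survival stage.
#' @param config a [pipeline_config()].
#' @param outdir if non-NULL, write all result tables and a provenance
#'   manifest there.
#' @return List with elements `modules_a`, `modules_b`, `flags_a`,
#'   `flags_b`, `candidates_a`, `candidates_b`, `signature`,
#'   `regulators`, `tf_net`, `hubs`, `pep`, `clusters`, `logrank`, `cox`
#'   (stages that were skipped are NULL).
#' @export
run_pipeline <- function(expr_a, expr_b, seed_genes,
                         regnet = NULL, cohort = NULL, surv = NULL,
                         config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(expr_a)) expr_a <- read_timeseries_tsv(expr_a)
  if (is.character(expr_b)) expr_b <- read_timeseries_tsv(expr_b)
  if (is.character(seed_genes) && length(seed_genes) == 1L &&
      file.exists(seed_genes))
    seed_genes <- read_gene_list(seed_genes)
  if (is.character(regnet)) regnet <- read_edge_list(regnet)
  if (is.character(cohort)) cohort <- read_cohort_tsv(cohort)
  if (is.character(surv)) surv <- read_survival_tsv(surv)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  fit_a <- stage("modules_a", coexpression_modules(
    expr_a, min_size = config$min_size, mode = config$mode,
    soft_power = config$soft_power, target_fit = config$target_fit,
    kme_threshold = config$kme_threshold))
  fit_b <- stage("modules_b", coexpression_modules(
    expr_b, min_size = config$min_size, mode = config$mode,
    soft_power = config$soft_power, target_fit = config$target_fit,
    kme_threshold = config$kme_threshold))

  sig <- stage("signature", {
    shared <- intersect(rownames(expr_a), rownames(expr_b))
    mem_a <- module_membership(expr_a[shared, ], fit_a$eigengenes)
    mem_b <- module_membership(expr_b[shared, ], fit_b$eigengenes)
    seeds_a <- intersect(seed_genes, rownames(expr_a))
    seeds_b <- intersect(seed_genes, rownames(expr_b))
    flags_a <- flag_emt_modules(expr_a[seeds_a, ], fit_a$eigengenes,
                                r_threshold = config$r_emt)
    flags_b <- flag_emt_modules(expr_b[seeds_b, ], fit_b$eigengenes,
                                r_threshold = config$r_emt)
    cand_a <- top_membership_genes(mem_a, flags_a, k = config$top_k)
    cand_b <- top_membership_genes(mem_b, flags_b, k = config$top_k)
    list(flags_a = flags_a, flags_b = flags_b,
         cand_a = cand_a, cand_b = cand_b,
         signature = intersect_signature(cand_a, cand_b))
  })

  regulators <- tf_net <- hubs <- NULL
  if (!is.null(regnet)) {
    regulators <- stage("regnet", module_regulators(
      fit_a$partition, fit_a$eigengenes, regnet, expr_a,
      p_threshold = config$p_tf, r_threshold = config$r_tf))
    if (nrow(regulators) > 0) {
      tf_net <- tf_subnetwork(regulators, regnet)
      hubs <- if (nrow(tf_net$edges) > 0) hub_scores(tf_net)
              else suppressWarnings(hub_scores(tf_net))
    }
  }

  pep <- clusters <- lr <- cox <- NULL
  if (!is.null(cohort)) {
    pep <- stage("staging", {
      sig_genes <- sig$signature$gene
      assign_pep(cohort, expr_a[intersect(sig_genes, rownames(expr_a)), ])
    })
    if (!is.null(surv)) {
      clusters <- stage("survival", filter_major_clusters(
        pep, surv, min_n = config$min_cluster,
        reference = config$reference_cluster))
      lr <- logrank_test(clusters)
      ref <- if (config$reference_cluster %in% clusters$group)
        config$reference_cluster else names(sort(table(clusters$group)))[1]
      cox <- cox_hazard_ratios(clusters, reference = ref)
    }
  }

  result <- list(modules_a = fit_a, modules_b = fit_b,
                 flags_a = sig$flags_a, flags_b = sig$flags_b,
                 candidates_a = sig$cand_a, candidates_b = sig$cand_b,
                 signature = sig$signature,
                 regulators = regulators, tf_net = tf_net, hubs = hubs,
                 pep = pep, clusters = clusters, logrank = lr, cox = cox,
                 config = config)
  if (!is.null(outdir)) write_run_artifacts(result, outdir)
  result
}

write_run_artifacts <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    name
  }
  files <- character(0)
  for (ds in c("a", "b")) {
    fit <- result[[paste0("modules_", ds)]]
    files <- c(files, wt(data.frame(gene = names(fit$partition$assignment),
                                    module = fit$partition$assignment),
                         sprintf("modules_%s.tsv", ds)))
    eg <- fit$eigengenes
    files <- c(files, wt(data.frame(module = rownames(eg$eigengenes),
                                    eg$eigengenes, check.names = FALSE),
                         sprintf("eigengenes_%s.tsv", ds)))
    files <- c(files, wt(result[[paste0("flags_", ds)]],
                         sprintf("emt_flags_%s.tsv", ds)))
  }
  files <- c(files, wt(result$signature, "signature.tsv"))
  if (!is.null(result$regulators))
    files <- c(files, wt(result$regulators, "regulators.tsv"))
  if (!is.null(result$hubs))
    files <- c(files, wt(data.frame(node = names(result$hubs),
                                    hub_score = result$hubs), "hub_scores.tsv"))
  if (!is.null(result$pep))
    files <- c(files, wt(result$pep, "pep.tsv"))
  if (!is.null(result$logrank)) {
    jsonlite::write_json(
      list(logrank = result$logrank[c("statistic", "df", "p_value")],
           cox = result$cox),
      file.path(outdir, "survival_tests.json"), auto_unbox = TRUE, digits = NA)
    files <- c(files, "survival_tests.json")
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("emtdyn")),
    config = unclass(result$config),
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(outdir, files))), files)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Generate the bundled synthetic inputs and write them as TSV
#'
#' Convenience wrapper running the three generators under one config and
#' writing every pipeline input (two time courses, seed gene list,
#' reference network, cohort matrix, survival records, ground truth) to a
#' directory, so the full pipeline can be exercised from files alone.
#'
#' @param cfg a [sim_config()].
#' @param outdir output directory.
#' @return `outdir`, invisibly; side effect: files written.
#' @export
simulate_inputs <- function(cfg = sim_config(), outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_timeseries_pair(cfg)
  regnet <- generate_reference_regnet(cfg, sim$truth)
  cohort <- generate_patient_cohort(cfg, sim$truth, sim$expr_a)
  write_timeseries_tsv(sim$expr_a, file.path(outdir, "timeseries_a.tsv"))
  write_timeseries_tsv(sim$expr_b, file.path(outdir, "timeseries_b.tsv"))
  writeLines(sim$truth$seed_emt_genes, file.path(outdir, "seed_genes.txt"))
  write_edge_list(regnet, file.path(outdir, "regnet.tsv"))
  write_cohort_tsv(cohort$expr, file.path(outdir, "cohort.tsv"))
  write_survival_tsv(cohort$survival, file.path(outdir, "survival.tsv"))
  utils::write.table(
    data.frame(gene = names(sim$truth$gene_module),
               module = sim$truth$gene_module),
    file.path(outdir, "truth_gene_module.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = names(cohort$patient_stage),
               stage_index = cohort$patient_stage,
               stage_hours = stages(sim$expr_a)[cohort$patient_stage]),
    file.path(outdir, "truth_patient_stage.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}
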