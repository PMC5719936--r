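#' Simulation configuration with planted ground truth
#'
#' Defines the study conditions for the bundled generator: a pair of EMT
#' time courses over two stage grids (emulating the H358 and A549
#' TGFbeta-induction designs), a reference TF-target network with planted
#' per-module regulators, and a bulk cohort whose samples are noisy copies
#' of time-course stages with stage-dependent survival hazards.
#'
#' Modules are assigned one of the four canonical temporal archetypes
#' (see [archetype_profile()]); when several modules share an archetype
#' class they receive alternating orientation, i.e. each temporal wave has
#' an up-regulated and a down-regulated gene program, as observed for
#' cell-cycle (down) versus immune (up) programs in EMT.
#'
#' @param n_modules number of planted co-expression modules.
#' @param module_size genes per module.
#' @param n_background_genes unstructured genes (pure noise profiles).
#' @param archetype_ids archetype class per module (values 1-4, recycled
#'   pattern by default).
#' @param archetype_signs orientation (+1/-1) per module; default
#'   alternates between repeats of the same class.
#' @param stage_grid_a,stage_grid_b ordered stage times in hours for the
#'   two datasets.
#' @param noise_sd i.i.d. expression noise SD, relative to the unit
#'   archetype amplitude.
#' @param n_tfs total transcription factors; the first `n_modules` are
#'   planted regulators (one per module), the rest decoys.
#' @param targets_per_tf reference-network targets drawn per TF.
#' @param bg_edge_prob probability of a spurious background edge per
#'   (TF, gene) pair.
#' @param tf_tf_edge_prob probability that one TF targets another in the
#'   reference network (regulators regulating each other), per ordered
#'   TF pair.
#' @param n_seed_genes size of the seed EMT gene list, drawn evenly from
#'   the planted modules.
#' @param n_patients cohort size.
#' @param patient_noise_sd per-gene noise SD added to the planted stage
#'   profile on log2 scale.
#' @param patient_stages hours (subset of `stage_grid_a`) patients are
#'   planted at. The default `c(0, 16, 72, 168)` uses stages whose
#'   signature profiles are mutually distinguishable: all archetypes are
#'   flat across 0-8 h (the epithelial plateau the PEP reference cluster
#'   pools, represented by 0 h) and 16 h and 24 h share one profile
#'   (represented by 16 h).
#' @param log_offset constant added to log2 expression before
#'   exponentiating to the FPKM-like scale (default 5, i.e. FPKM ~ 32).
#' @param baseline_hazard exponential event rate per month at the
#'   reference stage.
#' @param stage_loghr log hazard ratio per stage of `stage_grid_a`
#'   (later EMT stages default to higher hazard).
#' @param censor_max independent uniform censoring horizon in months.
#' @param seed integer seed controlling every generator draw.
#' @return A `sim_config` list with validated fields plus the derived
#'   `n_genes = n_modules * module_size + n_background_genes`.
#' @examples
#' cfg <- sim_config(n_modules = 4, module_size = 30,
#'                   n_background_genes = 60, seed = 7)
#' cfg$n_genes
#' @export
sim_config <- function(n_modules = 8L,
                       module_size = 120L,
                       n_background_genes = 240L,
                       archetype_ids = rep(1:4, length.out = n_modules),
                       archetype_signs = NULL,
                       stage_grid_a = c(0, 1, 2, 4, 6, 8, 16, 24, 72, 168),
                       stage_grid_b = c(0, 6, 12, 24, 36, 48, 72, 96),
                       noise_sd = 0.3,
                       n_tfs = 16L,
                       targets_per_tf = 60L,
                       bg_edge_prob = 0.01,
                       tf_tf_edge_prob = 0.15,
                       n_seed_genes = 5L * n_modules,
                       n_patients = 300L,
                       patient_noise_sd = 0.5,
                       patient_stages = c(0, 16, 72, 168),
                       log_offset = 5,
                       baseline_hazard = 0.02,
                       stage_loghr = NULL,
                       censor_max = 120,
                       seed = 1L) {
  n_modules <- check_count(n_modules, "n_modules")
  module_size <- check_count(module_size, "module_size")
  n_background_genes <- check_count(n_background_genes, "n_background_genes", min = 0L)
  if (length(archetype_ids) != n_modules)
    abort_field("archetype_ids", "needs one archetype per module")
  if (!all(archetype_ids %in% seq_along(archetype_names())))
    abort_field("archetype_ids", "archetypes are numbered 1-4")
  if (is.null(archetype_signs)) {
    # alternate orientation within repeats of the same archetype class
    archetype_signs <- integer(n_modules)
    for (a in unique(archetype_ids)) {
      idx <- which(archetype_ids == a)
      archetype_signs[idx] <- (-1L)^(seq_along(idx) - 1L)
    }
  }
  if (length(archetype_signs) != n_modules || !all(archetype_signs %in% c(-1, 1)))
    abort_field("archetype_signs", "one value in {-1, +1} per module")
  stage_grid_a <- check_stage_grid(stage_grid_a, "stage_grid_a")
  stage_grid_b <- check_stage_grid(stage_grid_b, "stage_grid_b")
  noise_sd <- check_scale(noise_sd, "noise_sd")
  n_tfs <- check_count(n_tfs, "n_tfs", min = 0L)
  targets_per_tf <- check_count(targets_per_tf, "targets_per_tf")
  if (targets_per_tf > module_size)
    abort_field("targets_per_tf", "cannot exceed module_size")
  bg_edge_prob <- check_prob(bg_edge_prob, "bg_edge_prob")
  tf_tf_edge_prob <- check_prob(tf_tf_edge_prob, "tf_tf_edge_prob")
  n_seed_genes <- check_count(n_seed_genes, "n_seed_genes")
  if (n_seed_genes > n_modules * module_size)
    abort_field("n_seed_genes", "cannot exceed the number of module genes")
  n_patients <- check_count(n_patients, "n_patients")
  patient_noise_sd <- check_scale(patient_noise_sd, "patient_noise_sd")
  if (!all(patient_stages %in% stage_grid_a))
    abort_field("patient_stages", "must be a subset of stage_grid_a")
  if (is.null(stage_loghr)) {
    hr <- c(1, 1.25, 1.5, 2, 3)
    bin <- findInterval(stage_grid_a, c(0, 16, 24, 72, 168))
    stage_loghr <- log(hr[bin])
  }
  if (length(stage_loghr) != length(stage_grid_a) || anyNA(stage_loghr))
    abort_field("stage_loghr", "needs one finite value per stage of stage_grid_a")
  baseline_hazard <- check_scale(baseline_hazard, "baseline_hazard")
  if (baseline_hazard <= 0) abort_field("baseline_hazard", "must be positive")
  censor_max <- check_scale(censor_max, "censor_max")
  if (censor_max <= 0) abort_field("censor_max", "must be positive")
  seed <- check_count(seed, "seed", min = 0L)

  structure(list(
    n_modules = n_modules, module_size = module_size,
    n_background_genes = n_background_genes,
    n_genes = n_modules * module_size + n_background_genes,
    archetype_ids = as.integer(archetype_ids),
    archetype_signs = as.integer(archetype_signs),
    stage_grid_a = stage_grid_a, stage_grid_b = stage_grid_b,
    noise_sd = noise_sd,
    n_tfs = n_tfs, targets_per_tf = targets_per_tf,
    bg_edge_prob = bg_edge_prob,
    tf_tf_edge_prob = tf_tf_edge_prob,
    n_seed_genes = n_seed_genes,
    n_patients = n_patients, patient_noise_sd = patient_noise_sd,
    patient_stages = as.numeric(patient_stages),
    log_offset = as.numeric(log_offset),
    baseline_hazard = baseline_hazard,
    stage_loghr = as.numeric(stage_loghr),
    censor_max = censor_max,
    seed = seed
  ), class = "sim_config")
}

gene_ids <- function(cfg) {
  w <- max(4L, nchar(as.character(cfg$n_genes)))
  sprintf(paste0("G%0", w, "d"), seq_len(cfg$n_genes))
}

tf_ids <- function(cfg) sprintf("TF%02d", seq_len(cfg$n_tfs))

#' Planted temporal profile of each module on a stage grid
#'
#' @param cfg a [sim_config()].
#' @param hours stage grid to evaluate on.
#' @return module x stage matrix of signed archetype values.
#' @export
planted_profiles <- function(cfg, hours) {
  p <- vapply(seq_len(cfg$n_modules), function(m) {
    cfg$archetype_signs[m] * archetype_profile(cfg$archetype_ids[m], hours)
  }, numeric(length(hours)))
  t(p)
}

#' Generate the paired EMT time courses with ground truth
#'
#' Produces two log-scale gene x stage matrices over the two configured
#' stage grids, sharing gene IDs. Each module gene is its module's signed
#' archetype profile plus i.i.d. Gaussian noise; background genes are pure
#' unit-variance noise. Transcription-factor rows are appended: planted
#' regulators co-express with their module, decoys are noise.
#'
#' @param cfg a [sim_config()].
#' @return List with `expr_a`, `expr_b` ([ts_matrix()]) and `truth`, a list
#'   carrying `gene_module` (gene -> module label or "background"),
#'   `module_archetype`, `module_sign`, per-grid planted profiles,
#'   `tf_module` (NA for decoys) and `seed_emt_genes`.
#' @examples
#' sim <- generate_timeseries_pair(sim_config(n_modules = 2,
#'   module_size = 10, n_background_genes = 5, n_tfs = 3,
#'   targets_per_tf = 5, n_seed_genes = 4, seed = 1))
#' table(sim$truth$gene_module)
#' @export
generate_timeseries_pair <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  genes <- gene_ids(cfg)
  tfs <- tf_ids(cfg)
  labels <- paste0("M", seq_len(cfg$n_modules))
  gene_module <- c(rep(labels, each = cfg$module_size),
                   rep("background", cfg$n_background_genes))
  names(gene_module) <- genes

  prof_a <- planted_profiles(cfg, cfg$stage_grid_a)
  prof_b <- planted_profiles(cfg, cfg$stage_grid_b)
  rownames(prof_a) <- rownames(prof_b) <- labels

  build <- function(prof, hours) {
    n_stage <- length(hours)
    vals <- matrix(0, cfg$n_genes + cfg$n_tfs, n_stage,
                   dimnames = list(c(genes, tfs), NULL))
    for (m in seq_len(cfg$n_modules)) {
      rows <- which(gene_module == labels[m])
      vals[rows, ] <- matrix(prof[m, ], length(rows), n_stage, byrow = TRUE) +
        matrix(stats::rnorm(length(rows) * n_stage, sd = cfg$noise_sd),
               length(rows), n_stage)
    }
    bg <- which(gene_module == "background")
    vals[bg, ] <- stats::rnorm(length(bg) * n_stage)
    for (tf in seq_len(cfg$n_tfs)) {
      row <- cfg$n_genes + tf
      if (tf <= cfg$n_modules) {
        vals[row, ] <- prof[tf, ] + stats::rnorm(n_stage, sd = cfg$noise_sd)
      } else {
        vals[row, ] <- stats::rnorm(n_stage)
      }
    }
    ts_matrix(vals, hours)
  }

  seeds <- with_seed(derive_seed(cfg$seed, 1L), {
    expr_a <- build(prof_a, cfg$stage_grid_a)
    expr_b <- build(prof_b, cfg$stage_grid_b)
    # seed EMT genes: drawn evenly across modules
    per_mod <- diff(round(seq(0, cfg$n_seed_genes, length.out = cfg$n_modules + 1)))
    seed_genes <- unlist(lapply(seq_len(cfg$n_modules), function(m) {
      sample(genes[gene_module == labels[m]], per_mod[m])
    }))
    list(expr_a = expr_a, expr_b = expr_b, seed_genes = sort(seed_genes))
  })

  tf_module <- c(labels[seq_len(min(cfg$n_modules, cfg$n_tfs))],
                 rep(NA_character_, max(0L, cfg$n_tfs - cfg$n_modules)))
  names(tf_module) <- tfs

  truth <- list(
    gene_module = gene_module,
    module_archetype = stats::setNames(cfg$archetype_ids, labels),
    module_sign = stats::setNames(cfg$archetype_signs, labels),
    module_profile_a = prof_a,
    module_profile_b = prof_b,
    tf_module = tf_module,
    seed_emt_genes = seeds$seed_genes
  )
  list(expr_a = seeds$expr_a, expr_b = seeds$expr_b, truth = truth)
}

#' Generate the reference TF-target regulatory network
#'
#' Planted TFs draw `targets_per_tf` targets from their assigned module;
#' decoy TFs draw the same number uniformly from all genes. Spurious
#' background edges are added independently with `bg_edge_prob`. The result
#' is a directed edge list with no self-loops and no duplicates.
#'
#' @param cfg a [sim_config()].
#' @param truth ground truth from [generate_timeseries_pair()] under the
#'   same config.
#' @return data.frame with columns `tf`, `target`.
#' @export
generate_reference_regnet <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$targets_per_tf > cfg$module_size)
    abort_field("targets_per_tf", "cannot exceed module_size")
  genes <- names(truth$gene_module)
  tfs <- names(truth$tf_module)
  with_seed(derive_seed(cfg$seed, 2L), {
    edges <- lapply(tfs, function(tf) {
      mod <- truth$tf_module[[tf]]
      pool <- if (is.na(mod)) genes else genes[truth$gene_module == mod]
      tgt <- sample(pool, cfg$targets_per_tf)
      if (cfg$bg_edge_prob > 0) {
        extra <- genes[stats::runif(length(genes)) < cfg$bg_edge_prob]
        tgt <- union(tgt, extra)
      }
      if (cfg$tf_tf_edge_prob > 0) {
        others <- setdiff(tfs, tf)
        tgt <- union(tgt, others[stats::runif(length(others)) < cfg$tf_tf_edge_prob])
      }
      data.frame(tf = tf, target = tgt, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, edges)
    out <- out[out$tf != out$target, ]
    out <- out[!duplicated(out), ]
    rownames(out) <- NULL
    out
  })
}

#' Generate a bulk patient cohort with recoverable stage identity
#'
#' Each patient is planted at one of the configured stages of the first
#' time course. Genes belonging to EMT wave programs (module genes and
#' planted TFs) take that stage's column value plus i.i.d. noise;
#' background genes and decoy TFs are drawn independently per patient
#' (their variation across a cohort reflects factors unrelated to EMT
#' stage). Log2 values are shifted by `log_offset` and exponentiated to
#' an FPKM-like nonnegative scale. Survival time is exponential with
#' hazard `baseline_hazard * exp(stage_loghr[stage])` under independent
#' uniform censoring on `[0, censor_max]` months.
#'
#' @param cfg a [sim_config()].
#' @param truth ground truth from [generate_timeseries_pair()].
#' @param stages_expr the time-series matrix whose columns define the
#'   stage profiles (normally `expr_a`).
#' @return List with `expr` (gene x sample FPKM matrix), `survival`
#'   (data.frame: sample, time_months, event) and `patient_stage`
#'   (named stage index into the stage grid of `stages_expr`).
#' @export
generate_patient_cohort <- function(cfg, truth, stages_expr) {
  stopifnot(inherits(cfg, "sim_config"), inherits(stages_expr, "ts_matrix"))
  grid <- stages(stages_expr)
  if (length(grid) == 0L) abort_field("stages_expr", "empty stage grid")
  if (length(cfg$stage_loghr) != length(grid))
    abort_field("stage_loghr", "needs one entry per stage of the stage grid")
  stage_pool <- match(cfg$patient_stages, grid)
  if (anyNA(stage_pool))
    abort_field("patient_stages", "must all lie on the stage grid")
  samples <- sprintf("P%04d", seq_len(cfg$n_patients))
  staged <- c(names(truth$gene_module)[truth$gene_module != "background"],
              names(truth$tf_module)[!is.na(truth$tf_module)])
  staged <- intersect(rownames(stages_expr), staged)
  unstaged <- setdiff(rownames(stages_expr), staged)
  with_seed(derive_seed(cfg$seed, 3L), {
    idx <- sample(stage_pool, cfg$n_patients, replace = TRUE)
    base <- unclass(stages_expr)[, idx, drop = FALSE]
    logexpr <- base +
      matrix(stats::rnorm(length(base), sd = cfg$patient_noise_sd),
             nrow(base), ncol(base)) + cfg$log_offset
    if (length(unstaged) > 0)
      logexpr[unstaged, ] <- matrix(
        stats::rnorm(length(unstaged) * cfg$n_patients),
        length(unstaged), cfg$n_patients) + cfg$log_offset
    expr <- 2^logexpr
    colnames(expr) <- samples
    rate <- cfg$baseline_hazard * exp(cfg$stage_loghr[idx])
    t_event <- stats::rexp(cfg$n_patients, rate = rate)
    t_cens <- stats::runif(cfg$n_patients, 0, cfg$censor_max)
    surv <- data.frame(
      sample = samples,
      time_months = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens),
      stringsAsFactors = FALSE
    )
    list(expr = expr, survival = surv,
         patient_stage = stats::setNames(idx, samples))
  })
}
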