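sig_fixture <- function(seed = 2) {
  cfg <- sim_config(seed = seed)
  sim <- generate_timeseries_pair(cfg)
  fit_a <- coexpression_modules(sim$expr_a, min_size = 30)
  fit_b <- coexpression_modules(sim$expr_b, min_size = 30)
  list(cfg = cfg, sim = sim, fit_a = fit_a, fit_b = fit_b)
}

fx <- sig_fixture()

test_that("membership equals the per-pair Pearson oracle", {
  x <- fx$sim$expr_a
  eig <- fx$fit_a$eigengenes
  mem <- module_membership(x, eig)
  set.seed(1)
  for (g in sample(rownames(x), 10)) for (m in rownames(eig$eigengenes)) {
    expect_equal(mem[g, m],
                 pearson_hand(unclass(x)[g, ], eig$eigengenes[m, ]),
                 tolerance = 1e-12)
  }
  # a gene equal to a rescaled eigengene has membership 1; negated, -1
  e1 <- eig$eigengenes[1, ]
  probe <- ts_matrix(rbind(up = 3 * e1 + 2, down = -e1), stages(x))
  memp <- module_membership(probe, eig)
  expect_equal(unname(memp["up", 1]), 1, tolerance = 1e-12)
  expect_equal(unname(memp["down", 1]), -1, tolerance = 1e-12)
})

test_that("stage-grid mismatch is rejected", {
  expect_error(module_membership(fx$sim$expr_b, fx$fit_a$eigengenes), "stage")
})

test_that("EMT flagging uses a strict signed threshold", {
  x <- fx$sim$expr_a
  eig <- fx$fit_a$eigengenes
  e1 <- eig$eigengenes[1, ]
  # construct seed profiles with exact correlations 1, 0, and 0.9 to e1
  c1 <- e1 - mean(e1)
  o <- e1[c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9)]
  oc <- o - mean(o)
  res <- oc - c1 * sum(oc * c1) / sum(c1^2)
  mix <- 0.9 * c1 / sqrt(sum(c1^2)) + sqrt(1 - 0.81) * res / sqrt(sum(res^2))
  seeds <- ts_matrix(rbind(s_exact = e1, s_ortho = res, s_090 = mix),
                     stages(x))
  flags <- flag_emt_modules(seeds, eig, r_threshold = 0.9)
  expect_true(flags$flag[flags$module == "M1"])
  expect_equal(flags$best_seed[flags$module == "M1"], "s_exact")
  # only the seed with r = 1 can flag M1; r = 0.9 exactly must NOT flag
  seeds2 <- ts_matrix(rbind(s_090 = mix), stages(x))
  r_check <- stats::cor(as.numeric(mix), e1)
  expect_equal(r_check, 0.9, tolerance = 1e-12)
  flags2 <- flag_emt_modules(seeds2, eig, r_threshold = 0.9)
  expect_false(flags2$flag[flags2$module == "M1"])
  expect_error(flag_emt_modules(x[character(0), ], eig), "seed")
})

test_that("raising the flagging threshold never flags more modules", {
  seeds <- fx$sim$truth$seed_emt_genes
  seed_expr <- fx$sim$expr_a[seeds, ]
  n_flagged <- vapply(c(0.5, 0.7, 0.9, 0.99), function(th)
    sum(flag_emt_modules(seed_expr, fx$fit_a$eigengenes, th)$flag),
    numeric(1))
  expect_true(all(diff(n_flagged) <= 0))
})

test_that("top-membership selection matches a full sort and breaks ties by ID", {
  mem <- matrix(c(0.9, 0.8, 0.8, 0.5, 0.2), ncol = 1,
                dimnames = list(c("gB", "gC", "gA", "gD", "gE"), "M1"))
  flags <- data.frame(module = "M1", flag = TRUE)
  top <- top_membership_genes(mem, flags, k = 2)
  expect_setequal(top$gene, c("gB", "gA"))  # gA beats gC at the 0.8 tie
  # k larger than the module yields all genes
  top_all <- top_membership_genes(mem, flags, k = 50)
  expect_setequal(top_all$gene, rownames(mem))
  # brute-force oracle on real data
  x <- fx$sim$expr_a
  memr <- module_membership(x, fx$fit_a$eigengenes)
  flags_r <- data.frame(module = "M2", flag = TRUE)
  top_r <- top_membership_genes(memr, flags_r, k = 25)
  ord <- order(-memr[, "M2"], rownames(memr))
  expect_setequal(top_r$gene, rownames(memr)[ord[1:25]])
})

test_that("raising k never shrinks the candidate set", {
  mem <- module_membership(fx$sim$expr_a, fx$fit_a$eigengenes)
  seed_expr <- fx$sim$expr_a[fx$sim$truth$seed_emt_genes, ]
  flags <- flag_emt_modules(seed_expr, fx$fit_a$eigengenes)
  sizes <- vapply(c(10, 30, 60, 120), function(k)
    nrow(top_membership_genes(mem, flags, k = k)), numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("no flagged modules yields an empty set with a warning", {
  mem <- module_membership(fx$sim$expr_a, fx$fit_a$eigengenes)
  flags <- data.frame(module = colnames(mem),
                      flag = FALSE)
  expect_warning(top <- top_membership_genes(mem, flags), "no flagged")
  expect_identical(nrow(top), 0L)
})

test_that("signature intersection is symmetric and warns when empty", {
  a <- data.frame(gene = c("g1", "g2", "g3"), module = "M1",
                  kme = c(0.9, 0.8, 0.7), rank = 1:3)
  b <- data.frame(gene = c("g2", "g3", "g4"), module = "M2",
                  kme = c(0.95, 0.85, 0.75), rank = 1:3)
  ab <- intersect_signature(a, b)
  ba <- intersect_signature(b, a)
  expect_identical(ab$gene, c("g2", "g3"))
  expect_identical(ab$gene, ba$gene)
  expect_identical(ab$kme_a, ba$kme_b)
  disjoint <- data.frame(gene = "g9", module = "M3", kme = 0.9, rank = 1L)
  expect_warning(empty <- intersect_signature(a, disjoint), "empty")
  expect_identical(nrow(empty), 0L)
  same <- intersect_signature(a, a)
  expect_identical(same$gene, sort(a$gene))
})

test_that("cross-dataset signature recovers the planted shared dynamic modules", {
  sim <- fx$sim
  shared <- intersect(rownames(sim$expr_a), rownames(sim$expr_b))
  mem_a <- module_membership(sim$expr_a[shared, ], fx$fit_a$eigengenes)
  mem_b <- module_membership(sim$expr_b[shared, ], fx$fit_b$eigengenes)
  seeds <- sim$truth$seed_emt_genes
  flags_a <- flag_emt_modules(sim$expr_a[seeds, ], fx$fit_a$eigengenes)
  flags_b <- flag_emt_modules(sim$expr_b[seeds, ], fx$fit_b$eigengenes)
  k <- fx$cfg$module_size
  sig <- intersect_signature(top_membership_genes(mem_a, flags_a, k = k),
                             top_membership_genes(mem_b, flags_b, k = k))
  gm <- sim$truth$gene_module
  # shared dynamic modules: waves detectable on both grids (late wave is
  # flat on the shorter grid by construction)
  shared_cls <- match(c("wave_early", "wave_mid", "wave_transient"),
                      archetype_names())
  planted <- names(gm)[gm != "background" &
                         sim$truth$module_archetype[gm] %in% shared_cls]
  recall <- mean(planted %in% sig$gene)
  contamination <- mean(gm[intersect(sig$gene, names(gm))] == "background")
  expect_gte(recall, 0.8)
  expect_lte(contamination, 0.1)
})

test_that("own-module membership beats other modules for planted genes", {
  mem <- module_membership(fx$sim$expr_a, fx$fit_a$eigengenes)
  gm <- fx$sim$truth$gene_module
  asg <- fx$fit_a$partition$assignment
  # map detected labels to planted modules by majority
  det <- setdiff(unique(asg), "unassigned")
  ok <- 0; tot <- 0
  for (m in det) {
    members <- intersect(names(asg)[asg == m], names(gm))
    planted <- names(sort(table(gm[members]), decreasing = TRUE))[1]
    if (planted == "background") next
    genes <- names(gm)[gm == planted]
    best <- colnames(mem)[max.col(mem[genes, , drop = FALSE])]
    ok <- ok + sum(best == m); tot <- tot + length(genes)
  }
  expect_gte(ok / tot, 0.95)
})

test_that("temporal grouping separates planted patterns and is deterministic", {
  hours <- c(0, 1, 2, 4, 6, 8, 16, 24, 72, 168)
  prof <- vapply(1:4, function(a) archetype_profile(a, hours),
                 numeric(length(hours)))
  m <- t(prof)[rep(1:4, each = 10), ]
  rownames(m) <- sprintf("g%02d", 1:40)
  x <- ts_matrix(m, hours)
  g1 <- temporal_groups(x, k = 4, seed = 7)
  expect_equal(ari(g1$group, rep(1:4, each = 10)), 1)
  g2 <- temporal_groups(x, k = 4, seed = 7)
  expect_identical(g1, g2)
  gk1 <- temporal_groups(x, k = 1, seed = 7)
  expect_true(all(gk1$group == 1L))
  expect_error(temporal_groups(x, k = 41, seed = 1), "k")
})

test_that("correlation contrast matches the ECDF oracle and detects planted signal", {
  # KS statistic equals the max CDF gap on explicit small lists
  r1 <- c(0.1, 0.4, 0.5, 0.7, 0.9)
  r2 <- c(0.2, 0.3, 0.35, 0.6, 0.65)
  expect_equal(suppressWarnings(stats::ks.test(r1, r2))$statistic[[1]],
               ks_stat_hand(r1, r2))
  # planted: set genes correlated with the covariate, others not
  hits <- vapply(1:60, function(s) {
    res <- with_seed_test(s, {
      n <- 200
      cov <- rnorm(n)
      set_expr <- t(sapply(1:30, function(i) 0.8 * cov + 0.6 * rnorm(n)))
      other_expr <- matrix(rnorm(60 * n), 60, n)
      cohort <- 2^rbind(set_expr, other_expr)
      rownames(cohort) <- sprintf("g%03d", 1:90)
      gene_set_correlation_contrast(cohort, cov, sprintf("g%03d", 1:30))
    })
    res$t_p < 1e-4
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("correlation contrast is null-calibrated when no signal is planted", {
  tstats <- vapply(1:100, function(s) {
    with_seed_test(s, {
      n <- 60
      cohort <- 2^matrix(rnorm(50 * n), 50, n,
                         dimnames = list(sprintf("g%02d", 1:50), NULL))
      gene_set_correlation_contrast(cohort, rnorm(n),
                                    sprintf("g%02d", 1:20))$t_stat
    })
  }, numeric(1))
  expect_lt(abs(mean(tstats)), 0.3)
  expect_error(gene_set_correlation_contrast(
    2^matrix(rnorm(20), 2, 10, dimnames = list(c("a", "b"), NULL)),
    rnorm(10), c("a", "b")), "complement")
})
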