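stage_fixture <- function(seed = 3, n_patients = 200, patient_noise_sd = 0.5) {
  cfg <- sim_config(seed = seed, n_patients = n_patients,
                    patient_noise_sd = patient_noise_sd)
  sim <- generate_timeseries_pair(cfg)
  coh <- generate_patient_cohort(cfg, sim$truth, sim$expr_a)
  gm <- sim$truth$gene_module
  shared_cls <- match(c("wave_early", "wave_mid", "wave_transient"),
                      archetype_names())
  sig_genes <- names(gm)[gm != "background" &
                           sim$truth$module_archetype[gm] %in% shared_cls]
  list(cfg = cfg, sim = sim, coh = coh, sig_genes = sig_genes,
       stages_expr = sim$expr_a[sig_genes, ])
}

fxs <- stage_fixture()

test_that("a sample equal to a stage column gets that PEP with r = 1", {
  S <- fxs$stages_expr
  hrs <- stages(S)
  # 2^(x+5) - 1 makes log2(FPKM + 1) exactly affine in the stage profile
  cohort <- 2^(unclass(S)[, c(which(hrs == 72), which(hrs == 16))] + 5) - 1
  colnames(cohort) <- c("p72", "p16")
  pep <- assign_pep(cohort, S)
  expect_equal(pep$pep_hours, c(72, 16))
  expect_equal(pep$r_max, c(1, 1), tolerance = 1e-12)
})

test_that("ties between identical stage profiles resolve to the earliest stage", {
  prof <- c(1, 2, 3, 5, 4, 2, 0, 1, 3, 2)
  vals <- cbind(prof, prof, rev(prof), prof + rnorm(10, sd = 2))
  rownames(vals) <- sprintf("g%02d", 1:10)
  S <- ts_matrix(vals, stages = c(0, 8, 24, 72))
  cohort <- matrix(2^(prof + 5) - 1, ncol = 1,
                   dimnames = list(rownames(S), "p1"))
  pep <- assign_pep(cohort, S)
  expect_equal(pep$pep_hours, 0)
  expect_equal(pep$r_h0, pep$r_h8, tolerance = 1e-14)
  expect_equal(pep$r_max, 1, tolerance = 1e-12)
})

test_that("staging is invariant to per-sample affine transforms of expression", {
  S <- fxs$stages_expr
  cohort <- fxs$coh$expr[rownames(S), 1:20]
  pep1 <- assign_pep(cohort, S, log_transform = FALSE)
  scaled <- sweep(sweep(cohort, 2, runif(20, 0.5, 2), "*"), 2,
                  runif(20, 1, 10), "+")
  pep2 <- assign_pep(scaled, S, log_transform = FALSE)
  expect_identical(pep1$pep_hours, pep2$pep_hours)
  expect_equal(pep1$r_max, pep2$r_max, tolerance = 1e-12)
})

test_that("planted stages are recovered for most patients", {
  pep <- assign_pep(fxs$coh$expr, fxs$stages_expr)
  planted <- stages(fxs$sim$expr_a)[fxs$coh$patient_stage]
  expect_gte(mean(pep$pep_hours == planted), 0.9)
})

test_that("PEP recovery degrades monotonically with patient noise", {
  acc <- vapply(c(1, 2.5, 5), function(ns) {
    fx <- stage_fixture(seed = 9, n_patients = 120, patient_noise_sd = ns)
    pep <- assign_pep(fx$coh$expr, fx$stages_expr)
    planted <- stages(fx$sim$expr_a)[fx$coh$patient_stage]
    mean(pep$pep_hours == planted)
  }, numeric(1))
  expect_true(all(diff(acc) <= 0))
  expect_gt(acc[1], acc[3])
})

test_that("insufficient shared genes and flat samples are handled", {
  S <- fxs$stages_expr
  expect_error(assign_pep(fxs$coh$expr[1:2, ], S), "2 signature genes")
  flat <- matrix(1, nrow(S), 2,
                 dimnames = list(rownames(S), c("s1", "s2")))
  expect_warning(pep <- assign_pep(flat, S), "variance")
  expect_true(all(is.na(pep$pep_hours)))
})

test_that("patient PCA separates constructed clusters and matches dense SVD", {
  set.seed(11)
  n <- 40
  base <- matrix(rnorm(20 * n, sd = 0.1), 20, n,
                 dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:n)))
  base[1, 21:40] <- base[1, 21:40] + 10
  cohort <- 2^base
  pc <- patient_pca(cohort, rownames(base))
  expect_gt(pc$explained_variance[1], 0.9)
  expect_true(all(pc$coords[1:20, 1] < 0) || all(pc$coords[1:20, 1] > 0))
  expect_true(max(pc$coords[1:20, 1]) < min(pc$coords[21:40, 1]) ||
                min(pc$coords[1:20, 1]) > max(pc$coords[21:40, 1]))
  # oracle: centered SVD reproduces the coordinates up to sign
  X <- t(log2(cohort + 1))
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc)
  for (j in 1:2)
    expect_equal(abs(unname(pc$coords[, j])), abs(sv$u[, j] * sv$d[j]),
                 tolerance = 1e-10)
  # duplicated samples land on identical coordinates
  dup <- cohort[, c(1, 1, 2)]
  colnames(dup) <- c("a", "b", "c")
  pcd <- patient_pca(dup, rownames(base))
  expect_equal(pcd$coords["a", ], pcd$coords["b", ], tolerance = 1e-12)
  expect_error(patient_pca(cohort, "g01"), "gene_set")
})

test_that("silhouette values match the all-pairs oracle", {
  # two tight far-apart clusters
  X <- rbind(matrix(rnorm(20, sd = 0.1), 10, 2),
             matrix(rnorm(20, sd = 0.1) + 10, 10, 2))
  labels <- rep(c("a", "b"), each = 10)
  cohort <- 2^t(X)
  rownames(cohort) <- c("g1", "g2")
  colnames(cohort) <- sprintf("s%02d", 1:20)
  rep <- silhouette_compare(cohort, labels, list(set = c("g1", "g2")),
                            log_transform = TRUE)
  oracle <- silhouette_hand(log2(2^X + 1), labels)
  expect_equal(unname(rep$values$set), oracle, tolerance = 1e-12)
  expect_gt(rep$means["set"], 0.8)
  # a point exactly equidistant between its own and another cluster: s = 0
  Y <- rbind(c(0, 0), c(2, 0), c(1, 0))
  laby <- c("a", "b", "a")
  expect_equal(silhouette_hand(Y, laby)[3], 0)
  cohorty <- 2^t(Y) - 1  # log2(x+1) recovers Y exactly
  rownames(cohorty) <- c("g1", "g2"); colnames(cohorty) <- c("s1", "s2", "s3")
  repy <- silhouette_compare(cohorty, laby, list(set = c("g1", "g2")))
  expect_equal(unname(repy$values$set[3]), 0, tolerance = 1e-12)
})

test_that("shuffled labels drive the mean silhouette to zero", {
  fx <- fxs
  pep <- assign_pep(fx$coh$expr[, 1:80], fx$stages_expr)
  means <- vapply(1:200, function(s) {
    lab <- with_seed_test(s, sample(pep$pep_hours))
    mean(silhouette_compare(fx$coh$expr[, 1:80], lab,
                            list(sig = fx$sig_genes))$values$sig)
  }, numeric(1))
  # high-dimensional Euclidean silhouettes carry a small positive bias
  # under random labels; "approximately zero" here means well below the
  # planted-signature signal (~0.4)
  expect_lt(abs(mean(means)), 0.06)
})

test_that("single-cluster labelings are rejected", {
  expect_error(silhouette_compare(fxs$coh$expr[, 1:10], rep("a", 10),
                                  list(s = fxs$sig_genes)), "2 clusters")
})

test_that("the planted signature clusters patients better than random genes", {
  fx <- fxs
  pep <- assign_pep(fx$coh$expr, fx$stages_expr)
  wins <- vapply(1:30, function(s) {
    rnd <- with_seed_test(s, sample(rownames(fx$coh$expr),
                                    length(fx$sig_genes)))
    rep <- silhouette_compare(fx$coh$expr, pep$pep_hours,
                              list(sig = fx$sig_genes, rnd = rnd))
    rep$means["sig"] > rep$means["rnd"]
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("PEP hour pooling follows the period bins", {
  expect_identical(pep_clusters(c(0, 4, 8, 16, 24, 72, 168, 500)),
                   c("h0-8", "h0-8", "h0-8", "h16-24", "h16-24",
                     "h72", "h168", "h>168"))
  expect_error(pep_clusters(1, breaks = c(8, 24), labels = c("a", "b")),
               "labels")
})
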