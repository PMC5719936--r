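#' Module membership (kME) matrix
#'
#' Pearson correlation between every gene's temporal profile and every
#' module eigengene. High membership marks the genes that follow a
#' module's dynamic pattern most closely.
#'
#' @param x a [ts_matrix()].
#' @param eig an [eigengene_set()] computed on the same stage grid.
#' @return gene x module matrix of correlations in `[-1, 1]`.
#' @export
module_membership <- function(x, eig) {
  stopifnot(inherits(x, "ts_matrix"), inherits(eig, "eigengene_set"))
  if (!isTRUE(all.equal(stages(x), eig$stages)))
    abort_field("eig", "stage grid does not match the expression matrix")
  kme <- stats::cor(t(unclass(x)), t(eig$eigengenes))
  rownames(kme) <- rownames(x)
  kme
}

#' Flag EMT modules against a seed gene list
#'
#' A module is an EMT module when its eigengene correlates r >
#' `r_threshold` (strict) with at least one seed EMT gene's expression
#' profile. By default the correlation is signed; `absolute = TRUE`
#' also admits anti-correlated seeds.
#'
#' @param seed_expr a [ts_matrix()] restricted to the seed EMT genes.
#' @param eig an [eigengene_set()] on the same stage grid.
#' @param r_threshold flagging threshold (default 0.9).
#' @param absolute use `|r|` instead of signed r.
#' @return data.frame with one row per module: `module`, `flag`,
#'   `best_seed`, `best_r`.
#' @export
flag_emt_modules <- function(seed_expr, eig, r_threshold = 0.9,
                             absolute = FALSE) {
  stopifnot(inherits(seed_expr, "ts_matrix"))
  if (nrow(seed_expr) == 0L) abort_field("seed_expr", "empty seed gene list")
  kme <- module_membership(seed_expr, eig)
  score <- if (absolute) abs(kme) else kme
  best <- apply(score, 2L, which.max)
  best_r <- score[cbind(best, seq_len(ncol(score)))]
  data.frame(module = colnames(kme),
             flag = best_r > r_threshold,
             best_seed = rownames(kme)[best],
             best_r = best_r,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Top-membership genes of the flagged modules
#'
#' For each flagged module, the `k` genes with the largest (signed)
#' membership; ties at the cutoff are broken by lexicographic gene ID;
#' modules with fewer than `k` genes contribute all members. The result is
#' the union across flagged modules, with each gene annotated by its
#' best-membership flagged module.
#'
#' @param mem membership matrix from [module_membership()].
#' @param flags data.frame from [flag_emt_modules()].
#' @param k genes to take per module (full-scale default 50).
#' @param absolute rank by `|kME|` instead of signed kME.
#' @return data.frame: `gene`, `module`, `kme`, `rank` (rank within the
#'   reported module), sorted by gene ID.
#' @export
top_membership_genes <- function(mem, flags, k = 50L, absolute = FALSE) {
  k <- check_count(k, "k")
  flagged <- flags$module[flags$flag]
  if (length(flagged) == 0L) {
    warning("no flagged modules; empty candidate set")
    return(data.frame(gene = character(0), module = character(0),
                      kme = numeric(0), rank = integer(0)))
  }
  score <- if (absolute) abs(mem) else mem
  per_module <- lapply(flagged, function(m) {
    ord <- order(-score[, m], rownames(mem))
    take <- ord[seq_len(min(k, nrow(mem)))]
    data.frame(gene = rownames(mem)[take], module = m,
               kme = mem[take, m], rank = seq_along(take),
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, per_module)
  # a gene selected by several flagged modules keeps its best-membership entry
  all <- all[order(-abs(all$kme)), ]
  all <- all[!duplicated(all$gene), ]
  all <- all[order(all$gene), ]
  rownames(all) <- NULL
  all
}

#' Cross-dataset EMT-dynamic signature
#'
#' Intersects the top-membership candidate sets of the two datasets: the
#' signature keeps the genes that display high membership in an EMT module
#' of *both* cell lines, with per-dataset provenance. Symmetric in its
#' arguments.
#'
#' @param cand_a,cand_b data.frames from [top_membership_genes()] for the
#'   two datasets.
#' @return data.frame sorted by gene ID: `gene`, `module_a`, `kme_a`,
#'   `rank_a`, `module_b`, `kme_b`, `rank_b`. Warns when empty.
#' @export
intersect_signature <- function(cand_a, cand_b) {
  shared <- intersect(cand_a$gene, cand_b$gene)
  if (length(shared) == 0L) warning("empty cross-dataset signature")
  a <- cand_a[match(shared, cand_a$gene), ]
  b <- cand_b[match(shared, cand_b$gene), ]
  out <- data.frame(gene = shared,
                    module_a = a$module, kme_a = a$kme, rank_a = a$rank,
                    module_b = b$module, kme_b = b$kme, rank_b = b$rank,
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene), ]
  rownames(out) <- NULL
  out
}

#' Temporal pattern groups of a gene set
#'
#' PCA of the per-gene standardized profiles (genes as observations)
#' followed by K-means with `k` centers on the first two principal
#' components, with multiple restarts keeping the best inertia. Mirrors
#' the grouping of a seed gene set into temporal pattern classes.
#'
#' @param x a [ts_matrix()] restricted to the gene set of interest.
#' @param k number of groups (default 4).
#' @param seed RNG seed for the K-means restarts.
#' @param nstart K-means restarts (default 10).
#' @return data.frame: `gene`, `PC1`, `PC2`, `group` (integer in 1..k).
#' @export
temporal_groups <- function(x, k = 4L, seed = 1L, nstart = 10L) {
  stopifnot(inherits(x, "ts_matrix"))
  k <- check_count(k, "k")
  if (k > nrow(x)) abort_field("k", "more groups than genes")
  z <- t(scale(t(unclass(x))))
  z[is.nan(z)] <- 0
  pc <- stats::prcomp(z, center = TRUE, scale. = FALSE)
  coords <- pc$x[, 1:2, drop = FALSE]
  km <- with_seed(seed, stats::kmeans(coords, centers = k, nstart = nstart))
  # relabel groups deterministically: by the smallest gene ID they contain
  first <- vapply(seq_len(k), function(g) min(rownames(x)[km$cluster == g]),
                  character(1))
  relab <- rank(first)
  data.frame(gene = rownames(x), PC1 = coords[, 1], PC2 = coords[, 2],
             group = as.integer(relab[km$cluster]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Contrast per-gene covariate correlations between a gene set and the rest
#'
#' Correlates every gene's cohort expression with a per-sample covariate
#' (e.g. tumor purity), then compares the correlation distributions of the
#' gene set against its complement with a Welch t-test and a two-sample
#' Kolmogorov-Smirnov test.
#'
#' @param cohort gene x sample nonnegative expression matrix.
#' @param covariate numeric vector, one value per sample.
#' @param set_genes gene IDs forming the set of interest.
#' @param log_transform correlate on `log2(x + 1)` (default); `FALSE`
#'   correlates the raw values.
#' @return List: `r_set`, `r_other` (per-gene correlations), `t_stat`,
#'   `t_p`, `ks_stat`, `ks_p`.
#' @export
gene_set_correlation_contrast <- function(cohort, covariate, set_genes,
                                          log_transform = TRUE) {
  if (length(covariate) != ncol(cohort))
    abort_field("covariate", "length must equal the number of samples")
  set_genes <- intersect(set_genes, rownames(cohort))
  other <- setdiff(rownames(cohort), set_genes)
  if (length(other) == 0L) abort_field("set_genes", "complement is empty")
  vals <- if (log_transform) log2(cohort + 1) else cohort
  r <- as.numeric(stats::cor(t(vals), covariate))
  names(r) <- rownames(cohort)
  r_set <- r[set_genes]
  r_other <- r[other]
  tt <- stats::t.test(r_set, r_other)
  ks <- suppressWarnings(stats::ks.test(r_set, r_other))
  list(r_set = r_set, r_other = r_other,
       t_stat = unname(tt$statistic), t_p = tt$p.value,
       ks_stat = unname(ks$statistic), ks_p = ks$p.value)
}
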