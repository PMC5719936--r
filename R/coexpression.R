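#' Gene-gene Pearson correlation matrix
#'
#' Edge weights of the co-expression network: Pearson correlation of the
#' time-series profiles of every gene pair.
#'
#' @param x a [ts_matrix()] (genes x stages, log scale).
#' @return Symmetric gene x gene matrix with unit diagonal.
#' @export
correlation_matrix <- function(x) {
  stopifnot(inherits(x, "ts_matrix"))
  v <- apply(unclass(x), 1L, stats::var)
  if (any(v <= 0)) {
    bad <- rownames(x)[v <= 0]
    stop(sprintf("zero-variance gene(s): %s; filter with filter_invariant_genes()",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  r <- stats::cor(t(unclass(x)))
  diag(r) <- 1
  r
}

#' Soft-threshold adjacency
#'
#' Raises correlations to the power `beta`. In `unsigned` mode the weight is
#' `|r|^beta` (anti-correlated genes are as connected as correlated ones);
#' in `signed` mode it is `((1 + r)/2)^beta`, which sends r = -1 to 0.
#'
#' @param corr correlation matrix from [correlation_matrix()].
#' @param beta integer soft power, >= 1.
#' @param mode `"signed"` (default) or `"unsigned"`.
#' @return Adjacency matrix in `[0, 1]` with zero diagonal.
#' @export
adjacency <- function(corr, beta, mode = c("signed", "unsigned")) {
  mode <- match.arg(mode)
  beta <- check_count(beta, "beta")
  a <- if (mode == "unsigned") abs(corr)^beta else ((1 + corr) / 2)^beta
  diag(a) <- 0
  a
}

#' Choose the soft power by scale-free topology fit
#'
#' For each candidate power the connectivity `k_i` is the row sum of the
#' soft-threshold adjacency. The scale-free fit is the squared correlation
#' between `log10 p(k)` and `log10 k` over connectivity bins (empty bins
#' dropped). The chosen power is the smallest candidate whose fit exceeds
#' `target_fit`; if none does, the best-fitting candidate is returned with
#' a warning flag.
#'
#' @param corr correlation matrix.
#' @param powers integer candidates (default 1-12).
#' @param target_fit required fit (default 0.8).
#' @param mode network mode, see [adjacency()].
#' @param n_bins connectivity bins for the degree distribution.
#' @return List of class `soft_power_report`: `candidate_powers`, `fit_r2`,
#'   `mean_connectivity`, `chosen_power`, `target_fit`, `warning_flag`.
#' @export
pick_soft_power <- function(corr, powers = 1:12, target_fit = 0.8,
                            mode = c("signed", "unsigned"), n_bins = 10L) {
  mode <- match.arg(mode)
  if (length(powers) == 0L) abort_field("powers", "must be nonempty")
  fits <- numeric(length(powers))
  meank <- numeric(length(powers))
  for (i in seq_along(powers)) {
    k <- rowSums(adjacency(corr, powers[i], mode))
    meank[i] <- mean(k)
    fits[i] <- scale_free_fit(k, n_bins)
  }
  off <- corr[upper.tri(corr)]
  if (all(abs(off - 1) < 1e-12))
    stop("all genes identical: degenerate connectivity", call. = FALSE)
  ok <- which(!is.na(fits) & fits >= target_fit)
  warn <- length(ok) == 0L
  chosen <- if (!warn) powers[min(ok)]
            else if (all(is.na(fits))) powers[1]
            else powers[which.max(fits)]
  if (warn)
    warning(sprintf("no candidate power reaches scale-free fit %.2f; falling back to power %d",
                    target_fit, chosen))
  structure(list(candidate_powers = powers, fit_r2 = fits,
                 mean_connectivity = meank, chosen_power = chosen,
                 target_fit = target_fit, warning_flag = warn),
            class = "soft_power_report")
}

# R^2 of the log-log degree distribution regression; NA when degenerate.
scale_free_fit <- function(k, n_bins = 10L) {
  k <- k[k > 0]
  if (length(k) < 2L || stats::sd(k) == 0) return(NA_real_)
  breaks <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, breaks, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  kmid <- tapply(k, bin, mean)
  keep <- !is.na(freq) & freq > 0
  if (sum(keep) < 3L) return(NA_real_)
  stats::cor(log10(freq[keep]), log10(kmid[keep]))^2
}

#' Topological overlap similarity
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' unit diagonal: two genes are similar when they share neighbors, not
#' merely when directly connected.
#'
#' @param adj adjacency from [adjacency()] (symmetric, zero diagonal,
#'   entries in `[0, 1]`).
#' @return Symmetric similarity matrix in `[0, 1]` with unit diagonal.
#' @export
tom_similarity <- function(adj) {
  if (!isSymmetric(unname(adj)) || any(diag(adj) != 0) ||
      any(adj < 0) || any(adj > 1))
    abort_field("adj", "must be symmetric with zero diagonal and entries in [0,1]")
  k <- rowSums(adj)
  shared <- adj %*% adj
  denom <- outer(k, k, pmin) + 1 - adj
  tom <- (shared + adj) / denom
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2   # symmetrize away numerical asymmetry
  tom
}

#' Detect co-expression modules from topological overlap
#'
#' Average-linkage hierarchical clustering on dissimilarity `1 - TOM`,
#' cut at a constant height. The height is chosen deterministically among
#' the tree's merge heights not exceeding `max_height` as the largest one
#' maximizing the number of clusters of at least `min_size`; smaller
#' clusters are left "unassigned". The cap excludes the top of the tree,
#' where unrelated genes coalesce into one undifferentiated cluster (pure
#' noise merges there), mirroring the static-cut convention of weighted
#' co-expression analysis. Module labels are `"M1", "M2", ...` by
#' decreasing size, ties broken by the lexicographically smallest member
#' gene ID.
#'
#' @param tom similarity from [tom_similarity()].
#' @param min_size minimum module size (full-scale default 100; synthetic
#'   presets use 30).
#' @param max_height largest admissible cut height on the `1 - TOM`
#'   dissimilarity scale (default 0.9).
#' @return List of class `module_partition`: `assignment` (named gene ->
#'   label or "unassigned"), `min_size`, `cut_height`, `tree`.
#' @export
detect_modules <- function(tom, min_size = 100L, max_height = 0.9) {
  min_size <- check_count(min_size, "min_size")
  genes <- rownames(tom)
  n <- nrow(tom)
  if (n < min_size) {
    warning("fewer genes than min_size; all genes unassigned")
    return(structure(list(
      assignment = stats::setNames(rep("unassigned", n), genes),
      min_size = min_size, cut_height = NA_real_, tree = NULL),
      class = "module_partition"))
  }
  d <- stats::as.dist(1 - tom)
  tree <- stats::hclust(d, method = "average")
  heights <- unique(tree$height)
  heights <- heights[heights <= max_height]
  assignment <- rep("unassigned", n)
  names(assignment) <- genes
  if (length(heights) == 0L)
    return(structure(list(assignment = assignment, min_size = min_size,
                          cut_height = NA_real_, tree = tree),
                     class = "module_partition"))
  n_big <- vapply(heights, function(h) {
    sum(table(stats::cutree(tree, h = h)) >= min_size)
  }, integer(1))
  best <- max(n_big)
  cut_height <- if (best == 0L) min(heights) else max(heights[n_big == best])
  cl <- stats::cutree(tree, h = cut_height)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_size]
  if (length(keep) > 0L) {
    # order modules by decreasing size, ties by smallest member gene ID
    first_gene <- vapply(keep, function(k) min(genes[cl == as.integer(k)]),
                         character(1))
    ord <- keep[order(-as.integer(sizes[keep]), first_gene)]
    for (i in seq_along(ord)) {
      assignment[cl == as.integer(ord[i])] <- paste0("M", i)
    }
  }
  structure(list(assignment = assignment, min_size = min_size,
                 cut_height = cut_height, tree = tree),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  tab <- table(x$assignment)
  cat(sprintf("module_partition: %d modules, %d/%d genes assigned (min_size %d)\n",
              sum(names(tab) != "unassigned"),
              sum(tab[names(tab) != "unassigned"]), length(x$assignment),
              x$min_size))
  invisible(x)
}

#' Module eigengene (first principal component of the module)
#'
#' Member genes are standardized across stages, and the eigengene is the
#' first right-singular vector of the member x stage matrix (unit L2
#' norm), sign-oriented so that its correlation with the mean member
#' profile is nonnegative. The summary captures the module's dominant
#' temporal pattern.
#'
#' @param x a [ts_matrix()].
#' @param members gene IDs belonging to the module.
#' @return List: `eigengene` (vector over stages), `explained_variance`
#'   (fraction in `[0, 1]`), `single_gene` flag.
#' @export
module_eigengene <- function(x, members) {
  stopifnot(inherits(x, "ts_matrix"))
  if (length(members) == 0L) abort_field("members", "must be nonempty")
  missing <- setdiff(members, rownames(x))
  if (length(missing) > 0L)
    abort_field("members", paste("not in matrix:",
                                 paste(utils::head(missing, 5), collapse = ", ")))
  m <- unclass(x)[members, , drop = FALSE]
  z <- t(scale(t(m)))   # per-gene standardization across stages
  if (length(members) == 1L) {
    e <- as.numeric(z) / sqrt(sum(z^2))
    return(list(eigengene = e, explained_variance = 1, single_gene = TRUE))
  }
  sv <- svd(z)
  e <- sv$v[, 1]
  if (stats::cor(e, colMeans(z)) < 0) e <- -e
  list(eigengene = e,
       explained_variance = sv$d[1]^2 / sum(sv$d^2),
       single_gene = FALSE)
}

#' Eigengenes for every module of a partition
#'
#' @param x a [ts_matrix()].
#' @param partition a [detect_modules()] result (or any named gene ->
#'   label vector; "unassigned" is skipped).
#' @return List of class `eigengene_set`: `eigengenes` (module x stage
#'   matrix, unit-norm rows), `explained_variance`, `stages`.
#' @export
eigengene_set <- function(x, partition) {
  assignment <- if (inherits(partition, "module_partition"))
    partition$assignment else partition
  labs <- setdiff(unique(assignment), "unassigned")
  labs <- labs[order(as.integer(sub("^M", "", labs)))]
  if (length(labs) == 0L)
    return(structure(list(eigengenes = matrix(0, 0, ncol(x)),
                          explained_variance = numeric(0),
                          stages = stages(x)), class = "eigengene_set"))
  res <- lapply(labs, function(l)
    module_eigengene(x, names(assignment)[assignment == l]))
  eg <- do.call(rbind, lapply(res, `[[`, "eigengene"))
  rownames(eg) <- labs
  colnames(eg) <- format_hours(stages(x))
  structure(list(eigengenes = eg,
                 explained_variance = stats::setNames(
                   vapply(res, `[[`, numeric(1), "explained_variance"), labs),
                 stages = stages(x)),
            class = "eigengene_set")
}

#' Refine a module partition by module membership
#'
#' After the tree cut, each gene is reassigned to the module whose
#' eigengene it correlates with most strongly (kME), provided that best
#' membership exceeds `kme_threshold`; otherwise it becomes "unassigned".
#' This strips weakly attached genes that average linkage accretes onto
#' clusters near the cut height. Modules falling below `min_size` after
#' reassignment are dissolved; labels are recomputed by decreasing size.
#'
#' @param x the [ts_matrix()] the partition was computed from.
#' @param partition a [detect_modules()] result.
#' @param kme_threshold minimum membership to stay in a module.
#' @param min_size minimum module size after refinement (defaults to the
#'   partition's).
#' @return A refined `module_partition`.
#' @export
refine_modules <- function(x, partition, kme_threshold = 0.75,
                           min_size = partition$min_size) {
  stopifnot(inherits(partition, "module_partition"))
  labs <- setdiff(unique(partition$assignment), "unassigned")
  if (length(labs) == 0L) return(partition)
  eig <- eigengene_set(x, partition)
  kme <- module_membership(x, eig)
  best <- max.col(kme, ties.method = "first")
  best_val <- kme[cbind(seq_len(nrow(kme)), best)]
  raw <- ifelse(best_val > kme_threshold, colnames(kme)[best], "unassigned")
  names(raw) <- rownames(kme)
  sizes <- table(raw[raw != "unassigned"])
  keep <- names(sizes)[sizes >= min_size]
  assignment <- rep("unassigned", length(raw))
  names(assignment) <- names(raw)
  if (length(keep) > 0L) {
    first_gene <- vapply(keep, function(k) min(names(raw)[raw == k]), character(1))
    ord <- keep[order(-as.integer(sizes[keep]), first_gene)]
    for (i in seq_along(ord)) assignment[raw == ord[i]] <- paste0("M", i)
  }
  structure(list(assignment = assignment, min_size = min_size,
                 cut_height = partition$cut_height, tree = partition$tree),
            class = "module_partition")
}

#' Full module-detection workflow for one dataset
#'
#' Correlation network, soft power (fixed or scale-free-fit selected),
#' adjacency, topological overlap, tree cut and eigengenes in one call.
#'
#' @param x a [ts_matrix()].
#' @param min_size minimum module size.
#' @param mode network mode, see [adjacency()].
#' @param soft_power fixed integer power, or `NULL` to select by
#'   [pick_soft_power()].
#' @param target_fit scale-free fit target when selecting the power.
#' @param refine run the [refine_modules()] membership cleanup
#'   (default TRUE).
#' @param kme_threshold membership threshold for the cleanup.
#' @return List: `partition`, `eigengenes`, `power_report` (NULL when the
#'   power was fixed), `soft_power`, `correlation`.
#' @export
coexpression_modules <- function(x, min_size = 100L,
                                 mode = c("signed", "unsigned"),
                                 soft_power = 6L, target_fit = 0.8,
                                 refine = TRUE, kme_threshold = 0.75) {
  mode <- match.arg(mode)
  x <- filter_invariant_genes(x)
  corr <- correlation_matrix(x)
  report <- NULL
  if (is.null(soft_power)) {
    report <- pick_soft_power(corr, target_fit = target_fit, mode = mode)
    soft_power <- report$chosen_power
  }
  adj <- adjacency(corr, soft_power, mode)
  tom <- tom_similarity(adj)
  partition <- detect_modules(tom, min_size)
  if (refine) partition <- refine_modules(x, partition, kme_threshold, min_size)
  list(partition = partition,
       eigengenes = eigengene_set(x, partition),
       power_report = report,
       soft_power = soft_power,
       correlation = corr)
}
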