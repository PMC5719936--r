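#' Assign each cohort sample a personalized EMT period (PEP)
#'
#' For every sample, the Pearson correlation between its expression over
#' the signature genes and each EMT stage's profile of those genes is
#' computed; the assigned PEP is the stage with the maximum correlation
#' (ties resolve to the earliest stage). Cohort values are
#' `log2(FPKM + 1)`-transformed by default so both sides of the
#' correlation live on a comparable log scale.
#'
#' @param cohort gene x sample nonnegative expression matrix (FPKM-like).
#' @param stage_profiles a [ts_matrix()] restricted to the signature
#'   genes (log scale), e.g. the cell-line time course rows of the
#'   signature.
#' @param log_transform apply `log2(x + 1)` to the cohort (default TRUE).
#' @return data.frame of class `pep_table`: `sample`, `pep_hours`,
#'   `r_max`, plus one `r_<stage>` column per stage. Samples with zero
#'   variance over the signature genes get `NA` with a warning.
#' @export
assign_pep <- function(cohort, stage_profiles, log_transform = TRUE) {
  stopifnot(inherits(stage_profiles, "ts_matrix"))
  shared <- intersect(rownames(cohort), rownames(stage_profiles))
  if (length(shared) < 3L)
    stop(sprintf("only %d signature genes shared with the cohort; need >= 3",
                 length(shared)), call. = FALSE)
  hrs <- stages(stage_profiles)
  S <- unclass(stage_profiles)[shared, , drop = FALSE]
  X <- cohort[shared, , drop = FALSE]
  if (log_transform) X <- log2(X + 1)
  ok <- apply(X, 2L, stats::sd) > 0
  if (any(!ok)) warning(sprintf("%d sample(s) without expression variance left unassigned",
                                sum(!ok)))
  R <- matrix(NA_real_, ncol(X), length(hrs),
              dimnames = list(colnames(X), format_hours(hrs)))
  R[ok, ] <- t(stats::cor(S, X[, ok, drop = FALSE]))
  best <- apply(R, 1L, function(r) if (anyNA(r)) NA_integer_ else which.max(r))
  out <- data.frame(sample = colnames(X),
                    pep_hours = hrs[best],
                    r_max = R[cbind(seq_len(nrow(R)), best)],
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(R))
  names(out)[-(1:3)] <- paste0("r_", format_hours(hrs))
  rownames(out) <- NULL
  class(out) <- c("pep_table", "data.frame")
  out
}

#' PCA of cohort samples over a gene set
#'
#' Samples are the observations, the gene set's (log-transformed)
#' expression values the features; features are centered (and optionally
#' unit-scaled). Returns the first two principal-component coordinates
#' and their explained-variance fractions.
#'
#' @param cohort gene x sample nonnegative expression matrix.
#' @param gene_set genes to use (intersected with the cohort).
#' @param scale. unit-scale the features (default FALSE: centering only).
#' @param log_transform apply `log2(x + 1)` first (default TRUE).
#' @return List: `coords` (sample x 2 matrix, columns PC1/PC2),
#'   `explained_variance` (length-2 fractions).
#' @export
patient_pca <- function(cohort, gene_set, scale. = FALSE,
                        log_transform = TRUE) {
  genes <- intersect(gene_set, rownames(cohort))
  if (length(genes) < 2L) abort_field("gene_set", "fewer than 2 usable genes")
  X <- cohort[genes, , drop = FALSE]
  if (log_transform) X <- log2(X + 1)
  keep <- apply(X, 1L, stats::sd) > 0 | !scale.
  pc <- stats::prcomp(t(X[keep, , drop = FALSE]), center = TRUE, scale. = scale.)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(2L, ncol(pc$x))
  coords <- pc$x[, seq_len(k), drop = FALSE]
  list(coords = coords, explained_variance = ev[seq_len(k)])
}

#' Compare PEP clustering quality across gene sets by silhouette
#'
#' For each named gene set, samples are embedded in that set's
#' (log-transformed) expression space and the silhouette value of every
#' sample against the PEP cluster labels is computed with Euclidean
#' distances (`s = (b - a) / max(a, b)`; singletons score 0). Gene sets
#' are then compared pairwise by Welch t-tests on the per-sample
#' silhouette distributions.
#'
#' @param cohort gene x sample nonnegative expression matrix.
#' @param labels per-sample cluster labels (e.g. `pep_hours` from
#'   [assign_pep()], or pooled PEP cluster names), aligned with the
#'   cohort columns.
#' @param gene_sets named list of gene ID vectors.
#' @param log_transform apply `log2(x + 1)` (default TRUE).
#' @return List of class `silhouette_report`: `values` (named list of
#'   per-sample silhouettes), `means`, `comparisons` (data.frame
#'   `set_a`, `set_b`, `t_stat`, `p_value`).
#' @export
silhouette_compare <- function(cohort, labels, gene_sets,
                               log_transform = TRUE) {
  if (length(labels) != ncol(cohort))
    abort_field("labels", "one label per cohort sample required")
  keep <- !is.na(labels)
  labs <- factor(labels[keep])
  if (nlevels(labs) < 2L)
    abort_field("labels", "silhouette needs at least 2 clusters")
  vals <- lapply(gene_sets, function(gs) {
    genes <- intersect(gs, rownames(cohort))
    if (length(genes) < 1L) return(rep(NA_real_, sum(keep)))
    X <- cohort[genes, keep, drop = FALSE]
    if (log_transform) X <- log2(X + 1)
    d <- stats::dist(t(X))
    sil <- cluster::silhouette(as.integer(labs), d)
    sil[, "sil_width"]
  })
  names(vals) <- names(gene_sets)
  sets <- names(gene_sets)
  comps <- list()
  if (length(sets) > 1L) {
    for (i in seq_len(length(sets) - 1L)) for (j in seq(i + 1L, length(sets))) {
      tt <- stats::t.test(vals[[i]], vals[[j]])
      comps[[length(comps) + 1L]] <- data.frame(
        set_a = sets[i], set_b = sets[j],
        t_stat = unname(tt$statistic), p_value = tt$p.value,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(values = vals,
                 means = vapply(vals, mean, numeric(1)),
                 comparisons = if (length(comps)) do.call(rbind, comps)
                               else data.frame()),
            class = "silhouette_report")
}

#' Pool PEP hours into named period clusters
#'
#' Maps assigned stage hours onto the conventional period bins
#' (epithelial plateau 0-8 h, the 16-24 h wave, 72 h, 168 h, and beyond),
#' yielding the cluster labels used for survival stratification.
#'
#' @param pep_hours numeric vector of assigned stages in hours.
#' @param breaks right-closed upper bin edges in hours.
#' @param labels bin names, one per break plus one overflow label.
#' @return Character vector of cluster labels.
#' @export
pep_clusters <- function(pep_hours,
                         breaks = c(8, 24, 72, 168),
                         labels = c("h0-8", "h16-24", "h72", "h168", "h>168")) {
  if (length(labels) != length(breaks) + 1L)
    abort_field("labels", "needs one more label than breaks")
  idx <- findInterval(pep_hours, breaks + 1e-9) + 1L
  labels[idx]
}
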