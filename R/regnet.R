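#' Hypergeometric enrichment of TF targets in a module
#'
#' Upper-tail probability of observing at least the overlap between a
#' module's genes and a TF's target set when targets are drawn without
#' replacement from the universe: `P(X >= q)` for
#' `X ~ Hypergeometric(N = |universe|, K = |targets|, n = |module|)`.
#' Computed exactly on log scale via [stats::phyper()].
#'
#' @param module_genes gene set of the module.
#' @param tf_targets gene set targeted by the TF.
#' @param universe the gene universe both sets live in.
#' @return List: `overlap`, `module_size`, `target_count`,
#'   `universe_size`, `p_value`.
#' @export
hypergeom_enrichment <- function(module_genes, tf_targets, universe) {
  if (length(universe) == 0L) abort_field("universe", "empty universe")
  if (length(module_genes) == 0L) abort_field("module_genes", "empty module")
  module_genes <- intersect(module_genes, universe)
  tf_targets <- intersect(tf_targets, universe)
  q <- length(intersect(module_genes, tf_targets))
  N <- length(universe)
  K <- length(tf_targets)
  n <- length(module_genes)
  # P(X >= q); q = 0 gives the full tail, p = 1
  p <- stats::phyper(q - 1L, K, N - K, n, lower.tail = FALSE)
  list(overlap = q, module_size = n, target_count = K,
       universe_size = N, p_value = p)
}

#' Per-module TF regulators by target enrichment
#'
#' For each module, every TF of the reference network is tested for
#' over-representation of its targets among the module genes; TFs with
#' `p < p_threshold` (strict) are retained and classified by the Pearson
#' correlation of their expression profile with the module eigengene:
#' positive if `r > r_threshold`, negative if `r < -r_threshold`,
#' otherwise unclassified. TFs absent from the expression data stay
#' unclassified with a missing `r` but are still reported.
#'
#' The universe defaults to the genes present in both the expression data
#' and the reference network's target space, so enrichment is never
#' inflated by genes that could not have been observed.
#'
#' @param partition a [detect_modules()] result (or named assignment
#'   vector).
#' @param eig the matching [eigengene_set()].
#' @param regnet data.frame edge list with columns `tf`, `target`.
#' @param tf_expr a [ts_matrix()] holding TF expression profiles (usually
#'   the full expression matrix).
#' @param p_threshold retention threshold on the raw hypergeometric p
#'   (default 0.05, no multiple-testing correction).
#' @param r_threshold classification threshold on the eigengene
#'   correlation (default 0.7).
#' @param universe optional override of the enrichment universe.
#' @param adjust apply Benjamini-Hochberg across TFs within each module
#'   before thresholding (off by default).
#' @return data.frame sorted by module then p-value: `module`, `tf`,
#'   `overlap`, `target_count` (K), `module_size` (n), `universe_size`
#'   (N), `p_value`, `r`, `class`.
#' @export
module_regulators <- function(partition, eig, regnet, tf_expr,
                              p_threshold = 0.05, r_threshold = 0.7,
                              universe = NULL, adjust = FALSE) {
  assignment <- if (inherits(partition, "module_partition"))
    partition$assignment else partition
  if (is.null(universe))
    universe <- intersect(names(assignment), unique(regnet$target))
  tf_sets <- split(regnet$target, regnet$tf)
  labs <- rownames(eig$eigengenes)
  rows <- list()
  for (mod in labs) {
    genes <- intersect(names(assignment)[assignment == mod], universe)
    if (length(genes) == 0L) next
    res <- lapply(names(tf_sets), function(tf)
      hypergeom_enrichment(genes, tf_sets[[tf]], universe))
    p <- vapply(res, `[[`, numeric(1), "p_value")
    p_use <- if (adjust) stats::p.adjust(p, "BH") else p
    sel <- which(p_use < p_threshold)
    if (length(sel) == 0L) next
    for (i in sel) {
      tf <- names(tf_sets)[i]
      r <- NA_real_
      cls <- "unclassified"
      if (tf %in% rownames(tf_expr)) {
        prof <- unclass(tf_expr)[tf, ]
        if (stats::sd(prof) > 0) {
          r <- stats::cor(prof, eig$eigengenes[mod, ])
          if (r > r_threshold) cls <- "positive"
          else if (r < -r_threshold) cls <- "negative"
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        module = mod, tf = tf,
        overlap = res[[i]]$overlap, target_count = res[[i]]$target_count,
        module_size = res[[i]]$module_size,
        universe_size = res[[i]]$universe_size,
        p_value = p_use[i], r = r, class = cls,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(module = character(0), tf = character(0),
                      overlap = integer(0), target_count = integer(0),
                      module_size = integer(0), universe_size = integer(0),
                      p_value = numeric(0), r = numeric(0),
                      class = character(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$module, out$p_value, out$tf), ]
  rownames(out) <- NULL
  out
}

#' TF-TF subnetwork among retained regulators
#'
#' Restricts the reference network to the retained TFs: an edge
#' `TF1 -> TF2` is kept iff both are retained regulators and the pair is
#' an edge of the reference network. Node attributes carry the
#' correlation class (a TF retained for several modules keeps the class
#' of its most significant enrichment).
#'
#' @param regulators data.frame from [module_regulators()].
#' @param regnet reference edge list (`tf`, `target`).
#' @return List of class `tf_network`: `nodes` (data.frame `tf`, `class`),
#'   `edges` (data.frame `from`, `to`).
#' @export
tf_subnetwork <- function(regulators, regnet) {
  if (nrow(regulators) == 0L) abort_field("regulators", "must be nonempty")
  byp <- regulators[order(regulators$p_value), ]
  byp <- byp[!duplicated(byp$tf), ]
  tfs <- sort(byp$tf)
  nodes <- data.frame(tf = tfs,
                      class = byp$class[match(tfs, byp$tf)],
                      stringsAsFactors = FALSE)
  keep <- regnet$tf %in% tfs & regnet$target %in% tfs
  edges <- data.frame(from = regnet$tf[keep], to = regnet$target[keep],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), ]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "tf_network")
}

#' HITS hub scores of a directed network
#'
#' Kleinberg's hub centrality: the principal eigenvector of `A %*% t(A)`
#' for the adjacency matrix `A`, computed by power iteration with
#' alternating hub/authority normalization, then scaled so the maximum
#' hub score is 1. A node scores highly when it points at many nodes that
#' are themselves pointed at by good hubs.
#'
#' @param network a `tf_network` from [tf_subnetwork()], or a data.frame
#'   edge list (`from`, `to`), or a square adjacency matrix with
#'   dimnames.
#' @param tol convergence tolerance on the hub vector (default 1e-10).
#' @param max_iter iteration cap.
#' @return Named numeric vector of hub scores in `[0, 1]` (max = 1 on any
#'   network with at least one edge; all zero, with a warning, on an
#'   edgeless network).
#' @export
hub_scores <- function(network, tol = 1e-10, max_iter = 10000L) {
  A <- as_adjacency(network)
  n <- nrow(A)
  if (n == 0L) abort_field("network", "needs at least one node")
  if (all(A == 0)) {
    warning("edgeless network; all hub scores 0")
    return(stats::setNames(rep(0, n), rownames(A)))
  }
  h <- rep(1 / sqrt(n), n)
  for (i in seq_len(max_iter)) {
    a <- drop(crossprod(A, h))        # authority update
    a_norm <- sqrt(sum(a^2))
    if (a_norm > 0) a <- a / a_norm
    h_new <- drop(A %*% a)            # hub update
    h_norm <- sqrt(sum(h_new^2))
    if (h_norm > 0) h_new <- h_new / h_norm
    delta <- max(abs(h_new - h))
    h <- h_new
    if (delta < tol) break
  }
  h <- pmax(h, 0)
  stats::setNames(h / max(h), rownames(A))
}

as_adjacency <- function(network) {
  if (is.matrix(network)) {
    if (nrow(network) != ncol(network) || is.null(rownames(network)))
      abort_field("network", "adjacency must be square with dimnames")
    return(network)
  }
  if (inherits(network, "tf_network")) {
    nodes <- network$nodes$tf
    edges <- network$edges
  } else {
    edges <- network
    nodes <- sort(unique(c(edges$from, edges$to)))
  }
  A <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  if (nrow(edges) > 0)
    A[cbind(match(edges$from, nodes), match(edges$to, nodes))] <- 1
  A
}
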