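# Small configs and independent brute-force oracles used across the suite.

tiny_config <- function(seed = 1L, ...) {
  args <- list(n_modules = 4L, module_size = 12L, n_background_genes = 12L,
               noise_sd = 0.2, n_tfs = 6L, targets_per_tf = 6L,
               bg_edge_prob = 0, n_seed_genes = 8L, n_patients = 40L,
               seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# textbook Pearson correlation, written out
pearson_hand <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# O(n^3) triple-loop topological overlap
tom_brute <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { out[i, j] <- 1; next }
    s <- 0
    for (u in seq_len(n)) if (u != i && u != j) s <- s + a[i, u] * a[u, j]
    out[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# exact hypergeometric upper tail by direct combinatorial sum
hyper_tail_hand <- function(q, N, K, n) {
  if (q <= 0) return(1)
  kk <- q:min(K, n)
  sum(exp(lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)))
}

# two-sample KS statistic as the max ECDF gap, by enumeration
ks_stat_hand <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(p) mean(x <= p) - mean(y <= p), numeric(1))))
}

# all-pairs silhouette from first principles
silhouette_hand <- function(X, labels) {
  d <- as.matrix(stats::dist(X))
  n <- nrow(X)
  vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    if (sum(own) == 1L) return(0)
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l)
      mean(d[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
}

# product-limit estimate tabulated by hand
km_hand <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  ts <- sort(unique(time))
  s <- 1
  out <- data.frame(time = ts, surv = NA_real_)
  for (i in seq_along(ts)) {
    n_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    if (d > 0) s <- s * (1 - d / n_risk)
    out$surv[i] <- s
  }
  out
}

# k-group log-rank statistic from the O/E/V tabulation
logrank_hand <- function(time, event, group) {
  groups <- sort(unique(group))
  k <- length(groups)
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    d <- sum(time == t & event == 1)
    ni <- vapply(groups, function(g) sum(at_risk & group == g), numeric(1))
    di <- vapply(groups, function(g) sum(time == t & event == 1 & group == g),
                 numeric(1))
    O <- O + di
    E <- E + d * ni / n
    if (n > 1) {
      v <- d * (ni / n) * (1 - ni / n) * (n - d) / (n - 1)
      V <- V + diag(v, k) -
        (d * outer(ni, ni) / n^2 * (n - d) / (n - 1)) * (1 - diag(k))
    }
  }
  oe <- (O - E)[-k]
  vv <- V[-k, -k, drop = FALSE]
  drop(t(oe) %*% solve(vv) %*% oe)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# run expr under a local seed without touching the global stream
with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

planted_module_ari <- function(truth, assignment) {
  mg <- names(truth$gene_module)[truth$gene_module != "background"]
  ari(truth$gene_module[mg], assignment[mg])
}
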