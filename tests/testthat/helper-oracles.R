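# Independent oracles and small fixture builders used across tests.
# These deliberately avoid the package's own code paths.

# exhaustive minimum within-cluster SS over all assignments of n points to
# exactly k non-empty clusters (k^n enumeration; keep n small)
brute_kmeans_wss <- function(X, k) {
  n <- nrow(X)
  best <- Inf
  grid <- do.call(expand.grid, rep(list(seq_len(k)), n))
  for (i in seq_len(nrow(grid))) {
    a <- as.integer(grid[i, ])
    if (length(unique(a)) < k) next
    wss <- 0
    for (cl in seq_len(k)) {
      sub <- X[a == cl, , drop = FALSE]
      wss <- wss + sum(sweep(sub, 2, colMeans(sub))^2)
    }
    if (wss < best) best <- wss
  }
  best
}

# all permutations of a vector, independent of the package's internal helper
perms_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in perms_of(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

# hypergeometric upper tail P(X >= k) by exhaustive enumeration of draws
enum_hyper_tail <- function(N, K, n, k) {
  hits <- utils::combn(N, n, function(draw) sum(draw <= K))
  mean(hits >= k)
}

# hand-built cluster_model for consensus tests
make_model <- function(assignments, centers, labels = NULL, stages = c(2, 4, 6, 8, 10, 12, 14)) {
  structure(
    list(k = nrow(centers), assignments = assignments, centers = centers,
         within_ss = 0, archetype_labels = labels, stages = stages,
         seed = 1L, n_starts = 1L, max_iter = 1L),
    class = "cluster_model")
}

# quick rpkm stage_matrix from a plain matrix
rpkm_fixture <- function(values, stages = c(2, 4, 6, 8, 10, 12, 14)) {
  values <- as.matrix(values)
  stage_matrix(values, sprintf("g%d", seq_len(nrow(values))),
               rep(1000, nrow(values)), stages[seq_len(ncol(values))],
               kind = "rpkm")
}
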