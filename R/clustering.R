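# squared Euclidean distances between rows of X (n x p) and C (k x p)
dist2 <- function(X, C) {
  outer(rowSums(X^2), rep(1, nrow(C))) - 2 * X %*% t(C) +
    outer(rep(1, nrow(X)), rowSums(C^2))
}

# one Lloyd run from given initial centers; empty clusters are re-seeded
# with the point currently farthest from its own center
lloyd_run <- function(X, centers, max_iter) {
  n <- nrow(X)
  k <- nrow(centers)
  assign_prev <- integer(n)
  for (it in seq_len(max_iter)) {
    d <- dist2(X, centers)
    assign <- max.col(-d, ties.method = "first")
    empty <- which(tabulate(assign, k) == 0L)
    if (length(empty)) {
      own <- d[cbind(seq_len(n), assign)]
      for (cl in empty) {
        far <- which.max(own)
        assign[far] <- cl
        own[far] <- -Inf
      }
    }
    if (identical(assign, assign_prev)) break
    assign_prev <- assign
    centers <- rowsum(X, assign) / tabulate(assign, k)
  }
  centers <- rowsum(X, assign) / tabulate(assign, k)
  wss <- sum((X - centers[assign, , drop = FALSE])^2)
  list(assignments = assign, centers = centers, within_ss = wss, iter = it)
}

#' K-means clustering of temporal gene profiles
#'
#' Lloyd's algorithm on row-centered log2 profiles, restarted `n_starts`
#' times from uniform-random sets of `k` distinct genes; the restart with
#' the smallest total within-cluster sum of squares wins. The whole
#' procedure is deterministic given `seed`. Defaults follow the reference
#' analysis: `k = 4`, `n_starts = 30`, `max_iter = 30000`.
#'
#' @param X A [stage_matrix()] of kind `"normalized"` (row-centered).
#' @param k Number of clusters.
#' @param n_starts Number of random restarts.
#' @param max_iter Maximum Lloyd iterations per restart.
#' @param seed Integer seed governing all restarts.
#' @return A `cluster_model`: `k`, `assignments` (named integer vector),
#'   `centers` (k x stages), `within_ss`, `archetype_labels` (`NULL` until
#'   [label_archetypes()]), plus the settings used.
#' @examples
#' sim <- generate_dataset(sim_config(n_genes = 200, seed = 3))
#' X <- log_normalize(compute_rpkm(sim$counts_a))
#' m <- kmeans_cluster(X, k = 4, seed = 1)
#' table(m$assignments)
#' @export
kmeans_cluster <- function(X, k = 4L, n_starts = 30L, max_iter = 30000L, seed = 1L) {
  stopifnot(inherits(X, "stage_matrix"))
  V <- X$values
  if (any(!is.finite(V))) stop("non-finite values in profile matrix", call. = FALSE)
  n <- nrow(V)
  if (k > n) stop("k exceeds the number of genes", call. = FALSE)
  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    init <- V[sample.int(n, k), , drop = FALSE]
    run <- lloyd_run(V, init, max_iter)
    if (is.null(best) || run$within_ss < best$within_ss) best <- run
  }
  dimnames(best$centers) <- list(NULL, colnames(V))
  structure(
    list(k = as.integer(k),
         assignments = stats::setNames(best$assignments, X$gene_ids),
         centers = best$centers,
         within_ss = best$within_ss,
         archetype_labels = NULL,
         stages = X$stages,
         seed = seed, n_starts = as.integer(n_starts),
         max_iter = as.integer(max_iter)),
    class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("cluster_model: k=%d, %d genes, within_ss=%.4g\n",
              x$k, length(x$assignments), x$within_ss))
  if (!is.null(x$archetype_labels))
    cat("archetypes:", paste(x$archetype_labels, collapse = ", "), "\n")
  invisible(x)
}

all_perms <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in all_perms(k - 1L))
    for (i in seq_len(k))
      out[[length(out) + 1L]] <- append(p, k, after = i - 1L)
  out
}

# shape-similarity score between two centered profiles: Pearson correlation
# where defined, otherwise (near-zero variance, e.g. flat profiles) a
# distance-based fallback mapped into [-1, 1]
profile_score <- function(a, b, eps = 1e-9) {
  if (stats::sd(a) > eps && stats::sd(b) > eps) return(stats::cor(a, b))
  d <- sqrt(sum((a - b)^2))
  (1 - d) / (1 + d)
}

#' Label clusters with archetype names
#'
#' Matches the `k` cluster centers to `k` row-centered archetype templates
#' by maximum total shape similarity over all bijections (Pearson
#' correlation, with a Euclidean-distance fallback for flat profiles whose
#' correlation is undefined). Each archetype name is used exactly once.
#'
#' @param model A `cluster_model` from [kmeans_cluster()].
#' @param templates Archetype list as in [archetype_templates()]; templates
#'   are centered internally. Must have exactly `k` entries.
#' @return The model with `archetype_labels` set (one name per cluster).
#' @export
label_archetypes <- function(model, templates = archetype_templates()) {
  stopifnot(inherits(model, "cluster_model"))
  if (length(templates) != model$k)
    stop("need exactly one template per cluster", call. = FALSE)
  if (model$k > 8) stop("archetype matching supports k <= 8", call. = FALSE)
  T <- do.call(rbind, lapply(templates, `[[`, "template"))
  T <- T - rowMeans(T)
  nm <- vapply(templates, `[[`, "", "name")
  S <- matrix(0, model$k, model$k)
  for (i in seq_len(model$k))
    for (j in seq_len(model$k))
      S[i, j] <- profile_score(model$centers[i, ], T[j, ])
  best <- NULL
  for (p in all_perms(model$k)) {
    sc <- sum(S[cbind(seq_len(model$k), unlist(p))])
    if (is.null(best) || sc > best$sc + 1e-12) best <- list(sc = sc, p = unlist(p))
  }
  model$archetype_labels <- nm[best$p]
  model
}

#' Hierarchical clustering of stages
#'
#' Agglomerative clustering of the stage columns of a log2(RPKM+1) matrix
#' (Euclidean distance, complete linkage by default). Cutting the tree at
#' two groups exposes the root bipartition of early versus late stages.
#'
#' @param X A [stage_matrix()] of kind `"log_rpkm"` (or `"normalized"`).
#' @param metric Distance metric passed to [stats::dist()].
#' @param linkage Linkage method passed to [stats::hclust()].
#' @return A `stage_dendrogram`: the `hclust` object plus `labels`,
#'   `heights` and `leaf_order`.
#' @export
cluster_stages <- function(X, metric = "euclidean", linkage = "complete") {
  stopifnot(inherits(X, "stage_matrix"))
  if (ncol(X$values) < 2) stop("need at least two stages", call. = FALSE)
  hc <- stats::hclust(stats::dist(t(X$values), method = metric), method = linkage)
  structure(list(hclust = hc, labels = hc$labels, heights = hc$height,
                 leaf_order = hc$order, metric = metric, linkage = linkage),
            class = "stage_dendrogram")
}

#' Cut a stage dendrogram into groups
#' @param dend A `stage_dendrogram`.
#' @param k Number of groups.
#' @return Named integer vector of group memberships, one per stage.
#' @export
cut_stages <- function(dend, k = 2) {
  stopifnot(inherits(dend, "stage_dendrogram"))
  stats::cutree(dend$hclust, k)
}

#' Write a stage dendrogram as Newick
#' @param dend A `stage_dendrogram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(dend, path) {
  stopifnot(inherits(dend, "stage_dendrogram"))
  ape::write.tree(ape::as.phylo(dend$hclust), file = path)
  invisible(path)
}

#' Serialize a cluster model
#'
#' Writes gene assignments as TSV (`gene_id`, `cluster`, `archetype`) and,
#' alongside, a JSON file with centers, within-cluster SS and settings.
#'
#' @param model A `cluster_model`.
#' @param path TSV output path; the JSON lands at `sub("tsv$", "json", path)`.
#' @return `path`, invisibly.
#' @export
write_cluster_model <- function(model, path) {
  stopifnot(inherits(model, "cluster_model"))
  lab <- model$archetype_labels
  df <- data.frame(gene_id = names(model$assignments),
                   cluster = unname(model$assignments),
                   archetype = if (is.null(lab)) NA_character_
                               else lab[model$assignments])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(k = model$k, within_ss = model$within_ss,
               centers = unname(apply(model$centers, 1, as.numeric, simplify = FALSE)),
               archetype_labels = lab, seed = model$seed,
               n_starts = model$n_starts, max_iter = model$max_iter)
  jsonlite::write_json(meta, sub("tsv$", "json", path),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
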