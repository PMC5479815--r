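#' Match clusters between two replicate models
#'
#' K-means cluster indices are arbitrary, so corresponding clusters in two
#' replicates must be aligned before intersecting. When both models carry
#' archetype labels, label identity defines the mapping (any disagreement
#' with the distance-optimal assignment is reported via a message);
#' otherwise the minimum-total-Euclidean-distance bijection between the
#' two center sets is found by enumerating all `k!` bijections.
#'
#' @param model_a,model_b `cluster_model` objects with equal `k` (<= 8).
#' @return Integer vector `mapping` of length `k`: cluster `c` of A
#'   corresponds to cluster `mapping[c]` of B.
#' @export
match_clusters <- function(model_a, model_b) {
  stopifnot(inherits(model_a, "cluster_model"), inherits(model_b, "cluster_model"))
  if (model_a$k != model_b$k)
    stop("models must have the same number of clusters", call. = FALSE)
  k <- model_a$k
  if (k > 8) stop("cluster matching supports k <= 8", call. = FALSE)
  D <- dist2(model_a$centers, model_b$centers)
  best <- NULL
  for (p in all_perms(k)) {
    tot <- sum(D[cbind(seq_len(k), unlist(p))])
    if (is.null(best) || tot < best$tot - 1e-12) best <- list(tot = tot, p = unlist(p))
  }
  by_dist <- best$p
  la <- model_a$archetype_labels
  lb <- model_b$archetype_labels
  if (!is.null(la) && !is.null(lb)) {
    by_label <- match(la, lb)
    if (anyNA(by_label))
      stop("archetype labels of the two models do not correspond", call. = FALSE)
    if (!identical(as.integer(by_label), as.integer(by_dist)))
      message("match_clusters: label-identity mapping differs from the ",
              "distance-optimal bijection; using labels")
    return(as.integer(by_label))
  }
  as.integer(by_dist)
}

#' Intersect matched clusters across replicates
#'
#' For every cluster `c` of model A, the shared set is the genes assigned
#' to `c` in A and to `mapping[c]` in B. The combined "up" set intersects
#' the union of A's two rising clusters with the union of B's matched
#' counterparts; with archetype labels these are `late_rise` and
#' `early_rise`, without labels clusters 1 and 2 of A.
#'
#' @param model_a,model_b `cluster_model` objects over the same genes.
#' @param mapping Cluster mapping from [match_clusters()].
#' @return A `consensus_result`: `mapping`, `shared_sets` (list of gene-ID
#'   vectors, named by A's archetype labels when available), `combined_up_set`
#'   and a `sizes` list with all cardinalities.
#' @export
intersect_clusters <- function(model_a, model_b, mapping = match_clusters(model_a, model_b)) {
  stopifnot(inherits(model_a, "cluster_model"), inherits(model_b, "cluster_model"))
  genes_a <- names(model_a$assignments)
  genes_b <- names(model_b$assignments)
  if (!setequal(genes_a, genes_b))
    stop("models must cover the same gene universe", call. = FALSE)
  k <- model_a$k
  if (length(mapping) != k || !setequal(mapping, seq_len(k)))
    stop("mapping must be a bijection over 1..k", call. = FALSE)
  b_of <- model_b$assignments[genes_a]  # align B to A's gene order
  shared <- lapply(seq_len(k), function(cl)
    genes_a[model_a$assignments == cl & b_of == mapping[cl]])
  la <- model_a$archetype_labels
  names(shared) <- if (is.null(la)) paste0("cluster", seq_len(k)) else la
  up <- if (!is.null(la)) which(la %in% c("late_rise", "early_rise")) else 1:2
  up_a <- genes_a[model_a$assignments %in% up]
  up_b <- genes_a[b_of %in% mapping[up]]
  combined <- intersect(up_a, up_b)
  structure(
    list(mapping = mapping,
         shared_sets = shared,
         combined_up_set = combined,
         sizes = list(cluster_a = as.list(table(factor(model_a$assignments, seq_len(k)))),
                      cluster_b = as.list(table(factor(b_of, seq_len(k)))),
                      shared = lapply(shared, length),
                      combined_up = length(combined))),
    class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("consensus_result: mapping", paste(seq_along(x$mapping), "->", x$mapping,
                                         collapse = ", "), "\n")
  cat("shared sizes:", paste(names(x$shared_sets), unlist(x$sizes$shared),
                             sep = "=", collapse = ", "), "\n")
  cat("combined up set:", length(x$combined_up_set), "genes\n")
  invisible(x)
}

#' Write consensus gene lists and summary
#'
#' One TSV gene list per matched cluster plus the combined up set, and a
#' JSON summary of the mapping and all sizes.
#'
#' @param consensus A `consensus_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_consensus <- function(consensus, dir) {
  stopifnot(inherits(consensus, "consensus_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(consensus$shared_sets))
    writeLines(consensus$shared_sets[[nm]],
               file.path(dir, paste0("shared_", nm, ".tsv")))
  writeLines(consensus$combined_up_set, file.path(dir, "combined_up.tsv"))
  jsonlite::write_json(list(mapping = consensus$mapping, sizes = consensus$sizes),
                       file.path(dir, "consensus.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
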