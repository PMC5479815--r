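#' Gene-set category collection with a background universe
#'
#' @param categories Named list of gene-ID vectors.
#' @param background Character vector: the gene universe. Category members
#'   outside the background are dropped; categories empty after that
#'   intersection are removed with a message.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(categories, background) {
  background <- unique(as.character(background))
  if (!length(background)) stop("background must be non-empty", call. = FALSE)
  if (!length(categories) || is.null(names(categories)))
    stop("categories must be a named list", call. = FALSE)
  categories <- lapply(categories, function(g) intersect(unique(g), background))
  empty <- vapply(categories, length, 0L) == 0L
  if (any(empty)) {
    message("dropping ", sum(empty), " categor(ies) empty after background intersection")
    categories <- categories[!empty]
  }
  structure(list(categories = categories, background = background),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d categories over %d background genes\n",
              length(x$categories), length(x$background)))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (per line: name, description, member genes).
#' @param background Gene universe; defaults to the union of all members.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, background = NULL) {
  cats <- fgsea::gmtPathways(path)
  if (is.null(background)) background <- unique(unlist(cats))
  gene_set_collection(cats, background)
}

#' Write gene sets as GMT
#' @param collection A [gene_set_collection()] (or named list of sets).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  cats <- if (inherits(collection, "gene_set_collection"))
    collection$categories else collection
  fgsea::writeGmtPathways(cats, path)
  invisible(path)
}

#' Hypergeometric gene-set enrichment
#'
#' One-sided over-representation test for a query gene set against every
#' category: with `N` background genes, `K` category members, `n` query
#' genes and `k` hits, \eqn{p = P(X \ge k)} for
#' \eqn{X \sim \mathrm{Hypergeometric}(N, K, n)}. Query genes outside the
#' background are dropped (a message reports how many). The `benjamini`
#' column is the BH adjustment across exactly the categories tested
#' (those with at least `min_category` background members). Records are
#' sorted by ascending p-value with the term name as tiebreak. With
#' `ease = TRUE` the tail is computed at `k - 1` (the more conservative
#' one-hit-discounted variant of annotation-chart tools).
#'
#' @param query Character vector of gene IDs.
#' @param collection A [gene_set_collection()].
#' @param min_category Minimum category size (within background) to test.
#' @param ease Use the one-hit-discounted tail.
#' @return A `data.frame` with columns `term`, `k`, `K`, `n`, `N`,
#'   `p_value`, `benjamini`.
#' @examples
#' gsc <- gene_set_collection(list(hit = paste0("g", 1:5)), paste0("g", 1:20))
#' enrich(paste0("g", 1:5), gsc)  # p = 1 / choose(20, 5)
#' @export
enrich <- function(query, collection, min_category = 2L, ease = FALSE) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(as.character(query))
  dropped <- setdiff(query, collection$background)
  if (length(dropped))
    message("enrich: ", length(dropped), " query gene(s) outside the background dropped")
  query <- intersect(query, collection$background)
  if (!length(query)) stop("query is empty after background intersection", call. = FALSE)
  N <- length(collection$background)
  n <- length(query)
  sizes <- vapply(collection$categories, length, 0L)
  test <- collection$categories[sizes >= min_category]
  if (!length(test)) stop("no category passes min_category", call. = FALSE)
  K <- vapply(test, length, 0L)
  k <- vapply(test, function(g) length(intersect(g, query)), 0L)
  kk <- if (ease) pmax(k - 1L, 0L) else k
  p <- stats::phyper(kk - 1L, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term = names(test), k = k, K = K, n = n, N = N,
                    p_value = p, benjamini = bh_adjust(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an enrichment chart as TSV
#' @param chart Output of [enrich()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(chart, path) {
  utils::write.table(chart, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
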