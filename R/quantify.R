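#' Compute RPKM from raw counts
#'
#' Reads per kilobase of transcript per million mapped reads:
#' \deqn{RPKM_{gj} = 10^9 \, c_{gj} / (N_j \ell_g)} with \eqn{N_j} the
#' per-stage total of mapped reads and \eqn{\ell_g} the gene length in bp.
#' Totals come from the matrix metadata (genome-wide mapped totals), not
#' from column sums; set `use_column_sums = TRUE` to fall back to column
#' sums when no totals are available (the fallback is reported via a
#' message).
#'
#' @param counts A [stage_matrix()] of kind `"counts"`.
#' @param use_column_sums Use column sums instead of the stored totals.
#' @return A [stage_matrix()] of kind `"rpkm"`, same genes and stages.
#' @examples
#' sm <- stage_matrix(matrix(10, 1, 7), "g1", 1000,
#'                    kind = "counts", mapped_totals = rep(1e6, 7))
#' compute_rpkm(sm)$values  # 10 reads / 1 kb / 1 M reads = 10 RPKM
#' @export
compute_rpkm <- function(counts, use_column_sums = FALSE) {
  stopifnot(inherits(counts, "stage_matrix"))
  if (counts$kind != "counts")
    stop("compute_rpkm expects a counts matrix, got ", counts$kind, call. = FALSE)
  totals <- counts$mapped_totals
  if (use_column_sums || is.null(totals)) {
    totals <- colSums(counts$values)
    message("compute_rpkm: using column sums as mapped totals")
  }
  if (any(totals <= 0)) stop("mapped totals must be positive", call. = FALSE)
  if (any(counts$lengths_bp <= 0)) stop("gene lengths must be positive", call. = FALSE)
  rpkm <- 1e9 * sweep(counts$values, 2, totals, "/") / counts$lengths_bp
  stage_matrix(rpkm, counts$gene_ids, counts$lengths_bp, counts$stages, "rpkm")
}

#' Trim low-expressed genes by the dual RPKM criteria
#'
#' Keeps genes satisfying both criteria: (1) day-14 RPKM at least
#' `day14_min` (inclusive), and (2) the sum of RPKM over all stages
#' strictly greater than `sum_min`. By default criterion (1) is evaluated
#' on replicate A and criterion (2) on replicate B, mirroring a design
#' where the second series is trimmed for cross-comparison; either
#' criterion can be applied to `"A"`, `"B"` or `"both"` replicates.
#'
#' @param rpkm_a,rpkm_b RPKM [stage_matrix()] objects over the same genes.
#' @param day14_min Inclusive day-14 RPKM threshold (default 0.2).
#' @param sum_min Exclusive cross-stage RPKM sum threshold (default 0.2).
#' @param day14_on,sum_on Which replicate each criterion applies to.
#' @param day Day defining criterion (1)'s stage (default 14).
#' @return A `filter_report` list: `n_input`, `n_kept`, `kept_ids` (in
#'   input order) and `criteria`.
#' @export
trim_genes <- function(rpkm_a, rpkm_b, day14_min = 0.2, sum_min = 0.2,
                       day14_on = c("A", "B", "both"),
                       sum_on = c("B", "A", "both"), day = 14) {
  stopifnot(inherits(rpkm_a, "stage_matrix"), inherits(rpkm_b, "stage_matrix"))
  day14_on <- match.arg(day14_on)
  sum_on <- match.arg(sum_on)
  if (!identical(rpkm_a$gene_ids, rpkm_b$gene_ids))
    stop("replicates must share an identical gene universe", call. = FALSE)
  jcol_a <- match(day, rpkm_a$stages)
  jcol_b <- match(day, rpkm_b$stages)
  if (is.na(jcol_a) || is.na(jcol_b))
    stop("day ", day, " stage not present", call. = FALSE)

  crit1_of <- function(m, j) m$values[, j] >= day14_min
  crit2_of <- function(m) rowSums(m$values) > sum_min
  crit1 <- switch(day14_on,
                  A = crit1_of(rpkm_a, jcol_a),
                  B = crit1_of(rpkm_b, jcol_b),
                  both = crit1_of(rpkm_a, jcol_a) & crit1_of(rpkm_b, jcol_b))
  crit2 <- switch(sum_on,
                  A = crit2_of(rpkm_a),
                  B = crit2_of(rpkm_b),
                  both = crit2_of(rpkm_a) & crit2_of(rpkm_b))
  keep <- crit1 & crit2
  structure(
    list(n_input = length(keep),
         n_kept = sum(keep),
         kept_ids = rpkm_a$gene_ids[keep],
         criteria = list(day14_min = day14_min, sum_min = sum_min,
                         day14_on = day14_on, sum_on = sum_on, day = day)),
    class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: %d of %d genes kept (day%d RPKM >= %g on %s AND stage sum > %g on %s)\n",
              x$n_kept, x$n_input, x$criteria$day, x$criteria$day14_min,
              x$criteria$day14_on, x$criteria$sum_min, x$criteria$sum_on))
  invisible(x)
}

#' Log-transform RPKM without centering
#'
#' `log2(RPKM + 1)`, the scale used for the stage dendrogram and heatmaps.
#'
#' @param rpkm An RPKM [stage_matrix()].
#' @return A [stage_matrix()] of kind `"log_rpkm"`.
#' @export
log_transform <- function(rpkm) {
  stopifnot(inherits(rpkm, "stage_matrix"))
  if (rpkm$kind != "rpkm")
    stop("log_transform expects an rpkm matrix", call. = FALSE)
  if (any(rpkm$values < 0)) stop("negative RPKM values", call. = FALSE)
  stage_matrix(log2(rpkm$values + 1), rpkm$gene_ids, rpkm$lengths_bp,
               rpkm$stages, "log_rpkm")
}

#' Log-transform and per-gene normalize RPKM for clustering
#'
#' Default (`method = "log2_center"`): \eqn{x_{gj} = \log_2(RPKM_{gj}+1)}
#' followed by subtraction of the per-gene mean over stages, so every row
#' of the output has mean zero -- "normalized to the stage average" in
#' log space. The alternative `method = "linear_mean"` divides each RPKM
#' row by its arithmetic mean in linear space before the log transform
#' (no further centering).
#'
#' @param rpkm An RPKM [stage_matrix()].
#' @param method `"log2_center"` (default) or `"linear_mean"`.
#' @return A [stage_matrix()] of kind `"normalized"`.
#' @examples
#' sm <- stage_matrix(matrix(c(0, 0, 0, 1, 3, 7, 15), 1), "g1", 1000, kind = "rpkm")
#' log_normalize(sm)$values  # log2 row (0,0,0,1,2,3,4) centered at 10/7
#' @export
log_normalize <- function(rpkm, method = c("log2_center", "linear_mean")) {
  stopifnot(inherits(rpkm, "stage_matrix"))
  method <- match.arg(method)
  if (rpkm$kind != "rpkm")
    stop("log_normalize expects an rpkm matrix", call. = FALSE)
  if (any(rpkm$values < 0)) stop("negative RPKM values", call. = FALSE)
  out <- switch(method,
    log2_center = {
      x <- log2(rpkm$values + 1)
      x - rowMeans(x)
    },
    linear_mean = {
      m <- rowMeans(rpkm$values)
      m[m == 0] <- 1  # all-zero rows stay zero
      log2(rpkm$values / m + 1)
    })
  stage_matrix(out, rpkm$gene_ids, rpkm$lengths_bp, rpkm$stages, "normalized")
}
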