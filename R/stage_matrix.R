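#' Stage-series expression matrix
#'
#' A `stage_matrix` holds one replicate's genes-by-stages expression table
#' together with the metadata every downstream step needs: gene identifiers,
#' gene lengths (bp), the ordered culture days, the kind of value stored
#' (`counts`, `rpkm`, `log_rpkm` or `normalized`) and, for count matrices,
#' the per-stage total of mapped reads used for RPKM scaling.
#'
#' @param values Numeric matrix, genes in rows and stages in columns.
#' @param gene_ids Character vector of unique gene identifiers (row names).
#' @param lengths_bp Positive integer vector of gene lengths in base pairs.
#' @param stages Numeric vector of culture days, strictly increasing
#'   (default `c(2, 4, 6, 8, 10, 12, 14)`).
#' @param kind One of `"counts"`, `"rpkm"`, `"log_rpkm"`, `"normalized"`.
#' @param mapped_totals Per-stage totals of mapped reads; required when
#'   `kind = "counts"`, ignored otherwise.
#'
#' @return An object of class `stage_matrix`.
#' @examples
#' sm <- stage_matrix(matrix(rpois(14, 50), 2, 7),
#'                    gene_ids = c("g1", "g2"), lengths_bp = c(1000, 2000),
#'                    kind = "counts", mapped_totals = rep(1e6, 7))
#' sm
#' @export
stage_matrix <- function(values, gene_ids, lengths_bp,
                         stages = c(2, 4, 6, 8, 10, 12, 14),
                         kind = c("counts", "rpkm", "log_rpkm", "normalized"),
                         mapped_totals = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (length(gene_ids) != nrow(values))
    stop("gene_ids length must equal nrow(values)", call. = FALSE)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene_ids are not allowed", call. = FALSE)
  if (length(lengths_bp) != nrow(values))
    stop("lengths_bp length must equal nrow(values)", call. = FALSE)
  if (any(!is.finite(lengths_bp)) || any(lengths_bp < 1))
    stop("gene lengths must be >= 1 bp", call. = FALSE)
  if (length(stages) != ncol(values))
    stop("stages length must equal ncol(values)", call. = FALSE)
  if (length(stages) < 2)
    stop("at least two stages are required", call. = FALSE)
  if (is.unsorted(stages, strictly = TRUE))
    stop("stages must be strictly increasing days", call. = FALSE)
  if (kind %in% c("counts", "rpkm") && any(values < 0, na.rm = TRUE))
    stop(kind, " values must be non-negative", call. = FALSE)
  if (kind == "counts") {
    if (is.null(mapped_totals))
      stop("mapped_totals are required for count matrices", call. = FALSE)
    if (length(mapped_totals) != ncol(values) || any(mapped_totals <= 0))
      stop("mapped_totals must be positive, one per stage", call. = FALSE)
  }
  dimnames(values) <- list(as.character(gene_ids), paste0("d", stages))
  structure(
    list(values = values,
         gene_ids = as.character(gene_ids),
         lengths_bp = as.numeric(lengths_bp),
         stages = as.numeric(stages),
         kind = kind,
         mapped_totals = if (kind == "counts") as.numeric(mapped_totals) else mapped_totals),
    class = "stage_matrix")
}

#' @export
print.stage_matrix <- function(x, ...) {
  cat(sprintf("stage_matrix [%s]: %d genes x %d stages (days %s)\n",
              x$kind, nrow(x$values), ncol(x$values),
              paste(x$stages, collapse = ",")))
  invisible(x)
}

#' @export
dim.stage_matrix <- function(x) dim(x$values)

#' Subset a stage matrix to a set of genes
#'
#' @param x A [stage_matrix()].
#' @param ids Gene identifiers to keep; order of `ids` is preserved.
#' @return A `stage_matrix` restricted to `ids`.
#' @export
subset_genes <- function(x, ids) {
  stopifnot(inherits(x, "stage_matrix"))
  ids <- as.character(ids)
  missing <- setdiff(ids, x$gene_ids)
  if (length(missing))
    stop("unknown gene ids: ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  idx <- match(ids, x$gene_ids)
  stage_matrix(x$values[idx, , drop = FALSE], ids, x$lengths_bp[idx],
               x$stages, x$kind, x$mapped_totals)
}

#' Write a stage matrix as TSV
#'
#' Layout: optional `#value_kind` / `#mapped_totals` comment header lines,
#' then columns `gene_id`, `length_bp` and one column per stage (`d2`..`d14`).
#'
#' @param x A [stage_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stage_matrix <- function(x, path) {
  stopifnot(inherits(x, "stage_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#value_kind\t", x$kind), con)
  if (!is.null(x$mapped_totals))
    writeLines(paste0("#mapped_totals\t",
                      paste(format(x$mapped_totals, scientific = FALSE, trim = TRUE),
                            collapse = "\t")), con)
  df <- data.frame(gene_id = x$gene_ids, length_bp = x$lengths_bp,
                   x$values, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a stage matrix from TSV
#'
#' Counterpart of [write_stage_matrix()]; recovers value kind and mapped
#' totals from the `#` header lines when present.
#'
#' @param path Input file path.
#' @param kind Override for the value kind when the header has none.
#' @return A [stage_matrix()].
#' @export
read_stage_matrix <- function(path, kind = NULL) {
  header <- character()
  con <- file(path, "r")
  while (length(ln <- readLines(con, 1)) && startsWith(ln, "#"))
    header <- c(header, ln)
  close(con)
  mapped <- NULL
  for (ln in header) {
    f <- strsplit(sub("^#", "", ln), "\t")[[1]]
    if (f[1] == "value_kind" && is.null(kind)) kind <- f[2]
    if (f[1] == "mapped_totals") mapped <- as.numeric(f[-1])
  }
  if (is.null(kind)) kind <- "counts"
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  stage_cols <- grep("^d[0-9]+$", names(df), value = TRUE)
  stages <- as.numeric(sub("^d", "", stage_cols))
  o <- order(stages)
  stage_matrix(as.matrix(df[, stage_cols[o], drop = FALSE]),
               df$gene_id, df$length_bp, stages[o], kind, mapped)
}
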