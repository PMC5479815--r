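#' Default temporal archetype templates
#'
#' Four archetype shapes over culture days 2--14, as relative log2
#' expression, with mixing fractions taken from the four K-means cluster
#' sizes of the organoid study design this simulator emulates
#' (559/1,998/9,658/1,909 genes of 14,124):
#'
#' * `late_rise` -- near-absent early, then a steep ~32-fold rise
#'   concentrated between days 8 and 10 (taste-receptor-like genes);
#' * `early_rise` -- ~4-fold rise, faster before day 8 than after
#'   (precursor/signaling genes);
#' * `flat` -- no change (housekeeping-like background, the majority);
#' * `early_drop` -- ~2.8-fold decrease between days 4 and 6, constant
#'   afterwards (proliferation genes diluted by differentiation).
#'
#' The late-rise magnitude deliberately dominates the others: receptors
#' that are undetectable early and robustly expressed late change far more
#' than 4-fold, and it is this transition that splits early-stage from
#' late-stage samples in the stage dendrogram.
#'
#' @return A list of archetype specifications, each with `name`,
#'   `template` (length-7 numeric) and `fraction`.
#' @export
archetype_templates <- function() {
  list(
    list(name = "late_rise",
         template = c(0, 0, 0, 0, 3.5, 4.5, 5) - 2.5,
         fraction = 559 / 14124),
    list(name = "early_rise",
         template = c(0, 0.7, 1.2, 1.7, 1.85, 2, 2) - 1,
         fraction = 1998 / 14124),
    list(name = "flat",
         template = rep(0, 7),
         fraction = 9658 / 14124),
    list(name = "early_drop",
         template = c(0, 0, -1.5, -1.5, -1.5, -1.5, -1.5),
         fraction = 1909 / 14124)
  )
}

validate_archetypes <- function(archetypes, n_stages = 7) {
  nm <- vapply(archetypes, `[[`, "", "name")
  ok <- c("late_rise", "early_rise", "flat", "early_drop")
  if (!all(nm %in% ok))
    stop("unknown archetype name(s): ", paste(setdiff(nm, ok), collapse = ", "),
         call. = FALSE)
  fr <- vapply(archetypes, `[[`, 0, "fraction")
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-9)
    stop("archetype fractions must be in [0,1] and sum to 1", call. = FALSE)
  for (a in archetypes) {
    t <- a$template
    if (length(t) != n_stages)
      stop("archetype template must have ", n_stages, " stages", call. = FALSE)
    d <- diff(t)
    switch(a$name,
      late_rise = {
        if (any(d < -1e-12) || max(d[1:3]) > min(d[4:6]) + 1e-12)
          stop("late_rise must be non-decreasing with its largest increments at days >= 10",
               call. = FALSE)
      },
      early_rise = {
        if (any(d < -1e-12) || !(min(d[1:3]) > max(d[4:6]) - 1e-12))
          stop("early_rise must be non-decreasing with larger increments before day 8",
               call. = FALSE)
      },
      flat = if (any(abs(d) > 1e-12))
        stop("flat template must be constant", call. = FALSE),
      early_drop = {
        if (d[2] >= 0 || any(abs(d[3:6]) > 1e-12))
          stop("early_drop must decrease between days 4 and 6 and stay constant after",
               call. = FALSE)
      })
  }
  invisible(archetypes)
}

#' Configure the stage-series simulator
#'
#' Defaults are the study conditions the simulator is meant to emulate:
#' two replicate series over days 2--14, archetype fractions matching the
#' reference cluster sizes, negative-binomial counts with gene-wise
#' dispersion (variance \eqn{\mu + \phi\mu^2}), correlated replicates via a
#' per-gene, per-replicate Gaussian offset in log2 space, and a planted
#' "taste transduction"-like category sampled preferentially from
#' late-rise genes.
#'
#' @param n_genes Number of genes to simulate.
#' @param archetypes Archetype specification list, see [archetype_templates()].
#' @param base_mean Expected RPKM at template level 0.
#' @param base_log2_sd SD of the per-gene log2 baseline around
#'   `log2(base_mean)` (gene-to-gene expression heterogeneity).
#' @param dispersion NB dispersion \eqn{\phi \ge 0}; scalar or per-gene
#'   vector. `0` gives Poisson counts.
#' @param replicate_shift_sd SD of the per-gene, per-replicate log2 offset.
#' @param library_sizes Per-stage mapped-read totals (length 7).
#' @param gene_length_range Integer range (min, max) of gene lengths in bp.
#' @param planted_category List with `name`, `size` and `enrichment_fold`
#'   (odds multiplier for drawing members from late-rise genes), or `NULL`
#'   to plant nothing.
#' @param n_decoy_categories Number of uniformly sampled decoy categories.
#' @param decoy_size_range Size range of the decoy categories.
#' @param stages Culture days.
#' @param seed Integer seed; identical configs reproduce identical data.
#'
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000,
                       archetypes = archetype_templates(),
                       base_mean = 32,
                       base_log2_sd = 0.8,
                       dispersion = 0.05,
                       replicate_shift_sd = 0.1,
                       library_sizes = rep(1e7, 7),
                       gene_length_range = c(500L, 5000L),
                       planted_category = list(name = "taste_transduction_like",
                                               size = 50, enrichment_fold = 40),
                       n_decoy_categories = 30,
                       decoy_size_range = c(20L, 100L),
                       stages = c(2, 4, 6, 8, 10, 12, 14),
                       seed = 1L) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  validate_archetypes(cfg$archetypes, length(cfg$stages))
  if (cfg$n_genes < length(cfg$archetypes))
    stop("n_genes must be at least the number of archetypes", call. = FALSE)
  if (any(cfg$dispersion < 0)) stop("dispersion must be >= 0", call. = FALSE)
  if (!length(cfg$dispersion) %in% c(1L, cfg$n_genes))
    stop("dispersion must be scalar or one value per gene", call. = FALSE)
  if (length(cfg$library_sizes) != length(cfg$stages) || any(cfg$library_sizes <= 0))
    stop("library_sizes must be positive, one per stage", call. = FALSE)
  if (cfg$base_mean <= 0) stop("base_mean must be positive", call. = FALSE)
  if (cfg$replicate_shift_sd < 0 || cfg$base_log2_sd < 0)
    stop("standard deviations must be >= 0", call. = FALSE)
  if (length(cfg$gene_length_range) != 2 || cfg$gene_length_range[1] < 1 ||
      diff(cfg$gene_length_range) < 0)
    stop("gene_length_range must be (min >= 1, max >= min)", call. = FALSE)
  if (!is.null(cfg$planted_category) &&
      (is.null(cfg$planted_category$name) || cfg$planted_category$size < 1 ||
       cfg$planted_category$enrichment_fold <= 0))
    stop("planted_category needs a name, size >= 1 and enrichment_fold > 0",
         call. = FALSE)
  invisible(cfg)
}

#' Simulate a two-replicate stage series with known truth
#'
#' Draws counts for two replicate series from the negative binomial with
#' mean \deqn{\mu_{gj} = 2^{b_g + t_{a(g),j} + \delta_{gr}} \cdot
#' L_j \ell_g / 10^9,} i.e. an expected RPKM of
#' \eqn{2^{b_g + t_{a(g),j} + \delta_{gr}}} where \eqn{b_g} is the gene
#' baseline, \eqn{t_{a,j}} the archetype template, \eqn{\delta_{gr}} the
#' replicate offset, \eqn{L_j} the stage library size and \eqn{\ell_g} the
#' gene length. Alongside the two count matrices it returns the true
#' archetype label of every gene and a GMT-style category collection with
#' one planted category enriched in late-rise genes plus uniform decoys.
#'
#' @param config A [sim_config()].
#' @return A list with elements `counts_a`, `counts_b` (both
#'   [stage_matrix()] of kind `"counts"`), `truth` (data.frame `gene_id`,
#'   `archetype`, `planted`) and `gene_sets` (a [gene_set_collection()]).
#' @examples
#' sim <- generate_dataset(sim_config(n_genes = 50, seed = 7))
#' table(sim$truth$archetype)
#' @export
generate_dataset <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_genes
  n_stage <- length(config$stages)
  arch_names <- vapply(config$archetypes, `[[`, "", "name")
  fractions <- vapply(config$archetypes, `[[`, 0, "fraction")
  templates <- do.call(rbind, lapply(config$archetypes, `[[`, "template"))
  rownames(templates) <- arch_names

  # sample from a pool even when it has a single element (avoid sample()'s
  # scalar expansion)
  draw_from <- function(pool, n) pool[sample.int(length(pool), n, replace = TRUE)]

  gene_ids <- sprintf("g%0*d", nchar(n) + 1L, seq_len(n))
  archetype <- sample(arch_names, n, replace = TRUE, prob = fractions)
  lengths_bp <- draw_from(seq(config$gene_length_range[1], config$gene_length_range[2]),
                          n)
  baseline <- log2(config$base_mean) + stats::rnorm(n, 0, config$base_log2_sd)
  offsets <- matrix(stats::rnorm(2L * n, 0, config$replicate_shift_sd), n, 2L)
  phi <- rep_len(config$dispersion, n)

  draw_rep <- function(r) {
    log2_rpkm <- baseline + templates[archetype, , drop = FALSE] + offsets[, r]
    mu <- 2^log2_rpkm * (lengths_bp / 1e3) *
      matrix(config$library_sizes / 1e6, n, n_stage, byrow = TRUE)
    y <- numeric(length(mu))
    pois <- rep(phi == 0, n_stage)
    if (any(pois)) y[pois] <- stats::rpois(sum(pois), mu[pois])
    if (any(!pois)) y[!pois] <- stats::rnbinom(sum(!pois), mu = mu[!pois],
                                               size = rep(1 / phi, n_stage)[!pois])
    stage_matrix(matrix(y, n, n_stage), gene_ids, lengths_bp, config$stages,
                 kind = "counts", mapped_totals = config$library_sizes)
  }
  counts_a <- draw_rep(1L)
  counts_b <- draw_rep(2L)

  categories <- list()
  planted_ids <- character()
  if (!is.null(config$planted_category)) {
    w <- ifelse(archetype == "late_rise", config$planted_category$enrichment_fold, 1)
    size <- min(config$planted_category$size, n)
    planted_ids <- sample(gene_ids, size, prob = w)
    categories[[config$planted_category$name]] <- sort(planted_ids)
  }
  if (config$n_decoy_categories > 0) {
    sizes <- draw_from(seq(config$decoy_size_range[1], min(config$decoy_size_range[2], n)),
                       config$n_decoy_categories)
    for (i in seq_len(config$n_decoy_categories))
      categories[[sprintf("decoy_%02d", i)]] <- sort(sample(gene_ids, sizes[i]))
  }

  list(counts_a = counts_a,
       counts_b = counts_b,
       truth = data.frame(gene_id = gene_ids, archetype = archetype,
                          planted = gene_ids %in% planted_ids,
                          stringsAsFactors = FALSE),
       gene_sets = if (length(categories))
         gene_set_collection(categories, background = gene_ids))
}

#' Write simulator truth labels as TSV
#' @param truth Truth data.frame from [generate_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
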