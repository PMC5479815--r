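#' Negative-binomial log-likelihood
#'
#' Exact log-likelihood of counts under NB with mean `mu` and dispersion
#' `phi` (variance \eqn{\mu + \phi\mu^2}); `phi = 0` degrades to Poisson.
#'
#' @param y Non-negative integer counts.
#' @param mu Fitted means (same length as `y`).
#' @param phi Dispersion, a single value >= 0.
#' @return The summed log-likelihood.
#' @export
nb_loglik <- function(y, mu, phi) {
  mu <- pmax(mu, 1e-12)
  if (phi <= 0) sum(stats::dpois(y, mu, log = TRUE))
  else sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
}

#' Fit a log-link negative-binomial GLM at fixed dispersion
#'
#' Iteratively reweighted least squares with working weights
#' \eqn{w = \mu/(1+\phi\mu)}, run until the relative change in deviance
#' (\eqn{-2\ell}) falls below `tol` or `max_iter` iterations. All-zero
#' response vectors are handled as a degenerate exact fit (mean 0,
#' log-likelihood 0) and flagged.
#'
#' @param y Count vector.
#' @param X Full-rank design matrix (rows = observations).
#' @param offset Per-observation log offset (e.g. log library size).
#' @param dispersion NB dispersion `phi >= 0`.
#' @param tol Relative deviance convergence tolerance.
#' @param max_iter Maximum IRLS iterations.
#' @return A list: `coefficients`, `fitted` (means), `loglik`, `deviance`
#'   (`-2 loglik`), `converged`, `iter`, `all_zero`, `dispersion`, `rank`.
#' @examples
#' y <- rpois(10, 20)
#' f <- fit_nb_glm(y, matrix(1, 10, 1))
#' exp(f$coefficients)  # intercept-only fit recovers the mean of y
#' @export
fit_nb_glm <- function(y, X, offset = rep(0, length(y)), dispersion = 0,
                       tol = 1e-8, max_iter = 100L) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (qr(X)$rank < p) stop("design matrix is rank deficient", call. = FALSE)
  if (length(y) < p) stop("fewer observations than parameters", call. = FALSE)
  if (all(y == 0)) {
    return(list(coefficients = stats::setNames(rep(NA_real_, p), colnames(X)),
                fitted = rep(0, length(y)), loglik = 0, deviance = 0,
                converged = TRUE, iter = 0L, all_zero = TRUE,
                dispersion = dispersion, rank = p))
  }
  phi <- dispersion
  mu <- pmax(y, 1 / 6) + mean(y) / 6
  eta <- log(mu) - offset
  dev <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- mu / (1 + phi * mu)
    z <- eta + (y - mu) / mu
    sw <- sqrt(w)
    fit <- qr(X * sw)
    beta <- qr.coef(fit, z * sw)
    eta <- pmin(pmax(drop(X %*% beta), -30), 30)
    mu <- exp(eta + offset)
    dev_new <- -2 * nb_loglik(y, mu, phi)
    if (is.finite(dev) && abs(dev - dev_new) / (abs(dev_new) + 0.1) < tol) {
      dev <- dev_new
      converged <- TRUE
      break
    }
    dev <- dev_new
  }
  list(coefficients = stats::setNames(drop(beta), colnames(X)),
       fitted = mu, loglik = -dev / 2, deviance = dev,
       converged = converged, iter = it, all_zero = FALSE,
       dispersion = phi, rank = p)
}

# Cox-Reid adjusted profile log-likelihood for the dispersion of one gene
apl_gene <- function(y, X, offset, phi, tol = 1e-8, max_iter = 100L) {
  f <- fit_nb_glm(y, X, offset, phi, tol, max_iter)
  if (f$all_zero) return(0)
  w <- f$fitted / (1 + phi * f$fitted)
  XtWX <- crossprod(X * sqrt(w))
  ld <- determinant(XtWX, logarithm = TRUE)$modulus
  f$loglik - 0.5 * as.numeric(ld)
}

#' Build the stage + replicate design
#'
#' Full model: intercept + stage factor + replicate factor; reduced model:
#' intercept + replicate. Observations are ordered replicate A's stages
#' then replicate B's.
#'
#' @param stages Culture days (factor levels in this order).
#' @param n_reps Number of replicates (2 in the standard design).
#' @return List with `X_full`, `X_reduced`, `stage`, `replicate`.
#' @export
stage_design <- function(stages, n_reps = 2L) {
  stage <- factor(rep(stages, n_reps), levels = stages)
  replicate <- factor(rep(seq_len(n_reps), each = length(stages)))
  if (n_reps == 1L) {
    list(X_full = stats::model.matrix(~ stage),
         X_reduced = matrix(1, length(stages), 1,
                            dimnames = list(NULL, "(Intercept)")),
         stage = stage, replicate = replicate)
  } else {
    list(X_full = stats::model.matrix(~ stage + replicate),
         X_reduced = stats::model.matrix(~ replicate),
         stage = stage, replicate = replicate)
  }
}

#' Estimate NB dispersions for a two-replicate stage series
#'
#' All modes work from the Cox-Reid adjusted profile likelihood (APL) of
#' the dispersion, evaluated per gene on a shared log-dispersion grid and
#' interpolated by splines. `genewise` maximizes each gene's own APL;
#' `common` maximizes the summed APL under one shared dispersion;
#' `shrunk` (default) maximizes the weighted-likelihood combination
#' \deqn{APL_g(\phi) + (prior.df / residual.df)\,\bar{APL}(\phi)} where
#' \eqn{\bar{APL}} is the average APL over all genes -- the
#' empirical-Bayes moderation used by edgeR-style analyses, which pulls
#' unstable genewise values toward the common dispersion. All-zero genes
#' get dispersion 0 and are flagged.
#'
#' @param counts_a,counts_b Count [stage_matrix()] replicates over the
#'   same genes (`counts_b = NULL` fits a stage-only single-replicate
#'   design, which has no residual degrees of freedom and is rejected).
#' @param mode `"shrunk"`, `"genewise"` or `"common"`.
#' @param prior_df Prior degrees of freedom for `"shrunk"` (weight of the
#'   average APL, relative to the residual degrees of freedom).
#' @param phi_max Upper bound of the dispersion search.
#' @param grid_length Number of log-spaced grid points.
#' @return List: `dispersion` (per-gene vector), `common` (pooled value),
#'   `all_zero` (logical flag vector), `mode`.
#' @export
estimate_dispersion <- function(counts_a, counts_b = NULL,
                                mode = c("shrunk", "genewise", "common"),
                                prior_df = 10, phi_max = 10,
                                grid_length = 15L) {
  mode <- match.arg(mode)
  dat <- de_input(counts_a, counts_b)
  Y <- dat$Y
  des <- dat$design
  X <- des$X_full
  n_obs <- ncol(Y)
  if (n_obs < ncol(X) + 1)
    stop("design leaves no residual degrees of freedom to estimate dispersion",
         call. = FALSE)
  if (min(table(des$stage)) < 2)
    stop("need at least two observations per stage across replicates",
         call. = FALSE)
  off <- dat$offset
  all_zero <- rowSums(Y) == 0
  use <- which(!all_zero)
  lgrid <- seq(log(1e-6), log(phi_max), length.out = grid_length)

  # per-gene APL curve over the grid
  apl <- matrix(0, length(use), grid_length)
  for (j in seq_len(grid_length))
    apl[, j] <- vapply(use, function(g) apl_gene(Y[g, ], X, off, exp(lgrid[j])), 0)

  max_spline <- function(vals) {
    f <- stats::splinefun(lgrid, vals)
    opt <- stats::optimize(f, range(lgrid), maximum = TRUE, tol = 1e-4)
    # guard against boundary maxima the interior search can miss
    cand <- c(opt$maximum, lgrid[1], lgrid[grid_length])
    exp(cand[which.max(f(cand))])
  }
  common <- max_spline(colSums(apl))

  phi <- rep(0, nrow(Y))
  phi[use] <- switch(mode,
    common = common,
    genewise = apply(apl, 1, max_spline),
    shrunk = {
      w <- prior_df / (n_obs - ncol(X))
      abar <- colMeans(apl)
      apply(apl, 1, function(v) max_spline(v + w * abar))
    })
  list(dispersion = stats::setNames(phi, rownames(Y)), common = common,
       all_zero = stats::setNames(all_zero, rownames(Y)), mode = mode)
}

# assemble the combined genes x (stages * reps) count matrix and design;
# counts_b may be NULL for a single-replicate design (stage-only model)
de_input <- function(counts_a, counts_b = NULL) {
  stopifnot(inherits(counts_a, "stage_matrix"))
  if (counts_a$kind != "counts")
    stop("differential testing requires raw counts, not ", counts_a$kind,
         "; RPKM cannot be modeled by the NB GLM", call. = FALSE)
  if (is.null(counts_b)) {
    Y <- counts_a$values
    rownames(Y) <- counts_a$gene_ids
    return(list(Y = Y, design = stage_design(counts_a$stages, 1L),
                offset = log(counts_a$mapped_totals)))
  }
  stopifnot(inherits(counts_b, "stage_matrix"))
  if (counts_b$kind != "counts")
    stop("differential testing requires raw counts, not ", counts_b$kind,
         call. = FALSE)
  if (!identical(counts_a$gene_ids, counts_b$gene_ids))
    stop("replicates must share an identical gene universe", call. = FALSE)
  if (!identical(counts_a$stages, counts_b$stages))
    stop("replicates must share the same stages", call. = FALSE)
  Y <- cbind(counts_a$values, counts_b$values)
  rownames(Y) <- counts_a$gene_ids
  list(Y = Y,
       design = stage_design(counts_a$stages, 2L),
       offset = log(c(counts_a$mapped_totals, counts_b$mapped_totals)))
}

#' Likelihood-ratio test between nested fits
#'
#' @param fit_full,fit_reduced Fits from [fit_nb_glm()] on the same counts
#'   with the same dispersion, reduced design nested in the full one.
#' @return List: `lr_stat` (clipped at 0), `df`, `p_value` (chi-square
#'   upper tail).
#' @export
lrt_stage <- function(fit_full, fit_reduced) {
  if (fit_full$rank <= fit_reduced$rank)
    stop("full model must have higher rank than the reduced model", call. = FALSE)
  if (!isTRUE(all.equal(fit_full$dispersion, fit_reduced$dispersion)))
    stop("fits must share the same dispersion", call. = FALSE)
  stat <- max(0, 2 * (fit_full$loglik - fit_reduced$loglik))
  df <- fit_full$rank - fit_reduced$rank
  list(lr_stat = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR-adjusted p-values (monotone in p rank, capped at 1).
#'
#' @param p_values Vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Genewise likelihood-ratio tests across stages
#'
#' Fits, for every gene, the full NB GLM (intercept + stage + replicate)
#' and the reduced model (intercept + replicate) with log library-size
#' offsets and a shared per-gene dispersion, and tests the stage effect
#' with an ANOVA-like likelihood-ratio test on 6 degrees of freedom
#' (7 stages), followed by Benjamini-Hochberg FDR adjustment.
#' Non-converged genes are flagged and their p-values set to `NA` (a
#' message reports the count); all-zero genes test as null.
#'
#' @param counts_a,counts_b Count [stage_matrix()] replicates.
#' @param dispersion_mode Passed to [estimate_dispersion()]; alternatively
#'   supply `dispersion` directly.
#' @param dispersion Optional per-gene (or scalar) dispersion overriding
#'   estimation.
#' @param alpha FDR threshold reported in the `significant` column.
#' @param prior_df Shrinkage prior df, see [estimate_dispersion()].
#' @param tol,max_iter IRLS settings, see [fit_nb_glm()].
#' @return A `data.frame` (one row per gene): `gene_id`, `lr_stat`, `df`,
#'   `p_value`, `fdr`, `dispersion`, `converged`, `significant`, and
#'   per-stage log2 effects relative to the first stage
#'   (`log2fc_d4` ... `log2fc_d14`).
#' @examples
#' sim <- generate_dataset(sim_config(n_genes = 40, seed = 11))
#' de <- de_test(sim$counts_a, sim$counts_b, dispersion = 0.05)
#' head(de[order(de$p_value), c("gene_id", "lr_stat", "p_value", "fdr")])
#' @export
de_test <- function(counts_a, counts_b,
                    dispersion_mode = c("shrunk", "genewise", "common"),
                    dispersion = NULL, alpha = 0.05, prior_df = 10,
                    tol = 1e-8, max_iter = 100L) {
  dat <- de_input(counts_a, counts_b)
  Y <- dat$Y
  des <- dat$design
  n <- nrow(Y)
  if (is.null(dispersion)) {
    dispersion_mode <- match.arg(dispersion_mode)
    phi <- estimate_dispersion(counts_a, counts_b, dispersion_mode,
                               prior_df = prior_df)$dispersion
  } else {
    phi <- rep_len(dispersion, n)
  }
  stage_cols <- grep("^stage", colnames(des$X_full))
  res <- vapply(seq_len(n), function(g) {
    ff <- fit_nb_glm(Y[g, ], des$X_full, dat$offset, phi[g], tol, max_iter)
    fr <- fit_nb_glm(Y[g, ], des$X_reduced, dat$offset, phi[g], tol, max_iter)
    lr <- lrt_stage(ff, fr)
    ok <- ff$converged && fr$converged
    c(lr$lr_stat, lr$df, if (ok) lr$p_value else NA_real_, as.numeric(ok),
      ff$coefficients[stage_cols] / log(2))
  }, numeric(4 + length(stage_cols)))
  res <- t(res)
  n_bad <- sum(res[, 4] == 0)
  if (n_bad > 0)
    message("de_test: ", n_bad, " gene(s) did not converge; excluded from testing")
  fdr <- bh_adjust(res[, 3])
  out <- data.frame(gene_id = rownames(Y),
                    lr_stat = res[, 1], df = as.integer(res[, 2]),
                    p_value = res[, 3], fdr = fdr,
                    dispersion = unname(phi),
                    converged = res[, 4] == 1,
                    significant = !is.na(fdr) & fdr <= alpha,
                    stringsAsFactors = FALSE)
  lfc <- res[, -(1:4), drop = FALSE]
  colnames(lfc) <- paste0("log2fc_d", counts_a$stages[-1])
  cbind(out, lfc)
}
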