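test_that("intercept-only fits recover the arithmetic mean at any dispersion", {
  set.seed(1)
  y <- rpois(12, 30)
  X1 <- matrix(1, 12, 1)
  expect_equal(unname(fit_nb_glm(y, X1, dispersion = 0)$fitted[1]), mean(y),
               tolerance = 1e-6)
  # the NB score equation with a log link and intercept only has the same
  # closed-form solution regardless of phi
  for (phi in c(0.1, 0.5, 2))
    expect_equal(unname(fit_nb_glm(y, X1, dispersion = phi)$fitted[1]), mean(y),
                 tolerance = 1e-6)
})

test_that("a saturated stage model reproduces the observations exactly", {
  set.seed(2)
  y <- rpois(7, 100)
  X <- stats::model.matrix(~ factor(1:7))
  f <- fit_nb_glm(y, X, dispersion = 0)
  expect_equal(unname(f$fitted), as.numeric(y), tolerance = 1e-6)
  expect_equal(f$loglik, nb_loglik(y, y, 0), tolerance = 1e-6)
})

test_that("the reported log-likelihood equals direct NB pmf summation", {
  set.seed(3)
  des <- stage_design(c(2, 4, 6, 8, 10, 12, 14))
  y <- rnbinom(14, mu = 80, size = 10)
  off <- rep(log(1e6), 14)
  f <- fit_nb_glm(y, des$X_full, off, dispersion = 0.1)
  expect_equal(f$loglik, sum(dnbinom(y, size = 10, mu = f$fitted, log = TRUE)),
               tolerance = 1e-8)
})

test_that("all-zero genes yield a flagged degenerate fit and a null test", {
  des <- stage_design(c(2, 4, 6, 8, 10, 12, 14))
  y <- rep(0, 14)
  ff <- fit_nb_glm(y, des$X_full, dispersion = 0.1)
  fr <- fit_nb_glm(y, des$X_reduced, dispersion = 0.1)
  expect_true(ff$all_zero)
  expect_equal(ff$loglik, 0)
  lr <- lrt_stage(ff, fr)
  expect_equal(lr$lr_stat, 0)
  expect_equal(lr$p_value, 1)
})

test_that("the LRT is invariant to reordering observations", {
  set.seed(4)
  des <- stage_design(c(2, 4, 6, 8, 10, 12, 14))
  y <- rnbinom(14, mu = exp(rep(log(50) + c(0, 0, 0, 0.3, 0.6, 0.9, 1), 2)), size = 10)
  off <- rep(0, 14)
  perm <- sample(14)
  lr1 <- lrt_stage(fit_nb_glm(y, des$X_full, off, 0.1),
                   fit_nb_glm(y, des$X_reduced, off, 0.1))
  lr2 <- lrt_stage(fit_nb_glm(y[perm], des$X_full[perm, ], off[perm], 0.1),
                   fit_nb_glm(y[perm], des$X_reduced[perm, , drop = FALSE], off[perm], 0.1))
  expect_equal(lr1$lr_stat, lr2$lr_stat, tolerance = 1e-6)
  expect_identical(lr1$df, 6L)
})

test_that("constant counts across stages give a null LRT", {
  des <- stage_design(c(2, 4, 6, 8, 10, 12, 14))
  y <- rep(50, 14)
  lr <- lrt_stage(fit_nb_glm(y, des$X_full, dispersion = 0.05),
                  fit_nb_glm(y, des$X_reduced, dispersion = 0.05))
  expect_lt(lr$lr_stat, 1e-4)
  expect_gt(lr$p_value, 0.999)
})

test_that("non-nested and mismatched-dispersion comparisons are rejected", {
  des <- stage_design(c(2, 4, 6, 8, 10, 12, 14))
  y <- rpois(14, 40)
  f1 <- fit_nb_glm(y, des$X_reduced, dispersion = 0.1)
  f2 <- fit_nb_glm(y, des$X_reduced, dispersion = 0.1)
  expect_error(lrt_stage(f1, f2), "higher rank")
  f3 <- fit_nb_glm(y, des$X_full, dispersion = 0.2)
  expect_error(lrt_stage(f3, f1), "dispersion")
})

test_that("rank-deficient designs are rejected", {
  expect_error(fit_nb_glm(rpois(4, 10), cbind(1, c(1, 1, 2, 2), c(2, 2, 4, 4))),
               "rank deficient")
})

test_that("genewise dispersion is near zero for Poisson-generated counts", {
  flat_only <- list(list(name = "flat", template = rep(0, 7), fraction = 1))
  sim <- generate_dataset(sim_config(n_genes = 800, archetypes = flat_only,
                                     dispersion = 0, base_log2_sd = 0.5,
                                     planted_category = NULL,
                                     n_decoy_categories = 0, seed = 5))
  ed <- estimate_dispersion(sim$counts_a, sim$counts_b, "genewise")
  expect_lt(median(ed$dispersion), 0.02)
})

test_that("common-mode dispersion recovers the simulation truth", {
  flat_only <- list(list(name = "flat", template = rep(0, 7), fraction = 1))
  sim <- generate_dataset(sim_config(n_genes = 1500, archetypes = flat_only,
                                     dispersion = 0.1, planted_category = NULL,
                                     n_decoy_categories = 0, seed = 6))
  ed <- estimate_dispersion(sim$counts_a, sim$counts_b, "common")
  expect_lt(abs(ed$common - 0.1) / 0.1, 0.1)
  # shrunk estimates sit between genewise and common
  es <- estimate_dispersion(sim$counts_a, sim$counts_b, "shrunk")
  expect_lt(mad(log(es$dispersion)),
            mad(log(pmax(estimate_dispersion(sim$counts_a, sim$counts_b,
                                             "genewise")$dispersion, 1e-6))))
})

test_that("dispersion estimation refuses unidentifiable designs", {
  sim <- generate_dataset(sim_config(n_genes = 20, seed = 7))
  # one observation per stage: the saturated stage model leaves no residual df
  expect_error(estimate_dispersion(sim$counts_a), "degrees of freedom")
})

test_that("null p-values are approximately uniform when counts are deep enough for the chi-square reference", {
  flat_only <- list(list(name = "flat", template = rep(0, 7), fraction = 1))
  sim <- generate_dataset(sim_config(n_genes = 2000, archetypes = flat_only,
                                     dispersion = 0.1, base_mean = 256,
                                     planted_category = NULL,
                                     n_decoy_categories = 0, seed = 105))
  de <- de_test(sim$counts_a, sim$counts_b, dispersion = 0.1)
  expect_gt(stats::ks.test(de$p_value, "punif")$p.value, 0.01)
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.3, 0.02, 1, 0.04)
  adj <- bh_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))  # monotone in p rank
  expect_true(all(adj <= 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("de_test refuses RPKM input and reports the full funnel", {
  sim <- generate_dataset(sim_config(n_genes = 60, seed = 8))
  expect_error(de_test(compute_rpkm(sim$counts_a), compute_rpkm(sim$counts_b)),
               "counts")
  de <- de_test(sim$counts_a, sim$counts_b, dispersion = 0.05)
  expect_identical(nrow(de), 60L)
  expect_true(all(de$df == 6L))
  expect_true(all(de$lr_stat >= 0))
  expect_true(all(de$p_value >= 0 & de$p_value <= 1, na.rm = TRUE))
  expect_true(all(c("log2fc_d4", "log2fc_d14") %in% names(de)))
})

test_that("LRT statistics agree with an independent NB GLM implementation", {
  skip_if_not_installed("edgeR")
  sim <- generate_dataset(sim_config(n_genes = 100, seed = 42))
  de <- de_test(sim$counts_a, sim$counts_b, dispersion = 0.05)
  Y <- cbind(sim$counts_a$values, sim$counts_b$values)
  des <- stage_design(sim$counts_a$stages)
  off <- log(c(sim$counts_a$mapped_totals, sim$counts_b$mapped_totals))
  fit <- edgeR::glmFit(Y, des$X_full, offset = off, dispersion = 0.05,
                       prior.count = 0)
  lrt <- edgeR::glmLRT(fit, coef = 2:7)
  expect_lt(max(abs(lrt$table$LR - de$lr_stat)), 1e-4)
})

test_that("strong stage effects are detected and flat genes mostly are not", {
  sim <- generate_dataset(sim_config(n_genes = 400, dispersion = 0.05, seed = 9))
  de <- de_test(sim$counts_a, sim$counts_b, dispersion = 0.05)
  arch <- sim$truth$archetype[match(de$gene_id, sim$truth$gene_id)]
  expect_gt(mean(de$significant[arch == "late_rise"]), 0.9)
  expect_lt(mean(de$significant[arch == "flat"]), 0.15)
})
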