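norm_fixture <- function(values, stages = c(2, 4, 6, 8, 10, 12, 14)) {
  values <- as.matrix(values)
  values <- values - rowMeans(values)
  stage_matrix(values, sprintf("g%d", seq_len(nrow(values))),
               rep(1000, nrow(values)), stages[seq_len(ncol(values))],
               kind = "normalized")
}

test_that("k = 1 degenerates to the column-mean center", {
  set.seed(2)
  X <- norm_fixture(matrix(rnorm(70), 10, 7))
  m <- kmeans_cluster(X, k = 1, n_starts = 3, max_iter = 100, seed = 1)
  expect_equal(unname(m$centers[1, ]), unname(colMeans(X$values)))
  expect_equal(m$within_ss, sum(sweep(X$values, 2, colMeans(X$values))^2))
  expect_true(all(m$assignments == 1L))
})

test_that("clustering agrees exactly with exhaustive within-SS minimization on tiny instances", {
  set.seed(42)
  cases <- expand.grid(n = c(5, 6, 8), k = c(2, 3))
  for (i in seq_len(nrow(cases))) {
    n <- cases$n[i]; k <- cases$k[i]
    for (rep in 1:3) {
      # mix of structured and unstructured point clouds
      X <- matrix(rnorm(n * 3), n, 3)
      if (rep == 1) X <- X + 3 * matrix(rnorm(k * 3), k, 3)[sample(k, n, TRUE), ]
      Xm <- norm_fixture(cbind(X, 0), stages = c(2, 4, 6, 8))
      m <- kmeans_cluster(Xm, k = k, n_starts = 100, max_iter = 500, seed = rep)
      expect_equal(m$within_ss, brute_kmeans_wss(Xm$values, k), tolerance = 1e-8)
    }
  }
})

test_that("two well-separated profile groups are recovered as the optimal bipartition", {
  X <- norm_fixture(rbind(matrix(rnorm(9, 0, 0.1), 3, 3) + rep(c(-2, 0, 2), each = 3),
                          matrix(rnorm(9, 0, 0.1), 3, 3) + rep(c(2, 0, -2), each = 3)),
                    stages = c(2, 4, 6))
  m <- kmeans_cluster(X, k = 2, n_starts = 20, max_iter = 100, seed = 5)
  expect_identical(unname(m$assignments[1:3]), rep(m$assignments[[1]], 3))
  expect_identical(unname(m$assignments[4:6]), rep(m$assignments[[4]], 3))
  expect_false(m$assignments[[1]] == m$assignments[[4]])
  expect_equal(m$within_ss, brute_kmeans_wss(X$values, 2), tolerance = 1e-8)
})

test_that("centers equal the means of their assigned profiles and defaults are recorded", {
  set.seed(9)
  X <- norm_fixture(matrix(rnorm(35 * 7), 35, 7))
  m <- kmeans_cluster(X, k = 4, seed = 3, max_iter = 1000)
  for (cl in seq_len(4)) {
    members <- X$values[m$assignments == cl, , drop = FALSE]
    expect_gt(nrow(members), 0)
    expect_equal(unname(m$centers[cl, ]), unname(colMeans(members)),
                 tolerance = 1e-6)
  }
  expect_identical(m$n_starts, 30L)
  expect_identical(m$max_iter, 1000L)
  expect_identical(m$k, 4L)
})

test_that("more restarts never worsen the best within-SS at a fixed seed stream", {
  set.seed(13)
  X <- norm_fixture(matrix(rnorm(40 * 7), 40, 7))
  w <- vapply(c(1, 5, 15, 30), function(s)
    kmeans_cluster(X, k = 3, n_starts = s, max_iter = 500, seed = 7)$within_ss, 0)
  expect_true(all(diff(w) <= 1e-12))
})

test_that("gene order does not affect the recovered partition on separable data", {
  skip_if_not_installed("mclust")
  sim <- generate_dataset(sim_config(n_genes = 300, dispersion = 0.01,
                                     replicate_shift_sd = 0, seed = 21))
  X <- log_normalize(compute_rpkm(sim$counts_a))
  m1 <- kmeans_cluster(X, seed = 2, max_iter = 1000)
  perm <- sample(nrow(X$values))
  Xp <- subset_genes(X, X$gene_ids[perm])
  m2 <- kmeans_cluster(Xp, seed = 2, max_iter = 1000)
  common <- X$gene_ids
  expect_equal(mclust::adjustedRandIndex(m1$assignments[common],
                                         m2$assignments[common]), 1)
})

test_that("the seeded Lloyd implementation matches stats::kmeans on separable data", {
  skip_if_not_installed("mclust")
  sim <- generate_dataset(sim_config(n_genes = 400, dispersion = 0.02, seed = 25))
  X <- log_normalize(compute_rpkm(sim$counts_a))
  mine <- kmeans_cluster(X, k = 4, n_starts = 30, max_iter = 1000, seed = 6)
  ref <- stats::kmeans(X$values, 4, nstart = 30, iter.max = 1000,
                       algorithm = "Lloyd")
  expect_equal(mclust::adjustedRandIndex(mine$assignments, ref$cluster), 1)
  expect_equal(mine$within_ss, ref$tot.withinss, tolerance = 1e-6)
})

test_that("invalid clustering inputs are rejected", {
  X <- norm_fixture(matrix(rnorm(21), 3, 7))
  expect_error(kmeans_cluster(X, k = 5, seed = 1), "exceeds")
  X$values[1, 1] <- NA
  expect_error(kmeans_cluster(X, k = 2, seed = 1), "non-finite")
})

test_that("archetype labeling recovers a planted permutation of templates", {
  tm <- archetype_templates()
  T <- do.call(rbind, lapply(tm, `[[`, "template"))
  T <- T - rowMeans(T)
  nm <- vapply(tm, `[[`, "", "name")
  perm <- c(3, 1, 4, 2)
  model <- make_model(setNames(perm[c(1, 2, 3, 4)], paste0("g", 1:4)),
                      T[perm, ], stages = c(2, 4, 6, 8, 10, 12, 14))
  labeled <- label_archetypes(model, tm)
  expect_identical(labeled$archetype_labels, nm[perm])
  # small perturbations do not change the labeling
  set.seed(4)
  noisy <- model
  noisy$centers <- noisy$centers + matrix(rnorm(28, 0, 0.05), 4, 7)
  expect_identical(label_archetypes(noisy, tm)$archetype_labels, nm[perm])
})

test_that("flat centers are matched through the degenerate-correlation fallback", {
  tm <- archetype_templates()[c(1, 3)]  # late_rise and flat
  centers <- rbind(rep(0, 7),
                   tm[[1]]$template - mean(tm[[1]]$template))
  model <- make_model(setNames(c(1L, 2L), c("g1", "g2")), centers)
  labeled <- label_archetypes(model, tm)
  expect_identical(labeled$archetype_labels, c("flat", "late_rise"))
})

test_that("labeling requires one template per cluster", {
  model <- make_model(setNames(1:2, c("g1", "g2")), matrix(0, 2, 7))
  expect_error(label_archetypes(model, archetype_templates()), "one template")
})

test_that("stage clustering merges the closest pair first", {
  # three columns with pairwise distances (1, 5, 5)
  v <- cbind(c(0, 0), c(1, 0), c(-3, 4))  # d(1,2)=1, d(1,3)=5, d(2,3)~5.83
  X <- stage_matrix(v, c("a", "b"), c(1, 1), stages = c(2, 4, 6), kind = "log_rpkm")
  dend <- cluster_stages(X)
  expect_equal(dend$heights[1], 1)
  expect_identical(sort(dend$hclust$merge[1, ]), c(-2L, -1L))
})

test_that("identical columns merge at height zero", {
  X <- stage_matrix(matrix(5, 3, 4), c("a", "b", "c"), rep(1, 3),
                    stages = c(2, 4, 6, 8), kind = "log_rpkm")
  dend <- cluster_stages(X)
  expect_true(all(dend$heights == 0))
})

test_that("stage dendrograms serialize to Newick", {
  sim <- generate_dataset(sim_config(n_genes = 100, seed = 14))
  dend <- cluster_stages(log_transform(compute_rpkm(sim$counts_a)))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(dend, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, paste0("d", c(2, 4, 6, 8, 10, 12, 14)))
})
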