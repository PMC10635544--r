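test_that("fractional descending ranks follow the mean-rank convention", {
  expect_equal(unname(rank_with_ties(c(5, 3, 1))), c(1, 2, 3))
  expect_equal(unname(rank_with_ties(c(5, 3, 3, 1))), c(1, 2.5, 2.5, 4))
  expect_equal(unname(rank_with_ties(rep(2, 7))), rep(4, 7))
  expect_error(rank_with_ties(c(1, Inf)), "finite")
})

test_that("outlier detection is conjunctive with a worst-rank selector", {
  grid_n <- 10
  traces <- rbind(s1 = rep(450, grid_n),
                  s2 = rep(50, grid_n),
                  s3 = rep(80, grid_n))
  expect_identical(detect_outlier(traces), "s1")

  # a single dip below the cutoff disqualifies
  traces_dip <- traces
  traces_dip["s1", 4] <- 150
  expect_identical(detect_outlier(traces_dip), NA_character_)

  # two qualifying traces: the one with the larger maximum wins
  traces2 <- rbind(s1 = rep(450, grid_n), s2 = rep(300, grid_n),
                   s3 = rep(10, grid_n))
  expect_identical(detect_outlier(traces2), "s1")
})

test_that("median optimal threshold snaps even-length medians to the grid", {
  expect_equal(median_optimal_threshold(c(0.93, 0.946, 0.95)), 0.946)
  expect_equal(median_optimal_threshold(c(0.90, 0.92)), 0.91)
  expect_equal(median_optimal_threshold(0.5), 0.5)
  grid <- c(0.1, 0.2, 0.3, 0.4)
  # median 0.25 is equidistant from 0.2 and 0.3: smaller wins
  expect_equal(median_optimal_threshold(c(0.2, 0.3), grid), 0.2)
  expect_error(median_optimal_threshold(numeric()), "no thresholds")
})

test_that("a zero-noise planted clique tunes to the smallest threshold", {
  # seeds + neighbors mutually r = 1, background uncorrelated: the held-out
  # seed ties with the module at every threshold, so the mean-rank argmin
  # tie resolves to the first grid value
  genes <- c(paste0("s", 1:4), paste0("n", 1:6), paste0("b", 1:10))
  W <- matrix(0, 20, 20, dimnames = list(genes, genes))
  module <- c(paste0("s", 1:4), paste0("n", 1:6))
  W[module, module] <- 1
  diag(W) <- 1
  net <- network_from_weights(W)
  grid <- threshold_grid(0.1, 0.9, 0.1)
  inner <- inner_loocv(net, paste0("s", 1:4), grid)
  expect_equal(inner$optimal_tau, grid[1])
  # pool = 17 genes (3 scorers removed); the held-out seed ties with the 6
  # neighbors at the top score, so its fractional rank is (7 + 1) / 2 = 4
  expect_equal(unname(inner$traces[1, ]), rep(4, length(grid)))

  expect_equal(inner_loocv(net, paste0("s", 1:4), 0.5)$optimal_tau, 0.5)
})

test_that("nested LOOCV equals the brute-force oracle on random networks", {
  grid <- threshold_grid(0.045, 0.945, 0.045)  # 21 thresholds
  for (s in 1:5) {
    n_genes <- sample(10:20, 1)
    n_seeds <- sample(3:4, 1)
    net <- correlation_network(random_profiles(n_genes, seed = 100 + s))
    seeds <- rownames(net$weights)[seq_len(n_seeds)]
    if (n_seeds < 4) {
      expect_error(outer_loocv(net, seeds, grid), ">= 4")
      next
    }
    ours <- outer_loocv(net, seeds, grid)
    oracle <- oracle_nested_loocv(net$weights, seeds, grid)
    expect_equal(ours$folds$optimal_tau, oracle$folds$optimal_tau)
    expect_equal(ours$folds$test_rank, oracle$folds$test_rank)
    expect_identical(ours$folds$excluded_outlier,
                     oracle$folds$excluded_outlier)
    expect_equal(ours$observed, oracle$observed)
  }
})

test_that("ranks are invariant under gene reordering", {
  profiles <- random_profiles(25, seed = 7)
  seeds <- rownames(profiles)[1:5]
  grid <- threshold_grid(0.1, 0.9, 0.1)
  a <- outer_loocv(correlation_network(profiles), seeds, grid)
  set.seed(1)
  b <- outer_loocv(correlation_network(profiles[sample(25), ]), seeds, grid)
  expect_equal(a$folds[order(a$folds$test_seed), ],
               b$folds[order(b$folds$test_seed), ], ignore_attr = TRUE)
})

test_that("final prediction recovers a noiseless module exactly", {
  sim <- simulate_timecourse(synthetic_spec(n_background = 100,
    n_module_true_neighbors = 20, n_seeds = 6, module_noise_sd_log2 = 0,
    rng_seed = 9))
  net <- correlation_network(fold_change_profiles(sim$expression))
  seeds <- sim$truth$gene_id[sim$truth$role == "seed"]
  neighbors <- sim$truth$gene_id[sim$truth$role == "true_neighbor"]
  pred <- predict_candidates(net, seeds, threshold_grid(), k = 20)
  expect_setequal(pred$top, neighbors)
  expect_false(any(seeds %in% pred$ranking$gene_id))

  # k = pool size returns the whole ranked pool
  all_pool <- final_prediction(net, seeds, pred$median_tau,
                               k = length(net$gene_ids) - length(seeds))
  expect_equal(length(all_pool$top), length(net$gene_ids) - length(seeds))
  expect_error(final_prediction(net, seeds, 0.5,
                                k = length(net$gene_ids)), "exceeds")
})

test_that("random seed sets rank near the middle of the pool", {
  ranks <- vapply(1:20, function(s) {
    profiles <- random_profiles(60, seed = 200 + s)
    net <- correlation_network(profiles)
    set.seed(s)
    seeds <- sample(rownames(profiles), 5)
    outer_loocv(net, seeds, threshold_grid(0.1, 0.9, 0.1))$observed
  }, numeric(1))
  pool <- 60 - 4
  expect_gt(mean(ranks), pool / 2 * 0.9)
  expect_lt(mean(ranks), pool / 2 * 1.35)
})

test_that("permutation p attains the add-one lower bound on a planted module", {
  sim <- simulate_timecourse(synthetic_spec(n_background = 80,
    n_module_true_neighbors = 15, n_seeds = 5, module_noise_sd_log2 = 0,
    rng_seed = 13))
  net <- correlation_network(fold_change_profiles(sim$expression))
  seeds <- sim$truth$gene_id[sim$truth$role == "seed"]
  perm <- permutation_test(net, seeds, B = 999, rng_seed = 5, tau = 0.99)
  expect_equal(perm$p, 1 / 1000)
  expect_equal(perm$n_leq, 0)
  expect_true(all(perm$null_stats >= perm$observed))
})

test_that("permutation results are bit-identical under a fixed seed", {
  net <- correlation_network(random_profiles(40, seed = 3))
  seeds <- rownames(net$weights)[1:4]
  a <- permutation_test(net, seeds, B = 200, rng_seed = 17, tau = 0.5)
  b <- permutation_test(net, seeds, B = 200, rng_seed = 17, tau = 0.5)
  expect_identical(a$null_stats, b$null_stats)
  expect_identical(a$p, b$p)
})

test_that("permutation p is calibrated when seeds come from the null", {
  net <- correlation_network(random_profiles(50, seed = 31))
  genes <- net$gene_ids
  set.seed(99)
  pvals <- vapply(1:200, function(i) {
    seeds <- sample(genes, 4)
    permutation_test(net, seeds, B = 199, rng_seed = 1000 + i,
                     tau = 0.5)$p
  }, numeric(1))
  frac <- mean(pvals <= 0.05)
  expect_gt(frac, 0.01)
  expect_lt(frac, 0.12)
})

test_that("nested-policy permutation reruns the full tuning per replicate", {
  net <- correlation_network(random_profiles(15, seed = 21))
  seeds <- rownames(net$weights)[1:4]
  grid <- threshold_grid(0.1, 0.9, 0.1)
  perm <- permutation_test(net, seeds, B = 20, rng_seed = 2,
                           tau_policy = "nested", grid = grid)
  expect_equal(perm$observed, outer_loocv(net, seeds, grid)$observed)
  expect_true(perm$p >= 1 / 21 && perm$p <= 1)
})
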