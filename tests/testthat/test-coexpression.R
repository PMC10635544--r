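test_that("correlation network has the expected exact values", {
  x <- c(1, 2, 3, 5, 4)
  profiles <- rbind(a = x, b = -x, c = c(1, 2, 3, 2, 1))
  colnames(profiles) <- paste0("wk", c(1, 2, 4, 6, 8))
  net <- correlation_network(profiles)
  expect_equal(net$weights["a", "a"], 1)
  expect_equal(net$weights["a", "b"], -1)
  expect_true(isSymmetric(net$weights))
  expect_true(all(abs(net$weights) <= 1))

  # hand value: x=(1,2,3), y=(1,3,2) -> r = 0.5
  p3 <- rbind(a = c(1, 2, 3), b = c(1, 3, 2))
  colnames(p3) <- paste0("t", 1:3)
  expect_equal(correlation_network(p3)$weights["a", "b"], 0.5)
})

test_that("zero-variance profiles are flagged and decorrelated", {
  profiles <- rbind(a = c(1, 2, 3, 4, 5), flat = rep(2, 5))
  colnames(profiles) <- paste0("wk", c(1, 2, 4, 6, 8))
  net <- correlation_network(profiles)
  expect_identical(net$flagged, "flat")
  expect_equal(net$weights["a", "flat"], 0)
  expect_equal(net$weights["flat", "flat"], 1)  # diagonal stays defined
  # it can never pass any positive threshold
  expect_false(any(binarize(net, 0.001)["flat", ]))
})

test_that("binarization is a signed threshold rule with empty diagonal", {
  W <- diag(3)
  dimnames(W) <- list(c("a", "b", "c"), c("a", "b", "c"))
  W["a", "b"] <- W["b", "a"] <- 0.95
  W["a", "c"] <- W["c", "a"] <- -1
  W["b", "c"] <- W["c", "b"] <- 0.5
  net <- network_from_weights(W)
  expect_true(binarize(net, 0.946)["a", "b"])
  expect_false(binarize(net, 0.951)["a", "b"])
  expect_false(any(diag(binarize(net, 0.001))))
  # anti-correlated pair never connects at any positive threshold
  for (tau in c(0.001, 0.5, 0.999)) {
    expect_false(binarize(net, tau)["a", "c"])
  }
  # absolute-value variant picks it up
  expect_true(binarize(net, 0.5, absolute = TRUE)["a", "c"])
  # tau just above zero on an all-positive network: complete graph
  Wp <- matrix(0.3, 4, 4); diag(Wp) <- 1
  dimnames(Wp) <- list(letters[1:4], letters[1:4])
  A <- binarize(network_from_weights(Wp), 0.001)
  expect_equal(sum(A), 4 * 3)
  expect_error(binarize(net, 0), "tau")
})

test_that("neighborhood scores count direct seed connections", {
  genes <- c("A", "B", "C", "D", "E")
  W <- matrix(0, 5, 5, dimnames = list(genes, genes))
  diag(W) <- 1
  W["A", "C"] <- W["C", "A"] <- 0.9
  W["B", "C"] <- W["C", "B"] <- 0.9
  W["A", "D"] <- W["D", "A"] <- 0.9
  adj <- binarize(network_from_weights(W), 0.5)
  sc <- neighborhood_scores(adj, c("A", "B"))
  expect_equal(sc, c(C = 2L, D = 1L, E = 0L))
  expect_error(neighborhood_scores(adj, character()), "empty")
  expect_error(neighborhood_scores(adj, "Z"), "not in network")
})

test_that("a gene connected to every seed scores the seed count", {
  genes <- c(paste0("s", 1:10), "hub", "iso")
  W <- matrix(0, 12, 12, dimnames = list(genes, genes))
  diag(W) <- 1
  W["hub", paste0("s", 1:10)] <- W[paste0("s", 1:10), "hub"] <- 0.99
  sc <- neighborhood_scores(binarize(network_from_weights(W), 0.9),
                            paste0("s", 1:10))
  expect_equal(sc[["hub"]], 10L)
  expect_equal(sc[["iso"]], 0L)
})

test_that("edge sets nest and scores decrease as the threshold rises", {
  for (s in 1:5) {
    net <- correlation_network(random_profiles(30, seed = s))
    seeds <- rownames(net$weights)[1:4]
    grid <- threshold_grid(0.05, 0.95, 0.05)
    prev_adj <- NULL
    prev_sc <- NULL
    for (tau in grid) {
      adj <- binarize(net, tau)
      sc <- neighborhood_scores(adj, seeds)
      if (!is.null(prev_adj)) {
        expect_false(any(adj & !prev_adj))   # nesting
        expect_true(all(sc <= prev_sc))      # monotone scores
      }
      prev_adj <- adj
      prev_sc <- sc
    }
  }
})

test_that("the network is equivariant under gene reordering", {
  profiles <- random_profiles(15, seed = 3)
  net <- correlation_network(profiles)
  perm <- sample(15)
  net_p <- correlation_network(profiles[perm, ])
  expect_equal(net_p$weights, net$weights[perm, perm])
})

test_that("a noiseless planted module is a perfect clique", {
  sim <- simulate_timecourse(synthetic_spec(n_background = 30,
    n_module_true_neighbors = 10, n_seeds = 5, module_noise_sd_log2 = 0,
    rng_seed = 4))
  prof <- fold_change_profiles(sim$expression)
  net <- correlation_network(prof)
  module <- sim$truth$gene_id[sim$truth$role %in% c("seed", "true_neighbor")]
  expect_equal(min(net$weights[module, module]), 1, tolerance = 1e-12)
  seeds <- sim$truth$gene_id[sim$truth$role == "seed"]
  for (tau in c(0.1, 0.9, 0.999)) {
    sc <- neighborhood_scores(binarize(net, tau), seeds)
    neigh <- sim$truth$gene_id[sim$truth$role == "true_neighbor"]
    expect_true(all(sc[neigh] == length(seeds)))
  }
})
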