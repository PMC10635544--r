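# Helpers building intensity matrices whose group means are exact.

test_that("low-intensity filter removes genes below the pooled quantile in all samples", {
  # 10 genes x 12 samples; gene g1 sits below the pooled 20th percentile
  # everywhere, the rest are well above it
  set.seed(1)
  vals <- matrix(runif(120, 100, 200), 10, 12)
  vals[1, ] <- runif(12, 1, 2)
  dimnames(vals) <- list(paste0("g", 1:10), paste0("s", 1:12))
  design <- data.frame(sample_id = paste0("s", 1:12),
                       group = rep(c("control", "uv"), 6),
                       week = rep(c(1, 2), 6), replicate = rep(1:6, each = 2))
  expr <- expression_data(vals, design)

  cutoff <- quantile(as.vector(vals), 0.20, names = FALSE)
  expect_true(all(vals[1, ] < cutoff))  # fixture sanity, by sorting pooled values
  expect_identical(low_intensity_filter(expr, 0.20), paste0("g", 2:10))

  # below the cutoff in 11 of 12 samples but not the 12th: retained
  vals2 <- vals
  vals2[2, ] <- c(rep(1.5, 11), 150)
  expr2 <- expression_data(vals2, design)
  expect_true("g2" %in% low_intensity_filter(expr2, 0.20))

  # fraction 0: nothing is ever below the minimum
  expect_identical(low_intensity_filter(expr, 0), paste0("g", 1:10))
})

test_that("control-drift exclusion is a symmetric fold-ratio rule", {
  ctrl1 <- c(a = 100, b = 100, c = 160, d = 100)
  ctrl8 <- c(a = 160, b = 140, c = 100, d = 100)
  uv <- matrix(100, 4, 5, dimnames = list(names(ctrl1), NULL))
  expr <- expression_from_means(ctrl1, ctrl8, uv)
  drift <- control_drift_genes(expr, fold = 1.5)
  expect_true("a" %in% drift)     # ratio 1.6
  expect_false("b" %in% drift)    # ratio 1.4
  expect_true("c" %in% drift)     # 1.6 the other way: symmetric
  expect_false("d" %in% drift)

  expr0 <- expression_from_means(c(a = 0, b = 100), c(a = 100, b = 100),
                                 matrix(100, 2, 5,
                                        dimnames = list(c("a", "b"), NULL)))
  expect_error(control_drift_genes(expr0), "gene 'a'")
})

test_that("fold-change profiles are log2 of UV mean over week-1 control mean", {
  ctrl1 <- c(a = 100, b = 100, c = 100)
  uv <- rbind(a = c(400, 100, 100, 100, 100),
              b = c(25, 100, 100, 100, 100),
              c = rep(100, 5))
  expr <- expression_from_means(ctrl1, ctrl1, uv)
  prof <- fold_change_profiles(expr)
  expect_equal(prof["a", "wk1"], 2)
  expect_equal(prof["b", "wk1"], -2)
  expect_equal(unname(prof["c", ]), rep(0, 5))
})

test_that("per-week Welch test matches t.test and handles degeneracy", {
  # identical groups: p = 1 by convention
  ctrl1 <- c(a = 256)
  uv <- matrix(256, 1, 5, dimnames = list("a", NULL))
  expr <- expression_from_means(ctrl1, ctrl1, uv)
  expect_equal(unname(per_week_test(expr)["a", ]), rep(1, 5))

  # hand-built separated groups: uv log2 {9.9,10,10.1} vs ctrl {7.9,8,8.1}
  vals <- cbind(matrix(2^c(7.9, 8, 8.1), 1), matrix(2^8, 1, 3),
                matrix(rep(2^c(9.9, 10, 10.1), 5), 1))
  design <- data.frame(
    sample_id = paste0("s", 1:21),
    group = c(rep("control", 6), rep("uv", 15)),
    week = c(rep(1, 3), rep(8, 3), rep(c(1, 2, 4, 6, 8), each = 3)),
    replicate = rep(1:3, 7))
  dimnames(vals) <- list("a", design$sample_id)
  expr <- expression_data(vals, design)
  p <- per_week_test(expr)
  expect_lt(p["a", "wk1"], 0.001)
  # dual route: Welch t.test on the same log2 values
  ref <- t.test(c(9.9, 10, 10.1), c(7.9, 8, 8.1))
  expect_equal(unname(p["a", "wk1"]), ref$p.value, tolerance = 1e-12)

  # two-sided symmetry: swapping the groups leaves p unchanged
  ref_swap <- t.test(c(7.9, 8, 8.1), c(9.9, 10, 10.1))
  expect_equal(ref$p.value, ref_swap$p.value)
})

test_that("row-wise Welch p-values agree with t.test on random matrices", {
  set.seed(9)
  for (i in 1:5) {
    sim <- simulate_timecourse(synthetic_spec(n_background = 20,
      n_module_true_neighbors = 5, n_seeds = 3, rng_seed = i))
    p <- per_week_test(sim$expression)
    d <- sim$expression$design
    lg <- log2(sim$expression$values)
    ref_samples <- d$sample_id[d$group == "control" & d$week == 1]
    gene <- sample(rownames(lg), 1)
    wk <- sample(c(1, 2, 4, 6, 8), 1)
    uv_samples <- d$sample_id[d$group == "uv" & d$week == wk]
    ref <- t.test(lg[gene, uv_samples], lg[gene, ref_samples])
    expect_equal(unname(p[gene, paste0("wk", wk)]), ref$p.value,
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment is the step-up procedure", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.5, 7)), rep(0.5, 7))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  # q >= p elementwise and order invariance
  set.seed(4)
  for (i in 1:10) {
    p <- runif(50)
    q <- bh_adjust(p)
    expect_true(all(q >= p))
    perm <- sample(50)
    expect_equal(bh_adjust(p[perm]), q[perm])
  }
})

test_that("DEG selection applies thresholds, exclusions and the tie rule", {
  weeks <- paste0("wk", c(1, 2, 4, 6, 8))
  profiles <- rbind(
    up1  = c(1.5, 0, 0, 0, 0),
    up2  = c(0, 0, 0, 2, 2),
    dn1  = c(-1.2, 0, 0, 0, 0),
    dn2  = c(0, 0, -3, 0, 0),
    dn3  = c(0, 0, 0, 0, -1.0),
    ns1  = c(0.9, 0.9, 0.9, 0.9, 0.9),       # below two-fold everywhere
    ns2  = c(3, 0, 0, 0, 0),                 # big fold but q too large
    drf  = c(3, 3, 3, 3, 3),                 # drift-excluded despite fc
    low  = c(-3, -3, -3, -3, -3),            # low-intensity takes precedence
    tie  = c(2, -2, 0, 0, 0))                # +/- tie at the max: down
  colnames(profiles) <- weeks
  q <- matrix(0, nrow(profiles), 5, dimnames = dimnames(profiles))
  q["ns2", ] <- 0.2

  deg <- select_degs(profiles, q, drift_excluded = c("drf", "low"),
                     low_excluded = "low")
  dir <- setNames(deg$direction, deg$gene_id)
  expect_identical(unname(dir[c("up1", "up2")]), c("up", "up"))
  expect_identical(unname(dir[c("dn1", "dn2", "dn3")]), rep("down", 3))
  expect_identical(unname(dir["ns1"]), "not_significant")
  expect_identical(unname(dir["ns2"]), "not_significant")
  expect_identical(unname(dir["drf"]), "excluded_drift")
  expect_identical(unname(dir["low"]), "excluded_low_intensity")
  expect_identical(unname(dir["tie"]), "down")
  expect_equal(sum(dir == "up"), 2)
  expect_equal(sum(dir == "down"), 4)
})

test_that("drift genes and only drift genes are excluded across seeded runs", {
  hits <- vapply(1:20, function(s) {
    sim <- simulate_timecourse(synthetic_spec(n_background = 50,
      n_module_true_neighbors = 10, n_seeds = 4, n_drift = 8,
      noise_sd_log2 = 0.05, module_noise_sd_log2 = 0.05, drift_fold = 2,
      rng_seed = s))
    excluded <- control_drift_genes(sim$expression, 1.5)
    truth_drift <- sim$truth$gene_id[sim$truth$role == "drift"]
    setequal(excluded, truth_drift)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("the cascade is monotone: each filter only shrinks the candidate pool", {
  sim <- simulate_timecourse(synthetic_spec(n_background = 60,
    n_module_true_neighbors = 15, n_seeds = 5, n_drift = 10, rng_seed = 8))
  expr <- sim$expression
  n0 <- nrow(expr$values)
  retained <- low_intensity_filter(expr, 0.2)
  drift <- control_drift_genes(expr, 1.5)
  after_low <- length(retained)
  after_drift <- length(setdiff(retained, drift))
  deg <- deg_cascade(expr)
  n_deg <- sum(deg$direction %in% c("up", "down"))
  expect_true(n0 >= after_low && after_low >= after_drift &&
                after_drift >= n_deg)
})
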