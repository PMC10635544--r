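# Independent oracle implementations used to cross-check the package.
# Deliberately naive: plain loops, combinatorial arithmetic via choose(),
# no code shared with the implementation under test.

# Hypergeometric exact test by full enumeration of tables with the observed
# margins, pmf from binomial coefficients.
oracle_fisher <- function(k, n, K, N, sided = "greater") {
  supp <- max(0, n + K - N):min(n, K)
  prob <- vapply(supp, function(j) {
    choose(K, j) * choose(N - K, n - j)
  }, numeric(1)) / choose(N, n)
  obs <- prob[supp == k]
  if (sided == "greater") {
    sum(prob[supp >= k])
  } else {
    sum(prob[prob <= obs * (1 + 1e-07)])
  }
}

# Chi-square statistic from the textbook closed form
# N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)) on the 2x2 table [[a,b],[c,d]].
oracle_chisq_stat <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# --- brute-force nested LOOCV ------------------------------------------------

oracle_score <- function(W, scorers, g, tau) {
  s <- 0L
  for (sc in scorers) if (W[sc, g] >= tau) s <- s + 1L
  s
}

oracle_rank <- function(scores, target) {
  v <- scores[[target]]
  greater <- 0L
  ties <- 0L
  for (g in names(scores)) {
    if (scores[[g]] > v) greater <- greater + 1L
    if (scores[[g]] == v) ties <- ties + 1L
  }
  greater + (ties + 1) / 2
}

oracle_pool_scores <- function(W, scorers, pool, tau) {
  out <- stats::setNames(numeric(length(pool)), pool)
  for (g in pool) out[[g]] <- oracle_score(W, scorers, g, tau)
  out
}

oracle_nested_loocv <- function(W, seeds, grid, rank_threshold = 200) {
  genes <- rownames(W)
  folds <- NULL
  for (test in seeds) {
    training <- setdiff(seeds, test)
    traces <- matrix(NA_real_, length(training), length(grid),
                     dimnames = list(training, NULL))
    for (h in training) {
      scorers <- setdiff(training, h)
      pool <- setdiff(genes, scorers)
      for (ti in seq_along(grid)) {
        sc <- oracle_pool_scores(W, scorers, pool, grid[ti])
        traces[h, ti] <- oracle_rank(as.list(sc), h)
      }
    }
    qual <- rownames(traces)[apply(traces, 1,
                                   function(r) all(r > rank_threshold))]
    outlier <- NA_character_
    if (length(qual)) {
      worst <- vapply(qual, function(g) max(traces[g, ]), numeric(1))
      outlier <- sort(qual[worst == max(worst)])[1]
    }
    keep <- setdiff(rownames(traces), outlier)
    mean_trace <- colMeans(traces[keep, , drop = FALSE])
    opt <- grid[which.min(mean_trace)]
    pool <- setdiff(genes, training)
    sc <- oracle_pool_scores(W, training, pool, opt)
    folds <- rbind(folds, data.frame(test_seed = test, optimal_tau = opt,
                                     test_rank = oracle_rank(as.list(sc), test),
                                     excluded_outlier = outlier,
                                     stringsAsFactors = FALSE))
  }
  list(folds = folds, observed = stats::median(folds$test_rank))
}
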