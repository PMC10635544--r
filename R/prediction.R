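#' Descending fractional ranks
#'
#' Rank 1 is the highest score; tied scores share the mean of the ranks they
#' span. Used for every evaluation statistic (mean ranks avoid optimistic
#' bias when many genes tie at the few integer neighborhood scores).
#'
#' @param scores Finite numeric vector (optionally named).
#' @return Numeric vector of ranks in [1, length(scores)].
#' @examples
#' rank_with_ties(c(5, 3, 3, 1))  # 1, 2.5, 2.5, 4
#' @export
rank_with_ties <- function(scores) {
  if (any(!is.finite(scores))) stop_uvk("scores must be finite")
  rank(-scores, ties.method = "average")
}

# Fractional rank of `target` among pool = others + target, given the
# score of the target and the scores of the others.
.rank_of_target <- function(other_scores, target_score) {
  sum(other_scores > target_score) +
    (sum(other_scores == target_score) + 2) / 2
}

# Rank of `target` across every threshold of `grid`, scored by `scorers`
# against pool = all genes minus scorers (which contains `target`).
# Returns a numeric vector over the grid.
.rank_trace <- function(network, scorers, target, grid) {
  genes <- network$gene_ids
  pool <- setdiff(genes, scorers)
  R <- network$weights[pool, scorers, drop = FALSE]
  S <- matrix(0, length(pool), length(grid))
  for (j in seq_along(scorers)) S <- S + outer(R[, j], grid, ">=")
  ti <- match(target, pool)
  t_sc <- S[ti, ]
  others <- S[-ti, , drop = FALSE]
  bcast <- matrix(t_sc, nrow(others), ncol(others), byrow = TRUE)
  greater <- colSums(others > bcast)
  equal <- colSums(others == bcast)
  greater + (equal + 2) / 2
}

#' Inner leave-one-out loop: threshold tuning over the grid
#'
#' Holds out each training seed in turn; the remaining seeds score a pool of
#' all network genes except themselves, and the held-out seed's fractional
#' rank is recorded at every threshold. The optimal threshold minimizes the
#' mean held-out rank across folds (excluding a detected outlier trace);
#' argmin ties resolve to the smallest threshold.
#'
#' @param network A `uvk_network`.
#' @param training_seeds Character vector of >= 3 seed gene ids.
#' @param grid Threshold grid from [threshold_grid()].
#' @param rank_threshold Outlier rule: a seed whose rank exceeds this at
#'   every threshold is an outlier candidate (default 200).
#' @return List with `traces` (seeds x grid matrix of ranks), `mean_trace`
#'   (outlier excluded), `outlier` (gene id or `NA`), `optimal_tau`.
#' @export
inner_loocv <- function(network, training_seeds, grid = threshold_grid(),
                        rank_threshold = 200) {
  stopifnot(inherits(network, "uvk_network"))
  if (length(training_seeds) < 3) stop_uvk("need >= 3 training seeds")
  missing <- setdiff(training_seeds, network$gene_ids)
  if (length(missing)) stop_uvk("seed '", missing[1], "' not in network")
  traces <- matrix(NA_real_, length(training_seeds), length(grid),
                   dimnames = list(training_seeds, NULL))
  for (h in training_seeds) {
    traces[h, ] <- .rank_trace(network, setdiff(training_seeds, h), h, grid)
  }
  outlier <- detect_outlier(traces, rank_threshold)
  keep <- if (is.na(outlier)) traces else traces[rownames(traces) != outlier, ,
                                                 drop = FALSE]
  mean_trace <- colMeans(keep)
  list(traces = traces, mean_trace = mean_trace, outlier = outlier,
       optimal_tau = grid[which.min(mean_trace)])
}

#' Detect the outlier seed among inner-loop traces
#'
#' An outlier is a seed whose rank exceeds `rank_threshold` at every
#' threshold (the condition is conjunctive); among qualifying seeds, the one
#' with the largest maximum rank is returned, ties resolving to the
#' alphabetically first gene id.
#'
#' @param traces Seeds x thresholds rank matrix (rownames = gene ids).
#' @param rank_threshold Rank cutoff (default 200).
#' @return The outlier gene id, or `NA_character_` if none qualifies.
#' @export
detect_outlier <- function(traces, rank_threshold = 200) {
  qualifies <- apply(traces > rank_threshold, 1, all)
  if (!any(qualifies)) return(NA_character_)
  cand <- traces[qualifies, , drop = FALSE]
  worst <- apply(cand, 1, max)
  ids <- rownames(cand)[worst == max(worst)]
  sort(ids)[1]
}

#' Outer leave-one-out loop: per-seed prediction rank
#'
#' Holds out each seed as the test gene; the inner loop tunes the threshold
#' on the remaining training seeds (with outlier exclusion applied to the
#' tuning evaluation), and the test seed's fractional rank is then computed
#' at that threshold with the training seeds as scorers, over the pool of
#' all genes minus the training seeds. The observed statistic is the median
#' of the per-seed test ranks.
#'
#' @param network A `uvk_network`.
#' @param seeds Character vector of >= 4 seed gene ids (the study used 11).
#' @param grid Threshold grid.
#' @param outlier_policy `"evaluation"` (default): the inner-loop outlier is
#'   excluded only from the tuning evaluation; `"scoring"`: it is also
#'   dropped from the scorer set when ranking the test seed.
#' @param rank_threshold Outlier rank cutoff (default 200).
#' @return An object of class `uvk_loocv`: list with `folds` (data frame:
#'   `test_seed`, `optimal_tau`, `test_rank`, `excluded_outlier`),
#'   `observed` (median test rank) and `pool_size`.
#' @export
outer_loocv <- function(network, seeds, grid = threshold_grid(),
                        outlier_policy = c("evaluation", "scoring"),
                        rank_threshold = 200) {
  stopifnot(inherits(network, "uvk_network"))
  outlier_policy <- match.arg(outlier_policy)
  if (length(seeds) < 4) stop_uvk("need >= 4 seeds for nested validation")
  folds <- lapply(seeds, function(test) {
    training <- setdiff(seeds, test)
    inner <- inner_loocv(network, training, grid, rank_threshold)
    scorers <- training
    if (outlier_policy == "scoring" && !is.na(inner$outlier)) {
      scorers <- setdiff(scorers, inner$outlier)
    }
    pool <- setdiff(network$gene_ids, scorers)
    tau <- inner$optimal_tau
    A <- binarize(network, tau)
    scores <- colSums(A[scorers, pool, drop = FALSE])
    rank <- .rank_of_target(scores[pool != test], scores[[test]])
    data.frame(test_seed = test, optimal_tau = tau, test_rank = rank,
               excluded_outlier = inner$outlier, stringsAsFactors = FALSE)
  })
  folds <- do.call(rbind, folds)
  structure(list(folds = folds, observed = stats::median(folds$test_rank),
                 pool_size = length(network$gene_ids) - (length(seeds) - 1)),
            class = "uvk_loocv")
}

#' @export
print.uvk_loocv <- function(x, ...) {
  cat("uvk_loocv:", nrow(x$folds), "folds | median test rank =",
      x$observed, "of", x$pool_size, "genes\n")
  print(x$folds, row.names = FALSE)
  invisible(x)
}

#' Median optimal threshold across LOOCV folds
#'
#' Median of the per-fold optimal thresholds; an even-length median (mean of
#' the central pair) is snapped to the nearest grid value, ties toward the
#' smaller value.
#'
#' @param taus Numeric vector of per-fold optimal thresholds.
#' @param grid Optional threshold grid to snap to.
#' @return The median threshold.
#' @export
median_optimal_threshold <- function(taus, grid = NULL) {
  if (!length(taus)) stop_uvk("no thresholds supplied")
  med <- stats::median(taus)
  if (is.null(grid)) return(med)
  d <- abs(grid - med)
  grid[which(d <= min(d) + 1e-12)[1]]
}

#' Final candidate prediction at a fixed threshold
#'
#' Neighborhood scores with the full seed set at threshold `tau`, ranked over
#' the non-seed pool. The top-k list is pure top-k in the deterministic
#' output order (score descending, then gene id ascending); no score cutoff
#' is applied. Seeds never appear in the list.
#'
#' @param network A `uvk_network`.
#' @param seeds Character vector of seed gene ids.
#' @param tau Threshold in (0, 1).
#' @param k Size of the candidate list (default 50).
#' @return List with `tau`, `ranking` (data frame `gene_id`, `score`,
#'   `rank`, in output order) and `top` (the k candidate gene ids).
#' @export
final_prediction <- function(network, seeds, tau, k = 50) {
  stopifnot(inherits(network, "uvk_network"))
  scores <- neighborhood_scores(binarize(network, tau), seeds)
  if (k > length(scores)) stop_uvk("k (", k, ") exceeds pool size (",
                                   length(scores), ")")
  ranks <- rank_with_ties(scores)
  ord <- order(-scores, names(scores))
  ranking <- data.frame(gene_id = names(scores)[ord],
                        score = as.numeric(scores)[ord],
                        rank = ranks[ord], stringsAsFactors = FALSE)
  rownames(ranking) <- NULL
  list(tau = tau, ranking = ranking, top = ranking$gene_id[seq_len(k)], k = k)
}

#' Nested-LOOCV candidate prediction
#'
#' The full procedure: outer leave-one-seed-out evaluation with inner
#' threshold tuning, median optimal threshold, and the final top-k candidate
#' list using all seeds at that threshold.
#'
#' @inheritParams outer_loocv
#' @param k Candidate list size (default 50).
#' @return An object of class `uvk_prediction`: list with `median_tau`,
#'   `ranking`, `top`, `loocv` (the [outer_loocv()] result) and `observed`
#'   (median test rank).
#' @export
predict_candidates <- function(network, seeds, grid = threshold_grid(),
                               k = 50,
                               outlier_policy = c("evaluation", "scoring"),
                               rank_threshold = 200) {
  outlier_policy <- match.arg(outlier_policy)
  loocv <- outer_loocv(network, seeds, grid, outlier_policy, rank_threshold)
  median_tau <- median_optimal_threshold(loocv$folds$optimal_tau, grid)
  fin <- final_prediction(network, seeds, median_tau, k)
  structure(list(median_tau = median_tau, ranking = fin$ranking,
                 top = fin$top, k = k, loocv = loocv,
                 observed = loocv$observed),
            class = "uvk_prediction")
}

#' @export
print.uvk_prediction <- function(x, ...) {
  cat("uvk_prediction: median tau =", x$median_tau,
      "| median LOOCV test rank =", x$observed,
      "of", x$loocv$pool_size, "genes\n")
  cat("top", x$k, "candidates:",
      paste(utils::head(x$top, 10), collapse = ", "),
      if (x$k > 10) "..." else "", "\n")
  invisible(x)
}

# Median leave-one-seed-out test rank at one fixed threshold: each seed in
# turn is ranked against pool = all genes minus the other seeds, scored by
# those other seeds. The fast statistic used by the permutation null.
.loo_median_rank_fixed <- function(adjacency, genes, seed_set) {
  full <- colSums(adjacency[seed_set, , drop = FALSE])
  nonseed <- setdiff(genes, seed_set)
  full_ns <- full[nonseed]
  ranks <- vapply(seq_along(seed_set), function(i) {
    s <- seed_set[i]
    other_scores <- full_ns - adjacency[s, nonseed]
    .rank_of_target(other_scores, full[[s]])
  }, numeric(1))
  stats::median(ranks)
}

#' Permutation significance of the seed-set prediction rank
#'
#' Null replicates draw seed sets of the same size uniformly without
#' replacement from the network genes and recompute the statistic (median
#' leave-one-seed-out test rank); p = (number of null statistics <= observed
#' + 1) / (B + 1) — lower ranks are more significant, and the add-one
#' estimator keeps p positive. With `tau_policy = "fixed"` the statistic is
#' evaluated at a single threshold (fast; suitable for large B); with
#' `"nested"` the full nested tuning runs per replicate (small B only).
#'
#' @param network A `uvk_network`.
#' @param seeds Character vector of seed gene ids.
#' @param B Number of permutations (default 10000).
#' @param rng_seed Integer seed; fixed seed gives bit-identical results.
#' @param tau_policy `"fixed"` (default) or `"nested"`.
#' @param tau Threshold for the fixed policy; if `NULL` it is taken from
#'   [predict_candidates()]'s median optimal threshold.
#' @param grid Threshold grid (used when `tau` is `NULL` or the policy is
#'   nested).
#' @param outlier_policy Passed to [outer_loocv()] under the nested policy.
#' @return An object of class `uvk_permutation`: list with `observed`, `B`,
#'   `n_leq`, `p`, `tau`, `tau_policy`, `rng_seed`.
#' @export
permutation_test <- function(network, seeds, B = 10000L, rng_seed = 1L,
                             tau_policy = c("fixed", "nested"), tau = NULL,
                             grid = threshold_grid(),
                             outlier_policy = "evaluation") {
  stopifnot(inherits(network, "uvk_network"))
  tau_policy <- match.arg(tau_policy)
  if (B < 1) stop_uvk("B must be >= 1")
  genes <- network$gene_ids
  m <- length(seeds)
  if (length(genes) < m) stop_uvk("pool smaller than seed count")
  missing <- setdiff(seeds, genes)
  if (length(missing)) stop_uvk("seed '", missing[1], "' not in network")

  if (tau_policy == "fixed") {
    if (is.null(tau)) {
      loocv <- outer_loocv(network, seeds, grid, outlier_policy)
      tau <- median_optimal_threshold(loocv$folds$optimal_tau, grid)
    }
    A <- binarize(network, tau)
    statistic <- function(s) .loo_median_rank_fixed(A, genes, s)
  } else {
    statistic <- function(s) outer_loocv(network, s, grid, outlier_policy)$observed
  }

  observed <- statistic(seeds)
  nulls <- with_rng(rng_seed, {
    vapply(seq_len(B), function(b) statistic(sample(genes, m)), numeric(1))
  })
  n_leq <- sum(nulls <= observed)
  structure(list(observed = observed, B = as.integer(B), n_leq = n_leq,
                 p = (n_leq + 1) / (B + 1),
                 tau = if (tau_policy == "fixed") tau else NA_real_,
                 tau_policy = tau_policy, rng_seed = as.integer(rng_seed),
                 null_stats = nulls),
            class = "uvk_permutation")
}

#' @export
print.uvk_permutation <- function(x, ...) {
  cat("uvk_permutation: observed median rank =", x$observed,
      "| B =", x$B, "| p =", format(x$p, digits = 4),
      "(", x$tau_policy, "tau policy )\n")
  invisible(x)
}
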