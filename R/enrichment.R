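#' Fold enrichment of a gene set in a selection
#'
#' The ratio of proportions (k/n) / (K/N): how much more frequent the set's
#' members are in the selection than in the background universe.
#'
#' @param k Hits in the selection.
#' @param n Selection size.
#' @param K Hits in the background.
#' @param N Background (universe) size.
#' @return Fold enrichment (unrounded; round only for display).
#' @examples
#' fold_enrichment(14, 175, 17, 514)  # ~2.42
#' @export
fold_enrichment <- function(k, n, K, N) {
  if (n <= 0 || K <= 0 || N <= 0) stop_uvk("n, K and N must be positive")
  check_contingency(k, n, K, N)
  (k / n) / (K / N)
}

check_contingency <- function(k, n, K, N) {
  vals <- c(k = k, n = n, K = K, N = N)
  if (any(vals < 0) || any(vals != floor(vals))) {
    stop_uvk("contingency counts must be non-negative integers")
  }
  if (k > min(n, K)) stop_uvk("k must be <= min(n, K)")
  if (n > N || K > N) stop_uvk("n and K must be <= N")
  if (N - n - K + k < 0) stop_uvk("negative derived cell: N - n - K + k < 0")
  invisible(TRUE)
}

#' Fisher's exact test on a (k, n, K, N) contingency summary
#'
#' Exact hypergeometric test on the 2x2 table [[k, n-k], [K-k, N-n-K+k]].
#' One-sided "greater" sums the upper tail P(X >= k); the two-sided variant
#' uses the point-probability rule (sum of all outcomes whose probability
#' does not exceed that of the observed table).
#'
#' @inheritParams fold_enrichment
#' @param sided `"greater"` (default, overrepresentation) or `"two_sided"`.
#' @return The exact p-value in (0, 1].
#' @export
fisher_exact <- function(k, n, K, N, sided = c("greater", "two_sided")) {
  sided <- match.arg(sided)
  check_contingency(k, n, K, N)
  support <- max(0, n + K - N):min(n, K)
  pmf <- stats::dhyper(support, K, N - K, n)
  obs <- stats::dhyper(k, K, N - K, n)
  p <- if (sided == "greater") {
    sum(pmf[support >= k])
  } else {
    sum(pmf[pmf <= obs * (1 + 1e-07)])
  }
  min(max(p, .Machine$double.xmin), 1)
}

#' Pearson chi-square test on a (k, n, K, N) contingency summary
#'
#' 1-df chi-square on the 2x2 table [[k, n-k], [K-k, N-n-K+k]], via
#' `stats::chisq.test`. Yates continuity correction is off by default.
#'
#' @inheritParams fold_enrichment
#' @param correction Apply the Yates correction (default `FALSE`).
#' @return List with `statistic` and `p`.
#' @export
chi_square <- function(k, n, K, N, correction = FALSE) {
  check_contingency(k, n, K, N)
  tab <- matrix(c(k, K - k, n - k, N - n - K + k), 2, 2)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) stop_uvk("chi-square undefined: zero expected cell")
  fit <- suppressWarnings(stats::chisq.test(tab, correct = correction))
  list(statistic = unname(fit$statistic), p = unname(fit$p.value))
}

#' Gene-set overrepresentation across a collection
#'
#' For each set: k = set members in the selection, n = selection size,
#' K = set members in the background, N = background size; fold enrichment,
#' one-sided Fisher p, chi-square p, and BH q across the collection. Set
#' memberships are intersected with the background before counting; a
#' selection gene absent from the background is an error (universe
#' mismatch), and a set disjoint from the background is flagged
#' `not_represented`.
#'
#' @param selection Character vector of selected gene ids (subset of
#'   `background`).
#' @param background Character vector, the gene universe.
#' @param gene_sets A `uvk_gene_sets` collection from [read_gmt()] (or a
#'   compatible named list with `members` elements).
#' @return Data frame, one row per set, sorted by Fisher p: `set_name`,
#'   `k`, `n`, `K`, `N`, `fold`, `fisher_p`, `chisq_p`, `q`,
#'   `not_represented`.
#' @export
enrich <- function(selection, background, gene_sets) {
  selection <- unique(as.character(selection))
  background <- unique(as.character(background))
  stray <- setdiff(selection, background)
  if (length(stray)) {
    stop_uvk("selection gene '", stray[1], "' absent from background")
  }
  n <- length(selection)
  N <- length(background)
  rows <- lapply(names(gene_sets), function(nm) {
    members <- intersect(gene_sets[[nm]]$members, background)
    K <- length(members)
    k <- length(intersect(members, selection))
    if (K == 0) {
      data.frame(set_name = nm, k = 0L, n = n, K = 0L, N = N,
                 fold = NA_real_, fisher_p = NA_real_, chisq_p = NA_real_,
                 not_represented = TRUE, stringsAsFactors = FALSE)
    } else {
      chi <- tryCatch(chi_square(k, n, K, N)$p, error = function(e) NA_real_)
      data.frame(set_name = nm, k = k, n = n, K = K, N = N,
                 fold = fold_enrichment(k, n, K, N),
                 fisher_p = fisher_exact(k, n, K, N, sided = "greater"),
                 chisq_p = chi,
                 not_represented = FALSE, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  idx <- !out$not_represented
  out$q[idx] <- bh_adjust(out$fisher_p[idx])
  out[order(out$fisher_p), , drop = FALSE]
}
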