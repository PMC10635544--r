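#' The binarization threshold grid
#'
#' The default grid sweeps 0.001 to 0.999 in steps of 0.001 (999 values) —
#' the resolution at which the binary adjacency family is examined during
#' threshold tuning.
#'
#' @param from,to,by Grid limits and step.
#' @return Strictly increasing numeric vector in (0, 1).
#' @export
threshold_grid <- function(from = 0.001, to = 0.999, by = 0.001) {
  grid <- round(seq(from, to, by = by), 9)
  if (any(grid <= 0) || any(grid >= 1)) stop_uvk("grid values must lie in (0, 1)")
  if (any(diff(grid) <= 0)) stop_uvk("grid must be strictly increasing")
  grid
}

#' Pearson co-expression network over kinetic profiles
#'
#' Pearson correlation of per-gene log2 fold-change vectors, stored as a
#' symmetric weight matrix with unit diagonal. A constant (zero-variance)
#' profile has no defined correlation: its entries are set to 0 and the gene
#' is flagged — a flat profile carries no co-expression evidence and can
#' never pass a positive threshold.
#'
#' @param profiles Numeric matrix, genes x weeks (>= 3 time points, >= 2
#'   genes), e.g. from [fold_change_profiles()].
#' @return An object of class `uvk_network`: list with `gene_ids`,
#'   `weights` (symmetric matrix, entries clipped to [-1, 1], diagonal 1)
#'   and `flagged` (gene ids with zero-variance profiles).
#' @export
correlation_network <- function(profiles) {
  if (!is.matrix(profiles)) profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2) stop_uvk("need at least 2 profiles")
  if (ncol(profiles) < 3) stop_uvk("profiles must span at least 3 time points")
  if (is.null(rownames(profiles))) stop_uvk("profiles must carry gene rownames")
  sds <- apply(profiles, 1, stats::sd)
  flagged <- rownames(profiles)[sds == 0]
  W <- suppressWarnings(stats::cor(t(profiles)))
  W[is.na(W)] <- 0
  W <- pmin(pmax(W, -1), 1)   # absorb floating-point overshoot
  W <- (W + t(W)) / 2
  diag(W) <- 1
  dimnames(W) <- list(rownames(profiles), rownames(profiles))
  structure(list(gene_ids = rownames(profiles), weights = W, flagged = flagged),
            class = "uvk_network")
}

#' @export
print.uvk_network <- function(x, ...) {
  cat("uvk_network:", length(x$gene_ids), "genes")
  if (length(x$flagged)) cat(" (", length(x$flagged), "zero-variance flagged )")
  cat("\n")
  invisible(x)
}

#' Binarize a weighted network at a threshold
#'
#' Edge (i, j) present iff r(i, j) >= tau and i != j. Thresholding is on
#' signed r by default — the grid spans positive values and co-regulated
#' genes correlate positively; set `absolute` for |r| >= tau.
#'
#' @param network A `uvk_network` (or a symmetric numeric matrix).
#' @param tau Threshold in (0, 1).
#' @param absolute Threshold |r| instead of signed r (default `FALSE`).
#' @return Symmetric logical adjacency matrix with zero (FALSE) diagonal.
#' @export
binarize <- function(network, tau, absolute = FALSE) {
  W <- if (inherits(network, "uvk_network")) network$weights else network
  if (tau <= 0 || tau >= 1) stop_uvk("tau must lie in (0, 1)")
  A <- if (absolute) abs(W) >= tau else W >= tau
  diag(A) <- FALSE
  A
}

#' Seed-gene neighborhood scores
#'
#' For every non-seed gene, the number of seed genes it is directly connected
#' to in the binary network — an integer in [0, number of seeds]. This is the
#' guilt-by-association statistic the candidate ranking is built on.
#'
#' @param adjacency Logical adjacency matrix from [binarize()].
#' @param seeds Character vector of seed gene ids (present in the network).
#' @return Named integer vector over the non-seed genes.
#' @export
neighborhood_scores <- function(adjacency, seeds) {
  genes <- rownames(adjacency)
  if (!length(seeds)) stop_uvk("seed set is empty")
  missing <- setdiff(seeds, genes)
  if (length(missing)) stop_uvk("seed '", missing[1], "' not in network")
  pool <- setdiff(genes, seeds)
  counts <- colSums(adjacency[seeds, pool, drop = FALSE])
  stats::setNames(as.integer(counts), pool)
}
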