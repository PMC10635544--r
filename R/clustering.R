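#' K-means clustering of kinetic profiles
#'
#' Lloyd's K-means on log2 fold-change profiles (Euclidean distance), run as
#' the best of `n_init` seeded restarts by total within-cluster sum of
#' squares. Initial centers for each restart are drawn from the distinct
#' profile rows; a restart that produces an empty cluster is redrawn (the
#' draw sequence is fixed by `rng_seed`, so results are deterministic).
#' Profiles are clustered on raw log2fc — magnitude is part of the kinetic
#' signature — unless `standardize` is set.
#'
#' @param profiles Numeric matrix, genes x weeks (e.g. from
#'   [fold_change_profiles()], usually restricted to one DEG direction).
#' @param k Number of clusters (study defaults: 3 for upregulated, 5 for
#'   downregulated genes).
#' @param rng_seed Integer seed for the restarts.
#' @param n_init Number of restarts (default 50).
#' @param max_iter Lloyd iterations per restart (default 300).
#' @param standardize Scale each profile to unit variance first (default
#'   `FALSE`).
#' @param direction Optional label ("up"/"down") carried in the result.
#' @return An object of class `uvk_clustering`: list with `assignments`
#'   (named integer vector), `centroids` (k x weeks matrix), `inertia`,
#'   `k`, `direction`, `rng_seed`, `n_init`.
#' @export
kmeans_profiles <- function(profiles, k, rng_seed = 1L, n_init = 50L,
                            max_iter = 300L, standardize = FALSE,
                            direction = NA_character_) {
  if (!is.matrix(profiles)) profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  if (k < 1) stop_uvk("k must be >= 1")
  if (n < k) stop_uvk("k (", k, ") exceeds number of profiles (", n, ")")
  if (is.null(rownames(profiles))) {
    stop_uvk("profiles must carry gene rownames")
  }
  x <- if (standardize) t(scale(t(profiles))) else profiles
  if (standardize) x[is.nan(x)] <- 0

  distinct <- !duplicated(x)
  n_distinct <- sum(distinct)
  if (n_distinct < k) {
    stop_uvk("only ", n_distinct, " distinct profiles for k = ", k)
  }
  distinct_idx <- which(distinct)

  best <- NULL
  with_rng(rng_seed, {
    done <- 0L
    attempts <- 0L
    while (done < n_init && attempts < 100L * n_init) {
      attempts <- attempts + 1L
      centers <- x[sample(distinct_idx, k), , drop = FALSE]
      fit <- tryCatch(
        stats::kmeans(x, centers = centers, iter.max = max_iter,
                      algorithm = "Lloyd"),
        error = function(e) NULL,
        warning = function(w) {
          # "did not converge" warnings still return a valid partition
          suppressWarnings(stats::kmeans(x, centers = centers,
                                         iter.max = max_iter,
                                         algorithm = "Lloyd"))
        }
      )
      if (is.null(fit) || any(fit$size == 0)) next  # empty cluster: redraw
      done <- done + 1L
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  if (is.null(best)) stop_uvk("k-means failed to produce a valid partition")

  centroids <- best$centers
  dimnames(centroids) <- list(seq_len(k), colnames(profiles))
  structure(list(assignments = stats::setNames(as.integer(best$cluster),
                                               rownames(profiles)),
                 centroids = centroids,
                 inertia = best$tot.withinss,
                 k = as.integer(k),
                 direction = direction,
                 rng_seed = as.integer(rng_seed),
                 n_init = as.integer(n_init),
                 standardized = standardize),
            class = "uvk_clustering")
}

#' @export
print.uvk_clustering <- function(x, ...) {
  cat("uvk_clustering: k =", x$k,
      if (!is.na(x$direction)) paste0("(", x$direction, ")") else "",
      "| n =", length(x$assignments),
      "| inertia =", format(x$inertia, digits = 6), "\n")
  print(table(cluster = x$assignments))
  invisible(x)
}

#' Per-cluster summary
#'
#' @param clustering A `uvk_clustering` from [kmeans_profiles()].
#' @return List with `table` (data frame: cluster, size), `centroids`
#'   (k x weeks matrix) and `members` (list of gene-id vectors, sorted).
#' @export
cluster_summary <- function(clustering) {
  stopifnot(inherits(clustering, "uvk_clustering"))
  a <- clustering$assignments
  members <- lapply(seq_len(clustering$k),
                    function(cl) sort(names(a)[a == cl]))
  list(table = data.frame(cluster = seq_len(clustering$k),
                          size = lengths(members)),
       centroids = clustering$centroids,
       members = members)
}

#' Concentration of a gene set in a union of clusters
#'
#' Fraction of a gene set's members (restricted to the clustered genes) that
#' fall inside the given cluster union — the quantity behind statements like
#' "14 of 17 matrix genes sit in clusters 4 and 6". Feeds the enrichment
#' stage as the `k` of a contingency table.
#'
#' @param clustering A `uvk_clustering`.
#' @param clusters Integer vector of cluster labels forming the union.
#' @param genes Character vector of gene ids (the gene set).
#' @return List with `k` (members inside the union), `n_set` (members among
#'   clustered genes), `union_size`, and `fraction` (= k / n_set).
#' @export
cluster_concentration <- function(clustering, clusters, genes) {
  stopifnot(inherits(clustering, "uvk_clustering"))
  a <- clustering$assignments
  present <- intersect(genes, names(a))
  inside <- names(a)[a %in% clusters]
  k <- length(intersect(present, inside))
  list(k = k, n_set = length(present), union_size = length(inside),
       fraction = if (length(present)) k / length(present) else NA_real_)
}
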