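#' Low-intensity gene filter
#'
#' Removes genes whose intensity is below the `fraction` quantile of the
#' pooled intensity distribution in every sample — a gene escapes the filter
#' if even one sample puts it above the cutoff. Mirrors the array practice of
#' discarding probes below 20% intensity in all samples.
#'
#' @param expr An [expression_data()] object.
#' @param fraction Pooled quantile defining "low" (default 0.20); `0` removes
#'   nothing.
#' @return Character vector of retained gene ids.
#' @export
low_intensity_filter <- function(expr, fraction = 0.20) {
  stopifnot(inherits(expr, "uvk_expression"))
  if (nrow(expr$values) == 0) stop_uvk("empty expression matrix")
  if (fraction < 0 || fraction >= 1) stop_uvk("fraction must be in [0, 1)")
  cutoff <- stats::quantile(as.vector(expr$values), probs = fraction,
                            names = FALSE)
  low_all <- apply(expr$values < cutoff, 1, all)
  rownames(expr$values)[!low_all]
}

#' Intrinsic-drift genes in the unirradiated controls
#'
#' Flags genes whose mean control intensity changes by `fold` or more between
#' week 1 and week 8 — changes attributable to chronological aging rather
#' than UV. The ratio is symmetric: `max(m8/m1, m1/m8) >= fold` excludes.
#'
#' @param expr An [expression_data()] object with control samples at weeks 1
#'   and 8.
#' @param fold Exclusion fold (default 1.5).
#' @return Character vector of excluded gene ids.
#' @export
control_drift_genes <- function(expr, fold = 1.5) {
  stopifnot(inherits(expr, "uvk_expression"))
  d <- validate_design(expr$design, require_week8_control = TRUE)
  c1 <- d$sample_id[d$group == "control" & d$week == 1L]
  c8 <- d$sample_id[d$group == "control" & d$week == 8L]
  m1 <- rowMeans(expr$values[, c1, drop = FALSE])
  m8 <- rowMeans(expr$values[, c8, drop = FALSE])
  zero <- which(m1 <= 0 | m8 <= 0)
  if (length(zero)) {
    stop_uvk("zero control mean for gene '", rownames(expr$values)[zero[1]], "'")
  }
  ratio <- pmax(m8 / m1, m1 / m8)
  rownames(expr$values)[ratio >= fold]
}

#' Per-gene log2 fold-change profiles over the UV time course
#'
#' For each gene, log2(mean UV intensity at week w) − log2(mean control
#' intensity at week 1), over weeks {1,2,4,6,8}. This is the kinetic profile
#' that all clustering and network stages consume.
#'
#' @param expr An [expression_data()] object.
#' @return Numeric matrix, genes x 5 weeks (columns `wk1`, `wk2`, `wk4`,
#'   `wk6`, `wk8`).
#' @export
fold_change_profiles <- function(expr) {
  stopifnot(inherits(expr, "uvk_expression"))
  d <- expr$design
  ref <- d$sample_id[d$group == "control" & d$week == 1L]
  if (!length(ref)) stop_uvk("no control samples at week 1")
  m_ref <- rowMeans(expr$values[, ref, drop = FALSE])
  if (any(m_ref <= 0)) {
    stop_uvk("non-positive control mean for gene '",
             rownames(expr$values)[which(m_ref <= 0)[1]], "'")
  }
  prof <- sapply(.uvk_weeks, function(w) {
    uv <- d$sample_id[d$group == "uv" & d$week == w]
    if (!length(uv)) stop_uvk("no uv samples at week ", w)
    m <- rowMeans(expr$values[, uv, drop = FALSE])
    if (any(m <= 0)) {
      stop_uvk("non-positive uv mean at week ", w, " for gene '",
               rownames(expr$values)[which(m <= 0)[1]], "'")
    }
    log2(m) - log2(m_ref)
  })
  prof <- matrix(prof, nrow = nrow(expr$values),
                 dimnames = list(rownames(expr$values),
                                 paste0("wk", .uvk_weeks)))
  prof
}

#' Per-week Welch tests against the week-1 control
#'
#' Two-sided Welch two-sample t-tests on log2 intensities, UV samples at each
#' week versus the week-1 control, computed row-wise over the matrix. If both
#' groups have zero variance: p = 1 when the means are equal (no evidence of
#' change), and the smallest representable p otherwise.
#'
#' @param expr An [expression_data()] object with >= 2 replicates per
#'   compared group.
#' @return Numeric matrix of p-values, genes x 5 weeks.
#' @export
per_week_test <- function(expr) {
  stopifnot(inherits(expr, "uvk_expression"))
  d <- expr$design
  lg <- log2(pmax(expr$values, .Machine$double.xmin))
  ref <- d$sample_id[d$group == "control" & d$week == 1L]
  if (length(ref) < 2) stop_uvk("need >= 2 control replicates at week 1")
  p <- sapply(.uvk_weeks, function(w) {
    uv <- d$sample_id[d$group == "uv" & d$week == w]
    if (length(uv) < 2) stop_uvk("need >= 2 uv replicates at week ", w)
    row_welch_p(lg[, uv, drop = FALSE], lg[, ref, drop = FALSE])
  })
  matrix(p, nrow = nrow(expr$values),
         dimnames = list(rownames(expr$values), paste0("wk", .uvk_weeks)))
}

# Row-wise two-sided Welch t-test p-values (Welch-Satterthwaite df).
row_welch_p <- function(x, y) {
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- apply(x, 1, stats::var); v2 <- apply(y, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(abs(m1 - m2)[degenerate] < .Machine$double.eps^0.5,
                          1, .Machine$double.xmin)
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (q-values), delegating to
#' `stats::p.adjust(method = "BH")` after validating the input.
#'
#' @param p Numeric vector or matrix of p-values in [0, 1]. A matrix is
#'   adjusted column-wise (one family per week).
#' @return q-values with the shape of `p`.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop_uvk("p-values must lie in [0, 1]")
  if (is.matrix(p)) {
    q <- apply(p, 2, stats::p.adjust, method = "BH")
    dimnames(q) <- dimnames(p)
    q
  } else {
    stats::p.adjust(p, method = "BH")
  }
}

#' Select differentially expressed genes
#'
#' Applies the full cascade: genes dropped by the low-intensity filter or the
#' intrinsic-drift filter are labelled as excluded; a remaining gene is a DEG
#' iff some week has |log2fc| >= `fc_threshold` with q <= `q_threshold`.
#' Direction comes from the sign of the fold change at the week of maximum
#' |log2fc| among the qualifying weeks; an exact tie between an up and a down
#' week is resolved to "down".
#'
#' @param profiles Matrix from [fold_change_profiles()].
#' @param q Matrix of BH q-values aligned with `profiles` (from
#'   [bh_adjust()] of [per_week_test()]).
#' @param drift_excluded Gene ids from [control_drift_genes()].
#' @param low_excluded Gene ids removed by [low_intensity_filter()] (i.e.
#'   genes NOT in its return value).
#' @param fc_threshold Log2 fold-change threshold (default 1 = two-fold).
#' @param q_threshold FDR threshold (default 0.05).
#' @return A `DEG table`: data frame with the per-week log2fc and q columns,
#'   `max_abs_log2fc`, and `direction` in up / down / excluded_drift /
#'   excluded_low_intensity / not_significant.
#' @export
select_degs <- function(profiles, q, drift_excluded = character(),
                        low_excluded = character(),
                        fc_threshold = 1, q_threshold = 0.05) {
  genes <- rownames(profiles)
  if (!identical(genes, rownames(q))) {
    stop_uvk("profiles and q-values must be aligned on the same gene ids")
  }
  direction <- character(length(genes))
  pass <- abs(profiles) >= fc_threshold & q <= q_threshold
  for (i in seq_along(genes)) {
    g <- genes[i]
    if (g %in% low_excluded) {
      direction[i] <- "excluded_low_intensity"
    } else if (g %in% drift_excluded) {
      direction[i] <- "excluded_drift"
    } else if (!any(pass[i, ])) {
      direction[i] <- "not_significant"
    } else {
      ok <- which(pass[i, ])
      best <- ok[abs(profiles[i, ok]) == max(abs(profiles[i, ok]))]
      # exact-magnitude tie across signs resolves to "down"
      direction[i] <- if (any(profiles[i, best] < 0)) "down" else "up"
    }
  }
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  fc <- as.data.frame(profiles); names(fc) <- paste0("log2fc_", colnames(profiles))
  qv <- as.data.frame(q); names(qv) <- paste0("q_", colnames(q))
  rownames(fc) <- rownames(qv) <- NULL
  out <- cbind(out, fc, qv)
  out$max_abs_log2fc <- apply(abs(profiles), 1, max)
  out$direction <- direction
  out
}

#' Run the full DEG cascade on an expression dataset
#'
#' Convenience wrapper: low-intensity filter, drift exclusion, fold-change
#' profiles, per-week Welch tests, BH adjustment (per week by default,
#' pooled across weeks optionally), and DEG selection.
#'
#' @param expr An [expression_data()] object (controls at weeks 1 and 8).
#' @param fold Linear fold-change threshold (default 2).
#' @param q_threshold FDR threshold (default 0.05).
#' @param drift_fold Control-drift exclusion fold (default 1.5).
#' @param low_intensity_q Pooled quantile for the low-intensity filter
#'   (default 0.20).
#' @param pool_weeks Adjust p-values pooled across all weeks rather than
#'   within each week (default `FALSE`).
#' @return The DEG table of [select_degs()].
#' @export
deg_cascade <- function(expr, fold = 2, q_threshold = 0.05, drift_fold = 1.5,
                        low_intensity_q = 0.20, pool_weeks = FALSE) {
  retained <- low_intensity_filter(expr, low_intensity_q)
  low_excluded <- setdiff(rownames(expr$values), retained)
  drift <- control_drift_genes(expr, drift_fold)
  profiles <- fold_change_profiles(expr)
  p <- per_week_test(expr)
  q <- if (pool_weeks) {
    qq <- matrix(bh_adjust(as.vector(p)), nrow(p), ncol(p), dimnames = dimnames(p))
    qq
  } else {
    bh_adjust(p)
  }
  select_degs(profiles, q, drift_excluded = drift, low_excluded = low_excluded,
              fc_threshold = log2(fold), q_threshold = q_threshold)
}
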