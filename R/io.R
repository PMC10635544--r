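#' Construct an expression dataset
#'
#' Binds a genes-by-samples matrix of linear-scale normalized intensities to
#' its sample design table and validates the pair. All downstream stages take
#' this object.
#'
#' @param values Numeric matrix, rows = genes (unique rownames), columns =
#'   samples (colnames matching the design). Linear scale, all values >= 0,
#'   no missing entries.
#' @param design Data frame with columns `sample_id`, `group` (one of
#'   `"control"`, `"uv"`), `week` (one of 1, 2, 4, 6, 8) and `replicate`
#'   (positive integer).
#' @return An object of class `uvk_expression`: a list with elements
#'   `values` and `design`.
#' @examples
#' d <- data.frame(sample_id = c("a", "b"), group = c("control", "uv"),
#'                 week = c(1, 1), replicate = c(1, 1))
#' m <- matrix(c(10, 20, 30, 40), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("a", "b")))
#' expression_data(m, d)
#' @export
expression_data <- function(values, design) {
  design <- validate_design(design)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_uvk("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_uvk("`values` must carry gene rownames and sample colnames")
  }
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup)) stop_uvk("duplicate gene id: ", dup[1])
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop_uvk("missing value for gene '", rownames(values)[bad[1]],
             "' in sample '", colnames(values)[bad[2]],
             "' (no imputation is performed)")
  }
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop_uvk("negative intensity for gene '", rownames(values)[bad[1]],
             "' in sample '", colnames(values)[bad[2]], "'")
  }
  missing_in_design <- setdiff(colnames(values), design$sample_id)
  if (length(missing_in_design)) {
    stop_uvk("sample '", missing_in_design[1], "' not in design")
  }
  missing_in_matrix <- setdiff(design$sample_id, colnames(values))
  if (length(missing_in_matrix)) {
    stop_uvk("sample '", missing_in_matrix[1], "' not in matrix")
  }
  design <- design[match(colnames(values), design$sample_id), , drop = FALSE]
  rownames(design) <- NULL
  structure(list(values = values, design = design), class = "uvk_expression")
}

#' @export
print.uvk_expression <- function(x, ...) {
  cat("uvk_expression:", nrow(x$values), "genes x", ncol(x$values), "samples\n")
  tab <- table(x$design$group, x$design$week)
  print(tab)
  invisible(x)
}

#' Validate a sample design table
#'
#' @param design Data frame with columns `sample_id`, `group`, `week`,
#'   `replicate`.
#' @param require_week8_control Require control replicates at week 8 (needed
#'   by the intrinsic-drift filter). Default `FALSE`.
#' @return The validated design, with `group` as character and `week` as
#'   integer.
#' @export
validate_design <- function(design, require_week8_control = FALSE) {
  needed <- c("sample_id", "group", "week", "replicate")
  miss <- setdiff(needed, names(design))
  if (length(miss)) stop_uvk("design lacks column(s): ",
                             paste(miss, collapse = ", "))
  design$sample_id <- as.character(design$sample_id)
  design$group <- as.character(design$group)
  dup <- design$sample_id[duplicated(design$sample_id)]
  if (length(dup)) stop_uvk("duplicate sample id: ", dup[1])
  bad_grp <- setdiff(unique(design$group), c("control", "uv"))
  if (length(bad_grp)) stop_uvk("unknown group '", bad_grp[1],
                                "' (expected control/uv)")
  wk <- suppressWarnings(as.integer(design$week))
  bad <- which(is.na(wk) | !(wk %in% .uvk_weeks))
  if (length(bad)) stop_uvk("sample '", design$sample_id[bad[1]],
                            "' has week outside {1,2,4,6,8}")
  design$week <- wk
  rep_ <- suppressWarnings(as.integer(design$replicate))
  if (any(is.na(rep_) | rep_ < 1)) stop_uvk("replicate must be a positive integer")
  design$replicate <- rep_
  if (!any(design$group == "control" & design$week == 1L)) {
    stop_uvk("design must contain control samples at week 1 (the reference)")
  }
  if (require_week8_control &&
      !any(design$group == "control" & design$week == 8L)) {
    stop_uvk("drift filtering needs control samples at week 8")
  }
  design
}

#' Read an expression matrix and its design
#'
#' The expression file is a TSV whose header row carries sample ids and whose
#' first column carries gene ids; the design file is a TSV with columns
#' `sample_id`, `group`, `week`, `replicate`. Values are linear-scale
#' intensities; missing or negative values are load errors (nothing is
#' imputed).
#'
#' @param path Path to the expression TSV.
#' @param design_path Path to the design TSV.
#' @return An [expression_data()] object.
#' @export
read_expression <- function(path, design_path) {
  raw <- utils::read.delim(path, check.names = FALSE,
                           colClasses = c("character"), sep = "\t")
  if (ncol(raw) < 2) stop_uvk("expression TSV must have gene id + >=1 sample column")
  gene_ids <- raw[[1]]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  suppressWarnings(storage <- matrix(as.numeric(vals), nrow(vals), ncol(vals),
                                     dimnames = list(gene_ids, colnames(vals))))
  bad <- which(is.na(storage) & !is.na(vals) & vals != "NA", arr.ind = TRUE)
  if (nrow(bad)) {
    stop_uvk("non-numeric value for gene '", gene_ids[bad[1, 1]],
             "' in sample '", colnames(storage)[bad[1, 2]], "'")
  }
  design <- utils::read.delim(design_path, check.names = FALSE, sep = "\t")
  expression_data(storage, design)
}

#' Write an expression dataset to TSV
#'
#' Full-precision inverse of [read_expression()].
#'
#' @param x An `uvk_expression` object.
#' @param path Output expression TSV.
#' @param design_path Output design TSV.
#' @return Invisibly, `x`.
#' @export
write_expression <- function(x, path, design_path) {
  stopifnot(inherits(x, "uvk_expression"))
  df <- data.frame(gene_id = rownames(x$values), check.names = FALSE)
  vals <- as.data.frame(x$values, check.names = FALSE)
  rownames(vals) <- NULL
  df <- cbind(df, vals)
  write_tsv_full(df, path)
  write_tsv_full(x$design, design_path)
  invisible(x)
}

# TSV writer used everywhere: full precision, no quoting, no row names.
write_tsv_full <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) format(v, digits = 17, trim = TRUE,
                                                scientific = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read gene sets in GMT format
#'
#' One set per line: name TAB description TAB member TAB member ...
#' Duplicate members within a set are collapsed; an empty set or a duplicate
#' set name is an error.
#'
#' @param path Path to a GMT file.
#' @return An object of class `uvk_gene_sets`: a named list of lists with
#'   elements `description` and `members`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_uvk("cannot read GMT file '", path, "'")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop_uvk("GMT parse error at line ", i, ": fewer than 3 fields")
    }
    name <- fields[1]
    if (name %in% names(sets)) {
      stop_uvk("duplicate gene set name '", name, "' at line ", i)
    }
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) stop_uvk("empty gene set '", name, "' at line ", i)
    sets[[name]] <- list(description = fields[2], members = members)
  }
  structure(sets, class = "uvk_gene_sets")
}

#' Write gene sets in GMT format
#'
#' @param sets A `uvk_gene_sets` object (or compatible named list).
#' @param path Output path.
#' @return Invisibly, `sets`.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, sets[[nm]]$description, sets[[nm]]$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(sets)
}

#' Export a thresholded network as an edge list
#'
#' Writes the binary network at threshold `tau` in SIF dialect
#' (`geneA co geneB`, one line per unordered pair, lexicographically smaller
#' id first), and optionally a weighted TSV variant with the Pearson r of
#' each edge.
#'
#' @param network A `uvk_network` from [correlation_network()].
#' @param tau Threshold in (0, 1).
#' @param path Output SIF path.
#' @param weighted_path Optional output TSV path (`gene_a`, `gene_b`, `r`).
#' @param absolute Threshold on |r| instead of signed r. Default `FALSE`.
#' @return Invisibly, a data frame of the exported edges.
#' @export
write_edge_list <- function(network, tau, path, weighted_path = NULL,
                            absolute = FALSE) {
  adj <- binarize(network, tau, absolute = absolute)
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  genes <- rownames(adj)
  if (nrow(idx)) {
    a <- genes[idx[, 1]]
    b <- genes[idx[, 2]]
    swap <- a > b
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    r <- network$weights[cbind(idx[, 1], idx[, 2])]
    ord <- order(a, b)
    edges <- data.frame(gene_a = a[ord], gene_b = b[ord], r = r[ord],
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(gene_a = character(), gene_b = character(),
                        r = numeric(), stringsAsFactors = FALSE)
  }
  writeLines(if (nrow(edges)) paste(edges$gene_a, "co", edges$gene_b) else character(),
             path)
  if (!is.null(weighted_path)) write_tsv_full(edges, weighted_path)
  invisible(edges)
}

#' Write a ranked gene list to TSV
#'
#' Deterministic output order: score descending, then gene id ascending.
#' Ranks are fractional (ties share the mean of the ranks they span).
#'
#' @param ranking Data frame with columns `gene_id`, `score`, `rank`.
#' @param path Output TSV path.
#' @return Invisibly, the ranking.
#' @export
write_ranked_list <- function(ranking, path) {
  stopifnot(all(c("gene_id", "score", "rank") %in% names(ranking)))
  write_tsv_full(ranking, path)
  invisible(ranking)
}

#' Read a ranked gene list written by [write_ranked_list()]
#'
#' @param path TSV path.
#' @return Data frame with columns `gene_id`, `score`, `rank`.
#' @export
read_ranked_list <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c(gene_id = "character"))
  df$score <- as.numeric(df$score)
  df$rank <- as.numeric(df$rank)
  df
}
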