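# Kinetic archetype templates on the week grid {1,2,4,6,8}, log2 fold change
# vs the week-1 control. Shapes are qualitative matches to the eight cluster
# kinetics observed in chronically UV-irradiated mouse skin: 1-3 induction
# patterns, 4-8 repression patterns. Magnitudes are generator defaults, not
# measured quantities; |entry| <= 2 throughout.
.uvk_archetypes <- list(
  "1"    = c(1.5,  0.0,  0.5,  2.0,  2.0),  # acute induction, relapse, late peak
  "2"    = c(0.0,  0.5,  1.5,  2.0,  2.0),  # subacute induction from wk 2-4
  "3"    = c(1.5,  1.5,  1.5,  1.5,  1.5),  # early induction, sustained
  "4"    = c(-1.0,  0.0, -0.5, -1.5, -1.5), # repressed wk1, restored wk2, re-repressed
  "5"    = c(-0.4, -0.8, -1.2, -1.6, -2.0), # continuous decline
  "6"    = c(-1.5,  0.0, -1.0, -1.5, -1.5), # repressed wk1, basal wk2, re-repressed
  "7"    = c(-1.0, -1.0, -1.0, -1.5, -2.0), # early repression held to wk4, late drop
  "8"    = c(-2.0, -0.5, -2.0, -2.0, -2.0), # deep wk1 drop, partial regain, deep again
  "flat" = c(0.0,  0.0,  0.0,  0.0,  0.0)
)

#' Kinetic archetype template
#'
#' Fixed log2 fold-change vector over weeks {1,2,4,6,8} for one of the eight
#' kinetic archetypes (1-3 induction, 4-8 repression) or `"flat"` (no UV
#' response). These are the building blocks of the synthetic generator.
#'
#' @param id Archetype id: `1:8` or `"flat"`.
#' @return Named numeric vector of length 5 (names `wk1`, `wk2`, ...).
#' @examples
#' archetype_template(5)      # strictly decreasing
#' archetype_template("flat") # zeros
#' @export
archetype_template <- function(id) {
  key <- as.character(id)
  if (!key %in% names(.uvk_archetypes)) {
    stop_uvk("unknown archetype id '", key, "' (expected 1..8 or \"flat\")")
  }
  stats::setNames(.uvk_archetypes[[key]], paste0("wk", .uvk_weeks))
}

#' Specification of a synthetic time-course dataset
#'
#' Describes a dataset with the statistical structure the pipeline assumes:
#' a planted co-expressed "collagen-regulatory" module (seed genes plus true
#' neighbors sharing one latent kinetic, archetype 6, with per-gene loadings),
#' background genes following their own archetypes, intrinsic-drift genes
#' whose week-8 control mean is shifted, and log-normal multiplicative noise
#' (Normal on the log2 scale).
#'
#' @param n_background Number of background genes.
#' @param n_module_true_neighbors Number of planted true-neighbor genes.
#' @param n_seeds Number of seed genes (the study used 11).
#' @param n_drift Number of intrinsic-drift genes.
#' @param archetype_assignments Archetype ids for the background genes:
#'   `NULL` (all `"flat"`), or a vector of ids recycled across background
#'   genes.
#' @param baseline_log2 Baseline log2 intensity (default 8).
#' @param noise_sd_log2 Per-sample noise sd on log2 scale for background and
#'   drift genes (default 0.25).
#' @param module_noise_sd_log2 Noise sd for module genes (default 0.10).
#' @param module_loading_range Range of the per-gene module loading `a_g`
#'   (default `c(0.8, 1.2)`); module effect is `a_g` times the shared latent
#'   kinetic.
#' @param drift_fold Linear-scale fold applied to the week-8 control mean of
#'   drift genes (default 2); must exceed 1.
#' @param replicates Replicates per (group, week) cell (default 3).
#' @param rng_seed Integer seed; identical specs generate bit-identical data.
#' @return An object of class `uvk_synthetic_spec`.
#' @export
synthetic_spec <- function(n_background = 450L,
                           n_module_true_neighbors = 50L,
                           n_seeds = 11L,
                           n_drift = 0L,
                           archetype_assignments = NULL,
                           baseline_log2 = 8,
                           noise_sd_log2 = 0.25,
                           module_noise_sd_log2 = 0.10,
                           module_loading_range = c(0.8, 1.2),
                           drift_fold = 2.0,
                           replicates = 3L,
                           rng_seed = 1L) {
  counts <- c(n_background = n_background,
              n_module_true_neighbors = n_module_true_neighbors,
              n_seeds = n_seeds, n_drift = n_drift)
  if (any(counts < 0)) stop_uvk("gene counts must be >= 0")
  if (noise_sd_log2 < 0 || module_noise_sd_log2 < 0) {
    stop_uvk("noise sds must be >= 0")
  }
  if (drift_fold <= 1) stop_uvk("drift_fold must exceed 1")
  if (length(module_loading_range) != 2 || diff(module_loading_range) < 0) {
    stop_uvk("module_loading_range must be an interval c(lo, hi)")
  }
  if (replicates < 2) stop_uvk("need >= 2 replicates per group for testing")
  if (!is.null(archetype_assignments)) {
    ok <- as.character(archetype_assignments) %in% names(.uvk_archetypes)
    if (!all(ok)) stop_uvk("unknown archetype id in assignments: ",
                           archetype_assignments[!ok][1])
  }
  structure(list(n_background = as.integer(n_background),
                 n_module_true_neighbors = as.integer(n_module_true_neighbors),
                 n_seeds = as.integer(n_seeds),
                 n_drift = as.integer(n_drift),
                 archetype_assignments = archetype_assignments,
                 baseline_log2 = baseline_log2,
                 noise_sd_log2 = noise_sd_log2,
                 module_noise_sd_log2 = module_noise_sd_log2,
                 module_loading_range = module_loading_range,
                 drift_fold = drift_fold,
                 replicates = as.integer(replicates),
                 rng_seed = as.integer(rng_seed)),
            class = "uvk_synthetic_spec")
}

#' Generate a synthetic time-course dataset
#'
#' Emulates the study design: `replicates` control mice at week 1 (the
#' reference), `replicates` at week 8 (intrinsic-aging control), and
#' `replicates` UV-irradiated mice at each of weeks 1, 2, 4, 6 and 8. Per
#' gene g and sample s, log2 intensity = baseline + effect_g(week, group) +
#' Normal(0, sd_g); intensities are 2^(log2 value). Module genes (seeds and
#' true neighbors) share the archetype-6 latent kinetic scaled by a per-gene
#' loading; background genes follow their assigned archetype; drift genes
#' have their week-8 control mean multiplied by `drift_fold`.
#'
#' @param spec A [synthetic_spec()].
#' @return List with elements `expression` (an [expression_data()] object)
#'   and `truth` (data frame: `gene_id`, `role` in
#'   seed/true_neighbor/background/drift, `archetype`, `direction`).
#' @examples
#' sim <- simulate_timecourse(synthetic_spec(n_background = 20,
#'   n_module_true_neighbors = 5, n_seeds = 3, rng_seed = 1))
#' sim$expression
#' @export
simulate_timecourse <- function(spec) {
  stopifnot(inherits(spec, "uvk_synthetic_spec"))
  pad <- function(prefix, n) {
    if (n == 0) return(character())
    sprintf("%s%0*d", prefix, max(2L, nchar(n)), seq_len(n))
  }
  seeds <- pad("seed", spec$n_seeds)
  neigh <- pad("neigh", spec$n_module_true_neighbors)
  bg <- pad("bg", spec$n_background)
  drift <- pad("drift", spec$n_drift)
  genes <- c(seeds, neigh, bg, drift)
  if (!length(genes)) stop_uvk("spec describes zero genes")

  bg_arch <- if (is.null(spec$archetype_assignments)) {
    rep("flat", spec$n_background)
  } else {
    rep(as.character(spec$archetype_assignments),
        length.out = spec$n_background)
  }
  role <- c(rep("seed", spec$n_seeds),
            rep("true_neighbor", spec$n_module_true_neighbors),
            rep("background", spec$n_background),
            rep("drift", spec$n_drift))
  arch <- c(rep("6", spec$n_seeds + spec$n_module_true_neighbors),
            bg_arch, rep("flat", spec$n_drift))

  reps <- spec$replicates
  design <- data.frame(
    sample_id = c(paste0("ctrl_wk1_r", seq_len(reps)),
                  paste0("ctrl_wk8_r", seq_len(reps)),
                  unlist(lapply(.uvk_weeks,
                                function(w) paste0("uv_wk", w, "_r", seq_len(reps))))),
    group = c(rep("control", 2 * reps), rep("uv", length(.uvk_weeks) * reps)),
    week = c(rep(1L, reps), rep(8L, reps), rep(.uvk_weeks, each = reps)),
    replicate = c(seq_len(reps), seq_len(reps),
                  rep(seq_len(reps), times = length(.uvk_weeks))),
    stringsAsFactors = FALSE
  )

  n_genes <- length(genes)
  n_samples <- nrow(design)
  is_module <- role %in% c("seed", "true_neighbor")
  latent <- archetype_template("6")

  vals <- with_rng(spec$rng_seed, {
    loading <- rep(1, n_genes)
    loading[is_module] <- stats::runif(sum(is_module),
                                       spec$module_loading_range[1],
                                       spec$module_loading_range[2])
    effect <- matrix(0, n_genes, n_samples)
    wk_col <- match(paste0("wk", design$week), paste0("wk", .uvk_weeks))
    for (j in seq_len(n_samples)) {
      if (design$group[j] == "uv") {
        w <- wk_col[j]
        effect[, j] <- ifelse(
          is_module,
          loading * latent[w],
          vapply(arch, function(a) archetype_template(a)[[w]], numeric(1))
        )
      } else if (design$week[j] == 8L) {
        effect[role == "drift", j] <- log2(spec$drift_fold)
      }
    }
    sd_g <- ifelse(is_module, spec$module_noise_sd_log2, spec$noise_sd_log2)
    noise <- matrix(stats::rnorm(n_genes * n_samples, 0, rep(sd_g, n_samples)),
                    n_genes, n_samples)
    2^(spec$baseline_log2 + effect + noise)
  })
  dimnames(vals) <- list(genes, design$sample_id)

  template_sign <- vapply(arch, function(a) {
    tpl <- archetype_template(a)
    if (any(tpl > 0)) "up" else if (any(tpl < 0)) "down" else "none"
  }, character(1))
  truth <- data.frame(gene_id = genes, role = role, archetype = arch,
                      direction = template_sign, stringsAsFactors = FALSE)

  list(expression = expression_data(vals, design), truth = truth)
}

#' Write a simulated dataset to a directory
#'
#' Writes `expression.tsv`, `design.tsv` and `truth.tsv`.
#'
#' @param sim Result of [simulate_timecourse()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("expression.tsv", "design.tsv", "truth.tsv"))
  write_expression(sim$expression, paths[1], paths[2])
  write_tsv_full(sim$truth, paths[3])
  invisible(paths)
}
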