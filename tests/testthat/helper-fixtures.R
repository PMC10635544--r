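# Shared fixture builders. Everything is generated in code; no stored data.

# A uvk_network built directly from an explicit symmetric weight matrix.
network_from_weights <- function(W, genes = rownames(W)) {
  dimnames(W) <- list(genes, genes)
  structure(list(gene_ids = genes, weights = W, flagged = character()),
            class = "uvk_network")
}

# Random kinetic profiles (rows = genes, 5 weeks) under a fixed seed.
random_profiles <- function(n_genes, seed, prefix = "g") {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * 5), n_genes, 5,
              dimnames = list(sprintf("%s%03d", prefix, seq_len(n_genes)),
                              paste0("wk", c(1, 2, 4, 6, 8))))
  m
}

# A small expression dataset built directly from per-group mean intensities.
# `means` is a list with entries ctrl1, ctrl8, and uv (genes x 5 weeks),
# all linear scale; replicates are exact copies unless jitter is supplied.
expression_from_means <- function(ctrl1, ctrl8, uv, reps = 3, jitter = NULL,
                                  seed = 1) {
  genes <- names(ctrl1)
  design <- data.frame(
    sample_id = c(paste0("c1_r", 1:reps), paste0("c8_r", 1:reps),
                  unlist(lapply(c(1, 2, 4, 6, 8),
                                function(w) paste0("uv", w, "_r", 1:reps)))),
    group = c(rep("control", 2 * reps), rep("uv", 5 * reps)),
    week = c(rep(1, reps), rep(8, reps), rep(c(1, 2, 4, 6, 8), each = reps)),
    replicate = c(1:reps, 1:reps, rep(1:reps, times = 5)))
  vals <- cbind(matrix(ctrl1, length(genes), reps),
                matrix(ctrl8, length(genes), reps),
                do.call(cbind, lapply(1:5, function(w)
                  matrix(uv[, w], length(genes), reps))))
  if (!is.null(jitter)) {
    set.seed(seed)
    vals <- vals * 2^matrix(rnorm(length(vals), 0, jitter),
                            nrow(vals), ncol(vals))
  }
  dimnames(vals) <- list(genes, design$sample_id)
  expression_data(vals, design)
}
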