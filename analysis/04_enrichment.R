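#!/usr/bin/env Rscript
# Stage 4: gene-set overrepresentation.
#
# Two parts: (a) on the synthetic data, testing whether the planted module
# is overrepresented among the repressed DEGs, with gene sets built from
# the ground-truth labels; (b) the desk-scale arithmetic on the published
# membership counts shipped with the package (GSE58915 study), reproducing
# the printed fold enrichments.

suppressPackageStartupMessages(library(uvkinet))

deg <- read.delim("results/deg.tsv", colClasses = c(gene_id = "character"))
truth <- read.delim("results/data/truth.tsv")

## (a) synthetic: truth-derived sets against the tested universe
universe <- deg$gene_id[!deg$direction %in%
                          c("excluded_drift", "excluded_low_intensity")]
down <- deg$gene_id[deg$direction == "down"]
sets <- structure(list(
  planted_module = list(description = "seeds + true neighbors",
                        members = truth$gene_id[truth$role %in%
                                                  c("seed", "true_neighbor")]),
  decline_archetype = list(description = "background archetype 5",
                           members = truth$gene_id[truth$archetype == "5"]),
  flat_background = list(description = "no UV response",
                         members = truth$gene_id[truth$archetype == "flat" &
                                                   truth$role == "background"])
), class = "uvk_gene_sets")
res <- enrich(down, universe, sets)
cat("Overrepresentation among", length(down), "repressed DEGs (universe",
    length(universe), "genes):\n")
print(cbind(res[, c("set_name", "k", "n", "K", "N")],
            fold = round(res$fold, 2),
            fisher_p = signif(res$fisher_p, 3),
            q = signif(res$q, 3)), row.names = FALSE)
write.table(res, "results/enrichment_down.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

## (b) published membership counts: printed-value arithmetic
gmt <- read_gmt(system.file("extdata", "go_sets_downregulated.gmt",
                            package = "uvkinet"))
top50 <- readLines(system.file("extdata", "top50_candidates.txt",
                               package = "uvkinet"))
annotated <- unique(top50[top50 != "N/A"])
cat("\nPublished-count arithmetic (514 downregulated genes, GSE58915):\n")
cat("  ECM in clusters 4+6:   fold =",
    round(fold_enrichment(14, 175, 17, 514), 2),
    "| 14/17 =", round(14 / 17 * 100, 1), "% | 175/514 =",
    round(175 / 514 * 100, 1), "%\n")
for (term in c("morphogenesis_of_an_epithelium",
               "proteinaceous_extracellular_matrix",
               "polysaccharide_binding")) {
  k <- length(intersect(annotated, gmt[[term]]$members))
  K <- length(gmt[[term]]$members)
  cat(sprintf("  %-36s k=%d/50, K=%d/514, fold = %.2f, Fisher p = %.3g\n",
              term, k, K, round(fold_enrichment(k, 50, K, 514), 2),
              fisher_exact(k, 50, K, 514)))
}
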