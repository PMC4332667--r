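#!/usr/bin/env Rscript

# Stage 1: simulate a nine-species, six-organ cohort with known ground
# truth and write every pipeline input as a plain TSV (trees as one
# newick string per cluster), so the later stages run from files alone.

source("analysis/00_config.R")

cfg <- analysis_config()
cohort <- simulate_cohort(cfg)

write_tsv_table(cohort$expression, file.path(COHORT_DIR, "expression.tsv"))
write_tsv_table(cohort$pairs, file.path(COHORT_DIR, "ortholog_pairs.tsv"))
write_tsv_table(cohort$template_groups, file.path(COHORT_DIR, "template_groups.tsv"))
write_tsv_table(cohort$homology_edges, file.path(COHORT_DIR, "homology_edges.tsv"))
write_tsv_table(cohort$gene_species, file.path(COHORT_DIR, "gene_species.tsv"))
write_tsv_table(cohort$tree_groups, file.path(COHORT_DIR, "tree_groups.tsv"))
write_tsv_table(data.frame(cluster_id = names(cohort$trees),
                           newick = vapply(cohort$trees, ape::write.tree, character(1))),
                file.path(COHORT_DIR, "trees.tsv"))
write_tsv_table(cohort$chip$peaks, file.path(COHORT_DIR, "chip_peaks.tsv"))
write_tsv_table(cohort$chip$genes, file.path(COHORT_DIR, "chip_genes.tsv"))
write_tsv_table(cohort$chip$ortholog_map, file.path(COHORT_DIR, "chip_ortholog_map.tsv"))
write_tsv_table(cohort$chip$truth, file.path(COHORT_DIR, "truth_chip.tsv"))
write_tsv_table(cohort$oser_truth, file.path(COHORT_DIR, "truth_oser.tsv"))
write_tsv_table(cohort$clusters, file.path(COHORT_DIR, "truth_clusters.tsv"))
write_tsv_table(cohort$family_truth, file.path(COHORT_DIR, "truth_families.tsv"))

message(sprintf("cohort: %d families, %d clusters (%d complete, %d one-to-one), %d planted organ-specific",
                cfg$n_families, nrow(cohort$clusters), sum(cohort$clusters$complete),
                sum(cohort$clusters$one_to_one), nrow(cohort$oser_truth)))
message(sprintf("expression: %d measurements over %d genes", nrow(cohort$expression),
                length(unique(cohort$expression$gene_id))))
message("inputs written under ", COHORT_DIR)
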