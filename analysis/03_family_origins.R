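#!/usr/bin/env Rscript

# Stage 3: build gene families over the 14-species homology graph, trace
# the evolutionary origin stratum of every OSER cluster through its
# family, count clusters per family as the large-scale duplication proxy,
# and contrast the duplication history of single-target versus
# multi-target families.

source("analysis/00_config.R")

edges <- read_tsv_table(file.path(COHORT_DIR, "homology_edges.tsv"))
gene_species <- read_tsv_table(file.path(COHORT_DIR, "gene_species.tsv"))
clusters <- read_tsv_table(file.path(COHORT_DIR, "clusters.tsv"))
calls <- read_tsv_table(file.path(TABLE_DIR, "oser_calls.tsv"))
normalized <- read_tsv_table(file.path(COHORT_DIR, "expression_normalized.tsv"))

families <- build_families(edges, genes = gene_species$gene_id)
origins <- family_origins(families, gene_species)
cluster_families <- map_clusters_to_families(clusters, families)
dup <- duplication_profile(cluster_families, families)

origin_tab <- origin_summary(calls, cluster_families, origins)
write_tsv_table(families, file.path(COHORT_DIR, "families.tsv"))
write_tsv_table(origin_tab, file.path(TABLE_DIR, "origins_by_target.tsv"))

cats <- categorize_families(calls, cluster_families)
write_tsv_table(cats$families, file.path(TABLE_DIR, "family_categories.tsv"))

message(sprintf("%d families; %d contain OSER clusters",
                length(unique(families$family_id)), nrow(cats$families)))
message(sprintf("duplicated families (>1 cluster): %d of %d with clusters",
                sum(dup$duplicated), sum(dup$n_clusters > 0)))
print(cats$summary)
if (!is.null(cats$rank_sum)) {
  message(sprintf("cluster-count contrast between categories: rank-sum p = %.3g",
                  cats$rank_sum$p_value))
}

sub <- subcategorize_families(cats, normalized, calls, cluster_families, families)
write_tsv_table(sub$families, file.path(TABLE_DIR, "family_subcategories.tsv"))
print(sub$summary)
if (!is.null(sub$rank_sum)) {
  message(sprintf("concordant vs discordant family contrast: rank-sum p = %.3g",
                  sub$rank_sum$p_value))
}
print(origin_tab)
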