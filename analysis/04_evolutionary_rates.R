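#!/usr/bin/env Rscript

# Stage 4: sum the branch lengths of each one-to-one cluster's tree as
# its cumulative evolutionary rate and compare the rate distributions of
# the OSER groups (testis- and liver-specific genes are expected to
# evolve fastest, nervous-tissue genes slowest).

source("analysis/00_config.R")

tree_tab <- read_tsv_table(file.path(COHORT_DIR, "trees.tsv"))
groups <- read_tsv_table(file.path(COHORT_DIR, "tree_groups.tsv"))
clusters <- read_tsv_table(file.path(COHORT_DIR, "clusters.tsv"))

trees <- lapply(tree_tab$newick, function(s) ape::read.tree(text = s))
names(trees) <- tree_tab$cluster_id

o2o <- unique(clusters[clusters$one_to_one, c("cluster_id", "one_to_one")])
records <- rate_records(trees, groups, o2o)
cmp <- suppressWarnings(group_rate_comparison(records))

write_tsv_table(records, file.path(TABLE_DIR, "rates.tsv"))
write_tsv_table(cmp$groups, file.path(TABLE_DIR, "rate_groups.tsv"))
write_tsv_table(cmp$comparisons, file.path(TABLE_DIR, "rate_comparisons.tsv"))

message(sprintf("rates computed for %d one-to-one clusters in %d groups",
                nrow(records), nrow(cmp$groups)))
print(cmp$groups[order(-cmp$groups$mean), ])
key <- cmp$comparisons$group1 == "testis_expressed" &
  cmp$comparisons$group2 == "nervous_expressed" |
  cmp$comparisons$group1 == "nervous_expressed" &
  cmp$comparisons$group2 == "testis_expressed"
if (any(key)) {
  r <- cmp$comparisons[key, ]
  ratio <- if (r$group1 == "testis_expressed") r$mean_ratio else 1 / r$mean_ratio
  message(sprintf("testis- vs nervous-expressed mean rate ratio %.2f (rank-sum p = %.3g)",
                  ratio, r$p_value))
}
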