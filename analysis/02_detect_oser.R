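#!/usr/bin/env Rscript

# Stage 2: normalize expression, assemble chicken-anchored ortholog
# clusters, and call organ-specifically expressed or repressed (OSER)
# clusters with the two-stage rule (ANOVA + Tukey screen on Z-scores,
# then the 50% expression-ratio filter on RPKM). Writes the per-target
# tally and checks the calls against the planted truth.

source("analysis/00_config.R")

expression <- read_tsv_table(file.path(COHORT_DIR, "expression.tsv"))
pairs <- read_tsv_table(file.path(COHORT_DIR, "ortholog_pairs.tsv"))
template_groups <- read_tsv_table(file.path(COHORT_DIR, "template_groups.tsv"))
truth <- read_tsv_table(file.path(COHORT_DIR, "truth_oser.tsv"))

normalized <- add_rank_bins(zscore_normalize(aggregate_replicates(expression)))
clusters <- build_clusters(pairs, template_groups = template_groups)
message(sprintf("%d complete clusters, %d one-to-one",
                length(unique(clusters$cluster_id)),
                length(unique(clusters$cluster_id[clusters$one_to_one]))))

calls <- detect_oser(normalized, clusters)
tab <- tabulate_oser(calls)

write_tsv_table(normalized, file.path(COHORT_DIR, "expression_normalized.tsv"))
write_tsv_table(clusters, file.path(COHORT_DIR, "clusters.tsv"))
write_tsv_table(calls, file.path(TABLE_DIR, "oser_calls.tsv"))
write_tsv_table(tab$table, file.path(TABLE_DIR, "oser_summary.tsv"))

hits <- merge(calls, truth, by = "cluster_id")
sens <- length(unique(hits$cluster_id)) / nrow(truth)
ok <- mean(hits$target.x == hits$target.y & hits$direction.x == hits$direction.y)
message(sprintf("OSER calls: %d on %d clusters (%d dual-call)", nrow(calls),
                length(unique(calls$cluster_id)), tab$dual_count))
message(sprintf("against truth: sensitivity %.1f%%, target/direction agreement %.1f%%",
                100 * sens, 100 * ok))
print(tab$table)
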