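#!/usr/bin/env Rscript

# Stage 5: assign TF ChIP peaks to their nearest TSS at the 2.5 kb
# proximal/distal boundary, rank the TFs binding each OSER gene group,
# intersect the per-target TF sets, and measure the cross-species
# conservation of binding on OSER genes.

source("analysis/00_config.R")

peaks <- read_tsv_table(file.path(COHORT_DIR, "chip_peaks.tsv"))
genes <- read_tsv_table(file.path(COHORT_DIR, "chip_genes.tsv"))
omap <- read_tsv_table(file.path(COHORT_DIR, "chip_ortholog_map.tsv"))
clusters <- read_tsv_table(file.path(COHORT_DIR, "clusters.tsv"))
calls <- read_tsv_table(file.path(TABLE_DIR, "oser_calls.tsv"))

asn_h <- assign_peaks(peaks[peaks$species == "human", ],
                      genes[genes$species == "human", ])
asn_o <- assign_peaks(peaks[peaks$species == "other", ],
                      genes[genes$species == "other", ])
write_tsv_table(asn_h, file.path(TABLE_DIR, "chip_assignments_human.tsv"))
message(sprintf("human: %d peaks assigned (%d proximal, %d distal)", nrow(asn_h),
                sum(asn_h$site_class == "proximal"), sum(asn_h$site_class == "distal")))

human_members <- clusters[clusters$species == "human", ]
oser_sets <- lapply(split(calls$cluster_id, calls$target), function(cids) {
  unique(human_members$gene_id[human_members$cluster_id %in% cids])
})

tally <- tf_target_tally(asn_h, oser_sets, top_k = 5L)
write_tsv_table(tally, file.path(TABLE_DIR, "tf_top5_by_target.tsv"))
print(tally[tally$rank <= 3L, ])

for (sc in c("proximal", "distal")) {
  sets <- lapply(oser_sets, function(gs) {
    unique(asn_h$tf[asn_h$gene_id %in% gs & asn_h$site_class == sc])
  })
  sets <- sets[lengths(sets) > 0L]
  if (length(sets) >= 2L) {
    venn <- shared_tf_sets(sets)
    write_tsv_table(venn$regions, file.path(TABLE_DIR, sprintf("venn_%s.tsv", sc)))
    message(sprintf("%s-binding TFs shared by all %d targets: %d",
                    sc, length(sets), venn$shared))
  }
}

oser_human <- unique(unlist(oser_sets))
rows <- lapply(c("proximal", "distal"), function(sc) {
  hb <- unique(asn_h$gene_id[asn_h$site_class == sc & asn_h$gene_id %in% oser_human])
  ob <- unique(asn_o$gene_id[asn_o$site_class == sc])
  r <- cross_species_overlap(hb, ob, omap, oser_genes = oser_human)
  data.frame(site_class = sc, n_human = r$n_human, n_other = r$n_other,
             n_overlap = r$n_overlap, percent = r$percent_label)
})
overlap_tab <- do.call(rbind, rows)
write_tsv_table(overlap_tab, file.path(TABLE_DIR, "cross_species_overlap.tsv"))
print(overlap_tab)
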