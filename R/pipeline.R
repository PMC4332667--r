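#' Run the full organ-specificity pipeline on a set of inputs
#'
#' Composes the stages in analysis order: normalize (replicate collapse,
#' log2/Z-score), cluster (template-anchored assembly), detect (two-stage
#' OSER calling and tallies), families (homology-graph components,
#' origins, duplication counts, category contrast), rates (branch-length
#' sums and group comparison) and chip (peak assignment, per-target TF
#' tallies, shared-TF Venn regions, cross-species overlap). Each stage
#' writes plain TSV artifacts into `out_dir` plus a JSON summary and a
#' manifest with md5 checksums, so any stage can be inspected or rerun
#' standalone. With all stages toggled off, an empty bundle (manifest
#' only) is written.
#'
#' @param inputs A list as produced by [simulate_cohort()]:
#'   `expression` (raw RPKM records), `pairs`, `template_groups`,
#'   `homology_edges`, `gene_species`, `trees`, `tree_groups`, and `chip`
#'   (`peaks`, `genes`, `ortholog_map`). Unused pieces may be `NULL` when
#'   the corresponding stage is off.
#' @param out_dir Output directory, created if needed.
#' @param cfg A [detection_config()].
#' @param stages Character vector of stages to run, a subset of
#'   `c("normalize", "cluster", "detect", "families", "rates", "chip")`.
#' @return Invisibly, a list with every stage's in-memory result.
#' @export
run_pipeline <- function(inputs, out_dir,
                         cfg = detection_config(),
                         stages = c("normalize", "cluster", "detect",
                                    "families", "rates", "chip")) {
  allowed <- c("normalize", "cluster", "detect", "families", "rates", "chip")
  bad <- setdiff(stages, allowed)
  if (length(bad) > 0L) stop_input("unknown stage(s): %s", paste(bad, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  summary <- list()
  written <- character(0)
  emit <- function(x, name) {
    path <- file.path(out_dir, name)
    write_tsv_table(x, path)
    written <<- c(written, path)
  }
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop_input("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  if ("normalize" %in% stages) {
    res$expression <- run_stage("normalize", function() {
      validate_expression(inputs$expression)
      expr <- aggregate_replicates(inputs$expression)
      expr <- zscore_normalize(expr)
      add_rank_bins(expr)
    })
    emit(res$expression, "expression_normalized.tsv")
  }

  if ("cluster" %in% stages) {
    res$clusters <- run_stage("cluster", function() {
      build_clusters(inputs$pairs, template_groups = inputs$template_groups)
    })
    emit(res$clusters, "clusters.tsv")
    summary$total_clusters <- data.table::uniqueN(res$clusters$cluster_id)
    summary$one_to_one_clusters <-
      data.table::uniqueN(res$clusters$cluster_id[res$clusters$one_to_one])
  }

  if ("detect" %in% stages) {
    res$oser_calls <- run_stage("detect", function() {
      detect_oser(res$expression, res$clusters, cfg)
    })
    emit(res$oser_calls, "oser_calls.tsv")
    tab <- tabulate_oser(res$oser_calls, targets = c(cfg$organs, names(cfg$tissue_groups)))
    res$oser_table <- tab$table
    emit(tab$table, "oser_summary.tsv")
    summary$oser_clusters <- data.table::uniqueN(res$oser_calls$cluster_id)
    summary$dual_call_clusters <- tab$dual_count
    summary$oser_per_target <- stats::setNames(
      as.list(tab$table$expressed + tab$table$repressed), tab$table$target)
  }

  if ("families" %in% stages) {
    res$families <- run_stage("families", function() {
      build_families(inputs$homology_edges, genes = inputs$gene_species$gene_id)
    })
    emit(res$families, "families.tsv")
    res$family_origins <- run_stage("families", function() {
      family_origins(res$families, inputs$gene_species)
    })
    res$cluster_families <- run_stage("families", function() {
      map_clusters_to_families(res$clusters, res$families)
    })
    res$duplication <- duplication_profile(res$cluster_families, res$families)
    emit(merge(res$family_origins, res$duplication, by = "family_id", all = TRUE),
         "family_profiles.tsv")
    if (!is.null(res$oser_calls)) {
      res$origin_table <- origin_summary(res$oser_calls, res$cluster_families,
                                         res$family_origins,
                                         targets = c(cfg$organs, names(cfg$tissue_groups)))
      emit(res$origin_table, "origins.tsv")
      res$categories <- categorize_families(res$oser_calls, res$cluster_families)
      emit(res$categories$families, "family_categories.tsv")
      summary$category_mean_clusters <- stats::setNames(
        as.list(res$categories$summary$mean_n_clusters),
        paste0("category_", res$categories$summary$category))
    }
  }

  if ("rates" %in% stages) {
    res$rates <- run_stage("rates", function() {
      o2o <- unique(res$clusters[res$clusters$one_to_one,
                                 c("cluster_id", "one_to_one"), with = FALSE])
      rate_records(inputs$trees, inputs$tree_groups, o2o)
    })
    emit(res$rates, "rates.tsv")
    res$rate_comparison <- group_rate_comparison(res$rates)
    emit(res$rate_comparison$groups, "rate_groups.tsv")
    emit(res$rate_comparison$comparisons, "rate_comparisons.tsv")
  }

  if ("chip" %in% stages) {
    chip <- inputs$chip
    res$chip_assignments <- run_stage("chip", function() {
      hg <- chip$genes[chip$genes$species == "human", ]
      hp <- chip$peaks[chip$peaks$species == "human", ]
      assign_peaks(hp, hg)
    })
    emit(res$chip_assignments, "chip_assignments.tsv")
    if (!is.null(res$oser_calls) && !is.null(res$clusters)) {
      calls <- res$oser_calls[!res$oser_calls$candidate_only, ]
      human_members <- res$clusters[res$clusters$species == "human", ]
      oser_sets <- lapply(split(calls$cluster_id, calls$target), function(cids) {
        unique(human_members$gene_id[human_members$cluster_id %in% cids])
      })
      res$tf_tally <- tf_target_tally(res$chip_assignments, oser_sets, top_k = 5L)
      emit(res$tf_tally, "tf_tally.tsv")
      for (sc in c("proximal", "distal")) {
        sets <- lapply(oser_sets, function(gs) {
          unique(res$chip_assignments$tf[res$chip_assignments$gene_id %in% gs &
                                           res$chip_assignments$site_class == sc])
        })
        sets <- sets[lengths(sets) > 0L]
        if (length(sets) >= 2L) {
          venn <- shared_tf_sets(sets)
          emit(venn$regions, sprintf("venn_%s.tsv", sc))
          summary[[paste0("shared_tfs_", sc)]] <- venn$shared
        }
      }
    }
  }

  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA)
  written <- c(written, summary_path)
  manifest <- data.frame(file = basename(written),
                         md5 = unname(tools::md5sum(written)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"))
  res$summary <- summary
  invisible(res)
}

#' Simulate a complete cohort: homology, expression and ChIP layers
#'
#' Convenience wrapper tying the three generators together so that
#' [run_pipeline()] can consume the result directly: the homology layer
#' defines families, clusters and trees; the expression layer measures
#' the focal-species genes of those clusters; the ChIP layer uses the
#' human member genes of one-to-one complete clusters as its gene
#' universe, with their mouse counterparts as the ortholog map.
#'
#' @param cfg A [sim_config()].
#' @return A list with all generator outputs plus the truth labels
#'   (`oser_truth`, `family_truth`, `clusters`).
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  orth <- simulate_orthology(cfg)
  expr <- simulate_expression(cfg, members = orth$members,
                              oser_truth = orth$oser_truth)
  o2o <- orth$clusters$cluster_id[orth$clusters$one_to_one]
  hm <- orth$members[orth$members$species == "human" &
                       orth$members$cluster_id %in% o2o, ]
  mm <- orth$members[orth$members$species == "mouse" &
                       orth$members$cluster_id %in% o2o, ]
  omap <- merge(hm[, c("cluster_id", "gene_id"), with = FALSE],
                mm[, c("cluster_id", "gene_id"), with = FALSE],
                by = "cluster_id", suffixes = c("_h", "_m"))
  chip <- simulate_chip(cfg, human_genes = hm$gene_id,
                        ortholog_map = data.table::data.table(
                          other_gene = omap$gene_id_m, human_gene = omap$gene_id_h))
  list(expression = expr$expression, pairs = orth$pairs,
       template_groups = orth$template_groups,
       homology_edges = orth$homology_edges,
       gene_species = orth$gene_species,
       members = orth$members, clusters = orth$clusters,
       oser_truth = orth$oser_truth, family_truth = orth$family_truth,
       trees = orth$trees, tree_groups = orth$tree_groups, chip = chip)
}
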