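#' Build gene families from the homology graph
#'
#' A gene family is a connected component of the undirected graph whose
#' edges are the pairwise ortholog and paralog relations over all fourteen
#' species (nine focal plus lizard, clawed frog, zebrafish, lamprey and
#' sea squirt). Genes listed in `genes` but touching no edge become
#' singleton families.
#'
#' @param edges A data.frame with columns `gene_a`, `gene_b` (and
#'   optionally `relation`, `confidence`, ignored here).
#' @param genes Optional character vector of the full gene universe.
#' @return A `data.table` (`family_id`, `gene_id`); family ids are
#'   deterministic (`fam_0001`, ... ordered by the smallest member gene id).
#' @export
build_families <- function(edges, genes = NULL) {
  edt <- data.table::as.data.table(edges)
  if (nrow(edt) > 0L && !all(c("gene_a", "gene_b") %in% names(edt))) {
    stop_input("homology edge table needs columns gene_a, gene_b")
  }
  verts <- unique(c(if (nrow(edt) > 0L) c(edt$gene_a, edt$gene_b), genes))
  if (length(verts) == 0L) {
    return(data.table::data.table(family_id = character(0), gene_id = character(0)))
  }
  g <- igraph::graph_from_data_frame(
    if (nrow(edt) > 0L) edt[, c("gene_a", "gene_b"), with = FALSE]
    else data.frame(gene_a = character(0), gene_b = character(0)),
    directed = FALSE, vertices = data.frame(name = verts))
  comp <- igraph::components(g)
  memb <- comp$membership
  # deterministic ids: order components by their smallest gene id
  first_gene <- tapply(names(memb), memb, min)
  ord <- order(first_gene)
  new_id <- stats::setNames(sprintf("fam_%04d", order(ord)), names(first_gene))
  out <- data.table::data.table(family_id = unname(new_id[as.character(memb)]),
                                gene_id = names(memb))
  data.table::setorderv(out, c("family_id", "gene_id"))
  out[]
}

#' Evolutionary origin stratum of a gene family
#'
#' The origin is the deepest stratum witnessed by any member species:
#' sea squirt = Chordata, lamprey = Craniata, zebrafish = Gnathostomata,
#' clawed frog = Tetrapoda, lizard or any focal amniote = Amniota. A family
#' must contain at least one member from the nine focal species.
#'
#' @param member_species Character vector of the species of the family's
#'   member genes.
#' @return One of `origin_strata()`.
#' @export
assign_origin <- function(member_species) {
  known <- species_stratum()
  bad <- setdiff(unique(member_species), names(known))
  if (length(bad) > 0L) stop_input("unknown species: %s", paste(bad, collapse = ", "))
  if (!any(member_species %in% focal_species())) {
    stop_input("family has no member in the nine focal species")
  }
  strata <- known[member_species]
  origin_strata()[min(match(strata, origin_strata()))]
}

#' Origins of all families in a cohort
#'
#' @param families Long family table (`family_id`, `gene_id`).
#' @param gene_species Mapping table (`gene_id`, `species`).
#' @return A `data.table` (`family_id`, `origin`).
#' @export
family_origins <- function(families, gene_species) {
  fam <- data.table::as.data.table(families)
  gs <- data.table::as.data.table(gene_species)
  m <- merge(fam, gs, by = "gene_id")
  if (nrow(m) < nrow(fam)) {
    miss <- setdiff(fam$gene_id, gs$gene_id)
    stop_input("no species known for gene(s): %s", paste(utils::head(miss, 5L), collapse = ", "))
  }
  m[, list(origin = assign_origin(species)), by = "family_id"]
}

#' Map each orthologous cluster to its gene family
#'
#' Every member gene of a cluster must belong to one and the same family;
#' a cluster spanning two families is an error naming the cluster.
#'
#' @param clusters Long cluster table (`cluster_id`, `gene_id`).
#' @param families Long family table (`family_id`, `gene_id`).
#' @return A `data.table` (`cluster_id`, `family_id`).
#' @export
map_clusters_to_families <- function(clusters, families) {
  clu <- data.table::as.data.table(clusters)
  fam <- data.table::as.data.table(families)
  m <- merge(clu[, c("cluster_id", "gene_id"), with = FALSE], fam, by = "gene_id")
  per <- m[, list(n_fam = data.table::uniqueN(family_id),
                  family_id = family_id[1L]), by = "cluster_id"]
  split_clu <- per$cluster_id[per$n_fam > 1L]
  if (length(split_clu) > 0L) {
    stop_input("cluster(s) span multiple families: %s",
               paste(utils::head(split_clu, 5L), collapse = ", "))
  }
  out <- per[, c("cluster_id", "family_id"), with = FALSE]
  data.table::setorderv(out, "cluster_id")
  out[]
}

#' Orthologous-cluster count of each family (duplication proxy)
#'
#' A family containing more than one orthologous cluster experienced at
#' least one large-scale gene duplication event, the clusters being
#' mutually paralogous.
#'
#' @param cluster_families Table from [map_clusters_to_families()].
#' @param families Optional long family table; families without any
#'   cluster then appear with `n_clusters = 0`.
#' @return A `data.table` (`family_id`, `n_clusters`, `duplicated`).
#' @export
duplication_profile <- function(cluster_families, families = NULL) {
  cf <- data.table::as.data.table(cluster_families)
  prof <- cf[, list(n_clusters = data.table::uniqueN(cluster_id)), by = "family_id"]
  if (!is.null(families)) {
    all_fam <- unique(data.table::as.data.table(families)$family_id)
    missing <- setdiff(all_fam, prof$family_id)
    if (length(missing) > 0L) {
      prof <- rbind(prof, data.table::data.table(family_id = missing, n_clusters = 0L))
    }
  }
  prof[, duplicated := n_clusters > 1L]
  data.table::setorderv(prof, "family_id")
  prof[]
}

#' Expression-diversity categories of OSER-containing families
#'
#' Category 1: all OSER calls in the family point at one organ/tissue;
#' category 2: the family's OSER clusters target two or more different
#' organs/tissues. Reports each family's orthologous-cluster count and the
#' rank-sum comparison of the counts between categories.
#'
#' @param oser_calls Call table from [detect_oser()].
#' @param cluster_families Table from [map_clusters_to_families()].
#' @return A list: `families` (`family_id`, `n_targets`, `category`,
#'   `n_clusters`), `summary` (per-category n and mean cluster count), and
#'   `rank_sum` (test of cluster counts between the categories, `NULL`
#'   when a category is empty).
#' @export
categorize_families <- function(oser_calls, cluster_families) {
  calls <- data.table::as.data.table(oser_calls)
  if ("candidate_only" %in% names(calls)) calls <- calls[!calls$candidate_only, ]
  cf <- data.table::as.data.table(cluster_families)
  m <- merge(calls, cf, by = "cluster_id")
  if (nrow(m) < nrow(calls)) {
    stop_input("every OSER cluster must map to exactly one family")
  }
  fam <- m[, list(n_targets = data.table::uniqueN(target)), by = "family_id"]
  fam[, category := ifelse(n_targets >= 2L, 2L, 1L)]
  prof <- duplication_profile(cf)
  fam <- merge(fam, prof[, c("family_id", "n_clusters"), with = FALSE], by = "family_id")
  summ <- fam[, list(n_families = .N, mean_n_clusters = mean(n_clusters)), by = "category"]
  data.table::setorderv(summ, "category")
  rs <- NULL
  if (all(c(1L, 2L) %in% fam$category)) {
    rs <- rank_sum_test(fam$n_clusters[fam$category == 1L],
                        fam$n_clusters[fam$category == 2L])
  }
  list(families = fam[], summary = summ[], rank_sum = rs)
}

#' Concordance of a family's pooled expression profile with its OSER call
#'
#' Re-runs the OSER caller (screen, candidate rule, fold filter) on the
#' pooled expression of all family members with expression data. The
#' family profile is "same" when the family-level call set contains the
#' cluster's (target, direction), otherwise "different".
#'
#' @param family_expression Normalized expression records of every family
#'   member gene with data (needs `z_score` and `rpkm`).
#' @param oser_call One-row data.frame (`target`, `direction`).
#' @param cfg A [detection_config()].
#' @return `"same"` or `"different"`.
#' @export
family_profile_concordance <- function(family_expression, oser_call,
                                       cfg = detection_config()) {
  dt <- data.table::as.data.table(family_expression)
  obs <- split(dt$z_score, dt$organ)
  obs <- obs[lengths(obs) >= 2L]
  if (length(obs) < 2L) return("different")
  scr <- organ_screen(obs, cfg)
  cand <- call_candidates(scr$pairwise, cfg)
  if (nrow(cand) == 0L) return("different")
  for (i in seq_len(nrow(cand))) {
    if (cand$target[i] == oser_call$target[1L] &&
        cand$direction[i] == oser_call$direction[1L]) {
      ff <- fold_filter(dt, cand[i, , drop = FALSE], cfg)
      if (ff$pass) return("same")
    }
  }
  "different"
}

#' Subdivide single-target families by family-profile concordance
#'
#' Within category-1 families (one OSER target), subcategory 1 collects
#' families whose pooled expression profile reproduces the cluster call
#' ("same"), subcategory 2 the rest ("different"); reports mean cluster
#' counts and their rank-sum comparison.
#'
#' @param categories Result of [categorize_families()].
#' @param expression Normalized expression table of the cohort.
#' @param oser_calls Call table from [detect_oser()].
#' @param cluster_families Table from [map_clusters_to_families()].
#' @param families Long family table (`family_id`, `gene_id`).
#' @param cfg A [detection_config()].
#' @return A list: `families` (with `concordance`), `summary`, `rank_sum`.
#' @export
subcategorize_families <- function(categories, expression, oser_calls,
                                   cluster_families, families,
                                   cfg = detection_config()) {
  expr <- data.table::as.data.table(expression)
  calls <- data.table::as.data.table(oser_calls)
  if ("candidate_only" %in% names(calls)) calls <- calls[!calls$candidate_only, ]
  cf <- data.table::as.data.table(cluster_families)
  fam_long <- data.table::as.data.table(families)
  cat1 <- categories$families[categories$families$category == 1L, ]
  calls <- merge(calls, cf, by = "cluster_id")
  conc <- vapply(cat1$family_id, function(fid) {
    members <- fam_long$gene_id[fam_long$family_id == fid]
    fx <- expr[expr$gene_id %in% members, ]
    fam_calls <- calls[calls$family_id == fid, ]
    res <- vapply(seq_len(nrow(fam_calls)), function(i) {
      family_profile_concordance(fx, fam_calls[i, , drop = FALSE], cfg)
    }, character(1))
    # one target per category-1 family; "same" if any of its calls is reproduced
    if (any(res == "same")) "same" else "different"
  }, character(1))
  out <- data.table::copy(cat1)
  out[, concordance := conc]
  summ <- out[, list(n_families = .N, mean_n_clusters = mean(n_clusters)),
              by = "concordance"]
  rs <- NULL
  if (all(c("same", "different") %in% out$concordance)) {
    rs <- rank_sum_test(out$n_clusters[out$concordance == "same"],
                        out$n_clusters[out$concordance == "different"])
  }
  list(families = out[], summary = summ[], rank_sum = rs)
}

#' Cross-tabulate OSER calls by origin stratum and target
#'
#' The origin of a cluster is the origin of its family. Rows follow
#' `origin_strata()` plus a `Total` row; columns are the targets.
#'
#' @param oser_calls Call table from [detect_oser()].
#' @param cluster_families Table from [map_clusters_to_families()].
#' @param fam_origins Table from [family_origins()].
#' @param targets Column order.
#' @return A `data.table`, one row per stratum plus `Total`.
#' @export
origin_summary <- function(oser_calls, cluster_families, fam_origins,
                           targets = c("brain", "cerebellum", "nervous",
                                       "heart", "kidney", "liver", "testis")) {
  calls <- data.table::as.data.table(oser_calls)
  if ("candidate_only" %in% names(calls)) calls <- calls[!calls$candidate_only, ]
  m <- merge(calls, data.table::as.data.table(cluster_families), by = "cluster_id")
  m <- merge(m, data.table::as.data.table(fam_origins), by = "family_id")
  out <- data.table::data.table(origin = c(origin_strata(), "Total"))
  for (tg in targets) {
    cnt <- vapply(origin_strata(), function(s) {
      sum(m$target == tg & m$origin == s)
    }, numeric(1))
    out[[tg]] <- as.integer(c(cnt, sum(cnt)))
  }
  out[]
}
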