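#' Assemble template-anchored orthologous gene clusters
#'
#' Each template-species gene (chicken by default), or a pre-grouped set of
#' template inparalogs, seeds one cluster containing all of its
#' high-confidence orthologs in the other focal species. Low-confidence
#' pairs are discarded before assembly. Only clusters with at least one
#' member in every one of the nine focal species are retained;
#' within-species paralogs are allowed inside one cluster.
#'
#' A target gene anchored to two different template seeds is an error
#' listing the conflicts, unless `keep_first = TRUE`, in which case the
#' first anchoring (in input row order) wins.
#'
#' @param pairs A data.frame of pairwise orthologs with columns
#'   `template_gene`, `target_species`, `target_gene`, `confidence`
#'   (`"high"` or `"low"`).
#' @param template_groups Optional data.frame (`template_gene`, `group_id`)
#'   grouping template inparalogs into a single seed; template genes not
#'   listed seed their own cluster.
#' @param template_species Name of the template species (default
#'   `"chicken"`).
#' @param target_species The non-template focal species expected in every
#'   retained cluster.
#' @param keep_first Resolve conflicting template anchors by keeping the
#'   first instead of erroring.
#' @return A `data.table` with columns `cluster_id`, `species`, `gene_id`,
#'   `one_to_one` (per-cluster flag), one row per member gene.
#' @export
build_clusters <- function(pairs, template_groups = NULL,
                           template_species = "chicken",
                           target_species = setdiff(focal_species(), template_species),
                           keep_first = FALSE) {
  need <- c("template_gene", "target_species", "target_gene", "confidence")
  miss <- setdiff(need, names(pairs))
  if (length(miss) > 0L) {
    stop_input("ortholog pair table lacks column(s): %s", paste(miss, collapse = ", "))
  }
  dt <- data.table::as.data.table(pairs)
  bad_sp <- setdiff(unique(dt$target_species), target_species)
  if (length(bad_sp) > 0L) {
    stop_input("unknown target species label(s): %s", paste(bad_sp, collapse = ", "))
  }
  bad_conf <- setdiff(unique(dt$confidence), c("high", "low"))
  if (length(bad_conf) > 0L) {
    stop_input("confidence must be high or low, got: %s", paste(bad_conf, collapse = ", "))
  }
  dt <- dt[dt$confidence == "high", ]
  if (nrow(dt) == 0L) return(empty_cluster_table())

  # seed = inparalog group when given, otherwise the template gene itself
  if (!is.null(template_groups)) {
    tg <- data.table::as.data.table(template_groups)
    seed_of <- stats::setNames(as.character(tg$group_id), tg$template_gene)
  } else {
    seed_of <- character(0)
  }
  seed <- ifelse(dt$template_gene %in% names(seed_of),
                 unname(seed_of[dt$template_gene]), dt$template_gene)
  dt[, seed := seed]

  # one target gene must not be claimed by two different seeds
  tkey <- paste(dt$target_species, dt$target_gene, sep = "\r")
  conflict <- stats::aggregate(seed ~ tkey, data = data.frame(tkey = tkey, seed = dt$seed),
                               FUN = function(s) length(unique(s)))
  dup <- conflict$tkey[conflict$seed > 1L]
  if (length(dup) > 0L) {
    if (!keep_first) {
      stop_input("target gene(s) anchored to multiple template seeds: %s",
                 paste(sub("\r", "/", utils::head(dup, 10L)), collapse = ", "))
    }
    first_seed <- dt$seed[match(tkey, tkey)]
    dt <- dt[dt$seed == first_seed, ]
    tkey <- paste(dt$target_species, dt$target_gene, sep = "\r")
  }

  members <- rbind(
    data.table::data.table(seed = dt$seed, species = dt$target_species, gene_id = dt$target_gene),
    unique(data.table::data.table(seed = dt$seed, species = template_species,
                                  gene_id = dt$template_gene))
  )
  if (!is.null(template_groups)) {
    # every template gene of a seeded inparalog group is a cluster member,
    # whether or not it anchors a pair itself
    tg <- data.table::as.data.table(template_groups)
    tg <- tg[as.character(tg$group_id) %in% members$seed, ]
    if (nrow(tg) > 0L) {
      members <- rbind(members,
                       data.table::data.table(seed = as.character(tg$group_id),
                                              species = template_species,
                                              gene_id = tg$template_gene))
    }
  }
  members <- unique(members)
  n_sp <- members[, list(n_species = data.table::uniqueN(species)), by = "seed"]
  complete <- n_sp$seed[n_sp$n_species == length(target_species) + 1L]
  members <- members[members$seed %in% complete, ]
  if (nrow(members) == 0L) return(empty_cluster_table())

  data.table::setorderv(members, c("seed", "species", "gene_id"))
  members[, cluster_id := paste0("clu_", seed)]
  flags <- is_one_to_one(members, n_species = length(target_species) + 1L)
  members <- merge(members, flags, by = "cluster_id", sort = TRUE)
  members[, c("cluster_id", "species", "gene_id", "one_to_one"), with = FALSE]
}

#' Flag one-to-one orthologous clusters
#'
#' A cluster is one-to-one when every species contributes exactly one gene.
#'
#' @param clusters A long cluster table with columns `cluster_id`,
#'   `species`, `gene_id`.
#' @param n_species Number of species a complete cluster must cover
#'   (default 9).
#' @return A `data.table` (`cluster_id`, `one_to_one`).
#' @export
is_one_to_one <- function(clusters, n_species = 9L) {
  dt <- data.table::as.data.table(clusters)
  dt[, list(one_to_one = data.table::uniqueN(species) == n_species && .N == n_species),
     by = "cluster_id"]
}

empty_cluster_table <- function() {
  data.table::data.table(cluster_id = character(0), species = character(0),
                         gene_id = character(0), one_to_one = logical(0))
}
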