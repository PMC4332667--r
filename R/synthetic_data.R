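#' Configuration of the synthetic-data generator
#'
#' Defines the statistical structure the generators emulate: six organs by
#' nine species by two sex batches of log-normal expression with planted
#' organ-specific shifts; chicken-anchored ortholog/paralog graphs with
#' planted duplications, losses and low-confidence pairs; per-cluster
#' trees with group-scaled exponential branch lengths; and TF binding
#' tables with controlled proximal fractions and cross-species
#' conservation.
#'
#' Expression model: `log2(RPKM) = baseline + cluster effect + planted
#' shift + noise`, with the cluster effect `N(0, gene_sd^2)` shared by all
#' orthologs of a cluster (conserved expression) and observation noise
#' `N(0, noise_sd^2)`. The within-stratum SD is therefore
#' `sqrt(gene_sd^2 + noise_sd^2)` = 0.5 at the defaults. Planted expressed
#' clusters are shifted by `log2(rpkm_fold)` in the target organ(s), i.e.
#' by `effect_shift` = 2 stratum SDs on the Z scale at the defaults;
#' planted repressed clusters are shifted to `log2(repressed_fold)`,
#' placed at the same log-margin below the repressed decision boundary as
#' expressed clusters sit above theirs (0.375 = 0.5 * 1.5 / 2.0), so that
#' both directions are planted equally far from their boundary.
#'
#' The default target/direction allocation follows the empirical spread of
#' organ-specific calls across the six organs and the nervous-tissue
#' group (testis-expressed dominating, liver the only organ with more
#' repressed than expressed calls). Missing samples are mimicked by
#' default: orangutan testis entirely, orangutan male cerebellum, human
#' female liver.
#'
#' @param seed Integer seed; every generator is a pure function of
#'   (config, seed).
#' @param n_families Number of gene families (expression-only runs: one
#'   cluster each).
#' @param oser_fraction Fraction of complete clusters with a planted
#'   organ-specific effect.
#' @param effect_shift Planted shift on the Z scale, in within-stratum
#'   SDs; used only when `rpkm_fold` is `NULL`.
#' @param rpkm_fold Planted expressed-cluster ratio of focal to rest
#'   expression on the natural scale.
#' @param repressed_fold Planted repressed-cluster focal/rest ratio;
#'   `NULL` mirrors the expressed shift (`1/rpkm_fold`).
#' @param baseline_log2_mean Organ baseline of log2 RPKM (equal across
#'   organs; Z-scoring removes organ location anyway).
#' @param gene_sd,noise_sd SDs of the cluster effect and the observation
#'   noise on the log2 scale.
#' @param oser_allocation Named weights `<target>_<direction>` for the
#'   planted calls.
#' @param duplication_prob Probability that a family experienced at least
#'   one large-scale duplication (more than one cluster).
#' @param extra_cluster_mean Poisson mean of additional clusters beyond
#'   the second in duplicated families.
#' @param loss_rate Per cluster and species, probability the ortholog was
#'   lost (species absent; cluster becomes incomplete).
#' @param lowconf_rate Per cluster and species, probability the pair is
#'   emitted with low orthology confidence.
#' @param inparalog_prob Per cluster and species, probability of a
#'   within-species duplicate gene.
#' @param origin_probs Named stratum probabilities for the planted family
#'   origins.
#' @param outgroup_extra_prob Probability that each outgroup species
#'   shallower than the planted origin also has a member.
#' @param rate_multipliers Named per-target branch-length multipliers
#'   (plus `none` for clusters without a planted effect).
#' @param tree_edge_mean Mean exponential edge length of an unscaled tree.
#' @param n_chip_genes,n_tfs,n_chromosomes Size of the synthetic ChIP
#'   layout when it is not derived from a cohort.
#' @param binding_prob Per TF and gene, probability of a binding site in
#'   the reference (human) species.
#' @param proximal_fraction Probability that a planted peak is proximal
#'   (within 2.5 kb of the TSS).
#' @param conservation_prob Probability that a bound reference gene's
#'   ortholog is bound in the other species.
#' @param background_binding_prob Binding probability in the other species
#'   independent of conservation.
#' @param mimic_missing Drop the three missing sample batches.
#' @return A list of class `oser_sim_config`.
#' @export
sim_config <- function(seed = 42L,
                       n_families = 300L,
                       oser_fraction = 0.10,
                       effect_shift = 2.0,
                       rpkm_fold = 2.0,
                       repressed_fold = 0.375,
                       baseline_log2_mean = 5,
                       gene_sd = 0.46,
                       noise_sd = 0.2,
                       oser_allocation = default_oser_allocation(),
                       duplication_prob = 0.35,
                       extra_cluster_mean = 1.0,
                       loss_rate = 0.03,
                       lowconf_rate = 0.03,
                       inparalog_prob = 0.04,
                       origin_probs = c(Chordata = 0.60, Craniata = 0.15,
                                        Gnathostomata = 0.10, Tetrapoda = 0.05,
                                        Amniota = 0.10),
                       outgroup_extra_prob = 0.5,
                       rate_multipliers = c(brain = 1.0, cerebellum = 1.0,
                                            nervous = 1.0, heart = 1.5,
                                            kidney = 1.5, liver = 2.2,
                                            testis = 2.5, none = 1.5),
                       tree_edge_mean = 0.08,
                       n_chip_genes = 300L,
                       n_tfs = 20L,
                       n_chromosomes = 3L,
                       binding_prob = 0.15,
                       proximal_fraction = 0.5,
                       conservation_prob = 0.5,
                       background_binding_prob = 0.05,
                       mimic_missing = TRUE) {
  probs <- c(oser_fraction, duplication_prob, loss_rate, lowconf_rate,
             inparalog_prob, outgroup_extra_prob, binding_prob,
             proximal_fraction, conservation_prob, background_binding_prob)
  if (any(probs < 0 | probs > 1)) stop_input("probabilities must be in [0,1]")
  if (is.null(seed) || is.na(seed)) stop_input("seed is mandatory")
  if (!is.null(rpkm_fold) && rpkm_fold <= 1) stop_input("rpkm_fold must be > 1")
  if (!is.null(repressed_fold) && (repressed_fold <= 0 || repressed_fold >= 1)) {
    stop_input("repressed_fold must be in (0,1)")
  }
  if (abs(sum(origin_probs[origin_strata()]) - 1) > 1e-8 ||
      anyNA(origin_probs[origin_strata()])) {
    stop_input("origin_probs must cover all strata and sum to 1")
  }
  structure(list(seed = as.integer(seed), n_families = as.integer(n_families),
                 oser_fraction = oser_fraction, effect_shift = effect_shift,
                 rpkm_fold = rpkm_fold, repressed_fold = repressed_fold,
                 baseline_log2_mean = baseline_log2_mean,
                 gene_sd = gene_sd, noise_sd = noise_sd,
                 oser_allocation = oser_allocation,
                 duplication_prob = duplication_prob,
                 extra_cluster_mean = extra_cluster_mean,
                 loss_rate = loss_rate, lowconf_rate = lowconf_rate,
                 inparalog_prob = inparalog_prob,
                 origin_probs = origin_probs,
                 outgroup_extra_prob = outgroup_extra_prob,
                 rate_multipliers = rate_multipliers,
                 tree_edge_mean = tree_edge_mean,
                 n_chip_genes = as.integer(n_chip_genes),
                 n_tfs = as.integer(n_tfs),
                 n_chromosomes = as.integer(n_chromosomes),
                 binding_prob = binding_prob,
                 proximal_fraction = proximal_fraction,
                 conservation_prob = conservation_prob,
                 background_binding_prob = background_binding_prob,
                 mimic_missing = mimic_missing),
            class = "oser_sim_config")
}

# empirical spread of organ-specific calls used as planting weights
default_oser_allocation <- function() {
  c(brain_expressed = 98, cerebellum_expressed = 49, heart_expressed = 139,
    kidney_expressed = 130, liver_expressed = 140, testis_expressed = 453,
    nervous_expressed = 269,
    brain_repressed = 9, cerebellum_repressed = 15, heart_repressed = 44,
    kidney_repressed = 2, liver_repressed = 154, testis_repressed = 46,
    nervous_repressed = 52)
}

species_code <- function() {
  c(chicken = "gga", platypus = "oan", opossum = "mdo", mouse = "mmu",
    macaque = "mml", orangutan = "pab", gorilla = "ggo", chimpanzee = "ptr",
    human = "hsa", lizard = "aca", clawed_frog = "xtr", zebrafish = "dre",
    lamprey = "pma", sea_squirt = "cin")
}

missing_sample_batches <- function() {
  data.table::data.table(
    species = c("orangutan", "orangutan", "orangutan", "human"),
    organ = c("testis", "testis", "cerebellum", "liver"),
    sex = c("female", "male", "male", "female"))
}

#' Simulate the homology layer: ortholog pairs, paralog edges, trees
#'
#' Families are seeded at a planted origin stratum (witness-species
#' membership drawn accordingly); with probability `duplication_prob` a
#' family splits into several mutually paralogous orthologous clusters;
#' per cluster and species, orthologs may be lost or demoted to low
#' confidence, and within-species inparalogs may be added. Complete
#' clusters receive a planted organ-specific label by the allocation
#' weights, and every one-to-one complete cluster gets a nine-leaf tree
#' with exponential edge lengths scaled by its group's rate multiplier.
#'
#' @param cfg A [sim_config()].
#' @return A list: `pairs` (ortholog pair table for [build_clusters()]),
#'   `template_groups`, `homology_edges`, `gene_species`, `members`
#'   (gene/cluster/family map), `clusters` (truth: `cluster_id`,
#'   `family_id`, `complete`, `one_to_one`), `oser_truth` (`cluster_id`,
#'   `target`, `direction`), `family_truth` (`family_id`, `origin`,
#'   `n_clusters`), `trees` (named list of `phylo`), `tree_groups`.
#' @export
simulate_orthology <- function(cfg = sim_config()) {
  set.seed(cfg$seed + 1L)
  sc <- species_code()
  focal <- focal_species()
  template <- "chicken"
  targets <- setdiff(focal, template)
  witness <- c(Chordata = "sea_squirt", Craniata = "lamprey",
               Gnathostomata = "zebrafish", Tetrapoda = "clawed_frog",
               Amniota = "lizard")
  stratum_depth <- stats::setNames(seq_along(origin_strata()), origin_strata())

  fam_origin <- sample(origin_strata(), cfg$n_families, replace = TRUE,
                       prob = cfg$origin_probs[origin_strata()])
  extra <- stats::rbinom(cfg$n_families, 1L, cfg$duplication_prob) *
    (1L + stats::rpois(cfg$n_families, cfg$extra_cluster_mean))
  n_clu <- 1L + extra

  pairs <- list(); tgroups <- list(); edges <- list()
  gene_sp <- list(); members <- list(); clusters <- list()
  for (f in seq_len(cfg$n_families)) {
    fam <- sprintf("F%04d", f)
    fam_id <- paste0("fam:", fam)
    chicken_first <- character(n_clu[f])
    for (cidx in seq_len(n_clu[f])) {
      tag <- sprintf("%s_C%d", fam, cidx)
      gg1 <- paste0(sc[["chicken"]], "_", tag, "_g1")
      chicken_genes <- gg1
      if (stats::runif(1) < cfg$inparalog_prob) {
        gg2 <- paste0(sc[["chicken"]], "_", tag, "_g2")
        chicken_genes <- c(gg1, gg2)
        edges[[length(edges) + 1L]] <- data.table::data.table(
          gene_a = gg1, gene_b = gg2, relation = "paralog", confidence = "high")
      }
      chicken_first[cidx] <- gg1
      tgroups[[length(tgroups) + 1L]] <- data.table::data.table(
        template_gene = chicken_genes, group_id = tag)
      gene_sp[[length(gene_sp) + 1L]] <- data.table::data.table(
        gene_id = chicken_genes, species = "chicken")
      members[[length(members) + 1L]] <- data.table::data.table(
        gene_id = chicken_genes, species = "chicken",
        cluster_id = paste0("clu_", tag), family_id = fam_id)
      complete <- TRUE
      one2one <- length(chicken_genes) == 1L
      for (sp in targets) {
        if (stats::runif(1) < cfg$loss_rate) { complete <- FALSE; next }
        conf <- if (stats::runif(1) < cfg$lowconf_rate) "low" else "high"
        if (conf == "low") complete <- FALSE
        sp_genes <- paste0(sc[[sp]], "_", tag, "_g1")
        if (stats::runif(1) < cfg$inparalog_prob) {
          sp_genes <- c(sp_genes, paste0(sc[[sp]], "_", tag, "_g2"))
          edges[[length(edges) + 1L]] <- data.table::data.table(
            gene_a = sp_genes[1L], gene_b = sp_genes[2L],
            relation = "paralog", confidence = "high")
        }
        if (length(sp_genes) > 1L) one2one <- FALSE
        pairs[[length(pairs) + 1L]] <- data.table::data.table(
          template_gene = gg1, target_species = sp, target_gene = sp_genes,
          confidence = conf)
        edges[[length(edges) + 1L]] <- data.table::data.table(
          gene_a = gg1, gene_b = sp_genes, relation = "ortholog", confidence = conf)
        gene_sp[[length(gene_sp) + 1L]] <- data.table::data.table(
          gene_id = sp_genes, species = sp)
        members[[length(members) + 1L]] <- data.table::data.table(
          gene_id = sp_genes, species = sp,
          cluster_id = paste0("clu_", tag), family_id = fam_id)
      }
      if (cidx > 1L) {
        edges[[length(edges) + 1L]] <- data.table::data.table(
          gene_a = chicken_first[1L], gene_b = gg1,
          relation = "paralog", confidence = "high")
      }
      clusters[[length(clusters) + 1L]] <- data.table::data.table(
        cluster_id = paste0("clu_", tag), family_id = fam_id,
        complete = complete, one_to_one = complete && one2one)
    }
    # outgroup membership: the witness of the planted origin, plus
    # possibly outgroups at shallower strata
    og <- fam_origin[f]
    if (og != "Amniota") {
      og_species <- witness[[og]]
      shallower <- names(witness)[stratum_depth[names(witness)] > stratum_depth[og] &
                                    names(witness) != "Amniota"]
      for (s in shallower) {
        if (stats::runif(1) < cfg$outgroup_extra_prob) {
          og_species <- c(og_species, witness[[s]])
        }
      }
    } else {
      og_species <- if (stats::runif(1) < cfg$outgroup_extra_prob) "lizard" else character(0)
    }
    for (sp in og_species) {
      gid <- paste0(sc[[sp]], "_", fam)
      edges[[length(edges) + 1L]] <- data.table::data.table(
        gene_a = chicken_first[1L], gene_b = gid,
        relation = "ortholog", confidence = "high")
      gene_sp[[length(gene_sp) + 1L]] <- data.table::data.table(
        gene_id = gid, species = sp)
    }
  }
  pairs <- data.table::rbindlist(pairs)
  tgroups <- data.table::rbindlist(tgroups)
  edges <- data.table::rbindlist(edges)
  gene_sp <- data.table::rbindlist(gene_sp)
  members <- data.table::rbindlist(members)
  clusters <- data.table::rbindlist(clusters)
  family_truth <- data.table::data.table(
    family_id = paste0("fam:", sprintf("F%04d", seq_len(cfg$n_families))),
    origin = fam_origin, n_clusters = n_clu)

  oser_truth <- plant_oser_labels(clusters$cluster_id[clusters$complete], cfg)

  grp <- merge(clusters[clusters$one_to_one, c("cluster_id", "one_to_one"), with = FALSE],
               oser_truth, by = "cluster_id", all.x = TRUE)
  grp[, group := ifelse(is.na(target), "none", paste(target, direction, sep = "_"))]
  tree_groups <- grp[, c("cluster_id", "group"), with = FALSE]
  trees <- simulate_cluster_trees(
    tree_groups, cfg,
    tip_labels = split(members$gene_id[members$cluster_id %in% tree_groups$cluster_id &
                                         members$species %in% focal],
                       members$cluster_id[members$cluster_id %in% tree_groups$cluster_id &
                                            members$species %in% focal]))

  list(pairs = pairs, template_groups = tgroups, homology_edges = edges,
       gene_species = gene_sp, members = members, clusters = clusters,
       oser_truth = oser_truth, family_truth = family_truth,
       trees = trees, tree_groups = tree_groups)
}

plant_oser_labels <- function(cluster_ids, cfg) {
  n_plant <- round(cfg$oser_fraction * length(cluster_ids))
  if (n_plant == 0L) {
    return(data.table::data.table(cluster_id = character(0),
                                  target = character(0), direction = character(0)))
  }
  planted <- cluster_ids[sample.int(length(cluster_ids), n_plant)]
  lab <- sample(names(cfg$oser_allocation), n_plant, replace = TRUE,
                prob = cfg$oser_allocation)
  out <- data.table::data.table(
    cluster_id = planted,
    target = sub("_(expressed|repressed)$", "", lab),
    direction = sub("^.*_", "", lab))
  data.table::setorderv(out, "cluster_id")
  out[]
}

#' Simulate per-cluster phylogenetic trees with group-scaled rates
#'
#' Random nine-leaf topologies with i.i.d. exponential edge lengths whose
#' mean is `tree_edge_mean` times the rate multiplier of the cluster's
#' group (`<target>_<direction>` labels use the target's multiplier,
#' anything else the `none` multiplier).
#'
#' @param groups A data.frame (`cluster_id`, `group`).
#' @param cfg A [sim_config()].
#' @param tip_labels Optional named list of tip labels per cluster
#'   (defaults to `<cluster_id>_t1..9`).
#' @param n_tips Leaves per tree (default 9, one per focal species).
#' @return A named list of `phylo` objects.
#' @export
simulate_cluster_trees <- function(groups, cfg = sim_config(),
                                   tip_labels = NULL, n_tips = 9L) {
  g <- data.table::as.data.table(groups)
  mult_of <- function(group) {
    tg <- sub("_(expressed|repressed)$", "", group)
    m <- cfg$rate_multipliers[tg]
    if (is.na(m)) m <- cfg$rate_multipliers[["none"]]
    unname(m)
  }
  trees <- vector("list", nrow(g))
  names(trees) <- g$cluster_id
  for (i in seq_len(nrow(g))) {
    cid <- g$cluster_id[i]
    tips <- if (!is.null(tip_labels) && !is.null(tip_labels[[cid]])) {
      tip_labels[[cid]]
    } else {
      paste0(cid, "_t", seq_len(n_tips))
    }
    tr <- ape::rtree(length(tips), tip.label = sort(tips))
    tr$edge.length <- stats::rexp(nrow(tr$edge),
                                  rate = 1 / (cfg$tree_edge_mean * mult_of(g$group[i])))
    trees[[i]] <- tr
  }
  trees
}

#' Simulate the expression layer with planted organ-specific effects
#'
#' One measurement per gene, species, organ and sex batch:
#' `log2(RPKM) = baseline + cluster effect + planted shift + noise` (see
#' [sim_config()]). When no cohort is supplied, a one-to-one layout of
#' `n_families` single-cluster families is generated and planted
#' internally. The three missing sample batches are omitted when
#' `mimic_missing` is set. Same config and seed give identical output.
#'
#' @param cfg A [sim_config()].
#' @param members Optional gene map (`gene_id`, `species`, `cluster_id`)
#'   from [simulate_orthology()].
#' @param oser_truth Optional planted labels matching `members`.
#' @return A list: `expression` (`gene_id`, `species`, `organ`, `sex`,
#'   `rpkm`), `truth` (`cluster_id`, `target`, `direction`), `clusters`
#'   (long member table with `one_to_one`).
#' @export
simulate_expression <- function(cfg = sim_config(), members = NULL,
                                oser_truth = NULL) {
  set.seed(cfg$seed + 2L)
  sc <- species_code()
  if (is.null(members)) {
    tags <- sprintf("F%04d_C1", seq_len(cfg$n_families))
    members <- data.table::CJ(tag = tags, species = focal_species(), sorted = FALSE)
    members[, cluster_id := paste0("clu_", tag)]
    members[, gene_id := paste0(sc[species], "_", tag, "_g1")]
    members[, tag := NULL]
    if (is.null(oser_truth)) {
      oser_truth <- plant_oser_labels(unique(members$cluster_id), cfg)
    }
  } else {
    members <- data.table::as.data.table(members)
    members <- members[members$species %in% focal_species(), ]
    if (is.null(oser_truth)) {
      oser_truth <- plant_oser_labels(unique(members$cluster_id), cfg)
    }
  }
  oser_truth <- data.table::as.data.table(oser_truth)

  clu_ids <- unique(members$cluster_id)
  clu_eff <- stats::setNames(stats::rnorm(length(clu_ids), 0, cfg$gene_sd), clu_ids)

  delta_up <- if (!is.null(cfg$rpkm_fold)) {
    log2(cfg$rpkm_fold)
  } else {
    cfg$effect_shift * sqrt(cfg$gene_sd^2 + cfg$noise_sd^2)
  }
  delta_down <- if (!is.null(cfg$repressed_fold)) log2(cfg$repressed_fold) else -delta_up

  organs <- organ_vocab()
  sexes <- c("female", "male")
  grid <- data.table::CJ(organ = organs, sex = sexes, sorted = FALSE)
  n_cells <- nrow(grid)
  expr <- members[rep(seq_len(nrow(members)), each = n_cells), ]
  expr[, organ := rep(grid$organ, times = nrow(members))]
  expr[, sex := rep(grid$sex, times = nrow(members))]

  # planted shift per (cluster, organ)
  if (nrow(oser_truth) > 0L) {
    shifts <- oser_truth[, {
      orgs <- if (target == "nervous") c("brain", "cerebellum") else target
      data.table::data.table(organ = orgs,
                             shift = if (direction == "expressed") delta_up else delta_down)
    }, by = "cluster_id"]
    expr <- merge(expr, shifts, by = c("cluster_id", "organ"), all.x = TRUE, sort = FALSE)
    expr[is.na(shift), shift := 0]
  } else {
    expr[, shift := 0]
  }
  expr[, log2v := cfg$baseline_log2_mean + clu_eff[cluster_id] + shift +
         stats::rnorm(.N, 0, cfg$noise_sd)]
  expr[, rpkm := 2^log2v]
  if (cfg$mimic_missing) {
    mb <- missing_sample_batches()
    expr <- expr[!mb, on = c("species", "organ", "sex")]
  }
  data.table::setorderv(expr, c("cluster_id", "gene_id", "organ", "sex"))
  clusters <- unique(members[, c("cluster_id", "species", "gene_id"), with = FALSE])
  clusters <- merge(clusters, is_one_to_one(clusters), by = "cluster_id")
  out_expr <- expr[, c("gene_id", "species", "organ", "sex", "rpkm"), with = FALSE]
  list(expression = out_expr, truth = oser_truth, clusters = clusters)
}

#' Simulate TF ChIP peaks, gene annotations and cross-species binding
#'
#' Genes are laid out on synthetic chromosomes with TSSs spaced 25-60 kb
#' apart; for each TF, bound reference genes are drawn with
#' `binding_prob`, and each binding event places one peak with its
#' midpoint within 2.5 kb of the TSS (probability `proximal_fraction`) or
#' 2.5-9 kb away (so a peak is always nearest to its intended gene). A
#' bound reference gene's ortholog is bound in the other species with
#' `conservation_prob` (same site class); other-species genes also carry
#' independent background binding.
#'
#' @param cfg A [sim_config()].
#' @param human_genes Optional character vector of reference gene ids.
#' @param ortholog_map Optional (`other_gene`, `human_gene`) bijection;
#'   generated as `mmu_*` counterparts when absent.
#' @return A list: `peaks` (`species`, `tf`, `chrom`, `start`, `end`),
#'   `genes` (`species`, `gene_id`, `chrom`, `start`, `end`, `strand`),
#'   `ortholog_map`, `truth` (`species`, `tf`, `gene_id`, `site_class`).
#' @export
simulate_chip <- function(cfg = sim_config(), human_genes = NULL,
                          ortholog_map = NULL) {
  set.seed(cfg$seed + 3L)
  if (is.null(human_genes)) {
    human_genes <- sprintf("hsa_chip_%04d", seq_len(cfg$n_chip_genes))
  }
  human_genes <- sort(unique(human_genes))
  if (is.null(ortholog_map)) {
    ortholog_map <- data.table::data.table(
      other_gene = paste0("mmu|", human_genes), human_gene = human_genes)
  } else {
    ortholog_map <- data.table::as.data.table(ortholog_map)
  }
  tfs <- sprintf("TF%02d", seq_len(cfg$n_tfs))

  layout_genome <- function(gene_ids) {
    n <- length(gene_ids)
    chrom <- paste0("chr", rep(seq_len(cfg$n_chromosomes), length.out = n))
    ord <- order(chrom)
    chrom <- chrom[ord]; gene_ids <- gene_ids[ord]
    tss <- integer(n)
    for (ch in unique(chrom)) {
      i <- which(chrom == ch)
      tss[i] <- cumsum(c(30000L, as.integer(stats::runif(length(i) - 1L, 25000, 60000))))
    }
    strand <- sample(c("+", "-"), n, replace = TRUE)
    len <- as.integer(stats::runif(n, 2000, 20000))
    start <- ifelse(strand == "+", tss, tss - len + 1L)
    end <- start + len
    data.table::data.table(gene_id = gene_ids, chrom = chrom,
                           start = as.integer(start), end = as.integer(end),
                           strand = strand, tss = tss)
  }

  place_peaks <- function(anno, bound) {
    # bound: data.table(tf, gene_id, site_class)
    if (nrow(bound) == 0L) {
      return(data.table::data.table(tf = character(0), chrom = character(0),
                                    start = integer(0), end = integer(0)))
    }
    m <- merge(bound, anno, by = "gene_id", sort = FALSE)
    off_mag <- ifelse(m$site_class == "proximal",
                      as.integer(stats::runif(nrow(m), 0, 2500)),
                      as.integer(stats::runif(nrow(m), 2501, 9000)))
    off <- off_mag * sample(c(-1L, 1L), nrow(m), replace = TRUE)
    mid <- pmax(m$tss + off, 500L)
    h <- as.integer(stats::runif(nrow(m), 100, 300))
    data.table::data.table(tf = m$tf, chrom = m$chrom,
                           start = pmax(mid - h, 0L), end = mid + h)
  }

  draw_bound <- function(gene_ids, prob) {
    grid <- data.table::CJ(tf = tfs, gene_id = gene_ids, sorted = FALSE)
    grid <- grid[stats::runif(nrow(grid)) < prob, ]
    grid[, site_class := ifelse(stats::runif(.N) < cfg$proximal_fraction,
                                "proximal", "distal")]
    grid
  }

  anno_h <- layout_genome(human_genes)
  bound_h <- draw_bound(human_genes, cfg$binding_prob)

  other_genes <- sort(ortholog_map$other_gene)
  anno_o <- layout_genome(other_genes)
  conserved <- merge(bound_h, ortholog_map, by.x = "gene_id", by.y = "human_gene",
                     sort = FALSE)
  conserved <- conserved[stats::runif(nrow(conserved)) < cfg$conservation_prob, ]
  conserved <- data.table::data.table(tf = conserved$tf,
                                      gene_id = conserved$other_gene,
                                      site_class = conserved$site_class)
  background <- draw_bound(other_genes, cfg$background_binding_prob)
  bound_o <- unique(rbind(conserved, background))
  # one site class per (tf, gene): conserved class wins
  bound_o <- bound_o[!duplicated(bound_o[, c("tf", "gene_id"), with = FALSE]), ]

  peaks <- rbind(
    data.table::data.table(species = "human", place_peaks(anno_h, bound_h)),
    data.table::data.table(species = "other", place_peaks(anno_o, bound_o)))
  genes <- rbind(
    data.table::data.table(species = "human",
                           anno_h[, c("gene_id", "chrom", "start", "end", "strand"), with = FALSE]),
    data.table::data.table(species = "other",
                           anno_o[, c("gene_id", "chrom", "start", "end", "strand"), with = FALSE]))
  truth <- rbind(
    data.table::data.table(species = "human", bound_h),
    data.table::data.table(species = "other", bound_o))
  list(peaks = peaks, genes = genes, ortholog_map = ortholog_map, truth = truth)
}
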