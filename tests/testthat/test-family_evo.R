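test_that("family construction equals connected components", {
  # no edges: singleton families
  fam <- build_families(data.frame(gene_a = character(0), gene_b = character(0)),
                        genes = c("a", "b", "c"))
  expect_equal(nrow(fam), 3L)
  expect_equal(data.table::uniqueN(fam$family_id), 3L)

  # a chain of edges is one family
  chain <- data.frame(gene_a = c("a", "b", "c"), gene_b = c("b", "c", "d"))
  fam <- build_families(chain)
  expect_equal(data.table::uniqueN(fam$family_id), 1L)
  expect_setequal(fam$gene_id, c("a", "b", "c", "d"))
})

test_that("family construction matches a BFS oracle on random graphs", {
  set.seed(55)
  for (i in 1:15) {
    n <- sample(20:120, 1)
    genes <- paste0("g", seq_len(n))
    m <- sample(5:(2 * n), 1)
    edges <- data.frame(gene_a = sample(genes, m, replace = TRUE),
                        gene_b = sample(genes, m, replace = TRUE))
    fam <- build_families(edges, genes = genes)
    got <- lapply(split(fam$gene_id, fam$family_id), sort)
    got <- got[order(vapply(got, min, character(1)))]
    want <- oracle_components(edges, genes)
    expect_equal(unname(got), unname(want))
    # a partition of the gene universe
    expect_setequal(fam$gene_id, genes)
    expect_false(anyDuplicated(fam$gene_id) > 0L)
  }
})

test_that("origin assignment picks the deepest witnessed stratum", {
  expect_equal(assign_origin(c("human", "mouse", "sea_squirt")), "Chordata")
  expect_equal(assign_origin(c("chicken", "lamprey")), "Craniata")
  expect_equal(assign_origin(c("human", "zebrafish", "clawed_frog")), "Gnathostomata")
  expect_equal(assign_origin(c("human", "clawed_frog")), "Tetrapoda")
  expect_equal(assign_origin(focal_species()), "Amniota")
  expect_equal(assign_origin(c("human", "lizard")), "Amniota")
  expect_error(assign_origin(c("sea_squirt")), "no member")
  expect_error(assign_origin(c("human", "fruitfly")), "unknown")
})

test_that("origin assignment is monotone under deeper members", {
  strata <- origin_strata()
  witnesses <- c("sea_squirt", "lamprey", "zebrafish", "clawed_frog", "lizard")
  base <- c("human", "chicken")
  for (i in seq_along(witnesses)) {
    with_i <- assign_origin(c(base, witnesses[i]))
    for (j in seq_len(i)) {
      deeper <- assign_origin(c(base, witnesses[i], witnesses[j]))
      expect_lte(match(deeper, strata), match(with_i, strata))
    }
  }
})

test_that("duplication counting reflects clusters per family", {
  cf <- data.frame(cluster_id = c("c1", "c2", "c3", "c4"),
                   family_id = c("f1", "f2", "f2", "f2"))
  prof <- duplication_profile(cf)
  expect_equal(prof$n_clusters[prof$family_id == "f1"], 1L)
  expect_false(prof$duplicated[prof$family_id == "f1"])
  expect_equal(prof$n_clusters[prof$family_id == "f2"], 3L)
  expect_true(prof$duplicated[prof$family_id == "f2"])
})

test_that("a cluster spanning two families is an error", {
  clusters <- data.frame(cluster_id = "c1", gene_id = c("a", "b"))
  families <- data.frame(family_id = c("f1", "f2"), gene_id = c("a", "b"))
  expect_error(map_clusters_to_families(clusters, families), "span")
})

test_that("duplication flags and origins agree with simulator truth", {
  cfg <- sim_config(seed = 66, n_families = 120, duplication_prob = 0.4)
  orth <- simulate_orthology(cfg)
  fam <- build_families(orth$homology_edges, genes = orth$gene_species$gene_id)
  org <- family_origins(fam, orth$gene_species)
  # translate built family ids to planted ones through shared membership
  key <- merge(fam, orth$members[, c("gene_id", "family_id")], by = "gene_id")
  lookup <- unique(key[, c("family_id.x", "family_id.y")])
  expect_false(anyDuplicated(lookup$family_id.x) > 0L)  # 1:1 correspondence
  m <- merge(merge(org, lookup, by.x = "family_id", by.y = "family_id.x"),
             orth$family_truth, by.x = "family_id.y", by.y = "family_id")
  expect_equal(m$origin.x, m$origin.y)

  clu <- build_clusters(orth$pairs, template_groups = orth$template_groups)
  cf <- map_clusters_to_families(clu, fam)
  prof <- duplication_profile(cf)
  truth_complete <- orth$clusters[orth$clusters$complete, ]
  want <- tapply(truth_complete$cluster_id, truth_complete$family_id, length)
  got <- stats::setNames(prof$n_clusters,
                         lookup$family_id.y[match(prof$family_id, lookup$family_id.x)])
  expect_equal(unname(got[names(want)]), unname(as.integer(want)))
})

test_that("family categories separate single- from multi-target families", {
  calls <- data.frame(cluster_id = c("c1", "c2", "c3", "c4"),
                      target = c("testis", "testis", "liver", "heart"),
                      direction = "expressed")
  cf <- data.frame(cluster_id = c("c1", "c2", "c3", "c4"),
                   family_id = c("f1", "f1", "f2", "f2"))
  cat <- categorize_families(calls, cf)
  expect_equal(cat$families$category[cat$families$family_id == "f1"], 1L)
  expect_equal(cat$families$category[cat$families$family_id == "f2"], 2L)
})

test_that("multi-target families carry more clusters on a planted cohort", {
  cfg <- sim_config(seed = 77, n_families = 350, oser_fraction = 0.4,
                    duplication_prob = 0.45)
  orth <- simulate_orthology(cfg)
  complete <- orth$clusters[orth$clusters$complete, ]
  cf <- complete[, c("cluster_id", "family_id")]
  calls <- orth$oser_truth  # planted labels stand in for detected calls
  cat <- categorize_families(calls, cf)
  expect_true(all(c(1L, 2L) %in% cat$summary$category))
  m1 <- cat$summary$mean_n_clusters[cat$summary$category == 1L]
  m2 <- cat$summary$mean_n_clusters[cat$summary$category == 2L]
  expect_gt(m2, m1)
  expect_lt(cat$rank_sum$p_value, 0.05)
})

test_that("family profile concordance dilutes when a flat paralog cluster joins", {
  organs <- organ_vocab()
  up <- stats::setNames(rep(10, 6), organs); up["testis"] <- 20
  flat <- stats::setNames(rep(10, 6), organs)
  spread <- function(v, genes) {
    flat_cluster_records(stats::setNames(rep(list(v), length(genes)), genes),
                         species = focal_species()[1:4])
  }
  # background gene universe so that Z-scores are relative to the cohort,
  # not to the family itself
  set.seed(99)
  bg_levels <- rlnorm(30, log(10), 0.8)
  bg <- do.call(rbind, lapply(seq_along(bg_levels), function(i) {
    spread(stats::setNames(rep(bg_levels[i], 6), organs), sprintf("bg%02d", i))
  }))
  noise <- function(df, sd = 0.05, seed = 1) {
    set.seed(seed); df$rpkm <- df$rpkm * exp(rnorm(nrow(df), 0, sd)); df
  }
  clusterA <- noise(spread(up, c("a1", "a2")), seed = 1)
  clusterB <- noise(spread(flat, c("b1", "b2")), seed = 2)
  all_rec <- zscore_normalize(rbind(noise(bg, seed = 3), clusterA, clusterB))
  call <- data.frame(target = "testis", direction = "expressed")
  # the cluster alone reproduces its call
  famA <- all_rec[all_rec$gene_id %in% c("a1", "a2"), ]
  expect_equal(family_profile_concordance(famA, call), "same")
  # pooled with an equally sized flat paralog cluster the per-gene fold
  # requirement fails (the flat genes sit at ratio ~1), so the family
  # profile no longer reproduces the cluster call
  famAB <- all_rec[all_rec$gene_id %in% c("a1", "a2", "b1", "b2"), ]
  expect_equal(family_profile_concordance(famAB, call), "different")
})

test_that("origin cross-tabulation is consistent with per-target call counts", {
  cfg <- sim_config(seed = 88, n_families = 150, oser_fraction = 0.3)
  orth <- simulate_orthology(cfg)
  complete <- orth$clusters[orth$clusters$complete, ]
  cf <- complete[, c("cluster_id", "family_id")]
  fam_org <- orth$family_truth[, c("family_id", "origin")]
  tab <- origin_summary(orth$oser_truth, cf, fam_org)
  for (tg in setdiff(names(tab), "origin")) {
    col <- tab[[tg]]
    expect_equal(col[length(col)], sum(col[-length(col)]))
    expect_equal(col[length(col)], sum(orth$oser_truth$target == tg))
  }
})
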