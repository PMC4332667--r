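test_that("detection config validates its thresholds", {
  expect_error(detection_config(alpha = 0), "alpha")
  expect_error(detection_config(fold_up = 1), "fold_up")
  expect_error(detection_config(fold_down = 1.2), "fold_down")
  expect_error(detection_config(tissue_groups = list(x = "spleen")), "unknown organs")
})

test_that("the screen flags a shifted organ and stays silent on flat clusters", {
  set.seed(1)
  obs <- lapply(organ_vocab(), function(o) rnorm(18, 0, 0.3))
  names(obs) <- organ_vocab()
  obs$liver <- obs$liver - 3
  scr <- organ_screen(obs)
  expect_lt(scr$anova$p_value, 1e-10)
  liver_rows <- scr$pairwise$group1 == "liver" | scr$pairwise$group2 == "liver"
  expect_true(all(scr$pairwise$adj_p[liver_rows] < 0.05))
  cand <- call_candidates(scr$pairwise)
  expect_equal(cand$target, "liver")
  expect_equal(cand$direction, "repressed")

  flat <- lapply(organ_vocab(), function(o) rep(1, 5))
  names(flat) <- organ_vocab()
  scr <- organ_screen(flat)
  expect_equal(scr$anova$f_stat, 0)
  expect_equal(scr$anova$p_value, 1)
  expect_equal(nrow(call_candidates(scr$pairwise)), 0L)

  expect_error(organ_screen(list(brain = 1:5)), "at least 2 organs")
})

test_that("the pairwise-ANOVA screening alternative produces 15 unadjusted pairs", {
  set.seed(2)
  obs <- lapply(organ_vocab(), function(o) rnorm(10))
  names(obs) <- organ_vocab()
  scr <- organ_screen(obs, detection_config(pairwise_anova = TRUE))
  expect_equal(nrow(scr$pairwise), 15L)
  ref <- anova_oneway(obs[c("brain", "heart")])$p_value
  row <- scr$pairwise[scr$pairwise$group1 == "brain" & scr$pairwise$group2 == "heart", ]
  expect_equal(row$adj_p, ref)
})

test_that("the nervous-tissue rule fires only when brain and cerebellum agree", {
  set.seed(3)
  base <- lapply(organ_vocab(), function(o) rnorm(15, 0, 0.3))
  names(base) <- organ_vocab()
  nerv <- base
  nerv$brain <- nerv$brain + 3
  nerv$cerebellum <- nerv$cerebellum + 3
  cand <- call_candidates(organ_screen(nerv)$pairwise)
  expect_equal(cand$target, "nervous")
  expect_equal(cand$direction, "expressed")
  expect_false(any(cand$target %in% c("brain", "cerebellum")))

  solo <- base
  solo$brain <- solo$brain + 3  # cerebellum left behind: brain-only call
  cand <- call_candidates(organ_screen(solo)$pairwise)
  expect_equal(cand$target, "brain")
})

test_that("fold filter behaves exactly at the 1.5x and 0.5x boundaries", {
  vals <- stats::setNames(rep(10, 6), organ_vocab())
  up <- vals; up["testis"] <- 15
  rec <- flat_cluster_records(list(g1 = up))
  r <- fold_filter(rec, data.frame(target = "testis", direction = "expressed"))
  expect_true(r$pass)
  expect_equal(r$fold_ratio, 1.5)

  down <- vals; down["liver"] <- 5
  rec <- flat_cluster_records(list(g1 = down))
  r <- fold_filter(rec, data.frame(target = "liver", direction = "repressed"))
  expect_true(r$pass)
  expect_equal(r$fold_ratio, 0.5)

  # just inside the boundary fails
  up["testis"] <- 15 - 1e-6
  r <- fold_filter(flat_cluster_records(list(g1 = up)),
                   data.frame(target = "testis", direction = "expressed"))
  expect_false(r$pass)
})

test_that("every member gene must pass the fold filter", {
  vals <- stats::setNames(rep(10, 6), organ_vocab())
  gA <- vals; gA["testis"] <- 20   # ratio 2.0
  gB <- vals; gB["testis"] <- 12   # ratio 1.2
  rec <- flat_cluster_records(list(gA = gA, gB = gB))
  r <- fold_filter(rec, data.frame(target = "testis", direction = "expressed"))
  expect_false(r$pass)
  expect_equal(unname(r$gene_ratios), c(2.0, 1.2))
})

test_that("a zero rest-organ level passes expressed and fails repressed, with warning", {
  vals <- stats::setNames(rep(0, 6), organ_vocab())
  vals["testis"] <- 8
  rec <- flat_cluster_records(list(g1 = vals))
  expect_warning(r <- fold_filter(rec, data.frame(target = "testis", direction = "expressed")),
                 "zero rest")
  expect_true(r$pass)
  expect_warning(r <- fold_filter(rec, data.frame(target = "testis", direction = "repressed")),
                 "zero rest")
  expect_false(r$pass)
})

test_that("nervous fold filter averages the two member organ means", {
  vals <- stats::setNames(rep(10, 6), organ_vocab())
  vals["brain"] <- 18; vals["cerebellum"] <- 12  # focal mean 15, rest 10
  rec <- flat_cluster_records(list(g1 = vals))
  r <- fold_filter(rec, data.frame(target = "nervous", direction = "expressed"))
  expect_true(r$pass)
  expect_equal(r$fold_ratio, 1.5)
})

test_that("planted effects are recovered exactly when noise is negligible", {
  alloc <- c(brain_expressed = 2, heart_expressed = 2,
             kidney_expressed = 2, liver_expressed = 2, testis_expressed = 4,
             liver_repressed = 3, testis_repressed = 1, heart_repressed = 1)
  cfg <- sim_config(seed = 21, n_families = 40, oser_fraction = 0.3,
                    gene_sd = 0.499, noise_sd = 0.03, oser_allocation = alloc)
  sim <- simulate_expression(cfg)
  ne <- zscore_normalize(aggregate_replicates(sim$expression))
  calls <- detect_oser(ne, sim$clusters)
  got <- calls[order(calls$cluster_id), c("cluster_id", "target", "direction")]
  want <- sim$truth[order(sim$truth$cluster_id), ]
  expect_equal(as.data.frame(got), as.data.frame(want), ignore_attr = TRUE)
  tab <- tabulate_oser(calls)
  planted <- table(paste(sim$truth$target, sim$truth$direction))
  for (nm in names(planted)) {
    parts <- strsplit(nm, " ")[[1]]
    expect_equal(tab$table[[parts[2L]]][tab$table$target == parts[1L]],
                 unname(planted[nm]))
  }
})

test_that("call tallies and dual counts follow their definitions", {
  empty <- tabulate_oser(data.frame())
  expect_true(all(empty$table$expressed == 0L) && all(empty$table$repressed == 0L))
  expect_equal(empty$dual_count, 0L)

  calls <- data.frame(cluster_id = c("c1", "c1", "c2"),
                      target = c("testis", "liver", "heart"),
                      direction = c("expressed", "repressed", "expressed"))
  tab <- tabulate_oser(calls)
  expect_equal(tab$dual_count, 1L)
  expect_equal(tab$table$expressed[tab$table$target == "testis"], 1L)
  expect_equal(tab$table$repressed[tab$table$target == "liver"], 1L)
})

test_that("emitted calls never mix directions for one target and match their folds", {
  cfg <- sim_config(seed = 31, n_families = 150, oser_fraction = 0.2)
  sim <- simulate_expression(cfg)
  ne <- zscore_normalize(aggregate_replicates(sim$expression))
  calls <- detect_oser(ne, sim$clusters)
  expect_gt(nrow(calls), 0L)
  both <- tapply(calls$direction, paste(calls$cluster_id, calls$target),
                 function(d) length(unique(d)))
  expect_true(all(both == 1L))
  dcfg <- detection_config()
  up <- calls$direction == "expressed"
  expect_true(all(calls$fold_ratio[up] >= dcfg$fold_up))
  expect_true(all(calls$fold_ratio[!up] <= dcfg$fold_down))
  expect_true(all(calls$min_focal_adj_p <= calls$max_focal_adj_p))
  expect_true(all(calls$max_focal_adj_p < dcfg$alpha))
})
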