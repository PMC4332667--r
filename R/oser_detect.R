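#' Detection configuration for the OSER caller
#'
#' Thresholds and vocabularies of the two-stage caller: the significance
#' level of the ANOVA/Tukey screen, the expression-ratio bounds of the
#' RPKM fold filter ("at least 50 percent higher or lower" reads as focal
#' >= 1.5 x rest for expressed calls and focal <= 0.5 x rest for repressed
#' calls), the organ list, and the tissue groups (nervous = brain +
#' cerebellum) tested after the single organs.
#'
#' @param alpha Significance level of the screen (default 0.05).
#' @param fold_up Expressed-call ratio bound, > 1 (default 1.5).
#' @param fold_down Repressed-call ratio bound, in (0,1) (default 0.5).
#' @param organs The organs screened, in evaluation order.
#' @param tissue_groups Named list of organ groups evaluated after the
#'   single organs; a group call requires no significant difference inside
#'   the group but joint separation from every other organ.
#' @param pairwise_anova If `TRUE`, the screen runs 15 separate two-group
#'   ANOVAs (unadjusted p per pair) instead of the omnibus ANOVA followed
#'   by Tukey HSD.
#' @param rest_mean How the "rest" expression level of the fold filter is
#'   formed: `"organ_means"` (unweighted mean of the other organs'
#'   per-organ means, the default) or `"pooled"` (mean over all rest-organ
#'   measurements).
#' @param cluster_level_correction Multiple-testing handling across
#'   clusters: `"none"` (default, as in the original procedure) or `"bh"`
#'   (Benjamini-Hochberg on the omnibus p-values, annotation only).
#' @return A list of class `oser_detection_config`.
#' @export
detection_config <- function(alpha = 0.05, fold_up = 1.5, fold_down = 0.5,
                             organs = organ_vocab(),
                             tissue_groups = list(nervous = c("brain", "cerebellum")),
                             pairwise_anova = FALSE,
                             rest_mean = c("organ_means", "pooled"),
                             cluster_level_correction = c("none", "bh")) {
  if (!(alpha > 0 && alpha < 1)) stop_input("alpha must be in (0,1)")
  if (!(fold_up > 1)) stop_input("fold_up must be > 1")
  if (!(fold_down > 0 && fold_down < 1)) stop_input("fold_down must be in (0,1)")
  for (g in names(tissue_groups)) {
    if (!all(tissue_groups[[g]] %in% organs)) {
      stop_input("tissue group %s references unknown organs", g)
    }
  }
  structure(list(alpha = alpha, fold_up = fold_up, fold_down = fold_down,
                 organs = organs, tissue_groups = tissue_groups,
                 pairwise_anova = pairwise_anova,
                 rest_mean = match.arg(rest_mean),
                 cluster_level_correction = match.arg(cluster_level_correction)),
            class = "oser_detection_config")
}

#' Statistical screen of one cluster across organs
#'
#' Runs the omnibus one-way ANOVA over the cluster's per-gene, per-species,
#' per-sex Z-scores grouped by organ, followed by Tukey HSD over all organ
#' pairs (15 for six organs). Missing strata simply reduce the group sizes.
#' With `pairwise_anova = TRUE` the pairwise table instead carries the
#' unadjusted p of a two-group ANOVA for each pair.
#'
#' @param cluster_obs Named list, organ -> numeric vector of Z-score
#'   observations. At least two organs with two or more observations each.
#' @param cfg A [detection_config()].
#' @return A list with `anova` (see [anova_oneway()]) and `pairwise`
#'   (see [tukey_hsd()]).
#' @export
organ_screen <- function(cluster_obs, cfg = detection_config()) {
  usable <- cluster_obs[lengths(cluster_obs) >= 2L]
  if (length(usable) < 2L) {
    stop_input("organ screen needs at least 2 organs with >= 2 observations")
  }
  usable <- usable[order(match(names(usable), cfg$organs))]
  fit <- anova_oneway(usable)
  if (cfg$pairwise_anova) {
    idx <- utils::combn(length(usable), 2L)
    pw <- do.call(rbind, lapply(seq_len(ncol(idx)), function(j) {
      i1 <- idx[1L, j]; i2 <- idx[2L, j]
      sub <- anova_oneway(usable[c(i1, i2)])
      data.frame(group1 = names(usable)[i1], group2 = names(usable)[i2],
                 mean_diff = unname(sub$group_means[1L] - sub$group_means[2L]),
                 adj_p = sub$p_value, significant = sub$p_value < cfg$alpha,
                 stringsAsFactors = FALSE)
    }))
  } else {
    pw <- tukey_hsd(usable, alpha = cfg$alpha)
  }
  list(anova = fit, pairwise = pw)
}

#' Candidate OSER calls from the pairwise comparison table
#'
#' An organ is a candidate when all of its pairwise comparisons with the
#' other organs are significant with mean differences in one direction. A
#' tissue group (nervous = brain + cerebellum) is a candidate when its
#' members are statistically indistinguishable from each other while every
#' member separates from every outside organ in the same single direction.
#' Candidates are evaluated in a fixed order (organs, then tissue groups)
#' and all surviving candidates are kept, so a cluster can be expressed for
#' one target and repressed for another.
#'
#' @param pairwise Pairwise table from [organ_screen()].
#' @param cfg A [detection_config()].
#' @return A data.frame (`target`, `direction`, `min_focal_adj_p`,
#'   `max_focal_adj_p`), zero rows when no candidate emerges.
#' @export
call_candidates <- function(pairwise, cfg = detection_config()) {
  present <- intersect(cfg$organs, unique(c(pairwise$group1, pairwise$group2)))
  out <- list()
  diff_of <- function(a, b) {
    # oriented difference a - b, whichever order the table stores
    i <- which(pairwise$group1 == a & pairwise$group2 == b)
    if (length(i) == 1L) return(c(pairwise$mean_diff[i], pairwise$adj_p[i]))
    i <- which(pairwise$group1 == b & pairwise$group2 == a)
    if (length(i) == 1L) return(c(-pairwise$mean_diff[i], pairwise$adj_p[i]))
    c(NA_real_, NA_real_)
  }
  for (org in present) {
    others <- setdiff(present, org)
    dd <- vapply(others, function(o) diff_of(org, o), numeric(2))
    if (anyNA(dd)) next
    sig <- dd[2L, ] < cfg$alpha
    if (all(sig) && (all(dd[1L, ] > 0) || all(dd[1L, ] < 0))) {
      out[[length(out) + 1L]] <- data.frame(
        target = org,
        direction = if (all(dd[1L, ] > 0)) "expressed" else "repressed",
        min_focal_adj_p = min(dd[2L, ]), max_focal_adj_p = max(dd[2L, ]),
        stringsAsFactors = FALSE)
    }
  }
  for (grp in names(cfg$tissue_groups)) {
    mem <- cfg$tissue_groups[[grp]]
    if (!all(mem %in% present)) next
    within_ok <- TRUE
    for (pair in utils::combn(mem, 2L, simplify = FALSE)) {
      dp <- diff_of(pair[1L], pair[2L])
      if (is.na(dp[2L]) || dp[2L] < cfg$alpha) within_ok <- FALSE
    }
    if (!within_ok) next
    others <- setdiff(present, mem)
    if (length(others) == 0L) next
    dd <- do.call(cbind, lapply(mem, function(m) {
      vapply(others, function(o) diff_of(m, o), numeric(2))
    }))
    if (anyNA(dd)) next
    sig <- dd[2L, ] < cfg$alpha
    if (all(sig) && (all(dd[1L, ] > 0) || all(dd[1L, ] < 0))) {
      out[[length(out) + 1L]] <- data.frame(
        target = grp,
        direction = if (all(dd[1L, ] > 0)) "expressed" else "repressed",
        min_focal_adj_p = min(dd[2L, ]), max_focal_adj_p = max(dd[2L, ]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(target = character(0), direction = character(0),
                      min_focal_adj_p = numeric(0), max_focal_adj_p = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Expression-ratio filter on a candidate call
#'
#' Confirms a screened candidate on the RPKM scale: every member gene must
#' average at least `fold_up` times higher (expressed) or at most
#' `fold_down` times lower (repressed) in the focal organ than in the rest.
#' Per gene, the focal value is its mean RPKM in the target organ (for a
#' tissue group, the mean of the member organs' per-organ means) and the
#' rest value is the unweighted mean of the other organs' per-organ means
#' (or the pooled rest mean, per config). A gene whose rest value is zero
#' passes an expressed candidate and fails a repressed one, with a warning.
#'
#' @param cluster_rpkm Expression records (`gene_id`, `species`, `organ`,
#'   `sex`, `rpkm`) of the cluster's member genes.
#' @param candidate One-row data.frame (`target`, `direction`) from
#'   [call_candidates()].
#' @param cfg A [detection_config()].
#' @return A list: `pass` (logical), `fold_ratio` (cluster mean of the
#'   per-gene focal/rest ratios), `gene_ratios` (named).
#' @export
fold_filter <- function(cluster_rpkm, candidate, cfg = detection_config()) {
  dt <- as_expression_dt(cluster_rpkm)
  target <- candidate$target[1L]
  direction <- candidate$direction[1L]
  focal_organs <- if (target %in% names(cfg$tissue_groups)) {
    cfg$tissue_groups[[target]]
  } else {
    target
  }
  organ_means <- dt[, list(m = mean(rpkm)), by = c("gene_id", "organ")]
  genes <- unique(organ_means$gene_id)
  ratios <- vapply(genes, function(g) {
    om <- organ_means[organ_means$gene_id == g, ]
    focal_m <- om$m[om$organ %in% focal_organs]
    if (length(focal_m) == 0L) return(NA_real_)  # no focal measurement (missing sample)
    focal <- mean(focal_m)
    rest_rows <- om[!(om$organ %in% focal_organs), ]
    if (nrow(rest_rows) == 0L) return(NA_real_)
    rest <- if (cfg$rest_mean == "organ_means") {
      mean(rest_rows$m)
    } else {
      per_obs <- dt[dt$gene_id == g & !(dt$organ %in% focal_organs), ]
      mean(per_obs$rpkm)
    }
    if (rest == 0) {
      warning(sprintf("gene %s has zero rest-organ expression", g), call. = FALSE)
      return(Inf)
    }
    focal / rest
  }, numeric(1))
  # genes without a measurable focal/rest contrast cannot vote
  evaluable <- ratios[!is.na(ratios)]
  pass_gene <- if (direction == "expressed") {
    evaluable >= cfg$fold_up
  } else {
    is.finite(evaluable) & evaluable <= cfg$fold_down
  }
  list(pass = length(pass_gene) > 0L && all(pass_gene),
       fold_ratio = mean(evaluable[is.finite(evaluable)]),
       gene_ratios = ratios)
}

#' Detect OSER clusters across a normalized expression cohort
#'
#' Applies [organ_screen()], [call_candidates()] and [fold_filter()] to
#' every cluster. Observations in the screen are the per-gene, per-species,
#' per-sex Z-scores of the cluster's member genes, grouped by organ.
#'
#' @param expression Normalized expression table (see [zscore_normalize()])
#'   covering the member genes of the clusters.
#' @param clusters Long cluster table (`cluster_id`, `gene_id`, ...).
#' @param cfg A [detection_config()].
#' @param keep_candidates Also return screened candidates that failed the
#'   fold filter, flagged `candidate_only = TRUE`.
#' @return A `data.table` of calls: `cluster_id`, `target`, `direction`,
#'   `anova_p`, `min_focal_adj_p`, `max_focal_adj_p`, `fold_ratio`,
#'   `candidate_only`.
#' @export
detect_oser <- function(expression, clusters, cfg = detection_config(),
                        keep_candidates = FALSE) {
  expr <- data.table::as.data.table(expression)
  if (!("z_score" %in% names(expr))) {
    stop_input("expression table must be normalized first (missing z_score)")
  }
  clu <- data.table::as.data.table(clusters)
  expr <- merge(expr, clu[, c("cluster_id", "gene_id"), with = FALSE],
                by = "gene_id", allow.cartesian = TRUE)
  pieces <- split(expr, by = "cluster_id", sorted = TRUE)
  calls <- lapply(names(pieces), function(cid) {
    sub <- pieces[[cid]]
    obs <- split(sub$z_score, sub$organ)
    obs <- obs[lengths(obs) >= 2L]
    if (length(obs) < 2L) return(NULL)
    scr <- organ_screen(obs, cfg)
    cand <- call_candidates(scr$pairwise, cfg)
    if (nrow(cand) == 0L) return(NULL)
    rows <- lapply(seq_len(nrow(cand)), function(i) {
      ff <- fold_filter(sub, cand[i, , drop = FALSE], cfg)
      if (!ff$pass && !keep_candidates) return(NULL)
      data.table::data.table(cluster_id = cid,
                             target = cand$target[i], direction = cand$direction[i],
                             anova_p = scr$anova$p_value,
                             min_focal_adj_p = cand$min_focal_adj_p[i],
                             max_focal_adj_p = cand$max_focal_adj_p[i],
                             fold_ratio = ff$fold_ratio,
                             candidate_only = !ff$pass)
    })
    data.table::rbindlist(rows)
  })
  out <- data.table::rbindlist(calls)
  if (nrow(out) == 0L) {
    out <- data.table::data.table(cluster_id = character(0), target = character(0),
                                  direction = character(0), anova_p = numeric(0),
                                  min_focal_adj_p = numeric(0), max_focal_adj_p = numeric(0),
                                  fold_ratio = numeric(0), candidate_only = logical(0))
  }
  if (cfg$cluster_level_correction == "bh" && nrow(out) > 0L) {
    out[, anova_p_bh := stats::p.adjust(anova_p, method = "BH")]
  }
  out[]
}

#' Tally OSER calls per target and direction
#'
#' Produces the per-organ/tissue expressed and repressed counts plus the
#' number of dual-call clusters (at least one expressed and one repressed
#' call on the same cluster).
#'
#' @param calls Call table from [detect_oser()]; `candidate_only` rows are
#'   excluded from the tallies.
#' @param targets Target order of the output (defaults to the six organs
#'   then `nervous`).
#' @return A list with `table` (`target`, `expressed`, `repressed`) and
#'   `dual_count`.
#' @export
tabulate_oser <- function(calls,
                          targets = c(organ_vocab(), "nervous")) {
  dt <- data.table::as.data.table(calls)
  if (nrow(dt) > 0L && "candidate_only" %in% names(dt)) {
    dt <- dt[!dt$candidate_only, ]
  }
  tab <- data.table::data.table(target = targets, expressed = 0L, repressed = 0L)
  if (nrow(dt) > 0L) {
    cnt <- dt[, list(n = .N), by = c("target", "direction")]
    for (i in seq_len(nrow(cnt))) {
      j <- match(cnt$target[i], tab$target)
      if (!is.na(j)) data.table::set(tab, j, cnt$direction[i], cnt$n[i])
    }
    per_clu <- dt[, list(has_e = any(direction == "expressed"),
                         has_r = any(direction == "repressed")), by = "cluster_id"]
    dual <- sum(per_clu$has_e & per_clu$has_r)
  } else {
    dual <- 0L
  }
  list(table = tab, dual_count = as.integer(dual))
}
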