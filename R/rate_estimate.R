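#' Total branch length of a phylogenetic tree
#'
#' The sum of all edge lengths, internal and terminal. For trees built
#' from an empirical amino-acid substitution model this total acts as the
#' cumulative evolutionary rate of the genes in the tree, which is why
#' only one-to-one clusters (nine leaves, one gene per species) are
#' admitted downstream: extra paralogs would add branches and inflate the
#' estimate. Edges without a length count as 0, with a warning.
#'
#' @param tree An `ape` `phylo` object, or a newick string/file path.
#' @return Nonnegative numeric.
#' @export
total_branch_length <- function(tree) {
  if (is.character(tree)) {
    tree <- read_newick(tree)
  }
  if (!inherits(tree, "phylo")) stop_input("tree must be a phylo object or newick")
  el <- tree$edge.length
  if (is.null(el)) {
    warning("tree has no edge lengths; total branch length is 0", call. = FALSE)
    return(0)
  }
  if (anyNA(el)) {
    warning(sprintf("%d edge(s) without length treated as 0", sum(is.na(el))),
            call. = FALSE)
    el[is.na(el)] <- 0
  }
  if (any(el < 0)) stop_input("negative edge length in tree")
  # a rooted binary tree may carry a root edge not in the edge matrix
  sum(el) + (tree$root.edge %||% 0)
}

read_newick <- function(x) {
  tr <- if (file.exists(x)) ape::read.tree(file = x) else ape::read.tree(text = x)
  if (is.null(tr)) stop_input("malformed newick input")
  tr
}

#' Read one newick tree per cluster
#'
#' @param paths Named character vector of newick file paths (names =
#'   cluster ids) or a directory containing `<cluster_id>.nwk` files.
#' @return A named list of `phylo` objects.
#' @export
read_cluster_trees <- function(paths) {
  if (length(paths) == 1L && dir.exists(paths)) {
    files <- list.files(paths, pattern = "\\.nwk$", full.names = TRUE)
    paths <- stats::setNames(files, sub("\\.nwk$", "", basename(files)))
  }
  if (is.null(names(paths))) stop_input("tree paths must be named by cluster id")
  lapply(paths, read_newick)
}

#' Per-cluster evolutionary-rate records
#'
#' Sums branch lengths per cluster tree and attaches the cluster's OSER
#' group. Only one-to-one clusters are admitted.
#'
#' @param trees Named list of `phylo` objects (names = cluster ids).
#' @param groups A data.frame (`cluster_id`, `group`), e.g. group =
#'   "testis_expressed".
#' @param one_to_one A data.frame (`cluster_id`, `one_to_one`) or a
#'   character vector of one-to-one cluster ids.
#' @return A `data.table` (`cluster_id`, `group`, `total_branch_length`).
#' @export
rate_records <- function(trees, groups, one_to_one) {
  if (is.data.frame(one_to_one)) {
    one_to_one <- one_to_one$cluster_id[one_to_one$one_to_one]
  }
  g <- data.table::as.data.table(groups)
  keep <- intersect(names(trees), intersect(g$cluster_id, one_to_one))
  tbl <- vapply(trees[keep], total_branch_length, numeric(1))
  out <- data.table::data.table(cluster_id = keep,
                                group = g$group[match(keep, g$cluster_id)],
                                total_branch_length = unname(tbl))
  data.table::setorderv(out, "cluster_id")
  out[]
}

#' Compare evolutionary-rate distributions across OSER groups
#'
#' Mean and median total branch length per group, plus a two-sided
#' rank-sum test for each requested (or every) group pair. Groups with
#' fewer than two records are skipped with a warning.
#'
#' @param records Table from [rate_records()].
#' @param pairs Optional list of 2-vectors of group names to compare;
#'   default all pairs.
#' @return A list: `groups` (`group`, `n`, `mean`, `median`) and
#'   `comparisons` (`group1`, `group2`, `statistic`, `p_value`,
#'   `mean_ratio` = mean1/mean2).
#' @export
group_rate_comparison <- function(records, pairs = NULL) {
  dt <- data.table::as.data.table(records)
  gs <- dt[, list(n = .N, mean = mean(total_branch_length),
                  median = stats::median(total_branch_length)), by = "group"]
  small <- gs$group[gs$n < 2L]
  if (length(small) > 0L) {
    warning(sprintf("group(s) with fewer than 2 records skipped: %s",
                    paste(small, collapse = ", ")), call. = FALSE)
  }
  usable <- setdiff(gs$group, small)
  if (is.null(pairs)) {
    pairs <- if (length(usable) >= 2L) {
      utils::combn(sort(usable), 2L, simplify = FALSE)
    } else {
      list()
    }
  } else {
    pairs <- Filter(function(p) all(p %in% usable), pairs)
  }
  comp <- data.table::rbindlist(lapply(pairs, function(p) {
    x <- dt$total_branch_length[dt$group == p[1L]]
    y <- dt$total_branch_length[dt$group == p[2L]]
    rs <- rank_sum_test(x, y)
    data.table::data.table(group1 = p[1L], group2 = p[2L],
                           statistic = rs$statistic, p_value = rs$p_value,
                           mean_ratio = mean(x) / mean(y))
  }))
  if (nrow(comp) == 0L) {
    comp <- data.table::data.table(group1 = character(0), group2 = character(0),
                                   statistic = numeric(0), p_value = numeric(0),
                                   mean_ratio = numeric(0))
  }
  list(groups = gs[], comparisons = comp[])
}
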