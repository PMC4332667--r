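# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# connected components by breadth-first search over an adjacency list
oracle_components <- function(edges, genes = NULL) {
  verts <- unique(c(edges$gene_a, edges$gene_b, genes))
  adj <- lapply(stats::setNames(vector("list", length(verts)), verts), function(x) character(0))
  for (i in seq_len(nrow(edges))) {
    a <- edges$gene_a[i]; b <- edges$gene_b[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- character(0)
  comps <- list()
  for (v in verts) {
    if (v %in% seen) next
    queue <- v
    comp <- character(0)
    while (length(queue) > 0L) {
      u <- queue[1L]; queue <- queue[-1L]
      if (u %in% comp) next
      comp <- c(comp, u)
      queue <- c(queue, setdiff(adj[[u]], comp))
    }
    seen <- c(seen, comp)
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps[order(vapply(comps, min, character(1)))]
}

# sum every ":<number>" token in a newick string
oracle_branch_sum <- function(newick) {
  toks <- regmatches(newick, gregexpr(":[0-9.eE+-]+", newick))[[1]]
  sum(as.numeric(sub(":", "", toks)))
}

# exhaustive nearest-TSS scan; tie -> smallest gene id
oracle_nearest <- function(mid, chrom, genes) {
  g <- genes[genes$chrom == chrom, ]
  tss <- ifelse(g$strand == "+", g$start, g$end - 1L)
  d <- abs(mid - tss)
  cand <- g$gene_id[d == min(d)]
  list(gene_id = min(cand), distance = min(d))
}

# per-seed scan reproducing the template-anchored grouping rule
oracle_clusters <- function(pairs, template_groups = NULL, n_target_species = 8L) {
  hi <- pairs[pairs$confidence == "high", ]
  seed <- hi$template_gene
  if (!is.null(template_groups)) {
    m <- match(hi$template_gene, template_groups$template_gene)
    seed[!is.na(m)] <- as.character(template_groups$group_id[m[!is.na(m)]])
  }
  out <- list()
  for (s in unique(seed)) {
    rows <- hi[seed == s, ]
    if (length(unique(rows$target_species)) == n_target_species) {
      tmpl <- unique(rows$template_gene)
      if (!is.null(template_groups)) {
        tmpl <- unique(c(tmpl, template_groups$template_gene[
          as.character(template_groups$group_id) == s]))
      }
      out[[s]] <- sort(unique(c(tmpl, rows$target_gene)))
    }
  }
  out
}

# exhaustive Venn region sizes by membership-vector enumeration
oracle_venn <- function(sets) {
  targets <- names(sets)
  universe <- unique(unlist(sets))
  out <- list()
  for (k in seq_along(targets)) {
    for (cm in utils::combn(targets, k, simplify = FALSE)) {
      size <- sum(vapply(universe, function(e) {
        inside <- vapply(targets, function(t) e %in% sets[[t]], logical(1))
        identical(targets[inside], cm)
      }, logical(1)))
      out[[paste(cm, collapse = "&")]] <- size
    }
  }
  out
}

random_grouped_sample <- function(k = 3L, n_range = c(4L, 10L), shift = 0) {
  ns <- sample(seq(n_range[1L], n_range[2L]), k, replace = TRUE)
  s <- lapply(seq_len(k), function(i) rnorm(ns[i], mean = if (i == 1L) shift else 0))
  names(s) <- paste0("g", seq_len(k))
  s
}

# exact constant-valued expression records for fold-filter fixtures:
# one value per organ, identical across species/sex
flat_cluster_records <- function(gene_values, organs = oserve::organ_vocab(),
                                 species = c("chicken", "human"),
                                 sexes = c("female", "male")) {
  # gene_values: named list gene_id -> named numeric (organ -> rpkm)
  rows <- list()
  for (g in names(gene_values)) {
    for (org in organs) {
      for (sp in species) {
        for (sx in sexes) {
          rows[[length(rows) + 1L]] <- data.frame(
            gene_id = g, species = sp, organ = org, sex = sx,
            rpkm = gene_values[[g]][[org]], stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}
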