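#' Assign ChIP peaks to their nearest gene at the 2.5 kb boundary
#'
#' Each peak is assigned to the gene with the smallest distance between
#' the peak midpoint (`floor((start+end)/2)`, 0-based half-open
#' coordinates) and the gene's strand-aware transcription start site
#' (`start` on +, `end - 1` on -). Following the ENCODE criterion, an
#' assignment is proximal when that distance is at most 2500 bp, distal
#' otherwise. Equidistant ties go to the lexicographically smaller
#' `gene_id`. Peaks on chromosomes without genes are dropped with a
#' warning. The result does not depend on peak input order.
#'
#' @param peaks A data.frame (`tf`, `chrom`, `start`, `end`), 0-based
#'   half-open, `0 <= start < end`.
#' @param genes A data.frame (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`), same conventions.
#' @param proximal_bp Proximal/distal boundary (default 2500).
#' @param anchor Distance anchor on the gene: `"tss"` (default) or
#'   `"body"` (distance to the nearest gene boundary, 0 inside the gene).
#' @return A `data.table` (`tf`, `chrom`, `peak_start`, `peak_end`,
#'   `midpoint`, `gene_id`, `distance_bp`, `site_class`).
#' @export
assign_peaks <- function(peaks, genes, proximal_bp = 2500L,
                         anchor = c("tss", "body")) {
  anchor <- match.arg(anchor)
  pk <- data.table::as.data.table(peaks)
  gn <- data.table::as.data.table(genes)
  need_p <- c("tf", "chrom", "start", "end")
  need_g <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(need_p %in% names(pk))) stop_input("peak table needs columns %s", paste(need_p, collapse = ", "))
  if (!all(need_g %in% names(gn))) stop_input("gene table needs columns %s", paste(need_g, collapse = ", "))
  if (any(pk$start < 0L) || any(pk$start >= pk$end)) stop_input("peaks must satisfy 0 <= start < end")
  if (any(gn$start >= gn$end)) stop_input("genes must satisfy start < end")
  if (!all(gn$strand %in% c("+", "-"))) stop_input("gene strand must be + or -")
  pk <- data.table::copy(pk)
  pk[, midpoint := as.integer(floor((start + end) / 2))]
  gn <- data.table::copy(gn)
  gn[, tss := ifelse(strand == "+", start, end - 1L)]

  orphan <- !(pk$chrom %in% gn$chrom)
  if (any(orphan)) {
    warning(sprintf("%d peak(s) on chromosomes without genes left unassigned",
                    sum(orphan)), call. = FALSE)
    pk <- pk[!orphan, ]
  }
  if (nrow(pk) == 0L) {
    return(data.table::data.table(tf = character(0), chrom = character(0),
                                  peak_start = integer(0), peak_end = integer(0),
                                  midpoint = integer(0), gene_id = character(0),
                                  distance_bp = integer(0), site_class = character(0)))
  }

  out <- lapply(split(pk, by = "chrom"), function(sub) {
    g <- gn[gn$chrom == sub$chrom[1L], ]
    if (anchor == "tss") {
      res <- nearest_point(sub$midpoint, g$tss, g$gene_id)
    } else {
      res <- nearest_interval(sub$midpoint, g$start, g$end, g$gene_id)
    }
    data.table::data.table(tf = sub$tf, chrom = sub$chrom,
                           peak_start = sub$start, peak_end = sub$end,
                           midpoint = sub$midpoint,
                           gene_id = res$gene_id, distance_bp = res$distance)
  })
  out <- data.table::rbindlist(out)
  out[, site_class := ifelse(distance_bp <= proximal_bp, "proximal", "distal")]
  data.table::setorderv(out, c("tf", "chrom", "peak_start", "peak_end", "gene_id"))
  out[]
}

# nearest anchor point for each query; tie on distance -> smallest gene_id;
# several genes can share one anchor position
nearest_point <- function(q, pos, ids) {
  o <- order(pos, ids)
  pos <- pos[o]; ids <- ids[o]
  u <- unique(pos)
  # smallest gene id at each unique position
  min_id <- vapply(split(ids, match(pos, u)), min, character(1))
  lo <- findInterval(q, u)
  hi <- pmin(lo + 1L, length(u))
  lo <- pmax(lo, 1L)
  d_lo <- abs(q - u[lo])
  d_hi <- abs(q - u[hi])
  pick_lo <- d_lo < d_hi | (d_lo == d_hi & min_id[lo] <= min_id[hi])
  idx <- ifelse(pick_lo, lo, hi)
  list(gene_id = min_id[idx], distance = as.integer(pmin(d_lo, d_hi)))
}

# distance to the nearest gene boundary (0 inside the gene body)
nearest_interval <- function(q, gstart, gend, ids) {
  gene_id <- character(length(q))
  distance <- integer(length(q))
  for (i in seq_along(q)) {
    d <- pmax(gstart - q[i], q[i] - (gend - 1L), 0L)
    dmin <- min(d)
    cand <- ids[d == dmin]
    gene_id[i] <- min(cand)
    distance[i] <- as.integer(dmin)
  }
  list(gene_id = gene_id, distance = distance)
}

#' Rank transcription factors by the OSER genes they bind
#'
#' For every target (organ/tissue) and site class, counts the distinct
#' OSER genes of that target bound by each TF (a gene counts as bound when
#' at least one peak of the TF is assigned to it in that site class).
#' Ranked by descending count, count ties broken by TF name.
#'
#' @param assignments Table from [assign_peaks()].
#' @param oser_genes Named list, target -> character vector of gene ids.
#' @param top_k Optional cutoff per (target, site_class).
#' @return A `data.table` (`target`, `site_class`, `tf`, `n_genes`,
#'   `rank`).
#' @export
tf_target_tally <- function(assignments, oser_genes, top_k = NULL) {
  asn <- data.table::as.data.table(assignments)
  out <- list()
  for (tg in names(oser_genes)) {
    gset <- oser_genes[[tg]]
    sub <- asn[asn$gene_id %in% gset, ]
    if (nrow(sub) == 0L) next
    cnt <- unique(sub[, c("tf", "gene_id", "site_class"), with = FALSE])
    cnt <- cnt[, list(n_genes = .N), by = c("site_class", "tf")]
    cnt[, target := tg]
    out[[tg]] <- cnt
  }
  if (length(out) == 0L) {
    return(data.table::data.table(target = character(0), site_class = character(0),
                                  tf = character(0), n_genes = integer(0),
                                  rank = integer(0)))
  }
  res <- data.table::rbindlist(out)
  data.table::setorderv(res, c("target", "site_class", "n_genes", "tf"),
                        order = c(1L, 1L, -1L, 1L))
  res[, rank := seq_len(.N), by = c("target", "site_class")]
  if (!is.null(top_k)) res <- res[res$rank <= top_k, ]
  res[, c("target", "site_class", "tf", "n_genes", "rank"), with = FALSE]
}

#' Transcription factors shared by all targets, with Venn regions
#'
#' @param tf_sets Named list, target -> character vector of TF names
#'   bound in the given site class; at least two targets.
#' @return A list: `shared` (size of the intersection over all targets),
#'   `shared_tfs` (sorted), and `regions` (a `data.table` of all
#'   2^k - 1 exclusive Venn region sizes; `members` joins target names
#'   with `&`).
#' @export
shared_tf_sets <- function(tf_sets) {
  if (length(tf_sets) < 2L) stop_input("need at least two targets")
  targets <- names(tf_sets)
  universe <- sort(unique(unlist(tf_sets)))
  if (length(universe) == 0L) {
    return(list(shared = 0L, shared_tfs = character(0),
                regions = data.table::data.table(members = character(0), size = integer(0))))
  }
  memb <- vapply(tf_sets, function(s) universe %in% s, logical(length(universe)))
  if (is.null(dim(memb))) memb <- matrix(memb, nrow = 1L)
  key <- apply(memb, 1L, function(r) paste(targets[r], collapse = "&"))
  combos <- unlist(lapply(seq_along(targets), function(k) {
    utils::combn(targets, k, FUN = paste, collapse = "&")
  }))
  size <- vapply(combos, function(cm) sum(key == cm), integer(1))
  shared_tfs <- universe[key == paste(targets, collapse = "&")]
  list(shared = length(shared_tfs), shared_tfs = shared_tfs,
       regions = data.table::data.table(members = combos, size = unname(size)))
}

#' Cross-species overlap of TF binding on OSER genes
#'
#' Maps the genes bound in the other species to their orthologs in the
#' reference (human) gene space and intersects with the human-bound set.
#' The percentage is relative to the human count and is formatted the way
#' the comparison tables print it: integer percent, one decimal below 10.
#'
#' @param human_bound Character vector of human OSER genes bound.
#' @param other_bound Character vector of bound genes in the other
#'   species' id space.
#' @param ortholog_map A data.frame (`other_gene`, `human_gene`),
#'   one-to-one.
#' @param oser_genes Optional character vector restricting the overlap to
#'   OSER genes.
#' @return A list: `n_human`, `n_other`, `n_overlap`, `percent`
#'   (numeric, NA when `n_human` is 0), `percent_label` (character).
#' @export
cross_species_overlap <- function(human_bound, other_bound, ortholog_map,
                                  oser_genes = NULL) {
  om <- data.table::as.data.table(ortholog_map)
  if (!all(c("other_gene", "human_gene") %in% names(om))) {
    stop_input("ortholog_map needs columns other_gene, human_gene")
  }
  if (anyDuplicated(om$other_gene) || anyDuplicated(om$human_gene)) {
    stop_input("ortholog_map must be one-to-one")
  }
  human_bound <- unique(human_bound)
  other_bound <- unique(other_bound)
  mapped <- om$human_gene[match(other_bound, om$other_gene)]
  mapped <- mapped[!is.na(mapped)]
  overlap <- intersect(human_bound, mapped)
  if (!is.null(oser_genes)) overlap <- intersect(overlap, oser_genes)
  n_h <- length(human_bound)
  pct <- if (n_h == 0L) NA_real_ else 100 * length(overlap) / n_h
  list(n_human = n_h, n_other = length(other_bound),
       n_overlap = length(overlap), percent = pct,
       percent_label = format_percent(pct))
}

format_percent <- function(pct) {
  if (is.na(pct)) return(NA_character_)
  if (pct < 10) sprintf("%.1f", round(pct, 1L)) else sprintf("%d", round(pct))
}
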