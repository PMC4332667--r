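#' Reads-per-kilobase-per-million normalization
#'
#' RPKM = 1e9 * C / (N * L) where C is the number of reads mapped to the
#' gene's exon model, L the summed exon length in bp, and N the number of
#' mapped reads in the library. Vectorized.
#'
#' @param mapped_reads Integer vector, reads on the gene (C), each >= 0 and
#'   <= `library_mapped_reads`.
#' @param exon_length_bp Integer vector, summed exon length (L), > 0.
#' @param library_mapped_reads Integer vector, library size (N), > 0.
#' @return Numeric RPKM values.
#' @export
compute_rpkm <- function(mapped_reads, exon_length_bp, library_mapped_reads) {
  if (any(exon_length_bp <= 0)) stop_input("exon_length_bp must be > 0")
  if (any(library_mapped_reads <= 0)) stop_input("library_mapped_reads must be > 0")
  if (any(mapped_reads < 0)) stop_input("mapped_reads must be >= 0")
  if (any(mapped_reads > library_mapped_reads)) {
    stop_input("mapped_reads cannot exceed library_mapped_reads")
  }
  1e9 * mapped_reads / (as.numeric(library_mapped_reads) * exon_length_bp)
}

#' Collapse replicate measurements to their mean RPKM
#'
#' Within each (gene, species, organ, sex) combination the RPKM is replaced
#' by the arithmetic mean over replicates. Female and male batches are kept
#' apart, never merged. Idempotent.
#'
#' @param records A data.frame with columns `gene_id`, `species`, `organ`,
#'   `sex`, `rpkm`.
#' @return A `data.table` with one row per (gene, species, organ, sex).
#' @export
aggregate_replicates <- function(records) {
  dt <- as_expression_dt(records)
  dt[, list(rpkm = mean(rpkm)), by = c("gene_id", "species", "organ", "sex")]
}

#' Log2-transform and Z-score expression within normalization strata
#'
#' Adds `log2_value = log2(rpkm + pseudocount)` and, within each
#' (species, organ, sex) stratum (or (species, organ) when sexes are
#' pooled), `z_score = (log2_value - stratum mean) / stratum SD` with the
#' n-1 denominator. This renders expression comparable across organs and
#' species. Strata must contain at least two genes with non-identical
#' values; a zero-variance stratum is an error naming the stratum.
#'
#' @inheritParams aggregate_replicates
#' @param pseudocount Added to RPKM before log2 (default 1, so zero RPKM
#'   maps to log2 value 0).
#' @param pool_sexes If `TRUE`, normalize within (species, organ) pooling
#'   the two sex batches; default `FALSE` keeps them separate strata.
#' @return The input as a `data.table` with `log2_value` and `z_score`
#'   columns added.
#' @export
zscore_normalize <- function(records, pseudocount = 1, pool_sexes = FALSE) {
  dt <- as_expression_dt(records)
  dt <- data.table::copy(dt)
  dt[, log2_value := log2(rpkm + pseudocount)]
  by_cols <- if (pool_sexes) c("species", "organ") else c("species", "organ", "sex")
  chk <- dt[, list(n = .N, sd = stats::sd(log2_value)), by = by_cols]
  bad <- chk[chk$n < 2L | is.na(chk$sd) | chk$sd == 0, ]
  if (nrow(bad) > 0L) {
    lab <- do.call(paste, c(bad[, by_cols, with = FALSE], list(sep = "/")))
    stop_input("degenerate normalization stratum (n < 2 or zero variance): %s",
               paste(lab, collapse = ", "))
  }
  dt[, z_score := (log2_value - mean(log2_value)) / stats::sd(log2_value), by = by_cols]
  dt[]
}

#' Expression-rank bin of an RPKM value within an organ
#'
#' Bins a gene's expression against the distribution of all genes expressed
#' (RPKM > 0) in the organ, on the empirical percentile scale: 0 = not
#' expressed, 1 = at or below the 5th percentile, 2 = (5,15], 3 = (15,35],
#' 4 = (35,65], 5 = (65,85], 6 = (85,95], 7 = above the 95th percentile.
#' Missing measurements return `NA`. Percentiles use mean ranks for ties,
#' so tied values always land in the same bin.
#'
#' @param rpkm Numeric vector of RPKM values to bin (NA = missing).
#' @param organ_expression_distribution Numeric vector of the RPKM values
#'   of all genes expressed in the organ (all > 0); must be nonempty.
#' @return Integer vector of bins in 0..7, NA for missing input.
#' @export
rank_bin <- function(rpkm, organ_expression_distribution) {
  dist <- organ_expression_distribution
  if (length(dist) == 0L) stop_input("empty organ expression distribution")
  if (any(is.na(dist)) || any(dist <= 0)) {
    stop_input("distribution must contain only expressed genes (rpkm > 0)")
  }
  n <- length(dist)
  sdist <- sort(dist)
  vapply(rpkm, function(v) {
    if (is.na(v)) return(NA_integer_)
    if (v == 0) return(0L)
    n_less <- sum(sdist < v)
    n_eq <- sum(sdist == v)
    pct <- 100 * (n_less + (n_eq + 1) / 2) / n
    if (pct <= 5) 1L else if (pct <= 15) 2L else if (pct <= 35) 3L
    else if (pct <= 65) 4L else if (pct <= 85) 5L else if (pct <= 95) 6L else 7L
  }, integer(1))
}

#' Add expression-rank bins to a normalized table
#'
#' Convenience wrapper applying [rank_bin()] to every measurement against
#' the expressed-gene distribution of its own (species, organ) group.
#'
#' @inheritParams aggregate_replicates
#' @return The table with a `rank_bin` column added.
#' @export
add_rank_bins <- function(records) {
  dt <- data.table::copy(as_expression_dt(records))
  dt[, rank_bin := {
    expressed <- rpkm[rpkm > 0]
    if (length(expressed) == 0L) rep(NA_integer_, .N) else rank_bin(rpkm, expressed)
  }, by = c("species", "organ")]
  dt[]
}

as_expression_dt <- function(records) {
  need <- c("gene_id", "species", "organ", "sex", "rpkm")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L) {
    stop_input("expression table lacks column(s): %s", paste(miss, collapse = ", "))
  }
  dt <- data.table::as.data.table(records)
  key_na <- !stats::complete.cases(dt[, c("gene_id", "species", "organ", "sex"), with = FALSE])
  if (any(key_na)) stop_input("conflicting or missing gene metadata in %d row(s)", sum(key_na))
  if (any(is.na(dt$rpkm)) || any(dt$rpkm < 0)) stop_input("rpkm must be >= 0 and non-missing")
  dt
}

#' Validate species and organ labels of an expression table
#'
#' @inheritParams aggregate_replicates
#' @param species,organs Allowed vocabularies.
#' @return The table, invisibly, if valid; otherwise an error.
#' @export
validate_expression <- function(records, species = focal_species(), organs = organ_vocab()) {
  dt <- as_expression_dt(records)
  bad_sp <- setdiff(unique(dt$species), species)
  if (length(bad_sp) > 0L) stop_input("unknown species label(s): %s", paste(bad_sp, collapse = ", "))
  bad_org <- setdiff(unique(dt$organ), organs)
  if (length(bad_org) > 0L) stop_input("unknown organ label(s): %s", paste(bad_org, collapse = ", "))
  bad_sex <- setdiff(unique(dt$sex), c("female", "male", "unknown"))
  if (length(bad_sex) > 0L) stop_input("unknown sex label(s): %s", paste(bad_sex, collapse = ", "))
  invisible(dt)
}
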