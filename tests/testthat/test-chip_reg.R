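simple_genes <- function() {
  data.frame(gene_id = c("gB", "gA", "gC"),
             chrom = c("chr1", "chr1", "chr2"),
             start = c(10000L, 50000L, 5000L),
             end = c(15000L, 60000L, 9000L),
             strand = c("+", "-", "+"))
}

test_that("peak assignment honors the 2.5 kb proximal boundary exactly", {
  genes <- simple_genes()  # gB tss 10000 (+), gA tss 59999 (-), gC tss 5000
  peaks <- data.frame(tf = "TFX", chrom = "chr1",
                      start = c(7900L, 7400L, 7398L, 59000L),
                      end = c(8100L, 7600L, 7600L, 59200L))
  # midpoints: 8000 (d=2000), 7500 (d=2500), 7499 (d=2501), 59100 (d=899 to gA)
  asn <- assign_peaks(peaks, genes)
  expect_equal(asn$distance_bp[asn$midpoint == 8000], 2000L)
  expect_equal(asn$site_class[asn$midpoint == 8000], "proximal")
  expect_equal(asn$site_class[asn$midpoint == 7500], "proximal")  # boundary included
  expect_equal(asn$site_class[asn$midpoint == 7499], "distal")
  expect_equal(asn$gene_id[asn$midpoint == 59100], "gA")
})

test_that("equidistant peaks go to the lexicographically smaller gene", {
  genes <- data.frame(gene_id = c("gZ", "gA"), chrom = "chr1",
                      start = c(1000L, 3000L), end = c(1500L, 3500L),
                      strand = c("+", "+"))  # tss 1000 and 3000
  peaks <- data.frame(tf = "T", chrom = "chr1", start = 1900L, end = 2100L)  # mid 2000
  asn <- assign_peaks(peaks, genes)
  expect_equal(asn$gene_id, "gA")
  expect_equal(asn$distance_bp, 1000L)

  # two genes sharing one TSS position
  genes2 <- data.frame(gene_id = c("gM", "gB"), chrom = "chr1",
                       start = c(1000L, 1000L), end = c(2000L, 3000L),
                       strand = c("+", "+"))
  asn2 <- assign_peaks(peaks, genes2)
  expect_equal(asn2$gene_id, "gB")
})

test_that("assignment is order-independent and warns on orphan chromosomes", {
  set.seed(7)
  genes <- simple_genes()
  peaks <- data.frame(tf = "T", chrom = sample(c("chr1", "chr2"), 30, replace = TRUE),
                      start = sample(1000:80000, 30))
  peaks$end <- peaks$start + 200L
  a1 <- assign_peaks(peaks, genes)
  a2 <- assign_peaks(peaks[sample(nrow(peaks)), ], genes)
  expect_equal(a1, a2)

  orphan <- data.frame(tf = "T", chrom = "chrX", start = 1L, end = 100L)
  expect_warning(r <- assign_peaks(rbind(peaks, orphan), genes), "unassigned")
  expect_equal(nrow(r), nrow(peaks))
  # proximal/distal partition
  expect_setequal(unique(r$site_class), intersect(c("proximal", "distal"), r$site_class))
  expect_equal(sum(r$site_class == "proximal") + sum(r$site_class == "distal"), nrow(r))
})

test_that("nearest-gene assignment matches an exhaustive all-pairs oracle", {
  set.seed(8)
  for (rep in 1:10) {
    n_g <- sample(20:60, 1)
    genes <- data.frame(gene_id = sprintf("g%03d", sample(999, n_g)),
                        chrom = sample(paste0("chr", 1:3), n_g, replace = TRUE),
                        start = sample(1000:500000, n_g))
    genes$end <- genes$start + sample(500:20000, n_g, replace = TRUE)
    genes$strand <- sample(c("+", "-"), n_g, replace = TRUE)
    n_p <- 150
    peaks <- data.frame(tf = "T", chrom = sample(paste0("chr", 1:3), n_p, replace = TRUE),
                        start = sample(1000:500000, n_p))
    peaks$end <- peaks$start + sample(100:600, n_p, replace = TRUE)
    asn <- assign_peaks(peaks, genes)
    for (i in seq_len(nrow(asn))) {
      want <- oracle_nearest(asn$midpoint[i], asn$chrom[i], genes)
      expect_equal(asn$gene_id[i], want$gene_id)
      expect_equal(asn$distance_bp[i], as.integer(want$distance))
    }
  }
})

test_that("gene-body anchoring measures zero inside the gene", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 1000L,
                      end = 5000L, strand = "+")
  peaks <- data.frame(tf = "T", chrom = "chr1",
                      start = c(2000L, 6000L), end = c(2200L, 6200L))
  asn <- assign_peaks(peaks, genes, anchor = "body")
  expect_equal(asn$distance_bp, c(0L, 1101L))  # mid 6100 vs last base 4999
})

test_that("TF tallies count distinct bound genes and rank with stable ties", {
  empty <- tf_target_tally(data.frame(tf = character(0), gene_id = character(0),
                                      site_class = character(0)),
                           list(brain = "g1"))
  expect_equal(nrow(empty), 0L)

  asn <- data.frame(tf = c(rep("REST", 10), rep("CTCF", 3), "AAA", "ZZZ"),
                    gene_id = c(paste0("b", c(1:9, 1)), paste0("b", 1:3), "b1", "b1"),
                    site_class = "proximal")
  tal <- tf_target_tally(asn, list(brain = paste0("b", 1:9)))
  expect_equal(tal$tf[1L], "REST")
  expect_equal(tal$n_genes[1L], 9L)  # gene b1 bound twice counts once
  expect_equal(tal$tf[2L], "CTCF")
  # ties broken alphabetically
  expect_equal(tal$tf[3:4], c("AAA", "ZZZ"))
  expect_equal(tf_target_tally(asn, list(brain = paste0("b", 1:9)), top_k = 2L)$tf,
               c("REST", "CTCF"))
})

test_that("shared TF sets and Venn regions match exhaustive enumeration", {
  same <- list(a = c("x", "y"), b = c("x", "y"), c = c("x", "y"))
  r <- shared_tf_sets(same)
  expect_equal(r$shared, 2L)
  disjoint <- list(a = "x", b = "y")
  expect_equal(shared_tf_sets(disjoint)$shared, 0L)

  set.seed(9)
  for (rep in 1:10) {
    k <- sample(2:5, 1)
    universe <- paste0("TF", 1:15)
    sets <- lapply(seq_len(k), function(i) sample(universe, sample(3:12, 1)))
    names(sets) <- paste0("t", seq_len(k))
    got <- shared_tf_sets(sets)
    want <- oracle_venn(sets)
    for (nm in names(want)) {
      expect_equal(got$regions$size[got$regions$members == nm], want[[nm]],
                   label = nm)
    }
    expect_equal(got$shared, length(Reduce(intersect, sets)))
    expect_lte(got$shared, min(lengths(sets)))
    expect_equal(sum(got$regions$size), length(unique(unlist(sets))))
  }
})

test_that("cross-species overlap reports counts and formatted percentages", {
  humans <- sprintf("h%03d", 1:72)
  map <- data.frame(other_gene = sprintf("m%04d", 1:2000),
                    human_gene = sprintf("h%03d", 1:2000))
  other <- c(sprintf("m%04d", 1:49), sprintf("m%04d", 1001:1655))  # 49 overlap, 704 total
  r <- cross_species_overlap(humans, other, map)
  expect_equal(r$n_human, 72L)
  expect_equal(r$n_other, 704L)
  expect_equal(r$n_overlap, 49L)
  expect_equal(r$percent_label, "68")

  r0 <- cross_species_overlap(humans, sprintf("m%04d", 1900:1999), map)
  expect_equal(r0$n_overlap, 0L)
  expect_equal(r0$percent, 0)

  rna <- cross_species_overlap(character(0), "m0001", map)
  expect_true(is.na(rna$percent))
  expect_true(is.na(rna$percent_label))

  expect_error(cross_species_overlap("h1", "m1",
    data.frame(other_gene = c("m1", "m1"), human_gene = c("h1", "h2"))), "one-to-one")
})

test_that("cross-species overlap matches a brute-force set oracle", {
  set.seed(10)
  for (rep in 1:20) {
    pool <- sprintf("H%03d", 1:120)
    bij <- sample(pool)  # random bijection other -> human
    map <- data.frame(other_gene = paste0("O", seq_along(bij)), human_gene = bij)
    hb <- sample(pool, sample(5:60, 1))
    ob <- sample(map$other_gene, sample(5:80, 1))
    r <- cross_species_overlap(hb, ob, map)
    want <- length(intersect(hb, map$human_gene[match(ob, map$other_gene)]))
    expect_equal(r$n_overlap, want)
    expect_lte(r$n_overlap, min(r$n_human, r$n_other))
    expect_true(r$percent >= 0 && r$percent <= 100)
  }
})
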