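#' Controlled vocabularies
#'
#' The six organs, the nine focal species with expression data, the five
#' outgroup species used only for gene-family construction, and the
#' phylostratigraphic origin strata (deepest first) with their witness
#' species.
#'
#' @return Character vectors.
#' @name vocab
NULL

#' @rdname vocab
#' @export
organ_vocab <- function() {
  c("brain", "cerebellum", "heart", "kidney", "liver", "testis")
}

#' @rdname vocab
#' @export
focal_species <- function() {
  c("chicken", "platypus", "opossum", "mouse", "macaque",
    "orangutan", "gorilla", "chimpanzee", "human")
}

#' @rdname vocab
#' @export
outgroup_species <- function() {
  c("lizard", "clawed_frog", "zebrafish", "lamprey", "sea_squirt")
}

#' @rdname vocab
#' @export
origin_strata <- function() {
  c("Chordata", "Craniata", "Gnathostomata", "Tetrapoda", "Amniota")
}

# stratum witnessed by each species; focal amniotes all witness Amniota
species_stratum <- function() {
  c(sea_squirt = "Chordata",
    lamprey = "Craniata",
    zebrafish = "Gnathostomata",
    clawed_frog = "Tetrapoda",
    lizard = "Amniota",
    stats::setNames(rep("Amniota", 9L), focal_species()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' Read / write tab-separated pipeline tables
#'
#' Thin wrappers around [data.table::fread()]/[data.table::fwrite()] fixing
#' the separator and header conventions used by every intermediate artifact.
#'
#' @param path File path.
#' @param x A data.frame.
#' @return `read_tsv_table` returns a `data.table`.
#' @export
read_tsv_table <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, data.table = TRUE)
}

#' @rdname read_tsv_table
#' @export
write_tsv_table <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE)
  invisible(path)
}
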