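# The published catalog of novel Ae. albopictus miRNAs ships as a plain-text
# fixture. The printed minus-strand loci have Start > End (the order encodes
# transcript orientation); the loader sorts each pair into (min, max),
# records the strand, and converts to the internal 0-based half-open
# convention. Sequences are never normalised silently; the file checksum is
# verified on load.

.table1_md5 <- "b1c0d5d6f95aa533dc0336eeb84538e1"

#' Load the packaged catalog of novel mosquito miRNAs
#'
#' Returns the printed records (name, most-abundant variant sequence, longest
#' variant extension, contig, locus, strand, lineage section), with star rows
#' linked to their genes and "-1"/"-2" locus suffixes linked to the shared
#' mature sequence they produce.
#'
#' @return a `data.table` with one row per printed record plus derived
#'   columns: `gene` (name without the star mark), `gene_family` (name
#'   without the locus suffix), `is_star`, `locus_start`/`locus_end`
#'   (0-based half-open, sorted) and `strand`.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_novel_mirnas.tsv", package = "mosmir")
  if (!nzchar(path)) stop("table 1 fixture not found in the installed package")
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, .table1_md5)) {
    stop("table 1 fixture checksum mismatch: ", sum)
  }
  tab <- fread(path, sep = "\t", colClasses = list(character = c(1:4, 7:8)))
  tab[, is_star := grepl("\\*$", name)]
  tab[, gene := sub("\\*$", "", name)]
  tab[, gene_family := sub("-[12]$", "", gene)]
  tab[, locus_start := pmin(start, end) - 1L]
  tab[, locus_end := pmax(start, end)]
  stopifnot(all(tab$strand %in% c("+", "-")),
            all(grepl("^[ACGT]+$", tab$sequence)))
  tab[]
}

#' Section tallies of the novel-miRNA catalog
#'
#' Counts distinct genes (mature names, star rows and locus suffixes
#' collapsed) overall and per lineage section.
#'
#' @param fixture output of [load_table1_fixture()] (loaded if missing).
#' @return list with `n_genes`, `n_records` and `per_section` (named integer
#'   vector of distinct gene-family counts).
#' @export
table1_tallies <- function(fixture = load_table1_fixture()) {
  per_section <- fixture[, .(n = data.table::uniqueN(gene_family)),
                         by = section]
  list(n_genes = data.table::uniqueN(fixture$gene_family),
       n_records = nrow(fixture),
       per_section = stats::setNames(per_section$n, per_section$section))
}
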