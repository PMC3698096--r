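# Seed-and-extend read mapping with at most one mismatch. Every tag is split
# into two halves; a hit with <= 1 mismatch leaves at least one half exact
# (pigeonhole), so looking up the leading k-mer of each half against a genome
# k-mer hash finds every candidate locus, which is then verified by Hamming
# comparison. Both strands are handled by also querying the tag's reverse
# complement.

#' Build a k-mer position index of a genome
#'
#' @param genome named character vector of contig sequences.
#' @param k k-mer size, at most 12. The default 9 equals half of the minimum
#'   tag length (18 nt), which preserves the pigeonhole guarantee for
#'   one-mismatch mapping of 18-30 nt tags.
#' @return a keyed `data.table` with columns `kmer`, `contig`, `pos`
#'   (0-based), plus attributes `k` and `contig_lengths`.
#' @export
build_index <- function(genome, k = 9L) {
  k <- as.integer(k)
  if (k > 12L) stop("build_index: k must be <= 12")
  if (k > 9L) {
    stop("build_index: k = ", k, " breaks the pigeonhole guarantee for 18-nt tags")
  }
  pieces <- lapply(seq_along(genome), function(ci) {
    s <- genome[[ci]]
    n <- nchar(s)
    if (n < k) return(NULL)
    data.table(kmer = substring(s, 1:(n - k + 1L), k:n),
               contig = names(genome)[ci],
               pos = 0:(n - k))
  })
  idx <- rbindlist(pieces)
  if (nrow(idx) == 0L) {
    idx <- data.table(kmer = character(), contig = character(),
                      pos = integer())
  }
  idx <- idx[!grepl("N", kmer, fixed = TRUE)]
  data.table::setkey(idx, kmer)
  data.table::setattr(idx, "k", k)
  data.table::setattr(idx, "contig_lengths",
                      stats::setNames(nchar(genome), names(genome)))
  idx
}

#' Map a set of tags to the genome with at most one mismatch
#'
#' All loci on both strands with Hamming distance <= 1 are reported; no
#' best-hit pruning is applied. Tags containing N are left unmapped.
#'
#' @param tags character vector of tag sequences (18-30 nt), or a
#'   `data.table` with a `sequence` column.
#' @param index k-mer index from [build_index()].
#' @param genome named character vector of contig sequences.
#' @return list with `hits` (a `data.table`: `tag_id`, `sequence`, `contig`,
#'   `start`, `end` 0-based half-open, `strand`, `mm`, `mm_pos` 0-based
#'   position in the tag or NA, `n_hits` multimapping count) and `unmapped`
#'   (character vector of tag sequences without any hit).
#' @export
map_all <- function(tags, index, genome) {
  seqs <- if (is.data.frame(tags)) tags$sequence else tags
  k <- attr(index, "k")
  clens <- attr(index, "contig_lengths")
  empty <- data.table(tag_id = integer(), sequence = character(),
                      contig = character(), start = integer(), end = integer(),
                      strand = character(), mm = integer(), mm_pos = integer(),
                      n_hits = integer())
  if (length(seqs) == 0L) return(list(hits = empty, unmapped = character(0)))
  tg <- data.table(tag_id = seq_along(seqs), sequence = seqs,
                   len = nchar(seqs))
  usable <- tg[len >= 2L * k & !grepl("N", sequence, fixed = TRUE)]
  if (nrow(usable) == 0L) return(list(hits = empty, unmapped = seqs))

  # two seeds per strand-orientation: the leading k-mer of each half
  seed_frame <- function(qseq, tag_id, len, strand) {
    h <- ceiling(len / 2)
    rbind(
      data.table(tag_id = tag_id, qseq = qseq, len = len, strand = strand,
                 kmer = substr(qseq, 1L, k), offset = 0L),
      data.table(tag_id = tag_id, qseq = qseq, len = len, strand = strand,
                 kmer = substr(qseq, h + 1L, h + k), offset = as.integer(h))
    )
  }
  fwd <- seed_frame(usable$sequence, usable$tag_id, usable$len, "+")
  rc <- revcomp(usable$sequence)
  rev <- seed_frame(rc, usable$tag_id, usable$len, "-")
  seeds <- rbind(fwd, rev)

  cand <- index[seeds, on = "kmer", allow.cartesian = TRUE, nomatch = NULL]
  if (nrow(cand) == 0L) return(list(hits = empty, unmapped = seqs))
  cand[, start := pos - offset]
  cand <- cand[start >= 0L & start + len <= clens[contig]]
  cand <- unique(cand, by = c("tag_id", "strand", "contig", "start"))
  if (nrow(cand) == 0L) return(list(hits = empty, unmapped = seqs))

  # verify candidates by direct comparison against the genome slice
  cand[, window := substring(genome[contig], start + 1L, start + len),
       by = contig]
  hm <- hamming_pairs_cpp(cand$qseq, cand$window, 1L)
  cand[, `:=`(mm = hm[, 1], first_mm = hm[, 2])]
  hits <- cand[mm >= 0L]
  if (nrow(hits) == 0L) return(list(hits = empty, unmapped = seqs))
  # mismatch position in tag coordinates (query was reverse-complemented on -)
  hits[, mm_pos := ifelse(mm == 0L, NA_integer_,
                          ifelse(strand == "+", first_mm, len - 1L - first_mm))]
  hits[, `:=`(end = start + len, window = NULL, first_mm = NULL,
              qseq = NULL, pos = NULL, offset = NULL, kmer = NULL, len = NULL)]
  hits <- merge(hits, tg[, .(tag_id, sequence)], by = "tag_id")
  hits[, n_hits := .N, by = tag_id]
  setorder(hits, tag_id, contig, start, strand)
  data.table::setcolorder(hits, c("tag_id", "sequence", "contig", "start",
                                  "end", "strand", "mm", "mm_pos", "n_hits"))
  unmapped <- setdiff(seqs, hits$sequence)
  list(hits = hits[], unmapped = unmapped)
}

#' Map a single tag (convenience wrapper around [map_all()])
#'
#' @inheritParams map_all
#' @param tag a single tag sequence.
#' @return the `hits` table of [map_all()] for this tag.
#' @export
map_tag <- function(tag, index, genome) {
  stopifnot(length(tag) == 1L)
  map_all(tag, index, genome)$hits
}
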