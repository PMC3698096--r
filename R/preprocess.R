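# Raw reads -> clean, length-selected, contaminant-free collapsed tags with
# per-sample counts. Structural-RNA and repeat matches are removed here;
# exon/intron matches are only flagged and consumed later by the hairpin
# locus-context criterion, so intronic miRNAs survive cleaning.

.sample_order <- c("E", "L", "P", "M", "F", "B")

#' Trim the 3' adapter from read sequences
#'
#' Locates the leftmost match of the adapter prefix with at least
#' `min_overlap` nt of overlap and at most `max_mismatch` mismatches and
#' truncates the read there. Reads without an adapter match, or whose trimmed
#' length is 0, yield `NA`.
#'
#' @param reads character vector of read sequences.
#' @param adapter3 3' adapter sequence (>= 6 nt).
#' @param min_overlap minimum adapter overlap (default 6).
#' @param max_mismatch mismatches tolerated in the overlap (default 1).
#' @return character vector of trimmed inserts, `NA` where no adapter was
#'   found or the insert is empty.
#' @export
trim_adapter <- function(reads, adapter3, min_overlap = 6L, max_mismatch = 1L) {
  if (nchar(adapter3) < 6L) stop("trim_adapter: adapter must be >= 6 nt")
  ins <- trim_adapter_cpp(reads, adapter3, as.integer(min_overlap),
                          as.integer(max_mismatch))
  out <- rep(NA_character_, length(reads))
  keep <- ins > 0L
  out[keep] <- substr(reads[keep], 1L, ins[keep])
  out
}

#' Keep tags within the analysed length range
#'
#' @param tags character vector (or a data.frame with a `sequence` column).
#' @param min_len,max_len inclusive bounds, default 18 and 30 nt.
#' @return the rows/elements whose length is within `[min_len, max_len]`,
#'   with an attribute `dropped` recording counts per drop reason.
#' @export
filter_length <- function(tags, min_len = 18L, max_len = 30L) {
  seqs <- if (is.data.frame(tags)) tags$sequence else tags
  n <- nchar(seqs)
  keep <- n >= min_len & n <= max_len
  out <- if (is.data.frame(tags)) tags[keep, ] else tags[keep]
  attr(out, "dropped") <- c(too_short = sum(n < min_len),
                            too_long = sum(n > max_len))
  out
}

# exact full-length matching of tags within a set of subject sequences
# (either strand); used for contaminant removal and exon/intron flagging.
# Returns a logical vector.
match_any_exact <- function(tags, subjects, k = 18L) {
  if (length(tags) == 0L || length(subjects) == 0L) {
    return(rep(FALSE, length(tags)))
  }
  subjects <- subjects[nchar(subjects) >= k]
  if (length(subjects) == 0L) return(rep(FALSE, length(tags)))
  both <- c(subjects, revcomp(subjects))
  idx <- rbindlist(lapply(seq_along(both), function(si) {
    s <- both[si]
    n <- nchar(s)
    data.table(kmer = substring(s, 1:(n - k + 1L), k:n), si = si,
               pos = 1:(n - k + 1L))
  }))
  data.table::setkey(idx, kmer)
  q <- data.table(tag_id = seq_along(tags), kmer = substr(tags, 1L, k),
                  len = nchar(tags))
  cand <- idx[q, on = "kmer", allow.cartesian = TRUE, nomatch = NULL]
  if (nrow(cand) == 0L) return(rep(FALSE, length(tags)))
  cand[, full := substring(both[si], pos, pos + len - 1L)]
  hit <- cand[full == tags[tag_id], unique(tag_id)]
  seq_along(tags) %in% hit
}

# extract the plus-strand sequence of annotation features of given types
feature_sequences <- function(annotation, genome, types) {
  feats <- annotation[annotation$type %in% types, ]
  if (nrow(feats) == 0L) return(character(0))
  substring(genome[feats$contig], feats$start + 1L, feats$end)
}

#' Remove structural-RNA/repeat contaminant tags; flag exon/intron matches
#'
#' A tag exactly matching (either strand) any rRNA, tRNA, snRNA, snoRNA or
#' repeat feature sequence is removed. Tags matching exon or intron sequence
#' are kept but flagged — the hairpin locus-context criterion consumes those
#' flags, preserving intronic miRNA candidates.
#'
#' @param tags a `data.table` of collapsed tags with a `sequence` column (see
#'   [collapse_tags()]), or a character vector.
#' @param annotation annotation table from [read_gff3()].
#' @param genome named character vector of contig sequences.
#' @return the surviving tags with added logical columns `flag_exon`,
#'   `flag_intron`, and an attribute `n_contaminant` with the removed count.
#' @export
filter_contaminants <- function(tags, annotation, genome) {
  tab <- if (is.data.frame(tags)) as.data.table(tags) else data.table(sequence = tags)
  contam <- feature_sequences(annotation, genome,
                              c("rRNA", "tRNA", "snRNA", "snoRNA", "repeat"))
  is_contam <- match_any_exact(tab$sequence, contam)
  out <- tab[!is_contam]
  out[, flag_exon := match_any_exact(sequence,
                                     feature_sequences(annotation, genome, "exon"))]
  out[, flag_intron := match_any_exact(sequence,
                                       feature_sequences(annotation, genome, "intron"))]
  data.table::setattr(out, "n_contaminant", sum(is_contam))
  out[]
}

#' Collapse per-sample read lists into unique tags with count vectors
#'
#' @param read_lists named list (names from E, L, P, M, F, B) of character
#'   vectors of clean read sequences; missing samples become zero columns.
#' @return a `data.table` with `sequence`, `len` and one `count_<sample>`
#'   column per sample; the column sums equal the numbers of input reads.
#' @export
collapse_tags <- function(read_lists) {
  stopifnot(all(names(read_lists) %in% .sample_order))
  long <- rbindlist(lapply(names(read_lists), function(s) {
    if (length(read_lists[[s]]) == 0L) return(NULL)
    data.table(sequence = read_lists[[s]], sample_id = s)
  }))
  cols <- paste0("count_", .sample_order)
  if (is.null(long) || nrow(long) == 0L) {
    out <- data.table(sequence = character(), len = integer())
    out[, (cols) := integer(0)]
    return(out)
  }
  counts <- long[, .N, by = .(sequence, sample_id)]
  wide <- data.table::dcast(counts, sequence ~ sample_id, value.var = "N",
                            fill = 0L)
  for (s in .sample_order) {
    cn <- paste0("count_", s)
    if (s %in% names(wide)) setnames(wide, s, cn) else wide[, (cn) := 0L]
  }
  wide[, len := nchar(sequence)]
  data.table::setcolorder(wide, c("sequence", "len", cols))
  setorder(wide, sequence)
  wide[]
}

#' Per-sample size distribution of collapsed tags
#'
#' @param tags collapsed tag table from [collapse_tags()].
#' @param min_len,max_len reported length range (default 18-30).
#' @param samples samples to report. By default, every sample with at least
#'   one read; explicitly requesting a sample with zero reads is an error.
#' @return a `data.table` with `len`, `sample_id`, `reads` and `fraction`;
#'   fractions sum to 1 within each sample.
#' @export
size_distribution <- function(tags, min_len = 18L, max_len = 30L,
                              samples = NULL) {
  cols <- grep("^count_", names(tags), value = TRUE)
  long <- data.table::melt(tags[, c("len", cols), with = FALSE],
                           id.vars = "len", variable.name = "sample_id",
                           value.name = "reads")
  long[, sample_id := sub("^count_", "", sample_id)]
  agg <- long[, .(reads = sum(reads)), by = .(sample_id, len)]
  nonzero <- agg[reads > 0, unique(sample_id)]
  if (is.null(samples)) {
    samples <- nonzero
  } else {
    zero <- setdiff(samples, nonzero)
    if (length(zero)) {
      stop("size_distribution: sample(s) with zero reads: ",
           paste(zero, collapse = ", "))
    }
  }
  long <- long[sample_id %in% samples]
  agg <- agg[sample_id %in% samples]
  grid <- data.table::CJ(sample_id = unique(agg$sample_id),
                         len = min_len:max_len)
  agg <- agg[grid, on = c("sample_id", "len")]
  agg[is.na(reads), reads := 0L]
  agg[, fraction := reads / sum(reads), by = sample_id]
  setorder(agg, sample_id, len)
  agg[]
}

#' Run the full preprocessing stage on raw FASTQ libraries
#'
#' Adapter trimming, quality filtering (any insert base below `min_qual` drops
#' the read), length selection, collapsing and contaminant filtering, with a
#' per-sample read-accounting table (input = kept + dropped by reason).
#'
#' @param fastq_paths named character vector (samples E, L, P, M, F, B) of
#'   FASTQ paths.
#' @param adapter3 3' adapter sequence.
#' @param annotation,genome used for contaminant removal and exon/intron
#'   flagging.
#' @param min_len,max_len tag length bounds (default 18-30 nt).
#' @param min_qual minimum per-base Phred quality in the insert (default 10).
#' @return list with `tags` (collapsed, filtered, flagged), `size_dist`
#'   (pre-contaminant-filter size distribution, the published view of library
#'   structure) and `accounting`.
#' @export
preprocess_libraries <- function(fastq_paths, adapter3, annotation, genome,
                                 min_len = 18L, max_len = 30L, min_qual = 10L) {
  stopifnot(!is.null(names(fastq_paths)))
  clean <- list()
  acct <- list()
  for (s in names(fastq_paths)) {
    reads <- read_fastq(fastq_paths[[s]])
    n_in <- nrow(reads)
    ins <- trim_adapter(reads$sequence, adapter3)
    no_adapter <- is.na(ins)
    ilen <- ifelse(no_adapter, 0L, nchar(ins))
    # quality over the insert only
    minq <- rep(Inf, n_in)
    ok <- !no_adapter
    if (any(ok)) {
      qsub <- substr(reads$quality[ok], 1L, ilen[ok])
      minq[ok] <- vapply(qsub, function(q) min(utf8ToInt(q)) - 33L, numeric(1),
                         USE.NAMES = FALSE)
    }
    lowq <- ok & minq < min_qual
    good <- ok & !lowq
    lens <- ilen[good]
    in_range <- lens >= min_len & lens <= max_len
    clean[[s]] <- ins[good][in_range]
    acct[[s]] <- data.table(sample_id = s, input = n_in,
                            no_adapter = sum(no_adapter),
                            low_quality = sum(lowq),
                            out_of_range = sum(!in_range),
                            kept = sum(in_range))
  }
  acct <- rbindlist(acct)
  stopifnot(all(acct$input ==
                  acct$no_adapter + acct$low_quality + acct$out_of_range + acct$kept))
  tags <- collapse_tags(clean)
  size_dist <- size_distribution(tags, min_len, max_len,
                                 samples = names(fastq_paths))
  tags <- filter_contaminants(tags, annotation, genome)
  list(tags = tags, size_dist = size_dist, accounting = acct)
}
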