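# Target prediction and GO enrichment: seed-weighted complementarity scoring
# of mature miRNAs against annotated 3'UTRs (score cutoff 150), and one-sided
# Fisher's exact over-representation tests per GO term with Benjamini-
# Hochberg FDR control at 0.01.

#' Score the best miRNA:UTR duplex in a window
#'
#' Local affine-gap alignment of the mature (antisense, 3'->5' against the
#' UTR 5'->3'): Watson-Crick pair +5, G:U wobble +1, mismatch -3, gap open
#' -9, gap extend -4, with positions 2-8 from the miRNA 5' end (the seed)
#' weighted x4. A perfect 22-nt complement scores 215.
#'
#' @param mature_seq mature miRNA sequence (DNA alphabet).
#' @param utr_window UTR window sequence, at least as long as the mature.
#' @return list with `score`, `mirna_span` and `window_span` (1-based
#'   inclusive), and the aligned `duplex` strings (miRNA 3'->5', pairing
#'   line, UTR 5'->3').
#' @export
score_duplex <- function(mature_seq, utr_window) {
  if (nchar(utr_window) < nchar(mature_seq)) {
    stop("score_duplex: window shorter than the mature sequence")
  }
  r <- duplex_score_cpp(mature_seq, utr_window)
  list(score = r$score,
       mirna_span = c(r$mirna_from, r$mirna_to),
       window_span = c(r$window_from, r$window_to),
       duplex = c(mirna_3to5 = r$aligned_mirna_3to5, pairing = r$pairing,
                  utr_5to3 = r$aligned_utr))
}

#' Predict 3'UTR target sites for a set of miRNAs
#'
#' Each UTR is scanned with [score_duplex()]; non-overlapping sites scoring
#' at least `cutoff` are emitted (best first, the occupied window is masked,
#' and the scan repeats). Transcripts lacking a 3'UTR annotation are skipped
#' and counted.
#'
#' @param genes gene table (needs `gene_id`, `mature_seq`).
#' @param utrs named character vector of 3'UTR sequences
#'   (transcript-oriented), e.g. from [get_utr_sequences()].
#' @param cutoff score cutoff (default 150).
#' @return `data.table`: mirna_id, transcript_id, site span within the UTR,
#'   score.
#' @export
predict_targets <- function(genes, utrs, cutoff = 150) {
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    m <- genes$mature_seq[i]
    for (tid in names(utrs)) {
      u <- utrs[[tid]]
      if (nchar(u) < nchar(m)) next
      repeat {
        r <- score_duplex(m, u)
        if (r$score < cutoff) break
        rows[[length(rows) + 1L]] <- data.table(
          mirna_id = genes$gene_id[i], transcript_id = tid,
          utr_from = r$window_span[1], utr_to = r$window_span[2],
          score = r$score)
        # mask the emitted site so remaining sites cannot overlap it
        substr(u, r$window_span[1], r$window_span[2]) <-
          strrep("N", r$window_span[2] - r$window_span[1] + 1L)
      }
    }
  }
  out <- rbindlist(rows)
  if (nrow(out) == 0L) {
    out <- data.table(mirna_id = character(), transcript_id = character(),
                      utr_from = integer(), utr_to = integer(),
                      score = numeric())
  }
  setorder(out, mirna_id, transcript_id, utr_from)
  out[]
}

#' Extract transcript-oriented 3'UTR sequences from the genome
#'
#' @param genome named character vector of contigs.
#' @param annotation annotation table ([read_gff3()] convention).
#' @return named character vector keyed by transcript_id.
#' @export
get_utr_sequences <- function(genome, annotation) {
  u <- annotation[type == "three_prime_UTR"]
  if (nrow(u) == 0L) return(character(0))
  stats::setNames(
    oriented_slice(genome, u$contig, u$start, u$end, u$strand),
    u$transcript_id)
}

# one-sided (over-representation) Fisher's exact p-value for the 2x2 table
# [[a, b], [c, d]]
fisher_over_p <- function(a, b, c, d) {
  stats::fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE),
                     alternative = "greater")$p.value
}

#' GO term over-representation among target transcripts
#'
#' One-sided Fisher's exact test per GO term carried by at least `min_hits`
#' target transcripts, against the background of all transcripts with an
#' annotated 3'UTR; Benjamini-Hochberg adjustment across tested terms;
#' significance at `q < fdr`.
#'
#' @param target_transcripts character vector of target transcript ids.
#' @param go_map `data.table` with `transcript_id` and `term` (one row per
#'   annotation; the background is every transcript present in this map that
#'   carries a 3'UTR).
#' @param background character vector of background transcript ids (all
#'   transcripts with annotated 3'UTR).
#' @param fdr FDR threshold (default 0.01).
#' @param min_hits minimum targets carrying a term for it to be tested
#'   (default 3).
#' @return `data.table`: term, a, b, c, d, p_value, fdr_q, significant.
#' @export
go_enrichment <- function(target_transcripts, go_map, background, fdr = 0.01,
                          min_hits = 3L) {
  empty <- data.table(term = character(), a = integer(), b = integer(),
                      c = integer(), d = integer(), p_value = numeric(),
                      fdr_q = numeric(), significant = logical())
  targets <- intersect(unique(target_transcripts), background)
  if (length(targets) == 0L) return(empty)
  non_targets <- setdiff(background, targets)
  gm <- as.data.table(go_map)[transcript_id %in% background]
  terms <- gm[transcript_id %in% targets, .N, by = term][N >= min_hits, term]
  if (length(terms) == 0L) return(empty)
  rows <- lapply(terms, function(tm) {
    with_term <- unique(gm[term == tm, transcript_id])
    a <- length(intersect(targets, with_term))
    b <- length(targets) - a
    cc <- length(intersect(non_targets, with_term))
    d <- length(non_targets) - cc
    data.table(term = tm, a = a, b = b, c = cc, d = d,
               p_value = fisher_over_p(a, b, cc, d))
  })
  out <- rbindlist(rows)
  out[, fdr_q := stats::p.adjust(p_value, method = "BH")]
  out[, significant := fdr_q < fdr]
  setorder(out, p_value)
  out[]
}
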