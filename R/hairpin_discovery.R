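# The core inference: 100-nt flanked windows around mapped tag loci are
# folded and judged against the stem-loop criteria (mature in one arm of the
# hairpin, clean duplex, free energy below the threshold, intergenic or
# intronic context) plus read-stack confirmation against the predicted
# precursor structure.

#' Extract the flanked precursor window around a tag hit
#'
#' The window spans `[start - flank, end + flank)` clipped at the contig
#' edges; minus-strand hits are reverse-complemented so the tag reads 5'->3'
#' within the window.
#'
#' @param hit one row of a hits table ([map_all()]).
#' @param genome named character vector of contigs.
#' @param flank flank width on each side (default 100 nt).
#' @return list with `sequence`, `contig`, `start`, `end` (plus-strand
#'   0-based half-open window interval), `strand` and `tag_offset` (0-based
#'   offset of the tag within the oriented window), or `NULL` when the
#'   clipped window is shorter than the tag plus 20 nt.
#' @export
extract_window <- function(hit, genome, flank = 100L) {
  clen <- nchar(genome[[hit$contig]])
  ws <- max(0L, hit$start - flank)
  we <- min(clen, hit$end + flank)
  if (we - ws < (hit$end - hit$start) + 20L) {
    message("extract_window: window too short after clipping at ", hit$contig,
            ":", hit$start, "; candidate skipped")
    return(NULL)
  }
  s <- substring(genome[[hit$contig]], ws + 1L, we)
  if (hit$strand == "-") {
    s <- revcomp(s)
    off <- we - hit$end
  } else {
    off <- hit$start - ws
  }
  list(sequence = s, contig = hit$contig, start = ws, end = we,
       strand = hit$strand, tag_offset = as.integer(off))
}

# star span from the pairing table under the 2-nt 3' overhang duplex rule:
# with mature span [a, b] (1-based, inclusive), the star runs from
# pairing(b - 2) to pairing(a) + 2 (order sorted). Unpaired terminal mature
# bases are stepped over (up to 4) to the nearest paired position.
predicted_star_span <- function(pairing, mature_span) {
  a <- mature_span[1]
  b2 <- mature_span[2] - 2L
  step_in <- function(i, dir) {
    for (k in 0:4) {
      j <- i + dir * k
      if (j >= 1 && j <= length(pairing) && !is.na(pairing[j])) {
        return(c(j, k))
      }
    }
    NULL
  }
  sa <- step_in(a, +1L)
  sb <- step_in(b2, -1L)
  if (is.null(sa) || is.null(sb)) return(NULL)
  # compensate the step so the overhang geometry is preserved
  ends <- sort(c(pairing[sb[1]] - sb[2], pairing[sa[1]] + sa[2] + 2L))
  if (ends[1] < 1 || ends[2] > length(pairing)) return(NULL)
  as.integer(ends)
}

#' Locate the mature arm on a folded hairpin and predict the star span
#'
#' The arm is `5p` when the mature lies entirely 5' of the hairpin loop and
#' `3p` when entirely 3' of it; a mature crossing the loop fails the one-arm
#' criterion (arm `NA`). The star span is the set of positions pairing with
#' the mature, shifted to give 2-nt 3' overhangs on both duplex ends.
#'
#' @param fold a [fold_mfe()] result.
#' @param mature_span integer vector `c(from, to)`, 1-based inclusive
#'   positions of the mature within the folded sequence.
#' @return list with `arm` (`"5p"`, `"3p"` or `NA`) and `star_span`
#'   (`c(from, to)` or `NULL`).
#' @export
locate_arms <- function(fold, mature_span) {
  pairing <- parse_dotbracket(fold$structure)
  paired <- which(!is.na(pairing))
  if (length(paired) == 0L) return(list(arm = NA_character_, star_span = NULL))
  # hairpin loop of the (single) stem: between the innermost pair
  inner_i <- max(paired[pairing[paired] > paired]) # last '(' of the chain
  loop <- c(inner_i + 1L, pairing[inner_i] - 1L)
  a <- mature_span[1]; b <- mature_span[2]
  arm <- if (b <= loop[1] - 1L + 2L && a < loop[1]) {
    # small tolerance: mature may overhang into the loop by <= 2 nt
    "5p"
  } else if (a >= loop[2] + 1L - 2L && b > loop[2]) {
    "3p"
  } else {
    NA_character_
  }
  if (is.na(arm)) return(list(arm = NA_character_, star_span = NULL))
  star <- predicted_star_span(pairing, mature_span)
  list(arm = arm, star_span = star)
}

#' Read-stack consistency of a candidate precursor
#'
#' True when (a) at least `min_reads` reads (pooled over samples) land on the
#' precursor window; (b) at least 70% of mature-arm reads share the modal 5'
#' end; (c) reads are confined to the two arms (at most 10% of read mass on
#' the loop or outside the mature/star regions); and (d) when star reads
#' exist, their modal 5' end is duplex-consistent (within 1 nt of the
#' predicted star 5' end).
#'
#' @param candidate list with `window` (from [extract_window()]),
#'   `mature_span` and `star_span` (window coordinates, 1-based inclusive).
#' @param locus_hits hits table rows overlapping the window (same strand),
#'   joined with pooled tag counts in a `pooled` column.
#' @param min_reads minimum pooled read support (default 5).
#' @return list with `ok` and diagnostic fields (`total_reads`,
#'   `modal5_fraction`, `arm_fraction`, `star_consistent`).
#' @export
read_stack_consistency <- function(candidate, locus_hits, min_reads = 5L) {
  w <- candidate$window
  out <- list(ok = FALSE, total_reads = 0, modal5_fraction = NA_real_,
              arm_fraction = NA_real_, star_consistent = NA)
  if (nrow(locus_hits) == 0L) return(out)
  # window coordinates (1-based) of each read, oriented with the window
  if (w$strand == "+") {
    from <- locus_hits$start - w$start + 1L
    to <- locus_hits$end - w$start
  } else {
    from <- w$end - locus_hits$end + 1L
    to <- w$end - locus_hits$start
  }
  cnt <- locus_hits$pooled
  inside <- from >= 1L & to <= (w$end - w$start)
  from <- from[inside]; to <- to[inside]; cnt <- cnt[inside]
  total <- sum(cnt)
  out$total_reads <- total
  if (total < min_reads) return(out)

  ms <- candidate$mature_span
  ss <- candidate$star_span
  tol <- 5L
  in_mature <- from >= ms[1] - tol & to <= ms[2] + tol
  in_star <- if (!is.null(ss)) from >= ss[1] - tol & to <= ss[2] + tol else
    rep(FALSE, length(from))
  arm_fraction <- sum(cnt[in_mature | in_star]) / total
  out$arm_fraction <- arm_fraction

  m5 <- from[in_mature]
  mc <- cnt[in_mature]
  if (length(m5) == 0L) return(out)
  tab <- tapply(mc, m5, sum)
  out$modal5_fraction <- max(tab) / sum(mc)

  star_ok <- TRUE
  if (!is.null(ss)) {
    s5 <- from[in_star & !in_mature]
    sc <- cnt[in_star & !in_mature]
    if (length(s5) > 0L) {
      stab <- tapply(sc, s5, sum)
      modal_s5 <- as.integer(names(stab)[which.max(stab)])
      star_ok <- abs(modal_s5 - ss[1]) <= 1L
    }
  }
  out$star_consistent <- star_ok
  out$ok <- total >= min_reads && out$modal5_fraction >= 0.7 &&
    arm_fraction >= 0.9 && star_ok
  out
}

# unpaired-mature-base and duplex loop/bulge geometry between the mature arm
# and its partner, from the pairing table
duplex_geometry <- function(pairing, mature_span) {
  idx <- mature_span[1]:mature_span[2]
  paired <- idx[!is.na(pairing[idx])]
  n_unpaired <- length(idx) - length(paired)
  max_gap <- 0L
  if (length(paired) >= 2L) {
    for (k in seq_len(length(paired) - 1L)) {
      g1 <- paired[k + 1L] - paired[k] - 1L
      g2 <- abs(pairing[paired[k]] - pairing[paired[k + 1L]]) - 1L
      max_gap <- max(max_gap, g1, g2)
    }
  }
  list(n_unpaired = n_unpaired, max_gap = max_gap)
}

# genomic context of a position: exon/UTR beats intron beats intergenic
genomic_context <- function(annotation, contig_, pos) {
  f <- annotation[contig == contig_ & start <= pos & end > pos]
  if (any(f$type %in% c("exon", "three_prime_UTR"))) return("exonic")
  if (any(f$type == "intron")) return("intronic")
  "intergenic"
}

#' Evaluate the stem-loop criteria for a folded candidate
#'
#' @param candidate list with `window`, `fold`, `mature_span`, `arm`,
#'   `star_span` (see [call_mirna_genes()] for construction).
#' @param annotation annotation table (internal coordinates).
#' @param read_stack result of [read_stack_consistency()].
#' @param energy_threshold free-energy threshold in kcal/mol; the criterion
#'   is strict (`energy < threshold`), default -20.
#' @param max_unpaired_mature,max_duplex_gap duplex cleanliness bounds
#'   (defaults 4 unpaired mature bases, no bulge/internal loop > 3 nt).
#' @return a one-row `data.table` criteria report: `in_one_arm`,
#'   `duplex_clean`, `energy_ok`, `context_ok`, `read_stack_ok`, `passed`.
#' @export
check_criteria <- function(candidate, annotation, read_stack,
                           energy_threshold = -20,
                           max_unpaired_mature = 4L, max_duplex_gap = 3L) {
  in_one_arm <- !is.na(candidate$arm)
  duplex_clean <- FALSE
  if (in_one_arm) {
    pairing <- parse_dotbracket(candidate$fold$structure)
    geo <- duplex_geometry(pairing, candidate$mature_span)
    duplex_clean <- geo$n_unpaired <= max_unpaired_mature &&
      geo$max_gap <= max_duplex_gap
  }
  energy_ok <- candidate$fold$energy < energy_threshold
  w <- candidate$window
  mid <- floor((w$start + w$end) / 2)
  ctx <- genomic_context(annotation, w$contig, mid)
  context_ok <- ctx %in% c("intergenic", "intronic")
  read_stack_ok <- isTRUE(read_stack$ok)
  data.table(in_one_arm = in_one_arm, duplex_clean = duplex_clean,
             energy_ok = energy_ok, context_ok = context_ok,
             read_stack_ok = read_stack_ok, context = ctx,
             passed = in_one_arm && duplex_clean && energy_ok && context_ok &&
               read_stack_ok)
}

#' Discover miRNA genes from mapped tags
#'
#' Candidate seeds are loci of mapped tags with at least `min_seed_reads`
#' pooled reads; hits of seed tags are merged into loci, each locus is
#' flank-extended, folded and judged against the full criteria set, and
#' overlapping candidate windows are merged keeping the lower-energy fold.
#' The mature is the most abundant tag at the locus; the star is marked
#' observed when any mapped tag starts within 2 nt of the predicted star.
#'
#' @param tags collapsed tag table (with `count_*` columns).
#' @param hits hits table from [map_all()] run on `tags`.
#' @param genome named character vector of contigs.
#' @param annotation annotation table.
#' @param flank flank width (default 100).
#' @param min_seed_reads pooled-read support needed to seed a candidate
#'   (default 5; discovery support, distinct from the 15-read expression
#'   gate).
#' @param energy_threshold passed to [check_criteria()].
#' @return list with `genes` (accepted gene table, one row per gene, with
#'   window/mature/star genomic spans, sequences, arm, energy) and `reports`
#'   (per-candidate criteria table).
#' @export
call_mirna_genes <- function(tags, hits, genome, annotation, flank = 100L,
                             min_seed_reads = 5L, energy_threshold = -20) {
  empty_genes <- data.table(
    gene_id = character(), contig = character(), strand = character(),
    window_start = integer(), window_end = integer(), energy = numeric(),
    structure = character(), precursor_seq = character(),
    mature_seq = character(), star_seq = character(),
    mature_g_start = integer(), mature_g_end = integer(),
    star_g_start = integer(), star_g_end = integer(), arm = character(),
    star_observed = logical())
  if (nrow(hits) == 0L) return(list(genes = empty_genes, reports = data.table()))
  cols <- grep("^count_", names(tags), value = TRUE)
  pooled_tab <- data.table(sequence = tags$sequence,
                           pooled = rowSums(tags[, cols, with = FALSE]))
  h <- merge(hits, pooled_tab, by = "sequence")

  seed_hits <- h[pooled >= min_seed_reads]
  if (nrow(seed_hits) == 0L) {
    return(list(genes = empty_genes, reports = data.table()))
  }
  # merge nearby seed-hit spans into loci (per contig and strand); the gap
  # allowance lets the mature- and star-arm stacks of one precursor seed a
  # single candidate
  merge_gap <- 40L
  setorder(seed_hits, contig, strand, start)
  seed_hits[, locus := {
    gap <- start > cummax(c(-1L, head(end, -1L))) + merge_gap
    cumsum(gap)
  }, by = .(contig, strand)]

  candidates <- list()
  reports <- list()
  for (key in unique(seed_hits[, paste(contig, strand, locus)])) {
    parts <- strsplit(key, " ")[[1]]
    lh <- seed_hits[contig == parts[1] & strand == parts[2] &
                      locus == as.integer(parts[3])]
    # mature = most abundant tag; prefer 0-mismatch placements
    setorder(lh, -pooled, mm, start, sequence)
    top <- lh[1]
    w <- extract_window(top, genome, flank)
    if (is.null(w)) next
    if (grepl("N", w$sequence, fixed = TRUE)) next
    fold <- fold_mfe(w$sequence)
    mature_span <- c(w$tag_offset + 1L, w$tag_offset + nchar(top$sequence))
    arms <- locate_arms(fold, mature_span)
    cand <- list(window = w, fold = fold, mature_span = mature_span,
                 arm = arms$arm, star_span = arms$star_span,
                 mature_seq = substr(w$sequence, mature_span[1], mature_span[2]))
    locus_hits <- h[contig == w$contig & strand == w$strand &
                      start < w$end & end > w$start]
    rs <- read_stack_consistency(cand, locus_hits)
    rep_row <- check_criteria(cand, annotation, rs,
                              energy_threshold = energy_threshold)
    rep_row <- cbind(
      data.table(candidate_id = key, contig = w$contig, strand = w$strand,
                 window_start = w$start, window_end = w$end,
                 energy = fold$energy, total_reads = rs$total_reads,
                 modal5_fraction = rs$modal5_fraction),
      rep_row)
    reports[[length(reports) + 1L]] <- rep_row
    cand$report <- rep_row
    cand$hits_here <- locus_hits
    candidates[[length(candidates) + 1L]] <- cand
  }
  reports <- rbindlist(reports, fill = TRUE)
  if (length(candidates) == 0L) {
    return(list(genes = empty_genes, reports = reports))
  }

  # merge overlapping candidate windows, keeping the lower-energy fold
  info <- data.table(
    idx = seq_along(candidates),
    contig = vapply(candidates, function(x) x$window$contig, character(1)),
    strand = vapply(candidates, function(x) x$window$strand, character(1)),
    start = vapply(candidates, function(x) x$window$start, integer(1)),
    end = vapply(candidates, function(x) x$window$end, integer(1)),
    energy = vapply(candidates, function(x) x$fold$energy, numeric(1)))
  setorder(info, contig, strand, start)
  info[, grp := {
    gap <- start > cummax(c(-1L, head(end, -1L)))
    cumsum(gap)
  }, by = .(contig, strand)]
  keep_idx <- info[, .(idx = idx[which.min(energy)]), by = .(contig, strand, grp)]$idx

  genes <- list()
  for (i in keep_idx) {
    cand <- candidates[[i]]
    if (!cand$report$passed) next
    w <- cand$window
    to_genomic <- function(span) {
      if (is.null(span)) return(c(NA_integer_, NA_integer_))
      if (w$strand == "+") c(w$start + span[1] - 1L, w$start + span[2])
      else c(w$end - span[2], w$end - span[1] + 1L)
    }
    msp <- to_genomic(cand$mature_span)
    ssp <- to_genomic(cand$star_span)
    star_seq <- if (!is.null(cand$star_span)) {
      substr(w$sequence, cand$star_span[1], cand$star_span[2])
    } else NA_character_
    star_obs <- FALSE
    if (!is.null(cand$star_span)) {
      lh <- cand$hits_here
      five_prime <- if (w$strand == "+") lh$start else lh$end - 1L
      star5 <- if (w$strand == "+") ssp[1] else ssp[2] - 1L
      star_obs <- any(abs(five_prime - star5) <= 2L)
    }
    genes[[length(genes) + 1L]] <- data.table(
      gene_id = sprintf("mir-%s-%d%s", w$contig, w$start,
                        ifelse(w$strand == "+", "p", "m")),
      contig = w$contig, strand = w$strand,
      window_start = w$start, window_end = w$end,
      energy = cand$fold$energy, structure = cand$fold$structure,
      precursor_seq = w$sequence,
      mature_seq = cand$mature_seq, star_seq = star_seq,
      mature_g_start = msp[1], mature_g_end = msp[2],
      star_g_start = ssp[1], star_g_end = ssp[2], arm = cand$arm,
      star_observed = star_obs)
  }
  genes <- if (length(genes)) rbindlist(genes) else empty_genes
  setorder(genes, contig, window_start)
  list(genes = genes, reports = reports)
}
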