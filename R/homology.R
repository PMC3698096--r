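# Homology and lineage classification: word-seeded catalog search (BLAST-like,
# permissive E-value cutoff), Mapmi-style genome scanning with a hairpin
# bonus and the published cutoff of 35, the lineage label lattice, and arm
# switch detection.

#' Word-seeded search of a mature sequence against a miRNA catalog
#'
#' Seeds are shared 7-mers; each seeded diagonal is scored as the best
#' ungapped segment under +1 match / -2 mismatch, and segments are assigned
#' an E-value `K * m * n * exp(-lambda * S)` with fixed small-catalog
#' parameters (lambda = 1.33, K = 0.621, m*n = query length x catalog
#' length). Hits with E <= `max_evalue` are returned sorted by score.
#'
#' @param mature_seq query sequence.
#' @param catalog named character vector of catalog mature sequences.
#' @param word_size seed word size (default 7).
#' @param max_evalue permissive E-value cutoff (default 10).
#' @return `data.table`: `subject`, `score`, `identities`, `mismatches`,
#'   `q_from`, `q_to`, `s_from`, `s_to`, `evalue`.
#' @export
catalog_search <- function(mature_seq, catalog, word_size = 7L, max_evalue = 10) {
  if (length(catalog) == 0L) stop("catalog_search: empty catalog")
  lambda <- 1.33
  K <- 0.621
  n_cat <- sum(nchar(catalog))
  qlen <- nchar(mature_seq)
  qwords <- substring(mature_seq, seq_len(qlen - word_size + 1L),
                      word_size:qlen)
  rows <- list()
  for (si in seq_along(catalog)) {
    s <- catalog[[si]]
    slen <- nchar(s)
    if (slen < word_size) next
    swords <- substring(s, seq_len(slen - word_size + 1L), word_size:slen)
    hits <- which(outer(qwords, swords, "=="), arr.ind = TRUE)
    if (nrow(hits) == 0L) next
    diags <- unique(hits[, 2] - hits[, 1])
    for (d in diags) {
      # overlap of query/subject along diagonal d (s_pos = q_pos + d)
      q_from <- max(1L, 1L - d)
      q_to <- min(qlen, slen - d)
      if (q_to < q_from) next
      qs <- strsplit(substr(mature_seq, q_from, q_to), "")[[1]]
      ss <- strsplit(substr(s, q_from + d, q_to + d), "")[[1]]
      sc <- ifelse(qs == ss, 1, -2)
      # best contiguous segment (Kadane with position tracking)
      best <- 0; cur <- 0; cs <- 1L; bs <- 1L; be <- 0L
      for (i in seq_along(sc)) {
        if (cur <= 0) { cur <- sc[i]; cs <- i } else cur <- cur + sc[i]
        if (cur > best) { best <- cur; bs <- cs; be <- i }
      }
      if (be < bs) next
      seg <- sc[bs:be]
      score <- sum(seg)
      ev <- K * qlen * n_cat * exp(-lambda * score)
      rows[[length(rows) + 1L]] <- data.table(
        subject = names(catalog)[si], score = score,
        identities = sum(seg > 0), mismatches = sum(seg < 0),
        q_from = q_from + bs - 1L, q_to = q_from + be - 1L,
        s_from = q_from + d + bs - 1L, s_to = q_from + d + be - 1L,
        evalue = ev)
    }
  }
  out <- rbindlist(rows)
  if (nrow(out) == 0L) return(out)
  out <- out[evalue <= max_evalue]
  # keep the best segment per subject
  out <- out[order(-score)][, head(.SD, 1L), by = subject]
  setorder(out, -score)
  out[]
}

#' Mapmi-style scan of a mature sequence against a species genome
#'
#' All loci within `max_mismatch` (Hamming, both strands) are found and
#' scored `S = 2 * (L - mm) - 4 * mm + B`, where the bonus B is +5 when the
#' 100-nt-flanked locus folds into a hairpin passing the structural criteria
#' (mature in one arm, clean duplex, energy below the threshold) and -20
#' otherwise. A homologue is called present when the best score reaches
#' `cutoff` (default 35).
#'
#' @param mature_seq query mature sequence.
#' @param species_genome named character vector (the mock species genome).
#' @param max_mismatch 1 or 3 (the two published settings).
#' @param cutoff presence cutoff (default 35).
#' @param energy_threshold hairpin energy threshold for the bonus.
#' @return list with `hits` (`data.table`: contig, start, end, strand, mm,
#'   hairpin_ok, score) and `present` (best score >= cutoff).
#' @export
genome_scan <- function(mature_seq, species_genome, max_mismatch = 3L,
                        cutoff = 35, energy_threshold = -20) {
  L <- nchar(mature_seq)
  rows <- list()
  for (ci in names(species_genome)) {
    s <- species_genome[[ci]]
    for (strand in c("+", "-")) {
      q <- if (strand == "+") mature_seq else revcomp(mature_seq)
      sc <- hamming_scan_cpp(s, q, as.integer(max_mismatch))
      if (nrow(sc) == 0L) next
      rows[[length(rows) + 1L]] <- data.table(
        contig = ci, start = as.integer(sc$pos), end = as.integer(sc$pos) + L,
        strand = strand, mm = as.integer(sc$mm))
    }
  }
  hits <- rbindlist(rows)
  if (nrow(hits) == 0L) {
    return(list(hits = data.table(contig = character(), start = integer(),
                                  end = integer(), strand = character(),
                                  mm = integer(), hairpin_ok = logical(),
                                  score = numeric()),
                present = FALSE))
  }
  hits[, hairpin_ok := FALSE]
  for (r in seq_len(nrow(hits))) {
    w <- extract_window(hits[r], species_genome, flank = 100L)
    if (is.null(w) || grepl("N", w$sequence, fixed = TRUE)) next
    fold <- fold_mfe(w$sequence)
    span <- c(w$tag_offset + 1L, w$tag_offset + L)
    arms <- locate_arms(fold, span)
    clean <- FALSE
    if (!is.na(arms$arm)) {
      geo <- duplex_geometry(parse_dotbracket(fold$structure), span)
      clean <- geo$n_unpaired <= 4L && geo$max_gap <= 3L
    }
    hits[r, hairpin_ok := !is.na(arms$arm) && clean &&
           fold$energy < energy_threshold]
  }
  hits[, score := 2 * (L - mm) - 4 * mm + ifelse(hairpin_ok, 5, -20)]
  setorder(hits, -score)
  list(hits = hits[], present = hits$score[1] >= cutoff)
}

.lineage_species <- c("Aal", "Aae", "Cqu", "Aga", "Dmel")

#' Classify the lineage of a gene from its species presence map
#'
#' Labels form a lattice from most to least inclusive: present in the
#' Drosophila group means conserved beyond mosquitoes; present in all three
#' mosquito genera, mosquito-specific; in Aedes and Culex only,
#' Culicinae-specific; in the two Aedes species only, Aedes-specific;
#' anything else (including inconsistent patterns such as Aedes + Anopheles
#' without Culex) is species-specific, with a warning for inconsistent maps.
#'
#' @param presence named logical vector over `Aal`, `Aae`, `Cqu`, `Aga`,
#'   `Dmel`.
#' @return list with `label` and the `presence` map.
#' @export
classify_lineage <- function(presence) {
  missing <- setdiff(.lineage_species, names(presence))
  if (length(missing)) {
    stop("classify_lineage: presence map missing species: ",
         paste(missing, collapse = ", "))
  }
  p <- presence[.lineage_species]
  label <- if (p[["Dmel"]]) {
    "conserved_beyond_mosquitoes"
  } else if (p[["Aae"]] && p[["Cqu"]] && p[["Aga"]]) {
    "mosquito_specific"
  } else if (p[["Aae"]] && p[["Cqu"]] && !p[["Aga"]]) {
    "culicinae_specific"
  } else if (p[["Aal"]] && p[["Aae"]] && !p[["Cqu"]] && !p[["Aga"]]) {
    "aedes_specific"
  } else {
    if (p[["Aga"]] && !p[["Cqu"]]) {
      warning("classify_lineage: inconsistent presence pattern ",
              "(Aedes + Anopheles without Culex); labelled species_specific")
    }
    "species_specific"
  }
  list(label = label, presence = as.list(p))
}

# best ungapped identity (number of matching positions over all offsets)
best_ungapped_identity <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  best <- 0L
  for (d in (-(la - 1L)):(lb - 1L)) {
    i <- max(1L, 1L - d); j <- min(la, lb - d)
    if (j < i) next
    best <- max(best, sum(av[i:j] == bv[(i:j) + d]))
  }
  best
}

#' Detect an arm switch between a gene and a homologous precursor
#'
#' True when the query's mature sequence aligns with at least `min_identity`
#' matching nucleotides to the homologue's star arm and vice versa.
#'
#' @param gene list or one-row table with `mature_seq` and `star_seq`.
#' @param homologue list or one-row table with `mature` and `star` (the other
#'   species' arms).
#' @param min_identity matching-nucleotide threshold (default 18).
#' @return logical.
#' @export
detect_arm_switch <- function(gene, homologue, min_identity = 18L) {
  if (is.na(gene$star_seq) || is.null(homologue$star)) return(FALSE)
  cross1 <- best_ungapped_identity(gene$mature_seq, homologue$star)
  cross2 <- best_ungapped_identity(gene$star_seq, homologue$mature)
  same1 <- best_ungapped_identity(gene$mature_seq, homologue$mature)
  cross1 >= min_identity && cross2 >= min_identity && cross1 > same1
}

#' Classify every discovered gene against the mock species set
#'
#' Presence in each species is decided by [genome_scan()] at the Mapmi
#' cutoff; both the 1-mismatch and 3-mismatch settings are run and reported.
#' Lineage labels use the 3-mismatch presence map (the more sensitive
#' setting); arm switches are checked against each present species' catalog
#' record.
#'
#' @param genes gene table from [call_mirna_genes()].
#' @param catalogs mock species list from [make_known_catalogs()].
#' @param cutoff Mapmi-style presence cutoff (default 35).
#' @return `data.table`: gene_id, per-species presence (both settings), best
#'   scores, lineage label, arm_switch flag.
#' @export
classify_genes <- function(genes, catalogs, cutoff = 35) {
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i]
    pres1 <- c(Aal = TRUE)
    pres3 <- c(Aal = TRUE)
    best <- c(Aal = NA_real_)
    arm_sw <- FALSE
    for (sp in names(catalogs)) {
      scan3 <- genome_scan(g$mature_seq, catalogs[[sp]]$genome,
                           max_mismatch = 3L, cutoff = cutoff)
      scan1 <- genome_scan(g$mature_seq, catalogs[[sp]]$genome,
                           max_mismatch = 1L, cutoff = cutoff)
      pres3[sp] <- scan3$present
      pres1[sp] <- scan1$present
      best[sp] <- if (nrow(scan3$hits)) scan3$hits$score[1] else NA_real_
      if (scan3$present && nrow(catalogs[[sp]]$catalog)) {
        # find the catalog record at the best locus
        hit <- scan3$hits[1]
        rec <- catalogs[[sp]]$catalog[locus_start <= hit$start &
                                        locus_end >= hit$end]
        if (nrow(rec) && detect_arm_switch(g, rec[1])) arm_sw <- TRUE
      }
    }
    lab <- classify_lineage(pres3)
    rows[[length(rows) + 1L]] <- data.table(
      gene_id = g$gene_id, lineage = lab$label, arm_switch = arm_sw,
      present_Aae = pres3[["Aae"]], present_Cqu = pres3[["Cqu"]],
      present_Aga = pres3[["Aga"]], present_Dmel = pres3[["Dmel"]],
      present_mm1_Aae = pres1[["Aae"]], present_mm1_Cqu = pres1[["Cqu"]],
      present_mm1_Aga = pres1[["Aga"]], present_mm1_Dmel = pres1[["Dmel"]],
      best_score_Aae = best[["Aae"]], best_score_Cqu = best[["Cqu"]],
      best_score_Aga = best[["Aga"]], best_score_Dmel = best[["Dmel"]])
  }
  rbindlist(rows)
}
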