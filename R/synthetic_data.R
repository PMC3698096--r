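# Synthetic dataset generator: a toy genome with planted pre-miRNA hairpins,
# gene/ncRNA/repeat annotation, GO map, mock catalogs for four related
# "species", and six stage-specific small RNA libraries (E, L, P, M, F, B).
# Planted genes are constructed to pass the discovery criteria (clean stem,
# free energy well below -20 kcal/mol, intergenic or intronic placement), so
# every downstream recovery test has a ground truth; a small held-out set is
# deliberately planted inside exons as negative controls for the
# locus-context criterion.

#' Simulation configuration
#'
#' Defaults define the study conditions emulated throughout the package:
#' six libraries of 100,000 reads over a 2 x 200 kb genome with 40 planted
#' miRNA genes; most reads are miRNA-derived so that every library has a
#' dominant ~22 nt (21-23) size class, and an additional 26-30 nt class
#' (piRNA-like, drawn from repeat loci) appears only in the embryo, larva and
#' female libraries.
#'
#' @param seed integer master seed; per-stage substreams are derived from it.
#' @param n_contigs,contig_length,gc genome shape and GC content.
#' @param n_planted number of planted miRNA genes (including controls).
#' @param n_exon_controls how many of them are planted inside exons as
#'   negative controls for the locus-context criterion.
#' @param reads_per_library reads simulated per stage library.
#' @param fraction_mirna,fraction_pirna,fraction_contaminant read-class
#'   fractions; the remainder is unmappable random noise. The piRNA-like
#'   fraction applies to the E, L, F and B libraries and is reallocated to
#'   miRNA reads in P and M.
#' @param adapter3 3' adapter ligated to every read.
#' @param read_length raw read length before trimming.
#' @param p5_shift,p3_shift isomiR end-shift distributions (named numeric
#'   vectors over shifts).
#' @param star_fraction fraction of miRNA-derived reads drawn from the star
#'   arm rather than the mature arm.
#' @param error_rate per-base substitution (sequencing error) rate.
#' @param low_qual_rate fraction of reads given one low-quality insert base.
#' @param n_transcripts,utr_fraction,n_repeats annotation scale.
#' @param n_targeted,n_regulators target-site planting: how many
#'   UTR-annotated transcripts receive perfect sites of how many regulator
#'   miRNAs.
#' @param go_background_rate,go_target_rate probability that a background /
#'   targeted transcript carries the planted marker GO term.
#' @return a validated list of class `mosmir_sim_config`.
#' @export
sim_config <- function(seed = 42L,
                       n_contigs = 2L, contig_length = 200000L, gc = 0.5,
                       n_planted = 40L, n_exon_controls = 4L,
                       reads_per_library = 100000L,
                       fraction_mirna = 0.70, fraction_pirna = 0.12,
                       fraction_contaminant = 0.10,
                       adapter3 = "TGGAATTCTCGGGTGCCAAGGAACTCCAGTCAC",
                       read_length = 40L,
                       p5_shift = c("-1" = 0.1, "0" = 0.8, "1" = 0.1),
                       p3_shift = c("-2" = 0.05, "-1" = 0.15, "0" = 0.6,
                                    "1" = 0.15, "2" = 0.05),
                       star_fraction = 0.15,
                       error_rate = 0.002, low_qual_rate = 0.005,
                       n_transcripts = 120L, utr_fraction = 0.7,
                       n_repeats = 20L,
                       n_targeted = 30L, n_regulators = 10L,
                       go_background_rate = 0.10, go_target_rate = 0.80) {
  cfg <- as.list(environment())
  fr <- c(cfg$fraction_mirna, cfg$fraction_pirna, cfg$fraction_contaminant)
  if (any(fr < 0 | fr > 1) || sum(fr) > 1) {
    stop("sim_config: read-class fractions must lie in [0,1] and sum to <= 1")
  }
  if (cfg$reads_per_library <= 0) stop("sim_config: reads_per_library must be > 0")
  stopifnot(abs(sum(p5_shift) - 1) < 1e-9, abs(sum(p3_shift) - 1) < 1e-9)
  class(cfg) <- "mosmir_sim_config"
  cfg
}

#' Derive a reproducible per-stage seed from the master seed
#'
#' @param seed master integer seed.
#' @param stage stage name (character); the seed is salted with it so stages
#'   can be re-run without replaying predecessors.
#' @return an integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  salt <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + salt * 16807) %% 2147483647)
}

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p), collapse = "")
}

.stage_templates <- matrix(c(
  10, 1, 1, 1, 1, 1,    # embryo-biased
  1, 10, 1, 1, 1, 1,    # larva-biased
  1, 3, 10, 1, 1, 1,    # larval/pupal
  1, 1, 1, 10, 1, 1,    # male-biased
  1, 1, 1, 1, 8, 8      # female-biased (B modified per gene)
), nrow = 5, byrow = TRUE,
  dimnames = list(NULL, c("E", "L", "P", "M", "F", "B")))

#' Generate the toy genome and its annotation
#'
#' Background sequence is i.i.d. at the configured GC content. Each contig
#' carries protein-coding gene models (exon-intron-exon plus, for a fraction
#' of transcripts, an annotated 3'UTR), structural ncRNA loci (rRNA, tRNA,
#' snRNA, snoRNA) and repeat intervals, leaving ample intergenic space for
#' hairpin planting. Deterministic for a fixed seed.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (named character vector) and `annotation`
#'   (internal 0-based table, see [read_gff3()]).
#' @export
generate_genome <- function(config) {
  set.seed(stage_seed(config$seed, "genome"))
  genome <- stats::setNames(
    vapply(seq_len(config$n_contigs),
           function(i) random_dna(config$contig_length, config$gc), character(1)),
    paste0("ctg", seq_len(config$n_contigs)))

  per_contig <- ceiling(config$n_transcripts / config$n_contigs)
  reps_per_contig <- ceiling(config$n_repeats / config$n_contigs)
  feats <- list()
  tcount <- 0L
  utr_cut <- ceiling(config$n_transcripts * config$utr_fraction)
  for (ci in names(genome)) {
    cursor <- 200L
    clen <- nchar(genome[[ci]])
    add <- function(type, width, strand, tid) {
      data.table(contig = ci, start = cursor, end = cursor + width,
                 strand = strand, type = type, transcript_id = tid)
    }
    # ncRNA loci first
    nc <- data.table(type = c("rRNA", "tRNA", "tRNA", "tRNA", "snRNA", "snoRNA"),
                     width = c(500L, 75L, 75L, 75L, 150L, 120L))
    for (r in seq_len(nrow(nc))) {
      feats[[length(feats) + 1L]] <- add(nc$type[r], nc$width[r], "+", NA_character_)
      cursor <- cursor + nc$width[r] + sample(200:400, 1L)
    }
    # repeats
    for (r in seq_len(reps_per_contig)) {
      feats[[length(feats) + 1L]] <- add("repeat", 500L, "+", NA_character_)
      cursor <- cursor + 500L + sample(300:600, 1L)
    }
    # gene models
    for (g in seq_len(per_contig)) {
      if (tcount >= config$n_transcripts) break
      tcount <- tcount + 1L
      tid <- sprintf("t%04d", tcount)
      strand <- if (tcount %% 2L == 0L) "-" else "+"
      has_utr <- tcount <= utr_cut
      widths <- c(exon = 200L, intron = 150L, exon = 150L,
                  utr = if (has_utr) 250L else 0L)
      gene_w <- sum(widths)
      if (cursor + gene_w + 800L > clen) {
        stop("generate_genome: contig ", ci, " too short for requested features")
      }
      gstart <- cursor
      feats[[length(feats) + 1L]] <- add("gene", gene_w, strand, tid)
      # exon/intron/UTR laid out left to right; orientation only affects strand
      feats[[length(feats) + 1L]] <- add("exon", widths[1], strand, tid)
      cursor <- cursor + widths[1]
      f <- data.table(contig = ci, start = cursor, end = cursor + widths[2],
                      strand = strand, type = "intron", transcript_id = tid)
      feats[[length(feats) + 1L]] <- f
      cursor <- cursor + widths[2]
      feats[[length(feats) + 1L]] <- data.table(
        contig = ci, start = cursor, end = cursor + widths[3], strand = strand,
        type = "exon", transcript_id = tid)
      cursor <- cursor + widths[3]
      if (has_utr) {
        feats[[length(feats) + 1L]] <- data.table(
          contig = ci, start = cursor, end = cursor + widths[4],
          strand = strand, type = "three_prime_UTR", transcript_id = tid)
        cursor <- cursor + widths[4]
      }
      cursor <- gstart + gene_w + sample(600:1400, 1L)
    }
  }
  annotation <- rbindlist(feats)
  if (any(annotation$end > nchar(genome[annotation$contig]))) {
    stop("generate_genome: contig too short for requested features")
  }
  list(genome = genome, annotation = annotation)
}

# designed precursor for a mature sequence: stem(mature arm) + unstructured
# loop + near-reverse-complement stem with two designed mismatches, and 2-nt
# 3' overhangs on both duplex ends. The mismatches emulate the bulged stems
# of real precursors and keep the two arms from cross-mapping to each other
# under one-mismatch alignment.
design_precursor <- function(mature, arm, loop_len, n_mismatch = 2L) {
  L <- nchar(mature)
  loop <- paste(sample(c("A", "C"), loop_len, replace = TRUE), collapse = "")
  core <- revcomp(substr(mature, 1L, L - 2L)) # core position i faces mature L-1-i
  if (n_mismatch > 0L) {
    at <- round(seq(5L, L - 7L, length.out = n_mismatch))
    for (i in at) {
      facing <- substr(mature, L - 1L - i, L - 1L - i) # same base cannot pair
      substr(core, i, i) <- facing
    }
  }
  star <- paste0(core,
                 paste(sample(c("C", "A"), 2L, replace = TRUE), collapse = ""))
  if (arm == "5p") {
    pre <- paste0(mature, loop, star)
    list(precursor = pre, star = star,
         mature_off = 0L, star_off = L + loop_len)
  } else {
    pre <- paste0(star, loop, mature)
    list(precursor = pre, star = star,
         mature_off = nchar(star) + loop_len, star_off = 0L)
  }
}

# does an MFE fold keep the designed duplex clean? `mature_span` is 1-based
# within the folded sequence. Checks the same geometry the discovery criteria
# check: mature in one arm, few unpaired mature bases, no large loop in the
# duplex, recoverable star span.
designed_fold_ok <- function(sequence, mature_span, min_energy = -25) {
  fr <- fold_mfe(sequence)
  if (fr$energy >= min_energy) return(FALSE)
  pairing <- parse_dotbracket(fr$structure)
  arms <- locate_arms(fr, mature_span)
  if (is.na(arms$arm) || is.null(arms$star_span)) return(FALSE)
  geo <- duplex_geometry(pairing, mature_span)
  geo$n_unpaired <= 4L && geo$max_gap <= 3L
}

#' Plant pre-miRNA hairpins into the genome
#'
#' Each planted gene is a designed stem-loop (perfectly complementary stem,
#' unstructured loop, 2-nt 3' overhangs) rejection-sampled until the built-in
#' folder reproduces the designed duplex at an energy below -25 kcal/mol, so
#' every non-control plant passes the structural criteria by construction.
#' Placement is intergenic or intronic according to a per-gene draw; the last
#' `n_exon_controls` genes are placed inside exons as negative controls.
#'
#' @param genome_ann list from [generate_genome()].
#' @param config a [sim_config()].
#' @return list with the modified `genome`, the unchanged `annotation` and
#'   `planted`, a `data.table` manifest (one row per planted gene: sequences,
#'   genomic spans, arm, lineage truth, stage profile, control flag).
#' @export
plant_hairpins <- function(genome_ann, config) {
  set.seed(stage_seed(config$seed, "plant"))
  genome <- genome_ann$genome
  annotation <- genome_ann$annotation
  n <- config$n_planted
  n_ctl <- config$n_exon_controls
  lineages <- rep(c("conserved", "mosquito", "culicinae", "aedes"), length.out = n)

  # candidate placement slots
  occupied <- annotation[type %in% c("gene", "rRNA", "tRNA", "snRNA", "snoRNA",
                                     "repeat")]
  slot_pool <- list()
  for (ci in names(genome)) {
    occ <- occupied[contig == ci][order(start)]
    gaps_start <- c(0L, occ$end)
    gaps_end <- c(occ$start, nchar(genome[[ci]]))
    ig <- data.table(contig = ci, start = gaps_start, end = gaps_end)[
      end - start >= 260L]
    ig[, kind := "intergenic"]
    slot_pool[[length(slot_pool) + 1L]] <- ig
  }
  intergenic <- rbindlist(slot_pool)
  if (nrow(intergenic) == 0L) stop("plant_hairpins: no free intergenic space")
  introns <- annotation[type == "intron"][, .(contig, start, end)]
  introns[, kind := "intronic"]
  exons <- annotation[type == "exon" & end - start >= 180L][, .(contig, start, end)]
  exons[, kind := "exonic"]

  mature_lens <- sample(c(21L, 22L, 23L), n, replace = TRUE,
                        prob = c(0.2, 0.6, 0.2))
  templates <- rep(seq_len(5L), length.out = n)
  blood_mod <- sample(c(1, 2, 0.5), n, replace = TRUE, prob = c(0.5, 0.25, 0.25))
  levels <- exp(stats::rnorm(n, 0, 0.6))

  used <- data.table(contig = character(), start = integer(), end = integer())
  rows <- list()
  intron_pick <- stats::runif(n) < 0.25
  for (i in seq_len(n)) {
    is_ctl <- i > n - n_ctl
    L <- mature_lens[i]
    arm <- if (i %% 2L == 0L) "3p" else "5p"
    pool <- if (is_ctl) exons else if (intron_pick[i]) introns else intergenic
    placed <- FALSE
    des <- NULL
    for (try in 1:400) {
      # redesign the sequence periodically in case it folds poorly in context
      if (is.null(des) || try %% 10L == 1L) {
        des <- NULL
        for (dtry in 1:60) {
          mature <- random_dna(L, 0.5)
          loop_len <- sample(14:18, 1L)
          cand <- design_precursor(mature, arm, loop_len)
          span <- c(cand$mature_off + 1L, cand$mature_off + L)
          if (designed_fold_ok(cand$precursor, span)) {
            des <- c(cand, list(mature = mature, loop_len = loop_len))
            break
          }
        }
        if (is.null(des)) stop("plant_hairpins: could not design precursor ", i)
      }
      plen <- nchar(des$precursor)
      slot <- pool[sample(nrow(pool), 1L)]
      margin <- 10L
      lo <- slot$start + margin
      hi <- slot$end - margin - plen
      if (hi <= lo) next
      p <- sample(lo:hi, 1L)
      clash <- used[contig == slot$contig & start < p + plen + 160L &
                      end > p - 160L]
      if (nrow(clash)) next
      strand <- sample(c("+", "-"), 1L)
      ins <- if (strand == "+") des$precursor else revcomp(des$precursor)
      g_old <- genome[[slot$contig]]
      genome[[slot$contig]] <- paste0(substr(g_old, 1L, p),
                                      ins,
                                      substr(g_old, p + plen + 1L, nchar(g_old)))
      # genomic spans of mature/star (0-based half-open, plus-strand coords)
      span_of <- function(off, width) {
        if (strand == "+") c(p + off, p + off + width)
        else c(p + plen - off - width, p + plen - off)
      }
      msp <- span_of(des$mature_off, L)
      ssp <- span_of(des$star_off, nchar(des$star))
      # the discovery window around the mature must itself fold into the
      # designed clean duplex and predict the designed star, so planted genes
      # pass the structural criteria by construction
      clen <- nchar(genome[[slot$contig]])
      ws <- max(0L, msp[1] - 100L)
      we <- min(clen, msp[2] + 100L)
      wseq <- oriented_slice(genome, slot$contig, ws, we, strand)
      off <- if (strand == "+") msp[1] - ws else we - msp[2]
      wspan <- c(off + 1L, off + L)
      fold_ok <- designed_fold_ok(wseq, wspan, min_energy = -25)
      star_ok <- FALSE
      if (fold_ok) {
        fr <- fold_mfe(wseq)
        ps <- predicted_star_span(parse_dotbracket(fr$structure), wspan)
        if (!is.null(ps)) {
          ps_genomic <- if (strand == "+") c(ws + ps[1] - 1L, ws + ps[2])
                        else c(we - ps[2], we - ps[1] + 1L)
          star_ok <- identical(as.integer(ps_genomic), as.integer(ssp))
        }
      }
      if (!fold_ok || !star_ok) {
        genome[[slot$contig]] <- g_old
        next
      }
      used <- rbind(used, data.table(contig = slot$contig, start = p,
                                     end = p + plen))
      tmpl <- .stage_templates[templates[i], ]
      tmpl["B"] <- tmpl["F"] * blood_mod[i]
      rows[[length(rows) + 1L]] <- data.table(
        gene_id = sprintf("sim-mir-%02d", i),
        contig = slot$contig, precursor_start = p, precursor_end = p + plen,
        strand = strand, arm = arm,
        mature_seq = des$mature, star_seq = des$star,
        mature_start = msp[1], mature_end = msp[2],
        star_start = ssp[1], star_end = ssp[2],
        precursor_seq = des$precursor,
        loop_len = des$loop_len,
        context = slot$kind, is_exon_control = is_ctl,
        lineage_truth = lineages[i],
        template = templates[i], blood_mod = blood_mod[i],
        expression_level = levels[i],
        profile_E = tmpl["E"], profile_L = tmpl["L"], profile_P = tmpl["P"],
        profile_M = tmpl["M"], profile_F = tmpl["F"], profile_B = tmpl["B"])
      placed <- TRUE
      break
    }
    if (!placed) stop("plant_hairpins: no free space for gene ", i)
  }
  list(genome = genome, annotation = annotation, planted = rbindlist(rows))
}

# oriented genomic slice (5'->3' on the feature strand)
oriented_slice <- function(genome, contig, start, end, strand) {
  s <- substring(genome[contig], start + 1L, end)
  ifelse(strand == "-", revcomp(s), s)
}

#' Simulate the six stage-specific small RNA libraries
#'
#' Per library: miRNA-derived reads are drawn from planted genes in
#' proportion to their stage profile, with isomiR 5'/3' end shifts and
#' sequencing errors; ~28 nt piRNA-like reads from repeat loci are added to
#' the E, L, F and B libraries only; contaminant reads come from structural
#' ncRNA loci; the remainder is random noise. Every read carries the 3'
#' adapter and is written as fixed-length FASTQ. Deterministic per seed.
#'
#' @param planted list from [plant_hairpins()].
#' @param config a [sim_config()].
#' @param out_dir output directory for `lib_<S>.fastq.gz`.
#' @return named character vector of the six FASTQ paths.
#' @export
simulate_libraries <- function(planted, config, out_dir) {
  genome <- planted$genome
  annotation <- planted$annotation
  genes <- planted$planted
  if (nrow(genes) == 0L) stop("simulate_libraries: no planted genes")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # per-gene extended arm contexts (6 nt of precursor/genome on each side)
  ext <- oriented_slice(genome, genes$contig,
                        pmax(genes$mature_start - 6L, 0L),
                        genes$mature_end + 6L, genes$strand)
  sext <- oriented_slice(genome, genes$contig,
                         pmax(genes$star_start - 6L, 0L),
                         genes$star_end + 6L, genes$strand)
  mlen <- nchar(genes$mature_seq)
  slen <- nchar(genes$star_seq)
  repeats <- annotation[type == "repeat"]
  ncrna <- annotation[type %in% c("rRNA", "tRNA", "snRNA", "snoRNA")]
  paths <- character(0)
  for (s in .sample_order) {
    set.seed(stage_seed(config$seed, paste0("lib_", s)))
    n <- config$reads_per_library
    f_pi <- if (s %in% c("E", "L", "F", "B")) config$fraction_pirna else 0
    f_mi <- config$fraction_mirna +
      (config$fraction_pirna - f_pi) # reallocate the piRNA share in P and M
    f_ct <- config$fraction_contaminant
    f_no <- 1 - f_mi - f_pi - f_ct
    cls <- sample(c("mi", "pi", "ct", "no"), n, replace = TRUE,
                  prob = c(f_mi, f_pi, f_ct, f_no))
    inserts <- character(n)

    i_mi <- which(cls == "mi")
    if (length(i_mi)) {
      if (config$fraction_mirna == 0) {
        warning("simulate_libraries: fraction_mirna is 0; libraries are pure noise")
      }
      w <- genes[[paste0("profile_", s)]] * genes$expression_level
      if (sum(w) <= 0) {
        # nothing expressed at this stage: these reads fall back to noise
        cls[i_mi] <- "no"
        i_mi <- integer(0)
      }
    }
    if (length(i_mi)) {
      gi <- sample(nrow(genes), length(i_mi), replace = TRUE, prob = w)
      s5 <- as.integer(sample(names(config$p5_shift), length(i_mi),
                              replace = TRUE, prob = config$p5_shift))
      s3 <- as.integer(sample(names(config$p3_shift), length(i_mi),
                              replace = TRUE, prob = config$p3_shift))
      from_star <- stats::runif(length(i_mi)) < config$star_fraction
      src <- ifelse(from_star, sext[gi], ext[gi])
      alen <- ifelse(from_star, slen[gi], mlen[gi])
      inserts[i_mi] <- substring(src, 7L + s5, 6L + alen + s3)
    }
    i_pi <- which(cls == "pi")
    if (length(i_pi) && nrow(repeats)) {
      ri <- sample(nrow(repeats), length(i_pi), replace = TRUE,
                   prob = repeats$end - repeats$start)
      plens <- sample(26:30, length(i_pi), replace = TRUE)
      starts <- repeats$start[ri] +
        floor(stats::runif(length(i_pi)) *
                (repeats$end[ri] - repeats$start[ri] - plens))
      pstrand <- sample(c("+", "-"), length(i_pi), replace = TRUE)
      inserts[i_pi] <- oriented_slice(genome, repeats$contig[ri], starts,
                                      starts + plens, pstrand)
    }
    i_ct <- which(cls == "ct")
    if (length(i_ct) && nrow(ncrna)) {
      ri <- sample(nrow(ncrna), length(i_ct), replace = TRUE,
                   prob = ncrna$end - ncrna$start)
      clens2 <- sample(18:25, length(i_ct), replace = TRUE)
      starts <- ncrna$start[ri] +
        floor(stats::runif(length(i_ct)) *
                (ncrna$end[ri] - ncrna$start[ri] - clens2))
      cstrand <- sample(c("+", "-"), length(i_ct), replace = TRUE)
      inserts[i_ct] <- oriented_slice(genome, ncrna$contig[ri], starts,
                                      starts + clens2, cstrand)
    }
    i_no <- which(cls == "no")
    if (length(i_no)) {
      nlens <- sample(18:25, length(i_no), replace = TRUE)
      chars <- sample(c("A", "C", "G", "T"), length(i_no) * 25L, replace = TRUE)
      mat <- matrix(chars, ncol = 25L)
      full <- do.call(paste0, as.data.frame(mat))
      inserts[i_no] <- substr(full, 1L, nlens)
    }

    # single-substitution sequencing errors
    ilen <- nchar(inserts)
    p_err <- 1 - (1 - config$error_rate)^ilen
    errored <- which(stats::runif(n) < p_err)
    if (length(errored)) {
      at <- 1L + floor(stats::runif(length(errored)) * ilen[errored])
      old <- substr(inserts[errored], at, at)
      subs <- c(A = "G", C = "T", G = "A", T = "C", N = "A")
      substr(inserts[errored], at, at) <- unname(subs[old])
    }

    reads <- substr(paste0(inserts, config$adapter3), 1L, config$read_length)
    qual <- rep(strrep("I", config$read_length), n)
    lowq <- which(stats::runif(n) < config$low_qual_rate & ilen > 0L)
    if (length(lowq)) {
      at <- 1L + floor(stats::runif(length(lowq)) * ilen[lowq])
      substr(qual[lowq], at, at) <- "#"
    }
    path <- file.path(out_dir, paste0("lib_", s, ".fastq.gz"))
    write_fastq(data.table(read_id = sprintf("%s_r%06d", s, seq_len(n)),
                           sequence = reads, quality = qual), path)
    paths[s] <- path
  }
  paths
}

#' Build mock catalogs and genomes for four related species
#'
#' Each planted gene is present (with at most two substitutions in the mature
#' region) exactly in the species implied by its lineage truth: Ae. aegypti
#' for all planted genes, plus Culex for culicinae-specific, plus Anopheles
#' for mosquito-specific, plus the Drosophila group for conserved genes. One
#' conserved gene is planted arm-switched in the Culex mock (its mature and
#' star roles are exchanged).
#'
#' @param planted list from [plant_hairpins()] (or its `planted` table).
#' @param config a [sim_config()].
#' @return named list (`Aae`, `Cqu`, `Aga`, `Dmel`), each with `genome`
#'   (single mock contig) and `catalog` (`data.table`: gene_id, mature, star,
#'   arm, precursor, locus in the mock).
#' @export
make_known_catalogs <- function(planted, config) {
  genes <- if (is.data.frame(planted)) as.data.table(planted) else planted$planted
  set.seed(stage_seed(config$seed, "catalogs"))
  presence_rule <- list(
    Aae = c("conserved", "mosquito", "culicinae", "aedes"),
    Cqu = c("conserved", "mosquito", "culicinae"),
    Aga = c("conserved", "mosquito"),
    Dmel = c("conserved"))
  n_subs <- c(Aae = 0L, Cqu = 1L, Aga = 1L, Dmel = 1L)
  arm_switch_gene <- genes[lineage_truth == "conserved" &
                             is_exon_control == FALSE]$gene_id[1]
  # the same hairpin-context check the Mapmi-style scorer applies
  mock_hairpin_ok <- function(window_seq, mature_span) {
    fold <- fold_mfe(window_seq)
    if (fold$energy >= -20) return(FALSE)
    arms <- locate_arms(fold, mature_span)
    if (is.na(arms$arm)) return(FALSE)
    geo <- duplex_geometry(parse_dotbracket(fold$structure), mature_span)
    geo$n_unpaired <= 4L && geo$max_gap <= 3L
  }
  out <- list()
  for (sp in names(presence_rule)) {
    members <- genes[lineage_truth %in% presence_rule[[sp]]]
    seqs <- character(0)
    rows <- list()
    cursor <- 0L
    for (gi in seq_len(nrow(members))) {
      g <- members[gi]
      moff <- if (g$arm == "5p") 0L else
        nchar(g$precursor_seq) - nchar(g$mature_seq)
      # rejection-sample the species substitutions and flanking spacers until
      # the scan window still passes the hairpin criteria (homologous loci
      # keep a foldable precursor context)
      pre <- NULL
      for (try in 1:60) {
        cand_pre <- g$precursor_seq
        if (n_subs[sp] > 0L) {
          # substitutions in the mature region (divergence between species)
          at <- moff + sample(3:(nchar(g$mature_seq) - 2L), n_subs[sp])
          for (a in at) {
            old <- substr(cand_pre, a, a)
            subs <- c(A = "G", C = "T", G = "A", T = "C")
            substr(cand_pre, a, a) <- unname(subs[old])
          }
        }
        sp_left <- random_dna(100L, 0.5)
        sp_right <- random_dna(100L, 0.5)
        ctx <- paste0(sp_left, cand_pre, sp_right)
        w_from <- max(1L, 100L + moff + 1L - 100L)
        w_to <- min(nchar(ctx), 100L + moff + nchar(g$mature_seq) + 100L)
        span <- c(100L + moff + 1L - w_from + 1L,
                  100L + moff + nchar(g$mature_seq) - w_from + 1L)
        if (mock_hairpin_ok(substr(ctx, w_from, w_to), span)) {
          pre <- cand_pre
          break
        }
      }
      if (is.null(pre)) {
        stop("make_known_catalogs: could not build a foldable mock locus for ",
             g$gene_id, " in ", sp)
      }
      seqs <- c(seqs, sp_left, pre, sp_right)
      locus_start <- cursor + 100L
      cursor <- cursor + 200L + nchar(pre)
      mature <- substr(pre, moff + 1L, moff + nchar(g$mature_seq))
      soff <- if (g$arm == "5p") nchar(pre) - nchar(g$star_seq) else 0L
      star <- substr(pre, soff + 1L, soff + nchar(g$star_seq))
      swapped <- sp == "Cqu" && identical(g$gene_id, arm_switch_gene)
      rows[[length(rows) + 1L]] <- data.table(
        gene_id = g$gene_id,
        mature = if (swapped) star else mature,
        star = if (swapped) mature else star,
        arm = if (swapped) setdiff(c("5p", "3p"), g$arm) else g$arm,
        precursor = pre, locus_start = locus_start,
        locus_end = locus_start + nchar(pre), arm_switched = swapped)
    }
    seqs <- c(seqs, random_dna(100L, 0.5))
    mock <- stats::setNames(paste(seqs, collapse = ""), paste0(sp, "_mock"))
    out[[sp]] <- list(genome = mock, catalog = rbindlist(rows))
  }
  out
}

# plant perfect complementary target sites of regulator miRNAs into 3'UTRs
# and build the GO map with one enriched marker term among targeted
# transcripts
plant_targets_and_go <- function(planted, config) {
  genes <- planted$planted
  genome <- planted$genome
  annotation <- planted$annotation
  set.seed(stage_seed(config$seed, "targets"))
  utrs <- annotation[type == "three_prime_UTR"]
  regs <- genes[is_exon_control == FALSE][seq_len(min(config$n_regulators,
                                              sum(!genes$is_exon_control)))]
  targeted <- sample(utrs$transcript_id, min(config$n_targeted, nrow(utrs)))
  # marker GO terms are keyed by the regulator's expression template, so the
  # targets of co-expressed miRNAs are functionally coherent (the pattern the
  # per-cluster enrichment test is meant to recover)
  marker_of <- function(template) sprintf("GO:SYN%04d", template)
  marker_rows <- list()
  for (tid in targeted) {
    u <- utrs[transcript_id == tid][1]
    picks <- regs[sample(nrow(regs), min(2L, nrow(regs)))]
    half <- (u$end - u$start) %/% 2L
    for (ri in seq_len(nrow(picks))) {
      site_sense <- revcomp(picks$mature_seq[ri]) # transcript orientation
      site_plus <- if (u$strand == "+") site_sense else revcomp(site_sense)
      w <- nchar(site_plus)
      lo <- u$start + (ri - 1L) * half
      p <- lo + sample.int(half - w, 1L)
      g <- genome[[u$contig]]
      genome[[u$contig]] <- paste0(substr(g, 1L, p), site_plus,
                                   substr(g, p + w + 1L, nchar(g)))
      if (stats::runif(1) < config$go_target_rate) {
        marker_rows[[length(marker_rows) + 1L]] <- data.table(
          transcript_id = tid, term = marker_of(picks$template[ri]))
      }
    }
  }
  all_tids <- unique(annotation[type == "gene"]$transcript_id)
  terms <- sprintf("GO:%07d", seq_len(12L))
  go_rows <- lapply(all_tids, function(tid) {
    k <- sample(1:3, 1L)
    data.table(transcript_id = tid, term = sample(terms, k))
  })
  bg <- all_tids[stats::runif(length(all_tids)) < config$go_background_rate]
  if (length(bg)) {
    marker_rows[[length(marker_rows) + 1L]] <- data.table(
      transcript_id = bg,
      term = marker_of(sample(unique(regs$template), length(bg),
                              replace = TRUE)))
  }
  go_map <- unique(rbind(rbindlist(go_rows), rbindlist(marker_rows)))
  planted$genome <- genome
  planted$go_map <- go_map
  planted$targeted_truth <- targeted
  planted
}

#' Generate the complete synthetic dataset
#'
#' Runs [generate_genome()], [plant_hairpins()], target-site/GO planting,
#' [simulate_libraries()] and [make_known_catalogs()], and writes all outputs
#' (genome.fa, annotation.gff3, truth.tsv, go_map.tsv, known_<species>.fa,
#' lib_<S>.fastq.gz) plus the ground-truth manifest to `out_dir`.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @param write_files write the on-disk artifacts (default TRUE); the in-memory
#'   objects are always returned.
#' @return list with `genome`, `annotation`, `planted` (truth manifest),
#'   `go_map`, `targeted_truth`, `catalogs`, `fastq_paths`, `config`.
#' @export
simulate_dataset <- function(config = sim_config(), out_dir = tempfile("simdata"),
                             write_files = TRUE) {
  ga <- generate_genome(config)
  pl <- plant_hairpins(ga, config)
  pl <- plant_targets_and_go(pl, config)
  catalogs <- make_known_catalogs(pl, config)
  fastq_paths <- simulate_libraries(pl, config, out_dir)
  if (write_files) {
    write_fasta(pl$genome, file.path(out_dir, "genome.fa"))
    write_gff3(pl$annotation, file.path(out_dir, "annotation.gff3"))
    fwrite(pl$planted, file.path(out_dir, "truth.tsv"), sep = "\t")
    fwrite(pl$go_map, file.path(out_dir, "go_map.tsv"), sep = "\t")
    for (sp in names(catalogs)) {
      cat_seqs <- c(stats::setNames(catalogs[[sp]]$catalog$mature,
                                    paste0(sp, "-", catalogs[[sp]]$catalog$gene_id)),
                    stats::setNames(catalogs[[sp]]$catalog$precursor,
                                    paste0(sp, "-", catalogs[[sp]]$catalog$gene_id, "-pre")))
      write_fasta(cat_seqs, file.path(out_dir, paste0("known_", sp, ".fa")))
    }
  }
  list(genome = pl$genome, annotation = pl$annotation, planted = pl$planted,
       go_map = pl$go_map, targeted_truth = pl$targeted_truth,
       catalogs = catalogs, fastq_paths = fastq_paths, config = config,
       out_dir = out_dir)
}

#' Dinucleotide-preserving shuffle of a genome (negative control)
#'
#' First-order Markov resample of each contig: the shuffled contig has the
#' same length and, in expectation, the same dinucleotide frequencies, but no
#' planted loci.
#'
#' @param genome named character vector.
#' @param seed integer seed.
#' @return named character vector of shuffled contigs.
#' @export
shuffle_genome_dinucleotide <- function(genome, seed = 1L) {
  set.seed(stage_seed(seed, "shuffle"))
  out <- vapply(genome, function(s) {
    ch <- strsplit(s, "")[[1]]
    n <- length(ch)
    from <- ch[-n]
    to <- ch[-1]
    trans <- table(factor(from, c("A", "C", "G", "T")),
                   factor(to, c("A", "C", "G", "T")))
    probs <- prop.table(trans + 1e-9, 1)
    bases <- c("A", "C", "G", "T")
    res <- character(n)
    res[1] <- ch[1]
    # vectorised Markov walk: draw all uniforms, then iterate with cumulative
    # probability lookup
    cum <- t(apply(probs, 1, cumsum))
    u <- stats::runif(n - 1)
    cur <- match(res[1], bases)
    for (i in 2:n) {
      cur <- findInterval(u[i - 1], cum[cur, ], left.open = TRUE) + 1L
      res[i] <- bases[cur]
    }
    paste(res, collapse = "")
  }, character(1))
  stats::setNames(out, names(genome))
}
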