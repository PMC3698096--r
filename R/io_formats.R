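# Readers/writers for the external formats the pipeline touches, and the one
# home of the coordinate convention: internally everything is 0-based
# half-open on the plus strand; GFF3 is 1-based inclusive and is converted at
# this boundary only.

#' Read a (possibly gzipped) FASTA file of genome or catalog sequences
#'
#' Sequences are upper-cased and U is converted to T on input, so RNA and DNA
#' catalogs share one alphabet. Duplicate identifiers and empty records are
#' rejected rather than repaired.
#'
#' @param path path to a FASTA file, plain or gzip-compressed.
#' @return a named character vector of sequences over `{A,C,G,T,N}`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) stop("FASTA parse error in ", path, ": ", conditionMessage(e))
  )
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop("FASTA parse error: empty header in ", path)
  if (any(nchar(seqs) == 0L)) {
    stop("FASTA parse error: empty record '", ids[which(nchar(seqs) == 0L)[1]],
         "' in ", path)
  }
  if (anyDuplicated(ids)) {
    stop("FASTA parse error: duplicate identifier '", ids[anyDuplicated(ids)],
         "' in ", path)
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("FASTA parse error: non-ACGTN characters in record '", ids[which(bad)[1]], "'")
  }
  stats::setNames(seqs, ids)
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output path (".gz" suffix gives gzip output).
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a (possibly gzipped) 4-line FASTQ file
#'
#' @param path path to a FASTQ file; gzip is detected transparently.
#' @return a `data.table` with columns `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  con <- gzfile(path, "rt") # gzfile reads plain files too
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) == 0L) {
    return(data.table(read_id = character(), sequence = character(),
                      quality = character()))
  }
  if (length(lines) %% 4L != 0L) {
    stop("FASTQ parse error: ", path, " has ", length(lines),
         " lines, not a multiple of 4")
  }
  ids <- lines[seq(1L, length(lines), by = 4L)]
  seqs <- lines[seq(2L, length(lines), by = 4L)]
  plus <- lines[seq(3L, length(lines), by = 4L)]
  quals <- lines[seq(4L, length(lines), by = 4L)]
  if (any(substr(ids, 1L, 1L) != "@") || any(substr(plus, 1L, 1L) != "+")) {
    stop("FASTQ parse error: malformed record markers in ", path)
  }
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad)) {
    stop("FASTQ parse error: sequence/quality length mismatch at record ",
         bad[1], " (", ids[bad[1]], ") in ", path)
  }
  data.table(read_id = sub("^@", "", sub("\\s.*$", "", ids)),
             sequence = toupper(chartr("U", "T", seqs)), quality = quals)
}

#' Write reads as 4-line FASTQ
#'
#' @param reads `data.table` with `read_id`, `sequence`, `quality`.
#' @param path output path; a ".gz" suffix gives gzip output.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(nchar(reads$sequence) == nchar(reads$quality)))
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$sequence, "+",
                           reads$quality))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

.known_feature_types <- c("exon", "intron", "gene", "three_prime_UTR",
                          "rRNA", "tRNA", "snRNA", "snoRNA", "repeat")

#' Read a GFF3 annotation into the internal 0-based half-open convention
#'
#' Feature types outside the recognised set (exon, intron, gene,
#' three_prime_UTR, rRNA, tRNA, snRNA, snoRNA, repeat) are dropped with a
#' message reporting how many were ignored.
#'
#' @param path GFF3 file (1-based inclusive coordinates).
#' @return a `data.table` with columns `contig`, `start` (0-based), `end`
#'   (exclusive), `strand`, `type`, `transcript_id`.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  empty <- data.table(contig = character(), start = integer(), end = integer(),
                      strand = character(), type = character(),
                      transcript_id = character())
  raw <- readLines(path, warn = FALSE)
  raw <- raw[!grepl("^#", raw) & nzchar(raw)]
  if (length(raw) == 0L) return(empty)
  g <- as.data.table(rtracklayer::readGFF(path))
  if (nrow(g) == 0L) return(empty)
  if (any(g$start > g$end)) {
    stop("GFF3 parse error: start > end at line with seqid ",
         g$seqid[which(g$start > g$end)[1]])
  }
  keep <- g$type %in% .known_feature_types
  n_ignored <- sum(!keep)
  if (n_ignored > 0L) {
    message("read_gff3: ignored ", n_ignored, " features of unrecognised type")
  }
  g <- g[keep]
  tid <- if ("ID" %in% names(g)) as.character(g$ID) else rep(NA_character_, nrow(g))
  if ("Parent" %in% names(g)) {
    parent <- vapply(g$Parent, function(p) if (length(p)) as.character(p[[1]]) else NA_character_,
                     character(1))
    tid <- ifelse(is.na(parent) | !nzchar(parent), tid, parent)
  }
  out <- data.table(contig = as.character(g$seqid),
                    start = as.integer(g$start) - 1L,
                    end = as.integer(g$end),
                    strand = ifelse(as.character(g$strand) == "-", "-", "+"),
                    type = as.character(g$type),
                    transcript_id = tid)
  out[]
}

#' Write an annotation table as GFF3 (converting back to 1-based inclusive)
#'
#' @param ann annotation `data.table` (internal convention).
#' @param path output path.
#' @export
write_gff3 <- function(ann, path) {
  attrs <- ifelse(is.na(ann$transcript_id), ".",
                  paste0("ID=", ann$transcript_id))
  lines <- paste(ann$contig, "mosmir", ann$type, ann$start + 1L, ann$end, ".",
                 ann$strand, ".", attrs, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Write discovered miRNA genes as a GFF3 catalog
#'
#' One `pre_miRNA` feature per gene with child `miRNA` features for the
#' mature and (when predicted) star sequence; attributes carry the lineage
#' label. Coordinates are re-converted to 1-based inclusive.
#'
#' @param genes gene table as returned by [call_mirna_genes()] (optionally
#'   with a `lineage` column from [classify_lineage()]).
#' @param path output path.
#' @export
write_mirna_gff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(genes))) {
    g <- genes[i]
    contained <- g$mature_g_start >= g$window_start && g$mature_g_end <= g$window_end
    if (!is.na(g$star_g_start)) {
      contained <- contained && g$star_g_start >= g$window_start &&
        g$star_g_end <= g$window_end
    }
    if (!contained) {
      stop("write_mirna_gff3: mature/star interval of ", g$gene_id,
           " not contained in its precursor window")
    }
    lineage <- if ("lineage" %in% names(genes) && !is.na(g$lineage)) {
      paste0(";lineage=", g$lineage)
    } else ""
    lines <- c(lines, paste(g$contig, "mosmir", "pre_miRNA",
                            g$window_start + 1L, g$window_end, ".", g$strand, ".",
                            paste0("ID=", g$gene_id, lineage), sep = "\t"))
    lines <- c(lines, paste(g$contig, "mosmir", "miRNA",
                            g$mature_g_start + 1L, g$mature_g_end, ".", g$strand, ".",
                            paste0("ID=", g$gene_id, ".mature;Parent=", g$gene_id),
                            sep = "\t"))
    if (!is.na(g$star_g_start)) {
      lines <- c(lines, paste(g$contig, "mosmir", "miRNA",
                              g$star_g_start + 1L, g$star_g_end, ".", g$strand, ".",
                              paste0("ID=", g$gene_id, ".star;Parent=", g$gene_id),
                              sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write Vienna-style dot-bracket records
#'
#' Layout per record: `>id`, sequence, then `STRUCT (ENERGY)` with the energy
#' printed to 0.1 kcal/mol.
#'
#' @param records list of lists with fields `id`, `sequence`, `structure`,
#'   `energy`.
#' @param path output path.
#' @export
write_dotbracket <- function(records, path) {
  lines <- character(0)
  for (r in records) {
    if (nchar(r$structure) != nchar(r$sequence)) {
      stop("write_dotbracket: structure length != sequence length for ", r$id)
    }
    op <- lengths(regmatches(r$structure, gregexpr("\\(", r$structure)))
    cl <- lengths(regmatches(r$structure, gregexpr("\\)", r$structure)))
    if (op != cl) stop("write_dotbracket: unbalanced brackets for ", r$id)
    lines <- c(lines, paste0(">", r$id), r$sequence,
               sprintf("%s (%.1f)", r$structure, r$energy))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of sequences over `{A,C,G,T,N}`.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# pairing table from a dot-bracket string: integer vector, pairing[i] = index
# of the partner of position i (1-based) or NA
parse_dotbracket <- function(db) {
  ch <- strsplit(db, "")[[1]]
  pairing <- rep(NA_integer_, length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairing[i] <- j
      pairing[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket string")
  pairing
}
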