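# Adapter trimming, length selection, contaminant filtering, collapsing and
# the size distribution.

adapter <- "TGGAATTCTCGGGTGCCAAGG"

test_that("adapter trimming finds the leftmost match and tolerates 1 mismatch", {
  insert <- "ACGTACGTACGTACGTACGTTT"
  expect_equal(trim_adapter(paste0(insert, adapter), adapter), insert)
  # no adapter
  expect_true(is.na(trim_adapter(strrep("ACGT", 10), adapter)))
  # adapter at position 0 trims to nothing
  expect_true(is.na(trim_adapter(paste0(adapter, "AAAA"), adapter)))
  # partial adapter at the end, >= 6 nt overlap
  expect_equal(trim_adapter(paste0(insert, substr(adapter, 1, 7)), adapter),
               insert)
  # < 6 nt overlap is not an adapter match
  expect_true(is.na(trim_adapter(paste0("CCCCCCCCCCCCCCCCCC",
                                        substr(adapter, 1, 5)), adapter)))
  expect_error(trim_adapter("ACGT", "ACG"), ">= 6")
})

test_that("one-mismatch adapter trimming agrees with a brute-force scan", {
  brute <- function(read, ad, min_ov = 6, max_mm = 1) {
    for (o in 0:(nchar(read) - min_ov)) {
      ov <- min(nchar(read) - o, nchar(ad))
      mm <- sum(strsplit(substr(read, o + 1, o + ov), "")[[1]] !=
                  strsplit(substr(ad, 1, ov), "")[[1]])
      if (mm <= max_mm) return(if (o == 0) NA_character_ else substr(read, 1, o))
    }
    NA_character_
  }
  set.seed(3)
  for (i in 1:200) {
    ins <- random_tag(sample(10:30, 1))
    read <- substr(paste0(ins, adapter), 1, 40)
    if (i %% 2 == 0) { # plant one mismatch inside the adapter copy
      at <- nchar(ins) + sample(6, 1)
      if (at <= nchar(read)) {
        substr(read, at, at) <- sample(setdiff(c("A", "C", "G", "T"),
                                               substr(read, at, at)), 1)
      }
    }
    expect_equal(trim_adapter(read, adapter), brute(read, adapter), label = read)
  }
})

test_that("length selection keeps exactly the closed 18-30 nt range", {
  tags <- c(strrep("A", 17), strrep("C", 18), strrep("G", 30), strrep("T", 31))
  kept <- filter_length(tags)
  expect_equal(nchar(kept), c(18L, 30L))
  expect_equal(attr(kept, "dropped"), c(too_short = 1L, too_long = 1L))
})

test_that("contaminant filtering removes structural-RNA matches on either strand", {
  set.seed(8)
  genome <- c(c1 = random_tag(3000))
  ann <- data.table::data.table(
    contig = "c1", start = c(100L, 500L), end = c(250L, 700L),
    strand = "+", type = c("tRNA", "exon"), transcript_id = c(NA, "t1"))
  trna_tag <- substr(genome[["c1"]], 121, 142)
  exon_tag <- substr(genome[["c1"]], 521, 542)
  clean_tag <- substr(genome[["c1"]], 1021, 1042)
  tags <- data.table::data.table(
    sequence = c(trna_tag, revcomp(trna_tag), exon_tag, clean_tag))
  out <- filter_contaminants(tags, ann, genome)
  # both orientations of the tRNA fragment are removed
  expect_false(trna_tag %in% out$sequence)
  expect_false(revcomp(trna_tag) %in% out$sequence)
  expect_equal(attr(out, "n_contaminant"), 2L)
  # exon matches are kept but flagged; intergenic tags stay unflagged
  expect_true(out[sequence == exon_tag, flag_exon])
  expect_false(out[sequence == clean_tag, flag_exon])
  expect_false(out[sequence == clean_tag, flag_intron])
  # idempotence: filtering the already-clean set changes nothing
  again <- filter_contaminants(out[, "sequence"], ann, genome)
  expect_equal(again$sequence, out$sequence)
  expect_equal(attr(again, "n_contaminant"), 0L)
})

test_that("collapsing produces per-sample count vectors that conserve reads", {
  reads <- list(E = c("ACGTACGTACGTACGTAA", "ACGTACGTACGTACGTAA",
                      "ACGTACGTACGTACGTAA", "TTTTCCCCGGGGAAAATT"),
                L = c("ACGTACGTACGTACGTAA", "ACGTACGTACGTACGTAA"))
  tags <- collapse_tags(reads)
  expect_equal(nrow(tags), 2L)
  row <- tags[sequence == "ACGTACGTACGTACGTAA"]
  expect_equal(unlist(row[, paste0("count_", c("E", "L", "P", "M", "F", "B")),
                          with = FALSE], use.names = FALSE),
               c(3L, 2L, 0L, 0L, 0L, 0L))
  cols <- grep("^count_", names(tags), value = TRUE)
  expect_equal(sum(as.matrix(tags[, cols, with = FALSE])),
               sum(lengths(reads)))
  empty <- collapse_tags(list(E = character(0)))
  expect_equal(nrow(empty), 0L)
})

test_that("size distribution normalises to 1 per sample and flags empty samples", {
  tags <- collapse_tags(list(E = c(strrep("A", 22), strrep("A", 22),
                                   strrep("C", 25)),
                             L = strrep("G", 20)))
  sd <- size_distribution(tags)
  expect_equal(sd[, sum(fraction), by = sample_id]$V1, c(1, 1),
               tolerance = 1e-12)
  expect_equal(sd[sample_id == "E" & len == 22, fraction], 2 / 3)
  single <- collapse_tags(list(E = strrep("A", 22)))
  sd1 <- size_distribution(single)
  expect_equal(sd1[len == 22, fraction], 1)
  # explicitly requesting a sample with zero reads is an error
  tags0 <- data.table::copy(tags)
  tags0[, count_L := 0L]
  expect_error(size_distribution(tags0, samples = c("E", "L")), "zero reads")
})

test_that("preprocessing accounts for every input read", {
  ds <- small_dataset()
  pp <- preprocess_libraries(ds$fastq_paths, ds$config$adapter3,
                             ds$annotation, ds$genome)
  acct <- pp$accounting
  expect_equal(acct$input,
               acct$no_adapter + acct$low_quality + acct$out_of_range + acct$kept)
  expect_equal(acct$input, rep(ds$config$reads_per_library, 6))
  cols <- grep("^count_", names(pp$tags), value = TRUE)
  # collapsed pre-filter counts match the kept reads minus removed contaminants
  expect_lte(sum(as.matrix(pp$tags[, cols, with = FALSE])), sum(acct$kept))
})
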