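# The generator: determinism, genome composition, designed hairpin
# properties, library structure and mock catalogs.

test_that("generation is deterministic for a fixed seed", {
  cfg <- sim_config(seed = 3, n_contigs = 2, contig_length = 20000,
                    n_planted = 0, n_transcripts = 8, n_repeats = 2,
                    reads_per_library = 100)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1, g2)
  expect_length(g1$genome, 2L)
  cfg3 <- sim_config(seed = 3, n_contigs = 3, contig_length = 20000,
                     n_planted = 0, n_transcripts = 9, n_repeats = 3,
                     reads_per_library = 100)
  expect_length(generate_genome(cfg3)$genome, 3L)
})

test_that("background GC content matches the configured value", {
  cfg <- sim_config(seed = 5, n_contigs = 1, contig_length = 100000,
                    n_planted = 0, n_transcripts = 0, n_repeats = 0,
                    reads_per_library = 100, gc = 0.5)
  g <- generate_genome(cfg)$genome[[1]]
  gc_obs <- sum(strsplit(g, "")[[1]] %in% c("G", "C")) / nchar(g)
  # direct count against a binomial bound at n = 100k
  expect_lt(abs(gc_obs - 0.5), 0.02)
})

test_that("contigs too short for the requested features raise an error", {
  cfg <- sim_config(seed = 1, n_contigs = 1, contig_length = 3000,
                    n_planted = 0, n_transcripts = 10, reads_per_library = 100)
  expect_error(generate_genome(cfg), "too short")
})

test_that("planted precursors satisfy the structural criteria by construction", {
  ds <- small_dataset()
  tr <- ds$planted
  expect_equal(nrow(tr), 8L)
  for (i in seq_len(nrow(tr))) {
    pre <- tr$precursor_seq[i]
    # mature is an exact substring of the precursor
    expect_true(grepl(tr$mature_seq[i], pre, fixed = TRUE))
    # precursor length in the pre-miRNA range and folding below -20 kcal/mol
    expect_gte(nchar(pre), 50L)
    expect_lte(nchar(pre), 100L)
    expect_lt(fold_mfe(pre)$energy, -20)
    # planted sequence is present in the genome at the recorded interval
    planted_seq <- substr(ds$genome[[tr$contig[i]]], tr$precursor_start[i] + 1,
                          tr$precursor_end[i])
    if (tr$strand[i] == "-") planted_seq <- revcomp(planted_seq)
    expect_equal(planted_seq, pre)
  }
})

test_that("exon-planted controls overlap exon features", {
  ds <- small_dataset()
  ctl <- ds$planted[is_exon_control == TRUE]
  expect_gte(nrow(ctl), 1L)
  exons <- ds$annotation[type == "exon"]
  for (i in seq_len(nrow(ctl))) {
    ov <- exons[contig == ctl$contig[i] & start < ctl$precursor_end[i] &
                  end > ctl$precursor_start[i]]
    expect_gte(nrow(ov), 1L)
  }
})

test_that("libraries are deterministic and reads carry the 3' adapter", {
  cfg <- small_sim_config()
  ds <- small_dataset()
  reads <- read_fastq(ds$fastq_paths[["E"]])
  expect_equal(nrow(reads), cfg$reads_per_library)
  expect_equal(unique(nchar(reads$sequence)), cfg$read_length)
  # most reads contain the adapter prefix (insert <= 30 nt out of 40)
  has_ad <- grepl(substr(cfg$adapter3, 1, 8), reads$sequence, fixed = TRUE)
  expect_gt(mean(has_ad), 0.9)
  # re-simulating with the same seed reproduces the library byte for byte
  dir2 <- tempfile()
  paths2 <- simulate_libraries(ds[c("genome", "annotation", "planted")],
                               cfg, dir2)
  expect_identical(read_fastq(paths2[["E"]]), reads)
})

test_that("a gene expressed only in embryos yields reads only in the embryo library", {
  cfg <- small_sim_config()
  ds <- small_dataset()
  tr <- data.table::copy(ds$planted[1])
  tr[, c("profile_E", "profile_L", "profile_P", "profile_M", "profile_F",
         "profile_B") := list(1, 0, 0, 0, 0, 0)]
  one <- list(genome = ds$genome, annotation = ds$annotation, planted = tr)
  cfg1 <- small_sim_config()
  cfg1$fraction_pirna <- 0
  cfg1$fraction_contaminant <- 0
  cfg1$fraction_mirna <- 1
  cfg1$error_rate <- 0
  paths <- simulate_libraries(one, cfg1, tempfile())
  mature <- tr$mature_seq
  for (s in c("E", "L", "P", "M", "F", "B")) {
    reads <- read_fastq(paths[[s]])
    n_gene <- sum(grepl(substr(mature, 3, 20), reads$sequence, fixed = TRUE))
    if (s == "E") expect_gt(n_gene, 0) else expect_equal(n_gene, 0)
  }
})

test_that("mock catalogs implement the lineage presence rules", {
  ds <- small_dataset()
  cats <- ds$catalogs
  tr <- ds$planted
  expect_setequal(names(cats), c("Aae", "Cqu", "Aga", "Dmel"))
  for (i in seq_len(nrow(tr))) {
    lin <- tr$lineage_truth[i]
    expected_in <- switch(lin,
                          conserved = c("Aae", "Cqu", "Aga", "Dmel"),
                          mosquito = c("Aae", "Cqu", "Aga"),
                          culicinae = c("Aae", "Cqu"),
                          aedes = "Aae")
    for (sp in names(cats)) {
      in_cat <- tr$gene_id[i] %in% cats[[sp]]$catalog$gene_id
      expect_equal(in_cat, sp %in% expected_in,
                   label = paste(tr$gene_id[i], sp))
      if (in_cat) {
        rec <- cats[[sp]]$catalog[gene_id == tr$gene_id[i]]
        # retrievable from the mock genome with <= 3 mismatches
        sc <- mosmir:::hamming_scan_cpp(cats[[sp]]$genome[[1]],
                                        tr$mature_seq[i], 3L)
        expect_gte(nrow(sc), 1L)
      }
    }
  }
  # exactly one planted arm switch, in the Culex mock
  expect_equal(sum(cats$Cqu$catalog$arm_switched), 1L)
  expect_equal(sum(cats$Aae$catalog$arm_switched), 0L)
})

test_that("config fractions and shift distributions are validated", {
  expect_error(sim_config(fraction_mirna = 0.8, fraction_pirna = 0.3),
               "sum to <= 1")
  expect_error(sim_config(fraction_mirna = -0.1), "\\[0,1\\]")
  expect_error(sim_config(reads_per_library = 0), "> 0")
  cfg <- sim_config()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, f)
  expect_equal(read_sim_config(f), cfg)
})

test_that("dinucleotide shuffling preserves length and composition roughly", {
  set.seed(2)
  g <- c(c1 = random_tag(20000))
  s <- shuffle_genome_dinucleotide(g, seed = 5)
  expect_equal(nchar(s[["c1"]]), 20000L)
  expect_false(identical(s[["c1"]], g[["c1"]]))
  din <- function(x) {
    ch <- strsplit(x, "")[[1]]
    table(paste0(ch[-length(ch)], ch[-1])) / (length(ch) - 1)
  }
  d1 <- din(g[["c1"]])
  d2 <- din(s[["c1"]])
  expect_lt(max(abs(d1 - d2[names(d1)])), 0.01)
})
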