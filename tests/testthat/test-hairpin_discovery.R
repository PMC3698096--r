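# Window extraction, arm location, criteria evaluation, read-stack
# confirmation and gene calling.

test_that("window extraction adds 100 nt of flank and clips at contig edges", {
  set.seed(12)
  g <- c(c1 = random_tag(2000))
  hit <- list(contig = "c1", start = 500L, end = 522L, strand = "+")
  w <- extract_window(hit, g)
  expect_equal(w$end - w$start, 222L)
  expect_equal(w$tag_offset, 100L)
  expect_equal(w$sequence, substr(g[["c1"]], 401, 622))

  near <- list(contig = "c1", start = 10L, end = 32L, strand = "+")
  w2 <- extract_window(near, g)
  expect_equal(w2$start, 0L)
  expect_equal(w2$tag_offset, 10L)

  minus <- list(contig = "c1", start = 500L, end = 522L, strand = "-")
  w3 <- extract_window(minus, g)
  expect_equal(w3$sequence, revcomp(substr(g[["c1"]], 401, 622)))
  expect_equal(w3$tag_offset, 100L)

  tiny <- list(contig = "c1", start = 0L, end = 22L, strand = "+")
  g_short <- c(c1 = substr(g[["c1"]], 1, 30))
  expect_message(w4 <- extract_window(tiny, g_short), "skipped")
  expect_null(w4)
})

test_that("arm location identifies 5p/3p and rejects loop-crossing matures", {
  # designed hairpin: 20 bp stem, 6 nt loop
  stem <- "GCGCAATTGGCCAGTCAGTC"
  hp <- paste0(stem, "AACAAC", revcomp(stem))
  f <- fold_mfe(hp)
  expect_lt(f$energy, -20)
  a5 <- locate_arms(f, c(1L, 18L))
  expect_equal(a5$arm, "5p")
  a3 <- locate_arms(f, c(29L, 46L))
  expect_equal(a3$arm, "3p")
  cross <- locate_arms(f, c(12L, 34L))
  expect_true(is.na(cross$arm))
})

test_that("predicted star spans match the designed duplex on planted genes", {
  ds <- small_dataset()
  tr <- ds$planted[is_exon_control == FALSE]
  for (i in seq_len(nrow(tr))) {
    hit <- list(contig = tr$contig[i], start = tr$mature_start[i],
                end = tr$mature_end[i], strand = tr$strand[i])
    w <- extract_window(hit, ds$genome)
    f <- fold_mfe(w$sequence)
    span <- c(w$tag_offset + 1L, w$tag_offset + nchar(tr$mature_seq[i]))
    arms <- locate_arms(f, span)
    expect_equal(arms$arm, tr$arm[i], label = tr$gene_id[i])
    star <- substr(w$sequence, arms$star_span[1], arms$star_span[2])
    expect_equal(star, tr$star_seq[i], label = tr$gene_id[i])
  }
})

test_that("criteria report evaluates each criterion and their conjunction", {
  ds <- small_dataset()
  tr <- ds$planted[is_exon_control == FALSE][1]
  hit <- list(contig = tr$contig, start = tr$mature_start,
              end = tr$mature_end, strand = tr$strand)
  w <- extract_window(hit, ds$genome)
  f <- fold_mfe(w$sequence)
  span <- c(w$tag_offset + 1L, w$tag_offset + nchar(tr$mature_seq))
  arms <- locate_arms(f, span)
  cand <- list(window = w, fold = f, mature_span = span, arm = arms$arm,
               star_span = arms$star_span)
  rs <- list(ok = TRUE)
  rep1 <- check_criteria(cand, ds$annotation, rs)
  expect_true(rep1$passed)
  expect_true(all(unlist(rep1[, c("in_one_arm", "duplex_clean", "energy_ok",
                                  "context_ok", "read_stack_ok")])))

  # energy threshold is strict: -19.9 fails, -20.1 passes
  c_lo <- cand; c_lo$fold$energy <- -19.9
  expect_false(check_criteria(c_lo, ds$annotation, rs)$energy_ok)
  c_hi <- cand; c_hi$fold$energy <- -20.1
  expect_true(check_criteria(c_hi, ds$annotation, rs)$energy_ok)
  expect_false(check_criteria(c_lo, ds$annotation, rs)$passed)

  # failed read stack blocks the conjunction
  rep2 <- check_criteria(cand, ds$annotation, list(ok = FALSE))
  expect_false(rep2$read_stack_ok)
  expect_false(rep2$passed)
})

test_that("read-stack consistency accepts coherent isomiR stacks and rejects scatter", {
  set.seed(33)
  w <- list(contig = "c1", start = 0L, end = 222L, strand = "+")
  cand <- list(window = w, mature_span = c(101L, 122L), star_span = c(140L, 161L))
  mk_hits <- function(starts, lens, pooled) {
    data.table::data.table(start = starts, end = starts + lens, pooled = pooled)
  }
  # 50 reads, 80% sharing the modal 5' end (the generator's shift law)
  s5 <- sample(c(-1L, 0L, 1L), 50, replace = TRUE, prob = c(.1, .8, .1))
  hits <- mk_hits(100L + s5, 22L, rep(1, 50))
  ok <- read_stack_consistency(cand, hits)
  expect_true(ok$ok)
  expect_gte(ok$modal5_fraction, 0.7)

  # uniform scatter across the window fails
  scatter <- mk_hits(sample(0:200, 50, replace = TRUE), 22L, rep(1, 50))
  expect_false(read_stack_consistency(cand, scatter)$ok)

  # fewer than 5 reads fails the support minimum
  few <- mk_hits(c(100L, 100L, 100L), 22L, rep(1, 3))
  expect_false(read_stack_consistency(cand, few)$ok)
  # 5 reads is the boundary
  five <- mk_hits(rep(100L, 5), 22L, rep(1, 5))
  expect_true(read_stack_consistency(cand, five)$ok)

  # star reads with an inconsistent modal 5' end fail
  bad_star <- rbind(hits, mk_hits(rep(145L, 10), 16L, rep(1, 10)))
  expect_false(read_stack_consistency(cand, bad_star)$ok)
})

test_that("gene calling recovers planted genes and merges nearby seed tags", {
  ds <- small_dataset()
  run <- small_run()
  tr <- ds$planted
  m <- match_genes_to_truth(run$genes, tr)
  expect_equal(nrow(m), sum(tr$is_exon_control == FALSE))
  # no called gene overlaps an exon-planted control
  ctl <- tr[is_exon_control == TRUE]
  for (i in seq_len(nrow(ctl))) {
    ov <- run$genes[contig == ctl$contig[i] &
                      window_start < ctl$precursor_end[i] &
                      window_end > ctl$precursor_start[i]]
    expect_equal(nrow(ov), 0L)
  }
  # mature- and star-arm tag stacks seeded a single gene per planted locus
  for (i in which(tr$is_exon_control == FALSE)) {
    ov <- run$genes[contig == tr$contig[i] &
                      window_start < tr$precursor_end[i] &
                      window_end > tr$precursor_start[i] &
                      strand == tr$strand[i]]
    expect_equal(nrow(ov), 1L, label = tr$gene_id[i])
  }
})

test_that("discovery is monotone in read support", {
  ds <- small_dataset()
  run <- small_run()
  tags <- data.table::copy(run$tags)
  passed_before <- run$genes$gene_id
  # double every count of tags that belong to called genes
  cols <- grep("^count_", names(tags), value = TRUE)
  boost <- tags$sequence %in% run$genes$mature_seq
  for (cn in cols) tags[boost, (cn) := get(cn) * 2L]
  idx <- build_index(ds$genome)
  hits <- map_all(tags, idx, ds$genome)$hits
  disc <- call_mirna_genes(tags, hits, ds$genome, ds$annotation)
  expect_true(all(passed_before %in% disc$genes$gene_id))
})
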