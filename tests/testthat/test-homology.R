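# Catalog search, Mapmi-style genome scanning, lineage classification and arm
# switch detection.

test_that("catalog search finds identical and near-identical matures, needs a shared 7-mer", {
  set.seed(14)
  catalog <- c(mirA = "TGAGGTAGTAGGTTGTATAGTT",
               mirB = "ACGGTCAGGACTTTCGATCGAT",
               mirC = random_tag(22))
  hit <- catalog_search(catalog[["mirA"]], catalog)
  expect_equal(hit$subject[1], "mirA")
  expect_equal(hit$identities[1], 22L)
  expect_equal(hit$mismatches[1], 0L)

  # two substitutions still found (all-pairs Hamming confirms a close entry)
  q <- catalog[["mirB"]]
  substr(q, 3, 3) <- "T"
  substr(q, 15, 15) <- "A"
  hams <- vapply(catalog, function(s) {
    sum(strsplit(q, "")[[1]] != strsplit(s, "")[[1]])
  }, integer(1))
  expect_equal(names(which.min(hams)), "mirB") # oracle: closest by Hamming
  hit2 <- catalog_search(q, catalog)
  expect_true("mirB" %in% hit2$subject)

  # no shared 7-mer -> no seeds -> empty result
  none <- catalog_search(strrep("AT", 11), c(x = strrep("GC", 11)))
  expect_equal(nrow(none), 0L)
  expect_error(catalog_search("ACGT", character(0)), "empty")
})

test_that("Mapmi-style scores follow 2(L-mm) - 4mm + hairpin bonus with cutoff 35", {
  ds <- small_dataset()
  tr <- ds$planted[is_exon_control == FALSE][1]
  aae <- ds$catalogs$Aae
  # exact 22-nt match at a hairpin-forming locus: S = 2L + 5
  scan <- genome_scan(tr$mature_seq, aae$genome, max_mismatch = 3)
  L <- nchar(tr$mature_seq)
  expect_true(scan$present)
  expect_equal(scan$hits$score[1], 2 * L + 5)

  # 3 mismatches at the same hairpin locus: S = 2(L-3) - 12 + 5, absent at 35
  q3 <- tr$mature_seq
  for (a in c(4L, 9L, 14L)) {
    substr(q3, a, a) <- c(A = "G", C = "T", G = "A", T = "C")[substr(q3, a, a)]
  }
  scan3 <- genome_scan(q3, aae$genome, max_mismatch = 3)
  expect_equal(scan3$hits[mm == 3]$score[1], 2 * (L - 3) - 12 + 5)
  if (nrow(scan3$hits[mm == 3]) == nrow(scan3$hits)) {
    expect_false(scan3$present)
  }

  # exact match at a non-hairpin locus: S = 2L - 20, absent
  flat <- c(m = paste0(strrep("AC", 60), tr$mature_seq, strrep("AG", 60)))
  scan_flat <- genome_scan(tr$mature_seq, flat, max_mismatch = 1)
  expect_equal(scan_flat$hits$score[1], 2 * L - 20)
  expect_false(scan_flat$present)

  # absent sequences yield no hits at all
  expect_false(genome_scan(random_tag(22), aae$genome, max_mismatch = 3)$present)
})

test_that("1-mismatch scan hits are a subset of 3-mismatch hits", {
  ds <- small_dataset()
  tr <- ds$planted
  for (i in seq_len(min(4, nrow(tr)))) {
    h1 <- genome_scan(tr$mature_seq[i], ds$catalogs$Aae$genome,
                      max_mismatch = 1)$hits
    h3 <- genome_scan(tr$mature_seq[i], ds$catalogs$Aae$genome,
                      max_mismatch = 3)$hits
    if (nrow(h1)) {
      key1 <- paste(h1$contig, h1$start, h1$strand)
      key3 <- paste(h3$contig, h3$start, h3$strand)
      expect_true(all(key1 %in% key3))
    }
  }
})

test_that("lineage labels partition the space of presence maps", {
  species <- c("Aal", "Aae", "Cqu", "Aga", "Dmel")
  labels <- character(0)
  for (mask in 0:31) {
    p <- stats::setNames(as.logical(bitwAnd(mask, 2^(0:4))), species)
    lab <- suppressWarnings(classify_lineage(p)$label)
    expect_length(lab, 1L)
    labels <- c(labels, lab)
  }
  expect_setequal(unique(labels),
                  c("conserved_beyond_mosquitoes", "mosquito_specific",
                    "culicinae_specific", "aedes_specific", "species_specific"))
  # the published footnote patterns
  expect_equal(classify_lineage(c(Aal = TRUE, Aae = TRUE, Cqu = FALSE,
                                  Aga = FALSE, Dmel = FALSE))$label,
               "aedes_specific")
  expect_equal(classify_lineage(c(Aal = TRUE, Aae = TRUE, Cqu = TRUE,
                                  Aga = FALSE, Dmel = FALSE))$label,
               "culicinae_specific")
  expect_equal(classify_lineage(c(Aal = TRUE, Aae = TRUE, Cqu = TRUE,
                                  Aga = TRUE, Dmel = TRUE))$label,
               "conserved_beyond_mosquitoes")
  # Aedes + Anopheles without Culex is inconsistent with mosquito phylogeny
  expect_warning(classify_lineage(c(Aal = TRUE, Aae = TRUE, Cqu = FALSE,
                                    Aga = TRUE, Dmel = FALSE)),
                 "inconsistent")
  expect_error(classify_lineage(c(Aal = TRUE)), "missing species")
})

test_that("arm switches are detected against the planted switched mock", {
  ds <- small_dataset()
  run <- small_run()
  switched <- ds$catalogs$Cqu$catalog[arm_switched == TRUE]
  expect_equal(nrow(switched), 1L)
  g <- run$genes[mature_seq %in% ds$planted[gene_id == switched$gene_id,
                                            mature_seq]]
  expect_equal(nrow(g), 1L)
  expect_true(detect_arm_switch(g, switched))
  # a same-arm record is not a switch
  normal <- ds$catalogs$Cqu$catalog[arm_switched == FALSE][1]
  g2 <- run$genes[mature_seq %in% ds$planted[gene_id == normal$gene_id,
                                             mature_seq]]
  if (nrow(g2) == 1L) expect_false(detect_arm_switch(g2, normal))
  # the full classification flags exactly the switched gene
  hom <- run$homology
  expect_equal(hom[arm_switch == TRUE, gene_id], g$gene_id)
})

test_that("lineage recovery on synthetic data is exact", {
  ds <- small_dataset()
  run <- small_run()
  m <- match_genes_to_truth(run$genes, ds$planted)
  hm <- merge(run$homology, m[, list(gene_id, lineage_truth)], by = "gene_id")
  expect_equal(hm$lineage, unname(lineage_label_map[hm$lineage_truth]))
})
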