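# Orchestration: a single configuration object holding every pipeline
# constant (each analysis default appears exactly once, here), a staged
# runner, and a run manifest for reproducibility.

#' Pipeline configuration
#'
#' Every stage threshold lives here and nowhere else: 100-nt flanks, the
#' 18-30 nt tag range, one-mismatch mapping, the strict -20 kcal/mol hairpin
#' energy threshold, the 15-read expression gate, the Mapmi-style presence
#' cutoff 35, the target score cutoff 150, FDR 0.01 and the 5-cluster cut.
#'
#' @param flank precursor window flank (nt).
#' @param min_len,max_len tag length selection bounds (nt).
#' @param max_mm_map mismatches allowed in genome mapping.
#' @param energy_threshold hairpin free-energy threshold (kcal/mol, strict).
#' @param min_seed_reads pooled reads needed to seed a discovery candidate.
#' @param expr_min_reads pooled reads needed for a gene to count as expressed.
#' @param mapmi_cutoff homologue presence score cutoff.
#' @param target_cutoff duplex score cutoff for target sites.
#' @param fdr GO enrichment false-discovery rate.
#' @param k_clusters number of expression clusters.
#' @param min_qual minimum insert base quality in preprocessing.
#' @param seed master seed for stochastic stages.
#' @return a list of class `mosmir_config`.
#' @export
pipeline_config <- function(flank = 100L, min_len = 18L, max_len = 30L,
                            max_mm_map = 1L, energy_threshold = -20.0,
                            min_seed_reads = 5L, expr_min_reads = 15L,
                            mapmi_cutoff = 35, target_cutoff = 150,
                            fdr = 0.01, k_clusters = 5L, min_qual = 10L,
                            seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "mosmir_config"
  cfg
}

#' Run the full analysis pipeline on a dataset
#'
#' Stages: preprocess -> map -> discover -> homology -> expression ->
#' targets/GO. The input is a dataset list as produced by
#' [simulate_dataset()] (or assembled from files with the same fields); all
#' stage outputs are returned and, when `out_dir` is given, written as TSV /
#' GFF3 / dot-bracket artifacts together with a JSON run manifest.
#'
#' @param dataset list with `genome`, `annotation`, `fastq_paths`, and
#'   optionally `catalogs` and `go_map`.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @param adapter3 3' adapter sequence used in preprocessing.
#' @return list with `tags`, `size_dist`, `hits`, `genes`, `reports`,
#'   `homology`, `expression`, `clusters`, `targets`, `enrichment`,
#'   `manifest`.
#' @export
run_pipeline <- function(dataset, config = pipeline_config(),
                         out_dir = NULL,
                         adapter3 = "TGGAATTCTCGGGTGCCAAGGAACTCCAGTCAC") {
  t0 <- Sys.time()
  pp <- preprocess_libraries(dataset$fastq_paths, adapter3,
                             dataset$annotation, dataset$genome,
                             min_len = config$min_len, max_len = config$max_len,
                             min_qual = config$min_qual)
  idx <- build_index(dataset$genome)
  mp <- map_all(pp$tags, idx, dataset$genome)
  disc <- call_mirna_genes(pp$tags, mp$hits, dataset$genome,
                           dataset$annotation, flank = config$flank,
                           min_seed_reads = config$min_seed_reads,
                           energy_threshold = config$energy_threshold)
  genes <- disc$genes

  hom <- NULL
  if (!is.null(dataset$catalogs) && nrow(genes) > 0L) {
    hom <- classify_genes(genes, dataset$catalogs, cutoff = config$mapmi_cutoff)
    genes <- merge(genes, hom[, .(gene_id, lineage)], by = "gene_id",
                   all.x = TRUE, sort = FALSE)
  }

  counts <- count_reads(genes, mp$hits, pp$tags)
  expressed <- filter_expressed(counts, min_reads = config$expr_min_reads)
  expr <- normalize_cpm(expressed)
  clusters <- NULL
  if (nrow(expr) >= config$k_clusters) {
    cl <- cluster_profiles(expr, k = config$k_clusters)
    spec <- stage_specificity(expr)
    clusters <- merge(cl$assignment, spec, by = "row_id")
  }

  targets <- NULL
  enrichment <- NULL
  if (!is.null(dataset$go_map) && nrow(genes) > 0L) {
    utrs <- get_utr_sequences(dataset$genome, dataset$annotation)
    targets <- predict_targets(genes, utrs, cutoff = config$target_cutoff)
    background <- names(utrs)
    if (!is.null(clusters) && nrow(targets) > 0L) {
      cl_of_gene <- clusters[grepl(":mature$", row_id)]
      cl_of_gene[, gene_id := sub(":mature$", "", row_id)]
      per_cluster <- lapply(sort(unique(cl_of_gene$cluster)), function(k) {
        gids <- cl_of_gene[cluster == k, gene_id]
        tt <- unique(targets[mirna_id %in% gids, transcript_id])
        res <- go_enrichment(tt, dataset$go_map, background, fdr = config$fdr)
        if (nrow(res)) res[, cluster := k]
        res
      })
      enrichment <- rbindlist(per_cluster, fill = TRUE)
    } else {
      enrichment <- go_enrichment(unique(targets$transcript_id),
                                  dataset$go_map, background,
                                  fdr = config$fdr)
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("mosmir")),
    seed = config$seed,
    parameters = unclass(config),
    n_tags = nrow(pp$tags), n_hits = nrow(mp$hits),
    n_candidates = nrow(disc$reports), n_genes = nrow(genes),
    started = format(t0, "%Y-%m-%dT%H:%M:%S"),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  res <- list(tags = pp$tags, size_dist = pp$size_dist,
              accounting = pp$accounting, hits = mp$hits, genes = genes,
              reports = disc$reports, homology = hom, expression = expr,
              counts = counts, clusters = clusters, targets = targets,
              enrichment = enrichment, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fwrite(disc$reports, file.path(out_dir, "candidates.tsv"), sep = "\t")
    if (nrow(genes)) {
      write_mirna_gff3(genes, file.path(out_dir, "genes.gff3"))
      recs <- lapply(seq_len(nrow(genes)), function(i) {
        list(id = genes$gene_id[i], sequence = genes$precursor_seq[i],
             structure = genes$structure[i], energy = genes$energy[i])
      })
      write_dotbracket(recs, file.path(out_dir, "precursors.dotbracket"))
    }
    fwrite(expr, file.path(out_dir, "expression.tsv"), sep = "\t")
    if (!is.null(clusters)) {
      fwrite(clusters, file.path(out_dir, "clusters.tsv"), sep = "\t")
    }
    if (!is.null(hom)) fwrite(hom, file.path(out_dir, "homology.tsv"), sep = "\t")
    if (!is.null(targets)) {
      fwrite(targets, file.path(out_dir, "targets.tsv"), sep = "\t")
    }
    if (!is.null(enrichment) && nrow(enrichment)) {
      fwrite(enrichment, file.path(out_dir, "enrichment.tsv"), sep = "\t")
    }
    writeLines(yaml::as.yaml(manifest), file.path(out_dir, "manifest.yaml"))
  }
  res
}

#' Read / write a simulation configuration as YAML
#'
#' @param path YAML file.
#' @return for the reader, a [sim_config()]; the writer returns the path.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  for (nm in c("p5_shift", "p3_shift")) {
    if (!is.null(vals[[nm]])) vals[[nm]] <- unlist(vals[[nm]])
  }
  do.call(sim_config, vals)
}

#' @rdname read_sim_config
#' @param config a [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  vals <- unclass(config)
  for (nm in c("p5_shift", "p3_shift")) {
    vals[[nm]] <- as.list(vals[[nm]]) # keep shift names as YAML map keys
  }
  writeLines(yaml::as.yaml(vals), path)
  invisible(path)
}
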