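# Expression quantification: isomiR-tolerant read counting per miRNA/miRNA*
# arm, the 15-read expression gate, counts-per-million normalisation by the
# exact formula raw / column_total * 1e6, hierarchical clustering of stage
# profiles (1 - Pearson correlation, average linkage) and stage-specificity
# labels.

#' Count reads per miRNA / miRNA* arm across the six samples
#'
#' A tag counts toward an arm when its hit lies on the same contig and
#' strand, its 5' end is within `tol5` nt and its 3' end within `tol3` nt of
#' the annotated span (isomiR tolerance). Tags hitting several gene copies
#' count fully at each (flagged multimapped). When one hit satisfies both the
#' mature and the star of a gene, it is assigned to the nearer 5' end.
#'
#' @param genes gene table from [call_mirna_genes()].
#' @param hits hits table from [map_all()].
#' @param tags collapsed tag table (provides the `count_*` columns).
#' @param tol5,tol3 end tolerances (defaults 2 and 5 nt).
#' @return `data.table` with `row_id` (`<gene>:mature` / `<gene>:star`),
#'   `gene_id`, `arm_role`, one `count_<sample>` column per sample and a
#'   `multimapped` flag.
#' @export
count_reads <- function(genes, hits, tags, tol5 = 2L, tol3 = 5L) {
  cols <- grep("^count_", names(tags), value = TRUE)
  arms <- rbind(
    data.table(gene_id = genes$gene_id, arm_role = "mature",
               contig = genes$contig, strand = genes$strand,
               a_start = genes$mature_g_start, a_end = genes$mature_g_end),
    data.table(gene_id = genes$gene_id, arm_role = "star",
               contig = genes$contig, strand = genes$strand,
               a_start = genes$star_g_start, a_end = genes$star_g_end))
  arms <- arms[!is.na(a_start)]
  out_rows <- data.table(row_id = paste0(arms$gene_id, ":", arms$arm_role),
                         gene_id = arms$gene_id, arm_role = arms$arm_role)
  for (cn in cols) out_rows[, (cn) := 0L]
  out_rows[, multimapped := FALSE]
  if (nrow(hits) == 0L || nrow(arms) == 0L) return(out_rows)

  h <- merge(hits, tags[, c("sequence", cols), with = FALSE], by = "sequence")
  # 5'/3' genomic ends by strand
  h[, `:=`(five_p = ifelse(strand == "+", start, end - 1L),
           three_p = ifelse(strand == "+", end - 1L, start))]
  arms[, `:=`(arm5 = ifelse(strand == "+", a_start, a_end - 1L),
              arm3 = ifelse(strand == "+", a_end - 1L, a_start))]
  j <- arms[h, on = .(contig, strand), allow.cartesian = TRUE, nomatch = NULL]
  j <- j[abs(five_p - arm5) <= tol5 & abs(three_p - arm3) <= tol3]
  if (nrow(j) == 0L) return(out_rows)
  # one assignment per (hit, gene): nearer 5' end wins on mature/star overlap
  j[, d5 := abs(five_p - arm5)]
  setorder(j, d5, arm_role)
  j <- unique(j, by = c("sequence", "contig", "start", "strand", "gene_id"))
  j[, multi := data.table::uniqueN(paste(gene_id, arm_role)) > 1L, by = sequence]
  agg <- j[, c(lapply(.SD, sum), list(multimapped = any(multi))),
           by = .(gene_id, arm_role), .SDcols = cols]
  agg[, row_id := paste0(gene_id, ":", arm_role)]
  out <- merge(out_rows[, .(row_id, gene_id, arm_role)],
               agg[, c("row_id", cols, "multimapped"), with = FALSE],
               by = "row_id", all.x = TRUE)
  for (cn in cols) out[is.na(get(cn)), (cn) := 0L]
  out[is.na(multimapped), multimapped := FALSE]
  out[]
}

#' Apply the 15-read expression gate
#'
#' A gene is retained when either its mature or its star arm has at least
#' `min_reads` reads pooled over the six samples; both rows of a retained
#' gene are kept.
#'
#' @param matrix_dt count table from [count_reads()].
#' @param min_reads pooled-read threshold (default 15).
#' @return the retained rows.
#' @export
filter_expressed <- function(matrix_dt, min_reads = 15L) {
  cols <- grep("^count_", names(matrix_dt), value = TRUE)
  tot <- rowSums(matrix_dt[, cols, with = FALSE])
  per_gene <- matrix_dt[, .(max_arm = max(tapply(tot[.I], arm_role, sum))),
                        by = gene_id]
  keep_genes <- per_gene[max_arm >= min_reads, gene_id]
  matrix_dt[gene_id %in% keep_genes]
}

#' Counts-per-million normalisation
#'
#' `cpm = raw / column_total * 1e6`, computed against the column totals of
#' the table given (so normalising the pre-gate table makes every column sum
#' to exactly one million).
#'
#' @param matrix_dt count table.
#' @return the table with added `cpm_<sample>` columns.
#' @export
normalize_cpm <- function(matrix_dt) {
  cols <- grep("^count_", names(matrix_dt), value = TRUE)
  out <- data.table::copy(matrix_dt)
  for (cn in cols) {
    tot <- sum(out[[cn]])
    if (tot == 0) stop("normalize_cpm: zero column sum in ", cn)
    out[, (sub("^count_", "cpm_", cn)) := get(cn) / tot * 1e6]
  }
  out[]
}

#' Hierarchical clustering of stage expression profiles
#'
#' Rows are transformed `log2(cpm + 1)`; the distance is `1 - Pearson
#' correlation` across the six samples (rows with zero variance get distance
#' 1 to everything, with a message); the tree is agglomerative average
#' linkage cut to exactly `k` clusters.
#'
#' @param matrix_dt table with `cpm_*` columns (see [normalize_cpm()]).
#' @param k number of clusters (default 5).
#' @return list with `assignment` (`data.table`: row_id, cluster) and `tree`
#'   (the `hclust` object).
#' @export
cluster_profiles <- function(matrix_dt, k = 5L) {
  cols <- grep("^cpm_", names(matrix_dt), value = TRUE)
  if (nrow(matrix_dt) < k) stop("cluster_profiles: fewer rows than clusters")
  m <- log2(as.matrix(matrix_dt[, cols, with = FALSE]) + 1)
  rownames(m) <- matrix_dt$row_id
  v <- apply(m, 1, stats::var)
  cc <- suppressWarnings(stats::cor(t(m)))
  cc[is.na(cc)] <- 0
  if (any(v == 0)) {
    message("cluster_profiles: ", sum(v == 0),
            " zero-variance rows assigned distance 1 to all others")
  }
  d <- 1 - cc
  diag(d) <- 0
  tree <- stats::hclust(stats::as.dist(d), method = "average")
  cl <- stats::cutree(tree, k = k)
  list(assignment = data.table(row_id = rownames(m), cluster = unname(cl)),
       tree = tree)
}

#' Stage-specificity and blood-meal response labels
#'
#' A row is labelled with the sample holding at least half of its total CPM
#' ("shared" otherwise, "none" for all-zero rows). The blood-meal flag is
#' "up" when the blood-fed CPM is at least `fold` times the sugar-fed CPM,
#' "down" for the reverse, both requiring the larger value to reach
#' `min_cpm`.
#'
#' @param matrix_dt table with `cpm_*` columns.
#' @param fold blood/sugar fold-change threshold (default 2).
#' @param min_cpm minimum CPM for a blood flag (default 10).
#' @return `data.table`: row_id, specificity, blood_response.
#' @export
stage_specificity <- function(matrix_dt, fold = 2, min_cpm = 10) {
  cols <- grep("^cpm_", names(matrix_dt), value = TRUE)
  samples <- sub("^cpm_", "", cols)
  m <- as.matrix(matrix_dt[, cols, with = FALSE])
  tot <- rowSums(m)
  frac <- m / ifelse(tot == 0, 1, tot)
  top <- max.col(frac, ties.method = "first")
  spec <- ifelse(tot == 0, "none",
                 ifelse(frac[cbind(seq_len(nrow(m)), top)] >= 0.5,
                        samples[top], "shared"))
  Fv <- m[, which(samples == "F")]
  Bv <- m[, which(samples == "B")]
  blood <- ifelse(Bv >= fold * Fv & Bv >= min_cpm, "up",
                  ifelse(Fv >= fold * Bv & Fv >= min_cpm, "down", "none"))
  data.table(row_id = matrix_dt$row_id, specificity = spec,
             blood_response = blood)
}
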