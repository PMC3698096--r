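#!/usr/bin/env Rscript
# Stage 5: count reads per miRNA/miRNA* with isomiR tolerance, apply the
# 15-read expression gate, normalise to counts per million, cluster stage
# profiles (1 - Pearson, average linkage, k = 5) and label stage specificity
# and blood-meal response.

suppressPackageStartupMessages({library(mosmir); library(data.table)})

ds <- readRDS("results/dataset.rds")
pp <- readRDS("results/preprocess.rds")
dd <- readRDS("results/discovery.rds")
genes <- readRDS("results/genes_classified.rds")

counts <- count_reads(genes, dd$hits, pp$tags)
expressed <- filter_expressed(counts)
expr <- normalize_cpm(expressed)
cl <- cluster_profiles(expr, k = 5)
spec <- stage_specificity(expr)
clusters <- merge(cl$assignment, spec, by = "row_id")
fwrite(expr, "results/expression.tsv", sep = "\t")
fwrite(clusters, "results/clusters.tsv", sep = "\t")
saveRDS(list(expr = expr, clusters = clusters), "results/expression.rds")

cat(sprintf("%d of %d miRNA/miRNA* rows pass the 15-read gate\n",
            nrow(expressed), nrow(counts)))
print(clusters[, .N, by = cluster])
print(clusters[, .N, by = specificity])
print(clusters[blood_response != "none", .N, by = blood_response])

tr <- ds$planted
cm <- merge(clusters[grepl(":mature$", row_id)][, gene_id := sub(":mature$", "", row_id)],
            merge(genes[, .(gene_id, contig, mature_seq)],
                  tr[, .(contig, mature_seq, template)],
                  by = c("contig", "mature_seq")), by = "gene_id")
tab <- table(cm$cluster, cm$template)
cat("cluster x planted-template contingency:\n")
print(tab)
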