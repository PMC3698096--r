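# Shared simulated datasets, built once per test run and cached. The small
# dataset drives unit tests; the default-scale dataset reproduces the study
# conditions (six libraries of 100k reads, 40 planted genes, seed 42) for
# the dataset-level checks.

.fixture_cache <- new.env(parent = emptyenv())

small_sim_config <- function(seed = 7) {
  sim_config(seed = seed, n_contigs = 1, contig_length = 60000, n_planted = 8,
             n_exon_controls = 1, reads_per_library = 4000,
             n_transcripts = 20, n_repeats = 4, n_targeted = 6,
             n_regulators = 3)
}

small_dataset <- function() {
  if (is.null(.fixture_cache$small)) {
    .fixture_cache$small <- simulate_dataset(small_sim_config(),
                                             out_dir = tempfile("smallsim"))
  }
  .fixture_cache$small
}

small_run <- function() {
  if (is.null(.fixture_cache$small_run)) {
    .fixture_cache$small_run <- run_pipeline(small_dataset(), pipeline_config())
  }
  .fixture_cache$small_run
}

default_dataset <- function() {
  if (is.null(.fixture_cache$default)) {
    .fixture_cache$default <- simulate_dataset(sim_config(),
                                               out_dir = tempfile("defaultsim"))
  }
  .fixture_cache$default
}

default_run <- function() {
  if (is.null(.fixture_cache$default_run)) {
    .fixture_cache$default_run <- run_pipeline(default_dataset(),
                                               pipeline_config())
  }
  .fixture_cache$default_run
}

# recovered genes joined with the planted truth manifest
match_genes_to_truth <- function(genes, truth) {
  merge(genes,
        truth[, list(contig, mature_seq, gene_id_true = gene_id,
                     lineage_truth, template, is_exon_control)],
        by = c("contig", "mature_seq"))
}

lineage_label_map <- c(conserved = "conserved_beyond_mosquitoes",
                       mosquito = "mosquito_specific",
                       culicinae = "culicinae_specific",
                       aedes = "aedes_specific")
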