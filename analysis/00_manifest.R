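# Shared path bookkeeping for the numbered analysis scripts: the input
# bundle written by 01_simulate.R and the manifest handed to the pipeline
# stages. Source this from the other scripts.

bundle_dir <- "results/synthetic_bundle"
results_dir <- "results"
dir.create(results_dir, showWarnings = FALSE, recursive = TRUE)

manifest <- list(
  enhancers = file.path(bundle_dir, sprintf("enhancers_source%d.bed", 1:3)),
  genes = file.path(bundle_dir, "genes.tsv"),
  lncrnas = file.path(bundle_dir, "lncrnas.tsv"),
  blacklist = file.path(bundle_dir, "blacklist.bed"),
  chrom_lengths = file.path(bundle_dir, "chrom_lengths.tsv"),
  counts = file.path(bundle_dir, "counts.tsv"),
  library_sizes = file.path(bundle_dir, "library_sizes.tsv"),
  metadata = file.path(bundle_dir, "metadata.tsv"),
  tf_list = file.path(bundle_dir, "tf_list.tsv"),
  hic = file.path(bundle_dir, "hic_oe.tsv"),
  cell_counts = file.path(bundle_dir, "cell_counts.tsv"),
  cell_library_sizes = file.path(bundle_dir, "cell_library_sizes.tsv"),
  auc = file.path(bundle_dir, "auc.tsv"),
  pathways = file.path(bundle_dir, "pathways.tsv"),
  drug_pathways = file.path(bundle_dir, "drug_pathways.tsv"))

pipeline_seed <- 1L
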