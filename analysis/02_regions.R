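#!/usr/bin/env Rscript
# Build eRNA regions: consensus enhancers supported by >= 2 annotation
# sources, +/- 3 kb regions around their midpoints, then removal of every
# region touching the exclusion mask (gene/lncRNA bodies extended 1 kb past
# TSS and TES, the 500 bp uaRNA window upstream of the extended TSS, and
# blacklist intervals).

suppressMessages(library(ernascape))
source("analysis/00_manifest.R")

config <- pipeline_config(seed = pipeline_seed)
res <- run_pipeline(manifest, results_dir, config, stages = "regions")

cat(sprintf("consensus enhancers surviving the mask: %d regions (%d dropped)\n",
            nrow(res$regions), nrow(res$dropped)))
if (nrow(res$dropped)) {
  cat("drop reasons:\n")
  print(table(res$dropped$reason))
}
cat("wrote erna_regions.tsv / erna_regions.bed / region_drop_audit.tsv\n")
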