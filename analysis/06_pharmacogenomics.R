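#!/usr/bin/env Rscript
# Correlate eRNA expression across the cell-line panel with drug-response
# AUC (higher AUC = more resistant): significant negative correlations are
# "sensitive", positive "resistant", and each association is classified as
# within- or cross-pathway via the eRNA's putative target genes.

suppressMessages(library(ernascape))
source("analysis/00_manifest.R")

config <- pipeline_config(seed = pipeline_seed)
res <- run_pipeline(manifest, results_dir, config,
                    stages = c("regions", "quantify", "network", "pharmaco"))

da <- res$drug_associations
cat(sprintf("associations tested: %d (eRNA x drug)\n", nrow(da)))
print(table(direction = da$direction))
print(table(pathway_relation = da$pathway_relation[da$direction != "none"]))
truth <- utils::read.delim(file.path(bundle_dir, "truth_drug.tsv"))
got <- da$direction[match(paste(truth$erna_id, truth$drug_id),
                          paste(da$erna_id, da$drug_id))]
cat(sprintf("planted drug effects with correct direction: %d/%d\n",
            sum(got == truth$expected_direction), nrow(truth)))
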