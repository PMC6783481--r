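#!/usr/bin/env Rscript
# Infer putative TF regulators of eRNAs per cohort (Spearman Rs >= 0.3,
# BH-FDR < 0.05 over all TF x eRNA tests within the cohort), flag master
# regulators (correlated with >= 25% of the cohort's detectable eRNAs) and
# general masters (master in >= 10 cancer types; with three synthetic
# cohorts that bar is deliberately out of reach).

suppressMessages(library(ernascape))
source("analysis/00_manifest.R")

config <- pipeline_config(seed = pipeline_seed)
res <- run_pipeline(manifest, results_dir, config,
                    stages = c("regions", "quantify", "regulators"))

cat(sprintf("regulator edges: %d across %d cohorts\n",
            nrow(res$regulator_edges),
            length(unique(res$regulator_edges$cohort))))
masters <- res$master_profiles[res$master_profiles$is_master, ]
cat("master regulators (TF x cohort):\n")
print(masters[, c("tf_id", "cohort", "fraction")], row.names = FALSE)
truth <- utils::read.delim(file.path(bundle_dir, "truth_master.tsv"))
cat(sprintf("planted master TF %s recovered in %d/%d cohorts\n",
            truth$tf_id[1], sum(masters$tf_id == truth$tf_id[1]),
            length(unique(res$regulator_edges$cohort))))
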