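#!/usr/bin/env Rscript
# Clinical relevance of eRNAs: paired tumor/normal differential expression
# (|fold change| >= 1.5 at BH-FDR < 0.05, cohorts with >= 5 pairs),
# group tests on subtype/stage/grade/smoking (groups >= 5; Welch t for two
# groups, ANOVA beyond), Cox survival association, and the summary flag
# (relevant = significant in >= 1 clinical category).

suppressMessages(library(ernascape))
source("analysis/00_manifest.R")

config <- pipeline_config(seed = pipeline_seed)
res <- run_pipeline(manifest, results_dir, config,
                    stages = c("regions", "quantify", "clinical"))

de <- res$differential
cat("differential expression calls by cohort:\n")
print(table(de$cohort, de$call))
truth <- utils::read.delim(file.path(bundle_dir, "truth_de.tsv"))
up <- tapply(de$call[de$erna_id %in% truth$erna_id] == "up",
             de$cohort[de$erna_id %in% truth$erna_id], mean)
cat("fraction of planted fold changes called up, per cohort:\n")
print(round(up, 3))
cat("clinical associations by feature (q < 0.05):\n")
sig <- res$clinical$per_cohort
print(table(sig$feature))
cat(sprintf("clinically relevant eRNAs: %d of %d (%.1f%%)\n",
            sum(res$clinical$per_erna$relevant),
            nrow(res$clinical$per_erna),
            100 * mean(res$clinical$per_erna$relevant)))
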