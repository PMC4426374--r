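#!/usr/bin/env Rscript
# Stage 2: marker quality control. Markers are kept when their
# proportion of missing values is below 0.90 in every subpopulation
# panel, then constant and collinear (|r| >= 0.999) variables are
# removed (keeping the better-observed member of each collinear pair),
# and finally markers with observed MAF < 0.05 are discarded.
#
# Reads:  results/data/{genotypes.tsv, truth.json}
# Writes: results/qc/{genotypes_qc.tsv, qc_dropped.tsv, qc_summary.json}

suppressPackageStartupMessages(library(migwas))
dir.create("results/qc", showWarnings = FALSE, recursive = TRUE)

X0 <- read_dosage_tsv("results/data/genotypes.tsv")
truth <- jsonlite::read_json("results/data/truth.json", simplifyVector = TRUE)

res <- run_qc(X0, groups = truth$subpop, maf_subset = rownames(X0))
write_dosage_tsv(res$X, "results/qc/genotypes_qc.tsv")
write.table(res$report$dropped, "results/qc/qc_dropped.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(n_in = res$report$n_input, n_kept = length(res$report$kept),
       dropped_by_reason = as.list(table(res$report$dropped$reason)),
       thresholds = res$report$thresholds),
  "results/qc/qc_summary.json", auto_unbox = TRUE)

print(res$report)
cat(sprintf("  kept %d of %d markers; mean PMV of kept markers %.1f%%\n",
            length(res$report$kept), res$report$n_input,
            100 * mean(colMeans(is.na(res$X)))))
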