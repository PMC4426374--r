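#!/usr/bin/env Rscript
# Stage 5: single-marker mixed-model association under the four
# schemes, with one PC and the realized relationship matrix as
# confounder controls (P3D: variance components estimated once under
# the null, the ratio then fixed for all marker tests):
#   CC  - complete cases per marker, structure from the AD matrix
#   AD  - average dosages, structure from the AD matrix
#   MI  - each impute, structure fixed; pooled by Rubin's rules
#   MI* - each impute with its own structure/kinship; pooled
# Pooled scans carry the gamma fraction of missing information; all
# scans get Storey q-values (FDR).
#
# Reads:  results/{data,qc,impute}/*
# Writes: results/assoc/{<trait>_<scheme>.tsv, scan_summary.tsv}

suppressPackageStartupMessages(library(migwas))
dir.create("results/assoc", showWarnings = FALSE, recursive = TRUE)

X <- read_dosage_tsv("results/qc/genotypes_qc.tsv")
traits <- read_trait_tsv("results/data/traits.tsv")
Xbar <- local({
  df <- read.delim("results/impute/average_dosage.tsv", check.names = FALSE)
  m <- as.matrix(df[, -1]); rownames(m) <- df$id; m
})
imputes <- lapply(list.files("results/impute", "impute_\\d+\\.tsv",
                             full.names = TRUE), read_dosage_tsv)

t_pc <- 1
Qbar <- pca_scores(Xbar, t_pc)$Q
Kbar <- kinship(Xbar)
structures <- mistar_structures(imputes, t_pc)
n <- nrow(X)

summary_rows <- NULL
for (tr in colnames(traits)) {
  g <- traits[, tr]
  vc <- fit_null(g, Qbar, Kbar)
  for (scheme in c("cc", "ad", "mi", "mistar")) {
    res <- run_scheme(scheme, g, X = X, Xbar = Xbar, S = imputes,
                      Q = Qbar, K = Kbar, t = t_pc,
                      structures = structures, vc = vc)
    if (scheme %in% c("mi", "mistar")) {
      res <- pool_scheme(res, n = n, t = t_pc)
      pcol <- "p_value"
    } else pcol <- "p"
    ok <- !is.na(res[[pcol]])
    res$q_value <- NA_real_
    res$q_value[ok] <- qvalues(res[[pcol]][ok])$qvalues
    out <- sprintf("results/assoc/%s_%s.tsv", tr, scheme)
    write.table(res, out, sep = "\t", quote = FALSE, row.names = FALSE)
    summary_rows <- rbind(summary_rows, data.frame(
      trait = tr, scheme = scheme,
      n_tests = sum(ok),
      min_p = signif(min(res[[pcol]], na.rm = TRUE), 3),
      n_fdr10 = sum(res$q_value < 0.1, na.rm = TRUE)))
  }
  cat(sprintf("%s: sigma2_u = %.2f, sigma2_e = %.2f\n",
              tr, vc$sigma2_u, vc$sigma2_e))
}
write.table(summary_rows, "results/assoc/scan_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nDetections at FDR < 0.1 by trait and scheme:\n")
print(summary_rows, row.names = FALSE)
cat(sprintf("\nBonferroni per-test threshold at alpha = 0.05, %d markers: %.3g\n",
            ncol(X), bonferroni_threshold(0.05, ncol(X))))
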