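#!/usr/bin/env Rscript
# Stage 6: imputation-uncertainty diagnostics over the association
# scans:
#   * regression of complete-case on average-dosage effects (bias
#     check; slope 1 means the imputation introduced no systematic
#     bias, residual variance inflates in the gamma > 0.2 stratum)
#   * regression of AD on pooled MI effects with a gamma interaction
#     (b3 > 0 is the shrinkage of uncertain effects toward zero)
#   * the arcsin(gamma) factor model on PMV, MAF and average mutual
#     information, with 10-fold cross-validation
#   * significance differentials CC -> MI* by gamma stratum
#   * pairwise r2 (LD proxy) among the most significant markers
#
# Reads:  results/{qc,impute,assoc}/*
# Writes: results/diagnostics/*.tsv

suppressPackageStartupMessages(library(migwas))
dir.create("results/diagnostics", showWarnings = FALSE, recursive = TRUE)

X <- read_dosage_tsv("results/qc/genotypes_qc.tsv")
Xbar <- local({
  df <- read.delim("results/impute/average_dosage.tsv", check.names = FALSE)
  m <- as.matrix(df[, -1]); rownames(m) <- df$id; m
})
traits <- sub("_cc\\.tsv$", "",
              basename(list.files("results/assoc", "_cc\\.tsv$")))

read_scan <- function(tr, scheme) {
  read.delim(sprintf("results/assoc/%s_%s.tsv", tr, scheme))
}
pairs <- do.call(rbind, lapply(traits, function(tr) {
  cc <- read_scan(tr, "cc"); ad <- read_scan(tr, "ad")
  mi <- read_scan(tr, "mi"); ms <- read_scan(tr, "mistar")
  data.frame(trait = tr, marker_id = cc$marker_id,
             beta_cc = cc$beta, p_cc = cc$p,
             beta_ad = ad$beta, beta_mi = mi$beta_bar,
             gamma_mi = mi$gamma, p_star = ms$p_value,
             gamma_star = ms$gamma)
}))
mi_obs <- mi_matrix(X)
covars <- data.frame(marker_id = colnames(X), pmv = colMeans(is.na(X)),
                     maf = compute_maf(X),
                     ami = rowMeans(mi_obs, na.rm = TRUE))
pairs <- merge(pairs, covars, by = "marker_id", sort = FALSE)

ok <- complete.cases(pairs[, c("beta_cc", "beta_ad", "gamma_star")])
bias <- consistency_regression(pairs$beta_cc[ok], pairs$beta_ad[ok],
                               pairs$gamma_star[ok], "cc_on_ad")
cat("\n-- CC on AD (unbiasedness check) --\n"); print(bias)
print(bias$strata, row.names = FALSE)
write.table(cbind(model = "cc_on_ad", bias$coefficients),
            "results/diagnostics/bias_regression.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(bias$strata, "results/diagnostics/bias_strata.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

ok2 <- complete.cases(pairs[, c("beta_ad", "beta_mi", "gamma_mi")])
shrink <- consistency_regression(pairs$beta_ad[ok2], pairs$beta_mi[ok2],
                                 pairs$gamma_mi[ok2], "ad_on_mi")
cat("\n-- AD on MI with gamma interaction (shrinkage check) --\n")
print(shrink)
write.table(cbind(model = "ad_on_mi", shrink$coefficients),
            "results/diagnostics/shrinkage_regression.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

ok3 <- complete.cases(pairs[, c("gamma_star", "pmv", "maf", "ami")])
fac <- gamma_factor_model(pairs$gamma_star[ok3], pairs$pmv[ok3],
                          pairs$maf[ok3], pairs$ami[ok3], seed = 7)
cat("\n-- arcsin(gamma) on PMV + MAF + AMI --\n"); print(fac)
cat(sprintf("  10-fold CV r2 = %.3f, MSE = %.5f (null %.5f)\n",
            fac$cv_r2, fac$cv_mse, fac$cv_mse_null))
write.table(cbind(model = "gamma_factors", fac$coefficients,
                  cv_r2 = fac$cv_r2, cv_mse = fac$cv_mse),
            "results/diagnostics/gamma_factors.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

ds <- delta_significance(pairs$p_cc, pairs$p_star, pairs$gamma_star)
cat("\n-- Delta(-log10 p) from CC to MI* --\n")
print(ds$summary, row.names = FALSE)
write.table(ds$summary, "results/diagnostics/delta_significance.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

top <- unique(pairs$marker_id[order(pairs$p_star)])[1:6]
ld <- pairwise_r2(Xbar, top)
cat("\n-- pairwise r2 among the 6 most significant markers --\n")
print(round(ld$r2, 2))
write.table(round(ld$r2, 4), "results/diagnostics/top_marker_r2.tsv",
            sep = "\t", quote = FALSE)
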