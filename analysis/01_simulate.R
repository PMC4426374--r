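#!/usr/bin/env Rscript
# Stage 1: generate the synthetic GBS study that the rest of the
# workflow analyses. The panel emulates a structured diversity panel
# genotyped at very low depth: two subpopulations, LD blocks of four
# markers with heterogeneous within-block correlation, per-marker
# missingness averaging 78%, and four polygenic traits with six sparse
# causal markers each.
#
# Writes: results/data/{genotypes.tsv, complete.tsv, traits.tsv,
#         truth.json}

suppressPackageStartupMessages(library(migwas))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 101
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(n_individuals = 250, n_markers = 300, n_subpops = 2,
                  fst = 0.1, ld_block_size = 4,
                  block_r = seq(0.4, 0.95, length.out = 75),
                  pmv_dist = pmv_dist_default(),
                  n_causal = 6,
                  effect_sizes = c(0.6, -0.6, 0.4, -0.4, 0.8, -0.8),
                  var_u = 1, var_e = 1, seed = seed)
pan <- simulate_panel(cfg, n_traits = 4)

write_dosage_tsv(pan$observed, "results/data/genotypes.tsv")
write_dosage_tsv(pan$complete, "results/data/complete.tsv")
write_trait_tsv(pan$traits, "results/data/traits.tsv")
jsonlite::write_json(
  list(seed = seed, subpop = pan$truth$subpop_labels,
       block_id = pan$truth$block_id, causal = pan$causal,
       effect_sizes = cfg$effect_sizes,
       var_u = cfg$var_u, var_e = cfg$var_e),
  "results/data/truth.json", auto_unbox = TRUE)

cat(sprintf("Simulated %d x %d panel (seed %d)\n", cfg$n_individuals,
            cfg$n_markers, seed))
cat(sprintf("  mean per-marker missingness: %.1f%%\n",
            100 * mean(colMeans(is.na(pan$observed)))))
cat(sprintf("  mean observed MAF: %.3f\n",
            mean(compute_maf(pan$observed), na.rm = TRUE)))
cat("  traits:", paste(colnames(pan$traits), collapse = ", "), "\n")
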