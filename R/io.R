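# File formats and pipeline orchestration. The canonical on-disk dosage
# format is tab-separated text: a header row of marker ids, a first
# column of individual ids, and cells in {-1, 0, 1, NA}.

#' Read a dosage matrix from tab-separated text
#'
#' @param path file with a header row of marker ids, first column
#'   (`id`) of individual ids, and cells in \{-1, 0, 1, NA\}.
#' @return numeric matrix (individuals x markers) with a missing mask.
#' @export
read_dosage_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, na.strings = "NA",
                          colClasses = "character")
  ids <- df[[1L]]
  cells <- as.matrix(df[, -1L, drop = FALSE])
  X <- suppressWarnings(matrix(as.numeric(cells), nrow(cells), ncol(cells),
                               dimnames = list(ids, colnames(cells))))
  bad <- which((is.na(X) & !is.na(cells) & cells != "NA") |
                 (!is.na(X) & !(X %in% c(-1, 0, 1))))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(X))
    stopf("invalid dosage cell '%s' at individual '%s', marker '%s' in %s",
          cells[bad[1L]], ids[i[1L]], colnames(X)[i[2L]], path)
  }
  X
}

#' Write a dosage matrix as tab-separated text
#'
#' Canonical formatting: marker ids as columns, individual ids in a
#' leading `id` column, missing cells as `NA`. Round-trips through
#' [read_dosage_tsv()].
#'
#' @param X dosage matrix.
#' @param path output file.
#' @export
write_dosage_tsv <- function(X, path) {
  check_dosages(X)
  df <- data.frame(id = if (is.null(rownames(X))) paste0("ind", seq_len(nrow(X)))
                   else rownames(X),
                   X, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("id", marker_ids(X))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read / write per-genotype trait tables
#'
#' Tab-separated: an `id` column of individual ids and one numeric column
#' per trait (best linear unbiased estimates of genotype values).
#'
#' @param path file path.
#' @return matrix of traits (individuals x traits).
#' @export
read_trait_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  storage.mode(m) <- "double"
  m
}

#' @rdname read_trait_tsv
#' @param traits matrix or data frame of traits with individual rownames.
#' @export
write_trait_tsv <- function(traits, path) {
  df <- data.frame(id = rownames(traits), traits, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Convert a VCF of biallelic diploid SNPs to a dosage matrix
#'
#' Genotypes map as 0/0 to -1, 0/1 or 1/0 to 0, 1/1 to 1, and ./. to
#' missing. Multiallelic records are skipped with a warning; non-diploid
#' calls are an error. Marker ids come from the ID field, or CHROM:POS
#' where ID is missing. VCF import is a convenience; the tab-separated
#' dosage matrix remains the canonical representation.
#'
#' @param path VCF file (uncompressed or gzipped).
#' @return dosage matrix (individuals x markers).
#' @export
vcf_to_dosage <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stopf("package 'vcfR' is required for VCF import")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(v)
  if (any(!bi)) {
    warning(sprintf("skipping %d multiallelic record(s)", sum(!bi)))
    v <- v[bi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- v@fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(v@fix[noid, "CHROM"], ":", v@fix[noid, "POS"])
  core <- gsub("\\|", "/", gt)
  map <- c("0/0" = -1, "0/1" = 0, "1/0" = 0, "1/1" = 1, "./." = NA)
  known <- is.na(core) | core %in% names(map)
  if (any(!known)) {
    stopf("non-diploid or unsupported genotype '%s' in %s",
          core[!known][1L], path)
  }
  X <- matrix(map[core], nrow = nrow(gt),
              dimnames = list(ids, colnames(gt)))
  X[is.na(core)] <- NA
  t(X)
}

#' Read and validate a pipeline configuration
#'
#' A single YAML (or JSON) document holding paths, QC thresholds,
#' imputation parameters, association settings, pooling parameters, and
#' the master seed; defaults fill anything omitted. Validation happens
#' before any compute.
#'
#' @param path configuration file.
#' @return validated named list (class `pipeline_config`).
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  as_pipeline_config(raw)
}

#' @rdname read_pipeline_config
#' @param config a named list of settings (as from YAML).
#' @export
as_pipeline_config <- function(config) {
  defaults <- list(genotypes = NULL, phenotypes = NULL, out_dir = "results",
                   panels = NULL,
                   pmv_max = 0.90, r_max = 0.999, var_eps = 1e-12,
                   maf_min = 0.05,
                   m = 20, L = 10, qsel = 500, min_leaf = 5,
                   schemes = c("cc", "ad", "mi", "mistar"), t = 1,
                   fdr_level = 0.1, seed = 1)
  cfg <- utils::modifyList(defaults, config[!vapply(config, is.null, TRUE)])
  if (is.null(cfg$genotypes) || is.null(cfg$phenotypes)) {
    stopf("config must name 'genotypes' and 'phenotypes' files")
  }
  for (f in c("genotypes", "phenotypes")) {
    if (!file.exists(cfg[[f]])) stopf("%s file not found: %s", f, cfg[[f]])
  }
  if (!(cfg$pmv_max > 0 && cfg$pmv_max <= 1)) stopf("pmv_max out of range")
  if (!all(cfg$schemes %in% c("cc", "ad", "mi", "mistar"))) {
    stopf("unknown scheme in config")
  }
  if (!is_count(cfg$m) || cfg$m < 1) stopf("m must be a positive count")
  if (!is_count(cfg$L) || cfg$L < 1) stopf("L must be a positive count")
  if (!is_count(cfg$t)) stopf("t must be a count")
  structure(cfg, class = "pipeline_config")
}

#' Run the full association pipeline from a configuration
#'
#' Executes QC, multiple imputation, structure/kinship estimation, the
#' configured association schemes for every trait, Rubin's-rules pooling
#' of the MI/MI* scans, and FDR control, writing each stage's artifacts
#' under `out_dir` and a JSON manifest recording parameters, seed and
#' input checksums. Reruns with the same configuration reproduce all
#' outputs exactly.
#'
#' @param config a `pipeline_config` (see [read_pipeline_config()]) or a
#'   named list coercible to one.
#' @return the manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config
  else as_pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(cfg$out_dir, ...)
  artifacts <- character(0)
  note <- function(path) { artifacts <<- c(artifacts, path); path }

  X0 <- read_dosage_tsv(cfg$genotypes)
  traits <- read_trait_tsv(cfg$phenotypes)
  if (!identical(rownames(X0), rownames(traits))) {
    stopf("genotype and phenotype individual ids disagree")
  }

  qc <- run_qc(X0, groups = cfg$panels, pmv_max = cfg$pmv_max,
               r_max = cfg$r_max, var_eps = cfg$var_eps,
               maf_min = cfg$maf_min, maf_subset = rownames(X0))
  X <- qc$X
  utils::write.table(qc$report$dropped, note(out("qc_dropped.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  S <- fcs_impute(X, m = cfg$m, L = cfg$L, qsel = cfg$qsel,
                  min_leaf = cfg$min_leaf, seed = child_seed(cfg$seed, 2L))
  Xbar <- average_dosage(S)
  write_dosage_tsv(round(S$imputes[[1L]]), note(out("impute_001.tsv")))
  utils::write.table(
    data.frame(id = rownames(Xbar), round(Xbar, 4), check.names = FALSE),
    note(out("average_dosage.tsv")), sep = "\t", quote = FALSE,
    row.names = FALSE)

  Qbar <- if (cfg$t > 0) pca_scores(Xbar, cfg$t)$Q else NULL
  Kbar <- kinship(Xbar)
  utils::write.table(round(Kbar, 6), note(out("kinship.tsv")),
                     sep = "\t", quote = FALSE)
  if (!is.null(Qbar)) {
    utils::write.table(round(Qbar, 6), note(out("pc_scores.tsv")),
                       sep = "\t", quote = FALSE)
  }
  structures <- if ("mistar" %in% cfg$schemes) {
    mistar_structures(S, cfg$t)
  } else NULL

  for (trait in colnames(traits)) {
    g <- traits[, trait]
    for (scheme in cfg$schemes) {
      res <- run_scheme(scheme, g, X = X, Xbar = Xbar, S = S,
                        Q = Qbar, K = Kbar, t = cfg$t,
                        structures = structures)
      if (scheme %in% c("mi", "mistar")) {
        pooled <- pool_scheme(res, n = length(g), t = cfg$t)
        okp <- !is.na(pooled$p_value)
        pooled$q_value <- NA_real_
        pooled$significant <- NA
        if (any(okp)) {
          fdr <- qvalues(pooled$p_value[okp], cfg$fdr_level)
          pooled$q_value[okp] <- fdr$qvalues
          pooled$significant[okp] <- fdr$significant
        }
        utils::write.table(pooled,
                           note(out(sprintf("%s_%s_pooled.tsv", trait, scheme))),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      } else {
        okp <- !is.na(res$p)
        res$q_value <- NA_real_
        res$significant <- NA
        if (any(okp)) {
          fdr <- qvalues(res$p[okp], cfg$fdr_level)
          res$q_value[okp] <- fdr$qvalues
          res$significant[okp] <- fdr$significant
        }
        utils::write.table(res,
                           note(out(sprintf("%s_%s.tsv", trait, scheme))),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("migwas")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed,
    parameters = cfg[c("pmv_max", "r_max", "var_eps", "maf_min", "m", "L",
                       "qsel", "min_leaf", "schemes", "t", "fdr_level")],
    inputs = list(genotypes = unname(tools::md5sum(cfg$genotypes)),
                  phenotypes = unname(tools::md5sum(cfg$phenotypes))),
    n_markers_in = ncol(X0), n_markers_kept = ncol(X),
    artifacts = artifacts)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
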