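#!/usr/bin/env Rscript
# Step 1: generate the synthetic twin cohort and its discovery summary
# statistics.
#
# The cohort emulates a blood-methylation twin study: ~1,200 twin pairs
# (half monozygotic), a beta-value matrix with correlated CpG blocks and
# cell-composition confounding, SNP dosages with MZ/DZ sharing from a
# parental-transmission model, one continuous and one liability-threshold
# binary trait with known variance fractions (10% methylation, 5%
# polygenic, 5% covariates; prevalence 20%), and EWAS/GWAS summary
# statistics from a simulated discovery cohort of 10,000.
#
# Everything is written as plain text under results/sim/ so later steps
# exercise the same readers a real analysis would use.

suppressPackageStartupMessages({
  library(omicscores)
  library(data.table)
})

out_dir <- "results/sim"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(n_pairs = 1200, mz_fraction = 0.5,
                  n_cpgs = 300, n_snps = 300,
                  n_causal_cpgs = 30, n_causal_snps = 30,
                  block_size = 10, block_rho = 0.3,
                  r2_ms_true = 0.10, r2_pgs_true = 0.05, r2_cov_true = 0.05,
                  prevalence = 0.20, n_discovery = 1e4, seed = 2026L)
cohort <- simulate_cohort(cfg)
stats <- simulate_discovery_stats(cohort)

# markers-in-rows on disk (array-export convention)
write_matrix <- function(m, id_col, path) {
  dt <- data.table(t(unclass(m)), keep.rownames = id_col)
  fwrite(dt, path, sep = "\t", quote = FALSE)
}
write_matrix(cohort$beta, "cpg", file.path(out_dir, "beta_matrix.tsv"))
write_matrix(cohort$dosage, "snp", file.path(out_dir, "dosage_matrix.tsv"))
fwrite(cohort$pheno, file.path(out_dir, "pheno.tsv"), sep = "\t", quote = FALSE)
fwrite(cohort$alleles, file.path(out_dir, "cohort_alleles.tsv"), sep = "\t",
       quote = FALSE)
write_ewas_stats(stats$ewas, file.path(out_dir, "ewas_stats.tsv"))
fwrite(stats$gwas, file.path(out_dir, "gwas_stats.tsv"), sep = "\t", quote = FALSE)

cat(sprintf("cohort: %d individuals (%d pairs, %.0f%% MZ)\n",
            nrow(cohort$pheno), cfg$n_pairs, 100 * cfg$mz_fraction))
cat(sprintf("binary-trait prevalence: %.3f (configured %.2f)\n",
            mean(cohort$pheno$trait_bin), cfg$prevalence))
cat("realized variance fractions (continuous trait):\n")
print(round(cohort$truth$realized, 4))
cat(sprintf("wrote %s\n", paste(list.files(out_dir), collapse = ", ")))
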