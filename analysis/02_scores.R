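#!/usr/bin/env Rscript
# Step 2: build methylation and polygenic scores from the discovery
# summary statistics written by 01_simulate.R.
#
# Methylation scores are built over the usual p-value threshold grid
# (1e-1, 1e-5, 1e-7), unpruned and pruned at |r| >= 0.1 on the cohort's
# own beta-value correlations. The polygenic score aligns each variant's
# weight to the cohort's counted allele (after MAF/ambiguity/duplicate QC
# of the GWAS file).

suppressPackageStartupMessages({
  library(omicscores)
  library(data.table)
})

sim <- "results/sim"
out_dir <- "results/scores"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

beta <- read_beta_matrix(file.path(sim, "beta_matrix.tsv"))
dosage <- read_dosage(file.path(sim, "dosage_matrix.tsv"))
alleles <- fread(file.path(sim, "cohort_alleles.tsv"))
ewas <- read_ewas_stats(file.path(sim, "ewas_stats.tsv"))
gwas <- read_gwas_stats(file.path(sim, "gwas_stats.tsv"), qc = TRUE)
cat("GWAS QC report:\n"); print(attr(gwas, "qc_report"))

rows <- list()
for (thr in c(1e-1, 1e-5, 1e-7)) {
  for (pr in c(FALSE, TRUE)) {
    ms <- build_ms(ewas, beta, p_threshold = thr, pruned = pr, r_cutoff = 0.1)
    def <- sprintf("p<%.0e%s", thr, if (pr) " pruned" else "")
    rows[[def]] <- data.table(definition = def,
                              n_markers = ms$n_markers_used,
                              coverage = ms$coverage,
                              score_sd = sd(ms$values))
    fwrite(data.table(sample_id = ms$sample_ids, score = unname(ms$values)),
           file.path(out_dir, paste0(gsub("[^a-z0-9]+", "_", tolower(def)), ".tsv")),
           sep = "\t")
  }
}
summary_tab <- rbindlist(rows)
cat("\nmethylation-score grid:\n")
print(summary_tab)

pgs <- build_pgs(gwas, dosage, alleles)
fwrite(data.table(sample_id = pgs$sample_ids, score = unname(pgs$values)),
       file.path(out_dir, "pgs.tsv"), sep = "\t")
cat(sprintf("\nPGS: %d/%d variants aligned (coverage %.1f%%)\n",
            pgs$n_markers_used, pgs$n_markers_requested, 100 * pgs$coverage))
fwrite(summary_tab, file.path(out_dir, "ms_grid_summary.tsv"), sep = "\t")
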