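#' Select markers below a p-value threshold
#'
#' Keeps summary-statistic records with `p < p_threshold` (strict), in their
#' original order. The conventional threshold grid for methylation scores is
#' 1e-1, 1e-5, 1e-7.
#'
#' @param stats data.frame/data.table of marker statistics with a `p` column.
#' @param p_threshold threshold in (0, 1].
#' @return The subset of `stats` with `p < p_threshold` (possibly empty).
#' @export
select_markers <- function(stats, p_threshold) {
  stopifnot(is.numeric(p_threshold), length(p_threshold) == 1,
            p_threshold > 0, p_threshold <= 1)
  stats[stats$p < p_threshold, , drop = FALSE]
}

#' Greedy correlation pruning of markers
#'
#' Step-wise selection of an approximately independent marker set: the most
#' significant remaining marker (ascending p, ties broken by marker id) is
#' moved into the keep-set, and every remaining marker whose correlation
#' with it — computed on the target cohort's own values — meets or exceeds
#' `r_cutoff` is discarded. By default the absolute correlation is used
#' (negatively correlated markers are equally redundant for a linear
#' score); set `use_abs = FALSE` for the signed variant. Markers with zero
#' variance in the cohort are excluded up front with a warning, since their
#' correlation is undefined.
#'
#' @param stats marker statistics (`cpg_id` or `snp_id` column, plus `p`).
#' @param mat an [omics_matrix()] containing all markers in `stats`.
#' @param r_cutoff correlation cut-off in (0, 1]; markers at or above it are
#'   removed (default 0.1).
#' @param use_abs prune on |r| (default) or signed r.
#' @return The kept subset of `stats`, in selection order.
#' @export
prune_markers <- function(stats, mat, r_cutoff = 0.1, use_abs = TRUE) {
  stopifnot(r_cutoff > 0, r_cutoff <= 1)
  id_col <- if ("cpg_id" %in% names(stats)) "cpg_id" else "snp_id"
  ids <- as.character(stats[[id_col]])
  missing <- setdiff(ids, colnames(mat))
  if (length(missing)) {
    stop(sprintf("%d marker(s) in stats absent from the matrix (e.g. %s); intersect first",
                 length(missing), missing[1]), call. = FALSE)
  }
  if (nrow(stats) == 0) return(stats)

  vals <- unclass(mat)[, ids, drop = FALSE]
  sds <- apply(vals, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("excluded %d zero-variance marker(s) before pruning",
                    sum(sds == 0)), call. = FALSE)
    keep0 <- sds > 0
    stats <- stats[keep0, , drop = FALSE]
    ids <- ids[keep0]
    vals <- vals[, keep0, drop = FALSE]
    if (nrow(stats) == 0) return(stats)
  }

  ord <- order(stats$p, ids)  # significance first, id as deterministic tie-break
  remaining <- ord
  kept <- integer()
  cm <- stats::cor(vals)
  if (use_abs) cm <- abs(cm)
  while (length(remaining) > 0) {
    pick <- remaining[1]
    kept <- c(kept, pick)
    r <- cm[pick, remaining]
    remaining <- remaining[r < r_cutoff]  # drops pick itself (r = 1)
  }
  stats[kept, , drop = FALSE]
}

.new_score_vector <- function(sample_ids, values, n_requested, n_used,
                              p_threshold = NA_real_, pruned = FALSE,
                              r_cutoff = NA_real_) {
  stopifnot(all(is.finite(values)), n_used >= 1, n_used <= n_requested)
  structure(list(sample_ids = sample_ids, values = stats::setNames(values, sample_ids),
                 n_markers_requested = n_requested, n_markers_used = n_used,
                 p_threshold = p_threshold, pruned = pruned,
                 r_cutoff = r_cutoff, coverage = n_used / n_requested),
            class = "score_vector")
}

#' @export
print.score_vector <- function(x, ...) {
  cat(sprintf("<score_vector> %d samples, %d/%d markers (coverage %.1f%%)%s\n",
              length(x$values), x$n_markers_used, x$n_markers_requested,
              100 * x$coverage,
              if (isTRUE(x$pruned)) sprintf(", pruned at |r| >= %g", x$r_cutoff) else ""))
  invisible(x)
}

#' Build a DNA-methylation score
#'
#' Per-individual weighted sum of methylation beta values,
#' `MS = sum_i effect_i * beta_i`, with weights taken from an independent
#' discovery EWAS. Markers are first restricted to `p < p_threshold` (or to
#' `marker_list` in fixed-set mode, e.g. an FDR-significant CpG list), then
#' optionally pruned at `r_cutoff` on the target cohort's correlations.
#' Weighted markers absent from the cohort are counted, warned about and
#' excluded without renormalising the remaining weights: scores are z-scored
#' before modelling, so only relative structure matters, and the reported
#' coverage lets callers gate on completeness.
#'
#' @param stats EWAS summary statistics (`cpg_id`, `effect`, `p`).
#' @param beta an [omics_matrix()] of kind `"beta"`.
#' @param p_threshold p-value threshold (ignored when `marker_list` given).
#' @param pruned apply greedy correlation pruning.
#' @param r_cutoff pruning cut-off (default 0.1).
#' @param marker_list optional fixed CpG set overriding the threshold rule.
#' @return A `score_vector` with per-sample scores and coverage metadata.
#' @export
build_ms <- function(stats, beta, p_threshold = 1, pruned = FALSE,
                     r_cutoff = 0.1, marker_list = NULL) {
  stopifnot(is_omics_matrix(beta), kind_of(beta) == "beta")
  sel <- if (is.null(marker_list)) {
    select_markers(stats, p_threshold)
  } else {
    stats[stats$cpg_id %in% marker_list, , drop = FALSE]
  }
  n_requested <- nrow(sel)
  if (n_requested == 0) {
    stop("no markers selected (threshold too strict or empty marker list)",
         call. = FALSE)
  }
  present <- sel$cpg_id %in% colnames(beta)
  if (!all(present)) {
    warning(sprintf("%d of %d selected CpG(s) absent from the cohort; excluded without weight renormalisation",
                    sum(!present), n_requested), call. = FALSE)
    sel <- sel[present, , drop = FALSE]
  }
  if (nrow(sel) == 0) {
    stop(sprintf("zero overlap between %d selected CpGs and %d cohort markers",
                 n_requested, ncol(beta)), call. = FALSE)
  }
  if (pruned) sel <- prune_markers(sel, beta, r_cutoff = r_cutoff)
  if (nrow(sel) == 0) stop("pruning removed all markers", call. = FALSE)
  vals <- drop(unclass(beta)[, sel$cpg_id, drop = FALSE] %*% sel$effect)
  .new_score_vector(rownames(beta), vals, n_requested, nrow(sel),
                    p_threshold = if (is.null(marker_list)) p_threshold else NA_real_,
                    pruned = pruned,
                    r_cutoff = if (pruned) r_cutoff else NA_real_)
}

#' Build a polygenic score with allele alignment
#'
#' Per-individual weighted sum of effect-allele dosages,
#' `PGS = sum_j effect_j * dosage_j`, after aligning each variant's weight
#' to the allele the cohort dosage counts: if the cohort's counted allele
#' equals the discovery effect allele the dosage is used as-is; if it equals
#' the discovery other allele the dosage is flipped to `2 - d`; variants
#' whose allele pair does not match the cohort annotation are dropped with
#' a warning.
#'
#' @param stats GWAS summary statistics (`snp_id`, `effect_allele`,
#'   `other_allele`, `effect`).
#' @param dosage an [omics_matrix()] of kind `"dosage"`.
#' @param cohort_alleles data.frame with `snp_id`, `counted_allele`,
#'   `other_allele` for the cohort (e.g. the `alleles` attribute of a VCF
#'   load, or a `sim_cohort$alleles` table).
#' @param p_threshold optional p-value threshold applied before alignment.
#' @return A `score_vector`.
#' @export
build_pgs <- function(stats, dosage, cohort_alleles, p_threshold = 1) {
  stopifnot(is_omics_matrix(dosage), kind_of(dosage) == "dosage")
  sel <- select_markers(stats, p_threshold)
  n_requested <- nrow(sel)
  if (n_requested == 0) stop("no variants selected", call. = FALSE)

  ann <- cohort_alleles[match(sel$snp_id, cohort_alleles$snp_id), , drop = FALSE]
  in_cohort <- !is.na(ann$snp_id) & sel$snp_id %in% colnames(dosage)
  if (!all(in_cohort)) {
    warning(sprintf("%d of %d variant(s) absent from the cohort; excluded",
                    sum(!in_cohort), n_requested), call. = FALSE)
    sel <- sel[in_cohort, , drop = FALSE]
    ann <- ann[in_cohort, , drop = FALSE]
  }
  direct <- sel$effect_allele == ann$counted_allele &
    sel$other_allele == ann$other_allele
  flipped <- sel$effect_allele == ann$other_allele &
    sel$other_allele == ann$counted_allele
  mismatch <- !(direct | flipped)
  if (any(mismatch)) {
    warning(sprintf("dropped %d variant(s) with mismatching alleles",
                    sum(mismatch)), call. = FALSE)
    sel <- sel[!mismatch, , drop = FALSE]
    direct <- direct[!mismatch]
    flipped <- flipped[!mismatch]
  }
  if (nrow(sel) == 0) stop("zero aligned variants", call. = FALSE)

  d <- unclass(dosage)[, sel$snp_id, drop = FALSE]
  d[, flipped] <- 2 - d[, flipped, drop = FALSE]
  vals <- drop(d %*% sel$effect)
  .new_score_vector(rownames(dosage), vals, n_requested, nrow(sel),
                    p_threshold = p_threshold)
}

#' Z-score transformation
#'
#' `(x - mean(x)) / sd(x)` with the sample standard deviation (n - 1
#' denominator). Traits, methylation scores and polygenic scores are all
#' z-scored before model fitting so that squared standardized coefficients
#' read as variance fractions.
#'
#' @param values numeric vector with at least two distinct values.
#' @return The standardized vector (mean 0, sample SD 1).
#' @export
zscore <- function(values) {
  stopifnot(is.numeric(values))
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    stop("cannot z-score a zero-variance (or all-missing) vector", call. = FALSE)
  }
  (values - mean(values)) / s
}
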