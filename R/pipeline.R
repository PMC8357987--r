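#' Define an analysis plan
#'
#' Collects the knobs of the end-to-end analysis: the p-value threshold
#' grid for methylation scores, the pruned/unpruned toggle and pruning
#' cut-off, the family-wise alpha, covariate sets and the seed driving the
#' one-twin-per-pair draws.
#'
#' @param p_thresholds threshold grid (default `c(1e-1, 1e-5, 1e-7)`).
#' @param pruned logical values of the pruning toggle (default both).
#' @param r_cutoff pruning correlation cut-off (default 0.1).
#' @param alpha family-wise significance level (default 0.05).
#' @param covariates_ewas,covariates_gwas covariate column sets.
#' @param cluster clustering column for GEE.
#' @param group cohort label stamped on report rows.
#' @param seed integer seed for random subsetting steps.
#' @return An `analysis_plan` list.
#' @export
analysis_plan <- function(p_thresholds = c(1e-1, 1e-5, 1e-7),
                          pruned = c(FALSE, TRUE), r_cutoff = 0.1,
                          alpha = 0.05,
                          covariates_ewas = c("sex", "age", "cell_prop", "batch"),
                          covariates_gwas = c("sex", "age", "PC1", "PC2"),
                          cluster = "family_id",
                          group = "simulated", seed = 1L) {
  stopifnot(all(p_thresholds > 0), all(p_thresholds <= 1),
            alpha > 0, alpha < 1)
  structure(list(p_thresholds = p_thresholds, pruned = pruned,
                 r_cutoff = r_cutoff, alpha = alpha,
                 covariates_ewas = covariates_ewas,
                 covariates_gwas = covariates_gwas,
                 cluster = cluster, group = group, seed = as.integer(seed)),
            class = "analysis_plan")
}

# Model-1 fit for a single methylation score; returns one grid row
.score_model_row <- function(trait, type, score, pheno, plan, one_per_pair,
                             definition) {
  spec <- model_spec(trait, type, covariates_ewas = plan$covariates_ewas,
                     covariates_gwas = character(0), cluster = plan$cluster,
                     one_per_pair = one_per_pair)
  df <- pheno
  df$MS <- score$values[match(df$sample_id, score$sample_ids)]
  need <- c(trait, plan$cluster, "MS", plan$covariates_ewas)
  df <- df[stats::complete.cases(df[, need, drop = FALSE]), , drop = FALSE]
  df$MS <- zscore(df$MS)
  y <- df[[trait]]

  if (type == "continuous") {
    y <- zscore(y)
    X <- .design_matrix(df, plan$covariates_ewas, extra = df[, "MS", drop = FALSE])
    fit <- fit_gee(y, X, df[[plan$cluster]], family = "gaussian")
    beta <- unname(fit$coefficients["MS"]); se <- unname(fit$robust_se["MS"])
    pval <- unname(fit$p["MS"]); r2 <- r2_continuous(fit, "MS")
  } else {
    X_a <- .design_matrix(df, plan$covariates_ewas, extra = df[, "MS", drop = FALSE])
    X_b <- .design_matrix(df, plan$covariates_ewas)
    f_a <- fit_logistic(y, X_a)
    f_b <- fit_logistic(y, X_b)
    r2 <- r2_liability(f_a, f_b)
    pfit <- if (one_per_pair) f_a
            else fit_gee(y, X_a, df[[plan$cluster]], family = "binomial")
    beta <- unname(pfit$coefficients["MS"])
    se <- unname(if (is.null(pfit$robust_se)) pfit$se["MS"] else pfit$robust_se["MS"])
    pval <- unname(pfit$p["MS"])
  }
  data.table::data.table(trait = trait, group = plan$group,
                         score_definition = definition,
                         n_markers = score$n_markers_used,
                         beta = beta, se = se, p = pval, r2_pct = r2,
                         n = nrow(df))
}

#' Evaluate the methylation-score grid for one trait
#'
#' Builds every methylation score in the plan's grid (each p-value
#' threshold crossed with the pruned/unpruned toggle, plus any fixed
#' marker-list scores), fits the single-score prediction model for each
#' (family-clustered GEE for continuous traits; nested logistic fits for
#' the liability R2 plus a GEE refit for the p-value for binary traits) and
#' flags the score explaining the most variance — the one carried forward
#' to the combined model. Ties are broken toward the score with fewer
#' markers (and logged).
#'
#' @param trait trait column name.
#' @param type `"continuous"` or `"binary"`.
#' @param stats EWAS summary statistics.
#' @param beta methylation [omics_matrix()].
#' @param pheno phenotype table (already subset to the analysis sample).
#' @param plan an [analysis_plan()].
#' @param marker_lists optional named list of fixed CpG sets, each also
#'   crossed with the pruning toggle.
#' @param one_per_pair use plain (non-GEE) fits for p-values.
#' @return A `data.table` of grid rows with a logical `best` column
#'   (exactly one TRUE), plus attribute `scores` holding the built
#'   `score_vector`s keyed by definition.
#' @export
run_score_grid <- function(trait, type, stats, beta, pheno, plan,
                           marker_lists = NULL, one_per_pair = FALSE) {
  cells <- list()
  for (thr in plan$p_thresholds) {
    for (pr in plan$pruned) {
      def <- sprintf("p<%.0e%s", thr, if (pr) " pruned" else "")
      cells[[def]] <- list(threshold = thr, pruned = pr, marker_list = NULL)
    }
  }
  for (nm in names(marker_lists)) {
    for (pr in plan$pruned) {
      def <- sprintf("%s%s", nm, if (pr) " pruned" else "")
      cells[[def]] <- list(threshold = NA, pruned = pr,
                           marker_list = marker_lists[[nm]])
    }
  }

  rows <- list(); scores <- list(); failures <- character()
  for (def in names(cells)) {
    cell <- cells[[def]]
    row <- tryCatch({
      sc <- build_ms(stats, beta,
                     p_threshold = if (is.null(cell$marker_list)) cell$threshold else 1,
                     pruned = cell$pruned, r_cutoff = plan$r_cutoff,
                     marker_list = cell$marker_list)
      scores[[def]] <- sc
      .score_model_row(trait, type, sc, pheno, plan, one_per_pair, def)
    }, error = function(e) {
      failures[[def]] <<- conditionMessage(e)
      NULL
    })
    rows[[def]] <- row
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    stop("every score-grid cell failed (no marker overlap?); first error: ",
         failures[1], call. = FALSE)
  }
  tab <- data.table::rbindlist(rows)
  ## best score: maximum R2; ties (to 1e-12) broken toward fewer markers
  top <- max(tab$r2_pct)
  tied <- which(tab$r2_pct > top - 1e-12)
  if (length(tied) > 1) {
    message(sprintf("best-score tie among %d cells; choosing fewest markers",
                    length(tied)))
  }
  best_idx <- tied[which.min(tab$n_markers[tied])]
  tab$best <- seq_len(nrow(tab)) == best_idx
  data.table::setattr(tab, "scores", scores)
  data.table::setattr(tab, "failures", failures)
  tab[]
}

#' Fit the polygenic-score prediction model for one trait
#'
#' Model-2 analogue of the score grid: regresses the trait on the
#' (z-scored) PGS plus sex, age and GWAS covariates, with family-clustered
#' GEE for continuous traits and the nested-logistic liability R2 plus a
#' GEE p-value for binary traits.
#'
#' @inheritParams run_score_grid
#' @param pgs a `score_vector`.
#' @return A one-row `data.table` (trait, group, beta, se, p, r2_pct, n).
#' @export
run_pgs_model <- function(trait, type, pgs, pheno, plan, one_per_pair = FALSE) {
  df <- pheno
  df$PGS <- pgs$values[match(df$sample_id, pgs$sample_ids)]
  need <- c(trait, plan$cluster, "PGS", plan$covariates_gwas)
  df <- df[stats::complete.cases(df[, need, drop = FALSE]), , drop = FALSE]
  df$PGS <- zscore(df$PGS)
  y <- df[[trait]]
  if (type == "continuous") {
    y <- zscore(y)
    X <- .design_matrix(df, plan$covariates_gwas, extra = df[, "PGS", drop = FALSE])
    fit <- fit_gee(y, X, df[[plan$cluster]], family = "gaussian")
    beta <- unname(fit$coefficients["PGS"]); se <- unname(fit$robust_se["PGS"])
    pval <- unname(fit$p["PGS"]); r2 <- r2_continuous(fit, "PGS")
  } else {
    X_a <- .design_matrix(df, plan$covariates_gwas, extra = df[, "PGS", drop = FALSE])
    X_b <- .design_matrix(df, plan$covariates_gwas)
    f_a <- fit_logistic(y, X_a); f_b <- fit_logistic(y, X_b)
    r2 <- r2_liability(f_a, f_b)
    pfit <- if (one_per_pair) f_a
            else fit_gee(y, X_a, df[[plan$cluster]], family = "binomial")
    beta <- unname(pfit$coefficients["PGS"])
    se <- unname(if (is.null(pfit$robust_se)) pfit$se["PGS"] else pfit$robust_se["PGS"])
    pval <- unname(pfit$p["PGS"])
  }
  data.table::data.table(trait = trait, group = plan$group,
                         score_definition = "PGS", n_markers = pgs$n_markers_used,
                         beta = beta, se = se, p = pval, r2_pct = r2,
                         n = nrow(df))
}

#' Combined multi-omics model for one trait
#'
#' Takes the best methylation score from [run_score_grid()] together with
#' the PGS into the combined model (full covariate union) and returns the
#' Table-5-shaped decomposition row.
#'
#' @inheritParams run_score_grid
#' @param best_ms the winning `score_vector`.
#' @param best_definition its grid label.
#' @param pgs the polygenic `score_vector`.
#' @return A one-row `data.table` with MS and PGS coefficients, component
#'   R2 percentages and their total.
#' @export
run_combined <- function(trait, type, best_ms, pgs, pheno, plan,
                         best_definition = "best MS", one_per_pair = FALSE) {
  spec <- model_spec(trait, type,
                     covariates_ewas = plan$covariates_ewas,
                     covariates_gwas = plan$covariates_gwas,
                     cluster = plan$cluster, one_per_pair = one_per_pair)
  d <- decompose(trait, best_ms, pgs, pheno, spec)
  data.table::data.table(trait = trait, group = plan$group,
                         score_definition = best_definition,
                         n_markers = best_ms$n_markers_used,
                         beta_ms = d$beta_ms, se_ms = d$se_ms, p_ms = d$p_ms,
                         r2_ms_pct = d$r2_ms,
                         beta_pgs = d$beta_pgs, se_pgs = d$se_pgs,
                         p_pgs = d$p_pgs, r2_pgs_pct = d$r2_pgs,
                         r2_total_pct = d$r2_total, scale = d$scale,
                         n = d$n_used)
}

#' Bonferroni-corrected significance threshold
#'
#' `alpha / n_tests`. When an audit breakdown is supplied (named test
#' counts per analysis stage) it is attached and must sum to `n_tests`.
#'
#' @param alpha family-wise significance level.
#' @param n_tests number of tests performed.
#' @param audit optional named integer vector decomposing `n_tests`.
#' @return The corrected threshold, with attributes `n_tests` and `audit`.
#' @export
bonferroni_alpha <- function(alpha = 0.05, n_tests, audit = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  if (length(n_tests) != 1 || n_tests < 1) {
    stop("n_tests must be a single integer >= 1", call. = FALSE)
  }
  if (!is.null(audit) && sum(audit) != n_tests) {
    stop(sprintf("audit counts sum to %d, not n_tests = %d", sum(audit), n_tests),
         call. = FALSE)
  }
  structure(alpha / n_tests, n_tests = as.integer(n_tests), audit = audit)
}

#' Time-gap sensitivity filter
#'
#' Keeps samples whose trait measurement lies within `max_years` of DNA
#' collection (inclusive boundary: a gap of exactly `max_years` is kept;
#' samples measured more than `max_years` before or after collection are
#' removed). Samples with a missing gap are excluded with a warning.
#'
#' @param pheno phenotype table.
#' @param dna_date_col,trait_date_col column names holding age (years) at
#'   DNA collection and at trait measurement.
#' @param max_years window half-width (default 3).
#' @return Logical keep-mask with attribute `n_removed`.
#' @export
sensitivity_time_gap <- function(pheno, dna_date_col, trait_date_col,
                                 max_years = 3) {
  stopifnot(all(c(dna_date_col, trait_date_col) %in% names(pheno)))
  gap <- pheno[[trait_date_col]] - pheno[[dna_date_col]]
  if (anyNA(gap)) {
    warning(sprintf("%d sample(s) with missing time gap excluded", sum(is.na(gap))),
            call. = FALSE)
  }
  keep <- !is.na(gap) & abs(gap) <= max_years
  attr(keep, "n_removed") <- sum(!keep)
  keep
}

#' Run the full multi-omics prediction analysis
#'
#' Drives the end-to-end workflow for a set of traits: phenotype
#' preparation (3-SD outlier removal for continuous traits; one twin per
#' pair for shared exposures), the methylation-score grid, the PGS model,
#' the combined model with the best score, optional time-gap sensitivity
#' reruns, and a multiple-testing audit. Each trait is isolated: a failure
#' is recorded and the remaining traits still run.
#'
#' @param beta methylation [omics_matrix()].
#' @param dosage dosage [omics_matrix()].
#' @param pheno phenotype/covariate table.
#' @param ewas_stats,gwas_stats discovery summary statistics.
#' @param cohort_alleles counted/other allele annotation for the cohort.
#' @param plan an [analysis_plan()].
#' @param traits list of trait descriptors: each a list with `name`,
#'   `type`, and optional `one_per_pair`, `marker_lists`,
#'   `sensitivity_gap` (logical; rerun the grid on the time-gap-filtered
#'   sample).
#' @param out_dir optional directory; when given, tables are written via
#'   [write_results()].
#' @return A `report_bundle`: `scores` (per-score table), `pgs`
#'   (PGS table), `combined` (decomposition table), `audit`
#'   (test counts and Bonferroni threshold), `errors` (per-trait failures),
#'   `best_scores` (the winning `score_vector` per trait).
#' @export
run_all <- function(beta, dosage, pheno, ewas_stats, gwas_stats,
                    cohort_alleles, plan = analysis_plan(),
                    traits = list(list(name = "trait_cont", type = "continuous"),
                                  list(name = "trait_bin", type = "binary")),
                    out_dir = NULL) {
  score_rows <- list(); pgs_rows <- list(); combined_rows <- list()
  errors <- list(); best_scores <- list()
  n_tests <- c()

  pgs <- build_pgs(gwas_stats, dosage, cohort_alleles)

  for (tr in traits) {
    name <- tr$name
    res <- tryCatch({
      opp <- isTRUE(tr$one_per_pair)
      ph <- pheno
      if (tr$type == "continuous") {
        keep <- remove_outliers(ph[[name]])
        ph <- ph[keep | is.na(ph[[name]]), , drop = FALSE]
        ph <- ph[!is.na(ph[[name]]), , drop = FALSE]
      }
      if (opp) {
        ids <- select_one_per_pair(ph, seed = plan$seed)
        ph <- ph[ph$sample_id %in% ids, , drop = FALSE]
      }
      grid <- run_score_grid(name, tr$type, ewas_stats, beta, ph, plan,
                             marker_lists = tr$marker_lists,
                             one_per_pair = opp)
      pgs_row <- run_pgs_model(name, tr$type, pgs, ph, plan, one_per_pair = opp)
      best_def <- grid$score_definition[grid$best]
      best_ms <- attr(grid, "scores")[[best_def]]
      comb <- run_combined(name, tr$type, best_ms, pgs, ph, plan,
                           best_definition = best_def, one_per_pair = opp)
      counts <- c(model1 = nrow(grid), model2 = 1L, model3 = 1L)

      sens <- NULL
      if (isTRUE(tr$sensitivity_gap)) {
        keep <- sensitivity_time_gap(ph, "age", "age_at_trait")
        sens_plan <- plan
        sens_plan$group <- paste0(plan$group, " (sensitivity)")
        sens <- run_score_grid(name, tr$type, ewas_stats, beta,
                               ph[keep, , drop = FALSE], sens_plan,
                               marker_lists = tr$marker_lists,
                               one_per_pair = opp)
        counts["sensitivity"] <- nrow(sens)
      }
      list(grid = grid, sens = sens, pgs_row = pgs_row, comb = comb,
           counts = counts, best_ms = best_ms)
    }, error = function(e) e)

    if (inherits(res, "error")) {
      errors[[name]] <- conditionMessage(res)
      next
    }
    score_rows[[name]] <- if (is.null(res$sens)) res$grid else
      data.table::rbindlist(list(res$grid, res$sens), fill = TRUE)
    pgs_rows[[name]] <- res$pgs_row
    combined_rows[[name]] <- res$comb
    best_scores[[name]] <- res$best_ms
    cnt <- res$counts
    names(cnt) <- paste(name, names(cnt), sep = ".")
    n_tests <- c(n_tests, cnt)
  }

  total_tests <- sum(n_tests)
  thr <- if (total_tests > 0) bonferroni_alpha(plan$alpha, total_tests,
                                               audit = n_tests) else NA_real_
  bundle <- structure(list(
    scores = if (length(score_rows)) data.table::rbindlist(score_rows, fill = TRUE)
             else NULL,
    pgs = if (length(pgs_rows)) data.table::rbindlist(pgs_rows) else NULL,
    combined = if (length(combined_rows)) data.table::rbindlist(combined_rows)
               else NULL,
    audit = list(n_tests = total_tests, breakdown = n_tests,
                 alpha = plan$alpha, threshold = as.numeric(thr)),
    errors = errors, best_scores = best_scores
  ), class = "report_bundle")

  if (!is.null(out_dir)) {
    write_results(list(scores = bundle$scores, combined = bundle$combined),
                  out_dir)
  }
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n")
  if (!is.null(x$scores)) {
    cat(sprintf("  %d score-grid rows over %d trait(s)\n", nrow(x$scores),
                length(unique(x$scores$trait))))
  }
  cat(sprintf("  %d tests; Bonferroni threshold %.4g\n",
              x$audit$n_tests, x$audit$threshold))
  if (length(x$errors)) {
    cat(sprintf("  failed traits: %s\n", paste(names(x$errors), collapse = ", ")))
  }
  invisible(x)
}
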