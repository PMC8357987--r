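#' Flag phenotype outliers beyond k standard deviations
#'
#' Single-pass rule: the mean and SD are computed once from all non-missing
#' values, and values with `|x - mean| > k_sd * SD` are flagged for removal.
#'
#' @param values numeric vector (may contain NA; NAs are kept out of the
#'   mask but not counted as outliers).
#' @param k_sd cut-off in standard deviations (default 3).
#' @return Logical keep-mask the length of `values` (FALSE for outliers and
#'   NAs), with attribute `n_removed` counting the flagged outliers.
#' @export
remove_outliers <- function(values, k_sd = 3) {
  ok <- !is.na(values)
  stopifnot(sum(ok) >= 3)
  m <- mean(values[ok]); s <- stats::sd(values[ok])
  keep <- ok & abs(values - m) <= k_sd * s
  keep[is.na(keep)] <- FALSE
  attr(keep, "n_removed") <- sum(ok) - sum(keep)
  keep
}

#' Randomly retain one member per family
#'
#' For exposures shared by co-twins (e.g. prenatal maternal smoking) one
#' twin per pair is analysed. One member of each family is drawn at random,
#' reproducibly from `seed`; singletons are always retained. The caller's
#' RNG state is left untouched.
#'
#' @param pheno data.frame with `sample_id` and `family_id`.
#' @param seed integer seed controlling the draw.
#' @return Character vector of retained sample ids.
#' @export
select_one_per_pair <- function(pheno, seed = 1L) {
  stopifnot(all(c("sample_id", "family_id") %in% names(pheno)))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  picked <- vapply(split(pheno$sample_id, pheno$family_id), function(ids) {
    if (length(ids) == 1) ids else sample(ids, 1)
  }, character(1))
  unname(picked[order(match(picked, pheno$sample_id))])
}

#' Variance explained by a standardized score coefficient
#'
#' For continuous traits, with trait and score both z-scored before
#' fitting, the percentage of trait variance explained by the score is the
#' squared regression coefficient times 100.
#'
#' @param fit a `fit_result`.
#' @param score_term name of the score column in the fit.
#' @return Percentage of variance explained.
#' @export
r2_continuous <- function(fit, score_term) {
  if (is.numeric(fit) && length(fit) == 1) {
    # convenience: accept a bare coefficient value
    return(100 * fit^2)
  }
  if (!score_term %in% names(fit$coefficients)) {
    stop(sprintf("term '%s' not in fitted model (has: %s)", score_term,
                 paste(names(fit$coefficients), collapse = ", ")), call. = FALSE)
  }
  100 * unname(fit$coefficients[score_term])^2
}

#' Liability-scale R2 difference between nested logistic fits
#'
#' Each model's latent-scale R2 is the variance of its fitted linear
#' predictor divided by that variance plus the residual variance of the
#' link (pi^2/3 for the logit; the probit convention, residual 1, is
#' available via `residual`). The score's contribution is 100 times the
#' difference between the full and reduced model's latent R2. Nested latent
#' R2 is not guaranteed monotone in finite samples, so negative differences
#' are floored at zero with a warning.
#'
#' @param fit_full,fit_reduced `fit_result`s from [fit_logistic()] on the
#'   same analysis sample.
#' @param residual `"logit"` (residual pi^2/3, default) or `"probit"`
#'   (residual 1).
#' @return Percentage-point difference in liability-scale R2 (>= 0).
#' @export
r2_liability <- function(fit_full, fit_reduced, residual = c("logit", "probit")) {
  residual <- match.arg(residual)
  if (fit_full$n_used != fit_reduced$n_used) {
    stop(sprintf("sample mismatch between fits (n = %d vs %d)",
                 fit_full$n_used, fit_reduced$n_used), call. = FALSE)
  }
  res_var <- if (residual == "logit") pi^2 / 3 else 1
  r2 <- function(f) f$lp_var / (f$lp_var + res_var)
  diff <- 100 * (r2(fit_full) - r2(fit_reduced))
  if (diff < 0) {
    warning(sprintf("negative nested liability R2 difference (%.3g%%) floored at 0",
                    diff), call. = FALSE)
    diff <- 0
  }
  diff
}

#' Specify a prediction model
#'
#' Names the trait, its type, and the covariate sets used by the nested
#' model grid: methylation models adjust for sex, age, cell proportions and
#' technical covariates (EWAS covariates); genetic models for sex, age,
#' genetic PCs and platform indicators (GWAS covariates); the combined
#' model for the union.
#'
#' @param trait trait column name in the phenotype table.
#' @param type `"continuous"` or `"binary"`.
#' @param covariates_ewas,covariates_gwas character vectors of covariate
#'   column names.
#' @param cluster clustering column (default `"family_id"`).
#' @param one_per_pair if TRUE the analysis sample holds one twin per
#'   family and p-values come from plain logistic/linear fits rather than
#'   GEE refits.
#' @return A `model_spec` list.
#' @export
model_spec <- function(trait, type = c("continuous", "binary"),
                       covariates_ewas = c("sex", "age", "cell_prop", "batch"),
                       covariates_gwas = c("sex", "age", "PC1", "PC2"),
                       cluster = "family_id", one_per_pair = FALSE) {
  type <- match.arg(type)
  structure(list(trait = trait, type = type,
                 covariates_ewas = covariates_ewas,
                 covariates_gwas = covariates_gwas,
                 cluster = cluster, one_per_pair = one_per_pair),
            class = "model_spec")
}

# intercept + dummy-coded covariates for the given columns
.design_matrix <- function(data, columns, extra = NULL) {
  if (length(columns) == 0) {
    X <- matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    X <- stats::model.matrix(stats::reformulate(columns), data)
  }
  if (!is.null(extra)) X <- cbind(X, as.matrix(extra))
  X
}

# align scores and phenotype rows; listwise-complete analysis frame
.analysis_frame <- function(trait, ms, pgs, pheno, spec) {
  df <- pheno
  if (!is.null(ms)) df$MS <- ms$values[match(df$sample_id, ms$sample_ids)]
  if (!is.null(pgs)) df$PGS <- pgs$values[match(df$sample_id, pgs$sample_ids)]
  need <- c(trait, spec$cluster,
            intersect(c("MS", "PGS"), names(df)),
            unique(c(spec$covariates_ewas, spec$covariates_gwas)))
  cc <- stats::complete.cases(df[, need, drop = FALSE])
  if (!all(cc)) {
    message(sprintf("decompose: %d sample(s) dropped by listwise deletion",
                    sum(!cc)))
  }
  df[cc, , drop = FALSE]
}

#' Decompose trait variance into MS and PGS contributions
#'
#' Fits the combined prediction model (trait on methylation score,
#' polygenic score and the union of EWAS and GWAS covariates) and returns
#' each score's variance contribution. Continuous traits: one
#' family-clustered GEE fit; each score's R2 is its squared standardized
#' coefficient times 100 and p-values come from the same fit. Binary
#' traits: liability-scale R2 from nested logistic fits — the full model
#' versus the model without the MS gives the MS contribution, versus the
#' model without the PGS gives the PGS contribution — while p-values come
#' from a binomial GEE refit of the full design (plain logistic when
#' `spec$one_per_pair`). The total is the sum of the two components; for
#' binary traits the full-model-minus-covariates-only difference is also
#' attached as attribute `r2_full_minus_baseline`.
#'
#' Trait (continuous), MS and PGS are z-scored within the analysis sample
#' after listwise deletion.
#'
#' @param trait trait column name.
#' @param ms,pgs `score_vector`s.
#' @param pheno phenotype/covariate table.
#' @param spec a [model_spec()].
#' @return A `variance_decomposition`: `r2_ms`, `r2_pgs`, `r2_total` (all
#'   %), `p_ms`, `p_pgs`, coefficient/SE pairs, `scale`
#'   (`"observed"`/`"liability"`), `n_used`.
#' @export
decompose <- function(trait, ms, pgs, pheno, spec) {
  stopifnot(inherits(spec, "model_spec"))
  df <- .analysis_frame(trait, ms, pgs, pheno, spec)
  covs <- unique(c(spec$covariates_ewas, spec$covariates_gwas))
  df$MS <- zscore(df$MS)
  df$PGS <- zscore(df$PGS)
  y <- df[[trait]]

  if (spec$type == "continuous") {
    y <- zscore(y)
    X <- .design_matrix(df, covs, extra = df[, c("MS", "PGS")])
    fit <- fit_gee(y, X, df[[spec$cluster]], family = "gaussian")
    out <- list(
      r2_ms = r2_continuous(fit, "MS"), r2_pgs = r2_continuous(fit, "PGS"),
      p_ms = unname(fit$p["MS"]), p_pgs = unname(fit$p["PGS"]),
      beta_ms = unname(fit$coefficients["MS"]),
      se_ms = unname(fit$robust_se["MS"]),
      beta_pgs = unname(fit$coefficients["PGS"]),
      se_pgs = unname(fit$robust_se["PGS"]),
      scale = "observed", n_used = fit$n_used
    )
    out$r2_total <- out$r2_ms + out$r2_pgs
  } else {
    if (!all(y %in% c(0, 1))) stop("binary trait must be coded 0/1", call. = FALSE)
    X_full <- .design_matrix(df, covs, extra = df[, c("MS", "PGS")])
    X_noms <- .design_matrix(df, covs, extra = df[, "PGS", drop = FALSE])
    X_nopgs <- .design_matrix(df, covs, extra = df[, "MS", drop = FALSE])
    X_base <- .design_matrix(df, covs)
    f_full <- fit_logistic(y, X_full)
    f_noms <- fit_logistic(y, X_noms)
    f_nopgs <- fit_logistic(y, X_nopgs)
    f_base <- fit_logistic(y, X_base)
    r2_ms <- r2_liability(f_full, f_noms)
    r2_pgs <- r2_liability(f_full, f_nopgs)

    pfit <- if (spec$one_per_pair) f_full
            else fit_gee(y, X_full, df[[spec$cluster]], family = "binomial")
    se <- if (is.null(pfit$robust_se)) pfit$se else pfit$robust_se
    out <- list(
      r2_ms = r2_ms, r2_pgs = r2_pgs,
      p_ms = unname(pfit$p["MS"]), p_pgs = unname(pfit$p["PGS"]),
      beta_ms = unname(pfit$coefficients["MS"]), se_ms = unname(se["MS"]),
      beta_pgs = unname(pfit$coefficients["PGS"]), se_pgs = unname(se["PGS"]),
      scale = "liability", n_used = f_full$n_used
    )
    out$r2_total <- out$r2_ms + out$r2_pgs
    attr(out, "r2_full_minus_baseline") <- r2_liability(f_full, f_base)
  }
  structure(out, class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf("<variance_decomposition> (%s scale, n = %d)\n", x$scale, x$n_used))
  cat(sprintf("  MS : R2 = %.3f%%  (beta %.3f, p %.3g)\n", x$r2_ms, x$beta_ms, x$p_ms))
  cat(sprintf("  PGS: R2 = %.3f%%  (beta %.3f, p %.3g)\n", x$r2_pgs, x$beta_pgs, x$p_pgs))
  cat(sprintf("  Total MS+PGS: %.3f%%\n", x$r2_total))
  invisible(x)
}
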