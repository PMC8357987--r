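## Tabular readers/writers for summary statistics, omics matrices and
## result tables. All delimited IO goes through data.table; VCF through vcfR.

# Explicit column-alias tables; matched case-insensitively, never fuzzily.
.EWAS_ALIASES <- list(
  cpg_id = c("cpg_id", "cpg", "probe", "probeid", "markername", "marker"),
  effect = c("effect", "beta", "b", "estimate"),
  se     = c("se", "stderr", "std_err", "standard_error"),
  p      = c("p", "pval", "p_value", "pvalue", "p.value")
)

.GWAS_ALIASES <- list(
  snp_id        = c("snp_id", "snp", "rsid", "markername", "variant_id"),
  effect_allele = c("effect_allele", "a1", "ea", "allele1"),
  other_allele  = c("other_allele", "a2", "oa", "allele2", "ref_allele"),
  effect        = c("effect", "beta", "b", "estimate"),
  se            = c("se", "stderr", "std_err", "standard_error"),
  p             = c("p", "pval", "p_value", "pvalue", "p.value"),
  maf           = c("maf", "minor_allele_frequency", "freq_minor")
)

.resolve_columns <- function(nms, aliases, required, path) {
  lower <- tolower(nms)
  out <- list()
  for (field in names(aliases)) {
    hit <- which(lower %in% aliases[[field]])
    if (length(hit) == 0) {
      if (field %in% required) {
        stop(sprintf("file '%s' is missing required column '%s' (accepted names: %s)",
                     path, field, paste(aliases[[field]], collapse = ", ")),
             call. = FALSE)
      }
      next
    }
    out[[field]] <- nms[hit[1]]
  }
  out
}

.read_delim <- function(path, sep = "auto") {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  # reject silently truncated files: every row must match the header width
  first <- readLines(path, n = 1)
  delim <- if (grepl("\t", first)) "\t" else ","
  widths <- utils::count.fields(path, sep = delim, quote = "\"")
  if (length(unique(widths)) > 1) {
    stop(sprintf("malformed delimited file '%s': row length mismatch (rows of %s fields)",
                 path, paste(unique(widths), collapse = "/")), call. = FALSE)
  }
  dt <- tryCatch(
    data.table::fread(path, sep = sep, header = TRUE, data.table = TRUE,
                      fill = FALSE, na.strings = c("NA", "")),
    error = function(e) stop(sprintf("malformed delimited file '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE))
  if (nrow(dt) == 0) stop(sprintf("file '%s' has a header but no data rows", path),
                          call. = FALSE)
  dt
}

#' Read EWAS summary statistics
#'
#' Reads a delimited file of per-CpG discovery statistics: probe id, effect
#' size (per unit beta-value, trait scale), standard error, p-value. Column
#' names are matched case-insensitively against a fixed alias table
#' (e.g. `CpG`/`probe`/`MarkerName`, `beta`/`effect`, `se`/`stderr`,
#' `p`/`pval`). Rows with a non-numeric effect, non-positive SE, or a
#' p-value outside (0, 1] are dropped with a counted warning; duplicated
#' probe ids are an error.
#'
#' @param path path to a TSV/CSV file with a header.
#' @return A `data.table` with columns `cpg_id`, `effect`, `se`, `p`, and an
#'   attribute `n_rejected` giving the count of dropped rows.
#' @export
read_ewas_stats <- function(path) {
  dt <- .read_delim(path)
  cols <- .resolve_columns(names(dt), .EWAS_ALIASES,
                           required = c("cpg_id", "effect", "se", "p"), path)
  out <- data.table::data.table(
    cpg_id = as.character(dt[[cols$cpg_id]]),
    effect = suppressWarnings(as.numeric(dt[[cols$effect]])),
    se     = suppressWarnings(as.numeric(dt[[cols$se]])),
    p      = suppressWarnings(as.numeric(dt[[cols$p]]))
  )
  bad <- !is.finite(out$effect) | !is.finite(out$se) | out$se <= 0 |
    !is.finite(out$p) | out$p <= 0 | out$p > 1
  if (any(bad)) {
    warning(sprintf("rejected %d row(s) with invalid effect/se/p in '%s'",
                    sum(bad), path), call. = FALSE)
    out <- out[!bad]
  }
  if (nrow(out) == 0) stop(sprintf("no valid rows in '%s'", path), call. = FALSE)
  dup <- unique(out$cpg_id[duplicated(out$cpg_id)])
  if (length(dup)) {
    stop(sprintf("duplicated cpg_id in '%s': %s", path,
                 paste(utils::head(dup, 5), collapse = ", ")), call. = FALSE)
  }
  data.table::setattr(out, "n_rejected", sum(bad))
  out[]
}

#' Write EWAS summary statistics
#'
#' Inverse of [read_ewas_stats()]; full-precision TSV so that
#' write-then-read round-trips bit-identically.
#'
#' @param stats data.table/data.frame with `cpg_id`, `effect`, `se`, `p`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ewas_stats <- function(stats, path) {
  data.table::fwrite(stats[, c("cpg_id", "effect", "se", "p")], path,
                     sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read GWAS summary statistics with optional QC
#'
#' Reads per-variant discovery statistics (variant id, effect/other allele,
#' weight, SE, p, optional MAF). With `qc = TRUE` applies the standard
#' score-construction filters: drop strand-ambiguous palindromic variants
#' (A/T and C/G pairs), duplicated variant ids (all copies), and variants
#' with MAF <= `maf_min` when a MAF column is present. When MAF is absent
#' the MAF rule is skipped with a message.
#'
#' @param path path to a delimited file with a header.
#' @param qc apply the QC filters (default `TRUE`).
#' @param maf_min MAF threshold; variants with `maf <= maf_min` are dropped.
#' @return A `data.table` with columns `snp_id`, `effect_allele`,
#'   `other_allele`, `effect`, `se`, `p` (and `maf` if present), plus a
#'   `qc_report` attribute: named counts dropped per rule.
#' @export
read_gwas_stats <- function(path, qc = TRUE, maf_min = 0.01) {
  dt <- .read_delim(path)
  cols <- .resolve_columns(names(dt), .GWAS_ALIASES,
                           required = c("snp_id", "effect_allele",
                                        "other_allele", "effect", "se", "p"),
                           path)
  out <- data.table::data.table(
    snp_id        = as.character(dt[[cols$snp_id]]),
    effect_allele = toupper(as.character(dt[[cols$effect_allele]])),
    other_allele  = toupper(as.character(dt[[cols$other_allele]])),
    effect        = suppressWarnings(as.numeric(dt[[cols$effect]])),
    se            = suppressWarnings(as.numeric(dt[[cols$se]])),
    p             = suppressWarnings(as.numeric(dt[[cols$p]]))
  )
  if (!is.null(cols$maf)) out$maf <- suppressWarnings(as.numeric(dt[[cols$maf]]))

  bad <- !is.finite(out$effect) | !is.finite(out$se) | out$se <= 0 |
    !is.finite(out$p) | out$p <= 0 | out$p > 1 |
    !(out$effect_allele %in% c("A", "C", "G", "T")) |
    !(out$other_allele %in% c("A", "C", "G", "T")) |
    out$effect_allele == out$other_allele
  if (any(bad)) {
    warning(sprintf("rejected %d malformed row(s) in '%s'", sum(bad), path),
            call. = FALSE)
    out <- out[!bad]
  }
  if (nrow(out) == 0) stop(sprintf("no valid rows in '%s'", path), call. = FALSE)

  report <- c(malformed = sum(bad), ambiguous = 0L, duplicated = 0L, maf = 0L)
  if (qc) {
    pal <- paste0(out$effect_allele, out$other_allele) %in%
      c("AT", "TA", "CG", "GC")
    report["ambiguous"] <- sum(pal)
    out <- out[!pal]
    dup_ids <- unique(out$snp_id[duplicated(out$snp_id)])
    report["duplicated"] <- sum(out$snp_id %in% dup_ids)
    out <- out[!out$snp_id %in% dup_ids]
    if (!is.null(out$maf)) {
      low <- !is.na(out$maf) & out$maf <= maf_min
      report["maf"] <- sum(low)
      out <- out[!low]
    } else {
      message("no MAF column in '", path, "'; MAF filter skipped")
    }
    if (nrow(out) == 0) stop(sprintf("QC removed all rows of '%s'", path),
                             call. = FALSE)
  }
  data.table::setattr(out, "qc_report", report)
  out[]
}

.read_matrix_tabular <- function(path, kind, na_frac_max = 0.05) {
  dt <- .read_delim(path)
  marker_ids <- as.character(dt[[1]])
  if (anyDuplicated(marker_ids)) {
    stop(sprintf("duplicate marker ids in '%s'", path), call. = FALSE)
  }
  m <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- marker_ids
  # Markers are rows on disk; drop markers missing in >na_frac_max of samples,
  # then mean-impute residual missing values per marker.
  na_frac <- rowMeans(is.na(m))
  dropped <- sum(na_frac > na_frac_max)
  if (dropped > 0) {
    warning(sprintf("dropped %d marker(s) with >%g%% missing values",
                    dropped, 100 * na_frac_max), call. = FALSE)
    m <- m[na_frac <= na_frac_max, , drop = FALSE]
  }
  n_imputed <- sum(is.na(m))
  if (n_imputed > 0) {
    means <- rowMeans(m, na.rm = TRUE)
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- means[idx[, 1]]
    message(sprintf("mean-imputed %d missing value(s) per marker", n_imputed))
  }
  om <- omics_matrix(t(m), kind = kind)
  attr(om, "n_markers_dropped") <- dropped
  attr(om, "n_imputed") <- n_imputed
  om
}

#' Read a methylation beta-value matrix
#'
#' Delimited text with markers in rows and samples in columns (first column
#' holds probe ids, header holds sample ids). Markers missing in more than
#' `na_frac_max` of samples are dropped; remaining missing cells are
#' mean-imputed per marker (logged). Values must lie in \[0, 1\].
#'
#' @param path path to the matrix file.
#' @param na_frac_max maximum tolerated per-marker missing fraction (0.05).
#' @return An [omics_matrix()] of kind `"beta"` (samples x markers), with
#'   attributes `n_markers_dropped` and `n_imputed`.
#' @export
read_beta_matrix <- function(path, na_frac_max = 0.05) {
  .read_matrix_tabular(path, "beta", na_frac_max)
}

#' Read allele dosages from tabular text or VCF
#'
#' Tabular input uses the same markers-in-rows layout as
#' [read_beta_matrix()]. VCF input (extension `.vcf` or `.vcf.gz`) uses the
#' per-genotype `DS` field when present, otherwise hard `GT` genotypes
#' converted to 0/1/2 counts of the ALT allele; multi-allelic records are
#' skipped with a warning. The ALT allele is the counted allele.
#'
#' @param path path to a dosage matrix or VCF file.
#' @param na_frac_max maximum tolerated per-variant missing fraction.
#' @return An [omics_matrix()] of kind `"dosage"`. For VCF input, an
#'   `alleles` attribute holds a data.frame (`snp_id`, `counted_allele`,
#'   `other_allele`) for downstream allele alignment.
#' @export
read_dosage <- function(path, na_frac_max = 0.05) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    return(.read_dosage_vcf(path, na_frac_max))
  }
  .read_matrix_tabular(path, "dosage", na_frac_max)
}

.read_dosage_vcf <- function(path, na_frac_max = 0.05) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    warning(sprintf("skipped %d multi-allelic VCF record(s)", sum(multi)),
            call. = FALSE)
  }
  keep <- !multi
  ids <- fix[keep, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix[keep, "CHROM"], ":", fix[keep, "POS"])[no_id]

  fmt <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  if (is.null(fmt) || all(is.na(fmt))) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    fmt <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
    })
  }
  m <- fmt[keep, , drop = FALSE]
  rownames(m) <- ids
  na_frac <- rowMeans(is.na(m))
  dropped <- sum(na_frac > na_frac_max)
  if (dropped > 0) {
    warning(sprintf("dropped %d variant(s) with >%g%% missing dosages",
                    dropped, 100 * na_frac_max), call. = FALSE)
  }
  sel <- na_frac <= na_frac_max
  m <- m[sel, , drop = FALSE]
  if (anyNA(m)) {
    means <- rowMeans(m, na.rm = TRUE)
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- means[idx[, 1]]
  }
  om <- omics_matrix(t(m), kind = "dosage")
  attr(om, "alleles") <- data.frame(
    snp_id = rownames(m),
    counted_allele = alt[keep][sel],
    other_allele = fix[keep, "REF"][sel],
    stringsAsFactors = FALSE
  )
  attr(om, "n_markers_dropped") <- dropped
  om
}

#' Write analysis result tables
#'
#' Writes the per-score table (one row per methylation-score grid cell:
#' trait, group, score definition, marker count, beta, SE, p, R2 %) and the
#' combined-model table (per-trait MS + PGS decomposition) as TSV files.
#' Betas and SEs are written to 3 decimals, p-values in scientific notation,
#' R2 percentages to 3 decimals.
#'
#' @param tables a list with elements `scores` and/or `combined`
#'   (data.frames, possibly empty).
#' @param path output directory (created if needed).
#' @return Named character vector of files written, invisibly.
#' @export
write_results <- function(tables, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  fmt_num <- function(x) formatC(x, digits = 3, format = "f")
  fmt_p <- function(x) formatC(x, digits = 3, format = "e")
  written <- character()
  if (!is.null(tables$scores)) {
    df <- as.data.frame(tables$scores)
    for (col in intersect(c("beta", "se", "r2_pct"), names(df))) {
      df[[col]] <- fmt_num(df[[col]])
    }
    if ("p" %in% names(df)) df$p <- fmt_p(df$p)
    f <- file.path(path, "score_results.tsv")
    data.table::fwrite(df, f, sep = "\t", quote = FALSE)
    written["scores"] <- f
  }
  if (!is.null(tables$combined)) {
    df <- as.data.frame(tables$combined)
    for (col in intersect(c("beta_ms", "se_ms", "beta_pgs", "se_pgs",
                            "r2_ms_pct", "r2_pgs_pct", "r2_total_pct"),
                          names(df))) {
      df[[col]] <- fmt_num(df[[col]])
    }
    for (col in intersect(c("p_ms", "p_pgs"), names(df))) {
      df[[col]] <- fmt_p(df[[col]])
    }
    f <- file.path(path, "combined_results.tsv")
    data.table::fwrite(df, f, sep = "\t", quote = FALSE)
    written["combined"] <- f
  }
  invisible(written)
}

#' Read back result tables written by [write_results()]
#'
#' @param path directory containing the result TSVs.
#' @return A list with the tables found (`scores`, `combined`), numeric
#'   columns re-parsed.
#' @export
read_results <- function(path) {
  out <- list()
  f <- file.path(path, "score_results.tsv")
  if (file.exists(f)) out$scores <- data.table::fread(f, sep = "\t")
  f <- file.path(path, "combined_results.tsv")
  if (file.exists(f)) out$combined <- data.table::fread(f, sep = "\t")
  out
}
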