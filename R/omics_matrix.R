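#' Samples-by-markers omics matrix
#'
#' Dense numeric matrix holding either methylation beta values (in \[0, 1\])
#' or allele dosages (in \[0, 2\]), with samples in rows and markers in
#' columns. On disk the conventional orientation is markers-in-rows
#' (array-export style); [read_beta_matrix()] and [read_dosage()] transpose
#' on load.
#'
#' @param values numeric matrix, samples x markers.
#' @param kind `"beta"` or `"dosage"`.
#' @param sample_ids,marker_ids character vectors; default to dimnames.
#'
#' @return An object of class `omics_matrix`: the matrix with row/column
#'   names set and a `kind` attribute.
#' @export
omics_matrix <- function(values, kind = c("beta", "dosage"),
                         sample_ids = rownames(values),
                         marker_ids = colnames(values)) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (samples x markers)", call. = FALSE)
  }
  if (is.null(sample_ids) || is.null(marker_ids)) {
    stop("sample and marker identifiers are required", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids", call. = FALSE)
  if (anyDuplicated(marker_ids)) stop("duplicate marker ids", call. = FALSE)
  if (anyNA(values)) {
    stop("missing values are not allowed in an omics_matrix; impute or drop first",
         call. = FALSE)
  }
  rng <- range(values)
  lim <- if (kind == "beta") c(0, 1) else c(0, 2)
  if (rng[1] < lim[1] || rng[2] > lim[2]) {
    bad <- which(values < lim[1] | values > lim[2], arr.ind = TRUE)[1, ]
    stop(sprintf("%s value out of [%g, %g] at row %d (sample %s), column %d (marker %s)",
                 kind, lim[1], lim[2], bad[1], sample_ids[bad[1]],
                 bad[2], marker_ids[bad[2]]), call. = FALSE)
  }
  dimnames(values) <- list(sample_ids, marker_ids)
  structure(values, kind = kind, class = c("omics_matrix", "matrix", "array"))
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix [%s]> %d samples x %d markers\n",
              attr(x, "kind"), nrow(x), ncol(x)))
  invisible(x)
}

#' @rdname omics_matrix
#' @param x object to test.
#' @export
is_omics_matrix <- function(x) inherits(x, "omics_matrix")

kind_of <- function(x) attr(x, "kind")

#' Subset an omics matrix, preserving class and kind
#'
#' @param x an `omics_matrix`.
#' @param samples,markers row / column selectors (ids, indices or logical).
#' @return An `omics_matrix` restricted to the requested samples and markers.
#' @export
subset_omics <- function(x, samples = NULL, markers = NULL) {
  stopifnot(is_omics_matrix(x))
  v <- unclass(x)
  if (!is.null(samples)) v <- v[samples, , drop = FALSE]
  if (!is.null(markers)) v <- v[, markers, drop = FALSE]
  omics_matrix(v, kind = kind_of(x))
}
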