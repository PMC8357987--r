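## Generalized estimating equations with an exchangeable working
## correlation, for family-clustered twin data. Gaussian/identity and
## binomial/logit variants, moment estimation of the working correlation,
## robust sandwich standard errors, at most 100 iterations.

#' Fit a GEE with exchangeable working correlation
#'
#' Marginal regression accounting for familial relatedness: observations
#' within a cluster (family) share a common working correlation `alpha`,
#' estimated by the usual moment estimator from Pearson residuals each
#' iteration. Identity link for `gaussian`, logit link for `binomial`.
#' Standard errors are robust (cluster sandwich) estimates; p-values are
#' two-sided Wald tests against the normal reference. With every cluster a
#' singleton the Gaussian fit reduces to ordinary least squares.
#'
#' Rows with missing values in `y` or `X` are removed (listwise deletion,
#' message with the count). Constant columns other than the intercept are
#' dropped; a design that is still rank-deficient is an error naming the
#' collinear columns.
#'
#' @param y response vector (numeric; 0/1 for binomial).
#' @param X design matrix including an intercept column.
#' @param clusters cluster identifiers, same length as `y`.
#' @param family `"gaussian"` or `"binomial"`.
#' @param max_iter maximum iterations (default 100).
#' @param tol convergence tolerance on the max coefficient change.
#' @return An object of class `fit_result`: `coefficients`, `robust_se`,
#'   `naive_se`, `p`, `converged`, `n_used`, `n_clusters`, `alpha`
#'   (working correlation), `phi` (dispersion), `lp_var` (variance of the
#'   fitted linear predictor) and `family`.
#' @export
fit_gee <- function(y, X, clusters, family = c("gaussian", "binomial"),
                    max_iter = 100L, tol = 1e-10) {
  family <- match.arg(family)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  stopifnot(length(y) == nrow(X), length(clusters) == nrow(X))

  cc <- stats::complete.cases(y, X)
  if (!all(cc)) {
    message(sprintf("fit_gee: %d row(s) removed by listwise deletion", sum(!cc)))
    y <- y[cc]; X <- X[cc, , drop = FALSE]; clusters <- clusters[cc]
  }
  X <- .clean_design(X)
  n <- length(y); p <- ncol(X)

  cl <- as.character(clusters)
  ni <- as.vector(table(cl)[unique(cl)])
  nmax <- max(ni)

  ## initialise at the independence (GLM) solution
  beta <- stats::glm.fit(X, y,
                         family = if (family == "gaussian") stats::gaussian()
                                  else stats::binomial())$coefficients
  alpha <- 0
  converged <- FALSE

  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    if (family == "gaussian") {
      mu <- eta; a <- rep(1, n); vfun <- rep(1, n)
    } else {
      mu <- stats::plogis(eta); vfun <- mu * (1 - mu); a <- vfun
      vfun <- pmax(vfun, 1e-10); a <- pmax(a, 1e-10)
    }
    s <- sqrt(vfun)
    r <- (y - mu) / s
    phi <- sum(r^2) / (n - p)

    ## moment estimator of the exchangeable correlation
    sum_r <- rowsum(r, cl)
    sum_r2 <- rowsum(r^2, cl)
    npairs <- sum(ni * (ni - 1) / 2)
    if (npairs > p) {
      alpha <- sum((sum_r^2 - sum_r2) / 2) / (phi * (npairs - p))
      alpha <- min(max(alpha, -0.99 / max(nmax - 1, 1)), 0.99)
    }

    ## update step via the closed-form exchangeable inverse:
    ## R^{-1} = c1 (I - c2 J), c1 = 1/(1-alpha),
    ## c2 = alpha / (1 + (n_i - 1) alpha)
    Wx <- X * (a / s)
    z <- (y - mu) / s
    SW <- rowsum(Wx, cl)
    Sz <- rowsum(z, cl)
    c1 <- 1 / (1 - alpha)
    c2 <- alpha / (1 + (ni - 1) * alpha)
    B <- c1 * (crossprod(Wx) - t(SW) %*% (SW * c2))
    u <- c1 * (crossprod(Wx, z) - t(SW) %*% (Sz * c2))
    step <- tryCatch(solve(B, u),
                     error = function(e) stop("GEE update failed: ",
                                              conditionMessage(e), call. = FALSE))
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning(sprintf("GEE did not converge in %d iterations (max step %.2e)",
                    max_iter, max(abs(step))), call. = FALSE)
  }

  ## final quantities at the converged estimate
  eta <- drop(X %*% beta)
  if (family == "gaussian") {
    mu <- eta; a <- rep(1, n); vfun <- rep(1, n)
  } else {
    mu <- stats::plogis(eta); vfun <- pmax(mu * (1 - mu), 1e-10); a <- vfun
  }
  s <- sqrt(vfun)
  Wx <- X * (a / s)
  z <- (y - mu) / s
  SW <- rowsum(Wx, cl)
  Sz <- rowsum(z, cl)
  c1 <- 1 / (1 - alpha)
  c2 <- alpha / (1 + (ni - 1) * alpha)
  B <- c1 * (crossprod(Wx) - t(SW) %*% (SW * c2))
  ## per-cluster estimating-function contributions
  G <- c1 * (rowsum(Wx * z, cl) - SW * drop(Sz * c2))
  Binv <- solve(B)
  vcov_robust <- Binv %*% crossprod(G) %*% Binv
  robust_se <- sqrt(diag(vcov_robust))
  phi <- sum(z^2) / (n - p)
  naive_se <- sqrt(diag(Binv) * phi)
  names(robust_se) <- names(naive_se) <- names(beta) <- colnames(X)
  zstat <- beta / robust_se
  pvals <- 2 * stats::pnorm(-abs(zstat))

  structure(list(coefficients = beta, robust_se = robust_se,
                 naive_se = naive_se, p = pvals,
                 vcov = vcov_robust, converged = converged,
                 n_used = n, n_clusters = length(ni), alpha = alpha,
                 phi = phi, lp_var = stats::var(eta), family = family,
                 method = "gee-exchangeable"),
            class = "fit_result")
}

# drop constant non-intercept columns; error (naming columns) if still
# rank-deficient
.clean_design <- function(X) {
  is_const <- apply(X, 2, function(col) all(col == col[1]))
  if (sum(is_const) > 1) {
    keep_int <- which(is_const)[1]
    drop_cols <- setdiff(which(is_const), keep_int)
    message(sprintf("dropping constant column(s): %s",
                    paste(colnames(X)[drop_cols], collapse = ", ")))
    X <- X[, -drop_cols, drop = FALSE]
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  X
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s (%s), n = %d%s%s\n", x$family, x$method,
              x$n_used,
              if (!is.null(x$n_clusters)) sprintf(", clusters = %d", x$n_clusters) else "",
              if (isTRUE(x$converged)) "" else " [NOT CONVERGED]"))
  print(data.frame(estimate = x$coefficients,
                   se = if (!is.null(x$robust_se)) x$robust_se else x$se,
                   p = x$p))
  invisible(x)
}

#' @export
coef.fit_result <- function(object, ...) object$coefficients

#' Maximum-likelihood logistic regression
#'
#' Plain logistic fit (binomial family, logit link) used for liability-scale
#' variance estimation; exposes the variance of the fitted linear predictor,
#' the quantity that enters the latent (McKelvey–Zavoina-style) R2. Perfect
#' separation is an error naming the separating column.
#'
#' @param y 0/1 response.
#' @param X design matrix including intercept.
#' @return A `fit_result` with `coefficients`, `se`, `p`, `lp_var`,
#'   `n_used`, `converged`.
#' @export
fit_logistic <- function(y, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  stopifnot(length(y) == nrow(X))
  if (!all(y %in% c(0, 1))) stop("y must be coded 0/1", call. = FALSE)
  cc <- stats::complete.cases(y, X)
  if (!all(cc)) {
    message(sprintf("fit_logistic: %d row(s) removed by listwise deletion",
                    sum(!cc)))
    y <- y[cc]; X <- X[cc, , drop = FALSE]
  }
  X <- .clean_design(X)

  ## proactive separation check, column by column
  for (j in seq_len(ncol(X))) {
    xj <- X[, j]
    if (length(unique(xj)) < 2) next
    if (max(xj[y == 0]) < min(xj[y == 1]) || max(xj[y == 1]) < min(xj[y == 0])) {
      stop(sprintf("perfect separation on column '%s'", colnames(X)[j]),
           call. = FALSE)
    }
  }

  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial())
  )
  if (!fit$converged || any(abs(fit$coefficients) > 25)) {
    stop("logistic fit did not converge (quasi-separation?)", call. = FALSE)
  }
  beta <- fit$coefficients
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  W <- mu * (1 - mu)
  info <- crossprod(X * sqrt(W))
  vc <- solve(info)
  se <- sqrt(diag(vc))
  names(se) <- names(beta)
  pvals <- 2 * stats::pnorm(-abs(beta / se))

  structure(list(coefficients = beta, se = se, robust_se = NULL, p = pvals,
                 vcov = vc, converged = TRUE, n_used = length(y),
                 lp_var = stats::var(eta), family = "binomial",
                 method = "ml-logistic"),
            class = "fit_result")
}
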