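test_that("outlier removal uses a single-pass 3-SD rule", {
  x <- c(rep(0, 100), 10)
  x[1:100] <- x[1:100] + rnorm(100, 0, 0.1)
  keep <- remove_outliers(x)
  expect_false(keep[101])
  expect_equal(attr(keep, "n_removed"), 1)

  y <- runif(50)  # everything well within 3 SD
  expect_equal(attr(remove_outliers(y), "n_removed"), 0)

  # Gaussian tail oracle: removal fraction ~ 2 * pnorm(-3) ~ 0.27%
  set.seed(99)
  g <- rnorm(10000)
  frac <- attr(remove_outliers(g), "n_removed") / 10000
  expect_lt(abs(frac - 2 * pnorm(-3)), 0.0015)
})

test_that("one-per-pair selection is reproducible and keeps singletons", {
  ph <- data.frame(sample_id = sprintf("S%02d", 1:21),
                   family_id = c(rep(sprintf("F%02d", 1:10), each = 2), "F11"))
  sel <- select_one_per_pair(ph, seed = 5)
  expect_length(sel, 11)
  expect_true("S21" %in% sel)  # singleton always retained
  expect_equal(anyDuplicated(ph$family_id[ph$sample_id %in% sel]), 0)
  expect_identical(sel, select_one_per_pair(ph, seed = 5))
  expect_false(identical(sel, select_one_per_pair(ph, seed = 6)) &&
                 identical(select_one_per_pair(ph, seed = 6),
                           select_one_per_pair(ph, seed = 7)))
})

test_that("gaussian GEE with singleton clusters reduces to OLS", {
  set.seed(1)
  n <- 200
  X <- cbind(1, x1 = rnorm(n), x2 = rnorm(n))
  colnames(X)[1] <- "(Intercept)"
  y <- 1 + 0.5 * X[, 2] - 0.3 * X[, 3] + rnorm(n)
  fit <- fit_gee(y, X, clusters = seq_len(n), family = "gaussian")
  ols <- stats::lm.fit(X, y)$coefficients
  expect_equal(unname(fit$coefficients), unname(ols), tolerance = 1e-8)
  expect_true(fit$converged)

  # exact linear response: zero residual variance, exact coefficients
  y2 <- 2 + 3 * X[, 2]
  fit2 <- fit_gee(y2, X, clusters = seq_len(n), family = "gaussian")
  expect_equal(unname(fit2$coefficients), c(2, 3, 0), tolerance = 1e-8)
  expect_lt(fit2$phi, 1e-16)
})

test_that("GEE recovers the intra-family correlation and sandwich SEs are consistent", {
  # clustered Gaussian data, intra-cluster correlation 0.5
  gen <- function(seed, n_cl = 500) {
    set.seed(seed)
    u <- rep(rnorm(n_cl, 0, sqrt(0.5)), each = 2)
    x <- rnorm(2 * n_cl)
    y <- 0.4 * x + u + rnorm(2 * n_cl, 0, sqrt(0.5))
    list(y = y, X = cbind(`(Intercept)` = 1, x = x),
         cl = rep(seq_len(n_cl), each = 2))
  }
  d <- gen(1)
  fit <- fit_gee(d$y, d$X, d$cl, family = "gaussian")
  expect_lt(abs(fit$alpha - 0.5), 0.08)

  ests <- ses <- numeric(80)
  for (i in seq_len(80)) {
    d <- gen(1000 + i)
    f <- fit_gee(d$y, d$X, d$cl, family = "gaussian")
    ests[i] <- f$coefficients["x"]; ses[i] <- f$robust_se["x"]
  }
  expect_lt(abs(mean(ses) / sd(ests) - 1), 0.20)
})

test_that("rank-deficient designs error with the collinear columns named", {
  X <- cbind(`(Intercept)` = 1, a = rnorm(20))
  X <- cbind(X, b = X[, "a"] * 2)
  expect_error(fit_gee(rnorm(20), X, 1:20), "collinear.*b|b.*collinear")
})

test_that("binomial GEE matches glm under independence on large samples", {
  set.seed(2)
  n <- 2000
  X <- cbind(`(Intercept)` = 1, x = rnorm(n))
  y <- rbinom(n, 1, plogis(-1 + 0.8 * X[, "x"]))
  fit <- fit_gee(y, X, clusters = seq_len(n), family = "binomial")
  ref <- stats::glm.fit(X, y, family = stats::binomial())$coefficients
  expect_equal(unname(fit$coefficients), unname(ref), tolerance = 1e-6)
})

test_that("logistic fits expose closed-form quantities and detect separation", {
  # intercept-only with mean(y) = 0.25: intercept log(1/3)
  y <- rep(c(1, 0, 0, 0), 25)
  X <- matrix(1, 100, 1, dimnames = list(NULL, "(Intercept)"))
  fit <- fit_logistic(y, X)
  expect_equal(unname(fit$coefficients), log(1 / 3), tolerance = 1e-8)
  expect_equal(fit$lp_var, 0)

  # duplicating every row leaves the estimates unchanged
  set.seed(3)
  X2 <- cbind(`(Intercept)` = 1, x = rnorm(80))
  y2 <- rbinom(80, 1, plogis(X2[, "x"]))
  f1 <- fit_logistic(y2, X2)
  f2 <- fit_logistic(rep(y2, 2), X2[rep(1:80, 2), ])
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-8)

  # ML consistency on a simulated logit model
  set.seed(4)
  n <- 5000
  X3 <- cbind(`(Intercept)` = 1, x = rnorm(n))
  y3 <- rbinom(n, 1, plogis(-0.5 + 0.7 * X3[, "x"]))
  f3 <- fit_logistic(y3, X3)
  expect_lt(abs(f3$coefficients["x"] - 0.7), 3 * f3$se["x"])

  # perfect separation names the offending column
  xs <- c(rnorm(20, -3), rnorm(20, 3))
  ys <- rep(c(0, 1), each = 20)
  expect_error(fit_logistic(ys, cbind(`(Intercept)` = 1, sepcol = xs)), "sepcol")
})

test_that("squared-coefficient variance explained follows the stated rule", {
  expect_equal(round(r2_continuous(0.277), 3), 7.673)
  expect_equal(r2_continuous(0), 0)
  expect_equal(r2_continuous(-0.3), 9)  # sign-invariant
  fit <- list(coefficients = c(`(Intercept)` = 0, MS = 0.5))
  class(fit) <- "fit_result"
  expect_equal(r2_continuous(fit, "MS"), 25)
  expect_error(r2_continuous(fit, "PGS"), "PGS")
})

test_that("liability R2 has the closed-form and nested-difference properties", {
  mkfit <- function(lp_var, n = 100) {
    structure(list(lp_var = lp_var, n_used = n), class = "fit_result")
  }
  # V = pi^2/3 gives latent R2 exactly 0.5
  expect_equal(r2_liability(mkfit(pi^2 / 3), mkfit(0)), 50)
  # identical fits: zero difference
  f <- mkfit(1.3)
  expect_equal(r2_liability(f, f), 0)
  # probit convention: residual variance 1
  expect_equal(r2_liability(mkfit(1), mkfit(0), residual = "probit"), 50)
  # negative difference floored at zero with warning
  expect_warning(out <- r2_liability(mkfit(0.1), mkfit(0.5)), "floored")
  expect_equal(out, 0)
  # mismatched analysis samples rejected
  expect_error(r2_liability(mkfit(1, 100), mkfit(0, 99)), "mismatch")
})

test_that("liability R2 recovers a configured latent signal", {
  # latent Gaussian liability with score R2 = 0.30, prevalence 0.2
  set.seed(6)
  n <- 4000
  x <- rnorm(n)
  liab <- sqrt(0.3) * x + sqrt(0.7) * rnorm(n)
  y <- as.integer(liab > qnorm(0.8))
  Xf <- cbind(`(Intercept)` = 1, score = x)
  Xr <- Xf[, 1, drop = FALSE]
  r2 <- r2_liability(fit_logistic(y, Xf), fit_logistic(y, Xr))
  expect_lt(abs(r2 - 30), 4)
})

test_that("liability R2 is invariant to relabelling cases and controls", {
  set.seed(7)
  n <- 600
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + x))
  Xf <- cbind(`(Intercept)` = 1, x = x)
  Xr <- Xf[, 1, drop = FALSE]
  a <- r2_liability(fit_logistic(y, Xf), fit_logistic(y, Xr))
  b <- r2_liability(fit_logistic(1 - y, Xf), fit_logistic(1 - y, Xr))
  expect_equal(a, b, tolerance = 1e-8)
})

test_that("decompose recovers independent MS and PGS signals on one cohort", {
  co <- simulate_cohort(sim_config(n_pairs = 1000, r2_ms_true = 0.20,
                                   r2_pgs_true = 0.05, n_discovery = 1e8,
                                   seed = 17))
  st <- simulate_discovery_stats(co)
  ms <- build_ms(st$ewas, co$beta, p_threshold = 1)
  pgs <- build_pgs(st$gwas, co$dosage, co$alleles)
  d <- decompose("trait_cont", ms, pgs, co$pheno,
                 model_spec("trait_cont", "continuous"))
  expect_lt(abs(d$r2_ms - 20), 4)
  expect_lt(abs(d$r2_pgs - 5), 3)
  expect_equal(d$r2_total, d$r2_ms + d$r2_pgs)

  # with orthogonal standardized predictors, single-score models agree with
  # the combined decomposition up to sampling error
  grid_spec <- model_spec("trait_cont", "continuous")
  df <- co$pheno
  df$MS <- zscore(unname(ms$values)); df$PGS <- zscore(unname(pgs$values))
  y <- zscore(df$trait_cont)
  f_ms <- fit_gee(y, cbind(`(Intercept)` = 1, MS = df$MS), df$family_id)
  expect_lt(abs(r2_continuous(f_ms, "MS") - d$r2_ms), 3)

  # a zero-variance score must fail loudly in z-scoring, not pass through
  pgs0 <- pgs; pgs0$values[] <- 0.5
  expect_error(decompose("trait_cont", ms, pgs0, co$pheno, grid_spec),
               "zero-variance")
})

test_that("decompose handles binary traits on the liability scale", {
  co <- simulate_cohort(sim_config(n_pairs = 1000, r2_ms_true = 0.20,
                                   r2_pgs_true = 0.05, n_discovery = 1e8,
                                   prevalence = 0.2, seed = 18))
  st <- simulate_discovery_stats(co)
  ms <- build_ms(st$ewas, co$beta, p_threshold = 1)
  pgs <- build_pgs(st$gwas, co$dosage, co$alleles)
  d <- decompose("trait_bin", ms, pgs, co$pheno,
                 model_spec("trait_bin", "binary"))
  expect_equal(d$scale, "liability")
  expect_lt(abs(d$r2_ms - 20), 6)
  expect_lt(abs(d$r2_pgs - 5), 4)
  expect_true(is.finite(attr(d, "r2_full_minus_baseline")))
})
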