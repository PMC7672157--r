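# Closed-form approximations of ridge prediction accuracy under the
# independent-variant model, as functions of the n/p ratio and the
# heritability, plus the exact bias/variance/irreducible decomposition for
# a fixed training design and the effective-number-of-SNPs adjustment that
# rescales the independent-marker theory to genomes with linkage
# disequilibrium.

#' Approximate out-of-sample prediction error of ridge regression
#'
#' Expected squared error of the ridge predictor at the
#' heritability-matched penalty, for a unit-variance trait:
#' `1 - (n/p) h^4` when `p >= n`, and
#' `(1 - h2) (1 + (n/p) h2) / (1 + h2 ((n/p) - 1))` otherwise.
#' The two branches agree at `n = p`; the error tends to the irreducible
#' error `1 - h2` as `n/p -> Inf` and to the trait variance 1 as
#' `n/p -> 0` (no prediction is possible however heritable the trait).
#'
#' @param h2 heritability in \[0, 1\] (vectorized).
#' @param n training-set size.
#' @param p number of variants.
#' @return expected test-set mean squared error.
#' @export
theory_test_error <- function(h2, n, p) {
  stopifnot(all(h2 >= 0 & h2 <= 1), n >= 1, p >= 1)
  r <- n / p
  ifelse(rep(p >= n, length(h2)),
         1 - r * h2^2,
         (1 - h2) * (1 + r * h2) / (1 + h2 * (r - 1)))
}

#' Approximate training-set error of ridge regression
#'
#' `(1 - h2)^2` when `p > n` (independent of the ratio), and
#' `1 - 2 a s + a^2 s` with `a = n / (n + lambda)`,
#' `s = (p/n)(1 - h2) + h2`, `lambda = p (1 - h2) / h2` when `n >= p`.
#' Both branches equal `(1 - h2)^2` at `n = p`, and the training error
#' climbs to the irreducible error `1 - h2` as `n/p -> Inf`.
#'
#' @inheritParams theory_test_error
#' @return expected training-set mean squared error.
#' @export
theory_train_error <- function(h2, n, p) {
  stopifnot(n >= 1, p >= 1)
  if (p > n) {
    stopifnot(all(h2 >= 0 & h2 <= 1))
    return((1 - h2)^2)
  }
  if (any(h2 <= 0 | h2 >= 1)) {
    stop("h2 must lie strictly inside (0, 1) when n >= p (the matched ",
         "penalty is degenerate at the endpoints)")
  }
  lam <- p * (1 - h2) / h2
  a <- n / (n + lam)
  s <- (p / n) * (1 - h2) + h2
  1 - 2 * a * s + a^2 * s
}

#' Approximate squared correlation between phenotype and prediction
#'
#' `(n/p) h^4` when `n < p`, and `h^4 / ((p/n)(1 - h2) + h2)` otherwise.
#' Continuous at `n = p`; tends to the heritability `h2` as `n/p -> Inf`
#' and to 0 as `n/p -> 0`. Never exceeds `h2`.
#'
#' @inheritParams theory_test_error
#' @return squared correlation in \[0, 1\].
#' @export
theory_corr2 <- function(h2, n, p) {
  stopifnot(all(h2 >= 0 & h2 <= 1), n >= 1, p >= 1)
  r <- n / p
  ifelse(rep(n < p, length(h2)),
         r * h2^2,
         h2^2 / ((1 - h2) / r + h2))
}

#' Exact error decomposition of ridge prediction for a fixed design
#'
#' For a fixed training matrix `Z`, true effects `u` and noise variance
#' `sigma2`, with a test genotype `z_te` of zero mean and identity
#' covariance, the expected squared prediction error splits into
#' irreducible error `sigma2`, variance `sigma2 tr(K K')` and squared
#' bias `u' (K Z - I)^2 u`, where `K = (Z'Z + lam I)^-1 Z'`. Computed via
#' the SVD of `Z`, so the sweep over penalties is cheap.
#'
#' @param Z training design matrix (n x p).
#' @param u true effect vector (length p).
#' @param lam positive penalty.
#' @param sigma2 noise variance.
#' @param cache optional [svd_cache()] of `Z` with right singular
#'   vectors.
#' @return object of class `error_decomposition`: list with
#'   `irreducible`, `variance`, `bias2`, `total`.
#' @export
exact_decomposition <- function(Z, u, lam, sigma2, cache = NULL) {
  if (lam <= 0) stop("lam must be positive")
  if (inherits(Z, "standardized_genotypes")) Z <- Z$Z
  Z <- as.matrix(Z)
  if (length(u) != ncol(Z)) stop("length(u) must equal ncol(Z)")
  if (is.null(cache) || is.null(cache$V)) cache <- svd_cache(Z)
  d2 <- cache$d^2
  variance <- sigma2 * sum(d2 / (d2 + lam)^2)
  b <- drop(crossprod(cache$V, u))       # coordinates of u on the row space
  perp2 <- max(sum(u^2) - sum(b^2), 0)   # component K Z cannot see
  bias2 <- sum((lam / (d2 + lam))^2 * b^2) + perp2
  structure(list(irreducible = sigma2, variance = variance, bias2 = bias2,
                 total = sigma2 + variance + bias2),
            class = "error_decomposition")
}

#' @export
print.error_decomposition <- function(x, ...) {
  cat(sprintf("error_decomposition: irreducible %.4f + variance %.4f + bias2 %.4f = %.4f\n",
              x$irreducible, x$variance, x$bias2, x$total))
  invisible(x)
}

#' Estimate the effective number of SNPs from observed test errors
#'
#' Real genomes violate the independent-variant assumption through
#' linkage disequilibrium; the theory can be rescaled by replacing `p`
#' with an effective count `p_e`. Each observation `(n, p, mse)` with
#' `p > n` is inverted through the high-dimensional branch
#' `mse = 1 - (n/p_e) h^4`, giving `n/p_e = (1 - mse) / h^4`, and the
#' slope of `n/p_e` on `n/p` by least squares through the origin
#' estimates `p / p_e`.
#'
#' @param observations data frame (or list of rows) with columns `n`,
#'   `p`, `mse` — the normalized test mean squared errors.
#' @param h2 heritability estimate used for the inversion.
#' @param intercept include an intercept in the regression (default
#'   `FALSE`, regression through the origin).
#' @return object of class `effective_snp_fit`: list with `points`
#'   (data frame `np`, `npe`), `slope` (`p / p_e`), `excluded` (rows with
#'   `mse >= 1`, implying a nonpositive ratio).
#' @export
effective_snp_fit <- function(observations, h2, intercept = FALSE) {
  obs <- as.data.frame(observations)
  stopifnot(all(c("n", "p", "mse") %in% names(obs)))
  if (any(obs$p <= obs$n)) stop("all observations must have p > n")
  bad <- obs$mse >= 1
  if (any(bad)) {
    warning(sum(bad), " observation(s) with normalized MSE >= 1 excluded")
  }
  obs <- obs[!bad, , drop = FALSE]
  if (!nrow(obs)) stop("no usable observations")
  np <- obs$n / obs$p
  npe <- (1 - obs$mse) / h2^2
  fit <- if (intercept) lm(npe ~ np) else lm(npe ~ np + 0)
  slope <- unname(coef(fit)[["np"]])
  structure(list(points = data.frame(np = np, npe = npe), slope = slope,
                 excluded = which(bad), intercept = intercept),
            class = "effective_snp_fit")
}

#' @export
print.effective_snp_fit <- function(x, ...) {
  cat(sprintf("effective_snp_fit: p/p_e = %.3f from %d observations\n",
              x$slope, nrow(x$points)))
  invisible(x)
}

#' Tabulate a theoretical accuracy curve over log(n/p)
#'
#' @param h2 heritability.
#' @param curve `"test_error"`, `"train_error"` or `"corr2"`.
#' @param log_np_min,log_np_max range of `log10(n/p)`.
#' @param points number of grid points.
#' @param n reference training-set size used to derive `p` from the ratio
#'   (default 1000).
#' @return data frame with columns `log_np`, `value`.
#' @export
theory_curve <- function(h2, curve = c("test_error", "train_error", "corr2"),
                         log_np_min = -3, log_np_max = 3, points = 200,
                         n = 1000) {
  curve <- match.arg(curve)
  log_np <- seq(log_np_min, log_np_max, length.out = points)
  value <- vapply(log_np, function(l) {
    p <- max(1, round(n / 10^l))
    switch(curve,
           test_error = theory_test_error(h2, n, p),
           train_error = theory_train_error(h2, n, p),
           corr2 = theory_corr2(h2, n, p))
  }, numeric(1))
  data.frame(log_np = log_np, value = value)
}
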