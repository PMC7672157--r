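# Heritability estimation by GCV over a heritability grid.
#
# The GCV criterion err(lambda) = ||y - H y||^2 / [tr(I - H)/n]^2 is an
# approximation of leave-one-out error computable from a single fit. With
# empirically centered data and p > n it degenerates: Z Z' acquires a null
# eigenvalue with constant eigenvector, the centered phenotype has no
# component on it, and the criterion collapses to 0 as lambda -> 0. Two
# corrections are implemented: projecting the system onto the orthogonal
# complement of the fixed-effect span with a semi-orthogonal contrast, or
# learning centers/scales and fixed effects on a disjoint standardization
# set.
#
# All estimators factorize the design once and sweep the whole penalty
# grid (and any number of phenotype columns) on the cached spectrum.

#' Generalized Cross-Validation error of a ridge fit
#'
#' Evaluates `||y - H_lam y||^2 / [(1/m) tr(I_m - H_lam)]^2` where
#' `H_lam = Z (Z'Z + lam I)^-1 Z'` and `m = length(y)`. With a cached
#' SVD the evaluation costs O(m) per penalty value.
#'
#' @param y response vector (possibly contrasted).
#' @param Z design matrix matching `y`.
#' @param lam positive penalty.
#' @param cache optional [svd_cache()] of `Z`.
#' @return nonnegative scalar; `+Inf` with attribute `degenerate = TRUE`
#'   if `tr(I - H)` vanishes.
#' @export
gcv_error <- function(y, Z, lam, cache = NULL) {
  if (lam < 0) stop("lam must be nonnegative")
  if (is.null(cache)) cache <- svd_cache(Z, compute_v = FALSE)
  m <- length(y)
  d2 <- cache$d^2
  a <- drop(crossprod(cache$U, y))
  shrink <- if (lam > 0) d2 / (d2 + lam) else as.numeric(d2 > 0)
  rss <- sum(y^2) - sum(a^2 * (2 * shrink - shrink^2))
  rss <- max(rss, 0)
  denom <- (m - sum(shrink)) / m
  if (denom <= 0) {
    return(structure(Inf, degenerate = TRUE))
  }
  rss / denom^2
}

#' Exact leave-one-out error via the hat-matrix diagonal
#'
#' Returns `sum_i ((y_i - yhat_i) / (1 - H_ii))^2`, the exact
#' leave-one-out residual sum of squares of ridge regression, without
#' refitting. A sum (not a mean) so that it parallels the GCV numerator.
#'
#' @inheritParams gcv_error
#' @return nonnegative scalar; `+Inf` with attribute `degenerate = TRUE`
#'   if any `H_ii >= 1`.
#' @export
loo_error <- function(y, Z, lam, cache = NULL) {
  if (lam <= 0) stop("lam must be positive")
  if (is.null(cache)) cache <- svd_cache(Z, compute_v = FALSE)
  d2 <- cache$d^2
  shrink <- d2 / (d2 + lam)
  a <- drop(crossprod(cache$U, y))
  fitted <- drop(cache$U %*% (shrink * a))
  hdiag <- drop((cache$U^2) %*% shrink)
  if (any(hdiag >= 1 - 1e-12)) {
    return(structure(Inf, degenerate = TRUE))
  }
  sum(((y - fitted) / (1 - hdiag))^2)
}

#' Build a semi-orthogonal contrast of the fixed-effect span
#'
#' Returns a `(n - r - 1) x n` matrix `C` whose rows are an orthonormal
#' basis of the orthogonal complement of `span(1, X)`, so `C C' = I`,
#' `C 1 = 0` and `C X = 0`. With covariates the basis comes from the QR
#' decomposition of `[1 | X]`. For the intercept-only case a genotype
#' matrix may be supplied: the left singular vectors of the empirically
#' centered `Z` then provide a contrast under which `(C Z)(C Z)'` is
#' already diagonal, making the subsequent penalty sweep trivial.
#'
#' @param n number of samples.
#' @param X optional n x r covariate matrix (without intercept column).
#' @param Z optional empirically centered genotype matrix enabling the
#'   intercept-only SVD shortcut.
#' @return object of class `contrast_basis`: list with `C` (m x n),
#'   `m = n - r - 1`, `absorbed` (description), and optionally `d`
#'   (singular values of `C Z` when the shortcut was used).
#' @export
build_contrast <- function(n, X = NULL, Z = NULL) {
  r <- if (is.null(X)) 0L else ncol(as.matrix(X))
  if (n <= r + 1) stop("need n > r + 1 samples to form a contrast")
  if (is.null(X) && !is.null(Z)) {
    if (inherits(Z, "standardized_genotypes")) Z <- Z$Z
    cache <- svd_cache(Z, compute_v = FALSE)
    # empirical centering forces a null singular value whose left vector
    # is constant; dropping it yields the contrast
    C <- t(cache$U[, -n, drop = FALSE])
    return(structure(list(C = C, m = n - 1L, absorbed = "intercept",
                          d = cache$d[-n]),
                     class = "contrast_basis"))
  }
  F <- cbind(`(Intercept)` = rep(1, n), X)
  qrF <- qr(F)
  if (qrF$rank < ncol(F)) {
    bad <- colnames(F)[qrF$pivot[-seq_len(qrF$rank)]]
    stop("fixed-effect columns are collinear: ", paste(bad, collapse = ", "))
  }
  Q <- qr.Q(qrF, complete = TRUE)
  C <- t(Q[, (r + 2):n, drop = FALSE])
  structure(list(C = C, m = n - r - 1L,
                 absorbed = if (r) sprintf("intercept + %d covariates", r)
                            else "intercept"),
            class = "contrast_basis")
}

#' @export
print.contrast_basis <- function(x, ...) {
  cat(sprintf("contrast_basis: %d x %d, absorbs %s\n",
              x$m, ncol(x$C), x$absorbed))
  invisible(x)
}

# Default heritability grid.
h2_default_grid <- function() seq(0.01, 0.99, by = 0.01)

new_gcv_curve <- function(h2_grid, lam_grid, err, method) {
  argmin_idx <- which.min(err)  # first minimum = smallest h2 on ties
  structure(list(h2_grid = h2_grid, lam_grid = lam_grid, err = err,
                 argmin_idx = argmin_idx, method = method),
            class = "gcv_curve")
}

new_h2_estimate <- function(h2, p_used, n_used, method) {
  structure(list(h2 = h2, lam = p_used * (1 - h2) / h2, method = method,
                 n_used = n_used, p_used = p_used),
            class = "h2_estimate")
}

new_h2_fit <- function(grid, err, p_used, n_used, method) {
  curve <- new_gcv_curve(grid, p_used * (1 - grid) / grid, err, method)
  est <- new_h2_estimate(grid[curve$argmin_idx], p_used, n_used, method)
  structure(list(curve = curve, estimate = est), class = "h2_fit")
}

#' @export
print.gcv_curve <- function(x, ...) {
  cat(sprintf("gcv_curve (%s): %d grid points, argmin h2 = %.2f\n",
              x$method, length(x$h2_grid), x$h2_grid[x$argmin_idx]))
  invisible(x)
}

#' @export
print.h2_estimate <- function(x, ...) {
  cat(sprintf("h2_estimate (%s): h2 = %.4f (lambda = %.6g, n = %d, p = %d)\n",
              x$method, x$h2, x$lam, x$n_used, x$p_used))
  invisible(x)
}

#' @export
print.h2_fit <- function(x, ...) {
  print(x$estimate)
  invisible(x)
}

# Evaluate the GCV criterion along the heritability grid given the
# eigenvalues d2 of the (possibly contrasted) system and the coefficients
# a = U'y; m is the system dimension, p maps the grid to penalties.
gcv_sweep <- function(d2, a, y2, m, p, grid) {
  vapply(grid, function(h) {
    lam <- p * (1 - h) / h
    shrink <- d2 / (d2 + lam)
    rss <- max(y2 - sum(a^2 * (2 * shrink - shrink^2)), 0)
    denom <- (m - sum(shrink)) / m
    if (denom <= 0) Inf else rss / denom^2
  }, numeric(1))
}

#' Estimate heritability by ridge regression on a heritability grid
#'
#' For each grid heritability, the corresponding penalty
#' `lambda = p (1 - h2) / h2` is scored by a criterion and the minimizing
#' grid value is the estimate. Methods:
#' \describe{
#'   \item{`gcv_projection`}{GCV on the contrasted system `(C y, C Z)`
#'     with `C` spanning the orthogonal complement of the intercept (and
#'     covariates). The recommended estimator.}
#'   \item{`gcv_naive`}{GCV after empirical centering of genotype columns
#'     and phenotype, no correction. In high dimension this is the known
#'     negative control: the criterion collapses toward `lambda -> 0` and
#'     the estimate saturates at the grid maximum.}
#'   \item{`gcv_two_set`}{centers, scales and fixed effects learned on a
#'     disjoint standardization set (`std_set`), then GCV without
#'     contrast on the externally standardized training data.}
#'   \item{`kfold_cv`}{mean validation mean-squared-error across k folds
#'     at each grid penalty, with fold-wise empirical standardization of
#'     the training folds applied to the held-out fold (no leakage).}
#' }
#' The design is factorized once: `y` may be a matrix of phenotype
#' columns sharing the genotypes, in which case a list of fits (one per
#' column) is returned for the cost of a single decomposition.
#'
#' @param geno a [genotype_matrix()] of raw allele counts, or a
#'   `standardized_genotypes` object (accepted for `gcv_projection` /
#'   `gcv_naive`, used as-is).
#' @param y phenotype vector of length n, or an n x q matrix of
#'   phenotypes.
#' @param method one of `"gcv_projection"`, `"gcv_naive"`,
#'   `"gcv_two_set"`, `"kfold_cv"`.
#' @param grid increasing heritability grid strictly inside (0, 1);
#'   default `seq(0.01, 0.99, by = 0.01)`.
#' @param covariates optional n x r covariate matrix (no intercept
#'   column).
#' @param std_set for `gcv_two_set`: list with fields `geno` (a
#'   [genotype_matrix()] of the standardization samples), `y` (vector or
#'   matrix matching `y`), and optionally `X` (covariates). Sample ids
#'   must be disjoint from the training samples.
#' @param k number of folds for `kfold_cv` (default 10).
#' @param seed seed for the fold shuffle of `kfold_cv`.
#' @param cache optional [svd_cache()] of the empirically standardized
#'   genotypes (`compute_v = FALSE` suffices), reused by
#'   `gcv_projection` / `gcv_naive`.
#' @return object of class `h2_fit`: list with `curve` (a `gcv_curve`)
#'   and `estimate` (an `h2_estimate`); a plain list of `h2_fit` when
#'   `y` is a matrix.
#' @export
estimate_h2 <- function(geno, y,
                        method = c("gcv_projection", "gcv_naive",
                                   "gcv_two_set", "kfold_cv"),
                        grid = h2_default_grid(), covariates = NULL,
                        std_set = NULL, k = 10L, seed = NULL, cache = NULL) {
  method <- match.arg(method)
  if (any(grid <= 0 | grid >= 1)) stop("grid must lie strictly inside (0, 1)")
  if (length(grid) > 1 && is.unsorted(grid, strictly = TRUE)) {
    stop("grid must be strictly increasing")
  }
  single <- is.null(dim(y))
  ymat <- as.matrix(y)
  n <- nrow(ymat)

  fits <- switch(method,
    gcv_two_set = estimate_h2_two_set(geno, ymat, grid, covariates, std_set),
    kfold_cv = estimate_h2_kfold(geno, ymat, grid, covariates, k, seed),
    {  # gcv_projection / gcv_naive
      Zs <- if (inherits(geno, "standardized_genotypes")) geno
            else standardize(geno, mode = "empirical")
      if (nrow(Zs$Z) != n) stop("y must match the number of samples")
      p_used <- ncol(Zs$Z)
      if (method == "gcv_naive") {
        if (is.null(cache)) cache <- svd_cache(Zs$Z, compute_v = FALSE)
        d2 <- cache$d^2
        lapply(seq_len(ncol(ymat)), function(j) {
          yc <- ymat[, j] - mean(ymat[, j])
          a <- drop(crossprod(cache$U, yc))
          new_h2_fit(grid, gcv_sweep(d2, a, sum(yc^2), n, p_used, grid),
                     p_used, n, method)
        })
      } else if (is.null(covariates)) {
        # intercept-only shortcut: contrast = left singular vectors of
        # the empirically centered Z minus its centering-null vector.
        # When p < n the thin SVD holds only p components; the remaining
        # contrast coordinates have zero singular value and their mass
        # enters the residual through ||Cy||^2 = ||y - mean(y)||^2.
        if (is.null(cache)) cache <- svd_cache(Zs$Z, compute_v = FALSE)
        if (p_used >= n) {
          U1 <- cache$U[, -n, drop = FALSE]
          d2 <- cache$d[-n]^2
        } else {
          U1 <- cache$U
          d2 <- cache$d^2
        }
        lapply(seq_len(ncol(ymat)), function(j) {
          yc <- ymat[, j] - mean(ymat[, j])
          a <- drop(crossprod(U1, yc))
          new_h2_fit(grid, gcv_sweep(d2, a, sum(yc^2), n - 1L, p_used, grid),
                     p_used, n, method)
        })
      } else {
        cb <- build_contrast(n, X = covariates)
        CZ <- cb$C %*% Zs$Z
        ccache <- svd_cache(CZ, compute_v = FALSE)
        d2 <- ccache$d^2
        lapply(seq_len(ncol(ymat)), function(j) {
          cy <- drop(cb$C %*% ymat[, j])
          a <- drop(crossprod(ccache$U, cy))
          new_h2_fit(grid, gcv_sweep(d2, a, sum(cy^2), cb$m, p_used, grid),
                     p_used, n, method)
        })
      }
    })
  if (single) fits[[1]] else fits
}

estimate_h2_two_set <- function(geno, ymat, grid, covariates, std_set) {
  if (is.null(std_set)) stop("method 'gcv_two_set' requires std_set")
  if (!inherits(geno, "genotype_matrix")) {
    stop("gcv_two_set needs raw allele counts (a genotype_matrix) to apply ",
         "externally estimated centers and scales")
  }
  g_std <- std_set$geno
  if (is.matrix(g_std)) g_std <- genotype_matrix(g_std)
  if (length(intersect(geno$sample_ids, g_std$sample_ids))) {
    stop("training and standardization sets share sample ids: ",
         paste(utils::head(intersect(geno$sample_ids, g_std$sample_ids), 5),
               collapse = ", "))
  }
  st <- col_mean_sd(g_std$counts)
  Zs <- standardize(geno, mode = "external_set",
                    external_stats = list(centers = st[, 1], scales = st[, 2]))
  n <- nrow(ymat)
  p_used <- ncol(Zs$Z)
  y_std <- as.matrix(std_set$y)
  if (ncol(y_std) != ncol(ymat)) {
    stop("std_set$y must have one column per phenotype column")
  }
  # fixed effects (intercept + covariates) learned on the std set by OLS
  X_std <- cbind(rep(1, nrow(y_std)),
                 if (!is.null(std_set$X)) as.matrix(std_set$X))
  qr_std <- qr(X_std)
  X_tr <- cbind(rep(1, n), if (!is.null(covariates)) as.matrix(covariates))
  if (ncol(X_tr) != ncol(X_std)) {
    stop("covariates of training and standardization sets must match")
  }
  cache <- svd_cache(Zs$Z, compute_v = FALSE)
  d2 <- cache$d^2
  lapply(seq_len(ncol(ymat)), function(j) {
    beta <- qr.coef(qr_std, y_std[, j])
    y_adj <- ymat[, j] - drop(X_tr %*% beta)
    a <- drop(crossprod(cache$U, y_adj))
    new_h2_fit(grid, gcv_sweep(d2, a, sum(y_adj^2), n, p_used, grid),
               p_used, n, "gcv_two_set")
  })
}

estimate_h2_kfold <- function(geno, ymat, grid, covariates, k, seed) {
  M <- if (inherits(geno, "genotype_matrix")) geno$counts
       else if (inherits(geno, "standardized_genotypes")) geno$Z
       else as.matrix(geno)
  n <- nrow(M)
  q <- ncol(ymat)
  if (k < 2 || k > n) stop("k must lie in [2, n]")
  # contiguous blocks after a seeded shuffle
  ord <- with_seed(if (is.null(seed)) NULL else stream_seed(seed, "shuffle"),
                   sample.int(n))
  sizes <- diff(floor(seq(0, n, length.out = k + 1)))
  fold_of <- integer(n)
  fold_of[ord] <- rep(seq_len(k), times = sizes)
  p_used <- NULL
  sse <- array(0, c(k, length(grid), q))
  nval <- integer(k)
  for (f in seq_len(k)) {
    val <- which(fold_of == f)
    tr <- setdiff(seq_len(n), val)
    st <- col_mean_sd(M[tr, , drop = FALSE])
    keep <- which(is.finite(st[, 2]) & st[, 2] > 0)
    Ztr <- standardize_matrix(M[tr, keep, drop = FALSE],
                              st[keep, 1], st[keep, 2])
    Zval <- standardize_matrix(M[val, keep, drop = FALSE],
                               st[keep, 1], st[keep, 2])
    if (is.null(p_used)) p_used <- length(keep)
    X_tr <- cbind(rep(1, length(tr)),
                  if (!is.null(covariates)) as.matrix(covariates)[tr, , drop = FALSE])
    X_val <- cbind(rep(1, length(val)),
                   if (!is.null(covariates)) as.matrix(covariates)[val, , drop = FALSE])
    qr_tr <- qr(X_tr)
    e <- eigen(tcrossprod(Ztr), symmetric = TRUE)
    ev <- pmax(e$values, 0)
    B <- tcrossprod(Zval, Ztr) %*% e$vectors  # cross-Gram times U
    for (j in seq_len(q)) {
      beta <- qr.coef(qr_tr, ymat[tr, j])
      ytr <- ymat[tr, j] - drop(X_tr %*% beta)
      yval <- ymat[val, j] - drop(X_val %*% beta)
      a <- drop(crossprod(e$vectors, ytr))
      for (g in seq_along(grid)) {
        lam <- p_used * (1 - grid[g]) / grid[g]
        pred <- drop(B %*% (a / (ev + lam)))
        sse[f, g, j] <- sum((yval - pred)^2)
      }
    }
    nval[f] <- length(val)
  }
  lapply(seq_len(q), function(j) {
    err <- colSums(sse[, , j, drop = FALSE][, , 1]) / sum(nval)
    new_h2_fit(grid, err, p_used, n, "kfold_cv")
  })
}

#' Profile-REML oracle on the heritability grid
#'
#' Evaluates the restricted log-likelihood of
#' `y ~ N(mu 1 + X beta, sigma_tot^2 (h2 K + (1 - h2) I))`, with
#' `K = Z Z' / p` the genetic relatedness matrix, on a heritability grid.
#' The total variance is profiled out analytically and fixed effects are
#' removed by the same semi-orthogonal contrast used for GCV, so a single
#' eigendecomposition serves the whole grid (and every phenotype column
#' when `y` is a matrix). Intended as an independent comparator for the
#' GCV estimators, not as a replacement for iterative AI-REML software.
#'
#' @param geno genotype input as in [estimate_h2()], or a precomputed
#'   `grm` object.
#' @param y phenotype vector or matrix.
#' @param covariates optional covariate matrix.
#' @param grid heritability grid.
#' @param cache optional [svd_cache()] of the empirically standardized
#'   genotypes, usable in the intercept-only case.
#' @return an `h2_fit` (or list of them); the curve's `err` holds the
#'   negative restricted log-likelihood, so the argmin is the REML
#'   estimate. A `flat` attribute on the curve flags likelihoods with
#'   numerically no curvature (e.g. `K = I`).
#' @export
reml_profile_oracle <- function(geno, y, covariates = NULL,
                                grid = h2_default_grid(), cache = NULL) {
  if (any(grid <= 0 | grid >= 1)) stop("grid must lie strictly inside (0, 1)")
  single <- is.null(dim(y))
  ymat <- as.matrix(y)
  n <- nrow(ymat)

  use_shortcut <- !inherits(geno, "grm") && is.null(covariates)
  if (use_shortcut) {
    Zs <- if (inherits(geno, "standardized_genotypes")) geno
          else standardize(geno, mode = "empirical")
    use_shortcut <- ncol(Zs$Z) >= n  # thin SVD covers the contrast space
  }
  if (use_shortcut) {
    # intercept-only, p >= n: the spectrum of the contrasted GRM is
    # d^2[-n]/p for the same SVD used by projection GCV
    p_used <- ncol(Zs$Z)
    if (is.null(cache)) cache <- svd_cache(Zs$Z, compute_v = FALSE)
    lamK <- pmax(cache$d[-n]^2, 0) / p_used
    W <- cache$U[, -n, drop = FALSE]
    m <- n - 1L
    wmat <- crossprod(W, ymat)
  } else {
    if (inherits(geno, "grm")) {
      K <- geno$K
      p_used <- attr(geno, "p") %||% n
    } else {
      if (!exists("Zs", inherits = FALSE)) {
        Zs <- if (inherits(geno, "standardized_genotypes")) geno
              else standardize(geno, mode = "empirical")
      }
      p_used <- ncol(Zs$Z)
      K <- tcrossprod(Zs$Z) / p_used
    }
    if (max(abs(K - t(K))) > 1e-8) stop("GRM must be symmetric")
    cb <- build_contrast(n, X = covariates)
    Kt <- cb$C %*% K %*% t(cb$C)
    e <- eigen(Kt, symmetric = TRUE)
    if (min(e$values) < -1e-6 * max(abs(e$values))) {
      stop("GRM is not positive semi-definite beyond tolerance")
    }
    lamK <- pmax(e$values, 0)
    m <- cb$m
    wmat <- crossprod(e$vectors, cb$C %*% ymat)
  }

  fits <- lapply(seq_len(ncol(ymat)), function(j) {
    w2 <- wmat[, j]^2
    negll <- vapply(grid, function(h) {
      v <- h * lamK + (1 - h)
      s2 <- mean(w2 / v)
      0.5 * (m * log(s2) + sum(log(v)) + m)
    }, numeric(1))
    fit <- new_h2_fit(grid, negll, p_used, n, "reml_oracle")
    attr(fit$curve, "flat") <- diff(range(negll)) < m * 1e-10
    fit
  })
  if (single) fits[[1]] else fits
}

`%||%` <- function(a, b) if (is.null(a)) b else a
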