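# Ridge estimation in primal and dual forms, hat-matrix machinery, and the
# SVD cache reused by every lambda sweep. The primal solution
# (Z'Z + lambda I)^-1 Z'y and the dual solution Z'(ZZ' + lambda I)^-1 y are
# algebraically identical; the cheaper route is chosen by min(n, p).

#' Thin singular value decomposition cache
#'
#' Computes (and caches) a thin SVD `Z = U diag(d) V'`. Singular values
#' below `rank_tol * max(d)` are snapped to exactly zero: the contrast
#' construction for empirically centered data depends on identifying the
#' exact null space that centering creates. For large p the right singular
#' vectors are not needed by GCV; set `compute_v = FALSE` to obtain `U`
#' and `d` from the eigendecomposition of `Z Z'` only.
#'
#' @param Z numeric matrix (or `standardized_genotypes`).
#' @param rank_tol relative tolerance for treating singular values as
#'   zero; default `max(dim(Z)) * .Machine$double.eps`.
#' @param compute_v keep the right singular vectors (default `TRUE`).
#' @return object of class `ridge_svd` with fields `U` (n x k), `d`
#'   (length k, nonincreasing, zeros snapped), `V` (p x k or `NULL`),
#'   `n`, `p`, `rank_tol`.
#' @export
svd_cache <- function(Z, rank_tol = NULL, compute_v = TRUE) {
  if (inherits(Z, "standardized_genotypes")) Z <- Z$Z
  Z <- as.matrix(Z)
  if (!all(is.finite(Z))) stop("Z contains non-finite entries")
  n <- nrow(Z); p <- ncol(Z)
  k <- min(n, p)
  if (is.null(rank_tol)) rank_tol <- max(n, p) * .Machine$double.eps
  if (compute_v) {
    s <- svd(Z, nu = k, nv = k)
    U <- s$u; d <- s$d[seq_len(k)]; V <- s$v
  } else if (n <= p) {
    e <- eigen(tcrossprod(Z), symmetric = TRUE)
    U <- e$vectors
    d <- sqrt(pmax(e$values, 0))
    V <- NULL
  } else {
    e <- eigen(crossprod(Z), symmetric = TRUE)
    d <- sqrt(pmax(e$values, 0))
    pos <- d > 0
    U <- matrix(0, n, k)
    U[, pos] <- Z %*% sweep(e$vectors[, pos, drop = FALSE], 2, d[pos], "/")
    V <- NULL
  }
  d[d < rank_tol * max(d, 0)] <- 0
  structure(list(U = U, d = d, V = V, n = n, p = p, rank_tol = rank_tol),
            class = "ridge_svd")
}

#' @export
print.ridge_svd <- function(x, ...) {
  cat(sprintf("ridge_svd: %d x %d, rank %d of %d stored singular values\n",
              x$n, x$p, sum(x$d > 0), length(x$d)))
  invisible(x)
}

#' Effective degrees of freedom of the ridge hat matrix
#'
#' Returns `tr(H_lambda) = sum_i d_i^2 / (d_i^2 + lambda)`, the effective
#' model dimension, computed from cached singular values.
#'
#' @param cache a [svd_cache()] object.
#' @param lam positive penalty.
#' @return scalar in `[0, min(n, p)]`.
#' @export
hat_trace <- function(cache, lam) {
  if (lam <= 0) stop("lam must be positive")
  d2 <- cache$d^2
  sum(d2 / (d2 + lam))
}

#' Fit a ridge regression
#'
#' Solves `min_u ||y - Z u||^2 + lambda ||u||^2`. The primal form
#' `(Z'Z + lambda I)^-1 Z' y`, the dual form `Z'(Z Z' + lambda I)^-1 y`
#' and the SVD route give identical estimates; `route` selects one, with
#' `"auto"` choosing by `min(n, p)` (SVD when a cache is supplied).
#'
#' @param Z numeric matrix (or `standardized_genotypes`).
#' @param y response vector of length n.
#' @param lam penalty; must be positive when p > n (the unpenalized
#'   problem is not identifiable there). `lam = 0` is allowed when Z has
#'   full column rank.
#' @param cache optional [svd_cache()] of `Z` (with `V` for the SVD route).
#' @param route `"auto"`, `"primal"`, `"dual"` or `"svd"`.
#' @return object of class `ridge_fit` with fields `lam`, `u_hat`,
#'   `fitted`, `hat_trace`.
#' @export
ridge_fit <- function(Z, y, lam, cache = NULL,
                      route = c("auto", "primal", "dual", "svd")) {
  route <- match.arg(route)
  if (inherits(Z, "standardized_genotypes")) Z <- Z$Z
  Z <- as.matrix(Z)
  n <- nrow(Z); p <- ncol(Z)
  if (length(y) != n) stop("length(y) must equal nrow(Z)")
  if (lam < 0) stop("lam must be nonnegative")
  if (lam == 0 && p > n) {
    stop("lam = 0 with p > n: the unpenalized least-squares problem is ",
         "not identifiable (infinitely many interpolating solutions)")
  }
  if (route == "auto") {
    route <- if (!is.null(cache) && !is.null(cache$V)) "svd"
             else if (n < p) "dual" else "primal"
  }
  u_hat <- switch(route,
    primal = drop(solve(crossprod(Z) + diag(lam, p), crossprod(Z, y))),
    dual = drop(crossprod(Z, solve(tcrossprod(Z) + diag(lam, n), y))),
    svd = {
      if (is.null(cache) || is.null(cache$V)) cache <- svd_cache(Z)
      d <- cache$d
      a <- drop(crossprod(cache$U, y))
      w <- ifelse(d^2 + lam > 0, d / (d^2 + lam), 0)
      drop(cache$V %*% (w * a))
    })
  tr <- if (!is.null(cache)) hat_trace(cache, max(lam, .Machine$double.xmin))
        else {
          d2 <- svd(Z, nu = 0, nv = 0)$d^2
          sum(d2 / (d2 + lam))
        }
  structure(list(lam = lam, u_hat = u_hat, fitted = drop(Z %*% u_hat),
                 hat_trace = tr),
            class = "ridge_fit")
}

#' @export
print.ridge_fit <- function(x, ...) {
  cat(sprintf("ridge_fit: lambda = %.6g, %d effects, tr(H) = %.3f\n",
              x$lam, length(x$u_hat), x$hat_trace))
  invisible(x)
}

#' Map heritability to the ridge penalty, and back
#'
#' Under the homoscedastic random-effects model the genomic heritability
#' and the ridge penalty are linked by `h2 = p / (p + lambda)`,
#' equivalently `lambda = p (1 - h2) / h2`. The endpoints h2 = 0 and
#' h2 = 1 map to infinite and zero penalty and are rejected.
#'
#' @param h2 heritability strictly inside (0, 1).
#' @param p number of variants.
#' @return `lambda_from_h2`: positive penalty; `h2_from_lambda`: value in
#'   (0, 1).
#' @export
lambda_from_h2 <- function(h2, p) {
  if (any(h2 <= 0 | h2 >= 1)) stop("h2 must lie strictly inside (0, 1)")
  p * (1 - h2) / h2
}

#' @rdname lambda_from_h2
#' @param lam positive penalty.
#' @export
h2_from_lambda <- function(lam, p) {
  if (any(lam <= 0)) stop("lam must be positive")
  p / (p + lam)
}
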