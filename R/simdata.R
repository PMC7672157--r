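# Simulation of linkage-equilibrium genotypes and additive polygenic traits.
#
# The simulated scenario is the classical independent-loci design: variant
# frequencies are uniform on [0.05, 0.5], allele counts are Binomial(2, f),
# a fraction f_c of variants carries i.i.d. normal effects with variance
# h2 / (p * f_c), and the environmental noise has variance 1 - h2, so the
# phenotype has unit variance in expectation.

#' Construct a genotype matrix object
#'
#' @param counts integer-like n x p matrix of allele counts in \{0, 1, 2\}
#'   (`NA` allowed for missing genotypes in real data).
#' @param sample_ids character vector of length n (default `s1..sn`).
#' @param variant_ids character vector of length p (default `v1..vp`).
#' @param true_freqs optional length-p vector of the generating allele
#'   frequencies, strictly inside (0, 1).
#' @return an object of class `genotype_matrix` with fields `counts`,
#'   `sample_ids`, `variant_ids`, `true_freqs`.
#' @export
genotype_matrix <- function(counts, sample_ids = NULL, variant_ids = NULL,
                            true_freqs = NULL) {
  counts <- as.matrix(counts)
  if (length(counts) && !all(is.na(counts))) {
    rng <- range(counts, na.rm = TRUE)
    whole <- is.integer(counts) ||
      !any(counts != floor(counts), na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 2 || !whole) {
      stop("genotype counts must be 0, 1, 2 or NA")
    }
  }
  n <- nrow(counts); p <- ncol(counts)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  if (is.null(variant_ids)) variant_ids <- paste0("v", seq_len(p))
  if (length(sample_ids) != n) stop("sample_ids must have length nrow(counts)")
  if (length(variant_ids) != p) stop("variant_ids must have length ncol(counts)")
  if (!is.null(true_freqs)) {
    if (length(true_freqs) != p) stop("true_freqs must have length ncol(counts)")
    if (any(true_freqs <= 0 | true_freqs >= 1)) {
      stop("true_freqs must lie strictly inside (0, 1)")
    }
  }
  structure(list(counts = counts, sample_ids = sample_ids,
                 variant_ids = variant_ids, true_freqs = true_freqs),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (%s true frequencies)\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$true_freqs)) "without" else "with"))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$counts)

#' Simulate variant allele frequencies
#'
#' Frequencies are drawn i.i.d. uniform on \[0.05, 0.5\], the standard
#' range excluding near-monomorphic variants.
#'
#' @param p number of variants (nonnegative integer).
#' @param seed optional integer seed.
#' @return numeric vector of length `p`.
#' @export
simulate_frequencies <- function(p, seed = NULL) {
  if (length(p) != 1 || is.na(p) || p < 0) stop("p must be a nonnegative integer")
  with_seed(seed, runif(p, min = 0.05, max = 0.5))
}

#' Simulate a linkage-equilibrium genotype matrix
#'
#' Entry (i, j) is drawn independently from Binomial(2, `freqs[j]`): the
#' independent-loci (perfect linkage equilibrium) scenario.
#'
#' @param freqs vector of allele frequencies, each strictly inside (0, 1).
#' @param n number of individuals.
#' @param seed optional integer seed.
#' @return a [genotype_matrix()] with `true_freqs = freqs`.
#' @export
simulate_genotypes <- function(freqs, n, seed = NULL) {
  if (any(freqs <= 0 | freqs >= 1)) stop("frequencies must lie strictly inside (0, 1)")
  if (length(n) != 1 || is.na(n) || n < 1) stop("n must be a positive integer")
  counts <- with_seed(seed, sim_binom2_matrix(as.integer(n), as.numeric(freqs)))
  genotype_matrix(counts, true_freqs = freqs)
}

#' Column-standardize a genotype matrix
#'
#' Three standardization modes are supported:
#' \describe{
#'   \item{`true_freq`}{uses the generating frequencies:
#'     `z = (m - 2 f) / sqrt(2 f (1 - f))`. Requires `true_freqs`.}
#'   \item{`empirical`}{column-wise `(m - mean) / sd` with the
#'     denominator-n (population) standard deviation, so that each column
#'     has exactly mean 0 and standard deviation 1.}
#'   \item{`external_set`}{applies centers and scales estimated on an
#'     independent sample (see `external_stats`), breaking the
#'     train/validation dependency created by empirical centering.}
#' }
#' Monomorphic columns (zero scale) cannot be standardized empirically;
#' they are removed and reported in the `removed` field rather than
#' producing divisions by zero.
#'
#' @param G a [genotype_matrix()] (or bare counts matrix).
#' @param mode `"true_freq"`, `"empirical"` or `"external_set"`.
#' @param external_stats for `external_set`: list with numeric fields
#'   `centers` and `scales` of length p (as returned in any
#'   `standardized_genotypes` object).
#' @return an object of class `standardized_genotypes` with fields `Z`
#'   (n x p numeric), `centers`, `scales`, `mode`, `variant_ids`,
#'   `sample_ids`, and `removed` (named integer vector of dropped columns).
#' @export
standardize <- function(G, mode = c("empirical", "true_freq", "external_set"),
                        external_stats = NULL) {
  mode <- match.arg(mode)
  if (is.matrix(G)) G <- genotype_matrix(G)
  M <- G$counts
  p <- ncol(M)
  removed <- integer(0)
  if (mode == "true_freq") {
    if (is.null(G$true_freqs)) stop("mode 'true_freq' requires true_freqs")
    centers <- 2 * G$true_freqs
    scales <- sqrt(2 * G$true_freqs * (1 - G$true_freqs))
  } else if (mode == "empirical") {
    st <- col_mean_sd(M)
    centers <- st[, 1]
    scales <- st[, 2]
    bad <- which(!is.finite(scales) | scales <= 0)
    if (length(bad)) {
      removed <- structure(bad, names = G$variant_ids[bad])
      M <- M[, -bad, drop = FALSE]
      centers <- centers[-bad]
      scales <- scales[-bad]
    }
  } else {
    if (is.null(external_stats) || is.null(external_stats$centers) ||
        is.null(external_stats$scales)) {
      stop("mode 'external_set' requires external_stats with centers and scales")
    }
    centers <- external_stats$centers
    scales <- external_stats$scales
    if (length(centers) != p || length(scales) != p) {
      stop("external_stats length does not match the number of variants")
    }
    bad <- which(!is.finite(scales) | scales <= 0)
    if (length(bad)) {
      removed <- structure(bad, names = G$variant_ids[bad])
      M <- M[, -bad, drop = FALSE]
      centers <- centers[-bad]
      scales <- scales[-bad]
    }
  }
  if (any(scales <= 0)) stop("non-positive scale encountered")
  Z <- standardize_matrix(M, as.numeric(centers), as.numeric(scales))
  keep <- if (length(removed)) setdiff(seq_len(p), removed) else seq_len(p)
  structure(list(Z = Z, centers = as.numeric(centers),
                 scales = as.numeric(scales), mode = mode,
                 sample_ids = G$sample_ids,
                 variant_ids = G$variant_ids[keep], removed = removed),
            class = "standardized_genotypes")
}

#' @export
print.standardized_genotypes <- function(x, ...) {
  cat(sprintf("standardized_genotypes: %d x %d, mode '%s'%s\n",
              nrow(x$Z), ncol(x$Z), x$mode,
              if (length(x$removed)) sprintf(", %d monomorphic columns removed",
                                             length(x$removed)) else ""))
  invisible(x)
}

#' Simulate an additive polygenic trait
#'
#' A fraction `f_c` of variants is sampled as causal; their effects are
#' i.i.d. normal with variance `h2_sim / (p * f_c)` and all other effects
#' are exactly zero, so the genetic variance is `h2_sim` in expectation.
#' The noise is `N(0, 1 - h2_sim)` and the phenotype is
#' `y = mu + Z u + X beta + e` (unit total variance in expectation).
#'
#' @param Z a `standardized_genotypes` object or bare numeric matrix.
#' @param h2_sim simulated heritability in \[0, 1\].
#' @param f_c fraction of causal variants in (0, 1\].
#' @param mu intercept (default 0).
#' @param X optional n x r covariate matrix; `beta` its effects.
#' @param beta optional length-r covariate effect vector.
#' @param seed optional integer seed.
#' @return an object of class `polygenic_trait` with fields `y`, `u`, `e`,
#'   `causal_idx`, `h2_sim`, `f_c`, `mu`, `X`, `beta`.
#' @export
simulate_phenotype <- function(Z, h2_sim, f_c = 1, mu = 0, X = NULL,
                               beta = NULL, seed = NULL) {
  Zm <- if (inherits(Z, "standardized_genotypes")) Z$Z else as.matrix(Z)
  n <- nrow(Zm); p <- ncol(Zm)
  if (length(h2_sim) != 1 || is.na(h2_sim) || h2_sim < 0 || h2_sim > 1) {
    stop("h2_sim must lie in [0, 1]")
  }
  if (f_c <= 0 || f_c > 1) stop("f_c must lie in (0, 1]")
  if (is.null(X) != is.null(beta)) stop("X and beta must be supplied together")
  with_seed(seed, {
    u <- numeric(p)
    causal_idx <- integer(0)
    if (h2_sim > 0) {
      n_causal <- max(1L, round(p * f_c))
      causal_idx <- sort(sample.int(p, n_causal))
      tau <- h2_sim / (p * f_c)
      u[causal_idx] <- rnorm(n_causal, mean = 0, sd = sqrt(tau))
    }
    e <- if (h2_sim < 1) rnorm(n, sd = sqrt(1 - h2_sim)) else numeric(n)
    y <- mu + drop(Zm %*% u) + e
    if (!is.null(X)) y <- y + drop(as.matrix(X) %*% beta)
    structure(list(y = y, u = u, e = e, causal_idx = causal_idx,
                   h2_sim = h2_sim, f_c = f_c, mu = mu, X = X, beta = beta),
              class = "polygenic_trait")
  })
}

#' Simulate a complete heritability study
#'
#' Convenience wrapper tying the generator's streams together: one
#' top-level seed spawns independent sub-streams for frequencies,
#' genotypes, effects and noise, so that changing `p` or adding a
#' standardization set does not perturb the noise draws.
#'
#' @param n training-set size.
#' @param p number of variants.
#' @param h2 simulated heritability.
#' @param f_c fraction of causal variants.
#' @param seed top-level integer seed.
#' @param n_std size of an optional disjoint standardization set
#'   (0 = none).
#' @param standardization `"true_freq"` (phenotype built on the
#'   truly-standardized matrix, the fully synthetic scenario) or
#'   `"empirical"`.
#' @return list with `geno` ([genotype_matrix()]), `Z`
#'   (`standardized_genotypes` used to build the phenotype), `trait`
#'   (`polygenic_trait`), and optionally `std` (list `geno`, `y` for the
#'   standardization set).
#' @export
sim_polygenic_study <- function(n, p, h2, f_c = 1, seed = NULL, n_std = 0,
                                standardization = c("true_freq", "empirical")) {
  standardization <- match.arg(standardization)
  freqs <- simulate_frequencies(p, seed = if (is.null(seed)) NULL else
    stream_seed(seed, "frequencies"))
  geno <- simulate_genotypes(freqs, n, seed = if (is.null(seed)) NULL else
    stream_seed(seed, "genotypes"))
  Z <- standardize(geno, mode = if (standardization == "true_freq")
    "true_freq" else "empirical")
  trait <- simulate_phenotype(Z, h2_sim = h2, f_c = f_c,
                              seed = if (is.null(seed)) NULL else
                                stream_seed(seed, "effects"))
  out <- list(geno = geno, Z = Z, trait = trait)
  if (n_std > 0) {
    g_std <- simulate_genotypes(freqs, n_std,
                                seed = if (is.null(seed)) NULL else
                                  stream_seed(seed, "std_genotypes"))
    g_std$sample_ids <- paste0("std", seq_len(n_std))
    Z_std <- standardize(g_std, mode = if (standardization == "true_freq")
      "true_freq" else "empirical")
    # same effect vector, fresh noise: the standardization set is an
    # independent sample from the same population and trait model
    e_std <- with_seed(if (is.null(seed)) NULL else
      stream_seed(seed, "std_noise"),
      rnorm(n_std, sd = sqrt(max(0, 1 - h2))))
    y_std <- drop(Z_std$Z %*% trait$u) + e_std
    out$std <- list(geno = g_std, y = y_std)
  }
  out
}

#' Rescale nested effect subsets
#'
#' For nested variant subsets of a global effect vector drawn at `p_max`,
#' the leading-p effects are multiplied by `sqrt(p_max / p)` so that the
#' genetic variance stays at its target for every subset size.
#'
#' @param u global effect vector of length `p_max`.
#' @param p subset size (leading variants, original order).
#' @return length-p rescaled effect vector.
#' @export
rescale_effects <- function(u, p) {
  p_max <- length(u)
  if (p < 1 || p > p_max) stop("p must lie in [1, length(u)]")
  u[seq_len(p)] * sqrt(p_max / p)
}
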