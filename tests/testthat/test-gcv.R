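test_that("gcv_error equals the dense hat-matrix criterion", {
  for (seed in 1:20) {
    n <- sample(5:12, 1); p <- sample(2:9, 1)
    Z <- rand_mat(n, p, seed = 1000 + seed)
    y <- with_seed(2000 + seed, rnorm(n))
    lam <- with_seed(3000 + seed, runif(1, 0.05, 10))
    expect_equal(gcv_error(y, Z, lam), dense_gcv(y, Z, lam),
                 tolerance = 1e-10)
  }
})

test_that("gcv_error tends to ||y||^2 at infinite penalty", {
  Z <- rand_mat(8, 3, seed = 81)
  y <- with_seed(82, rnorm(8))
  expect_equal(gcv_error(y, Z, 1e12), sum(y^2), tolerance = 1e-6)
})

test_that("empirical centering collapses the naive criterion as lambda -> 0", {
  # p > n, columns and phenotype empirically centered: the GCV error must
  # vanish with the penalty (the high-dimensional degeneracy)
  Z <- scale(rand_mat(15, 60, seed = 91))
  y0 <- with_seed(92, rnorm(15))
  y <- y0 - mean(y0)
  cache <- svd_cache(Z, compute_v = FALSE)
  errs <- vapply(10^seq(0, -6, by = -1), function(l) {
    gcv_error(y, Z, l, cache)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[length(errs)], 1e-6 * errs[1])

  # and exact leave-one-out shows the same collapse
  loos <- vapply(10^seq(0, -6, by = -1), function(l) loo_error(y, Z, l, cache),
                 numeric(1))
  expect_lt(loos[length(loos)], 1e-4 * loos[1])
})

test_that("loo_error matches brute-force refits and the null-model limit", {
  for (seed in 1:6) {
    Z <- rand_mat(12, 4, seed = 1100 + seed)
    y <- with_seed(1200 + seed, rnorm(12))
    lam <- with_seed(1300 + seed, runif(1, 0.2, 4))
    expect_equal(loo_error(y, Z, lam), brute_loo(y, Z, lam),
                 tolerance = 1e-8)
  }
  Z <- rand_mat(10, 3, seed = 1400)
  y <- with_seed(1401, rnorm(10))
  expect_equal(loo_error(y, Z, 1e12), sum(y^2), tolerance = 1e-6)
})

test_that("contrast bases annihilate the fixed-effect span", {
  cb <- build_contrast(3)
  expect_equal(dim(cb$C), c(2L, 3L))
  expect_equal(cb$C %*% t(cb$C), diag(2), tolerance = 1e-10)
  expect_lt(max(abs(cb$C %*% rep(1, 3))), 1e-10)

  X <- rand_mat(20, 2, seed = 121)
  cb2 <- build_contrast(20, X = X)
  expect_equal(cb2$m, 17L)
  expect_equal(cb2$C %*% t(cb2$C), diag(17), tolerance = 1e-8)
  mu <- 0.7; beta <- c(-1.2, 0.4)
  expect_lt(max(abs(cb2$C %*% (mu + X %*% beta))), 1e-10)

  expect_error(build_contrast(20, X = cbind(1, X[, 1])), "collinear")
})

test_that("the intercept-only SVD shortcut diagonalizes the contrasted Gram", {
  Z <- scale(rand_mat(12, 40, seed = 131))
  cb <- build_contrast(12, Z = Z)
  G <- cb$C %*% tcrossprod(Z) %*% t(cb$C)
  off <- G - diag(diag(G))
  expect_lt(max(abs(off)), 1e-8 * max(diag(G)))
  expect_lt(max(abs(cb$C %*% rep(1, 12))), 1e-8)
})

test_that("the criterion is invariant to the choice of contrast basis", {
  s <- small_study(n = 80, p = 200, h2 = 0.5, seed = 141)
  Zs <- standardize(s$geno, "empirical")
  grid <- seq(0.05, 0.95, by = 0.05)
  # route 1: implicit SVD shortcut inside estimate_h2
  e1 <- estimate_h2(Zs, s$trait$y, "gcv_projection", grid = grid)
  # route 2: explicit QR-based contrast of the same span
  cb <- build_contrast(80)
  CZ <- cb$C %*% Zs$Z
  cy <- drop(cb$C %*% s$trait$y)
  cache <- svd_cache(CZ, compute_v = FALSE)
  err2 <- vapply(grid, function(h) {
    gcv_error(cy, CZ, lambda_from_h2(h, ncol(CZ)), cache)
  }, numeric(1))
  expect_equal(e1$curve$err, err2, tolerance = 1e-8)
})

test_that("the projection criterion matches the dense contrast when n > p", {
  s <- small_study(n = 50, p = 20, h2 = 0.5, seed = 145)
  Zs <- standardize(s$geno, "empirical")
  cb <- build_contrast(50)
  CZ <- cb$C %*% Zs$Z
  cy <- drop(cb$C %*% s$trait$y)
  grid <- c(0.2, 0.5, 0.8)
  fit <- estimate_h2(Zs, s$trait$y, "gcv_projection", grid = grid)
  dense <- vapply(grid, function(h) {
    dense_gcv(cy, CZ, lambda_from_h2(h, ncol(CZ)))
  }, numeric(1))
  expect_equal(fit$curve$err, dense, tolerance = 1e-8)
})

test_that("single-point grids return that point and ties break low", {
  s <- small_study(n = 40, p = 30, h2 = 0.4, seed = 151)
  est <- estimate_h2(s$geno, s$trait$y, "gcv_projection", grid = 0.5)
  expect_equal(est$estimate$h2, 0.5)
  expect_equal(est$estimate$lam, 30 * (1 - 0.5) / 0.5)
  cv <- new_gcv_curve(c(0.2, 0.4), c(1, 2), c(3, 3), "gcv_naive")
  expect_equal(cv$argmin_idx, 1L)
})

test_that("estimate consistency: h2 = p/(p + lambda) to 1e-10", {
  s <- small_study(n = 60, p = 90, h2 = 0.5, seed = 161)
  for (m in c("gcv_projection", "gcv_naive")) {
    est <- estimate_h2(s$geno, s$trait$y, m)$estimate
    expect_equal(est$h2, est$p_used / (est$p_used + est$lam),
                 tolerance = 1e-10)
  }
})

test_that("two-set mode requires a disjoint standardization set", {
  s <- small_study(n = 50, p = 80, h2 = 0.5, seed = 171, n_std = 30)
  expect_error(estimate_h2(s$geno, s$trait$y, "gcv_two_set"), "std_set")
  overlap <- s$std
  overlap$geno$sample_ids <- s$geno$sample_ids[seq_len(30)]
  expect_error(estimate_h2(s$geno, s$trait$y, "gcv_two_set",
                           std_set = overlap), "share sample ids")
  est <- estimate_h2(s$geno, s$trait$y, "gcv_two_set", std_set = s$std)
  expect_s3_class(est, "h2_fit")
})

test_that("externally standardized p > n systems need no contrast", {
  # centers/scales from an independent sample: no lambda -> 0 collapse,
  # the criterion has an interior minimum on the grid
  s <- sim_polygenic_study(100, 400, h2 = 0.5, seed = 181, n_std = 100)
  est <- estimate_h2(s$geno, s$trait$y, "gcv_two_set", std_set = s$std)
  err <- est$curve$err
  expect_gt(est$curve$argmin_idx, 1)
  expect_lt(est$curve$argmin_idx, length(err))
  # while the naive criterion keeps falling toward the grid maximum
  naive <- estimate_h2(s$geno, s$trait$y, "gcv_naive")
  expect_equal(naive$estimate$h2, 0.99)
})

test_that("kfold cross-validation recovers a plausible heritability", {
  s <- small_study(n = 150, p = 100, h2 = 0.6, seed = 191)
  est <- estimate_h2(s$geno, s$trait$y, "kfold_cv", k = 5, seed = 3)
  expect_s3_class(est, "h2_fit")
  expect_true(est$estimate$h2 > 0.2 && est$estimate$h2 < 0.95)
  # reproducible under the same fold seed
  est2 <- estimate_h2(s$geno, s$trait$y, "kfold_cv", k = 5, seed = 3)
  expect_identical(est$curve$err, est2$curve$err)
})

test_that("the REML oracle detects flat likelihoods and pure noise", {
  # GRM = I: likelihood flat in h2
  K <- structure(list(K = diag(20), sample_ids = paste0("s", 1:20)),
                 p = 20, class = "grm")
  y <- with_seed(201, rnorm(20))
  fit <- reml_profile_oracle(K, y, grid = seq(0.1, 0.9, by = 0.1))
  expect_true(attr(fit$curve, "flat"))

  # h2 = 0 data: estimate at the grid minimum
  s <- small_study(n = 150, p = 80, h2 = 0, seed = 202)
  est <- reml_profile_oracle(s$geno, s$trait$y,
                             grid = seq(0.01, 0.99, by = 0.01))
  expect_lte(est$estimate$h2, 0.1)
})

test_that("REML and projection GCV agree on simulated data", {
  diffs <- vapply(1:5, function(r) {
    s <- sim_polygenic_study(300, 1000, h2 = 0.5, seed = 210 + r)
    g <- estimate_h2(s$geno, s$trait$y, "gcv_projection")$estimate$h2
    m <- reml_profile_oracle(s$geno, s$trait$y)$estimate$h2
    abs(g - m)
  }, numeric(1))
  expect_lt(mean(diffs), 0.05)
})
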