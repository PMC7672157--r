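h2_grid_dense <- seq(0.01, 0.99, by = 0.01)

test_that("both error branches agree at n = p and at the printed values", {
  expect_equal(theory_test_error(0.6, 100, 100), 1 - 0.6^2)
  for (h2 in h2_grid_dense) {
    lo <- theory_test_error(h2, 500, 500)          # p >= n branch
    hi <- (1 - h2) * (1 + h2) / (1 + h2 * (1 - 1)) # n >= p branch at ratio 1
    expect_equal(lo, hi, tolerance = 1e-12)
  }
  # train error branches both reduce to (1-h2)^2 at n = p
  expect_equal(theory_train_error(h2_grid_dense, 200, 200),
               (1 - h2_grid_dense)^2, tolerance = 1e-12)
  expect_equal(theory_train_error(0.6, 100, 1000), 0.16)
  # corr2 branches both give h^4 at n = p
  expect_equal(theory_corr2(h2_grid_dense, 300, 300), h2_grid_dense^2,
               tolerance = 1e-12)
})

test_that("theory limits: irreducible error and heritability ceilings", {
  for (h2 in c(0.1, 0.5, 0.9)) {
    expect_equal(theory_test_error(h2, 1e9, 10), 1 - h2, tolerance = 1e-6)
    expect_equal(theory_test_error(h2, 10, 1e9), 1, tolerance = 1e-6)
    expect_equal(theory_train_error(h2, 1e9, 10), 1 - h2, tolerance = 1e-5)
    expect_equal(theory_corr2(h2, 1e9, 10), h2, tolerance = 1e-6)
    expect_equal(theory_corr2(h2, 10, 1e9), 0, tolerance = 1e-6)
  }
})

test_that("error decreases and correlation increases with n/p", {
  h2 <- 0.6
  ns <- round(10^seq(1, 5, length.out = 40))
  errs <- vapply(ns, function(n) theory_test_error(h2, n, 1000), numeric(1))
  cors <- vapply(ns, function(n) theory_corr2(h2, n, 1000), numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
  expect_true(all(diff(cors) >= -1e-12))
  # more heritable traits are easier at any fixed ratio
  errs_h <- theory_test_error(seq(0.1, 0.9, by = 0.1), 500, 2000)
  expect_true(all(diff(errs_h) < 0))
  # bounds: never below irreducible error, correlation never above h2
  for (n in c(50, 1000, 50000)) {
    expect_gte(theory_test_error(h2, n, 1000), 1 - h2 - 1e-12)
    expect_lte(theory_corr2(h2, n, 1000), h2 + 1e-12)
  }
})

test_that("the over-fitting gap is nonnegative, shrinking in n/p", {
  h2 <- 0.5
  ns <- round(10^seq(1.5, 5, length.out = 30))
  gaps <- vapply(ns, function(n) {
    theory_test_error(h2, n, 1000) - theory_train_error(h2, n, 1000)
  }, numeric(1))
  expect_true(all(gaps >= -1e-12))
  expect_true(all(diff(gaps) <= 1e-10))
  expect_lt(gaps[length(gaps)], 0.02)
})

test_that("exact decomposition: zero bias without signal or without penalty", {
  Z <- rand_mat(30, 5, seed = 301)
  d0 <- exact_decomposition(Z, rep(0, 5), lam = 2, sigma2 = 0.5)
  expect_equal(d0$bias2, 0)
  expect_equal(d0$total, d0$irreducible + d0$variance)

  u <- with_seed(302, rnorm(5))
  d_small <- exact_decomposition(Z, u, lam = 1e-8, sigma2 = 0.5)
  expect_lt(d_small$bias2, 1e-12)
  expect_error(exact_decomposition(Z, rnorm(4), 1, 0.5), "length")
})

test_that("decomposition components match a Monte-Carlo experiment", {
  n <- 300; p <- 50; h2 <- 0.5
  sigma2 <- 1 - h2
  Z <- standardize(simulate_genotypes(simulate_frequencies(p, seed = 311),
                                      n, seed = 312), "true_freq")$Z
  u <- with_seed(313, rnorm(p, sd = sqrt(h2 / p)))
  lam <- lambda_from_h2(h2, p)
  dec <- exact_decomposition(Z, u, lam, sigma2)

  # simulate: fixed Z and u; noise redrawn per training replicate, fresh
  # test individuals with E[z]=0, var(z)=I
  signal <- drop(Z %*% u)
  K <- solve(crossprod(Z) + diag(lam, p), t(Z))
  errs <- with_seed(314, vapply(1:200, function(k) {
    y <- signal + rnorm(n, sd = sqrt(sigma2))
    u_hat <- drop(K %*% y)
    z_te <- matrix(rnorm(2000 * p), 2000, p)
    y_te <- drop(z_te %*% u) + rnorm(2000, sd = sqrt(sigma2))
    mean((y_te - drop(z_te %*% u_hat))^2)
  }, numeric(1)))
  se <- sd(errs) / sqrt(length(errs))
  expect_lt(abs(mean(errs) - dec$total), 3 * se + 1e-8)
})

test_that("at an orthogonal design the decomposition meets the closed form", {
  # Z Z' = p I with effects spreading h2 evenly: the approximation's own
  # derivation becomes exact
  n <- 40; p <- 100; h2 <- 0.35
  Z <- cbind(diag(sqrt(p), n), matrix(0, n, p - n))
  u <- rep(sqrt(h2 / p), p)
  lam <- lambda_from_h2(h2, p)
  dec <- exact_decomposition(Z, u, lam, 1 - h2)
  expect_equal(dec$total, theory_test_error(h2, n, p), tolerance = 1e-8)
})

test_that("effective SNP regression recovers constructed slopes", {
  h2 <- 0.6
  ns <- c(1000, 2000, 5000)
  p <- 50000
  obs1 <- data.frame(n = ns, p = p, mse = 1 - (ns / p) * h2^2)
  expect_equal(effective_snp_fit(obs1, h2)$slope, 1, tolerance = 1e-10)

  # mse generated with p_e = p/5: slope must be exactly 5
  obs5 <- data.frame(n = ns, p = p, mse = 1 - (ns / (p / 5)) * h2^2)
  expect_equal(effective_snp_fit(obs5, h2)$slope, 5, tolerance = 1e-10)

  bad <- rbind(obs1, data.frame(n = 100, p = p, mse = 1.2))
  expect_warning(fit <- effective_snp_fit(bad, h2), "excluded")
  expect_equal(fit$slope, 1, tolerance = 1e-10)
  expect_error(effective_snp_fit(data.frame(n = 10, p = 5, mse = 0.5), h2),
               "p > n")
})

test_that("simulated independent-variant errors give unit effective-SNP slope", {
  h2 <- 0.6
  rows <- do.call(rbind, lapply(c(800, 1600), function(n) {
    exp <- replicate_experiment(list(n = n, n_te = 4000, p_list = 3000,
                                     h2 = h2, n_replicates = 8,
                                     seed = 321 + n))
    data.frame(n = n, p = 3000, mse = attr(exp, "summary")$err)
  }))
  fit <- effective_snp_fit(rows, h2)
  expect_equal(fit$slope, 1, tolerance = 0.15)
})

test_that("theory_curve tabulates the requested curve", {
  tab <- theory_curve(0.6, "test_error", -2, 2, points = 50)
  expect_equal(nrow(tab), 50)
  expect_true(all(diff(tab$value) <= 1e-9))
})
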