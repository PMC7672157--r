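make_split <- function(n_tr = 60, n_te = 40, p = 30, h2 = 0.5, seed = 401) {
  f <- simulate_frequencies(p, seed = seed)
  Ztr <- standardize(simulate_genotypes(f, n_tr, seed = seed + 1), "true_freq")
  Zte <- standardize(simulate_genotypes(f, n_te, seed = seed + 2), "true_freq")
  u <- with_seed(seed + 3, rnorm(p, sd = sqrt(h2 / p)))
  e_tr <- with_seed(seed + 4, rnorm(n_tr, sd = sqrt(1 - h2)))
  e_te <- with_seed(seed + 5, rnorm(n_te, sd = sqrt(1 - h2)))
  list(train = list(Z = Ztr, y = drop(Ztr$Z %*% u) + e_tr),
       test = list(Z = Zte, y = drop(Zte$Z %*% u) + e_te),
       u = u)
}

test_that("an infinite penalty yields the null predictor", {
  sp <- make_split()
  rep <- fit_predict(sp$train, sp$test, lam = 1e12)
  expect_lt(max(abs(rep$pred)), 1e-6)
  expect_equal(rep$mse, mean(sp$test$y^2), tolerance = 1e-6)
})

test_that("contrasted, plain dual and primal routes predict identically", {
  sp <- make_split(n_tr = 25, n_te = 15, p = 40)
  lam <- 12.5
  plain <- fit_predict(sp$train, sp$test, lam = lam, contrast = "none")
  u_primal <- drop(solve(crossprod(sp$train$Z$Z) + diag(lam, 40),
                         crossprod(sp$train$Z$Z, sp$train$y)))
  expect_lt(max(abs(plain$u_hat - u_primal)), 1e-8)

  # an explicit intercept contrast on centered data matches the plain fit
  y_c <- sp$train$y - mean(sp$train$y)
  tr_c <- list(Z = sp$train$Z, y = y_c)
  cb <- build_contrast(25)
  CZ <- cb$C %*% sp$train$Z$Z
  u_contrast <- drop(crossprod(CZ, solve(tcrossprod(CZ) + diag(lam, cb$m),
                                         cb$C %*% y_c)))
  with_c <- fit_predict(tr_c, sp$test, lam = lam, center_y = TRUE)
  expect_lt(max(abs(with_c$u_hat - u_contrast)), 1e-8)
})

test_that("variant mismatches between sets are refused", {
  sp <- make_split()
  te_bad <- sp$test
  te_bad$Z$Z <- te_bad$Z$Z[, -1]
  te_bad$Z$variant_ids <- te_bad$Z$variant_ids[-1]
  expect_error(fit_predict(sp$train, te_bad, lam = 1), "different variant")
})

test_that("mean corr2 over training replicates tracks the closed form (n >> p)", {
  exp <- replicate_experiment(list(n = 1000, n_te = 2000, p_list = 20,
                                   h2 = 0.6, n_replicates = 30, seed = 411))
  s <- attr(exp, "summary")
  ens <- exp[[1]]
  # with only 20 causal effects the realized genetic variance of the one
  # global draw deviates noticeably from its 0.6 target; score against
  # the theory evaluated at the realized heritability
  h2_real <- var(ens$signal) / var(ens$y_te)
  expect_lt(abs(s$corr2_mean - theory_corr2(h2_real, 1000, 20)),
            3 * s$corr2_se + 0.015)
  expect_lt(abs(s$err - s$theory_err), 3 * s$err_se + 0.05)
  # and the nominal theory is still the right scale
  expect_lt(abs(s$corr2_mean - s$theory_corr2), 0.1)
})

test_that("replicate ensembles satisfy the error decomposition identity", {
  exp <- replicate_experiment(list(n = 150, n_te = 500, p_list = c(600, 60),
                                   h2 = 0.5, n_replicates = 12, seed = 421))
  for (ens in exp) {
    # err ~ bias2 + var + irreducible, within Monte-Carlo tolerance
    gap <- ens$err - (ens$bias2 + ens$var + (1 - ens$h2))
    expect_lt(abs(gap), 0.1)
    expect_gte(ens$err, 1 - ens$h2 - 0.1)  # never below irreducible
  }
  # monotone trend: more individuals per variant helps
  s <- attr(exp, "summary")
  expect_lt(s$err[1], 1.1)
  expect_gt(s$corr2_mean[s$p == 60], s$corr2_mean[s$p == 600])
  expect_lt(s$err[s$p == 60], s$err[s$p == 600])
})

test_that("single replicates have no ensemble spread; h2 = 0 has no signal", {
  one <- replicate_experiment(list(n = 50, n_te = 80, p_list = 40, h2 = 0.4,
                                   n_replicates = 1, seed = 431))
  expect_equal(one[[1]]$var, 0)

  null <- replicate_experiment(list(n = 80, n_te = 300, p_list = 60, h2 = 0,
                                    n_replicates = 6, seed = 432))
  expect_lt(null[[1]]$corr2_mean, 0.05)
  expect_equal(null[[1]]$err, 1, tolerance = 0.15)
})

test_that("error-bar strategies: replicate spread vs individual spread", {
  ens <- replicate_experiment(list(n = 200, n_te = 400, p_list = 800,
                                   h2 = 0.6, n_replicates = 10,
                                   seed = 441))[[1]]
  bars <- error_bar_decomposition(ens)
  # individual errors are dominated by the environmental residual: their
  # spread across individuals far exceeds the training-replicate spread
  expect_gt(bars$sd_across_individuals, bars$sd_across_replicates)

  # identical replicates: zero spread across replicates
  fake <- ens
  fake$predictions <- matrix(ens$predictions[, 1], ens$n_te, 3)
  fake$mse_k <- rep(ens$mse_k[1], 3)
  fake$n_replicates <- 3
  expect_equal(error_bar_decomposition(fake)$sd_across_replicates, 0)

  # homoscedastic pure-noise test set: per-individual mean squared error
  # behaves like sigma^2 chi2_1, whose sd is sigma^2 sqrt(2)
  null <- replicate_experiment(list(n = 60, n_te = 3000, p_list = 30, h2 = 0,
                                    n_replicates = 5, seed = 442))[[1]]
  bars0 <- error_bar_decomposition(null)
  expect_equal(bars0$sd_across_individuals, sqrt(2), tolerance = 0.15)
})
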