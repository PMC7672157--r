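# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so each file's suite runs in seconds.

# Random dense matrix with reproducible entries.
rand_mat <- function(n, p, seed = 1) {
  with_seed(seed, matrix(rnorm(n * p), n, p))
}

# Small simulated study reused across files.
small_study <- function(n = 120, p = 300, h2 = 0.5, f_c = 1, seed = 11,
                        n_std = 0) {
  sim_polygenic_study(n, p, h2, f_c = f_c, seed = seed, n_std = n_std)
}

# Dense-algebra GCV criterion (independent oracle for gcv_error): builds
# the hat matrix explicitly through a matrix inverse.
dense_gcv <- function(y, Z, lam) {
  n <- nrow(Z)
  H <- Z %*% solve(crossprod(Z) + diag(lam, ncol(Z)), t(Z))
  num <- sum((y - H %*% y)^2)
  den <- (sum(diag(diag(n) - H)) / n)^2
  num / den
}

# Delta-method standard deviation induced on the theoretical error and
# squared correlation by the chi-square spread of a single global effect
# draw (realized genetic variance h2 * chisq_p / p).
effect_draw_se <- function(h2, n, p) {
  sd_g <- h2 * sqrt(2 / p)
  eps <- 1e-4
  derr <- (theory_test_error(h2 + eps, n, p) -
             theory_test_error(h2 - eps, n, p)) / (2 * eps)
  dc2 <- (theory_corr2(h2 + eps, n, p) -
            theory_corr2(h2 - eps, n, p)) / (2 * eps)
  list(err = abs(derr) * sd_g, corr2 = abs(dc2) * sd_g)
}

# Brute-force leave-one-out: n refits with observation i held out.
brute_loo <- function(y, Z, lam) {
  n <- nrow(Z)
  sum(vapply(seq_len(n), function(i) {
    Zi <- Z[-i, , drop = FALSE]
    u <- solve(crossprod(Zi) + diag(lam, ncol(Z)), crossprod(Zi, y[-i]))
    (y[i] - drop(Z[i, , drop = FALSE] %*% u))^2
  }, numeric(1)))
}
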