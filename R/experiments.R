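# Scripted, seeded reproductions of the package's validating simulation
# studies, at configurable scale: the high-dimensional centering-bias
# negative control, the parameter-recovery grid, and the accuracy sweeps
# against the closed-form theory.

#' Build an experiment configuration
#'
#' @param scenario `"centering_bias"` (naive vs projection GCV on one p > n
#'   design), `"recovery_grid"` (estimator recovery over an h2 grid),
#'   `"error_sweep"` / `"corr_sweep"` (prediction accuracy sweep over a
#'   variant-count list, scored against the closed-form theory).
#' @param n,p training-set size and variant count (for recovery
#'   scenarios).
#' @param h2 heritability value or vector (grid for `recovery_grid`).
#' @param f_c fraction of causal variants.
#' @param replicates number of replicates.
#' @param seed top-level seed.
#' @param methods estimator methods for recovery scenarios (subset of
#'   `"gcv_projection"`, `"gcv_naive"`, `"gcv_two_set"`, `"kfold_cv"`,
#'   `"reml_oracle"`).
#' @param n_te,p_list,p_max test-set size and variant sweep for the
#'   accuracy scenarios.
#' @param n_std standardization-set size for `gcv_two_set` (default
#'   1000).
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(scenario = c("centering_bias", "recovery_grid",
                                           "error_sweep", "corr_sweep"),
                              n = 1000, p = 10000, h2 = 0.25, f_c = 1,
                              replicates = 10, seed = 1,
                              methods = c("gcv_naive", "gcv_projection"),
                              n_te = 5000, p_list = NULL, p_max = NULL,
                              n_std = 1000) {
  scenario <- match.arg(scenario)
  stopifnot(replicates >= 1)
  known <- c("gcv_projection", "gcv_naive", "gcv_two_set", "kfold_cv",
             "reml_oracle")
  if (!all(methods %in% known)) {
    stop("unknown method(s): ", paste(setdiff(methods, known), collapse = ", "))
  }
  structure(list(scenario = scenario, n = n, p = p, h2 = h2, f_c = f_c,
                 replicates = replicates, seed = seed, methods = methods,
                 n_te = n_te, p_list = p_list, p_max = p_max, n_std = n_std),
            class = "experiment_config")
}

#' Run a configured experiment
#'
#' Fully deterministic given the configuration's seed; returns a tidy
#' table with one row per (replicate, method, parameter combination).
#'
#' @param cfg an [experiment_config()].
#' @return data frame of results; columns depend on the scenario
#'   (`estimate`/`h2_sim` for recovery scenarios, `err`/`corr2` plus
#'   their theoretical values for accuracy sweeps).
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  # pre-flight size check: refuse designs that cannot fit in memory
  cells <- max(cfg$n, cfg$n_te) * max(cfg$p, max(cfg$p_list %||% 0), 1)
  if (cells > 5e8) {
    stop("requested design needs > 4 GB for a single genotype matrix; ",
         "reduce n, p or p_list")
  }
  switch(cfg$scenario,
         centering_bias = ,
         recovery_grid = run_recovery(cfg),
         error_sweep = ,
         corr_sweep = run_accuracy(cfg))
}

run_recovery <- function(cfg) {
  grid_h2 <- cfg$h2
  needs_std <- "gcv_two_set" %in% cfg$methods
  needs_cache <- any(c("gcv_projection", "gcv_naive", "reml_oracle") %in%
                       cfg$methods)
  rows <- list()
  for (rep_i in seq_len(cfg$replicates)) {
    # one genotype draw per replicate, shared across the h2 grid;
    # effects and noise are fresh per (replicate, h2)
    rep_seed <- stream_seed(cfg$seed, "replicate", rep_i)
    freqs <- simulate_frequencies(cfg$p, seed = stream_seed(rep_seed, "frequencies"))
    geno <- simulate_genotypes(freqs, cfg$n,
                               seed = stream_seed(rep_seed, "genotypes"))
    Z_true <- standardize(geno, mode = "true_freq")
    g_std <- NULL
    Zs_true <- NULL
    if (needs_std) {
      g_std <- simulate_genotypes(freqs, cfg$n_std,
                                  seed = stream_seed(rep_seed, "std_genotypes"))
      g_std$sample_ids <- paste0("std", seq_len(cfg$n_std))
      Zs_true <- standardize(g_std, mode = "true_freq")
    }
    ymat <- matrix(0, cfg$n, length(grid_h2))
    ystd <- if (needs_std) matrix(0, cfg$n_std, length(grid_h2))
    for (g in seq_along(grid_h2)) {
      h2 <- grid_h2[g]
      tr <- simulate_phenotype(Z_true, h2, f_c = cfg$f_c,
                               seed = stream_seed(rep_seed, "effects",
                                                  round(h2 * 1000)))
      ymat[, g] <- tr$y
      if (needs_std) {
        e_std <- with_seed(stream_seed(rep_seed, "std_noise", round(h2 * 1000)),
                           rnorm(cfg$n_std, sd = sqrt(max(0, 1 - h2))))
        ystd[, g] <- drop(Zs_true$Z %*% tr$u) + e_std
      }
    }
    cache <- NULL
    Z_emp <- NULL
    if (needs_cache) {
      Z_emp <- standardize(geno, mode = "empirical")
      cache <- svd_cache(Z_emp, compute_v = FALSE)
    }
    for (m in cfg$methods) {
      fits <- switch(m,
        reml_oracle = reml_profile_oracle(Z_emp, ymat, cache = cache),
        gcv_two_set = estimate_h2(geno, ymat, method = m,
                                  std_set = list(geno = g_std, y = ystd)),
        kfold_cv = estimate_h2(geno, ymat, method = m, seed = rep_seed),
        estimate_h2(Z_emp, ymat, method = m, cache = cache))
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = cfg$scenario, replicate = rep_i, method = m,
        n = cfg$n, p = cfg$p, f_c = cfg$f_c, h2_sim = grid_h2,
        estimate = vapply(fits, function(f) f$estimate$h2, numeric(1)))
    }
  }
  res <- do.call(rbind, rows)
  res$error <- res$estimate - res$h2_sim
  res <- res[order(res$replicate, match(res$method, cfg$methods), res$h2_sim), ]
  rownames(res) <- NULL
  res
}

run_accuracy <- function(cfg) {
  p_list <- cfg$p_list %||% stop("accuracy scenarios need p_list")
  exp <- replicate_experiment(list(
    n = cfg$n, n_te = cfg$n_te, p_list = p_list, h2 = cfg$h2,
    n_replicates = cfg$replicates, seed = cfg$seed,
    p_max = cfg$p_max %||% max(p_list)), keep_predictions = FALSE)
  rows <- lapply(exp, function(ens) {
    data.frame(scenario = cfg$scenario, p = ens$p, n = ens$n,
               replicate = seq_len(ens$n_replicates),
               err = ens$mse_k, corr2 = ens$corr2_k,
               theory_err = theory_test_error(cfg$h2, ens$n, ens$p),
               theory_corr2 = theory_corr2(cfg$h2, ens$n, ens$p))
  })
  do.call(rbind, rows)
}

#' The variant-count sweep of the accuracy study
#'
#' The full list of training-set variant counts used by the prediction
#' accuracy simulations (n = 1000 against p from 50,000 down to 20,
#' spanning log(n/p) from -1.7 to +1.7).
#'
#' @return integer vector of 24 variant counts.
#' @export
accuracy_p_list <- function() {
  c(50000L, 25000L, 16667L, 12500L, 10000L, 5000L, 3333L, 2500L, 2000L,
    1667L, 1429L, 1250L, 1111L, 1000L, 500L, 136L, 79L, 56L, 43L, 35L,
    29L, 25L, 22L, 20L)
}
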