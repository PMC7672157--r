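# Empirical prediction machinery: fit ridge on a training set, predict a
# test set, and summarize MSE / squared correlation / bias-variance across
# replicated training sets. Supports the three-set protocol for real data
# (training / standardization / test) and the pure-simulation design with
# true-frequency standardization.

#' Fit on a training set and score predictions on a test set
#'
#' The genetic effects are estimated by (optionally contrasted) ridge:
#' `u_hat = Z' C' (C Z Z' C' + lam I)^-1 C y`. Non-penalized effects
#' (intercept, covariates) are learned by ordinary least squares on the
#' standardization set when one is given, otherwise on the training set;
#' predictions are compared with test phenotypes after removal of those
#' effects.
#'
#' @param train list with fields `Z` (n x p standardized genotypes or
#'   `standardized_genotypes`), `y`, optional `X` (covariates).
#' @param test list with the same fields for the test samples. Variants
#'   must be the same ordered set as in training; the caller is expected
#'   to have standardized both sets with the same centers/scales.
#' @param lam positive penalty; alternatively give `h2` and the penalty
#'   is `p (1 - h2) / h2`.
#' @param h2 heritability used to derive `lam` when `lam` is missing.
#' @param std_set optional list with fields `y` and optional `X`: the
#'   standardization samples used to learn non-penalized effects.
#' @param contrast `"auto"` (contrast the fixed-effect span when an
#'   intercept/covariates are in play, i.e. when `std_set` or `X` is
#'   present, or when `center_y = TRUE`), `"none"`, or a
#'   [build_contrast()] object.
#' @param center_y logical: treat the model as containing an intercept
#'   even without covariates (default `FALSE`, matching the
#'   pure-simulation design `y = Z u + e`).
#' @return object of class `prediction_report`: list with `mse`,
#'   `mse_normalized`, `corr2`, `n_train`, `n_test`, `p`, `lam_used`,
#'   `u_hat`, `pred` (genetic predictions for the test set).
#' @export
fit_predict <- function(train, test, lam = NULL, h2 = NULL, std_set = NULL,
                        contrast = c("auto", "none"), center_y = FALSE) {
  Ztr <- if (inherits(train$Z, "standardized_genotypes")) train$Z$Z else as.matrix(train$Z)
  Zte <- if (inherits(test$Z, "standardized_genotypes")) test$Z$Z else as.matrix(test$Z)
  if (ncol(Ztr) != ncol(Zte)) {
    stop("training and test sets carry different variant sets (",
         ncol(Ztr), " vs ", ncol(Zte), " columns)")
  }
  vtr <- if (inherits(train$Z, "standardized_genotypes")) train$Z$variant_ids
  vte <- if (inherits(test$Z, "standardized_genotypes")) test$Z$variant_ids
  if (!is.null(vtr) && !is.null(vte) && !identical(vtr, vte)) {
    stop("variant ids differ between training and test sets: ",
         paste(utils::head(setdiff(vte, vtr), 5), collapse = ", "))
  }
  n <- nrow(Ztr); p <- ncol(Ztr)
  if (is.null(lam)) {
    if (is.null(h2)) stop("supply either lam or h2")
    lam <- lambda_from_h2(h2, p)
  }
  if (lam <= 0) stop("lam must be positive")

  # non-penalized effects
  has_fixed <- !is.null(std_set) || !is.null(train$X) || center_y
  y_tr <- train$y
  y_te <- test$y
  if (has_fixed) {
    src_y <- if (!is.null(std_set)) std_set$y else train$y
    src_X <- cbind(rep(1, length(src_y)),
                   if (!is.null(std_set)) {
                     if (!is.null(std_set$X)) as.matrix(std_set$X)
                   } else if (!is.null(train$X)) as.matrix(train$X))
    qrX <- qr(src_X)
    if (qrX$rank < ncol(src_X)) stop("singular fixed-effect design on the standardization set")
    beta <- qr.coef(qrX, src_y)
    X_tr <- cbind(rep(1, n), if (!is.null(train$X)) as.matrix(train$X))
    X_te <- cbind(rep(1, nrow(Zte)), if (!is.null(test$X)) as.matrix(test$X))
    y_tr <- y_tr - drop(X_tr %*% beta)
    y_te <- y_te - drop(X_te %*% beta)
  }

  use_contrast <- if (is.character(contrast)) {
    match.arg(contrast) == "auto" && has_fixed && is.null(std_set)
  } else TRUE
  if (use_contrast) {
    cb <- if (inherits(contrast, "contrast_basis")) contrast
          else build_contrast(n, X = train$X)
    Cy <- drop(cb$C %*% y_tr)
    CZ <- cb$C %*% Ztr
    alpha <- solve(tcrossprod(CZ) + diag(lam, cb$m), Cy)
    u_hat <- drop(crossprod(CZ, alpha))
  } else {
    alpha <- solve(tcrossprod(Ztr) + diag(lam, n), y_tr)
    u_hat <- drop(crossprod(Ztr, alpha))
  }
  pred <- drop(Zte %*% u_hat)
  resid_var <- mean((y_te - mean(y_te) * has_fixed)^2)
  mse <- mean((y_te - pred)^2)
  structure(list(mse = mse,
                 mse_normalized = mse / resid_var,
                 corr2 = suppressWarnings(cor(y_te, pred))^2,
                 n_train = n, n_test = nrow(Zte), p = p, lam_used = lam,
                 u_hat = u_hat, pred = pred),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("prediction_report: n_tr = %d, n_te = %d, p = %d, lambda = %.4g\n",
              x$n_train, x$n_test, x$p, x$lam_used))
  cat(sprintf("  MSE = %.4f (normalized %.4f), corr2 = %.4f\n",
              x$mse, x$mse_normalized, x$corr2))
  invisible(x)
}

#' Replicated prediction experiment over a variant-count sweep
#'
#' Implements the nested-subset prediction design: one global frequency
#' vector and effect vector are drawn at `p_max`; for each `p` in
#' `p_list` the leading-p effects are rescaled by `sqrt(p_max / p)`
#' (keeping unit total variance), one fixed test set is simulated, and
#' `n_replicates` training sets are simulated and fitted with the
#' heritability-matched penalty `lam = p (1 - h2) / h2`. Per `p` the
#' ensemble summaries are: `err` (mean over replicates of the test MSE),
#' `bias2` (squared distance between the known genetic signal and the
#' ensemble-mean prediction), `var` (mean squared distance of replicate
#' predictions from the ensemble mean), and the mean squared correlation.
#'
#' @param design list (or arguments) with fields `n`, `n_te`, `p_list`,
#'   `h2`, `n_replicates`, `seed`, optional `p_max` (default
#'   `max(p_list)`).
#' @param keep_predictions keep the per-replicate test predictions in
#'   each ensemble (default `TRUE`; switch off to bound memory in large
#'   sweeps).
#' @return list of `replicate_ensemble` objects (one per `p`), with a
#'   `summary` attribute: data frame with one row per `p` (`p`, `np`,
#'   `err`, `bias2`, `var`, `corr2_mean`, `err_se`, plus the matching
#'   closed-form `theory_err`, `theory_corr2`).
#' @export
replicate_experiment <- function(design, keep_predictions = TRUE) {
  n <- design$n; n_te <- design$n_te; p_list <- design$p_list
  h2 <- design$h2; R <- design$n_replicates
  seed <- design$seed %||% 1L
  p_max <- design$p_max %||% max(p_list)
  if (is.null(p_list) || !length(p_list)) stop("p_list must be nonempty")
  if (h2 < 0 || h2 > 1) stop("h2 must lie in [0, 1]")
  if (any(p_list > p_max)) stop("p_list entries exceed p_max")

  f_all <- simulate_frequencies(p_max, seed = stream_seed(seed, "frequencies"))
  u_all <- with_seed(stream_seed(seed, "effects"),
                     rnorm(p_max, sd = sqrt(h2 / p_max)))

  out <- lapply(seq_along(p_list), function(ip) {
    p <- p_list[ip]
    f <- f_all[seq_len(p)]
    u_p <- rescale_effects(u_all, p)
    lam <- if (h2 > 0 && h2 < 1) p * (1 - h2) / h2 else
      if (h2 == 0) Inf else stop("h2 = 1 has no matched penalty")
    centers <- 2 * f
    scales <- sqrt(2 * f * (1 - f))

    # training replicates: only the effect estimates are retained
    Uhat <- matrix(0, p, R)
    for (k in seq_len(R)) {
      idx <- (ip - 1L) * 100000L + k
      Ztr <- with_seed(stream_seed(seed, "genotypes", idx),
                       standardize_matrix(sim_binom2_matrix(n, f),
                                          centers, scales))
      e_tr <- with_seed(stream_seed(seed, "noise", idx),
                        rnorm(n, sd = sqrt(max(0, 1 - h2))))
      y_tr <- drop(Ztr %*% u_p) + e_tr
      if (is.finite(lam)) {
        alpha <- solve(tcrossprod(Ztr) + diag(lam, n), y_tr)
        Uhat[, k] <- drop(crossprod(Ztr, alpha))
      }  # infinite penalty: null predictor, Uhat stays 0
    }

    # fixed test set for this p, its own stream, streamed in column
    # chunks so that n_te x p never has to be held in memory; the fixed
    # chunk width keeps accumulation order (hence results) reproducible
    chunk <- 4096L
    signal <- numeric(n_te)
    preds <- matrix(0, n_te, R)
    with_seed(stream_seed(seed, "test_genotypes", ip), {
      for (start in seq.int(1L, p, by = chunk)) {
        cols <- start:min(start + chunk - 1L, p)
        Zc <- standardize_matrix(sim_binom2_matrix(n_te, f[cols]),
                                 centers[cols], scales[cols])
        signal <- signal + drop(Zc %*% u_p[cols])
        preds <- preds + Zc %*% Uhat[cols, , drop = FALSE]
      }
    })
    e_te <- with_seed(stream_seed(seed, "test_noise", ip),
                      rnorm(n_te, sd = sqrt(max(0, 1 - h2))))
    y_te <- signal + e_te
    mse_k <- colMeans((y_te - preds)^2)
    corr2 <- apply(preds, 2, function(pr) {
      if (sd(pr) > 0) cor(y_te, pr)^2 else 0
    })
    g_bar <- rowMeans(preds)
    ens <- structure(list(
      p = p, n = n, n_te = n_te, h2 = h2, lam = lam, n_replicates = R,
      y_te = y_te, signal = signal, g_bar = g_bar,
      predictions = if (keep_predictions) preds else NULL,
      mse_k = mse_k, corr2_k = corr2,
      err = mean(mse_k),
      bias2 = mean((signal - g_bar)^2),
      var = mean(colMeans((preds - g_bar)^2)),
      corr2_mean = mean(corr2)),
      class = "replicate_ensemble")
    ens
  })
  summary <- data.frame(
    p = p_list,
    np = n / p_list,
    err = vapply(out, `[[`, numeric(1), "err"),
    bias2 = vapply(out, `[[`, numeric(1), "bias2"),
    var = vapply(out, `[[`, numeric(1), "var"),
    corr2_mean = vapply(out, `[[`, numeric(1), "corr2_mean"),
    err_se = vapply(out, function(e) sd(e$mse_k) / sqrt(e$n_replicates),
                    numeric(1)),
    corr2_se = vapply(out, function(e) sd(e$corr2_k) / sqrt(e$n_replicates),
                      numeric(1)),
    theory_err = vapply(p_list, function(p) theory_test_error(h2, n, p),
                        numeric(1)),
    theory_corr2 = vapply(p_list, function(p) theory_corr2(h2, n, p),
                          numeric(1)))
  attr(out, "summary") <- summary
  class(out) <- "replicate_experiment"
  out
}

#' @export
print.replicate_experiment <- function(x, ...) {
  cat("replicate_experiment:\n")
  print(attr(x, "summary"), digits = 4)
  invisible(x)
}

#' Two aggregation strategies for test-error spread
#'
#' Summarizes the spread of the test-set error of a replicate ensemble in
#' the two complementary ways: (a) the standard deviation, across
#' training replicates, of the per-replicate mean test error — the
#' training-sampling spread; and (b) the standard deviation, across test
#' individuals, of the per-individual squared error averaged over
#' replicates — the test-individual spread, typically much larger because
#' the environmental residual dominates individual errors.
#'
#' @param ensemble a `replicate_ensemble` (with stored predictions).
#' @return list with `sd_across_replicates` and `sd_across_individuals`.
#' @export
error_bar_decomposition <- function(ensemble) {
  if (ensemble$n_replicates < 2 || ensemble$n_te < 2) {
    stop("need at least 2 replicates and 2 test individuals")
  }
  if (is.null(ensemble$predictions)) {
    stop("ensemble was built with keep_predictions = FALSE")
  }
  per_indiv <- rowMeans((ensemble$y_te - ensemble$predictions)^2)
  list(sd_across_replicates = sd(ensemble$mse_k),
       sd_across_individuals = sd(per_indiv))
}
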