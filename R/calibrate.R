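#' The logistic calibration curve
#'
#' Maps a wildtype voxel fraction `x` to the probability that the subject is
#' IDH-wildtype, `P(y = 1 | x) = 1 / (1 + exp(-(alpha + beta * x)))`. The
#' same curve is used by the maximum-likelihood and the Bayesian fits; only
#' how `(alpha, beta)` are estimated differs.
#'
#' @param x wildtype voxel fraction(s) in \[0, 1\] (any real is accepted; the
#'   function is total).
#' @param alpha intercept (bias term).
#' @param beta slope on `x`.
#' @return probability vector; computed overflow-safely via [stats::plogis()].
#' @examples
#' logistic(0.5, alpha = 0, beta = 4)
#' @export
logistic <- function(x, alpha, beta) {
  plogis(alpha + beta * x)
}

#' Fit the calibration curve by maximum likelihood (logistic regression)
#'
#' Fits `(alpha, beta)` of the logistic curve to (fraction, truth) pairs by
#' iteratively reweighted least squares. Complete separation — a threshold on
#' `x` that splits the classes perfectly, under which the MLE diverges — is
#' detected and flagged rather than silently returning runaway estimates;
#' callers are expected to fall back to the Bayesian fit, whose priors
#' regularize separation.
#'
#' @param x wildtype voxel fractions in \[0, 1\].
#' @param y binary ground truth (1 = wildtype, the positive class), or a
#'   mutant/wildtype label vector.
#' @return an `idh_calibrator` with `method = "LR"`, point estimates
#'   `alpha`, `beta`, their covariance, and a `separated` flag.
#' @export
fit_lr <- function(x, y) {
  y <- if (is.numeric(y)) as.integer(y) else .label_to_y(y)
  if (length(x) != length(y) || length(x) < 2L)
    .idh_stop("idh_usage_error", "need >= 2 (x, y) pairs of equal length")
  if (!all(y %in% c(0L, 1L)))
    .idh_stop("idh_usage_error", "y must be binary 0/1 (wildtype = 1)")
  if (length(unique(y)) < 2L)
    .idh_stop("idh_degenerate_fit_error",
              "single-class input: the calibration curve is not identifiable")
  # monotone complete separation on a single covariate
  separated <- max(x[y == 0]) < min(x[y == 1]) || max(x[y == 1]) < min(x[y == 0])
  fit <- suppressWarnings(glm(y ~ x, family = binomial()))
  structure(list(method = "LR",
                 alpha = unname(coef(fit)[1]),
                 beta = unname(coef(fit)[2]),
                 vcov = unname(vcov(fit)),
                 separated = separated,
                 converged = fit$converged,
                 n = length(y)),
            class = "idh_calibrator")
}

#' Fit the calibration curve by Bayesian logistic regression
#'
#' Samples the posterior `p(alpha, beta | x, y) %prop% likelihood x
#' N(alpha; 0, prior_variance) x N(beta; 0, prior_variance)` with
#' random-walk Metropolis: chains are initialised at the posterior mode
#' (found by BFGS), proposals use the inverse-Hessian covariance at the mode
#' scaled by 2.38^2/2, and the global step size adapts during warm-up.
#' `prior_variance = 1` is the informative prior (weights believed close to
#' zero, regularizing the curve); `prior_variance = 1000` is the
#' non-informative prior that lets the data dominate, approaching the
#' maximum-likelihood fit at large n.
#'
#' The fit fails loudly (a non-convergence error carrying the diagnostics)
#' if split-R-hat of either parameter reaches 1.01.
#'
#' @inheritParams fit_lr
#' @param prior_variance variance of the zero-mean Gaussian prior shared by
#'   alpha and beta.
#' @param chains number of Metropolis chains (>= 2 so R-hat is meaningful).
#' @param warmup,draws warm-up iterations discarded / draws retained per
#'   chain.
#' @param thin post-warmup iterations per retained draw (thinning tames the
#'   random-walk autocorrelation).
#' @param extend number of automatic budget doublings attempted when
#'   split-R-hat is still at or above 1.01 (a doubled, re-seeded run replaces
#'   the draws); non-convergence is declared only once these are exhausted.
#' @param seed integer seed; chain `c` of attempt `a` uses
#'   `seed + c + 1000 * (a - 1)`.
#' @return an `idh_calibrator` with `method = "BLR"`: posterior draws
#'   (`draws`, a `(chains*draws) x 2` matrix), posterior means in `alpha`,
#'   `beta`, the prior spec, and `diagnostics` (R-hat, ESS, acceptance).
#' @export
fit_blr <- function(x, y, prior_variance = 1000, chains = 4L, warmup = 1000L,
                    draws = 2000L, thin = 5L, extend = 2L, seed = 1L) {
  y <- if (is.numeric(y)) as.integer(y) else .label_to_y(y)
  if (length(x) != length(y) || length(x) < 2L)
    .idh_stop("idh_usage_error", "need >= 2 (x, y) pairs of equal length")
  if (!all(y %in% c(0L, 1L)))
    .idh_stop("idh_usage_error", "y must be binary 0/1 (wildtype = 1)")
  if (!is.finite(prior_variance) || prior_variance <= 0)
    .idh_stop("idh_usage_error", "prior_variance must be > 0")
  if (chains < 2L)
    .idh_stop("idh_usage_error", "need >= 2 chains for convergence diagnostics")

  lp <- function(theta) .blr_log_post(theta, x, y, prior_variance)
  opt <- optim(c(0, 0), function(th) -lp(th), method = "BFGS", hessian = TRUE)
  sigma <- tryCatch(solve(opt$hessian), error = function(e) diag(2))
  if (any(!is.finite(sigma)) || any(diag(sigma) <= 0)) sigma <- diag(2)
  chol_sigma <- chol(sigma * (2.38^2 / 2))

  draws_cur <- draws
  for (attempt in seq_len(extend + 1L)) {
    runs <- lapply(seq_len(chains), function(c) {
      .rw_metropolis(lp, init = opt$par, chol_sigma = chol_sigma,
                     warmup = warmup, draws = draws_cur,
                     seed = seed + c + 1000L * (attempt - 1L), thin = thin)
    })
    # iterations x chains per parameter, for diagnostics
    arr <- lapply(1:2, function(p) vapply(runs, function(r) r$draws[, p],
                                          numeric(draws_cur)))
    rhat <- vapply(arr, split_rhat, numeric(1))
    ess <- vapply(arr, mcmc_ess, numeric(1))
    names(rhat) <- names(ess) <- c("alpha", "beta")
    if (all(rhat < 1.01)) break
    if (attempt > extend) {
      .idh_stop("idh_nonconvergence_error",
                sprintf("MCMC did not converge: R-hat alpha=%.4f beta=%.4f (limit 1.01)",
                        rhat[1], rhat[2]),
                diagnostics = list(rhat = rhat, ess = ess))
    }
    draws_cur <- draws_cur * 2L
  }
  all_draws <- do.call(rbind, lapply(runs, `[[`, "draws"))
  colnames(all_draws) <- c("alpha", "beta")
  structure(list(method = "BLR",
                 prior_variance = prior_variance,
                 prior_sd = sqrt(prior_variance),
                 alpha = mean(all_draws[, 1]),
                 beta = mean(all_draws[, 2]),
                 draws = all_draws,
                 chain = rep(seq_len(chains), each = draws_cur),
                 diagnostics = list(
                   rhat = rhat, ess = ess,
                   accept_rate = vapply(runs, `[[`, numeric(1), "accept_rate")),
                 mode = opt$par,
                 seed = as.integer(seed),
                 n = length(y)),
            class = "idh_calibrator")
}

#' @export
print.idh_calibrator <- function(x, ...) {
  if (x$method == "LR") {
    cat(sprintf("Logistic calibration (MLE, n=%d): alpha=%.3f beta=%.3f%s\n",
                x$n, x$alpha, x$beta,
                if (isTRUE(x$separated)) "  [complete separation]" else ""))
  } else {
    q <- apply(x$draws, 2, quantile, c(0.05, 0.95))
    cat(sprintf("Bayesian logistic calibration (N(0, %g) priors, n=%d, %d draws)\n",
                x$prior_variance, x$n, nrow(x$draws)))
    cat(sprintf("  alpha: %.3f [90%%: %.3f, %.3f]  R-hat %.3f\n",
                x$alpha, q[1, 1], q[2, 1], x$diagnostics$rhat["alpha"]))
    cat(sprintf("  beta : %.3f [90%%: %.3f, %.3f]  R-hat %.3f\n",
                x$beta, q[1, 2], q[2, 2], x$diagnostics$rhat["beta"]))
  }
  invisible(x)
}

#' Convert wildtype fractions into confidence scores
#'
#' For a maximum-likelihood fit the wildtype probability is the logistic
#' curve at the point estimates. For a Bayesian fit it is the
#' posterior-predictive mean — the average of the logistic curve over the
#' stored posterior draws — which is the Bayes estimate under squared-error
#' loss, the loss the Brier score measures; the posterior median and a
#' central 90% band are reported alongside. The confidence in the *call*
#' (`p_predicted_class`) is the wildtype probability when the call is
#' wildtype and its complement otherwise.
#'
#' @param fit an `idh_calibrator` from [fit_lr()] or [fit_blr()].
#' @param x wildtype voxel fractions.
#' @param call optional label vector (mutant/wildtype) of the subject-level
#'   calls; when supplied, `p_predicted_class` is added.
#' @return data frame with `x`, `p_wildtype`, and for Bayesian fits
#'   `p_median`, `p_lo`, `p_hi` (central 90% band); plus
#'   `p_predicted_class` when `call` is given.
#' @export
confidence <- function(fit, x, call = NULL) {
  if (!inherits(fit, "idh_calibrator"))
    .idh_stop("idh_usage_error", "fit must be an idh_calibrator")
  if (fit$method == "LR") {
    out <- data.frame(x = x, p_wildtype = logistic(x, fit$alpha, fit$beta))
  } else {
    # n x S matrix of per-draw curves, averaged over draws
    curves <- plogis(outer(x, fit$draws[, "beta"]) +
                       rep(fit$draws[, "alpha"], each = length(x)))
    qs <- t(apply(curves, 1, quantile, c(0.05, 0.5, 0.95)))
    out <- data.frame(x = x,
                      p_wildtype = rowMeans(curves),
                      p_median = qs[, 2], p_lo = qs[, 1], p_hi = qs[, 3])
  }
  if (!is.null(call)) {
    call <- .as_idh_label(call)
    out$p_predicted_class <- ifelse(call == "wildtype",
                                    out$p_wildtype, 1 - out$p_wildtype)
  }
  out
}

#' Serialize a fitted calibrator to JSON
#'
#' Writes method, point estimates/posterior means, prior spec, seed and a
#' draw summary; full posterior draws can be written alongside as CSV.
#'
#' @param fit an `idh_calibrator`.
#' @param path output JSON path.
#' @param draws_csv optional path for the full posterior draws (BLR only).
#' @return `path`, invisibly.
#' @export
write_calibrator_json <- function(fit, path, draws_csv = NULL) {
  stopifnot(inherits(fit, "idh_calibrator"))
  obj <- list(method = fit$method, alpha = fit$alpha, beta = fit$beta, n = fit$n)
  if (fit$method == "BLR") {
    obj$prior_variance <- fit$prior_variance
    obj$seed <- fit$seed
    obj$n_draws <- nrow(fit$draws)
    obj$posterior_sd <- apply(fit$draws, 2, sd)
    obj$rhat <- fit$diagnostics$rhat
    obj$ess <- fit$diagnostics$ess
    if (!is.null(draws_csv))
      write.csv(data.frame(chain = fit$chain, fit$draws), draws_csv, row.names = FALSE)
  } else {
    obj$separated <- fit$separated
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
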