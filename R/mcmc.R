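# Random-walk Metropolis sampler and convergence diagnostics for the
# two-parameter Bayesian logistic calibration posterior.

# log posterior of (alpha, beta) under Bernoulli likelihood + N(0, pv) priors
.blr_log_post <- function(theta, x, y, prior_variance) {
  eta <- theta[1] + theta[2] * x
  # log(1 + exp(eta)) computed without overflow
  log1pe <- ifelse(eta > 35, eta, log1p(exp(eta)))
  sum(y * eta - log1pe) - sum(theta^2) / (2 * prior_variance)
}

# one Metropolis chain; proposal N(0, scale^2 * Sigma), scale adapted during
# warmup toward ~35% acceptance (near-optimal for 2-d random walk); kept
# draws are thinned to cut random-walk autocorrelation
.rw_metropolis <- function(lp, init, chol_sigma, warmup, draws, seed, thin = 5L) {
  set.seed(seed)
  d <- length(init)
  total <- warmup + draws * thin
  out <- matrix(NA_real_, nrow = draws, ncol = d)
  theta <- init
  lp_cur <- lp(theta)
  scale <- 1
  acc_win <- 0L
  n_accept <- 0L
  for (t in seq_len(total)) {
    prop <- theta + scale * drop(rnorm(d) %*% chol_sigma)
    lp_prop <- lp(prop)
    if (is.finite(lp_prop) && log(runif(1)) < lp_prop - lp_cur) {
      theta <- prop
      lp_cur <- lp_prop
      acc_win <- acc_win + 1L
      if (t > warmup) n_accept <- n_accept + 1L
    }
    if (t <= warmup && t %% 50L == 0L) {
      rate <- acc_win / 50
      scale <- scale * exp(rate - 0.35)  # nudge toward target acceptance
      acc_win <- 0L
    }
    if (t > warmup && (t - warmup) %% thin == 0L)
      out[(t - warmup) %/% thin, ] <- theta
  }
  list(draws = out, accept_rate = n_accept / (draws * thin), scale = scale)
}

#' Split-half potential scale reduction (R-hat)
#'
#' Rank-free split-R-hat: each chain is halved, and the ratio of pooled to
#' within-sequence variance is computed over the resulting sequences. Values
#' near 1 indicate the chains have mixed.
#'
#' @param draws numeric matrix, `iterations x chains`.
#' @return scalar R-hat.
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  half <- n %/% 2L
  seqs <- do.call(cbind, lapply(seq_len(ncol(draws)), function(j) {
    cbind(draws[seq_len(half), j], draws[(n - half + 1L):n, j])
  }))
  m <- ncol(seqs)
  nn <- nrow(seqs)
  means <- colMeans(seqs)
  vars <- apply(seqs, 2, var)
  w <- mean(vars)
  b <- nn * var(means)
  if (w == 0) return(1)
  sqrt(((nn - 1) / nn * w + b / nn) / w)
}

#' Effective sample size of MCMC draws
#'
#' Autocorrelation-based ESS with Geyer's initial positive sequence
#' truncation, computed per chain and summed.
#'
#' @param draws numeric matrix, `iterations x chains`.
#' @return scalar effective sample size.
#' @export
mcmc_ess <- function(draws) {
  draws <- as.matrix(draws)
  per_chain <- vapply(seq_len(ncol(draws)), function(j) {
    z <- draws[, j]
    n <- length(z)
    if (var(z) == 0) return(1)
    rho <- as.numeric(stats::acf(z, lag.max = min(n - 1L, 250L), plot = FALSE)$acf)[-1]
    # sum consecutive pairs; stop at first negative pair (initial positive seq)
    s <- 0
    for (k in seq(1, length(rho) - 1L, by = 2)) {
      pair <- rho[k] + rho[k + 1L]
      if (pair < 0) break
      s <- s + pair
    }
    n / (1 + 2 * s)
  }, numeric(1))
  sum(per_chain)
}
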