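# Brute-force oracles, deliberately written with per-element loops so they
# share no code path with the vectorised implementations they check.

# per-voxel plurality vote with tie priority 2 > 1 > 0
oracle_vote <- function(mat) {
  vapply(seq_len(ncol(mat)), function(j) {
    v <- mat[, j]
    counts <- c(sum(v == 0L), sum(v == 1L), sum(v == 2L))
    winners <- c(0L, 1L, 2L)[counts == max(counts)]
    max(winners)
  }, integer(1))
}

# full-scan voxel tally
oracle_counts <- function(arr) {
  n1 <- 0L; n2 <- 0L
  for (v in as.vector(arr)) {
    if (v == 1L) n1 <- n1 + 1L
    if (v == 2L) n2 <- n2 + 1L
  }
  c(n_mutant = n1, n_wildtype = n2)
}

# all-pairs AUC with half-credit ties
oracle_auc <- function(scores, y) {
  pos <- scores[y == 1L]
  neg <- scores[y == 0L]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# element-by-element confusion matrix (wildtype positive)
oracle_confusion <- function(truth, predicted) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(truth)) {
    t_wt <- truth[i] == "wildtype"
    p_wt <- predicted[i] == "wildtype"
    if (t_wt && p_wt) tp <- tp + 1L
    else if (!t_wt && p_wt) fp <- fp + 1L
    else if (t_wt && !p_wt) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# data simulated from the logistic curve itself
sim_logistic <- function(n, alpha, beta, seed) {
  set.seed(seed)
  x <- runif(n)
  y <- rbinom(n, 1, plogis(alpha + beta * x))
  list(x = x, y = y)
}

# small two-class fraction sample resembling cohort output
sim_fractions <- function(n, prevalence = 0.75, seed = 1) {
  set.seed(seed)
  y <- rbinom(n, 1, prevalence)
  x <- ifelse(y == 1, rbeta(n, 8, 2.5), rbeta(n, 2.5, 8))
  list(x = x, y = y)
}
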