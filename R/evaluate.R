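#' Subject-level classification metrics
#'
#' Computes accuracy, per-truth-class accuracy, precision, recall, F1 and
#' AUC with IDH-wildtype as the positive class. With that convention, recall
#' is identical to the wildtype-class accuracy by definition. AUC is the
#' rank statistic of the score against truth with midrank tie handling
#' (equivalent to the trapezoidal ROC area). Percentages are kept at full
#' precision; rounding belongs to the reporting layer.
#'
#' @param truth mutant/wildtype label vector (ground truth).
#' @param predicted mutant/wildtype label vector (calls).
#' @param scores optional numeric scores (e.g. wildtype fraction) for AUC.
#' @param percent report rate metrics on the 0-100 scale (default) rather
#'   than 0-1.
#' @return list of class `idh_metrics`: `n`, `n_mutant`, `n_wildtype`,
#'   confusion cells (`tp`, `fp`, `fn`, `tn`), `accuracy`,
#'   `accuracy_mutant_class`, `accuracy_wildtype_class`, `precision`,
#'   `recall`, `f1` and `auc` (NA with an explanatory attribute when only
#'   one truth class is present).
#' @export
classification_metrics <- function(truth, predicted, scores = NULL, percent = TRUE) {
  truth <- .as_idh_label(truth)
  predicted <- .as_idh_label(predicted)
  if (length(truth) != length(predicted) || length(truth) < 1L)
    .idh_stop("idh_usage_error", "truth and predicted must be equal-length, non-empty")
  y <- truth == "wildtype"
  yhat <- predicted == "wildtype"
  tp <- sum(y & yhat); fp <- sum(!y & yhat)
  fn <- sum(y & !yhat); tn <- sum(!y & !yhat)
  scl <- if (percent) 100 else 1
  one_class <- !any(y) || all(y)
  prec <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  rec <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) NA_real_ else
    2 * prec * rec / (prec + rec)
  auc <- if (one_class || is.null(scores)) NA_real_ else auc_midrank(scores, as.integer(y))
  out <- list(
    n = length(y), n_mutant = sum(!y), n_wildtype = sum(y),
    tp = tp, fp = fp, fn = fn, tn = tn,
    accuracy = scl * (tp + tn) / length(y),
    accuracy_mutant_class = if (any(!y)) scl * (tn / (tn + fp)) else NA_real_,
    # identical expression to recall: with wildtype positive the two coincide
    accuracy_wildtype_class = if (any(y)) scl * rec else NA_real_,
    precision = scl * prec, recall = scl * rec, f1 = scl * f1,
    auc = auc
  )
  if (one_class)
    attr(out, "undefined") <- "single-class cohort: AUC (and possibly precision) undefined"
  class(out) <- "idh_metrics"
  out
}

#' @export
print.idh_metrics <- function(x, ...) {
  cat(sprintf("n=%d (%d mutant / %d wildtype)\n", x$n, x$n_mutant, x$n_wildtype))
  cat(sprintf("  accuracy %.1f (mutant %.1f, wildtype %.1f)\n",
              x$accuracy, x$accuracy_mutant_class, x$accuracy_wildtype_class))
  cat(sprintf("  precision %.1f  recall %.1f  F1 %.1f  AUC %s\n",
              x$precision, x$recall, x$f1,
              if (is.na(x$auc)) "NA" else sprintf("%.2f", x$auc)))
  invisible(x)
}

#' Rank-based AUC with midrank tie handling
#'
#' @param scores numeric scores, higher meaning more wildtype-like.
#' @param y binary truth, 1 = wildtype.
#' @return AUC in \[0, 1\].
#' @export
auc_midrank <- function(scores, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L)
    .idh_stop("idh_usage_error", "AUC needs both classes present")
  r <- rank(scores)  # average (mid) ranks for ties
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Count-weighted pooling of per-cohort metric values
#'
#' The overall cell of a multi-site report: `sum(w * v) / sum(w)` with the
#' site sizes (or per-class counts) as weights. Rounding to one decimal is
#' left to the caller's reporting layer.
#'
#' @param values per-cohort metric values.
#' @param weights positive counts, same length.
#' @return pooled value at full precision.
#' @examples
#' pooled_weighted(c(96.0, 93.6, 96.3, 98.0), c(177, 204, 456, 399))
#' @export
pooled_weighted <- function(values, weights) {
  if (length(values) != length(weights) || length(values) < 1L)
    .idh_stop("idh_usage_error", "values and weights must be equal-length, non-empty")
  if (any(weights <= 0))
    .idh_stop("idh_usage_error", "weights must be positive counts")
  sum(values * weights) / sum(weights)
}

#' Brier score of probabilistic confidence scores
#'
#' Mean squared difference between the predicted wildtype probability and the
#' binary outcome (1 = wildtype): lower is better calibrated. Applied
#' identically to the raw wildtype fraction used as a probability and to
#' each calibrated score, which is what makes the methods comparable.
#'
#' @param scores probabilities in \[0, 1\].
#' @param y binary outcomes (1 = wildtype) or label vector.
#' @return scalar in \[0, 1\].
#' @export
brier_score <- function(scores, y) {
  y <- if (is.numeric(y)) as.integer(y) else .label_to_y(y)
  if (length(scores) != length(y) || length(y) < 1L)
    .idh_stop("idh_usage_error", "scores and y must be equal-length, non-empty")
  if (any(scores < 0 | scores > 1))
    .idh_stop("idh_usage_error", "scores must lie in [0, 1]")
  mean((scores - y)^2)
}

#' Reliability-diagram data
#'
#' Bins scores into `bins` equal-width bins over \[0, 1\] and reports, per
#' bin, the mean score and the empirical outcome rate — the data behind a
#' calibration (reliability) plot.
#'
#' @inheritParams brier_score
#' @param bins number of equal-width bins.
#' @return data frame `bin`, `lower`, `upper`, `n`, `mean_score`,
#'   `outcome_rate` (empty bins dropped).
#' @export
reliability_table <- function(scores, y, bins = 10L) {
  y <- if (is.numeric(y)) as.integer(y) else .label_to_y(y)
  br <- seq(0, 1, length.out = bins + 1L)
  idx <- pmin(pmax(findInterval(scores, br, rightmost.closed = TRUE), 1L), bins)
  out <- do.call(rbind, lapply(seq_len(bins), function(b) {
    sel <- idx == b
    if (!any(sel)) return(NULL)
    data.frame(bin = b, lower = br[b], upper = br[b + 1L], n = sum(sel),
               mean_score = mean(scores[sel]), outcome_rate = mean(y[sel]))
  }))
  out
}

#' Two-stage held-out calibration protocol
#'
#' The core evaluation design: calibration curves (maximum-likelihood LR and
#' Bayesian fits under the informative N(0,1) and non-informative N(0,1000)
#' priors) are fitted exclusively on cohort A's (fraction, truth) pairs, so
#' cohort B's confidence scores are independent of every fitting step; cohort
#' B is then scored with all three curves plus the raw fraction, and each
#' method's Brier score is computed on cohort B. Any subject id shared
#' between the cohorts is data leakage and raises an error listing the
#' offenders.
#'
#' @param cohort_a,cohort_b subject-record data frames as from
#'   [call_subjects()] (columns `subject_id`, `x`, `true_label`,
#'   `predicted_label`).
#' @param chains,warmup,draws MCMC budget passed to [fit_blr()].
#' @param seed seed for the Bayesian fits.
#' @param prior_variances named vector of prior variances for the Bayesian
#'   fits; the defaults are the informative and non-informative priors.
#' @return list of class `idh_two_stage`: `fits` (named list of
#'   calibrators), `brier` (named vector: raw, lr, blr_informative,
#'   blr_noninformative), `metrics_a`, `metrics_b` ([classification_metrics()]
#'   of each cohort), and `scores_b` (cohort B's records with one confidence
#'   column per method).
#' @export
two_stage_protocol <- function(cohort_a, cohort_b,
                               chains = 4L, warmup = 1000L, draws = 2000L,
                               seed = 1L,
                               prior_variances = c(blr_informative = 1,
                                                   blr_noninformative = 1000)) {
  for (nm in c("subject_id", "x", "true_label", "predicted_label")) {
    if (!nm %in% names(cohort_a) || !nm %in% names(cohort_b))
      .idh_stop("idh_usage_error", sprintf("cohorts must carry column '%s'", nm))
  }
  overlap <- intersect(cohort_a$subject_id, cohort_b$subject_id)
  if (length(overlap) > 0L)
    .idh_stop("idh_leakage_error",
              sprintf("cohorts share %d subject id(s): %s",
                      length(overlap), paste(head(overlap, 10), collapse = ", ")))

  y_a <- .label_to_y(cohort_a$true_label)
  y_b <- .label_to_y(cohort_b$true_label)

  fits <- list(lr = fit_lr(cohort_a$x, y_a))
  for (i in seq_along(prior_variances)) {
    fits[[names(prior_variances)[i]]] <-
      fit_blr(cohort_a$x, y_a, prior_variance = prior_variances[i],
              chains = chains, warmup = warmup, draws = draws, seed = seed + i)
  }

  scores_b <- cohort_b
  scores_b$p_raw <- cohort_b$x
  brier <- c(raw = brier_score(cohort_b$x, y_b))
  for (nm in names(fits)) {
    p <- confidence(fits[[nm]], cohort_b$x, call = cohort_b$predicted_label)
    scores_b[[paste0("p_wildtype_", nm)]] <- p$p_wildtype
    scores_b[[paste0("confidence_", nm)]] <- p$p_predicted_class
    brier[[nm]] <- brier_score(p$p_wildtype, y_b)
  }

  structure(list(
    fits = fits,
    brier = brier,
    metrics_a = classification_metrics(cohort_a$true_label, cohort_a$predicted_label,
                                       scores = cohort_a$x),
    metrics_b = classification_metrics(cohort_b$true_label, cohort_b$predicted_label,
                                       scores = cohort_b$x),
    scores_b = scores_b
  ), class = "idh_two_stage")
}

#' @export
print.idh_two_stage <- function(x, ...) {
  cat("Two-stage held-out calibration\n")
  cat(sprintf("  cohort A: n=%d, accuracy %.1f%%\n", x$metrics_a$n, x$metrics_a$accuracy))
  cat(sprintf("  cohort B: n=%d, accuracy %.1f%%, AUC %.2f\n",
              x$metrics_b$n, x$metrics_b$accuracy, x$metrics_b$auc))
  cat("  Brier on cohort B:\n")
  for (nm in names(x$brier))
    cat(sprintf("    %-20s %.4f\n", nm, x$brier[[nm]]))
  invisible(x)
}
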