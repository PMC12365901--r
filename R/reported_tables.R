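# Published site-level numbers of the multi-institutional MC-net IDH study,
# kept as plain code so the pooling arithmetic of the reporting layer can be
# checked against the printed overall cells.

#' Published cohort composition of the multi-institution IDH study
#'
#' Per-site IDH-mutant / IDH-wildtype case counts of the 2,481-case glioma
#' cohort the confidence framework was evaluated on, and each site's role
#' (training, first held-out test group TG-1, second held-out test group
#' TG-2).
#'
#' @return data frame `site`, `role`, `mutant`, `wildtype`.
#' @export
reference_cohort_counts <- function() {
  data.frame(
    site = c("TCIA", "Ivy-GAP", "UCSF", "EGD", "UPenn",
             "UTSW-1", "UTSW-2", "UTSW-3", "NYU", "UWM"),
    role = c("train", "train", "train", "tg1", "tg1",
             "train", "tg2", "tg2", "tg1", "tg1"),
    mutant = c(92L, 2L, 103L, 150L, 11L, 106L, 22L, 28L, 47L, 16L),
    wildtype = c(112L, 21L, 392L, 306L, 387L, 254L, 37L, 77L, 130L, 188L)
  )
}

#' Published per-site classification metrics of the MC-net IDH classifier
#'
#' Site-level performance (percent scale; AUC on \[0,1\]) of the voxel-wise
#' classifier on the two held-out test groups, together with the per-site
#' case counts used as pooling weights (`n` total cases, `n_mutant` /
#' `n_wildtype` truth-class counts as printed in the performance table —
#' note UPenn is listed there with 399 cases, 388 wildtype).
#'
#' @return data frame, one row per test site.
#' @export
reference_site_metrics <- function() {
  data.frame(
    site = c("NYU", "UWM", "EGD", "UPenn", "UTSW-2", "UTSW-3"),
    group = c("tg1", "tg1", "tg1", "tg1", "tg2", "tg2"),
    n = c(177L, 204L, 456L, 399L, 59L, 105L),
    n_mutant = c(47L, 16L, 150L, 11L, 22L, 28L),
    n_wildtype = c(130L, 188L, 306L, 388L, 37L, 77L),
    accuracy = c(96.0, 93.6, 96.3, 98.0, 93.2, 96.2),
    accuracy_mutant_class = c(93.6, 81.2, 93.3, 81.8, 95.5, 96.4),
    accuracy_wildtype_class = c(96.9, 94.7, 97.7, 98.5, 91.9, 96.1),
    precision = c(97.7, 98.3, 96.8, 99.5, 97.1, 98.6),
    recall = c(96.9, 94.7, 97.7, 98.5, 91.9, 96.1),
    f1 = c(97.3, 96.5, 97.2, 99.0, 94.4, 97.3),
    auc = c(0.97, 0.96, 0.98, 0.98, 0.98, 0.97)
  )
}

#' Published overall (pooled) metrics of the MC-net IDH classifier
#'
#' The printed overall column per test group, for consistency checks of the
#' pooling arithmetic. (The pooled mutant-class accuracy prints as 92.0
#' although count-weighted pooling of the printed per-site values yields
#' 91.9; the package treats the arithmetic as authoritative and reports it
#' unrounded.)
#'
#' @return data frame, one row per test group.
#' @export
reference_overall_metrics <- function() {
  data.frame(
    group = c("tg1", "tg2"),
    accuracy = c(96.4, 95.1),
    accuracy_mutant_class = c(92.0, 96.0),
    accuracy_wildtype_class = c(97.3, 94.7),
    precision = c(98.2, 98.2),
    recall = c(97.3, 94.7),
    f1 = c(97.8, 96.4),
    auc = c(0.98, 0.98),
    brier_raw = c(NA, 0.0435),
    brier_lr = c(NA, 0.0158),
    brier_blr_informative = c(NA, 0.0150),
    brier_blr_noninformative = c(NA, 0.0125)
  )
}

#' Pool the published per-site metrics into overall cells
#'
#' Applies the package's count-weighted pooling ([pooled_weighted()]) to the
#' published per-site rows: whole-cohort metrics (accuracy) are weighted by
#' site size; truth-class accuracies by the corresponding class counts;
#' precision, recall and F1 — metrics of the positive (wildtype) class — by
#' the wildtype counts; and pooled F1 is also recomputed as the harmonic mean
#' of pooled precision and recall.
#'
#' @param group `"tg1"` or `"tg2"`.
#' @return named list of pooled values at full precision.
#' @export
pool_reference_metrics <- function(group = c("tg1", "tg2")) {
  group <- match.arg(group)
  s <- reference_site_metrics()
  s <- s[s$group == group, ]
  prec <- pooled_weighted(s$precision, s$n_wildtype)
  rec <- pooled_weighted(s$recall, s$n_wildtype)
  list(
    accuracy = pooled_weighted(s$accuracy, s$n),
    accuracy_mutant_class = pooled_weighted(s$accuracy_mutant_class, s$n_mutant),
    accuracy_wildtype_class = pooled_weighted(s$accuracy_wildtype_class, s$n_wildtype),
    precision = prec,
    recall = rec,
    f1 = pooled_weighted(s$f1, s$n_wildtype),
    f1_from_pooled = 2 * prec * rec / (prec + rec),
    n = sum(s$n)
  )
}
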