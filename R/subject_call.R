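#' Ensemble per-fold labellings by per-voxel plurality vote
#'
#' Each cross-validation fold produces one labelling of the same grid; the
#' final two-class segmentation takes, at every voxel, the plurality class
#' over \{0, 1, 2\} across folds. Exact ties are broken by the fixed priority
#' 2 > 1 > 0 (prefer calling tumor over background, and the prevalent
#' wildtype class over the rare mutant one) and tallied.
#'
#' @param maps either a list of [label_map()]s / 3-D arrays with identical
#'   dimensions (one per fold), or an `n_folds x n_voxels` integer matrix of
#'   per-fold labels.
#' @return for map input, an [label_map()] with attribute `n_ties`; for
#'   matrix input, a list with `labels` (integer vector) and `n_ties`.
#' @examples
#' votes <- rbind(c(1L, 1L, 0L), c(1L, 2L, 2L), c(2L, 2L, 1L))
#' ensemble_folds(votes)
#' @export
ensemble_folds <- function(maps) {
  if (is.matrix(maps)) {
    ens <- .ensemble_matrix(maps)
    return(ens)
  }
  if (!is.list(maps) || length(maps) < 1L)
    .idh_stop("idh_usage_error", "need at least one fold labelling")
  arrs <- lapply(maps, function(m) if (inherits(m, "idh_label_map")) m$labels else m)
  dims <- lapply(arrs, dim)
  ref <- dims[[1]]
  same <- vapply(dims, function(d) length(d) == length(ref) && all(d == ref), logical(1))
  if (!all(same)) {
    .idh_stop("idh_shape_error",
              sprintf("fold grids disagree: %s",
                      paste(sprintf("fold %d is %s", seq_along(dims),
                                    vapply(dims, paste, "", collapse = "x")),
                            collapse = "; ")))
  }
  stacked <- do.call(rbind, lapply(arrs, as.vector))
  ens <- .ensemble_matrix(stacked)
  sid <- if (inherits(maps[[1]], "idh_label_map")) maps[[1]]$subject_id else NA_character_
  ref_img <- if (inherits(maps[[1]], "idh_label_map")) maps[[1]]$reference else NULL
  out <- label_map(array(ens$labels, dim = ref), subject_id = sid, reference = ref_img)
  attr(out, "n_ties") <- ens$n_ties
  out
}

# plurality vote per column of an n_folds x n_voxels matrix, tie priority 2>1>0
.ensemble_matrix <- function(m) {
  if (!all(m %in% c(0L, 1L, 2L)))
    .idh_stop("idh_format_error", "fold labels must lie in {0,1,2}")
  n0 <- colSums(m == 0L)
  n1 <- colSums(m == 1L)
  n2 <- colSums(m == 2L)
  top <- pmax(n0, n1, n2)
  winner <- ifelse(n2 == top, 2L, ifelse(n1 == top, 1L, 0L))
  n_ties <- sum((n0 == top) + (n1 == top) + (n2 == top) > 1L)
  list(labels = as.integer(winner), n_ties = n_ties)
}

#' Wildtype voxel fraction
#'
#' The single covariate of the confidence model: the proportion of predicted
#' tumor voxels labelled IDH-wildtype, `n_wildtype / (n_mutant +
#' n_wildtype)`. Stored and modelled as a fraction in \[0, 1\]; any
#' percent-scale I/O is converted at the boundary because the logistic slope
#' (and the reach of an N(0,1) prior on it) is scale-sensitive.
#'
#' @param n_mutant,n_wildtype non-negative voxel counts (vectorised).
#' @return numeric vector in \[0, 1\].
#' @export
wildtype_fraction <- function(n_mutant, n_wildtype) {
  total <- n_mutant + n_wildtype
  if (any(total < 1))
    .idh_stop("idh_empty_tumor_error",
              "wildtype fraction undefined for tumors with zero voxels")
  n_wildtype / total
}

#' Subject-level IDH call by majority voting over voxel classes
#'
#' The subject is called wildtype iff strictly more tumor voxels are labelled
#' wildtype than mutant (equivalently, wildtype fraction > 0.5). An exact
#' 50/50 tie is resolved to wildtype — the positive and far more prevalent
#' class — and flagged, never silently absorbed.
#'
#' @param n_mutant,n_wildtype non-negative voxel counts (vectorised).
#' @return data frame with `predicted_label` (factor mutant/wildtype) and
#'   `tie_flag`.
#' @export
majority_vote <- function(n_mutant, n_wildtype) {
  total <- n_mutant + n_wildtype
  if (any(total < 1))
    .idh_stop("idh_empty_tumor_error", "majority vote undefined for empty tumors")
  data.frame(
    predicted_label = .as_idh_label(ifelse(n_wildtype >= n_mutant, "wildtype", "mutant")),
    tie_flag = n_wildtype == n_mutant
  )
}

#' Build subject records from a simulated cohort or a fold-counts table
#'
#' Runs the subject-level half of the pipeline: per-voxel fold ensembling,
#' whole-tumor counting, wildtype fraction, and the majority-vote IDH call.
#'
#' For a simulated cohort the ensemble is an exact per-voxel plurality vote
#' over the stored fold labellings. For a counts table, rows are ensembled by
#' summing the per-fold counts (the voxel identities needed for a per-voxel
#' vote are no longer available; the pooled vote is the count-level
#' equivalent and identical whenever folds agree).
#'
#' @param x an `idh_cohort`, or a data frame as from [read_counts_csv()].
#' @param truth optional data frame `subject_id`, `true_label` attaching
#'   ground truth (taken from the cohort automatically).
#' @return data frame with one row per subject: `subject_id`, `n_mutant`,
#'   `n_wildtype`, `x` (wildtype fraction), `predicted_label`, `tie_flag`,
#'   `ensemble_ties`, and `true_label` when available.
#' @export
call_subjects <- function(x, truth = NULL) {
  if (inherits(x, "idh_cohort")) {
    recs <- lapply(seq_along(x$fold_labels), function(i) {
      ens <- .ensemble_matrix(x$fold_labels[[i]])
      data.frame(subject_id = x$truth$subject_id[i],
                 n_mutant = sum(ens$labels == 1L),
                 n_wildtype = sum(ens$labels == 2L),
                 ensemble_ties = ens$n_ties)
    })
    df <- do.call(rbind, recs)
    truth <- x$truth[, c("subject_id", "true_label")]
  } else if (is.data.frame(x)) {
    agg <- stats::aggregate(cbind(n_mutant, n_wildtype) ~ subject_id, data = x, FUN = sum)
    df <- data.frame(subject_id = agg$subject_id,
                     n_mutant = agg$n_mutant,
                     n_wildtype = agg$n_wildtype,
                     ensemble_ties = NA_integer_)
  } else {
    .idh_stop("idh_usage_error", "x must be an idh_cohort or a counts data frame")
  }
  empty <- df$n_mutant + df$n_wildtype == 0
  if (any(empty)) {
    warning(sprintf("excluding %d subject(s) with empty tumors: %s",
                    sum(empty), paste(df$subject_id[empty], collapse = ", ")))
    df <- df[!empty, , drop = FALSE]
  }
  df$x <- wildtype_fraction(df$n_mutant, df$n_wildtype)
  vote <- majority_vote(df$n_mutant, df$n_wildtype)
  df$predicted_label <- vote$predicted_label
  df$tie_flag <- vote$tie_flag
  if (!is.null(truth)) {
    m <- match(df$subject_id, truth$subject_id)
    df$true_label <- .as_idh_label(truth$true_label[m])
  }
  rownames(df) <- NULL
  df
}
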