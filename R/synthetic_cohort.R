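#' Configuration for the synthetic glioma cohort generator
#'
#' Builds and validates the full set of knobs for [simulate_cohort()]. The
#' generator emulates the statistical shape of voxel-wise two-class tumor
#' segmentations produced by a cross-validated network: each subject carries a
#' latent wildtype voxel fraction drawn from a class-conditional Beta
#' distribution (mutant-truth subjects concentrated near 0, wildtype-truth
#' near 1, giving the characteristic bimodal fraction histogram), a tumor size
#' drawn from a log-normal, and per-fold label maps in which each tumor
#' voxel's class is flipped independently with a small probability to mimic
#' fold-to-fold disagreement.
#'
#' Defaults mirror a large multi-institutional glioma cohort: wildtype
#' prevalence 1904/2481 and five cross-validation folds. The Beta and noise
#' defaults place the default pipeline in a realistic high-accuracy regime
#' (subject accuracy around 96%) while leaving the raw fraction visibly
#' miscalibrated as a probability, so calibration has work to do.
#'
#' @param n_subjects number of subjects to simulate.
#' @param wildtype_prevalence probability that a subject is IDH-wildtype.
#' @param frac_dist_mutant,frac_dist_wildtype length-2 positive numeric:
#'   Beta(shape1, shape2) over the latent wildtype fraction for mutant-truth
#'   and wildtype-truth subjects respectively.
#' @param tumor_size_meanlog,tumor_size_sdlog log-normal parameters for the
#'   tumor voxel count (count is `max(1, round(.))` of the draw).
#' @param n_folds number of cross-validation folds emulated (>= 1).
#' @param fold_flip_rate probability that a tumor voxel's class label flips
#'   (1 <-> 2) independently in each fold.
#' @param volume_shape integer length-3 grid dimensions used when label
#'   volumes are emitted.
#' @param seed integer seed; identical seed + config gives bit-identical
#'   cohorts, and draws for subject `i` do not change when `n_subjects`
#'   grows.
#' @return an object of class `idh_cohort_config` (a validated list).
#' @seealso [simulate_cohort()]
#' @export
cohort_config <- function(n_subjects = 1400L,
                          wildtype_prevalence = 1904 / 2481,
                          frac_dist_mutant = c(2.5, 8),
                          frac_dist_wildtype = c(8, 2.5),
                          tumor_size_meanlog = log(3000),
                          tumor_size_sdlog = 0.7,
                          n_folds = 5L,
                          fold_flip_rate = 0.05,
                          volume_shape = c(64L, 64L, 64L),
                          seed = 20250725L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    wildtype_prevalence = wildtype_prevalence,
    frac_dist_mutant = as.numeric(frac_dist_mutant),
    frac_dist_wildtype = as.numeric(frac_dist_wildtype),
    tumor_size_meanlog = tumor_size_meanlog,
    tumor_size_sdlog = tumor_size_sdlog,
    n_folds = as.integer(n_folds),
    fold_flip_rate = fold_flip_rate,
    volume_shape = as.integer(volume_shape),
    seed = as.integer(seed)
  )
  class(cfg) <- "idh_cohort_config"
  validate_cohort_config(cfg)
}

#' @rdname cohort_config
#' @param config object to validate.
#' @export
validate_cohort_config <- function(config) {
  stopifnot(inherits(config, "idh_cohort_config"))
  probs <- c(wildtype_prevalence = config$wildtype_prevalence,
             fold_flip_rate = config$fold_flip_rate)
  bad <- probs < 0 | probs > 1 | !is.finite(probs)
  if (any(bad)) {
    .idh_stop("idh_config_error",
              sprintf("probabilities out of [0,1]: %s",
                      paste(names(probs)[bad], collapse = ", ")))
  }
  if (config$n_subjects < 1L)
    .idh_stop("idh_config_error", "n_subjects must be >= 1")
  if (config$n_folds < 1L)
    .idh_stop("idh_config_error", "n_folds must be >= 1")
  for (nm in c("frac_dist_mutant", "frac_dist_wildtype")) {
    p <- config[[nm]]
    if (length(p) != 2L || any(!is.finite(p)) || any(p <= 0))
      .idh_stop("idh_config_error",
                sprintf("%s must be two strictly positive Beta shapes", nm))
  }
  if (!is.finite(config$tumor_size_sdlog) || config$tumor_size_sdlog <= 0 ||
      !is.finite(config$tumor_size_meanlog))
    .idh_stop("idh_config_error", "log-normal tumor size parameters invalid")
  if (length(config$volume_shape) != 3L || any(config$volume_shape < 1L))
    .idh_stop("idh_config_error", "volume_shape must be three positive integers")
  config
}

#' Simulate a synthetic cohort of per-fold voxel label maps
#'
#' Draws, for each subject, a true IDH status, a latent wildtype voxel
#' fraction from the class-conditional Beta distribution, and a tumor size;
#' builds the base tumor labelling in which `round(fraction * size)` voxels
#' carry label 2 (wildtype) and the remainder label 1 (mutant); and then
#' derives one labelling per fold by flipping each tumor voxel's class
#' independently with probability `fold_flip_rate`. Background voxels are
#' label 0 and only appear when a full volume is materialised with
#' [cohort_label_map()].
#'
#' Randomness is split per subject: a subject-level seed stream is drawn once
#' from the cohort seed, so enlarging `n_subjects` leaves earlier subjects'
#' draws untouched.
#'
#' @param config an [cohort_config()] object.
#' @return an object of class `idh_cohort`: a list with
#'   \describe{
#'     \item{truth}{data frame `subject_id`, `true_label`, `latent_fraction`,
#'       `tumor_voxels`.}
#'     \item{fold_labels}{list (one per subject) of `n_folds x tumor_voxels`
#'       integer matrices with values in \{1, 2\}.}
#'     \item{config}{the generating configuration.}
#'   }
#' @examples
#' coh <- simulate_cohort(cohort_config(n_subjects = 20, seed = 1))
#' head(coh$truth)
#' @export
simulate_cohort <- function(config = cohort_config()) {
  config <- validate_cohort_config(config)
  n <- config$n_subjects
  # prefix-stable per-subject seeds: sequential sampling means subject i's
  # seed is the same for every cohort size >= i
  set.seed(config$seed)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n)

  truth <- data.frame(
    subject_id = sprintf("S%05d", seq_len(n)),
    true_label = character(n),
    latent_fraction = numeric(n),
    tumor_voxels = integer(n),
    stringsAsFactors = FALSE
  )
  fold_labels <- vector("list", n)

  for (i in seq_len(n)) {
    set.seed(subject_seeds[i])
    is_wt <- runif(1) < config$wildtype_prevalence
    shp <- if (is_wt) config$frac_dist_wildtype else config$frac_dist_mutant
    f <- rbeta(1, shp[1], shp[2])
    size <- max(1L, as.integer(round(rlnorm(1, config$tumor_size_meanlog,
                                            config$tumor_size_sdlog))))
    n_wt <- as.integer(round(f * size))
    base <- c(rep(2L, n_wt), rep(1L, size - n_wt))
    labs <- matrix(base, nrow = config$n_folds, ncol = size, byrow = TRUE)
    if (config$fold_flip_rate > 0) {
      flips <- matrix(runif(config$n_folds * size) < config$fold_flip_rate,
                      nrow = config$n_folds)
      labs[flips] <- 3L - labs[flips]
    }
    truth$true_label[i] <- if (is_wt) "wildtype" else "mutant"
    truth$latent_fraction[i] <- f
    truth$tumor_voxels[i] <- size
    fold_labels[[i]] <- labs
  }
  truth$true_label <- .as_idh_label(truth$true_label)
  structure(list(truth = truth, fold_labels = fold_labels, config = config),
            class = "idh_cohort")
}

#' @export
print.idh_cohort <- function(x, ...) {
  n <- nrow(x$truth)
  cat(sprintf("idh_cohort: %d subjects, %d folds, %.1f%% wildtype\n",
              n, x$config$n_folds,
              100 * mean(x$truth$true_label == "wildtype")))
  cat(sprintf("  tumor size: median %d voxels (range %d-%d)\n",
              as.integer(median(x$truth$tumor_voxels)),
              min(x$truth$tumor_voxels), max(x$truth$tumor_voxels)))
  invisible(x)
}

#' Per-subject per-fold tumor voxel counts of a simulated cohort
#'
#' @param cohort an `idh_cohort`.
#' @return data frame `subject_id`, `fold_id`, `n_mutant`, `n_wildtype`.
#' @export
cohort_fold_counts <- function(cohort) {
  stopifnot(inherits(cohort, "idh_cohort"))
  n_folds <- cohort$config$n_folds
  out <- lapply(seq_along(cohort$fold_labels), function(i) {
    m <- cohort$fold_labels[[i]]
    data.frame(subject_id = cohort$truth$subject_id[i],
               fold_id = seq_len(n_folds),
               n_mutant = as.integer(rowSums(m == 1L)),
               n_wildtype = as.integer(rowSums(m == 2L)))
  })
  do.call(rbind, out)
}

# voxel indices of a centered ellipsoidal blob of exactly n voxels:
# voxels ranked by normalised squared distance to the volume center, so the
# blob is a filled (discretised) ellipsoid scaled to the grid
.blob_indices <- function(volume_shape, n) {
  if (n > prod(volume_shape)) {
    .idh_stop("idh_config_error",
              sprintf("tumor blob of %d voxels exceeds volume of %d voxels (%s)",
                      n, prod(volume_shape),
                      paste(volume_shape, collapse = "x")))
  }
  ctr <- (volume_shape + 1) / 2
  semi <- volume_shape / 2
  ax <- lapply(1:3, function(k) ((seq_len(volume_shape[k]) - ctr[k]) / semi[k])^2)
  d <- outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
  order(d)[seq_len(n)]
}

#' Materialise one subject/fold labelling as a 3-D label volume
#'
#' Embeds the subject's fold labelling into a `volume_shape` grid as a filled
#' ellipsoidal blob at the volume center (background label 0). Geometry is
#' cosmetic: downstream computation depends only on voxel counts, and the
#' blob exists to exercise the NIfTI path realistically.
#'
#' @param cohort an `idh_cohort`.
#' @param subject subject index or `subject_id`.
#' @param fold fold index in `1:n_folds`.
#' @return an [label_map()] with the cohort's `volume_shape`.
#' @export
cohort_label_map <- function(cohort, subject, fold) {
  stopifnot(inherits(cohort, "idh_cohort"))
  if (is.character(subject))
    subject <- match(subject, cohort$truth$subject_id)
  if (is.na(subject) || subject < 1L || subject > nrow(cohort$truth))
    .idh_stop("idh_usage_error", "unknown subject")
  labs <- cohort$fold_labels[[subject]][fold, ]
  vol <- array(0L, dim = cohort$config$volume_shape)
  vol[.blob_indices(cohort$config$volume_shape, length(labs))] <- labs
  label_map(vol, subject_id = cohort$truth$subject_id[subject], fold_id = fold)
}

#' Write a simulated cohort to disk
#'
#' Writes the truth table (`truth.csv`), per-fold voxel counts
#' (`fold_counts.csv`), the generating configuration (`config.yaml`), and —
#' optionally — one NIfTI label volume per subject and fold under
#' `volumes/<subject>_fold<k>.nii.gz`.
#'
#' @param cohort an `idh_cohort`.
#' @param dir output directory (created if missing).
#' @param write_volumes also write NIfTI volumes (slow and large for big
#'   cohorts; the counts CSV alone drives the full pipeline).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, write_volumes = FALSE) {
  stopifnot(inherits(cohort, "idh_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- cohort$truth
  truth$true_label <- as.character(truth$true_label)
  write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  write.csv(cohort_fold_counts(cohort), file.path(dir, "fold_counts.csv"),
            row.names = FALSE)
  yaml::write_yaml(unclass(cohort$config), file.path(dir, "config.yaml"))
  if (write_volumes) {
    vdir <- file.path(dir, "volumes")
    dir.create(vdir, showWarnings = FALSE)
    for (i in seq_len(nrow(cohort$truth))) {
      for (k in seq_len(cohort$config$n_folds)) {
        write_label_map(cohort_label_map(cohort, i, k),
                        file.path(vdir, sprintf("%s_fold%d.nii.gz",
                                                cohort$truth$subject_id[i], k)))
      }
    }
  }
  invisible(dir)
}
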