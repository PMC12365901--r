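#' End-to-end pipeline configuration
#'
#' One object driving the whole analysis: where the inputs come from
#' (simulate a cohort, read a per-fold counts CSV, or read NIfTI volumes),
#' how the two held-out cohorts are formed, the MCMC budget, and the seed
#' every random stage derives from. The default simulated split mirrors the
#' two held-out test groups of the reference study: 1236 calibration
#' subjects (TG-1 analogue) and 164 scored subjects (TG-2 analogue).
#'
#' @param mode `"simulate"`, `"counts"` or `"volumes"` — exactly one input
#'   mode.
#' @param n_a,n_b simulated cohort sizes (simulate mode).
#' @param sim overrides for [cohort_config()] fields (named list), applied to
#'   both cohorts.
#' @param counts_csv,truth_csv input paths (counts mode).
#' @param volumes,truth_csv_volumes volume manifest data frame
#'   (`subject_id`, `fold_id`, `path`) and truth CSV (volumes mode).
#' @param cohort_a_ids,cohort_b_ids subject-id membership of the two cohorts
#'   (counts/volumes modes).
#' @param chains,warmup,draws MCMC budget for the Bayesian fits.
#' @param seed master seed; all stage seeds derive from it.
#' @param bins reliability-diagram bin count.
#' @return list of class `idh_pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "counts", "volumes"),
                            n_a = 1236L, n_b = 164L, sim = list(),
                            counts_csv = NULL, truth_csv = NULL,
                            volumes = NULL, truth_csv_volumes = NULL,
                            cohort_a_ids = NULL, cohort_b_ids = NULL,
                            chains = 4L, warmup = 1000L, draws = 2000L,
                            seed = 20250725L, bins = 10L) {
  mode <- match.arg(mode)
  cfg <- list(mode = mode, n_a = as.integer(n_a), n_b = as.integer(n_b),
              sim = sim, counts_csv = counts_csv, truth_csv = truth_csv,
              volumes = volumes, truth_csv_volumes = truth_csv_volumes,
              cohort_a_ids = cohort_a_ids, cohort_b_ids = cohort_b_ids,
              chains = as.integer(chains), warmup = as.integer(warmup),
              draws = as.integer(draws), seed = as.integer(seed),
              bins = as.integer(bins))
  if (mode == "counts" && (is.null(counts_csv) || is.null(truth_csv)))
    .idh_stop("idh_config_error", "counts mode needs counts_csv and truth_csv")
  if (mode != "simulate" &&
      (is.null(cohort_a_ids) || is.null(cohort_b_ids)))
    .idh_stop("idh_config_error",
              "counts/volumes modes need explicit cohort_a_ids and cohort_b_ids")
  if (!is.null(cohort_a_ids) && length(intersect(cohort_a_ids, cohort_b_ids)) > 0L)
    .idh_stop("idh_leakage_error",
              sprintf("cohort A/B membership overlaps: %s",
                      paste(head(intersect(cohort_a_ids, cohort_b_ids), 10),
                            collapse = ", ")))
  class(cfg) <- "idh_pipeline_config"
  cfg
}

# simulate the two disjoint cohorts, with ids prefixed so they never collide
.simulate_split <- function(config) {
  base <- do.call(cohort_config, c(list(n_subjects = config$n_a,
                                        seed = config$seed), config$sim))
  coh_a <- simulate_cohort(base)
  cfg_b <- base
  cfg_b$n_subjects <- config$n_b
  cfg_b$seed <- base$seed + 1L
  coh_b <- simulate_cohort(validate_cohort_config(cfg_b))
  coh_a$truth$subject_id <- paste0("A_", coh_a$truth$subject_id)
  coh_b$truth$subject_id <- paste0("B_", coh_b$truth$subject_id)
  list(a = coh_a, b = coh_b)
}

#' Simulate a cohort pair and write it to disk
#'
#' Wraps [simulate_cohort()] for the configured A/B split and writes truth
#' tables, per-fold counts, the generating config and a manifest recording
#' the config hash and seed. With `write_volumes = TRUE` one NIfTI per
#' subject and fold is emitted too.
#'
#' @param config an [pipeline_config()] in simulate mode.
#' @param dir output directory.
#' @param write_volumes also write NIfTI label volumes.
#' @return `dir`, invisibly.
#' @export
run_simulate <- function(config, dir, write_volumes = FALSE) {
  stopifnot(inherits(config, "idh_pipeline_config"))
  if (config$mode != "simulate")
    .idh_stop("idh_config_error", "run_simulate needs a simulate-mode config")
  cohorts <- .simulate_split(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(cohorts$a, file.path(dir, "cohort_a"), write_volumes = write_volumes)
  write_cohort(cohorts$b, file.path(dir, "cohort_b"), write_volumes = write_volumes)
  cfg_path <- file.path(dir, "pipeline_config.yaml")
  yaml::write_yaml(.config_as_list(config), cfg_path)
  manifest <- list(
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    n_subjects = c(cohort_a = config$n_a, cohort_b = config$n_b),
    files = list.files(dir, recursive = TRUE)
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

.config_as_list <- function(config) {
  out <- unclass(config)
  out$volumes <- NULL
  out
}

#' Run the full confidence pipeline
#'
#' Executes ensemble -> wildtype fraction -> majority vote ->
#' two-stage held-out calibration -> metrics, from whichever input mode the
#' config selects. When `out` is given, writes `subjects.csv`,
#' `metrics.json`, `reliability.csv`, `manifest.yaml` and `run.log` there.
#'
#' @param config an [pipeline_config()].
#' @param out optional output directory.
#' @param quiet suppress progress messages.
#' @return list of class `idh_run`: `records_a`, `records_b` (subject
#'   records), `protocol` (the [two_stage_protocol()] result), `reliability`
#'   (per scoring method), `log` (character vector of stage messages).
#' @export
run_all <- function(config, out = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "idh_pipeline_config"))
  logln <- local({
    log <- character()
    function(fmt = NULL, ...) {
      if (is.null(fmt)) return(log)
      line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
      log <<- c(log, line)
      if (!quiet) message(line)
      invisible(line)
    }
  })

  if (config$mode == "simulate") {
    logln("simulating cohorts A (n=%d) and B (n=%d), seed %d",
          config$n_a, config$n_b, config$seed)
    cohorts <- .simulate_split(config)
    rec_a <- call_subjects(cohorts$a)
    rec_b <- call_subjects(cohorts$b)
  } else {
    truth <- read.csv(if (config$mode == "counts") config$truth_csv
                      else config$truth_csv_volumes, stringsAsFactors = FALSE)
    if (config$mode == "counts") {
      counts <- read_counts_csv(config$counts_csv)
      recs <- call_subjects(counts, truth = truth)
    } else {
      logln("reading %d label volumes", nrow(config$volumes))
      recs <- .call_from_volumes(config$volumes, truth)
    }
    rec_a <- recs[recs$subject_id %in% config$cohort_a_ids, , drop = FALSE]
    rec_b <- recs[recs$subject_id %in% config$cohort_b_ids, , drop = FALSE]
  }
  logln("cohort A: %d subjects (%d ties); cohort B: %d subjects (%d ties)",
        nrow(rec_a), sum(rec_a$tie_flag), nrow(rec_b), sum(rec_b$tie_flag))

  logln("fitting calibration on cohort A; scoring cohort B")
  prot <- two_stage_protocol(rec_a, rec_b, chains = config$chains,
                             warmup = config$warmup, draws = config$draws,
                             seed = config$seed)
  logln("Brier on cohort B: %s",
        paste(sprintf("%s=%.4f", names(prot$brier), prot$brier), collapse = " "))

  y_b <- .label_to_y(prot$scores_b$true_label)
  rel_list <- list()
  for (nm in c("raw", "lr", "blr_informative", "blr_noninformative")) {
    col <- if (nm == "raw") "p_raw" else paste0("p_wildtype_", nm)
    r <- reliability_table(prot$scores_b[[col]], y_b, bins = config$bins)
    r$method <- nm
    rel_list[[nm]] <- r
  }
  rel <- do.call(rbind, rel_list)
  rownames(rel) <- NULL

  res <- structure(list(records_a = rec_a, records_b = rec_b,
                        protocol = prot, reliability = rel,
                        config = config, log = logln()),
                   class = "idh_run")
  if (!is.null(out)) .write_run(res, out)
  res
}

.call_from_volumes <- function(volumes, truth) {
  need <- c("subject_id", "fold_id", "path")
  if (!is.data.frame(volumes) || !all(need %in% names(volumes)))
    .idh_stop("idh_config_error",
              "volumes manifest needs columns subject_id, fold_id, path")
  recs <- lapply(split(volumes, volumes$subject_id), function(vs) {
    maps <- lapply(seq_len(nrow(vs)), function(i)
      read_label_map(vs$path[i], subject_id = vs$subject_id[i],
                     fold_id = vs$fold_id[i]))
    ens <- ensemble_folds(maps)
    cts <- whole_tumor_counts(ens)
    data.frame(subject_id = vs$subject_id[1], n_mutant = cts$n_mutant,
               n_wildtype = cts$n_wildtype,
               ensemble_ties = attr(ens, "n_ties"))
  })
  df <- do.call(rbind, recs)
  df$x <- wildtype_fraction(df$n_mutant, df$n_wildtype)
  vote <- majority_vote(df$n_mutant, df$n_wildtype)
  df$predicted_label <- vote$predicted_label
  df$tie_flag <- vote$tie_flag
  m <- match(df$subject_id, truth$subject_id)
  df$true_label <- .as_idh_label(truth$true_label[m])
  rownames(df) <- NULL
  df
}

.write_run <- function(res, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  sub <- res$protocol$scores_b
  sub$true_label <- as.character(sub$true_label)
  sub$predicted_label <- as.character(sub$predicted_label)
  write.csv(sub, file.path(out, "subjects.csv"), row.names = FALSE)
  write.csv(res$reliability, file.path(out, "reliability.csv"), row.names = FALSE)
  m <- function(mm) mm[c("n", "n_mutant", "n_wildtype", "accuracy",
                         "accuracy_mutant_class", "accuracy_wildtype_class",
                         "precision", "recall", "f1", "auc")]
  cfg_path <- file.path(out, "config.yaml")
  yaml::write_yaml(.config_as_list(res$config), cfg_path)
  metrics <- list(
    package_version = as.character(utils::packageVersion("idhconf")),
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = res$config$seed,
    cohort_a = m(res$protocol$metrics_a),
    cohort_b = m(res$protocol$metrics_b),
    brier_b = as.list(res$protocol$brier),
    ties_b = sum(res$records_b$tie_flag)
  )
  jsonlite::write_json(metrics, file.path(out, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(res$log, file.path(out, "run.log"))
  invisible(out)
}

#' @export
print.idh_run <- function(x, ...) {
  print(x$protocol)
  invisible(x)
}
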