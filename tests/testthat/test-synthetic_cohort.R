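test_that("config validation rejects out-of-range parameters", {
  expect_s3_class(cohort_config(), "idh_cohort_config")
  expect_error(cohort_config(wildtype_prevalence = 1.2), class = "idh_config_error")
  expect_error(cohort_config(fold_flip_rate = -0.1), class = "idh_config_error")
  expect_error(cohort_config(frac_dist_mutant = c(0, 2)), class = "idh_config_error")
  expect_error(cohort_config(n_folds = 0), class = "idh_config_error")
  expect_error(cohort_config(tumor_size_sdlog = 0), class = "idh_config_error")
})

test_that("identical seed and config give bit-identical cohorts", {
  cfg <- cohort_config(n_subjects = 30, seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$fold_labels, b$fold_labels)
})

test_that("adding subjects leaves earlier subjects' draws untouched", {
  small <- simulate_cohort(cohort_config(n_subjects = 40, seed = 11))
  big <- simulate_cohort(cohort_config(n_subjects = 80, seed = 11))
  expect_identical(small$truth, big$truth[1:40, ])
  expect_identical(small$fold_labels, big$fold_labels[1:40])
})

test_that("noise-free degenerate wildtype distribution labels every voxel 2", {
  cfg <- cohort_config(n_subjects = 15, wildtype_prevalence = 1,
                       frac_dist_wildtype = c(1e8, 1e-8),
                       fold_flip_rate = 0, n_folds = 3, seed = 3)
  coh <- simulate_cohort(cfg)
  expect_true(all(coh$truth$true_label == "wildtype"))
  for (m in coh$fold_labels) expect_true(all(m == 2L))
})

test_that("with zero flip rate all folds are identical", {
  coh <- simulate_cohort(cohort_config(n_subjects = 20, fold_flip_rate = 0, seed = 5))
  for (m in coh$fold_labels) {
    expect_true(all(m == rep(m[1, ], each = nrow(m))))
  }
})

test_that("sampled mutant-truth fractions recover the Beta mean", {
  coh <- simulate_cohort(cohort_config(n_subjects = 5000,
                                       frac_dist_mutant = c(2, 20), seed = 99))
  f <- coh$truth$latent_fraction[coh$truth$true_label == "mutant"]
  mc_se <- sd(f) / sqrt(length(f))
  expect_lt(abs(mean(f) - 2 / 22), 3 * mc_se)
})

test_that("class prevalence converges to the configured value", {
  coh <- simulate_cohort(cohort_config(n_subjects = 2500, seed = 13))
  p_hat <- mean(coh$truth$true_label == "wildtype")
  p <- 1904 / 2481
  ci <- p + c(-1, 1) * 3 * sqrt(p * (1 - p) / 2500)
  expect_gt(p_hat, ci[1])
  expect_lt(p_hat, ci[2])
})

test_that("the two truth classes form a bimodal fraction distribution", {
  coh <- simulate_cohort(cohort_config(n_subjects = 2000, seed = 17))
  f <- split(coh$truth$latent_fraction, coh$truth$true_label)
  gap <- abs(mean(f$wildtype) - mean(f$mutant))
  expect_gt(gap, sd(f$wildtype) + sd(f$mutant))
})

test_that("fold counts table tallies the stored labellings", {
  coh <- simulate_cohort(cohort_config(n_subjects = 6, seed = 21))
  fc <- cohort_fold_counts(coh)
  expect_equal(nrow(fc), 6 * coh$config$n_folds)
  i <- 4; k <- 2
  row <- fc[fc$subject_id == coh$truth$subject_id[i] & fc$fold_id == k, ]
  expect_equal(row$n_mutant, sum(coh$fold_labels[[i]][k, ] == 1L))
  expect_equal(row$n_wildtype, sum(coh$fold_labels[[i]][k, ] == 2L))
  expect_equal(row$n_mutant + row$n_wildtype, coh$truth$tumor_voxels[i])
})

test_that("a tumor larger than the volume is a configuration error naming both sizes", {
  cfg <- cohort_config(n_subjects = 2, volume_shape = c(6, 6, 6),
                       tumor_size_meanlog = log(5000), tumor_size_sdlog = 0.01,
                       seed = 2)
  coh <- simulate_cohort(cfg)
  err <- expect_error(cohort_label_map(coh, 1, 1), class = "idh_config_error")
  expect_match(conditionMessage(err), "216")
  expect_match(conditionMessage(err), as.character(coh$truth$tumor_voxels[1]))
})

test_that("materialised volumes carry the subject's exact voxel counts", {
  coh <- simulate_cohort(cohort_config(n_subjects = 3, volume_shape = c(24, 24, 24),
                                       tumor_size_meanlog = log(300),
                                       tumor_size_sdlog = 0.3, seed = 8))
  for (i in 1:3) {
    vol <- cohort_label_map(coh, i, 1)
    cts <- whole_tumor_counts(vol)
    expect_equal(cts$n_mutant + cts$n_wildtype, coh$truth$tumor_voxels[i])
    expect_equal(cts$n_wildtype, sum(coh$fold_labels[[i]][1, ] == 2L))
  }
})
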