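test_that("an all-correct cohort scores 100 everywhere", {
  truth <- rep(c("wildtype", "mutant"), c(7, 3))
  m <- classification_metrics(truth, truth, scores = c(rep(0.9, 7), rep(0.1, 3)))
  expect_equal(m$accuracy, 100)
  expect_equal(m$f1, 100)
  expect_equal(m$precision, 100)
  expect_equal(m$recall, 100)
  expect_equal(m$auc, 1.0)
})

test_that("a perfect ranking has AUC 1", {
  truth <- c("wildtype", "wildtype", "mutant", "mutant")
  m <- classification_metrics(truth, truth, scores = c(0.9, 0.8, 0.2, 0.1))
  expect_equal(m$auc, 1.0)
})

test_that("metrics on random cohorts match confusion-matrix and pairwise oracles", {
  set.seed(71)
  for (rep in 1:5) {
    n <- 200
    truth <- sample(c("mutant", "wildtype"), n, replace = TRUE, prob = c(0.3, 0.7))
    predicted <- ifelse(runif(n) < 0.85, truth,
                        ifelse(truth == "mutant", "wildtype", "mutant"))
    scores <- round(runif(n), 2)  # coarse grid to force score ties
    m <- classification_metrics(truth, predicted, scores = scores)
    cm <- oracle_confusion(truth, predicted)
    expect_equal(m$accuracy, 100 * (cm["tp"] + cm["tn"]) / n, ignore_attr = TRUE)
    expect_equal(m$precision, 100 * cm["tp"] / (cm["tp"] + cm["fp"]), ignore_attr = TRUE)
    expect_equal(m$recall, 100 * cm["tp"] / (cm["tp"] + cm["fn"]), ignore_attr = TRUE)
    p <- cm["tp"] / (cm["tp"] + cm["fp"]); r <- cm["tp"] / (cm["tp"] + cm["fn"])
    expect_equal(m$f1, 100 * 2 * p * r / (p + r), ignore_attr = TRUE)
    expect_equal(m$auc, oracle_auc(scores, as.integer(truth == "wildtype")))
  }
})

test_that("recall equals wildtype-class accuracy by construction", {
  set.seed(73)
  truth <- sample(c("mutant", "wildtype"), 150, replace = TRUE)
  predicted <- sample(c("mutant", "wildtype"), 150, replace = TRUE)
  m <- classification_metrics(truth, predicted)
  expect_identical(m$recall, m$accuracy_wildtype_class)
})

test_that("single-class cohorts report AUC as undefined with a reason", {
  truth <- rep("wildtype", 10)
  m <- classification_metrics(truth, truth, scores = runif(10))
  expect_true(is.na(m$auc))
  expect_match(attr(m, "undefined"), "single-class")
})

test_that("count-weighted pooling reproduces multi-site overall cells", {
  expect_equal(round(pooled_weighted(c(96.0, 93.6, 96.3, 98.0),
                                     c(177, 204, 456, 399)), 1), 96.4)
  expect_equal(round(pooled_weighted(c(93.2, 96.2), c(59, 105)), 1), 95.1)
  expect_equal(pooled_weighted(87.3, 42), 87.3)  # single cohort is the identity
  expect_error(pooled_weighted(c(1, 2), c(1, 0)), class = "idh_usage_error")
})

test_that("Brier score matches its closed forms and a summation oracle", {
  y <- c(1, 1, 0, 0, 1)
  expect_equal(brier_score(y, y), 0)
  expect_equal(brier_score(rep(0.5, 5), y), 0.25)
  set.seed(75)
  s <- runif(100); yy <- rbinom(100, 1, 0.5)
  acc <- 0
  for (i in 1:100) acc <- acc + (s[i] - yy[i])^2
  expect_equal(brier_score(s, yy), acc / 100)
  expect_error(brier_score(c(0.5, 1.2), c(0, 1)), class = "idh_usage_error")
})

test_that("reliability table partitions the cohort and tracks outcome rates", {
  set.seed(77)
  s <- runif(500); y <- rbinom(500, 1, s)
  rel <- reliability_table(s, y, bins = 10)
  expect_equal(sum(rel$n), 500)
  expect_true(all(rel$mean_score >= rel$lower & rel$mean_score <= rel$upper))
})

test_that("the two-stage protocol refuses shared subject ids", {
  d <- sim_fractions(60, seed = 79)
  rec <- data.frame(subject_id = sprintf("S%02d", 1:60), x = d$x,
                    true_label = ifelse(d$y == 1, "wildtype", "mutant"),
                    predicted_label = ifelse(d$x > 0.5, "wildtype", "mutant"))
  err <- expect_error(two_stage_protocol(rec[1:40, ], rec[35:60, ]),
                      class = "idh_leakage_error")
  expect_match(conditionMessage(err), "S35")
})

test_that("a distributional copy of cohort A scores its in-sample Brier", {
  d <- sim_fractions(300, seed = 81)
  a <- data.frame(subject_id = sprintf("A%03d", 1:300), x = d$x,
                  true_label = ifelse(d$y == 1, "wildtype", "mutant"),
                  predicted_label = ifelse(d$x > 0.5, "wildtype", "mutant"))
  b <- a
  b$subject_id <- sprintf("B%03d", 1:300)
  prot <- two_stage_protocol(a, b, chains = 2, warmup = 300, draws = 400, seed = 1)
  in_sample <- brier_score(confidence(prot$fits$lr, a$x)$p_wildtype,
                           ifelse(a$true_label == "wildtype", 1, 0))
  expect_equal(unname(prot$brier["lr"]), in_sample)
})

test_that("no cohort-B datum influences the fits", {
  d <- sim_fractions(200, seed = 83)
  a <- data.frame(subject_id = sprintf("A%03d", 1:200), x = d$x,
                  true_label = ifelse(d$y == 1, "wildtype", "mutant"),
                  predicted_label = ifelse(d$x > 0.5, "wildtype", "mutant"))
  mk_b <- function(seed) {
    e <- sim_fractions(50, seed = seed)
    data.frame(subject_id = sprintf("B%03d", 1:50), x = e$x,
               true_label = ifelse(e$y == 1, "wildtype", "mutant"),
               predicted_label = ifelse(e$x > 0.5, "wildtype", "mutant"))
  }
  p1 <- two_stage_protocol(a, mk_b(1), chains = 2, warmup = 300, draws = 400, seed = 2)
  p2 <- two_stage_protocol(a, mk_b(99), chains = 2, warmup = 300, draws = 400, seed = 2)
  expect_identical(p1$fits$lr[c("alpha", "beta")], p2$fits$lr[c("alpha", "beta")])
  expect_identical(p1$fits$blr_noninformative$draws, p2$fits$blr_noninformative$draws)
})
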