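test_that("spearman screen recovers exact monotone relationships", {
  set.seed(101)
  score <- rnorm(50)
  feats <- cbind(identity = score, antitone = -score,
                 monotone = exp(score))
  rec <- spearman_screen(score, feats)
  expect_equal(rec$estimate[rec$feature == "identity"], 1)
  expect_lt(rec$p_value[rec$feature == "identity"], 1e-6)
  expect_equal(rec$estimate[rec$feature == "antitone"], -1)
  # invariance under strictly monotone transforms
  expect_equal(rec$estimate[rec$feature == "monotone"], 1)
})

test_that("constant features are reported untested with a message", {
  set.seed(102)
  feats <- cbind(flat = rep(1, 30), ok = rnorm(30))
  expect_message(rec <- spearman_screen(rnorm(30), feats), "constant")
  expect_true(is.na(rec$estimate[rec$feature == "flat"]))
  expect_false(rec$tested[rec$feature == "flat"])
  expect_true(rec$tested[rec$feature == "ok"])
})

test_that("screen FDR reproduces textbook Benjamini-Hochberg step-up", {
  # features engineered to give a known p-value vector, then compare the
  # screen's fdr column against the step-up formula computed inline
  set.seed(103)
  score <- rnorm(40)
  feats <- sapply(1:6, function(j) 0.3 * j * score + rnorm(40))
  colnames(feats) <- paste0("f", 1:6)
  rec <- spearman_screen(score, feats)
  p <- rec$p_value
  m <- length(p)
  o <- order(p)
  stepup <- numeric(m)
  stepup[o] <- rev(cummin(rev(p[o] * m / seq_len(m))))
  expect_equal(rec$fdr, pmin(stepup, 1))
})

test_that("planted recurrent features pass the filter, sporadic ones fail", {
  cfg <- generator_config(n_cohorts = 22, samples_per_cohort = 100,
                          features = list(n_features = 30))
  truth <- generate_profiles(cfg, seed = 111, scores_only = TRUE)$truth
  feat <- generate_features(cfg, truth)
  rec <- suppressMessages(
    spearman_screen(truth$ncs_true, feat$matrix, cohort = truth$cohort))
  calls <- recurrence_filter(rec)
  planted <- feat$truth
  recurrent <- planted$feature[1:2]    # planted in 10 cohorts
  sporadic <- planted$feature[3]       # planted in 3 cohorts
  expect_true(all(calls$passes_filter[calls$feature %in% recurrent]))
  expect_false(calls$passes_filter[calls$feature == sporadic])
  # null features never pass
  nulls <- setdiff(calls$feature, planted$feature)
  expect_true(all(!calls$passes_filter[calls$feature %in% nulls]))
})

test_that("recurrence filter honours its thresholds", {
  rec <- data.frame(
    feature = rep(c("a", "b"), each = 10),
    cohort = rep(sprintf("C%02d", 1:10), 2),
    estimate = c(rep(0.5, 10), rep(0.5, 3), rep(0.1, 7)),
    fdr = 0.01, tested = TRUE, stringsAsFactors = FALSE)
  calls <- recurrence_filter(rec)
  expect_true(calls$passes_filter[calls$feature == "a"])   # 10 cohorts
  expect_false(calls$passes_filter[calls$feature == "b"])  # 3 cohorts
  # negative correlations never count even with rho_min <= 0
  rec$estimate <- -0.5
  expect_equal(recurrence_filter(rec, rho_min = -1)$n_cohorts_passing,
               c(0L, 0L))
})

test_that("single-cohort regression equals the two-group mean difference", {
  set.seed(121)
  y <- rnorm(100)
  g <- rbinom(100, 1, 0.4)
  res <- regress_alterations(y, cbind(gene = g), rep("C1", 100))
  expect_equal(res$estimate, mean(y[g == 1]) - mean(y[g == 0]),
               tolerance = 1e-12)
})

test_that("regression matches limma's fit on the same design", {
  skip_if_not_installed("limma")
  set.seed(122)
  n <- 120
  cohort <- rep(c("A", "B", "C"), each = 40)
  g <- rbinom(n, 1, 0.4)
  y <- 2 * g + (cohort == "B") + rnorm(n)
  ours <- regress_alterations(y, cbind(gene = g), cohort)
  design <- stats::model.matrix(~ g + factor(cohort))
  lf <- limma::lmFit(matrix(y, nrow = 1), design)
  expect_equal(ours$estimate, unname(lf$coefficients[1, "g"]),
               tolerance = 1e-10)
})

test_that("eligibility and collinearity rules are enforced", {
  set.seed(123)
  n <- 200
  cohort <- rep(c("A", "B"), each = 100)
  y <- rnorm(n)
  rare <- c(rep(1, 19), rep(0, n - 19))          # 19 carriers: not tested
  confounded <- as.integer(cohort == "A")        # aliased with cohort
  ok <- rbinom(n, 1, 0.3)
  res <- suppressMessages(regress_alterations(
    y, cbind(rare = rare, confounded = confounded, ok = ok), cohort))
  expect_false(res$tested[res$feature == "rare"])
  expect_false(res$tested[res$feature == "confounded"])
  expect_true(res$collinear[res$feature == "confounded"])
  expect_true(res$tested[res$feature == "ok"])
  expect_true(is.na(res$fdr[res$feature == "confounded"]))
})

test_that("planted CIN-driver alteration effect is recovered from profiles", {
  cfg <- generator_config(n_cohorts = 4, samples_per_cohort = 100)
  sim <- simulate_cohort(cfg, seed = 131)
  sc <- score_cohort(sim$segments, sim$samples)
  res <- suppressMessages(regress_alterations(
    sc$ncs, sim$alterations, sim$truth$cohort))
  est <- res$estimate[res$feature == "GENE_CINDRIVER"]
  expect_gt(est, 2.5)
  expect_lt(est, 5.5)
  expect_lt(res$fdr[res$feature == "GENE_CINDRIVER"], 0.05)
  # the ~10-carrier gene is excluded by the sample-count filter
  expect_false(res$tested[res$feature == "GENE_RARE"])
})

test_that("hypermutated-sample exclusion follows flags or cutoffs", {
  ann <- data.frame(sample_id = paste0("S", 1:10),
                    min_flag = c(rep(TRUE, 10)), MIN = 1:10)
  expect_message(out <- exclude_hypermutated(ann), "removed 10")
  expect_equal(nrow(out), 0)

  ann$min_flag <- FALSE
  expect_equal(nrow(suppressMessages(exclude_hypermutated(ann))), 10)

  out <- suppressMessages(
    exclude_hypermutated(ann[, c("sample_id", "MIN")], cutoff = 7))
  expect_equal(nrow(out), 7)
  expect_error(exclude_hypermutated(ann[, "sample_id", drop = FALSE]),
               "cutoff")
})
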