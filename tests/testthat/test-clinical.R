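test_that("median stratification sends ties to the low group by default", {
  expect_equal(as.character(stratify_by_median(c(1, 2, 3, 4, 5))),
               c("low", "low", "low", "high", "high"))
  expect_equal(as.character(stratify_by_median(c(0, 0, 10, 10))),
               c("low", "low", "high", "high"))
  # ties = "high" flips the median-tied sample
  expect_equal(as.character(stratify_by_median(c(1, 2, 3), ties = "high")),
               c("low", "high", "high"))
  expect_error(stratify_by_median(rep(2, 5)), "constant")
})

test_that("stratification counts behave at odd n and within cohorts", {
  set.seed(201)
  x <- rnorm(501)
  g <- stratify_by_median(x)
  expect_equal(length(g), 501)
  expect_equal(sum(g == "high") + sum(g == "low"), 501)
  expect_lte(sum(g == "high"), 250)

  # per-cohort medians differ from the global one
  cohort <- rep(c("A", "B"), c(250, 251))
  x2 <- c(rnorm(250, 0), rnorm(251, 10))
  g2 <- stratify_by_median(x2, cohort)
  expect_lte(abs(sum(g2[cohort == "A"] == "high") -
                 sum(g2[cohort == "A"] == "low")), 1)
})

test_that("identical survival in both groups gives p ~ 1 and HR ~ 1", {
  time <- rep(c(100, 200, 300, 400, 500), 2)
  event <- rep(c(1, 1, 0, 1, 0), 2)
  group <- factor(rep(c("low", "high"), each = 5), levels = c("low", "high"))
  res <- survival_compare(time, event, group)
  expect_gt(res$logrank_p, 0.99)
  expect_equal(res$hr, 1, tolerance = 1e-6)
  expect_true(res$reliable)
})

test_that("log-rank p is invariant under permuting sample order", {
  set.seed(211)
  n <- 80
  time <- rexp(n, 1 / 500)
  event <- rbinom(n, 1, 0.7)
  group <- factor(sample(c("low", "high"), n, TRUE),
                  levels = c("low", "high"))
  r1 <- survival_compare(time, event, group)
  perm <- sample(n)
  r2 <- survival_compare(time[perm], event[perm], group[perm])
  expect_equal(r1$logrank_p, r2$logrank_p)
  expect_equal(r1$hr, r2$hr)
})

test_that("Cox HR is unchanged when the dataset is duplicated", {
  set.seed(212)
  n <- 60
  time <- rexp(n, 1 / 400)
  event <- rbinom(n, 1, 0.8)
  group <- factor(rep(c("low", "high"), n / 2), levels = c("low", "high"))
  r1 <- survival_compare(time, event, group)
  r2 <- survival_compare(rep(time, 2), rep(event, 2), rep(group, 2))
  expect_equal(r1$hr, r2$hr, tolerance = 1e-6)
})

test_that("KM five-year survival equals the empirical survivor function
           without censoring", {
  time <- c(500, 1000, 1500, 2000, 2500, 3000)
  event <- rep(1, 6)
  group <- factor(rep(c("low", "high"), each = 3), levels = c("low", "high"))
  res <- survival_compare(time, event, group)
  # low group: events at 500/1000/1500, all before 1826 days -> S(1826) = 0
  expect_equal(res$surv5y_low, 0)
  # high group: no event before 1826 days -> S(1826) = 1
  expect_equal(res$surv5y_high, 1)
})

test_that("a group without events is flagged unreliable", {
  time <- c(100, 200, 300, 400)
  event <- c(1, 1, 0, 0)
  group <- factor(c("low", "low", "high", "high"),
                  levels = c("low", "high"))
  expect_false(survival_compare(time, event, group)$reliable)
})

test_that("per-cohort survival driver returns one row per cohort", {
  sim <- simulate_cohort(generator_config(n_cohorts = 3,
                                          samples_per_cohort = 60), seed = 221)
  sc <- score_cohort(sim$segments, sim$samples)
  res <- survival_by_cohort(sc, sim$annotations, score = "ncs",
                            endpoint = "os")
  expect_equal(nrow(res), 3)
  expect_true(all(res$n_low + res$n_high > 0))
  expect_true(all(res$hr > 0, na.rm = TRUE))
  expect_true(all(res$hr_lower <= res$hr & res$hr <= res$hr_upper,
                  na.rm = TRUE))
})

test_that("responder rank test handles ties, shifts and degenerate input", {
  expect_equal(response_test(rep(3, 10),
                             rep(c("responder", "non-responder"), 5))$p_value,
               1)
  expect_error(response_test(1:5, rep("responder", 5)), "non-empty")

  # p decreases monotonically with the location shift
  set.seed(231)
  base <- rnorm(200)
  labels <- rep(c("responder", "non-responder"), each = 100)
  p_at_shift <- vapply(c(0.3, 0.8, 1.5), function(shift) {
    median(vapply(1:20, function(i) {
      x <- c(rnorm(100) - shift, rnorm(100))
      response_test(x, labels)$p_value
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(p_at_shift) < 0))
})
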