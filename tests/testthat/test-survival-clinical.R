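test_that("Kaplan-Meier matches hand product-limit computations", {
  # all censored: survival stays at 1
  km0 <- kaplan_meier(c(5, 8, 12), c(0, 0, 0))
  expect_true(all(km0$survival == 1))

  # no censoring: 1 - ECDF at each event time
  km1 <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km1$survival, c(2 / 3, 1 / 3, 0))

  # censoring at 2: S(1) = 2/3, then the last subject's event takes S to 0
  km2 <- kaplan_meier(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$survival[km2$time == 1], 2 / 3)
  expect_equal(km2$survival[km2$time == 3], 0)

  # randomized agreement with the brute-force estimator under no censoring
  set.seed(11)
  for (i in 1:5) {
    t <- rexp(30, 0.1)
    km <- kaplan_meier(t, rep(1, 30))
    ref <- brute_km(t, rep(1, 30))
    expect_equal(km$survival[km$n_event > 0], ref$survival, tolerance = 1e-12)
    # and equals 1 - ECDF exactly at event times
    expect_equal(ref$survival, 1 - ecdf(t)(ref$time), tolerance = 1e-12)
  }
  expect_error(kaplan_meier(numeric(0), numeric(0)), "empty")
  expect_error(kaplan_meier(c(-1, 2), c(1, 1)), "negative")
})

test_that("log-rank is null on identical groups, symmetric, and powered under HR = 3", {
  t <- c(2, 4, 6, 8, 10)
  res <- logrank_test(rep(t, 2), rep(1, 10), rep(c("a", "b"), each = 5))
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)

  set.seed(12)
  hits <- 0
  for (s in 1:10) {
    t1 <- rexp(200, 1); t2 <- rexp(200, 3)
    r <- logrank_test(c(t1, t2), rep(1, 400), rep(c("a", "b"), each = 200))
    if (r$p_value < 0.01) hits <- hits + 1
    # invariance to label swap
    r_swap <- logrank_test(c(t2, t1), rep(1, 400), rep(c("b", "a"), each = 200))
    expect_equal(r$statistic, r_swap$statistic, tolerance = 1e-9)
  }
  expect_gte(hits, 9)
  expect_error(logrank_test(t, rep(1, 5), rep("a", 5)), "2 groups")
})

test_that("Cox recovers a planted hazard ratio and rejects degenerate designs", {
  set.seed(13)
  n <- 500
  cimp <- rep(c("negative", "positive"), each = n / 2)
  t <- rexp(n, 0.01 * ifelse(cimp == "positive", 2, 1))
  cens <- runif(n, 0, 200)
  res <- cox_cimp(pmin(t, cens), as.integer(t <= cens), cimp)
  expect_lt(abs(res$log_hr - log(2)), 0.3)
  expect_lt(res$p_value, 1e-4)
  expect_true(res$ci[1] < res$hr & res$hr < res$ci[2])

  # adjusted model still reports the CIMP coefficient
  age <- rnorm(n, 60, 8)
  res_adj <- cox_cimp(pmin(t, cens), as.integer(t <= cens), cimp,
                      covariates = data.frame(age = age))
  expect_lt(abs(res_adj$log_hr - log(2)), 0.3)

  expect_error(cox_cimp(t, rep(1, n), rep("positive", n)), "both CIMP classes")
})

test_that("Cox confidence intervals cover a null hazard ratio at nominal rate", {
  set.seed(14)
  covered <- 0
  for (i in 1:30) {
    n <- 120
    cimp <- rep(c("negative", "positive"), each = n / 2)
    t <- rexp(n, 0.01)
    cens <- runif(n, 0, 250)
    r <- cox_cimp(pmin(t, cens), as.integer(t <= cens), cimp)
    if (r$ci[1] <= 1 && 1 <= r$ci[2]) covered <- covered + 1
  }
  expect_gte(covered, 25)  # ~95% nominal; 3 binomial SE leeway on 30 reps
})

test_that("clinical associations pick the right test per covariate type", {
  set.seed(15)
  n <- 400
  ids <- sprintf("S%03d", 1:n)
  labels <- rep(c("negative", "positive"), each = n / 2)
  call <- structure(list(tissue = "t", sample_ids = ids,
                         label = setNames(factor(labels, c("negative", "positive")), ids),
                         k = 2L), class = "cimp_call")
  # planted: age shift of 8 years; MSI strongly associated; ER null
  msi <- ifelse(labels == "positive",
                sample(c("MSI-H", "MSS"), n, TRUE, prob = c(0.55, 0.45)),
                sample(c("MSI-H", "MSS"), n, TRUE, prob = c(0.08, 0.92)))
  clin <- data.frame(sample_id = ids,
                     age = rnorm(n, 60, 10) + 8 * (labels == "positive"),
                     msi = msi,
                     er = sample(c("positive", "negative"), n, TRUE),
                     all_missing = NA_character_,
                     stringsAsFactors = FALSE)
  res <- clinical_associations(call, clin)
  expect_identical(res$test[res$covariate == "age"], "welch_t")
  expect_lt(res$p_value[res$covariate == "age"], 1e-3)
  expect_identical(res$test[res$covariate == "msi"], "chisq")
  expect_lt(res$p_value[res$covariate == "msi"], 1e-6)
  expect_gt(res$p_value[res$covariate == "er"], 0.01)
  expect_match(res$note[res$covariate == "all_missing"], "entirely missing")

  # chi-squared arithmetic on a fixed 2x2 table: (50,10 / 10,50)
  ids2 <- sprintf("T%03d", 1:120)
  lab2 <- rep(c("negative", "positive"), each = 60)
  call2 <- structure(list(tissue = "t", sample_ids = ids2,
                          label = setNames(factor(lab2, c("negative", "positive")), ids2),
                          k = 2L), class = "cimp_call")
  clin2 <- data.frame(sample_id = ids2,
                      status = rep(c("A", "B", "A", "B"), c(50, 10, 10, 50)))
  res2 <- clinical_associations(call2, clin2)
  expect_lt(res2$p_value[res2$covariate == "status"], 1e-10)
})

test_that("age associations are calibrated under the null", {
  set.seed(16)
  pvals <- vapply(1:40, function(i) {
    n <- 80
    ids <- sprintf("S%03d", 1:n)
    labels <- sample(rep(c("negative", "positive"), each = n / 2))
    call <- structure(list(tissue = "t", sample_ids = ids,
                           label = setNames(factor(labels, c("negative", "positive")), ids),
                           k = 2L), class = "cimp_call")
    clin <- data.frame(sample_id = ids, age = rnorm(n, 60, 10))
    clinical_associations(call, clin)$p_value[1]
  }, numeric(1))
  expect_lte(mean(pvals < 0.05), 0.125)  # 40 reps: <= 5 rejections
  expect_gt(mean(pvals), 0.3)            # roughly uniform p-values
})
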