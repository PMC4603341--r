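test_that("majority_baseline reproduces known cohort imbalances", {
  expect_equal(round(majority_baseline(rep(c("n", "p"), c(27, 16))), 3), 0.628)
  expect_equal(round(majority_baseline(rep(c("p", "n"), c(178, 131))), 3), 0.576)
  expect_equal(majority_baseline(rep(0:1, 10)), 0.5)
  expect_error(majority_baseline(integer(0)), "non-empty")
})

test_that("prepare_features log-transforms and standardizes per tissue, dropping constants", {
  set.seed(2)
  mk_expr <- function(n) {
    e <- matrix(rexp(6 * n, rate = 0.1), 6, n,
                dimnames = list(paste0("G", 1:6), sprintf("s%02d", 1:n)))
    e["G6", ] <- 3            # constant gene: must be dropped
    e["G5", 1] <- 0           # zero RPKM allowed
    e
  }
  mk_call <- function(ids, labels) {
    structure(list(tissue = "t", sample_ids = ids,
                   label = setNames(factor(labels, c("negative", "positive")), ids),
                   k = 2L), class = "cimp_call")
  }
  ids <- sprintf("s%02d", 1:20)
  expr <- list(t1 = mk_expr(20), t2 = mk_expr(20))
  calls <- list(t1 = mk_call(ids, rep(c("negative", "positive"), 10)),
                t2 = mk_call(ids, rep(c("positive", "negative"), 10)))
  task <- prepare_features(expr, calls)
  expect_false("G6" %in% task$gene_ids)
  expect_equal(nrow(task$x), 40L)
  for (t in levels(task$tissue)) {
    xt <- task$x[task$tissue == t, , drop = FALSE]
    expect_lt(max(abs(colMeans(xt))), 1e-10)
    expect_lt(max(abs(apply(xt, 2, var) - 1)), 1e-10)
  }
  # a tissue with a single class is excluded with a warning
  calls_bad <- calls
  calls_bad$t2 <- mk_call(ids, rep("negative", 20))
  expect_warning(task2 <- prepare_features(expr, calls_bad), "excluded")
  expect_equal(nlevels(droplevels(task2$tissue)), 1L)
})

test_that("lasso solver: lambda_max zeroes everything and the objective is optimal-side", {
  task <- planted_task(seed = 3)
  big <- fit_lasso_logistic(task, lambda = 10)
  expect_length(big$selected_genes, 0L)
  pred <- predict(big, task$x)
  expect_equal(mean(pred == task$y), majority_baseline(task$y))

  fit <- fit_lasso_logistic(task, lambda = 0.02)
  # optimality: penalized objective no worse than the intercept-only model's loss
  zero_obj <- mean(.softplus(-(2 * task$y - 1) * qlogis(mean(task$y))))
  expect_lte(fit$objective, zero_obj + 1e-10)
  expect_gt(length(fit$selected_genes), 0L)
})

test_that("at lambda = 0 a separating gene drives training accuracy to 1", {
  task <- separable_task(n = 40)
  fit <- suppressWarnings(fit_lasso_logistic(task, lambda = 0, max_iter = 300))
  expect_equal(mean(predict(fit, task$x) == task$y), 1)
})

test_that("lasso solution matches glmnet on the shared objective scale", {
  task <- planted_task(seed = 5)
  for (lam in c(0.08, 0.03, 0.01)) {
    fit <- fit_lasso_logistic(task, lam, tol = 1e-9)
    ref <- glmnet::glmnet(task$x, task$y, family = "binomial", lambda = lam,
                          standardize = FALSE, thresh = 1e-13)
    expect_lt(max(abs(fit$coefficients[, 1] - as.numeric(ref$beta))), 5e-4)
  }
})

test_that("group lasso at T = 1 reduces to the lasso", {
  task <- planted_task(n_tissues = 1, seed = 7)
  for (lam in c(0.05, 0.01)) {
    la <- fit_lasso_logistic(task, lam, tol = 1e-9)
    gr <- fit_group_lasso_logistic(task, lam, tol = 1e-9)
    expect_lt(abs(la$objective - gr$objective) / max(1e-12, abs(la$objective)),
              1e-4)
    expect_setequal(la$selected_genes, gr$selected_genes)
  }
})

test_that("group lasso zeroes all groups above its lambda_max and selects planted genes below", {
  task <- planted_task(seed = 11)
  big <- fit_group_lasso_logistic(task, lambda = 10)
  expect_length(big$selected_genes, 0L)

  fit <- fit_group_lasso_logistic(task, lambda = 0.03)
  planted <- sprintf("G%03d", 1:6)
  expect_gte(sum(planted %in% fit$selected_genes), 5L)
  expect_equal(dim(fit$coefficients), c(60L, 3L))
  # selection consistent with group norms at tolerance
  norms <- sqrt(rowSums(fit$coefficients^2))
  expect_setequal(fit$selected_genes, names(norms)[norms > 1e-8])
})

test_that("combined lasso respects duplication symmetry and per-tissue intercepts", {
  task1 <- planted_task(n_tissues = 1, seed = 13)
  dup <- prediction_task(rbind(task1$x, task1$x), c(task1$y, task1$y),
                         rep(c("a", "b"), each = nrow(task1$x)))
  lam <- 0.03
  single <- suppressWarnings(fit_lasso_logistic(task1, lam, tol = 1e-9))
  both <- suppressWarnings(fit_combined_lasso(dup, lam, tol = 1e-9))
  expect_lt(max(abs(single$coefficients[, 1] - both$coefficients[, 1])), 1e-4)
  expect_length(both$intercepts, 2L)
})

test_that("solutions are invariant to gene-column permutation", {
  task <- planted_task(seed = 17)
  fit <- fit_group_lasso_logistic(task, 0.04, tol = 1e-9)
  perm <- sample(ncol(task$x))
  task_p <- prediction_task(task$x[, perm], task$y, task$tissue)
  fit_p <- fit_group_lasso_logistic(task_p, 0.04, tol = 1e-9)
  expect_lt(max(abs(fit_p$coefficients[task$gene_ids, ] - fit$coefficients)),
            1e-5)
})

test_that("cross-validated accuracy is high for a separable gene and seed-reproducible", {
  task <- separable_task(n = 60, seed = 19)
  rep1 <- evaluate_cv(task, "lasso", n_repeats = 3, n_lambda = 15, seed = 4)
  expect_gte(rep1$mean_accuracy, 0.95)
  expect_lt(rep1$p_value, 0.01)
  rep2 <- evaluate_cv(task, "lasso", n_repeats = 3, n_lambda = 15, seed = 4)
  expect_identical(rep1$accuracies, rep2$accuracies)

  tiny <- prediction_task(task$x[1:5, ], c(0, 0, 0, 0, 1))
  expect_error(suppressWarnings(evaluate_cv(tiny, "lasso", n_repeats = 2)),
               "fewer members")
})

test_that("null features do not beat the majority baseline in CV", {
  res <- t(vapply(1:30, function(s) {
    set.seed(s)
    y <- rep(0:1, c(24, 16))
    x <- matrix(rnorm(40 * 10), 40, 10,
                dimnames = list(NULL, sprintf("G%02d", 1:10)))
    task <- prediction_task(scale(x), y)
    r <- evaluate_cv(task, "lasso", n_repeats = 3, n_folds = 4, n_lambda = 10,
                     seed = s)
    c(acc = r$mean_accuracy, p = r$p_value, base = r$baseline)
  }, numeric(3)))
  # mean accuracy hugs the baseline and the t test rarely rejects
  expect_lt(mean(res[, "acc"]) - mean(res[, "base"]),
            2 * sd(res[, "acc"]) / sqrt(nrow(res)) + 0.02)
  expect_lte(mean(res[, "p"] < 0.05), 0.07)
})

test_that("bootstrap frequencies separate planted from background genes", {
  task <- planted_task(n_per_tissue = 60, seed = 23, effect = 1.5)
  boot <- bootstrap_signature(task, "group_lasso", n_boot = 20, n_lambda = 15,
                              seed = 6)
  planted <- sprintf("G%03d", 1:6)
  expect_gt(median(boot$frequencies[planted]),
            median(boot$frequencies[setdiff(names(boot$frequencies), planted)]))
  # a gene selected in every refit has frequency 1 and enters the signature
  expect_true(any(boot$frequencies == 1))
  expect_true(all(names(boot$frequencies)[boot$frequencies == 1] %in% boot$signature))
  # strictly-below-threshold genes are excluded ("at least 50%")
  expect_true(all(boot$frequencies[boot$signature] >= 0.5))
  expect_false(any(boot$frequencies[setdiff(names(boot$frequencies),
                                            boot$signature)] >= 0.5))
})

test_that("method signatures compare by intersection with frequency ranking", {
  r1 <- structure(list(method = "combined_lasso",
                       frequencies = c(A = 1, B = 0.8, C = 0.6, D = 0.2),
                       signature = c("A", "B", "C")), class = "bootstrap_signature")
  r2 <- structure(list(method = "group_lasso",
                       frequencies = c(A = 0.9, B = 0.4, C = 0.7, E = 0.55),
                       signature = c("A", "C", "E")), class = "bootstrap_signature")
  cmp <- compare_method_signatures(list(r1, r2))
  expect_identical(cmp$common, c("A", "C"))  # ranked by min frequency
  expect_equal(cmp$frequency["E", "combined_lasso"], 0)

  cmp_same <- compare_method_signatures(list(r1, r1))
  expect_setequal(cmp_same$common, r1$signature)
  r3 <- structure(list(method = "lasso", frequencies = c(Z = 0.9),
                       signature = "Z"), class = "bootstrap_signature")
  expect_length(compare_method_signatures(list(r1, r3))$common, 0L)
})
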