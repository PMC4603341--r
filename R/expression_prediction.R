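#' Construct a CIMP prediction task
#'
#' Low-level constructor pairing a standardized expression feature matrix
#' with binary CIMP labels and tissue membership. Most users should build
#' tasks with [prepare_features()].
#'
#' @param x Numeric matrix, samples x genes (rownames = sample ids,
#'   colnames = gene ids).
#' @param y Binary labels (0 = CIMP-negative, 1 = CIMP-positive), length
#'   `nrow(x)`.
#' @param tissue Factor/character of tissue membership per sample.
#' @return Object of class `prediction_task`.
#' @export
prediction_task <- function(x, y, tissue = rep("cohort", nrow(x))) {
  if (!is.matrix(x) || is.null(colnames(x)))
    .stopf("'x' must be a matrix with gene ids as colnames")
  y <- as.integer(y)
  if (length(y) != nrow(x) || !all(y %in% c(0L, 1L)))
    .stopf("'y' must be 0/1 and aligned with rows of 'x'")
  tissue <- factor(tissue)
  if (length(tissue) != nrow(x))
    .stopf("'tissue' must be aligned with rows of 'x'")
  both <- tapply(y, tissue, function(v) length(unique(v)) == 2L)
  if (!all(both))
    .warnf("tissue(s) with a single CIMP class: %s",
           paste(names(both)[!both], collapse = ", "))
  structure(list(x = x, y = y, tissue = tissue,
                 gene_ids = colnames(x),
                 sample_ids = rownames(x)),
            class = "prediction_task")
}

#' Build prediction tasks from expression matrices and CIMP calls
#'
#' Intersects expression and methylation sample ids per tissue, transforms
#' RPKM values by `log2(x + 1)` and standardizes every gene to zero mean /
#' unit variance *within tissue* (required for penalized fits and for
#' pooling cohorts with different expression scales). Genes constant in any
#' retained tissue are dropped so that all tissues share one gene universe.
#'
#' @param expression Named list (by tissue) of gene x sample RPKM matrices.
#' @param calls Named list (by tissue) of [`cimp_call`][call_cimp] objects.
#' @return A [prediction_task()] over the pooled samples. Tissues with
#'   fewer than 2 samples in either CIMP class are excluded with a warning.
#' @export
prepare_features <- function(expression, calls) {
  tissues <- names(expression)
  if (is.null(tissues) || !all(tissues %in% names(calls)))
    .stopf("'expression' and 'calls' must be named lists over the same tissues")
  pieces <- list()
  for (t in tissues) {
    expr <- expression[[t]]
    call <- calls[[t]]
    if (call$k != 2L) .stopf("tissue '%s': prediction requires a binary CIMP call", t)
    common <- intersect(colnames(expr), call$sample_ids)
    if (!length(common))
      .stopf("tissue '%s': no samples shared between expression and CIMP call", t)
    y <- as.integer(call$label[common] == "positive")
    if (min(table(factor(y, levels = 0:1))) < 2L) {
      .warnf("tissue '%s' excluded: fewer than 2 samples in one CIMP class", t)
      next
    }
    x <- t(log2(expr[, common, drop = FALSE] + 1))
    pieces[[t]] <- list(x = x, y = y)
  }
  if (!length(pieces)) .stopf("no tissue with both CIMP classes")
  genes <- Reduce(intersect, lapply(pieces, function(p) colnames(p$x)))
  keep <- genes
  for (t in names(pieces)) {
    sds <- apply(pieces[[t]]$x[, genes, drop = FALSE], 2, sd)
    keep <- intersect(keep, genes[sds > 0])
  }
  if (!length(keep)) .stopf("all genes are constant after preprocessing")
  xs <- lapply(names(pieces), function(t) {
    scale(pieces[[t]]$x[, keep, drop = FALSE])
  })
  x <- do.call(rbind, xs)
  y <- unlist(lapply(pieces, `[[`, "y"), use.names = FALSE)
  tissue <- rep(names(pieces), vapply(pieces, function(p) length(p$y), integer(1)))
  rownames(x) <- paste(tissue, unlist(lapply(pieces, function(p) rownames(p$x))),
                       sep = ":")
  prediction_task(x, y, tissue)
}

#' Majority-class baseline accuracy
#'
#' The accuracy of the trivial classifier that always predicts the most
#' frequent class; the reference ("random") predictor for imbalanced CIMP
#' cohorts.
#'
#' @param labels Vector of class labels (any type).
#' @return Fraction in `[0, 1]`.
#' @examples
#' majority_baseline(rep(c("neg", "pos"), c(27, 16)))  # 0.628
#' @export
majority_baseline <- function(labels) {
  if (!length(labels)) .stopf("'labels' must be non-empty")
  max(table(labels)) / length(labels)
}

.selection_tol <- 1e-8

.as_sparse_model <- function(fit, method, gene_ids, tissues) {
  B <- fit$beta
  rownames(B) <- gene_ids
  colnames(B) <- if (ncol(B) == length(tissues)) tissues else "shared"
  norms <- sqrt(rowSums(B * B))
  structure(list(
    method = method,
    coefficients = B,
    intercepts = setNames(fit$intercept, tissues),
    lambda = fit$lambda,
    selected_genes = gene_ids[norms > .selection_tol],
    objective = fit$objective,
    converged = fit$converged,
    n_iter = fit$n_iter
  ), class = "cimp_sparse_model")
}

#' @export
print.cimp_sparse_model <- function(x, ...) {
  cat(sprintf("%s logistic model: %d/%d genes selected at lambda = %.4g (objective %.5g)\n",
              x$method, length(x$selected_genes), nrow(x$coefficients),
              x$lambda, x$objective))
  invisible(x)
}

.task_weights <- function(task, mode) {
  if (mode == "per_tissue") {
    nt <- table(task$tissue)
    1 / as.numeric(nt[task$tissue])
  } else rep(1 / length(task$y), length(task$y))
}

#' Lasso-penalized logistic regression
#'
#' Minimizes the mean logistic loss plus `lambda * sum(|beta|)` with an
#' unpenalized intercept, by monotone accelerated proximal gradient
#' (FISTA). The task is treated as a single cohort (one intercept); use
#' [fit_combined_lasso()] for pooled multi-tissue fits.
#'
#' @param task A [prediction_task()].
#' @param lambda Non-negative penalty weight.
#' @param max_iter,tol Solver controls (default 5000 iterations, 1e-7
#'   relative objective tolerance).
#' @param on_nonconvergence `"warn"` (default), `"error"` or `"silent"`.
#' @return Object of class `cimp_sparse_model`.
#' @export
fit_lasso_logistic <- function(task, lambda, max_iter = 5000L, tol = 1e-7,
                               on_nonconvergence = "warn") {
  n <- length(task$y)
  fit <- .fista_logistic(task$x, task$y, rep(1L, n), 1L, grouped = FALSE,
                         lambda = lambda, w = rep(1 / n, n),
                         max_iter = max_iter, tol = tol,
                         on_nonconvergence = on_nonconvergence)
  .as_sparse_model(fit, "lasso", task$gene_ids, "cohort")
}

#' Combined-lasso logistic regression across tissues
#'
#' A single lasso logistic model on the pooled samples: one shared
#' coefficient vector, but an unpenalized intercept *per tissue* to absorb
#' the different CIMP prevalences. Assumes tissues share both the gene
#' signature and its coefficients.
#'
#' @inheritParams fit_lasso_logistic
#' @return Object of class `cimp_sparse_model`.
#' @export
fit_combined_lasso <- function(task, lambda, max_iter = 5000L, tol = 1e-7,
                               on_nonconvergence = "warn") {
  tidx <- as.integer(task$tissue)
  fit <- .fista_logistic(task$x, task$y, tidx, nlevels(task$tissue),
                         grouped = FALSE, lambda = lambda,
                         w = .task_weights(task, "pooled"),
                         max_iter = max_iter, tol = tol,
                         on_nonconvergence = on_nonconvergence)
  .as_sparse_model(fit, "combined_lasso", task$gene_ids, levels(task$tissue))
}

#' Multi-task group-lasso logistic regression
#'
#' Jointly fits one logistic model per tissue under the constraint that the
#' *selected* genes coincide across tissues while their coefficients may
#' differ: the penalty `lambda * sqrt(T) * sum_g ||beta_g.||_2` acts on each
#' gene's coefficient vector across the `T` tissues, zeroing whole genes at
#' once. Each tissue's logistic loss is weighted by `1 / n_t` so large
#' cohorts do not dominate, and intercepts are per tissue and unpenalized.
#' With a single tissue the objective reduces exactly to the lasso.
#'
#' @inheritParams fit_lasso_logistic
#' @return Object of class `cimp_sparse_model` with a gene x tissue
#'   coefficient matrix; a gene is selected iff its group norm exceeds 1e-8.
#' @export
fit_group_lasso_logistic <- function(task, lambda, max_iter = 5000L, tol = 1e-7,
                                     on_nonconvergence = "warn") {
  tidx <- as.integer(task$tissue)
  fit <- .fista_logistic(task$x, task$y, tidx, nlevels(task$tissue),
                         grouped = TRUE, lambda = lambda,
                         w = .task_weights(task, "per_tissue"),
                         max_iter = max_iter, tol = tol,
                         on_nonconvergence = on_nonconvergence)
  .as_sparse_model(fit, "group_lasso", task$gene_ids, levels(task$tissue))
}

#' Predict CIMP status from a fitted sparse model
#'
#' @param object A `cimp_sparse_model`.
#' @param x Standardized feature matrix (samples x genes, same gene order
#'   as at fit time).
#' @param tissue Tissue of each sample (matched to the model's intercepts;
#'   ignored for single-cohort models).
#' @param type `"class"` (0/1), `"link"` or `"prob"`.
#' @param ... Unused.
#' @export
predict.cimp_sparse_model <- function(object, x, tissue = NULL,
                                      type = c("class", "link", "prob"), ...) {
  type <- match.arg(type)
  B <- object$coefficients
  tissues <- names(object$intercepts)
  if (is.null(tissue)) {
    if (length(tissues) > 1L) .stopf("'tissue' required for multi-tissue models")
    tissue <- rep(tissues, nrow(x))
  }
  tissue <- as.character(tissue)
  unknown <- setdiff(unique(tissue), tissues)
  if (length(unknown))
    .stopf("unknown tissue(s): %s", paste(unknown, collapse = ", "))
  eta <- object$intercepts[tissue]
  if (ncol(B) == 1L) {
    eta <- eta + drop(x %*% B[, 1L])
  } else {
    for (t in tissues) {
      rows <- which(tissue == t)
      if (length(rows)) eta[rows] <- eta[rows] + drop(x[rows, , drop = FALSE] %*% B[, t])
    }
  }
  switch(type,
         link = unname(eta),
         prob = unname(plogis(eta)),
         class = unname(as.integer(eta > 0)))
}

.fit_by_method <- function(task, method, lambda, ...) {
  switch(method,
         lasso = fit_lasso_logistic(task, lambda, ...),
         combined_lasso = fit_combined_lasso(task, lambda, ...),
         group_lasso = fit_group_lasso_logistic(task, lambda, ...),
         .stopf("unknown method '%s'", method))
}

.method_solver_args <- function(task, method) {
  tidx <- as.integer(task$tissue)
  switch(method,
         lasso = list(tidx = rep(1L, length(task$y)), n_tissues = 1L,
                      grouped = FALSE, wmode = "pooled"),
         combined_lasso = list(tidx = tidx, n_tissues = nlevels(task$tissue),
                               grouped = FALSE, wmode = "pooled"),
         group_lasso = list(tidx = tidx, n_tissues = nlevels(task$tissue),
                            grouped = TRUE, wmode = "per_tissue"),
         .stopf("unknown method '%s'", method))
}

.subset_task <- function(task, idx) {
  structure(list(x = task$x[idx, , drop = FALSE],
                 y = task$y[idx],
                 tissue = factor(task$tissue[idx], levels = levels(task$tissue)),
                 gene_ids = task$gene_ids,
                 sample_ids = task$sample_ids[idx]),
            class = "prediction_task")
}

#' Repeated cross-validated accuracy of CIMP prediction
#'
#' Stratified k-fold cross-validation repeated `n_repeats` times. Within
#' each training split the penalty is chosen by an inner k-fold CV over a
#' log-spaced grid from `lambda_max` down to `0.01 * lambda_max`
#' (minimum held-out deviance, no one-standard-error rule); the model is
#' refitted at the chosen penalty and scored on the held-out fold. Folds
#' are stratified by CIMP class crossed with tissue. Significance against
#' the majority-class baseline is a one-sided one-sample Student t test of
#' the per-repeat mean accuracies.
#'
#' @param task A [prediction_task()].
#' @param method `"lasso"`, `"combined_lasso"` or `"group_lasso"`.
#' @param n_repeats Number of CV repeats. Default 100.
#' @param n_folds Outer folds. Default 3.
#' @param n_lambda Penalty grid size. Default 50.
#' @param inner_folds Folds of the inner lambda-selection CV. Default 3.
#' @param seed Optional integer seed (same seed, identical report).
#' @return Object of class `prediction_report`: per-repeat `accuracies`,
#'   `mean_accuracy`, `baseline`, `p_value`, and the settings used.
#' @export
evaluate_cv <- function(task, method = c("lasso", "combined_lasso", "group_lasso"),
                        n_repeats = 100L, n_folds = 3L, n_lambda = 50L,
                        inner_folds = 3L, seed = NULL) {
  method <- match.arg(method)
  n_repeats <- .check_count(n_repeats, "n_repeats")
  n_folds <- .check_count(n_folds, "n_folds", min = 2L)
  class_counts <- table(factor(task$y, levels = 0:1))
  if (min(class_counts) < n_folds)
    .stopf("a CIMP class has fewer members (%d) than folds (%d)",
           min(class_counts), n_folds)
  .with_seed(seed, NULL)
  args <- .method_solver_args(task, method)
  strata <- interaction(task$y, task$tissue, drop = TRUE)
  baseline <- majority_baseline(task$y)
  n <- length(task$y)
  accuracies <- numeric(n_repeats)
  for (rep_i in seq_len(n_repeats)) {
    fold <- .stratified_folds(strata, n_folds)
    correct <- 0L
    for (f in seq_len(n_folds)) {
      tr <- which(fold != f); te <- which(fold == f)
      tr_task <- .subset_task(task, tr)
      sel <- .choose_lambda(tr_task$x, tr_task$y, args$tidx[tr], args$n_tissues,
                            args$grouped, args$wmode,
                            n_lambda = n_lambda, inner_folds = inner_folds)
      model <- .fit_by_method(tr_task, method, sel$lambda,
                              on_nonconvergence = "silent")
      pred <- predict(model, task$x[te, , drop = FALSE],
                      tissue = if (method == "lasso") NULL else as.character(task$tissue[te]))
      correct <- correct + sum(pred == task$y[te])
    }
    accuracies[rep_i] <- correct / n
  }
  p_value <- if (sd(accuracies) < .Machine$double.eps^0.5) {
    if (mean(accuracies) > baseline) 0 else 1
  } else {
    t.test(accuracies, mu = baseline, alternative = "greater")$p.value
  }
  structure(list(method = method,
                 accuracies = accuracies,
                 mean_accuracy = mean(accuracies),
                 baseline = baseline,
                 p_value = p_value,
                 n_repeats = n_repeats, n_folds = n_folds,
                 n_lambda = n_lambda, inner_folds = inner_folds),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("%s: mean CV accuracy %.3f (baseline %.3f, p = %.3g, %d repeats x %d folds)\n",
              x$method, x$mean_accuracy, x$baseline, x$p_value,
              x$n_repeats, x$n_folds))
  invisible(x)
}

#' Bootstrap stability of the predictive gene signature
#'
#' Fixes the penalty by an inner CV on the full data, then refits the model
#' on `n_boot` bootstrap resamples (drawn with replacement within tissue)
#' and records how often each gene is selected. The signature is the set of
#' genes selected in at least 50 % of the resamples, ranked by decreasing
#' frequency.
#'
#' @inheritParams evaluate_cv
#' @param n_boot Number of bootstrap resamples. Default 100.
#' @param frequency_threshold Minimum selection frequency for signature
#'   membership. Default 0.5.
#' @param lambda_policy `"1se"` (default) fixes the penalty at the largest
#'   value within one standard error of the CV-minimum deviance — the
#'   sparser choice customary for stability selection; `"min"` uses the
#'   CV-minimum itself (the policy [evaluate_cv()] uses for accuracy).
#' @param inner_folds Folds of the lambda-selection CV. Default 5 here
#'   (the standard-error estimate needs more folds than accuracy CV).
#' @return Object of class `bootstrap_signature`: per-gene `frequencies`
#'   (sorted decreasing), `signature`, the fixed `lambda` and settings.
#' @export
bootstrap_signature <- function(task, method = c("lasso", "combined_lasso", "group_lasso"),
                                n_boot = 100L, frequency_threshold = 0.5,
                                lambda_policy = c("1se", "min"),
                                n_lambda = 50L, inner_folds = 5L, seed = NULL) {
  lambda_policy <- match.arg(lambda_policy)
  method <- match.arg(method)
  n_boot <- .check_count(n_boot, "n_boot", min = 2L)
  .check_fraction(frequency_threshold, "frequency_threshold")
  .with_seed(seed, NULL)
  args <- .method_solver_args(task, method)
  sel <- .choose_lambda(task$x, task$y, args$tidx, args$n_tissues,
                        args$grouped, args$wmode,
                        n_lambda = n_lambda, inner_folds = inner_folds,
                        lambda_policy = lambda_policy)
  by_tissue <- split(seq_along(task$y), task$tissue)
  counts <- setNames(numeric(length(task$gene_ids)), task$gene_ids)
  for (b in seq_len(n_boot)) {
    idx <- NULL
    for (attempt in seq_len(10L)) {
      idx <- unlist(lapply(by_tissue, function(s) sample(s, length(s), replace = TRUE)),
                    use.names = FALSE)
      ok <- all(tapply(task$y[idx], task$tissue[idx],
                       function(v) length(unique(v)) == 2L), na.rm = TRUE)
      if (ok) break
      idx <- NULL
    }
    if (is.null(idx))
      .stopf("could not draw a bootstrap sample with both classes in every tissue (10 attempts)")
    model <- .fit_by_method(.subset_task(task, idx), method, sel$lambda,
                            on_nonconvergence = "silent")
    counts[model$selected_genes] <- counts[model$selected_genes] + 1
  }
  freq <- counts / n_boot
  ord <- order(-freq, names(freq))
  freq <- freq[ord]
  structure(list(method = method,
                 frequencies = freq,
                 signature = names(freq)[freq >= frequency_threshold],
                 frequency_threshold = frequency_threshold,
                 lambda = sel$lambda,
                 n_boot = n_boot),
            class = "bootstrap_signature")
}

#' @export
print.bootstrap_signature <- function(x, ...) {
  cat(sprintf("%s bootstrap signature: %d genes with frequency >= %.0f%% over %d resamples\n",
              x$method, length(x$signature), 100 * x$frequency_threshold, x$n_boot))
  invisible(x)
}

#' Compare predictive gene signatures across methods
#'
#' Intersections and differences of bootstrap signatures from several
#' methods, with genes ranked by their minimum selection frequency across
#' the compared methods.
#'
#' @param reports Named list (>= 2) of [`bootstrap_signature`]
#'   [bootstrap_signature] objects.
#' @return List with `common` (genes in every signature, ranked by
#'   decreasing minimum frequency), `per_method` signatures, and a gene x
#'   method `frequency` matrix for the union of signatures.
#' @export
compare_method_signatures <- function(reports) {
  if (!is.list(reports) || length(reports) < 2L)
    .stopf("need at least 2 signature reports")
  if (is.null(names(reports)))
    names(reports) <- vapply(reports, `[[`, character(1), "method")
  sigs <- lapply(reports, `[[`, "signature")
  union_genes <- sort(unique(unlist(sigs)))
  freq <- vapply(reports, function(r) {
    f <- unname(r$frequencies[union_genes])
    f[is.na(f)] <- 0
    f
  }, numeric(length(union_genes)))
  freq <- matrix(freq, nrow = length(union_genes),
                 dimnames = list(union_genes, names(reports)))
  common <- Reduce(intersect, sigs)
  if (length(common)) {
    minf <- apply(freq[common, , drop = FALSE], 1, min)
    common <- common[order(-minf, common)]
  }
  list(common = common, per_method = sigs, frequency = freq)
}
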