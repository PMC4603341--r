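.default_config <- function() {
  list(
    data_dir = ".",
    tissues = NULL,                     # inferred from probes_<tissue>.tsv
    signature_fraction = 0.05,
    k_range = c(2L, 5L),
    consensus = list(n_resamples = 100L, subsample_fraction = 0.8),
    cv = list(n_repeats = 100L, n_folds = 3L, n_lambda = 50L, inner_folds = 3L),
    bootstrap = list(n_boot = 100L),
    thresholds = list(signature_frequency = 0.5, bh_alpha = 0.05,
                      cgi_missing_fraction = 0.3),
    min_mutated = 3L,
    mc_overlap_reps = 2000L,
    stability_fractions = seq(0.01, 0.10, by = 0.01),
    seed = 1L
  )
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a YAML file path or a list, fills in the documented defaults
#' (signature fraction 0.05, K range 2--5, 100 consensus resamples at 80 %
#' subsampling, 3-fold CV repeated 100 times, 100 bootstraps, 50 %
#' signature-frequency threshold, BH alpha 0.05, CGI missingness 0.3),
#' checks ranges and rejects unknown keys, and resolves `data_dir` to an
#' absolute path.
#'
#' @param config Path to a YAML file, or a named list of overrides (may be
#'   empty).
#' @return Normalized configuration list of class `pipeline_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) .stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (!is.list(config)) .stopf("'config' must be a list or a YAML file path")
  defaults <- .default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    .stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  merged <- defaults
  for (k in names(config)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      sub_unknown <- setdiff(names(config[[k]]), names(defaults[[k]]))
      if (length(sub_unknown))
        .stopf("unknown config key(s): %s",
               paste(paste(k, sub_unknown, sep = "."), collapse = ", "))
      merged[[k]][names(config[[k]])] <- config[[k]]
    } else {
      merged[[k]] <- config[[k]]
    }
  }
  .check_fraction(merged$signature_fraction, "signature_fraction", lo_open = TRUE)
  kr <- merged$k_range
  if (length(kr) != 2L || any(kr < 2L) || kr[1L] > kr[2L])
    .stopf("empty K range: k_range must be (lo, hi) with 2 <= lo <= hi")
  merged$k_range <- as.integer(kr)
  .check_count(merged$consensus$n_resamples, "consensus.n_resamples", min = 2L)
  .check_fraction(merged$consensus$subsample_fraction,
                  "consensus.subsample_fraction", lo_open = TRUE)
  .check_count(merged$cv$n_repeats, "cv.n_repeats")
  .check_count(merged$cv$n_folds, "cv.n_folds", min = 2L)
  .check_count(merged$cv$n_lambda, "cv.n_lambda", min = 2L)
  .check_count(merged$cv$inner_folds, "cv.inner_folds", min = 2L)
  .check_count(merged$bootstrap$n_boot, "bootstrap.n_boot", min = 2L)
  .check_fraction(merged$thresholds$signature_frequency,
                  "thresholds.signature_frequency")
  .check_fraction(merged$thresholds$bh_alpha, "thresholds.bh_alpha", lo_open = TRUE)
  .check_fraction(merged$thresholds$cgi_missing_fraction,
                  "thresholds.cgi_missing_fraction")
  .check_count(merged$min_mutated, "min_mutated")
  .check_count(merged$mc_overlap_reps, "mc_overlap_reps", min = 100L)
  .check_fraction(merged$stability_fractions, "stability_fractions", lo_open = TRUE)
  .check_count(merged$seed, "seed", min = 0L)
  merged$data_dir <- normalizePath(merged$data_dir, mustWork = FALSE)
  structure(merged, class = c("pipeline_config", "list"))
}

.pipeline_log <- function(verbose, stage, fmt, ...) {
  if (verbose)
    message(sprintf("[%s] [%s] %s", format(Sys.time(), "%H:%M:%S"),
                    stage, sprintf(fmt, ...)))
}

#' Run the CIMP analysis pipeline end to end
#'
#' Executes, per tissue and then jointly: probe-to-CGI aggregation, CIMP
#' signature selection and calling, consensus clustering with Delta(K),
#' signature-size stability, cross-cancer signature intersection (with
#' analytic and Monte-Carlo random-overlap nulls) and pan-cancer calling,
#' expression-based CIMP prediction (per-tissue lasso, combined lasso,
#' group lasso; repeated CV and bootstrap signatures), mutation
#' association, and survival/clinical association. Inputs are the files
#' produced by [write_dataset()] (or real data in the same formats) under
#' `config$data_dir`. All module outputs are written under `outdir`
#' together with `summary.json` and a `manifest.tsv` of output files and
#' their MD5 hashes; the same config and seed reproduce the outputs
#' byte for byte.
#'
#' @param config A [validate_config()] result, YAML path or override list.
#' @param outdir Output directory (created if needed).
#' @param verbose Log stage progress. Default `TRUE`.
#' @return The summary list, invisibly. On stage failure, the error names
#'   the failing stage and the manifest of completed stages is retained.
#' @export
run_pipeline <- function(config, outdir, verbose = TRUE) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  summary <- list(config = unclass(config))
  completed <- character()
  outputs <- character()
  manifest_path <- file.path(outdir, "manifest.tsv")
  finalize_manifest <- function() {
    if (length(outputs)) {
      md5 <- tools::md5sum(outputs)
      write.table(data.frame(file = basename(outputs), md5 = unname(md5)),
                  manifest_path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  run_stage <- function(name, fun) {
    .pipeline_log(verbose, name, "starting")
    res <- tryCatch(fun(), error = function(e) {
      finalize_manifest()
      writeLines(completed, file.path(outdir, "completed_stages.txt"))
      .stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
    completed <<- c(completed, name)
    .pipeline_log(verbose, name, "done")
    res
  }
  dd <- config$data_dir

  # ---- load + aggregate -------------------------------------------------
  env <- new.env(parent = emptyenv())
  run_stage("aggregate", function() {
    ann <- read_annotation(file.path(dd, "annotation.csv"))
    tissues <- config$tissues
    if (is.null(tissues)) {
      hits <- list.files(dd, pattern = "^probes_.*\\.tsv$")
      tissues <- sub("^probes_(.*)\\.tsv$", "\\1", hits)
    }
    if (!length(tissues)) stop("no probe matrices found in ", dd)
    cgi <- list()
    for (t in tissues) {
      pm <- read_probe_matrix(file.path(dd, sprintf("probes_%s.tsv", t)))
      cgi[[t]] <- filter_cgis(aggregate_by_cgi(pm, ann),
                              config$thresholds$cgi_missing_fraction)
    }
    env$annotation <- ann
    env$tissues <- tissues
    env$cgi <- cgi
    summary$aggregate <<- list(
      tissues = tissues,
      n_cgis = vapply(cgi, nrow, integer(1)),
      n_samples = vapply(cgi, ncol, integer(1)))
  })

  run_stage("cimp_calling", function() {
    env$signatures <- list(); env$calls <- list()
    blocks <- list()
    for (t in env$tissues) {
      sig <- select_signature(env$cgi[[t]], config$signature_fraction, tissue = t)
      call <- call_cimp(env$cgi[[t]], sig)
      env$signatures[[t]] <- sig
      env$calls[[t]] <- call
      write_cimp_calls(call, file.path(outdir, sprintf("cimp_calls_%s.tsv", t)))
      write_signature(sig, file.path(outdir, sprintf("signature_%s.tsv", t)),
                      annotation = env$annotation)
      outputs <<- c(outputs,
                    file.path(outdir, sprintf("cimp_calls_%s.tsv", t)),
                    file.path(outdir, sprintf("signature_%s.tsv", t)))
      tab <- table(call$label)
      blocks[[t]] <- list(n_signature_cgis = length(sig$cgi_ids),
                          n_negative = unname(tab["negative"]),
                          n_positive = unname(tab["positive"]),
                          positive_ratio = unname(tab["positive"]) / sum(tab))
    }
    summary$cimp_calling <<- blocks
  })

  run_stage("consensus", function() {
    blocks <- list()
    for (t in env$tissues) {
      prof <- consensus_cluster(env$cgi[[t]], env$signatures[[t]],
                                k_range = seq(config$k_range[1L], config$k_range[2L]),
                                n_resamples = config$consensus$n_resamples,
                                subsample_fraction = config$consensus$subsample_fraction)
      stab <- signature_stability(env$cgi[[t]],
                                  fractions = config$stability_fractions,
                                  reference_fraction = config$signature_fraction)
      blocks[[t]] <- list(areas = as.list(prof$areas),
                          delta = as.list(prof$delta),
                          suggested_k = prof$k_range[which.max(prof$delta)],
                          stability_min_ari = min(stab$ari))
    }
    summary$consensus <<- blocks
  })

  run_stage("cross_cancer", function() {
    if (length(env$tissues) >= 2L) {
      ov <- intersect_signatures(env$signatures)
      mc <- monte_carlo_overlap(ov$n_universe, config$signature_fraction,
                                length(env$tissues),
                                n_reps = config$mc_overlap_reps,
                                observed = length(ov$common_cgis))
      pan <- pan_cancer_call(env$cgi, ov$common_cgis,
                             per_tissue_calls = env$calls)
      agree <- mean(vapply(seq_along(pan$sample_ids), function(i) {
        t <- pan$tissue_of_sample[i]
        s <- sub("^[^:]*:", "", pan$sample_ids[i])
        as.character(env$calls[[t]]$label[s]) == as.character(pan$label[i])
      }, logical(1)))
      write_signature(ov$common_cgis,
                      file.path(outdir, "cross_cancer_signature.tsv"),
                      annotation = env$annotation)
      outputs <<- c(outputs, file.path(outdir, "cross_cancer_signature.tsv"))
      summary$cross_cancer <<- list(
        signature_sizes = as.list(ov$sizes),
        n_common = length(ov$common_cgis),
        expected_overlap = ov$expected_overlap,
        mc_mean = mc$mean, mc_se = mc$se, mc_p_exceed = mc$p_exceed,
        pan_cancer_agreement = agree)
      env$common <- ov$common_cgis
    } else {
      summary$cross_cancer <<- list(note = "single tissue: no intersection")
    }
  })

  run_stage("expression_prediction", function() {
    expr <- lapply(env$tissues, function(t)
      read_expression_matrix(file.path(dd, sprintf("expression_%s.tsv", t))))
    names(expr) <- env$tissues
    task <- prepare_features(expr, env$calls)
    methods <- if (nlevels(droplevels(task$tissue)) >= 2L)
      c("combined_lasso", "group_lasso") else "lasso"
    blocks <- list()
    sigs <- list()
    for (m in methods) {
      cv_report <- evaluate_cv(task, m,
                               n_repeats = config$cv$n_repeats,
                               n_folds = config$cv$n_folds,
                               n_lambda = config$cv$n_lambda,
                               inner_folds = config$cv$inner_folds)
      boot <- bootstrap_signature(task, m,
                                  n_boot = config$bootstrap$n_boot,
                                  frequency_threshold = config$thresholds$signature_frequency,
                                  n_lambda = config$cv$n_lambda,
                                  inner_folds = config$cv$inner_folds)
      sigs[[m]] <- boot
      sig_path <- file.path(outdir, sprintf("expression_signature_%s.tsv", m))
      write.table(data.frame(gene = names(boot$frequencies),
                             frequency = unname(boot$frequencies)),
                  sig_path, sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <<- c(outputs, sig_path)
      blocks[[m]] <- list(mean_accuracy = cv_report$mean_accuracy,
                          baseline = cv_report$baseline,
                          p_value = cv_report$p_value,
                          n_signature_genes = length(boot$signature))
    }
    if (length(sigs) >= 2L)
      blocks$signature_comparison <- list(
        n_common = length(compare_method_signatures(sigs)$common))
    summary$expression_prediction <<- blocks
  })

  run_stage("mutation_association", function() {
    muts <- lapply(env$tissues, function(t)
      read_mutation_matrix(file.path(dd, sprintf("mutations_%s.tsv", t))))
    names(muts) <- env$tissues
    blocks <- list()
    for (t in env$tissues) {
      scan <- genomewide_mutation_scan(muts[[t]], env$calls[[t]],
                                       min_mutated = config$min_mutated)
      scan_path <- file.path(outdir, sprintf("mutation_scan_%s.tsv", t))
      write.table(scan, scan_path, sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <<- c(outputs, scan_path)
      burden <- burden_comparison(muts[[t]], env$calls[[t]])
      blocks[[t]] <- list(
        n_tested = nrow(scan),
        n_significant = sum(scan$q < config$thresholds$bh_alpha),
        burden_p = burden$p_value,
        burden_median_positive = burden$median_positive,
        burden_median_negative = burden$median_negative)
    }
    summary$mutation_association <<- blocks
  })

  run_stage("survival_clinical", function() {
    blocks <- list()
    for (t in env$tissues) {
      clin <- read_clinical(file.path(dd, sprintf("clinical_%s.tsv", t)))
      common <- intersect(clin$sample_id, env$calls[[t]]$sample_ids)
      clin <- clin[match(common, clin$sample_id), , drop = FALSE]
      lab <- env$calls[[t]]$label[common]
      lr <- logrank_test(clin$time, clin$event, lab)
      cox <- tryCatch(
        cox_cimp(clin$time, clin$event, lab,
                 covariates = clin[, "age", drop = FALSE]),
        error = function(e) NULL)
      assoc <- clinical_associations(env$calls[[t]], clin)
      assoc_path <- file.path(outdir, sprintf("clinical_assoc_%s.tsv", t))
      write.table(assoc, assoc_path, sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <<- c(outputs, assoc_path)
      blocks[[t]] <- list(
        logrank_p = lr$p_value,
        cox_hr = if (is.null(cox)) NA else cox$hr,
        cox_p = if (is.null(cox)) NA else cox$p_value,
        n_covariates_tested = sum(!is.na(assoc$p_value)))
    }
    summary$survival_clinical <<- blocks
  })

  summary_path <- file.path(outdir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  outputs <- c(outputs, summary_path)
  finalize_manifest()
  outputs <- c(outputs, manifest_path)
  .pipeline_log(verbose, "pipeline", "complete: %d output files", length(outputs))
  invisible(summary)
}
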