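#' Configuration for the synthetic multi-tissue CIMP dataset
#'
#' Validates and assembles all generator parameters. Defaults describe a
#' three-tissue study of 200 tumors each in which 30 % of samples carry a
#' methylator phenotype: a planted set of CGIs is hypermethylated by 0.35
#' (beta scale) in CIMP-positive samples, a planted gene set separates the
#' classes in expression, a few genes are preferentially mutated in
#' CIMP-positive tumors, and right-censored survival can carry a CIMP
#' hazard ratio.
#'
#' @param n_tissues Number of tissue cohorts.
#' @param samples_per_tissue Samples per tissue (recycled to `n_tissues`).
#' @param cimp_prevalence Expected CIMP-positive fraction per tissue
#'   (recycled), in `[0, 1]`.
#' @param n_cgis Number of CpG islands on the simulated array.
#' @param n_probes_per_cgi Length-2 integer (min, max) probes per CGI.
#' @param signature_size Number of planted CIMP CGIs per tissue.
#' @param shared_signature_fraction Fraction of planted CGIs common to all
#'   tissues.
#' @param beta_background List with `hypo` and `hyper` beta-distribution
#'   shape pairs and `weight_hypo`, the mixing weight of the low mode.
#' @param cimp_shift Mean methylation increase (beta scale) of planted CGIs
#'   in CIMP-positive samples.
#' @param probe_noise_sd SD of probe-level noise around the CGI value.
#' @param open_sea_fraction Extra open-sea probes as a fraction of CGI
#'   probes.
#' @param n_genes,n_predictive_genes Expression universe and planted
#'   predictive gene count.
#' @param expression_effect Standardized mean expression difference of
#'   predictive genes between CIMP classes (log2 scale, per-gene sd 1).
#' @param mutation_rate_background Per-gene per-sample mutation probability.
#' @param n_assoc_mut_genes Genes whose mutation odds are inflated in
#'   CIMP-positive samples.
#' @param mutation_odds_ratio Odds ratio of that inflation.
#' @param survival_hr Hazard ratio CIMP-positive vs negative (exponential
#'   baseline, median 1500 days).
#' @param censoring_rate Target fraction of censored samples (uniform
#'   censoring).
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_tissues = 3L,
                              samples_per_tissue = 200L,
                              cimp_prevalence = 0.3,
                              n_cgis = 500L,
                              n_probes_per_cgi = c(3L, 8L),
                              signature_size = 50L,
                              shared_signature_fraction = 0.8,
                              beta_background = list(hypo = c(1.5, 10),
                                                     hyper = c(8, 2),
                                                     weight_hypo = 0.7),
                              cimp_shift = 0.35,
                              probe_noise_sd = 0.03,
                              open_sea_fraction = 0.05,
                              n_genes = 200L,
                              n_predictive_genes = 10L,
                              expression_effect = 1.0,
                              mutation_rate_background = 0.02,
                              n_assoc_mut_genes = 5L,
                              mutation_odds_ratio = 8,
                              survival_hr = 1.0,
                              censoring_rate = 0.3,
                              seed = 1L) {
  n_tissues <- .check_count(n_tissues, "n_tissues")
  samples_per_tissue <- rep_len(.check_count(samples_per_tissue,
                                             "samples_per_tissue", min = 2L),
                                n_tissues)
  cimp_prevalence <- rep_len(.check_fraction(cimp_prevalence, "cimp_prevalence"),
                             n_tissues)
  n_cgis <- .check_count(n_cgis, "n_cgis")
  n_probes_per_cgi <- .check_count(n_probes_per_cgi, "n_probes_per_cgi")
  if (length(n_probes_per_cgi) != 2L || n_probes_per_cgi[1L] > n_probes_per_cgi[2L])
    .stopf("'n_probes_per_cgi' must be (min, max) with min <= max")
  signature_size <- .check_count(signature_size, "signature_size")
  if (signature_size > n_cgis)
    .stopf("'signature_size' (%d) exceeds 'n_cgis' (%d)", signature_size, n_cgis)
  .check_fraction(shared_signature_fraction, "shared_signature_fraction")
  .check_fraction(cimp_shift, "cimp_shift")
  .check_fraction(open_sea_fraction, "open_sea_fraction")
  if (!is.list(beta_background) ||
      !all(c("hypo", "hyper", "weight_hypo") %in% names(beta_background)) ||
      any(beta_background$hypo <= 0) || any(beta_background$hyper <= 0))
    .stopf("'beta_background' must list positive shape pairs 'hypo', 'hyper' and 'weight_hypo'")
  .check_fraction(beta_background$weight_hypo, "beta_background$weight_hypo")
  if (probe_noise_sd < 0) .stopf("'probe_noise_sd' must be non-negative")
  n_genes <- .check_count(n_genes, "n_genes")
  n_predictive_genes <- .check_count(n_predictive_genes, "n_predictive_genes", min = 0L)
  if (n_predictive_genes > n_genes)
    .stopf("'n_predictive_genes' (%d) exceeds 'n_genes' (%d)",
           n_predictive_genes, n_genes)
  if (expression_effect < 0) .stopf("'expression_effect' must be non-negative")
  .check_fraction(mutation_rate_background, "mutation_rate_background")
  n_assoc_mut_genes <- .check_count(n_assoc_mut_genes, "n_assoc_mut_genes", min = 0L)
  if (n_assoc_mut_genes > n_genes)
    .stopf("'n_assoc_mut_genes' exceeds 'n_genes'")
  if (mutation_odds_ratio <= 0) .stopf("'mutation_odds_ratio' must be positive")
  if (survival_hr <= 0) .stopf("'survival_hr' must be positive")
  .check_fraction(censoring_rate, "censoring_rate", hi = 0.95)
  seed <- .check_count(seed, "seed", min = 0L)
  structure(list(n_tissues = n_tissues,
                 samples_per_tissue = samples_per_tissue,
                 cimp_prevalence = cimp_prevalence,
                 n_cgis = n_cgis,
                 n_probes_per_cgi = n_probes_per_cgi,
                 signature_size = signature_size,
                 shared_signature_fraction = shared_signature_fraction,
                 beta_background = beta_background,
                 cimp_shift = cimp_shift,
                 probe_noise_sd = probe_noise_sd,
                 open_sea_fraction = open_sea_fraction,
                 n_genes = n_genes,
                 n_predictive_genes = n_predictive_genes,
                 expression_effect = expression_effect,
                 mutation_rate_background = mutation_rate_background,
                 n_assoc_mut_genes = n_assoc_mut_genes,
                 mutation_odds_ratio = mutation_odds_ratio,
                 survival_hr = survival_hr,
                 censoring_rate = censoring_rate,
                 seed = seed),
            class = "simulation_config")
}

# logit offset d such that E[plogis(qlogis(V) + d)] = target for
# V ~ Beta(a, b), computed on a quantile grid; exact in expectation so the
# realized CIMP+ / CIMP- mean difference matches cimp_shift
.logit_shift_for <- function(shape, shift, n_grid = 2000L) {
  if (shift <= 0) return(0)
  m0 <- shape[1L] / (shape[1L] + shape[2L])
  target <- min(m0 + shift, 0.995)
  v <- qbeta((seq_len(n_grid) - 0.5) / n_grid, shape[1L], shape[2L])
  v <- .clip01(v, 1e-6)
  f <- function(d) mean(plogis(qlogis(v) + d)) - target
  uniroot(f, c(0, 30), tol = 1e-10)$root
}

# uniform censoring horizon c for exponential(rate) event times such that
# P(C < T) = (1 - exp(-rate * c)) / (rate * c) equals the target rate
.censoring_horizon <- function(rate, target) {
  if (target <= 0) return(Inf)
  f <- function(cc) (1 - exp(-rate * cc)) / (rate * cc) - target
  uniroot(f, c(1e-6, 1e9), tol = 1e-8)$root
}

#' Simulate a multi-tissue dataset with planted CIMP structure
#'
#' Generates, for each tissue: probe-level methylation (CGI values drawn
#' from a hypo/hyper beta mixture, probe values adding clipped Gaussian
#' noise), RPKM-like expression, binary mutations, and clinical tables with
#' right-censored survival, together with the ground truth (CIMP labels,
#' planted CGI / gene sets). Planted CGIs belong to the hypomethylated
#' background mode; CIMP-positive samples receive a logit-scale shift
#' calibrated so their expected beta increase equals `cimp_shift`.
#'
#' All randomness flows from `config$seed` in a fixed stream order:
#' annotation, planted sets, gene means, then per tissue (labels,
#' methylation, expression, mutations, clinical), so the same configuration
#' reproduces the dataset bit for bit.
#'
#' @param config A [simulation_config()].
#' @return Object of class `synthetic_dataset`: `annotation`, named
#'   per-tissue lists `probes`, `expression`, `mutations`, `clinical`,
#'   `truth`, plus `planted_cgis` (per tissue and `shared`),
#'   `predictive_genes`, `mutation_genes` and the `config`.
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "simulation_config"))
    .stopf("'config' must be created by simulation_config()")
  set.seed(config$seed)
  bb <- config$beta_background
  tissues <- sprintf("tissue%02d", seq_len(config$n_tissues))
  cgi_ids <- sprintf("CGI%04d", seq_len(config$n_cgis))
  gene_ids <- sprintf("G%04d", seq_len(config$n_genes))

  # --- annotation (shared across tissues) -------------------------------
  n_probes <- sample(seq(config$n_probes_per_cgi[1L], config$n_probes_per_cgi[2L]),
                     config$n_cgis, replace = TRUE)
  cgi_of_probe <- rep(cgi_ids, n_probes)
  cgi_idx <- rep(seq_len(config$n_cgis), n_probes)
  relation <- sample(c("island", "shore", "shelf"), length(cgi_of_probe),
                     replace = TRUE, prob = c(0.6, 0.25, 0.15))
  cgi_start <- seq_len(config$n_cgis) * 10000L
  offset <- ifelse(relation == "island", sample(0:999, length(relation), replace = TRUE),
            ifelse(relation == "shore",
                   1000L + sample(0:1999, length(relation), replace = TRUE),
                   3000L + sample(0:1999, length(relation), replace = TRUE)))
  pos <- cgi_start[cgi_idx] + offset
  chrom <- paste0("chr", (cgi_idx - 1L) %% 22L + 1L)
  genes_of_cgi <- ifelse(seq_len(config$n_cgis) <= config$n_genes,
                         gene_ids[pmin(seq_len(config$n_cgis), config$n_genes)], "")
  annotation <- data.frame(
    probe_id = sprintf("cg%07d", seq_along(cgi_of_probe)),
    chrom = chrom,
    pos = pos,
    cgi_id = cgi_of_probe,
    relation = relation,
    genes = genes_of_cgi[cgi_idx],
    stringsAsFactors = FALSE)
  n_sea <- round(config$open_sea_fraction * nrow(annotation))
  if (n_sea > 0L) {
    sea <- data.frame(
      probe_id = sprintf("cg%07d", nrow(annotation) + seq_len(n_sea)),
      chrom = paste0("chr", sample(1:22, n_sea, replace = TRUE)),
      pos = sample.int(5e6L, n_sea),
      cgi_id = NA_character_,
      relation = "open_sea",
      genes = "",
      stringsAsFactors = FALSE)
    annotation <- rbind(annotation, sea)
  }

  # --- planted feature sets ---------------------------------------------
  n_shared <- round(config$shared_signature_fraction * config$signature_size)
  shared_cgis <- sort(sample(cgi_ids, n_shared))
  planted_cgis <- lapply(tissues, function(t) {
    extra <- sample(setdiff(cgi_ids, shared_cgis),
                    config$signature_size - n_shared)
    sort(c(shared_cgis, extra))
  })
  names(planted_cgis) <- tissues
  predictive_genes <- sort(sample(gene_ids, config$n_predictive_genes))
  mutation_genes <- sort(sample(gene_ids, config$n_assoc_mut_genes))
  gene_mu <- rnorm(config$n_genes, mean = 4, sd = 1)  # log2 baseline, fixed

  # CGI background mode: planted CGIs are forced hypomethylated so CIMP
  # hypermethylation is observable against them
  hypo <- runif(config$n_cgis) < bb$weight_hypo
  hypo[cgi_ids %in% unique(unlist(planted_cgis))] <- TRUE
  shift_d <- .logit_shift_for(bb$hypo, config$cimp_shift)

  surv_rate0 <- log(2) / 1500  # exponential baseline, median 1500 days
  probes <- expression <- mutations <- clinical <- truth <- list()
  for (ti in seq_along(tissues)) {
    t <- tissues[ti]
    n <- config$samples_per_tissue[ti]
    sample_ids <- sprintf("%s_S%03d", t, seq_len(n))
    label <- rbinom(n, 1L, config$cimp_prevalence[ti])

    # CGI-level methylation
    cgi_beta <- matrix(NA_real_, config$n_cgis, n,
                       dimnames = list(cgi_ids, sample_ids))
    cgi_beta[hypo, ] <- rbeta(sum(hypo) * n, bb$hypo[1L], bb$hypo[2L])
    if (any(!hypo))
      cgi_beta[!hypo, ] <- rbeta(sum(!hypo) * n, bb$hyper[1L], bb$hyper[2L])
    planted <- cgi_ids %in% planted_cgis[[t]]
    pos_samples <- which(label == 1L)
    if (length(pos_samples) && shift_d > 0) {
      block <- cgi_beta[planted, pos_samples, drop = FALSE]
      cgi_beta[planted, pos_samples] <- plogis(qlogis(.clip01(block, 1e-6)) + shift_d)
    }
    # probe-level values
    pm <- cgi_beta[match(annotation$cgi_id, cgi_ids), , drop = FALSE]
    sea_rows <- is.na(annotation$cgi_id)
    if (any(sea_rows))
      pm[sea_rows, ] <- rbeta(sum(sea_rows) * n, 1, 3)
    pm[] <- round(.clip01(pm + rnorm(length(pm), sd = config$probe_noise_sd)), 6)
    dimnames(pm) <- list(annotation$probe_id, sample_ids)
    probes[[t]] <- pm

    # expression: log2 scale, predictive genes shifted in CIMP+
    ex <- matrix(rnorm(config$n_genes * n, mean = gene_mu, sd = 1),
                 config$n_genes, n, dimnames = list(gene_ids, sample_ids))
    if (length(pos_samples) && config$expression_effect > 0)
      ex[gene_ids %in% predictive_genes, pos_samples] <-
        ex[gene_ids %in% predictive_genes, pos_samples] + config$expression_effect
    expression[[t]] <- round(2^ex, 4)

    # mutations
    p_bg <- config$mutation_rate_background
    odds_pos <- config$mutation_odds_ratio * p_bg / (1 - p_bg)
    p_pos <- odds_pos / (1 + odds_pos)
    pmat <- matrix(p_bg, config$n_genes, n)
    if (length(pos_samples))
      pmat[gene_ids %in% mutation_genes, pos_samples] <- p_pos
    mutations[[t]] <- matrix(rbinom(length(pmat), 1L, pmat),
                             config$n_genes, n,
                             dimnames = list(gene_ids, sample_ids))

    # clinical: exponential survival with uniform censoring
    rate <- surv_rate0 * ifelse(label == 1L, config$survival_hr, 1)
    t_event <- rexp(n, rate = rate)
    horizon <- .censoring_horizon(surv_rate0, config$censoring_rate)
    t_cens <- if (is.finite(horizon)) runif(n, 0, horizon) else rep(Inf, n)
    clinical[[t]] <- data.frame(
      sample_id = sample_ids,
      time = round(pmin(t_event, t_cens), 1),
      event = as.integer(t_event <= t_cens),
      age = round(rnorm(n, 63, 10), 1),
      msi = sample(c("MSI-H", "MSS"), n, replace = TRUE, prob = c(0.15, 0.85)),
      er = sample(c("positive", "negative"), n, replace = TRUE, prob = c(0.6, 0.4)),
      pr = sample(c("positive", "negative"), n, replace = TRUE, prob = c(0.5, 0.5)),
      her2 = sample(c("positive", "negative"), n, replace = TRUE, prob = c(0.2, 0.8)),
      t_size = sample(paste0("T", 1:4), n, replace = TRUE),
      n_node = sample(paste0("N", 0:2), n, replace = TRUE),
      m_met = sample(c("M0", "M1"), n, replace = TRUE, prob = c(0.85, 0.15)),
      tissue = t,
      stringsAsFactors = FALSE)
    truth[[t]] <- data.frame(sample_id = sample_ids,
                             tissue = t,
                             cimp_label = ifelse(label == 1L, "positive", "negative"),
                             stringsAsFactors = FALSE)
  }
  structure(list(annotation = annotation,
                 tissues = tissues,
                 probes = probes,
                 expression = expression,
                 mutations = mutations,
                 clinical = clinical,
                 truth = truth,
                 planted_cgis = c(planted_cgis, list(shared = shared_cgis)),
                 predictive_genes = predictive_genes,
                 mutation_genes = mutation_genes,
                 config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic CIMP dataset: %d tissue(s), %s samples, %d CGIs (%d planted/tissue), %d genes\n",
              length(x$tissues),
              paste(vapply(x$probes, ncol, integer(1)), collapse = "/"),
              x$config$n_cgis, x$config$signature_size, x$config$n_genes))
  invisible(x)
}

#' Simulate a CGI methylation matrix with K planted clusters
#'
#' Companion generator for cluster-number assessment: samples fall into
#' `n_clusters` groups that differ in mean methylation on a planted
#' signature fraction of CGIs, with beta-distributed noise around each
#' cluster mean. Used to check that the consensus Delta(K) criterion
#' recovers the planted K.
#'
#' @param n_samples Number of samples.
#' @param n_cgis Number of CGIs. Default 300.
#' @param n_clusters Number of planted clusters. Default 3.
#' @param cluster_means Mean signature methylation per cluster; default
#'   equally spaced on `[0.15, 0.85]`.
#' @param signature_fraction Fraction of CGIs carrying the cluster
#'   structure. Default 0.1.
#' @param precision Beta precision (a + b) of the noise around each mean;
#'   larger = tighter clusters. Default 40.
#' @param seed Optional integer seed.
#' @return List with `beta` (CGI x sample matrix) and `labels` (integer
#'   cluster per sample).
#' @export
simulate_methylation_clusters <- function(n_samples, n_cgis = 300L,
                                          n_clusters = 3L,
                                          cluster_means = NULL,
                                          signature_fraction = 0.1,
                                          precision = 40,
                                          seed = NULL) {
  n_samples <- .check_count(n_samples, "n_samples", min = 2L)
  n_cgis <- .check_count(n_cgis, "n_cgis")
  n_clusters <- .check_count(n_clusters, "n_clusters")
  .check_fraction(signature_fraction, "signature_fraction", lo_open = TRUE)
  if (is.null(cluster_means))
    cluster_means <- seq(0.15, 0.85, length.out = n_clusters)
  if (length(cluster_means) != n_clusters)
    .stopf("'cluster_means' must have length n_clusters")
  .with_seed(seed, NULL)
  labels <- sort(rep_len(seq_len(n_clusters), n_samples))
  cgi_ids <- sprintf("CGI%04d", seq_len(n_cgis))
  sample_ids <- sprintf("S%03d", seq_len(n_samples))
  n_sig <- max(1L, round(signature_fraction * n_cgis))
  beta <- matrix(rbeta(n_cgis * n_samples, 1.5, 10), n_cgis, n_samples,
                 dimnames = list(cgi_ids, sample_ids))
  m <- cluster_means[labels]
  for (g in seq_len(n_sig)) {
    beta[g, ] <- rbeta(n_samples, m * precision, (1 - m) * precision)
  }
  list(beta = beta, labels = labels)
}

#' Write a synthetic dataset to disk
#'
#' Emits the pipeline's input formats: per tissue `probes_<tissue>.tsv`,
#' `expression_<tissue>.tsv`, `mutations_<tissue>.tsv`,
#' `clinical_<tissue>.tsv` and `truth_<tissue>.tsv`, plus one shared
#' `annotation.csv`. Everything round-trips losslessly through the
#' [read_probe_matrix()] family.
#'
#' @param dataset A [simulate_dataset()] result.
#' @param directory Output directory (created if absent).
#' @return Named character vector of written file paths, invisibly.
#' @export
write_dataset <- function(dataset, directory) {
  if (!inherits(dataset, "synthetic_dataset"))
    .stopf("'dataset' must be a synthetic_dataset")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) .stopf("cannot create directory '%s'", directory)
  paths <- c(annotation = file.path(directory, "annotation.csv"))
  write.csv(dataset$annotation, paths["annotation"], row.names = FALSE)
  for (t in dataset$tissues) {
    p <- c(probes = file.path(directory, sprintf("probes_%s.tsv", t)),
           expression = file.path(directory, sprintf("expression_%s.tsv", t)),
           mutations = file.path(directory, sprintf("mutations_%s.tsv", t)),
           clinical = file.path(directory, sprintf("clinical_%s.tsv", t)),
           truth = file.path(directory, sprintf("truth_%s.tsv", t)))
    .write_matrix_tsv(dataset$probes[[t]], p["probes"], "probe_id")
    .write_matrix_tsv(dataset$expression[[t]], p["expression"], "gene_id")
    .write_matrix_tsv(dataset$mutations[[t]], p["mutations"], "gene_id")
    write.table(dataset$clinical[[t]], p["clinical"], sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(dataset$truth[[t]], p["truth"], sep = "\t",
                quote = FALSE, row.names = FALSE)
    names(p) <- paste(names(p), t, sep = "_")
    paths <- c(paths, p)
  }
  invisible(paths)
}
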