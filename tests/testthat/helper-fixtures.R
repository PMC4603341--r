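# Fixture builders shared across test files; everything is generated in
# code so tests carry their own ground truth.

tiny_annotation <- function() {
  data.frame(
    probe_id = paste0("cg", 1:7),
    chrom = "chr1",
    pos = c(100L, 150L, 1200L, 5000L, 5100L, 6200L, 900000L),
    cgi_id = c("CGI_A", "CGI_A", "CGI_A", "CGI_B", "CGI_B", "CGI_B", NA),
    relation = c("island", "island", "shore", "island", "island", "shelf",
                 "open_sea"),
    genes = c("GENE1", "GENE1", "GENE1", "", "", "", ""),
    stringsAsFactors = FALSE)
}

tiny_probe_matrix <- function(values) {
  m <- matrix(values, nrow = 7,
              dimnames = list(paste0("cg", 1:7), c("s1", "s2")))
  m
}

# noiseless two-block CGI matrix: block 1 at beta lo, block 2 at beta hi
two_block_beta <- function(n1 = 3, n2 = 3, n_cgis = 10, lo = 0.1, hi = 0.9) {
  beta <- cbind(matrix(lo, n_cgis, n1), matrix(hi, n_cgis, n2))
  dimnames(beta) <- list(sprintf("CGI%03d", seq_len(n_cgis)),
                         sprintf("S%02d", seq_len(n1 + n2)))
  beta
}

make_signature <- function(ids, universe = ids, fraction = 0.05,
                           tissue = NULL) {
  structure(list(tissue = tissue,
                 cgi_ids = ids,
                 variances = setNames(rep(1, length(ids)), ids),
                 fraction = fraction,
                 n_total = length(universe),
                 universe = universe),
            class = "cimp_signature")
}

# task whose first gene separates the classes perfectly
separable_task <- function(n = 40, p = 5, gap = 2, seed = 1) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("S%02d", 1:n), sprintf("G%02d", 1:p)))
  x[, 1] <- ifelse(y == 1, gap, -gap) + rnorm(n, sd = 0.1)
  x <- scale(x)
  prediction_task(x, y)
}

# multi-tissue task with planted predictive genes shared across tissues
planted_task <- function(n_per_tissue = 50, n_tissues = 3, p = 60,
                         n_planted = 6, effect = 1.2, seed = 1) {
  set.seed(seed)
  xs <- list(); ys <- list()
  for (t in seq_len(n_tissues)) {
    y <- rbinom(n_per_tissue, 1, 0.4)
    while (length(unique(y)) < 2 || min(table(y)) < 3)
      y <- rbinom(n_per_tissue, 1, 0.4)
    x <- matrix(rnorm(n_per_tissue * p), n_per_tissue, p)
    x[, seq_len(n_planted)] <- x[, seq_len(n_planted)] + effect * y
    xs[[t]] <- scale(x); ys[[t]] <- y
  }
  x <- do.call(rbind, xs)
  dimnames(x) <- list(sprintf("S%03d", seq_len(nrow(x))),
                      sprintf("G%03d", seq_len(p)))
  prediction_task(x, unlist(ys),
                  rep(sprintf("tis%d", seq_len(n_tissues)), each = n_per_tissue))
}

# quick per-tissue CIMP calls from a synthetic dataset
dataset_calls <- function(ds, fraction = 0.05) {
  calls <- lapply(ds$tissues, function(t) {
    cgi <- filter_cgis(aggregate_by_cgi(ds$probes[[t]], ds$annotation))
    call_cimp(cgi, select_signature(cgi, fraction, tissue = t))
  })
  names(calls) <- ds$tissues
  calls
}

dataset_cgi <- function(ds, tissue) {
  filter_cgis(aggregate_by_cgi(ds$probes[[tissue]], ds$annotation))
}

truth_labels <- function(ds, tissue) {
  setNames(ds$truth[[tissue]]$cimp_label, ds$truth[[tissue]]$sample_id)
}
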