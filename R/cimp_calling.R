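#' Select the CIMP signature: the most variant CpG islands
#'
#' The per-tissue CIMP signature is the set of CGIs with the largest
#' across-sample variance; by default the top 5 %. Size is
#' `ceiling(fraction * n_cgis)`. Ties at the cutoff variance are broken by
#' lexicographic CGI id so the selection is deterministic.
#'
#' @param beta CGI x sample matrix (>= 2 samples).
#' @param fraction Fraction of CGIs to keep, in `(0, 1]`. Default 0.05.
#' @param tissue Optional cohort label carried along for reporting.
#' @return An object of class `cimp_signature`: list with `cgi_ids`
#'   (selected, ordered by decreasing variance), `variances` (for the
#'   selected CGIs), `fraction`, `n_total`, `universe` (all CGI ids in the
#'   input) and `tissue`.
#' @export
select_signature <- function(beta, fraction = 0.05, tissue = NULL) {
  if (!is.matrix(beta) || is.null(rownames(beta)))
    .stopf("'beta' must be a matrix with CGI ids as rownames")
  if (ncol(beta) < 2L)
    .stopf("variance is undefined with fewer than 2 samples")
  .check_fraction(fraction, "fraction", lo_open = TRUE)
  n <- ncol(beta)
  mu <- rowMeans(beta, na.rm = TRUE)
  v <- rowSums((beta - mu)^2, na.rm = TRUE) / (n - 1L)  # unbiased
  ord <- order(-v, rownames(beta))
  m <- ceiling(fraction * nrow(beta))
  sel <- ord[seq_len(m)]
  structure(list(
    tissue = tissue,
    cgi_ids = rownames(beta)[sel],
    variances = setNames(v[sel], rownames(beta)[sel]),
    fraction = fraction,
    n_total = nrow(beta),
    universe = rownames(beta)
  ), class = "cimp_signature")
}

#' @export
print.cimp_signature <- function(x, ...) {
  cat(sprintf("CIMP signature%s: %d / %d CGIs (top %.1f%% by variance)\n",
              if (is.null(x$tissue)) "" else paste0(" [", x$tissue, "]"),
              length(x$cgi_ids), x$n_total, 100 * x$fraction))
  invisible(x)
}

# Ward clustering of samples on the signature CGIs; shared by call_cimp and
# the consensus resampler. Returns integer cluster ids 1..k in hclust order.
.ward_clusters <- function(x, k) {
  hc <- hclust(dist(x), method = "ward.D2")
  cutree(hc, k = k)
}

#' Call CIMP status by Ward hierarchical clustering
#'
#' Clusters samples with Ward linkage on Euclidean distances over the
#' signature CGIs and cuts the tree into `k` clusters. Clusters are ordered
#' by their mean signature methylation; with `k = 2` the hypermethylated
#' cluster is labelled `positive` and the other `negative`, the defining
#' property of the methylator phenotype.
#'
#' @param beta CGI x sample matrix containing all signature CGIs.
#' @param signature A [`cimp_signature`][select_signature] (or character
#'   vector of CGI ids).
#' @param k Number of clusters (>= 2). Default 2.
#' @return Object of class `cimp_call`: `sample_ids`, `label` (factor
#'   negative/positive for k = 2, otherwise ranks "1".."k" ordered by
#'   increasing methylation), `cluster` (integer rank), per-cluster
#'   `cluster_mean_methylation`, the `signature`, `k` and `tissue`.
#' @export
call_cimp <- function(beta, signature, k = 2L) {
  k <- .check_count(k, "k", min = 2L)
  cgis <- if (inherits(signature, "cimp_signature")) signature$cgi_ids else signature
  missing_cgis <- setdiff(cgis, rownames(beta))
  if (length(missing_cgis))
    .stopf("signature CGI(s) absent from matrix: %s",
           paste(head(missing_cgis, 5L), collapse = ", "))
  x <- t(beta[cgis, , drop = FALSE])
  if (k > nrow(x))
    .stopf("k = %d exceeds the number of samples (%d)", k, nrow(x))
  if (anyNA(x))
    .stopf("matrix contains missing values; run filter_cgis() first")
  if (max(x) - min(x) < .Machine$double.eps^0.5)
    .stopf("no methylation variation among samples on the signature CGIs")
  cl <- .ward_clusters(x, k)
  sample_means <- rowMeans(x)
  cluster_means <- tapply(sample_means, cl, mean)
  rank_by_meth <- rank(cluster_means, ties.method = "first")  # 1 = lowest
  cluster <- as.integer(rank_by_meth[as.character(cl)])
  label <- if (k == 2L) {
    factor(c("negative", "positive")[cluster], levels = c("negative", "positive"))
  } else {
    factor(cluster, levels = seq_len(k))
  }
  means_sorted <- sort(as.numeric(cluster_means))
  names(means_sorted) <- if (k == 2L) c("negative", "positive") else as.character(seq_len(k))
  stopifnot(!is.unsorted(means_sorted))  # labelling rule: positive >= negative
  structure(list(
    tissue = if (inherits(signature, "cimp_signature")) signature$tissue else NULL,
    sample_ids = rownames(x),
    label = setNames(label, rownames(x)),
    cluster = setNames(cluster, rownames(x)),
    cluster_mean_methylation = means_sorted,
    signature = if (inherits(signature, "cimp_signature")) signature else NULL,
    k = k
  ), class = "cimp_call")
}

#' @export
print.cimp_call <- function(x, ...) {
  tab <- table(x$label)
  cat(sprintf("CIMP call%s: %s over %d samples (k = %d)\n",
              if (is.null(x$tissue)) "" else paste0(" [", x$tissue, "]"),
              paste(sprintf("%s = %d", names(tab), tab), collapse = ", "),
              length(x$sample_ids), x$k))
  cat("cluster mean methylation:",
      paste(sprintf("%s %.3f", names(x$cluster_mean_methylation),
                    x$cluster_mean_methylation), collapse = ", "), "\n")
  invisible(x)
}

#' Clustering stability across signature sizes
#'
#' Re-derives the signature and the CIMP call for a range of variance
#' fractions and reports the adjusted Rand index of each call against the
#' call at the reference fraction, quantifying how sensitive the sample
#' partition is to the signature size.
#'
#' @param beta CGI x sample matrix.
#' @param fractions Signature fractions to scan. Default 1--10 %.
#' @param reference_fraction Fraction defining the reference call. Default 0.05.
#' @param k Number of clusters. Default 2.
#' @return Data frame with columns `fraction`, `n_cgis`, `ari`.
#' @export
signature_stability <- function(beta, fractions = seq(0.01, 0.10, by = 0.01),
                                reference_fraction = 0.05, k = 2L) {
  .check_fraction(fractions, "fractions", lo_open = TRUE)
  .check_fraction(reference_fraction, "reference_fraction", lo_open = TRUE)
  ref_call <- call_cimp(beta, select_signature(beta, reference_fraction), k = k)
  res <- lapply(fractions, function(f) {
    sig <- select_signature(beta, f)
    cl <- call_cimp(beta, sig, k = k)
    data.frame(fraction = f, n_cgis = length(sig$cgi_ids),
               ari = mclust::adjustedRandIndex(as.integer(cl$label),
                                               as.integer(ref_call$label)))
  })
  do.call(rbind, res)
}
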