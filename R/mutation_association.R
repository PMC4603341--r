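#' Hypergeometric enrichment tail probability
#'
#' Upper-tail probability `P(X >= k)` that at least `k` of the `n_pos`
#' CIMP-positive samples are mutated, for `X` hypergeometric with `n_mut`
#' mutated samples among `n_total`. This is the one-sided Fisher test of a
#' 2x2 mutation-by-CIMP table.
#'
#' @param k Observed mutated CIMP-positive samples.
#' @param n_pos Number of CIMP-positive samples.
#' @param n_mut Number of mutated samples overall.
#' @param n_total Total number of samples.
#' @return Upper-tail p-value in `[0, 1]`.
#' @export
hypergeom_enrichment <- function(k, n_pos, n_mut, n_total) {
  k <- .check_count(k, "k", min = 0L)
  n_pos <- .check_count(n_pos, "n_pos", min = 0L)
  n_mut <- .check_count(n_mut, "n_mut", min = 0L)
  n_total <- .check_count(n_total, "n_total", min = 1L)
  if (any(k > pmin(n_pos, n_mut)) || any(n_pos > n_total) || any(n_mut > n_total))
    .stopf("inconsistent margins: need k <= min(n_pos, n_mut) and n_pos, n_mut <= n_total")
  phyper(k - 1, n_mut, n_total - n_mut, n_pos, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (delegates to
#' [stats::p.adjust()] with `method = "BH"` after validating the input).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same length.
#' @export
benjamini_hochberg <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    .stopf("all p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

.binary_call_sets <- function(mutations, call) {
  if (!is.matrix(mutations) || is.null(rownames(mutations)))
    .stopf("'mutations' must be a gene x sample matrix with gene rownames")
  if (!all(mutations %in% c(0, 1)))
    .stopf("'mutations' entries must be 0/1")
  if (call$k != 2L) .stopf("mutation association requires a binary CIMP call")
  common <- intersect(colnames(mutations), call$sample_ids)
  if (!length(common))
    .stopf("no samples shared between mutation matrix and CIMP call")
  lab <- call$label[common]
  list(mut = mutations[, common, drop = FALSE],
       pos = common[lab == "positive"],
       neg = common[lab == "negative"])
}

#' Genome-wide scan for mutation-CIMP association
#'
#' For every gene mutated in at least `min_mutated` samples, tests whether
#' its mutations are enriched in either CIMP class with two one-sided
#' hypergeometric tails (`p = min(1, 2 * min(tails))`, direction reported),
#' then applies Benjamini-Hochberg correction across the tested genes.
#'
#' @param mutations Binary gene x sample matrix.
#' @param call A binary [`cimp_call`][call_cimp].
#' @param min_mutated Minimum mutated samples for a gene to be tested.
#'   Default 3.
#' @return Data frame sorted by `q`: `gene`, counts (`k_pos`, `k_neg`,
#'   `n_mut`), `direction` (class with the higher mutation rate), `p`, `q`.
#'   Empty (with a warning) if no gene passes the filter.
#' @export
genomewide_mutation_scan <- function(mutations, call, min_mutated = 3L) {
  min_mutated <- .check_count(min_mutated, "min_mutated", min = 1L)
  d <- .binary_call_sets(mutations, call)
  n_pos <- length(d$pos); n_neg <- length(d$neg)
  n_total <- n_pos + n_neg
  n_mut <- rowSums(d$mut)
  test <- n_mut >= min_mutated
  if (!any(test)) {
    .warnf("no gene mutated in >= %d samples; nothing to test", min_mutated)
    return(data.frame(gene = character(), k_pos = integer(), k_neg = integer(),
                      n_mut = integer(), direction = character(),
                      p = numeric(), q = numeric()))
  }
  k <- rowSums(d$mut[, d$pos, drop = FALSE])[test]
  nm <- n_mut[test]
  up <- phyper(k - 1, nm, n_total - nm, n_pos, lower.tail = FALSE)
  lo <- phyper(k, nm, n_total - nm, n_pos)
  p <- pmin(1, 2 * pmin(up, lo))
  rate_pos <- if (n_pos > 0) k / n_pos else 0
  rate_neg <- if (n_neg > 0) (nm - k) / n_neg else 0
  out <- data.frame(gene = rownames(d$mut)[test],
                    k_pos = as.integer(k),
                    k_neg = as.integer(nm - k),
                    n_mut = as.integer(nm),
                    direction = ifelse(rate_pos >= rate_neg, "positive", "negative"),
                    p = p,
                    q = benjamini_hochberg(p))
  out[order(out$q, out$p, out$gene), , drop = FALSE]
}

#' Mutation burden by CIMP class
#'
#' Compares per-sample mutation counts between CIMP-positive and -negative
#' samples with a two-sided Wilcoxon rank-sum test (robust to the heavy
#' tails of somatic mutation counts).
#'
#' @inheritParams genomewide_mutation_scan
#' @return List with class medians, the rank-sum `statistic` and `p_value`.
#' @export
burden_comparison <- function(mutations, call) {
  d <- .binary_call_sets(mutations, call)
  if (!length(d$pos) || !length(d$neg))
    .stopf("both CIMP classes must be present")
  counts_pos <- colSums(d$mut[, d$pos, drop = FALSE])
  counts_neg <- colSums(d$mut[, d$neg, drop = FALSE])
  if (length(unique(c(counts_pos, counts_neg))) == 1L) {
    return(list(median_positive = median(counts_pos),
                median_negative = median(counts_neg),
                statistic = NA_real_, p_value = 1))
  }
  wt <- suppressWarnings(wilcox.test(counts_pos, counts_neg,
                                     alternative = "two.sided", exact = FALSE))
  list(median_positive = median(counts_pos),
       median_negative = median(counts_neg),
       statistic = unname(wt$statistic),
       p_value = wt$p.value)
}

#' Candidate-gene mutation association table
#'
#' Re-assesses, per tissue, the association between CIMP and mutations in
#' candidate genes with reported CIMP links (IDH1/IDH2 in glioma and
#' leukemia, BRAF/KRAS in colon, TET2 in leukemia). Genes absent from a
#' tissue's matrix are flagged rather than tested; BH correction is applied
#' across all tested gene x tissue rows.
#'
#' @param mutations Named list (by tissue) of binary gene x sample matrices
#'   (a single matrix is treated as one tissue).
#' @param calls Named list of binary [`cimp_call`][call_cimp] objects.
#' @param genes Candidate gene symbols. Default IDH1, IDH2, BRAF, KRAS, TET2.
#' @return Data frame: `gene`, `tissue`, `present`, counts, upper-tail
#'   hypergeometric `p` (enrichment in CIMP-positive) and `q`.
#' @export
candidate_gene_table <- function(mutations, calls,
                                 genes = c("IDH1", "IDH2", "BRAF", "KRAS", "TET2")) {
  if (is.matrix(mutations)) mutations <- list(cohort = mutations)
  if (inherits(calls, "cimp_call")) calls <- list(cohort = calls)
  tissues <- names(mutations)
  rows <- list()
  for (t in tissues) {
    d <- .binary_call_sets(mutations[[t]], calls[[t]])
    n_pos <- length(d$pos); n_total <- n_pos + length(d$neg)
    for (g in genes) {
      if (!g %in% rownames(d$mut)) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, tissue = t, present = FALSE,
          k_pos = NA_integer_, k_neg = NA_integer_, n_mut = NA_integer_,
          p = NA_real_)
        next
      }
      k <- sum(d$mut[g, d$pos])
      nm <- sum(d$mut[g, ])
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, tissue = t, present = TRUE,
        k_pos = as.integer(k), k_neg = as.integer(nm - k),
        n_mut = as.integer(nm),
        p = hypergeom_enrichment(k, n_pos, nm, n_total))
    }
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  tested <- out$present
  if (any(tested)) out$q[tested] <- benjamini_hochberg(out$p[tested])
  out
}

#' Collapse a minimal MAF to a binary gene x sample matrix
#'
#' Helper for mutation ingestion: counts any non-silent variant. The MAF
#' dialect required is minimal: columns `Hugo_Symbol`,
#' `Tumor_Sample_Barcode` and `Variant_Classification` (variants classed
#' `Silent` are dropped).
#'
#' @param maf Data frame with the three columns above.
#' @param samples Optional sample universe (columns of the result); defaults
#'   to the samples present in the MAF.
#' @return Binary gene x sample matrix.
#' @export
maf_to_matrix <- function(maf, samples = NULL) {
  required <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  missing <- setdiff(required, names(maf))
  if (length(missing))
    .stopf("MAF is missing column(s): %s", paste(missing, collapse = ", "))
  maf <- maf[maf$Variant_Classification != "Silent", , drop = FALSE]
  if (is.null(samples)) samples <- sort(unique(maf$Tumor_Sample_Barcode))
  genes <- sort(unique(maf$Hugo_Symbol))
  m <- matrix(0L, length(genes), length(samples),
              dimnames = list(genes, samples))
  keep <- maf$Tumor_Sample_Barcode %in% samples
  m[cbind(match(maf$Hugo_Symbol[keep], genes),
          match(maf$Tumor_Sample_Barcode[keep], samples))] <- 1L
  m
}
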