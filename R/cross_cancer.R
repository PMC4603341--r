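#' Intersect per-tissue CIMP signatures
#'
#' Computes the exact intersection of the CGI sets across tissues plus all
#' pairwise overlap counts, and the expected overlap size if the signatures
#' had been independent uniform random subsets of the common CGI universe.
#'
#' @param signatures List of [`cimp_signature`][select_signature] objects
#'   (>= 2) over overlapping CGI universes.
#' @return Object of class `signature_overlap`: `common_cgis`, `pairwise`
#'   (count matrix), per-signature `sizes`, `n_universe` (size of the common
#'   universe) and `expected_overlap` (`n_universe * prod(fractions)`).
#' @export
intersect_signatures <- function(signatures) {
  if (!is.list(signatures) || length(signatures) < 2L)
    .stopf("need at least 2 signatures")
  if (!all(vapply(signatures, inherits, logical(1), "cimp_signature")))
    .stopf("all elements must be cimp_signature objects")
  tissues <- vapply(seq_along(signatures), function(i) {
    t <- signatures[[i]]$tissue
    if (is.null(t)) sprintf("tissue%d", i) else t
  }, character(1))
  names(signatures) <- tissues
  universes <- lapply(signatures, `[[`, "universe")
  for (i in seq_along(universes)) {
    for (j in seq_len(i - 1L)) {
      if (!length(intersect(universes[[i]], universes[[j]])))
        .stopf("signatures '%s' and '%s' are defined over disjoint CGI universes",
               tissues[j], tissues[i])
    }
  }
  sets <- lapply(signatures, `[[`, "cgi_ids")
  common <- Reduce(intersect, sets)
  m <- length(sets)
  pairwise <- matrix(0L, m, m, dimnames = list(tissues, tissues))
  for (i in seq_len(m)) for (j in seq_len(m))
    pairwise[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  universe <- Reduce(intersect, universes)
  fractions <- vapply(signatures, `[[`, numeric(1), "fraction")
  structure(list(
    tissues = tissues,
    sizes = setNames(lengths(sets), tissues),
    common_cgis = sort(common),
    pairwise = pairwise,
    n_universe = length(universe),
    fractions = fractions,
    expected_overlap = unname(length(universe) * prod(fractions))
  ), class = "signature_overlap")
}

#' @export
print.signature_overlap <- function(x, ...) {
  cat(sprintf("Signature overlap across %d tissues: %d common CGIs (expected under the random-subset null: %.4g)\n",
              length(x$tissues), length(x$common_cgis), x$expected_overlap))
  invisible(x)
}

#' Expected overlap of independent random CGI subsets
#'
#' If each of `n_sets` signatures were an independent uniform random subset
#' containing a `fraction` of all `n_total` CGIs, the expected size of their
#' full intersection is `n_total * fraction^n_sets`. This is the analytic
#' null against which an observed cross-cancer signature is judged.
#'
#' @param n_total Number of CGIs in the universe (>= 1).
#' @param fraction Subset fraction in `[0, 1]`.
#' @param n_sets Number of independent subsets (>= 1).
#' @return Expected intersection size (non-negative number).
#' @examples
#' expected_random_overlap(21176, 0.05, 5)  # ~0.0066 CGI
#' @export
expected_random_overlap <- function(n_total, fraction, n_sets) {
  n_total <- .check_count(n_total, "n_total", min = 1L)
  .check_fraction(fraction, "fraction")
  n_sets <- .check_count(n_sets, "n_sets", min = 1L)
  n_total * fraction^n_sets
}

#' Monte-Carlo check of the random-overlap null
#'
#' Draws `n_sets` uniform random subsets of size `round(fraction * n_total)`
#' and reports the mean full-intersection size with its standard error,
#' plus the exceedance fraction against an optional observed overlap (an
#' extension beyond the analytic expectation).
#'
#' @inheritParams expected_random_overlap
#' @param n_reps Number of Monte-Carlo replicates (>= 100).
#' @param observed Optional observed overlap count for an exceedance
#'   probability `P(overlap >= observed)`.
#' @param seed Optional integer seed.
#' @return List with `mean`, `se`, `n_reps`, `expected` (analytic) and,
#'   when `observed` is given, `p_exceed`.
#' @export
monte_carlo_overlap <- function(n_total, fraction, n_sets, n_reps = 10000L,
                                observed = NULL, seed = NULL) {
  n_total <- .check_count(n_total, "n_total", min = 1L)
  .check_fraction(fraction, "fraction")
  n_sets <- .check_count(n_sets, "n_sets", min = 1L)
  n_reps <- .check_count(n_reps, "n_reps", min = 100L)
  .with_seed(seed, NULL)
  size <- round(fraction * n_total)
  counts <- integer(n_reps)
  if (size > 0L) {
    for (r in seq_len(n_reps)) {
      tab <- integer(n_total)
      for (s in seq_len(n_sets)) {
        idx <- sample.int(n_total, size)
        tab[idx] <- tab[idx] + 1L
      }
      counts[r] <- sum(tab == n_sets)
    }
  }
  out <- list(mean = mean(counts),
              se = sd(counts) / sqrt(n_reps),
              n_reps = n_reps,
              expected = expected_random_overlap(n_total, fraction, n_sets))
  if (!is.null(observed))
    out$p_exceed <- mean(counts >= observed)
  out
}

#' Pan-cancer CIMP call on the cross-cancer signature
#'
#' Pools samples from all tissues, restricts them to the common signature
#' CGIs and re-runs the two-class Ward clustering, testing whether
#' CIMP-positive samples cluster together independently of tissue of
#' origin. When per-tissue calls are supplied, their cross-tabulation
#' against the pooled call is reported.
#'
#' @param matrices Named list of CGI x sample matrices, one per tissue, all
#'   containing the common CGIs.
#' @param common_cgis Character vector of cross-cancer signature CGI ids
#'   (non-empty), e.g. `intersect_signatures(...)$common_cgis`.
#' @param per_tissue_calls Optional named list of [`cimp_call`][call_cimp]
#'   objects aligned with `matrices`.
#' @return A [`cimp_call`][call_cimp] over the pooled samples with extra
#'   fields `tissue_of_sample` and (if calls were given) `crosstab`.
#' @export
pan_cancer_call <- function(matrices, common_cgis, per_tissue_calls = NULL) {
  if (!length(common_cgis))
    .stopf("no cross-cancer signature: the common CGI set is empty")
  if (is.null(names(matrices)))
    names(matrices) <- sprintf("tissue%d", seq_along(matrices))
  for (t in names(matrices)) {
    absent <- setdiff(common_cgis, rownames(matrices[[t]]))
    if (length(absent))
      .stopf("tissue '%s' lacks common CGI(s): %s", t,
             paste(head(absent, 5L), collapse = ", "))
  }
  pooled <- do.call(cbind, lapply(names(matrices), function(t) {
    m <- matrices[[t]][common_cgis, , drop = FALSE]
    colnames(m) <- paste(t, colnames(m), sep = ":")
    m
  }))
  tissue_of_sample <- rep(names(matrices),
                          vapply(matrices, ncol, integer(1)))
  call <- call_cimp(pooled, common_cgis, k = 2L)
  call$tissue_of_sample <- setNames(tissue_of_sample, colnames(pooled))
  if (!is.null(per_tissue_calls)) {
    per_label <- unlist(lapply(names(matrices), function(t) {
      as.character(per_tissue_calls[[t]]$label[colnames(matrices[[t]])])
    }))
    call$crosstab <- table(pooled = as.character(call$label),
                           per_tissue = per_label)
  }
  call
}
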