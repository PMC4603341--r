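#' Consensus clustering over resampled sample subsets
#'
#' Monti-style assessment of cluster number: for each candidate `K`,
#' samples are repeatedly subsampled without replacement, Ward-clustered on
#' the signature CGIs, and the consensus matrix records how often each
#' sample pair co-clusters among the resamples in which both were drawn.
#' A well-supported `K` yields consensus entries near 0 or 1; the area
#' `A(K)` under the empirical CDF of the off-diagonal consensus entries and
#' its relative increase `Delta(K)` (see [delta_k()]) summarize this.
#'
#' `A(K)` is the exact integral over `[0, 1]` of the right-continuous
#' empirical CDF of the consensus entries (a step integral), so ideal
#' block-structured data give `A(K)` equal to its combinatorial closed form
#' to machine precision. The CDF is additionally tabulated on a 101-point
#' grid for reporting.
#'
#' @param beta CGI x sample matrix.
#' @param signature [`cimp_signature`][select_signature] or CGI id vector.
#' @param k_range Candidate cluster numbers, contiguous from 2. Default 2:5.
#' @param n_resamples Number of subsampling iterations per K. Default 100.
#' @param subsample_fraction Fraction of samples drawn each iteration,
#'   in `(0, 1]`. Default 0.8.
#' @param seed Optional integer seed.
#' @return Object of class `consensus_profile`: per-K list (`consensus`
#'   matrix with `NA` for never co-sampled pairs, `cdf_grid`, `cdf`, `area`,
#'   `n_skipped`), vector `areas`, vector `delta`, and the resampling
#'   parameters.
#' @export
consensus_cluster <- function(beta, signature, k_range = 2:5,
                              n_resamples = 100L, subsample_fraction = 0.8,
                              seed = NULL) {
  n_resamples <- .check_count(n_resamples, "n_resamples", min = 2L)
  .check_fraction(subsample_fraction, "subsample_fraction", lo_open = TRUE)
  k_range <- sort(.check_count(k_range, "k_range", min = 2L))
  if (!identical(k_range, seq.int(min(k_range), max(k_range))))
    .stopf("'k_range' must be contiguous")
  cgis <- if (inherits(signature, "cimp_signature")) signature$cgi_ids else signature
  x <- t(beta[cgis, , drop = FALSE])
  n <- nrow(x)
  size <- max(1L, round(subsample_fraction * n))
  .with_seed(seed, NULL)

  per_k <- lapply(k_range, function(K) {
    hits <- matrix(0, n, n)
    tries <- matrix(0, n, n)
    n_skipped <- 0L
    for (r in seq_len(n_resamples)) {
      idx <- sort(sample.int(n, size))
      if (length(idx) < K) {
        .warnf("resample of size %d cannot support K = %d clusters; skipped",
               length(idx), K)
        n_skipped <- n_skipped + 1L
        next
      }
      cl <- .ward_clusters(x[idx, , drop = FALSE], K)
      z <- outer(cl, cl, "==") + 0
      hits[idx, idx] <- hits[idx, idx] + z
      tries[idx, idx] <- tries[idx, idx] + 1
    }
    if (n_skipped == n_resamples)
      .stopf("all %d resamples were too small for K = %d", n_resamples, K)
    consensus <- hits / tries
    consensus[tries == 0] <- NA_real_
    dimnames(consensus) <- list(rownames(x), rownames(x))
    entries <- consensus[upper.tri(consensus)]
    entries <- entries[!is.na(entries)]
    grid <- seq(0, 1, length.out = 101L)
    Fhat <- ecdf(entries)
    list(K = K,
         consensus = consensus,
         cdf_grid = grid,
         cdf = Fhat(grid),
         area = .cdf_area(entries),
         n_skipped = n_skipped)
  })
  names(per_k) <- as.character(k_range)
  areas <- vapply(per_k, `[[`, numeric(1), "area")
  structure(list(
    k_range = k_range,
    per_k = per_k,
    areas = areas,
    delta = delta_k(areas),
    n_resamples = n_resamples,
    subsample_fraction = subsample_fraction
  ), class = "consensus_profile")
}

# exact integral over [0,1] of the right-continuous ECDF of `entries`
.cdf_area <- function(entries) {
  stopifnot(length(entries) > 0L, all(entries >= 0 & entries <= 1))
  xs <- unique(sort(c(0, entries, 1)))
  if (length(xs) == 1L) return(if (xs == 1) 0 else 1)
  Fhat <- ecdf(entries)
  sum(Fhat(xs[-length(xs)]) * diff(xs))
}

#' Relative increase in consensus CDF area, Delta(K)
#'
#' `Delta(2) = A(2)` and `Delta(K) = (A(K) - A(K-1)) / A(K-1)` for `K >= 3`
#' (the Monti et al. relative-increase criterion). The `K` at which
#' `Delta(K)` peaks indicates the number of clusters supported by the data.
#'
#' @param areas Named numeric vector of areas `A(K)`, names = K, contiguous
#'   from K = 2.
#' @return Named numeric vector `Delta(K)`.
#' @export
delta_k <- function(areas) {
  ks <- as.integer(names(areas))
  if (length(ks) == 0L || anyNA(ks) || ks[1L] != 2L ||
      !identical(ks, seq.int(2L, length.out = length(ks))))
    .stopf("'areas' must be named by contiguous K starting at 2")
  delta <- numeric(length(ks))
  delta[1L] <- areas[1L]
  if (length(ks) > 1L) {
    prev <- areas[-length(areas)]
    if (any(prev == 0))
      .stopf("A(K-1) = 0: Delta(K) undefined for K = %d",
             ks[which(prev == 0)[1L] + 1L])
    delta[-1L] <- diff(areas) / prev
  }
  setNames(delta, names(areas))
}

#' @export
print.consensus_profile <- function(x, ...) {
  cat("Consensus clustering profile\n")
  df <- data.frame(K = x$k_range, A = round(x$areas, 4), delta = round(x$delta, 4))
  print(df, row.names = FALSE)
  cat(sprintf("suggested K (argmax Delta): %d\n",
              x$k_range[which.max(x$delta)]))
  invisible(x)
}
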