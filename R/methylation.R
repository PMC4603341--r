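#' Beta value from methylated and unmethylated intensities
#'
#' Converts Illumina 450K-style channel intensities to the methylation
#' fraction (beta value) `M / (M + U)`. Probes with zero total intensity
#' yield `NA` rather than an error, since they correspond to failed
#' measurements.
#'
#' @param methylated Numeric vector of methylated signal intensities (>= 0).
#' @param unmethylated Numeric vector of unmethylated signal intensities
#'   (>= 0), same length.
#' @return Numeric vector of beta values in `[0, 1]`, `NA` where
#'   `methylated + unmethylated == 0`.
#' @examples
#' compute_beta(300, 100)  # 0.75
#' @export
compute_beta <- function(methylated, unmethylated) {
  if (length(methylated) != length(unmethylated))
    .stopf("'methylated' and 'unmethylated' must have the same length")
  if (any(methylated < 0, na.rm = TRUE) || any(unmethylated < 0, na.rm = TRUE))
    .stopf("intensities must be non-negative")
  total <- methylated + unmethylated
  beta <- methylated / total
  beta[!is.na(total) & total == 0] <- NA_real_
  beta
}

.relation_levels <- c("island", "shore", "shelf", "open_sea")

# checks the annotation contract: required columns, known relations, and
# open_sea <=> no CGI assignment
.validate_annotation <- function(annotation) {
  required <- c("probe_id", "chrom", "pos", "cgi_id", "relation", "genes")
  missing <- setdiff(required, names(annotation))
  if (length(missing))
    .stopf("annotation is missing column(s): %s", paste(missing, collapse = ", "))
  bad_rel <- setdiff(unique(annotation$relation), .relation_levels)
  if (length(bad_rel))
    .stopf("unknown probe relation(s): %s", paste(bad_rel, collapse = ", "))
  open_sea <- annotation$relation == "open_sea"
  no_cgi <- is.na(annotation$cgi_id) | annotation$cgi_id == ""
  if (any(open_sea != no_cgi))
    .stopf("annotation violates open_sea <=> missing cgi_id for probe(s): %s",
           paste(head(annotation$probe_id[open_sea != no_cgi], 5L), collapse = ", "))
  if (anyDuplicated(annotation$probe_id))
    .stopf("duplicated probe_id in annotation")
  invisible(annotation)
}

#' Aggregate probe-level methylation to one value per CpG island
#'
#' Averages beta values of all probes assigned to each CpG island. By
#' default a CGI's profile includes its shore (0--2 kb) and shelf (2--4 kb)
#' probes as well as the island probes themselves; open-sea probes never
#' contribute. Missing probe values are ignored in the mean.
#'
#' @param probes Numeric matrix of beta values, probes in rows (rownames =
#'   probe ids), samples in columns.
#' @param annotation Data frame with columns `probe_id`, `chrom`, `pos`,
#'   `cgi_id`, `relation` (one of island/shore/shelf/open_sea) and `genes`.
#' @param include_shores_shelves If `FALSE`, only `relation == "island"`
#'   probes contribute.
#' @return Numeric matrix, CGIs x samples, with attribute `n_probes`
#'   (contributing probes per CGI). CGIs with no non-missing probe value in
#'   any sample are dropped.
#' @export
aggregate_by_cgi <- function(probes, annotation, include_shores_shelves = TRUE) {
  if (!is.matrix(probes) || is.null(rownames(probes)))
    .stopf("'probes' must be a matrix with probe ids as rownames")
  .validate_annotation(annotation)
  unknown <- setdiff(rownames(probes), annotation$probe_id)
  if (length(unknown))
    .stopf("probe(s) absent from annotation: %s%s",
           paste(head(unknown, 5L), collapse = ", "),
           if (length(unknown) > 5L) sprintf(" (and %d more)", length(unknown) - 5L) else "")
  ann <- annotation[match(rownames(probes), annotation$probe_id), ]
  keep <- !is.na(ann$cgi_id) & ann$cgi_id != "" & ann$relation != "open_sea"
  if (!include_shores_shelves)
    keep <- keep & ann$relation == "island"
  if (!any(keep))
    .stopf("no probes assigned to a CGI under the requested settings")
  x <- probes[keep, , drop = FALSE]
  grp <- ann$cgi_id[keep]
  observed <- !is.na(x)
  x0 <- x
  x0[!observed] <- 0
  sums <- rowsum(x0, grp)
  counts <- rowsum(observed + 0L, grp)
  beta <- sums / counts
  beta[counts == 0L] <- NA_real_
  informative <- rowSums(!is.na(beta)) > 0L
  beta <- beta[informative, , drop = FALSE]
  n_probes <- as.integer(table(grp)[rownames(beta)])
  names(n_probes) <- rownames(beta)
  attr(beta, "n_probes") <- n_probes
  beta
}

#' Drop sparsely observed CGIs and impute the remainder
#'
#' Removes CGIs whose fraction of missing samples exceeds
#' `max_missing_fraction`; remaining missing entries are imputed with the
#' CGI's mean over observed samples (per cohort, so imputation never crosses
#' tissues when matrices are kept per tissue).
#'
#' @param beta CGI x sample matrix as returned by [aggregate_by_cgi()].
#' @param max_missing_fraction Maximum tolerated missing-sample fraction per
#'   CGI, in `[0, 1]`. Default 0.3.
#' @return Filtered, complete matrix (attribute `n_probes` subset along).
#' @export
filter_cgis <- function(beta, max_missing_fraction = 0.3) {
  .check_fraction(max_missing_fraction, "max_missing_fraction")
  if (!is.matrix(beta)) .stopf("'beta' must be a matrix")
  miss <- rowMeans(is.na(beta))
  keep <- miss <= max_missing_fraction
  if (!any(keep))
    .stopf("all %d CGIs exceed the missingness threshold %g", nrow(beta),
           max_missing_fraction)
  out <- beta[keep, , drop = FALSE]
  if (anyNA(out)) {
    rm <- rowMeans(out, na.rm = TRUE)
    idx <- which(is.na(out), arr.ind = TRUE)
    out[idx] <- rm[idx[, 1L]]
  }
  np <- attr(beta, "n_probes")
  if (!is.null(np)) attr(out, "n_probes") <- np[rownames(out)]
  out
}
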