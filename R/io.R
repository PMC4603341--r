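# Readers and writers for the pipeline's plain-text formats. Matrices are
# TSV with the id column first and sample ids in the header; annotation is
# CSV per the 450K-manifest-like convention.

.write_matrix_tsv <- function(m, path, id_col) {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_matrix_tsv <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Read a probe beta-value matrix (probes x samples TSV)
#' @param path TSV file, first column `probe_id`, header = sample ids.
#' @return Numeric matrix.
#' @export
read_probe_matrix <- function(path) {
  m <- .read_matrix_tsv(path)
  if (any(m < 0 | m > 1, na.rm = TRUE))
    .stopf("beta values outside [0, 1] in %s", path)
  m
}

#' Read a gene expression matrix (genes x samples TSV)
#' @param path TSV file, first column `gene_id`, header = sample ids.
#' @return Numeric matrix (non-negative RPKM).
#' @export
read_expression_matrix <- function(path) {
  m <- .read_matrix_tsv(path)
  if (any(m < 0, na.rm = TRUE)) .stopf("negative expression values in %s", path)
  m
}

#' Read a binary mutation matrix (genes x samples TSV)
#' @param path TSV file, values 0/1.
#' @return Integer matrix.
#' @export
read_mutation_matrix <- function(path) {
  m <- .read_matrix_tsv(path)
  if (!all(m %in% c(0, 1))) .stopf("mutation matrix in %s is not binary", path)
  storage.mode(m) <- "integer"
  m
}

#' Read a probe annotation table (CSV)
#' @param path CSV with columns probe_id, chrom, pos, cgi_id, relation,
#'   genes (semicolon-separated symbols).
#' @return Data frame, validated.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  ann <- read.csv(path, stringsAsFactors = FALSE)
  if ("cgi_id" %in% names(ann)) ann$cgi_id[ann$cgi_id %in% ""] <- NA_character_
  if ("genes" %in% names(ann)) ann$genes[is.na(ann$genes)] <- ""
  .validate_annotation(ann)
  ann
}

#' Read a clinical table (TSV)
#' @param path TSV with sample_id, time, event and covariate columns.
#' @return Data frame.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) .stopf("clinical table needs a sample_id column")
  df
}

#' Write CIMP calls as TSV
#'
#' One row per sample: `sample_id`, `tissue`, `cimp_label`,
#' `cluster_mean_methylation` (the mean of the sample's cluster).
#'
#' @param call A [`cimp_call`][call_cimp].
#' @param path Output file.
#' @export
write_cimp_calls <- function(call, path) {
  df <- data.frame(
    sample_id = call$sample_ids,
    tissue = if (is.null(call$tissue)) NA_character_ else call$tissue,
    cimp_label = as.character(call$label),
    cluster_mean_methylation =
      unname(call$cluster_mean_methylation[call$cluster]),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a CIMP signature as TSV and optionally BED
#'
#' The TSV lists the signature CGIs with their variances. When an
#' annotation is supplied, a BED file of 0-based half-open CGI intervals
#' (min to max island-probe position) is written alongside.
#'
#' @param signature A [`cimp_signature`][select_signature] or character
#'   vector of CGI ids.
#' @param path Output TSV path.
#' @param annotation Optional annotation data frame for BED export.
#' @param bed_path BED output path; default `path` with a `.bed` extension.
#' @return Written path(s), invisibly.
#' @export
write_signature <- function(signature, path, annotation = NULL,
                            bed_path = sub("\\.tsv$", ".bed", path)) {
  if (inherits(signature, "cimp_signature")) {
    df <- data.frame(cgi_id = signature$cgi_ids,
                     variance = unname(signature$variances))
  } else {
    df <- data.frame(cgi_id = signature, variance = NA_real_)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- path
  if (!is.null(annotation)) {
    ann <- annotation[!is.na(annotation$cgi_id) &
                        annotation$cgi_id %in% df$cgi_id &
                        annotation$relation == "island", , drop = FALSE]
    if (nrow(ann)) {
      # 1-based probe positions -> 0-based half-open intervals
      agg <- do.call(rbind, lapply(split(ann, ann$cgi_id), function(a) {
        data.frame(chrom = a$chrom[1L], start = min(a$pos) - 1L,
                   end = max(a$pos), name = a$cgi_id[1L])
      }))
      agg <- agg[order(agg$chrom, agg$start), , drop = FALSE]
      write.table(agg, bed_path, sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
      paths <- c(paths, bed_path)
    }
  }
  invisible(paths)
}
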