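# VCF ingestion shim: bridges caller output to report variant records. The
# VCF itself carries coordinates only; the clinical annotation (HGNC id,
# HGVS notation, effect, database id, classification) comes from a sidecar
# table keyed by CHROM:POS:REF:ALT. A structural pre-scan reports malformed
# files with a line number; record parsing is delegated to vcfR.

.scan_vcf_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !startsWith(lines[1], "##fileformat=VCF")) {
    stop("malformed VCF at line 1: missing ##fileformat header")
  }
  header_at <- which(startsWith(lines, "#CHROM"))
  if (length(header_at) == 0) {
    stop("malformed VCF at line ", length(lines) + 1,
         ": truncated header, no #CHROM line")
  }
  header_at <- header_at[1]
  for (i in seq_len(header_at - 1)) {
    if (!startsWith(lines[i], "##")) {
      stop("malformed VCF at line ", i, ": expected a ## meta line")
    }
  }
  if (length(strsplit(lines[header_at], "\t", fixed = TRUE)[[1]]) < 8) {
    stop("malformed VCF at line ", header_at, ": #CHROM header has fewer than 8 columns")
  }
  body <- lines[seq_len(length(lines))[-seq_len(header_at)]]
  body <- body[nzchar(body)]
  for (j in seq_along(body)) {
    if (length(strsplit(body[j], "\t", fixed = TRUE)[[1]]) < 8) {
      stop("malformed VCF at line ", header_at + j,
           ": record has fewer than 8 columns")
    }
  }
  invisible(TRUE)
}

#' Convert VCF records to report variant records
#'
#' Joins each VCF record with a sidecar annotation row keyed by
#' \code{CHROM:POS:REF:ALT}. Records with no sidecar match are reported in
#' the \code{unmatched} component, never silently dropped.
#'
#' @param vcf_path Path to an uncompressed VCF file.
#' @param annotations A data frame (or path to a CSV) with columns \code{key},
#'   \code{gene_hgnc_id}, \code{gene_symbol}, \code{hgvs_notation},
#'   \code{variant_effect}, \code{variant_db_id}, \code{classification}, and
#'   optionally the per-variant reporting metadata columns
#'   (\code{result_status}, \code{assay_code}, \code{observed_date},
#'   \code{test_method}, \code{interpretation}, \code{comment}).
#' @return List with \code{variants} (list of [variant_record()]s, VCF order)
#'   and \code{unmatched} (character vector of unmatched record keys).
#' @export
vcf_to_variants <- function(vcf_path, annotations) {
  .scan_vcf_structure(vcf_path)
  if (is.character(annotations)) {
    annotations <- utils::read.csv(annotations, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(annotations), "key" %in% names(annotations))
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  keys <- paste(fix[, "CHROM"], fix[, "POS"], fix[, "REF"], fix[, "ALT"], sep = ":")
  variants <- list()
  unmatched <- character(0)
  opt_col <- function(row, col) {
    if (col %in% names(annotations) && !is.na(row[[col]]) && nzchar(row[[col]])) {
      row[[col]]
    } else NULL
  }
  for (i in seq_along(keys)) {
    hit <- annotations[annotations$key == keys[i], , drop = FALSE]
    if (nrow(hit) == 0) {
      unmatched <- c(unmatched, keys[i])
      next
    }
    row <- hit[1, , drop = FALSE]
    variants <- c(variants, list(variant_record(
      gene_hgnc_id = row$gene_hgnc_id, gene_symbol = row$gene_symbol,
      hgvs_notation = row$hgvs_notation, variant_effect = row$variant_effect,
      variant_db_id = row$variant_db_id,
      classification = parse_classification(row$classification),
      result_status = opt_col(row, "result_status"),
      assay_code = opt_col(row, "assay_code"),
      observed_date = opt_col(row, "observed_date"),
      test_method = opt_col(row, "test_method"),
      interpretation = opt_col(row, "interpretation"),
      comment = opt_col(row, "comment"))))
  }
  list(variants = variants, unmatched = unmatched)
}
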