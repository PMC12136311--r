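#' Write variant records to a VCF file
#'
#' Emits the header's meta lines, the `#CHROM` column line, then one data
#' line per record. Phased genotypes are written `a|b`, unphased `a/b`.
#' When a record carries dosages, FORMAT is `GT:DS`, otherwise `GT`.
#'
#' @param records A list of `variant_record`s or a `genotype_block`.
#' @param header A `vcf_header` whose sample count all records must match.
#' @param path Output path.
#' @param file_mode `"GZ"`, `"NORMAL"` or `"AUTO"` (suffix-based).
#' @return Invisibly, the number of data lines written.
#' @export
write_vcf <- function(records, header, path, file_mode = "AUTO") {
  stopifnot(inherits(header, "vcf_header"))
  if (inherits(records, "genotype_block")) records <- records$records
  if (inherits(records, "variant_record")) records <- list(records)
  mode <- resolve_file_mode(path, file_mode, for_write = TRUE)
  con <- open_text_connection(path, mode, write = TRUE)
  on.exit(close(con))
  writeLines(c(header$meta_lines, vcf_column_line(header)), con)
  n <- 0L
  for (rec in records) {
    writeLines(format_vcf_line(rec, header$n_samples), con)
    n <- n + 1L
  }
  invisible(n)
}

vcf_column_line <- function(header) {
  paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", header$sample_ids), collapse = "\t")
}

format_vcf_line <- function(rec, n_samples) {
  if (length(rec$allele_a) != n_samples) {
    stop("record at ", rec$chrom, ":", rec$pos, " has ",
         length(rec$allele_a), " samples; header declares ", n_samples,
         call. = FALSE)
  }
  gt <- paste0(rec$allele_a, ifelse(rec$phased, "|", "/"), rec$allele_b)
  gt[is.na(rec$allele_a) | is.na(rec$allele_b)] <-
    ifelse(rec$phased[is.na(rec$allele_a) | is.na(rec$allele_b)],
           ".|.", "./.")
  if (!is.null(rec$dosages)) {
    fmt <- "GT:DS"
    cols <- paste0(gt, ":", format_ds(rec$dosages))
  } else {
    fmt <- "GT"
    cols <- gt
  }
  paste(c(rec$chrom, rec$pos, rec$id, rec$ref,
          paste(rec$alt, collapse = ","),
          rec$qual, rec$filter, rec$info, fmt, cols),
        collapse = "\t")
}

# Dosages print with up to 3 decimals, trailing zeros trimmed but at least
# one decimal kept ("1.0", "0.25").
format_ds <- function(x) {
  out <- sub("0+$", "", formatC(x, format = "f", digits = 3))
  sub("\\.$", ".0", out)
}
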