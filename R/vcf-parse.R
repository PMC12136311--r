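#' Parse one VCF data line into a variant record
#'
#' Captures the nine site columns and, per sample, the GT field (allele pair
#' plus phase flag) and optionally the DS dosage. All other FORMAT fields are
#' skipped, not stored. GT may sit at any position in FORMAT; it is located
#' per record.
#'
#' @param line A raw tab-separated VCF data line.
#' @param n_samples Sample count from the governing header.
#' @param parse_fields Character vector containing `"GT"` and optionally
#'   `"DS"`.
#' @param line_no Line number used in error messages.
#' @param missing_genotypes `"error"` (default) rejects `./.`-style missing
#'   genotypes; `"allow"` stores them as `NA` alleles so that downstream
#'   eligibility filtering can skip the record.
#' @return A `variant_record`: site fields `chrom`, `pos`, `id`, `ref`,
#'   `alt` (character vector, one element per ALT allele), `qual`, `filter`,
#'   `info`, plus per-sample vectors `allele_a`, `allele_b` (integer),
#'   `phased` (logical) and `dosages` (numeric, or `NULL` when DS was not
#'   requested or not present in this record's FORMAT).
#' @export
parse_record <- function(line, n_samples, parse_fields = "GT",
                         line_no = NA_integer_,
                         missing_genotypes = c("error", "allow")) {
  missing_genotypes <- match.arg(missing_genotypes)
  parse_lines(line, n_samples, parse_fields, line_nos = line_no,
              n_workers = 1L, missing_genotypes = missing_genotypes)[[1]]
}

# Vectorised multi-line parser. Lines are split into n_workers contiguous
# chunks; chunk order restores file order whatever the completion order.
parse_lines <- function(lines, n_samples, parse_fields, line_nos,
                        n_workers = 1L,
                        missing_genotypes = "error") {
  if (length(line_nos) == 1L && length(lines) > 1L) {
    line_nos <- line_nos + seq_along(lines) - 1L
  }
  if (n_workers <= 1L || length(lines) < 2L * n_workers) {
    return(parse_chunk(lines, n_samples, parse_fields, line_nos,
                       missing_genotypes))
  }
  chunk_id <- sort(rep_len(seq_len(n_workers), length(lines)))
  idx <- split(seq_along(lines), chunk_id)
  results <- parallel::mclapply(idx, function(i) {
    tryCatch(
      parse_chunk(lines[i], n_samples, parse_fields, line_nos[i],
                  missing_genotypes),
      error = function(e) e)
  }, mc.cores = n_workers)
  # surface the first error in file order, as a serial read would
  for (r in results) if (inherits(r, "error")) stop(r)
  unlist(results, recursive = FALSE, use.names = FALSE)
}

parse_chunk <- function(lines, n_samples, parse_fields, line_nos,
                        missing_genotypes) {
  want_ds <- "DS" %in% parse_fields
  out <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    out[[k]] <- parse_one_line(lines[[k]], n_samples, want_ds, line_nos[[k]],
                               missing_genotypes)
  }
  out
}

parse_one_line <- function(line, n_samples, want_ds, line_no,
                           missing_genotypes) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(f) != 9L + n_samples) {
    stop("parse error at line ", line_no, ": expected ", 9L + n_samples,
         " tab-separated fields, found ", length(f), call. = FALSE)
  }
  pos <- suppressWarnings(as.integer(f[2]))
  if (is.na(pos)) {
    stop("parse error at line ", line_no, ": POS is not an integer: ",
         f[2], call. = FALSE)
  }
  alt <- strsplit(f[5], ",", fixed = TRUE)[[1]]
  fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
  gt_i <- match("GT", fmt)
  if (is.na(gt_i)) {
    stop("parse error at line ", line_no, ": FORMAT has no GT field (",
         f[9], ")", call. = FALSE)
  }
  ds_i <- if (want_ds) match("DS", fmt) else NA_integer_
  samples <- f[10:(9L + n_samples)]

  if (length(fmt) == 1L) {
    gt <- samples
    ds_tok <- NULL
  } else {
    parts <- strsplit(samples, ":", fixed = TRUE)
    npart <- lengths(parts)
    if (any(npart < gt_i)) {
      stop("parse error at line ", line_no,
           ": sample field has no GT value", call. = FALSE)
    }
    flat <- unlist(parts, use.names = FALSE)
    offset <- cumsum(c(0L, npart[-length(npart)]))
    gt <- flat[offset + gt_i]
    ds_tok <- if (!is.na(ds_i)) {
      if (any(npart < ds_i)) {
        stop("parse error at line ", line_no,
             ": FORMAT declares DS but a sample field lacks it",
             call. = FALSE)
      }
      flat[offset + ds_i]
    }
  }

  ok <- grepl("^(\\.|[0-9]+)[|/](\\.|[0-9]+)$", gt)
  if (!all(ok)) {
    stop("parse error at line ", line_no, ": malformed GT token \"",
         gt[which(!ok)[1]], "\" (expected allele[|/]allele)", call. = FALSE)
  }
  sep_at <- regexpr("[|/]", gt)
  a_tok <- substr(gt, 1L, sep_at - 1L)
  b_tok <- substr(gt, sep_at + 1L, nchar(gt))
  phased <- substr(gt, sep_at, sep_at) == "|"
  miss <- a_tok == "." | b_tok == "."
  if (any(miss) && missing_genotypes == "error") {
    stop("parse error at line ", line_no, ": missing genotype \"",
         gt[which(miss)[1]],
         "\" (haplotype compression needs complete phased data; ",
         "use the permissive mode to skip such records)", call. = FALSE)
  }
  allele_a <- suppressWarnings(as.integer(a_tok))
  allele_b <- suppressWarnings(as.integer(b_tok))
  hi <- pmax(allele_a, allele_b)
  if (any(!is.na(hi) & hi > length(alt))) {
    stop("parse error at line ", line_no, ": allele index ",
         max(hi, na.rm = TRUE), " exceeds the ", length(alt),
         " ALT allele(s)", call. = FALSE)
  }

  dosages <- NULL
  if (want_ds && !is.na(ds_i) && !is.null(ds_tok)) {
    dosages <- suppressWarnings(as.numeric(ds_tok))
    if (anyNA(dosages)) {
      stop("parse error at line ", line_no, ": DS token \"",
           ds_tok[which(is.na(dosages))[1]], "\" is not a number",
           call. = FALSE)
    }
  }

  structure(
    list(chrom = f[1], pos = pos, id = f[3], ref = f[4], alt = alt,
         qual = f[6], filter = f[7], info = f[8],
         allele_a = allele_a, allele_b = allele_b, phased = phased,
         dosages = dosages),
    class = "variant_record")
}

#' @export
print.variant_record <- function(x, ...) {
  gt <- paste0(x$allele_a, ifelse(x$phased, "|", "/"), x$allele_b)
  shown <- paste(utils::head(gt, 6L), collapse = " ")
  if (length(gt) > 6L) shown <- paste(shown, "...")
  cat(sprintf("%s:%d %s %s>%s GT[%d]: %s\n", x$chrom, x$pos, x$id, x$ref,
              paste(x$alt, collapse = ","), length(gt), shown))
  invisible(x)
}
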