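# Write a VCF from raw body lines with n samples named S001... .
write_toy_vcf <- function(body, n_samples, path = tempfile(fileext = ".vcf"),
                          format = "GT") {
  header <- c(
    "##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sprintf("S%03d", seq_len(n_samples))),
          collapse = "\t"))
  writeLines(c(header, body), path)
  path
}

vcf_line <- function(gt, pos = 100L, ref = "A", alt = "G", chrom = "22",
                     id = ".", format = "GT") {
  paste(c(chrom, pos, id, ref, alt, ".", "PASS", ".", format, gt),
        collapse = "\t")
}

# All GT strings of a VCF/converted file as a markers x samples matrix,
# read through the package stream (record by record).
read_gt_matrix <- function(path, parse_fields = "GT") {
  st <- open_vcf(path, parse_fields = parse_fields)
  on.exit(close_stream(st))
  read_header(st)
  rows <- list()
  repeat {
    r <- read_record(st)
    if (is.null(r)) break
    rows[[length(rows) + 1L]] <- paste0(r$allele_a,
                                        ifelse(r$phased, "|", "/"),
                                        r$allele_b)
  }
  do.call(rbind, rows)
}

# Site columns (chrom, pos, id, ref, alt) of every record.
read_sites <- function(path) {
  st <- open_vcf(path)
  on.exit(close_stream(st))
  read_header(st)
  rows <- list()
  repeat {
    r <- read_record(st)
    if (is.null(r)) break
    rows[[length(rows) + 1L]] <-
      data.frame(chrom = r$chrom, pos = r$pos, id = r$id, ref = r$ref,
                 alt = paste(r$alt, collapse = ","))
  }
  do.call(rbind, rows)
}

tmp_path <- function(ext) tempfile(fileext = ext)

# A pipeline source that hands out the items of a list, then NULL.
list_source <- function(items) {
  i <- 0L
  function() {
    i <<- i + 1L
    if (i > length(items)) NULL else items[[i]]
  }
}
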