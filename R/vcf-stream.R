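#' Open a VCF (or M3VCF) text stream
#'
#' Opens a plain-text or gzip-compressed VCF for streaming access. The stream
#' must have its header read with [read_header()] before any records can be
#' read. Only the GT and DS FORMAT fields are ever parsed; `parse_fields`
#' selects which of the two (GT is mandatory, DS optional).
#'
#' @param path Path to an existing, readable file.
#' @param file_mode `"GZ"` for gzip-compressed input, `"NORMAL"` for plain
#'   text, or `"AUTO"` (default) to sniff the gzip magic bytes.
#' @param parse_fields Character vector of FORMAT fields to parse; must
#'   contain `"GT"`, may additionally contain `"DS"`.
#' @return A `vcf_stream` object (an environment): fields `path`,
#'   `file_mode`, `parse_fields`, `header` (populated by [read_header()]).
#' @examples
#' vcf <- system.file("extdata", "toy.vcf", package = "m3vcf")
#' s <- open_vcf(vcf, "NORMAL", c("GT", "DS"))
#' hdr <- read_header(s)
#' rec <- read_record(s)
#' close_stream(s)
#' @seealso [read_header()], [read_record()], [read_block()], [close_stream()]
#' @export
open_vcf <- function(path, file_mode = "AUTO", parse_fields = "GT") {
  if (!is.character(path) || length(path) != 1L) {
    stop("path must be a single file path", call. = FALSE)
  }
  if (!"GT" %in% parse_fields) {
    stop("parse_fields must include \"GT\" (DS alone is not supported)",
         call. = FALSE)
  }
  bad <- setdiff(parse_fields, c("GT", "DS"))
  if (length(bad)) {
    stop("unsupported parse_fields: ", paste(bad, collapse = ", "),
         " (only GT and DS are parsed)", call. = FALSE)
  }
  if (!file.exists(path) || dir.exists(path)) {
    stop("the vcf file: ", path, ", open error (no such file)", call. = FALSE)
  }
  mode <- resolve_file_mode(path, file_mode)
  if (mode == "GZ" && !is_gzip_file(path)) {
    stop("the vcf file: ", path,
         ", format error (FILE_MODE_GZ but not a gzip stream)", call. = FALSE)
  }
  stream <- new.env(parent = emptyenv())
  stream$path <- path
  stream$file_mode <- mode
  stream$parse_fields <- unique(parse_fields)
  stream$con <- open_text_connection(path, mode)
  stream$header <- NULL
  stream$line_no <- 0L         # lines consumed so far (1-based numbering)
  stream$block_index <- 0L     # next block index handed out by read_block
  stream$is_open <- TRUE
  stream$missing_genotypes <- "error"
  class(stream) <- "vcf_stream"
  stream
}

# Pull up to n raw lines off the stream, maintaining the line counter.
stream_read_lines <- function(stream, n) {
  stopifnot(stream$is_open)
  lines <- readLines(stream$con, n = n, warn = FALSE)
  stream$line_no <- stream$line_no + length(lines)
  lines
}

#' Read and validate the header of an open stream
#'
#' Consumes all `##` meta lines verbatim plus the mandatory `#CHROM` column
#' line, leaving the stream positioned at the first data line.
#'
#' @param stream A `vcf_stream` from [open_vcf()] or [open_m3vcf()].
#' @return A `vcf_header` list: `meta_lines` (character vector of raw `##`
#'   lines), `sample_ids`, `n_samples`.
#' @export
read_header <- function(stream) {
  stopifnot(inherits(stream, "vcf_stream"))
  if (!is.null(stream$header)) {
    stop("header has already been read on this stream", call. = FALSE)
  }
  meta <- character()
  repeat {
    line <- stream_read_lines(stream, 1L)
    if (length(line) == 0L) {
      stop("malformed header in ", stream$path,
           ": end of file before a #CHROM column line", call. = FALSE)
    }
    if (startsWith(line, "##")) {
      meta <- c(meta, line)
      next
    }
    if (!startsWith(line, "#CHROM")) {
      stop("malformed header in ", stream$path, " at line ", stream$line_no,
           ": expected a #CHROM column line, got: ",
           substr(line, 1L, 60L), call. = FALSE)
    }
    break
  }
  cols <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(cols) < 10L) {
    stop("malformed header in ", stream$path,
         ": column line has ", length(cols),
         " fields; need 9 fixed columns plus at least one sample",
         call. = FALSE)
  }
  fixed <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
             "FORMAT")
  if (!identical(cols[1:9], fixed)) {
    stop("malformed header in ", stream$path,
         ": first nine columns must be ", paste(fixed, collapse = " "),
         call. = FALSE)
  }
  sample_ids <- cols[-(1:9)]
  if (anyDuplicated(sample_ids)) {
    stop("malformed header in ", stream$path, ": duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  header <- new_vcf_header(meta, sample_ids)
  stream$header <- header
  header
}

new_vcf_header <- function(meta_lines, sample_ids) {
  structure(
    list(meta_lines = meta_lines,
         sample_ids = sample_ids,
         n_samples = length(sample_ids)),
    class = "vcf_header")
}

#' @export
print.vcf_header <- function(x, ...) {
  cat("VCF header:", length(x$meta_lines), "meta lines,",
      x$n_samples, "samples\n")
  invisible(x)
}

#' Read the next variant record from a stream
#'
#' @param stream A `vcf_stream` whose header has been read.
#' @return A `variant_record`, or `NULL` at end of file.
#' @export
read_record <- function(stream) {
  stopifnot(inherits(stream, "vcf_stream"))
  if (is.null(stream$header)) {
    stop("read_header() must be called before reading records", call. = FALSE)
  }
  repeat {
    line <- stream_read_lines(stream, 1L)
    if (length(line) == 0L) return(NULL)
    if (nzchar(line)) break   # tolerate a trailing blank line
  }
  parse_record(line, stream$header$n_samples, stream$parse_fields,
               line_no = stream$line_no,
               missing_genotypes = stream$missing_genotypes)
}

#' Read a block of consecutive records, parsing across workers
#'
#' Reads up to `num_lines` raw lines serially, then parses them across
#' `n_workers` contiguous chunks. Chunk results are reassembled in file
#' order, so output is identical for every worker count.
#'
#' @param stream A `vcf_stream` whose header has been read.
#' @param num_lines Maximum records per block (>= 1).
#' @param n_workers Parse workers (>= 1; 1 = serial).
#' @return A `genotype_block` (fields `records`, `numDataLines`,
#'   `block_index`), or `NULL` at end of file.
#' @export
read_block <- function(stream, num_lines, n_workers = 1L) {
  stopifnot(inherits(stream, "vcf_stream"))
  if (is.null(stream$header)) {
    stop("read_header() must be called before reading records", call. = FALSE)
  }
  num_lines <- as.integer(num_lines)
  n_workers <- as.integer(n_workers)
  if (is.na(num_lines) || num_lines < 1L) {
    stop("num_lines must be >= 1", call. = FALSE)
  }
  if (is.na(n_workers) || n_workers < 1L) {
    stop("n_workers must be >= 1", call. = FALSE)
  }
  first_line_no <- stream$line_no + 1L
  lines <- stream_read_lines(stream, num_lines)
  lines_kept <- nzchar(lines)
  line_nos <- first_line_no + seq_along(lines) - 1L
  lines <- lines[lines_kept]
  line_nos <- line_nos[lines_kept]
  if (length(lines) == 0L) return(NULL)
  records <- parse_lines(lines, stream$header$n_samples, stream$parse_fields,
                         line_nos = line_nos, n_workers = n_workers,
                         missing_genotypes = stream$missing_genotypes)
  block <- new_genotype_block(records, stream$block_index)
  stream$block_index <- stream$block_index + 1L
  block
}

new_genotype_block <- function(records, block_index) {
  structure(
    list(records = records,
         numDataLines = length(records),
         block_index = as.integer(block_index)),
    class = "genotype_block")
}

#' @export
print.genotype_block <- function(x, ...) {
  n <- if (x$numDataLines) length(x$records[[1]]$allele_a) else 0L
  cat("genotype block", x$block_index, "-", x$numDataLines,
      "records x", n, "samples\n")
  invisible(x)
}

#' Close a stream; releasing records and blocks
#'
#' `close_stream()` closes the underlying connection (a second call is a
#' no-op). `release_record()` and `release_block()` exist for API symmetry
#' with explicit-deallocation interfaces; in R the garbage collector owns
#' the memory, so they simply return `NULL` invisibly.
#'
#' @param stream A `vcf_stream`.
#' @export
close_stream <- function(stream) {
  stopifnot(inherits(stream, "vcf_stream"))
  if (isTRUE(stream$is_open)) {
    close(stream$con)
    stream$is_open <- FALSE
  }
  invisible(NULL)
}

#' @rdname close_stream
#' @param record A `variant_record`.
#' @export
release_record <- function(record) invisible(NULL)

#' @rdname close_stream
#' @param block A `genotype_block`.
#' @export
release_block <- function(block) invisible(NULL)
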