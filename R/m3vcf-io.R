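# M3VCF dialect (one text stream, optionally gzip-wrapped):
#   header : the source VCF's "##" lines + "##M3VCF.version=<tag>" +
#            the usual "#CHROM ... FORMAT s1...sN" column line
#   block  : 1 block-header line
#              CHROM, POS of first marker, ID "<BLOCK:first-last>" (1-based
#              global marker indices), REF ".", ALT ".", QUAL ".",
#              FILTER ".", INFO "VARIANTS=l;REPS=u", empty FORMAT column,
#              then N sample columns "a|b" = the 0-based representative
#              indices of the sample's two haplotypes
#            followed by l variant lines
#              CHROM, POS, ID, REF, ALT, ".", ".", ".", then ONE column:
#              a u-character 0/1 string, character r = allele of
#              representative r at this marker

M3VCF_VERSION_TAG <- "m3vcf-r/0.1"

#' Open an M3VCF stream for reading
#'
#' @inheritParams open_vcf
#' @return A `vcf_stream`; read its header with [read_header()], then blocks
#'   with [read_m3vcf_block()].
#' @export
open_m3vcf <- function(path, file_mode = "AUTO") {
  if (!file.exists(path) || dir.exists(path)) {
    stop("the m3vcf file: ", path, ", open error (no such file)",
         call. = FALSE)
  }
  mode <- resolve_file_mode(path, file_mode)
  if (mode == "GZ" && !is_gzip_file(path)) {
    stop("the m3vcf file: ", path,
         ", format error (FILE_MODE_GZ but not a gzip stream)",
         call. = FALSE)
  }
  stream <- new.env(parent = emptyenv())
  stream$path <- path
  stream$file_mode <- mode
  stream$parse_fields <- "GT"
  stream$con <- open_text_connection(path, mode)
  stream$header <- NULL
  stream$line_no <- 0L
  stream$block_index <- 0L
  stream$is_open <- TRUE
  stream$missing_genotypes <- "error"
  class(stream) <- "vcf_stream"
  stream
}

# Header emitted at the top of every M3VCF file. Any stale version tags from
# a previous round trip are dropped before appending the current one.
write_m3vcf_header <- function(con, header) {
  meta <- header$meta_lines
  meta <- meta[!startsWith(meta, "##M3VCF.version=")]
  writeLines(c(meta, paste0("##M3VCF.version=", M3VCF_VERSION_TAG),
               vcf_column_line(header)), con)
}

#' Serialize one haplotype block
#'
#' @param hblock A `haplotype_block`; its `first_idx`/`last_idx` fields
#'   (1-based global marker indices) must be set, as the writer embeds them
#'   in the block-header ID.
#' @param con An open writable text connection (header already written).
#' @return Invisibly, the number of lines written (1 + l).
#' @seealso [read_m3vcf_block()]
#' @export
write_m3vcf_block <- function(hblock, con) {
  stopifnot(inherits(hblock, "haplotype_block"))
  sites <- hblock$variant_sites
  l <- nrow(sites)
  u <- hblock$n_reps
  if (is.na(hblock$first_idx) || is.na(hblock$last_idx)) {
    stop("haplotype block has no global marker indices; set first_idx and ",
         "last_idx before writing", call. = FALSE)
  }
  map <- hblock$hap_map
  even <- seq(1L, length(map), by = 2L)
  sample_cols <- paste0(map[even], "|", map[even + 1L])
  head_line <- paste(
    c(hblock$chrom, sites$pos[1],
      sprintf("<BLOCK:%d-%d>", hblock$first_idx, hblock$last_idx),
      ".", ".", ".", ".",
      sprintf("VARIANTS=%d;REPS=%d", l, u),
      "",                                   # empty FORMAT column
      sample_cols),
    collapse = "\t")
  hap_strings <- do.call(paste0, lapply(seq_len(u), function(r) {
    hblock$rep_haplotypes[r, ]
  }))
  variant_lines <- paste(sites$chrom, sites$pos, sites$id, sites$ref,
                         sites$alt, ".", ".", ".", hap_strings, sep = "\t")
  writeLines(c(head_line, variant_lines), con)
  invisible(1L + l)
}

#' Read the next haplotype block from an M3VCF stream
#'
#' @param stream A `vcf_stream` from [open_m3vcf()] whose header has been
#'   read.
#' @return A `haplotype_block` (with `first_idx`/`last_idx` recovered from
#'   the block-header ID), or `NULL` at end of file. A file truncated
#'   mid-block raises a format error rather than returning silently.
#' @export
read_m3vcf_block <- function(stream) {
  stopifnot(inherits(stream, "vcf_stream"))
  if (is.null(stream$header)) {
    stop("read_header() must be called before reading blocks", call. = FALSE)
  }
  repeat {
    line <- stream_read_lines(stream, 1L)
    if (length(line) == 0L) return(NULL)
    if (nzchar(line)) break
  }
  n_samples <- stream$header$n_samples
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(f) != 9L + n_samples) {
    stop("m3vcf format error at line ", stream$line_no,
         ": block header has ", length(f), " fields, expected ",
         9L + n_samples, call. = FALSE)
  }
  idx <- regmatches(f[3], regexec("^<BLOCK:([0-9]+)-([0-9]+)>$", f[3]))[[1]]
  if (length(idx) != 3L) {
    stop("m3vcf format error at line ", stream$line_no,
         ": malformed block ID \"", f[3], "\"", call. = FALSE)
  }
  info <- regmatches(f[8],
                     regexec("^VARIANTS=([0-9]+);REPS=([0-9]+)$", f[8]))[[1]]
  if (length(info) != 3L) {
    stop("m3vcf format error at line ", stream$line_no,
         ": malformed block INFO \"", f[8], "\"", call. = FALSE)
  }
  l <- as.integer(info[2])
  u <- as.integer(info[3])
  map_tok <- f[10:(9L + n_samples)]
  ok <- grepl("^[0-9]+\\|[0-9]+$", map_tok)
  if (!all(ok)) {
    stop("m3vcf format error at line ", stream$line_no,
         ": malformed haplotype map entry \"", map_tok[which(!ok)[1]],
         "\"", call. = FALSE)
  }
  bar <- regexpr("|", map_tok, fixed = TRUE)
  hap_map <- integer(2L * n_samples)
  even <- seq(1L, 2L * n_samples, by = 2L)
  hap_map[even] <- as.integer(substr(map_tok, 1L, bar - 1L))
  hap_map[even + 1L] <- as.integer(substr(map_tok, bar + 1L,
                                          nchar(map_tok)))
  if (any(hap_map >= u)) {
    stop("m3vcf format error at line ", stream$line_no,
         ": haplotype map index ", max(hap_map), " >= REPS=", u,
         call. = FALSE)
  }

  vlines <- stream_read_lines(stream, l)
  if (length(vlines) < l) {
    stop("m3vcf format error: file truncated inside block starting at ",
         f[1], ":", f[2], " (expected ", l, " variant lines, found ",
         length(vlines), ")", call. = FALSE)
  }
  vf <- strsplit(vlines, "\t", fixed = TRUE)
  if (any(lengths(vf) != 9L)) {
    bad <- which(lengths(vf) != 9L)[1]
    stop("m3vcf format error at line ", stream$line_no - l + bad,
         ": variant line has ", lengths(vf)[bad], " fields, expected 9",
         call. = FALSE)
  }
  vm <- matrix(unlist(vf), nrow = 9L)
  hap_strings <- vm[9, ]
  if (any(nchar(hap_strings) != u)) {
    bad <- which(nchar(hap_strings) != u)[1]
    stop("m3vcf format error at line ", stream$line_no - l + bad,
         ": haplotype string length ", nchar(hap_strings[bad]),
         " != REPS=", u, call. = FALSE)
  }
  if (any(grepl("[^01]", hap_strings))) {
    stop("m3vcf format error: haplotype strings must be over {0,1}",
         call. = FALSE)
  }
  # u x l matrix: column j from the j-th variant line's string
  reps <- matrix(as.integer(unlist(strsplit(hap_strings, "", fixed = FALSE))),
                 nrow = u)
  sites <- data.frame(chrom = vm[1, ],
                      pos = as.integer(vm[2, ]),
                      id = vm[3, ], ref = vm[4, ], alt = vm[5, ],
                      stringsAsFactors = FALSE)
  new_haplotype_block(
    chrom = f[1], variant_sites = sites, n_samples = n_samples,
    rep_haplotypes = reps, hap_map = hap_map,
    first_idx = as.integer(idx[2]), last_idx = as.integer(idx[3]))
}
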