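#' Test whether a variant record can enter an M3VCF haplotype block
#'
#' M3VCF stores phased haplotypes over bi-allelic SNPs only. A record is
#' eligible iff it has exactly one ALT allele, REF and ALT are each a single
#' base in A/C/G/T, no genotype is missing, every genotype is phased, and
#' all allele indices are 0 or 1. The first failing condition (checked in
#' that order) is reported as the reason.
#'
#' @param record A `variant_record`.
#' @return A list `list(eligible = logical, reason = character)`; `reason`
#'   is `NA` for eligible records, otherwise one of `"multi-allelic"`,
#'   `"not a SNP"`, `"missing genotype"`, `"unphased"`,
#'   `"allele out of range"`.
#' @export
is_eligible <- function(record) {
  stopifnot(inherits(record, "variant_record"))
  reason <- eligibility_reason(record)
  list(eligible = is.na(reason), reason = reason)
}

eligibility_reason <- function(record) {
  if (length(record$alt) != 1L) return("multi-allelic")
  if (nchar(record$ref) != 1L || nchar(record$alt) != 1L ||
      !record$ref %in% c("A", "C", "G", "T") ||
      !record$alt %in% c("A", "C", "G", "T")) {
    return("not a SNP")
  }
  if (anyNA(record$allele_a) || anyNA(record$allele_b)) {
    return("missing genotype")
  }
  if (!all(record$phased)) return("unphased")
  if (any(record$allele_a > 1L) || any(record$allele_b > 1L)) {
    return("allele out of range")
  }
  NA_character_
}

#' Compress a genotype block into an M3VCF haplotype block
#'
#' Builds the 2N haplotype vectors of a block of l consecutive bi-allelic
#' SNPs (sample s contributes haplotype 2s from `allele_a` and haplotype
#' 2s+1 from `allele_b`, alleles taken across markers in file order),
#' deduplicates them, and stores only the u unique (representative)
#' haplotypes plus a length-2N index map. Representatives are numbered by
#' first occurrence over the haplotype scan order, so the first map entry is
#' always 0. The transform is lossless for GT: [decompress_block()] restores
#' every genotype exactly.
#'
#' @param block A `genotype_block` whose records are all eligible
#'   (see [is_eligible()]) and share one sample count.
#' @return A `haplotype_block`: `chrom`, `variant_sites` (data.frame with
#'   columns chrom, pos, id, ref, alt), `n_samples`, `n_reps` (u),
#'   `rep_haplotypes` (u x l integer 0/1 matrix), `hap_map` (integer vector
#'   of length 2N with 0-based representative indices).
#' @export
compress_block <- function(block) {
  stopifnot(inherits(block, "genotype_block"))
  records <- block$records
  l <- length(records)
  if (l == 0L) stop("cannot compress an empty block", call. = FALSE)
  n_samples <- length(records[[1]]$allele_a)
  for (rec in records) {
    if (length(rec$allele_a) != n_samples) {
      stop("codec error at ", rec$chrom, ":", rec$pos,
           ": sample count differs within the block", call. = FALSE)
    }
    reason <- eligibility_reason(rec)
    if (!is.na(reason)) {
      stop("codec error at ", rec$chrom, ":", rec$pos,
           ": record is not compressible (", reason, ")", call. = FALSE)
    }
  }

  # 2N x l haplotype matrix: rows interleave each sample's two haplotypes.
  mat_a <- vapply(records, `[[`, integer(n_samples), "allele_a")
  mat_b <- vapply(records, `[[`, integer(n_samples), "allele_b")
  mat_a <- matrix(mat_a, nrow = n_samples)
  mat_b <- matrix(mat_b, nrow = n_samples)
  H <- matrix(0L, nrow = 2L * n_samples, ncol = l)
  H[seq(1L, 2L * n_samples, by = 2L), ] <- mat_a
  H[seq(2L, 2L * n_samples, by = 2L), ] <- mat_b

  keys <- do.call(paste0, lapply(seq_len(l), function(j) H[, j]))
  hap_map <- match(keys, unique(keys)) - 1L
  reps <- H[!duplicated(keys), , drop = FALSE]

  sites <- data.frame(
    chrom = vapply(records, `[[`, character(1), "chrom"),
    pos = vapply(records, `[[`, integer(1), "pos"),
    id = vapply(records, `[[`, character(1), "id"),
    ref = vapply(records, `[[`, character(1), "ref"),
    alt = vapply(records, function(r) r$alt[[1]], character(1)),
    stringsAsFactors = FALSE)

  new_haplotype_block(
    chrom = records[[1]]$chrom, variant_sites = sites,
    n_samples = n_samples, rep_haplotypes = reps, hap_map = hap_map)
}

new_haplotype_block <- function(chrom, variant_sites, n_samples,
                                rep_haplotypes, hap_map,
                                first_idx = NA_integer_,
                                last_idx = NA_integer_) {
  structure(
    list(chrom = chrom, variant_sites = variant_sites,
         n_samples = as.integer(n_samples),
         n_reps = nrow(rep_haplotypes),
         rep_haplotypes = rep_haplotypes,
         hap_map = as.integer(hap_map),
         first_idx = as.integer(first_idx),
         last_idx = as.integer(last_idx)),
    class = "haplotype_block")
}

#' @export
print.haplotype_block <- function(x, ...) {
  cat(sprintf(
    "haplotype block %s:%d  %d markers, %d samples, u = %d of %d haplotypes\n",
    x$chrom, x$variant_sites$pos[1], nrow(x$variant_sites), x$n_samples,
    x$n_reps, 2L * x$n_samples))
  invisible(x)
}

#' Decompress an M3VCF haplotype block back to genotypes
#'
#' Inverse of [compress_block()]: for marker j and sample s, `allele_a` is
#' the allele of representative `hap_map[2s]` at j and `allele_b` that of
#' `hap_map[2s+1]`. All genotypes come back phased; dosages are not emitted
#' (the format carries haplotypes only).
#'
#' @param hblock A `haplotype_block`.
#' @return A `genotype_block` with `block_index` 0.
#' @export
decompress_block <- function(hblock) {
  stopifnot(inherits(hblock, "haplotype_block"))
  u <- hblock$n_reps
  map <- hblock$hap_map
  if (length(map) != 2L * hblock$n_samples) {
    stop("corrupt block: hap_map length ", length(map),
         " != 2 x ", hblock$n_samples, " samples", call. = FALSE)
  }
  if (any(map < 0L) || any(map >= u)) {
    stop("corrupt block: hap_map index out of range [0, ", u, ")",
         call. = FALSE)
  }
  A <- hblock$rep_haplotypes[map + 1L, , drop = FALSE]   # 2N x l
  odd <- seq(1L, nrow(A), by = 2L)
  sites <- hblock$variant_sites
  records <- lapply(seq_len(nrow(sites)), function(j) {
    structure(
      list(chrom = sites$chrom[j], pos = sites$pos[j], id = sites$id[j],
           ref = sites$ref[j], alt = sites$alt[j],
           qual = ".", filter = ".", info = ".",
           allele_a = A[odd, j], allele_b = A[odd + 1L, j],
           phased = rep(TRUE, hblock$n_samples), dosages = NULL),
      class = "variant_record")
  })
  new_genotype_block(records, 0L)
}
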