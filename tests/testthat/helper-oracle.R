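# Brute-force first-occurrence deduplication: scans the 2N haplotype rows
# left to right, comparing each against the representatives found so far
# with identical(). Independent of the match()/unique() path in the codec.
oracle_dedup <- function(H) {
  reps <- list()
  map <- integer(nrow(H))
  for (i in seq_len(nrow(H))) {
    found <- NA_integer_
    for (r in seq_along(reps)) {
      if (identical(reps[[r]], H[i, ])) {
        found <- r
        break
      }
    }
    if (is.na(found)) {
      reps[[length(reps) + 1L]] <- H[i, ]
      found <- length(reps)
    }
    map[i] <- found - 1L
  }
  list(u = length(reps), map = map,
       reps = do.call(rbind, reps))
}

# Build a variant_record directly from allele vectors (bypasses the text
# parser so codec tests do not depend on it).
make_record <- function(allele_a, allele_b, phased = TRUE,
                        chrom = "22", pos = 100L, id = ".",
                        ref = "A", alt = "G", dosages = NULL) {
  n <- length(allele_a)
  structure(
    list(chrom = chrom, pos = as.integer(pos), id = id, ref = ref,
         alt = alt, qual = ".", filter = ".", info = ".",
         allele_a = as.integer(allele_a), allele_b = as.integer(allele_b),
         phased = rep_len(phased, n), dosages = dosages),
    class = "variant_record")
}

# Genotype block from a 2N x l haplotype matrix (rows interleaved per
# sample, as the codec lays them out).
block_from_hapmat <- function(H, start_pos = 100L) {
  n2 <- nrow(H)
  stopifnot(n2 %% 2 == 0)
  odd <- seq(1L, n2, by = 2L)
  records <- lapply(seq_len(ncol(H)), function(j) {
    make_record(H[odd, j], H[odd + 1L, j],
                pos = start_pos + (j - 1L) * 10L, id = paste0("M", j))
  })
  m3vcf:::new_genotype_block(records, 0L)
}

random_hapmat <- function(n_haps, l) {
  matrix(sample(0:1, n_haps * l, replace = TRUE), nrow = n_haps)
}
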