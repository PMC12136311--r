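#' Specification for a synthetic phased VCF
#'
#' Describes a seeded synthetic cohort of phased diploid genotypes over
#' bi-allelic SNPs. Haplotypes are drawn with replacement from a founder
#' pool of `n_founder_haplotypes` haplotypes, so the haplotype redundancy
#' that block compression exploits is present and tunable: the unique
#' count u within any block is at most the pool size. Per-marker minor
#' allele frequencies are drawn uniformly from `maf_range`. Fractions of
#' records can be made deliberately invalid -- multi-allelic, indel
#' (non-SNP), containing a missing genotype, or containing an unphased
#' genotype -- with exactly one defect per invalid record so the rejection
#' reason is unambiguous.
#'
#' @param n_samples,n_markers Cohort dimensions (>= 1).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @param maf_range Two-element range within (0, 0.5] for per-marker minor
#'   allele frequencies.
#' @param n_founder_haplotypes Founder pool size (>= 1); use a large value
#'   (e.g. `2 * n_samples` or more with `iid = TRUE`) for low-redundancy
#'   data.
#' @param iid If `TRUE`, ignore the founder pool and draw every allele
#'   independently -- the worst case for compression (u close to 2N).
#' @param with_ds Emit a DS dosage equal to the genotype's ALT count plus
#'   `ds_noise`-bounded uniform noise, clipped to `[0, 2]`.
#' @param ds_noise Half-width of the dosage noise.
#' @param frac_multiallelic,frac_indel,frac_missing,frac_unphased
#'   Fractions of markers given the corresponding defect; their sum must
#'   be < 1.
#' @param chrom,start_pos,pos_step Site coordinates; positions are
#'   `start_pos + (0:(n_markers-1)) * pos_step`, strictly increasing.
#' @return A `vcf_fixture_spec` list.
#' @export
vcf_fixture_spec <- function(n_samples, n_markers, seed = 1L,
                             maf_range = c(0.05, 0.5),
                             n_founder_haplotypes = 8L,
                             iid = FALSE,
                             with_ds = FALSE, ds_noise = 0,
                             frac_multiallelic = 0, frac_indel = 0,
                             frac_missing = 0, frac_unphased = 0,
                             chrom = "22", start_pos = 16050000L,
                             pos_step = 100L) {
  stopifnot(n_samples >= 1, n_markers >= 1, n_founder_haplotypes >= 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2], ds_noise >= 0, pos_step >= 1)
  fracs <- c(multiallelic = frac_multiallelic, indel = frac_indel,
             missing = frac_missing, unphased = frac_unphased)
  if (any(fracs < 0) || any(fracs >= 1) || sum(fracs) >= 1) {
    stop("defect fractions must each lie in [0, 1) and sum to < 1",
         call. = FALSE)
  }
  structure(
    list(n_samples = as.integer(n_samples),
         n_markers = as.integer(n_markers),
         seed = as.integer(seed), maf_range = maf_range,
         n_founder_haplotypes = as.integer(n_founder_haplotypes),
         iid = isTRUE(iid), with_ds = isTRUE(with_ds), ds_noise = ds_noise,
         fracs = fracs, chrom = as.character(chrom),
         start_pos = as.integer(start_pos),
         pos_step = as.integer(pos_step)),
    class = "vcf_fixture_spec")
}

#' Generate a synthetic phased VCF file
#'
#' Writes a valid VCF per the given [vcf_fixture_spec()] and, next to it, a
#' JSON manifest of ground truth for assertions: which records are
#' ineligible and why, plus the founder haplotype pool. Generation is
#' byte-deterministic for a given spec and leaves the caller's RNG state
#' untouched.
#'
#' @param spec A `vcf_fixture_spec`.
#' @param path Output path.
#' @param file_mode `"GZ"`, `"NORMAL"` or `"AUTO"` (suffix).
#' @param manifest_path Where to write the JSON manifest; `NULL` for
#'   `<path>.manifest.json`, `NA` to skip writing it.
#' @return Invisibly, the manifest list: `n_markers`, `n_eligible`,
#'   `n_invalid_by_reason` (named counts), `invalid_pos` (positions by
#'   reason), `founder_pool` (pool x markers 0/1 matrix; absent in iid
#'   mode), `sample_ids`.
#' @export
generate_vcf <- function(spec, path, file_mode = "AUTO",
                         manifest_path = NULL) {
  stopifnot(inherits(spec, "vcf_fixture_spec"))
  with_seed(spec$seed, {
    n <- spec$n_samples
    m <- spec$n_markers
    pos <- spec$start_pos + (seq_len(m) - 1L) * spec$pos_step
    maf <- stats::runif(m, spec$maf_range[1], spec$maf_range[2])
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, m, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L),
                  character(1))

    if (spec$iid) {
      pool <- NULL
      H <- matrix(stats::rbinom(2L * n * m, 1L, rep(maf, each = 2L * n)),
                  nrow = 2L * n)
    } else {
      k <- spec$n_founder_haplotypes
      pool <- matrix(stats::rbinom(k * m, 1L, rep(maf, each = k)),
                     nrow = k)
      draw <- sample.int(k, 2L * n, replace = TRUE)
      H <- pool[draw, , drop = FALSE]
    }
    a_rows <- seq(1L, 2L * n, by = 2L)
    b_rows <- a_rows + 1L

    # assign defects to disjoint marker sets, one defect per record
    n_defect <- vapply(spec$fracs, function(f) as.integer(round(f * m)),
                       integer(1))
    if (sum(n_defect) >= m) stop("defect fractions leave no valid markers",
                                 call. = FALSE)
    shuffled <- sample.int(m)
    defect <- rep(NA_character_, m)
    at <- 0L
    reasons <- c(multiallelic = "multi-allelic", indel = "not a SNP",
                 missing = "missing genotype", unphased = "unphased")
    for (d in names(n_defect)) {
      if (n_defect[[d]] > 0L) {
        defect[shuffled[at + seq_len(n_defect[[d]])]] <- reasons[[d]]
        at <- at + n_defect[[d]]
      }
    }

    sample_ids <- sprintf("S%03d", seq_len(n))
    lines <- character(m)
    fmt <- if (spec$with_ds) "GT:DS" else "GT"
    for (j in seq_len(m)) {
      a <- H[a_rows, j]
      b <- H[b_rows, j]
      gt <- paste0(a, "|", b)
      alt_j <- alt[j]
      ref_j <- ref[j]
      dj <- defect[j]
      if (!is.na(dj)) {
        if (dj == "multi-allelic") {
          alt_j <- paste(alt_j, sample(setdiff(bases, c(ref_j, alt_j)), 1L),
                         sep = ",")
        } else if (dj == "not a SNP") {
          alt_j <- paste0(alt_j, sample(bases, 1L))
        } else if (dj == "missing genotype") {
          gt[sample.int(n, 1L)] <- ".|."
        } else if (dj == "unphased") {
          s <- sample.int(n, 1L)
          gt[s] <- paste0(a[s], "/", b[s])
        }
      }
      cols <- gt
      if (spec$with_ds) {
        ds <- a + b
        if (spec$ds_noise > 0) {
          ds <- pmin(2, pmax(0, ds + stats::runif(n, -spec$ds_noise,
                                                  spec$ds_noise)))
        }
        cols <- paste0(gt, ":", format_ds(ds))
      }
      lines[j] <- paste(c(spec$chrom, pos[j], sprintf("M%05d", j), ref_j,
                          alt_j, ".", "PASS", ".", fmt, cols),
                        collapse = "\t")
    }

    header <- c("##fileformat=VCFv4.2",
                sprintf("##source=m3vcf synthetic fixture seed=%d",
                        spec$seed),
                paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", sample_ids),
                      collapse = "\t"))
    mode <- resolve_file_mode(path, file_mode, for_write = TRUE)
    con <- open_text_connection(path, mode, write = TRUE)
    writeLines(c(header, lines), con)
    close(con)

    by_reason <- table(defect[!is.na(defect)])
    manifest <- list(
      n_markers = m,
      n_eligible = m - sum(n_defect),
      n_invalid_by_reason = stats::setNames(as.integer(by_reason),
                                            names(by_reason)),
      invalid_pos = lapply(split(pos[!is.na(defect)],
                                 defect[!is.na(defect)]), as.integer),
      founder_pool = if (!is.null(pool)) unname(pool),
      sample_ids = sample_ids,
      seed = spec$seed)
    if (is.null(manifest_path) || !is.na(manifest_path)) {
      mp <- manifest_path %||% paste0(path, ".manifest.json")
      jsonlite::write_json(manifest, mp, auto_unbox = FALSE, digits = NA,
                           null = "null")
    }
    invisible(manifest)
  })
}

#' Gzip a plain-text fixture in place
#'
#' @param path Path to an existing plain-text file.
#' @param out Output path; defaults to `<path>.gz`.
#' @return The output path.
#' @export
gzip_fixture <- function(path, out = paste0(path, ".gz")) {
  stopifnot(file.exists(path))
  inc <- file(path, "rb")
  onc <- gzfile(out, "wb")
  repeat {
    chunk <- readBin(inc, "raw", n = 1048576L)
    if (length(chunk) == 0L) break
    writeBin(chunk, onc)
  }
  close(inc)
  close(onc)
  out
}
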