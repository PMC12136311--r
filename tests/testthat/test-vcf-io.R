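test_that("open_vcf validates path, mode and parse fields", {
  expect_error(open_vcf(tempfile("absent-")), "open error")
  p <- write_toy_vcf(vcf_line("0|1"), 1)
  expect_error(open_vcf(p, parse_fields = "DS"), "must include \"GT\"")
  expect_error(open_vcf(p, parse_fields = c("GT", "GP")), "unsupported")
  expect_error(open_vcf(p, file_mode = "GZ"), "format error")
  s <- open_vcf(p, "NORMAL", c("GT", "DS"))
  expect_s3_class(s, "vcf_stream")
  expect_identical(s$file_mode, "NORMAL")
  close_stream(s)
})

test_that("read_header captures meta lines and samples, rejects bad headers", {
  p <- tmp_path(".vcf")
  writeLines(c("##fileformat=VCFv4.2", "##contig=<ID=22>",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", "s1", "s2"),
                     collapse = "\t"),
               vcf_line(c("0|1", "1|1"))), p)
  s <- open_vcf(p)
  h <- read_header(s)
  expect_identical(h$n_samples, 2L)
  expect_identical(h$sample_ids, c("s1", "s2"))
  expect_identical(h$meta_lines,
                   c("##fileformat=VCFv4.2", "##contig=<ID=22>"))
  expect_error(read_header(s), "already been read")
  close_stream(s)

  # duplicate sample ids
  p2 <- tmp_path(".vcf")
  writeLines(c("##x=1",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", "s1", "s1"),
                     collapse = "\t")), p2)
  s2 <- open_vcf(p2)
  expect_error(read_header(s2), "duplicate sample ids")
  close_stream(s2)

  # first non-## line is not a #CHROM line
  p3 <- tmp_path(".vcf")
  writeLines(c("##x=1", "CHROM\tPOS"), p3)
  s3 <- open_vcf(p3)
  expect_error(read_header(s3), "expected a #CHROM")
  close_stream(s3)

  # zero sample columns
  p4 <- tmp_path(".vcf")
  writeLines(c("##x=1",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT"), collapse = "\t")), p4)
  s4 <- open_vcf(p4)
  expect_error(read_header(s4), "at least one sample")
  close_stream(s4)
})

test_that("parse_record extracts GT and DS and skips other FORMAT fields", {
  r <- parse_record("22\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0|1\t1|1", 2)
  expect_identical(r$allele_a, c(0L, 1L))
  expect_identical(r$allele_b, c(1L, 1L))
  expect_true(all(r$phased))
  expect_null(r$dosages)
  expect_identical(r$pos, 100L)

  r2 <- parse_record("22\t100\t.\tA\tG\t.\tPASS\t.\tGT:DS\t0|1:1.0\t1|1:2",
                     2, c("GT", "DS"))
  expect_identical(r2$dosages, c(1, 2))

  # DS present in FORMAT but not requested -> not stored
  r3 <- parse_record("22\t100\t.\tA\tG\t.\tPASS\t.\tGT:DS\t0|1:1.0\t1|1:2",
                     2, "GT")
  expect_null(r3$dosages)

  # GT not in first FORMAT position
  r4 <- parse_record("22\t100\t.\tA\tG\t.\tPASS\t.\tDS:GT\t1.0:0|1\t2:1|1",
                     2, c("GT", "DS"))
  expect_identical(r4$allele_a, c(0L, 1L))
  expect_identical(r4$dosages, c(1, 2))

  # multi-allelic parses; eligibility is decided downstream
  r5 <- parse_record("22\t100\t.\tA\tG,T\t.\tPASS\t.\tGT\t0|2\t1|1", 2)
  expect_length(r5$alt, 2)
  expect_identical(r5$allele_b, c(2L, 1L))

  # unphased parses with phased = FALSE
  r6 <- parse_record("22\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t1|1", 2)
  expect_identical(r6$phased, c(FALSE, TRUE))
})

test_that("parse_record rejects malformed lines with the line number", {
  expect_error(parse_record("22\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0|1", 2,
                            line_no = 7L),
               "line 7.*expected 11.*found 10")
  expect_error(parse_record("22\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0|x\t1|1", 2,
                            line_no = 3L),
               "line 3.*malformed GT")
  expect_error(parse_record("22\t100\t.\tA\tG\t.\tPASS\t.\tGT:DS\t0|1:z\t1|1:1",
                            2, c("GT", "DS"), line_no = 4L),
               "line 4.*DS token.*not a number")
  expect_error(parse_record("22\t100\t.\tA\tG\t.\tPASS\t.\tGT\t./.\t1|1", 2,
                            line_no = 5L),
               "line 5.*missing genotype")
  # permissive mode stores missing genotypes as NA alleles
  r <- parse_record("22\t100\t.\tA\tG\t.\tPASS\t.\tGT\t./.\t1|1", 2,
                    missing_genotypes = "allow")
  expect_true(is.na(r$allele_a[1]) && is.na(r$allele_b[1]))
  expect_identical(r$allele_a[2], 1L)
  # allele index beyond the ALT list
  expect_error(parse_record("22\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0|2\t1|1", 2,
                            line_no = 9L),
               "line 9.*allele index 2 exceeds")
})

test_that("read_record enumerates every data line exactly once", {
  p <- write_toy_vcf(c(vcf_line("0|1", pos = 100),
                       vcf_line("1|1", pos = 200),
                       vcf_line("0|0", pos = 300)), 1)
  s <- open_vcf(p)
  read_header(s)
  recs <- list(read_record(s), read_record(s), read_record(s))
  expect_identical(vapply(recs, `[[`, integer(1), "pos"),
                   c(100L, 200L, 300L))
  expect_null(read_record(s))
  expect_null(read_record(s))
  close_stream(s)

  # empty body -> immediate EOF
  p2 <- write_toy_vcf(character(), 1)
  s2 <- open_vcf(p2)
  read_header(s2)
  expect_null(read_record(s2))
  close_stream(s2)

  # corrupt second line: first record fine, second raises with its line no
  p3 <- write_toy_vcf(c(vcf_line("0|1"), "22\tbroken"), 1)
  s3 <- open_vcf(p3)
  read_header(s3)
  expect_silent(read_record(s3))
  expect_error(read_record(s3), "line 4")
  close_stream(s3)
})

test_that("read_block partitions the file and matches the serial read", {
  spec <- vcf_fixture_spec(n_samples = 4, n_markers = 25, seed = 11)
  p <- tmp_path(".vcf")
  generate_vcf(spec, p, manifest_path = NA)
  s <- open_vcf(p)
  read_header(s)
  sizes <- integer()
  repeat {
    b <- read_block(s, 10)
    if (is.null(b)) break
    sizes <- c(sizes, b$numDataLines)
  }
  expect_identical(sizes, c(10L, 10L, 5L))
  close_stream(s)

  # stream equivalence: blocks (any num_lines, any workers) == records
  spec2 <- vcf_fixture_spec(n_samples = 50, n_markers = 200, seed = 7)
  p2 <- tmp_path(".vcf")
  generate_vcf(spec2, p2, manifest_path = NA)
  serial <- read_gt_matrix(p2)
  for (num_lines in c(1L, 7L, 64L, 500L)) {
    for (workers in c(1L, 4L)) {
      st <- open_vcf(p2)
      read_header(st)
      rows <- list()
      repeat {
        b <- read_block(st, num_lines, workers)
        if (is.null(b)) break
        for (r in b$records) {
          rows[[length(rows) + 1L]] <- paste0(r$allele_a, "|", r$allele_b)
        }
      }
      close_stream(st)
      expect_identical(do.call(rbind, rows), serial,
                       label = sprintf("blocks(num_lines=%d, workers=%d)",
                                       num_lines, workers))
    }
  }
})

test_that("write_vcf round-trips records and honours GZ mode", {
  spec <- vcf_fixture_spec(n_samples = 6, n_markers = 5, seed = 3,
                           with_ds = TRUE, ds_noise = 0.1)
  p <- tmp_path(".vcf")
  generate_vcf(spec, p, manifest_path = NA)
  s <- open_vcf(p, parse_fields = c("GT", "DS"))
  h <- read_header(s)
  b <- read_block(s, 10)
  close_stream(s)

  out <- tmp_path(".vcf")
  n <- write_vcf(b, h, out, "NORMAL")
  expect_identical(n, 5L)
  expect_identical(read_gt_matrix(out), read_gt_matrix(p))
  expect_identical(read_sites(out), read_sites(p))

  # zero records -> header-only file
  out0 <- tmp_path(".vcf")
  expect_identical(write_vcf(list(), h, out0, "NORMAL"), 0L)
  s0 <- open_vcf(out0)
  expect_identical(read_header(s0)$sample_ids, h$sample_ids)
  expect_null(read_record(s0))
  close_stream(s0)

  # GZ output is a real gzip member, re-readable in GZ mode
  outgz <- tmp_path(".vcf.gz")
  write_vcf(b, h, outgz, "GZ")
  expect_true(m3vcf:::is_gzip_file(outgz))
  expect_identical(read_gt_matrix(outgz), read_gt_matrix(p))
})

test_that("gzipped and plain input yield identical records", {
  spec <- vcf_fixture_spec(n_samples = 8, n_markers = 30, seed = 5)
  p <- tmp_path(".vcf")
  generate_vcf(spec, p, manifest_path = NA)
  pgz <- gzip_fixture(p)
  expect_identical(read_gt_matrix(pgz), read_gt_matrix(p))
  s <- open_vcf(pgz)
  expect_identical(s$file_mode, "GZ")
  close_stream(s)
})

test_that("close_stream is idempotent and releases are no-ops", {
  p <- write_toy_vcf(vcf_line("0|1"), 1)
  s <- open_vcf(p)
  read_header(s)
  r <- read_record(s)
  close_stream(s)
  expect_silent(close_stream(s))
  expect_null(release_record(r))
  expect_null(release_block(NULL))
})
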