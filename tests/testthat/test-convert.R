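test_that("20 eligible markers with block size 10 give two blocks", {
  spec <- vcf_fixture_spec(n_samples = 10, n_markers = 20, seed = 1)
  p <- tmp_path(".vcf.gz")
  generate_vcf(spec, p, "GZ", manifest_path = NA)
  out <- tmp_path(".m3vcf.gz")
  s <- vcf_to_m3vcf(p, out, buffer_size = 10)
  expect_identical(s$status, "ok")
  expect_identical(s$markers_read, 20L)
  expect_identical(s$markers_compressed, 20L)
  expect_identical(s$blocks_written, 2L)
  expect_true(m3vcf:::is_gzip_file(out))
})

test_that("skip mode drops and counts ineligible records", {
  body <- c(vcf_line("0|1", pos = 100),
            vcf_line("0|1", pos = 200, alt = "G,T"),
            vcf_line("1|1", pos = 300),
            vcf_line("0|0", pos = 400, alt = "GA,T"),
            vcf_line("0|1", pos = 500))
  p <- write_toy_vcf(body, 1)
  out <- tmp_path(".m3vcf")
  s <- vcf_to_m3vcf(p, out, output_mode = "NORMAL", buffer_size = 10,
                    skip_invalid = TRUE)
  expect_identical(s$status, "ok")
  expect_identical(s$markers_compressed, 3L)
  expect_identical(s$markers_rejected, 2L)
  expect_identical(s$rejected_by_reason[["multi-allelic"]], 2L)
  expect_identical(s$blocks_written, 1L)

  # strict mode aborts on the first ineligible record, naming the file
  s2 <- vcf_to_m3vcf(p, tmp_path(".m3vcf"), output_mode = "NORMAL")
  expect_identical(s2$status, "error")
  expect_match(s2$message, "vcffile:\\[.*\\] compressed error!")
  expect_match(s2$message, "multi-allelic")
})

test_that("compression output is identical across thread counts", {
  spec <- vcf_fixture_spec(n_samples = 30, n_markers = 120, seed = 17,
                           n_founder_haplotypes = 12)
  p <- tmp_path(".vcf")
  generate_vcf(spec, p, manifest_path = NA)
  outs <- lapply(c(1L, 4L), function(th) {
    out <- tmp_path(".m3vcf")
    s <- vcf_to_m3vcf(p, out, output_mode = "NORMAL", buffer_size = 10,
                      threads = th)
    expect_identical(s$status, "ok")
    readLines(out)
  })
  expect_identical(outs[[1]], outs[[2]])
})

test_that("compress then convert restores the full GT matrix and sites", {
  for (seed in c(2, 23)) {
    spec <- vcf_fixture_spec(n_samples = 25, n_markers = 83, seed = seed,
                             n_founder_haplotypes = 10)
    p <- tmp_path(".vcf")
    generate_vcf(spec, p, manifest_path = NA)
    m3 <- tmp_path(".m3vcf.gz")
    back <- tmp_path(".vcf")
    expect_identical(vcf_to_m3vcf(p, m3, buffer_size = 7)$status, "ok")
    cv <- m3vcf_to_vcf(m3, back, output_mode = "NORMAL")
    expect_identical(cv$status, "ok")
    expect_identical(cv$markers_written, 83L)
    expect_identical(read_gt_matrix(back), read_gt_matrix(p))
    expect_identical(read_sites(back), read_sites(p))
  }
})

test_that("shared-boundary blocks are written and converted back losslessly", {
  spec <- vcf_fixture_spec(n_samples = 12, n_markers = 41, seed = 31)
  p <- tmp_path(".vcf")
  generate_vcf(spec, p, manifest_path = NA)
  m3 <- tmp_path(".m3vcf")
  s <- vcf_to_m3vcf(p, m3, output_mode = "NORMAL", buffer_size = 10,
                    overlap_boundary = TRUE)
  expect_identical(s$status, "ok")
  # 10 new markers, then 9 new per block sharing one boundary marker:
  # blocks cover 1-10, 10-19, 19-28, 28-37, 37-41
  ids <- grep("<BLOCK:", readLines(m3), value = TRUE)
  ranges <- regmatches(ids, regexpr("<BLOCK:[0-9]+-[0-9]+>", ids))
  expect_identical(ranges, c("<BLOCK:1-10>", "<BLOCK:10-19>",
                             "<BLOCK:19-28>", "<BLOCK:28-37>",
                             "<BLOCK:37-41>"))
  back <- tmp_path(".vcf")
  cv <- m3vcf_to_vcf(m3, back, output_mode = "NORMAL")
  expect_identical(cv$status, "ok")
  expect_identical(cv$markers_written, 41L)
  expect_identical(read_gt_matrix(back), read_gt_matrix(p))

  # degenerate combination is refused
  s2 <- vcf_to_m3vcf(p, tmp_path(".m3vcf"), output_mode = "NORMAL",
                     buffer_size = 1, overlap_boundary = TRUE)
  expect_identical(s2$status, "error")
})

test_that("header-only and corrupt m3vcf inputs are handled", {
  spec <- vcf_fixture_spec(n_samples = 5, n_markers = 12, seed = 4)
  p <- tmp_path(".vcf")
  generate_vcf(spec, p, manifest_path = NA)
  m3 <- tmp_path(".m3vcf")
  vcf_to_m3vcf(p, m3, output_mode = "NORMAL", buffer_size = 5)

  # header-only m3vcf converts to zero markers, status ok
  lines <- readLines(m3)
  header_only <- tmp_path(".m3vcf")
  writeLines(lines[seq_len(grep("^#CHROM", lines))], header_only)
  cv <- m3vcf_to_vcf(header_only, tmp_path(".vcf"), output_mode = "NORMAL")
  expect_identical(cv$status, "ok")
  expect_identical(cv$markers_written, 0L)

  # corrupt hap_map index -> error naming the block
  bad <- lines
  bh <- grep("<BLOCK:", bad)[1]
  bad[bh] <- sub("^(([^\t]*\t){9})[0-9]+\\|[0-9]+", "\\199|99", bad[bh])
  badp <- tmp_path(".m3vcf")
  writeLines(bad, badp)
  cv2 <- m3vcf_to_vcf(badp, tmp_path(".vcf"), output_mode = "NORMAL")
  expect_identical(cv2$status, "error")
  expect_match(cv2$message, "m3vcffile:\\[.*\\] convert error!")
  expect_match(cv2$message, "block 1")
})

test_that("blocks_written follows the ceiling rule for every buffer size", {
  spec <- vcf_fixture_spec(n_samples = 6, n_markers = 47, seed = 8)
  p <- tmp_path(".vcf")
  generate_vcf(spec, p, manifest_path = NA)
  for (l in c(1L, 7L, 10L, 64L)) {
    out <- tmp_path(".m3vcf")
    s <- vcf_to_m3vcf(p, out, output_mode = "NORMAL", buffer_size = l)
    expect_identical(s$blocks_written, as.integer(ceiling(47 / l)),
                     label = paste("buffer_size", l))
  }
})
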