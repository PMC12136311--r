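Package: m3vcf
Title: Block-Wise Unique-Haplotype Compression of Phased VCF Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Streaming reader and writer for VCF genotype data (plain text or
    gzip) that parses only the GT and DS FORMAT fields, a codec that
    compresses runs of consecutive bi-allelic SNP records into the compact
    M3VCF haplotype-block representation (unique haplotypes plus a
    per-sample-haplotype index map) and decompresses them back losslessly, a
    staged read/parse/compress/write conversion pipeline with bounded
    in-flight memory and deterministic output, an analytic timing model for
    the pipelined workflow (per-stage savings and Amdahl's-law speedup), a
    seeded synthetic VCF generator for testing, and a command-line interface
    with compress, convert and model subcommands.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
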