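# m3vcf

Block-wise unique-haplotype compression of phased VCF genotypes, with a
streaming GT/DS-only VCF reader, a staged parallel conversion pipeline, and
an analytic model of what pipelining and multi-threading buy.

## The problem

Genotype imputation servers and GWAS pipelines spend a surprising amount of
time just *loading* VCF files: the text format stores every genotype of
every sample at every marker, so a cohort of N samples and m markers costs
O(N·m) parsing work even though phased haplotypes in a population are
massively redundant. Reference panels for imputation (Minimac3/Minimac4)
therefore use **M3VCF**, a block-wise format that stores, for each run of l
consecutive bi-allelic SNPs, only the u *unique* haplotypes observed in the
block plus a per-sample-haplotype index map. Within a block, a diploid
sample s is two integers pointing into a u × l 0/1 matrix; because
haplotypes are shared through descent, u ≪ 2N in real panels.

This package provides:

* **`vcf_io`** — streaming VCF reader/writer (plain text or gzip) that
  parses only the GT and optionally DS FORMAT fields, record by record
  (`read_record`) or block by block with parallel parsing (`read_block`).
* **`m3vcf` codec** — `compress_block` / `decompress_block` implement the
  unique-haplotype deduplication and its exact inverse, plus reader/writer
  for a documented M3VCF text dialect (see below).
* **`pipeline`** — `run_pipeline` executes read → parse(q) → compress(p) →
  ordered write as overlapping stages with bounded in-flight memory;
  output is byte-identical for every worker count.
* **`perf_model`** — the timing model of the staged workflow as executable
  formulas, and Amdahl's law.
* **fixtures** — `generate_vcf` writes seeded synthetic phased cohorts
  (founder-pool haplotype redundancy, optional deliberately invalid
  records) with a JSON ground-truth manifest.
* **CLI** — `exec/m3vcf` with `compress`, `convert` and `model`
  subcommands.

## The model in brief

A file of m markers is processed in n = ⌈m/l⌉ blocks of l markers. With
per-block stage times T_read (= T_load + T_parse), T_compress, T_write:

* sequential: T_old = n·(T_read + T_compress + T_write)
* pipelined: T_new = 1·T_read + n·T_compress + 1·T_write, saving
  T1 = (n−1)·(T_read + T_write)
* p compress threads: T2 = (p−1)·T_compress/p
* q parse threads: T3 = (q−1)·T_parse/q; total savings Ts = T1 + T2 + T3
* speedup is bounded by Amdahl's law S = 1/((1−α) + α/p)

In step terms, 3 records through 3 sequential stages take 9 steps; the
pipelined schedule takes n + stages − 1 = 5 (`step_count`).

## Worked example

```r
library(m3vcf)
vcf <- system.file("extdata", "toy.vcf", package = "m3vcf")
out <- tempfile(fileext = ".m3vcf")
vcf_to_m3vcf(vcf, out, output_mode = "NORMAL", buffer_size = 3)
#> $markers_read        [1] 6
#> $markers_compressed  [1] 6
#> $markers_rejected    [1] 0
#> $blocks_written      [1] 2
#> $status              [1] "ok"
```

Six markers over three samples, block size 3 → two blocks. The first block
of the output reads:

```text
22  16050075  <BLOCK:1-3>  .  .  .  .  VARIANTS=3;REPS=4     0|0  0|1  2|3
22  16050075  rs1  A  G  .  .  .  0111
22  16050115  rs2  G  A  .  .  .  0001
22  16050213  rs3  C  T  .  .  .  1011
```

The block header says the 3 markers needed only u = 4 of the 6 possible
haplotypes; sample S003's two haplotypes are representatives 2 and 3, and
the per-marker strings give each representative's allele (e.g. at rs1 the
four representatives carry 0,1,1,1). `m3vcf_to_vcf(out, back)` restores
every genotype exactly (`markers_written = 6, status = "ok"`).

The analytic model for a 100-marker workload in blocks of 10 with stage
times (load 1, parse 4, compress 10, write 1), p = 4, q = 2, α = 0.9:

```r
w <- workload_model(m = 100, l = 10, t_load = 1, t_parse = 4,
                    t_compress = 10, t_write = 1)
model_table(w, p = 4, q = 2, alpha = 0.9)
#> blocks n                 10.00000
#> T_sequential             160.00000
#> T_pipelined              106.00000
#> T1 workflow savings      54.00000
#> T2 compress savings (p)  7.50000
#> T3 parse savings (q)     2.00000
#> Ts total savings         63.50000
#> Amdahl speedup bound     3.07692
```

From a shell, the same conversions are:

```sh
exec/m3vcf compress cohort.vcf.gz -O m -o cohort.m3vcf.gz
exec/m3vcf convert cohort.m3vcf.gz -O M -o cohort.roundtrip.vcf
```

`-O m` writes gzip, `-O M` plain text; input compression is auto-detected.
`--threads`, `--buffer-size` and `--memory-limit` accept 0 for optimized
defaults; `--skip-invalid` drops (and counts) records that are not phased
bi-allelic SNPs instead of aborting.

## The M3VCF dialect

M3VCF's internal layout is not publicly documented; this package writes a
**package-defined text dialect** (documented in `R/m3vcf-io.R` and the
vignette): the source header plus an `##M3VCF.version` tag, then per block
one header line (`VARIANTS=l;REPS=u`, per-sample representative pairs
`a|b`) followed by l variant lines each carrying a u-character 0/1
haplotype string. It round-trips losslessly through this package;
interoperability with Minimac binaries is not promised.

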