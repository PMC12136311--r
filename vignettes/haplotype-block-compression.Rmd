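---
title: "Haplotype-block compression of phased VCF genotypes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-block compression of phased VCF genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m3vcf)
```

## The compression model

A phased diploid cohort of N samples contributes 2N haplotypes. Over a run
of l consecutive bi-allelic SNPs, each haplotype is a vector in {0,1}^l,
and because haplotypes are inherited in shared segments, the number u of
*distinct* vectors in a population panel is typically far below both 2N
and 2^l. The M3VCF representation exploits this: a block stores the u
unique ("representative") haplotypes as a u × l matrix plus a length-2N
integer map from sample haplotypes to representatives. Storage drops from
2N·l genotype characters to u·l + 2N integers per block, and downstream
consumers (imputation engines) can compute once per representative instead
of once per sample.

`compress_block` lays the 2N haplotypes out in a fixed scan order — sample
1 haplotype a, sample 1 haplotype b, sample 2 haplotype a, ... — and
numbers representatives by first occurrence in that scan. This makes the
output fully deterministic, makes `hap_map[1] == 0` an invariant worth
testing, and costs nothing: any fixed order works. Deduplication uses
string keys with `match(keys, unique(keys))`; the test suite checks it
against an independent brute-force scan that compares rows with
`identical()`.

The transform is exact for GT by construction, and `decompress_block`
inverts it index-by-index. Dosages (DS) are *not* carried into M3VCF: the
format stores haplotypes only, and emitting a fabricated DS equal to the
hard-genotype allele count on decompression would misrepresent imputation
uncertainty, so conversion back to VCF writes GT only.

## Eligibility

Only phased bi-allelic SNPs are compressible: one single-base REF, one
single-base ALT (both in A/C/G/T), no missing genotypes, all genotypes
phased, alleles in {0,1}. `is_eligible` reports the first failed condition
in that order. Two policies are offered because strictness is a genuine
judgement call: the default aborts the conversion on the first ineligible
record (silent data loss in a reference panel is worse than a failed run),
while `skip_invalid = TRUE` drops such records and counts them per reason
in the summary. Missing genotypes are rejected at parse time by default
for the same reason; the permissive mode stores them as `NA` so the
eligibility filter can classify and skip them. Unphased `a/b` genotypes
are parsed (with `phased = FALSE`) but refused by the codec — treating
`a/b` as `a|b` would silently fabricate haplotype structure.

## Block structure

Blocks are non-overlapping runs of `buffer_size` eligible markers
(default 10); the final block holds the remainder and is never padded.
Historical Minimac panels share one boundary marker between adjacent
blocks for imputation-state continuity; `overlap_boundary = TRUE`
reproduces that convention (each block after the first starts at the
previous block's last marker), and the converter detects shared boundaries
from the blocks' global marker indices so the round trip stays lossless.
The plain scheme is the default because it is simpler and the shared
marker buys nothing outside an imputation engine. Larger blocks reduce
per-block overhead and improve the u ≪ 2N payoff on redundant panels, but
increase the work quantum; 10 is a sensible default for testing-scale
data, and files with many markers and few samples benefit from raising it.

## The staged pipeline

Conversion runs as read → parse(q) → compress(p) → ordered write. The
implementation is a bounded-window scheduler: at most `capacity` blocks
are admitted between reader and writer (backpressure), parse and compress
are applied to the window's blocks with forked workers
(`parallel::mclapply`) when more than one lane is configured, and results
are written strictly in block order. Because every stage callable is pure
per block, the schedule can change but the bytes cannot — determinism
across worker counts is an invariant under test, with the serial
composition as oracle. On a failure the earliest failing block (by block
order) is reported with its stage, after all preceding blocks have been
written.

Auto-resolution of zeros: `p = max(1, cpus − 2)` (reader and writer each
get a core), `q = max(1, min(p, cpus/2))` (parsing saturates before
compression), capacity `2·max(p, q)` blocks, or
`floor(memory_limit / block_bytes)` when a byte budget is given. The
memory limit is interpreted in bytes and converted to a block capacity —
the bound that actually controls peak memory in a staged pipeline.

`StageTrace` is produced by a discrete-event simulation
(`simulate_schedule`) with logical ticks rather than wall-clock
measurements: per-block stage costs, single read/write lanes, q parse and
p compress lanes (earliest-free, lowest-index grant), and the same
backpressure gate. Hardware-independent traces keep scheduling assertions
meaningful on any machine, including single-CPU CI; with unit
read/compress/write costs the simulated make-span reproduces the
step-count model (`n + stages − 1`), which is cross-checked in the tests
and the acceptance script.

## The analytic timing model

`workload_model` + the `time_*`/`savings_*` functions implement the staged
workflow's timing algebra: n = ⌈m/l⌉ blocks (the ceiling covers remainder
blocks), sequential total n·(T_read + T_compress + T_write), pipelined
total T_read + n·T_compress + T_write, and the three savings terms T1, T2,
T3 with total Ts. The pipelined total is a compress-dominated
idealization — read and write are counted once overall rather than as
per-block overlapping maxima — and is implemented literally because the
T1 identity (sequential − pipelined = T1) only holds in that form; the
identity is asserted exactly in the tests. `amdahl_speedup` supplies the
saturation bound 1/((1−α) + α/p) that explains why thread scaling
flattens: the serial fraction (I/O, scheduling) caps the gain at
1/(1−α).

Exactness note: the identity tests draw workloads with integer-valued
stage times, where double arithmetic is exact, so `==` is a meaningful
assertion rather than a tolerance in disguise.

## The synthetic generator

`generate_vcf` emulates the one property of real panels the codec exists
to exploit — haplotype redundancy — by drawing each sample haplotype with
replacement from a founder pool of `n_founder_haplotypes` haplotypes
(pool alleles Bernoulli with per-marker MAF uniform on `maf_range`,
default 0.05–0.5). The pool size directly bounds u within any block,
giving tests a constructive ground truth; `iid = TRUE` gives the
worst-case u ≈ 2N regime. Deliberately invalid records (multi-allelic,
indel, missing genotype, unphased) are injected on disjoint marker sets,
one defect per record, so rejection reasons are unambiguous, and the JSON
manifest records the ground truth the filters are checked against.
Dosages, when requested, are the ALT-allele count plus bounded uniform
noise clipped to [0, 2].

What the generator does *not* emulate: linkage-disequilibrium decay,
recombination and pedigree structure, realistic allele-frequency spectra,
multi-chromosome files, or million-sample scale. Passing tests therefore
demonstrate correctness of parsing, compression, ordering and bookkeeping
— not compression ratios or throughput on real cohorts.

## Numerical and formatting choices

* Coordinates stay 1-based as in VCF; no normalization or liftover.
* GT may sit at any FORMAT position; it is located per record. Only GT and
  DS are ever parsed; everything else is skipped unstored.
* Gzip means plain RFC 1952 streams (BGZF reads fine, being valid gzip;
  no virtual offsets). `FILE_MODE_GZ` against a non-gzip file is refused
  at open via the magic bytes.
* Dosages are written with up to three decimals, trailing zeros trimmed,
  at least one decimal kept.
* Parsing work is split into contiguous chunks reassembled by chunk
  index, so worker count can never reorder records.
* Test problem sizes: round-trip sweeps use 20 seeded cohorts up to
  1000 markers × 200 samples with block sizes {1, 7, 10, 64} and 1 or 4
  threads assigned round-robin; the dedup oracle sweep uses 500 random
  blocks with 2N ≤ 64, l ≤ 16. These sizes exercise every code path
  (remainders, single-marker blocks, worker hand-off) while keeping the
  default suite fast.

## Known limitations

* The M3VCF text dialect is package-defined (the historical format's
  internals are undocumented); files are self-describing and round-trip
  exactly through this package, but byte-compatibility with Minimac
  tooling is not claimed.
* Diploid samples only; haploid or polyploid GT is a codec error.
* Concurrency uses process forking, so on platforms without `fork` the
  worker lanes degrade to serial execution with identical output.
* The analytic model is an idealization for reasoning about schedules; it
  is not fitted to wall-clock measurements, and the package deliberately
  asserts nothing about real-hardware speedups.
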