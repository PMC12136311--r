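#' Compress a VCF file into M3VCF haplotype blocks
#'
#' Streams the input through the staged pipeline -- serial block reading,
#' `q` parse workers, `p` compress workers, one ordered writer -- grouping
#' eligible bi-allelic SNP records into blocks of `buffer_size` markers and
#' writing each as an M3VCF haplotype block. Output bytes are identical for
#' every thread count.
#'
#' @param input Input VCF path (plain or gzip).
#' @param output Output M3VCF path.
#' @param input_mode,output_mode `"GZ"`, `"NORMAL"` or `"AUTO"`
#'   (magic-byte / suffix detection).
#' @param buffer_size Markers per block; 0 selects the default of 10.
#'   Larger blocks trade per-block overhead against load balance.
#' @param threads Compress workers p; 0 resolves an optimized default from
#'   the CPU count (see [resolve_auto()]). Parse workers q are resolved
#'   alongside.
#' @param memory_limit In-flight byte budget; 0 resolves to a capacity of
#'   `2 * max(p, q)` blocks.
#' @param skip_invalid If `FALSE` (default) any record that is not an
#'   eligible phased bi-allelic SNP aborts with an error; if `TRUE` such
#'   records (including those with missing genotypes) are dropped and
#'   counted per reason.
#' @param overlap_boundary If `TRUE`, adjacent blocks share one boundary
#'   marker (the convention used by historical imputation-panel files for
#'   state continuity across blocks); the default writes plain
#'   non-overlapping runs. Requires `buffer_size >= 2`.
#' @param parse_fields FORMAT fields to parse from the input; dosages are
#'   never stored in M3VCF, so `"GT"` suffices.
#' @param parse_workers Parse workers q; 0 resolves a default alongside
#'   `threads`.
#' @return A summary list: `markers_read`, `markers_compressed`,
#'   `markers_rejected`, `rejected_by_reason` (named integer),
#'   `blocks_written`, `status` (`"ok"`/`"error"`) and `message`.
#' @examples
#' vcf <- system.file("extdata", "toy.vcf", package = "m3vcf")
#' out <- file.path(tempdir(), "toy.m3vcf")
#' vcf_to_m3vcf(vcf, out, buffer_size = 3)
#' @export
vcf_to_m3vcf <- function(input, output, input_mode = "AUTO",
                         output_mode = "AUTO", buffer_size = 0L,
                         threads = 0L, memory_limit = 0L,
                         skip_invalid = FALSE, overlap_boundary = FALSE,
                         parse_fields = "GT", parse_workers = 0L) {
  state <- new.env(parent = emptyenv())
  state$markers_read <- 0L
  state$markers_compressed <- 0L
  state$rejected <- integer()   # named counts by reason
  state$blocks_written <- 0L

  result <- tryCatch({
    compress_run(input, output, input_mode, output_mode, buffer_size,
                 threads, parse_workers, memory_limit, skip_invalid,
                 overlap_boundary, parse_fields, state)
    list(status = "ok", message = "")
  }, error = function(e) {
    list(status = "error",
         message = paste0("vcffile:[", input, "] compressed error! ",
                          conditionMessage(e)))
  })

  list(markers_read = state$markers_read,
       markers_compressed = state$markers_compressed,
       markers_rejected = sum(state$rejected),
       rejected_by_reason = state$rejected,
       blocks_written = state$blocks_written,
       status = result$status,
       message = result$message)
}

compress_run <- function(input, output, input_mode, output_mode,
                         buffer_size, threads, parse_workers, memory_limit,
                         skip_invalid, overlap_boundary, parse_fields,
                         state) {
  config <- resolve_auto(pipeline_config(p = threads, q = parse_workers,
                                         buffer_size = buffer_size,
                                         memory_limit = memory_limit))
  l <- config$buffer_size
  if (overlap_boundary && l < 2L) {
    stop("overlap_boundary needs buffer_size >= 2 (a 1-marker block has ",
         "no interior)", call. = FALSE)
  }

  stream <- open_vcf(input, input_mode, parse_fields)
  on.exit(close_stream(stream), add = TRUE)
  if (skip_invalid) stream$missing_genotypes <- "allow"
  header <- read_header(stream)

  out_mode <- resolve_file_mode(output, output_mode, for_write = TRUE)
  con <- open_text_connection(output, out_mode, write = TRUE)
  on.exit(close(con), add = TRUE)
  write_m3vcf_header(con, header)

  pending <- list()
  carry <- NULL            # shared boundary record in overlap mode
  consumed <- 0L           # distinct eligible markers placed in blocks
  produced <- 0L           # blocks handed to the pipeline
  eof <- FALSE
  read_chunk <- max(l, 64L)

  take_block <- function(k) {
    recs <- pending[seq_len(k)]
    pending <<- pending[-seq_len(k)]
    if (overlap_boundary) {
      if (is.null(carry)) {
        first_idx <- consumed + 1L
      } else {
        recs <- c(list(carry), recs)
        first_idx <- consumed
      }
      carry <<- recs[[length(recs)]]
    } else {
      first_idx <- consumed + 1L
    }
    consumed <<- consumed + k
    state$markers_compressed <- state$markers_compressed + k
    produced <<- produced + 1L
    list(block = new_genotype_block(recs, produced - 1L),
         first_idx = first_idx, last_idx = consumed)
  }

  source_fn <- function() {
    repeat {
      need <- if (overlap_boundary && !is.null(carry)) l - 1L else l
      if (length(pending) >= need) return(take_block(need))
      if (eof) {
        if (length(pending) > 0L) return(take_block(length(pending)))
        return(NULL)
      }
      blk <- read_block(stream, read_chunk, config$q)
      if (is.null(blk)) {
        eof <<- TRUE
        next
      }
      state$markers_read <- state$markers_read + blk$numDataLines
      for (rec in blk$records) {
        reason <- eligibility_reason(rec)
        if (is.na(reason)) {
          pending[[length(pending) + 1L]] <<- rec
        } else if (skip_invalid) {
          prev <- if (reason %in% names(state$rejected)) {
            state$rejected[[reason]]
          } else 0L
          state$rejected[reason] <- prev + 1L
        } else {
          stop("codec error at ", rec$chrom, ":", rec$pos,
               ": record is not compressible (", reason, ")",
               call. = FALSE)
        }
      }
    }
  }

  compress_fn <- function(item) {
    hb <- compress_block(item$block)
    hb$first_idx <- item$first_idx
    hb$last_idx <- item$last_idx
    hb
  }
  sink_fn <- function(hb, block_index) {
    write_m3vcf_block(hb, con)
    state$blocks_written <- state$blocks_written + 1L
  }

  run_pipeline(source_fn, identity, compress_fn, sink_fn, config)
  invisible(NULL)
}

#' Decompress an M3VCF file back to VCF
#'
#' Reads haplotype blocks in file order, reconstructs each genotype from
#' the representative-haplotype matrix and the per-sample index map, and
#' writes a phased GT-only VCF. Files written with shared block boundaries
#' (see `overlap_boundary` in [vcf_to_m3vcf()]) are detected from the
#' blocks' global marker indices and the duplicated boundary markers are
#' emitted once.
#'
#' @param input Input M3VCF path (plain or gzip).
#' @param output Output VCF path.
#' @param input_mode,output_mode `"GZ"`, `"NORMAL"` or `"AUTO"`.
#' @return A summary list: `blocks_read`, `markers_written`, `status`,
#'   `message`.
#' @export
m3vcf_to_vcf <- function(input, output, input_mode = "AUTO",
                         output_mode = "AUTO") {
  state <- new.env(parent = emptyenv())
  state$blocks_read <- 0L
  state$markers_written <- 0L

  result <- tryCatch({
    convert_run(input, output, input_mode, output_mode, state)
    list(status = "ok", message = "")
  }, error = function(e) {
    list(status = "error",
         message = paste0("m3vcffile:[", input, "] convert error! ",
                          conditionMessage(e)))
  })

  list(blocks_read = state$blocks_read,
       markers_written = state$markers_written,
       status = result$status,
       message = result$message)
}

convert_run <- function(input, output, input_mode, output_mode, state) {
  stream <- open_m3vcf(input, input_mode)
  on.exit(close_stream(stream), add = TRUE)
  header <- read_header(stream)

  out_mode <- resolve_file_mode(output, output_mode, for_write = TRUE)
  con <- open_text_connection(output, out_mode, write = TRUE)
  on.exit(close(con), add = TRUE)
  meta <- header$meta_lines
  meta <- meta[!startsWith(meta, "##M3VCF.version=")]
  writeLines(c(meta, vcf_column_line(header)), con)

  prev_last <- NA_integer_
  repeat {
    hb <- tryCatch(read_m3vcf_block(stream), error = function(e) {
      stop("block ", state$blocks_read + 1L, ": ", conditionMessage(e),
           call. = FALSE)
    })
    if (is.null(hb)) break
    state$blocks_read <- state$blocks_read + 1L
    gb <- tryCatch(decompress_block(hb), error = function(e) {
      stop("block ", state$blocks_read, " (", hb$chrom, ":",
           hb$variant_sites$pos[1], "): ", conditionMessage(e),
           call. = FALSE)
    })
    records <- gb$records
    if (!is.na(prev_last) && !is.na(hb$first_idx) &&
        hb$first_idx == prev_last && length(records) > 0L) {
      records <- records[-1L]   # shared boundary marker already written
    }
    for (rec in records) {
      writeLines(format_vcf_line(rec, header$n_samples), con)
    }
    state$markers_written <- state$markers_written + length(records)
    prev_last <- hb$last_idx
  }
  invisible(NULL)
}
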