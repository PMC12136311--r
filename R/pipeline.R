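#' Pipeline configuration
#'
#' Bundles the concurrency knobs of the conversion pipeline: `p` compress
#' workers, `q` parse workers, `buffer_size` markers per block, and a memory
#' limit that bounds the number of in-flight blocks. A value of 0 means
#' "resolve an optimized default from the machine" (see [resolve_auto()]).
#'
#' @param p Compress workers (>= 1, or 0 for auto).
#' @param q Parse workers (>= 1, or 0 for auto).
#' @param buffer_size Markers per block (>= 1, or 0 for the default, 10).
#' @param memory_limit In-flight budget in bytes (0 = auto).
#' @param capacity Maximum blocks in flight between reader and writer; `NA`
#'   until resolved.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(p = 0L, q = 0L, buffer_size = 0L,
                            memory_limit = 0L, capacity = NA_integer_) {
  for (v in list(p = p, q = q, buffer_size = buffer_size,
                 memory_limit = memory_limit)) {
    if (length(v) != 1L || is.na(v) || v < 0) {
      stop("pipeline_config fields must be single non-negative numbers",
           call. = FALSE)
    }
  }
  structure(
    list(p = as.integer(p), q = as.integer(q),
         buffer_size = as.integer(buffer_size),
         memory_limit = as.numeric(memory_limit),
         capacity = as.integer(capacity)),
    class = "pipeline_config")
}

#' Resolve zero-valued ("optimized default") pipeline settings
#'
#' Thread count 0 resolves to `p = max(1, cpus - 2)` (one core reserved for
#' the reader, one for the writer) and `q = max(1, min(p, cpus / 2))`.
#' Memory limit 0 resolves to a queue capacity of `2 * max(p, q)` blocks; an
#' explicit limit becomes `max(1, floor(memory_limit / block_bytes))`.
#' `buffer_size` 0 resolves to the default block size of 10 markers.
#'
#' @param config A `pipeline_config`.
#' @param cpus Available CPU count (defaults to the detected core count).
#' @param block_bytes Typical in-memory size of one block, used to convert
#'   a byte budget into a block capacity.
#' @return The `pipeline_config` with all fields >= 1 and `capacity` set.
#' @export
resolve_auto <- function(config, cpus = NULL, block_bytes = 1e6) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(cpus)) {
    cpus <- parallel::detectCores()
    if (is.na(cpus)) cpus <- 1L
  }
  cpus <- max(1L, as.integer(cpus))
  p <- if (config$p == 0L) max(1L, cpus - 2L) else config$p
  q <- if (config$q == 0L) max(1L, min(p, cpus %/% 2L)) else config$q
  buffer_size <- if (config$buffer_size == 0L) 10L else config$buffer_size
  capacity <- if (config$memory_limit == 0) {
    2L * max(p, q)
  } else {
    max(1L, as.integer(config$memory_limit %/% block_bytes))
  }
  pipeline_config(p = p, q = q, buffer_size = buffer_size,
                  memory_limit = config$memory_limit, capacity = capacity)
}

#' Discrete-event schedule of a staged pipeline
#'
#' Simulates n blocks flowing through four stages -- read (single lane),
#' parse (q lanes), compress (p lanes), ordered write (single lane) -- with
#' a backpressure gate of `capacity` in-flight blocks. Ticks are a logical
#' event counter, not wall time, so traces are hardware-independent. A
#' stage with cost 0 takes no ticks. Lanes are granted to the earliest-free,
#' lowest-index lane, which makes the schedule deterministic.
#'
#' With unit read/compress/write costs, zero parse cost and ample lanes the
#' make-span equals `n_blocks + 2` ticks, the classic "fill the pipe, then
#' one block per tick" schedule that [step_count()] models.
#'
#' @param n_blocks Number of blocks (>= 0).
#' @param t_read,t_parse,t_compress,t_write Per-block stage costs in ticks
#'   (non-negative; parse defaults to 0, folding it into read).
#' @param p,q Compress / parse lane counts (>= 1).
#' @param capacity Backpressure bound: block i cannot start reading before
#'   block i - capacity has finished writing.
#' @return A `stage_trace` data frame with columns `block_index`, `stage`,
#'   `lane`, `start`, `finish`, and attribute `makespan`.
#' @export
simulate_schedule <- function(n_blocks, t_read = 1, t_parse = 0,
                              t_compress = 1, t_write = 1,
                              p = 1L, q = 1L, capacity = Inf) {
  stopifnot(n_blocks >= 0, t_read >= 0, t_parse >= 0, t_compress >= 0,
            t_write >= 0, p >= 1, q >= 1, capacity >= 1)
  n <- as.integer(n_blocks)
  if (n == 0L) {
    tr <- data.frame(block_index = integer(), stage = character(),
                     lane = integer(), start = numeric(), finish = numeric())
    class(tr) <- c("stage_trace", "data.frame")
    attr(tr, "makespan") <- 0
    return(tr)
  }
  read_fin <- parse_fin <- comp_fin <- write_fin <- numeric(n)
  read_sta <- parse_sta <- comp_sta <- write_sta <- numeric(n)
  parse_lane <- comp_lane <- integer(n)
  parse_free <- numeric(q)
  comp_free <- numeric(p)
  for (i in seq_len(n)) {
    gate <- if (is.finite(capacity) && i > capacity) {
      write_fin[i - capacity]
    } else 0
    read_sta[i] <- max(if (i > 1L) read_fin[i - 1L] else 0, gate)
    read_fin[i] <- read_sta[i] + t_read

    lane <- which.min(parse_free)
    parse_sta[i] <- max(read_fin[i], parse_free[lane])
    parse_fin[i] <- parse_sta[i] + t_parse
    parse_free[lane] <- parse_fin[i]
    parse_lane[i] <- lane

    lane <- which.min(comp_free)
    comp_sta[i] <- max(parse_fin[i], comp_free[lane])
    comp_fin[i] <- comp_sta[i] + t_compress
    comp_free[lane] <- comp_fin[i]
    comp_lane[i] <- lane

    write_sta[i] <- max(comp_fin[i], if (i > 1L) write_fin[i - 1L] else 0)
    write_fin[i] <- write_sta[i] + t_write
  }
  idx <- rep(seq_len(n) - 1L, times = 4L)
  tr <- data.frame(
    block_index = idx,
    stage = rep(c("read", "parse", "compress", "write"), each = n),
    lane = c(rep(1L, n), parse_lane, comp_lane, rep(1L, n)),
    start = c(read_sta, parse_sta, comp_sta, write_sta),
    finish = c(read_fin, parse_fin, comp_fin, write_fin))
  tr <- tr[order(tr$block_index, match(tr$stage, c("read", "parse",
                                                   "compress", "write"))), ]
  rownames(tr) <- NULL
  class(tr) <- c("stage_trace", "data.frame")
  attr(tr, "makespan") <- write_fin[n]
  tr
}

#' Run the staged conversion pipeline
#'
#' Drives blocks from `source` through `parse_fn` (q workers) and
#' `compress_fn` (p workers) into the ordered `sink`. The scheduler admits
#' at most `capacity` blocks between reader and writer (backpressure), and
#' the sink always receives results in ascending block order whatever the
#' workers' completion order -- the pipeline changes the schedule, never
#' the results. On a worker failure the earliest-failing block (by block
#' order) is reported with its stage; all preceding blocks are still
#' written.
#'
#' Workers are realized with forked processes (`parallel::mclapply`) when
#' more than one lane is requested; the callables must therefore be pure
#' per block.
#'
#' @param source Function of no arguments returning the next input item or
#'   `NULL` at end of input.
#' @param parse_fn Function applied to each item (use `identity` when the
#'   source already yields parsed blocks).
#' @param compress_fn Function applied to each parsed block.
#' @param sink Function `(result, block_index)` consuming results in order.
#' @param config A `pipeline_config`; resolved with [resolve_auto()] if any
#'   field is 0 or `capacity` is `NA`.
#' @param stage_ticks Optional numeric vector
#'   `c(read =, parse =, compress =, write =)` of logical stage costs used
#'   to build the returned [stage trace][simulate_schedule].
#' @return A list: `blocks` (count written), `status` (`"ok"`), `config`
#'   (the resolved configuration) and `trace` (a `stage_trace`).
#' @export
run_pipeline <- function(source, parse_fn, compress_fn, sink, config,
                         stage_ticks = c(read = 1, parse = 0, compress = 1,
                                         write = 1)) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$p == 0L || config$q == 0L || is.na(config$capacity)) {
    config <- resolve_auto(config)
  }
  capacity <- max(1L, config$capacity)
  next_index <- 0L
  exhausted <- FALSE
  written <- 0L

  apply_stage <- function(items, fn, workers) {
    wrapped <- function(x) tryCatch(list(ok = fn(x)),
                                    error = function(e) list(err = e))
    if (workers > 1L && length(items) > 1L) {
      parallel::mclapply(items, wrapped,
                         mc.cores = min(workers, length(items)))
    } else {
      lapply(items, wrapped)
    }
  }

  while (!exhausted) {
    # admit at most `capacity` blocks before the next write drain
    window <- list()
    indices <- integer()
    while (length(window) < capacity) {
      item <- source()
      if (is.null(item)) {
        exhausted <- TRUE
        break
      }
      window[[length(window) + 1L]] <- item
      indices <- c(indices, next_index)
      next_index <- next_index + 1L
    }
    if (length(window) == 0L) break

    parsed <- apply_stage(window, parse_fn, config$q)
    fail_at <- NA_integer_
    fail_stage <- NA_character_
    fail_err <- NULL
    for (k in seq_along(parsed)) {
      if (!is.null(parsed[[k]]$err)) {
        fail_at <- k; fail_stage <- "parse"; fail_err <- parsed[[k]]$err
        break
      }
    }
    ok_upto <- if (is.na(fail_at)) length(parsed) else fail_at - 1L
    compressed <- apply_stage(lapply(parsed[seq_len(ok_upto)],
                                     `[[`, "ok"),
                              compress_fn, config$p)
    for (k in seq_len(ok_upto)) {
      if (!is.null(compressed[[k]]$err) &&
          (is.na(fail_at) || k < fail_at)) {
        fail_at <- k; fail_stage <- "compress"
        fail_err <- compressed[[k]]$err
        break
      }
    }
    write_upto <- if (is.na(fail_at)) length(compressed) else fail_at - 1L
    for (k in seq_len(write_upto)) {
      res <- tryCatch(list(ok = sink(compressed[[k]]$ok, indices[k])),
                      error = function(e) list(err = e))
      if (!is.null(res$err)) {
        fail_at <- k; fail_stage <- "write"; fail_err <- res$err
        break
      }
      written <- written + 1L
    }
    if (!is.na(fail_at)) {
      stop(pipeline_error(indices[fail_at], fail_stage, fail_err))
    }
  }

  trace <- simulate_schedule(
    written,
    t_read = stage_ticks[["read"]], t_parse = stage_ticks[["parse"]],
    t_compress = stage_ticks[["compress"]], t_write = stage_ticks[["write"]],
    p = config$p, q = config$q, capacity = capacity)
  list(blocks = written, status = "ok", config = config, trace = trace)
}

pipeline_error <- function(block_index, stage, parent) {
  structure(
    class = c("pipeline_error", "error", "condition"),
    list(message = paste0("pipeline error at block ", block_index, ", ",
                          stage, " stage: ", conditionMessage(parent)),
         call = NULL, block_index = block_index, stage = stage,
         parent = parent))
}

#' Export a stage trace as TSV
#'
#' @param trace A `stage_trace` from [simulate_schedule()] or
#'   [run_pipeline()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_stage_trace <- function(trace, path) {
  stopifnot(inherits(trace, "stage_trace"))
  utils::write.table(as.data.frame(trace), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
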