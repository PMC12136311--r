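#' Workload model for the staged conversion
#'
#' Describes a conversion workload of `m` markers processed in blocks of
#' `l` markers (so `n = ceiling(m / l)` blocks) together with the
#' per-block stage times: `t_load` (raw line reading), `t_parse` (field
#' parsing), `t_compress` and `t_write`. The Read stage is the sum of its
#' two phases, `t_read = t_load + t_parse`.
#'
#' @param m Total markers (>= 1).
#' @param l Markers per block (>= 1).
#' @param t_load,t_parse,t_compress,t_write Non-negative per-block stage
#'   times (any consistent unit).
#' @return A `workload_model` list with fields `m`, `l`, `n`, `t_load`,
#'   `t_parse`, `t_read`, `t_compress`, `t_write`.
#' @export
workload_model <- function(m, l, t_load = 0, t_parse = 0, t_compress = 0,
                           t_write = 0) {
  stopifnot(m >= 1, l >= 1, t_load >= 0, t_parse >= 0, t_compress >= 0,
            t_write >= 0)
  structure(
    list(m = as.numeric(m), l = as.numeric(l),
         n = ceiling(m / l),
         t_load = t_load, t_parse = t_parse,
         t_read = t_load + t_parse,
         t_compress = t_compress, t_write = t_write),
    class = "workload_model")
}

#' Execution steps of a blocked multi-stage workflow
#'
#' A strictly sequential workflow runs every stage of every block back to
#' back: `n_blocks * n_stages` steps. A pipelined workflow overlaps stages
#' of consecutive blocks: once the pipe is full one new block completes per
#' step, giving `n_blocks + n_stages - 1` steps. For 3 records through 3
#' stages that is 9 sequential steps versus 5 pipelined.
#'
#' @param n_blocks Number of blocks (>= 1).
#' @param n_stages Number of stages (>= 1).
#' @param mode `"sequential"` or `"pipelined"`.
#' @return Integer step count.
#' @export
step_count <- function(n_blocks, n_stages, mode = c("sequential",
                                                    "pipelined")) {
  mode <- match.arg(mode)
  n_blocks <- as.integer(n_blocks)
  n_stages <- as.integer(n_stages)
  stopifnot(n_blocks >= 1L, n_stages >= 1L)
  if (mode == "sequential") n_blocks * n_stages
  else n_blocks + n_stages - 1L
}

#' Total time of the sequential workflow
#'
#' Every block pays the full read + compress + write cost in turn:
#' `n * (t_read + t_compress + t_write)`.
#'
#' @param w A [workload_model()].
#' @return Total time.
#' @export
time_sequential <- function(w) {
  stopifnot(inherits(w, "workload_model"))
  w$n * (w$t_read + w$t_compress + w$t_write)
}

#' Total time of the pipelined workflow
#'
#' In the compress-dominated idealization the read and write stages are
#' paid once for the whole dataset while compression remains on the
#' critical path for every block: `t_read + n * t_compress + t_write`.
#'
#' @param w A [workload_model()].
#' @return Total time.
#' @export
time_pipelined <- function(w) {
  stopifnot(inherits(w, "workload_model"))
  w$t_read + w$n * w$t_compress + w$t_write
}

#' Time saved by pipelining the workflow (T1)
#'
#' `(n - 1) * (t_read + t_write)`: the redundant per-block read and write
#' passes that overlap away. Identically equal to
#' `time_sequential(w) - time_pipelined(w)`.
#'
#' @param w A [workload_model()].
#' @return Time saved.
#' @export
savings_workflow <- function(w) {
  stopifnot(inherits(w, "workload_model"))
  (w$n - 1) * (w$t_read + w$t_write)
}

#' Time saved by parallel compression (T2)
#'
#' With p threads and ideal scaling the compress time drops from
#' `t_compress` to `t_compress / p`, saving `(p - 1) * t_compress / p`.
#'
#' @param t_compress Compress time (>= 0).
#' @param p Compress threads (>= 1).
#' @return A list `list(parallel_time =, savings =)`.
#' @export
savings_compress <- function(t_compress, p) {
  if (p < 1) stop("p must be >= 1", call. = FALSE)
  stopifnot(t_compress >= 0)
  list(parallel_time = t_compress / p,
       savings = (p - 1) * t_compress / p)
}

#' Time saved by parallel parsing (T3)
#'
#' The Read stage splits into serial data loading (`t_load`) and
#' parallelizable parsing (`t_parse`); with q threads the stage takes
#' `t_load + t_parse / q`, saving `(q - 1) * t_parse / q`.
#'
#' @param t_load Raw-line loading time (>= 0).
#' @param t_parse Parsing time (>= 0).
#' @param q Parse threads (>= 1).
#' @return A list `list(read_time =, savings =)`.
#' @export
savings_parse <- function(t_load, t_parse, q) {
  if (q < 1) stop("q must be >= 1", call. = FALSE)
  stopifnot(t_load >= 0, t_parse >= 0)
  list(read_time = t_load + t_parse / q,
       savings = (q - 1) * t_parse / q)
}

#' Total time savings Ts = T1 + T2 + T3
#'
#' Sum of the workflow-pipelining, parallel-compression and
#' parallel-parsing savings for one workload under `p` compress and `q`
#' parse threads.
#'
#' @param w A [workload_model()].
#' @param p Compress threads (>= 1).
#' @param q Parse threads (>= 1).
#' @return Total time saved.
#' @export
total_savings <- function(w, p, q) {
  stopifnot(inherits(w, "workload_model"))
  savings_workflow(w) +
    savings_compress(w$t_compress, p)$savings +
    savings_parse(w$t_load, w$t_parse, q)$savings
}

#' Amdahl's-law speedup bound
#'
#' `1 / ((1 - alpha) + alpha / p)` for a task whose parallelizable fraction
#' is `alpha` on `p` threads. Saturates at `1 / (1 - alpha)` as p grows,
#' which is why speedup curves flatten at high thread counts.
#'
#' @param alpha Parallelizable fraction in `[0, 1]`.
#' @param p Threads (>= 1).
#' @return Speedup factor (>= 1).
#' @export
amdahl_speedup <- function(alpha, p) {
  if (length(alpha) != 1L || is.na(alpha) || alpha < 0 || alpha > 1) {
    stop("alpha must lie in [0, 1]", call. = FALSE)
  }
  if (length(p) != 1L || is.na(p) || p < 1) {
    stop("p must be >= 1", call. = FALSE)
  }
  1 / ((1 - alpha) + alpha / p)
}

#' Print the analytic model for one workload
#'
#' Formats the sequential and pipelined times, the three savings terms,
#' their total, and the Amdahl bound, as a small table.
#'
#' @param w A [workload_model()].
#' @param p,q Compress / parse threads.
#' @param alpha Parallelizable fraction for the Amdahl row.
#' @return Invisibly, a data frame of the printed quantities.
#' @export
model_table <- function(w, p = 1L, q = 1L, alpha = 0.9) {
  sc <- savings_compress(w$t_compress, p)
  sp <- savings_parse(w$t_load, w$t_parse, q)
  df <- data.frame(
    quantity = c("blocks n", "T_sequential", "T_pipelined",
                 "T1 workflow savings", "T2 compress savings (p)",
                 "T3 parse savings (q)", "Ts total savings",
                 "Amdahl speedup bound"),
    value = c(w$n, time_sequential(w), time_pipelined(w),
              savings_workflow(w), sc$savings, sp$savings,
              total_savings(w, p, q), amdahl_speedup(alpha, p)))
  fmt <- format(df$value, digits = 6, trim = TRUE)
  cat(sprintf("%-24s %s\n", df$quantity, fmt), sep = "")
  invisible(df)
}
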