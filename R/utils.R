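`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detect whether a file starts with the gzip magic bytes
#'
#' @param path Path to an existing file.
#' @return `TRUE` if the first two bytes are the RFC 1952 gzip magic
#'   (`0x1f 0x8b`), `FALSE` otherwise (including for empty files).
#' @keywords internal
is_gzip_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

# Resolve a file-mode argument ("GZ", "NORMAL" or "AUTO") against a path.
# AUTO sniffs magic bytes for existing files and falls back to the suffix.
resolve_file_mode <- function(path, file_mode, for_write = FALSE) {
  file_mode <- toupper(file_mode)
  if (!file_mode %in% c("GZ", "NORMAL", "AUTO")) {
    stop("file_mode must be one of \"GZ\", \"NORMAL\", \"AUTO\", got \"",
         file_mode, "\"", call. = FALSE)
  }
  if (file_mode != "AUTO") return(file_mode)
  if (!for_write && file.exists(path)) {
    return(if (is_gzip_file(path)) "GZ" else "NORMAL")
  }
  if (grepl("\\.gz$", path)) "GZ" else "NORMAL"
}

# Open a text connection for reading/writing honouring the resolved mode.
open_text_connection <- function(path, file_mode, write = FALSE) {
  mode <- if (write) "wt" else "rt"
  if (file_mode == "GZ") gzfile(path, mode) else file(path, mode)
}

# Seed-scoped RNG: runs `expr` under `seed` and restores the caller's RNG
# state so generators do not perturb user simulations.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
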