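# internal helpers shared across modules

#' @importFrom data.table data.table as.data.table setorder := .N .SD fread fwrite rbindlist setnames shift
#' @importFrom stats pnorm qnorm dnorm approx rnorm rexp rpois rbinom median sd var cor uniroot runif
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# seed = NULL means: use (and advance) the current RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

is_gzip <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

# gzip-aware line reader; compression detected by magic bytes, not extension
read_lines_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- if (is_gzip(path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
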