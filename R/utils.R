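# Shared plumbing: TSV convention (tab-separated, header row, '#' comments),
# stage logging, and the package-local cache environment.

.grfevol_cache <- new.env(parent = emptyenv())

#' Read a tab-separated table with the package conventions
#'
#' Tab-separated, header row, `#`-prefixed comment lines, no quoting.
#' @param path File path.
#' @return data.frame with character columns as-is (no factors).
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write a tab-separated table with the package conventions
#' @param x data.frame to write.
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Control pipeline logging verbosity
#'
#' Every pipeline stage logs its inputs, parameter values and record counts
#' at normal verbosity. Logging goes to `message()` so it can be suppressed
#' or sunk independently of results.
#'
#' @param on Logical; `TRUE` enables stage logging.
#' @return Invisibly, the previous setting.
#' @export
grfevol_verbose <- function(on = TRUE) {
  old <- isTRUE(.grfevol_cache$verbose)
  .grfevol_cache$verbose <- isTRUE(on)
  invisible(old)
}

log_stage <- function(stage, ...) {
  if (isTRUE(.grfevol_cache$verbose))
    message(sprintf("[%s] %s", stage, paste0(...)))
  invisible(NULL)
}

# Derive a reproducible 32-bit sub-seed from a base seed and string key.
sub_seed <- function(seed, key) {
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)) %% 7919L)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}

# Run code under a local RNG state so library functions never disturb the
# caller's stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
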