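.log_env <- new.env(parent = emptyenv())
.log_env$level <- "info"
.LOG_LEVELS <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)

#' Set the logging verbosity
#'
#' Messages are written to stderr; `"quiet"` suppresses everything.
#'
#' @param level one of `"debug"`, `"info"`, `"warn"`, `"quiet"`.
#' @return the previous level, invisibly.
#' @export
spetLogLevel <- function(level = c("info", "debug", "warn", "quiet")) {
  level <- match.arg(level)
  old <- .log_env$level
  .log_env$level <- level
  invisible(old)
}

spetLog <- function(..., level = "info") {
  if (.LOG_LEVELS[[level]] >= .LOG_LEVELS[[.log_env$level]])
    message("[spetkit] ", ...)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Offset of the target SNP from the probe 3' end, in bp (1 = adjacent).
probeTargetOffset <- function(probes) {
  ifelse(probes$orientation == "readout-right",
         probes$target_pos - GenomicRanges::end(probes),
         GenomicRanges::start(probes) - probes$target_pos)
}

gcFraction <- function(seq) {
  f <- Biostrings::letterFrequency(Biostrings::DNAStringSet(seq),
                                   letters = c("G", "C"))
  rowSums(f) / nchar(seq)
}

# Derive a stream-specific 32-bit seed from a base seed, stable across runs.
deriveSeed <- function(seed, stream) {
  (as.integer(seed) * 1103L + as.integer(stream) * 12347L) %% 2147483587L
}

withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}
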