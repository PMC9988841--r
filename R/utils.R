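#' @import GenomicRanges IRanges
#' @importFrom S4Vectors metadata metadata<- mcols mcols<- queryHits subjectHits runValue runLength Rle
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqlevels<- seqnames
#' @importFrom data.table fread fwrite data.table as.data.table setnames :=
#' @importFrom stats hclust as.dist kmeans rnorm rpois runif rlnorm setNames complete.cases wilcox.test
#' @importFrom utils head tail modifyList
NULL

.log_levels <- c(debug = 10L, info = 20L, warn = 30L, error = 40L)

#' Set or query the logging threshold
#'
#' Messages below the threshold are suppressed. All logs go to stderr.
#'
#' @param level one of "debug", "info", "warn", "error"
#' @return the previous level, invisibly
#' @export
ca_log_level <- function(level = c("info", "debug", "warn", "error")) {
  level <- match.arg(level)
  old <- getOption("chromassoc.loglevel", "info")
  options(chromassoc.loglevel = level)
  invisible(old)
}

ca_log <- function(level, fmt, ...) {
  thr <- .log_levels[[getOption("chromassoc.loglevel", "info")]]
  if (.log_levels[[level]] >= thr) {
    message(sprintf("[%s] %s", toupper(level), sprintf(fmt, ...)))
  }
  invisible(NULL)
}

#' Derive a reproducible sub-stream seed
#'
#' Expands one master seed into independent per-component seeds so that, e.g.,
#' adding a reader to a simulation never perturbs mark placement. Uses a
#' Lehmer-style step on the Mersenne-prime modulus 2^31 - 1; results stay in
#' integer range.
#'
#' @param seed master seed (integer)
#' @param stream small non-negative integer identifying the consumer
#' @return an integer seed
#' @export
stream_seed <- function(seed, stream) {
  m <- 2147483647
  s <- (abs(as.numeric(seed)) %% m)
  for (k in seq_len(2L)) s <- (s * 48271 + as.numeric(stream) * 7919 + 1) %% m
  as.integer(s)
}

# FNV-1a 32-bit hash of a character scalar; used to fingerprint resolved
# pipeline configurations in reports.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^30), as.integer(b))  # keep in int range
    h <- (as.numeric(h) + 2^30) %% 2^32
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
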