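#' @useDynLib bridgepet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import IRanges
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom stats rbinom runif setNames
#' @importFrom utils head
NULL

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character vectors (ACGTN
#' alphabet; other letters map to N).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTacgt", "TGCAtgca", x))
}

# Run code with a temporary RNG state so that seeded helpers do not disturb
# the caller's random stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Deterministic labelled sub-seed derived from a master seed: all random
# streams in the simulator are keyed by (master, label) so that stages can
# be re-run independently and reproducibly. Kept below 2^31 - 1.
sub_seed <- function(master, label) {
  h <- 0
  for (v in utf8ToInt(label)) h <- (h * 31 + v) %% 2147483647
  as.integer((as.numeric(master) * 7919 + h) %% 2147483647)
}

stop_if_not_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
  invisible(x)
}

# genomic intervals as a plain data.frame -> GRanges (0-based half-open in,
# 1-based closed inside GenomicRanges)
as_granges <- function(df, chrom = "chrom", start = "start", end = "end",
                       strand_col = NULL) {
  strand <- if (!is.null(strand_col) && strand_col %in% names(df)) {
    df[[strand_col]]
  } else "*"
  GenomicRanges::GRanges(
    seqnames = df[[chrom]],
    ranges = IRanges::IRanges(start = df[[start]] + 1L, end = df[[end]]),
    strand = strand
  )
}
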