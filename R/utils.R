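#' @importFrom stats rbinom rpois rnbinom runif rnorm pchisq pt r2dtable
#'   setNames aggregate sd var complete.cases
#' @importFrom utils head tail write.table read.table
NULL

# Interval convention: every interval in this package is 0-based half-open
# [start, end) unless a file format dictates otherwise (GFF3 is 1-based
# closed on disk; conversion happens at I/O boundaries only).

#' Convert 0-based half-open intervals to an IRanges
#'
#' @param start,end integer vectors, 0-based half-open.
#' @return an [IRanges::IRanges] (1-based closed, as IRanges requires).
#' @keywords internal
iranges0 <- function(start, end) {
  stopifnot(all(end >= start))
  IRanges::IRanges(start = as.integer(start) + 1L, end = as.integer(end))
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Independent random streams for pipeline stages are derived from one master
#' seed so that changing one stage's draws does not perturb another's.
#'
#' @param seed master seed (integer).
#' @param stage integer offset identifying the consumer.
#' @return an integer seed strictly below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(stage)) %% 2147483629)
}

#' Sample a random DNA sequence with controlled GC content
#' @param n length in bp.
#' @param gc target GC fraction in \[0,1\].
#' @return a single character string.
#' @keywords internal
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Reverse complement of a DNA string
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# stop() with sprintf-style formatting, no call in the condition
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# warning() without call
warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
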