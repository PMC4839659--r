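#' @useDynLib smrnakit, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rbinom rlnorm runif rnorm phyper median sd setNames
#' @importFrom utils read.delim write.table packageVersion head tail
NULL

# Internal coordinate convention: 0-based, half-open [start, end), explicit
# strand. Conversion to/from 1-based inclusive happens only at I/O boundaries.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T, case-insensitive).
#' @return character vector of reverse complements, uppercase.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  x <- gsub("U", "T", toupper(x), fixed = TRUE)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Normalize a sequence to uppercase DNA; returns list(seq, rna_origin).
normalize_dna <- function(x) {
  up <- toupper(x)
  rna <- grepl("U", up, fixed = TRUE)
  list(seq = gsub("U", "T", up, fixed = TRUE), rna_origin = rna)
}

# 0-based half-open substring of a 1-based R string.
substr0 <- function(seq, start0, end0) substr(seq, start0 + 1L, end0)

# Overlap length of two half-open intervals.
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

# Lower median: for even n, the n/2-th order statistic.
lower_median <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n == 0L) stop("lower_median of empty vector")
  x[[ceiling(n / 2)]]
}

# Deterministic seed derivation for named sub-streams, kept < 2^31.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
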