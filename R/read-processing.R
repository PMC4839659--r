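# Collapse raw reads to unique sequences with counts and apply the library's
# length and contaminant filters.

#' Collapse reads to unique sequences with counts
#'
#' @param reads character vector of sequences, or a data.frame from
#'   [read_sequences()] whose `count` column is honored (so collapsed
#'   libraries collapse idempotently).
#' @return data.frame `seq`,`count` ordered by descending count then
#'   lexicographically; `sum(count)` equals the input read total.
#' @export
collapse_reads <- function(reads) {
  if (is.data.frame(reads)) {
    seqs <- reads$seq
    counts <- if (is.null(reads$count)) rep(1L, length(seqs)) else reads$count
  } else {
    seqs <- as.character(reads)
    counts <- rep(1L, length(seqs))
  }
  if (length(seqs) == 0L) {
    return(data.frame(seq = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  tab <- tapply(counts, seqs, sum)
  out <- data.frame(seq = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$seq), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter unique reads by length and contaminant match
#'
#' Keeps reads whose length lies in `len_range` and whose sequence is not a
#' perfect match to a contaminant. Small RNAs are typically fragments of
#' tRNA/rRNA molecules, so the default match mode treats a read contained
#' anywhere inside a contaminant as a match (`containment = "substring"`);
#' `"whole"` requires full-sequence equality. `both_strands` additionally
#' matches the read's reverse complement.
#'
#' @param ur data.frame `seq`,`count` from [collapse_reads()].
#' @param len_range `c(min, max)` length window, nt.
#' @param contaminants character vector of contaminant sequences (DNA,
#'   case-insensitive), or NULL.
#' @param containment `"substring"` (default) or `"whole"`.
#' @param both_strands also remove reverse-complement matches (default TRUE).
#' @return filtered data.frame, counts unchanged on survivors. Idempotent.
#' @export
filter_reads <- function(ur, len_range, contaminants = NULL,
                         containment = c("substring", "whole"),
                         both_strands = TRUE) {
  containment <- match.arg(containment)
  if (nrow(ur) == 0L) return(ur)
  len <- nchar(ur$seq)
  keep <- len >= len_range[1] & len <= len_range[2]
  if (!is.null(contaminants) && length(contaminants) > 0L) {
    cont <- toupper(gsub("U", "T", toupper(contaminants), fixed = TRUE))
    is_cont <- function(seqs) {
      if (containment == "whole") {
        seqs %in% cont
      } else {
        vapply(seqs, function(s) any(grepl(s, cont, fixed = TRUE)), logical(1),
               USE.NAMES = FALSE)
      }
    }
    hit <- is_cont(ur$seq)
    if (both_strands) hit <- hit | is_cont(revcomp(ur$seq))
    keep <- keep & !hit
  }
  out <- ur[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Length histogram of a unique-read set
#'
#' @param ur data.frame `seq`,`count`.
#' @param weighted if TRUE, bins sum library counts; if FALSE, they count
#'   unique sequences.
#' @param range length window to bin over (default 15-30 nt).
#' @return named integer vector, one bin per length in `range`.
#' @export
length_histogram <- function(ur, weighted = TRUE, range = c(15L, 30L)) {
  lens <- seq.int(range[1], range[2])
  bins <- setNames(integer(length(lens)), as.character(lens))
  if (nrow(ur) == 0L) return(bins)
  len <- nchar(ur$seq)
  w <- if (weighted) ur$count else rep(1L, nrow(ur))
  agg <- tapply(w, len, sum)
  hitlens <- intersect(names(agg), names(bins))
  bins[hitlens] <- as.integer(agg[hitlens])
  bins
}
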