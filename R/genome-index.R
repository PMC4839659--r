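# Exact-match placement of short reads on both genome strands: a fixed-k
# seed table (hash of all k-mers) plus full-length verification. Reads are
# 15-30 nt and desk-scale genomes are small, so exactness is the rule and a
# full-text index is unnecessary.

#' Build an exact-match seed index of a genome
#'
#' @param genome named character vector of scaffold sequences (A/C/G/T), or a
#'   `synthetic_genome`.
#' @param k seed length; must not exceed the shortest queried read
#'   (default 12).
#' @return `genome_index` object supporting [map_exact()].
#' @export
build_index <- function(genome, k = 12L) {
  scaffolds <- if (inherits(genome, "synthetic_genome")) genome$scaffolds else genome
  stopifnot(is.character(scaffolds))
  if (is.null(names(scaffolds)) && length(scaffolds) > 0L) {
    names(scaffolds) <- paste0("scaffold_", seq_along(scaffolds))
  }
  k <- as.integer(k)
  seeds <- new.env(parent = emptyenv(), hash = TRUE)
  for (sc in names(scaffolds)) {
    seq <- scaffolds[[sc]]
    L <- nchar(seq)
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    kmers <- substring(seq, starts, starts + k - 1L)
    byk <- split(starts - 1L, kmers)  # 0-based starts
    for (km in names(byk)) {
      seeds[[km]] <- c(seeds[[km]], list(list(sc = sc, pos = byk[[km]])))
    }
  }
  structure(list(scaffolds = scaffolds, k = k, seeds = seeds),
            class = "genome_index")
}

.map_one_strand <- function(index, read) {
  k <- index$k
  seed <- substr(read, 1L, k)
  entries <- index$seeds[[seed]]
  if (is.null(entries)) return(NULL)
  n <- nchar(read)
  out <- list()
  for (e in entries) {
    seq <- index$scaffolds[[e$sc]]
    pos <- e$pos
    pos <- pos[pos + n <= nchar(seq)]
    if (length(pos) == 0L) next
    ok <- substring(seq, pos + 1L, pos + n) == read
    if (any(ok)) out[[length(out) + 1L]] <- data.frame(
      scaffold = e$sc, start = pos[ok], end = pos[ok] + n,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) NULL else do.call(rbind, out)
}

#' Map a read to all exact genomic occurrences on both strands
#'
#' A plus-strand hit means the genome substring at `[start, end)` equals the
#' read; a minus-strand hit means it equals the read's reverse complement.
#' Multi-mapping is preserved: one read can yield many hits.
#'
#' @param index `genome_index` from [build_index()].
#' @param read a single sequence (length >= the index seed size).
#' @return data.frame `scaffold`,`start`,`end`,`strand` (0-based half-open),
#'   sorted by scaffold, start, strand; zero rows when absent.
#' @export
map_exact <- function(index, read) {
  stopifnot(inherits(index, "genome_index"))
  read <- toupper(gsub("U", "T", toupper(read), fixed = TRUE))
  if (nchar(read) < index$k) {
    stop("read shorter than index seed length k = ", index$k, call. = FALSE)
  }
  plus <- .map_one_strand(index, read)
  minus <- .map_one_strand(index, revcomp(read))
  if (!is.null(plus)) plus$strand <- "+"
  if (!is.null(minus)) minus$strand <- "-"
  hits <- rbind(plus, minus)
  if (is.null(hits)) {
    return(data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  hits <- hits[order(hits$scaffold, hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Map a unique-read set, preserving multi-mapping
#'
#' @param index `genome_index`.
#' @param ur data.frame `seq`,`count`.
#' @param max_loci reads with more hits than this are flagged
#'   hyper-repetitive and excluded (they are repeat-derived by definition);
#'   default 1000.
#' @return list with `hits` (data.frame `seq`,`count`,`scaffold`,`start`,
#'   `end`,`strand`) and `hyper_repetitive` (character vector of excluded
#'   read sequences).
#' @export
map_reads <- function(index, ur, max_loci = 1000L) {
  hits <- vector("list", nrow(ur))
  hyper <- character(0)
  for (i in seq_len(nrow(ur))) {
    h <- map_exact(index, ur$seq[i])
    if (nrow(h) == 0L) next
    if (nrow(h) > max_loci) {
      hyper <- c(hyper, ur$seq[i])
      next
    }
    h$seq <- ur$seq[i]
    h$count <- ur$count[i]
    hits[[i]] <- h
  }
  hits <- do.call(rbind, hits)
  if (is.null(hits)) {
    hits <- data.frame(scaffold = character(0), start = integer(0),
                       end = integer(0), strand = character(0),
                       seq = character(0), count = integer(0),
                       stringsAsFactors = FALSE)
  }
  rownames(hits) <- NULL
  list(hits = hits, hyper_repetitive = hyper)
}
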