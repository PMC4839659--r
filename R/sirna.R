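# Classification of non-miRNA small RNAs: repeat-associated, phased
# trans-acting (hypergeometric phasing statistic), natural-antisense, and
# piRNA-like, with positional-bias diagnostics.

#' Flag repeat-associated small-RNA hits
#'
#' A hit is repeat-associated iff it is fully contained in a masked interval
#' (a read entirely inside a repeat is unambiguously repeat-derived; hits
#' straddling a mask boundary are not flagged).
#'
#' @param hits data.frame `seq`,`count`,`scaffold`,`start`,`end`,`strand`.
#' @param repeats masked intervals `scaffold`,`start`,`end` (0-based
#'   half-open).
#' @return list: `hits` with a logical `repeat_associated` column, and
#'   `summary` with the unique-read and count-weighted repeat fractions.
#' @export
rasirna_calls <- function(hits, repeats) {
  flag <- rep(FALSE, nrow(hits))
  if (nrow(repeats) > 0L && nrow(hits) > 0L) {
    for (r in seq_len(nrow(repeats))) {
      flag <- flag | (hits$scaffold == repeats$scaffold[r] &
                      hits$start >= repeats$start[r] &
                      hits$end <= repeats$end[r])
    }
  }
  hits$repeat_associated <- flag
  per_read <- tapply(flag, hits$seq, any)
  counts <- tapply(hits$count, hits$seq, max)
  uf <- if (length(per_read)) mean(per_read) else 0
  wf <- if (length(per_read)) sum(counts[per_read]) / sum(counts) else 0
  list(hits = hits,
       summary = list(unique_fraction = unname(uf),
                      weighted_fraction = unname(wf)))
}

#' Upper-tail hypergeometric phasing probability
#'
#' P[X >= k] for X ~ Hypergeometric(N population positions, K in-register
#' positions, n occupied positions), computed by log-stable summation of the
#' exact terms.
#'
#' @param k observed in-register occupied positions.
#' @param n occupied positions total.
#' @param K in-register positions available.
#' @param N total positions available.
#' @return probability in `[0, 1]`.
#' @export
phasing_pvalue <- function(k, n, K, N) {
  k <- as.integer(k); n <- as.integer(n); K <- as.integer(K); N <- as.integer(N)
  if (any(is.na(c(k, n, K, N))) || N < 0L || K < 0L || K > N || n < 0L ||
      n > N || k < 0L || k > min(n, K)) {
    stop("inconsistent hypergeometric counts (need 0 <= k <= min(n, K) <= N)")
  }
  if (k == 0L) return(1)
  upper <- min(n, K)
  logs <- vapply(k:upper, function(x) {
    lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)
  }, numeric(1))
  mx <- max(logs)
  min(1, exp(mx) * sum(exp(logs - mx)))
}

# Counts of occupied / in-register positions for one anchored window.
# Distinct read start positions on both strands; the antisense register is
# offset by +2 nt (the Dicer two-base overhang on the minus strand). A
# position occupied on both strands counts once per strand.
.window_phase_counts <- function(starts_plus, starts_minus, anchor, thresholds) {
  plen <- thresholds$phase_len
  wlen <- thresholds$phase_window
  sp <- unique(starts_plus[starts_plus >= anchor & starts_plus < anchor + wlen])
  sm <- unique(starts_minus[starts_minus >= anchor & starts_minus < anchor + wlen])
  k <- sum((sp - anchor) %% plen == 0L) + sum((sm - anchor - 2L) %% plen == 0L)
  n <- length(sp) + length(sm)
  K <- 2L * (wlen %/% plen)
  N <- 2L * wlen
  list(k = k, n = n, K = K, N = N)
}

#' Scan 21-nt hits for phased (ta-siRNA-like) loci
#'
#' Anchors a phase window at each distinct 21-nt read start, counts distinct
#' occupied start positions on both strands (antisense register offset
#' +2 nt), and tests the in-register occupancy against the hypergeometric
#' distribution. Because the anchoring read defines the register, the
#' p-value is computed conditionally on the anchor (k-1 of n-1 occupied
#' positions among K-1 of N-1); the reported `k`,`n`,`K`,`N` are the raw
#' window counts. Windows with p <= `phase_alpha` are reported, deduplicated
#' by overlap (lowest p wins).
#'
#' @param hits data.frame of hits restricted to 21-nt reads with repeats
#'   masked out upstream.
#' @param thresholds `smrna_thresholds`.
#' @return data.frame `scaffold`,`start`,`register`,`k`,`n`,`K`,`N`,
#'   `p_value`, one row per reported locus.
#' @export
tasirna_scan <- function(hits, thresholds = default_thresholds()) {
  empty <- data.frame(scaffold = character(0), start = integer(0),
                      register = integer(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p_value = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(empty)
  hits <- hits[hits$end - hits$start == thresholds$phase_len, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty)
  out <- list()
  for (sc in unique(hits$scaffold)) {
    h <- hits[hits$scaffold == sc, , drop = FALSE]
    sp <- sort(unique(h$start[h$strand == "+"]))
    sm <- sort(unique(h$start[h$strand == "-"]))
    for (anchor in sort(unique(h$start))) {
      cts <- .window_phase_counts(sp, sm, anchor, thresholds)
      if (cts$n < 2L || cts$k < 1L) next
      p <- phasing_pvalue(max(0L, cts$k - 1L), cts$n - 1L, cts$K - 1L,
                          cts$N - 1L)
      if (p <= thresholds$phase_alpha) {
        out[[length(out) + 1L]] <- data.frame(
          scaffold = sc, start = anchor,
          register = anchor %% thresholds$phase_len,
          k = cts$k, n = cts$n, K = cts$K, N = cts$N, p_value = p,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) return(empty)
  loci <- do.call(rbind, out)
  loci <- loci[order(loci$p_value, loci$scaffold, loci$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(loci))
  wlen <- thresholds$phase_window
  for (i in seq_len(nrow(loci))) {
    if (!keep[i]) next
    later <- which(keep & seq_len(nrow(loci)) > i &
                   loci$scaffold == loci$scaffold[i] &
                   abs(loci$start - loci$start[i]) < wlen)
    keep[later] <- FALSE
  }
  loci <- loci[keep, , drop = FALSE]
  loci <- loci[order(loci$scaffold, loci$start), , drop = FALSE]
  rownames(loci) <- NULL
  loci
}

#' Natural-antisense siRNA calls and overlapping gene pairs
#'
#' Flags hits whose locus overlaps an exon on the opposite strand of the
#' annotated gene, and separately reports all gene pairs on opposite strands
#' whose spans overlap by at least `nat_min_overlap` nt.
#'
#' @param hits data.frame of hits.
#' @param genes `gene_models`.
#' @param thresholds `smrna_thresholds`.
#' @return list: `hits` with a logical `antisense_exon` column, and `pairs`
#'   (data.frame `gene_a`,`gene_b`,`overlap`).
#' @export
natsirna_calls <- function(hits, genes, thresholds = default_thresholds()) {
  ex <- genes$exons
  flag <- rep(FALSE, nrow(hits))
  if (nrow(ex) > 0L && nrow(hits) > 0L) {
    for (r in seq_len(nrow(ex))) {
      flag <- flag | (hits$scaffold == ex$scaffold[r] &
                      hits$start < ex$end[r] & hits$end > ex$start[r] &
                      hits$strand != ex$strand[r])
    }
  }
  hits$antisense_exon <- flag
  g <- genes$genes
  pairs <- list()
  if (nrow(g) > 1L) {
    for (i in seq_len(nrow(g) - 1L)) {
      for (j in seq.int(i + 1L, nrow(g))) {
        if (g$scaffold[i] != g$scaffold[j] || g$strand[i] == g$strand[j]) next
        ov <- interval_overlap(g$start[i], g$end[i], g$start[j], g$end[j])
        if (ov >= thresholds$nat_min_overlap) {
          pairs[[length(pairs) + 1L]] <- data.frame(
            gene_a = g$gene_id[i], gene_b = g$gene_id[j], overlap = ov,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(gene_a = character(0), gene_b = character(0),
               overlap = integer(0), stringsAsFactors = FALSE)
  list(hits = hits, pairs = pairs)
}

.context_labels <- c("antisense_exon", "antisense_intron", "intergenic",
                     "sense_exon", "sense_intron")

.label_one_hit <- function(scaffold, start, end, strand, genes) {
  ex <- genes$exons; g <- genes$genes
  if (nrow(ex) > 0L) {
    hit <- ex$scaffold == scaffold & ex$start < end & ex$end > start
    if (any(hit)) {
      same <- any(hit & ex$strand == strand)
      return(if (same) "sense_exon" else "antisense_exon")
    }
  }
  if (nrow(g) > 0L) {
    hit <- g$scaffold == scaffold & g$start < end & g$end > start
    if (any(hit)) {
      same <- any(hit & g$strand == strand)
      return(if (same) "sense_intron" else "antisense_intron")
    }
  }
  "intergenic"
}

#' Per-read genomic context from multi-mapping hits
#'
#' Each hit gets one label from sense/antisense exon/intron or intergenic;
#' each read then takes its most frequent non-intergenic label across its
#' hits (intergenic only when all hits are intergenic), ties broken by the
#' lexicographically first label.
#'
#' @param hits data.frame of hits with a `seq` column.
#' @param genes `gene_models`.
#' @return list: `hits` with a `context` column, `reads` (data.frame
#'   `seq`,`context`), and `summary` (label counts over reads).
#' @export
annotate_hit_context <- function(hits, genes) {
  if (nrow(hits) == 0L) {
    return(list(hits = cbind(hits, context = character(0)),
                reads = data.frame(seq = character(0), context = character(0),
                                   stringsAsFactors = FALSE),
                summary = table(factor(character(0), levels = .context_labels))))
  }
  hits$context <- vapply(seq_len(nrow(hits)), function(i) {
    .label_one_hit(hits$scaffold[i], hits$start[i], hits$end[i],
                   hits$strand[i], genes)
  }, character(1))
  per_read <- vapply(split(hits$context, hits$seq), function(lbl) {
    feat <- lbl[lbl != "intergenic"]
    if (length(feat) == 0L) return("intergenic")
    tab <- table(feat)
    names(tab)[order(-tab, names(tab))][1]   # most frequent, then lexicographic
  }, character(1))
  reads <- data.frame(seq = names(per_read), context = unname(per_read),
                      stringsAsFactors = FALSE)
  list(hits = hits, reads = reads,
       summary = table(factor(reads$context,
                              levels = c(.context_labels))))
}

# k-mer frequency features, k = 1..5 (dimension 4+16+64+256+1024 = 1364).
pirna_features <- function(seqs) {
  ks <- 1:5
  cols <- unlist(lapply(ks, function(k) {
    apply(expand.grid(rep(list(DNA_BASES), k))[, k:1, drop = FALSE], 1,
          paste, collapse = "")
  }))
  X <- matrix(0, nrow = length(seqs), ncol = length(cols),
              dimnames = list(NULL, cols))
  for (i in seq_along(seqs)) {
    s <- toupper(gsub("U", "T", toupper(seqs[i]), fixed = TRUE))
    L <- nchar(s)
    for (k in ks) {
      if (L < k) next
      starts <- seq_len(L - k + 1L)
      kmers <- substring(s, starts, starts + k - 1L)
      tab <- table(kmers) / length(kmers)
      known <- intersect(names(tab), cols)
      X[i, known] <- as.numeric(tab[known])
    }
  }
  X
}

#' k-mer Fisher-discriminant piRNA classifier
#'
#' Features are normalized k-mer frequencies for k = 1..5 (1364 dimensions).
#' A Fisher linear discriminant is fitted on the two training sets with a
#' ridge-regularized pooled covariance; the decision threshold is the
#' midpoint of the projected class means. Deterministic.
#'
#' @param train_pos,train_neg character vectors of training sequences
#'   (positive = piRNA-like).
#' @param queries sequences to score (26-30 nt is the expected range).
#' @param ridge covariance regularization (default 1e-3).
#' @return data.frame `seq`,`score`,`label` (`TRUE` = piRNA-like); the
#'   fitted direction and threshold in attributes `weights`,`threshold`.
#' @export
pirna_classify <- function(train_pos, train_neg, queries, ridge = 1e-3) {
  if (length(train_pos) == 0L || length(train_neg) == 0L) {
    stop("both training sets must be non-empty")
  }
  Xp <- pirna_features(train_pos)
  Xn <- pirna_features(train_neg)
  mp <- colMeans(Xp); mn <- colMeans(Xn)
  center <- function(X, m) sweep(X, 2, m)
  Sw <- (crossprod(center(Xp, mp)) + crossprod(center(Xn, mn))) /
    max(1L, nrow(Xp) + nrow(Xn) - 2L)
  d <- ncol(Xp)
  w <- solve(Sw + diag(ridge, d), mp - mn)
  thr <- as.numeric((mp + mn) %*% w / 2)
  Xq <- pirna_features(queries)
  score <- as.numeric(Xq %*% w)
  structure(
    data.frame(seq = queries, score = score, label = score > thr,
               stringsAsFactors = FALSE),
    weights = w, threshold = thr)
}

#' Base frequency at a fixed position
#'
#' Fraction of sequences of length >= `position` carrying `base` at that
#' position (e.g. the 5'-uracil bias at position 1, or the ping-pong
#' adenosine signature at position 10). Diagnostic only, never a filter.
#'
#' @param seqs character vector.
#' @param position 1-based position.
#' @param base single base (T and U are equivalent).
#' @return fraction in `[0, 1]`; 0 with a warning for an empty input.
#' @export
positional_bias <- function(seqs, position, base) {
  stopifnot(position >= 1L)
  base <- gsub("U", "T", toupper(base), fixed = TRUE)
  seqs <- seqs[nchar(seqs) >= position]
  if (length(seqs) == 0L) {
    warning("no sequences long enough for position ", position)
    return(0)
  }
  s <- gsub("U", "T", toupper(seqs), fixed = TRUE)
  mean(substr(s, position, position) == base)
}
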