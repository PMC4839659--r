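# Core discovery computation: window extraction around genome hits, hairpin
# curation, miRNA* duplex detection, abundance-threshold candidate selection,
# and genomic-context classification.

#' Candidate precursor windows around a genomic hit
#'
#' For each window length w in `{window_min, window_min + step, ...,
#' window_max}` (13 lengths under defaults), emits up to three placements:
#' mature anchored near the window 5' end with a 10-nt flank, near the 3'
#' end with a 10-nt flank, and centered. Placements falling outside the
#' scaffold are dropped; duplicates are removed. The window sequence is
#' taken on the hit's strand and the mature span is reported in window-local
#' 1-based coordinates on that strand.
#'
#' @param hit list or one-row data.frame with `scaffold`,`start`,`end`,
#'   `strand` (0-based half-open).
#' @param genome named character vector of scaffolds (or `synthetic_genome`).
#' @param thresholds `smrna_thresholds`.
#' @return data.frame `scaffold`,`start`,`end`,`strand`,`width`,`seq`,
#'   `mature_start`,`mature_end`.
#' @export
scan_windows <- function(hit, genome, thresholds = default_thresholds()) {
  scaffolds <- if (inherits(genome, "synthetic_genome")) genome$scaffolds else genome
  sc <- hit$scaffold
  L <- nchar(scaffolds[[sc]])
  hs <- hit$start; he <- hit$end; hlen <- he - hs
  widths <- seq.int(thresholds$window_min, thresholds$window_max,
                    by = thresholds$window_step)
  rows <- list()
  for (w in widths) {
    if (w < hlen) next
    starts <- unique(c(hs - 10L,                       # mature near one end
                       he + 10L - w,                   # mature near the other
                       hs - (w - hlen) %/% 2L))        # centered
    for (ws in starts) {
      we <- ws + w
      if (ws < 0L || we > L) next          # out-of-bounds placements dropped
      if (hs < ws || he > we) next
      rows[[length(rows) + 1L]] <- c(ws, we)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      width = integer(0), seq = character(0),
                      mature_start = integer(0), mature_end = integer(0),
                      stringsAsFactors = FALSE))
  }
  m <- unique(do.call(rbind, rows))
  ws <- m[, 1]; we <- m[, 2]
  seqs <- substring(scaffolds[[sc]], ws + 1L, we)
  if (hit$strand == "-") {
    seqs <- revcomp(seqs)
    mstart <- we - he + 1L
    mend <- we - hs
  } else {
    mstart <- hs - ws + 1L
    mend <- he - ws
  }
  data.frame(scaffold = sc, start = ws, end = we, strand = hit$strand,
             width = we - ws, seq = seqs, mature_start = mstart,
             mature_end = mend, stringsAsFactors = FALSE)
}

.n_hairpin_loops <- function(structure) {
  hits <- gregexpr("\\(\\.*\\)", structure)[[1]]
  if (hits[1] == -1L) 0L else length(hits)
}

# Mismatch/bulge accounting over the mature region. For each maximal
# unpaired run inside the mature, the opposing gap between the partners of
# its flanking paired positions determines how many run positions face a
# nucleotide (mismatches, up to the opposing gap size) and how many are
# unopposed (one bulge run of the excess length). Terminal unpaired runs
# with no paired flank on one side count as mismatches.
.mature_defects <- function(partner, a, b) {
  mm <- 0L; bulges <- 0L; max_bulge <- 0L
  pos <- a:b
  unp <- partner[pos] == 0L
  if (!any(unp)) return(list(mismatches = 0L, bulges = 0L, max_bulge_len = 0L))
  r <- rle(unp)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    run_len <- r$lengths[k]
    r1 <- pos[starts[k]]; r2 <- pos[ends[k]]
    left <- if (r1 > 1L) max(which(partner[seq_len(r1 - 1L)] > 0L), -Inf) else -Inf
    right_cand <- which(partner > 0L)
    right_cand <- right_cand[right_cand > r2]
    right <- if (length(right_cand)) min(right_cand) else Inf
    if (!is.finite(left) || !is.finite(right)) {
      mm <- mm + run_len
      next
    }
    g <- partner[left] - partner[right] - 1L
    if (g < 0L) {            # flanks not on a common stem: count as mismatches
      mm <- mm + run_len
      next
    }
    mm <- mm + min(run_len, g)
    excess <- run_len - g
    if (excess > 0L) {
      bulges <- bulges + 1L
      max_bulge <- max(max_bulge, excess)
    }
  }
  list(mismatches = mm, bulges = bulges, max_bulge_len = max_bulge)
}

#' Curate a precursor window against the hairpin ("good structure") criteria
#'
#' Folds the window and checks: exactly one terminal loop; at least half of
#' the window positions paired; at most four mismatched and two short
#' (<= 2 nt) bulged positions runs in the mature region; and a minimum free
#' energy below `mfe_coeff * length` (e.g. below -35 kcal/mol for a 100-nt
#' precursor).
#'
#' @param window precursor window sequence.
#' @param mature_span `c(start, end)` of the mature read within the window,
#'   1-based inclusive.
#' @param thresholds `smrna_thresholds`.
#' @param fold optional precomputed `fold_result` for `window`.
#' @return `hairpin_verdict`: list with `passes`, `reasons`, `paired_frac`,
#'   `n_loops`, `mismatches_in_mature`, `bulges_in_mature`, `mfe`,
#'   `mfe_threshold`, `structure`, `partner`.
#' @export
evaluate_hairpin <- function(window, mature_span,
                             thresholds = default_thresholds(), fold = NULL) {
  L <- nchar(window)
  a <- as.integer(mature_span[1]); b <- as.integer(mature_span[2])
  if (a < 1L || b > L || a > b) stop("mature_span outside window")
  if (is.null(fold)) fold <- fold_mfe(window)
  partner <- fold$partner
  reasons <- character(0)
  n_loops <- .n_hairpin_loops(fold$structure)
  paired_frac <- mean(partner > 0L)
  defects <- .mature_defects(partner, a, b)
  mfe_threshold <- thresholds$mfe_coeff * L
  if (n_loops != 1L) reasons <- c(reasons, "multi_loop")
  if (paired_frac < thresholds$min_paired_frac) reasons <- c(reasons, "low_paired_frac")
  if (defects$mismatches > thresholds$max_mismatch_mature) reasons <- c(reasons, "mismatch_excess")
  if (defects$bulges > thresholds$max_bulge_mature) reasons <- c(reasons, "bulge_excess")
  if (defects$max_bulge_len > thresholds$max_bulge_len) reasons <- c(reasons, "bulge_too_long")
  if (!(fold$energy < mfe_threshold)) reasons <- c(reasons, "mfe_above_threshold")
  structure(
    list(passes = length(reasons) == 0L, reasons = reasons,
         paired_frac = paired_frac, n_loops = n_loops,
         mismatches_in_mature = defects$mismatches,
         bulges_in_mature = defects$bulges,
         mfe = fold$energy, mfe_threshold = mfe_threshold,
         structure = fold$structure, partner = partner),
    class = "hairpin_verdict"
  )
}

# Expected miRNA* span from the fold: the opposite-arm segment pairing with
# the mature, with both 3' ends shifted by the Dicer overhang.
infer_star_span <- function(partner, mature_span, overhang = 2L) {
  a <- mature_span[1]; b <- mature_span[2]
  duplex_pos <- a:max(a, b - overhang)
  paired <- duplex_pos[partner[duplex_pos] > 0L]
  if (length(paired) == 0L) return(NULL)
  p1 <- min(paired); p2 <- max(paired)
  d1 <- p1 - a
  d2 <- (b - overhang) - p2
  star_start <- partner[p2] - d2
  star_end <- partner[p1] + d1 + overhang
  if (star_start < 1L || star_end > length(partner) || star_start >= star_end) return(NULL)
  if (interval_overlap(star_start, star_end + 1L, a, b + 1L) > 0L) return(NULL)
  c(star_start, star_end)
}

#' Locate the miRNA* read of a curated hairpin
#'
#' Derives the expected star span from the structure (opposite-arm partner
#' segment of the mature, both 3' ends shifted by the 2-nt overhang) and
#' reports a star only when a mapped read coincides with that span within
#' +/- 1 nt at each end and the duplex carries at most four mismatches.
#'
#' @param verdict a passing `hairpin_verdict` for the window.
#' @param mature_span `c(start, end)` 1-based inclusive within the window.
#' @param window_reads data.frame of reads mapped inside the window on its
#'   strand, window-local 1-based inclusive `start`,`end` plus `seq`,`count`.
#' @param thresholds `smrna_thresholds`.
#' @return list `start`,`end`,`seq`,`count` or `NULL` when absent.
#' @export
locate_star <- function(verdict, mature_span, window_reads,
                        thresholds = default_thresholds()) {
  span <- infer_star_span(verdict$partner, as.integer(mature_span),
                          thresholds$overhang)
  if (is.null(span)) return(NULL)
  a <- mature_span[1]; b <- mature_span[2]
  duplex_pos <- a:max(a, b - thresholds$overhang)
  if (sum(verdict$partner[duplex_pos] == 0L) > thresholds$max_mismatch_mature) {
    return(NULL)
  }
  if (nrow(window_reads) == 0L) return(NULL)
  ok <- abs(window_reads$start - span[1]) <= 1L &
        abs(window_reads$end - span[2]) <= 1L
  if (!any(ok)) return(NULL)
  cand <- window_reads[ok, , drop = FALSE]
  cand <- cand[order(-cand$count, cand$seq), , drop = FALSE]
  list(start = cand$start[1], end = cand$end[1],
       seq = cand$seq[1], count = cand$count[1])
}

#' Classify a locus relative to annotated gene models
#'
#' Exon if the locus overlaps any exon by at least 1 nt; otherwise intron if
#' it lies within a gene span; otherwise intergenic. Strand-agnostic.
#'
#' @param scaffold,start,end locus (0-based half-open).
#' @param genes `gene_models` or `NULL`.
#' @return one of `"exon"`, `"intron"`, `"intergenic"`.
#' @export
classify_context <- function(scaffold, start, end, genes) {
  if (is.null(genes) || nrow(genes$genes) == 0L) return("intergenic")
  ex <- genes$exons
  if (nrow(ex) > 0L) {
    hit <- ex$scaffold == scaffold & ex$start < end & ex$end > start
    if (any(hit)) return("exon")
  }
  g <- genes$genes
  hit <- g$scaffold == scaffold & g$start < end & g$end > start
  if (any(hit)) return("intron")
  "intergenic"
}

# Reads mapped within a window, converted to window-local 1-based
# coordinates on the window strand.
.window_local_reads <- function(hits, scaffold, ws, we, strand) {
  sel <- hits$scaffold == scaffold & hits$strand == strand &
    hits$start >= ws & hits$end <= we
  h <- hits[sel, , drop = FALSE]
  if (nrow(h) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      seq = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  if (strand == "-") {
    data.frame(start = we - h$end + 1L, end = we - h$start,
               seq = h$seq, count = h$count, stringsAsFactors = FALSE)
  } else {
    data.frame(start = h$start - ws + 1L, end = h$end - ws,
               seq = h$seq, count = h$count, stringsAsFactors = FALSE)
  }
}

#' Discover miRNA candidates from a filtered read library
#'
#' Full pipeline per read: exact-match mapping, precursor window scan,
#' hairpin curation, miRNA* location, abundance rules (count >= 3 with a
#' star read on the opposite arm, or >= 100 for well-folded precursors
#' without one), deduplication of overlapping precursors, and genomic
#' context classification.
#'
#' @param ur unique reads (`seq`,`count`), already length-filtered to the
#'   mature-miRNA range and contaminant-filtered.
#' @param genome named character vector of scaffolds or `synthetic_genome`.
#' @param genes `gene_models` or `NULL`.
#' @param thresholds `smrna_thresholds`.
#' @param max_loci hyper-repetitive cutoff passed to [map_reads()].
#' @return `mirna_candidates` data.frame, one row per candidate, sorted in
#'   genome order with ids assigned in that order.
#' @export
call_mirnas <- function(ur, genome, genes = NULL,
                        thresholds = default_thresholds(), max_loci = 1000L) {
  scaffolds <- if (inherits(genome, "synthetic_genome")) genome$scaffolds else genome
  empty <- data.frame(
    id = character(0), seq = character(0), length = integer(0),
    abundance = integer(0), star_abundance = integer(0),
    scaffold = character(0), precursor_start = integer(0),
    precursor_end = integer(0), strand = character(0),
    precursor_length = integer(0), precursor_seq = character(0),
    structure = character(0), mfe = numeric(0), genomic_region = character(0),
    has_star = logical(0), n_loci = integer(0), stringsAsFactors = FALSE
  )
  class(empty) <- c("mirna_candidates", "data.frame")
  if (nrow(ur) == 0L) return(empty)

  idx <- build_index(scaffolds)
  mapped <- map_reads(idx, ur, max_loci = max_loci)
  hits <- mapped$hits
  if (nrow(hits) == 0L) return(empty)

  len <- nchar(ur$seq)
  cand <- ur[ur$count >= thresholds$min_abund_with_star &
             len >= thresholds$mirna_len_min &
             len <= thresholds$mirna_len_max, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)

  verdict_cache <- new.env(parent = emptyenv(), hash = TRUE)
  rows <- list()
  for (i in seq_len(nrow(cand))) {
    rseq <- cand$seq[i]; rcount <- cand$count[i]
    rhits <- hits[hits$seq == rseq, , drop = FALSE]
    n_loci <- nrow(rhits)
    if (n_loci == 0L) next
    for (h in seq_len(n_loci)) {
      hit <- rhits[h, ]
      wins <- scan_windows(hit, scaffolds, thresholds)
      for (wi in seq_len(nrow(wins))) {
        w <- wins[wi, ]
        key <- paste0(w$seq, "|", w$mature_start, "|", w$mature_end)
        verdict <- verdict_cache[[key]]
        if (is.null(verdict)) {
          verdict <- evaluate_hairpin(w$seq, c(w$mature_start, w$mature_end),
                                      thresholds)
          verdict_cache[[key]] <- verdict
        }
        if (!verdict$passes) next
        wreads <- .window_local_reads(hits, w$scaffold, w$start, w$end, w$strand)
        wreads <- wreads[wreads$seq != rseq, , drop = FALSE]
        star <- locate_star(verdict, c(w$mature_start, w$mature_end), wreads,
                            thresholds)
        rows[[length(rows) + 1L]] <- data.frame(
          seq = rseq, length = nchar(rseq), abundance = rcount,
          star_abundance = if (is.null(star)) NA_integer_ else star$count,
          scaffold = w$scaffold, precursor_start = w$start,
          precursor_end = w$end, strand = w$strand,
          precursor_length = w$width, precursor_seq = w$seq,
          structure = verdict$structure, mfe = verdict$mfe,
          has_star = !is.null(star), n_loci = n_loci,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  tab <- do.call(rbind, rows)

  # abundance rule + best window per read: prefer eligible windows, then
  # lowest MFE, then shortest precursor, then leftmost.
  tab$eligible <- (tab$has_star & tab$abundance >= thresholds$min_abund_with_star) |
    tab$abundance >= thresholds$min_abund_no_star
  tab <- tab[order(tab$seq, -tab$eligible, tab$mfe, tab$precursor_length,
                   tab$scaffold, tab$precursor_start), , drop = FALSE]
  tab <- tab[!duplicated(tab$seq), , drop = FALSE]
  tab <- tab[tab$eligible, , drop = FALSE]
  tab$eligible <- NULL
  if (nrow(tab) == 0L) return(empty)

  # merge candidates whose precursors overlap >= 50% of the shorter locus,
  # keeping the higher-abundance mature
  tab <- tab[order(-tab$abundance, tab$seq), , drop = FALSE]
  keep <- rep(TRUE, nrow(tab))
  for (i in seq_len(nrow(tab))) {
    if (!keep[i]) next
    if (i == nrow(tab)) break
    for (j in seq.int(i + 1L, nrow(tab))) {
      if (!keep[j]) next
      if (tab$scaffold[j] != tab$scaffold[i]) next
      ov <- interval_overlap(tab$precursor_start[i], tab$precursor_end[i],
                             tab$precursor_start[j], tab$precursor_end[j])
      shorter <- min(tab$precursor_length[i], tab$precursor_length[j])
      if (ov >= 0.5 * shorter) keep[j] <- FALSE
    }
  }
  tab <- tab[keep, , drop = FALSE]

  tab <- tab[order(tab$scaffold, tab$precursor_start, tab$seq), , drop = FALSE]
  tab$id <- sprintf("mir%02d", seq_len(nrow(tab)))
  tab$genomic_region <- vapply(seq_len(nrow(tab)), function(i) {
    classify_context(tab$scaffold[i], tab$precursor_start[i],
                     tab$precursor_end[i], genes)
  }, character(1))
  tab <- tab[, c("id", "seq", "length", "abundance", "star_abundance",
                 "scaffold", "precursor_start", "precursor_end", "strand",
                 "precursor_length", "precursor_seq", "structure", "mfe",
                 "genomic_region", "has_star", "n_loci")]
  rownames(tab) <- NULL
  class(tab) <- c("mirna_candidates", "data.frame")
  tab
}

#' Longest suffix of one sequence equal to a prefix of another
#'
#' @param a,b sequences.
#' @return overlap length in nt.
#' @export
suffix_prefix_overlap <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  for (k in seq.int(min(na, nb), 1L, length.out = min(na, nb))) {
    k <- as.integer(k)
    if (substr(a, na - k + 1L, na) == substr(b, 1L, k)) return(k)
  }
  0L
}

#' Summary statistics of a candidate table
#'
#' Medians are lower medians (for even n, the n/2-th order statistic);
#' context percentages are rounded to the nearest integer.
#'
#' @param cands `mirna_candidates` or any data.frame with columns `length`,
#'   `abundance`, `star_abundance`, `precursor_length`, `genomic_region`.
#' @return list of summary statistics.
#' @export
summarize_candidates <- function(cands) {
  if (nrow(cands) == 0L) stop("cannot summarize an empty candidate list")
  ab <- cands$abundance[!is.na(cands$abundance)]
  ctx <- table(tolower(cands$genomic_region))
  pct <- round(100 * as.numeric(ctx) / nrow(cands))
  names(pct) <- names(ctx)
  list(
    n = nrow(cands),
    median_mature_len = lower_median(cands$length),
    min_mature_len = min(cands$length),
    max_mature_len = max(cands$length),
    min_abundance = if (length(ab)) min(ab) else NA_integer_,
    max_abundance = if (length(ab)) max(ab) else NA_integer_,
    n_star = sum(!is.na(cands$star_abundance)),
    median_precursor_len = lower_median(cands$precursor_length),
    min_precursor_len = min(cands$precursor_length),
    max_precursor_len = max(cands$precursor_length),
    context_pct = pct
  )
}

#' Curated reference miRNA candidate table
#'
#' The 18-candidate curated set for the coccolithophore *Emiliania huxleyi*
#' (mature sequence, library abundance, star abundance where a miRNA* was
#' sequenced, precursor length, and genomic context), bundled as a
#' regression fixture for the summary statistics.
#'
#' @return data.frame with columns `id`, `sequence`, `length`, `abundance`,
#'   `star_abundance`, `precursor_length`, `genomic_region`.
#' @export
ehux_mirna_candidates <- function() {
  path <- system.file("extdata", "ehux_mirna_candidates.tsv",
                      package = "smrnakit", mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$genomic_region <- tolower(df$genomic_region)
  names(df)[names(df) == "sequence"] <- "seq"
  df$length <- nchar(df$seq)
  df
}
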