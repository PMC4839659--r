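# miRNA target prediction in two modes: plant-like (near-perfect reverse
# complementarity with weighted mismatches plus a site-accessibility screen)
# and animal-like (perfect seed pairing plus a duplex-energy bound), with
# GO level-2 clustering of target genes.

.comp_base <- c(A = "T", C = "G", G = "C", T = "A")

# weighted mismatch score of miRNA (5'->3') against a target site (5'->3'):
# Watson-Crick 0, G:U wobble 0.5, else 1. The miRNA pairs the site
# antiparallel, so miRNA position i faces site position (len - i + 1).
.site_mismatch_score <- function(mirna_chars, site_chars) {
  n <- length(mirna_chars)
  face <- rev(site_chars)
  score <- 0
  for (i in seq_len(n)) {
    a <- mirna_chars[i]; b <- face[i]
    if (.comp_base[[a]] == b) next
    wobble <- (a == "G" && b == "T") || (a == "T" && b == "G")
    score <- score + if (wobble) 0.5 else 1
  }
  score
}

#' Site-opening (unpaired) energy of a target site
#'
#' Energetic cost of forcing the site open within a context window centered
#' on it: `fold_constrained(context, site) - fold_mfe(context)`.
#'
#' @param transcript transcript sequence.
#' @param site_start,site_end 1-based inclusive site interval.
#' @param context_len context window length, nt (default 200, clipped at the
#'   transcript ends).
#' @return UPE in kcal/mol (>= 0).
#' @export
site_upe <- function(transcript, site_start, site_end, context_len = 200L) {
  L <- nchar(transcript)
  half <- context_len %/% 2L
  mid <- (site_start + site_end) %/% 2L
  cs <- max(1L, mid - half)
  ce <- min(L, cs + context_len - 1L)
  cs <- max(1L, ce - context_len + 1L)
  ctx <- substr(transcript, cs, ce)
  rel <- c(site_start - cs + 1L, site_end - cs + 1L)
  open <- fold_constrained(ctx, rel)$energy
  closed <- fold_mfe(ctx)$energy
  max(0, open - closed)
}

# merge overlapping sites of one miRNA-transcript pair to the best-scoring
# one (one biological site, many alignments)
.merge_sites <- function(df, score_col, decreasing = FALSE) {
  if (nrow(df) <= 1L) return(df)
  df <- df[order(df$transcript, df[[score_col]] * if (decreasing) -1 else 1,
                 df$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!keep[i]) next
    later <- which(keep & seq_len(nrow(df)) > i &
                   df$transcript == df$transcript[i] &
                   df$start < df$end[i] + 1L & df$end > df$start[i] - 1L)
    keep[later] <- FALSE
  }
  out <- df[keep, , drop = FALSE]
  out[order(out$transcript, out$start), , drop = FALSE]
}

#' Plant-mode target prediction
#'
#' Scans every transcript position for reverse-complement alignments of the
#' miRNA, scoring full mismatches 1 and G:U wobbles 0.5; sites with weighted
#' mismatches <= `plant_max_mismatch` are then screened by the unpaired
#' energy needed to open the site ([site_upe()]), keeping
#' UPE <= `plant_max_upe`. Overlapping alignments are merged to the
#' best-scoring site.
#'
#' @param mirna mature miRNA sequence (18-26 nt).
#' @param transcripts named character vector of transcript sequences, or a
#'   data.frame with `id` and `seq`.
#' @param thresholds `smrna_thresholds`.
#' @param context_len UPE context window (default 200 nt).
#' @return data.frame `transcript`,`start`,`end`,`mismatches`,`gu_pairs`,
#'   `energy`,`upe`,`mode` (1-based inclusive site coordinates).
#' @export
plant_targets <- function(mirna, transcripts,
                          thresholds = default_thresholds(),
                          context_len = 200L) {
  tx <- .as_tx(transcripts)
  mirna <- toupper(gsub("U", "T", toupper(mirna), fixed = TRUE))
  n <- nchar(mirna)
  if (n < thresholds$mirna_len_min || n > thresholds$mirna_len_max) {
    stop("miRNA length outside the mature range")
  }
  mch <- strsplit(mirna, "")[[1]]
  rows <- list()
  for (t in seq_along(tx)) {
    s <- tx[[t]]
    L <- nchar(s)
    if (L < n) next
    sch <- strsplit(s, "")[[1]]
    for (st in seq_len(L - n + 1L)) {
      site <- sch[st:(st + n - 1L)]
      sc <- .site_mismatch_score(mch, site)
      if (sc > thresholds$plant_max_mismatch) next
      face <- rev(site)
      gu <- sum((mch == "G" & face == "T") | (mch == "T" & face == "G"))
      rows[[length(rows) + 1L]] <- data.frame(
        transcript = names(tx)[t], start = st, end = st + n - 1L,
        mismatches = sc, gu_pairs = gu, stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(transcript = character(0), start = integer(0),
                      end = integer(0), mismatches = numeric(0),
                      gu_pairs = integer(0), energy = numeric(0),
                      upe = numeric(0), mode = character(0),
                      stringsAsFactors = FALSE)
  if (length(rows) == 0L) return(empty)
  df <- do.call(rbind, rows)
  df <- .merge_sites(df, "mismatches")
  df$energy <- vapply(seq_len(nrow(df)), function(i) {
    duplex_energy(mirna, substr(tx[[df$transcript[i]]], df$start[i], df$end[i]))
  }, numeric(1))
  df$upe <- vapply(seq_len(nrow(df)), function(i) {
    site_upe(tx[[df$transcript[i]]], df$start[i], df$end[i], context_len)
  }, numeric(1))
  df <- df[df$upe <= thresholds$plant_max_upe, , drop = FALSE]
  if (nrow(df) == 0L) return(empty)
  df$mode <- "plant"
  rownames(df) <- NULL
  df
}

#' Animal-mode target prediction
#'
#' Candidate sites are exact matches of the reverse complement of the seed
#' (miRNA positions 2-8 from the 5' end) in the transcript; each is extended
#' to the full miRNA length and kept when the intermolecular duplex energy
#' is below `animal_max_energy` (default -20 kcal/mol).
#'
#' @inheritParams plant_targets
#' @return data.frame `transcript`,`start`,`end`,`energy`,`mode`.
#' @export
animal_targets <- function(mirna, transcripts,
                           thresholds = default_thresholds()) {
  tx <- .as_tx(transcripts)
  mirna <- toupper(gsub("U", "T", toupper(mirna), fixed = TRUE))
  n <- nchar(mirna)
  seed <- substr(mirna, thresholds$animal_seed_start, thresholds$animal_seed_end)
  seed_rc <- revcomp(seed)
  empty <- data.frame(transcript = character(0), start = integer(0),
                      end = integer(0), energy = numeric(0),
                      mode = character(0), stringsAsFactors = FALSE)
  rows <- list()
  for (t in seq_along(tx)) {
    s <- tx[[t]]
    L <- nchar(s)
    hits <- gregexpr(seed_rc, s, fixed = TRUE)[[1]]
    if (hits[1] == -1L) next
    for (h in as.integer(hits)) {
      # seed (miRNA 2-8) pairs the 3' part of the site; extend so the whole
      # miRNA faces the site: site runs 5'->3', miRNA position 1 faces its
      # 3' end
      seed_rc_end <- h + nchar(seed_rc) - 1L
      site_start <- seed_rc_end + thresholds$animal_seed_start - n
      site_end <- site_start + n - 1L
      if (site_start < 1L || site_end > L) next
      e <- duplex_energy(mirna, substr(s, site_start, site_end))
      if (e < thresholds$animal_max_energy) {
        rows[[length(rows) + 1L]] <- data.frame(
          transcript = names(tx)[t], start = site_start, end = site_end,
          energy = e, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  df <- do.call(rbind, rows)
  df <- .merge_sites(df, "energy")
  df$mode <- "animal"
  rownames(df) <- NULL
  df
}

.as_tx <- function(transcripts) {
  if (is.data.frame(transcripts)) {
    tx <- setNames(transcripts$seq, transcripts$id)
  } else {
    tx <- transcripts
    if (is.null(names(tx)) && length(tx) > 0L) {
      names(tx) <- paste0("tx", seq_along(tx))
    }
  }
  if (length(tx) == 0L) return(setNames(character(0), character(0)))
  toupper(gsub("U", "T", toupper(tx), fixed = TRUE))
}

#' Cluster genes by second-level Gene Ontology terms
#'
#' Level-2 terms are the direct children of the namespace roots (terms with
#' no parents). A gene joins every level-2 cluster that is an ancestor (or
#' the term itself) of any of its annotations, so genes may join multiple
#' clusters.
#'
#' @param gene_to_terms data.frame `gene`,`term`.
#' @param ontology data.frame `child`,`parent` edge list (acyclic).
#' @return named list: level-2 term -> character vector of member genes.
#' @export
go_level2_clusters <- function(gene_to_terms, ontology) {
  parents_of <- split(ontology$parent, ontology$child)
  all_terms <- unique(c(ontology$child, ontology$parent, gene_to_terms$term))
  # validate acyclicity with an iterative three-color DFS over child->parent
  color <- new.env(parent = emptyenv())
  for (start in all_terms) {
    if (!is.null(color[[start]])) next
    stack <- list(list(node = start, i = 0L))
    color[[start]] <- 1L  # gray
    while (length(stack) > 0L) {
      top <- stack[[length(stack)]]
      ps <- parents_of[[top$node]]
      if (is.null(ps) || top$i >= length(ps)) {
        color[[top$node]] <- 2L  # black
        stack[[length(stack)]] <- NULL
        next
      }
      stack[[length(stack)]]$i <- top$i + 1L
      nxt <- ps[[top$i + 1L]]
      cn <- color[[nxt]]
      if (is.null(cn)) {
        color[[nxt]] <- 1L
        stack[[length(stack) + 1L]] <- list(node = nxt, i = 0L)
      } else if (cn == 1L) {
        stop("cycle detected in the ontology near term '", nxt, "'")
      }
    }
  }
  roots <- setdiff(all_terms, names(parents_of))
  level2 <- unique(ontology$child[ontology$parent %in% roots])
  anc_cache <- new.env(parent = emptyenv())
  ancestors <- function(term) {
    hit <- anc_cache[[term]]
    if (!is.null(hit)) return(hit)
    seen <- character(0)
    frontier <- term
    while (length(frontier) > 0L) {
      nxt <- unique(unlist(parents_of[intersect(frontier, names(parents_of))]))
      nxt <- setdiff(nxt, seen)
      seen <- c(seen, frontier)
      frontier <- nxt
    }
    anc_cache[[term]] <- unique(seen)
    unique(seen)
  }
  clusters <- setNames(vector("list", length(level2)), level2)
  for (g in unique(gene_to_terms$gene)) {
    terms <- gene_to_terms$term[gene_to_terms$gene == g]
    anc <- unique(unlist(lapply(terms, ancestors)))
    for (l2 in intersect(level2, anc)) {
      clusters[[l2]] <- c(clusters[[l2]], g)
    }
  }
  lapply(clusters, function(x) sort(unique(x %||% character(0))))
}
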