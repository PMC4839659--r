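# Truth-labelled synthetic genome, annotation and read library with the
# statistical structure the downstream stages assume: a GC-rich multi-
# scaffold genome; planted hairpin loci emitting mature/star reads with a
# 2-nt 3' overhang duplex; 21-nt phased loci; multi-copy repeat families;
# overlapping antisense gene pairs; tRNA/rRNA contaminants; and a
# heavy-tailed read-abundance distribution.

.random_dna <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Build a random multi-scaffold genome
#'
#' @param n_scaffolds number of scaffolds (>= 1).
#' @param scaffold_len length of each scaffold, nt (>= 1000).
#' @param gc target GC fraction in (0, 1).
#' @param seed integer seed; generation is deterministic for a fixed seed.
#' @return `synthetic_genome`: named scaffold sequences, the target GC, an
#'   (initially empty) list of planted-feature truth records, and an
#'   occupancy map used to place features without collisions.
#' @export
build_genome <- function(n_scaffolds, scaffold_len, gc, seed) {
  if (n_scaffolds < 1L) stop("n_scaffolds must be >= 1")
  if (scaffold_len < 1000L) stop("scaffold_len must be >= 1000")
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  set.seed(derive_seed(seed, "genome"))
  scaffolds <- setNames(
    vapply(seq_len(n_scaffolds), function(i) .random_dna(scaffold_len, gc),
           character(1)),
    paste0("scaffold_", seq_len(n_scaffolds))
  )
  structure(
    list(scaffolds = scaffolds, gc_content = gc, truth = list(),
         occupied = data.frame(scaffold = character(0), start = integer(0),
                               end = integer(0), stringsAsFactors = FALSE)),
    class = "synthetic_genome"
  )
}

#' Observed GC fraction of a genome
#' @param genome `synthetic_genome` or named character vector.
#' @return fraction of G/C bases.
#' @export
gc_content <- function(genome) {
  scaffolds <- if (inherits(genome, "synthetic_genome")) genome$scaffolds else genome
  all <- paste(scaffolds, collapse = "")
  mean(strsplit(all, "")[[1]] %in% c("G", "C"))
}

# Random unoccupied locus with a safety margin; errors after max_try draws.
.random_locus <- function(genome, len, margin = 30L, max_try = 400L) {
  for (t in seq_len(max_try)) {
    sc <- sample(names(genome$scaffolds), 1L)
    L <- nchar(genome$scaffolds[[sc]])
    if (L < len + 2L * margin) next
    start <- sample.int(L - len - 2L * margin, 1L) + margin
    occ <- genome$occupied
    clash <- occ$scaffold == sc &
      occ$start < start + len + margin & occ$end > start - margin
    if (!any(clash)) return(list(scaffold = sc, start = start, end = start + len))
  }
  stop("could not place a feature of length ", len, " after ", max_try, " tries")
}

.occupy <- function(genome, sc, start, end) {
  genome$occupied <- rbind(genome$occupied,
                           data.frame(scaffold = sc, start = start, end = end,
                                      stringsAsFactors = FALSE))
  genome
}

.splice_in <- function(genome, sc, start, seq) {
  s <- genome$scaffolds[[sc]]
  genome$scaffolds[[sc]] <- paste0(substr(s, 1L, start),
                                   seq,
                                   substr(s, start + nchar(seq) + 1L, nchar(s)))
  genome
}

# Heavy-tailed read multiplicity (counts 1 to ~10^4).
rmultiplicity <- function(n, mu = 0, sigma = 2.5) {
  pmax(1L, as.integer(round(rlnorm(n, meanlog = mu, sdlog = sigma))))
}

# Construct one compliant hairpin precursor: 10-nt lower stem + mature +
# 8-15 nt loop + (mutated) reverse complement of mature-plus-stem + an
# unpaired tail padding the precursor to the nearest scan-window width, so
# one 5'-anchored window reproduces the precursor exactly. Verified against
# evaluate_hairpin and redrawn on failure (construction-by-rejection).
.make_hairpin <- function(genome, mature, thresholds, max_try = 30L) {
  gc <- genome$gc_content
  widths <- seq.int(thresholds$window_min, thresholds$window_max,
                    by = thresholds$window_step)
  for (t in seq_len(max_try)) {
    m <- nchar(mature)
    stem5 <- .random_dna(10L, gc)
    loop <- .random_dna(sample(8:15, 1L), gc)
    arm2 <- strsplit(revcomp(paste0(stem5, mature)), "")[[1]]
    n_sub <- sample(0:2, 1L)
    if (n_sub > 0L) {
      at <- sample(length(arm2), n_sub)
      arm2[at] <- vapply(arm2[at], function(b) sample(setdiff(DNA_BASES, b), 1L),
                         character(1))
    }
    core <- paste0(stem5, mature, loop, paste(arm2, collapse = ""))
    w <- widths[widths >= nchar(core)][1]
    if (is.na(w)) next
    tail <- if (w > nchar(core)) .random_dna(w - nchar(core), gc) else ""
    precursor <- paste0(core, tail)
    mature_span <- c(11L, 10L + m)
    verdict <- evaluate_hairpin(precursor, mature_span, thresholds)
    if (!verdict$passes) next
    star_span <- infer_star_span(verdict$partner, mature_span, thresholds$overhang)
    if (is.null(star_span)) next
    star <- substr(precursor, star_span[1], star_span[2])
    return(list(precursor = precursor, mature_span = mature_span,
                star = star, star_span = star_span, verdict = verdict))
  }
  stop("could not construct a compliant hairpin after ", max_try, " tries")
}

#' Plant a feature into a synthetic genome
#'
#' Overwrites the genome sequence at a free locus with the constructed
#' feature and appends a truth record. Supported kinds and their `spec`
#' parameters:
#' * `mirna_hairpin`: `mature` (sequence, optional), `mature_len`,
#'   `mature_count`, `star_count`, `strand`. The precursor is built as
#'   mature + 8-15 nt loop + reverse complement carrying a few substitutions
#'   over a 10-nt lower stem, then verified to pass [evaluate_hairpin()]
#'   (redrawn on failure), so planted positives are true positives under the
#'   package's own folding engine.
#' * `phased_locus`: `n_sense`, `n_antisense`; read starts sit at p + 21k on
#'   the sense strand and p + 21k + 2 on the antisense strand (the Dicer
#'   2-nt overhang geometry on the minus strand).
#' * `repeat_copy`: `n_copies`, `unit_len`, `family`; plants all copies of
#'   one family.
#' * `antisense_pair`: `gene_len`, `overlap` (must be >= `nat_min_overlap`
#'   unless `allow_below = TRUE`, in which case the truth record is flagged).
#' * `contaminant_gene`: `type` ("tRNA" or "rRNA"), `len`.
#' * `background_gene`: `n_exons`, `exon_len`, `intron_len`.
#'
#' @param genome `synthetic_genome`.
#' @param kind feature kind (see above).
#' @param spec named list of kind-specific parameters.
#' @param seed integer seed.
#' @param thresholds `smrna_thresholds` used for hairpin verification.
#' @return the modified genome; the new truth record(s) are appended to
#'   `genome$truth` (R value semantics: the input object is not mutated).
#' @export
plant_feature <- function(genome, kind, spec = list(), seed = 1L,
                          thresholds = default_thresholds()) {
  stopifnot(inherits(genome, "synthetic_genome"))
  set.seed(derive_seed(seed, paste0("plant_", kind, "_", length(genome$truth))))
  add <- function(g, rec) { g$truth[[length(g$truth) + 1L]] <- rec; g }

  if (kind == "mirna_hairpin") {
    mature <- spec[["mature"]] %||% .random_dna(spec[["mature_len"]] %||% sample(19:23, 1L),
                                           genome$gc_content)
    if (nchar(mature) < thresholds$mirna_len_min ||
        nchar(mature) > thresholds$mirna_len_max) {
      stop("mature length outside the miRNA length range")
    }
    hp <- .make_hairpin(genome, mature, thresholds)
    strand <- spec[["strand"]] %||% sample(c("+", "-"), 1L)
    loc <- .random_locus(genome, nchar(hp$precursor))
    ins <- if (strand == "-") revcomp(hp$precursor) else hp$precursor
    genome <- .splice_in(genome, loc$scaffold, loc$start, ins)
    genome <- .occupy(genome, loc$scaffold, loc$start, loc$end)
    rec <- list(kind = kind, scaffold = loc$scaffold, start = loc$start,
                end = loc$end, strand = strand,
                payload = list(
                  mature = mature, star = hp$star,
                  mature_count = spec[["mature_count"]] %||% max(3L, rmultiplicity(1L)),
                  star_count = spec[["star_count"]] %||% max(1L, rmultiplicity(1L, sigma = 1.5)),
                  precursor = hp$precursor,
                  mature_span = hp$mature_span, star_span = hp$star_span))
    return(add(genome, rec))
  }

  if (kind == "phased_locus") {
    n_sense <- spec[["n_sense"]] %||% 9L
    n_anti <- spec[["n_antisense"]] %||% 0L
    plen <- thresholds$phase_len
    wlen <- thresholds$phase_window
    loc <- .random_locus(genome, wlen)
    genome <- .occupy(genome, loc$scaffold, loc$start, loc$end)
    registers <- seq.int(0L, wlen - plen, by = plen)
    sense_pos <- loc$start + registers[seq_len(min(n_sense, length(registers)))]
    anti_pos <- if (n_anti > 0L) {
      loc$start + 2L + registers[seq_len(min(n_anti, length(registers)))]
    } else integer(0)
    rec <- list(kind = kind, scaffold = loc$scaffold, start = loc$start,
                end = loc$end, strand = "+",
                payload = list(sense_starts = sense_pos,
                               antisense_starts = anti_pos))
    return(add(genome, rec))
  }

  if (kind == "repeat_copy") {
    n_copies <- spec[["n_copies"]] %||% 6L
    unit_len <- spec[["unit_len"]] %||% 300L
    family <- spec[["family"]] %||% "repfam1"
    consensus <- .random_dna(unit_len, genome$gc_content)
    for (cp in seq_len(n_copies)) {
      loc <- .random_locus(genome, unit_len)
      genome <- .splice_in(genome, loc$scaffold, loc$start, consensus)
      genome <- .occupy(genome, loc$scaffold, loc$start, loc$end)
      genome <- add(genome, list(
        kind = kind, scaffold = loc$scaffold, start = loc$start, end = loc$end,
        strand = "+", payload = list(family = family, consensus = consensus)))
    }
    return(genome)
  }

  if (kind == "antisense_pair") {
    gene_len <- spec[["gene_len"]] %||% 600L
    overlap <- spec[["overlap"]] %||% 60L
    if (overlap < thresholds$nat_min_overlap && !isTRUE(spec[["allow_below"]])) {
      stop("antisense_pair overlap ", overlap, " below nat_min_overlap ",
           thresholds$nat_min_overlap, " (set allow_below = TRUE to flag instead)")
    }
    span <- 2L * gene_len - overlap
    loc <- .random_locus(genome, span)
    genome <- .occupy(genome, loc$scaffold, loc$start, loc$end)
    rec <- list(kind = kind, scaffold = loc$scaffold, start = loc$start,
                end = loc$end, strand = "+",
                payload = list(gene_len = gene_len, overlap = overlap,
                               below_threshold = overlap < thresholds$nat_min_overlap,
                               plus_gene = c(loc$start, loc$start + gene_len),
                               minus_gene = c(loc$start + gene_len - overlap,
                                              loc$end)))
    return(add(genome, rec))
  }

  if (kind == "contaminant_gene") {
    type <- spec[["type"]] %||% "tRNA"
    len <- spec[["len"]] %||% if (type == "tRNA") 80L else 150L
    seq <- .random_dna(len, genome$gc_content)
    loc <- .random_locus(genome, len)
    genome <- .splice_in(genome, loc$scaffold, loc$start, seq)
    genome <- .occupy(genome, loc$scaffold, loc$start, loc$end)
    rec <- list(kind = kind, scaffold = loc$scaffold, start = loc$start,
                end = loc$end, strand = "+",
                payload = list(type = type, sequence = seq))
    return(add(genome, rec))
  }

  if (kind == "background_gene") {
    n_exons <- spec[["n_exons"]] %||% 3L
    exon_len <- spec[["exon_len"]] %||% 250L
    intron_len <- spec[["intron_len"]] %||% 400L
    span <- n_exons * exon_len + (n_exons - 1L) * intron_len
    loc <- .random_locus(genome, span)
    genome <- .occupy(genome, loc$scaffold, loc$start, loc$end)
    starts <- loc$start + (seq_len(n_exons) - 1L) * (exon_len + intron_len)
    rec <- list(kind = kind, scaffold = loc$scaffold, start = loc$start,
                end = loc$end, strand = sample(c("+", "-"), 1L),
                payload = list(exon_starts = starts, exon_len = exon_len))
    return(add(genome, rec))
  }

  stop("unknown feature kind: ", kind)
}

#' Simulate a small-RNA read library from a planted genome
#'
#' Planted features emit reads at their truth counts (hairpins) or with
#' heavy-tailed log-normal multiplicities (phased loci, repeats,
#' contaminants), so the count histogram spans 1 to ~10^4. Noise reads are
#' uniform random genomic substrings of 15-30 nt with multiplicity 1.
#'
#' @param genome `synthetic_genome` with planted features.
#' @param depth scale for the noise component: `round(depth * noise_frac)`
#'   noise reads are drawn.
#' @param noise_frac fraction in `[0, 1)`.
#' @param seed integer seed; deterministic for a fixed seed.
#' @return data.frame of read records `seq`,`count`,`origin_kind`,
#'   `origin_scaffold`,`origin_start`,`origin_end`,`origin_strand`
#'   (uncollapsed; pass to [collapse_reads()]); total emitted read count in
#'   `attr(, "total_reads")`.
#' @export
simulate_reads <- function(genome, depth = 5000L, noise_frac = 0.2, seed = 1L) {
  stopifnot(inherits(genome, "synthetic_genome"))
  if (depth < 1L) stop("depth must be >= 1")
  if (noise_frac < 0 || noise_frac >= 1) stop("noise_frac must be in [0, 1)")
  set.seed(derive_seed(seed, "reads"))
  rows <- list()
  emit <- function(seq, count, kind, sc, start, end, strand) {
    rows[[length(rows) + 1L]] <<- data.frame(
      seq = seq, count = as.integer(count), origin_kind = kind,
      origin_scaffold = sc, origin_start = start, origin_end = end,
      origin_strand = strand, stringsAsFactors = FALSE)
  }
  for (f in genome$truth) {
    sc <- f$scaffold
    scseq <- genome$scaffolds[[sc]]
    if (f$kind == "mirna_hairpin") {
      p <- f$payload
      prec_len <- nchar(p$precursor)
      # window-local 1-based spans -> genome coords on the feature strand
      loc_span <- function(span) {
        if (f$strand == "+") c(f$start + span[1] - 1L, f$start + span[2])
        else c(f$start + prec_len - span[2], f$start + prec_len - span[1] + 1L)
      }
      ms <- loc_span(p$mature_span); ss <- loc_span(p$star_span)
      emit(p$mature, p$mature_count, f$kind, sc, ms[1], ms[2], f$strand)
      emit(p$star, p$star_count, f$kind, sc, ss[1], ss[2], f$strand)
    } else if (f$kind == "phased_locus") {
      p <- f$payload
      for (s in p$sense_starts) {
        emit(substr0(scseq, s, s + 21L), rmultiplicity(1L), f$kind,
             sc, s, s + 21L, "+")
      }
      for (s in p$antisense_starts) {
        emit(revcomp(substr0(scseq, s, s + 21L)), rmultiplicity(1L), f$kind,
             sc, s, s + 21L, "-")
      }
    } else if (f$kind == "repeat_copy") {
      unit <- f$payload$consensus
      n_frag <- 3L
      for (k in seq_len(n_frag)) {
        flen <- sample(18:26, 1L)
        fs <- sample.int(nchar(unit) - flen, 1L)
        emit(substr(unit, fs, fs + flen - 1L), rmultiplicity(1L), f$kind,
             sc, f$start + fs - 1L, f$start + fs - 1L + flen, "+")
      }
    } else if (f$kind == "contaminant_gene") {
      cseq <- f$payload$sequence
      for (k in seq_len(4L)) {
        flen <- sample(18:26, 1L)
        fs <- sample.int(nchar(cseq) - flen, 1L)
        emit(substr(cseq, fs, fs + flen - 1L), rmultiplicity(1L), f$kind,
             sc, f$start + fs - 1L, f$start + fs - 1L + flen, "+")
      }
    } else if (f$kind == "antisense_pair") {
      p <- f$payload
      ov <- c(p$minus_gene[1], p$plus_gene[2])  # the overlap region
      flen <- min(21L, ov[2] - ov[1])
      emit(revcomp(substr0(scseq, ov[1], ov[1] + flen)), rmultiplicity(1L),
           f$kind, sc, ov[1], ov[1] + flen, "-")
    }
  }
  n_noise <- round(depth * noise_frac)
  if (n_noise > 0L) {
    for (k in seq_len(n_noise)) {
      sc <- sample(names(genome$scaffolds), 1L)
      flen <- sample(15:30, 1L)
      L <- nchar(genome$scaffolds[[sc]])
      fs <- sample.int(L - flen, 1L)
      strand <- sample(c("+", "-"), 1L)
      s <- substr(genome$scaffolds[[sc]], fs, fs + flen - 1L)
      emit(if (strand == "-") revcomp(s) else s, 1L, "noise",
           sc, fs - 1L, fs - 1L + flen, strand)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(seq = character(0), count = integer(0),
                      origin_kind = character(0), origin_scaffold = character(0),
                      origin_start = integer(0), origin_end = integer(0),
                      origin_strand = character(0), stringsAsFactors = FALSE)
  }
  attr(out, "total_reads") <- sum(out$count)
  out
}

#' Gene models implied by a planted genome's truth records
#'
#' Background genes contribute multi-exon models; antisense pairs contribute
#' two overlapping single-exon genes on opposite strands.
#'
#' @param genome `synthetic_genome`.
#' @return `gene_models`.
#' @export
truth_gene_models <- function(genome) {
  genes <- list(); exons <- list(); gi <- 0L
  for (f in genome$truth) {
    if (f$kind == "background_gene") {
      gi <- gi + 1L
      gid <- sprintf("gene%03d", gi)
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = gid, scaffold = f$scaffold, start = f$start, end = f$end,
        strand = f$strand, stringsAsFactors = FALSE)
      for (es in f$payload$exon_starts) {
        exons[[length(exons) + 1L]] <- data.frame(
          gene_id = gid, scaffold = f$scaffold, start = es,
          end = es + f$payload$exon_len, strand = f$strand,
          stringsAsFactors = FALSE)
      }
    } else if (f$kind == "antisense_pair") {
      p <- f$payload
      for (side in c("plus", "minus")) {
        gi <- gi + 1L
        gid <- sprintf("gene%03d", gi)
        span <- if (side == "plus") p$plus_gene else p$minus_gene
        strand <- if (side == "plus") "+" else "-"
        genes[[length(genes) + 1L]] <- data.frame(
          gene_id = gid, scaffold = f$scaffold, start = span[1], end = span[2],
          strand = strand, stringsAsFactors = FALSE)
        exons[[length(exons) + 1L]] <- data.frame(
          gene_id = gid, scaffold = f$scaffold, start = span[1], end = span[2],
          strand = strand, stringsAsFactors = FALSE)
      }
    }
  }
  empty <- data.frame(gene_id = character(0), scaffold = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
  new_gene_models(if (length(genes)) do.call(rbind, genes) else empty,
                  if (length(exons)) do.call(rbind, exons) else empty)
}

#' Repeat-mask intervals from a planted genome's truth records
#' @param genome `synthetic_genome`.
#' @return data.frame `scaffold`,`start`,`end` (0-based half-open).
#' @export
truth_repeats <- function(genome) {
  reps <- Filter(function(f) f$kind == "repeat_copy", genome$truth)
  if (length(reps) == 0L) {
    return(data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  data.frame(scaffold = vapply(reps, `[[`, "", "scaffold"),
             start = vapply(reps, `[[`, 0L, "start"),
             end = vapply(reps, `[[`, 0L, "end"), stringsAsFactors = FALSE)
}

#' Contaminant (tRNA/rRNA) sequences from a planted genome's truth records
#' @param genome `synthetic_genome`.
#' @return named character vector of contaminant sequences.
#' @export
truth_contaminants <- function(genome) {
  cont <- Filter(function(f) f$kind == "contaminant_gene", genome$truth)
  if (length(cont) == 0L) return(character(0))
  setNames(vapply(cont, function(f) f$payload$sequence, character(1)),
           vapply(seq_along(cont), function(i)
             paste0(cont[[i]]$payload$type, "_", i), character(1)))
}

#' Build the default synthetic world
#'
#' One call that plants the standard test bed: 30 compliant miRNA hairpins
#' (mature count >= 3, star count >= 1), 4 phased 21-nt loci with 9
#' in-register sense starts each, 2 six-copy repeat families, 4 overlapping
#' antisense gene pairs, 4 tRNA/rRNA contaminant genes and 8 background
#' genes on a 6 x 30 kb genome at GC 0.65, plus a simulated read library.
#'
#' @param seed master seed; all stages derive named sub-streams from it.
#' @param n_hairpins,n_phased,n_repeat_families,n_antisense_pairs,n_contaminants,n_background_genes
#'   feature counts.
#' @param n_scaffolds,scaffold_len,gc genome shape.
#' @param depth,noise_frac read-simulation parameters.
#' @param thresholds `smrna_thresholds`.
#' @return list with `genome`, `genes`, `repeats`, `contaminants`, `reads`
#'   (read records) and `thresholds`.
#' @export
synthesize_world <- function(seed = 42L, n_hairpins = 30L, n_phased = 4L,
                             n_repeat_families = 2L, n_antisense_pairs = 4L,
                             n_contaminants = 4L, n_background_genes = 8L,
                             n_scaffolds = 6L, scaffold_len = 30000L,
                             gc = 0.65, depth = 5000L, noise_frac = 0.2,
                             thresholds = default_thresholds()) {
  genome <- build_genome(n_scaffolds, scaffold_len, gc, seed)
  for (i in seq_len(n_background_genes)) {
    genome <- plant_feature(genome, "background_gene",
                            seed = derive_seed(seed, paste0("bg", i)),
                            thresholds = thresholds)
  }
  for (i in seq_len(n_hairpins)) {
    mc <- max(3L, rmultiplicity(1L))
    genome <- plant_feature(
      genome, "mirna_hairpin",
      spec = list(mature_count = mc,
                  star_count = max(1L, as.integer(round(mc * runif(1, 0.1, 0.6))))),
      seed = derive_seed(seed, paste0("hp", i)), thresholds = thresholds)
  }
  for (i in seq_len(n_phased)) {
    genome <- plant_feature(genome, "phased_locus", spec = list(n_sense = 9L),
                            seed = derive_seed(seed, paste0("ph", i)),
                            thresholds = thresholds)
  }
  for (i in seq_len(n_repeat_families)) {
    genome <- plant_feature(genome, "repeat_copy",
                            spec = list(family = paste0("repfam", i)),
                            seed = derive_seed(seed, paste0("rep", i)),
                            thresholds = thresholds)
  }
  for (i in seq_len(n_antisense_pairs)) {
    genome <- plant_feature(genome, "antisense_pair",
                            seed = derive_seed(seed, paste0("nat", i)),
                            thresholds = thresholds)
  }
  for (i in seq_len(n_contaminants)) {
    genome <- plant_feature(genome, "contaminant_gene",
                            spec = list(type = if (i %% 2L) "tRNA" else "rRNA"),
                            seed = derive_seed(seed, paste0("cont", i)),
                            thresholds = thresholds)
  }
  reads <- simulate_reads(genome, depth = depth, noise_frac = noise_frac,
                          seed = seed)
  list(genome = genome, genes = truth_gene_models(genome),
       repeats = truth_repeats(genome),
       contaminants = truth_contaminants(genome),
       reads = reads, thresholds = thresholds)
}

#' Write a synthetic world to disk in standard formats
#'
#' Emits genome FASTA, gene annotation GFF3, repeat-mask BED, contaminant
#' FASTA, reads FASTA (multiplicity as a `-countN` header suffix) and a
#' truth TSV.
#'
#' @param world list from [synthesize_world()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             genes = file.path(dir, "genes.gff3"),
             repeats = file.path(dir, "repeats.bed"),
             contaminants = file.path(dir, "contaminants.fa"),
             reads = file.path(dir, "reads.fa"),
             truth = file.path(dir, "truth.tsv"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(world$genome$scaffolds), paths[["genome"]])
  write_gff3(world$genes, paths[["genes"]])
  write_bed(world$repeats, paths[["repeats"]])
  cont <- world$contaminants
  if (length(cont) == 0L) cont <- setNames(character(0), character(0))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(cont),
                              paths[["contaminants"]])
  ur <- collapse_reads(world$reads)
  ur$id <- sprintf("read%06d", seq_len(nrow(ur)))
  write_sequences(data.frame(id = ur$id, seq = ur$seq, count = ur$count,
                             stringsAsFactors = FALSE), paths[["reads"]])
  truth <- do.call(rbind, lapply(world$genome$truth, function(f) {
    data.frame(kind = f$kind, scaffold = f$scaffold, start = f$start,
               end = f$end, strand = f$strand, stringsAsFactors = FALSE)
  }))
  if (is.null(truth)) truth <- data.frame(kind = character(0))
  write_report(truth, paths[["truth"]])
  invisible(paths)
}
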