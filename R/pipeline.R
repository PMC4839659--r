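# Single entry point orchestrating the stages with logging, a reproducible
# seed, and a run manifest. All randomness flows from one user-supplied seed
# through named per-stage sub-streams, so stages rerun alone reproduce.

.log_stage <- function(stage, ..., level = "info") {
  message(sprintf("[%s] %s %s", level, stage, paste0(..., collapse = " ")))
}

.require_inputs <- function(args, keys) {
  for (k in keys) {
    p <- args[[k]]
    if (is.null(p)) stop("missing required input --", k, call. = FALSE)
    if (!file.exists(p)) stop("input file for --", k, " not found: ", p,
                              call. = FALSE)
  }
}

.write_manifest <- function(out_dir, command, args, thresholds, seed) {
  inputs <- args[vapply(args, function(a)
    is.character(a) && length(a) == 1L && file.exists(a), logical(1))]
  manifest <- list(
    command = command,
    thresholds = unclass(thresholds),
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    seed = seed,
    tool_version = as.character(packageVersion("smrnakit")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run one pipeline stage
#'
#' Subcommands: `simulate` (synthetic world to disk), `collapse` (collapse +
#' filter a read library), `mirna` (candidate discovery), `sirna` (siRNA
#' classification), `targets` (target prediction), `qpcr` (CT table
#' arithmetic), `report` (candidate summary). Outputs are deterministic
#' given the seed; a manifest (command, thresholds, input digests, seed,
#' version) is written to the output directory.
#'
#' @param command one of the subcommands above.
#' @param genome,gff,repeats,reads,contaminants,transcripts,mirnas,ct,candidates
#'   input paths as required by the subcommand.
#' @param config optional thresholds config file.
#' @param seed integer seed (default 1).
#' @param out_dir output directory (created; default `"."`).
#' @param ... passed to stage functions (e.g. `reference` for qpcr).
#' @return named vector of output paths, invisibly.
#' @export
run_pipeline <- function(command = c("simulate", "collapse", "mirna", "sirna",
                                     "targets", "qpcr", "report"),
                         genome = NULL, gff = NULL, repeats = NULL,
                         reads = NULL, contaminants = NULL, transcripts = NULL,
                         mirnas = NULL, ct = NULL, candidates = NULL,
                         config = NULL, seed = 1L, out_dir = ".", ...) {
  command <- match.arg(command)
  thresholds <- load_thresholds(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  args <- list(genome = genome, gff = gff, repeats = repeats, reads = reads,
               contaminants = contaminants, transcripts = transcripts,
               mirnas = mirnas, ct = ct, candidates = candidates,
               config = config)
  t0 <- Sys.time()
  out <- switch(
    command,
    simulate = {
      world <- synthesize_world(seed = seed, thresholds = thresholds, ...)
      .log_stage("simulate", "features:", length(world$genome$truth),
                 "reads:", attr(world$reads, "total_reads"))
      write_world(world, out_dir)
    },
    collapse = {
      .require_inputs(args, "reads")
      recs <- read_sequences(reads, format = "fasta")
      ur <- collapse_reads(recs)
      cont <- if (!is.null(contaminants))
        read_sequences(contaminants, format = "fasta")$seq else NULL
      flt <- filter_reads(ur, c(thresholds$read_len_min, thresholds$read_len_max),
                          cont)
      .log_stage("collapse", "in:", sum(ur$count), "uniques:", nrow(ur),
                 "kept:", nrow(flt))
      p1 <- file.path(out_dir, "collapsed.fa")
      flt$id <- sprintf("read%06d", seq_len(nrow(flt)))
      write_sequences(flt[, c("id", "seq", "count")], p1)
      p2 <- file.path(out_dir, "length_histogram.tsv")
      h <- length_histogram(flt, weighted = TRUE,
                            c(thresholds$read_len_min, thresholds$read_len_max))
      write_report(data.frame(length = as.integer(names(h)), reads = h), p2)
      c(collapsed = p1, histogram = p2)
    },
    mirna = {
      .require_inputs(args, c("genome", "reads"))
      g <- .read_genome_fasta(genome)
      recs <- read_sequences(reads, format = "fasta")
      ur <- collapse_reads(recs)
      cont <- if (!is.null(contaminants))
        read_sequences(contaminants, format = "fasta")$seq else NULL
      ur <- filter_reads(ur, c(thresholds$mirna_len_min, thresholds$mirna_len_max),
                         cont)
      genes <- if (!is.null(gff)) read_annotation(gff, "gff3") else NULL
      cands <- call_mirnas(ur, g, genes, thresholds)
      .log_stage("mirna", "reads:", nrow(ur), "candidates:", nrow(cands))
      p1 <- file.path(out_dir, "candidates.tsv")
      write_report(cands[, setdiff(names(cands), "partner")], p1)
      p2 <- file.path(out_dir, "precursors.fa")
      if (nrow(cands) > 0L) {
        write_sequences(data.frame(id = cands$id, seq = cands$precursor_seq,
                                   count = 1L, stringsAsFactors = FALSE), p2)
      } else writeLines(character(0), p2)
      p3 <- file.path(out_dir, "structures.txt")
      writeLines(sprintf("%s\t%s\t%.2f", cands$id, cands$structure, cands$mfe), p3)
      c(candidates = p1, precursors = p2, structures = p3)
    },
    sirna = {
      .require_inputs(args, c("genome", "reads"))
      g <- .read_genome_fasta(genome)
      ur <- collapse_reads(read_sequences(reads, format = "fasta"))
      cont <- if (!is.null(contaminants))
        read_sequences(contaminants, format = "fasta")$seq else NULL
      ur <- filter_reads(ur, c(thresholds$read_len_min, thresholds$read_len_max),
                         cont)
      idx <- build_index(g)
      hits <- map_reads(idx, ur)$hits
      rep_iv <- if (!is.null(repeats)) read_annotation(repeats, "bed") else
        data.frame(scaffold = character(0), start = integer(0), end = integer(0))
      ra <- rasirna_calls(hits, rep_iv)
      nonrep <- ra$hits[!ra$hits$repeat_associated, , drop = FALSE]
      tas <- tasirna_scan(nonrep, thresholds)
      genes <- if (!is.null(gff)) read_annotation(gff, "gff3") else
        new_gene_models(data.frame(gene_id = character(0), scaffold = character(0),
                                   start = integer(0), end = integer(0),
                                   strand = character(0)),
                        data.frame(gene_id = character(0), scaffold = character(0),
                                   start = integer(0), end = integer(0),
                                   strand = character(0)))
      nat <- natsirna_calls(nonrep, genes, thresholds)
      ctx <- annotate_hit_context(hits, genes)
      .log_stage("sirna", "hits:", nrow(hits), "tas loci:", nrow(tas),
                 "nat pairs:", nrow(nat$pairs))
      p1 <- file.path(out_dir, "rasirna.tsv"); write_report(ra$hits, p1)
      p2 <- file.path(out_dir, "tasirna.tsv"); write_report(tas, p2)
      p3 <- file.path(out_dir, "natsirna_pairs.tsv"); write_report(nat$pairs, p3)
      p4 <- file.path(out_dir, "read_context.tsv"); write_report(ctx$reads, p4)
      c(rasirna = p1, tasirna = p2, nat_pairs = p3, context = p4)
    },
    targets = {
      .require_inputs(args, c("mirnas", "transcripts"))
      mi <- read_sequences(mirnas, format = "fasta")
      tx <- read_sequences(transcripts, format = "fasta")
      txv <- setNames(tx$seq, tx$id)
      cols <- c("mirna", "transcript", "start", "end", "mismatches",
                "gu_pairs", "energy", "upe", "mode")
      out <- list()
      for (i in seq_len(nrow(mi))) {
        pt <- plant_targets(mi$seq[i], txv, thresholds)
        at <- animal_targets(mi$seq[i], txv, thresholds)
        if (nrow(pt)) { pt$mirna <- mi$id[i]; out[[length(out) + 1L]] <- pt[, cols] }
        if (nrow(at)) {
          at$mismatches <- NA_real_; at$gu_pairs <- NA_integer_
          at$upe <- NA_real_; at$mirna <- mi$id[i]
          out[[length(out) + 1L]] <- at[, cols]
        }
      }
      tgt <- if (length(out)) do.call(rbind, out) else
        data.frame(mirna = character(0), transcript = character(0),
                   start = integer(0), end = integer(0),
                   mismatches = numeric(0), gu_pairs = integer(0),
                   energy = numeric(0), upe = numeric(0), mode = character(0))
      .log_stage("targets", "miRNAs:", nrow(mi), "sites:", nrow(tgt))
      p1 <- file.path(out_dir, "targets.tsv"); write_report(tgt, p1)
      c(targets = p1)
    },
    qpcr = {
      .require_inputs(args, "ct")
      tab <- read_report(ct)
      res <- qpcr_table(tab, ...)
      .log_stage("qpcr", "rows:", nrow(res))
      p1 <- file.path(out_dir, "qpcr_relative_expression.tsv")
      write_report(res, p1)
      c(qpcr = p1)
    },
    report = {
      .require_inputs(args, "candidates")
      cands <- read_report(candidates)
      s <- summarize_candidates(cands)
      .log_stage("report", "candidates:", s$n)
      p1 <- file.path(out_dir, "summary.tsv")
      flat <- data.frame(statistic = names(unlist(s)), value = unlist(s),
                         stringsAsFactors = FALSE)
      write_report(flat, p1)
      c(summary = p1)
    }
  )
  .write_manifest(out_dir, command, args, thresholds, seed)
  .log_stage(command, sprintf("done in %.1fs",
                              as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(out)
}

.read_genome_fasta <- function(path) {
  recs <- read_sequences(path, format = "fasta")
  setNames(recs$seq, recs$id)
}
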