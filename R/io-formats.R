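# Readers/writers for the formats the pipeline touches. Coordinates are
# converted at these boundaries only: GFF3 is 1-based inclusive on disk and
# 0-based half-open in memory; BED is already 0-based half-open.

#' Read sequence records from FASTA or FASTQ
#'
#' Sequences are uppercased and RNA is normalized (U -> T) with a per-record
#' `rna_origin` flag. Collapsed-library multiplicities carried in FASTA
#' headers as a `-countN` suffix are parsed into the `count` column
#' (defaulting to 1).
#'
#' @param path input file.
#' @param format `"fasta"` or `"fastq"`.
#' @return data.frame with columns `id`, `seq`, `count`, `rna_origin`,
#'   preserving record order.
#' @export
read_sequences <- function(path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("sequence file not found: ", path, call. = FALSE)
  if (format == "fastq") .validate_fastq(path)
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = format),
    error = function(e) stop("failed to parse ", format, " file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) {
    return(data.frame(id = character(0), seq = character(0),
                      count = integer(0), rna_origin = logical(0),
                      stringsAsFactors = FALSE))
  }
  ids <- sub("\\s.*$", "", names(set))
  norm <- normalize_dna(as.character(set))
  count <- rep(1L, length(ids))
  has_count <- grepl("-count[0-9]+$", ids)
  count[has_count] <- as.integer(sub("^.*-count([0-9]+)$", "\\1", ids[has_count]))
  data.frame(id = ids, seq = norm$seq, count = count,
             rna_origin = norm$rna_origin, stringsAsFactors = FALSE)
}

.validate_fastq <- function(path) {
  n <- length(readLines(path, warn = FALSE))
  if (n %% 4L != 0L) {
    stop("ragged FASTQ (", n, " lines, not a multiple of 4) near line ", n,
         " in ", path, call. = FALSE)
  }
}

#' Write sequence records to FASTA
#'
#' Multiplicities > 1 are encoded in the header as a `-countN` suffix, the
#' collapsed-library dialect understood by [read_sequences()].
#'
#' @param df data.frame with `id`, `seq` and optionally `count`.
#' @param path output path.
#' @export
write_sequences <- function(df, path) {
  ids <- df$id
  if (!is.null(df$count)) {
    tag <- df$count > 1L & !grepl("-count[0-9]+$", ids)
    ids[tag] <- paste0(ids[tag], "-count", df$count[tag])
  }
  set <- Biostrings::BStringSet(setNames(df$seq, ids))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read gene models from GFF3 or intervals from BED
#'
#' GFF3 gene/mRNA/exon features become a `gene_models` object; BED3+ becomes
#' a plain interval data.frame. All coordinates are internal convention
#' (0-based half-open).
#'
#' @param path annotation file.
#' @param format `"gff3"` or `"bed"`.
#' @return `gene_models` (list of `genes` and `exons` data.frames) for GFF3;
#'   data.frame `scaffold`,`start`,`end`(,`strand`) for BED.
#' @export
read_annotation <- function(path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  if (format == "bed") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (length(lines) == 0L) {
      return(data.frame(scaffold = character(0), start = integer(0),
                        end = integer(0), stringsAsFactors = FALSE))
    }
    f <- strsplit(lines, "\t")
    if (any(lengths(f) < 3L)) stop("BED line with fewer than 3 fields in ", path)
    df <- data.frame(
      scaffold = vapply(f, `[[`, "", 1L),
      start = as.integer(vapply(f, `[[`, "", 2L)),
      end = as.integer(vapply(f, `[[`, "", 3L)),
      stringsAsFactors = FALSE
    )
    if (all(lengths(f) >= 6L)) df$strand <- vapply(f, `[[`, "", 6L)
    return(df)
  }
  .read_gff3(path)
}

.gff_attr <- function(attrs, key) {
  pat <- paste0("(^|;)\\s*", key, "=([^;]*)")
  out <- rep(NA_character_, length(attrs))
  hit <- regexpr(pat, attrs)
  has <- hit > 0
  out[has] <- sub(pat, "\\2", regmatches(attrs, hit)[seq_len(sum(has))])
  out
}

.read_gff3 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(new_gene_models(
    data.frame(gene_id = character(0), scaffold = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               stringsAsFactors = FALSE),
    data.frame(gene_id = character(0), scaffold = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               stringsAsFactors = FALSE)))
  f <- strsplit(lines, "\t")
  if (any(lengths(f) != 9L)) stop("malformed GFF3 (expected 9 fields) in ", path)
  m <- do.call(rbind, f)
  type <- m[, 3]
  start0 <- as.integer(m[, 4]) - 1L  # 1-based inclusive -> 0-based half-open
  end <- as.integer(m[, 5])
  strand <- m[, 7]
  attrs <- m[, 9]
  keep <- type %in% c("gene", "mRNA", "exon")
  if (any(keep & !strand %in% c("+", "-"))) {
    stop("feature with missing strand ('", strand[keep & !strand %in% c("+", "-")][1],
         "') in ", path, call. = FALSE)
  }
  is_gene <- type == "gene"
  genes <- data.frame(
    gene_id = .gff_attr(attrs[is_gene], "ID"),
    scaffold = m[is_gene, 1], start = start0[is_gene], end = end[is_gene],
    strand = strand[is_gene], stringsAsFactors = FALSE
  )
  mrna <- data.frame(id = .gff_attr(attrs[type == "mRNA"], "ID"),
                     parent = .gff_attr(attrs[type == "mRNA"], "Parent"),
                     stringsAsFactors = FALSE)
  is_ex <- type == "exon"
  parent <- .gff_attr(attrs[is_ex], "Parent")
  gene_of <- ifelse(parent %in% mrna$id,
                    mrna$parent[match(parent, mrna$id)], parent)
  exons <- data.frame(
    gene_id = gene_of, scaffold = m[is_ex, 1], start = start0[is_ex],
    end = end[is_ex], strand = strand[is_ex], stringsAsFactors = FALSE
  )
  new_gene_models(genes, exons)
}

#' Construct a gene-models object
#'
#' @param genes data.frame `gene_id`,`scaffold`,`start`,`end`,`strand`
#'   (0-based half-open).
#' @param exons data.frame with the same columns keyed by `gene_id`.
#' @return validated `gene_models` object.
#' @export
new_gene_models <- function(genes, exons) {
  if (nrow(exons) > 0L) {
    bad <- !exons$gene_id %in% genes$gene_id
    if (any(bad)) stop("exon with unknown parent gene: ", exons$gene_id[bad][1])
    idx <- match(exons$gene_id, genes$gene_id)
    out <- exons$start < genes$start[idx] | exons$end > genes$end[idx]
    if (any(out)) stop("exon outside its parent gene span: ", exons$gene_id[out][1])
    # exons must be sorted and non-overlapping within a gene
    for (g in unique(exons$gene_id)) {
      e <- exons[exons$gene_id == g, ]
      e <- e[order(e$start), ]
      if (nrow(e) > 1L && any(e$start[-1] < e$end[-nrow(e)])) {
        stop("overlapping exons in gene ", g)
      }
    }
  }
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' Write a gene-models object as GFF3
#'
#' @param gm `gene_models` object.
#' @param path output path.
#' @export
write_gff3 <- function(gm, path) {
  stopifnot(inherits(gm, "gene_models"))
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(gm$genes))) {
    g <- gm$genes[i, ]
    lines <- c(lines, sprintf("%s\tsmrnakit\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                              g$scaffold, g$start + 1L, g$end, g$strand, g$gene_id))
    ex <- gm$exons[gm$exons$gene_id == g$gene_id, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    for (j in seq_len(nrow(ex))) {
      e <- ex[j, ]
      lines <- c(lines, sprintf("%s\tsmrnakit\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                                e$scaffold, e$start + 1L, e$end, e$strand,
                                g$gene_id, j, g$gene_id))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a BED3 file from an interval data.frame (0-based half-open)
#' @param df data.frame `scaffold`,`start`,`end`.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  lines <- sprintf("%s\t%d\t%d", df$scaffold, df$start, df$end)
  writeLines(lines, path)
  invisible(path)
}

#' Write a pipeline result table as TSV
#'
#' Deterministic column order (as given), header row, `NA` written as "NA";
#' round-trips losslessly through [read_report()].
#'
#' @param records data.frame.
#' @param path output path.
#' @export
write_report <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read a TSV written by [write_report()]
#' @param path input path.
#' @return data.frame.
#' @export
read_report <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
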