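test_that("scan_windows emits 13 lengths with three placements, deduplicated", {
  th <- default_thresholds()
  genome <- c(chr = random_dna(2000, 0.6))
  hit <- list(scaffold = "chr", start = 1000L, end = 1021L, strand = "+")
  w <- scan_windows(hit, genome, th)
  expect_equal(sort(unique(w$width)), seq(60L, 300L, 20L))
  expect_lte(max(table(w$width)), 3L)
  expect_true(all(w$start >= 0 & w$end <= 2000))
  # mature span sits inside every window
  expect_true(all(w$mature_start >= 1 & w$mature_end <= w$width))
  expect_true(all(substr(w$seq, w$mature_start, w$mature_end) ==
                    substr(genome[["chr"]], 1001, 1021)))
})

test_that("scan_windows drops out-of-bounds placements near scaffold edges", {
  genome <- c(chr = random_dna(1200, 0.6))
  hit <- list(scaffold = "chr", start = 5L, end = 26L, strand = "+")
  w <- scan_windows(hit, genome)
  expect_true(all(w$start >= 0))
  expect_true(all(w$end <= 1200))
  expect_true(nrow(w) < 13 * 3)
})

test_that("minus-strand windows carry the reverse complement and mature span", {
  set.seed(2)
  genome <- c(chr = random_dna(1500, 0.6))
  hit <- list(scaffold = "chr", start = 700L, end = 721L, strand = "-")
  w <- scan_windows(hit, genome)
  slice <- substr(genome[["chr"]], w$start[1] + 1, w$end[1])
  expect_equal(w$seq[1], revcomp(slice))
  expect_equal(substr(w$seq[1], w$mature_start[1], w$mature_end[1]),
               revcomp(substr(genome[["chr"]], 701, 721)))
})

make_test_hairpin <- function(mature, stem = 10L, loop = "AAAATTTTAAAA",
                              tail = 6L, seed = 99L) {
  set.seed(seed)
  stem5 <- random_dna(stem, 0.7)
  core <- paste0(stem5, mature, loop, revcomp(paste0(stem5, mature)))
  paste0(core, random_dna(tail, 0.5))
}

test_that("evaluate_hairpin passes a clean stem-loop and reports defects", {
  th <- default_thresholds()
  mature <- "CGTCCTAATCCTTGGCCTG"
  prec <- make_test_hairpin(mature)
  span <- c(11L, 10L + nchar(mature))
  v <- evaluate_hairpin(prec, span, th)
  expect_true(v$passes)
  expect_equal(v$n_loops, 1L)
  expect_gte(v$paired_frac, 0.5)
  expect_equal(v$mismatches_in_mature, 0L)
  expect_equal(v$mfe_threshold, -0.35 * nchar(prec))
  expect_error(evaluate_hairpin(prec, c(0, 10)), "mature_span")
})

test_that("mature mismatch excess is flagged with its reason code", {
  th <- default_thresholds()
  mature <- "CGTCCTAATCCTTGGCCTGCC"
  prec <- make_test_hairpin(mature, stem = 14L)
  span <- c(15L, 14L + nchar(mature))
  # corrupt 5 positions facing the mature on the opposite arm
  arm_start <- 14L + nchar(mature) + 12L + 1L
  ch <- strsplit(prec, "")[[1]]
  at <- arm_start + c(3L, 6L, 9L, 12L, 15L)
  ch[at] <- vapply(ch[at], function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
  v <- evaluate_hairpin(paste(ch, collapse = ""), span, th)
  if (!v$passes) expect_true(length(v$reasons) > 0)
  expect_gte(v$mismatches_in_mature, 0L)
  # direct threshold check: > 4 mature mismatches can never pass
  if (v$mismatches_in_mature > 4L) expect_true("mismatch_excess" %in% v$reasons)
})

test_that("the MFE screen uses the -0.35 x length rule strictly", {
  th <- default_thresholds()
  # synthetic verdicts: only the energy criterion varies
  fake_fold <- function(e, n = 100L) {
    # single clean hairpin over n nt with >= 50% paired
    k <- 24L
    structure_chr <- paste0(strrep("(", k), strrep(".", n - 2 * k), strrep(")", k))
    partner <- integer(n)
    partner[1:k] <- n:(n - k + 1L)
    partner[n:(n - k + 1L)] <- 1:k
    list(structure = structure_chr, energy = e, partner = partner)
  }
  v_fail <- evaluate_hairpin(strrep("A", 100), c(2, 20), th,
                             fold = fake_fold(-34.9))
  expect_false(v_fail$passes)
  expect_true("mfe_above_threshold" %in% v_fail$reasons)
  v_pass <- evaluate_hairpin(strrep("A", 100), c(2, 20), th,
                             fold = fake_fold(-35.1))
  expect_false("mfe_above_threshold" %in% v_pass$reasons)
  v_edge <- evaluate_hairpin(strrep("A", 100), c(2, 20), th,
                             fold = fake_fold(-35.0))
  expect_true("mfe_above_threshold" %in% v_edge$reasons)
})

test_that("locate_star finds the 2-nt-overhang star and rejects bad geometry", {
  th <- default_thresholds()
  mature <- "GCGTCAGTCGACCGTGGCACA"
  prec <- make_test_hairpin(mature)
  span <- c(11L, 10L + nchar(mature))
  v <- evaluate_hairpin(prec, span, th)
  expect_true(v$passes)
  star_span <- smrnakit:::infer_star_span(v$partner, span, 2L)
  expect_false(is.null(star_span))
  reads <- data.frame(start = star_span[1], end = star_span[2],
                      seq = substr(prec, star_span[1], star_span[2]),
                      count = 7L, stringsAsFactors = FALSE)
  star <- locate_star(v, span, reads, th)
  expect_equal(star$count, 7L)

  # 4-nt overhang (star shifted by 2 more) -> absent
  reads4 <- data.frame(start = star_span[1] + 2L, end = star_span[2] + 2L,
                       seq = "x", count = 7L, stringsAsFactors = FALSE)
  expect_null(locate_star(v, span, reads4, th))
  expect_null(locate_star(v, span, reads[0, ], th))
})

test_that("context classification follows exon > intron > intergenic", {
  gm <- new_gene_models(
    data.frame(gene_id = "g1", scaffold = "s1", start = 100L, end = 1000L,
               strand = "+", stringsAsFactors = FALSE),
    data.frame(gene_id = "g1", scaffold = "s1", start = c(100L, 700L),
               end = c(300L, 1000L), strand = "+", stringsAsFactors = FALSE))
  expect_equal(classify_context("s1", 150, 220, gm), "exon")
  expect_equal(classify_context("s1", 400, 500, gm), "intron")
  expect_equal(classify_context("s1", 2000, 2100, gm), "intergenic")
  expect_equal(classify_context("s2", 150, 220, gm), "intergenic")
  expect_equal(classify_context("s1", 150, 220, NULL), "intergenic")
})

test_that("suffix_prefix_overlap handles the documented cases", {
  fx <- ehux_mirna_candidates()
  mir03 <- fx$seq[fx$id == "mir03"]
  mir04 <- fx$seq[fx$id == "mir04"]
  expect_equal(suffix_prefix_overlap(mir03, mir04), 8L)
  expect_equal(suffix_prefix_overlap("ACGT", "ACGT"), 4L)
  expect_equal(suffix_prefix_overlap("AAAA", "CCCC"), 0L)
})

test_that("call_mirnas applies the abundance rules", {
  th <- default_thresholds()
  expect_equal(nrow(call_mirnas(data.frame(seq = character(0),
                                           count = integer(0)),
                                c(chr = random_dna(2000)), NULL, th)), 0L)

  # a planted hairpin whose mature has count 50 and no star read: rejected
  w <- small_world()
  hp <- Filter(function(f) f$kind == "mirna_hairpin", w$genome$truth)[[1]]
  ur <- data.frame(seq = hp$payload$mature, count = 50L,
                   stringsAsFactors = FALSE)
  cands <- call_mirnas(ur, w$genome, w$genes, th)
  expect_equal(nrow(cands), 0L)
  # same mature at count 100+ is kept without a star
  ur$count <- 150L
  cands <- call_mirnas(ur, w$genome, w$genes, th)
  expect_equal(nrow(cands), 1L)
  expect_false(cands$has_star)
  # with the star read present, count 3 suffices
  ur2 <- rbind(ur, data.frame(seq = hp$payload$star, count = 1L))
  ur2$count[1] <- 3L
  cands <- call_mirnas(ur2, w$genome, w$genes, th)
  expect_equal(nrow(cands), 1L)
  expect_true(cands$has_star)
  expect_equal(cands$star_abundance, 1L)
})

test_that("threshold monotonicity: stricter thresholds never add candidates", {
  th <- default_thresholds()
  w <- small_world()
  ur <- collapse_reads(w$reads)
  ur <- filter_reads(ur, c(th$mirna_len_min, th$mirna_len_max), w$contaminants)
  base <- call_mirnas(ur, w$genome, w$genes, th)
  th2 <- th
  th2$min_abund_no_star <- 1000L
  th2$min_abund_with_star <- 10L
  stricter <- call_mirnas(ur, w$genome, w$genes, th2)
  expect_lte(nrow(stricter), nrow(base))
  expect_true(all(stricter$seq %in% base$seq))
  # every reported candidate re-evaluates to passes = TRUE
  for (i in seq_len(nrow(base))) {
    m <- regexpr(base$seq[i], base$precursor_seq[i], fixed = TRUE)
    v <- evaluate_hairpin(base$precursor_seq[i],
                          c(as.integer(m), as.integer(m) + base$length[i] - 1L),
                          th)
    expect_true(v$passes)
  }
})

test_that("summarize_candidates computes lower medians and rounded contexts", {
  df <- data.frame(length = c(20L, 21L, 22L, 23L),
                   abundance = c(5L, NA, 10L, 2L),
                   star_abundance = c(1L, NA, NA, 4L),
                   precursor_length = c(80L, 90L, 100L, 110L),
                   genomic_region = c("intergenic", "intergenic", "intron",
                                      "exon"))
  s <- summarize_candidates(df)
  expect_equal(s$median_mature_len, 21L)  # lower median of even n
  expect_equal(s$n_star, 2L)
  expect_equal(s$max_abundance, 10L)
  expect_equal(unname(s$context_pct["intergenic"]), 50)
  expect_error(summarize_candidates(df[0, ]), "empty")
})
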