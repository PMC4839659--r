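test_that("phasing p-value handles documented cases exactly", {
  expect_equal(phasing_pvalue(0, 5, 22, 462), 1)
  expect_equal(phasing_pvalue(2, 2, 2, 10), 1 / 45)
  expect_error(phasing_pvalue(3, 2, 2, 10), "inconsistent")
  expect_error(phasing_pvalue(1, 2, 12, 10), "inconsistent")
})

test_that("phasing p-value matches stats::phyper on random cases (N <= 60)", {
  set.seed(55)
  for (i in 1:200) {
    N <- sample(2:60, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(phasing_pvalue(k, n, K, N),
                 phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-12,
                 label = sprintf("k=%d n=%d K=%d N=%d", k, n, K, N))
  }
})

test_that("phasing p-value is monotone non-increasing in k", {
  for (n in c(5, 11, 20)) {
    p <- vapply(0:min(n, 22), function(k) phasing_pvalue(k, n, 22, 462),
                numeric(1))
    expect_true(all(diff(p) <= 1e-12))
  }
})

test_that("tasirna_scan reports a planted phased locus and nothing else", {
  th <- default_thresholds()
  # 9 in-register sense starts anchored at 1000
  hits <- data.frame(
    seq = paste0("r", 1:9), count = 1L, scaffold = "s1",
    start = 1000L + 21L * (0:8), stringsAsFactors = FALSE)
  hits$end <- hits$start + 21L
  hits$strand <- "+"
  loci <- tasirna_scan(hits, th)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$start, 1000L)
  expect_equal(loci$k, 9L)
  expect_lt(loci$p_value, th$phase_alpha)

  expect_equal(nrow(tasirna_scan(hits[0, ], th)), 0L)
  # non-21-nt hits are ignored
  h22 <- hits; h22$end <- h22$start + 22L
  expect_equal(nrow(tasirna_scan(h22, th)), 0L)
})

test_that("tasirna_scan honors the antisense +2 register", {
  th <- default_thresholds()
  sense <- data.frame(seq = paste0("s", 1:5), count = 1L, scaffold = "s1",
                      start = 2000L + 21L * (0:4), stringsAsFactors = FALSE)
  anti <- data.frame(seq = paste0("a", 1:4), count = 1L, scaffold = "s1",
                     start = 2000L + 2L + 21L * (5:8), stringsAsFactors = FALSE)
  hits <- rbind(sense, anti)
  hits$end <- hits$start + 21L
  hits$strand <- c(rep("+", 5), rep("-", 4))
  loci <- tasirna_scan(hits, th)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$k, 9L)
  expect_equal(loci$n, 9L)
})

test_that("tasirna_scan type-I error under uniform placement stays nominal", {
  # 10,000 read-anchored windows with uniformly placed co-occupants
  th <- default_thresholds()
  set.seed(4242)
  n_win <- 10000L
  alpha <- th$phase_alpha
  N <- 2L * th$phase_window
  K <- 2L * (th$phase_window %/% th$phase_len)
  rejected <- 0L
  for (i in seq_len(n_win)) {
    n_extra <- sample(3:12, 1)
    occ <- sample.int(N - 1L, n_extra)  # positions 1..N-1, anchor at 0
    # anchor occupies an in-register position by construction
    k_extra <- sum(occ %% th$phase_len == 0L & occ < th$phase_window |
                   (occ - th$phase_window - 2L) %% th$phase_len == 0L &
                   occ >= th$phase_window)
    p <- phasing_pvalue(k_extra, n_extra, K - 1L, N - 1L)
    if (p <= alpha) rejected <- rejected + 1L
  }
  expect_lte(rejected / n_win, alpha + 3 * sqrt(alpha / n_win))
})

test_that("ra-siRNA containment rule and truth fractions", {
  repeats <- data.frame(scaffold = "s1", start = 100L, end = 400L,
                        stringsAsFactors = FALSE)
  hits <- data.frame(
    seq = c("in", "straddle", "out"), count = c(10L, 1L, 1L),
    scaffold = "s1", start = c(150L, 390L, 600L), end = c(171L, 411L, 621L),
    strand = "+", stringsAsFactors = FALSE)
  ra <- rasirna_calls(hits, repeats)
  expect_equal(ra$hits$repeat_associated, c(TRUE, FALSE, FALSE))
  expect_equal(ra$summary$unique_fraction, 1 / 3)
  expect_equal(ra$summary$weighted_fraction, 10 / 12)

  # synthetic world: weighted repeat fraction within 2% of planted truth
  w <- small_world()
  ur <- collapse_reads(w$reads)
  idx <- build_index(w$genome)
  allhits <- map_reads(idx, ur)$hits
  ra2 <- rasirna_calls(allhits, w$repeats)
  truth_frac <- local({
    rep_reads <- w$reads$origin_kind == "repeat_copy"
    mapped <- w$reads$seq %in% allhits$seq
    sum(w$reads$count[rep_reads & mapped]) / sum(w$reads$count[mapped])
  })
  expect_lt(abs(ra2$summary$weighted_fraction - truth_frac), 0.02)
})

test_that("nat-siRNA calls respect the 25-nt gene-pair overlap boundary", {
  gm24 <- new_gene_models(
    data.frame(gene_id = c("a", "b"), scaffold = "s1",
               start = c(100L, 576L), end = c(600L, 1100L),
               strand = c("+", "-"), stringsAsFactors = FALSE),
    data.frame(gene_id = c("a", "b"), scaffold = "s1",
               start = c(100L, 576L), end = c(600L, 1100L),
               strand = c("+", "-"), stringsAsFactors = FALSE))
  expect_equal(nrow(natsirna_calls(data.frame(), gm24)$pairs), 0L)  # 24 nt
  gm25 <- new_gene_models(
    data.frame(gene_id = c("a", "b"), scaffold = "s1",
               start = c(100L, 575L), end = c(600L, 1100L),
               strand = c("+", "-"), stringsAsFactors = FALSE),
    data.frame(gene_id = c("a", "b"), scaffold = "s1",
               start = c(100L, 575L), end = c(600L, 1100L),
               strand = c("+", "-"), stringsAsFactors = FALSE))
  pairs <- natsirna_calls(data.frame(), gm25)$pairs
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$overlap, 25L)

  hits <- data.frame(seq = c("sense", "anti"), count = 1L, scaffold = "s1",
                     start = c(200L, 200L), end = c(221L, 221L),
                     strand = c("+", "-"), stringsAsFactors = FALSE)
  nat <- natsirna_calls(hits, gm25)
  expect_equal(nat$hits$antisense_exon, c(FALSE, TRUE))
})

test_that("per-read context uses the most-frequent-feature rule", {
  gm <- new_gene_models(
    data.frame(gene_id = "g1", scaffold = "s1", start = 0L, end = 1000L,
               strand = "+", stringsAsFactors = FALSE),
    data.frame(gene_id = "g1", scaffold = "s1", start = 0L, end = 1000L,
               strand = "+", stringsAsFactors = FALSE))
  hits <- data.frame(
    seq = c("r1", "r1", "r1", "r2"),
    count = 1L, scaffold = "s1",
    start = c(100L, 500L, 5000L, 6000L),
    end = c(121L, 521L, 5021L, 6021L),
    strand = "+", stringsAsFactors = FALSE)
  ctx <- annotate_hit_context(hits, gm)
  expect_equal(ctx$reads$context[ctx$reads$seq == "r1"], "sense_exon")
  expect_equal(ctx$reads$context[ctx$reads$seq == "r2"], "intergenic")

  # tie: one sense-exon hit and one antisense-exon hit -> lexicographic
  hits2 <- data.frame(seq = "t", count = 1L, scaffold = "s1",
                      start = c(100L, 200L), end = c(121L, 221L),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  ctx2 <- annotate_hit_context(hits2, gm)
  expect_equal(ctx2$reads$context, "antisense_exon")
})

test_that("piRNA classifier has the stated feature dimension and separates", {
  expect_equal(ncol(smrnakit:::pirna_features("ACGT")), 1364L)

  set.seed(77)
  pos <- replicate(40, paste0(strrep("A", 10), random_dna(18, 0.2)))
  neg <- replicate(40, paste0(strrep("G", 10), random_dna(18, 0.8)))
  res <- pirna_classify(pos, neg, c(pos, neg))
  expect_true(all(res$label[1:40]))
  expect_false(any(res$label[41:80]))
  expect_error(pirna_classify(character(0), neg, pos), "non-empty")
})

test_that("positional bias estimates planted base frequencies", {
  expect_equal(positional_bias(c("TACG", "TGGC"), 1, "U"), 1)
  expect_warning(out <- positional_bias(character(0), 1, "T"))
  expect_equal(out, 0)

  set.seed(88)
  n <- 1000
  first <- sample(c("T", "A", "G", "C"), n, TRUE, prob = c(0.35, 0.25, 0.2, 0.2))
  seqs <- paste0(first, vapply(1:n, function(i) random_dna(25), character(1)))
  expect_lt(abs(positional_bias(seqs, 1, "T") - 0.35), 0.05)
  # position beyond some sequences: only long-enough ones count
  expect_equal(positional_bias(c("AC", "ACGTACGTACG"), 11, "G"), 1)
})
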