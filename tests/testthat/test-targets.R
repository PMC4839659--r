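test_that("plant mode finds an exact reverse-complement site", {
  set.seed(12)
  mirna <- "CAGAAACTCACGGACCTCGAC"
  # unstructured A/T-rich context so the UPE screen passes trivially
  tx <- c(t1 = paste0(strrep("A", 80), revcomp(mirna), strrep("A", 80)))
  hits <- plant_targets(mirna, tx)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$mismatches, 0)
  expect_equal(hits$start, 81L)
  expect_equal(substr(tx[["t1"]], hits$start, hits$end), revcomp(mirna))
})

test_that("weighted mismatch scoring counts G:U as 0.5 and caps at 3", {
  mirna <- "CAGAAACTCACGGACCTCGAC"
  site <- strsplit(revcomp(mirna), "")[[1]]
  # two full mismatches: target positions facing miRNA 5,8 -> set to the
  # same base as the miRNA (never complementary, never G:U)
  n <- length(site)
  site[n - 5 + 1] <- substr(mirna, 5, 5)
  site[n - 8 + 1] <- substr(mirna, 8, 8)
  # two G:U wobbles: miRNA G at positions 11,13 faces target T
  expect_equal(substr(mirna, 11, 11), "C")
  mm <- strsplit(mirna, "")[[1]]
  g_at <- which(mm == "G")[1:2]
  site[n - g_at + 1] <- "T"
  tx <- c(t1 = paste0(strrep("A", 60), paste(site, collapse = ""),
                      strrep("A", 60)))
  hits <- plant_targets(mirna, tx)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$mismatches, 3.0)  # 2 x 1 + 2 x 0.5
  expect_equal(hits$gu_pairs, 2L)

  # one more full mismatch pushes past the budget
  site[n - 3 + 1] <- substr(mirna, 3, 3)
  tx2 <- c(t1 = paste0(strrep("A", 60), paste(site, collapse = ""),
                       strrep("A", 60)))
  expect_equal(nrow(plant_targets(mirna, tx2)), 0L)
})

test_that("relaxed plant thresholds reduce to exact substring search", {
  set.seed(13)
  th <- default_thresholds()
  th$plant_max_mismatch <- 0
  th$plant_max_upe <- Inf
  mirna <- "GTGGCTAGTATCCGACGCTGTC"
  tgt <- revcomp(mirna)
  tx <- vapply(1:6, function(i) random_dna(300, 0.5), character(1))
  names(tx) <- paste0("t", 1:6)
  # plant the exact site in half of them
  for (i in c(1, 3, 5)) {
    tx[i] <- paste0(substr(tx[i], 1, 100), tgt, substr(tx[i], 101, 300))
  }
  hits <- plant_targets(mirna, tx, th)
  oracle <- lapply(names(tx), function(nm) {
    at <- gregexpr(tgt, tx[[nm]], fixed = TRUE)[[1]]
    if (at[1] == -1) NULL else data.frame(transcript = nm, start = as.integer(at))
  })
  oracle <- do.call(rbind, oracle)
  expect_equal(hits$transcript, oracle$transcript)
  expect_equal(hits$start, oracle$start)
})

test_that("tightening plant thresholds never adds sites", {
  set.seed(14)
  mirna <- "CGGAGGAGATGTGCCGTTCCG"
  tx <- c(t1 = paste0(random_dna(80), revcomp(mirna), random_dna(80)))
  th <- default_thresholds()
  base <- plant_targets(mirna, tx, th)
  th$plant_max_mismatch <- 1
  th$plant_max_upe <- 10
  tight <- plant_targets(mirna, tx, th)
  expect_lte(nrow(tight), nrow(base))
})

test_that("animal mode requires a perfect seed and a strong duplex", {
  mirna <- "CGTTGATGAGGCCGATCTGGT"
  tx_good <- c(t1 = paste0(strrep("AT", 20), revcomp(mirna), strrep("TA", 20)))
  hits <- animal_targets(mirna, tx_good)
  expect_equal(nrow(hits), 1L)
  expect_lt(hits$energy, -20)
  expect_equal(substr(tx_good[["t1"]], hits$start, hits$end), revcomp(mirna))

  # break seed position 5 (G -> C in the target facing base)
  expect_equal(substr(mirna, 5, 5), "G")
  site <- strsplit(revcomp(mirna), "")[[1]]
  n <- length(site)
  site[n - 5 + 1] <- "G"  # no longer complementary to G
  tx_bad <- c(t1 = paste0(strrep("AT", 20), paste(site, collapse = ""),
                          strrep("TA", 20)))
  expect_equal(nrow(animal_targets(mirna, tx_bad)), 0L)

  expect_equal(nrow(animal_targets(mirna, character(0))), 0L)
})

test_that("GO level-2 clustering follows ancestor closure", {
  ontology <- data.frame(
    child = c("bp2a", "bp2b", "leaf1", "leaf1", "leaf2", "mid", "leaf3"),
    parent = c("root_bp", "root_bp", "bp2a", "bp2b", "bp2a", "bp2a", "mid"),
    stringsAsFactors = FALSE)
  g2t <- data.frame(gene = c("gA", "gB", "gC"),
                    term = c("leaf1", "bp2a", "leaf3"),
                    stringsAsFactors = FALSE)
  cl <- go_level2_clusters(g2t, ontology)
  expect_setequal(names(cl), c("bp2a", "bp2b"))
  expect_true(all(c("gA") %in% cl$bp2a) && "gA" %in% cl$bp2b)  # two ancestors
  expect_true("gB" %in% cl$bp2a)   # direct annotation to a level-2 term
  expect_true("gC" %in% cl$bp2a)   # via mid
  expect_false("gC" %in% cl$bp2b)

  expect_equal(unname(lengths(go_level2_clusters(g2t[0, ], ontology))),
               c(0L, 0L))

  cyc <- rbind(ontology, data.frame(child = "root_bp", parent = "leaf1"))
  expect_error(go_level2_clusters(g2t, cyc), "cycle")
})
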