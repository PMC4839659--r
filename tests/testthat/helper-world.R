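# Small shared synthetic world, built once per test run.
small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- synthesize_world(
        seed = 11L, n_hairpins = 3L, n_phased = 1L, n_repeat_families = 1L,
        n_antisense_pairs = 2L, n_contaminants = 2L, n_background_genes = 3L,
        n_scaffolds = 3L, scaffold_len = 12000L, depth = 600L)
    }
    cache
  }
})

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
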