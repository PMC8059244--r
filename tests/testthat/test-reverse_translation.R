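test_that("single-codon residues reverse-translate exactly", {
  tab <- default_codon_table()
  expect_equal(reverse_translate("M", tab)$sequence, "ATG")
  expect_equal(reverse_translate("W", tab)$sequence, "TGG")
})

test_that("translation round-trips against the Biostrings oracle", {
  skip_if_not_installed("Biostrings")
  tab <- default_codon_table()
  set.seed(71)
  prots <- replicate(100L, rand_protein(sample(20:60, 1L)))
  for (strategy in c("max_frequency", "weighted_sampling")) {
    dna <- vapply(prots, function(p)
      reverse_translate(p, tab, strategy = strategy, seed = 7L)$sequence,
      character(1L))
    back <- as.character(Biostrings::translate(Biostrings::DNAStringSet(dna),
                                               no.init.codon = TRUE))
    expect_equal(unname(back), unname(prots))
    # and against the package's own translator
    expect_equal(unname(vapply(dna, translate_dna, character(1L))),
                 unname(prots))
  }
})

test_that("max_frequency is deterministic; weighted sampling honors its seed", {
  tab <- default_codon_table()
  p <- "MALWMRLLPLLALLALWGPDPAAA"
  expect_identical(reverse_translate(p, tab)$sequence,
                   reverse_translate(p, tab)$sequence)
  w1 <- reverse_translate(p, tab, strategy = "weighted_sampling", seed = 1L)
  w2 <- reverse_translate(p, tab, strategy = "weighted_sampling", seed = 1L)
  w3 <- reverse_translate(p, tab, strategy = "weighted_sampling", seed = 2L)
  expect_identical(w1$sequence, w2$sequence)
  expect_false(identical(w1$sequence, w3$sequence))
})

test_that("motif avoidance removes a planted EcoRI site without changing translation", {
  tab <- default_codon_table()
  # Glu-Phe: GAA+TTC spells GAATTC across the codon boundary
  ins <- reverse_translate("KEFK", tab, strategy = "max_frequency")
  ins$sequence <- "AAAGAATTCAAA"  # force the motif-bearing encoding
  expect_equal(translate_dna(ins$sequence), "KEFK")
  out <- avoid_motifs(ins, "GAATTC", tab)
  expect_false(grepl("GAATTC", out$sequence, fixed = TRUE))
  expect_equal(translate_dna(out$sequence), "KEFK")
  expect_null(out$unresolved_motifs)

  # no motif present: identity
  clean <- reverse_translate("MKTAYLNW", tab)
  same <- avoid_motifs(clean, "GGTACC", tab)
  expect_identical(same$sequence, clean$sequence)

  # Met-Trp has no synonymous move: reported unresolvable, not fatal
  mw <- reverse_translate("MW", tab)
  expect_message(stuck <- avoid_motifs(mw, "ATGTGG", tab),
                 "could not be removed")
  expect_equal(nrow(stuck$unresolved_motifs), 1L)
  expect_equal(translate_dna(stuck$sequence), "MW")
})

test_that("motif avoidance never increases total motif count", {
  tab <- default_codon_table()
  set.seed(73)
  motifs <- c("GAATTC", "GGATCC", "AAGCTT")
  for (rep in seq_len(30L)) {
    p <- rand_protein(40L)
    ins <- reverse_translate(p, tab, strategy = "weighted_sampling",
                             seed = rep)
    before <- sum(vapply(motifs, function(m)
      length(gregexpr(m, ins$sequence, fixed = TRUE)[[1L]][
        gregexpr(m, ins$sequence, fixed = TRUE)[[1L]] > 0]), numeric(1L)))
    out <- suppressMessages(avoid_motifs(ins, motifs, tab))
    after <- sum(vapply(motifs, function(m)
      length(gregexpr(m, out$sequence, fixed = TRUE)[[1L]][
        gregexpr(m, out$sequence, fixed = TRUE)[[1L]] > 0]), numeric(1L)))
    expect_lte(after, before)
    expect_equal(translate_dna(out$sequence), p)
  }
})

test_that("flanks add start/stop codons only when appropriate", {
  tab <- default_codon_table()
  ins <- reverse_translate("KTA", tab)
  with_stop <- add_flanks(ins, add_stop = TRUE)
  expect_true(endsWith(with_stop$sequence, "TAA"))

  with_both <- add_flanks(ins, add_start = TRUE, add_stop = TRUE)
  expect_true(startsWith(with_both$sequence, "ATG"))
  expect_equal(nchar(with_both$sequence), 9L + 6L)

  m_first <- reverse_translate("MKT", tab)
  no_dup <- add_flanks(m_first, add_start = TRUE)
  expect_equal(nchar(no_dup$sequence), 9L)  # no duplicate ATG

  nothing <- add_flanks(ins)
  expect_identical(nothing$sequence, ins$sequence)
})

test_that("layout features carry over to nucleotide coordinates", {
  set.seed(79)
  segs <- stats::setNames(c(rand_protein(25L), rand_protein(25L)),
                          c("e1", "e2"))
  layout <- assemble_construct(segs, spacers = "AAY",
                               config = design_config())
  dna <- reverse_translate(layout)
  expect_equal(nchar(dna$sequence), 3L * nchar(layout$protein))
  expect_equal(dna$features$start, (layout$features$start - 1L) * 3L + 1L)
  expect_equal(dna$features$end, layout$features$end * 3L)
  expect_equal(translate_dna(dna$sequence), layout$protein)
})
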