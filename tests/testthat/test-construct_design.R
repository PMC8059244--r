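test_that("long epitopes center the substitution and respect protein bounds", {
  set.seed(41)
  prot <- rand_protein(60L)
  v <- toy_variant(position = 30L, ref_aa = substr(prot, 30, 30),
                   alt_aa = setdiff(AA, substr(prot, 30, 30))[1L])
  seg <- make_long_epitope(prot, v, target_len = 25L)
  expect_equal(nchar(seg$sequence), 25L)
  expect_equal(seg$mut_offset, 12L)
  expect_equal(substr(seg$sequence, 13L, 13L), v$alt_aa)

  # near the N terminus: right-extended to full target length
  v2 <- toy_variant(position = 3L, ref_aa = substr(prot, 3, 3),
                    alt_aa = setdiff(AA, substr(prot, 3, 3))[1L])
  seg2 <- make_long_epitope(prot, v2, target_len = 25L)
  expect_equal(nchar(seg2$sequence), 25L)
  expect_equal(seg2$mut_offset, 2L)

  # even target length is left-biased
  seg3 <- make_long_epitope(prot, v, target_len = 24L)
  expect_equal(seg3$mut_offset, 12L)

  # protein shorter than the target yields the whole protein
  short <- rand_protein(18L)
  v3 <- toy_variant(position = 9L, ref_aa = substr(short, 9, 9),
                    alt_aa = setdiff(AA, substr(short, 9, 9))[1L])
  expect_message(seg4 <- make_long_epitope(short, v3), "whole protein")
  expect_equal(nchar(seg4$sequence), 18L)

  expect_error(make_long_epitope(prot, v, target_len = 19L), "\\[20, 25\\]")
})

test_that("junction enumeration matches the labelled brute-force scan", {
  # worked examples
  j1 <- enumerate_junction_peptides("AAAA", "", "CCCC", 3L)
  expect_equal(j1$peptide, c("AAC", "ACC"))
  j2 <- enumerate_junction_peptides("AAAA", "Y", "CCCC", 3L)
  expect_equal(j2$offset, c(2L, 3L, 4L))
  j3 <- enumerate_junction_peptides("AAA", "", "CCC", 9L)
  expect_equal(nrow(j3), 0L)

  set.seed(43)
  for (rep in seq_len(300L)) {
    left <- rand_protein(sample(1:20, 1L))
    right <- rand_protein(sample(1:20, 1L))
    spacer <- if (runif(1L) < 0.5) "" else
      rand_protein(sample(1:3, 1L))
    k <- sample(2:11, 1L)
    got <- enumerate_junction_peptides(left, spacer, right, k)
    expect_equal(got$peptide, oracle_junction_peptides(left, spacer,
                                                       right, k))
  }
})

test_that("junction cost counts sub-threshold peptide-allele pairs", {
  peps <- enumerate_junction_peptides("AAAAAAAAAA", "", "CCCCCCCCCC", 9L)
  planted <- peps$peptide[c(2L, 5L)]
  tp <- table_predictor(stats::setNames(c(100, 100),
                                        paste(planted, "A1", sep = "|")),
                        name = "t")
  jc <- junction_cost(peps, "A1", list(tp), threshold = 500)
  expect_equal(jc$cost, 2)
  expect_equal(sum(jc$peptides$below), 2L)

  # threshold below every score: cost 0
  jc0 <- junction_cost(peps, "A1", list(tp), threshold = 50)
  expect_equal(jc0$cost, 0)
})

test_that("planted pairwise costs steer the optimizer and spacers obey tie-breaks", {
  segs <- stats::setNames(
    c("AAAAAAAAAAAAAAAAAAAAA", "CCCCCCCCCCCCCCCCCCCCC",
      "DDDDDDDDDDDDDDDDDDDDD"), c("sA", "sC", "sD"))
  # plant binders on every inter-segment junction except A->C and C->D
  cfg <- design_config(junction_lengths = 9L, scan_terminal_junctions = FALSE)
  bad <- character(0L)
  combos <- expand.grid(l = names(segs), r = names(segs),
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    l <- combos$l[i]; r <- combos$r[i]
    if (l == r || paste(l, r) %in% c("sA sC", "sC sD")) next
    for (sp in cfg$spacers)
      bad <- c(bad, enumerate_junction_peptides(segs[l], sp, segs[r],
                                                9L)$peptide)
  }
  tp <- table_predictor(stats::setNames(rep(10, length(bad)),
                                        paste(bad, "A1", sep = "|")),
                        name = "t")
  layout <- optimize_order(segs, "A1", list(tp), cfg)
  expect_equal(vapply(layout$segments, function(s) s$id, character(1L)),
               c("sA", "sC", "sD"))
  expect_equal(layout$total_cost, 0)
  # zero-cost junctions prefer no spacer
  expect_equal(layout$spacers, c("", ""))
})

test_that("a single segment assembles with terminal costs only", {
  seg <- stats::setNames(rand_protein(25L), "only")
  tp <- table_predictor(numeric(), name = "t")
  layout <- optimize_order(seg, "A1", list(tp),
                           design_config(junction_lengths = 9L))
  expect_equal(length(layout$segments), 1L)
  expect_equal(layout$total_cost, 0)
  expect_error(optimize_order(list(), "A1", list(tp)), "no segments")
})

test_that("exhaustive optimizer equals the permutation oracle on random instances", {
  set.seed(47)
  for (rep in seq_len(15L)) {
    n <- sample(2:5, 1L)
    inst <- generate_ordering_instance(n, seed = 1000L + rep,
                                       structure = "random")
    layout <- optimize_order(inst$segments, inst$alleles, inst$predictors,
                             inst$config)
    tabs <- cost_tables(as.list(inst$segments), inst$alleles,
                        inst$predictors, inst$config)
    expect_equal(layout$total_cost,
                 oracle_min_path_cost(tabs$C, tabs$ub, tabs$tag))
  }
})

test_that("DP and exhaustive solvers agree where both run", {
  set.seed(53)
  for (n in c(8L, 9L)) {
    inst <- generate_ordering_instance(n, seed = 600L + n,
                                       structure = "random")
    tabs <- cost_tables(as.list(inst$segments), inst$alleles,
                        inst$predictors, inst$config)
    ex <- polyvax:::solve_order_exhaustive(tabs$C, tabs$ub, tabs$tag)
    dp <- polyvax:::solve_order_dp(tabs$C, tabs$ub, tabs$tag)
    expect_equal(dp$cost, ex$cost)
  }
})

test_that("per-junction spacer choice never exceeds the all-no-spacer cost", {
  set.seed(59)
  for (rep in seq_len(10L)) {
    inst <- generate_ordering_instance(4L, seed = 700L + rep,
                                       structure = "random")
    layout <- optimize_order(inst$segments, inst$alleles, inst$predictors,
                             inst$config)
    # rebuild the same order with no spacers anywhere and rescore
    cfg_ns <- inst$config
    cfg_ns$spacers <- ""
    ids <- vapply(layout$segments, function(s) s$id, character(1L))
    perm <- match(ids, names(inst$segments))
    tabs <- cost_tables(as.list(inst$segments), inst$alleles,
                        inst$predictors, cfg_ns)
    no_spacer_cost <- tabs$ub[perm[1L]] +
      sum(tabs$C[cbind(perm[-length(perm)], perm[-1L])]) +
      tabs$tag[perm[length(perm)]]
    expect_lte(layout$total_cost, no_spacer_cost)
  }
})

test_that("simulated annealing is reproducible and not worse than greedy identity", {
  set.seed(61)
  n <- 14L
  C <- matrix(sample(0:5, n * n, replace = TRUE), n, n)
  diag(C) <- 0
  ub <- sample(0:2, n, replace = TRUE)
  tg <- sample(0:2, n, replace = TRUE)
  cfg <- design_config(sa_steps = 5000L, sa_restarts = 3L)
  s1 <- polyvax:::solve_order_sa(C, ub, tg, cfg)
  s2 <- polyvax:::solve_order_sa(C, ub, tg, cfg)
  expect_identical(s1, s2)
  expect_lte(s1$cost, polyvax:::path_cost(seq_len(n), C, ub, tg))
})

test_that("assembly produces the degron-fused protein with exact arithmetic", {
  ub <- ubiquitin_mut()
  expect_equal(nchar(ub), 76L)
  expect_equal(substr(ub, 76L, 76L), "V")
  expect_equal(substr(ub, 75L, 75L), "G")

  set.seed(67)
  segs <- stats::setNames(c(rand_protein(25L), rand_protein(25L)),
                          c("e1", "e2"))
  layout <- assemble_construct(segs, spacers = "AAY",
                               config = design_config(include_tag = FALSE))
  expect_equal(nchar(layout$protein), 76L + 25L + 3L + 25L)
  expect_true(startsWith(layout$protein, ub))

  tagged <- assemble_construct(segs, spacers = "AAY",
                               config = design_config())
  expect_true(endsWith(tagged$protein, ha_tag()))
  expect_equal(nchar(ha_tag()), 9L)

  bare <- assemble_construct(segs, spacers = "",
                             config = design_config(include_ubmut = FALSE,
                                                    include_tag = FALSE))
  expect_equal(nchar(bare$protein), 50L)
})

test_that("every selected variant appears in exactly one layout segment", {
  b <- generate_scenario(scenario_spec(seed = 5L))
  pri <- run_prioritize(b$proteome, b$variants, b$expression,
                        predictors = b$predictors, alleles = b$spec$alleles)
  des <- run_design(pri)
  ids <- vapply(des$layout$segments, function(s) s$id, character(1L))
  expect_setequal(
    vapply(strsplit(ids, "_"), `[[`, character(1L), 1L),
    pri$selected$gene)
  expect_equal(anyDuplicated(ids), 0L)
  # ledger sum equals the reported total
  expect_equal(des$layout$total_cost,
               sum(vapply(des$layout$junction_ledger, `[[`, numeric(1L),
                          "cost")))
})
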