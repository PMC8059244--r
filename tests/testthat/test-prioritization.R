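# Shared fixture: one variant whose mutant window contains a single planted
# strong binder.
planted_candidate_fixture <- function() {
  set.seed(21)
  prot <- rand_protein(40L)
  pos <- 20L
  v <- toy_variant(position = pos, ref_aa = substr(prot, pos, pos),
                   alt_aa = setdiff(AA, substr(prot, pos, pos))[1L])
  ctx <- extract_context(prot, v, flank = 12L)
  subs <- enumerate_subpeptides(ctx, 9L)
  planted <- subs$mt_peptide[subs$offset == 8L]  # one 9-mer, planted to 1 nM
  list(ctx = ctx, planted = planted,
       predictors = list(pwm_predictor(list(planted_pwm(planted, "A1")),
                                       name = "p")))
}

test_that("the best mutant sub-peptide per (variant, allele) is selected", {
  fx <- planted_candidate_fixture()
  cands <- evaluate_candidates(list(fx$ctx), "A1", fx$predictors,
                               lengths = 9L,
                               expression = c(GeneX = 10))
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$mt_peptide, fx$planted)
  expect_equal(cands$mt_ic50, 1)
  expect_equal(cands$fpkm, 10)
  expect_equal(cands$fold_change, cands$wt_ic50 / cands$mt_ic50)
})

test_that("ties break by lower offset then shorter length", {
  # constant predictor: every sub-peptide ties; the lowest offset wins,
  # and among same-offset ties the shorter length
  fx <- planted_candidate_fixture()
  const <- table_predictor(numeric(), default_ic50 = 77, name = "const")
  cands <- evaluate_candidates(list(fx$ctx), "A1", list(const),
                               lengths = c(9L, 10L))
  subs <- enumerate_subpeptides(fx$ctx, c(9L, 10L))
  expect_equal(cands$peptide_offset, min(subs$offset))
  expect_equal(cands$peptide_length,
               min(subs$length[subs$offset == min(subs$offset)]))
})

test_that("fold change is the WT/MT ratio of median IC50s", {
  fx <- planted_candidate_fixture()
  subs <- enumerate_subpeptides(fx$ctx, 9L)
  wt_at_plant <- subs$wt_peptide[subs$mt_peptide == fx$planted]
  tp <- table_predictor(
    stats::setNames(c(200, 800),
                    paste(c(fx$planted, wt_at_plant), "A1", sep = "|")),
    default_ic50 = 50000, name = "t")
  cands <- evaluate_candidates(list(fx$ctx), "A1", list(tp), lengths = 9L)
  expect_equal(cands$mt_peptide, fx$planted)
  expect_equal(cands$mt_ic50, 200)
  expect_equal(cands$wt_ic50, 800)
  expect_equal(cands$fold_change, 4.0)
})

test_that("filter cascade applies strict thresholds flag by flag", {
  base <- data.frame(mt_ic50 = 499, dna_vaf = 0.31, rna_vaf = 0.35,
                     fpkm = 1.5, fold_change = 2.1)
  f <- apply_filters(base)
  expect_true(f$pass)

  # strict boundaries fail exactly one flag each
  cases <- list(
    list(col = "mt_ic50", val = 500, flag = "flag_binding"),
    list(col = "dna_vaf", val = 0.30, flag = "flag_dna_vaf"),
    list(col = "rna_vaf", val = 0.30, flag = "flag_rna_vaf"),
    list(col = "fpkm", val = 1, flag = "flag_expression"),
    list(col = "fold_change", val = 2, flag = "flag_fold_change"))
  flag_cols <- c("flag_binding", "flag_dna_vaf", "flag_rna_vaf",
                 "flag_expression", "flag_fold_change")
  for (cs in cases) {
    row <- base
    row[[cs$col]] <- cs$val
    f <- apply_filters(row)
    expect_false(f[[cs$flag]])
    expect_true(all(unlist(f[setdiff(flag_cols, cs$flag)])))
    expect_false(f$pass)
  }

  # missing expression flags, never drops
  row <- base
  row$fpkm <- NA_real_
  f <- apply_filters(row)
  expect_true(f$fpkm_missing)
  expect_false(f$flag_expression)
})

test_that("filtering is idempotent", {
  set.seed(31)
  df <- data.frame(mt_ic50 = runif(20L, 1, 1000),
                   dna_vaf = runif(20L), rna_vaf = runif(20L),
                   fpkm = runif(20L, 0, 5), fold_change = runif(20L, 0.5, 5))
  once <- apply_filters(df)
  twice <- apply_filters(once)
  expect_identical(once, twice)
})

test_that("ranking sorts by fold change with documented tie-breaks and cuts at max_n", {
  df <- data.frame(
    gene = c("g1", "g2", "g3", "g4"), protein_id = paste0("p", 1:4),
    position = 1:4, ref_aa = "A", alt_aa = "V",
    dna_vaf = 0.5, rna_vaf = 0.5, allele = "A1",
    mt_peptide = "X", wt_peptide = "Y", peptide_length = 9L,
    peptide_offset = 0L,
    mt_ic50 = c(100, 200, 100, 50), wt_ic50 = 1,
    fold_change = c(4.0, 3.0, 3.0, 2.1), fpkm = 5,
    stringsAsFactors = FALSE)
  df <- apply_filters(df)
  sel <- rank_and_select(df, max_n = 3L)
  expect_equal(sel$rank, 1:3)
  expect_equal(sel$gene, c("g1", "g3", "g2"))  # FC tie: lower MT IC50 first

  sel2 <- rank_and_select(df, max_n = 2L)
  expect_equal(nrow(sel2), 2L)

  # each selected candidate re-satisfies all five strict inequalities
  th <- filter_thresholds()
  expect_true(all(sel$mt_ic50 < th$ic50_max & sel$dna_vaf > th$vaf_min &
                    sel$rna_vaf > th$vaf_min & sel$fpkm > th$fpkm_min &
                    sel$fold_change > th$fold_change_min))

  none <- df
  none$pass <- FALSE
  expect_warning(empty <- rank_and_select(none), "no candidate")
  expect_equal(nrow(empty), 0L)
})

test_that("best-per-variant collapsing keeps one allele per variant", {
  df <- data.frame(
    gene = c("g1", "g1"), protein_id = "p1", position = 1L,
    ref_aa = "A", alt_aa = "V", dna_vaf = 0.5, rna_vaf = 0.5,
    allele = c("A1", "B1"),
    mt_peptide = "X", wt_peptide = "Y", peptide_length = 9L,
    peptide_offset = 0L,
    mt_ic50 = c(100, 10), wt_ic50 = 1000,
    fold_change = c(10, 100), fpkm = 5, stringsAsFactors = FALSE)
  df <- apply_filters(df)
  sel <- rank_and_select(df)
  expect_equal(nrow(sel), 1L)
  expect_equal(sel$allele, "B1")  # higher fold change wins
})
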