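test_that("PWM scoring maps the normalized score range onto (1, 50000] nM", {
  m <- planted_pwm("KLMNPQRST", "A1")
  expect_equal(pwm_predict(m, "KLMNPQRST"), 1)          # x = 1
  expect_equal(pwm_predict(m, "AAAAAAAAA"), 50000)      # x = 0

  # uniform matrix: every peptide of that length scores identically
  u <- pwm_model("A1", 9L,
                 matrix(0.5, 20L, 9L, dimnames = list(AA, NULL)),
                 score_min = 0, score_max = 9)
  set.seed(1)
  vals <- replicate(20L, pwm_predict(u, rand_protein(9L)))
  expect_equal(vals, rep(vals[1L], 20L))

  expect_error(pwm_predict(m, "KLMNPQRS"), "length")
  expect_error(pwm_model("A1", 9L,
                         matrix(0, 20L, 9L, dimnames = list(AA, NULL)),
                         score_min = 1, score_max = 1), "strictly less")
})

test_that("raising a matrix cell used by the peptide never increases IC50", {
  set.seed(7)
  for (rep in seq_len(50L)) {
    mat <- matrix(runif(180L), 20L, 9L, dimnames = list(AA, NULL))
    m <- pwm_model("A1", 9L, mat, score_min = 0, score_max = 9)
    pep <- rand_protein(9L)
    base <- pwm_predict(m, pep)
    i <- sample(9L, 1L)
    mat2 <- mat
    mat2[substr(pep, i, i), i] <- mat2[substr(pep, i, i), i] + runif(1L)
    m2 <- pwm_model("A1", 9L, mat2, score_min = 0, score_max = 9)
    expect_lte(pwm_predict(m2, pep), base)
  }
})

test_that("mock predictor is a pure deterministic function with full range", {
  p1 <- mock_predictor(1L)
  p2 <- mock_predictor(2L)
  expect_identical(predict_ic50(p1, "SIINFEKL", "H-2-Kb"),
                   predict_ic50(p1, "SIINFEKL", "H-2-Kb"))
  expect_false(predict_ic50(p1, "SIINFEKL", "H-2-Kb") ==
                 predict_ic50(p2, "SIINFEKL", "H-2-Kb"))
  set.seed(3)
  vals <- vapply(replicate(2000L, rand_protein(9L)),
                 function(pep) predict_ic50(p1, pep, "A1"), numeric(1L))
  expect_true(all(vals > 0 & vals <= 50000))
  # approximately spans the range
  expect_lt(min(vals), 1000)
  expect_gt(max(vals), 49000)
  expect_gt(length(unique(round(vals / 5000))), 8L)
})

test_that("predictor contract holds across implementations under random calls", {
  set.seed(5)
  preds <- list(mock_predictor(11L),
                pwm_predictor(list(planted_pwm("KLMNPQRST", "A1")),
                              name = "p"),
                table_predictor(c("KLMNPQRST|A1" = 12), name = "t"))
  for (rep in seq_len(300L)) {
    pep <- rand_protein(9L)
    for (p in preds) {
      if (!predictor_supports(p, "A1", 9L)) next
      v1 <- predict_ic50(p, pep, "A1")
      v2 <- predict_ic50(p, pep, "A1")
      expect_true(is.finite(v1) && v1 > 0)
      expect_identical(v1, v2)
    }
  }
})

test_that("median aggregation follows the even-count convention and skips absent predictors", {
  fixed <- function(val, name, lengths = NULL)
    table_predictor(numeric(), default_ic50 = val, name = name,
                    lengths = lengths)
  prof <- median_affinity("KLMNPQRST", "A1",
                          list(fixed(100, "a"), fixed(300, "b"),
                               fixed(500, "c")))
  expect_equal(prof$median_ic50, 300)

  prof2 <- median_affinity("KLMNPQRST", "A1",
                           list(fixed(100, "a"), fixed(400, "b")))
  expect_equal(prof2$median_ic50, 250)

  prof3 <- median_affinity("KLMNPQRST", "A1", list(fixed(42, "a")))
  expect_equal(prof3$median_ic50, 42)

  # a predictor not supporting the length is absent, not imputed
  prof4 <- median_affinity("KLMNPQRST", "A1",
                           list(fixed(100, "a"),
                                fixed(99999 - 49999, "len8", lengths = 8L)))
  expect_equal(names(prof4$per_predictor), "a")
  expect_equal(prof4$median_ic50, 100)

  expect_error(median_affinity("KLMNPQRST", "A1",
                               list(fixed(10, "len8", lengths = 8L))),
               "no predictor supports allele A1 at peptide length 9")
})

test_that("median is invariant to predictor order", {
  set.seed(9)
  preds <- lapply(1:5, function(i) mock_predictor(i))
  pep <- rand_protein(10L)
  base <- median_affinity(pep, "A1", preds)$median_ic50
  for (rep in 1:10) {
    shuffled <- sample(preds)
    expect_equal(median_affinity(pep, "A1", shuffled)$median_ic50, base)
  }
})
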