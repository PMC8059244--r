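# Peptide-MHC binding: a pluggable predictor contract (every predictor maps
# (peptide, allele) to a strictly positive, finite, deterministic IC50 in
# nM), three concrete implementations, and median aggregation across a
# predictor suite.

IC50_CEILING <- 50000

#' Construct a position-weight-matrix binding model
#'
#' Scores a peptide as the sum of per-position residue weights; the raw
#' score is min-max normalized to `x` in `[0, 1]` and mapped to
#' `IC50 = 50000^(1 - x)` nM, the conventional transform from a normalized
#' binding score to nanomolar affinity (so `x = 1` is a 1 nM binder and
#' `x = 0` a 50 uM non-binder).
#'
#' @param allele Allele label (e.g. `"HLA-A*02:01"`).
#' @param length Peptide length this matrix scores.
#' @param matrix Numeric matrix, 20 rows named by [AA_ALPHABET], `length`
#'   columns.
#' @param score_min,score_max Normalization bounds (`score_min < score_max`).
#' @return A `pwm_model`.
#' @export
pwm_model <- function(allele, length, matrix, score_min, score_max) {
  length <- as.integer(length)
  stopifnot(is.matrix(matrix), ncol(matrix) == length)
  if (!setequal(rownames(matrix), AA_ALPHABET))
    stop("PWM matrix rows must cover exactly the 20 canonical residues",
         call. = FALSE)
  if (!(score_min < score_max))
    stop("score_min must be strictly less than score_max", call. = FALSE)
  structure(list(allele = allele, length = length,
                 matrix = matrix[AA_ALPHABET, , drop = FALSE],
                 score_min = score_min, score_max = score_max),
            class = "pwm_model")
}

#' Predict IC50 from a single PWM model
#'
#' @param model A `pwm_model`.
#' @param peptide Peptide of exactly `model$length` canonical residues.
#' @return IC50 in nM (strictly decreasing in the raw matrix score).
#' @export
pwm_predict <- function(model, peptide) {
  stopifnot(inherits(model, "pwm_model"))
  chars <- str_chars(peptide)
  if (length(chars) != model$length)
    stop(sprintf("peptide length %d does not match model length %d",
                 length(chars), model$length), call. = FALSE)
  if (!all(chars %in% AA_ALPHABET))
    stop("peptide contains non-canonical residue(s): ",
         paste(setdiff(chars, AA_ALPHABET), collapse = ", "), call. = FALSE)
  raw <- sum(model$matrix[cbind(match(chars, rownames(model$matrix)),
                                seq_along(chars))])
  x <- (raw - model$score_min) / (model$score_max - model$score_min)
  x <- min(max(x, 0), 1)
  IC50_CEILING^(1 - x)
}

# ---- predictor contract -----------------------------------------------

#' Binding-predictor contract
#'
#' `predictor_supports()` reports whether a predictor covers an
#' (allele, peptide length) pair; `predict_ic50()` returns a finite,
#' strictly positive IC50 in nM and is deterministic in its inputs.
#'
#' @param predictor A `binding_predictor`.
#' @param allele Allele label.
#' @param length Peptide length.
#' @export
predictor_supports <- function(predictor, allele, length) {
  UseMethod("predictor_supports")
}

#' @rdname predictor_supports
#' @param peptide Peptide string.
#' @export
predict_ic50 <- function(predictor, peptide, allele) {
  UseMethod("predict_ic50")
}

#' Predictor backed by a set of PWM models
#'
#' @param models List of `pwm_model` objects (one per allele/length).
#' @param name Predictor name (appears in affinity profiles).
#' @return A `binding_predictor`.
#' @export
pwm_predictor <- function(models, name = "pwm") {
  stopifnot(length(models) > 0L,
            all(vapply(models, inherits, logical(1L), "pwm_model")))
  keys <- vapply(models, function(m) paste(m$allele, m$length, sep = "|"),
                 character(1L))
  if (anyDuplicated(keys))
    stop("duplicate (allele, length) among PWM models", call. = FALSE)
  structure(list(name = name, models = stats::setNames(models, keys)),
            class = c("pwm_predictor", "binding_predictor"))
}

#' @export
predictor_supports.pwm_predictor <- function(predictor, allele, length) {
  paste(allele, as.integer(length), sep = "|") %in% names(predictor$models)
}

#' @export
predict_ic50.pwm_predictor <- function(predictor, peptide, allele) {
  key <- paste(allele, nchar(peptide), sep = "|")
  m <- predictor$models[[key]]
  if (is.null(m))
    stop(sprintf("predictor '%s' does not support allele %s at length %d",
                 predictor$name, allele, nchar(peptide)), call. = FALSE)
  pwm_predict(m, peptide)
}

#' Hash-seeded deterministic mock predictor
#'
#' A pure function of (seed, peptide, allele) with values spanning
#' (0, 50000] nM; intended for test suites and randomized instances where
#' a reproducible but unstructured affinity landscape is wanted.
#'
#' @param seed Integer salt.
#' @param name Predictor name.
#' @param alleles,lengths Optional support restriction (default: all).
#' @return A `binding_predictor`.
#' @export
mock_predictor <- function(seed = 1L, name = paste0("mock-", seed),
                           alleles = NULL, lengths = NULL) {
  structure(list(name = name, seed = as.integer(seed),
                 alleles = alleles, lengths = lengths),
            class = c("mock_predictor", "binding_predictor"))
}

#' @export
predictor_supports.mock_predictor <- function(predictor, allele, length) {
  (is.null(predictor$alleles) || allele %in% predictor$alleles) &&
    (is.null(predictor$lengths) || as.integer(length) %in% predictor$lengths)
}

#' @export
predict_ic50.mock_predictor <- function(predictor, peptide, allele) {
  hash01(predictor$seed, peptide, allele) * IC50_CEILING
}

#' Lookup-table predictor
#'
#' Maps explicit (peptide, allele) pairs to IC50 values, with a default for
#' everything else. This is the ingestion path for precomputed affinities
#' from external tools, and the exact-control predictor used by planted
#' ordering instances.
#'
#' @param ic50 Named numeric vector; names are `"<peptide>|<allele>"`.
#' @param default_ic50 IC50 returned for unlisted pairs.
#' @param name Predictor name.
#' @param alleles,lengths Optional support restriction (default: all).
#' @return A `binding_predictor`.
#' @export
table_predictor <- function(ic50 = numeric(), default_ic50 = IC50_CEILING,
                            name = "table", alleles = NULL, lengths = NULL) {
  stopifnot(all(ic50 > 0), default_ic50 > 0)
  structure(list(name = name, ic50 = ic50, default_ic50 = default_ic50,
                 alleles = alleles, lengths = lengths),
            class = c("table_predictor", "binding_predictor"))
}

#' @export
predictor_supports.table_predictor <- function(predictor, allele, length) {
  (is.null(predictor$alleles) || allele %in% predictor$alleles) &&
    (is.null(predictor$lengths) || as.integer(length) %in% predictor$lengths)
}

#' @export
predict_ic50.table_predictor <- function(predictor, peptide, allele) {
  key <- paste(peptide, allele, sep = "|")
  v <- predictor$ic50[key]
  if (is.na(v)) predictor$default_ic50 else unname(v)
}

# ---- aggregation -------------------------------------------------------

#' Median binding affinity across a predictor suite
#'
#' Each supporting predictor contributes one IC50; the profile's summary is
#' the median over supporting predictors only (an even count averages the
#' two central values). Predictors that do not cover the (allele, length)
#' pair are absent from the profile, never imputed.
#'
#' @param peptide Peptide string.
#' @param allele Allele label.
#' @param predictors List of `binding_predictor` objects.
#' @return An `affinity_profile` with fields `peptide`, `allele`,
#'   `per_predictor` (named numeric) and `median_ic50`.
#' @export
median_affinity <- function(peptide, allele, predictors) {
  stopifnot(length(predictors) > 0L)
  vals <- numeric(0L)
  for (p in predictors) {
    if (predictor_supports(p, allele, nchar(peptide)))
      vals[p$name] <- predict_ic50(p, peptide, allele)
  }
  if (!length(vals))
    stop(sprintf("no predictor supports allele %s at peptide length %d",
                 allele, nchar(peptide)), call. = FALSE)
  structure(list(peptide = peptide, allele = allele, per_predictor = vals,
                 median_ic50 = stats::median(vals)),
            class = "affinity_profile")
}

#' @export
print.affinity_profile <- function(x, ...) {
  cat(sprintf("%s @ %s: median IC50 %.2f nM over %d predictor(s)\n",
              x$peptide, x$allele, x$median_ic50, length(x$per_predictor)))
  invisible(x)
}
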