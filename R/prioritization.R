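# Neoantigen prioritization: score every substitution-spanning sub-peptide
# on every allele, keep the best mutant binder per (variant, allele), apply
# the filter cascade, rank by WT/MT fold change.

#' Default filter thresholds
#'
#' All comparisons are strict: mutant median IC50 < `ic50_max`, both VAFs >
#' `vaf_min`, FPKM > `fpkm_min`, fold change > `fold_change_min`.
#'
#' @param ic50_max Mutant median IC50 ceiling in nM.
#' @param vaf_min Minimum tumor DNA and RNA variant-allele fraction.
#' @param fpkm_min Minimum gene expression (FPKM).
#' @param fold_change_min Minimum WT/MT median-IC50 ratio.
#' @return Named list of thresholds.
#' @export
filter_thresholds <- function(ic50_max = 500, vaf_min = 0.30,
                              fpkm_min = 1, fold_change_min = 2) {
  list(ic50_max = ic50_max, vaf_min = vaf_min, fpkm_min = fpkm_min,
       fold_change_min = fold_change_min)
}

variant_key <- function(v) {
  paste(v$gene, v$protein_id, v$position, v$ref_aa, v$alt_aa, sep = "|")
}

#' Evaluate epitope candidates for every (variant, allele) pair
#'
#' For each mutant context and allele, all substitution-spanning
#' sub-peptides of the requested lengths are scored with the predictor
#' suite; the sub-peptide with the minimal mutant median IC50 is retained
#' (ties broken by lower offset, then shorter length) and its wild-type
#' counterpart is scored at the same offset and length. Fold change is the
#' WT/MT ratio of median IC50s, so values above 1 mean the mutation
#' improves predicted binding.
#'
#' Lengths no predictor covers for an allele are skipped; a (variant,
#' allele) pair with nothing scoreable is dropped with a warning. A variant
#' whose gene has no expression value keeps an `NA` FPKM and is flagged at
#' filtering, not dropped here.
#'
#' @param contexts List of `mutant_context` objects.
#' @param alleles Character vector of allele labels.
#' @param predictors List of `binding_predictor` objects.
#' @param lengths Sub-peptide lengths (default 8--11).
#' @param expression Optional expression table (`data.frame` with `gene`,
#'   `fpkm`) or named numeric vector.
#' @return `data.frame` of class `epitope_candidates`, one row per
#'   (variant, allele).
#' @export
evaluate_candidates <- function(contexts, alleles, predictors,
                                lengths = c(8L, 9L, 10L, 11L),
                                expression = NULL) {
  stopifnot(length(contexts) > 0L, length(alleles) > 0L)
  fpkm_of <- function(gene) {
    if (is.null(expression)) return(NA_real_)
    if (is.data.frame(expression)) {
      i <- match(gene, expression$gene)
      if (is.na(i)) NA_real_ else expression$fpkm[i]
    } else {
      v <- expression[gene]
      if (is.na(v)) NA_real_ else unname(v)
    }
  }
  rows <- list()
  for (ctx in contexts) {
    v <- ctx$variant
    subs <- suppressMessages(enumerate_subpeptides(ctx, lengths))
    for (allele in alleles) {
      keep <- vapply(subs$length, function(k) {
        any(vapply(predictors, predictor_supports, logical(1L), allele, k))
      }, logical(1L))
      sk <- subs[keep, , drop = FALSE]
      if (!nrow(sk)) {
        warning(sprintf("no scoreable sub-peptide for %s on %s; pair skipped",
                        variant_key(v), allele), call. = FALSE)
        next
      }
      mt_med <- vapply(sk$mt_peptide, function(p)
        median_affinity(p, allele, predictors)$median_ic50, numeric(1L),
        USE.NAMES = FALSE)
      best <- order(mt_med, sk$offset, sk$length)[1L]
      wt_med <- median_affinity(sk$wt_peptide[best], allele,
                                predictors)$median_ic50
      rows[[length(rows) + 1L]] <- data.frame(
        gene = v$gene, protein_id = v$protein_id, position = v$position,
        ref_aa = v$ref_aa, alt_aa = v$alt_aa,
        dna_vaf = v$dna_vaf, rna_vaf = v$rna_vaf,
        allele = allele,
        mt_peptide = sk$mt_peptide[best], wt_peptide = sk$wt_peptide[best],
        peptide_length = sk$length[best], peptide_offset = sk$offset[best],
        mt_ic50 = mt_med[best], wt_ic50 = wt_med,
        fold_change = wt_med / mt_med[best],
        fpkm = fpkm_of(v$gene),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame()
  class(out) <- c("epitope_candidates", "data.frame")
  out
}

#' Apply the filter cascade
#'
#' Sets one logical flag per criterion plus the conjunction `pass`. All
#' inequalities are strict; a missing FPKM fails the expression flag and is
#' additionally marked in `fpkm_missing`. Filtering never errors and is
#' idempotent.
#'
#' @param candidates Output of [evaluate_candidates()].
#' @param thresholds See [filter_thresholds()].
#' @return `candidates` with flag columns added.
#' @export
apply_filters <- function(candidates, thresholds = filter_thresholds()) {
  th <- thresholds
  candidates$flag_binding <- candidates$mt_ic50 < th$ic50_max
  candidates$flag_dna_vaf <- candidates$dna_vaf > th$vaf_min
  candidates$flag_rna_vaf <- candidates$rna_vaf > th$vaf_min
  candidates$fpkm_missing <- is.na(candidates$fpkm)
  candidates$flag_expression <- !is.na(candidates$fpkm) &
    candidates$fpkm > th$fpkm_min
  candidates$flag_fold_change <- candidates$fold_change > th$fold_change_min
  candidates$pass <- candidates$flag_binding & candidates$flag_dna_vaf &
    candidates$flag_rna_vaf & candidates$flag_expression &
    candidates$flag_fold_change
  candidates
}

#' Rank passing candidates and select the vaccine set
#'
#' Passing candidates are collapsed to the best allele per variant, sorted
#' by fold change (descending) with ties broken by lower mutant median
#' IC50, then gene name, and the top `max_n` are assigned ranks `1..n`.
#'
#' @param candidates Filtered candidates (after [apply_filters()]).
#' @param max_n Maximum number of neoantigens to encode.
#' @return `data.frame` of selected candidates with a `rank` column
#'   (class `prioritized_neoantigens`).
#' @export
rank_and_select <- function(candidates, max_n = Inf) {
  stopifnot(max_n >= 1)
  if (is.null(candidates$pass))
    stop("candidates have no filter flags; run apply_filters() first",
         call. = FALSE)
  passing <- candidates[candidates$pass, , drop = FALSE]
  if (!nrow(passing)) {
    warning("no candidate passes all filters; empty selection",
            call. = FALSE)
    passing$rank <- integer(0L)
    class(passing) <- c("prioritized_neoantigens", "data.frame")
    return(passing)
  }
  ord <- order(-passing$fold_change, passing$mt_ic50, passing$gene,
               passing$allele)
  passing <- passing[ord, , drop = FALSE]
  key <- apply(passing[c("gene", "protein_id", "position", "ref_aa",
                         "alt_aa")], 1L, paste, collapse = "|")
  passing <- passing[!duplicated(key), , drop = FALSE]
  passing <- utils::head(passing, max_n)
  passing$rank <- seq_len(nrow(passing))
  rownames(passing) <- NULL
  class(passing) <- c("prioritized_neoantigens", "data.frame")
  passing
}

#' @export
print.prioritized_neoantigens <- function(x, ...) {
  cat(sprintf("Prioritized neoantigens: %d selected\n", nrow(x)))
  if (nrow(x)) {
    show <- x[c("rank", "gene", "position", "ref_aa", "alt_aa", "allele",
                "mt_peptide", "mt_ic50", "fold_change")]
    print.data.frame(show, digits = 4L, row.names = FALSE)
  }
  invisible(x)
}
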