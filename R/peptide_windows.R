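# Mutant peptide windows: apply missense variants, extract flanked
# mutant/wild-type context windows, enumerate substitution-spanning
# sub-peptides.

#' Apply a missense variant to a protein sequence
#'
#' @param protein Wild-type amino-acid string.
#' @param variant A single-row variant record (list or `data.frame` row with
#'   `position`, `ref_aa`, `alt_aa`).
#' @return The mutant protein sequence.
#' @export
apply_variant <- function(protein, variant) {
  p <- as.integer(variant$position)
  if (is.na(p) || p < 1L || p > nchar(protein))
    stop(sprintf("variant position %s out of range 1..%d",
                 as.character(variant$position), nchar(protein)),
         call. = FALSE)
  obs <- substr(protein, p, p)
  if (obs != variant$ref_aa)
    stop(sprintf(
      "reference mismatch at position %d: expected '%s', protein has '%s'",
      p, variant$ref_aa, obs), call. = FALSE)
  paste0(substr(protein, 1L, p - 1L), variant$alt_aa,
         substr(protein, p + 1L, nchar(protein)))
}

#' Extract the flanked mutant/wild-type context window around a variant
#'
#' The window spans `flank` residues either side of the substitution,
#' clipped at the protein termini. Mutant and wild-type windows have equal
#' length and differ only at the substituted position.
#'
#' @param protein Wild-type amino-acid string.
#' @param variant A single-row variant record.
#' @param flank Residues requested per side (default 12; the conventional
#'   working range is 10--14 so that every MHC class I sub-peptide
#'   containing the substitution exists within the window).
#' @param allow_any_flank Lift the 10--14 restriction.
#' @return A `mutant_context` object with fields `variant`, `wt_window`,
#'   `mt_window`, `mut_index` (0-based offset of the substitution inside
#'   the window), `flank_requested`, `window_start` (1-based protein
#'   coordinate of the first window residue).
#' @export
extract_context <- function(protein, variant, flank = 12L,
                            allow_any_flank = FALSE) {
  flank <- as.integer(flank)
  if (!allow_any_flank && (flank < 10L || flank > 14L))
    stop("flank must lie in [10, 14] (set allow_any_flank = TRUE to override)",
         call. = FALSE)
  mt_protein <- apply_variant(protein, variant)
  p <- as.integer(variant$position)
  start <- max(1L, p - flank)
  end <- min(nchar(protein), p + flank)
  ctx <- list(variant = as.list(variant),
              wt_window = substr(protein, start, end),
              mt_window = substr(mt_protein, start, end),
              mut_index = p - start,
              flank_requested = flank,
              window_start = start)
  class(ctx) <- "mutant_context"
  ctx
}

#' Enumerate all sub-peptides containing the substitution
#'
#' Returns every window substring of each requested length whose span
#' includes the substituted residue, paired with the wild-type substring at
#' the same offset. Order is deterministic: by length (ascending), then
#' offset.
#'
#' @param context A `mutant_context`.
#' @param lengths Integer vector of peptide lengths (default 8--11, the
#'   standard MHC class I range).
#' @return `data.frame` with columns `length`, `offset` (0-based within the
#'   window), `mt_peptide`, `wt_peptide`.
#' @export
enumerate_subpeptides <- function(context, lengths = c(8L, 9L, 10L, 11L)) {
  stopifnot(inherits(context, "mutant_context"), all(lengths >= 1L))
  L <- nchar(context$mt_window)
  m <- context$mut_index
  out <- list()
  for (k in sort(unique(as.integer(lengths)))) {
    if (k > L) {
      message(sprintf("enumerate_subpeptides: length %d exceeds window length %d; skipped",
                      k, L))
      next
    }
    offs <- seq.int(max(0L, m - k + 1L), min(m, L - k))
    out[[length(out) + 1L]] <- data.frame(
      length = k, offset = offs,
      mt_peptide = substring(context$mt_window, offs + 1L, offs + k),
      wt_peptide = substring(context$wt_window, offs + 1L, offs + k),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(length = integer(), offset = integer(),
                      mt_peptide = character(), wt_peptide = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' @export
print.mutant_context <- function(x, ...) {
  v <- x$variant
  cat(sprintf("Mutant context %s %s%d%s (%s)\n", v$gene %||% "?",
              v$ref_aa, v$position, v$alt_aa, v$protein_id %||% "?"))
  marker <- paste0(strrep(" ", x$mut_index), "*")
  cat("  WT ", x$wt_window, "\n  MT ", x$mt_window, "\n     ", marker, "\n",
      sep = "")
  invisible(x)
}
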