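# Codon-usage-driven reverse translation of the assembled polyepitope
# protein into a synthesizable DNA insert, with restriction-motif
# avoidance and cloning flanks.

#' Translate DNA under the standard genetic code
#'
#' @param dna DNA string over `{A,C,G,T}`, length divisible by 3.
#' @return Amino-acid string (`*` for stop codons).
#' @export
translate_dna <- function(dna) {
  dna <- toupper(dna)
  if (nchar(dna) %% 3L != 0L)
    stop("DNA length not divisible by 3", call. = FALSE)
  starts <- seq(1L, nchar(dna), by = 3L)
  codons <- substring(dna, starts, starts + 2L)
  aa <- GENETIC_CODE_STD[codons]
  if (anyNA(aa))
    stop("invalid codon(s): ",
         paste(unique(codons[is.na(aa)]), collapse = ", "), call. = FALSE)
  paste(aa, collapse = "")
}

#' Reverse-translate a protein into a codon-optimized DNA insert
#'
#' `max_frequency` (the default) picks each residue's most frequent codon
#' (ties resolved to the lexicographically smallest codon), giving a
#' deterministic, platform-independent insert. `weighted_sampling` draws
#' codons proportional to their usage frequencies under a fixed seed.
#' Translation of the result always round-trips to the input protein.
#'
#' @param protein Amino-acid string over canonical residues, or a
#'   `construct_layout` (its protein is used and its features carried over
#'   in nucleotide coordinates).
#' @param table A `codon_table` (default: bundled human usage).
#' @param strategy `"max_frequency"` or `"weighted_sampling"`.
#' @param seed Seed for `weighted_sampling`.
#' @return A `dna_insert`: `sequence`, `features` (nt coordinates),
#'   `protein`, `codon_table_name`, `core_start` (nt offset of the first
#'   protein codon, changed by [add_flanks()]).
#' @export
reverse_translate <- function(protein, table = default_codon_table(),
                              strategy = c("max_frequency",
                                           "weighted_sampling"),
                              seed = 1L) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(table, "codon_table"))
  features <- NULL
  if (inherits(protein, "construct_layout")) {
    layout <- protein
    protein <- layout$protein
    if (!is.null(layout$features)) {
      features <- layout$features
      features$start <- (features$start - 1L) * 3L + 1L
      features$end <- features$end * 3L
    }
  }
  chars <- str_chars(protein)
  missing <- setdiff(unique(chars), names(table$frequencies))
  if (length(missing))
    stop("residue(s) absent from codon table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  pick_max <- function(aa) {
    fr <- table$frequencies[[aa]]
    names(fr)[order(-fr, names(fr))][1L]
  }
  codons <- if (strategy == "max_frequency") {
    lut <- vapply(unique(chars), pick_max, character(1L))
    lut[chars]
  } else {
    with_seed(seed, vapply(chars, function(aa) {
      fr <- table$frequencies[[aa]]
      sample(names(fr), 1L, prob = fr)
    }, character(1L)))
  }
  structure(list(sequence = paste(codons, collapse = ""),
                 features = features, protein = protein,
                 codon_table_name = table$name, core_start = 1L,
                 unresolved_motifs = NULL),
            class = "dna_insert")
}

insert_core <- function(insert) {
  substr(insert$sequence, insert$core_start,
         insert$core_start + 3L * nchar(insert$protein) - 1L)
}

set_insert_core <- function(insert, core) {
  insert$sequence <- paste0(
    substr(insert$sequence, 1L, insert$core_start - 1L), core,
    substr(insert$sequence, insert$core_start + nchar(core),
           nchar(insert$sequence)))
  insert
}

count_motifs <- function(sequence, forbidden) {
  sum(vapply(forbidden, function(m) {
    hits <- gregexpr(m, sequence, fixed = TRUE)[[1L]]
    sum(hits > 0L)
  }, numeric(1L)))
}

#' Recode the insert to avoid forbidden DNA motifs
#'
#' Wherever a forbidden motif (e.g. a restriction site) occurs, the
#' overlapping codon offering the best next-ranked synonymous alternative
#' is substituted, repeating to a fixpoint or a bounded 10 passes. A
#' substitution is only kept if it reduces the total motif count, so the
#' count never increases; translation is unchanged by construction.
#' Unresolvable occurrences (no synonymous move removes them) are reported
#' in the `unresolved_motifs` field, not fatal.
#'
#' @param insert A `dna_insert`.
#' @param forbidden Character vector of DNA motifs (each length >= 4).
#' @param table The codon table used for ranking alternatives.
#' @return The recoded `dna_insert`.
#' @export
avoid_motifs <- function(insert, forbidden,
                         table = default_codon_table()) {
  stopifnot(inherits(insert, "dna_insert"))
  forbidden <- toupper(forbidden)
  if (any(nchar(forbidden) < 4L))
    stop("forbidden motifs must be at least 4 nt long", call. = FALSE)
  core <- insert_core(insert)
  chars <- str_chars(insert$protein)
  hopeless <- character(0L)  # "motif@codon-range" tried and unresolvable
  for (pass in seq_len(10L)) {
    changed <- FALSE
    for (motif in forbidden) {
      repeat {
        hits <- gregexpr(motif, core, fixed = TRUE)[[1L]]
        hits <- hits[hits > 0L]
        if (!length(hits)) break
        hits <- hits[!(paste0(motif, "@", (hits - 1L) %/% 3L + 1L) %in%
                         hopeless)]
        if (!length(hits)) break
        h <- hits[1L]
        tag <- paste0(motif, "@", (h - 1L) %/% 3L + 1L)
        first_codon <- (h - 1L) %/% 3L + 1L
        last_codon <- (h + nchar(motif) - 2L) %/% 3L + 1L
        cands <- list()
        for (ci in first_codon:last_codon) {
          aa <- chars[ci]
          fr <- sort(table$frequencies[[aa]], decreasing = TRUE)
          cur <- substr(core, (ci - 1L) * 3L + 1L, ci * 3L)
          for (alt in setdiff(names(fr), cur))
            cands[[length(cands) + 1L]] <-
              list(ci = ci, alt = alt, freq = fr[[alt]])
        }
        if (length(cands))
          cands <- cands[order(-vapply(cands, `[[`, numeric(1L), "freq"))]
        fixed <- FALSE
        before <- count_motifs(core, forbidden)
        for (cand in cands) {
          trial <- core
          substr(trial, (cand$ci - 1L) * 3L + 1L, cand$ci * 3L) <- cand$alt
          if (count_motifs(trial, forbidden) < before) {
            core <- trial
            fixed <- TRUE
            changed <- TRUE
            break
          }
        }
        if (!fixed) hopeless <- c(hopeless, tag)
      }
    }
    if (!changed) break
  }
  insert <- set_insert_core(insert, core)
  leftover <- do.call(rbind, lapply(forbidden, function(m) {
    hits <- gregexpr(m, insert$sequence, fixed = TRUE)[[1L]]
    hits <- hits[hits > 0L]
    if (!length(hits)) return(NULL)
    data.frame(motif = m, position = hits, stringsAsFactors = FALSE)
  }))
  insert$unresolved_motifs <- leftover
  if (!is.null(leftover) && nrow(leftover))
    message(sprintf("avoid_motifs: %d motif occurrence(s) could not be removed",
                    nrow(leftover)))
  stopifnot(identical(translate_dna(insert_core(insert)), insert$protein))
  insert
}

#' Add cloning flanks to a DNA insert
#'
#' Optionally prepends an ATG start codon (only when the protein does not
#' already begin with methionine) and appends a stop codon. Feature
#' coordinates shift accordingly.
#'
#' @param insert A `dna_insert`.
#' @param add_start Request a start codon.
#' @param add_stop Request a stop codon.
#' @param stop_codon Stop codon to use (default `"TAA"`).
#' @return The flanked `dna_insert`.
#' @export
add_flanks <- function(insert, add_start = FALSE, add_stop = FALSE,
                       stop_codon = "TAA") {
  stopifnot(inherits(insert, "dna_insert"))
  if (add_start && substr(insert$protein, 1L, 1L) != "M") {
    insert$sequence <- paste0("ATG", insert$sequence)
    insert$core_start <- insert$core_start + 3L
    if (!is.null(insert$features)) {
      insert$features$start <- insert$features$start + 3L
      insert$features$end <- insert$features$end + 3L
    }
  }
  if (add_stop) {
    stopifnot(GENETIC_CODE_STD[stop_codon] == "*")
    insert$sequence <- paste0(insert$sequence, stop_codon)
  }
  insert
}

#' @export
print.dna_insert <- function(x, ...) {
  cat(sprintf("DNA insert: %d nt encoding %d aa (codon table: %s)\n",
              nchar(x$sequence), nchar(x$protein), x$codon_table_name))
  if (!is.null(x$unresolved_motifs) && nrow(x$unresolved_motifs))
    cat(sprintf("  %d unresolved forbidden motif occurrence(s)\n",
                nrow(x$unresolved_motifs)))
  invisible(x)
}
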