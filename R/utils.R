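# Internal helpers shared across modules.

#' The twenty canonical amino-acid one-letter codes
#'
#' @format Character vector of length 20, alphabetical.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Standard genetic code, codon -> one-letter amino acid ("*" = stop).
GENETIC_CODE_STD <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

# Human ubiquitin monomer (76 aa) with the C-terminal glycine replaced by
# valine: the "uncleavable" degron fused N-terminally to the polyepitope.
UBIQUITIN_WT <-
  "MQIFVKTLTGKTITLEVEPSDTIENVKAKIQDKEGIPPDQQRLIFAGKQLEDGRTLSDYNIQKESTLHLVLRLRGG"

#' N-terminal degron and C-terminal tag sequences
#'
#' `ubiquitin_mut()` returns the 76-residue ubiquitin monomer carrying the
#' G76V substitution that renders the fusion resistant to deubiquitinases,
#' so the whole polyepitope is routed to the proteasome. `ha_tag()` returns
#' the canonical 9-mer influenza hemagglutinin epitope tag used for
#' antibody-based detection of the expressed protein.
#'
#' @return A single amino-acid string.
#' @export
ubiquitin_mut <- function() {
  paste0(substr(UBIQUITIN_WT, 1L, 75L), "V")
}

#' @rdname ubiquitin_mut
#' @export
ha_tag <- function() "YPYDVPDYA"

`%||%` <- function(a, b) if (is.null(a)) b else a

str_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

# Deterministic, platform-independent hash of strings onto (0, 1].
# Modular arithmetic stays below 2^53 so results are exact doubles.
hash01 <- function(...) {
  s <- paste(..., sep = "\r")
  m <- 2147483647
  h <- 0
  for (cp in utf8ToInt(s)) h <- (h * 31 + cp) %% m
  h <- (h * 48271 + 11) %% m
  h <- (h * 16807 + 12345) %% m
  (h + 1) / (m + 1)
}

assert_aa_string <- function(x, what = "sequence", allow_x = FALSE) {
  chars <- str_chars(x)
  ok <- chars %in% c(AA_ALPHABET, if (allow_x) "X")
  if (!all(ok)) {
    stop(sprintf("%s contains non-amino-acid character(s): %s",
                 what, paste(unique(chars[!ok]), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}
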