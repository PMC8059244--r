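# External representations: FASTA proteomes, variant/expression TSVs,
# codon-usage and PWM JSON, report TSVs, and construct FASTA/GenBank output.

#' Read a protein FASTA file
#'
#' Sequences are uppercased and whitespace-stripped; record order is
#' preserved. IDs are the first whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file.
#' @param allow_x Allow the ambiguity letter `X` in sequences.
#' @return Named character vector of sequences (names are record IDs).
#' @export
read_fasta <- function(path, allow_x = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  headers <- grep("^>", lines)
  if (length(headers) == 0L) stop("not a FASTA file (no '>' header): ", path,
                                  call. = FALSE)
  if (any(nzchar(trimws(lines[seq_len(headers[1L] - 1L)]))))
    stop("sequence data before first FASTA header in ", path, call. = FALSE)
  ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[headers])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA ID(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  starts <- headers + 1L
  ends <- c(headers[-1L] - 1L, length(lines))
  alphabet <- c(AA_ALPHABET, if (allow_x) "X")
  seqs <- character(length(ids))
  for (i in seq_along(ids)) {
    if (starts[i] > ends[i]) {
      stop("empty sequence for FASTA record '", ids[i], "'", call. = FALSE)
    }
    body_idx <- starts[i]:ends[i]
    body <- toupper(gsub("\\s+", "", lines[body_idx]))
    for (j in seq_along(body)) {
      bad <- setdiff(unique(str_chars(body[j])), alphabet)
      if (length(bad)) {
        stop(sprintf(
          "invalid character(s) %s in record '%s' (line %d)",
          paste(bad, collapse = ", "), ids[i], body_idx[j]), call. = FALSE)
      }
    }
    seqs[i] <- paste(body, collapse = "")
    if (!nzchar(seqs[i]))
      stop("empty sequence for FASTA record '", ids[i], "'", call. = FALSE)
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(length(seqs) > 0L, !is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read an annotated somatic missense variant table
#'
#' Expects a tab-separated file with header columns `gene`, `protein_id`,
#' `position` (1-based protein coordinate), `ref_aa`, `alt_aa`, `dna_vaf`,
#' `rna_vaf`. Variant-allele fractions may be given as fractions (values
#' \eqn{\le} 1) or percentages (values > 1, divided by 100); the ambiguous
#' value 1.0 is treated as a fraction. A message notes any percent-dialect
#' conversion.
#'
#' @param path Path to the TSV file.
#' @return `data.frame` with typed columns, one row per variant.
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  need <- c("gene", "protein_id", "position", "ref_aa", "alt_aa",
            "dna_vaf", "rna_vaf")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("variant table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df <- df[need]
  parse_num <- function(x, col) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & nzchar(trimws(x)))
    bad <- c(bad, which(!nzchar(trimws(x))))
    if (length(bad))
      stop(sprintf("unparsable value in column '%s' at row %d", col,
                   min(bad)), call. = FALSE)
    v
  }
  df$position <- parse_num(df$position, "position")
  if (any(df$position < 1 | df$position != floor(df$position)))
    stop("'position' must be a 1-based integer coordinate", call. = FALSE)
  df$position <- as.integer(df$position)
  for (col in c("ref_aa", "alt_aa")) {
    bad <- which(!(df[[col]] %in% AA_ALPHABET))
    if (length(bad))
      stop(sprintf("invalid amino acid in column '%s' at row %d", col,
                   bad[1L]), call. = FALSE)
  }
  same <- which(df$ref_aa == df$alt_aa)
  if (length(same))
    stop("ref_aa equals alt_aa at row ", same[1L],
         " (not a missense change)", call. = FALSE)
  converted <- FALSE
  for (col in c("dna_vaf", "rna_vaf")) {
    v <- parse_num(df[[col]], col)
    pct <- v > 1
    if (any(pct)) {
      v[pct] <- v[pct] / 100
      converted <- TRUE
    }
    bad <- which(v < 0 | v > 1)
    if (length(bad))
      stop(sprintf("VAF out of [0,1] in column '%s' at row %d after dialect conversion",
                   col, bad[1L]), call. = FALSE)
    df[[col]] <- v
  }
  if (converted)
    message("read_variants: VAF values > 1 interpreted as percentages and divided by 100")
  df
}

#' Read a gene-expression table
#'
#' Tab-separated file with header columns `gene` and `fpkm`.
#'
#' @param path Path to the TSV file.
#' @return `data.frame` with columns `gene` (character) and `fpkm` (numeric).
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  miss <- setdiff(c("gene", "fpkm"), names(df))
  if (length(miss))
    stop("expression table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  fpkm <- suppressWarnings(as.numeric(df$fpkm))
  bad <- which(is.na(fpkm) | fpkm < 0)
  if (length(bad))
    stop("invalid (negative or non-numeric) FPKM at row ", bad[1L],
         call. = FALSE)
  data.frame(gene = as.character(df$gene), fpkm = fpkm,
             stringsAsFactors = FALSE)
}

#' Read a codon-usage table from JSON
#'
#' Layout: `{"name": ..., "frequencies": {"A": {"GCT": 0.27, ...}, ...}}`
#' with an entry for every canonical amino acid plus the stop symbol `*`.
#' Per-residue frequencies off unity by at most 1e-3 are renormalized;
#' larger deviations are an error.
#'
#' @param path Path to the JSON file.
#' @return A `codon_table` object.
#' @export
read_codon_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw$frequencies))
    stop("codon table JSON lacks a 'frequencies' field", call. = FALSE)
  codon_table(name = raw$name %||% basename(path),
              frequencies = lapply(raw$frequencies, unlist))
}

#' Construct a codon table
#'
#' @param name Table name (provenance only).
#' @param frequencies Named list: amino-acid letter (plus `"*"` for stop) to
#'   named numeric vector of codon relative frequencies.
#' @return A `codon_table` object.
#' @export
codon_table <- function(name, frequencies) {
  need <- c(AA_ALPHABET, "*")
  miss <- setdiff(need, names(frequencies))
  if (length(miss))
    stop("codon table missing amino acid(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  frequencies <- frequencies[need]
  for (aa in need) {
    fr <- frequencies[[aa]]
    if (is.null(names(fr)) || any(!nzchar(names(fr))))
      stop("codons for '", aa, "' must be named", call. = FALSE)
    bad <- names(fr)[!grepl("^[ACGT]{3}$", names(fr))]
    if (length(bad))
      stop("invalid codon(s) for '", aa, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    wrong <- names(fr)[GENETIC_CODE_STD[names(fr)] != aa]
    if (length(wrong))
      stop("codon(s) ", paste(wrong, collapse = ", "),
           " do not encode '", aa, "' under the standard code", call. = FALSE)
    s <- sum(fr)
    if (abs(s - 1) > 1e-3)
      stop(sprintf("codon frequencies for '%s' sum to %.4f (off by > 1e-3)",
                   aa, s), call. = FALSE)
    frequencies[[aa]] <- fr / s
  }
  structure(list(name = name, frequencies = frequencies),
            class = "codon_table")
}

#' Bundled human codon-usage table
#'
#' Relative synonymous codon frequencies typical of highly expressed human
#' genes, for "humanized" reverse translation of vaccine inserts.
#'
#' @return A `codon_table` object.
#' @export
default_codon_table <- function() {
  read_codon_table(system.file("extdata", "codon_usage_human.json",
                               package = "polyvax", mustWork = TRUE))
}

#' Read / write a set of position-weight-matrix binding models
#'
#' The JSON layout is an array of objects `{allele, length, matrix,
#' score_min, score_max}` where `matrix` maps each canonical residue to a
#' vector of `length` per-position scores.
#'
#' @param path JSON file path.
#' @return `read_pwm_set`: list of `pwm_model` objects.
#' @export
read_pwm_set <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(raw)) raw <- split(raw, seq_len(nrow(raw)))
  lapply(seq_along(raw), function(i) {
    m <- raw[[i]]
    mat <- m$matrix
    if (is.data.frame(mat) || is.list(mat)) {
      mat <- do.call(rbind, lapply(as.list(mat), unlist))
    }
    if (is.null(rownames(mat)))
      stop("PWM entry ", i, ": matrix rows must be named by residue",
           call. = FALSE)
    pwm_model(allele = m$allele, length = as.integer(m$length),
              matrix = mat[AA_ALPHABET, , drop = FALSE],
              score_min = m$score_min, score_max = m$score_max)
  })
}

#' @rdname read_pwm_set
#' @param models List of `pwm_model` objects to serialize.
#' @export
write_pwm_set <- function(models, path) {
  payload <- lapply(models, function(m) {
    list(allele = m$allele, length = m$length,
         matrix = stats::setNames(
           lapply(seq_len(nrow(m$matrix)), function(i) unname(m$matrix[i, ])),
           rownames(m$matrix)),
         score_min = m$score_min, score_max = m$score_max)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write the candidate report TSV
#'
#' One row per evaluated candidate carrying all intermediate values,
#' per-criterion pass/fail flags and (where assigned) the final rank. An
#' empty candidate set yields a header-only file.
#'
#' @param candidates Candidate `data.frame` (see [evaluate_candidates()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(candidates, path) {
  utils::write.table(candidates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an assembled construct as FASTA or annotated GenBank
#'
#' FASTA output holds the construct protein (and, when `dna` is supplied,
#' the DNA insert as a second record) and round-trips through
#' [read_fasta()]. GenBank output annotates every segment (degron, each
#' epitope with its source variant, each spacer, tag) as a `misc_feature`
#' with 1-based inclusive coordinates tiling the sequence.
#'
#' @param layout A `construct_layout` from [optimize_order()] /
#'   [assemble_construct()].
#' @param path Output path.
#' @param format `"fasta"` or `"genbank"`.
#' @param dna Optional `dna_insert` (from [reverse_translate()]); GenBank
#'   coordinates are then nucleotide-level.
#' @param name Record name.
#' @return `path`, invisibly.
#' @export
write_construct <- function(layout, path, format = c("fasta", "genbank"),
                            dna = NULL, name = "polyepitope") {
  format <- match.arg(format)
  if (format == "fasta") {
    seqs <- c(stats::setNames(layout$protein, paste0(name, "_protein")))
    if (!is.null(dna))
      seqs <- c(seqs, stats::setNames(dna$sequence, paste0(name, "_insert")))
    return(write_fasta(seqs, path))
  }
  if (is.null(dna)) {
    write_genbank(path, name, layout$protein, layout$features,
                  moltype = "PROTEIN", unit = "aa")
  } else {
    write_genbank(path, name, dna$sequence, dna$features,
                  moltype = "DNA", unit = "bp")
  }
  invisible(path)
}

# Minimal deterministic GenBank flat-file writer (fixed date so reruns are
# byte-identical). `features`: data.frame(name, type, start, end).
write_genbank <- function(path, name, sequence, features,
                          moltype = "DNA", unit = "bp") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %-16s %11d %s    %-7s linear   SYN 01-JAN-2000",
                     substr(name, 1L, 16L), nchar(sequence), unit, moltype),
             con)
  writeLines(c("DEFINITION  Polyepitope neoantigen vaccine construct.",
               "ACCESSION   .",
               "FEATURES             Location/Qualifiers"), con)
  writeLines(sprintf("     source          1..%d", nchar(sequence)), con)
  if (!is.null(features) && nrow(features)) {
    for (i in seq_len(nrow(features))) {
      writeLines(sprintf("     misc_feature    %d..%d",
                         features$start[i], features$end[i]), con)
      writeLines(sprintf("                     /label=\"%s\"",
                         features$name[i]), con)
      if (!is.null(features$type))
        writeLines(sprintf("                     /note=\"%s\"",
                           features$type[i]), con)
    }
  }
  writeLines("ORIGIN", con)
  s <- tolower(sequence)
  starts <- seq(1L, nchar(s), by = 60L)
  for (st in starts) {
    chunk <- substr(s, st, min(st + 59L, nchar(s)))
    sub <- seq(1L, nchar(chunk), by = 10L)
    blocks <- substring(chunk, sub, pmin(sub + 9L, nchar(chunk)))
    writeLines(sprintf("%9d %s", st, paste(blocks, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' @export
print.codon_table <- function(x, ...) {
  cat("Codon-usage table:", x$name, "\n")
  n <- vapply(x$frequencies, length, integer(1L))
  cat(sprintf("  %d amino acids + stop, %d codons total\n",
              length(n) - 1L, sum(n)))
  invisible(x)
}
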