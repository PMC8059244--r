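# Stage orchestration: prioritize -> design -> reverse-translate, with
# file I/O, a resolved-configuration echo and a provenance log. These
# functions are the package's primary interface; inst/cli/polyvax.R is a
# thin command-line wrapper over them.

resolve_proteome <- function(x) if (is.character(x) && length(x) == 1L &&
                                    file.exists(x)) read_fasta(x) else x
resolve_table <- function(x, reader) if (is.character(x) && length(x) == 1L)
  reader(x) else x

#' Prioritize neoantigens from annotated inputs
#'
#' Reads (or accepts in-memory) the proteome, variant table, expression
#' table and PWM set, builds flanked mutant contexts, scores all
#' substitution-spanning sub-peptides on every allele, applies the filter
#' cascade and ranks the survivors by WT/MT fold change.
#'
#' @param proteome FASTA path or named character vector.
#' @param variants TSV path or variant `data.frame`.
#' @param expression TSV path or expression `data.frame`.
#' @param pwm PWM-set JSON path or list of `pwm_model`s; ignored when
#'   `predictors` is given.
#' @param predictors Optional list of `binding_predictor`s (overrides
#'   `pwm`).
#' @param alleles Alleles to evaluate (default: all alleles in the
#'   predictor models).
#' @param flank Context flank per side (default 12).
#' @param lengths Sub-peptide lengths (default 8--11).
#' @param thresholds See [filter_thresholds()].
#' @param max_n Maximum neoantigens to select.
#' @param report_path Optional TSV path for the full candidate report.
#' @return A `prioritization_result`: `candidates` (all, with flags and a
#'   `rank` column, `NA` when unselected) and `selected`.
#' @export
run_prioritize <- function(proteome, variants, expression = NULL,
                           pwm = NULL, predictors = NULL, alleles = NULL,
                           flank = 12L, lengths = c(8L, 9L, 10L, 11L),
                           thresholds = filter_thresholds(), max_n = Inf,
                           report_path = NULL) {
  proteome <- resolve_proteome(proteome)
  variants <- resolve_table(variants, read_variants)
  expression <- if (!is.null(expression))
    resolve_table(expression, read_expression)
  if (is.null(predictors)) {
    if (is.null(pwm)) stop("supply either 'pwm' or 'predictors'",
                           call. = FALSE)
    models <- resolve_table(pwm, read_pwm_set)
    predictors <- list(pwm_predictor(models, name = "pwm-suite"))
    if (is.null(alleles))
      alleles <- unique(vapply(models, `[[`, character(1L), "allele"))
  }
  if (is.null(alleles))
    stop("'alleles' must be given when predictors carry no allele list",
         call. = FALSE)
  contexts <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    prot <- proteome[v$protein_id]
    if (is.na(prot))
      stop(sprintf("protein '%s' (variant row %d) not in proteome",
                   v$protein_id, i), call. = FALSE)
    extract_context(unname(prot), v, flank = flank)
  })
  cands <- evaluate_candidates(contexts, alleles, predictors,
                               lengths = lengths, expression = expression)
  cands <- apply_filters(cands, thresholds)
  selected <- rank_and_select(cands, max_n = max_n)
  sel_key <- apply(selected[c("gene", "protein_id", "position", "ref_aa",
                              "alt_aa", "allele")], 1L, paste,
                   collapse = "|")
  all_key <- apply(cands[c("gene", "protein_id", "position", "ref_aa",
                           "alt_aa", "allele")], 1L, paste, collapse = "|")
  cands$rank <- selected$rank[match(all_key, sel_key)]
  if (!is.null(report_path)) write_report(cands, report_path)
  structure(list(candidates = cands, selected = selected,
                 thresholds = thresholds, alleles = alleles,
                 predictors = predictors, proteome = proteome),
            class = "prioritization_result")
}

#' @export
print.prioritization_result <- function(x, ...) {
  cat(sprintf("Prioritization: %d candidate pair(s), %d passing, %d selected\n",
              nrow(x$candidates), sum(x$candidates$pass),
              nrow(x$selected)))
  print(x$selected)
  invisible(x)
}

#' Design the polyepitope construct for a selected neoantigen set
#'
#' Extracts 20--25-mer long epitopes with native flanks around each
#' selected variant, finds the junction-cost-minimizing order and spacer
#' placement, assembles the ubiquitin(G76V)-fused construct and
#' reverse-translates it into a codon-optimized DNA insert.
#'
#' @param prioritization A `prioritization_result`, or a `data.frame` of
#'   selected candidates (then `proteome`, `predictors`, `alleles` must be
#'   given).
#' @param proteome,predictors,alleles Overrides / required when
#'   `prioritization` is a plain table.
#' @param config See [design_config()].
#' @param codon_table A `codon_table` for reverse translation.
#' @param forbidden_motifs Optional DNA motifs to recode away (e.g.
#'   restriction sites used for cloning).
#' @param add_start,add_stop Cloning flank options (see [add_flanks()]).
#' @param out_prefix Optional path prefix; writes `<prefix>_construct.fasta`,
#'   `<prefix>_construct.gb` and `<prefix>_junctions.tsv`.
#' @return A `design_result`: `layout` (`construct_layout`), `dna`
#'   (`dna_insert`), `segments`.
#' @export
run_design <- function(prioritization, proteome = NULL, predictors = NULL,
                       alleles = NULL, config = design_config(),
                       codon_table = default_codon_table(),
                       forbidden_motifs = NULL,
                       add_start = FALSE, add_stop = FALSE,
                       out_prefix = NULL) {
  if (inherits(prioritization, "prioritization_result")) {
    selected <- prioritization$selected
    proteome <- proteome %||% prioritization$proteome
    predictors <- predictors %||% prioritization$predictors
    alleles <- alleles %||% prioritization$alleles
  } else {
    selected <- prioritization
  }
  if (!nrow(selected)) stop("empty epitope list", call. = FALSE)
  stopifnot(!is.null(proteome), !is.null(predictors), !is.null(alleles))
  proteome <- resolve_proteome(proteome)
  segments <- lapply(seq_len(nrow(selected)), function(i) {
    v <- selected[i, ]
    make_long_epitope(unname(proteome[v$protein_id]), v,
                      target_len = config$epitope_length)
  })
  layout <- optimize_order(segments, alleles, predictors, config)
  dna <- reverse_translate(layout, table = codon_table)
  if (!is.null(forbidden_motifs))
    dna <- avoid_motifs(dna, forbidden_motifs, table = codon_table)
  dna <- add_flanks(dna, add_start = add_start, add_stop = add_stop)
  if (!is.null(out_prefix)) {
    write_construct(layout, paste0(out_prefix, "_construct.fasta"),
                    format = "fasta", dna = dna)
    write_construct(layout, paste0(out_prefix, "_construct.gb"),
                    format = "genbank", dna = dna)
    utils::write.table(junction_ledger_table(layout),
                       paste0(out_prefix, "_junctions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  structure(list(layout = layout, dna = dna, segments = segments),
            class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  print(x$layout)
  print(x$dna)
  invisible(x)
}

#' Run the full pipeline with a provenance log
#'
#' Prioritization followed by construct design; when `out_dir` is given,
#' writes the candidate report, construct FASTA/GenBank, junction ledger
#' and a JSON provenance log (resolved configuration, input file MD5s,
#' package version) sufficient to reproduce the run.
#'
#' @inheritParams run_prioritize
#' @inheritParams run_design
#' @param out_dir Output directory (created if needed).
#' @return List with `prioritization` and `design`.
#' @export
run_full <- function(proteome, variants, expression, pwm,
                     alleles = NULL, flank = 12L,
                     lengths = c(8L, 9L, 10L, 11L),
                     thresholds = filter_thresholds(), max_n = Inf,
                     config = design_config(),
                     codon_table = default_codon_table(),
                     forbidden_motifs = NULL,
                     add_start = FALSE, add_stop = FALSE,
                     out_dir = NULL) {
  report_path <- NULL
  out_prefix <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    report_path <- file.path(out_dir, "candidates.tsv")
    out_prefix <- file.path(out_dir, "polyepitope")
  }
  pri <- run_prioritize(proteome, variants, expression, pwm,
                        alleles = alleles, flank = flank,
                        lengths = lengths, thresholds = thresholds,
                        max_n = max_n, report_path = report_path)
  des <- run_design(pri, config = config, codon_table = codon_table,
                    forbidden_motifs = forbidden_motifs,
                    add_start = add_start, add_stop = add_stop,
                    out_prefix = out_prefix)
  if (!is.null(out_dir)) {
    input_files <- Filter(function(p) is.character(p) && length(p) == 1L &&
                            file.exists(p),
                          list(proteome = proteome, variants = variants,
                               expression = expression, pwm = pwm))
    prov <- list(
      package = "polyvax",
      version = as.character(utils::packageVersion("polyvax")),
      parameters = list(flank = flank, lengths = lengths,
                        thresholds = thresholds,
                        max_n = if (is.finite(max_n)) max_n else "unlimited",
                        design = config),
      inputs = lapply(input_files, function(p)
        list(path = p, md5 = unname(tools::md5sum(p)))),
      n_selected = nrow(pri$selected),
      total_junction_cost = des$layout$total_cost)
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(prioritization = pri, design = des)
}
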