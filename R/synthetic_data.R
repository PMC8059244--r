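# Seeded synthetic scenarios with planted ground truth: engineered PWM
# binders, stratified VAF/FPKM draws, and single-violation failing variants
# so every filter flag is individually testable. The generator verifies its
# own plant by running the real evaluation/filter path and redrawing any
# protein whose random sequence creates accidental PWM cross-talk, so the
# planted labels hold by construction.

#' Specify a synthetic scenario
#'
#' @param seed Integer seed; the whole bundle is a pure function of it.
#' @param n_variants Total somatic missense variants.
#' @param n_planted_pass Variants engineered to pass every filter; the
#'   remainder each violate exactly one named criterion (cycling through
#'   binding, DNA VAF, RNA VAF, expression, fold change).
#' @param alleles MHC class I allele labels (defaults mimic a human
#'   HLA-A*02:01 and a murine H-2Db restriction element).
#' @param margin Safety factor: planted passing mutant peptides score below
#'   `500 / margin` nM and their wild-type counterparts at least
#'   `2 * margin` times higher, so every strict inequality holds with room.
#' @param protein_length_range Min/max protein length.
#' @param n_decoy_proteins Extra proteins carrying no variant.
#' @return A `scenario_spec`.
#' @export
scenario_spec <- function(seed = 17L, n_variants = 10L, n_planted_pass = 5L,
                          alleles = c("HLA-A*02:01", "H-2-Db"),
                          margin = 10,
                          protein_length_range = c(60L, 120L),
                          n_decoy_proteins = 3L) {
  stopifnot(n_planted_pass <= n_variants, n_variants >= 1L, margin > 1,
            length(protein_length_range) == 2L,
            protein_length_range[1L] >= 50L)
  structure(list(seed = as.integer(seed), n_variants = as.integer(n_variants),
                 n_planted_pass = as.integer(n_planted_pass),
                 alleles = alleles, margin = margin,
                 protein_length_range = as.integer(protein_length_range),
                 n_decoy_proteins = as.integer(n_decoy_proteins)),
            class = "scenario_spec")
}

x_of_ic50 <- function(ic50) 1 - log(ic50) / log(IC50_CEILING)

# Per-stratum engineered IC50 targets (nM) for the planted 9-mer.
plant_targets <- function(type, margin) {
  switch(type,
         pass = ,
         fail_dna_vaf = ,
         fail_rna_vaf = ,
         fail_fpkm = list(mt = 1, wt = 5000),
         fail_ic50 = list(mt = 500 * margin, wt = 3 * 500 * margin),
         fail_fold_change = list(mt = 100, wt = 150),
         stop("unknown plant type: ", type))
}

FAIL_TYPES <- c("fail_ic50", "fail_dna_vaf", "fail_rna_vaf", "fail_fpkm",
                "fail_fold_change")

#' Generate a complete synthetic scenario bundle
#'
#' Writes (through the package's own readers/writers, so the files always
#' re-validate) a proteome FASTA, variant and expression TSVs, an
#' engineered PWM set JSON and a ground-truth JSON into `outdir`.
#' Re-running with the same spec reproduces byte-identical files.
#'
#' @param spec A `scenario_spec`.
#' @param outdir Output directory (created if needed); `NULL` keeps the
#'   bundle in memory only.
#' @return A `scenario_bundle`: in-memory objects (`proteome`, `variants`,
#'   `expression`, `pwm_models`, `predictors`, `truth`, `spec`) plus
#'   `paths` when written.
#' @export
generate_scenario <- function(spec, outdir = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  bundle <- with_seed(spec$seed, build_scenario(spec))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      proteome = file.path(outdir, "proteome.fasta"),
      variants = file.path(outdir, "variants.tsv"),
      expression = file.path(outdir, "expression.tsv"),
      pwm_set = file.path(outdir, "pwm_set.json"),
      truth = file.path(outdir, "truth.json"))
    write_fasta(bundle$proteome, paths$proteome)
    utils::write.table(bundle$variants, paths$variants, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(bundle$expression, paths$expression, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_pwm_set(bundle$pwm_models, paths$pwm_set)
    jsonlite::write_json(bundle$truth, paths$truth, auto_unbox = TRUE,
                         digits = NA)
    bundle$paths <- paths
  }
  bundle
}

random_protein <- function(len) paste(sample(AA_ALPHABET, len, replace = TRUE),
                                      collapse = "")

build_scenario <- function(spec) {
  n <- spec$n_variants
  types <- c(rep("pass", spec$n_planted_pass),
             rep_len(FAIL_TYPES, n - spec$n_planted_pass))
  genes <- sprintf("Gene%03d", seq_len(n))
  prot_ids <- paste0("P_", genes)
  allele_of <- rep_len(spec$alleles, n)
  lr <- spec$protein_length_range

  # Each variant's context window is drawn from a 4-residue sub-alphabet,
  # disjoint across variants sharing an allele (cycling when an allele
  # carries more than five variants), so engineered PWM cells never
  # overlap between plants and cross-talk is structurally impossible.
  idx_in_allele <- stats::ave(seq_len(n), allele_of, FUN = seq_along)
  sub_alpha <- lapply(idx_in_allele, function(k) {
    set_id <- (k - 1L) %% 5L
    AA_ALPHABET[set_id * 4L + 1:4]
  })

  draw_variant <- function(i) {
    len <- sample(lr[1L]:lr[2L], 1L)
    chars <- sample(AA_ALPHABET, len, replace = TRUE)
    pos <- sample(25L:(len - 24L), 1L)
    win <- (pos - 12L):(pos + 12L)
    chars[win] <- sample(sub_alpha[[i]], length(win), replace = TRUE)
    ref <- chars[pos]
    alt <- sample(setdiff(sub_alpha[[i]], ref), 1L)
    list(seq = paste(chars, collapse = ""), pos = pos, ref = ref, alt = alt)
  }
  prot <- lapply(seq_len(n), draw_variant)

  dna_vaf <- ifelse(types == "fail_dna_vaf", stats::runif(n, 0.05, 0.25),
                    stats::runif(n, 0.35, 0.60))
  rna_vaf <- ifelse(types == "fail_rna_vaf", stats::runif(n, 0.05, 0.25),
                    stats::runif(n, 0.35, 0.60))
  fpkm <- ifelse(types == "fail_fpkm", stats::runif(n, 0.05, 0.90),
                 stats::runif(n, 2, 50))

  assemble_all <- function() {
    variants <- data.frame(
      gene = genes, protein_id = prot_ids,
      position = vapply(prot, `[[`, integer(1L), "pos"),
      ref_aa = vapply(prot, `[[`, character(1L), "ref"),
      alt_aa = vapply(prot, `[[`, character(1L), "alt"),
      dna_vaf = round(dna_vaf, 4L), rna_vaf = round(rna_vaf, 4L),
      stringsAsFactors = FALSE)
    proteome <- stats::setNames(vapply(prot, `[[`, character(1L), "seq"),
                                prot_ids)
    models <- engineer_pwms(spec, variants, proteome, allele_of, types)
    list(variants = variants, proteome = proteome, models = models)
  }

  planted_peptide <- function(i) {
    mt <- apply_variant(prot[[i]]$seq, list(position = prot[[i]]$pos,
                                            ref_aa = prot[[i]]$ref,
                                            alt_aa = prot[[i]]$alt))
    substr(mt, prot[[i]]$pos - 4L, prot[[i]]$pos + 4L)
  }

  done <- FALSE
  for (attempt in seq_len(30L)) {
    parts <- assemble_all()
    if (is.character(parts$models)) {  # cell conflict: redraw named variants
      for (i in as.integer(parts$models)) prot[[i]] <- draw_variant(i)
      next
    }
    predictors <- list(pwm_predictor(parts$models, name = "pwm-suite"))
    bad <- verify_plant(spec, parts, predictors, allele_of, types,
                        fpkm, planted_peptide)
    if (!length(bad)) {
      done <- TRUE
      break
    }
    for (i in bad) prot[[i]] <- draw_variant(i)
  }
  if (!done)
    stop("could not realize scenario free of PWM cross-talk; ",
         "try another seed or fewer variants", call. = FALSE)

  decoy_genes <- if (spec$n_decoy_proteins > 0L)
    sprintf("Decoy%02d", seq_len(spec$n_decoy_proteins)) else character(0L)
  decoys <- stats::setNames(
    vapply(seq_along(decoy_genes), function(i)
      random_protein(sample(lr[1L]:lr[2L], 1L)), character(1L)),
    paste0("P_", decoy_genes))
  expression <- data.frame(
    gene = c(genes, decoy_genes),
    fpkm = round(c(fpkm, stats::runif(length(decoy_genes), 0.1, 20)), 3L),
    stringsAsFactors = FALSE)

  targets <- lapply(types, plant_targets, margin = spec$margin)
  truth <- data.frame(
    gene = genes, protein_id = prot_ids,
    position = parts$variants$position,
    ref_aa = parts$variants$ref_aa, alt_aa = parts$variants$alt_aa,
    type = types, allele = allele_of,
    planted_mt_peptide = vapply(seq_len(n), planted_peptide, character(1L)),
    mt_ic50_target = vapply(targets, `[[`, numeric(1L), "mt"),
    wt_ic50_target = vapply(targets, `[[`, numeric(1L), "wt"),
    stringsAsFactors = FALSE)

  structure(list(
    spec = spec,
    proteome = c(parts$proteome, decoys),
    variants = parts$variants,
    expression = expression,
    pwm_models = parts$models,
    predictors = predictors,
    truth = truth), class = "scenario_bundle")
}

# Engineer the PWM set: zero matrices for lengths 8-11 per allele, with the
# planted 9-mer's per-position cells carrying the exact raw score for the
# target mutant IC50 and the wild-type residue cell at the substitution
# column adjusted for the wild-type target. Returns a character vector of
# conflicting variant indices when two plants claim a cell differently.
engineer_pwms <- function(spec, variants, proteome, allele_of, types) {
  mats <- list()
  claims <- list()
  for (al in spec$alleles) for (k in 8:11) {
    key <- paste(al, k, sep = "|")
    mats[[key]] <- matrix(0, nrow = 20L, ncol = k,
                          dimnames = list(AA_ALPHABET, NULL))
    claims[[key]] <- matrix(NA_real_, nrow = 20L, ncol = k,
                            dimnames = list(AA_ALPHABET, NULL))
  }
  conflicts <- integer(0L)
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    tg <- plant_targets(types[i], spec$margin)
    mt_prot <- apply_variant(proteome[[v$protein_id]], v)
    pep <- substr(mt_prot, v$position - 4L, v$position + 4L)
    key <- paste(allele_of[i], 9L, sep = "|")
    r_mt <- 9 * x_of_ic50(tg$mt)
    r_wt <- 9 * x_of_ic50(tg$wt)
    cells <- cbind(row = match(str_chars(pep), AA_ALPHABET), col = 1:9)
    vals <- rep(r_mt / 9, 9L)
    # wild-type residue cell at the substitution column (index 5)
    cells <- rbind(cells, c(match(v$ref_aa, AA_ALPHABET), 5L))
    vals <- c(vals, r_wt - 8 * r_mt / 9)
    for (ci in seq_len(nrow(cells))) {
      prev <- claims[[key]][cells[ci, 1L], cells[ci, 2L]]
      if (!is.na(prev) && abs(prev - vals[ci]) > 1e-12) {
        conflicts <- c(conflicts, i)
        break
      }
      claims[[key]][cells[ci, 1L], cells[ci, 2L]] <- vals[ci]
      mats[[key]][cells[ci, 1L], cells[ci, 2L]] <- vals[ci]
    }
  }
  if (length(conflicts)) return(as.character(unique(conflicts)))
  models <- list()
  for (key in names(mats)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1L]]
    k <- as.integer(parts[2L])
    models[[length(models) + 1L]] <-
      pwm_model(allele = parts[1L], length = k, matrix = mats[[key]],
                score_min = 0, score_max = k)
  }
  models
}

# Run the real evaluation/filter path and return indices of variants whose
# realized flags, selected peptide or off-allele behavior deviate from the
# design (accidental cross-talk from the random sequences).
verify_plant <- function(spec, parts, predictors, allele_of, types, fpkm,
                         planted_peptide) {
  n <- nrow(parts$variants)
  contexts <- lapply(seq_len(n), function(i)
    extract_context(parts$proteome[[parts$variants$protein_id[i]]],
                    parts$variants[i, ], flank = 12L))
  expr <- data.frame(gene = parts$variants$gene, fpkm = fpkm,
                     stringsAsFactors = FALSE)
  cands <- suppressWarnings(
    evaluate_candidates(contexts, spec$alleles, predictors,
                        lengths = 8:11, expression = expr))
  cands <- apply_filters(cands)
  bad <- integer(0L)
  flag_cols <- c(fail_ic50 = "flag_binding", fail_dna_vaf = "flag_dna_vaf",
                 fail_rna_vaf = "flag_rna_vaf", fail_fpkm = "flag_expression",
                 fail_fold_change = "flag_fold_change")
  all_flags <- unname(flag_cols)
  for (i in seq_len(n)) {
    g <- parts$variants$gene[i]
    own <- cands[cands$gene == g & cands$allele == allele_of[i], ]
    other <- cands[cands$gene == g & cands$allele != allele_of[i], ]
    ok <- nrow(own) == 1L &&
      own$mt_peptide == planted_peptide(i) &&
      all(!other$pass)
    if (ok) {
      if (types[i] == "pass") {
        ok <- own$pass
      } else {
        fail_col <- flag_cols[[types[i]]]
        ok <- !own[[fail_col]] &&
          all(vapply(setdiff(all_flags, fail_col),
                     function(cn) own[[cn]], logical(1L)))
      }
    }
    if (!ok) bad <- c(bad, i)
  }
  bad
}

#' Generate a segment-ordering instance with known structure
#'
#' `chain_zero_cost` plants a unique epitope order whose every junction
#' (with either spacer option) contains no sub-threshold junctional
#' peptide, while every other ordered adjacency contains at least one
#' planted binder under both spacer options -- so the planted order is the
#' unique zero-cost optimum. `random` emits unstructured instances (mock
#' predictor landscape) for oracle comparison.
#'
#' @param n Number of segments (>= 2).
#' @param seed Integer seed.
#' @param structure `"chain_zero_cost"` or `"random"`.
#' @return List with `segments`, `alleles`, `predictors`, `config`, and
#'   (for planted instances) `truth` (`order`, `total_cost`).
#' @export
generate_ordering_instance <- function(n, seed = 1L,
                                       structure = c("chain_zero_cost",
                                                     "random")) {
  structure_kind <- match.arg(structure)
  stopifnot(n >= 2L)
  allele <- "HLA-A*02:01"
  with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i)
      random_protein(sample(20:25, 1L)), character(1L))
    names(seqs) <- sprintf("Seg%02d", seq_len(n))
    if (structure_kind == "random") {
      cfg <- design_config(junction_lengths = 9L,
                           junction_ic50_threshold = 10000)
      preds <- list(mock_predictor(1000L + seed, name = "mock-a"),
                    mock_predictor(2000L + seed, name = "mock-b"))
      return(list(segments = seqs, alleles = allele, predictors = preds,
                  config = cfg, truth = NULL))
    }
    cfg <- design_config(junction_lengths = 9L)
    order_true <- sample.int(n)
    protected <- character(0L)
    chain <- cbind(order_true[-n], order_true[-1L])
    for (r in seq_len(nrow(chain))) for (sp in cfg$spacers) {
      protected <- c(protected,
                     enumerate_junction_peptides(seqs[chain[r, 1L]], sp,
                                                 seqs[chain[r, 2L]],
                                                 9L)$peptide)
    }
    for (i in seq_len(n)) for (sp in cfg$spacers) {
      protected <- c(
        protected,
        enumerate_junction_peptides(ubiquitin_mut(), sp, seqs[i],
                                    9L)$peptide,
        enumerate_junction_peptides(seqs[i], sp, ha_tag(), 9L)$peptide)
    }
    protected <- unique(protected)
    planted <- character(0L)
    chain_key <- paste(chain[, 1L], chain[, 2L])
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j || paste(i, j) %in% chain_key) next
      for (sp in cfg$spacers) {
        cand <- enumerate_junction_peptides(seqs[i], sp, seqs[j],
                                            9L)$peptide
        cand <- setdiff(cand, protected)
        if (!length(cand))
          stop("could not plant a binder free of chain junctions; ",
               "try another seed", call. = FALSE)
        planted <- c(planted, cand[1L])
      }
    }
    ic50 <- stats::setNames(rep(10, length(planted)),
                            paste(planted, allele, sep = "|"))
    preds <- list(table_predictor(ic50, default_ic50 = IC50_CEILING,
                                  name = "planted"))
    list(segments = seqs, alleles = allele, predictors = preds,
         config = cfg, truth = list(order = order_true, total_cost = 0))
  })
}
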