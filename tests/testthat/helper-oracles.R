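# Independent oracles and small fixture builders used across the suite.

AA <- polyvax::AA_ALPHABET

rand_protein <- function(len, alphabet = AA) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Exhaustive scan: number of k-mers of a length-L window whose index span
# covers 0-based position m.
oracle_subpeptide_count <- function(L, m, k) {
  if (k > L) return(0L)
  count <- 0L
  for (off in 0:(L - k)) {
    if (off <= m && m <= off + k - 1L) count <- count + 1L
  }
  count
}

# Closed form for the same count.
closed_form_count <- function(L, m, k) {
  if (k > L) return(0L)
  max(0L, min(k, m + 1L, L - m, L - k + 1L))
}

# Brute-force junction enumeration: label every concatenation position by
# its source (left / spacer / right) and keep k-mers not wholly from one
# flank.
oracle_junction_peptides <- function(left, spacer, right, k) {
  labels <- c(rep("L", nchar(left)), rep("S", nchar(spacer)),
              rep("R", nchar(right)))
  concat <- paste0(left, spacer, right)
  out <- character(0L)
  if (k > nchar(concat)) return(out)
  for (off in 0:(nchar(concat) - k)) {
    lab <- labels[(off + 1L):(off + k)]
    if (!all(lab == "L") && !all(lab == "R"))
      out <- c(out, substr(concat, off + 1L, off + k))
  }
  out
}

# All permutations of 1..n (lexicographic), for the ordering oracle.
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# Minimum open-path cost over all n! orders, computed directly from a
# pairwise cost matrix and terminal cost vectors.
oracle_min_path_cost <- function(C, ub_cost, tag_cost) {
  n <- nrow(C)
  best <- Inf
  for (p in all_perms(n)) {
    cost <- ub_cost[p[1L]] + tag_cost[p[n]]
    if (n > 1L) cost <- cost + sum(C[cbind(p[-n], p[-1L])])
    best <- min(best, cost)
  }
  best
}

# Pairwise + terminal cost tables computed through the package's scoring
# path (shared by optimizer-vs-oracle comparisons).
cost_tables <- function(segments, alleles, predictors, config) {
  n <- length(segments)
  C <- matrix(Inf, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    costs <- vapply(config$spacers, function(sp) {
      peps <- enumerate_junction_peptides(segments[[i]], sp, segments[[j]],
                                          config$junction_lengths)
      junction_cost(peps, alleles, predictors,
                    config$junction_ic50_threshold)$cost
    }, numeric(1L))
    C[i, j] <- min(costs)
  }
  term <- function(lhs, rhs) {
    min(vapply(config$spacers, function(sp) {
      peps <- enumerate_junction_peptides(lhs, sp, rhs,
                                          config$junction_lengths)
      junction_cost(peps, alleles, predictors,
                    config$junction_ic50_threshold)$cost
    }, numeric(1L)))
  }
  ub <- vapply(seq_len(n), function(i)
    if (config$include_ubmut && config$scan_terminal_junctions)
      term(ubiquitin_mut(), segments[[i]]) else 0, numeric(1L))
  tg <- vapply(seq_len(n), function(i)
    if (config$include_tag && config$scan_terminal_junctions)
      term(segments[[i]], ha_tag()) else 0, numeric(1L))
  list(C = C, ub = ub, tag = tg)
}

# A PWM in which exactly one target peptide reaches the top of the score
# range (IC50 1 nM) and every unrelated peptide scores near the floor.
planted_pwm <- function(peptide, allele) {
  k <- nchar(peptide)
  m <- matrix(0, nrow = 20L, ncol = k, dimnames = list(AA, NULL))
  chars <- strsplit(peptide, "")[[1L]]
  for (i in seq_len(k)) m[chars[i], i] <- 1
  pwm_model(allele = allele, length = k, matrix = m,
            score_min = 0, score_max = k)
}

# Minimal single-variant fixture shared by prioritization tests.
toy_variant <- function(gene = "GeneX", protein_id = "P_X", position = 15L,
                        ref_aa = "A", alt_aa = "V", dna_vaf = 0.5,
                        rna_vaf = 0.5) {
  data.frame(gene = gene, protein_id = protein_id, position = position,
             ref_aa = ref_aa, alt_aa = alt_aa, dna_vaf = dna_vaf,
             rna_vaf = rna_vaf, stringsAsFactors = FALSE)
}
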