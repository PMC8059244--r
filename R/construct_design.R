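# String-of-beads construct design: long-epitope extraction, junctional
# peptide enumeration and scoring, epitope-order optimization, assembly of
# the ubiquitin(G76V)-fused polyepitope protein.

#' Construct-design configuration
#'
#' @param epitope_length Long-epitope target length (20--25 residues,
#'   default 25: the minimal epitope plus generous native flanks).
#' @param spacers Spacer vocabulary tried at each junction; `""` (direct
#'   fusion, preferred on ties) and the classic proteasome-liberation
#'   tripeptide `"AAY"`.
#' @param junction_lengths Peptide lengths scanned across junctions.
#' @param junction_ic50_threshold Median IC50 (nM) below which a junctional
#'   peptide counts as an unwanted binder (default 500, the same
#'   conventional binder cutoff used for prioritization).
#' @param cost_mode `"count"` (number of sub-threshold junctional
#'   peptide-allele pairs) or `"weighted"` (sum of `log(threshold/IC50)`
#'   over sub-threshold pairs).
#' @param include_ubmut Fuse the G76V ubiquitin degron N-terminally.
#' @param include_tag Append the HA tag C-terminally.
#' @param scan_terminal_junctions Also score degron/first-epitope and
#'   last-epitope/tag junctions (the G76V fusion is uncleavable, so these
#'   junctions persist in the expressed protein).
#' @param exhaustive_max Largest segment count solved by exhaustive
#'   permutation search.
#' @param dp_max Largest segment count solved by exact subset dynamic
#'   programming; beyond this, seeded simulated annealing is used.
#' @param sa_steps,sa_restarts,sa_cooling Annealing schedule: geometric
#'   cooling over `sa_steps` steps, `sa_restarts` independent restarts.
#' @param seed Seed for the annealing stage (deterministic stages ignore it).
#' @return Named list of settings.
#' @export
design_config <- function(epitope_length = 25L,
                          spacers = c("", "AAY"),
                          junction_lengths = c(8L, 9L, 10L, 11L),
                          junction_ic50_threshold = 500,
                          cost_mode = c("count", "weighted"),
                          include_ubmut = TRUE,
                          include_tag = TRUE,
                          scan_terminal_junctions = TRUE,
                          exhaustive_max = 7L,
                          dp_max = 12L,
                          sa_steps = 20000L,
                          sa_restarts = 5L,
                          sa_cooling = 0.9995,
                          seed = 17L) {
  list(epitope_length = as.integer(epitope_length), spacers = spacers,
       junction_lengths = as.integer(junction_lengths),
       junction_ic50_threshold = junction_ic50_threshold,
       cost_mode = match.arg(cost_mode),
       include_ubmut = include_ubmut, include_tag = include_tag,
       scan_terminal_junctions = scan_terminal_junctions,
       exhaustive_max = as.integer(exhaustive_max),
       dp_max = as.integer(dp_max), sa_steps = as.integer(sa_steps),
       sa_restarts = as.integer(sa_restarts), sa_cooling = sa_cooling,
       seed = as.integer(seed))
}

#' Extract a long (20--25-mer) epitope segment around a variant
#'
#' The segment is the `target_len`-mer of the mutant protein centered on
#' the substitution (left-biased by one residue for even lengths). When a
#' protein terminus truncates one side, the other side is extended up to
#' availability; a protein shorter than `target_len` yields the whole
#' protein with a message.
#'
#' @param protein Wild-type protein sequence.
#' @param variant Single-row variant record.
#' @param target_len Target segment length in `[20, 25]`.
#' @param id Segment identifier (default: gene plus change).
#' @return An `epitope_segment` with fields `id`, `sequence`, `mut_offset`
#'   (0-based position of the substitution within the segment), `variant`.
#' @export
make_long_epitope <- function(protein, variant, target_len = 25L, id = NULL) {
  target_len <- as.integer(target_len)
  if (target_len < 20L || target_len > 25L)
    stop("target_len must lie in [20, 25]", call. = FALSE)
  mt <- apply_variant(protein, variant)
  L <- nchar(mt)
  p <- as.integer(variant$position)
  if (L < target_len) {
    message(sprintf("make_long_epitope: protein length %d < target %d; using whole protein",
                    L, target_len))
    start <- 1L; end <- L
  } else {
    left <- target_len %/% 2L
    right <- target_len - 1L - left
    start <- p - left
    end <- p + right
    if (start < 1L) { end <- min(L, end + (1L - start)); start <- 1L }
    if (end > L) { start <- max(1L, start - (end - L)); end <- L }
  }
  v <- as.list(variant)
  id <- id %||% sprintf("%s_%s%d%s", v$gene, v$ref_aa, v$position, v$alt_aa)
  structure(list(id = id, sequence = substr(mt, start, end),
                 mut_offset = p - start, variant = v,
                 protein_start = start),
            class = "epitope_segment")
}

#' Enumerate junctional peptides across a junction
#'
#' Over the concatenation `left + spacer + right`, returns every k-mer that
#' is not wholly contained within `left` alone nor within `right` alone --
#' i.e. all novel peptide sequence created by the junction (spacer residues
#' belong to neither side). Deterministic order: length, then offset.
#'
#' @param left,right Flanking segment sequences.
#' @param spacer Spacer peptide (may be `""`).
#' @param lengths Peptide lengths to scan.
#' @return `data.frame` with columns `peptide`, `length`, `offset` (0-based
#'   in the concatenation).
#' @export
enumerate_junction_peptides <- function(left, spacer, right,
                                        lengths = c(8L, 9L, 10L, 11L)) {
  stopifnot(length(lengths) > 0L)
  concat <- paste0(left, spacer, right)
  n <- nchar(concat)
  ll <- nchar(left)
  ls <- nchar(spacer)
  out <- list()
  for (k in sort(unique(as.integer(lengths)))) {
    if (k > n) next
    offs <- 0:(n - k)
    keep <- !(offs + k <= ll) & !(offs >= ll + ls)
    offs <- offs[keep]
    if (!length(offs)) next
    out[[length(out) + 1L]] <- data.frame(
      peptide = substring(concat, offs + 1L, offs + k),
      length = k, offset = offs, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(peptide = character(), length = integer(),
                      offset = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Score a junction's peptides and compute its cost
#'
#' Every (junctional peptide, allele) pair that at least one predictor
#' covers receives a median IC50; the junction cost is the count of pairs
#' below the threshold (or the log-weighted sum under
#' `cost_mode = "weighted"`).
#'
#' @param peptides Output of [enumerate_junction_peptides()].
#' @param alleles Allele labels to scan.
#' @param predictors Predictor suite.
#' @param threshold Binder threshold in nM (> 0).
#' @param cost_mode See [design_config()].
#' @return List with `peptides` (scored ledger: peptide, offset, allele,
#'   median_ic50, below) and `cost`.
#' @export
junction_cost <- function(peptides, alleles, predictors, threshold = 500,
                          cost_mode = "count") {
  stopifnot(threshold > 0)
  rows <- list()
  if (nrow(peptides)) {
    for (allele in alleles) {
      ks <- unique(peptides$length)
      sup <- ks[vapply(ks, function(k)
        any(vapply(predictors, predictor_supports, logical(1L), allele, k)),
        logical(1L))]
      pk <- peptides[peptides$length %in% sup, , drop = FALSE]
      if (!nrow(pk)) next
      med <- vapply(pk$peptide, function(p)
        median_affinity(p, allele, predictors)$median_ic50, numeric(1L),
        USE.NAMES = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = pk$peptide, offset = pk$offset, allele = allele,
        median_ic50 = med, below = med < threshold,
        stringsAsFactors = FALSE)
    }
  }
  scored <- if (length(rows)) do.call(rbind, rows) else
    data.frame(peptide = character(), offset = integer(),
               allele = character(), median_ic50 = numeric(),
               below = logical(), stringsAsFactors = FALSE)
  cost <- if (cost_mode == "count") sum(scored$below) else
    sum(log(threshold / scored$median_ic50[scored$below]))
  list(peptides = scored, cost = cost)
}

# Best spacer for one ordered junction: min cost over the spacer
# vocabulary, earlier vocabulary entries (i.e. "") preferred on ties.
assess_junction <- function(left_seq, right_seq, left_id, right_id,
                            alleles, predictors, config) {
  best <- NULL
  for (sp in config$spacers) {
    peps <- enumerate_junction_peptides(left_seq, sp, right_seq,
                                        config$junction_lengths)
    jc <- junction_cost(peps, alleles, predictors,
                        config$junction_ic50_threshold, config$cost_mode)
    if (is.null(best) || jc$cost < best$cost) {
      best <- list(left_id = left_id, right_id = right_id, spacer = sp,
                   cost = jc$cost, peptides = jc$peptides)
    }
  }
  best
}

#' Find the epitope ordering minimizing junctional-epitope cost
#'
#' Computes, for every ordered segment pair, the junction cost minimized
#' over the spacer vocabulary, plus terminal costs against the ubiquitin
#' degron and the HA tag when terminal scanning is enabled, then solves the
#' open-path ordering problem: exhaustive search up to
#' `config$exhaustive_max` segments, exact Held-Karp subset DP up to
#' `config$dp_max`, seeded simulated annealing beyond.
#'
#' @param segments List of `epitope_segment` objects (or plain named
#'   character vector of sequences).
#' @param alleles Allele labels to scan at junctions.
#' @param predictors Predictor suite.
#' @param config See [design_config()].
#' @return A `construct_layout` (see [assemble_construct()]).
#' @export
optimize_order <- function(segments, alleles, predictors,
                           config = design_config()) {
  segments <- as_segment_list(segments)
  n <- length(segments)
  if (n == 0L) stop("no segments to order", call. = FALSE)
  seqs <- vapply(segments, function(s) s$sequence, character(1L))
  ids <- vapply(segments, function(s) s$id, character(1L))

  pair <- vector("list", n * n)  # pair[[(i-1)*n + j]] = assessment i -> j
  C <- matrix(Inf, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    a <- assess_junction(seqs[i], seqs[j], ids[i], ids[j],
                         alleles, predictors, config)
    pair[[(i - 1L) * n + j]] <- a
    C[i, j] <- a$cost
  }
  ub_seq <- if (config$include_ubmut) ubiquitin_mut() else NULL
  tag_seq <- if (config$include_tag) ha_tag() else NULL
  ub_assess <- tag_assess <- vector("list", n)
  ub_cost <- tag_cost <- rep(0, n)
  if (config$scan_terminal_junctions) {
    for (i in seq_len(n)) {
      if (!is.null(ub_seq)) {
        ub_assess[[i]] <- assess_junction(ub_seq, seqs[i], "UB", ids[i],
                                          alleles, predictors, config)
        ub_cost[i] <- ub_assess[[i]]$cost
      }
      if (!is.null(tag_seq)) {
        tag_assess[[i]] <- assess_junction(seqs[i], tag_seq, ids[i], "TAG",
                                           alleles, predictors, config)
        tag_cost[i] <- tag_assess[[i]]$cost
      }
    }
  }

  sol <- if (n <= config$exhaustive_max) {
    solve_order_exhaustive(C, ub_cost, tag_cost)
  } else if (n <= config$dp_max) {
    solve_order_dp(C, ub_cost, tag_cost)
  } else {
    solve_order_sa(C, ub_cost, tag_cost, config)
  }
  perm <- sol$perm

  ledger <- list()
  if (config$scan_terminal_junctions && !is.null(ub_seq))
    ledger[[length(ledger) + 1L]] <- ub_assess[[perm[1L]]]
  if (n > 1L) for (k in seq_len(n - 1L))
    ledger[[length(ledger) + 1L]] <-
      pair[[(perm[k] - 1L) * n + perm[k + 1L]]]
  if (config$scan_terminal_junctions && !is.null(tag_seq))
    ledger[[length(ledger) + 1L]] <- tag_assess[[perm[n]]]

  layout <- assemble_construct(segments[perm], ledger = ledger,
                               config = config)
  stopifnot(isTRUE(all.equal(layout$total_cost, sol$cost)))
  layout$solver <- sol$solver
  layout
}

as_segment_list <- function(segments) {
  if (inherits(segments, "epitope_segment")) return(list(segments))
  if (is.character(segments)) {
    ids <- names(segments) %||% paste0("seg", seq_along(segments))
    return(lapply(seq_along(segments), function(i)
      structure(list(id = ids[i], sequence = unname(segments[i]),
                     mut_offset = NA_integer_, variant = NULL),
                class = "epitope_segment")))
  }
  stopifnot(all(vapply(segments, inherits, logical(1L), "epitope_segment")))
  segments
}

# Exhaustive permutation search with admissible partial-cost pruning;
# among ties the lexicographically first optimum is kept.
solve_order_exhaustive <- function(C, ub_cost, tag_cost) {
  n <- nrow(C)
  best <- new.env(parent = emptyenv())
  best$cost <- Inf
  best$perm <- NULL
  rec <- function(perm, used, cost) {
    if (cost >= best$cost) return(invisible())
    k <- length(perm)
    if (k == n) {
      total <- cost + tag_cost[perm[n]]
      if (total < best$cost) {
        best$cost <- total
        best$perm <- perm
      }
      return(invisible())
    }
    for (j in seq_len(n)) {
      if (used[j]) next
      step <- if (k == 0L) ub_cost[j] else C[perm[k], j]
      used[j] <- TRUE
      rec(c(perm, j), used, cost + step)
      used[j] <- FALSE
    }
  }
  rec(integer(0L), logical(n), 0)
  list(perm = best$perm, cost = best$cost, solver = "exhaustive")
}

# Exact open-path Held-Karp: f[S][j] = min cost of a path that starts at
# the N-terminus, visits exactly the segments in S, and ends at j.
solve_order_dp <- function(C, ub_cost, tag_cost) {
  n <- nrow(C)
  nmask <- bitwShiftL(1L, n)
  f <- matrix(Inf, nmask, n)
  parent <- matrix(NA_integer_, nmask, n)
  for (j in seq_len(n)) f[bitwShiftL(1L, j - 1L) + 1L, j] <- ub_cost[j]
  for (mask in seq_len(nmask - 1L)) {
    members <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    if (length(members) < 2L) next
    for (j in members) {
      prev_mask <- mask - bitwShiftL(1L, j - 1L)
      prevs <- setdiff(members, j)
      vals <- f[prev_mask + 1L, prevs] + C[prevs, j]
      b <- which.min(vals)
      f[mask + 1L, j] <- vals[b]
      parent[mask + 1L, j] <- prevs[b]
    }
  }
  full <- nmask - 1L
  totals <- f[full + 1L, ] + tag_cost
  last <- which.min(totals)
  perm <- integer(n)
  mask <- full
  j <- last
  for (k in n:1) {
    perm[k] <- j
    pj <- parent[mask + 1L, j]
    mask <- mask - bitwShiftL(1L, j - 1L)
    j <- pj
  }
  list(perm = perm, cost = totals[last], solver = "dp")
}

path_cost <- function(perm, C, ub_cost, tag_cost) {
  n <- length(perm)
  inner <- if (n > 1L) sum(C[cbind(perm[-n], perm[-1L])]) else 0
  ub_cost[perm[1L]] + inner + tag_cost[perm[n]]
}

# Seeded simulated annealing: geometric cooling, swap/reversal moves,
# independent restarts; bit-reproducible under a fixed config seed.
solve_order_sa <- function(C, ub_cost, tag_cost, config) {
  n <- nrow(C)
  best_perm <- seq_len(n)
  best_cost <- path_cost(best_perm, C, ub_cost, tag_cost)
  for (r in seq_len(config$sa_restarts)) {
    res <- with_seed(config$seed + r - 1L, {
      cur <- sample.int(n)
      cur_cost <- path_cost(cur, C, ub_cost, tag_cost)
      loc_best <- cur
      loc_cost <- cur_cost
      temp <- max(cur_cost, 1)
      for (step in seq_len(config$sa_steps)) {
        ij <- sort(sample.int(n, 2L))
        cand <- cur
        if (stats::runif(1L) < 0.5) {
          cand[ij] <- cand[rev(ij)]
        } else {
          cand[ij[1L]:ij[2L]] <- rev(cand[ij[1L]:ij[2L]])
        }
        cand_cost <- path_cost(cand, C, ub_cost, tag_cost)
        if (cand_cost <= cur_cost ||
            stats::runif(1L) < exp((cur_cost - cand_cost) / temp)) {
          cur <- cand
          cur_cost <- cand_cost
          if (cur_cost < loc_cost) {
            loc_best <- cur
            loc_cost <- cur_cost
          }
        }
        temp <- temp * config$sa_cooling
      }
      list(perm = loc_best, cost = loc_cost)
    })
    if (res$cost < best_cost) {
      best_cost <- res$cost
      best_perm <- res$perm
    }
  }
  list(perm = best_perm, cost = best_cost, solver = "sa")
}

#' Assemble the polyepitope construct protein
#'
#' Concatenates the (already ordered) segments with their per-junction
#' spacers, fuses the 76-residue G76V ubiquitin degron N-terminally and the
#' HA tag C-terminally as configured, and records 1-based inclusive feature
#' coordinates tiling the full protein.
#'
#' @param segments Ordered list of `epitope_segment` objects.
#' @param spacers Character vector of spacers between consecutive segments
#'   (length `n - 1`); ignored when `ledger` is given (spacer choices are
#'   then taken from the junction assessments).
#' @param ledger Optional list of junction assessments (from
#'   [optimize_order()]); supplies spacer choices and the cost total.
#' @param config See [design_config()].
#' @return A `construct_layout`: `n_terminus`, `segments`, `spacers`,
#'   `c_tag`, `protein`, `features`, `total_cost`, `junction_ledger`.
#' @export
assemble_construct <- function(segments, spacers = NULL, ledger = NULL,
                               config = design_config()) {
  segments <- as_segment_list(segments)
  n <- length(segments)
  stopifnot(n >= 1L)
  ids <- vapply(segments, function(s) s$id, character(1L))
  ub <- if (config$include_ubmut) ubiquitin_mut() else ""
  tag <- if (config$include_tag) ha_tag() else ""

  lead_spacer <- ""
  tail_spacer <- ""
  if (!is.null(ledger)) {
    spacers <- character(max(0L, n - 1L))
    for (a in ledger) {
      if (identical(a$left_id, "UB")) lead_spacer <- a$spacer
      else if (identical(a$right_id, "TAG")) tail_spacer <- a$spacer
      else {
        k <- match(a$left_id, ids)
        spacers[k] <- a$spacer
      }
    }
  } else if (is.null(spacers)) {
    spacers <- rep("", max(0L, n - 1L))
  }
  stopifnot(length(spacers) == n - 1L)

  feats <- list()
  pos <- 0L
  add_feat <- function(name, type, seq) {
    if (!nzchar(seq)) return(invisible())
    feats[[length(feats) + 1L]] <<- data.frame(
      name = name, type = type, start = pos + 1L, end = pos + nchar(seq),
      stringsAsFactors = FALSE)
    pos <<- pos + nchar(seq)
  }
  parts <- character(0L)
  if (nzchar(ub)) { add_feat("Ub_G76V", "degron", ub); parts <- c(parts, ub) }
  if (nzchar(lead_spacer)) {
    add_feat("spacer", "spacer", lead_spacer)
    parts <- c(parts, lead_spacer)
  }
  for (k in seq_len(n)) {
    add_feat(ids[k], "epitope", segments[[k]]$sequence)
    parts <- c(parts, segments[[k]]$sequence)
    if (k < n && nzchar(spacers[k])) {
      add_feat("spacer", "spacer", spacers[k])
      parts <- c(parts, spacers[k])
    }
  }
  if (nzchar(tail_spacer)) {
    add_feat("spacer", "spacer", tail_spacer)
    parts <- c(parts, tail_spacer)
  }
  if (nzchar(tag)) { add_feat("HA_tag", "tag", tag); parts <- c(parts, tag) }

  total_cost <- if (is.null(ledger)) NA_real_ else
    sum(vapply(ledger, function(a) a$cost, numeric(1L)))
  structure(list(
    n_terminus = if (nzchar(ub)) ub else NULL,
    segments = segments,
    spacers = spacers,
    c_tag = if (nzchar(tag)) tag else NULL,
    protein = paste(parts, collapse = ""),
    features = do.call(rbind, feats),
    total_cost = total_cost,
    junction_ledger = ledger), class = "construct_layout")
}

#' Flatten a layout's junction ledger to a table
#'
#' @param layout A `construct_layout`.
#' @return `data.frame` with one row per scored junctional peptide-allele
#'   pair (columns `left_id`, `right_id`, `spacer`, `peptide`, `offset`,
#'   `allele`, `median_ic50`, `below`).
#' @export
junction_ledger_table <- function(layout) {
  stopifnot(inherits(layout, "construct_layout"))
  rows <- lapply(layout$junction_ledger, function(a) {
    if (!nrow(a$peptides))
      return(data.frame(left_id = a$left_id, right_id = a$right_id,
                        spacer = a$spacer, peptide = NA_character_,
                        offset = NA_integer_, allele = NA_character_,
                        median_ic50 = NA_real_, below = FALSE,
                        stringsAsFactors = FALSE))
    cbind(data.frame(left_id = a$left_id, right_id = a$right_id,
                     spacer = a$spacer, stringsAsFactors = FALSE),
          a$peptides, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' @export
print.construct_layout <- function(x, ...) {
  ids <- vapply(x$segments, function(s) s$id, character(1L))
  cat("Polyepitope construct layout\n")
  cat(sprintf("  %s%s%s\n",
              if (!is.null(x$n_terminus)) "Ub(G76V) + " else "",
              paste(ids, collapse = " + "),
              if (!is.null(x$c_tag)) " + HA" else ""))
  cat(sprintf("  protein length: %d aa; junction cost: %s\n",
              nchar(x$protein),
              if (is.na(x$total_cost)) "not scored" else
                format(x$total_cost)))
  invisible(x)
}
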