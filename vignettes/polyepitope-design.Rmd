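---
title: "Designing polyepitope neoantigen DNA vaccine inserts with polyvax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing polyepitope neoantigen DNA vaccine inserts with polyvax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyvax)
```

## The design problem

A polyepitope ("string-of-beads") DNA vaccine concatenates several
tumor-specific neoantigen epitopes into a single open reading frame. Two
computational problems dominate the design. First, *which* neoantigens to
encode: somatic missense variants must be triaged by predicted MHC class I
binding, tumor purity, and expression. Second, *in what order* to
concatenate them: every junction between two epitopes creates novel
peptide sequence, and a junctional peptide that binds MHC as well as a
real epitope can divert the immune response to a specificity that does
not exist on the tumor. `polyvax` treats both as explicit optimization
problems over predicted binding affinities.

## Prioritization model

Each variant is applied to its wild-type protein and evaluated in a
window of `flank` residues per side (default 12, within the conventional
10–14 range; 12 is chosen so the window exactly contains the default
25-mer long epitope extracted later). All sub-peptides of lengths 8–11
whose span covers the substitution are enumerated — the closed-form count
for one length is `min(k, m + 1, L - m, L - k + 1)` for a window of
length `L` with the substitution at 0-based `m` — and each is scored on
each allele by a suite of binding predictors.

A predictor is any object honoring the contract *(peptide, allele) → IC50
in nM, finite, positive, deterministic*. Three implementations ship with
the package: a position-weight-matrix scorer whose normalized score `x`
maps to affinity by the conventional transform `IC50 = 50000^(1-x)` (so
`x = 1` is a 1 nM binder and `x = 0` a 50 µM non-binder, and thresholds
like 500 nM are meaningful); a hash-seeded mock with values spanning
(0, 50000] for randomized tests; and a lookup table, which is also the
natural ingestion path for affinities precomputed by external neural
predictors. The summary statistic is the **median IC50 across the
predictors that support the (allele, length) pair** — an even count
averages the two central values, and a predictor that does not cover a
pair is absent from the median rather than imputed, since treating
non-coverage as a worst case would bias medians for rare alleles.

For each (variant, allele) pair the sub-peptide with the minimal mutant
median IC50 is retained (ties: lower offset, then shorter length), its
wild-type counterpart is scored at the same offset and length, and the
**fold change is defined as IC50(WT) / IC50(MT)**, so values above 1 mean
the mutation improves binding. The field sometimes labels this quantity
"MT/WT fold change" (comparing MT *versus* WT); we use the WT/MT ratio
because requiring a literal IC50(MT)/IC50(WT) > 2 would select mutants
that bind *worse* than germline, the opposite of the selection intent.

The filter cascade is conjunctive and strict:

| criterion   | default  | meaning                                   |
|-------------|----------|-------------------------------------------|
| binding     | MT median IC50 < 500 nM | conventional binder cutoff |
| DNA VAF     | > 0.30   | variant clonality in tumor DNA            |
| RNA VAF     | > 0.30   | the mutant allele is actually transcribed |
| expression  | FPKM > 1 | the gene is expressed at all              |
| fold change | > 2      | mutation-specific binding improvement     |

Each criterion sets its own flag, so a failing candidate always reveals
*why* it failed; a variant whose gene lacks an expression value is
flagged, never silently dropped. Survivors are ranked by fold change
(ties: lower mutant IC50, then gene name), collapsed to the best allele
per variant, and cut at `max_n`.

## Junction-minimizing construct design

Each selected variant contributes a long epitope: the 25-mer (configurable
20–25) of the mutant protein centered on the substitution, left-biased by
one residue for even lengths, and extended on the opposite side when a
protein terminus truncates one flank. Long epitopes with native flanking
residues are used rather than minimal 8–10-mers because natural flanks
support TAP transport and proteasomal trimming; for the same reason the
spacer vocabulary at each junction is just `{none, AAY}` with *none
preferred on ties* — a spacer is only accepted when it strictly lowers
the junction cost.

A *junctional peptide* at a junction is any k-mer (default k in 8–11) of
`left + spacer + right` not wholly contained in the left epitope alone
nor in the right epitope alone; spacer residues belong to neither side,
so every novel peptide created by the concatenation is scanned. The
junction cost is the count of (junctional peptide, allele) pairs whose
median IC50 falls below the threshold (default 500 nM, deliberately
reusing the prioritization binder cutoff; a log-weighted variant
`sum(log(threshold/IC50))` is available behind `cost_mode = "weighted"`).
Counting, rather than weighting, is the default because the design goal
is "no junctional binders at all", not "weak ones".

Because the ubiquitin fusion is uncleavable (below), the degron–first
epitope and last epitope–tag junctions persist in the expressed protein
and are scanned by default too (`scan_terminal_junctions`). Ordering is
an open-path problem: minimize `c(UB → s₁) + Σ c(sᵢ → sᵢ₊₁) + c(sₙ →
TAG)` where each pairwise cost is already minimized over the spacer
vocabulary. Three exact-to-heuristic regimes keep runtime interactive:

* **n ≤ 7** — exhaustive permutation search with admissible partial-cost
  pruning (first lexicographic optimum kept);
* **8 ≤ n ≤ 12** — exact Held–Karp subset dynamic programming over
  `2^n · n` states, still provably optimal;
* **n > 12** — simulated annealing (geometric cooling, 20 000 steps, 5
  restarts, swap and segment-reversal moves) under a fixed default seed
  17, so results are bit-reproducible; the schedule was chosen for
  sub-minute runtime at a few dozen epitopes.

The assembled construct is `Ub(G76V) + Σ(epitope + spacer) + HA`. The
N-terminal module is the canonical 76-residue ubiquitin monomer with its
C-terminal glycine replaced by valine; the G76V substitution blocks
deubiquitinases, so the fusion is a stable degradation signal that routes
the whole polyepitope into the proteasome and enhances class I
presentation. The optional C-terminal HA tag (the canonical 9-mer
epitope) enables antibody detection of the expressed protein. Every
segment, spacer, degron and tag is recorded as a 1-based inclusive
feature tiling the protein, and the reported total cost is re-verified
against the per-junction ledger at assembly time.

## Reverse translation

The construct protein becomes DNA via a codon-usage table (bundled:
relative synonymous codon frequencies typical of highly expressed human
genes; any table in the documented JSON layout can be substituted).
`max_frequency` picks each residue's most frequent codon with
lexicographic tie-breaks — deterministic and platform-independent —
while `weighted_sampling` draws codons proportional to usage under a
fixed seed. Forbidden motifs (e.g. restriction sites needed for cloning)
are removed by substituting, within each motif occurrence, the
overlapping codon offering the best next-ranked synonymous alternative;
a substitution is kept only if it strictly reduces the total motif
count, the procedure iterates to a fixpoint (bounded at 10 passes), and
occurrences no synonymous move can remove (e.g. a motif spelled by
Met-Trp codons) are reported rather than fatal. Translation under the
standard genetic code round-trips to the source protein after every
operation, and the test suite checks this against Biostrings as an
independent oracle. GC-content shaping, mRNA structure and codon-pair
optimization are deliberately out of scope — commercial synthesis
providers handle these — as are vector elements (promoter, IRES-GFP,
Kozak context).

## What the synthetic scenarios emulate

`generate_scenario` emulates the *inputs* of a tumor/normal sequencing
workflow — a proteome, annotated missense variants with DNA/RNA VAFs, an
FPKM table, and binding models — with planted ground truth:

* planted *passing* variants carry an engineered 9-mer whose mutant
  median IC50 is 1 nM (well below `500 / margin` with the default margin
  10), a wild-type counterpart at 5000 nM (fold change far above 2), and
  VAF/FPKM draws comfortably above the thresholds;
* planted *failing* variants violate exactly one named criterion each
  (binding at `500 × margin` nM, VAF below 0.30, FPKM below 1, or fold
  change 1.5), so every flag is individually testable.

PWM engineering is by direct matrix surgery: the planted 9-mer's
per-position cells carry the exact raw score for the target affinity,
with the wild-type residue cell at the substitution column adjusted for
the wild-type target. Each variant's context window is drawn from a
4-residue sub-alphabet disjoint across variants sharing an allele, so
engineered cells never collide between plants; the generator additionally
*verifies* its plant by running the real evaluation/filter path and
redrawing any protein whose random sequence still produces accidental
cross-talk (bounded, deterministic under the seed). Scenario files are
byte-identical across reruns of the same spec.

What the scenarios do **not** emulate: real mutational spectra, codon
bias or homology structure of real proteomes (the 4-residue windows are
visibly low-complexity), correlated expression/VAF noise, predictor
disagreement (the engineered suite is a single PWM predictor), or class
II epitopes. Passing tests therefore demonstrate the *correctness of the
selection and ordering machinery given a predictor*, not the accuracy of
any particular binding predictor on real data — the latter is governed by
whichever external predictor the user plugs in through the contract.

`generate_ordering_instance` provides the ordering analogue:
`chain_zero_cost` plants a unique order whose junctions are all free of
sub-threshold binders while every other adjacency contains at least one
planted binder under both spacer options (built with the exact lookup
predictor), and `random` emits unstructured mock-predictor instances for
comparison against the brute-force permutation oracle.

## Numerical and interface choices

* All user-facing coordinates are 1-based inclusive (protein and DNA);
  offsets inside windows and concatenations are 0-based and documented
  as such.
* Variant input is a flat annotated TSV (gene, protein ID, position,
  ref/alt, DNA/RNA VAF), not VCF: the pipeline's inputs are
  protein-level changes, and re-implementing transcript consequence
  annotation is out of scope. VAFs are accepted as fractions or
  percentages (values > 1 are divided by 100; 1.0 is a fraction).
* Codon-table frequencies off unity by ≤ 1e-3 are renormalized; larger
  deviations are schema errors.
* The median of an even predictor count is the mean of the two central
  values; medians are permutation-invariant in predictor order.
* Stop-gain, frameshift and indel variants are rejected with a clear
  error; the pipeline models single-residue substitutions only.
* Test and acceptance problem sizes (10-variant scenarios, 100 seeds,
  1000-instance enumeration oracles, ordering instances up to n = 9 for
  the exact cross-check) were chosen so the whole suite runs in about
  two minutes on one CPU while still exercising every solver regime.

## Known limitations

Proteasomal cleavage and TAP transport at junctions are not modeled —
the junction score is binding-based only, which is the standard
practical proxy. The per-variant best-allele collapse keeps a single
(variant, allele) pair in the vaccine set; per-allele retention is
available via `rank_and_select` on the un-collapsed candidate table.
The bundled PWM scorer is a transparent, deterministic stand-in for
desk-scale work and testing; production designs should ingest
affinities from trained external predictors through the
`table_predictor` route or a custom `binding_predictor` implementation.
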