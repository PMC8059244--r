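# polyvax

Design of string-of-beads polyepitope DNA vaccine inserts from annotated
somatic missense variants.

## The problem

Personalized cancer vaccines encode tumor-specific neoantigens — peptides
created by somatic protein-altering mutations and absent from normal
tissue. Building a DNA vaccine from a patient's (or a model tumor's)
variant calls requires four computational steps, and `polyvax` implements
all of them as a reusable pipeline:

1. **Prioritization.** Every missense variant is evaluated in the context
   of 10–14 flanking amino acids; all substitution-spanning sub-peptides
   (8–11-mers) are scored against the MHC class I alleles of interest with
   a suite of binding predictors, and the median predicted IC50 is taken.
   Candidates survive the filter cascade

   * mutant median IC50 < 500 nM,
   * tumor DNA VAF > 30% and RNA VAF > 30%,
   * gene expression FPKM > 1,
   * fold change FC = IC50(WT) / IC50(MT) > 2,

   (all strict) and are ranked by fold change, so mutations that *improve*
   predicted binding over their germline counterpart rank first.

2. **Construct design.** Each selected neoantigen becomes a 20–25-mer long
   epitope with native flanking residues. Concatenating epitopes creates
   novel junctional peptides that can divert immune responses, so the
   pipeline scores every possible junctional k-mer on every allele and
   finds the epitope ordering (and per-junction choice between direct
   fusion and an AAY spacer) minimizing the number of predicted junctional
   binders — exact search up to 7 epitopes, exact subset dynamic
   programming up to 12, seeded simulated annealing beyond.

3. **Assembly.** The ordered epitopes are fused to an N-terminal
   "uncleavable" ubiquitin degron (the 76-residue monomer with G76V, which
   resists deubiquitination and routes the whole polyepitope into the
   proteasome) and an optional C-terminal HA tag for detection.

4. **Reverse translation.** The construct protein is converted to a
   synthesizable DNA insert using a codon-usage table (bundled human
   table, max-frequency or weighted-sampling strategy), with optional
   removal of restriction-site motifs and addition of start/stop codons.

A seeded synthetic-scenario generator (`generate_scenario`) produces
complete inputs — proteome FASTA, variant/expression TSVs, engineered PWM
binding models and a ground-truth listing — so the entire pipeline is
testable without any external download. Utilities for the standard
immunological readouts (percent specific lysis from chromium release,
caliper tumor volume L×W²/2, background-subtracted ELISpot counts) are
included.

## Worked example

```r
library(polyvax)

bundle <- generate_scenario(scenario_spec(seed = 17), outdir = "demo")
res <- run_full(bundle$paths$proteome, bundle$paths$variants,
                bundle$paths$expression, bundle$paths$pwm_set,
                out_dir = "demo_out")
res$prioritization
res$design
```

```
Prioritization: 20 candidate pair(s), 5 passing, 5 selected
Prioritized neoantigens: 5 selected
 rank    gene position ref_aa alt_aa      allele mt_peptide mt_ic50 fold_change
    1 Gene001       62      D      E HLA-A*02:01  EECDEDCDD       1        5000
    2 Gene002       25      C      E      H-2-Db  CDCEEDCAC       1        5000
    3 Gene003       29      H      F HLA-A*02:01  IIGGFGHGG       1        5000
    4 Gene004       42      I      G      H-2-Db  HHGIGFGFI       1        5000
    5 Gene005       48      L      N HLA-A*02:01  KKKKNNKNL       1        5000
Polyepitope construct layout
  Ub(G76V) + Gene003_H29F + Gene001_D62E + Gene005_L48N + Gene004_I42G + Gene002_C25E + HA
  protein length: 216 aa; junction cost: 7
DNA insert: 648 nt encoding 216 aa (codon table: human)
```

The scenario plants five variants that satisfy every filter and five that
each violate exactly one criterion; the report lists 20 (variant, allele)
pairs, the cascade passes exactly the five planted winners, and each is
selected with its engineered 1 nM mutant 9-mer. The optimizer then orders
the five 25-mer epitopes so that only 7 junctional peptide–allele pairs
remain below the 500 nM binder threshold, fuses the G76V ubiquitin degron
and HA tag, and emits a 648 nt codon-optimized insert. `demo_out/`
contains the candidate report TSV, construct FASTA, an annotated GenBank
record (degron, each epitope, each spacer and tag as features), the
per-junction ledger and a provenance log.

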