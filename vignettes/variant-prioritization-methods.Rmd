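---
title: "Methods: germline variant prioritization in a quartet, ACMG combining, and preranked GSEA"
author: "quartetprio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: germline variant prioritization in a quartet, ACMG combining, and preranked GSEA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quartetprio)
```

# The problem

When two siblings in an otherwise healthy nuclear family present with the
same rare childhood malignancy, the parsimonious hypothesis is a shared
germline cause. `quartetprio` implements the standard desk workflow for that
setting: take whole-genome variant calls for the quartet from two independent
callers, keep the consensus, filter to rare non-silent variants carried by
both affected children, characterize Mendelian transmission patterns, gate
missense candidates on in-silico pathogenicity scores, and combine manually
curated ACMG-AMP evidence into five-tier classifications. A separate module
performs preranked gene-set enrichment analysis (GSEA) on two-condition
expression matrices, the usual downstream step for arguing which pathways a
candidate gene's loss perturbs.

Every stage is exercised end-to-end by a synthetic-cohort generator, so the
pipeline's behaviour is testable without access to any patient data.

# Pipeline stages and their assumptions

## Consensus after normalization

Variant representations differ between callers, most visibly for indels in
repeats. All records are therefore reduced to a minimal left-aligned
representation before keys are compared: shared trailing bases are trimmed,
emptied alleles are left-extended from the reference, and shared leading
bases are trimmed while both alleles remain longer than one base. The
operation is idempotent and preserves the edited haplotype (both properties
are property-tested on random indels). Consensus then keeps records whose
normalized (chrom, pos, ref, alt) key occurs in both call sets — an
allele-level intersection, the stricter of the two defensible keying
choices; a site-level intersection would admit allele-discordant calls.

Genotypes of jointly detected records are taken from the first caller. The
two callers' genotype fields can disagree; with no principled way to
reconcile them at this layer, the first caller wins and a warning counts the
disagreements. Multiallelic records are split before normalization, with
per-sample genotype indices remapped per split allele; an allele index
pointing at a non-tracked alternate folds to 0, which loses information but
keeps the one-alternate-per-record invariant that every downstream stage
relies on. Missing genotypes (`./.`) exclude a variant from inheritance
analysis but not from the frequency or consequence filters.

## Rarity

A variant is rare when its allele frequency is below the threshold
(`maf`, default 0.01) in **every** configured population source; the
phrasing "MAF < 0.01 from source A and source B" is ambiguous between AND
and OR across sources, and the AND reading (rare everywhere) is both
stricter and the common practice. A missing frequency counts as rare — the
absent-from-controls convention, which also feeds the PM2 ACMG criterion.
Lowering the threshold can only shrink the survivor set (tested as a
monotonicity property).

## Consequences

Toy transcript models carry ordered exons, CDS bounds and the spliced CDS
sequence. Substitutions are classified by translating the reference and
mutant codon with the standard genetic code (selenocysteine and alternative
codes are out of scope). Two consequence rules deserve comment:

* **Start-loss with re-initiation.** A substitution destroying the
  initiator ATG is modelled as translation re-initiating at the next
  in-frame ATG at codon *k*, reported as `p.M1-<aa><k-1>del` — a protein
  shortened by its first *k* − 1 residues — rather than the agnostic
  `p.Met1?`. This follows the biological reading that a near-start AUG
  rescues a truncated protein; when no downstream in-frame ATG exists the
  consequence carries a whole-protein-loss flag instead.
* **Severity.** When a variant hits several transcripts, one consequence is
  reported, by fixed severity order: stop_gain > frameshift > start_loss >
  splicing > stop_loss > nonsynonymous > inframe_indel > synonymous >
  non_coding.

The splice window is 2 intronic bases (the canonical GT/AG dinucleotides),
configurable; window 0 disables splice calls. Indels classify by length
change modulo 3; an indel spanning an exon/intron junction is splicing.
HGVS-style descriptors use the one-letter protein dialect of clinical
summary tables (`p.R536X`, `p.M1-P5del`), not the three-letter standard.

## Shared-by-affected and inheritance patterns

The shared filter keeps variants where every affected member carries at
least one alternate allele (hemizygous X calls count). Pattern definitions:

* *de novo*: every affected child carries the alternate, both parents are
  homozygous reference. Never assigned when any parent carries the allele.
* *autosomal recessive*: affected children homozygous alternate, both
  parents heterozygous, autosomes only.
* *X-linked*: chrX variant, affected males hemizygous or homozygous
  alternate, carrier mother, reference father. The father must be reference
  because an affected-father transmission to a son would be father-to-son X
  transmission, which does not occur.
* *compound heterozygous*: within one gene, a variant pair where every
  affected child is heterozygous at both sites and the two alternates are
  transmitted from different parents. Phase is resolved purely by
  transmission: a variant carried by both parents cannot be phased this way
  and never joins a flagged pair; children homozygous at a site route to
  the recessive pattern instead. Both members of a pair must already be in
  the candidate set, i.e. non-silent and rare.

Parental origin (maternal / paternal / both / de novo / undetermined) is
read directly off which parent carries the allele.

## The score gate and the final candidate set

Only nonsynonymous candidates face the four-score gate: SIFT ≤ 0.05 AND
PolyPhen2 ≥ 0.957 AND MutationTaster = disease_causing AND M-CAP > 0.025
(the inequality directions are deliberate: SIFT inclusive, M-CAP strict). A
missing score fails the gate — the gate exists to pass only unanimously
supported missense variants, and treating absence as a pass would defeat
that. Truncating, initial-codon, splicing and in-frame candidates bypass the
gate entirely.

The funnel's final stage selects the ACMG-eligible categories — stop-gain,
start-loss and (score-passing) nonsynonymous. Frameshift and splicing
variants are retained and counted through the funnel but are not routed
into ACMG classification; this mirrors the clinical workflow the pipeline
reproduces, where the curated evidence evaluation was applied to truncating,
initial-codon and filtered missense variants.

## ACMG-AMP combining

Evidence assignment is an input, not a computation: deciding that a variant
merits PVS1 or PS1 requires disease-gene databases, literature and
functional data. The engine's job is only to parse tokens (with strength
overrides: `PP1-S` is PP1 applied at strong level) and count effective
strength levels into the published combining clauses. Pathogenic clauses are
labelled Ia–Id, II, III in the order given in the guideline; when several
fire, the earliest label is reported. Strength overrides are honoured in the
counting — `PP1-S` counts as a strong criterion, which is exactly what lets
clause Ia (≥1 very strong + ≥1 strong) fire for an evidence set like
`PVS1, PS1, PP1-S, PM2, PP3, BP1`.

A classification conflict is declared only when the pathogenic and benign
sides **independently** reach classifications (the InterVar reading), in
which case the result is uncertain significance with a conflict flag.
Isolated benign-supporting evidence — a lone BP1 next to PVS1 and strong
criteria — reaches no benign classification and therefore does not veto a
pathogenic call. This is the only reading under which such mixed sets
classify as pathogenic, and it matches how clinical tables print them.
Benign-side codes only take benign-side strength levels (`-S`, `-P`); BA1 is
stand-alone.

The engine is validated against a brute-force clause-table oracle over
exhaustive small evidence multisets, plus monotonicity (adding pathogenic
evidence never demotes the pathogenic side) and permutation invariance.

# Preranked GSEA

Genes are ranked by `log2(mean_case + eps) − log2(mean_control + eps)` with
a pseudo-count `eps = 1` guarding zero expression (configurable; with
normalized array intensities in the hundreds it is effectively inert). Ties
are broken by gene symbol so the ranking is deterministic — real normalized
values rarely tie, but synthetic data can.

The enrichment score is the signed maximum deviation of the weighted
running sum: hits increment by `|score|^exponent` (normalized over hits),
misses decrement by 1/(N − N_hits); exponent 1 is the weighted default,
exponent 0 the Kolmogorov–Smirnov statistic. An exact tie between the
positive and negative extremum resolves to the positive one (ties cannot
occur for continuous scores at exponent 1; the rule only matters for the
rational increments of exponent 0). Degenerate sets (no overlap with the
list, or covering the whole list) are rejected.

The null distribution permutes **gene labels** — random same-size gene sets
from the ranked universe — because a preranked analysis has no phenotype
labels to permute; this is documented as the only option, and its p-values
are anti-conservative relative to phenotype permutation when genes are
co-expressed. The nominal p-value uses a pseudo-count over same-sign null
scores, so it is never zero and its floor is 1/(1 + #same-sign nulls).
NES = ES / mean(|null ES| of the same sign). The FDR q-value is the
NES-ratio estimator of the original GSEA description — the fraction of
pooled null NES at least as extreme divided by the fraction of observed NES
at least as extreme, clipped to [0, 1]. Exact numeric agreement with the
desktop tool is not promised, only the documented estimator; the ES itself
is cross-checked in the test suite against an independent implementation
(fgsea) and a brute-force running-sum oracle. Permutations require a seed
and at least 100 rounds (tails are unstable below that).

The leading edge is the set members at or before the running-sum peak
(positive ES) or at or after the trough (negative ES). Cell-type analyses
(e.g. NK/dendritic-cell signatures) are represented as ordinary gene sets
supplied via GMT; no deconvolution is implemented.

# What the synthetic cohort emulates — and what it does not

`make_toy_genes()` builds two-exon genes with valid CDSs (ATG start, stop
end, length divisible by 3, canonical GT/AG introns) on a toy karyotype.
Two designated genes host the worked consequence facts: an autosomal gene
whose codon spanning CDS positions 1606–1608 is CGA (so c.1606C>T creates a
stop at residue 536) and a chrX gene whose codon 6 is ATG with proline at
residue 5 (so c.3G>T deletes residues 1–5 under re-initiation). All
generated models are plus-strand; minus-strand consequence logic is
exercised by hand-built transcripts in the unit tests.

`simulate_quartet()` plants one variant class per configuration knob:
maternal-dominant stop-gain, X-linked start-loss, compound-heterozygous
pairs, de novo singletons (carried by one child, so they fall at the shared
filter), recessive homozygotes, common benign variants, shared silent
variants, and caller-discordant records present in one VCF only. Planted
genotypes are **constructed**, not sampled — the generator is deliberately
Hardy–Weinberg-free, and the quartet must not be treated as a population
sample. Background variants are Mendelian-sampled at mixture allele
frequencies with ~99% of them common, and background missense scores are
drawn from Beta distributions (SIFT and PolyPhen2 ~ Beta(2,2), M-CAP ~
Beta(1,40), MutationTaster mostly "polymorphism") so the joint probability
of a background variant clearing the four-score gate is orders of magnitude
below the 1% design target. Plants that must not survive the funnel carry a
deterministic failing MutationTaster call so recovery tests are exact
rather than probabilistic. The two caller VCFs differ only in
representation — a subset of caller B's records is padded with a shared
trailing reference base — so consensus genuinely exercises normalization.

With the default specification the only funnel survivors are the two
signature plants; an optional score-passing missense class (default 0)
emulates a missense variant that clears the gate but stalls at ACMG with
"not enough evidence". A truth-table JSON accompanies every dataset and is
audited in the tests by re-deriving each planted class from the emitted
genotypes.

`simulate_expression()` uses a log-normal baseline (log2 means uniform on
[5, 9]), multiplies the planted set by `fold` in cases, and adds Gaussian
log2-scale noise. Defaults — 600 genes, 4 samples per group, a planted set
of 50, fold 2, noise SD 0.25 — reflect a small two-condition array study:
a twofold change against 0.25 SD noise with n = 4 is comfortably
detectable at the pathway level but not trivially so at the single-gene
level. What the generator does **not** emulate: gene–gene correlation,
library-size artefacts, batch effects, heavy-tailed counts. Passing the
recovery tests therefore demonstrates correctness of the machinery, not
performance on real expression data.

# Numerical and degenerate-input choices

* Coordinates are 1-based fully closed throughout, matching VCF.
* Chromosome names are preserved as read; chrX detection strips an
  optional `chr` prefix case-insensitively.
* Normalization refuses to left-extend past position 1 and treats a
  REF/reference mismatch as a contract violation, not a warning.
* An empty VCF yields an empty call set with a warning, and the pipeline
  completes with an empty report.
* `combine_evidence({})` is uncertain significance; candidates without
  evidence classify the same way with a warning.
* Funnel stage counts are non-increasing along the main path by
  construction and asserted in tests.
* All randomness flows through explicit integer seeds; pipeline outputs are
  byte-identical across reruns on fixed inputs and seed.

# Problem sizes used by the test suite

The suite validates the properties at sizes chosen to keep the whole run in
the minutes range on one core while leaving no logic untested: 20 seeded
quartets (default plant spec, 120 background variants each) for exact
funnel recovery; 1,000 random indels for normalization idempotence and
haplotype preservation; exhaustive ACMG multisets with ≤2 criteria per
strength level plus targeted clause-III cases; 100–200 random instances
(N ≤ 50) for the ES oracle; 20 seeds at fold 2 (600 genes, 200
permutations) for GSEA recovery and 20 seeds at fold 1 for null
calibration.

# Known limitations

* Single-proband prioritization is explicitly out of scope; the shared
  filter requires at least two affected members.
* No structural variants, CNVs, gVCF blocks, or tabix random access; VCFs
  are streamed whole.
* Evidence assignment for ACMG is manual by design; only the machinery that
  combines it is automated.
* The gene-label permutation null understates between-gene correlation, as
  noted above.
* X-inactivation, mosaicism and mutation-rate modelling are not attempted.
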