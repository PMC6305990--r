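Package: quartetprio
Title: Germline Variant Prioritization in Nuclear Pedigrees with ACMG
    Classification and Preranked GSEA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for prioritizing germline candidate variants
    in small nuclear pedigrees with multiple affected siblings: dual-caller
    consensus after allele normalization, rare-variant filtering against
    population allele frequencies, functional consequence annotation against
    transcript models (including stop-gain and start-loss with downstream
    re-initiation), shared-by-affected selection, Mendelian inheritance
    pattern detection (de novo, autosomal recessive, X-linked, compound
    heterozygous by transmission phasing), in-silico pathogenicity score
    gating, and an ACMG-AMP evidence-combining engine producing five-tier
    classifications with clause labels. A preranked gene-set enrichment
    module (weighted running-sum enrichment score, gene-set permutation null,
    NES and FDR q estimation, leading-edge extraction) supports downstream
    pathway analysis of two-condition expression matrices. A synthetic-cohort
    generator emits pedigree VCFs, annotation tables, toy transcript models
    and expression matrices with planted signal so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
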