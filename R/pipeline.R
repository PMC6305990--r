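# End-to-end orchestration: consensus -> filters -> inheritance -> scores ->
# ACMG -> report, and separately rank -> preranked GSEA. Every stage logs its
# input/output counts; outputs are written in deterministic, text-only
# formats so a fixed (inputs, seed) pair reproduces byte-identical results.

#' Assemble and validate a pipeline configuration
#'
#' @param vcf_a,vcf_b Paths to the two callers' VCFs.
#' @param ped Path to the PED file.
#' @param annotations Path to the annotation TSV.
#' @param transcripts,cds_fasta Paths to the transcript model TSV and CDS
#'   FASTA.
#' @param genome Path to the reference genome FASTA (for allele
#'   normalization).
#' @param cpg_list Optional path to a cancer-predisposition gene list.
#' @param expression,gmt Optional paths for the GSEA arm.
#' @param maf,sift,polyphen2,mcap,splice_window,gsea_exponent,n_perm
#'   Thresholds (defaults: 0.01, 0.05, 0.957, 0.025, 2, 1, 1000).
#' @param seed Integer seed (used by the GSEA permutations).
#' @param out_dir Output directory.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf_a, vcf_b, ped, annotations, transcripts,
                            cds_fasta, genome, cpg_list = NULL,
                            expression = NULL, gmt = NULL,
                            maf = 0.01, sift = 0.05, polyphen2 = 0.957,
                            mcap = 0.025, splice_window = 2L,
                            gsea_exponent = 1, n_perm = 1000L, seed = 1L,
                            out_dir = tempfile("pipeline")) {
  cfg <- list(vcf_a = vcf_a, vcf_b = vcf_b, ped = ped,
              annotations = annotations, transcripts = transcripts,
              cds_fasta = cds_fasta, genome = genome, cpg_list = cpg_list,
              expression = expression, gmt = gmt,
              maf = maf, sift = sift, polyphen2 = polyphen2, mcap = mcap,
              splice_window = as.integer(splice_window),
              gsea_exponent = gsea_exponent, n_perm = as.integer(n_perm),
              seed = as.integer(seed), out_dir = out_dir)
  stopifnot(cfg$maf > 0, cfg$maf <= 1, cfg$sift >= 0, cfg$sift <= 1,
            cfg$polyphen2 >= 0, cfg$polyphen2 <= 1, cfg$mcap >= 0,
            cfg$mcap <= 1, cfg$splice_window >= 0)
  for (p in c("vcf_a", "vcf_b", "ped", "annotations", "transcripts",
              "cds_fasta", "genome")) {
    if (!file.exists(cfg[[p]]))
      stop("configured path does not exist (", p, "): ", cfg[[p]])
  }
  for (p in c("cpg_list", "expression", "gmt")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
      stop("configured path does not exist (", p, "): ", cfg[[p]])
  }
  structure(cfg, class = "pipeline_config")
}

#' Convenience: configuration for a simulated quartet directory
#'
#' @param sim Output of [simulate_quartet()].
#' @param ... Overrides passed on to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
config_from_simulation <- function(sim, ...) {
  pipeline_config(vcf_a = sim$paths$vcf_a, vcf_b = sim$paths$vcf_b,
                  ped = sim$paths$ped, annotations = sim$paths$annotations,
                  transcripts = sim$paths$transcripts,
                  cds_fasta = sim$paths$cds_fasta, genome = sim$paths$genome,
                  cpg_list = sim$paths$cpg_list,
                  out_dir = file.path(sim$out_dir, "results"), ...)
}

#' Run the variant-prioritization funnel
#'
#' Stages, in order: read + normalize both callers' VCFs; consensus
#' intersection; annotation join and consequence annotation; rare-variant
#' filter; non-silent filter; shared-by-affected selection;
#' cancer-predisposition flagging, inheritance-pattern and
#' compound-heterozygote detection (annotations, not filters); four-score
#' gate for missense; selection of the ACMG-eligible set; ACMG
#' classification of candidates carrying evidence.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage count logging.
#' @return List of class `prioritization_result` with `report` (a
#'   `funnel_report`), `candidates` (the final data frame), `table2` (the
#'   summary-table-shaped view: Chr, Position, Ref, Alt, Variant, Effect,
#'   Evidence, Origin), `compound_het_pairs` and `n_pathogenic`. Outputs are
#'   also written under `config$out_dir`.
#' @export
run_prioritization <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) if (!quiet) message("[prioritize] ", sprintf(...))

  genome <- Biostrings::readDNAStringSet(config$genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  ref_lookup <- fasta_ref_lookup(genome)
  calls_a <- normalize_calls(read_vcf(config$vcf_a, "caller_a"), ref_lookup)
  calls_b <- normalize_calls(read_vcf(config$vcf_b, "caller_b"), ref_lookup)
  consensus <- consensus_intersect(calls_a, calls_b)
  log_stage("caller A %d, caller B %d, consensus %d",
            length(calls_a), length(calls_b), length(consensus))

  ped <- read_ped(config$ped)
  ann <- read_annotation(config$annotations)
  transcripts <- read_transcripts(config$transcripts, config$cds_fasta)

  cand <- consensus$variants
  if (nrow(cand) > 0L) {
    gt_df <- as.data.frame(consensus$gt, stringsAsFactors = FALSE)
    names(gt_df) <- paste0("gt.", consensus$samples)
    cand <- cbind(cand, gt_df)
  } else {
    for (s in consensus$samples) cand[[paste0("gt.", s)]] <- character(0)
  }
  key <- variant_key(cand$chrom, cand$pos, cand$ref, cand$alt)
  ann_key <- variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)
  m <- match(key, ann_key)
  for (col in setdiff(names(ann), c("chrom", "pos", "ref", "alt")))
    cand[[col]] <- ann[[col]][m]
  cand <- annotate_consequences(cand, transcripts, config$splice_window)
  cand$gene <- ifelse(is.na(cand$gene), cand$tx_gene, cand$gene)

  rare <- filter_rare(cand, threshold = config$maf)
  log_stage("rare (MAF < %g in every source): %d", config$maf, nrow(rare))
  nonsilent <- filter_nonsilent(rare)
  shared <- shared_by_affected(nonsilent, ped)
  class_counts <- table(factor(shared$category,
                               levels = NONSILENT_CATEGORIES))
  log_stage("non-silent %d, shared by affected %d",
            nrow(nonsilent), nrow(shared))

  cpg_genes <- if (!is.null(config$cpg_list)) read_gene_list(config$cpg_list)
               else character(0)
  if (length(cpg_genes) > 0L) shared <- annotate_cpg(shared, cpg_genes)
  shared <- detect_inheritance(shared, ped)
  ch <- detect_compound_het(shared, ped)
  shared <- ch$candidates
  pattern_counts <- c(
    de_novo = sum(grepl("de_novo", shared$patterns)),
    autosomal_recessive = sum(grepl("autosomal_recessive", shared$patterns)),
    x_linked = sum(grepl("x_linked", shared$patterns)),
    compound_het = sum(grepl("compound_het", shared$patterns)),
    cpg = sum(shared$is_cpg_gene, na.rm = TRUE))

  gated <- filter_by_scores(shared, thresholds = list(
    sift = config$sift, polyphen2 = config$polyphen2, mcap = config$mcap))
  final <- select_acmg_candidates(gated)
  log_stage("score-gated %d, ACMG-eligible %d", nrow(gated), nrow(final))

  cls <- classify_candidates(final)
  final <- cls$candidates
  log_stage("pathogenic classifications: %d", cls$n_pathogenic)

  report <- new_funnel_report(
    counts = list(caller_a = length(calls_a), caller_b = length(calls_b),
                  consensus = length(consensus), rare = nrow(rare),
                  nonsilent = nrow(nonsilent), shared_by_affected = nrow(shared),
                  score_gated = nrow(gated), acmg_eligible = nrow(final),
                  pathogenic = cls$n_pathogenic),
    class_counts = class_counts, pattern_counts = pattern_counts)

  table2 <- data.frame(
    Chr = final$chrom, Position = final$pos, Ref = final$ref,
    Alt = final$alt,
    Variant = if (nrow(final) > 0L) paste0(final$gene, ".", final$hgvs_p)
              else character(0),
    Effect = final$effect, Evidence = final$acmg_evidence,
    Origin = final$origin, stringsAsFactors = FALSE)

  utils::write.table(final, file.path(config$out_dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(table2, file.path(config$out_dir, "summary_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  funnel_report_json(report, file.path(config$out_dir, "funnel.json"))

  structure(list(report = report, candidates = final, table2 = table2,
                 compound_het_pairs = ch$pairs,
                 n_pathogenic = cls$n_pathogenic),
            class = "prioritization_result")
}

#' @export
print.prioritization_result <- function(x, ...) {
  print(x$report)
  cat("\nFinal candidates:\n")
  print(x$table2)
  invisible(x)
}

#' Run the preranked GSEA arm
#'
#' Ranks genes by log2 fold change between the two conditions of the
#' expression matrix and computes permutation statistics for the GMT
#' collection.
#'
#' @param config A [pipeline_config()] with `expression` and `gmt` set, or a
#'   plain list with those fields plus `n_perm`, `seed`, `gsea_exponent`,
#'   `out_dir`.
#' @param case_label Condition label of the case group (default "case").
#' @param quiet Suppress logging.
#' @return List of class `gsea_run` with `ranked` and `results` (a
#'   `gsea_results` data frame); both are also written under
#'   `config$out_dir`.
#' @export
run_gsea <- function(config, case_label = "case", quiet = FALSE) {
  if (is.null(config$expression) || is.null(config$gmt))
    stop("config must provide 'expression' and 'gmt' paths")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  expr <- read_expression(config$expression)
  if (!case_label %in% expr$condition)
    stop("condition label '", case_label, "' not present in the matrix")
  sets <- read_gmt(config$gmt)
  case <- expr$mat[, expr$condition == case_label, drop = FALSE]
  ctrl <- expr$mat[, expr$condition != case_label, drop = FALSE]
  ranked <- rank_genes(case, ctrl)
  results <- permutation_stats(ranked, sets,
                               n_perm = config$n_perm %||% 1000L,
                               seed = config$seed %||% 1L,
                               exponent = config$gsea_exponent %||% 1)
  if (!quiet)
    message(sprintf("[gsea] %d genes ranked, %d sets scored; top set %s (NES %.2f, q %.3g)",
                    nrow(ranked), nrow(results), results$set[1],
                    results$nes[1], results$fdr_q[1]))
  utils::write.table(ranked, file.path(config$out_dir, "ranked_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(results, file.path(config$out_dir, "gsea_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  structure(list(ranked = ranked, results = results), class = "gsea_run")
}

#' @export
print.gsea_run <- function(x, ...) {
  cat(sprintf("<gsea_run> %d ranked gene(s), %d set(s)\n",
              nrow(x$ranked), nrow(x$results)))
  print(utils::head(x$results[, c("set", "n_hits", "es", "nes",
                                  "p_nominal", "fdr_q")], 10L))
  invisible(x)
}
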