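# Synthetic-cohort generator: toy transcript models on a toy genome, a
# quartet (two affected brothers + unaffected parents) with planted variants
# of every funnel class emitted as two caller VCFs + PED + annotation TSV +
# truth table, and two-condition expression matrices with a planted
# up-regulated pathway. Generation is a pure function of (spec, seed).

QUARTET_SAMPLES <- c("FATHER", "MOTHER", "SIB1", "SIB2")

STOP_CODONS <- c("TAA", "TAG", "TGA")

nonstop_codons <- function() {
  codons <- names(Biostrings::GENETIC_CODE)
  codons[Biostrings::GENETIC_CODE != "*"]
}

random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Planting specification for the synthetic quartet
#'
#' Per-class plant counts. The two signature plants (the maternal-dominant
#' stop-gain and the X-linked start-loss) are each limited to one per family
#' and are the only plants intended to survive the funnel; an optional
#' score-passing missense class (off by default) emulates a missense variant
#' that clears the four-score gate but lacks ACMG evidence.
#'
#' @param shared_maternal_dominant_stopgain,shared_xlinked_startloss 0 or 1.
#' @param compound_het_pairs,de_novo_singletons,ar_homozygous,common_benign,silent_shared,caller_discordant,score_passing_missense,n_background
#'   Non-negative counts.
#' @param seed Integer seed driving all randomness of the generator.
#' @return List of class `plant_spec`.
#' @export
plant_spec <- function(shared_maternal_dominant_stopgain = 1L,
                       shared_xlinked_startloss = 1L,
                       compound_het_pairs = 1L,
                       de_novo_singletons = 1L,
                       ar_homozygous = 1L,
                       common_benign = 30L,
                       silent_shared = 5L,
                       caller_discordant = 3L,
                       score_passing_missense = 0L,
                       n_background = 120L,
                       seed = 1L) {
  spec <- list(shared_maternal_dominant_stopgain =
                 as.integer(shared_maternal_dominant_stopgain),
               shared_xlinked_startloss = as.integer(shared_xlinked_startloss),
               compound_het_pairs = as.integer(compound_het_pairs),
               de_novo_singletons = as.integer(de_novo_singletons),
               ar_homozygous = as.integer(ar_homozygous),
               common_benign = as.integer(common_benign),
               silent_shared = as.integer(silent_shared),
               caller_discordant = as.integer(caller_discordant),
               score_passing_missense = as.integer(score_passing_missense),
               n_background = as.integer(n_background),
               seed = as.integer(seed))
  counts <- unlist(spec[names(spec) != "seed"])
  if (any(counts < 0L)) stop("plant counts must be non-negative")
  if (spec$shared_maternal_dominant_stopgain > 1L ||
      spec$shared_xlinked_startloss > 1L)
    stop("at most one of each signature plant per family")
  structure(spec, class = "plant_spec")
}

#' Generate toy transcript models and their reference genome
#'
#' Every gene gets a valid two-exon CDS (ATG start, stop end, length
#' divisible by 3, canonical GT/AG intron). Two designated genes reproduce
#' the worked coordinate facts hosted by the consequence annotator: an
#' autosomal gene (`APCL`, chr5) whose CDS codon spanning positions 1606-1608
#' is CGA so that c.1606C>T yields a stop at residue 536, and a chrX gene
#' (`WASL`) whose codon 6 is ATG and codon 5 is proline so that c.3G>T
#' yields a start-loss deleting residues 1-5.
#'
#' @param n_genes Number of genes (>= 2; default 8).
#' @param seed Integer seed.
#' @return List with `transcripts` (named [transcript_model()] list),
#'   `genome` (named `DNAStringSet`), and the designated gene names
#'   `stopgain_gene` ("APCL") and `startloss_gene` ("WASL").
#' @export
make_toy_genes <- function(n_genes = 8L, seed = 1L) {
  if (n_genes < 2L) stop("need at least 2 genes (one autosomal, one on chrX)")
  set.seed(as.integer(seed))
  ok <- nonstop_codons()
  chroms <- c("chr5", "chrX",
              paste0("chr", setdiff(as.character(1:22), "5")))
  if (n_genes > length(chroms)) stop("too many genes for the toy karyotype")
  gene_names <- c("APCL", "WASL",
                  sprintf("GENE%02d", seq_len(max(0L, n_genes - 2L)) + 2L))
  transcripts <- list()
  genome <- character(0)
  for (i in seq_len(n_genes)) {
    g <- gene_names[i]
    if (g == "APCL") {
      n_codons <- 560L
      codons <- sample(ok, n_codons, replace = TRUE)
      codons[1] <- "ATG"
      codons[536] <- "CGA"   # c.1606-1608; c.1606C>T -> TGA (p.R536X)
    } else if (g == "WASL") {
      n_codons <- 120L
      codons <- sample(ok, n_codons, replace = TRUE)
      codons[1] <- "ATG"
      codons[2:4][codons[2:4] == "ATG"] <- "GCA"
      codons[5] <- "CCA"     # proline at residue 5
      codons[6] <- "ATG"     # re-initiation codon -> p.M1-P5del
    } else {
      n_codons <- sample(80:200, 1L)
      codons <- sample(ok, n_codons, replace = TRUE)
      codons[1] <- "ATG"
    }
    cds <- paste(c(codons, sample(STOP_CODONS, 1L)), collapse = "")
    len <- nchar(cds)
    split_at <- sample(seq(30L, len - 30L), 1L)
    intron <- paste0("GT", random_bases(146L), "AG")
    chrom_seq <- paste0(random_bases(500L),
                        substr(cds, 1L, split_at),
                        intron,
                        substr(cds, split_at + 1L, len),
                        random_bases(500L))
    exon1 <- c(501L, 500L + split_at)
    exon2 <- c(500L + split_at + 151L, 500L + 150L + len)
    transcripts[[g]] <- transcript_model(
      gene = g, chrom = chroms[i], strand = "+",
      exon_starts = c(exon1[1], exon2[1]),
      exon_ends = c(exon1[2], exon2[2]),
      cds_start = exon1[1], cds_end = exon2[2],
      sequence = cds)
    genome[chroms[i]] <- chrom_seq
  }
  list(transcripts = transcripts,
       genome = Biostrings::DNAStringSet(genome),
       stopgain_gene = "APCL", startloss_gene = "WASL")
}

# ---- site pickers -----------------------------------------------------------

# Random coding SNV in gene t avoiding start and stop codons and previously
# used CDS positions; kind = "nonsynonymous" or "synonymous".
pick_coding_snv <- function(t, kind, used) {
  n_codons <- nchar(t$sequence) / 3L
  for (attempt in 1:500) {
    j <- sample(2:(n_codons - 1L), 1L)
    o <- sample(1:3, 1L)
    cds_pos <- 3L * (j - 1L) + o
    if (cds_pos %in% used[[t$gene]]) next
    ref_codon <- codon_at(t, j)
    ref_base <- substr(ref_codon, o, o)
    for (alt_base in sample(setdiff(c("A", "C", "G", "T"), ref_base))) {
      alt_codon <- ref_codon
      substr(alt_codon, o, o) <- alt_base
      ref_aa <- codon_aa(ref_codon)
      alt_aa <- codon_aa(alt_codon)
      if (alt_aa == "*") next
      if (kind == "nonsynonymous" && ref_aa == alt_aa) next
      if (kind == "synonymous" && ref_aa != alt_aa) next
      return(list(cds_pos = cds_pos, ref = ref_base, alt = alt_base))
    }
  }
  stop("could not place a ", kind, " SNV in gene ", t$gene)
}

# ---- genotype builders ------------------------------------------------------

# GT vector (FATHER, MOTHER, SIB1, SIB2) for a planted configuration.
plant_genotypes <- function(config, chrx = FALSE) {
  g <- switch(config,
    maternal_dominant = c("0/0", "0/1", "0/1", "0/1"),
    xlinked           = c("0",   "0/1", "1",   "1"),
    chet_maternal     = c("0/0", "0/1", "0/1", "0/1"),
    chet_paternal     = c("0/1", "0/0", "0/1", "0/1"),
    de_novo_sib1      = c("0/0", "0/0", "0/1", "0/0"),
    de_novo_sib2      = c("0/0", "0/0", "0/0", "0/1"),
    ar                = c("0/1", "0/1", "1/1", "1/1"),
    shared_het_m      = c("0/0", "0/1", "0/1", "0/1"),
    shared_het_p      = c("0/1", "0/0", "0/1", "0/1"),
    stop("unknown genotype configuration ", config))
  names(g) <- QUARTET_SAMPLES
  g
}

# Mendelian-sampled background genotypes at population frequency af.
sample_genotypes <- function(af, chrx = FALSE) {
  draw <- function(n) sample(0:1, n, replace = TRUE, prob = c(1 - af, af))
  if (!chrx) {
    f <- draw(2); m <- draw(2)
    s1 <- c(sample(f, 1L), sample(m, 1L))
    s2 <- c(sample(f, 1L), sample(m, 1L))
    g <- c(paste(f, collapse = "/"), paste(m, collapse = "/"),
           paste(s1, collapse = "/"), paste(s2, collapse = "/"))
  } else {
    f <- draw(1); m <- draw(2)
    g <- c(as.character(f), paste(m, collapse = "/"),
           as.character(sample(m, 1L)), as.character(sample(m, 1L)))
  }
  names(g) <- QUARTET_SAMPLES
  g
}

draw_failing_scores <- function(force_fail = TRUE) {
  list(sift = round(stats::rbeta(1, 2, 2), 4),
       polyphen2 = round(stats::rbeta(1, 2, 2), 4),
       mutation_taster = if (force_fail) "polymorphism" else
         sample(c("disease_causing", "polymorphism"), 1L, prob = c(0.2, 0.8)),
       mcap = round(stats::rbeta(1, 1, 40), 4))
}

draw_passing_scores <- function() {
  list(sift = round(stats::runif(1, 0, 0.05), 4),
       polyphen2 = round(stats::runif(1, 0.96, 1), 4),
       mutation_taster = "disease_causing",
       mcap = round(stats::runif(1, 0.03, 0.3), 4))
}

TABLE2_EVIDENCE <- c(
  stopgain = "PVS1, PS1, PP1-S, PM2, PP3, BP1",
  startloss = "PS1, PS3, PM2, PM4, PP3",
  passing_missense = "PM2, PP3, BP4, PM5")

# ---- quartet simulation -----------------------------------------------------

#' Simulate a quartet dataset with planted variants
#'
#' Emits two caller VCFs (caller B perturbs the representation of a subset of
#' records by padding a shared trailing reference base, which normalization
#' removes), a PED file, the annotation TSV, transcript models + FASTA, a
#' cancer-predisposition gene list, and a truth-table JSON mapping every
#' planted variant key to its intended class, origin and
#' should-survive-the-funnel flag. Genotypes of planted classes are
#' constructed (not sampled) to be Mendelian-consistent; background variants
#' are Mendelian-sampled at mixture allele frequencies with ~99% of them
#' common (>= 0.01), and background missense scores are drawn so the
#' four-score gate's background pass rate is far below 1%.
#'
#' @param spec A [plant_spec()].
#' @param genes Output of [make_toy_genes()].
#' @param out_dir Output directory (created if needed).
#' @return List with the written `paths`, the `truth` table (data frame) and
#'   the in-memory call sets.
#' @export
simulate_quartet <- function(spec, genes, out_dir = tempfile("quartet")) {
  stopifnot(inherits(spec, "plant_spec"))
  tx <- genes$transcripts
  chrx_genes <- names(tx)[vapply(tx, function(t) is_chrx(t$chrom), logical(1))]
  if (spec$shared_xlinked_startloss > 0L && length(chrx_genes) == 0L)
    stop("X-linked plant requested but no gene lies on chrX")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)

  autosomal <- setdiff(names(tx), c(genes$stopgain_gene, chrx_genes))
  used <- stats::setNames(vector("list", length(tx)), names(tx))
  rows <- list()
  add_row <- function(gene, cds_pos, ref, alt, gts, class, origin,
                      survive, af = c(NA_real_, NA_real_),
                      scores = NULL, evidence = "", callers = c("A", "B")) {
    t <- tx[[gene]]
    used[[gene]] <<- c(used[[gene]], cds_pos)
    rows[[length(rows) + 1L]] <<- c(
      list(chrom = t$chrom, pos = cds_to_genomic(t, cds_pos),
           ref = ref, alt = alt, gene = gene,
           af_kg_asian = af[1], af_exac_nontcga = af[2]),
      scores %||% list(sift = NA_real_, polyphen2 = NA_real_,
                       mutation_taster = NA_character_, mcap = NA_real_),
      list(evidence = evidence, class = class, origin = origin,
           survive = survive, callers = paste(callers, collapse = ""),
           gts = gts))
  }

  if (spec$shared_maternal_dominant_stopgain > 0L) {
    t <- tx[[genes$stopgain_gene]]
    stopifnot(codon_at(t, 536L) == "CGA")
    add_row(genes$stopgain_gene, 1606L, "C", "T",
            plant_genotypes("maternal_dominant"),
            class = "shared_maternal_dominant_stopgain", origin = "maternal",
            survive = TRUE, evidence = TABLE2_EVIDENCE[["stopgain"]])
  }
  if (spec$shared_xlinked_startloss > 0L) {
    g <- genes$startloss_gene
    stopifnot(codon_at(tx[[g]], 1L) == "ATG")
    add_row(g, 3L, "G", "T", plant_genotypes("xlinked"),
            class = "shared_xlinked_startloss", origin = "maternal",
            survive = TRUE, evidence = TABLE2_EVIDENCE[["startloss"]])
  }
  for (k in seq_len(spec$compound_het_pairs)) {
    g <- sample(autosomal, 1L)
    s1 <- pick_coding_snv(tx[[g]], "nonsynonymous", used)
    add_row(g, s1$cds_pos, s1$ref, s1$alt, plant_genotypes("chet_maternal"),
            class = "compound_het", origin = "maternal", survive = FALSE,
            scores = draw_failing_scores())
    s2 <- pick_coding_snv(tx[[g]], "nonsynonymous", used)
    add_row(g, s2$cds_pos, s2$ref, s2$alt, plant_genotypes("chet_paternal"),
            class = "compound_het", origin = "paternal", survive = FALSE,
            scores = draw_failing_scores())
  }
  for (k in seq_len(spec$de_novo_singletons)) {
    g <- sample(autosomal, 1L)
    s <- pick_coding_snv(tx[[g]], "nonsynonymous", used)
    cfg <- if (k %% 2L == 1L) "de_novo_sib1" else "de_novo_sib2"
    add_row(g, s$cds_pos, s$ref, s$alt, plant_genotypes(cfg),
            class = "de_novo", origin = "de_novo", survive = FALSE,
            scores = draw_failing_scores())
  }
  for (k in seq_len(spec$ar_homozygous)) {
    g <- sample(autosomal, 1L)
    s <- pick_coding_snv(tx[[g]], "nonsynonymous", used)
    add_row(g, s$cds_pos, s$ref, s$alt, plant_genotypes("ar"),
            class = "autosomal_recessive", origin = "both", survive = FALSE,
            scores = draw_failing_scores())
  }
  for (k in seq_len(spec$common_benign)) {
    g <- sample(autosomal, 1L)
    s <- pick_coding_snv(tx[[g]], "nonsynonymous", used)
    af <- round(stats::runif(1, 0.011, 0.5), 4)
    add_row(g, s$cds_pos, s$ref, s$alt, sample_genotypes(af),
            class = "common_benign", origin = "background", survive = FALSE,
            af = c(af, round(pmin(1, af * stats::runif(1, 0.8, 1.2)), 4)),
            scores = draw_failing_scores(force_fail = FALSE))
  }
  for (k in seq_len(spec$silent_shared)) {
    g <- sample(autosomal, 1L)
    s <- pick_coding_snv(tx[[g]], "synonymous", used)
    add_row(g, s$cds_pos, s$ref, s$alt, plant_genotypes("shared_het_m"),
            class = "silent_shared", origin = "maternal", survive = FALSE)
  }
  for (k in seq_len(spec$caller_discordant)) {
    g <- sample(autosomal, 1L)
    s <- pick_coding_snv(tx[[g]], "nonsynonymous", used)
    add_row(g, s$cds_pos, s$ref, s$alt, plant_genotypes("shared_het_m"),
            class = "caller_discordant", origin = "maternal", survive = FALSE,
            scores = draw_failing_scores(), callers = "A")
  }
  for (k in seq_len(spec$score_passing_missense)) {
    g <- sample(autosomal, 1L)
    s <- pick_coding_snv(tx[[g]], "nonsynonymous", used)
    add_row(g, s$cds_pos, s$ref, s$alt, plant_genotypes("shared_het_p"),
            class = "score_passing_missense", origin = "paternal",
            survive = TRUE, scores = draw_passing_scores(),
            evidence = TABLE2_EVIDENCE[["passing_missense"]])
  }
  for (k in seq_len(spec$n_background)) {
    g <- sample(names(tx), 1L)
    kind <- if (stats::runif(1) < 0.8) "nonsynonymous" else "synonymous"
    s <- pick_coding_snv(tx[[g]], kind, used)
    rare <- stats::runif(1) < 0.01
    af <- if (rare) round(stats::runif(1, 0, 0.009), 4)
          else round(stats::runif(1, 0.011, 0.5), 4)
    add_row(g, s$cds_pos, s$ref, s$alt,
            sample_genotypes(af, chrx = is_chrx(tx[[g]]$chrom)),
            class = "background", origin = "background", survive = FALSE,
            af = c(af, round(pmin(1, af * stats::runif(1, 0.8, 1.2)), 4)),
            scores = if (kind == "nonsynonymous")
              draw_failing_scores(force_fail = FALSE) else NULL)
  }

  # assemble tables, sorted by (chromosome order, position)
  tab <- do.call(rbind, lapply(rows, function(r)
    data.frame(chrom = r$chrom, pos = r$pos, ref = r$ref, alt = r$alt,
               gene = r$gene, af_kg_asian = r$af_kg_asian,
               af_exac_nontcga = r$af_exac_nontcga, sift = r$sift,
               polyphen2 = r$polyphen2, mutation_taster = r$mutation_taster,
               mcap = r$mcap, acmg_evidence = r$evidence, class = r$class,
               origin = r$origin, survive = r$survive, callers = r$callers,
               stringsAsFactors = FALSE)))
  gts <- do.call(rbind, lapply(rows, `[[`, "gts"))
  chrom_order <- names(genes$genome)
  ord <- order(match(tab$chrom, chrom_order), tab$pos)
  tab <- tab[ord, , drop = FALSE]
  gts <- gts[ord, , drop = FALSE]
  rownames(tab) <- NULL

  cpg_genes <- c(genes$stopgain_gene, "GENE03", "TP53L", "BRCA1L")
  tab$is_cpg_gene <- tab$gene %in% cpg_genes

  ref_lookup <- fasta_ref_lookup(genes$genome)
  mkvcf <- function(caller) {
    keep <- grepl(caller, tab$callers)
    v <- tab[keep, c("chrom", "pos", "ref", "alt"), drop = FALSE]
    v$id <- NA_character_
    g <- gts[keep, , drop = FALSE]
    if (caller == "B" && nrow(v) > 0L) {
      pad <- which(seq_len(nrow(v)) %% 5L == 0L)
      for (i in pad) {
        nxt <- ref_lookup(v$chrom[i], v$pos[i] + nchar(v$ref[i]),
                          v$pos[i] + nchar(v$ref[i]))
        v$ref[i] <- paste0(v$ref[i], nxt)
        v$alt[i] <- paste0(v$alt[i], nxt)
      }
    }
    variant_calls(v[, c("chrom", "pos", "id", "ref", "alt")], g,
                  QUARTET_SAMPLES, paste0("caller_", tolower(caller)))
  }
  calls_a <- mkvcf("A")
  calls_b <- mkvcf("B")

  paths <- list(
    vcf_a = file.path(out_dir, "caller_a.vcf"),
    vcf_b = file.path(out_dir, "caller_b.vcf"),
    ped = file.path(out_dir, "family.ped"),
    annotations = file.path(out_dir, "annotations.tsv"),
    transcripts = file.path(out_dir, "transcripts.tsv"),
    cds_fasta = file.path(out_dir, "cds.fa"),
    genome = file.path(out_dir, "genome.fa"),
    cpg_list = file.path(out_dir, "cpg_genes.txt"),
    truth = file.path(out_dir, "truth.json"))

  write_vcf(calls_a, paths$vcf_a)
  write_vcf(calls_b, paths$vcf_b)
  writeLines(c("FAM1\tFATHER\t0\t0\t1\t1",
               "FAM1\tMOTHER\t0\t0\t2\t1",
               "FAM1\tSIB1\tFATHER\tMOTHER\t1\t2",
               "FAM1\tSIB2\tFATHER\tMOTHER\t1\t2"), paths$ped)
  ann <- tab[, c(ANNOTATION_COLUMNS, "acmg_evidence")]
  utils::write.table(ann, paths$annotations, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_transcripts(tx, paths$transcripts, paths$cds_fasta)
  Biostrings::writeXStringSet(genes$genome, paths$genome)
  writeLines(cpg_genes, paths$cpg_list)

  truth <- tab[, c("chrom", "pos", "ref", "alt", "class", "origin", "survive")]
  truth$key <- variant_key(truth$chrom, truth$pos, truth$ref, truth$alt)
  truth_list <- stats::setNames(
    lapply(seq_len(nrow(truth)), function(i)
      list(class = truth$class[i], origin = truth$origin[i],
           should_survive = truth$survive[i])),
    truth$key)
  jsonlite::write_json(truth_list, paths$truth, auto_unbox = TRUE,
                       pretty = TRUE)

  list(paths = paths, truth = truth, calls_a = calls_a, calls_b = calls_b,
       genes = genes, out_dir = out_dir)
}

# ---- expression simulation --------------------------------------------------

#' Simulate a two-condition expression matrix with a planted pathway
#'
#' Log-normal baseline expression; genes of the planted set are multiplied by
#' `fold` in the case group; Gaussian noise with sd `noise_sd` is added on
#' the log2 scale. Alongside the matrix, a gene-set collection containing the
#' planted set plus size-matched random decoys is produced.
#'
#' @param n_genes Size of the gene universe (default 600).
#' @param n_per_group Samples per condition (default 4).
#' @param planted_size Genes in the planted pathway (default 50; >= 10
#'   recommended).
#' @param fold Expression fold change of the planted set in cases (default 2;
#'   1 plants no signal).
#' @param noise_sd Log2-scale noise standard deviation (default 0.25).
#' @param seed Integer seed.
#' @param n_decoys Number of size-matched decoy sets (default 11).
#' @param out_dir Optional output directory; when given, the expression TSV
#'   (two-line condition header) and GMT are written there.
#' @return List with `mat`, `condition`, `planted_set` (gene symbols),
#'   `planted_name`, `collection`, and `paths` when files were written.
#' @export
simulate_expression <- function(n_genes = 600L, n_per_group = 4L,
                                planted_size = 50L, fold = 2,
                                noise_sd = 0.25, seed = 1L,
                                n_decoys = 11L, out_dir = NULL) {
  if (planted_size > n_genes)
    stop("planted set larger than the gene universe")
  if (fold < 1) stop("fold must be >= 1 (up-regulation plants)")
  set.seed(as.integer(seed))
  genes <- sprintf("G%04d", seq_len(n_genes))
  planted <- sort(sample(genes, planted_size))
  baseline <- stats::runif(n_genes, 5, 9)       # log2 baseline per gene
  n_s <- 2L * n_per_group
  log2_expr <- matrix(rep(baseline, n_s), ncol = n_s) +
    matrix(stats::rnorm(n_genes * n_s, 0, noise_sd), ncol = n_s)
  case_cols <- seq_len(n_per_group)
  log2_expr[genes %in% planted, case_cols] <-
    log2_expr[genes %in% planted, case_cols] + log2(fold)
  mat <- round(2^log2_expr, 4)
  rownames(mat) <- genes
  colnames(mat) <- c(sprintf("CASE%d", seq_len(n_per_group)),
                     sprintf("CTRL%d", seq_len(n_per_group)))
  condition <- rep(c("case", "control"), each = n_per_group)

  sets <- c(list(PLANTED_PATHWAY = planted),
            stats::setNames(
              lapply(seq_len(n_decoys),
                     function(i) sort(sample(genes, planted_size))),
              sprintf("DECOY_%02d", seq_len(n_decoys))))
  collection <- structure(list(sets = sets, source = "synthetic"),
                          class = "gene_set_collection")
  out <- list(mat = mat, condition = condition, planted_set = planted,
              planted_name = "PLANTED_PATHWAY", collection = collection)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(expression = file.path(out_dir, "expression.tsv"),
                  gmt = file.path(out_dir, "genesets.gmt"))
    write_expression(mat, condition, paths$expression)
    write_gmt(collection, paths$gmt)
    out$paths <- paths
  }
  out
}
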