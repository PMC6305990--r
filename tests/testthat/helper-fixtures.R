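# Fixtures and independent oracles shared across the suite. All fixtures are
# built in code at test time.

# ---- quartet pedigree -------------------------------------------------------

quartet_ped <- function() {
  ped <- data.frame(
    id = c("FATHER", "MOTHER", "SIB1", "SIB2"),
    father = c(NA, NA, "FATHER", "FATHER"),
    mother = c(NA, NA, "MOTHER", "MOTHER"),
    sex = c("male", "female", "male", "male"),
    affected = c(FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# Candidate table skeleton with genotype columns (FATHER, MOTHER, SIB1, SIB2).
make_candidates <- function(chrom, pos, ref, alt, gene, category, gt,
                            ...) {
  n <- length(pos)
  df <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                   gene = gene, category = category,
                   stringsAsFactors = FALSE)
  gt <- matrix(gt, nrow = n, byrow = TRUE)
  df$gt.FATHER <- gt[, 1]; df$gt.MOTHER <- gt[, 2]
  df$gt.SIB1 <- gt[, 3]; df$gt.SIB2 <- gt[, 4]
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  df
}

# ---- tiny transcript + genome ----------------------------------------------

# Hand-built single-gene fixture: two exons, plus or minus strand, CDS given
# as codons. Returns list(t = transcript_model, genome = named character).
toy_transcript <- function(codons, strand = "+", chrom = "chrT",
                           intron_len = 20L, split_at = NULL) {
  cds <- paste(codons, collapse = "")
  len <- nchar(cds)
  if (is.null(split_at)) split_at <- len %/% 2L
  flank1 <- paste(rep("ACGTACGTAC", 3), collapse = "")  # 30 bp
  intron <- paste0("GT", paste(rep("C", intron_len - 4L), collapse = ""), "AG")
  gseq_coding <- paste0(flank1, substr(cds, 1, split_at), intron,
                        substr(cds, split_at + 1L, len), flank1)
  e1 <- c(31L, 30L + split_at)
  e2 <- c(30L + split_at + intron_len + 1L, 30L + intron_len + len)
  if (strand == "+") {
    gseq <- gseq_coding
    exons <- list(starts = c(e1[1], e2[1]), ends = c(e1[2], e2[2]))
    cds_b <- c(e1[1], e2[2])
  } else {
    # genome holds the reverse complement; exon coordinates mirror
    gl <- nchar(gseq_coding)
    gseq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(gseq_coding)))
    mirror <- function(x) gl - x + 1L
    exons <- list(starts = c(mirror(e2[2]), mirror(e1[2])),
                  ends = c(mirror(e2[1]), mirror(e1[1])))
    cds_b <- c(mirror(e2[2]), mirror(e1[1]))
  }
  t <- transcript_model(gene = "TOY", chrom = chrom, strand = strand,
                        exon_starts = exons$starts, exon_ends = exons$ends,
                        cds_start = cds_b[1], cds_end = cds_b[2],
                        sequence = cds)
  list(t = t, genome = stats::setNames(gseq, chrom))
}

# Random valid CDS of n_codons (ATG start, stop end, no internal stop).
random_codons <- function(n_codons) {
  ok <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  c("ATG", sample(ok, n_codons - 2L, replace = TRUE),
    sample(c("TAA", "TAG", "TGA"), 1L))
}

# ---- independent oracles ----------------------------------------------------

# Full-translation consequence oracle: edits the CDS string directly and
# diffs the reference vs mutant peptides.
oracle_substitution <- function(cds, cds_pos, alt_base) {
  mut <- cds
  substr(mut, cds_pos, cds_pos) <- alt_base
  tr <- function(s) {
    n <- nchar(s)
    paste(unname(Biostrings::GENETIC_CODE[
      substring(s, seq(1, n, 3), seq(3, n, 3))]), collapse = "")
  }
  p_ref <- tr(cds); p_mut <- tr(mut)
  if (p_ref == p_mut) return(list(category = "synonymous", residue = NA))
  i <- which(strsplit(p_ref, "")[[1]] != strsplit(p_mut, "")[[1]])[1]
  aa_r <- substr(p_ref, i, i); aa_m <- substr(p_mut, i, i)
  cat_ <- if (aa_m == "*") "stop_gain"
          else if (aa_r == "*") "stop_loss"
          else "nonsynonymous"
  list(category = cat_, residue = i)
}

# Oracle for start-loss re-initiation: scan all codons for the first
# downstream in-frame ATG.
oracle_next_atg <- function(cds) {
  n <- nchar(cds) / 3L
  for (k in 2:n) {
    if (substr(cds, 3 * (k - 1) + 1, 3 * k) == "ATG") return(k)
  }
  NA_integer_
}

# Brute-force leftmost-representation check for an anchored indel: TRUE when
# no equivalent representation of the same type exists at a smaller position
# within the window.
oracle_is_leftmost <- function(genome_seq, v) {
  edited <- apply_variant(genome_seq, v)
  L <- abs(nchar(v$ref) - nchar(v$alt))
  is_del <- nchar(v$ref) > nchar(v$alt)
  for (p in seq_len(v$pos - 1L)) {
    if (is_del) {
      if (p + L > nchar(genome_seq)) next
      cand <- list(pos = p, ref = substr(genome_seq, p, p + L),
                   alt = substr(genome_seq, p, p))
    } else {
      ins <- substr(edited, p + 1L, p + L)
      cand <- list(pos = p, ref = substr(genome_seq, p, p),
                   alt = paste0(substr(genome_seq, p, p), ins))
    }
    if (identical(apply_variant(genome_seq, cand), edited)) return(FALSE)
  }
  TRUE
}

# Brute-force running-sum enumeration of the weighted enrichment score
# (positive extremum wins an exact tie of maximum deviations).
oracle_es <- function(scores, hit, exponent = 1) {
  n <- length(scores)
  nh <- sum(hit)
  denom <- sum(abs(scores[hit])^exponent)
  run <- 0; hi <- -Inf; lo <- Inf
  for (i in seq_len(n)) {
    run <- run + if (hit[i]) abs(scores[i])^exponent / denom else -1 / (n - nh)
    if (run > hi) hi <- run
    if (run < lo) lo <- run
  }
  if (hi >= -lo) hi else lo
}

# Data-driven enumeration of the published ACMG combining clause table,
# independent of the engine's control flow.
oracle_acmg_class <- function(vs, s, m, p, ba, bs, bp) {
  meets <- function(req) {
    all(vapply(names(req), function(k) {
      v <- c(vs = vs, s = s, m = m, p = p)[[k]]
      r <- req[[k]]
      if (length(r) == 2L) v >= r[1] && v <= r[2] else v >= r
    }, logical(1)))
  }
  path_clauses <- list(
    Ia = list(vs = 1, s = 1), Ib = list(vs = 1, m = 2),
    Ic = list(vs = 1, m = c(1, 1), p = c(1, 1)), Id = list(vs = 1, p = 2),
    II = list(s = 2),
    IIIa = list(s = c(1, 1), m = 3),
    IIIb = list(s = c(1, 1), m = c(2, 2), p = 2),
    IIIc = list(s = c(1, 1), m = c(1, 1), p = 4))
  lp_clauses <- list(
    list(vs = 1, m = c(1, 1)), list(s = c(1, 1), m = c(1, 2)),
    list(s = c(1, 1), p = 2), list(m = 3), list(m = c(2, 2), p = 2),
    list(m = c(1, 1), p = 4))
  fired <- names(path_clauses)[vapply(path_clauses, meets, logical(1))]
  pclass <- if (length(fired) > 0) "pathogenic"
            else if (any(vapply(lp_clauses, meets, logical(1)))) "likely_pathogenic"
            else NA
  bclass <- if (ba >= 1 || bs >= 2) "benign"
            else if ((bs == 1 && bp == 1) || bp >= 2) "likely_benign"
            else NA
  if (!is.na(pclass) && !is.na(bclass)) return("uncertain_significance")
  if (!is.na(pclass)) return(pclass)
  if (!is.na(bclass)) return(bclass)
  "uncertain_significance"
}

# Evidence token list realizing given strength-level counts, using overrides
# where base codes run out.
tokens_for_counts <- function(vs = 0, s = 0, m = 0, p = 0,
                              ba = 0, bs = 0, bp = 0) {
  tok <- character()
  if (vs >= 1) tok <- c(tok, "PVS1")
  if (vs >= 2) tok <- c(tok, paste0("PS", 4, "-VS"))
  if (s > 0) tok <- c(tok, paste0("PS", seq_len(s)))
  if (m > 0) tok <- c(tok, paste0("PM", seq_len(m)))
  if (p > 0) tok <- c(tok, paste0("PP", seq_len(p)))
  if (ba >= 1) tok <- c(tok, "BA1")
  if (bs > 0) tok <- c(tok, paste0("BS", seq_len(bs)))
  if (bp > 0) tok <- c(tok, paste0("BP", seq_len(bp)))
  tok
}

# ---- VCF text fixture -------------------------------------------------------

write_vcf_text <- function(path, records, samples = c("S1")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records), path)
  path
}
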