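# Functional consequence annotation against toy transcript models:
# codon arithmetic, substitution / start-loss / indel / splice classification,
# and HGVS-style c. / p. descriptors in the one-letter dialect (stop = "X").

CONSEQUENCE_SEVERITY <- c(
  stop_gain = 1L, frameshift_indel = 2L, start_loss = 3L, splicing = 4L,
  stop_loss = 5L, nonsynonymous = 6L, inframe_indel = 7L,
  synonymous = 8L, non_coding = 9L)

NONSILENT_CATEGORIES <- c("splicing", "frameshift_indel", "nonsynonymous",
                          "stop_gain", "stop_loss", "start_loss",
                          "inframe_indel")

#' Construct a transcript model
#'
#' A minimal coding transcript: ordered non-overlapping exons on one strand,
#' genomic CDS bounds, and the spliced CDS sequence (coding strand). The CDS
#' must begin with ATG, end with a stop codon, and have length divisible by 3.
#'
#' @param gene Gene symbol.
#' @param chrom Chromosome name.
#' @param strand "+" or "-".
#' @param exon_starts,exon_ends 1-based closed genomic exon intervals, sorted.
#' @param cds_start,cds_end Genomic bounds of the coding region.
#' @param sequence Spliced CDS nucleotide string (coding strand).
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(gene, chrom, strand, exon_starts, exon_ends,
                             cds_start, cds_end, sequence) {
  stopifnot(strand %in% c("+", "-"),
            length(exon_starts) == length(exon_ends),
            all(exon_starts <= exon_ends))
  if (is.unsorted(exon_starts, strictly = TRUE) ||
      any(utils::head(exon_ends, -1L) >= utils::tail(exon_starts, -1L)))
    stop("exons must be sorted and non-overlapping")
  sequence <- toupper(sequence)
  if (nchar(sequence) %% 3L != 0L)
    stop("CDS length must be divisible by 3 for ", gene)
  if (substr(sequence, 1L, 3L) != "ATG")
    stop("CDS of ", gene, " does not begin with ATG")
  last <- substr(sequence, nchar(sequence) - 2L, nchar(sequence))
  if (!last %in% c("TAA", "TAG", "TGA"))
    stop("CDS of ", gene, " does not end with a stop codon")
  t <- structure(list(gene = gene, chrom = chrom, strand = strand,
                      exons = cbind(start = as.integer(exon_starts),
                                    end = as.integer(exon_ends)),
                      cds_start = as.integer(cds_start),
                      cds_end = as.integer(cds_end),
                      sequence = sequence),
                 class = "transcript_model")
  if (cds_genomic_length(t) != nchar(sequence))
    stop("spliced CDS sequence length disagrees with exon/CDS coordinates for ",
         gene)
  t
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s %s:%d-%d (%s), %d exon(s), CDS %d nt / %d aa\n",
              x$gene, x$chrom, x$exons[1, 1], x$exons[nrow(x$exons), 2],
              x$strand, nrow(x$exons), nchar(x$sequence),
              nchar(x$sequence) / 3L - 1L))
  invisible(x)
}

# Coding sub-intervals of each exon, clipped to the CDS bounds.
coding_intervals <- function(t) {
  s <- pmax(t$exons[, 1], t$cds_start)
  e <- pmin(t$exons[, 2], t$cds_end)
  keep <- s <= e
  cbind(start = s[keep], end = e[keep])
}

cds_genomic_length <- function(t) {
  ci <- coding_intervals(t)
  sum(ci[, 2] - ci[, 1] + 1L)
}

#' Map a genomic position into CDS coordinates
#'
#' @param t A [transcript_model()].
#' @param gpos 1-based genomic position.
#' @return 1-based CDS coordinate, or `NA` when the position is intronic or
#'   outside the coding region.
#' @export
genomic_to_cds <- function(t, gpos) {
  ci <- coding_intervals(t)
  hit <- which(gpos >= ci[, 1] & gpos <= ci[, 2])
  if (length(hit) == 0L) return(NA_integer_)
  before <- if (hit > 1L) sum(ci[seq_len(hit - 1L), 2] -
                              ci[seq_len(hit - 1L), 1] + 1L) else 0L
  plus_idx <- before + (gpos - ci[hit, 1]) + 1L
  if (t$strand == "+") as.integer(plus_idx)
  else as.integer(cds_genomic_length(t) - plus_idx + 1L)
}

#' Map a CDS coordinate back to its genomic position
#'
#' Inverse of [genomic_to_cds()].
#'
#' @param t A [transcript_model()].
#' @param cds_pos 1-based CDS coordinate.
#' @return 1-based genomic position.
#' @export
cds_to_genomic <- function(t, cds_pos) {
  n <- cds_genomic_length(t)
  if (cds_pos < 1L || cds_pos > n) stop("CDS position out of range")
  plus_idx <- if (t$strand == "+") cds_pos else n - cds_pos + 1L
  ci <- coding_intervals(t)
  lens <- ci[, 2] - ci[, 1] + 1L
  cum <- cumsum(lens)
  e <- which(plus_idx <= cum)[1]
  before <- if (e > 1L) cum[e - 1L] else 0L
  as.integer(ci[e, 1] + (plus_idx - before) - 1L)
}

#' Codon index and within-codon offset of a CDS position
#'
#' @param cds_pos 1-based CDS coordinate.
#' @param cds_length Total CDS length (for range checking); optional.
#' @return List with `codon` (1-based codon index) and `offset` (1..3).
#' @export
cds_position_to_codon <- function(cds_pos, cds_length = NULL) {
  cds_pos <- as.integer(cds_pos)
  if (cds_pos < 1L || (!is.null(cds_length) && cds_pos > cds_length))
    stop("CDS position out of range: ", cds_pos)
  list(codon = (cds_pos - 1L) %/% 3L + 1L,
       offset = (cds_pos - 1L) %% 3L + 1L)
}

codon_at <- function(t, codon_idx) {
  substr(t$sequence, 3L * (codon_idx - 1L) + 1L, 3L * codon_idx)
}

codon_aa <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) stop("not a valid codon: ", codon)
  aa
}

# One-letter protein dialect as printed in clinical reports: stop is "X".
aa_print <- function(aa) ifelse(aa == "*", "X", aa)

translate_cds <- function(seq) {
  n <- nchar(seq)
  codons <- substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
  paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
}

complement_base <- function(b) chartr("ACGTacgt", "TGCAtgca", b)

new_consequence <- function(category, hgvs_c = NA_character_,
                            hgvs_p = NA_character_, residue = NA_integer_,
                            gene = NA_character_,
                            whole_protein_loss = FALSE) {
  structure(list(category = category, hgvs_c = hgvs_c, hgvs_p = hgvs_p,
                 residue = residue, gene = gene,
                 whole_protein_loss = whole_protein_loss),
            class = "consequence")
}

#' @export
print.consequence <- function(x, ...) {
  cat(sprintf("<consequence> %s %s %s %s\n", x$gene %||% "", x$category,
              x$hgvs_c %||% "", x$hgvs_p %||% ""))
  invisible(x)
}

# Alleles of v expressed on the coding strand of t.
coding_strand_alleles <- function(t, v) {
  if (t$strand == "+") list(ref = v$ref, alt = v$alt)
  else list(ref = complement_base(v$ref), alt = complement_base(v$alt))
}

#' Classify a coding single-nucleotide substitution
#'
#' Translates the reference and mutant codon with the standard genetic code
#' and emits the category plus HGVS c./p. strings (one-letter dialect, e.g.
#' `c.1606C>T`, `p.R536X` for a CGA-to-TGA change at codon 536).
#'
#' @param t A [transcript_model()].
#' @param v SNV with `pos`, `ref`, `alt` (genomic strand).
#' @return A `consequence` object; category `non_coding` when the variant
#'   does not hit the CDS.
#' @export
classify_substitution <- function(t, v) {
  cds_pos <- genomic_to_cds(t, v$pos)
  if (is.na(cds_pos)) return(new_consequence("non_coding", gene = t$gene))
  al <- coding_strand_alleles(t, v)
  cp <- cds_position_to_codon(cds_pos, nchar(t$sequence))
  ref_codon <- codon_at(t, cp$codon)
  if (substr(ref_codon, cp$offset, cp$offset) != al$ref)
    stop(sprintf("REF disagrees with CDS of %s at c.%d", t$gene, cds_pos))
  alt_codon <- ref_codon
  substr(alt_codon, cp$offset, cp$offset) <- al$alt
  ref_aa <- codon_aa(ref_codon)
  alt_aa <- codon_aa(alt_codon)
  hgvs_c <- sprintf("c.%d%s>%s", cds_pos, al$ref, al$alt)
  category <-
    if (ref_aa == alt_aa) "synonymous"
    else if (alt_aa == "*") "stop_gain"
    else if (ref_aa == "*") "stop_loss"
    else "nonsynonymous"
  hgvs_p <- switch(category,
    synonymous = sprintf("p.%s%d=", aa_print(ref_aa), cp$codon),
    sprintf("p.%s%d%s", aa_print(ref_aa), cp$codon, aa_print(alt_aa)))
  new_consequence(category, hgvs_c, hgvs_p, residue = cp$codon, gene = t$gene)
}

#' Classify a substitution that disrupts the initiator ATG
#'
#' Models translational re-initiation: scans downstream for the next in-frame
#' ATG at codon k and reports a start-loss deleting residues 1..k-1
#' (`p.M1-<aa><k-1>del`). When no downstream in-frame ATG exists, the
#' consequence carries a whole-protein-loss flag. A substitution at CDS
#' positions 1-3 that happens to preserve ATG falls through to
#' [classify_substitution()].
#'
#' @param t A [transcript_model()].
#' @param v SNV with `pos`, `ref`, `alt` at CDS positions 1-3.
#' @return A `consequence` object.
#' @export
classify_start_loss <- function(t, v) {
  cds_pos <- genomic_to_cds(t, v$pos)
  if (is.na(cds_pos) || cds_pos > 3L)
    stop("classify_start_loss expects a variant at CDS positions 1-3")
  al <- coding_strand_alleles(t, v)
  start_codon <- codon_at(t, 1L)
  if (substr(start_codon, cds_pos, cds_pos) != al$ref)
    stop(sprintf("REF disagrees with CDS of %s at c.%d", t$gene, cds_pos))
  mutated <- start_codon
  substr(mutated, cds_pos, cds_pos) <- al$alt
  if (mutated == "ATG") return(classify_substitution(t, v))
  hgvs_c <- sprintf("c.%d%s>%s", cds_pos, al$ref, al$alt)
  n_codons <- nchar(t$sequence) / 3L
  k <- NA_integer_
  for (j in 2:(n_codons - 1L)) {
    if (codon_at(t, j) == "ATG") { k <- j; break }
  }
  if (is.na(k)) {
    return(new_consequence("start_loss", hgvs_c, "p.0",
                           residue = 1L, gene = t$gene,
                           whole_protein_loss = TRUE))
  }
  aa_last <- codon_aa(codon_at(t, k - 1L))
  new_consequence("start_loss", hgvs_c,
                  sprintf("p.M1-%s%ddel", aa_print(aa_last), k - 1L),
                  residue = c(1L, k - 1L), gene = t$gene)
}

#' Classify an insertion or deletion overlapping the CDS
#'
#' @param t A [transcript_model()].
#' @param v Indel with `pos`, `ref`, `alt` (VCF-style, anchored).
#' @return A `consequence` object: `frameshift_indel` when the length change
#'   is not a multiple of 3, `inframe_indel` otherwise, `non_coding` when the
#'   CDS is untouched.
#' @export
classify_indel <- function(t, v) {
  shift <- nchar(v$alt) - nchar(v$ref)
  if (shift == 0L) stop("classify_indel expects a length-changing variant")
  # changed reference footprint excludes the anchor base
  span <- if (nchar(v$ref) > 1L) c(v$pos + 1L, v$pos + nchar(v$ref) - 1L)
          else c(v$pos, v$pos)  # pure insertion: anchor position
  ci <- coding_intervals(t)
  in_cds <- any(span[2] >= ci[, 1] & span[1] <= ci[, 2])
  if (!in_cds) return(new_consequence("non_coding", gene = t$gene))
  cds_pos <- genomic_to_cds(t, span[1]) %||% NA_integer_
  category <- if (abs(shift) %% 3L != 0L) "frameshift_indel" else "inframe_indel"
  hgvs_c <- sprintf("c.%s%s%d",
                    ifelse(is.na(cds_pos), "?", as.character(cds_pos)),
                    ifelse(shift < 0L, "del", "ins"), abs(shift))
  cp <- if (!is.na(cds_pos)) cds_position_to_codon(cds_pos)$codon else NA_integer_
  new_consequence(category, hgvs_c, residue = cp, gene = t$gene)
}

#' Flag variants in the canonical splice window
#'
#' @param t A [transcript_model()].
#' @param v Variant with `pos`, `ref`, `alt`.
#' @param window Number of intronic bases flanking each internal exon
#'   boundary to treat as splice-disrupting (default 2, the canonical GT/AG
#'   dinucleotides).
#' @return A `consequence` of category `splicing`, or `NULL` when the variant
#'   lies outside every splice window.
#' @export
classify_splice <- function(t, v, window = 2L) {
  if (window <= 0L || nrow(t$exons) < 2L) return(NULL)
  span <- c(v$pos, v$pos + max(nchar(v$ref) - 1L, 0L))
  n_ex <- nrow(t$exons)
  donors <- t$exons[-n_ex, 2]      # intron starts at donor end + 1
  acceptors <- t$exons[-1L, 1]     # intron ends at acceptor start - 1
  windows <- rbind(cbind(donors + 1L, donors + window),
                   cbind(acceptors - window, acceptors - 1L))
  hit <- any(span[2] >= windows[, 1] & span[1] <= windows[, 2])
  # an indel spanning an exon/intron junction is also splice-disrupting
  spans_junction <- nchar(v$ref) > 1L &&
    any((span[1] <= donors & span[2] > donors) |
        (span[1] < acceptors & span[2] >= acceptors))
  if (!hit && !spans_junction) return(NULL)
  new_consequence("splicing", sprintf("c.splice(%s:%d)", t$chrom, v$pos),
                  gene = t$gene)
}

#' Classify a variant against one transcript
#'
#' Dispatcher applying the precedence splice > start-loss > substitution for
#' SNVs and splice > frameshift/inframe for indels.
#'
#' @param t A [transcript_model()].
#' @param v Variant with `pos`, `ref`, `alt`.
#' @param splice_window See [classify_splice()].
#' @return A `consequence` object.
#' @export
classify_variant <- function(t, v, splice_window = 2L) {
  sp <- classify_splice(t, v, splice_window)
  is_snv <- nchar(v$ref) == 1L && nchar(v$alt) == 1L
  if (is_snv) {
    cds_pos <- genomic_to_cds(t, v$pos)
    if (!is.na(cds_pos)) {
      if (cds_pos <= 3L) {
        al <- coding_strand_alleles(t, v)
        mutated <- codon_at(t, 1L)
        substr(mutated, cds_pos, cds_pos) <- al$alt
        if (mutated != "ATG") return(classify_start_loss(t, v))
      }
      return(classify_substitution(t, v))
    }
    if (!is.null(sp)) return(sp)
    return(new_consequence("non_coding", gene = t$gene))
  }
  if (!is.null(sp)) return(sp)
  if (nchar(v$ref) != nchar(v$alt)) return(classify_indel(t, v))
  new_consequence("non_coding", gene = t$gene)  # MNV outside scope
}

#' Annotate a candidate table with its most severe consequence
#'
#' Each variant is classified against every transcript on its chromosome and
#' the most severe category is kept (severity order: stop_gain > frameshift >
#' start_loss > splicing > stop_loss > nonsynonymous > inframe_indel >
#' synonymous > non_coding).
#'
#' @param candidates Data frame with `chrom`, `pos`, `ref`, `alt`.
#' @param transcripts List of [transcript_model()] objects.
#' @param splice_window See [classify_splice()].
#' @return `candidates` with added columns `category`, `hgvs_c`, `hgvs_p`,
#'   `residue`, `tx_gene`.
#' @export
annotate_consequences <- function(candidates, transcripts, splice_window = 2L) {
  n <- nrow(candidates)
  category <- rep("non_coding", n)
  hgvs_c <- rep(NA_character_, n)
  hgvs_p <- rep(NA_character_, n)
  residue <- rep(NA_integer_, n)
  tx_gene <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    v <- list(chrom = candidates$chrom[i], pos = candidates$pos[i],
              ref = candidates$ref[i], alt = candidates$alt[i])
    best <- NULL
    for (t in transcripts) {
      if (t$chrom != v$chrom) next
      span <- range(t$exons) + c(-splice_window, splice_window)
      if (v$pos + nchar(v$ref) - 1L < span[1] || v$pos > span[2]) next
      cons <- classify_variant(t, v, splice_window)
      if (is.null(best) ||
          CONSEQUENCE_SEVERITY[[cons$category]] <
          CONSEQUENCE_SEVERITY[[best$category]])
        best <- cons
    }
    if (!is.null(best)) {
      category[i] <- best$category
      hgvs_c[i] <- best$hgvs_c
      hgvs_p[i] <- best$hgvs_p
      residue[i] <- best$residue[1]
      tx_gene[i] <- best$gene
    }
  }
  candidates$category <- category
  candidates$hgvs_c <- hgvs_c
  candidates$hgvs_p <- hgvs_p
  candidates$residue <- residue
  candidates$tx_gene <- tx_gene
  candidates
}
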