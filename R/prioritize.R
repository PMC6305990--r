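# The prioritization funnel: rare-variant filtering, non-silent selection,
# shared-by-affected selection, cancer-predisposition-gene flagging,
# Mendelian inheritance-pattern detection (de novo / autosomal recessive /
# X-linked / compound heterozygous by transmission), and the four-score
# in-silico gate for missense variants.

DEFAULT_FREQ_SOURCES <- c("af_kg_asian", "af_exac_nontcga")

DEFAULT_SCORE_THRESHOLDS <- list(sift = 0.05, polyphen2 = 0.957,
                                 mcap = 0.025,
                                 mutation_taster = "disease_causing")

# ---- pedigree helpers -------------------------------------------------------

# The nuclear-family roles needed by trio/quartet analyses. Requires >=1
# affected member whose two parents are both in the pedigree and shared by
# every affected member.
nuclear_roles <- function(ped) {
  aff <- ped$id[ped$affected]
  if (length(aff) == 0L) stop("pedigree has no affected members")
  i <- match(aff, ped$id)
  fathers <- unique(stats::na.omit(ped$father[i]))
  mothers <- unique(stats::na.omit(ped$mother[i]))
  if (length(fathers) != 1L || length(mothers) != 1L ||
      any(is.na(ped$father[i])) || any(is.na(ped$mother[i])))
    stop("inheritance analysis needs all affected members to share both parents ",
         "present in the pedigree")
  list(affected = aff, father = fathers, mother = mothers,
       affected_sex = ped$sex[i])
}

gt_col <- function(sample) paste0("gt.", sample)

# ---- filters ----------------------------------------------------------------

#' Filter candidates to rare variants
#'
#' Keeps variants whose allele frequency is below `threshold` in every
#' configured population source; a missing frequency counts as rare (the
#' absent-from-controls convention).
#'
#' @param candidates Candidate data frame carrying the frequency columns.
#' @param threshold Frequency threshold, default 0.01 (strict `<`).
#' @param sources Column names of the population sources.
#' @return The rare subset of `candidates`.
#' @export
filter_rare <- function(candidates, threshold = 0.01,
                        sources = DEFAULT_FREQ_SOURCES) {
  stopifnot(threshold > 0, threshold <= 1)
  missing_src <- setdiff(sources, names(candidates))
  if (length(missing_src) > 0L)
    stop("unknown frequency source(s): ", paste(missing_src, collapse = ", "))
  keep <- rep(TRUE, nrow(candidates))
  for (s in sources) {
    af <- candidates[[s]]
    keep <- keep & (is.na(af) | af < threshold)
  }
  candidates[keep, , drop = FALSE]
}

#' Keep non-silent candidates
#'
#' Retains splicing, frameshift, nonsynonymous, stop-gain, stop-loss,
#' start-loss and in-frame indel consequences; drops synonymous and
#' non-coding variants.
#'
#' @param candidates Candidate data frame with a `category` column.
#' @return The non-silent subset.
#' @export
filter_nonsilent <- function(candidates) {
  if (is.null(candidates$category) || anyNA(candidates$category))
    stop("candidates must carry a consequence category; run annotate_consequences()")
  candidates[candidates$category %in% NONSILENT_CATEGORIES, , drop = FALSE]
}

#' Keep variants carried by every affected member
#'
#' @param candidates Candidate data frame with per-member `gt.<id>` columns.
#' @param ped A [read_ped()] pedigree with at least two affected members.
#' @return The shared subset (a missing genotype in an affected member drops
#'   the variant).
#' @export
shared_by_affected <- function(candidates, ped) {
  aff <- ped$id[ped$affected]
  if (length(aff) < 2L)
    stop("shared-by-affected selection needs >=2 affected members; ",
         "single-proband prioritization is out of scope")
  keep <- rep(TRUE, nrow(candidates))
  for (a in aff) {
    col <- gt_col(a)
    if (!col %in% names(candidates)) stop("no genotype column for member ", a)
    carries <- vapply(candidates[[col]], gt_carries_alt, logical(1))
    keep <- keep & !is.na(carries) & carries
  }
  candidates[keep, , drop = FALSE]
}

#' Flag cancer-predisposition genes
#'
#' Adds/overwrites the `is_cpg_gene` flag by case-insensitive symbol match;
#' removes nothing.
#'
#' @param candidates Candidate data frame with a `gene` column.
#' @param cpg_genes Character vector of cancer-predisposition gene symbols.
#' @return `candidates` with the flag set.
#' @export
annotate_cpg <- function(candidates, cpg_genes) {
  if (length(cpg_genes) == 0L) {
    warning("empty cancer-predisposition gene list; all flags FALSE")
    candidates$is_cpg_gene <- rep(FALSE, nrow(candidates))
    return(candidates)
  }
  candidates$is_cpg_gene <- toupper(candidates$gene) %in% toupper(cpg_genes)
  candidates
}

# ---- inheritance ------------------------------------------------------------

# Parental origin of the alternate allele for one candidate row.
variant_origin <- function(dose_f, dose_m, dose_children) {
  if (is.na(dose_f) || is.na(dose_m)) return("undetermined")
  f <- dose_f >= 1L
  m <- dose_m >= 1L
  if (f && m) "both"
  else if (m) "maternal"
  else if (f) "paternal"
  else if (any(dose_children >= 1L, na.rm = TRUE)) "de_novo"
  else "undetermined"
}

#' Detect Mendelian inheritance patterns
#'
#' Adds a `patterns` column (comma-joined subset of de_novo,
#' autosomal_recessive, x_linked) and an `origin` column (maternal, paternal,
#' both, de_novo, undetermined) per candidate. Patterns are assigned only when
#' all family genotypes are present; a missing parental genotype leaves the
#' pattern set empty with origin undetermined (one warning summarises such
#' rows). Compound heterozygotes are detected separately by
#' [detect_compound_het()].
#'
#' De novo requires every affected child to carry the alternate while both
#' parents are homozygous reference. Autosomal recessive requires affected
#' children homozygous alternate with both parents heterozygous, off
#' chromosome X. X-linked requires a chrX variant, affected males
#' hemizygous/homozygous alternate, a carrier mother and a reference father
#' (an affected-father transmission would be father-to-son X transmission).
#'
#' @param candidates Candidate data frame with `gt.<id>` columns.
#' @param ped A [read_ped()] pedigree forming a nuclear family.
#' @return `candidates` with `patterns` and `origin` columns.
#' @export
detect_inheritance <- function(candidates, ped) {
  roles <- nuclear_roles(ped)
  n <- nrow(candidates)
  patterns <- character(n)
  origin <- character(n)
  n_missing <- 0L
  male_affected <- roles$affected[roles$affected_sex == "male"]
  for (i in seq_len(n)) {
    gf <- candidates[[gt_col(roles$father)]][i]
    gm <- candidates[[gt_col(roles$mother)]][i]
    gc <- vapply(roles$affected, function(a) candidates[[gt_col(a)]][i], "")
    dose_f <- gt_dose(gf); dose_m <- gt_dose(gm)
    dose_c <- vapply(gc, gt_dose, integer(1))
    if (is.na(dose_f) || is.na(dose_m) || anyNA(dose_c)) {
      n_missing <- n_missing + 1L
      patterns[i] <- ""
      origin[i] <- "undetermined"
      next
    }
    chrom <- candidates$chrom[i]
    pats <- character()
    if (all(dose_c >= 1L) && dose_f == 0L && dose_m == 0L)
      pats <- c(pats, "de_novo")
    if (!is_chrx(chrom) && !is_chry(chrom) &&
        all(vapply(gc, gt_is_hom_alt, logical(1))) &&
        gt_is_het(gf) && gt_is_het(gm))
      pats <- c(pats, "autosomal_recessive")
    if (is_chrx(chrom) && length(male_affected) > 0L &&
        all(vapply(gc[roles$affected %in% male_affected],
                   function(g) gt_is_hemi(g) && gt_dose(g) >= 1L ||
                               gt_is_hom_alt(g), logical(1))) &&
        all(dose_c >= 1L) && dose_m >= 1L && dose_f == 0L)
      pats <- c(pats, "x_linked")
    patterns[i] <- paste(pats, collapse = ",")
    origin[i] <- variant_origin(dose_f, dose_m, dose_c)
  }
  if (n_missing > 0L)
    warning(n_missing, " candidate(s) with missing family genotypes: ",
            "pattern set left empty, origin undetermined")
  candidates$patterns <- patterns
  candidates$origin <- origin
  candidates
}

#' Detect compound heterozygotes by transmission phasing
#'
#' Within each gene, flags variant pairs in trans configuration: every
#' affected child heterozygous at both sites, one variant transmitted only by
#' the mother and the other only by the father. A variant carried by both
#' parents cannot be phased by transmission and is never part of a flagged
#' pair.
#'
#' @param candidates Candidate data frame with `gene`, `origin` and `gt.<id>`
#'   columns (run [detect_inheritance()] first or origins are recomputed).
#' @param ped A [read_ped()] pedigree forming a nuclear family.
#' @return List with `pairs` (data frame gene/key1/key2) and `candidates`
#'   (input with "compound_het" appended to `patterns` on flagged rows).
#' @export
detect_compound_het <- function(candidates, ped) {
  roles <- nuclear_roles(ped)
  if (is.null(candidates$origin))
    candidates <- detect_inheritance(candidates, ped)
  if (is.null(candidates$patterns)) candidates$patterns <- ""
  key <- variant_key(candidates$chrom, candidates$pos,
                     candidates$ref, candidates$alt)
  gene <- candidates$gene
  skip <- is.na(gene) | gene == ""
  if (any(skip))
    warning(sum(skip), " candidate(s) without a gene symbol skipped in ",
            "compound-heterozygote detection")
  all_children_het <- vapply(seq_len(nrow(candidates)), function(i) {
    all(vapply(roles$affected,
               function(a) gt_is_het(candidates[[gt_col(a)]][i]), logical(1)))
  }, logical(1))
  pairs <- list()
  flagged <- logical(nrow(candidates))
  for (g in unique(gene[!skip])) {
    idx <- which(gene == g & !skip & all_children_het &
                 candidates$origin %in% c("maternal", "paternal"))
    if (length(idx) < 2L) next
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      if (a >= b) next
      i <- idx[a]; j <- idx[b]
      if (candidates$origin[i] != candidates$origin[j]) {
        pairs[[length(pairs) + 1L]] <-
          data.frame(gene = g, key1 = key[i], key2 = key[j],
                     stringsAsFactors = FALSE)
        flagged[c(i, j)] <- TRUE
      }
    }
  }
  candidates$patterns[flagged] <- ifelse(
    candidates$patterns[flagged] == "", "compound_het",
    paste0(candidates$patterns[flagged], ",compound_het"))
  list(pairs = if (length(pairs)) do.call(rbind, pairs) else
         data.frame(gene = character(), key1 = character(),
                    key2 = character(), stringsAsFactors = FALSE),
       candidates = candidates)
}

# ---- score gate -------------------------------------------------------------

#' Gate missense candidates on in-silico pathogenicity scores
#'
#' Applies only to nonsynonymous candidates; every other category passes
#' through untouched (truncating, initial-codon and splicing variants are
#' retained regardless of scores). A nonsynonymous candidate is kept iff
#' SIFT <= 0.05 AND PolyPhen2 >= 0.957 AND MutationTaster is disease_causing
#' AND M-CAP > 0.025 (inclusive/strict directions as stated); a missing score
#' fails the gate.
#'
#' @param candidates Candidate data frame with score columns.
#' @param thresholds Named list overriding `sift`, `polyphen2`, `mcap`,
#'   `mutation_taster` defaults.
#' @return The gated subset.
#' @export
filter_by_scores <- function(candidates,
                             thresholds = DEFAULT_SCORE_THRESHOLDS) {
  th <- utils::modifyList(DEFAULT_SCORE_THRESHOLDS, thresholds)
  is_mis <- candidates$category == "nonsynonymous"
  pass <- !is.na(candidates$sift) & candidates$sift <= th$sift &
    !is.na(candidates$polyphen2) & candidates$polyphen2 >= th$polyphen2 &
    !is.na(candidates$mutation_taster) &
    candidates$mutation_taster == th$mutation_taster &
    !is.na(candidates$mcap) & candidates$mcap > th$mcap
  candidates[!is_mis | pass, , drop = FALSE]
}

#' Select the ACMG-eligible final candidate set
#'
#' The funnel routes stop-gain, initial-codon (start-loss) and score-passing
#' missense variants into ACMG evaluation; run after [filter_by_scores()].
#'
#' @param candidates Gated candidate data frame.
#' @return The subset with category in {stop_gain, start_loss, nonsynonymous}.
#' @export
select_acmg_candidates <- function(candidates) {
  candidates[candidates$category %in%
               c("stop_gain", "start_loss", "nonsynonymous"), , drop = FALSE]
}

# ---- funnel report ----------------------------------------------------------

new_funnel_report <- function(counts, class_counts, pattern_counts) {
  structure(list(counts = counts, class_counts = class_counts,
                 pattern_counts = pattern_counts),
            class = "funnel_report")
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("Variant prioritization funnel\n")
  for (nm in names(x$counts))
    cat(sprintf("  %-28s %6d\n", nm, x$counts[[nm]]))
  cat("  non-silent classes:",
      paste(sprintf("%s=%d", names(x$class_counts), x$class_counts),
            collapse = ", "), "\n")
  cat("  inheritance patterns:",
      paste(sprintf("%s=%d", names(x$pattern_counts), x$pattern_counts),
            collapse = ", "), "\n")
  invisible(x)
}

funnel_report_json <- function(report, path) {
  jsonlite::write_json(list(counts = report$counts,
                            class_counts = as.list(report$class_counts),
                            pattern_counts = as.list(report$pattern_counts)),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
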