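# Small internal helpers shared across modules.

`%||%` <- function(a, b) {
  if (is.null(a) || length(a) == 0L) b else a
}

#' Split a genotype string into allele indices
#'
#' Accepts diploid ("0/1", "1|0"), hemizygous ("1") and missing ("./.", ".")
#' genotype strings. Phase separators are ignored: genotypes are always
#' treated as unphased on input.
#'
#' @param gt A single genotype string.
#' @return Integer vector of allele indices (length 1 for hemizygous calls),
#'   with `NA` for missing alleles.
#' @keywords internal
gt_alleles <- function(gt) {
  if (is.na(gt) || gt == "" || gt == ".") return(NA_integer_)
  parts <- strsplit(gt, "[/|]")[[1]]
  suppressWarnings(as.integer(ifelse(parts == ".", NA, parts)))
}

# Number of alternate alleles carried (NA if any allele missing).
gt_dose <- function(gt) {
  a <- gt_alleles(gt)
  if (any(is.na(a))) return(NA_integer_)
  sum(a)
}

gt_is_missing <- function(gt) any(is.na(gt_alleles(gt)))

gt_is_het <- function(gt) {
  a <- gt_alleles(gt)
  length(a) == 2L && !any(is.na(a)) && sum(a) == 1L
}

gt_is_hom_alt <- function(gt) {
  a <- gt_alleles(gt)
  length(a) == 2L && !any(is.na(a)) && all(a == 1L)
}

gt_is_hemi <- function(gt) {
  a <- gt_alleles(gt)
  length(a) == 1L && !is.na(a)
}

# TRUE when the sample carries at least one alternate allele; NA if missing.
gt_carries_alt <- function(gt) {
  d <- gt_dose(gt)
  if (is.na(d)) NA else d >= 1L
}

is_chrx <- function(chrom) toupper(sub("^chr", "", chrom, ignore.case = TRUE)) == "X"
is_chry <- function(chrom) toupper(sub("^chr", "", chrom, ignore.case = TRUE)) == "Y"

# Deterministic integer sub-seed derivation, kept well below .Machine$integer.max.
derive_seed <- function(seed, k) {
  (as.integer(seed) * 1103L + as.integer(k) * 12289L) %% 2147480000L
}
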