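# Variant container, allele normalization and dual-caller consensus.
#
# A variant call set is the in-memory image of one caller's multi-sample VCF
# after multiallelic splitting: a data frame of normalized-or-raw alternate
# alleles plus a genotype matrix (records x samples) of GT strings.

#' Construct a variant call set
#'
#' @param variants Data frame with columns `chrom`, `pos` (1-based integer),
#'   `id`, `ref`, `alt` — one row per alternate allele.
#' @param gt Character matrix of GT strings, `nrow(variants)` rows, one column
#'   per sample.
#' @param samples Character vector of sample identifiers (column order of `gt`).
#' @param caller Free-text tag naming the originating caller.
#' @return An object of class `variant_calls`.
#' @export
variant_calls <- function(variants, gt, samples, caller = "caller") {
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos", "id", "ref", "alt") %in% names(variants)))
  gt <- as.matrix(gt)
  if (nrow(variants) > 0L && nrow(gt) != nrow(variants))
    stop("genotype matrix must have one row per variant record")
  if (ncol(gt) != length(samples) && nrow(variants) > 0L)
    stop("genotype matrix must have one column per sample")
  colnames(gt) <- samples
  variants$pos <- as.integer(variants$pos)
  rownames(variants) <- NULL
  structure(list(variants = variants, gt = gt,
                 samples = samples, caller = caller),
            class = "variant_calls")
}

#' @export
print.variant_calls <- function(x, ...) {
  cat(sprintf("<variant_calls> %d record(s), %d sample(s) [%s]\n",
              nrow(x$variants), length(x$samples), x$caller))
  if (nrow(x$variants) > 0L)
    print(utils::head(cbind(x$variants, x$gt), 10L))
  invisible(x)
}

#' @export
length.variant_calls <- function(x) nrow(x$variants)

#' Canonical variant key
#'
#' @param chrom,pos,ref,alt Vectors describing normalized alternate alleles.
#' @return Character vector `"chrom:pos:ref:alt"`.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

calls_keys <- function(vc) {
  with(vc$variants, variant_key(chrom, pos, ref, alt))
}

#' Build a reference-base lookup from a genome
#'
#' @param genome A named `Biostrings::DNAStringSet` (or named character vector
#'   of chromosome sequences).
#' @return A function `f(chrom, start, end)` returning the uppercase reference
#'   bases on the closed 1-based interval.
#' @export
fasta_ref_lookup <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  nm <- names(genome)
  function(chrom, start, end) {
    i <- match(chrom, nm)
    if (is.na(i)) stop("chromosome not in reference: ", chrom)
    if (start < 1L || end > length(genome[[i]]))
      stop("reference lookup out of bounds on ", chrom)
    toupper(as.character(Biostrings::subseq(genome[[i]], start, end)))
  }
}

#' Normalize one alternate allele to its minimal left-aligned representation
#'
#' Trailing bases shared by REF and ALT are trimmed; emptied alleles are
#' left-extended with reference bases (left alignment of indels); finally
#' leading shared bases are trimmed while both alleles remain longer than one
#' base. The operation is idempotent and preserves the edited haplotype.
#'
#' @param v List or one-row data frame with `chrom`, `pos`, `ref`, `alt`
#'   (and optionally `id`).
#' @param ref_lookup Function `(chrom, start, end) -> bases`, e.g. from
#'   [fasta_ref_lookup()]. Used to verify REF against the reference and to
#'   left-extend during alignment.
#' @return List with fields `chrom`, `pos`, `ref`, `alt`, `id`.
#' @export
normalize_variant <- function(v, ref_lookup) {
  chrom <- as.character(v$chrom)
  pos <- as.integer(v$pos)
  ref <- toupper(as.character(v$ref))
  alt <- toupper(as.character(v$alt))
  if (nchar(ref) == 0L || nchar(alt) == 0L)
    stop("REF and ALT must be non-empty base strings")
  if (ref == alt) stop("REF and ALT are identical at ", chrom, ":", pos)
  obs <- ref_lookup(chrom, pos, pos + nchar(ref) - 1L)
  if (!identical(obs, ref))
    stop(sprintf("REF mismatch at %s:%d: record has '%s', reference has '%s'",
                 chrom, pos, ref, obs))
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    if (nr > 0L && na > 0L &&
        substr(ref, nr, nr) == substr(alt, na, na) &&
        !(nr == 1L && na == 1L)) {
      ref <- substr(ref, 1L, nr - 1L)
      alt <- substr(alt, 1L, na - 1L)
    } else if (nr == 0L || na == 0L) {
      if (pos <= 1L)
        stop("cannot left-extend past the start of contig ", chrom)
      b <- ref_lookup(chrom, pos - 1L, pos - 1L)
      ref <- paste0(b, ref)
      alt <- paste0(b, alt)
      pos <- pos - 1L
    } else break
  }
  while (nchar(ref) >= 2L && nchar(alt) >= 2L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(chrom = chrom, pos = pos, ref = ref, alt = alt,
       id = as.character(v$id %||% NA_character_))
}

#' Normalize every record of a call set
#'
#' @param vc A `variant_calls` object.
#' @param ref_lookup See [normalize_variant()].
#' @return A `variant_calls` object with normalized records, re-sorted by
#'   (chrom, pos, ref, alt) within the original chromosome order.
#' @export
normalize_calls <- function(vc, ref_lookup) {
  stopifnot(inherits(vc, "variant_calls"))
  if (nrow(vc$variants) == 0L) return(vc)
  out <- vc$variants
  for (i in seq_len(nrow(out))) {
    n <- normalize_variant(out[i, ], ref_lookup)
    out$pos[i] <- n$pos
    out$ref[i] <- n$ref
    out$alt[i] <- n$alt
  }
  ord <- order(match(out$chrom, unique(out$chrom)), out$pos, out$ref, out$alt)
  variant_calls(out[ord, , drop = FALSE],
                vc$gt[ord, , drop = FALSE], vc$samples, vc$caller)
}

# A record still carrying a shared trailing base is not normalized.
has_shared_trailing_base <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  !(nr == 1L & na == 1L) &
    substr(ref, nr, nr) == substr(alt, na, na)
}

#' Intersect two callers' variant sets
#'
#' Keeps records whose normalized (chrom, pos, ref, alt) key occurs in both
#' call sets. Genotypes are taken from the first caller; a warning is issued
#' when the two callers disagree on any genotype of a jointly detected record.
#'
#' @param calls_a,calls_b `variant_calls` objects, already normalized
#'   (records with a shared trailing REF/ALT base are rejected).
#' @return A `variant_calls` object (subset of `calls_a`).
#' @export
consensus_intersect <- function(calls_a, calls_b) {
  stopifnot(inherits(calls_a, "variant_calls"),
            inherits(calls_b, "variant_calls"))
  for (vc in list(calls_a, calls_b)) {
    if (nrow(vc$variants) > 0L &&
        any(has_shared_trailing_base(vc$variants$ref, vc$variants$alt)))
      stop("input contains un-normalized records (shared trailing base); ",
           "run normalize_calls() first")
  }
  ka <- calls_keys(calls_a)
  kb <- calls_keys(calls_b)
  keep <- ka %in% kb
  common <- intersect(calls_a$samples, calls_b$samples)
  if (length(common) > 0L && any(keep)) {
    ia <- which(keep)
    ib <- match(ka[keep], kb)
    ga <- calls_a$gt[ia, common, drop = FALSE]
    gb <- calls_b$gt[ib, common, drop = FALSE]
    ndis <- sum(ga != gb, na.rm = TRUE)
    if (ndis > 0L)
      warning(sprintf(
        "callers disagree on %d genotype(s) of jointly detected records; keeping '%s'",
        ndis, calls_a$caller))
  }
  variant_calls(calls_a$variants[keep, , drop = FALSE],
                calls_a$gt[keep, , drop = FALSE],
                calls_a$samples,
                caller = paste0(calls_a$caller, "&", calls_b$caller))
}

#' Apply a variant to a reference sequence
#'
#' Utility for haplotype-equivalence checks: splice the alternate allele into
#' the reference string at the variant position.
#'
#' @param seq Reference sequence (character scalar) whose first base is
#'   coordinate `offset`.
#' @param v List with `pos`, `ref`, `alt`.
#' @param offset 1-based coordinate of the first base of `seq` (default 1).
#' @return The edited sequence.
#' @export
apply_variant <- function(seq, v, offset = 1L) {
  p <- as.integer(v$pos) - as.integer(offset) + 1L
  r <- as.character(v$ref)
  if (p < 1L || p + nchar(r) - 1L > nchar(seq))
    stop("variant does not fit in the supplied sequence window")
  if (substr(seq, p, p + nchar(r) - 1L) != r)
    stop("REF does not match the supplied sequence")
  paste0(substr(seq, 1L, p - 1L), v$alt,
         substr(seq, p + nchar(r), nchar(seq)))
}
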