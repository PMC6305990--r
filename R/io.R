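# Readers and writers for the file formats the pipeline touches:
# VCF 4.x (via vcfR), 6-column PED, GMT gene sets, the annotation TSV,
# transcript model TSV + CDS FASTA, and the two-condition expression TSV.

#' Read a multi-sample VCF into a variant call set
#'
#' Multiallelic records are split into one record per alternate allele before
#' any downstream use; per-sample genotype indices are remapped per split
#' allele (the tracked allele becomes index 1, reference stays 0, and any
#' other alternate at the same site is folded into 0 with a message). Phased
#' separators are normalized to "/": genotypes are treated as unphased.
#'
#' @param path Path to an uncompressed VCF 4.x file with at least one sample
#'   column.
#' @param caller_tag Tag recorded on the returned object (e.g. the caller
#'   name).
#' @return A [variant_calls()] object.
#' @export
read_vcf <- function(path, caller_tag = basename(path)) {
  lines <- readLines(path)
  hdr_i <- grep("^#CHROM\t", lines)
  if (length(hdr_i) != 1L)
    stop("malformed VCF '", path, "': expected exactly one #CHROM header line")
  hdr <- strsplit(lines[hdr_i], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 10L)
    stop("VCF '", path, "' has no sample columns (need FORMAT plus >=1 sample)")
  samples <- hdr[-(1:9)]
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(hdr))
      stop(sprintf("malformed VCF record at line %d of '%s': %d fields, expected %d",
                   i, path, length(f), length(hdr)))
    if (is.na(suppressWarnings(as.integer(f[2]))))
      stop(sprintf("malformed VCF record at line %d of '%s': POS is not an integer", i, path))
  }
  if (length(body) == 0L) {
    warning("VCF '", path, "' contains no variant records")
    empty <- data.frame(chrom = character(), pos = integer(), id = character(),
                        ref = character(), alt = character(),
                        stringsAsFactors = FALSE)
    return(variant_calls(empty, matrix(character(), 0L, length(samples)),
                         samples, caller_tag))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt_raw)))
    gt_raw <- matrix(gt_raw, nrow = nrow(fix), ncol = length(samples))
  gt_raw[is.na(gt_raw)] <- "./."
  gt_raw <- gsub("|", "/", gt_raw, fixed = TRUE)

  rows <- list(); gts <- list(); k <- 0L; folded <- 0L
  for (r in seq_len(nrow(fix))) {
    alts <- strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1]]
    for (i in seq_along(alts)) {
      if (alts[i] == "." || alts[i] == "") next
      k <- k + 1L
      rows[[k]] <- data.frame(
        chrom = fix[r, "CHROM"], pos = as.integer(fix[r, "POS"]),
        id = ifelse(is.na(fix[r, "ID"]) || fix[r, "ID"] == ".",
                    NA_character_, fix[r, "ID"]),
        ref = toupper(fix[r, "REF"]), alt = toupper(alts[i]),
        stringsAsFactors = FALSE)
      g <- gt_raw[r, ]
      if (length(alts) > 1L) {
        g <- vapply(g, function(s) {
          a <- strsplit(s, "/", fixed = TRUE)[[1]]
          mapped <- vapply(a, function(x) {
            if (x == ".") return(".")
            xi <- as.integer(x)
            if (xi == i) "1" else {
              if (xi != 0L) folded <<- folded + 1L
              "0"
            }
          }, character(1))
          paste(mapped, collapse = "/")
        }, character(1), USE.NAMES = FALSE)
      }
      gts[[k]] <- g
    }
  }
  if (folded > 0L)
    message(folded, " genotype allele(s) pointing at a non-tracked alternate ",
            "were folded to 0 during multiallelic splitting")
  variants <- do.call(rbind, rows)
  gt <- do.call(rbind, gts)
  colnames(gt) <- samples
  variant_calls(variants, gt, samples, caller_tag)
}

#' Write a variant call set as VCF 4.2
#'
#' @param vc A [variant_calls()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vc, path) {
  stopifnot(inherits(vc, "variant_calls"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", vc$samples), collapse = "\t")), con)
  if (nrow(vc$variants) > 0L) {
    id <- ifelse(is.na(vc$variants$id), ".", vc$variants$id)
    body <- paste(vc$variants$chrom, vc$variants$pos, id,
                  vc$variants$ref, vc$variants$alt,
                  ".", ".", ".", "GT",
                  apply(vc$gt, 1L, paste, collapse = "\t"),
                  sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a 6-column PED pedigree file
#'
#' Columns: family, individual, father (0 = none), mother (0 = none),
#' sex (1 = male, 2 = female), phenotype (2 = affected). Parent identifiers
#' must resolve within the file; cyclic parentage is rejected.
#'
#' @param path Path to a whitespace-delimited PED file.
#' @return A data frame of class `pedigree` with columns `id`, `father`,
#'   `mother`, `sex` ("male"/"female") and `affected` (logical).
#' @export
read_ped <- function(path) {
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#",
                           col.names = c("family", "id", "father", "mother",
                                         "sex", "phenotype"))
  ped <- data.frame(
    id = as.character(raw$id),
    father = ifelse(raw$father %in% c("0", 0), NA_character_,
                    as.character(raw$father)),
    mother = ifelse(raw$mother %in% c("0", 0), NA_character_,
                    as.character(raw$mother)),
    sex = c("male", "female")[match(raw$sex, c(1, 2))],
    affected = raw$phenotype == 2,
    stringsAsFactors = FALSE)
  if (anyDuplicated(ped$id)) stop("duplicate individual ids in PED")
  for (p in stats::na.omit(c(ped$father, ped$mother)))
    if (!p %in% ped$id) stop("unknown parent id in PED: ", p)
  # cycle check: walking parent links must terminate for every member
  for (id in ped$id) {
    seen <- character()
    frontier <- id
    while (length(frontier) > 0L) {
      if (any(frontier %in% seen))
        stop("cyclic parentage in PED involving ", id)
      seen <- c(seen, frontier)
      i <- match(frontier, ped$id)
      frontier <- stats::na.omit(c(ped$father[i], ped$mother[i]))
      if (length(seen) > 2L * nrow(ped) + 2L)
        stop("cyclic parentage in PED involving ", id)
    }
  }
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("<pedigree> %d member(s), %d affected\n",
              nrow(x), sum(x$affected)))
  NextMethod()
}

#' Read gene sets in GMT format
#'
#' @param path Path to a tab-separated GMT file (name, description, genes...).
#' @param source_tag Free-text provenance tag stored on the collection.
#' @return A list of class `gene_set_collection` with elements `sets`
#'   (named list of unique uppercased gene symbols, input order preserved)
#'   and `source`.
#' @export
read_gmt <- function(path, source_tag = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("GMT file '", path, "' contains no gene sets")
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d has %d field(s); need name, description and >=1 gene",
                   i, length(f)))
    genes <- unique(toupper(f[-(1:2)]))
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L)
      stop(sprintf("GMT line %d defines an empty gene set", i))
    sets[[f[1]]] <- genes
  }
  structure(list(sets = sets, source = source_tag),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d set(s) [%s]; sizes %s\n",
              length(x$sets), x$source,
              paste(range(lengths(x$sets)), collapse = "-")))
  invisible(x)
}

ANNOTATION_COLUMNS <- c("chrom", "pos", "ref", "alt", "gene",
                        "af_kg_asian", "af_exac_nontcga",
                        "sift", "polyphen2", "mutation_taster", "mcap",
                        "is_cpg_gene")

#' Read the per-variant annotation table
#'
#' Tab-separated with a header naming at least the documented columns
#' (chrom, pos, ref, alt, gene, af_kg_asian, af_exac_nontcga, sift,
#' polyphen2, mutation_taster, mcap, is_cpg_gene). Extra columns (e.g.
#' `acmg_evidence`) are carried through.
#'
#' @param path Path to the TSV file.
#' @return Data frame keyed by (chrom, pos, ref, alt).
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  missing_cols <- setdiff(ANNOTATION_COLUMNS, names(ann))
  if (length(missing_cols) > 0L)
    stop("annotation table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in c("af_kg_asian", "af_exac_nontcga", "sift", "polyphen2", "mcap")) {
    x <- ann[[col]]
    if (any(!is.na(x) & (x < 0 | x > 1)))
      stop("annotation column '", col, "' has values outside [0, 1]")
  }
  ann$pos <- as.integer(ann$pos)
  ann$is_cpg_gene <- as.logical(ann$is_cpg_gene)
  ann
}

#' Read a cancer-predisposition gene list
#'
#' @param path Plain-text file, one gene symbol per line.
#' @return Character vector of symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read transcript models from a TSV plus a CDS FASTA
#'
#' The TSV has columns gene, chrom, strand, exon_starts, exon_ends
#' (comma-joined 1-based closed intervals), cds_start, cds_end. The FASTA
#' holds the spliced CDS sequence of each gene, keyed by gene symbol.
#'
#' @param tsv_path,fasta_path Input paths.
#' @return Named list of [transcript_model()] objects.
#' @export
read_transcripts <- function(tsv_path, fasta_path) {
  tab <- utils::read.delim(tsv_path, stringsAsFactors = FALSE)
  cds <- Biostrings::readDNAStringSet(fasta_path)
  models <- list()
  for (i in seq_len(nrow(tab))) {
    g <- tab$gene[i]
    if (!g %in% names(cds)) stop("no CDS sequence for gene ", g)
    models[[g]] <- transcript_model(
      gene = g, chrom = tab$chrom[i], strand = tab$strand[i],
      exon_starts = as.integer(strsplit(tab$exon_starts[i], ",")[[1]]),
      exon_ends = as.integer(strsplit(tab$exon_ends[i], ",")[[1]]),
      cds_start = as.integer(tab$cds_start[i]),
      cds_end = as.integer(tab$cds_end[i]),
      sequence = toupper(as.character(cds[[g]])))
  }
  models
}

write_transcripts <- function(models, tsv_path, fasta_path) {
  tab <- do.call(rbind, lapply(models, function(t) {
    data.frame(gene = t$gene, chrom = t$chrom, strand = t$strand,
               exon_starts = paste(t$exons[, 1], collapse = ","),
               exon_ends = paste(t$exons[, 2], collapse = ","),
               cds_start = t$cds_start, cds_end = t$cds_end,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  seqs <- Biostrings::DNAStringSet(vapply(models, `[[`, "", "sequence"))
  names(seqs) <- vapply(models, `[[`, "", "gene")
  Biostrings::writeXStringSet(seqs, fasta_path)
  invisible(tsv_path)
}

#' Read a two-condition expression matrix
#'
#' Tab-separated, genes in rows. The first header line names the samples; the
#' second line (first field `condition`) assigns each sample to a condition
#' label (e.g. case/control).
#'
#' @param path Path to the TSV file.
#' @return List with `mat` (numeric matrix, genes x samples) and `condition`
#'   (character vector along the columns).
#' @export
read_expression <- function(path) {
  lines <- readLines(path, n = 2L)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  cond <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  if (cond[1] != "condition")
    stop("expression matrix must carry a second 'condition' header line")
  tab <- utils::read.delim(path, skip = 2L, header = FALSE,
                           stringsAsFactors = FALSE)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- toupper(tab[[1]])
  colnames(mat) <- hdr[-1]
  list(mat = mat, condition = cond[-1])
}

write_expression <- function(mat, condition, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene", colnames(mat)), collapse = "\t"), con)
  writeLines(paste(c("condition", condition), collapse = "\t"), con)
  utils::write.table(data.frame(rownames(mat), mat, check.names = FALSE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$source, collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
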