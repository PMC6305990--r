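# Consequence annotation: codon arithmetic, substitution / start-loss /
# indel / splice classification, strand symmetry.

test_that("CDS position maps to codon index and offset", {
  expect_equal(cds_position_to_codon(1606), list(codon = 536L, offset = 1L))
  expect_equal(cds_position_to_codon(3), list(codon = 1L, offset = 3L))
  expect_equal(cds_position_to_codon(1), list(codon = 1L, offset = 1L))
  expect_error(cds_position_to_codon(0), "out of range")
  expect_error(cds_position_to_codon(10, cds_length = 9), "out of range")
  # round-trip: 3(c-1)+o recovers the input position
  for (pos in sample.int(3000, 200)) {
    cp <- cds_position_to_codon(pos)
    expect_equal(3L * (cp$codon - 1L) + cp$offset, pos)
  }
})

test_that("c.1606C>T on a CGA codon at 1606-1608 is a stop-gain at residue 536", {
  set.seed(11)
  codons <- random_codons(540)
  codons[536] <- "CGA"
  fx <- toy_transcript(codons)
  gpos <- cds_to_genomic(fx$t, 1606L)
  cons <- classify_substitution(fx$t, list(pos = gpos, ref = "C", alt = "T"))
  expect_equal(cons$category, "stop_gain")
  expect_equal(cons$residue, 536L)
  expect_equal(cons$hgvs_c, "c.1606C>T")
  expect_equal(cons$hgvs_p, "p.R536X")
})

test_that("third-base substitutions in degenerate codons are synonymous", {
  set.seed(12)
  codons <- random_codons(20)
  codons[7] <- "GCT"  # Ala, fourfold degenerate
  fx <- toy_transcript(codons)
  gpos <- cds_to_genomic(fx$t, 21L)  # third base of codon 7
  cons <- classify_substitution(fx$t, list(pos = gpos, ref = "T", alt = "C"))
  expect_equal(cons$category, "synonymous")
  expect_equal(cons$hgvs_p, "p.A7=")
})

test_that("substitution classification agrees with a full-translation oracle", {
  set.seed(13)
  for (rep in 1:40) {
    codons <- random_codons(sample(10:60, 1))
    strand <- sample(c("+", "-"), 1)
    fx <- toy_transcript(codons, strand = strand)
    cds <- fx$t$sequence
    for (k in 1:10) {
      cds_pos <- sample(4:(nchar(cds) - 3L), 1)  # skip start & stop codons
      ref_base <- substr(cds, cds_pos, cds_pos)
      alt_base <- sample(setdiff(c("A", "C", "G", "T"), ref_base), 1)
      gpos <- cds_to_genomic(fx$t, cds_pos)
      gref <- if (strand == "+") ref_base else
        chartr("ACGT", "TGCA", ref_base)
      galt <- if (strand == "+") alt_base else
        chartr("ACGT", "TGCA", alt_base)
      cons <- classify_substitution(fx$t, list(pos = gpos, ref = gref,
                                               alt = galt))
      orc <- oracle_substitution(cds, cds_pos, alt_base)
      expect_equal(cons$category, orc$category)
      if (cons$category != "synonymous")
        expect_equal(cons$residue, orc$residue)
    }
  }
})

test_that("minus-strand transcripts match their plus-strand equivalents", {
  set.seed(14)
  codons <- random_codons(30)
  fxp <- toy_transcript(codons, strand = "+")
  fxm <- toy_transcript(codons, strand = "-")
  for (cds_pos in c(5L, 17L, 40L, 61L)) {
    ref_base <- substr(fxp$t$sequence, cds_pos, cds_pos)
    alt_base <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
    cp <- classify_substitution(fxp$t, list(pos = cds_to_genomic(fxp$t, cds_pos),
                                            ref = ref_base, alt = alt_base))
    cm <- classify_substitution(fxm$t, list(pos = cds_to_genomic(fxm$t, cds_pos),
                                            ref = chartr("ACGT", "TGCA", ref_base),
                                            alt = chartr("ACGT", "TGCA", alt_base)))
    expect_equal(cm$category, cp$category)
    expect_equal(cm$hgvs_c, cp$hgvs_c)
    expect_equal(cm$hgvs_p, cp$hgvs_p)
  }
})

test_that("start-loss with downstream re-initiation deletes residues 1..k-1", {
  set.seed(15)
  codons <- random_codons(50)
  codons[2:5][codons[2:5] == "ATG"] <- "GCA"
  codons[5] <- "CCA"  # proline at residue 5
  codons[6] <- "ATG"
  fx <- toy_transcript(codons)
  gpos <- cds_to_genomic(fx$t, 3L)
  cons <- classify_start_loss(fx$t, list(pos = gpos, ref = "G", alt = "T"))
  expect_equal(cons$category, "start_loss")
  expect_equal(cons$hgvs_c, "c.3G>T")
  expect_equal(cons$hgvs_p, "p.M1-P5del")
  expect_equal(cons$residue, c(1L, 5L))
  expect_false(cons$whole_protein_loss)
  # deletion count equals oracle-scanned next in-frame ATG minus one
  k <- oracle_next_atg(fx$t$sequence)
  expect_equal(cons$residue[2], k - 1L)

  # c.3G>A (ATG -> ATA) also destroys the start
  cons2 <- classify_start_loss(fx$t, list(pos = gpos, ref = "G", alt = "A"))
  expect_equal(cons2$category, "start_loss")
})

test_that("start loss with no downstream in-frame ATG flags whole-protein loss", {
  set.seed(16)
  repeat {
    codons <- random_codons(30)
    codons[codons == "ATG"] <- "GCA"
    codons[1] <- "ATG"
    if (is.na(oracle_next_atg(paste(codons, collapse = "")))) break
  }
  fx <- toy_transcript(codons)
  cons <- classify_start_loss(fx$t, list(pos = cds_to_genomic(fx$t, 3L),
                                         ref = "G", alt = "T"))
  expect_equal(cons$category, "start_loss")
  expect_true(cons$whole_protein_loss)
})

test_that("random start-codon disruptions match the re-initiation oracle", {
  set.seed(17)
  for (rep in 1:25) {
    codons <- random_codons(sample(10:80, 1))
    fx <- toy_transcript(codons)
    cds_pos <- sample(1:3, 1)
    ref_base <- substr("ATG", cds_pos, cds_pos)
    alt_base <- sample(setdiff(c("A", "C", "G", "T"), ref_base), 1)
    mutated <- "ATG"; substr(mutated, cds_pos, cds_pos) <- alt_base
    if (mutated == "ATG") next
    cons <- classify_start_loss(fx$t, list(pos = cds_to_genomic(fx$t, cds_pos),
                                           ref = ref_base, alt = alt_base))
    k <- oracle_next_atg(fx$t$sequence)
    if (is.na(k)) {
      expect_true(cons$whole_protein_loss)
    } else {
      expect_equal(cons$residue[2], k - 1L)
    }
  }
})

test_that("indels classify by frame shift of the length change", {
  set.seed(18)
  fx <- toy_transcript(random_codons(30))
  g <- cds_to_genomic(fx$t, 10L)
  base <- function(p) substr(fx$genome, p, p)
  del1 <- list(pos = g, ref = paste0(base(g), base(g + 1L)), alt = base(g))
  expect_equal(classify_indel(fx$t, del1)$category, "frameshift_indel")
  del3 <- list(pos = g,
               ref = substr(fx$genome, g, g + 3L), alt = base(g))
  expect_equal(classify_indel(fx$t, del3)$category, "inframe_indel")
  ins4 <- list(pos = g, ref = base(g), alt = paste0(base(g), "ACGT"))
  expect_equal(classify_indel(fx$t, ins4)$category, "frameshift_indel")
})

test_that("the splice window flags canonical dinucleotide positions only", {
  set.seed(19)
  fx <- toy_transcript(random_codons(30), intron_len = 20L)
  donor_end <- fx$t$exons[1, 2]
  snv <- function(p) list(pos = p, ref = substr(fx$genome, p, p), alt = "A")
  expect_equal(classify_splice(fx$t, snv(donor_end + 1L), 2L)$category,
               "splicing")
  expect_null(classify_splice(fx$t, snv(donor_end + 3L), 2L))
  expect_null(classify_splice(fx$t, snv(donor_end + 1L), 0L))
  # acceptor side
  acc_start <- fx$t$exons[2, 1]
  expect_equal(classify_splice(fx$t, snv(acc_start - 2L), 2L)$category,
               "splicing")
  # dispatcher precedence: intronic SNV near the junction is splicing
  expect_equal(classify_variant(fx$t, snv(donor_end + 2L))$category,
               "splicing")
  # and an exonic SNV is never splicing
  expect_false(identical(classify_variant(fx$t, snv(donor_end))$category,
                         "splicing"))
})
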