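# The prioritization funnel: rarity, non-silent, shared-by-affected,
# inheritance patterns, compound heterozygotes, score gate, CPG flags.

base_gt <- c("0/0", "0/1", "0/1", "0/1")  # father, mother, sib1, sib2

test_that("the rarity filter applies strictly in every source", {
  cand <- make_candidates(
    chrom = rep("chr1", 3), pos = 1:3, ref = "A", alt = "T",
    gene = "G1", category = "nonsynonymous", gt = rep(base_gt, 3),
    af_kg_asian = c(0.005, 0.02, NA),
    af_exac_nontcga = c(0.005, 0.001, NA))
  out <- filter_rare(cand)
  # 0.005 in both kept; 0.02 in one source removed; both missing kept
  expect_equal(out$pos, c(1L, 3L))
  expect_error(filter_rare(cand, sources = "af_nope"), "unknown frequency")
  # monotonicity: lowering the threshold never increases survivors
  set.seed(51)
  cand2 <- make_candidates(
    chrom = rep("chr1", 50), pos = 1:50, ref = "A", alt = "T",
    gene = "G1", category = "nonsynonymous", gt = rep(base_gt, 50),
    af_kg_asian = round(runif(50, 0, 0.05), 4),
    af_exac_nontcga = round(runif(50, 0, 0.05), 4))
  ths <- c(0.05, 0.02, 0.01, 0.005, 0.001)
  ns <- vapply(ths, function(t) nrow(filter_rare(cand2, t)), integer(1))
  expect_false(is.unsorted(rev(ns)))
})

test_that("the non-silent filter keeps exactly the damaging categories", {
  cats <- c("synonymous", "non_coding", "stop_gain", "start_loss",
            "nonsynonymous", "splicing", "frameshift_indel", "stop_loss",
            "inframe_indel")
  cand <- make_candidates(
    chrom = rep("chr1", length(cats)), pos = seq_along(cats), ref = "A",
    alt = "T", gene = "G1", category = cats, gt = rep(base_gt, length(cats)))
  out <- filter_nonsilent(cand)
  expect_setequal(out$category, setdiff(cats, c("synonymous", "non_coding")))
  cand$category[1] <- NA
  expect_error(filter_nonsilent(cand), "consequence category")
})

test_that("shared-by-affected keeps variants carried by every affected member", {
  ped <- quartet_ped()
  cand <- make_candidates(
    chrom = c("chr1", "chr1", "chrX"), pos = 1:3, ref = "G", alt = "T",
    gene = "G1", category = "nonsynonymous",
    gt = c("0/0", "0/1", "0/1", "0/1",    # both sons het -> kept
           "0/0", "0/1", "0/1", "0/0",    # only elder son -> removed
           "0",   "0/1", "0/1", "1"))     # het + hemizygous alt -> kept
  out <- shared_by_affected(cand, ped)
  expect_equal(out$pos, c(1L, 3L))
  solo <- ped[ped$id == "SIB1", ]
  expect_error(shared_by_affected(cand, solo), ">=2 affected")
})

test_that("inheritance patterns follow their Mendelian definitions", {
  ped <- quartet_ped()
  cand <- make_candidates(
    chrom = c("chrX", "chr1", "chr1", "chr1", "chr1"), pos = 1:5,
    ref = "G", alt = "T", gene = paste0("G", 1:5),
    category = "nonsynonymous",
    gt = c("0",   "0/1", "1",   "1",      # X-linked, maternal
           "0/0", "0/1", "0/1", "0/1",    # dominant maternal, no trio pattern
           "0/0", "0/0", "0/1", "0/1",    # de novo
           "0/1", "0/1", "1/1", "1/1",    # autosomal recessive
           "./.", "0/1", "0/1", "0/1"))   # missing father genotype
  out <- suppressWarnings(detect_inheritance(cand, ped))
  expect_equal(out$patterns[1], "x_linked")
  expect_equal(out$origin[1], "maternal")
  expect_equal(out$patterns[2], "")
  expect_equal(out$origin[2], "maternal")
  expect_equal(out$patterns[3], "de_novo")
  expect_equal(out$origin[3], "de_novo")
  expect_equal(out$patterns[4], "autosomal_recessive")
  expect_equal(out$origin[4], "both")
  expect_equal(out$patterns[5], "")
  expect_equal(out$origin[5], "undetermined")
  expect_warning(detect_inheritance(cand, ped), "missing family genotypes")
})

test_that("de novo is never called when a parent carries the allele, and x_linked only on chrX", {
  ped <- quartet_ped()
  set.seed(52)
  gts <- c("0/0", "0/1", "1/1")
  for (gf in gts) for (gm in gts) {
    cand <- make_candidates(chrom = "chr7", pos = 1L, ref = "A", alt = "G",
                            gene = "G1", category = "nonsynonymous",
                            gt = c(gf, gm, "0/1", "0/1"))
    out <- detect_inheritance(cand, ped)
    if (grepl("de_novo", out$patterns[1]))
      expect_true(gf == "0/0" && gm == "0/0")
    expect_false(grepl("x_linked", out$patterns[1]))
  }
})

test_that("compound heterozygotes need trans configuration by transmission", {
  ped <- quartet_ped()
  # v1 fixed maternal-only; sweep v2 over all 3x3 parental genotype combos
  # and compare against the brute-force phase rule: flagged iff v2 is
  # paternal-only (father carries, mother does not)
  gts <- c("0/0", "0/1", "1/1")
  for (gf in gts) for (gm in gts) {
    cand <- make_candidates(
      chrom = "chr2", pos = c(10L, 20L), ref = "A", alt = "G", gene = "GENE1",
      category = "nonsynonymous",
      gt = c("0/0", "0/1", "0/1", "0/1",
             gf,    gm,    "0/1", "0/1"))
    res <- detect_compound_het(detect_inheritance(cand, ped), ped)
    expect_oracle <- gf != "0/0" && gm == "0/0"
    expect_equal(nrow(res$pairs) == 1L, expect_oracle,
                 label = sprintf("father %s mother %s", gf, gm))
    if (expect_oracle) {
      expect_equal(res$pairs$gene, "GENE1")
      expect_true(all(grepl("compound_het", res$candidates$patterns)))
    }
  }
  # both variants maternal: cis by transmission, never flagged
  cis <- make_candidates(
    chrom = "chr2", pos = c(10L, 20L), ref = "A", alt = "G", gene = "GENE1",
    category = "nonsynonymous",
    gt = c("0/0", "0/1", "0/1", "0/1",
           "0/0", "0/1", "0/1", "0/1"))
  expect_equal(nrow(detect_compound_het(detect_inheritance(cis, ped),
                                        ped)$pairs), 0L)
  # a homozygous child at one site is not compound-het eligible
  hom <- make_candidates(
    chrom = "chr2", pos = c(10L, 20L), ref = "A", alt = "G", gene = "GENE1",
    category = "nonsynonymous",
    gt = c("0/0", "0/1", "0/1", "0/1",
           "0/1", "0/1", "1/1", "0/1"))
  expect_equal(nrow(detect_compound_het(detect_inheritance(hom, ped),
                                        ped)$pairs), 0L)
})

test_that("the four-score gate applies to missense only, with printed directions", {
  mk <- function(category, sift, pp2, mt, mcap) {
    make_candidates(chrom = "chr1", pos = 1L, ref = "A", alt = "G",
                    gene = "G1", category = category, gt = base_gt,
                    sift = sift, polyphen2 = pp2, mutation_taster = mt,
                    mcap = mcap)
  }
  pass <- mk("nonsynonymous", 0.01, 0.99, "disease_causing", 0.03)
  expect_equal(nrow(filter_by_scores(pass)), 1L)
  # boundary directions: SIFT <= is inclusive, M-CAP > is strict
  expect_equal(nrow(filter_by_scores(
    mk("nonsynonymous", 0.05, 0.99, "disease_causing", 0.03))), 1L)
  expect_equal(nrow(filter_by_scores(
    mk("nonsynonymous", 0.01, 0.99, "disease_causing", 0.025))), 0L)
  expect_equal(nrow(filter_by_scores(
    mk("nonsynonymous", 0.01, 0.956, "disease_causing", 0.03))), 0L)
  expect_equal(nrow(filter_by_scores(
    mk("nonsynonymous", 0.01, 0.99, "polymorphism", 0.03))), 0L)
  # a missing score fails the gate
  expect_equal(nrow(filter_by_scores(
    mk("nonsynonymous", NA, 0.99, "disease_causing", 0.03))), 0L)
  # non-missense candidates pass through untouched, scores or not
  expect_equal(nrow(filter_by_scores(mk("stop_gain", NA, NA, NA, NA))), 1L)
  expect_equal(nrow(filter_by_scores(mk("start_loss", NA, NA, NA, NA))), 1L)
})

test_that("CPG flagging is case-insensitive, non-destructive and countable", {
  cand <- make_candidates(chrom = rep("chr1", 4), pos = 1:4, ref = "A",
                          alt = "G", gene = c("APC", "apc2", "WAS", "OTHER"),
                          category = "nonsynonymous", gt = rep(base_gt, 4))
  out <- annotate_cpg(cand, c("Apc", "APC2", "TP53"))
  expect_equal(nrow(out), 4L)
  expect_equal(out$is_cpg_gene, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(sum(out$is_cpg_gene),
               length(intersect(toupper(cand$gene),
                                toupper(c("Apc", "APC2", "TP53")))))
  expect_warning(annotate_cpg(cand, character(0)), "empty")
})

test_that("filters are subsets and commute when independent", {
  set.seed(53)
  ped <- quartet_ped()
  n <- 60
  gt_pool <- c("0/0", "0/1", "1/1")
  gts <- cbind(sample(gt_pool, n, TRUE), sample(gt_pool, n, TRUE),
               sample(gt_pool, n, TRUE), sample(gt_pool, n, TRUE))
  cand <- make_candidates(
    chrom = "chr3", pos = 1:n, ref = "A", alt = "G", gene = "G1",
    category = sample(c("synonymous", "nonsynonymous", "stop_gain"), n, TRUE),
    gt = as.vector(t(gts)),
    af_kg_asian = round(runif(n, 0, 0.05), 4),
    af_exac_nontcga = round(runif(n, 0, 0.05), 4),
    sift = round(runif(n), 3), polyphen2 = round(runif(n), 3),
    mutation_taster = sample(c("disease_causing", "polymorphism"), n, TRUE),
    mcap = round(runif(n, 0, 0.1), 3))
  key <- function(df) variant_key(df$chrom, df$pos, df$ref, df$alt)
  a <- shared_by_affected(filter_nonsilent(filter_rare(cand)), ped)
  b <- filter_rare(shared_by_affected(filter_nonsilent(cand), ped))
  c_ <- filter_nonsilent(filter_rare(shared_by_affected(cand, ped)))
  expect_setequal(key(a), key(b))
  expect_setequal(key(a), key(c_))
  expect_true(all(key(a) %in% key(cand)))
  expect_true(nrow(filter_rare(cand)) <= nrow(cand))
  expect_true(nrow(filter_by_scores(cand)) <= nrow(cand))
})
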