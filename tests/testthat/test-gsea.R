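# Preranked GSEA: ranking, enrichment score, leading edge, permutation
# statistics.

test_that("log2 fold-change ranking matches direct recomputation", {
  set.seed(41)
  n <- 50
  case <- matrix(2^runif(n * 3, 4, 8), nrow = n,
                 dimnames = list(sprintf("g%02d", 1:n), NULL))
  ctrl <- matrix(2^runif(n * 3, 4, 8), nrow = n,
                 dimnames = list(sprintf("g%02d", 1:n), NULL))
  r <- rank_genes(case, ctrl, eps = 1)
  # independent arithmetic check
  want <- log2(rowMeans(case) + 1) - log2(rowMeans(ctrl) + 1)
  expect_equal(r$score, unname(sort(want, decreasing = TRUE)), tolerance = 1e-12)
  expect_false(is.unsorted(rev(r$score)))

  # equal means score 0; exact doubling scores 1.0 with eps = 0
  case2 <- matrix(c(10, 20), nrow = 2, dimnames = list(c("A", "B"), NULL))
  ctrl2 <- matrix(c(10, 10), nrow = 2, dimnames = list(c("A", "B"), NULL))
  r2 <- rank_genes(case2, ctrl2, eps = 0)
  expect_equal(r2$score[r2$gene == "A"], 0)
  expect_equal(r2$score[r2$gene == "B"], 1.0)
})

test_that("ties are broken by gene symbol so the ranking is deterministic", {
  case <- matrix(rep(8, 4), nrow = 4, dimnames = list(c("D", "B", "C", "A"), NULL))
  ctrl <- matrix(rep(4, 4), nrow = 4, dimnames = list(c("D", "B", "C", "A"), NULL))
  expect_equal(rank_genes(case, ctrl)$gene, c("A", "B", "C", "D"))
})

test_that("single-gene sets hit the ES extremes as expected", {
  ranked <- data.frame(gene = c("A", "B", "C", "D", "E"),
                       score = c(3, 2, 1, -1, -2), stringsAsFactors = FALSE)
  # set member at rank 1: running sum peaks at 1 immediately
  es1 <- enrichment_score(ranked, "A")
  expect_equal(es1$es, 1.0)
  expect_equal(leading_edge(ranked, "A", es1), "A")
  # member at the last rank: deviation dominated by misses
  es5 <- enrichment_score(ranked, "E")
  expect_lt(es5$es, 0)
})

test_that("the worked 5-gene example matches the step-by-step oracle", {
  ranked <- data.frame(gene = c("A", "B", "C", "D", "E"),
                       score = c(3, 2, 1, -1, -2), stringsAsFactors = FALSE)
  hit <- c(TRUE, FALSE, FALSE, TRUE, FALSE)  # set = {rank1, rank4}
  es <- enrichment_score(ranked, c("A", "D"))
  expect_equal(es$es, oracle_es(ranked$score, hit), tolerance = 1e-12)
  # by hand: hits weighted 3/4 and 1/4, misses -1/3 each; peak after rank 1
  expect_equal(es$es, 3 / 4)
  expect_equal(leading_edge(ranked, c("A", "D"), es), "A")
  # peak at the last hit includes all hits
  es2 <- enrichment_score(ranked, c("A", "B"))
  expect_equal(leading_edge(ranked, c("A", "B"), es2), c("A", "B"))
})

test_that("ES equals the brute-force running sum on random small instances", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(5:50, 1)
    scores <- sort(round(rnorm(n), 3), decreasing = TRUE)
    ranked <- data.frame(gene = sprintf("G%03d", 1:n), score = scores,
                         stringsAsFactors = FALSE)
    k <- sample(1:(n - 1), 1)
    members <- sample(ranked$gene, k)
    expon <- sample(c(0, 1, 1.5), 1)
    es <- enrichment_score(ranked, members, exponent = expon)
    expect_equal(es$es,
                 oracle_es(scores, ranked$gene %in% members, expon),
                 tolerance = 1e-12)
    expect_lte(abs(es$es), 1)
  }
})

test_that("ES agrees with an independent reference implementation", {
  set.seed(43)
  for (rep in 1:25) {
    n <- sample(20:60, 1)
    scores <- sort(rnorm(n), decreasing = TRUE)
    ranked <- data.frame(gene = sprintf("G%03d", 1:n), score = scores,
                         stringsAsFactors = FALSE)
    members <- sample(ranked$gene, sample(3:10, 1))
    mine <- enrichment_score(ranked, members, exponent = 1)$es
    ref <- fgsea::calcGseaStat(stats = setNames(scores, ranked$gene),
                               selectedStats = which(ranked$gene %in% members),
                               gseaParam = 1)
    expect_equal(mine, unname(ref), tolerance = 1e-9)
  }
})

test_that("reversing the ranked list negates the unweighted ES", {
  set.seed(44)
  n <- 40
  scores <- sort(rnorm(n), decreasing = TRUE)
  ranked <- data.frame(gene = sprintf("G%03d", 1:n), score = scores,
                       stringsAsFactors = FALSE)
  rev_ranked <- ranked[n:1, ]
  for (rep in 1:20) {
    members <- sample(ranked$gene, 8)
    f <- enrichment_score(ranked, members, exponent = 0)
    r <- enrichment_score(rev_ranked, members, exponent = 0)
    # magnitudes always mirror; the sign flips too except in the exact-tie
    # case (max deviation equal on both sides), where both resolve positive
    expect_equal(abs(f$es), abs(r$es), tolerance = 1e-12)
    tied <- abs(max(f$running) + min(f$running)) < 1e-12
    if (!tied) expect_equal(f$es, -r$es, tolerance = 1e-12)
  }
})

test_that("degenerate set inputs error per contract", {
  ranked <- data.frame(gene = c("A", "B"), score = c(1, -1),
                       stringsAsFactors = FALSE)
  expect_error(enrichment_score(ranked, "Z"), "no genes")
  expect_error(enrichment_score(ranked, c("A", "B")), "whole ranked list")
})

test_that("permutation statistics are seeded, guarded, and floor p-values", {
  sim <- simulate_expression(n_genes = 300, n_per_group = 4,
                             planted_size = 30, fold = 2, noise_sd = 0.25,
                             seed = 45, n_decoys = 5)
  ranked <- rank_genes(sim$mat[, 1:4], sim$mat[, 5:8])
  expect_error(permutation_stats(ranked, sim$collection, n_perm = 50, seed = 1),
               "n_perm")
  expect_error(permutation_stats(ranked, sim$collection, n_perm = 200),
               "seed")
  r1 <- permutation_stats(ranked, sim$collection, n_perm = 150, seed = 9)
  r2 <- permutation_stats(ranked, sim$collection, n_perm = 150, seed = 9)
  expect_identical(r1, r2)
  expect_true(all(r1$p_nominal > 0))
  expect_true(all(abs(r1$es) <= 1))
  expect_true(all(sign(r1$nes) == sign(r1$es)))
  expect_true(all(r1$fdr_q >= 0 & r1$fdr_q <= 1))
  # planted signal: p at the pseudo-count floor, q small, top NES
  top <- r1[r1$set == "PLANTED_PATHWAY", ]
  expect_equal(r1$set[1], "PLANTED_PATHWAY")
  expect_lt(top$fdr_q, 0.05)
  # leading edge is a subset of the planted set present in the list
  le <- strsplit(top$leading_edge, ";")[[1]]
  expect_true(all(le %in% sim$planted_set))
})

test_that("random gene sets yield roughly uniform nominal p-values", {
  set.seed(46)
  n <- 300
  scores <- sort(rnorm(n), decreasing = TRUE)
  ranked <- data.frame(gene = sprintf("G%03d", 1:n), score = scores,
                       stringsAsFactors = FALSE)
  sets <- setNames(lapply(1:200, function(i) sample(ranked$gene, 15)),
                   sprintf("R%03d", 1:200))
  res <- permutation_stats(ranked, sets, n_perm = 100, seed = 7)
  frac <- mean(res$p_nominal < 0.05)
  # binomial 99.9% envelope around 0.05 with 200 draws
  expect_gt(frac, 0.0)
  expect_lt(frac, 0.11)
})
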