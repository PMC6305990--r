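# Preranked gene-set enrichment: log2 fold-change ranking, weighted
# running-sum enrichment score, gene-set permutation null, signed-mean NES,
# NES-ratio FDR q, and leading-edge extraction.

#' Rank genes by log2 fold change between two conditions
#'
#' score(g) = log2(mean_case(g) + eps) - log2(mean_control(g) + eps), sorted
#' descending; ties are broken by gene symbol lexicographic order so the
#' ranking is deterministic.
#'
#' @param expr_case,expr_control Numeric matrices (genes x samples) with the
#'   same rownames (gene symbols); expression values are assumed positive and
#'   already normalized.
#' @param eps Pseudo-count guarding zero expression (default 1).
#' @return Data frame of class `ranked_gene_list` with columns `gene`,
#'   `score`, in rank order.
#' @export
rank_genes <- function(expr_case, expr_control, eps = 1) {
  genes <- intersect(rownames(expr_case), rownames(expr_control))
  if (length(genes) == 0L) stop("no genes shared between the two groups")
  mc <- rowMeans(expr_case[genes, , drop = FALSE], na.rm = TRUE)
  mx <- rowMeans(expr_control[genes, , drop = FALSE], na.rm = TRUE)
  bad <- is.nan(mc) | is.nan(mx)
  if (any(bad)) {
    warning(sum(bad), " gene(s) with all-missing values dropped")
    genes <- genes[!bad]; mc <- mc[!bad]; mx <- mx[!bad]
  }
  score <- log2(mc + eps) - log2(mx + eps)
  ord <- order(-score, genes, method = "radix")
  out <- data.frame(gene = toupper(genes[ord]), score = unname(score[ord]),
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_gene_list", "data.frame")
  out
}

#' Weighted running-sum enrichment score
#'
#' At each hit the running sum increments by |score|^exponent normalized by
#' the sum over hits; at each miss it decrements by 1/(N - N_hits). The
#' enrichment score is the signed maximum deviation from zero.
#'
#' @param ranked A [rank_genes()] data frame (or any data frame with `gene`
#'   and `score` in rank order).
#' @param gene_set Character vector of gene symbols.
#' @param exponent Weighting exponent (default 1, the tool's weighted
#'   default; 0 gives the unweighted Kolmogorov-Smirnov statistic).
#' @return List with `es`, `running` (running-sum vector along the list),
#'   `hit_idx` (positions of the set's genes) and `peak` (index of the
#'   extremum).
#' @export
enrichment_score <- function(ranked, gene_set, exponent = 1) {
  genes <- ranked$gene
  n <- length(genes)
  hit <- genes %in% toupper(gene_set)
  n_hit <- sum(hit)
  if (n_hit == 0L) stop("gene set shares no genes with the ranked list")
  if (n_hit == n) stop("gene set covers the whole ranked list; misses undefined")
  w <- abs(ranked$score)^exponent
  denom_hit <- sum(w[hit])
  inc <- ifelse(hit,
                if (denom_hit > 0) w / denom_hit else 1 / n_hit,
                -1 / (n - n_hit))
  # all-zero hit weights degenerate to equal hit increments
  if (denom_hit == 0) inc[hit] <- 1 / n_hit
  running <- cumsum(inc)
  mx <- max(running)
  mn <- min(running)
  # signed maximum deviation; an exact tie resolves to the positive extremum
  if (mx >= -mn) {
    es <- mx; peak <- which.max(running)
  } else {
    es <- mn; peak <- which.min(running)
  }
  list(es = es, running = running, hit_idx = which(hit), peak = peak)
}

#' Leading-edge subset of a gene set
#'
#' For a positive enrichment score, the set members at or before the
#' running-sum peak; for a negative score, at or after the trough.
#'
#' @param ranked A [rank_genes()] data frame.
#' @param gene_set Character vector of gene symbols.
#' @param es_info Output of [enrichment_score()] for the same set (computed
#'   if omitted).
#' @param exponent Passed to [enrichment_score()] when `es_info` is missing.
#' @return Character vector of leading-edge genes, in rank order.
#' @export
leading_edge <- function(ranked, gene_set, es_info = NULL, exponent = 1) {
  if (is.null(es_info)) es_info <- enrichment_score(ranked, gene_set, exponent)
  idx <- es_info$hit_idx
  keep <- if (es_info$es >= 0) idx[idx <= es_info$peak]
          else idx[idx >= es_info$peak]
  ranked$gene[keep]
}

#' Permutation statistics for a gene-set collection
#'
#' The preranked null permutes gene labels: for each set, `n_perm` random
#' gene sets of matched size are drawn from the ranked universe and scored.
#' The nominal p-value uses a pseudo-count over same-sign null scores,
#' p = (1 + #{null ES >= observed, same sign}) / (1 + #{null, same sign}),
#' so it is never zero. NES = ES / mean(|null ES| of the same sign). The FDR
#' q-value is the NES-ratio estimator: the fraction of pooled null NES at
#' least as extreme (same sign) divided by the fraction of observed NES at
#' least as extreme, clipped to [0, 1].
#'
#' @param ranked A [rank_genes()] data frame.
#' @param sets A [read_gmt()] collection (or named list of gene vectors).
#' @param n_perm Number of permutations (>= 100; default 1000).
#' @param seed Mandatory integer seed; results are reproducible given the
#'   seed.
#' @param exponent Weighting exponent for [enrichment_score()].
#' @return Data frame of class `gsea_results` with one row per set retaining
#'   >= 1 ranked gene: `set`, `n_hits`, `es`, `nes`, `p_nominal`, `fdr_q`,
#'   `leading_edge` (semicolon-joined), sorted by decreasing NES.
#' @export
permutation_stats <- function(ranked, sets, n_perm = 1000L, seed,
                              exponent = 1) {
  if (missing(seed)) stop("a seed is mandatory for permutation statistics")
  if (n_perm < 100L) stop("n_perm must be >= 100 (unstable null tails below)")
  if (inherits(sets, "gene_set_collection")) sets <- sets$sets
  genes <- ranked$gene
  set.seed(as.integer(seed))
  obs <- list(); null_es <- list(); kept <- character()
  for (nm in names(sets)) {
    members <- intersect(toupper(sets[[nm]]), genes)
    if (length(members) == 0L) {
      warning("gene set '", nm, "' shares no genes with the ranked list; skipped")
      next
    }
    if (length(members) == length(genes)) {
      warning("gene set '", nm, "' covers the whole ranked list; skipped")
      next
    }
    kept <- c(kept, nm)
    es_info <- enrichment_score(ranked, members, exponent)
    obs[[nm]] <- list(info = es_info, members = members)
    null_es[[nm]] <- vapply(seq_len(n_perm), function(j) {
      enrichment_score(ranked, sample(genes, length(members)), exponent)$es
    }, numeric(1))
  }
  if (length(kept) == 0L) stop("no gene set overlaps the ranked list")

  res <- lapply(kept, function(nm) {
    es <- obs[[nm]]$info$es
    nulls <- null_es[[nm]]
    same <- if (es >= 0) nulls[nulls >= 0] else nulls[nulls < 0]
    p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
    denom <- mean(abs(same))
    if (!is.finite(denom) || denom == 0) denom <- mean(abs(nulls))
    nes <- es / denom
    pos <- nulls[nulls >= 0]
    neg <- nulls[nulls < 0]
    pos_mean <- if (length(pos) > 0L) mean(pos) else denom
    neg_mean <- if (length(neg) > 0L) mean(abs(neg)) else denom
    null_nes <- ifelse(nulls >= 0, nulls / pos_mean, nulls / neg_mean)
    le <- leading_edge(ranked, obs[[nm]]$members, obs[[nm]]$info)
    list(set = nm, n_hits = length(obs[[nm]]$members), es = es, nes = nes,
         p_nominal = p, null_nes = null_nes,
         leading_edge = paste(le, collapse = ";"))
  })

  obs_nes <- vapply(res, `[[`, numeric(1), "nes")
  pooled_null <- unlist(lapply(res, `[[`, "null_nes"))
  fdr_q <- vapply(obs_nes, function(nes_star) {
    if (nes_star >= 0) {
      num_tot <- sum(pooled_null >= 0)
      num <- if (num_tot > 0) sum(pooled_null >= nes_star) / num_tot else 1
      den_tot <- sum(obs_nes >= 0)
      den <- if (den_tot > 0) sum(obs_nes >= nes_star) / den_tot else 1
    } else {
      num_tot <- sum(pooled_null < 0)
      num <- if (num_tot > 0) sum(pooled_null <= nes_star) / num_tot else 1
      den_tot <- sum(obs_nes < 0)
      den <- if (den_tot > 0) sum(obs_nes <= nes_star) / den_tot else 1
    }
    min(1, max(0, if (den > 0) num / den else 1))
  }, numeric(1))

  out <- data.frame(
    set = vapply(res, `[[`, "", "set"),
    n_hits = vapply(res, `[[`, integer(1), "n_hits"),
    es = vapply(res, `[[`, numeric(1), "es"),
    nes = obs_nes,
    p_nominal = vapply(res, `[[`, numeric(1), "p_nominal"),
    fdr_q = fdr_q,
    leading_edge = vapply(res, `[[`, "", "leading_edge"),
    stringsAsFactors = FALSE)
  out <- out[order(-out$nes), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gsea_results", "data.frame")
  out
}
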