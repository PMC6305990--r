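# ACMG-AMP evidence combining: parse criterion tokens with optional strength
# overrides, count effective strength levels, and fire the published
# combining clauses to produce a five-tier classification with the
# pathogenic clause label (Ia-Id, II, III).

ACMG_CODES <- c("PVS1", paste0("PS", 1:4), paste0("PM", 1:6), paste0("PP", 1:5),
                "BA1", paste0("BS", 1:4), paste0("BP", 1:7))

acmg_default_strength <- function(code) {
  if (code == "PVS1") "very_strong"
  else if (startsWith(code, "PS")) "strong"
  else if (startsWith(code, "PM")) "moderate"
  else if (startsWith(code, "PP")) "supporting"
  else if (code == "BA1") "stand_alone"
  else if (startsWith(code, "BS")) "strong"
  else "supporting"
}

acmg_side <- function(code) {
  if (startsWith(code, "B")) "benign" else "pathogenic"
}

#' Parse ACMG evidence tokens
#'
#' Tokens are criterion codes with an optional strength-override suffix:
#' `-VS` (very strong), `-S` (strong), `-M` (moderate), `-P` (supporting).
#' `"PP1-S"` therefore means PP1 applied at strong level. Benign-side codes
#' only take benign-side levels (`-S`/`-P`); BA1 is stand-alone and takes no
#' override.
#'
#' @param tokens Character vector of tokens, or a single comma-separated
#'   string such as `"PVS1, PS1, PP1-S, PM2, PP3, BP1"`.
#' @return Data frame of class `acmg_evidence` with columns `code`, `side`,
#'   `strength`.
#' @export
parse_evidence <- function(tokens) {
  if (length(tokens) == 1L && grepl(",", tokens))
    tokens <- strsplit(tokens, ",")[[1]]
  tokens <- trimws(tokens)
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) {
    out <- data.frame(code = character(), side = character(),
                      strength = character(), stringsAsFactors = FALSE)
    class(out) <- c("acmg_evidence", "data.frame")
    return(out)
  }
  m <- regmatches(tokens,
                  regexec("^([A-Z]+[0-9]+)(?:-(VS|S|M|P))?$", tokens))
  codes <- character(length(tokens))
  strengths <- character(length(tokens))
  override_map <- c(VS = "very_strong", S = "strong",
                    M = "moderate", P = "supporting")
  for (i in seq_along(tokens)) {
    if (length(m[[i]]) == 0L || !m[[i]][2] %in% ACMG_CODES)
      stop("unknown ACMG criterion '", tokens[i], "'; valid codes: ",
           paste(ACMG_CODES, collapse = ", "))
    codes[i] <- m[[i]][2]
    ov <- m[[i]][3]
    if (is.na(ov) || ov == "") {
      strengths[i] <- acmg_default_strength(codes[i])
    } else {
      if (acmg_side(codes[i]) == "benign" && !ov %in% c("S", "P"))
        stop("benign criterion ", codes[i],
             " only takes benign-side levels (-S or -P)")
      if (codes[i] == "BA1")
        stop("BA1 is stand-alone and takes no strength override")
      strengths[i] <- override_map[[ov]]
    }
  }
  if (anyDuplicated(codes))
    stop("duplicate ACMG criterion: ",
         paste(unique(codes[duplicated(codes)]), collapse = ", "))
  out <- data.frame(code = codes, side = vapply(codes, acmg_side, ""),
                    strength = strengths, stringsAsFactors = FALSE)
  class(out) <- c("acmg_evidence", "data.frame")
  out
}

#' Combine ACMG evidence into a classification
#'
#' Counts criteria by effective strength level and applies the published
#' combining rules. Pathogenic clauses (first firing label reported):
#' Ia >=1 very strong AND >=1 strong; Ib >=1 very strong AND >=2 moderate;
#' Ic >=1 very strong AND exactly 1 moderate AND exactly 1 supporting;
#' Id >=1 very strong AND >=2 supporting; II >=2 strong; III 1 strong AND
#' (>=3 moderate OR (2 moderate AND >=2 supporting) OR (1 moderate AND >=4
#' supporting)). Likely pathogenic: 1 very strong + 1 moderate; 1 strong +
#' 1-2 moderate; 1 strong + >=2 supporting; >=3 moderate; 2 moderate + >=2
#' supporting; 1 moderate + >=4 supporting. Benign: BA1 or >=2 benign strong.
#' Likely benign: 1 benign strong + 1 benign supporting, or >=2 benign
#' supporting. When both sides independently reach a classification the
#' result is uncertain significance with the conflict flag set; isolated
#' benign evidence that reaches no benign classification does not veto a
#' pathogenic call.
#'
#' @param evidence An `acmg_evidence` data frame from [parse_evidence()]
#'   (or a token vector/string, which is parsed first).
#' @return List of class `acmg_result` with `classification` (pathogenic,
#'   likely_pathogenic, uncertain_significance, likely_benign, benign),
#'   `tier` (Ia/Ib/Ic/Id/II/III or NA), `conflict` (logical) and `counts`.
#' @export
combine_evidence <- function(evidence) {
  if (!inherits(evidence, "acmg_evidence")) evidence <- parse_evidence(evidence)
  pat <- evidence[evidence$side == "pathogenic", ]
  ben <- evidence[evidence$side == "benign", ]
  n_vs <- sum(pat$strength == "very_strong")
  n_s  <- sum(pat$strength == "strong")
  n_m  <- sum(pat$strength == "moderate")
  n_p  <- sum(pat$strength == "supporting")
  n_ba <- sum(ben$strength == "stand_alone")
  n_bs <- sum(ben$strength == "strong")
  n_bp <- sum(ben$strength == "supporting")

  tier <- NA_character_
  if      (n_vs >= 1L && n_s >= 1L)                tier <- "Ia"
  else if (n_vs >= 1L && n_m >= 2L)                tier <- "Ib"
  else if (n_vs >= 1L && n_m == 1L && n_p == 1L)   tier <- "Ic"
  else if (n_vs >= 1L && n_p >= 2L)                tier <- "Id"
  else if (n_s >= 2L)                              tier <- "II"
  else if (n_s == 1L &&
           (n_m >= 3L || (n_m == 2L && n_p >= 2L) ||
            (n_m == 1L && n_p >= 4L)))             tier <- "III"

  likely_path <-
    (n_vs >= 1L && n_m == 1L) ||
    (n_s == 1L && n_m >= 1L && n_m <= 2L) ||
    (n_s == 1L && n_p >= 2L) ||
    (n_m >= 3L) ||
    (n_m == 2L && n_p >= 2L) ||
    (n_m == 1L && n_p >= 4L)

  path_class <- if (!is.na(tier)) "pathogenic"
                else if (likely_path) "likely_pathogenic"
                else NA_character_

  ben_class <- if (n_ba >= 1L || n_bs >= 2L) "benign"
               else if ((n_bs == 1L && n_bp == 1L) || n_bp >= 2L) "likely_benign"
               else NA_character_

  conflict <- !is.na(path_class) && !is.na(ben_class)
  classification <-
    if (conflict) "uncertain_significance"
    else if (!is.na(path_class)) path_class
    else if (!is.na(ben_class)) ben_class
    else "uncertain_significance"
  if (classification != "pathogenic") tier <- NA_character_

  structure(list(classification = classification, tier = tier,
                 conflict = conflict,
                 counts = c(very_strong = n_vs, strong = n_s, moderate = n_m,
                            supporting = n_p, stand_alone_benign = n_ba,
                            strong_benign = n_bs, supporting_benign = n_bp)),
            class = "acmg_result")
}

#' @export
print.acmg_result <- function(x, ...) {
  cat(sprintf("<acmg_result> %s%s%s\n", x$classification,
              ifelse(is.na(x$tier), "", paste0(" (", x$tier, ")")),
              ifelse(x$conflict, " [conflicting evidence]", "")))
  invisible(x)
}

# Report-style label, mirroring clinical summary tables.
format_acmg_effect <- function(result) {
  switch(result$classification,
         pathogenic = sprintf("Pathogenic(%s)", result$tier),
         likely_pathogenic = "Likely pathogenic",
         likely_benign = "Likely benign",
         benign = "Benign",
         "Not enough evidence")
}

#' Classify a candidate table carrying evidence assignments
#'
#' Evidence assignment is an input (comma-separated tokens in an
#' `acmg_evidence` column), not auto-derived: deciding that a variant merits
#' e.g. PVS1 requires disease-gene knowledge the engine does not model. A
#' candidate without evidence is classified uncertain_significance with a
#' warning (one warning summarises such rows).
#'
#' @param candidates Data frame with an `acmg_evidence` character column.
#' @return List with `candidates` (added columns `classification`, `tier`,
#'   `conflict`, `effect`) and `n_pathogenic`.
#' @export
classify_candidates <- function(candidates) {
  n <- nrow(candidates)
  ev <- candidates$acmg_evidence %||% rep("", n)
  ev[is.na(ev)] <- ""
  classification <- character(n)
  tier <- rep(NA_character_, n)
  conflict <- logical(n)
  effect <- character(n)
  n_empty <- 0L
  for (i in seq_len(n)) {
    if (!nzchar(ev[i])) n_empty <- n_empty + 1L
    res <- combine_evidence(ev[i])
    classification[i] <- res$classification
    tier[i] <- res$tier
    conflict[i] <- res$conflict
    effect[i] <- format_acmg_effect(res)
  }
  if (n_empty > 0L)
    warning(n_empty, " candidate(s) without ACMG evidence classified as ",
            "uncertain_significance")
  candidates$classification <- classification
  candidates$tier <- tier
  candidates$conflict <- conflict
  candidates$effect <- effect
  list(candidates = candidates,
       n_pathogenic = sum(classification == "pathogenic"))
}
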