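# Shared fixtures: raw/harmonized record constructors and an independent
# brute-force implementation of the staged classification rules.

# raw activity record rows with defaults for every field
rawRecords <- function(...) {
  args <- list(...)
  n <- max(c(1L, lengths(args)))
  defaults <- list(
    record_id = sprintf("r%03d", seq_len(n)),
    compound_structure = "c1ccc(CCN(C)C)cc1CCc1ccccc1",
    source_id = "src",
    reference_id = NA_character_,
    measure_name = "IC50",
    relation = "=",
    value = 100,
    unit = "nM",
    test_concentration_uM = NA_real_,
    assay_description = "patch clamp",
    phenotype = "none",
    outcome_comment = NA_character_,
    data_validity_comment = NA_character_,
    year = 2010L,
    invalid = FALSE
  )
  for (nm in names(args)) defaults[[nm]] <- args[[nm]]
  out <- as.data.frame(lapply(defaults, rep_len, n), stringsAsFactors = FALSE)
  out
}

# harmonized record rows (bypassing the harmonization driver) for direct
# classification tests
harmRecords <- function(potency_nM = numeric(0), relation = "=",
                        inhibition_pct = numeric(0), conc_uM = 10,
                        is_hts = FALSE, n_qualitative = 0L,
                        key = "K1") {
  rows <- list()
  if (length(potency_nM)) {
    rows[[1]] <- data.frame(
      record_id = sprintf("ic%03d", seq_along(potency_nM)),
      canonical_key = key,
      value_kind = "ic50_like",
      potency_nM = potency_nM,
      relation = rep_len(relation, length(potency_nM)),
      inhibition_pct = NA_real_,
      test_concentration_uM = NA_real_,
      is_hts_source = FALSE,
      stringsAsFactors = FALSE)
  }
  if (length(inhibition_pct)) {
    rows[[length(rows) + 1]] <- data.frame(
      record_id = sprintf("in%03d", seq_along(inhibition_pct)),
      canonical_key = key,
      value_kind = "inhibition_like",
      potency_nM = NA_real_,
      relation = "=",
      inhibition_pct = inhibition_pct,
      test_concentration_uM = rep_len(conc_uM, length(inhibition_pct)),
      is_hts_source = rep_len(is_hts, length(inhibition_pct)),
      stringsAsFactors = FALSE)
  }
  if (n_qualitative > 0) {
    rows[[length(rows) + 1]] <- data.frame(
      record_id = sprintf("q%03d", seq_len(n_qualitative)),
      canonical_key = key,
      value_kind = "qualitative_negative",
      potency_nM = NA_real_,
      relation = "none",
      inhibition_pct = NA_real_,
      test_concentration_uM = NA_real_,
      is_hts_source = FALSE,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(record_id = character(0), canonical_key = character(0),
                      value_kind = character(0), potency_nM = numeric(0),
                      relation = character(0), inhibition_pct = numeric(0),
                      test_concentration_uM = numeric(0),
                      is_hts_source = logical(0)))
  }
  do.call(rbind, rows)
}

# Independent brute-force evaluation of the staged rules, written from the
# rule statements with no shared code: extreme filter, votes, unanimity,
# single-pass removal around the log-average, two-thirds majority with IC50
# priority, inhibition + qualitative fallback.
bruteForceClassify <- function(rec, threshold = 10000, fold = 10,
                               majority = 2 / 3) {
  ic <- rec[rec$value_kind == "ic50_like", , drop = FALSE]
  ic <- ic[!is.na(ic$potency_nM) & ic$potency_nM >= 1e-3 &
             ic$potency_nM <= 1e6, , drop = FALSE]
  vote_of <- function(p, r) {
    if (r == "=") { if (p <= threshold) "pos" else "neg" }
    else if (r == "<") { if (p <= threshold) "pos" else "none" }
    else if (r == ">") { if (p >= threshold) "neg" else "none" }
    else "none"
  }
  if (nrow(ic)) {
    v <- mapply(vote_of, ic$potency_nM, ic$relation)
    p <- sum(v == "pos"); n <- sum(v == "neg")
    if (p + n > 0) {
      if (n == 0) return("inhibitor")
      if (p == 0) return("inactive")
      exact <- ic$relation == "="
      vals <- ic$potency_nM[exact]
      logmean <- 10^mean(log10(vals))
      keep_exact <- vals < fold * logmean & vals > logmean / fold
      kept_p <- c(ic$potency_nM[!exact], vals[keep_exact])
      kept_r <- c(ic$relation[!exact], rep("=", sum(keep_exact)))
      v2 <- if (length(kept_p)) mapply(vote_of, kept_p, kept_r) else character(0)
      p2 <- sum(v2 == "pos"); n2 <- sum(v2 == "neg")
      if (p2 + n2 == 0) return("inconclusive")
      if (p2 / (p2 + n2) >= majority) return("inhibitor")
      if (n2 / (p2 + n2) >= majority) return("inactive")
      return("inconclusive")
    }
  }
  inh <- rec[rec$value_kind == "inhibition_like", , drop = FALSE]
  ivote <- function(pct, conc, hts) {
    if (is.na(pct) || is.na(conc)) return("none")
    if (!hts) {
      if (pct >= 50 && conc <= 10) "pos"
      else if (pct < 50 && conc >= 10) "neg"
      else "none"
    } else {
      if (pct > 70 && conc <= 10) "pos"
      else if (pct < 30 && conc >= 10) "neg"
      else "none"
    }
  }
  v <- if (nrow(inh)) {
    mapply(ivote, inh$inhibition_pct, inh$test_concentration_uM,
           inh$is_hts_source)
  } else character(0)
  p <- sum(v == "pos")
  n <- sum(v == "neg") + sum(rec$value_kind == "qualitative_negative")
  if (p + n == 0) return("unclassified")
  if (n == 0) return("inhibitor")
  if (p == 0) return("inactive")
  if (p / (p + n) >= majority) return("inhibitor")
  if (n / (p + n) >= majority) return("inactive")
  "inconclusive"
}

# obabel canonicalization shortcut for comparing structure strings in tests
canonical <- function(smi) hergdb:::obConvert(smi, "smi", "can")

# potency in nM at a given pIC50 (test-side arithmetic)
nmFromPic50_t <- function(pic50) 10^(9 - pic50)
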