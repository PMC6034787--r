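# Step-wise consensus classification into hERG inhibitors, inactives and
# inconclusives: unanimity, 10-fold outlier elimination, two-thirds
# majority, with IC50-type evidence taking priority over inhibition-type
# evidence and stricter thresholds for HTS sources.

#' Vote of a single IC50-type record
#'
#' An exact value at or below the 10 uM threshold is a positive
#' (inhibitor) vote; an exact value above it is negative. Qualified values
#' vote only when their bound is decisive: an upper bound ("<") at or below
#' the threshold is positive, a lower bound (">") at or above it is
#' negative; other qualified values are uninformative.
#'
#' @param potency_nM numeric vector of potencies in nM.
#' @param relation character vector in \code{c("=", "<", ">")}.
#' @param config a \linkS4class{HergConfig}.
#' @return character vector in \code{c("positive", "negative",
#'   "uninformative")}.
#' @examples
#' ic50Vote(5000, "=")   # positive
#' ic50Vote(10000, "=")  # positive (inclusive threshold)
#' ic50Vote(30000, ">")  # negative
#' @export
ic50Vote <- function(potency_nM, relation, config = hergConfig()) {
  n <- max(length(potency_nM), length(relation))
  potency_nM <- rep_len(as.numeric(potency_nM), n)
  relation <- rep_len(as.character(relation), n)
  thr <- config@potency_threshold_nM
  out <- rep("uninformative", n)
  ok <- !is.na(potency_nM)
  out[ok & relation == "=" & potency_nM <= thr] <- "positive"
  out[ok & relation == "=" & potency_nM > thr] <- "negative"
  out[ok & relation == "<" & potency_nM <= thr] <- "positive"
  out[ok & relation == ">" & potency_nM >= thr] <- "negative"
  out
}

#' Vote of a single inhibition-type record
#'
#' Non-HTS records: at least 50\% inhibition at a concentration at or below
#' 10 uM votes positive; below 50\% at a concentration at or above 10 uM
#' votes negative. HTS records use the stricter thresholds: strictly more
#' than 70\% for positive, strictly less than 30\% for negative, at the same
#' concentration conditions. Everything else is uninformative.
#'
#' @param pct numeric percent inhibition (as measured; may fall outside
#'   [0, 100]).
#' @param conc_uM numeric test concentration in uM.
#' @param is_hts logical; record comes from an HTS-scale source.
#' @param config a \linkS4class{HergConfig}.
#' @return character vector in \code{c("positive", "negative",
#'   "uninformative")}.
#' @examples
#' inhibitionVote(60, 10, FALSE)  # positive
#' inhibitionVote(60, 10, TRUE)   # uninformative (HTS needs > 70)
#' inhibitionVote(80, 30, FALSE)  # uninformative (concentration too high)
#' @export
inhibitionVote <- function(pct, conc_uM, is_hts = FALSE,
                           config = hergConfig()) {
  n <- max(length(pct), length(conc_uM), length(is_hts))
  pct <- rep_len(as.numeric(pct), n)
  conc_uM <- rep_len(as.numeric(conc_uM), n)
  is_hts <- rep_len(as.logical(is_hts), n)
  conc_thr <- config@potency_threshold_nM / 1000
  out <- rep("uninformative", n)
  ok <- !is.na(pct) & !is.na(conc_uM)
  std_pos <- ok & !is_hts & pct >= config@inhibition_threshold_pct & conc_uM <= conc_thr
  std_neg <- ok & !is_hts & pct < config@inhibition_threshold_pct & conc_uM >= conc_thr
  hts_pos <- ok & is_hts & pct > config@hts_positive_pct & conc_uM <= conc_thr
  hts_neg <- ok & is_hts & pct < config@hts_negative_pct & conc_uM >= conc_thr
  out[std_pos | hts_pos] <- "positive"
  out[std_neg | hts_neg] <- "negative"
  out
}

#' Drop implausibly extreme IC50 values
#'
#' Values below 1 pM or above 1 mM are typically unit-registration errors
#' and are removed before voting and deviation statistics (strict
#' inequalities: exactly 1 pM or 1 mM is kept).
#'
#' @param potency_nM numeric vector.
#' @param config a \linkS4class{HergConfig}.
#' @return logical vector, TRUE = keep.
#' @export
extremeValueFilter <- function(potency_nM, config = hergConfig()) {
  !is.na(potency_nM) &
    potency_nM >= config@extreme_low_nM &
    potency_nM <= config@extreme_high_nM
}

#' Single-pass outlier removal around the per-compound mean
#'
#' Computes the mean of all values (geometric by default: IC50s span orders
#' of magnitude, and an arithmetic mean lets a single large outlier shield
#' itself) and removes every value at least \code{outlier_fold} higher or
#' lower than that mean. One pass only; the removal is not iterated.
#' With fewer than two values nothing is removed.
#'
#' @param potencies_nM numeric vector of exact ("=") potencies.
#' @param config a \linkS4class{HergConfig}.
#' @return list with \code{kept} and \code{removed} (indices into the
#'   input) plus \code{mean_nM}.
#' @examples
#' removeOutliers(c(100, 120, 90, 5000))$removed  # index of 5000
#' @export
removeOutliers <- function(potencies_nM, config = hergConfig()) {
  v <- as.numeric(potencies_nM)
  if (length(v) < 2L || anyNA(v)) {
    return(list(kept = seq_along(v), removed = integer(0), mean_nM = NA_real_))
  }
  m <- if (config@outlier_mean == "geometric") geomean(v) else mean(v)
  out <- which(v >= config@outlier_fold * m | v <= m / config@outlier_fold)
  list(kept = setdiff(seq_along(v), out), removed = out, mean_nM = m)
}

# classify one compound's records; rec is the subset data.frame
.classify_one <- function(rec, config) {
  res <- list(label = "unclassified", stage = "none",
              votes_positive = 0L, votes_negative = 0L,
              removed_outlier_record_ids = "")
  decide <- function(pos, neg) {
    tot <- pos + neg
    if (tot == 0L) return(NA_character_)
    fp <- pos / tot; fn <- neg / tot
    th <- config@majority_fraction
    hit <- if (config@majority_strict) function(f) f > th else function(f) f >= th
    if (hit(fp)) "inhibitor" else if (hit(fn)) "inactive" else "inconclusive"
  }

  ic <- rec[rec$value_kind == "ic50_like", , drop = FALSE]
  if (nrow(ic)) {
    ic <- ic[extremeValueFilter(ic$potency_nM, config), , drop = FALSE]
  }
  if (nrow(ic)) {
    votes <- ic50Vote(ic$potency_nM, ic$relation, config)
    pos <- sum(votes == "positive"); neg <- sum(votes == "negative")
    if (pos + neg > 0L) {
      if (pos == 0L || neg == 0L) {
        res$label <- if (pos > 0L) "inhibitor" else "inactive"
        res$stage <- "ic50_unanimous"
        res$votes_positive <- pos; res$votes_negative <- neg
        return(res)
      }
      # contradictory: single-pass outlier removal on exact values only
      exact <- which(ic$relation == "=" & !is.na(ic$potency_nM))
      rem <- removeOutliers(ic$potency_nM[exact], config)
      removed_idx <- exact[rem$removed]
      keep_idx <- setdiff(seq_len(nrow(ic)), removed_idx)
      votes2 <- ic50Vote(ic$potency_nM[keep_idx], ic$relation[keep_idx], config)
      pos2 <- sum(votes2 == "positive"); neg2 <- sum(votes2 == "negative")
      res$votes_positive <- pos2; res$votes_negative <- neg2
      res$removed_outlier_record_ids <-
        paste(ic$record_id[removed_idx], collapse = ";")
      lab <- decide(pos2, neg2)
      res$label <- if (is.na(lab)) "inconclusive" else lab
      res$stage <- "ic50_majority_after_outlier_removal"
      return(res)
    }
    # IC50 records exist but none is informative: no usable IC50 evidence,
    # fall through to the inhibition stage
  }

  inh <- rec[rec$value_kind == "inhibition_like", , drop = FALSE]
  qual_neg <- sum(rec$value_kind == "qualitative_negative")
  votes <- character(0)
  if (nrow(inh)) {
    votes <- inhibitionVote(inh$inhibition_pct, inh$test_concentration_uM,
                            inh$is_hts_source, config)
  }
  pos <- sum(votes == "positive")
  neg <- sum(votes == "negative") + qual_neg
  res$votes_positive <- pos; res$votes_negative <- neg
  if (pos + neg == 0L) return(res)
  if (pos == 0L || neg == 0L) {
    res$label <- if (pos > 0L) "inhibitor" else "inactive"
    res$stage <- if (nrow(inh)) "inhibition_unanimous" else "qualitative_only"
    return(res)
  }
  lab <- decide(pos, neg)
  res$label <- if (is.na(lab)) "inconclusive" else lab
  res$stage <- "inhibition_majority"
  res
}

#' Classify a single compound's records
#'
#' Stage order: (1) if informative IC50-type votes exist (after the
#' extreme-value filter), decide by unanimity, otherwise remove outliers
#' (exact values only; qualified bounds are not point estimates and are
#' excluded from the mean), recompute votes and decide by two-thirds
#' majority; a split vote is inconclusive. Inhibition-type and qualitative
#' records are ignored whenever usable IC50 evidence exists. (2) With no
#' usable IC50 evidence, the same unanimity-then-majority logic runs over
#' inhibition-type votes plus qualitative "no activity" records (counted as
#' negative votes). (3) No informative votes at all leaves the compound
#' unclassified.
#'
#' @param records data.frame of one compound's harmonized records.
#' @param config a \linkS4class{HergConfig}.
#' @return one-row data.frame: \code{label}, \code{stage},
#'   \code{votes_positive}, \code{votes_negative},
#'   \code{removed_outlier_record_ids}.
#' @export
classifyCompound <- function(records, config = hergConfig()) {
  res <- .classify_one(records, config)
  as.data.frame(res, stringsAsFactors = FALSE)
}

#' Classify every compound of a CompoundSet
#'
#' Applies \code{\link{classifyCompound}} to each merged compound that
#' passes the drug-likeness filter (failing compounds are dropped first).
#' Classification is independent of record order.
#'
#' @param x a \linkS4class{CompoundSet}.
#' @param config a \linkS4class{HergConfig}.
#' @return a \linkS4class{ClassifiedSet}.
#' @export
classifyCompounds <- function(x, config = hergConfig()) {
  stopifnot(is(x, "CompoundSet"))
  x <- filterCompounds(x)
  cd <- x@compounds
  rec <- x@records
  groups <- split(seq_len(nrow(rec)), rec$canonical_key)
  out <- vector("list", nrow(cd))
  for (i in seq_len(nrow(cd))) {
    idx <- groups[[cd$canonical_key[i]]]
    sub <- rec[idx, , drop = FALSE]
    out[[i]] <- .classify_one(sub, config)
  }
  cls <- do.call(rbind, lapply(out, as.data.frame, stringsAsFactors = FALSE))
  if (is.null(cls)) {
    cls <- data.frame(label = character(0), stage = character(0),
                      votes_positive = integer(0), votes_negative = integer(0),
                      removed_outlier_record_ids = character(0))
  }
  cd <- cbind(cd, cls)
  methods::new("ClassifiedSet", compounds = cd, records = rec,
               metadata = x@metadata)
}
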