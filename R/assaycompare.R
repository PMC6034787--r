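# Binding-vs-electrostatic assay concordance and per-compound IC50
# deviation statistics.

#' Validity filter for IC50-type records
#'
#' For quantitative comparisons, only exact values are usable: records
#' using inequality signs, missing values, or an implausible range
#' (IC50 above 1 mM) are dropped with reasons.
#'
#' @param records harmonized record data.frame.
#' @param config a \linkS4class{HergConfig}.
#' @return data.frame with logical \code{keep} and character \code{reason}
#'   (NA when kept; only IC50-type rows are ever kept).
#' @export
validityFilterIc50 <- function(records, config = hergConfig()) {
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  is_ic <- records$value_kind == "ic50_like"
  reason[!is_ic] <- "not ic50-type"
  reason[is.na(reason) & records$relation %in% c("<", ">")] <- "inequality"
  reason[is.na(reason) & is.na(records$potency_nM)] <- "null"
  reason[is.na(reason) & records$potency_nM > config@extreme_high_nM] <- "range"
  data.frame(keep = is.na(reason), reason = reason, stringsAsFactors = FALSE)
}

#' Binding vs electrostatic assay concordance
#'
#' Restricts the record set to valid exact IC50-type values, selects the
#' compounds measured by both a binding assay and an electrostatic assay,
#' computes the per-compound arithmetic mean pIC50 for each assay class,
#' and reports the squared Pearson correlation (R squared), the root mean
#' squared pIC50 deviation, the per-class overall mean potency
#' (back-converted from the mean of per-compound mean pIC50s), and the
#' number of compounds more potent in the electrostatic assay. Compounds
#' whose assay class is unknown are excluded.
#'
#' @param x a \linkS4class{CompoundSet} or \linkS4class{ClassifiedSet}.
#' @param config a \linkS4class{HergConfig}.
#' @return list: \code{n_common_compounds}, \code{mean_potency_binding_nM},
#'   \code{mean_potency_electro_nM}, \code{r_squared}, \code{rmsd_pic50},
#'   \code{n_more_potent_electro}, and the per-compound table
#'   \code{per_compound}.
#' @export
concordance <- function(x, config = hergConfig()) {
  stopifnot(is(x, "CompoundSet"))
  rec <- x@records
  keep <- validityFilterIc50(rec, config)$keep &
    extremeValueFilter(rec$potency_nM, config)
  rec <- rec[keep & rec$assay_class %in% c("binding", "electrostatic"), ,
             drop = FALSE]
  pic <- pic50FromNM(rec$potency_nM)
  mean_by <- function(cls) {
    sel <- rec$assay_class == cls
    vapply(split(pic[sel], rec$canonical_key[sel]), mean, numeric(1))
  }
  mb <- mean_by("binding"); me <- mean_by("electrostatic")
  common <- intersect(names(mb), names(me))
  if (length(common) < 2L) {
    stop("fewer than 2 compounds measured by both assay classes")
  }
  b <- mb[common]; e <- me[common]
  r2 <- stats::cor(b, e)^2
  rmsd <- sqrt(mean((b - e)^2))
  list(
    n_common_compounds = length(common),
    mean_potency_binding_nM = nmFromPic50(mean(b)),
    mean_potency_electro_nM = nmFromPic50(mean(e)),
    r_squared = unname(r2),
    rmsd_pic50 = rmsd,
    n_more_potent_electro = sum(e > b),
    per_compound = data.frame(canonical_key = common,
                              pic50_binding = unname(b),
                              pic50_electro = unname(e),
                              stringsAsFactors = FALSE)
  )
}

#' Per-compound IC50 deviation statistics
#'
#' For compounds with strictly more than \code{min_values} valid exact
#' IC50 values (extreme values pre-dropped), reports the max/min fold
#' spread and the 75th/25th percentile fold spread (linear interpolation
#' between closest ranks), plus summary bins (fold at most 10, 10 to 100,
#' above 100) for both measures.
#'
#' @param x a \linkS4class{CompoundSet} or \linkS4class{ClassifiedSet}.
#' @param min_values report compounds with strictly more values (default
#'   3, i.e. at least 4 values).
#' @param config a \linkS4class{HergConfig}.
#' @return list with \code{per_compound} (data.frame: canonical_key,
#'   n_values, fold_max_min, fold_iqr) and \code{bins} (data.frame of
#'   counts per measure and bin).
#' @export
deviationStats <- function(x, min_values = 3, config = hergConfig()) {
  stopifnot(is(x, "CompoundSet"))
  rec <- x@records
  keep <- validityFilterIc50(rec, config)$keep &
    extremeValueFilter(rec$potency_nM, config)
  rec <- rec[keep, , drop = FALSE]
  groups <- split(rec$potency_nM, rec$canonical_key)
  groups <- groups[lengths(groups) > min_values]
  per <- do.call(rbind, lapply(names(groups), function(k) {
    v <- groups[[k]]
    q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    data.frame(canonical_key = k, n_values = length(v),
               fold_max_min = max(v) / min(v),
               fold_iqr = q[2] / q[1], stringsAsFactors = FALSE)
  }))
  if (is.null(per)) {
    per <- data.frame(canonical_key = character(0), n_values = integer(0),
                      fold_max_min = numeric(0), fold_iqr = numeric(0))
  }
  bin <- function(v) {
    c(`<=10` = sum(v <= 10), `10-100` = sum(v > 10 & v <= 100),
      `>100` = sum(v > 100))
  }
  bins <- rbind(
    data.frame(measure = "fold_max_min", bin = names(bin(per$fold_max_min)),
               n_compounds = unname(bin(per$fold_max_min))),
    data.frame(measure = "fold_iqr", bin = names(bin(per$fold_iqr)),
               n_compounds = unname(bin(per$fold_iqr)))
  )
  list(per_compound = per, bins = bins)
}
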