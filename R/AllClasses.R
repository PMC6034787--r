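#' Pipeline configuration
#'
#' Holds every tunable threshold of the integration pipeline. Defaults are
#' the study conditions: the 10 uM potency threshold, the 50\% inhibition
#' threshold, the stricter 70\%/30\% thresholds for HTS sources, the 200
#' distinct-compound HTS trigger, the 10-fold outlier rule, the two-thirds
#' majority, the 1 pM / 1 mM extreme-value window, and the drug-likeness
#' bounds (150--700 g/mol, 10 heavy atoms).
#'
#' @slot potency_threshold_nM numeric; IC50-type positives at or below this.
#' @slot inhibition_threshold_pct numeric; percent-inhibition positives at or
#'   above this (non-HTS).
#' @slot hts_positive_pct,hts_negative_pct numeric; strict HTS vote
#'   thresholds (exclusive).
#' @slot hts_source_min_compounds integer; a source is HTS-like when it
#'   carries inhibition-type data for strictly more distinct compounds.
#' @slot outlier_fold numeric; records at least this many fold from the
#'   per-compound mean are outliers.
#' @slot outlier_mean character; "geometric" (default) or "arithmetic".
#' @slot majority_fraction numeric; vote fraction that decides a label.
#' @slot majority_strict logical; if TRUE the fraction must strictly exceed
#'   \code{majority_fraction}.
#' @slot extreme_low_nM,extreme_high_nM numeric; IC50 plausibility window.
#' @slot mw_min,mw_max numeric; inclusive molecular-weight bounds.
#' @slot min_heavy_atoms integer; inclusive lower bound.
#' @slot framework_keep_exocyclic logical; retain atoms double/triple bonded
#'   to a Murcko scaffold atom.
#' @slot random_seed integer seed used by pipeline-level randomness.
#' @export
setClass("HergConfig", representation(
  potency_threshold_nM = "numeric",
  inhibition_threshold_pct = "numeric",
  hts_positive_pct = "numeric",
  hts_negative_pct = "numeric",
  hts_source_min_compounds = "integer",
  outlier_fold = "numeric",
  outlier_mean = "character",
  majority_fraction = "numeric",
  majority_strict = "logical",
  extreme_low_nM = "numeric",
  extreme_high_nM = "numeric",
  mw_min = "numeric",
  mw_max = "numeric",
  min_heavy_atoms = "integer",
  framework_keep_exocyclic = "logical",
  random_seed = "integer"
), prototype(
  potency_threshold_nM = 10000,
  inhibition_threshold_pct = 50,
  hts_positive_pct = 70,
  hts_negative_pct = 30,
  hts_source_min_compounds = 200L,
  outlier_fold = 10,
  outlier_mean = "geometric",
  majority_fraction = 2 / 3,
  majority_strict = FALSE,
  extreme_low_nM = 1e-3,
  extreme_high_nM = 1e6,
  mw_min = 150,
  mw_max = 700,
  min_heavy_atoms = 10L,
  framework_keep_exocyclic = TRUE,
  random_seed = 1L
))

setValidity("HergConfig", function(object) {
  msg <- character(0)
  if (!(object@hts_negative_pct > 0 &&
        object@hts_negative_pct < object@inhibition_threshold_pct &&
        object@inhibition_threshold_pct < object@hts_positive_pct &&
        object@hts_positive_pct < 100))
    msg <- c(msg, "need 0 < hts_negative_pct < inhibition_threshold_pct < hts_positive_pct < 100")
  if (object@outlier_fold <= 1) msg <- c(msg, "outlier_fold must exceed 1")
  if (!(object@majority_fraction > 0.5 && object@majority_fraction <= 1))
    msg <- c(msg, "majority_fraction must be in (0.5, 1]")
  if (!(object@extreme_low_nM < object@potency_threshold_nM &&
        object@potency_threshold_nM < object@extreme_high_nM))
    msg <- c(msg, "need extreme_low_nM < potency_threshold_nM < extreme_high_nM")
  if (!object@outlier_mean %in% c("geometric", "arithmetic"))
    msg <- c(msg, "outlier_mean must be 'geometric' or 'arithmetic'")
  if (length(msg)) msg else TRUE
})

#' Create a pipeline configuration
#'
#' @param ... named values overriding the defaults documented in
#'   \linkS4class{HergConfig}.
#' @return a validated \linkS4class{HergConfig} object.
#' @examples
#' cfg <- hergConfig()
#' cfg2 <- hergConfig(majority_strict = TRUE)
#' @export
hergConfig <- function(...) {
  args <- list(...)
  for (nm in c("hts_source_min_compounds", "min_heavy_atoms", "random_seed")) {
    if (nm %in% names(args)) args[[nm]] <- as.integer(args[[nm]])
  }
  do.call(methods::new, c(list(Class = "HergConfig"), args))
}

# columns the record table is expected to carry after harmonization
.HARMONIZED_COLS <- c(
  "record_id", "compound_structure", "source_id", "reference_id",
  "measure_name", "relation", "value", "unit", "value_kind", "potency_nM",
  "inhibition_pct", "test_concentration_uM", "assay_class", "is_hts_source",
  "exclusion_reason", "year"
)

#' Merged, standardized compound collection
#'
#' Container produced by \code{\link{standardizeCompounds}}: one row of
#' \code{compoundData} per distinct canonical structure key, and the full
#' harmonized record table in \code{recordData}, linked by
#' \code{canonical_key}. The design mirrors the rowData/assay split of
#' Bioconductor containers: per-compound annotation separate from
#' per-observation data.
#'
#' @slot compounds data.frame with columns \code{canonical_key}, \code{mw},
#'   \code{heavy_atoms}, \code{filter_status}, \code{fail_reasons},
#'   \code{first_year} and (once computed) \code{framework}.
#' @slot records data.frame of harmonized records with a
#'   \code{canonical_key} column.
#' @slot metadata list; provenance notes (canonicalizer identity etc.).
#' @export
setClass("CompoundSet", representation(
  compounds = "data.frame",
  records = "data.frame",
  metadata = "list"
))

setValidity("CompoundSet", function(object) {
  msg <- character(0)
  cd <- object@compounds
  need <- c("canonical_key", "mw", "heavy_atoms", "filter_status", "fail_reasons")
  if (!all(need %in% names(cd)))
    msg <- c(msg, paste("compounds must carry columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(cd$canonical_key))
    msg <- c(msg, "canonical_key must be unique per compound")
  if (nrow(object@records) &&
      !all(object@records$canonical_key %in% c(cd$canonical_key, NA)))
    msg <- c(msg, "every record must map to a known compound")
  if (length(msg)) msg else TRUE
})

#' Classified compound collection
#'
#' A \linkS4class{CompoundSet} whose compound table additionally carries the
#' consensus label (\code{inhibitor}, \code{inactive}, \code{inconclusive},
#' \code{unclassified}), the deciding stage, the vote tallies and the record
#' ids removed as outliers.
#'
#' @export
setClass("ClassifiedSet", contains = "CompoundSet")

setValidity("ClassifiedSet", function(object) {
  cd <- object@compounds
  need <- c("label", "stage", "votes_positive", "votes_negative")
  if (!all(need %in% names(cd)))
    return(paste("classified compounds must carry:", paste(need, collapse = ", ")))
  if (!all(cd$label %in% c("inhibitor", "inactive", "inconclusive", "unclassified")))
    return("unknown label value")
  TRUE
})

#' @describeIn CompoundSet number of compounds
#' @param object a CompoundSet
#' @export
setMethod("show", "CompoundSet", function(object) {
  cd <- object@compounds
  cat(class(object), "with", nrow(cd), "compounds and",
      nrow(object@records), "records\n")
  if (nrow(cd)) {
    cat("  filter: ", sum(cd$filter_status == "pass"), " pass / ",
        sum(cd$filter_status == "fail"), " fail\n", sep = "")
  }
  if (is(object, "ClassifiedSet") && nrow(cd)) {
    tab <- table(cd$label)
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(NULL)
})

#' Accessors for compound collections
#'
#' @param x a \linkS4class{CompoundSet} (or \linkS4class{ClassifiedSet}).
#' @return \code{compoundData} and \code{recordData} return data.frames;
#'   \code{canonicalKeys} a character vector; \code{compoundLabels} the label
#'   vector (classified sets only).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("compoundData", function(x) standardGeneric("compoundData"))
#' @rdname accessors
#' @export
setMethod("compoundData", "CompoundSet", function(x) x@compounds)

#' @rdname accessors
#' @export
setGeneric("recordData", function(x) standardGeneric("recordData"))
#' @rdname accessors
#' @export
setMethod("recordData", "CompoundSet", function(x) x@records)

#' @rdname accessors
#' @export
setGeneric("canonicalKeys", function(x) standardGeneric("canonicalKeys"))
#' @rdname accessors
#' @export
setMethod("canonicalKeys", "CompoundSet", function(x) x@compounds$canonical_key)

#' @rdname accessors
#' @export
setGeneric("compoundLabels", function(x) standardGeneric("compoundLabels"))
#' @rdname accessors
#' @export
setMethod("compoundLabels", "ClassifiedSet", function(x) {
  stats::setNames(x@compounds$label, x@compounds$canonical_key)
})
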