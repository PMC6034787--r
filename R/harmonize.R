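# Harmonization: value-kind taxonomy, unit normalization, remaining->
# inhibition conversion, source-specific exclusions, assay-class assignment
# and HTS-source flagging.

#' Keyword dictionaries driving the text-based steps
#'
#' The measure taxonomy, assay-protocol classification and qualitative
#' comment detection are all case-insensitive substring matches against
#' editable dictionaries: a transparent, reproducible stand-in for manual
#' curation of free-text assay descriptions.
#'
#' @return list of character vectors: \code{ic50_like}, \code{log_forms},
#'   \code{inhibition}, \code{remaining}, \code{qualitative_negative},
#'   \code{discard}, \code{electrostatic}, \code{binding},
#'   \code{validity_flags}.
#' @export
defaultKeywordDictionaries <- function() {
  list(
    ic50_like = c("ic50", "ec50", "ed50", "ki", "kd"),
    log_forms = c("pic50", "pec50", "ped50", "pki", "pkd",
                  "log ic50", "-log ic50", "log(ic50)"),
    inhibition = c("% inhibition", "percent inhibition", "inhibition",
                   "inhibitory activity", "% block", "percent block", "block"),
    remaining = c("remaining", "residual"),
    qualitative_negative = c("no activity", "not active", "no inhibition",
                             "no significant inhibition", "inactive"),
    discard = c("current", "qt interval", "qt ratio", "selectivity",
                "tail current", "fold change"),
    electrostatic = c("patch clamp", "patch-clamp", "ionworks", "qpatch",
                      "current", "voltage", "electrophys", "flux",
                      "population patch"),
    binding = c("binding", "displacement", "radioligand", "radio-ligand",
                "[3h]", "dofetilide", "astemizole", "mk-499"),
    validity_flags = c("nonstandard unit for type", "outside typical range")
  )
}

.norm_measure <- function(x) gsub("[ _]+", " ", trimws(tolower(x)))

#' Classify a measure/unit pair into a value kind
#'
#' Point-potency measures (IC50, EC50, ED50, Ki, Kd and their log forms)
#' become \code{ic50_like}; percent-inhibition and percent-remaining
#' measures become \code{inhibition_like}; measures matching the
#' "no activity" dictionary become \code{qualitative_negative}. Non-50\%
#' threshold concentrations (IC70, IC30, ...), raw currents, QT ratios and
#' anything unrecognized are \code{excluded}, with a reason recorded by the
#' harmonization driver.
#'
#' @param measure_name character vector of measure labels.
#' @param unit character vector of unit labels (same length or length 1).
#' @param dict keyword dictionaries; see
#'   \code{\link{defaultKeywordDictionaries}}.
#' @return character vector in \code{c("ic50_like", "inhibition_like",
#'   "qualitative_negative", "excluded")}.
#' @examples
#' classifyValueKind("Ki", "nM")        # ic50_like
#' classifyValueKind("IC70", "uM")      # excluded
#' classifyValueKind("% inhibition", "%")  # inhibition_like
#' @export
classifyValueKind <- function(measure_name, unit = "",
                              dict = defaultKeywordDictionaries()) {
  n <- max(length(measure_name), length(unit))
  measure_name <- rep_len(as.character(measure_name), n)
  unit <- rep_len(as.character(unit), n)
  vapply(seq_len(n), function(i) {
    m <- .norm_measure(measure_name[i])
    if (is.na(m) || !nzchar(m)) return("excluded")
    if (m %in% dict$log_forms || m %in% dict$ic50_like) return("ic50_like")
    # IC<nn> style thresholds other than 50
    mm <- regmatches(m, regexec("^[ie]c([0-9]{1,3})$", m))[[1]]
    if (length(mm) == 2L) {
      return(if (identical(mm[2], "50")) "ic50_like" else "excluded")
    }
    if (any(vapply(dict$qualitative_negative, grepl, logical(1), x = m, fixed = TRUE)))
      return("qualitative_negative")
    if (any(vapply(dict$remaining, grepl, logical(1), x = m, fixed = TRUE)))
      return("inhibition_like")
    if (any(vapply(dict$discard, grepl, logical(1), x = m, fixed = TRUE)))
      return("excluded")
    if (any(vapply(dict$inhibition, grepl, logical(1), x = m, fixed = TRUE)))
      return("inhibition_like")
    "excluded"
  }, character(1))
}

#' Detect log-form potency measures
#'
#' A measure is a log form when its name begins with "p" ahead of a known
#' potency measure (pIC50, pKi, ...) or the unit is a -log(M) style label.
#'
#' @inheritParams classifyValueKind
#' @return logical vector.
#' @export
isLogForm <- function(measure_name, unit = "",
                      dict = defaultKeywordDictionaries()) {
  n <- max(length(measure_name), length(unit))
  m <- .norm_measure(rep_len(as.character(measure_name), n))
  u <- tolower(trimws(rep_len(as.character(unit), n)))
  in_log <- m %in% dict$log_forms
  log_unit <- !is.na(u) & u %in% c("-log(m)", "-log m", "log m", "-logm")
  (!is.na(m) & in_log) | log_unit
}

.UNIT_TO_NM <- c("m" = 1e9, "mm" = 1e6, "um" = 1e3, "µm" = 1e3,
                 "μm" = 1e3, "nm" = 1, "pm" = 1e-3)

#' Convert a potency value to nanomolar
#'
#' Exact scale conversion for molar units; log forms are converted as
#' \code{10^(9 - x)} nM (pIC50 6 is 1000 nM). Unit conversion happens
#' exactly once, at harmonization: all potencies are stored in nM
#' downstream.
#'
#' @param value numeric vector.
#' @param unit character vector of unit labels.
#' @param is_log_form logical vector; TRUE for pIC50-style values.
#' @return numeric vector of potencies in nM; NA where the unit is not
#'   recognized (the driver then excludes the record with reason "unit").
#' @examples
#' toNanomolar(1, "uM", FALSE)    # 1000
#' toNanomolar(6, "pIC50", TRUE)  # 1000
#' @export
toNanomolar <- function(value, unit, is_log_form = FALSE) {
  n <- max(length(value), length(unit), length(is_log_form))
  value <- rep_len(as.numeric(value), n)
  unit <- rep_len(as.character(unit), n)
  is_log_form <- rep_len(as.logical(is_log_form), n)
  out <- rep(NA_real_, n)
  out[is_log_form] <- 10^(9 - value[is_log_form])
  u <- tolower(trimws(unit))
  f <- .UNIT_TO_NM[u]
  sel <- !is_log_form & !is.na(f)
  out[sel] <- value[sel] * f[sel]
  out
}

#' Convert percent remaining activity to percent inhibition
#'
#' @param pct_remaining numeric vector.
#' @return \code{100 - pct_remaining}.
#' @export
remainingToInhibition <- function(pct_remaining) 100 - pct_remaining

#' Complement a missing test concentration from the assay description
#'
#' Scans the free-text assay description for an "at <x> uM/nM/mM" pattern
#' and returns the concentration in micromolar; \code{NA} when no
#' concentration can be recovered (the driver then excludes the record with
#' reason "no concentration").
#'
#' @param assay_description character vector.
#' @return numeric vector of concentrations in uM (NA when not found).
#' @examples
#' complementConcentration("inhibition at 10 uM")    # 10
#' complementConcentration("percent block at 300 nM") # 0.3
#' @export
complementConcentration <- function(assay_description) {
  pat <- "(?:at|@)\\s*([0-9]*\\.?[0-9]+)\\s*(p|n|u|µ|μ|m)?M"
  vapply(as.character(assay_description), function(d) {
    if (is.na(d)) return(NA_real_)
    m <- regmatches(d, regexec(pat, d, ignore.case = TRUE))[[1]]
    if (length(m) < 2L || !nzchar(m[2])) return(NA_real_)
    val <- as.numeric(m[2])
    scale <- tolower(m[3])
    mult <- switch(ifelse(nzchar(scale), scale, "molar"),
                   "p" = 1e-6, "n" = 1e-3, "u" = 1, "µ" = 1,
                   "μ" = 1, "m" = 1e3, "molar" = 1e6)
    val * mult
  }, numeric(1), USE.NAMES = FALSE)
}

#' Assign the assay protocol class from the assay description
#'
#' Electrostatic assays (automated patch clamp and other current/voltage
#' measurements) and binding assays (radioligand displacement) are told
#' apart by a keyword dictionary; descriptions matching neither or both
#' classes are \code{unknown}.
#'
#' @param assay_description character vector.
#' @param dict keyword dictionaries.
#' @return character vector in \code{c("binding", "electrostatic",
#'   "unknown")}.
#' @examples
#' assignAssayClass("automated patch clamp")            # electrostatic
#' assignAssayClass("[3H]dofetilide displacement binding") # binding
#' assignAssayClass("hERG assay")                        # unknown
#' @export
assignAssayClass <- function(assay_description,
                             dict = defaultKeywordDictionaries()) {
  vapply(as.character(assay_description), function(d) {
    eb <- matchesAny(d, dict$binding)
    ee <- matchesAny(d, dict$electrostatic)
    if (eb && !ee) "binding" else if (ee && !eb) "electrostatic" else "unknown"
  }, character(1), USE.NAMES = FALSE)
}

#' Apply source-specific record filters
#'
#' Excludes records whose data validity comment carries a known curation
#' flag ("Nonstandard unit for type", "Outside typical range"), whose
#' outcome comment contains "Inconclusive", or whose phenotype is
#' \code{activator} (activation entries are out of scope for an inhibition
#' dataset). Cross-source duplicates -- identical (reference, structure,
#' measure, value, unit) -- collapse to the first occurrence.
#'
#' @param records activity record data.frame.
#' @param dict keyword dictionaries.
#' @return the records with an \code{exclusion_reason} column
#'   (\code{NA} = keep); duplicate rows carry reason \code{"duplicate"}.
#' @export
applySourceFilters <- function(records, dict = defaultKeywordDictionaries()) {
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  dv <- tolower(ifelse(is.na(records$data_validity_comment), "",
                       records$data_validity_comment))
  for (flag in dict$validity_flags) {
    reason[is.na(reason) & grepl(flag, dv, fixed = TRUE)] <- "data validity"
  }
  oc <- tolower(ifelse(is.na(records$outcome_comment), "", records$outcome_comment))
  reason[is.na(reason) & grepl("inconclusive", oc, fixed = TRUE)] <- "inconclusive"
  reason[is.na(reason) & records$phenotype %in% "activator"] <- "activator"
  dup_key <- paste(records$reference_id, records$compound_structure,
                   .norm_measure(records$measure_name), records$value,
                   tolower(records$unit), sep = "\r")
  has_ref <- !is.na(records$reference_id)
  dup <- duplicated(dup_key) & has_ref
  reason[is.na(reason) & dup] <- "duplicate"
  records$exclusion_reason <- reason
  records
}

#' Harmonize raw activity records
#'
#' Drives the full harmonization of a raw activity table: source filters,
#' value-kind taxonomy, unit conversion to nM, remaining-to-inhibition
#' conversion, concentration complementation from assay descriptions,
#' assay-class assignment and HTS-source flagging. Every input record maps
#' to exactly one of \{harmonized, excluded-with-reason\}; counts conserve.
#'
#' Records whose measure is absent but whose outcome comment matches the
#' "no activity" dictionary are routed to \code{qualitative_negative}.
#' Percent values outside [0, 100] are retained as measured (a message is
#' emitted); clipping would distort vote boundaries.
#'
#' @param records activity record data.frame from
#'   \code{\link{readActivityTable}}.
#' @param config a \linkS4class{HergConfig}.
#' @param dict keyword dictionaries.
#' @param verbose emit per-reason exclusion counts.
#' @return data.frame of harmonized records: all input rows, with
#'   \code{value_kind}, \code{potency_nM}, \code{inhibition_pct},
#'   \code{test_concentration_uM}, \code{assay_class}, \code{is_hts_source}
#'   and \code{exclusion_reason} columns. Rows with
#'   \code{value_kind == "excluded"} carry their reason.
#' @export
harmonizeRecords <- function(records, config = hergConfig(),
                             dict = defaultKeywordDictionaries(),
                             verbose = FALSE) {
  stopifnot(is.data.frame(records))
  n <- nrow(records)
  if (!"invalid" %in% names(records)) records$invalid <- FALSE
  records <- applySourceFilters(records, dict)
  kind <- classifyValueKind(records$measure_name, records$unit, dict)
  # measure-less records with a "no activity" comment are qualitative negatives
  oc <- tolower(ifelse(is.na(records$outcome_comment), "", records$outcome_comment))
  no_measure <- is.na(records$measure_name) | !nzchar(trimws(records$measure_name))
  qual_by_comment <- no_measure & vapply(
    oc, function(x) matchesAny(x, dict$qualitative_negative), logical(1),
    USE.NAMES = FALSE)
  kind[qual_by_comment] <- "qualitative_negative"

  reason <- records$exclusion_reason
  reason[is.na(reason) & records$invalid] <- "invalid record"
  reason[is.na(reason) & kind == "excluded"] <- vapply(
    which(is.na(reason) & kind == "excluded"), function(i) {
      m <- .norm_measure(records$measure_name[i])
      if (!is.na(m) && grepl("^[ie]c[0-9]{1,3}$", m) && !grepl("50$", m))
        "non-50% threshold" else "unrecognized measure"
    }, character(1))

  log_form <- isLogForm(records$measure_name, records$unit, dict)
  potency <- rep(NA_real_, n)
  sel_ic <- kind == "ic50_like" & is.na(reason)
  potency[sel_ic] <- toNanomolar(records$value[sel_ic], records$unit[sel_ic],
                                 log_form[sel_ic])
  bad_unit <- sel_ic & is.na(potency) & !is.na(records$value)
  reason[bad_unit] <- "unit"
  bad_val <- sel_ic & is.na(records$value) & records$relation %in% c("=", "<", ">")
  reason[is.na(reason) & bad_val] <- "no value"
  nonpos <- sel_ic & !is.na(potency) & potency <= 0
  reason[is.na(reason) & nonpos] <- "non-positive potency"
  potency[nonpos] <- NA_real_

  inh <- rep(NA_real_, n)
  sel_in <- kind == "inhibition_like" & is.na(reason)
  is_remaining <- vapply(.norm_measure(records$measure_name), function(m) {
    !is.na(m) && any(vapply(dict$remaining, grepl, logical(1), x = m, fixed = TRUE))
  }, logical(1), USE.NAMES = FALSE)
  inh[sel_in] <- ifelse(is_remaining[sel_in],
                        remainingToInhibition(records$value[sel_in]),
                        records$value[sel_in])
  reason[sel_in & is.na(inh)] <- "no value"

  conc <- records$test_concentration_uM
  need_conc <- sel_in & is.na(conc) & is.na(reason)
  conc[need_conc] <- complementConcentration(records$assay_description[need_conc])
  reason[sel_in & is.na(conc) & is.na(reason)] <- "no concentration"

  out_of_range <- sel_in & !is.na(inh) & (inh < 0 | inh > 100)
  if (any(out_of_range) && verbose) {
    message(sum(out_of_range),
            " percent value(s) outside [0,100] retained as measured")
  }

  kind[!is.na(reason)] <- "excluded"
  potency[kind != "ic50_like"] <- NA_real_
  inh[kind != "inhibition_like"] <- NA_real_
  conc[kind != "inhibition_like"] <- NA_real_

  relation <- records$relation
  relation[kind %in% c("ic50_like", "inhibition_like") & relation == "none"] <- "="

  out <- records
  out$value_kind <- kind
  out$potency_nM <- potency
  out$inhibition_pct <- inh
  out$test_concentration_uM <- conc
  out$relation <- relation
  out$assay_class <- assignAssayClass(records$assay_description, dict)
  out$exclusion_reason <- reason
  out$is_hts_source <- FALSE
  out <- flagHtsSources(out, config)
  .log_exclusions(out[out$value_kind == "excluded", , drop = FALSE],
                  "harmonize", verbose)
  out
}

#' Flag HTS-scale data sources
#'
#' A source is HTS-like when it contributes inhibition-type records for
#' strictly more than \code{hts_source_min_compounds} distinct compounds;
#' the flag is set on that source's inhibition-type records only (the
#' stricter vote thresholds apply to single-concentration data, never to
#' IC50-type records).
#'
#' @param records harmonized record data.frame.
#' @param config a \linkS4class{HergConfig}.
#' @return the records with \code{is_hts_source} updated.
#' @export
flagHtsSources <- function(records, config = hergConfig()) {
  records$is_hts_source <- FALSE
  sel <- records$value_kind == "inhibition_like"
  if (!any(sel)) return(records)
  cnt <- tapply(records$compound_structure[sel], records$source_id[sel],
                function(x) length(unique(x)))
  hts_sources <- names(cnt)[cnt > config@hts_source_min_compounds]
  records$is_hts_source[sel & records$source_id %in% hts_sources] <- TRUE
  records
}
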