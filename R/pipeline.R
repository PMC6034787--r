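# Pipeline orchestration: harmonize -> standardize -> merge -> classify ->
# diversity -> properties -> assay comparison, with funnel accounting.

#' Run the full integration pipeline
#'
#' Executes every stage on a raw activity table and returns the classified
#' compound set together with a funnel report whose counts reconcile
#' exactly from stage to stage (every excluded record carries a reason;
#' nothing is silently dropped).
#'
#' @param records raw activity record data.frame (from
#'   \code{\link{readActivityTable}} or \code{\link{generateSynthData}}).
#' @param config a \linkS4class{HergConfig}.
#' @param compute_frameworks attach Murcko frameworks (default TRUE).
#' @param compute_properties attach the 12-descriptor profile (default
#'   FALSE; descriptor computation dominates run time on large sets).
#' @param outdir optional directory; when given, the integrated table,
#'   funnel report (JSON) and per-class summaries are written there.
#' @param verbose logical.
#' @return list with elements \code{result} (a
#'   \linkS4class{ClassifiedSet}), \code{harmonized} (record table) and
#'   \code{funnel} (named list of stage counts).
#' @export
runPipeline <- function(records, config = hergConfig(),
                        compute_frameworks = TRUE,
                        compute_properties = FALSE,
                        outdir = NULL, verbose = FALSE) {
  if (!is.data.frame(records) || !nrow(records)) {
    stop("[ingest] no input records", call. = FALSE)
  }
  harm <- harmonizeRecords(records, config, verbose = verbose)
  excl <- harm[harm$value_kind == "excluded", , drop = FALSE]
  cs <- standardizeCompounds(harm, config, verbose = verbose)
  cls <- classifyCompounds(cs, config)
  if (compute_frameworks) cls <- addFrameworks(cls, config)
  if (compute_properties) cls <- addProperties(cls)

  cd <- compoundData(cls)
  funnel <- list(
    n_input_records = nrow(records),
    n_excluded_records = nrow(excl),
    excluded_by_reason = as.list(table(excl$exclusion_reason)),
    n_harmonized_records = sum(harm$value_kind != "excluded"),
    n_unparseable_records = cls@metadata$n_unparseable_records,
    n_merged_compounds = nrow(compoundData(cs)),
    n_filtered_out_compounds = sum(compoundData(cs)$filter_status == "fail"),
    n_classified_compounds = nrow(cd),
    labels = as.list(table(cd$label)),
    per_source_records = as.list(table(records$source_id))
  )
  # reconciliation: input = excluded + harmonized
  stopifnot(funnel$n_input_records ==
              funnel$n_excluded_records + funnel$n_harmonized_records)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    writeIntegratedTable(cls, file.path(outdir, "integrated.csv"))
    jsonlite::write_json(funnel, file.path(outdir, "funnel.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(result = cls, harmonized = harm, funnel = funnel)
}

#' Per-source and integrated compound/framework counts
#'
#' Builds the per-source and integrated tabulation of compound and unique
#' Murcko framework counts for inhibitors, inactives and their union.
#' Because sources share compounds, the integrated row counts the union of
#' per-source compound sets, not their sum; within every row, inhibitors
#' plus inactives equals the "all" column.
#'
#' @param x a \linkS4class{ClassifiedSet} with frameworks attached.
#' @return data.frame with columns \code{source}, \code{class},
#'   \code{n_compounds}, \code{n_frameworks}.
#' @export
makeTable1 <- function(x) {
  stopifnot(is(x, "ClassifiedSet"))
  x <- addFrameworks(x)
  cd <- compoundData(x)
  rec <- recordData(x)
  cd <- cd[cd$label %in% c("inhibitor", "inactive"), , drop = FALSE]
  src_of <- split(rec$source_id, rec$canonical_key)
  rows <- list()
  tally <- function(sub, source_label) {
    for (cl in c("inhibitor", "inactive", "all")) {
      s <- if (cl == "all") sub else sub[sub$label == cl, , drop = FALSE]
      rows[[length(rows) + 1L]] <<- data.frame(
        source = source_label, class = cl,
        n_compounds = nrow(s),
        n_frameworks = length(unique(s$framework[!is.na(s$framework)])),
        stringsAsFactors = FALSE)
    }
  }
  for (sid in sort(unique(rec$source_id))) {
    keys <- names(src_of)[vapply(src_of, function(v) sid %in% v, logical(1))]
    tally(cd[cd$canonical_key %in% keys, , drop = FALSE], sid)
  }
  tally(cd, "integrated")
  do.call(rbind, rows)
}
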