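# Reading/writing the interchange formats: activity tables (CSV/TSV),
# structure SDF files, and the integrated output table.

.ACTIVITY_COLS <- c(
  "record_id", "compound_structure", "source_id", "reference_id",
  "measure_name", "relation", "value", "unit", "test_concentration_uM",
  "assay_description", "phenotype", "outcome_comment",
  "data_validity_comment", "year"
)

#' Default column mapping for activity tables
#'
#' Sources differ in their column schemas; the reader takes a named character
#' vector mapping internal field names to file column names. The default is
#' the identity mapping for the package's own interchange format (also the
#' format the synthetic generator emits).
#'
#' @return named character vector (internal name -> file column name).
#' @export
defaultColumnMapping <- function() {
  stats::setNames(.ACTIVITY_COLS, .ACTIVITY_COLS)
}

#' Read an activity table
#'
#' Reads one raw assay observation per row. Missing cells become \code{NA}
#' (or \code{"none"} for the categorical fields \code{relation} and
#' \code{phenotype}). A row that carries a relation qualifier but no value
#' violates the record invariant; such rows are kept and flagged in the
#' \code{invalid} column (with a message), never silently dropped, so that
#' record counts always reconcile.
#'
#' @param path file path.
#' @param format \code{"csv"} or \code{"tsv"}.
#' @param mapping named character vector (internal field -> file column);
#'   see \code{\link{defaultColumnMapping}}.
#' @return data.frame of activity records in file order, with an
#'   \code{invalid} logical column.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' df <- data.frame(record_id = "r1", compound_structure = "CCO",
#'                  source_id = "src", reference_id = "ref",
#'                  measure_name = "IC50", relation = "=", value = 1,
#'                  unit = "uM", test_concentration_uM = NA,
#'                  assay_description = "patch clamp", phenotype = "",
#'                  outcome_comment = "", data_validity_comment = "",
#'                  year = 2010)
#' write.csv(df, f, row.names = FALSE)
#' readActivityTable(f)
#' @export
readActivityTable <- function(path, format = c("csv", "tsv"),
                              mapping = defaultColumnMapping()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read activity table: ", path, call. = FALSE)
  sep <- if (format == "csv") "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, comment.char = "",
                           check.names = FALSE, colClasses = "character",
                           fileEncoding = "UTF-8")
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (field in .ACTIVITY_COLS) {
    col <- mapping[[field]]
    if (!is.null(col) && col %in% names(raw)) {
      out[[field]] <- raw[[col]]
    } else {
      out[[field]] <- rep(NA_character_, nrow(raw))
    }
  }
  blank2na <- function(x) { x[!nzchar(trimws(x)) | is.na(x)] <- NA_character_; x }
  for (field in .ACTIVITY_COLS) out[[field]] <- blank2na(out[[field]])
  out$value <- suppressWarnings(as.numeric(out$value))
  out$test_concentration_uM <- suppressWarnings(as.numeric(out$test_concentration_uM))
  out$year <- suppressWarnings(as.integer(out$year))
  out$relation[is.na(out$relation)] <- "none"
  out$phenotype[is.na(out$phenotype)] <- "none"
  out$phenotype <- tolower(out$phenotype)
  out$invalid <- out$relation %in% c("=", "<", ">") & is.na(out$value)
  if (any(out$invalid)) {
    message(sum(out$invalid),
            " record(s) carry a relation but no value; flagged invalid")
  }
  if (any(!is.na(out$test_concentration_uM) & out$test_concentration_uM <= 0)) {
    bad <- !is.na(out$test_concentration_uM) & out$test_concentration_uM <= 0
    out$invalid <- out$invalid | bad
    message(sum(bad), " record(s) have non-positive test concentration; flagged invalid")
  }
  rownames(out) <- NULL
  out
}

#' Write an activity table
#'
#' Inverse of \code{\link{readActivityTable}} for the interchange format;
#' a read-write-read cycle preserves every field.
#'
#' @param records activity record data.frame.
#' @param path output path.
#' @param format \code{"csv"} or \code{"tsv"}.
#' @return invisibly, the path.
#' @export
writeActivityTable <- function(records, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  sep <- if (format == "csv") "," else "\t"
  cols <- intersect(.ACTIVITY_COLS, names(records))
  utils::write.table(records[, cols, drop = FALSE], path, sep = sep,
                     row.names = FALSE, quote = TRUE, na = "",
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read structures from an SDF (V2000) file
#'
#' Every parseable molecule is keyed by its identifier: the value of the
#' named data field \code{id_field} when present, otherwise the molecule
#' title line. Unparseable entries are counted and reported, not silently
#' dropped; a file with zero parseable molecules is an error.
#'
#' @param path SDF file path.
#' @param id_field optional name of the SDF data field holding the record
#'   identifier.
#' @return named character vector of SMILES, one per parseable molecule.
#' @export
readStructuresSDF <- function(path, id_field = NULL) {
  if (!file.exists(path)) stop("cannot read SDF: ", path, call. = FALSE)
  sdf <- suppressWarnings(ChemmineR::read.SDFset(path))
  ok <- ChemmineR::validSDF(sdf)
  n_bad <- sum(!ok)
  if (!any(ok)) stop("no parseable molecules in ", path, call. = FALSE)
  if (n_bad) message(n_bad, " unparseable SDF entr(y/ies) skipped")
  sdf <- sdf[ok]
  smi_raw <- tryCatch(ChemmineR::sdf2smiles(sdf), error = function(e) NULL)
  if (is.null(smi_raw)) stop("SMILES conversion failed for ", path, call. = FALSE)
  smi <- unname(as.character(smi_raw))
  ids <- ChemmineR::sdfid(sdf)
  if (!is.null(id_field)) {
    db <- ChemmineR::datablock(sdf)
    got <- vapply(db, function(d) {
      if (id_field %in% names(d)) d[[id_field]] else NA_character_
    }, character(1))
    ids <- ifelse(is.na(got), ids, got)
  }
  stats::setNames(smi, ids)
}

#' Write the integrated compound table
#'
#' Emits the classified compound set as a CSV (canonical key, label, stage,
#' vote tallies, drug-likeness verdict, per-source provenance and first
#' year) plus a companion SDF of the standardized structures. The persisted
#' fields round-trip losslessly through \code{\link{readIntegratedTable}}.
#'
#' @param x a \linkS4class{ClassifiedSet}.
#' @param path output CSV path; the SDF is written next to it with extension
#'   \code{.sdf}.
#' @param write_sdf write the companion SDF (default TRUE).
#' @return invisibly, a character vector of the written paths.
#' @export
writeIntegratedTable <- function(x, path, write_sdf = TRUE) {
  stopifnot(is(x, "ClassifiedSet"))
  cd <- compoundData(x)
  rec <- recordData(x)
  if (!nrow(cd)) message("writing empty integrated table (header only)")
  src <- vapply(cd$canonical_key, function(k) {
    paste(sort(unique(rec$source_id[rec$canonical_key %in% k])), collapse = ";")
  }, character(1))
  tab <- data.frame(
    canonical_key = cd$canonical_key,
    label = cd$label,
    stage = cd$stage,
    votes_positive = cd$votes_positive,
    votes_negative = cd$votes_negative,
    removed_outlier_record_ids = cd$removed_outlier_record_ids,
    mw = cd$mw,
    heavy_atoms = cd$heavy_atoms,
    filter_status = cd$filter_status,
    fail_reasons = cd$fail_reasons,
    first_year = cd$first_year,
    sources = unname(src),
    stringsAsFactors = FALSE
  )
  if ("framework" %in% names(cd)) tab$framework <- cd$framework
  utils::write.table(tab, path, sep = ",", row.names = FALSE, quote = TRUE,
                     na = "", fileEncoding = "UTF-8")
  paths <- path
  if (write_sdf && nrow(tab)) {
    sdf_path <- sub("\\.[^.]+$", ".sdf", path)
    if (identical(sdf_path, path)) sdf_path <- paste0(path, ".sdf")
    keys <- tab$canonical_key
    sdf <- suppressWarnings(
      ChemmineR::smiles2sdf(stats::setNames(keys, keys)))
    ChemmineR::write.SDF(sdf, sdf_path)
    paths <- c(paths, sdf_path)
  }
  invisible(paths)
}

#' Read an integrated compound table written by \code{writeIntegratedTable}
#'
#' @param path CSV path.
#' @return data.frame of the persisted compound fields.
#' @export
readIntegratedTable <- function(path) {
  if (!file.exists(path)) stop("cannot read integrated table: ", path, call. = FALSE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                         fileEncoding = "UTF-8")
  for (col in c("votes_positive", "votes_negative", "first_year", "heavy_atoms")) {
    if (col %in% names(out)) out[[col]] <- suppressWarnings(as.integer(out[[col]]))
  }
  if ("mw" %in% names(out)) out$mw <- suppressWarnings(as.numeric(out$mw))
  out
}
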