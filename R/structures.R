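# Structure standardization, drug-likeness filtering and structure-keyed
# merging of harmonized records into compounds.

#' Desalt a SMILES string
#'
#' Keeps the largest organic fragment: fragments containing carbon are
#' preferred over purely inorganic counter-ions; ties break by heavy-atom
#' count, then string length, then lexicographic order (deterministic).
#'
#' @param smiles character vector.
#' @return character vector of parent-fragment SMILES.
#' @export
desaltSmiles <- function(smiles) {
  vapply(as.character(smiles), function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    frags <- strsplit(s, ".", fixed = TRUE)[[1]]
    if (length(frags) == 1L) return(s)
    has_c <- vapply(frags, function(f) {
      any(smilesAtoms(f)$element == "C")
    }, logical(1))
    pool <- if (any(has_c)) frags[has_c] else frags
    ha <- smilesHeavyAtoms(pool)
    pool <- pool[ha == max(ha)]
    pool <- pool[nchar(pool) == max(nchar(pool))]
    sort(pool)[1]
  }, character(1), USE.NAMES = FALSE)
}

#' Standardize chemical structures to canonical parent keys
#'
#' Applies the standardization chain: desalting (largest organic fragment),
#' neutralization of protonation states where chemically valid (permanent
#' charges such as quaternary ammonium are retained), deterministic
#' canonical tautomer selection via a standard InChI round-trip (mobile-H
#' tautomers collapse), and canonical SMILES serialization. Chemically
#' identical inputs map to identical keys; stereochemistry is preserved
#' (enantiomers remain distinct). The function is idempotent.
#'
#' @param smiles character vector of raw structures.
#' @return character vector of canonical keys; \code{NA} for unparseable
#'   input.
#' @examples
#' \dontrun{
#' standardizeStructure(c("CCN.Cl", "CC[NH3+].[Cl-]", "CCN"))
#' # all three give the same key
#' }
#' @export
standardizeStructure <- function(smiles) {
  n <- length(smiles)
  if (!n) return(character(0))
  out <- rep(NA_character_, n)
  ok <- !is.na(smiles) & nzchar(smiles)
  if (!any(ok)) return(out)
  uniq <- unique(smiles[ok])
  parent <- desaltSmiles(uniq)
  neut <- obConvert(parent, "smi", "can", extra = "--neutralize")
  inchi <- obConvert(neut, "smi", "inchi")
  can <- obConvert(inchi, "inchi", "can")
  # fall back to the neutralized canonical SMILES when the InChI round-trip
  # fails for an otherwise parseable molecule
  can[is.na(can) & !is.na(neut)] <- neut[is.na(can) & !is.na(neut)]
  out[ok] <- can[match(smiles[ok], uniq)]
  out
}

#' Drug-likeness filter
#'
#' Fails structures that contain a metal atom (any element outside the
#' common organic subset H, B, C, N, O, F, Si, P, S, Cl, Se, Br, I), whose
#' molecular weight is below 150 or above 700 g/mol (bounds inclusive:
#' exactly 150 or 700 passes), with fewer than 10 heavy atoms (exactly 10
#' passes), or carrying a non-default isotope. All triggered reasons are
#' reported.
#'
#' @param canonical_key character vector of standardized SMILES keys
#'   (\code{NA} = unparseable).
#' @param mw numeric molecular weights (computed if missing).
#' @param heavy_atoms integer heavy-atom counts (computed if missing).
#' @param config a \linkS4class{HergConfig}.
#' @return data.frame with columns \code{filter_status} ("pass"/"fail") and
#'   \code{fail_reasons} (semicolon-joined subset of \code{metal},
#'   \code{mw_low}, \code{mw_high}, \code{too_few_atoms}, \code{isotope},
#'   \code{unparseable}).
#' @export
druglikeFilter <- function(canonical_key, mw = NULL, heavy_atoms = NULL,
                           config = hergConfig()) {
  n <- length(canonical_key)
  if (is.null(mw) || is.null(heavy_atoms)) {
    info <- structureInfo(canonical_key)
    if (is.null(mw)) mw <- info$mw
    if (is.null(heavy_atoms)) heavy_atoms <- info$heavy_atoms
  }
  reasons <- vector("list", n)
  for (i in seq_len(n)) {
    k <- canonical_key[i]
    if (is.na(k)) { reasons[[i]] <- "unparseable"; next }
    r <- character(0)
    atoms <- smilesAtoms(k)
    if (any(!atoms$element %in% .ORGANIC_ELEMENTS)) r <- c(r, "metal")
    if (!is.na(mw[i]) && mw[i] < config@mw_min) r <- c(r, "mw_low")
    if (!is.na(mw[i]) && mw[i] > config@mw_max) r <- c(r, "mw_high")
    if (!is.na(heavy_atoms[i]) && heavy_atoms[i] < config@min_heavy_atoms)
      r <- c(r, "too_few_atoms")
    if (any(atoms$isotope)) r <- c(r, "isotope")
    reasons[[i]] <- r
  }
  data.frame(
    filter_status = ifelse(lengths(reasons) > 0, "fail", "pass"),
    fail_reasons = vapply(reasons, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
}

#' Molecular weight and heavy-atom count for SMILES keys
#'
#' @param smiles character vector.
#' @return data.frame with \code{mw} and \code{heavy_atoms}.
#' @export
structureInfo <- function(smiles) {
  n <- length(smiles)
  mw <- rep(NA_real_, n); ha <- rep(NA_integer_, n)
  ok <- which(!is.na(smiles) & nzchar(smiles))
  if (length(ok)) {
    uniq <- unique(smiles[ok])
    sdf <- tryCatch(
      suppressWarnings(ChemmineR::smiles2sdf(
        stats::setNames(uniq, sprintf("s%06d", seq_along(uniq))))),
      error = function(e) NULL)
    if (!is.null(sdf)) {
      valid <- ChemmineR::validSDF(sdf)
      mw_u <- rep(NA_real_, length(uniq))
      ha_u <- rep(NA_integer_, length(uniq))
      if (any(valid)) {
        idx <- which(valid)
        mw_u[idx] <- suppressWarnings(ChemmineR::MW(sdf[valid], addH = TRUE))
        ha_u[idx] <- vapply(ChemmineR::atomcount(sdf[valid]), function(a) {
          sum(a[names(a) != "H"])
        }, numeric(1))
      }
      mw[ok] <- mw_u[match(smiles[ok], uniq)]
      ha[ok] <- ha_u[match(smiles[ok], uniq)]
    }
  }
  data.frame(mw = mw, heavy_atoms = as.integer(ha))
}

#' Merge harmonized records into compounds by canonical structure
#'
#' Standardizes every record's structure and groups records by canonical
#' key: one compound per distinct key, every non-excluded record assigned to
#' exactly one compound (record multiset conserved). Excluded records and
#' records whose structure cannot be parsed are reported via the returned
#' object's metadata.
#'
#' @param records harmonized record data.frame from
#'   \code{\link{harmonizeRecords}}.
#' @param config a \linkS4class{HergConfig}.
#' @param verbose logical.
#' @return a \linkS4class{CompoundSet}.
#' @export
standardizeCompounds <- function(records, config = hergConfig(),
                                 verbose = FALSE) {
  stopifnot(is.data.frame(records))
  keep <- records$value_kind != "excluded"
  rec <- records[keep, , drop = FALSE]
  rec$canonical_key <- standardizeStructure(rec$compound_structure)
  unparseable <- is.na(rec$canonical_key)
  if (any(unparseable) && verbose) {
    message(sum(unparseable), " record(s) with unparseable structures set aside")
  }
  body <- rec[!unparseable, , drop = FALSE]
  keys <- unique(body$canonical_key)
  info <- structureInfo(keys)
  filt <- druglikeFilter(keys, info$mw, info$heavy_atoms, config)
  first_year <- vapply(split(body$year, body$canonical_key)[keys], function(y) {
    y <- y[!is.na(y)]
    if (length(y)) min(y) else NA_integer_
  }, integer(1))
  compounds <- data.frame(
    canonical_key = keys,
    mw = info$mw,
    heavy_atoms = info$heavy_atoms,
    filter_status = filt$filter_status,
    fail_reasons = filt$fail_reasons,
    first_year = unname(first_year),
    stringsAsFactors = FALSE
  )
  methods::new("CompoundSet",
    compounds = compounds,
    records = body,
    metadata = list(
      canonicalizer = "OpenBabel canonical SMILES after desalting, --neutralize and standard InChI round-trip",
      n_input_records = nrow(records),
      n_excluded_records = sum(!keep),
      n_unparseable_records = sum(unparseable),
      unparseable_record_ids = rec$record_id[unparseable]
    ))
}

#' Drop compounds failing the drug-likeness filter
#'
#' @param x a \linkS4class{CompoundSet}.
#' @return a \linkS4class{CompoundSet} restricted to passing compounds.
#' @export
filterCompounds <- function(x) {
  stopifnot(is(x, "CompoundSet"))
  cd <- x@compounds
  keep_keys <- cd$canonical_key[cd$filter_status == "pass"]
  methods::initialize(x,
    compounds = cd[cd$filter_status == "pass", , drop = FALSE],
    records = x@records[x@records$canonical_key %in% keep_keys, , drop = FALSE],
    metadata = c(x@metadata,
                 list(n_filtered_compounds = sum(cd$filter_status == "fail"))))
}

#' Records-per-compound histogram
#'
#' Counts, for each compound, the assay records that specify a definite
#' value: relation \code{"="} with a value present (records using NULL
#' values or inequality qualifiers are not counted). A compound whose
#' records are all qualified contributes at count 0.
#'
#' @param x a \linkS4class{CompoundSet}.
#' @return data.frame with \code{n_records} and \code{n_compounds};
#'   one row per observed count (including 0).
#' @export
countRecordsPerCompound <- function(x) {
  stopifnot(is(x, "CompoundSet"))
  rec <- x@records
  definite <- rec$relation == "=" & (!is.na(rec$potency_nM) |
                                     !is.na(rec$inhibition_pct))
  cnt <- vapply(split(definite, rec$canonical_key), sum, numeric(1))
  all_keys <- x@compounds$canonical_key
  per_comp <- stats::setNames(rep(0, length(all_keys)), all_keys)
  per_comp[names(cnt)] <- cnt
  tab <- table(per_comp)
  data.frame(n_records = as.integer(names(tab)),
             n_compounds = as.integer(tab))
}
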