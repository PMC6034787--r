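# Murcko-framework decomposition, per-class scaffold counting, chemical
# space coverage, time series and per-scaffold potency spread.

# framework atoms by iterative terminal pruning: the ring systems plus the
# acyclic linker atoms on paths between them survive; everything else is a
# side chain. Optionally atoms attached to the surviving core by a multiple
# bond (exocyclic =O etc.) are retained.
.framework_atoms <- function(bonds, n_atoms, keep_exocyclic = TRUE) {
  keep <- rep(TRUE, n_atoms)
  if (!nrow(bonds)) return(logical(n_atoms))
  repeat {
    deg <- tabulate(c(bonds[keep[bonds[, 1]] & keep[bonds[, 2]], 1],
                      bonds[keep[bonds[, 1]] & keep[bonds[, 2]], 2]),
                    nbins = n_atoms)
    drop <- keep & deg <= 1L
    if (!any(drop)) break
    keep[drop] <- FALSE
  }
  if (!any(keep)) return(keep)
  if (keep_exocyclic) {
    sel <- bonds[, 3] >= 2L & (keep[bonds[, 1]] | keep[bonds[, 2]])
    keep[bonds[sel, 1]] <- TRUE
    keep[bonds[sel, 2]] <- TRUE
  }
  keep
}

#' Murcko framework of one or more structures
#'
#' The Murcko framework is the union of a molecule's ring systems and the
#' acyclic linker atoms connecting them; side-chain atoms are removed. By
#' default, atoms attached to the framework by a double or triple bond
#' (e.g. a carbonyl oxygen on a ring or linker) are retained, the common
#' convention. Acyclic molecules have no framework and return \code{NA}.
#' The result is canonically serialized, keeping elements and bond orders,
#' so that the framework of a framework is itself.
#'
#' @param smiles character vector of standardized structures.
#' @param keep_exocyclic retain exocyclic multiple-bond atoms (default
#'   TRUE).
#' @return character vector of canonical framework SMILES; \code{NA} for
#'   acyclic or unparseable molecules.
#' @examples
#' \dontrun{
#' murckoFramework("Cc1ccccc1")  # "c1ccccc1"
#' murckoFramework("CCCCCC")     # NA (no ring)
#' }
#' @export
murckoFramework <- function(smiles, keep_exocyclic = TRUE) {
  n <- length(smiles)
  if (!n) return(character(0))
  out <- rep(NA_character_, n)
  ok <- which(!is.na(smiles) & nzchar(smiles))
  if (!length(ok)) return(out)
  uniq <- unique(smiles[ok])
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(
      stats::setNames(uniq, sprintf("m%06d", seq_along(uniq))))),
    error = function(e) NULL)
  fw_u <- rep(NA_character_, length(uniq))
  if (!is.null(sdf)) {
    valid <- ChemmineR::validSDF(sdf)
    blocks <- character(0)
    block_of <- integer(0)
    for (i in which(valid)) {
      mol <- sdf[[i]]
      ab <- ChemmineR::atomblock(mol)
      bb <- ChemmineR::bondblock(mol)
      if (is.null(dim(bb)) || nrow(bb) == 0L) next
      bonds <- cbind(as.integer(bb[, 1]), as.integer(bb[, 2]),
                     as.integer(bb[, 3]))
      keep <- .framework_atoms(bonds, nrow(ab), keep_exocyclic)
      if (!any(keep)) next
      sub <- ChemmineR::atomsubset(mol, atomrows = which(keep),
                                   datablock = FALSE)
      tmp <- tempfile(fileext = ".sdf")
      ChemmineR::write.SDF(sub, tmp)
      txt <- readLines(tmp, warn = FALSE)
      unlink(tmp)
      txt <- txt[txt != "$$$$"]
      txt[1] <- sprintf("hdbk%07d", length(blocks) + 1L)
      blocks <- c(blocks, paste(txt, collapse = "\n"))
      block_of <- c(block_of, i)
    }
    if (length(blocks)) {
      keys <- obConvertSdfBlocks(blocks)
      fw_u[block_of] <- keys
    }
  }
  out[ok] <- fw_u[match(smiles[ok], uniq)]
  out
}

#' Attach Murcko frameworks to a compound collection
#'
#' Computes (once) the framework of every compound's canonical structure
#' and stores it in the compound table's \code{framework} column.
#'
#' @param x a \linkS4class{CompoundSet}.
#' @param config a \linkS4class{HergConfig}.
#' @return the updated object.
#' @export
addFrameworks <- function(x, config = hergConfig()) {
  stopifnot(is(x, "CompoundSet"))
  if (!"framework" %in% names(x@compounds)) {
    x@compounds$framework <- murckoFramework(
      x@compounds$canonical_key, config@framework_keep_exocyclic)
  }
  x
}

#' Per-class unique framework counts
#'
#' Counts the distinct Murcko frameworks over compounds of an activity
#' class. Compounds without a framework (acyclic) count towards
#' \code{n_compounds} but contribute no framework.
#'
#' @param x a \linkS4class{ClassifiedSet} with frameworks attached (they
#'   are computed on the fly otherwise).
#' @param class_label \code{"inhibitor"}, \code{"inactive"} or \code{"all"}
#'   (inhibitors plus inactives; inconclusive and unclassified compounds
#'   are excluded from class summaries).
#' @param reference_count optional size of a reference framework universe;
#'   when given, the coverage fraction is reported.
#' @return list with \code{class_label}, \code{n_compounds},
#'   \code{n_frameworks}, \code{framework_keys} and (optionally)
#'   \code{coverage_vs_reference}.
#' @export
countFrameworks <- function(x, class_label = c("all", "inhibitor", "inactive"),
                            reference_count = NULL) {
  stopifnot(is(x, "ClassifiedSet"))
  class_label <- match.arg(class_label)
  x <- addFrameworks(x)
  cd <- x@compounds
  sel <- if (class_label == "all") cd$label %in% c("inhibitor", "inactive")
         else cd$label == class_label
  fw <- unique(cd$framework[sel & !is.na(cd$framework)])
  out <- list(class_label = class_label,
              n_compounds = sum(sel),
              n_frameworks = length(fw),
              framework_keys = fw)
  if (!is.null(reference_count)) {
    out$coverage_vs_reference <- length(fw) / reference_count
  }
  out
}

#' Chemical-space coverage percentage
#'
#' The fraction of a reference framework universe covered by a framework
#' set, as a percentage to one decimal.
#'
#' @param n_frameworks integer count of frameworks in the set.
#' @param reference_count integer size of the reference universe (> 0).
#' @return numeric percentage, rounded to one decimal.
#' @examples
#' coverage(79806, 438551)  # 18.2
#' @export
coverage <- function(n_frameworks, reference_count) {
  if (any(reference_count <= 0)) stop("reference_count must be positive")
  round(100 * n_frameworks / reference_count, 1)
}

#' Cumulative compound and framework counts per year
#'
#' For each calendar year in the observed range, counts the distinct
#' compounds first reported up to that year and the distinct frameworks
#' they cover, per activity class. Compounds lacking a year are excluded
#' (and counted in the \code{n_no_year} attribute).
#'
#' @param x a \linkS4class{ClassifiedSet}.
#' @return data.frame with columns \code{year}, \code{class_label},
#'   \code{n_compounds}, \code{n_frameworks} (cumulative).
#' @export
scaffoldTimeSeries <- function(x) {
  stopifnot(is(x, "ClassifiedSet"))
  x <- addFrameworks(x)
  cd <- x@compounds
  cd <- cd[cd$label %in% c("inhibitor", "inactive"), , drop = FALSE]
  no_year <- sum(is.na(cd$first_year))
  cd <- cd[!is.na(cd$first_year), , drop = FALSE]
  if (!nrow(cd)) {
    out <- data.frame(year = integer(0), class_label = character(0),
                      n_compounds = integer(0), n_frameworks = integer(0))
    attr(out, "n_no_year") <- no_year
    return(out)
  }
  years <- seq(min(cd$first_year), max(cd$first_year))
  rows <- list()
  for (cl in c("inhibitor", "inactive", "all")) {
    sub <- if (cl == "all") cd else cd[cd$label == cl, , drop = FALSE]
    for (y in years) {
      upto <- sub[sub$first_year <= y, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        year = y, class_label = cl,
        n_compounds = nrow(upto),
        n_frameworks = length(unique(upto$framework[!is.na(upto$framework)])))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_no_year") <- no_year
  out
}

#' Per-scaffold potency spread
#'
#' Groups compounds carrying valid IC50-type data by Murcko framework. Each
#' compound is represented by its mean pIC50 (arithmetic mean in log space)
#' back-converted to nM. Groups with more members than
#' \code{min_members} are reported with their max/min fold spread, sorted
#' by their most potent member.
#'
#' @param x a \linkS4class{ClassifiedSet}.
#' @param min_members report groups with strictly more members (default
#'   10).
#' @param config a \linkS4class{HergConfig}.
#' @return data.frame with \code{framework_key}, \code{n_members},
#'   \code{min_potency_nM}, \code{max_potency_nM}, \code{max_min_fold} and
#'   a list-column \code{member_potencies_nM}.
#' @export
scaffoldPotencySpread <- function(x, min_members = 10,
                                  config = hergConfig()) {
  stopifnot(is(x, "ClassifiedSet"))
  x <- addFrameworks(x)
  rec <- x@records
  valid <- validityFilterIc50(rec, config)
  rec <- rec[valid$keep & extremeValueFilter(rec$potency_nM, config), ,
             drop = FALSE]
  if (!nrow(rec)) {
    return(data.frame(framework_key = character(0), n_members = integer(0),
                      min_potency_nM = numeric(0), max_potency_nM = numeric(0),
                      max_min_fold = numeric(0)))
  }
  mean_pic50 <- vapply(split(rec$potency_nM, rec$canonical_key), function(v) {
    mean(pic50FromNM(v))
  }, numeric(1))
  comp_potency <- nmFromPic50(mean_pic50)
  cd <- x@compounds
  fw <- cd$framework[match(names(comp_potency), cd$canonical_key)]
  ok <- !is.na(fw)
  groups <- split(comp_potency[ok], fw[ok])
  rows <- lapply(names(groups), function(k) {
    v <- groups[[k]]
    data.frame(framework_key = k, n_members = length(v),
               min_potency_nM = min(v), max_potency_nM = max(v),
               max_min_fold = max(v) / min(v), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  members <- groups
  out <- out[out$n_members > min_members, , drop = FALSE]
  out <- out[order(out$min_potency_nM), , drop = FALSE]
  out$member_potencies_nM <- unname(members[out$framework_key])
  rownames(out) <- NULL
  out
}
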