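# Synthetic multi-source activity data with known ground truth.
#
# The generator emulates the statistical structure of the real source
# landscape: literature-like sources with roughly 1:1 inhibitor:inactive
# ratios and multiple records per compound; an HTS-like source with one
# percent-inhibition record per compound at 10 uM and a heavily negative
# class balance (about 1:64); a phenotype-annotated source with EC50
# values, Inhibitor/Activator/Inactive phenotypes and "Inconclusive"
# outcome flags; plus injected 100-fold outliers, unit heterogeneity,
# inequality-qualified values, salt forms and cross-source duplicates.

# two-slot scaffold cores; substituents use ring-closure digit 8 so they
# can never collide with the cores' digits
.SYNTH_CORES <- c(
  "c1cc(%s)ccc1%s", "Cc1cc(%s)ccc1%s", "c1ccc(%s)nc1%s", "c1cc(%s)cnc1%s",
  "c1ccc2cc(%s)ccc2c1%s", "c1ccc(%s)c(%s)c1", "c1cc(%s)cc(%s)c1",
  "c1ccc2[nH]c(%s)cc2c1%s", "c1ccc2oc(%s)cc2c1%s", "c1ccc2sc(%s)cc2c1%s",
  "c1ccc2nc(%s)ccc2c1%s", "c1cnc(%s)nc1%s", "c1csc(%s)c1%s",
  "c1coc(%s)c1%s", "c1cnn(%s)c1%s", "C1CCC(%s)CC1%s", "C1CCN(%s)CC1%s",
  "C1CCC(%s)C(%s)C1", "c1ccc(-c2ccc(%s)cc2)cc1%s",
  "c1ccc(Cc2ccc(%s)cc2)cc1%s", "c1ccc(Oc2ccc(%s)cc2)cc1%s",
  "c1ccc(N(%s)c2ccccc2)cc1%s", "c1ccc(C(=O)Nc2ccc(%s)cc2)cc1%s",
  "c1ccc2c(c1)CCN(%s)C2%s", "c1ccc(OCCN(%s)C)cc1%s",
  "c1ccc2c(c1)ncc(%s)n2%s", "c1ccc(CN(%s)C(=O)c2ccccc2)cc1%s",
  "c1ccc(S(=O)(=O)Nc2ccc(%s)cc2)cc1%s",
  "c1ccc(/C=C/c2ccc(%s)cc2)cc1%s", "C1CN(%s)CCN1%s"
)
# cores whose two substitution sites are exchangeable by a symmetry of the
# core; for these only ordered substituent pairs (a <= b) enter the grid
.SYNTH_CORE_SYMMETRIC <- c(1L, 3L, 6L, 7L, 16L, 18L, 30L)
# basic, lipophilic substituents (inhibitor-like chemistry: hERG blockers
# tend to carry a protonatable amine and aromatic bulk)
.SYNTH_SUBS_BASIC <- c(
  "CCN(C)C", "CCCN(C)C", "CN(C)C", "CCN8CCCCC8", "CCN8CCCC8", "CCCN8CCCC8",
  "CCN8CCN(C)CC8", "CCNC", "CCCNC(C)C", "CCNCC", "CCCCN(C)C", "CCN(CC)CC",
  "CCCN8CCCCC8", "CN8CCN(CC)CC8", "CCCNC", "CCN(C)CC", "CCCN(CC)C",
  "CCNC(C)C", "CCN8CCOCC8", "CCCN8CCN(C)CC8"
)
# polar / acidic / small neutral substituents (inactive-like chemistry)
.SYNTH_SUBS_POLAR <- c(
  "C(=O)O", "CC(=O)O", "CCC(=O)O", "OC", "OCC", "C(=O)NC", "C(=O)N",
  "CC(=O)NC", "S(=O)(=O)N", "S(=O)(=O)C", "C#N", "C(F)(F)F", "OCCO",
  "C(=O)OC", "CC#N", "CCS(=O)(=O)N", "COC", "CC(=O)N", "CCOC(C)=O",
  "CCC#N"
)

#' Deterministic drug-like structure library
#'
#' Enumerates parent structures by combining ring-system cores with
#' substituent pairs drawn from a class-flavoured pool: inhibitor-flavoured
#' parents carry basic, lipophilic substituents (the classic hERG
#' pharmacophore of a protonatable amine plus aromatic bulk); inactive
#' parents carry polar or acidic substituents. The two pools are disjoint,
#' so parents are unique across classes.
#'
#' @param n number of parents required.
#' @param flavour \code{"basic"} or \code{"polar"}.
#' @return character vector of \code{n} unique SMILES, deterministic order.
#' @export
scaffoldLibrary <- function(n, flavour = c("basic", "polar")) {
  flavour <- match.arg(flavour)
  subs <- if (flavour == "basic") .SYNTH_SUBS_BASIC else .SYNTH_SUBS_POLAR
  cache_key <- paste0("grid_", flavour)
  grid <- .synth_cache[[cache_key]]
  if (is.null(grid)) {
    # additive fragment masses: substituting H by a group adds the group's
    # standalone MW minus one hydrogen; core mass comes from the dimethyl
    # parent minus two CH2 increments
    h <- 1.00794; ch2 <- 14.01565
    core_mw <- structureInfo(vapply(.SYNTH_CORES, sprintf, character(1),
                                    "C", "C"))$mw - 2 * ch2
    sub_info <- structureInfo(subs)
    sub_mw <- sub_info$mw - h
    core_ha <- smilesHeavyAtoms(vapply(.SYNTH_CORES, sprintf, character(1),
                                       "", "")) # heavy atoms of bare core
    sub_ha <- sub_info$heavy_atoms
    grid <- expand.grid(core = seq_along(.SYNTH_CORES),
                        a = seq_along(subs), b = seq_along(subs),
                        KEEP.OUT.ATTRS = FALSE)
    sym <- grid$core %in% .SYNTH_CORE_SYMMETRIC
    grid <- grid[!sym | grid$a <= grid$b, , drop = FALSE]
    mw <- core_mw[grid$core] + sub_mw[grid$a] + sub_mw[grid$b]
    ha <- core_ha[grid$core] + sub_ha[grid$a] + sub_ha[grid$b]
    grid <- grid[!is.na(mw) & mw >= 165 & mw <= 690 & ha >= 11, , drop = FALSE]
    rownames(grid) <- NULL
    .synth_cache[[cache_key]] <- grid
  }
  if (n > nrow(grid)) stop("structure library exhausted: need ", n,
                           " parents, have ", nrow(grid))
  vapply(seq_len(n), function(i) {
    sprintf(.SYNTH_CORES[grid$core[i]], subs[grid$a[i]], subs[grid$b[i]])
  }, character(1))
}

.synth_cache <- new.env(parent = emptyenv())

# size of the filtered parent grid for a flavour
.libSize <- function(flavour) {
  invisible(scaffoldLibrary(1, flavour))  # populate the cache
  nrow(.synth_cache[[paste0("grid_", flavour)]])
}

#' Synthetic data generation settings
#'
#' @slot sources data.frame describing each emulated source: columns
#'   \code{source_id}, \code{kind} ("literature", "hts", "phenotype"),
#'   \code{n_compounds}, \code{inhibitor_fraction}, \code{min_records},
#'   \code{max_records}.
#' @slot inhibitor_median_nM,inactive_median_nM class-conditional medians
#'   of the true-potency log-normal (1 uM and 50 uM: they straddle the
#'   10 uM threshold with a controllable borderline mass).
#' @slot potency_spread_log log10 SD of true potency around its class
#'   median.
#' @slot noise_sd per-record assay noise, log10 units.
#' @slot outlier_rate,outlier_fold probability that an eligible record is
#'   replaced by a fold-scale outlier, and the fold itself. Outliers are
#'   only injected into compounds with at least three exact IC50 records
#'   and are capped at one third of those records per compound.
#' @slot qualified_value_rate fraction of literature IC50 records emitted
#'   as censored bounds ("<" / ">").
#' @slot salt_variant_rate fraction of per-source structures emitted as a
#'   hydrochloride salt.
#' @slot duplicate_structure_rate fraction of compounds in later sources
#'   that reuse a parent already emitted by an earlier source.
#' @slot inconclusive_rate fraction of phenotype-source records flagged
#'   "Inconclusive" in the outcome comment.
#' @slot activator_rate fraction of extra activator-phenotype compounds in
#'   the phenotype source.
#' @slot qualitative_negative_rate chance an inactive literature compound
#'   gains a qualitative "no activity" record.
#' @slot pct_record_rate chance a literature record is inhibition-type
#'   rather than IC50-type.
#' @slot seed integer random seed.
#' @export
setClass("SynthSpec", representation(
  sources = "data.frame",
  inhibitor_median_nM = "numeric",
  inactive_median_nM = "numeric",
  potency_spread_log = "numeric",
  noise_sd = "numeric",
  outlier_rate = "numeric",
  outlier_fold = "numeric",
  qualified_value_rate = "numeric",
  salt_variant_rate = "numeric",
  duplicate_structure_rate = "numeric",
  inconclusive_rate = "numeric",
  activator_rate = "numeric",
  qualitative_negative_rate = "numeric",
  pct_record_rate = "numeric",
  seed = "integer"
))

setValidity("SynthSpec", function(object) {
  rates <- c(object@outlier_rate, object@qualified_value_rate,
             object@salt_variant_rate, object@duplicate_structure_rate,
             object@inconclusive_rate, object@activator_rate,
             object@qualitative_negative_rate, object@pct_record_rate)
  if (any(rates < 0 | rates > 1)) return("all rates must lie in [0, 1]")
  src <- object@sources
  need <- c("source_id", "kind", "n_compounds", "inhibitor_fraction",
            "min_records", "max_records")
  if (!all(need %in% names(src))) {
    return(paste("sources must carry columns:", paste(need, collapse = ", ")))
  }
  if (any(src$inhibitor_fraction <= 0 | src$inhibitor_fraction >= 1))
    return("inhibitor fractions must lie strictly inside (0, 1)")
  if (!all(src$kind %in% c("literature", "hts", "phenotype")))
    return("unknown source kind")
  TRUE
})

.default_sources <- function(scale = 1) {
  data.frame(
    source_id = c("litA", "litB", "phenoC", "htsD"),
    kind = c("literature", "literature", "phenotype", "hts"),
    n_compounds = as.integer(round(scale * c(1500, 1200, 500, 6500))),
    inhibitor_fraction = c(0.5, 0.5, 1 / 7, 1 / 65),
    min_records = c(1L, 1L, 1L, 1L),
    max_records = c(5L, 5L, 1L, 1L),
    stringsAsFactors = FALSE
  )
}

#' Create synthetic-data generation settings
#'
#' Defaults are the emulated study conditions: two literature sources with
#' 1:1 class balance and 1-5 records per compound, a phenotype source at
#' about 1:6, and an HTS source at 1:64 with a single 10 uM
#' percent-inhibition record per compound.
#'
#' @param scale multiplies every source's compound count (use small values
#'   in unit tests).
#' @param sources optional replacement source table.
#' @param ... named overrides of the \linkS4class{SynthSpec} slots.
#' @return a validated \linkS4class{SynthSpec}.
#' @examples
#' sp <- synthSpec(scale = 0.05, seed = 7)
#' @export
synthSpec <- function(scale = 1, sources = NULL, ...) {
  args <- list(...)
  defaults <- list(
    sources = if (is.null(sources)) .default_sources(scale) else sources,
    inhibitor_median_nM = 1000,
    inactive_median_nM = 50000,
    potency_spread_log = 0.5,
    noise_sd = 0.3,
    outlier_rate = 0.05,
    outlier_fold = 100,
    qualified_value_rate = 0.05,
    salt_variant_rate = 0.10,
    duplicate_structure_rate = 0.05,
    inconclusive_rate = 0.10,
    activator_rate = 0.05,
    qualitative_negative_rate = 0.03,
    pct_record_rate = 0.15,
    seed = 1L
  )
  for (nm in names(args)) defaults[[nm]] <- args[[nm]]
  defaults$seed <- as.integer(defaults$seed)
  do.call(methods::new, c(list(Class = "SynthSpec"), defaults))
}

#' Percent inhibition from potency at a test concentration
#'
#' The single-concentration response of a compound with half-maximal
#' inhibitory concentration \code{potency_nM} at concentration
#' \code{conc_uM}, under a Hill model with coefficient 1:
#' \code{100 * C / (C + IC50)} with both in nM.
#'
#' @param potency_nM numeric.
#' @param conc_uM numeric.
#' @return percent inhibition in (0, 100).
#' @examples
#' percentInhibitionFromPotency(10000, 10)  # 50
#' percentInhibitionFromPotency(1000, 10)   # ~90.9
#' @export
percentInhibitionFromPotency <- function(potency_nM, conc_uM) {
  c_nM <- conc_uM * 1000
  100 * c_nM / (c_nM + potency_nM)
}

# value conversion: potency in nM -> (value, unit, measure) for emission
.emit_ic50 <- function(potency_nM, measure) {
  if (measure == "pIC50") {
    list(value = 9 - log10(potency_nM), unit = "-log(M)")
  } else if (measure %in% c("IC50", "EC50") && stats::runif(1) < 0.5) {
    list(value = potency_nM / 1000, unit = "uM")
  } else if (stats::runif(1) < 0.05) {
    list(value = potency_nM / 1e6, unit = "mM")
  } else {
    list(value = potency_nM, unit = "nM")
  }
}

.BINDING_DESCRIPTIONS <- c(
  "[3H]dofetilide displacement binding assay",
  "radioligand binding to hERG membranes",
  "[3H]astemizole displacement binding")
.ELECTRO_DESCRIPTIONS <- c(
  "automated patch clamp assay",
  "whole-cell patch-clamp, tail current block",
  "QPatch automated electrophysiology")

#' Generate a synthetic multi-source activity dataset
#'
#' Deterministic for a fixed seed. Per compound a true potency is drawn
#' from the class-conditional log-normal; each emitted record measures the
#' true potency under multiplicative log-normal assay noise, converted into
#' heterogeneous measures and units; HTS records report a Hill-model
#' percent inhibition at 10 uM. Designated fractions of records are salt
#' forms, cross-source duplicates, censored bounds, activator or
#' inconclusive phenotype entries, and fold-scale outliers.
#'
#' The ground truth labels each parent by its realized true potency
#' against the 10 uM threshold, flags borderline parents (within 2-fold of
#' the threshold) and parents whose only usable evidence is
#' single-concentration percent data with a response inside the strict
#' 70\%/30\% no-vote band (such parents carry no recoverable signal once
#' the strict thresholds apply, mirroring the removal of near-threshold
#' HTS entries from the integrated set).
#'
#' @param spec a \linkS4class{SynthSpec}.
#' @return list with \code{records} (activity table), \code{parents}
#'   (ground-truth table: \code{parent_id}, \code{parent_smiles},
#'   \code{true_label}, \code{true_potency_nM}, \code{borderline},
#'   \code{hts_only}, \code{pct_only}, \code{hts_ambiguous}) and
#'   \code{record_map}
#'   (\code{record_id} to \code{parent_id}).
#' @export
generateSynthData <- function(spec = synthSpec()) {
  stopifnot(is(spec, "SynthSpec"))
  set.seed(spec@seed)
  thr <- 10000

  src <- spec@sources
  n_total <- sum(src$n_compounds)
  n_inh_max <- ceiling(n_total * 0.75) + 64
  n_ina_max <- n_total + 64
  lib_basic <- scaffoldLibrary(min(n_inh_max, .libSize("basic")), "basic")
  lib_polar <- scaffoldLibrary(min(n_ina_max, .libSize("polar")), "polar")
  next_basic <- 1L; next_polar <- 1L

  parents <- list()
  parent_source_kinds <- list()
  cap <- sum(src$n_compounds * (src$max_records + 1L)) + 1000L
  rows <- vector("list", cap)
  record_map_pid <- character(cap)
  rid_counter <- 0L

  new_parent <- function(class) {
    if (class == "inhibitor" || class == "activator") {
      smi <- lib_basic[next_basic]; next_basic <<- next_basic + 1L
    } else {
      smi <- lib_polar[next_polar]; next_polar <<- next_polar + 1L
    }
    mu <- if (class == "inhibitor") log10(spec@inhibitor_median_nM)
          else log10(spec@inactive_median_nM)
    # true potencies stay inside the 1 pM - 1 mM plausibility window (the
    # extreme-value filter targets curation errors, not biology)
    pot <- 10^(stats::rnorm(1, mu, spec@potency_spread_log))
    pot <- min(max(pot, 0.1), 9e5)
    pid <- sprintf("P%06d", length(parents) + 1L)
    parents[[pid]] <<- list(parent_id = pid, parent_smiles = smi,
                            true_potency_nM = pot,
                            phenotype_class = class)
    parent_source_kinds[[pid]] <<- character(0)
    pid
  }

  emit <- function(pid, source_id, measure, relation, value, unit, conc,
                   description, phenotype, outcome, validity, year,
                   structure) {
    rid_counter <<- rid_counter + 1L
    i <- rid_counter
    # each emitted record cites its own reference: repeat measurements of
    # one compound represent independent publications, so the
    # reference-keyed duplicate collapse must not merge them
    rows[[i]] <<- list(
      record_id = sprintf("r%07d", i),
      compound_structure = structure,
      source_id = source_id,
      reference_id = sprintf("ref_%s_%s_%d", source_id, pid, i),
      measure_name = measure,
      relation = relation,
      value = if (is.na(value)) NA_real_ else as.numeric(value),
      unit = unit,
      test_concentration_uM = if (is.na(conc)) NA_real_ else as.numeric(conc),
      assay_description = description,
      phenotype = phenotype,
      outcome_comment = outcome,
      data_validity_comment = "",
      year = as.integer(year))
    record_map_pid[i] <<- pid
  }

  used_pids <- character(0)

  for (s in seq_len(nrow(src))) {
    kind <- src$kind[s]
    n <- src$n_compounds[s]
    frac <- src$inhibitor_fraction[s]
    sid <- src$source_id[s]
    cur_source_pids <- character(0)
    for (ci in seq_len(n)) {
      dup_pool <- setdiff(used_pids, cur_source_pids)
      dup <- length(dup_pool) > 0 && s > 1 &&
        stats::runif(1) < spec@duplicate_structure_rate
      if (dup) {
        pid <- if (length(dup_pool) == 1L) dup_pool else sample(dup_pool, 1)
      } else {
        class <- if (stats::runif(1) < frac) "inhibitor" else "inactive"
        pid <- new_parent(class)
      }
      p <- parents[[pid]]
      parent_source_kinds[[pid]] <- union(parent_source_kinds[[pid]], kind)
      structure <- p$parent_smiles
      if (stats::runif(1) < spec@salt_variant_rate) {
        structure <- paste0(structure, ".Cl")
      }
      true_label <- if (p$true_potency_nM <= thr) "inhibitor" else "inactive"

      if (kind == "literature") {
        k <- sample(seq(src$min_records[s], src$max_records[s]), 1)
        rec_specs <- list()
        for (r in seq_len(k)) {
          measured <- p$true_potency_nM * 10^stats::rnorm(1, 0, spec@noise_sd)
          is_pct <- stats::runif(1) < spec@pct_record_rate
          qualified <- !is_pct && stats::runif(1) < spec@qualified_value_rate
          rec_specs[[r]] <- list(measured = measured, is_pct = is_pct,
                                 qualified = qualified)
        }
        # fold-scale outliers: only exact unqualified IC50 records, and at
        # most one third of them per compound, so that removal around the
        # geometric mean can always separate them from the consistent values
        exact_idx <- which(!vapply(rec_specs, `[[`, logical(1), "is_pct") &
                           !vapply(rec_specs, `[[`, logical(1), "qualified"))
        if (length(exact_idx) >= 3) {
          n_out <- stats::rbinom(1, length(exact_idx), spec@outlier_rate)
          n_out <- min(n_out, floor(length(exact_idx) / 3))
          if (n_out > 0) {
            for (oi in sample(exact_idx, n_out)) {
              dirn <- if (stats::runif(1) < 0.5) spec@outlier_fold else 1 / spec@outlier_fold
              rec_specs[[oi]]$measured <- rec_specs[[oi]]$measured * dirn
            }
          }
        }
        year_pool <- sample(2006:2016, k, replace = TRUE)
        for (r in seq_len(k)) {
          rs <- rec_specs[[r]]
          binding <- stats::runif(1) < 0.5
          desc <- if (binding) sample(.BINDING_DESCRIPTIONS, 1)
                  else sample(.ELECTRO_DESCRIPTIONS, 1)
          if (rs$is_pct) {
            conc <- 10
            pct <- percentInhibitionFromPotency(rs$measured, conc)
            remaining <- stats::runif(1) < 0.3
            in_desc <- stats::runif(1) < 0.3
            emit(pid, sid,
                 measure = if (remaining) "remaining activity" else "% inhibition",
                 relation = "=",
                 value = if (remaining) 100 - pct else pct,
                 unit = "%",
                 conc = if (in_desc) NA else conc,
                 description = if (in_desc)
                   sprintf("%s, inhibition at %g uM", desc, conc) else desc,
                 phenotype = "", outcome = "", validity = "",
                 year = year_pool[r], structure = structure)
          } else {
            qualified <- rs$qualified
            measure <- sample(c("IC50", "Ki", "Kd", "IC50", "pIC50"), 1)
            if (qualified) {
              if (true_label == "inhibitor") {
                relation <- "<"; v_nM <- max(rs$measured, 1)
              } else {
                relation <- ">"; v_nM <- max(rs$measured, thr)
              }
              if (measure == "pIC50") measure <- "IC50"
            } else {
              relation <- "="
              v_nM <- rs$measured
            }
            vv <- .emit_ic50(v_nM, measure)
            emit(pid, sid, measure = measure, relation = relation,
                 value = vv$value, unit = vv$unit, conc = NA,
                 description = desc, phenotype = "", outcome = "",
                 validity = "", year = year_pool[r], structure = structure)
          }
        }
        if (true_label == "inactive" &&
            stats::runif(1) < spec@qualitative_negative_rate) {
          emit(pid, sid, measure = "", relation = "none", value = NA,
               unit = "", conc = NA, description = "literature comment",
               phenotype = "", outcome = "no activity", validity = "",
               year = sample(2006:2016, 1), structure = structure)
        }
      } else if (kind == "phenotype") {
        measured <- p$true_potency_nM * 10^stats::rnorm(1, 0, spec@noise_sd)
        vv <- .emit_ic50(measured, "EC50")
        outcome <- if (stats::runif(1) < spec@inconclusive_rate) "Inconclusive" else ""
        emit(pid, sid, measure = "EC50", relation = "=", value = vv$value,
             unit = vv$unit, conc = NA,
             description = "thallium flux assay, Hill fit",
             phenotype = true_label,
             outcome = outcome, validity = "",
             year = sample(2010:2014, 1), structure = structure)
      } else if (kind == "hts") {
        measured <- p$true_potency_nM * 10^stats::rnorm(1, 0, spec@noise_sd)
        pct <- percentInhibitionFromPotency(measured, 10)
        emit(pid, sid, measure = "% inhibition", relation = "=",
             value = pct, unit = "%", conc = 10,
             description = "IonWorks population patch clamp at 10 uM",
             phenotype = "", outcome = "", validity = "",
             year = 2011L, structure = structure)
      }
      used_pids <- union(used_pids, pid)
      cur_source_pids <- c(cur_source_pids, pid)
    }
    # phenotype source: extra activator compounds (excluded downstream)
    if (kind == "phenotype" && spec@activator_rate > 0) {
      n_act <- round(n * spec@activator_rate)
      for (ai in seq_len(n_act)) {
        pid <- new_parent("activator")
        parent_source_kinds[[pid]] <- union(parent_source_kinds[[pid]], kind)
        p <- parents[[pid]]
        emit(pid, sid, measure = "EC50", relation = "=",
             value = p$true_potency_nM, unit = "nM", conc = NA,
             description = "thallium flux assay, negative Hill coefficient",
             phenotype = "activator", outcome = "", validity = "",
             year = sample(2010:2014, 1), structure = p$parent_smiles)
        used_pids <- union(used_pids, pid)
      }
    }
  }

  rows <- rows[seq_len(rid_counter)]
  fields <- names(rows[[1]])
  rec_df <- as.data.frame(
    stats::setNames(lapply(fields, function(f) {
      unlist(lapply(rows, function(r) r[[f]]), use.names = FALSE)
    }), fields), stringsAsFactors = FALSE)
  record_map_pid <- record_map_pid[seq_len(rid_counter)]
  truth <- do.call(rbind, lapply(parents, function(p) {
    data.frame(parent_id = p$parent_id, parent_smiles = p$parent_smiles,
               true_potency_nM = p$true_potency_nM,
               phenotype_class = p$phenotype_class,
               stringsAsFactors = FALSE)
  }))
  rownames(truth) <- NULL
  truth$true_label <- ifelse(
    truth$phenotype_class == "activator", "activator",
    ifelse(truth$true_potency_nM <= thr, "inhibitor", "inactive"))
  truth$borderline <- abs(log10(truth$true_potency_nM / thr)) < log10(2)
  kinds <- parent_source_kinds[truth$parent_id]
  truth$hts_only <- vapply(kinds, function(k) identical(k, "hts"), logical(1))
  # parents whose only usable evidence is single-concentration percent data:
  # when their noise-free 10 uM response falls inside the strict 70%/30%
  # no-vote band applied to HTS-scale sources, no vote can fire for them
  ic50_measures <- c("IC50", "Ki", "Kd", "EC50", "pIC50")
  usable <- !grepl("Inconclusive", rec_df$outcome_comment, fixed = TRUE) &
    rec_df$phenotype != "activator"
  pid_all <- record_map_pid
  has <- function(sel) {
    hits <- unique(pid_all[sel])
    truth$parent_id %in% hits
  }
  has_ic <- has(usable & rec_df$measure_name %in% ic50_measures)
  has_pct <- has(usable & rec_df$measure_name %in%
                   c("% inhibition", "remaining activity"))
  has_qual <- has(grepl("no activity", rec_df$outcome_comment, fixed = TRUE))
  lo <- thr * 3 / 7   # potency at which the 10 uM response is exactly 70%
  hi <- thr * 7 / 3   # potency at which the 10 uM response is exactly 30%
  truth$pct_only <- has_pct & !has_ic & !has_qual
  truth$hts_ambiguous <- truth$pct_only &
    truth$true_potency_nM >= lo & truth$true_potency_nM <= hi
  list(records = rec_df,
       parents = truth,
       record_map = data.frame(record_id = rec_df$record_id,
                               parent_id = record_map_pid,
                               stringsAsFactors = FALSE))
}
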