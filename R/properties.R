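# Physicochemical descriptor profiles: 12 descriptors per compound and
# class-wise summary statistics.

# SMARTS rule table for ionizable groups with typical aqueous pKa values.
# Served through a pluggable predictor interface: directional fidelity, not
# numerical reproduction of closed commercial predictors, is the contract.
.PKA_RULES <- data.frame(
  group = c("aliphatic_primary_amine", "aliphatic_secondary_amine",
            "aliphatic_tertiary_amine", "amidine_guanidine",
            "aromatic_n_basic", "aniline",
            "carboxylic_acid", "phenol", "sulfonamide_nh",
            "tetrazole", "thiol", "sulfonic_acid"),
  smarts = c("[NX3;H2;!$(NC=O);!$(NS=O);!$(N[a]);!$(N*=*)]",
             "[NX3;H1;!$(NC=O);!$(NS=O);!$(N[a]);!$(N*=*)]",
             "[NX3;H0;!$(NC=O);!$(NS=O);!$(N[a]);!$(N*=*);!$([N+])]",
             "[NX2]=[CX3][NX3]",
             "[nX2;!$([nH])]",
             "[NX3;$(N[a]);!$(NC=O);!$(NS=O)]",
             "[CX3](=O)[OX2H1]",
             "[OX2H][c]",
             "[SX4](=[OX1])(=[OX1])[NX3;H1,H2]",
             "c1nnn[nH]1",
             "[SX2H]",
             "[SX4](=[OX1])(=[OX1])[OX2H1]"),
  type = c("base", "base", "base", "base", "base", "base",
           "acid", "acid", "acid", "acid", "acid", "acid"),
  pka = c(10.6, 10.8, 9.8, 12.5, 5.2, 4.6,
          4.2, 10.0, 10.0, 4.9, 8.3, -1.0),
  stringsAsFactors = FALSE
)

#' The shipped pKa rule table
#'
#' @return data.frame with columns \code{group}, \code{smarts}, \code{type}
#'   ("base"/"acid") and \code{pka}.
#' @export
pkaRules <- function() .PKA_RULES

# van der Waals and single-bond covalent radii (Angstrom) for the
# approximate surface computation
.VDW <- c(H = 1.20, B = 1.92, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
          Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75, Se = 1.90, Br = 1.85,
          I = 1.98)
.COV <- c(H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
          Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02, Se = 1.20, Br = 1.20,
          I = 1.39)
.DEFAULT_VALENCE <- c(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4,
                      P = 3, S = 2, Cl = 1, Se = 2, Br = 1, I = 1)

# approximate molecular surface area by pairwise spherical-cap subtraction:
# each atom (including implicit hydrogens) contributes its vdW sphere minus
# the caps buried in bonded neighbours at ideal covalent distances. An
# isolated-pair approximation; labeled approximate in the output metadata.
.atom_surface <- function(elements, bonds, implicit_h) {
  n <- length(elements)
  r <- .VDW[elements]; r[is.na(r)] <- 1.7
  rc <- .COV[elements]; rc[is.na(rc)] <- 0.77
  area <- 4 * pi * r^2
  cap <- function(ri, rj, d) {
    h <- ri - (d^2 + ri^2 - rj^2) / (2 * d)
    if (h <= 0) return(0)
    2 * pi * ri * h
  }
  if (nrow(bonds)) {
    for (b in seq_len(nrow(bonds))) {
      i <- bonds[b, 1]; j <- bonds[b, 2]
      d <- rc[i] + rc[j]
      area[i] <- area[i] - cap(r[i], r[j], d)
      area[j] <- area[j] - cap(r[j], r[i], d)
    }
  }
  rH <- .VDW[["H"]]; rcH <- .COV[["H"]]
  h_area <- vapply(seq_len(n), function(i) {
    if (implicit_h[i] <= 0) return(0)
    d <- rc[i] + rcH
    per_h <- 4 * pi * rH^2 - cap(rH, r[i], d)
    area[i] <<- area[i] - implicit_h[i] * cap(r[i], rH, d)
    implicit_h[i] * max(per_h, 0)
  }, numeric(1))
  sum(pmax(area, 0.05 * 4 * pi * r^2)) + sum(h_area)
}

# implicit hydrogen counts from default valences and bond orders
.implicit_h <- function(elements, bonds, charges) {
  n <- length(elements)
  bo <- rep(0, n)
  if (nrow(bonds)) {
    for (b in seq_len(nrow(bonds))) {
      o <- bonds[b, 3]
      bo[bonds[b, 1]] <- bo[bonds[b, 1]] + o
      bo[bonds[b, 2]] <- bo[bonds[b, 2]] + o
    }
  }
  dv <- .DEFAULT_VALENCE[elements]; dv[is.na(dv)] <- 0
  pmax(dv + charges - bo, 0)
}

#' Compute the 12-descriptor physicochemical profile
#'
#' Computes, per structure: molecular weight (MW), atomic-contribution
#' octanol-water partition coefficient of the neutral form (AlogP),
#' distribution coefficient at pH 7.4 (logD, from AlogP and the rule-based
#' pKa of the most basic and most acidic group), hydrogen-bond acceptor and
#' donor counts (HBA, HBD), counts of positively and negatively charged
#' atoms at pH 7.4 (N_Cations, N_Anions, from the rule table), approximate
#' molecular surface area (MSA), topological polar surface area (MPSA),
#' rotatable bond count (N_Rot: non-ring single bonds between non-terminal
#' heavy atoms, amide bonds excluded), and the pKa of the most basic and
#' most acidic atom (absent when no ionizable group matches).
#'
#' @param smiles character vector of standardized structures.
#' @param rules pKa rule table, see \code{\link{pkaRules}}.
#' @return data.frame with one row per input and columns \code{mw},
#'   \code{alogp}, \code{logd}, \code{hba}, \code{hbd}, \code{n_cations},
#'   \code{n_anions}, \code{msa}, \code{mpsa}, \code{n_rot},
#'   \code{pka_base}, \code{pka_acid}.
#' @export
computeProperties <- function(smiles, rules = pkaRules()) {
  n <- length(smiles)
  empty <- data.frame(mw = numeric(n), alogp = numeric(n), logd = numeric(n),
                      hba = numeric(n), hbd = numeric(n),
                      n_cations = numeric(n), n_anions = numeric(n),
                      msa = numeric(n), mpsa = numeric(n), n_rot = numeric(n),
                      pka_base = rep(NA_real_, n), pka_acid = rep(NA_real_, n))
  if (!n) return(empty)
  ok <- which(!is.na(smiles) & nzchar(smiles))
  if (!length(ok)) { empty[] <- NA_real_; return(empty) }
  uniq <- unique(smiles[ok])
  ids <- sprintf("p%06d", seq_along(uniq))
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(uniq, ids)))
  valid <- ChemmineR::validSDF(sdf)
  if (!all(valid)) sdf <- sdf[valid]
  props <- suppressWarnings(ChemmineR::propOB(sdf))
  kept_ids <- ids[valid]

  # SMARTS counts for every ionization rule
  counts <- matrix(0, nrow = length(kept_ids), ncol = nrow(rules))
  for (ri in seq_len(nrow(rules))) {
    hit <- tryCatch(
      suppressWarnings(ChemmineR::smartsSearchOB(sdf, rules$smarts[ri],
                                                 uniqueMatches = TRUE)),
      error = function(e) rep(0, length(kept_ids)))
    counts[, ri] <- as.numeric(hit)
  }
  base_cols <- which(rules$type == "base")
  acid_cols <- which(rules$type == "acid")

  res_u <- data.frame(matrix(NA_real_, nrow = length(uniq), ncol = 12))
  names(res_u) <- names(empty)
  for (k in seq_along(kept_ids)) {
    u_idx <- match(kept_ids[k], ids)
    mol <- sdf[[k]]
    ab <- ChemmineR::atomblock(mol)
    bb <- ChemmineR::bondblock(mol)
    elements <- gsub("_.*$", "", rownames(ab))
    bonds <- if (!is.null(dim(bb)) && nrow(bb)) {
      cbind(as.integer(bb[, 1]), as.integer(bb[, 2]), as.integer(bb[, 3]))
    } else matrix(integer(0), ncol = 3)
    charges <- rep(0, length(elements))
    if ("charge" %in% colnames(ab)) charges <- as.numeric(ab[, "charge"])
    heavy <- elements != "H"
    imp_h <- .implicit_h(elements, bonds, charges)

    # rotatable bonds: single, not in a ring, between heavy atoms that each
    # have another heavy neighbour, excluding amide C-N bonds
    n_rot <- 0
    if (nrow(bonds)) {
      bridges <- graphBridges(bonds[, 1:2, drop = FALSE], length(elements))
      hdeg <- tabulate(c(bonds[heavy[bonds[, 1]] & heavy[bonds[, 2]], 1],
                         bonds[heavy[bonds[, 1]] & heavy[bonds[, 2]], 2]),
                       nbins = length(elements))
      is_amide <- function(i, j) {
        # C(=O)-N in either orientation
        for (pair in list(c(i, j), c(j, i))) {
          ci <- pair[1]; nj <- pair[2]
          if (elements[ci] == "C" && elements[nj] == "N") {
            dbl_o <- any(bonds[, 3] == 2 &
                         ((bonds[, 1] == ci & elements[bonds[, 2]] == "O") |
                          (bonds[, 2] == ci & elements[bonds[, 1]] == "O")))
            if (dbl_o) return(TRUE)
          }
        }
        FALSE
      }
      for (b in seq_len(nrow(bonds))) {
        i <- bonds[b, 1]; j <- bonds[b, 2]
        if (bonds[b, 3] != 1L) next
        if (!heavy[i] || !heavy[j]) next
        if (!bridges[b]) next            # ring bond
        if (hdeg[i] < 2L || hdeg[j] < 2L) next  # terminal
        if (is_amide(i, j)) next
        n_rot <- n_rot + 1
      }
    }

    pka_b <- if (any(counts[k, base_cols] > 0)) {
      max(rules$pka[base_cols][counts[k, base_cols] > 0])
    } else NA_real_
    pka_a <- if (any(counts[k, acid_cols] > 0)) {
      min(rules$pka[acid_cols][counts[k, acid_cols] > 0])
    } else NA_real_
    n_cat <- sum(counts[k, base_cols][rules$pka[base_cols] > 7.4])
    n_an <- sum(counts[k, acid_cols][rules$pka[acid_cols] < 7.4])

    alogp <- as.numeric(props$logP[k])
    logd <- alogp
    if (!is.na(pka_b)) logd <- logd - log10(1 + 10^(pka_b - 7.4))
    if (!is.na(pka_a)) logd <- logd - log10(1 + 10^(7.4 - pka_a))

    res_u[u_idx, ] <- list(
      mw = as.numeric(props$MW[k]),
      alogp = alogp,
      logd = logd,
      hba = as.numeric(props$HBA2[k]),
      hbd = as.numeric(props$HBD[k]),
      n_cations = n_cat,
      n_anions = n_an,
      msa = {
        hb <- bonds[heavy[bonds[, 1]] & heavy[bonds[, 2]], , drop = FALSE]
        remap <- cumsum(heavy)
        if (nrow(hb)) hb <- cbind(remap[hb[, 1]], remap[hb[, 2]], hb[, 3])
        .atom_surface(elements[heavy], hb, imp_h[heavy])
      },
      mpsa = as.numeric(props$TPSA[k]),
      n_rot = n_rot,
      pka_base = pka_b,
      pka_acid = pka_a
    )
  }
  out <- res_u[match(smiles, uniq), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Class-wise descriptor summary
#'
#' Mean and population standard deviation of every descriptor over the
#' compounds of a class. Only drug-likeness-passing compounds with a
#' definite label (never inconclusive/unclassified) enter; compounds with
#' an absent pKa are excluded descriptor-wise.
#'
#' @param x a \linkS4class{ClassifiedSet} whose compound table carries
#'   descriptor columns (see \code{\link{addProperties}}).
#' @param class_label \code{"inhibitor"}, \code{"inactive"} or
#'   \code{"all"}.
#' @return data.frame with one row per descriptor: \code{descriptor},
#'   \code{mean}, \code{sd}, \code{n}.
#' @export
summarizeProperties <- function(x, class_label = c("all", "inhibitor",
                                                   "inactive")) {
  stopifnot(is(x, "ClassifiedSet"))
  class_label <- match.arg(class_label)
  cd <- x@compounds
  desc <- c("mw", "alogp", "logd", "hba", "hbd", "n_cations", "n_anions",
            "msa", "mpsa", "n_rot", "pka_base", "pka_acid")
  if (!all(desc %in% names(cd))) {
    stop("descriptor columns missing; run addProperties() first")
  }
  sel <- cd$filter_status == "pass" &
    (if (class_label == "all") cd$label %in% c("inhibitor", "inactive")
     else cd$label == class_label)
  if (!any(sel)) stop("no compounds in class ", class_label)
  sub <- cd[sel, desc, drop = FALSE]
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  rows <- lapply(desc, function(d) {
    v <- sub[[d]]
    v <- v[!is.na(v)]
    data.frame(descriptor = d, mean = mean(v), sd = pop_sd(v), n = length(v))
  })
  do.call(rbind, rows)
}

#' Attach descriptor profiles to a compound collection
#'
#' @param x a \linkS4class{CompoundSet}.
#' @return the object with descriptor columns added to the compound table.
#' @export
addProperties <- function(x) {
  stopifnot(is(x, "CompoundSet"))
  if (!"alogp" %in% names(x@compounds)) {
    props <- computeProperties(x@compounds$canonical_key)
    props$mw <- NULL  # keep the MW already computed at standardization
    x@compounds <- cbind(x@compounds, props)
  }
  x
}
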