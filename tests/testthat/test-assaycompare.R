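# helper: a classified set carrying IC50 records with assay classes
.assay_set <- function(per_compound) {
  # per_compound: list of lists(key, binding = potencies, electro = potencies)
  recs <- list()
  for (pc in per_compound) {
    if (length(pc$binding)) {
      r <- harmRecords(potency_nM = pc$binding, key = pc$key)
      r$assay_class <- "binding"
      recs[[length(recs) + 1]] <- r
    }
    if (length(pc$electro)) {
      r <- harmRecords(potency_nM = pc$electro, key = pc$key)
      r$assay_class <- "electrostatic"
      recs[[length(recs) + 1]] <- r
    }
  }
  rec <- do.call(rbind, recs)
  rec$record_id <- sprintf("r%04d", seq_len(nrow(rec)))
  keys <- unique(rec$canonical_key)
  cd <- data.frame(canonical_key = keys, mw = 300, heavy_atoms = 20L,
                   filter_status = "pass", fail_reasons = "",
                   first_year = NA_integer_, stringsAsFactors = FALSE)
  new("CompoundSet", compounds = cd, records = rec, metadata = list())
}

test_that("the validity filter keeps only exact, in-range IC50 values", {
  rec <- harmRecords(potency_nM = c(1e4, 2e6, 500, NA, 700),
                     relation = c(">", "=", "=", "=", "<"))
  rec$potency_nM[4] <- NA
  v <- validityFilterIc50(rec)
  expect_equal(v$keep, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(v$reason[1], "inequality")
  expect_equal(v$reason[2], "range")
  expect_equal(v$reason[4], "null")
  expect_equal(v$reason[5], "inequality")
  # non-IC50 records are never kept
  pr <- harmRecords(inhibition_pct = 50)
  expect_false(validityFilterIc50(pr)$keep)
})

test_that("concordance is exact on degenerate and shifted fixtures", {
  # identical per-class values: perfect agreement
  x <- .assay_set(list(
    list(key = "K1", binding = 100, electro = 100),
    list(key = "K2", binding = 1000, electro = 1000),
    list(key = "K3", binding = 10000, electro = 10000)))
  r <- concordance(x)
  expect_equal(r$r_squared, 1)
  expect_equal(r$rmsd_pic50, 0)
  expect_equal(r$n_more_potent_electro, 0L)
  # a uniform 10-fold electro shift: r2 1, rmsd exactly 1 log unit
  y <- .assay_set(list(
    list(key = "K1", binding = 100, electro = 10),
    list(key = "K2", binding = 1000, electro = 100),
    list(key = "K3", binding = 40000, electro = 4000)))
  r2 <- concordance(y)
  expect_equal(r2$r_squared, 1)
  expect_equal(r2$rmsd_pic50, 1)
  expect_equal(r2$n_more_potent_electro, 3L)
  expect_error(concordance(.assay_set(list(
    list(key = "K1", binding = 100, electro = 100)))), "fewer than 2")
})

test_that("concordance matches an independent hand calculation", {
  # three compounds; binding pIC50 {6, 7, 5}, electro pIC50 {6.5, 7.5, 5.2};
  # multi-record compounds use the arithmetic mean of pIC50s
  x <- .assay_set(list(
    list(key = "K1", binding = 1000, electro = nmFromPic50_t(6.5)),
    list(key = "K2", binding = c(nmFromPic50_t(6.8), nmFromPic50_t(7.2)),
         electro = nmFromPic50_t(7.5)),
    list(key = "K3", binding = 1e4, electro = nmFromPic50_t(5.2))))
  r <- concordance(x)
  b <- c(6, 7, 5); e <- c(6.5, 7.5, 5.2)
  # spreadsheet-style oracle, written out in full
  mb <- mean(b); me <- mean(e)
  r2_hand <- (sum((b - mb) * (e - me)) /
                sqrt(sum((b - mb)^2) * sum((e - me)^2)))^2
  rmsd_hand <- sqrt(sum((b - e)^2) / 3)
  expect_equal(r$r_squared, r2_hand, tolerance = 1e-12)
  expect_equal(r$rmsd_pic50, rmsd_hand, tolerance = 1e-12)
  expect_equal(r$n_common_compounds, 3L)
  expect_equal(r$n_more_potent_electro, 3L)
  expect_equal(r$mean_potency_binding_nM, 10^(9 - mean(b)), tolerance = 1e-9)
})

test_that("concordance is symmetric in the class labels up to sign counts", {
  x <- .assay_set(list(
    list(key = "K1", binding = 120, electro = 480),
    list(key = "K2", binding = 5500, electro = 900),
    list(key = "K3", binding = 3e4, electro = 7e4),
    list(key = "K4", binding = 50, electro = 51)))
  r <- concordance(x)
  swapped <- x
  rec <- recordData(swapped)
  rec$assay_class <- c(binding = "electrostatic",
                       electrostatic = "binding")[rec$assay_class]
  swapped@records <- rec
  r2 <- concordance(swapped)
  expect_equal(r2$r_squared, r$r_squared)
  expect_equal(r2$rmsd_pic50, r$rmsd_pic50)
  expect_equal(r2$mean_potency_binding_nM, r$mean_potency_electro_nM)
  expect_equal(r2$n_more_potent_electro,
               r$n_common_compounds - r$n_more_potent_electro)
})

test_that("deviation statistics need more than three values and use linear-interpolation percentiles", {
  mk <- function(key, v) harmRecords(potency_nM = v, key = key)
  rec <- rbind(mk("K1", c(100, 100, 100, 100)),
               mk("K2", c(10, 10, 10, 2000)),
               mk("K3", c(1, 10, 100, 1000)),
               mk("K4", c(5, 5, 5)))          # only three: excluded
  rec$record_id <- sprintf("r%03d", seq_len(nrow(rec)))
  cd <- data.frame(canonical_key = c("K1", "K2", "K3", "K4"), mw = 300,
                   heavy_atoms = 20L, filter_status = "pass",
                   fail_reasons = "", first_year = NA_integer_,
                   stringsAsFactors = FALSE)
  x <- new("CompoundSet", compounds = cd, records = rec, metadata = list())
  d <- deviationStats(x)
  expect_setequal(d$per_compound$canonical_key, c("K1", "K2", "K3"))
  p <- d$per_compound
  expect_equal(p$fold_max_min[p$canonical_key == "K1"], 1)
  expect_equal(p$fold_iqr[p$canonical_key == "K1"], 1)
  expect_equal(p$fold_max_min[p$canonical_key == "K2"], 200)
  # brute-force percentile oracle for [1, 10, 100, 1000], linear
  # interpolation between closest ranks: rank position 1 + 0.25*(4-1)
  q25 <- 1 + 0.75 * (10 - 1)       # 7.75
  q75 <- 100 + 0.25 * (1000 - 100) # 325
  expect_equal(p$fold_iqr[p$canonical_key == "K3"], q75 / q25,
               tolerance = 1e-12)
  # bins
  bins <- d$bins
  expect_equal(bins$n_compounds[bins$measure == "fold_max_min" &
                                  bins$bin == ">100"], 2L)
  expect_equal(bins$n_compounds[bins$measure == "fold_max_min" &
                                  bins$bin == "<=10"], 1L)
})

test_that("deviation folds are scale invariant", {
  mk <- function(key, v) harmRecords(potency_nM = v, key = key)
  base <- c(3, 17, 230, 4200, 11)
  rec1 <- mk("K1", base); rec2 <- mk("K1", base * 7.3)
  cd <- data.frame(canonical_key = "K1", mw = 300, heavy_atoms = 20L,
                   filter_status = "pass", fail_reasons = "",
                   first_year = NA_integer_, stringsAsFactors = FALSE)
  d1 <- deviationStats(new("CompoundSet", compounds = cd, records = rec1,
                           metadata = list()))
  d2 <- deviationStats(new("CompoundSet", compounds = cd, records = rec2,
                           metadata = list()))
  expect_equal(d1$per_compound$fold_max_min, d2$per_compound$fold_max_min)
  expect_equal(d1$per_compound$fold_iqr, d2$per_compound$fold_iqr)
})
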