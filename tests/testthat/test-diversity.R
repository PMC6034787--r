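# Expected framework SMILES computed once with an independent reference
# scaffold implementation (RDKit MurckoScaffold) and frozen here; the
# comparison canonicalizes both sides with the package's serializer so
# toolkit-specific SMILES dialects cannot cause spurious mismatches.
.SCAFFOLD_ORACLE <- list(
  c("Cc1ccccc1", "c1ccccc1"),
  c("C(c1ccccc1)c1ccccc1", "c1ccc(Cc2ccccc2)cc1"),
  c("O=C1CCCCC1", "O=C1CCCCC1"),
  c("CCN(CC)CCOC(=O)c1ccc(N)cc1", "c1ccccc1"),
  c("CN1CCC(CC1)Cc1ccccc1", "c1ccc(CC2CCNCC2)cc1"),
  c("O=C(Nc1ccccc1)c1ccccc1", "O=C(Nc1ccccc1)c1ccccc1"),
  c("c1ccc(-c2ccccc2)cc1", "c1ccc(-c2ccccc2)cc1"),
  c("CC(=O)Oc1ccccc1C(=O)O", "c1ccccc1"),
  c("CN1CCN(CC1)c1ccc(F)cc1", "c1ccc(N2CCNCC2)cc1"),
  c("O=S(=O)(N)c1ccc(CCNC(=O)C)cc1", "c1ccccc1"),
  c("c1ccc2[nH]ccc2c1", "c1ccc2[nH]ccc2c1"),
  c("CCOC(=O)C1CCN(Cc2ccccc2)CC1", "c1ccc(CN2CCCCC2)cc1"),
  c("CC(C)Cc1ccc(C(C)C(=O)O)cc1", "c1ccccc1"),
  c("O=C(CCCN1CCC(O)(c2ccc(Cl)cc2)CC1)c1ccc(F)cc1",
    "O=C(CCCN1CCC(c2ccccc2)CC1)c1ccccc1"),
  c("Clc1ccccc1CN1CCN(CC1)C", "c1ccc(CN2CCNCC2)cc1"),
  c("CC(N)Cc1ccccc1", "c1ccccc1"),
  c("C1CCNCC1", "C1CCNCC1"),
  c("CC(c1ccccc1)N1CCN(Cc2ccc(F)cc2)CC1",
    "c1ccc(CN2CCN(Cc3ccccc3)CC2)cc1")
)

test_that("Murcko frameworks keep rings plus linkers and drop side chains", {
  expect_equal(murckoFramework("Cc1ccccc1"), canonical("c1ccccc1"))
  expect_true(is.na(murckoFramework("CCCCCC")))
  expect_true(is.na(murckoFramework("CC(C)CC(N)C(=O)O")))
  got <- murckoFramework("C(c1ccccc1)c1ccccc1")
  expect_equal(got, canonical("c1ccc(Cc2ccccc2)cc1"))
})

test_that("frameworks match the independent reference implementation", {
  mols <- vapply(.SCAFFOLD_ORACLE, `[`, character(1), 1)
  want <- canonical(vapply(.SCAFFOLD_ORACLE, `[`, character(1), 2))
  got <- murckoFramework(mols)
  for (i in seq_along(mols)) {
    expect_equal(got[i], want[i], info = mols[i])
  }
})

test_that("the framework of a framework is itself", {
  mols <- vapply(.SCAFFOLD_ORACLE, `[`, character(1), 1)
  fw <- murckoFramework(mols)
  fw <- fw[!is.na(fw)]
  expect_identical(murckoFramework(fw), fw)
})

test_that("frameworks are invariant to salt and charge variants", {
  pairs <- list(
    c("CCN(CC)CCOC(=O)c1ccc(N)cc1.Cl", "CCN(CC)CCOC(=O)c1ccc(N)cc1"),
    c("OC(=O)c1ccccc1CCN1CCCCC1.Cl", "[O-]C(=O)c1ccccc1CCN1CCCCC1"))
  for (p in pairs) {
    keys <- standardizeStructure(p)
    expect_equal(murckoFramework(keys[1]), murckoFramework(keys[2]))
  }
})

test_that("exocyclic double bonds can be kept or stripped", {
  with_o <- murckoFramework("CC1CCC(=O)CC1", keep_exocyclic = TRUE)
  without <- murckoFramework("CC1CCC(=O)CC1", keep_exocyclic = FALSE)
  expect_equal(with_o, canonical("O=C1CCCCC1"))
  expect_equal(without, canonical("C1CCCCC1"))
})

.toy_classified <- function(keys, labels, years = NA_integer_,
                             frameworks = NULL) {
  cd <- data.frame(canonical_key = keys, mw = 300, heavy_atoms = 20L,
                   filter_status = "pass", fail_reasons = "",
                   first_year = rep_len(years, length(keys)),
                   label = labels, stage = "ic50_unanimous",
                   votes_positive = 1L, votes_negative = 0L,
                   removed_outlier_record_ids = "",
                   stringsAsFactors = FALSE)
  if (!is.null(frameworks)) cd$framework <- frameworks
  new("ClassifiedSet", compounds = cd,
      records = harmRecords()[0, ], metadata = list())
}

test_that("framework counting is class-aware with set semantics", {
  x <- .toy_classified(
    keys = c("K1", "K2", "K3", "K4", "K5"),
    labels = c("inhibitor", "inhibitor", "inactive", "inactive",
               "inconclusive"),
    frameworks = c("F1", "F1", "F1", "F2", "F9"))
  inh <- countFrameworks(x, "inhibitor")
  ina <- countFrameworks(x, "inactive")
  all <- countFrameworks(x, "all")
  expect_equal(inh$n_frameworks, 1L)        # shared scaffold counted once
  expect_equal(ina$n_frameworks, 2L)
  expect_equal(all$n_compounds, 4L)         # inconclusive excluded
  expect_setequal(all$framework_keys,
                  union(inh$framework_keys, ina$framework_keys))
  # acyclic compounds count as compounds but contribute no framework
  y <- .toy_classified(c("K1", "K2"), c("inhibitor", "inhibitor"),
                       frameworks = c("F1", NA))
  s <- countFrameworks(y, "inhibitor")
  expect_equal(s$n_compounds, 2L)
  expect_equal(s$n_frameworks, 1L)
  # empty class
  expect_equal(countFrameworks(y, "inactive")$n_frameworks, 0L)
})

test_that("framework counts grow monotonically as compounds are added", {
  fw <- c("F1", "F2", "F1", "F3", "F2", "F4")
  counts <- vapply(seq_along(fw), function(k) {
    x <- .toy_classified(sprintf("K%d", 1:k), rep("inhibitor", k),
                         frameworks = fw[1:k])
    countFrameworks(x, "inhibitor")$n_frameworks
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("chemical-space coverage is a one-decimal percentage", {
  expect_equal(coverage(79806, 438551), 18.2)
  expect_equal(coverage(0, 1000), 0.0)
  expect_equal(coverage(777, 777), 100.0)
  expect_error(coverage(10, 0), "positive")
})

test_that("cumulative time series uses first-report years and set semantics", {
  x <- .toy_classified(
    keys = sprintf("K%d", 1:5),
    labels = c("inhibitor", "inhibitor", "inhibitor", "inactive", "inactive"),
    years = c(2006L, 2007L, 2009L, 2006L, 2008L),
    frameworks = c("F1", "F1", "F2", "F3", "F3"))
  ts <- scaffoldTimeSeries(x)
  inh <- ts[ts$class_label == "inhibitor", ]
  expect_equal(inh$n_compounds, c(1L, 2L, 2L, 3L))       # 2006..2009
  expect_equal(inh$n_frameworks, c(1L, 1L, 1L, 2L))      # F1 not recounted
  all_cl <- ts[ts$class_label == "all", ]
  expect_true(all(diff(all_cl$n_compounds) >= 0))
  # single-year data: flat series
  y <- .toy_classified("K1", "inhibitor", years = 2010L, frameworks = "F1")
  ts2 <- scaffoldTimeSeries(y)
  expect_equal(unique(ts2$year), 2010L)
})

test_that("per-scaffold potency spread uses mean pIC50 per compound", {
  # two compounds sharing one framework: potencies via mean pIC50
  rec <- rbind(
    harmRecords(potency_nM = c(1e6 / 1e6, 10), key = "K1"),     # pIC50 9, 8 -> mean 8.5
    harmRecords(potency_nM = 1e5, key = "K2"))
  rec$potency_nM[1] <- 1
  x <- .toy_classified(c("K1", "K2"), c("inhibitor", "inactive"),
                       frameworks = c("F1", "F1"))
  x@records <- rec
  out <- scaffoldPotencySpread(x, min_members = 1)
  expect_equal(nrow(out), 1L)
  expect_equal(out$n_members, 2L)
  # K1: mean pIC50 of {9, 8} is 8.5 -> 10^(9-8.5) nM
  expect_equal(out$min_potency_nM, 10^0.5, tolerance = 1e-10)
  expect_equal(out$max_potency_nM, 1e5)
  expect_equal(out$max_min_fold, 1e5 / 10^0.5, tolerance = 1e-10)
  # groups at or below the member threshold are not reported
  expect_equal(nrow(scaffoldPotencySpread(x, min_members = 2)), 0L)
})
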