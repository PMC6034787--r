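test_that("value-kind taxonomy routes measures correctly", {
  expect_equal(classifyValueKind("Ki", "nM"), "ic50_like")
  expect_equal(classifyValueKind("Kd", "uM"), "ic50_like")
  expect_equal(classifyValueKind("EC50", "nM"), "ic50_like")
  expect_equal(classifyValueKind("pIC50", "-log(M)"), "ic50_like")
  expect_equal(classifyValueKind("IC70", "uM"), "excluded")
  expect_equal(classifyValueKind("IC30", "uM"), "excluded")
  expect_equal(classifyValueKind("% inhibition", "%"), "inhibition_like")
  expect_equal(classifyValueKind("remaining activity", "%"), "inhibition_like")
  expect_equal(classifyValueKind("tail current", "nA"), "excluded")
  expect_equal(classifyValueKind("no activity", ""), "qualitative_negative")
  expect_equal(classifyValueKind("banana equivalent", ""), "excluded")
})

test_that("unit conversion to nanomolar is exact and round-trips", {
  expect_equal(toNanomolar(1, "uM", FALSE), 1000)
  expect_equal(toNanomolar(6, "pIC50", TRUE), 1000)
  expect_equal(toNanomolar(0.5, "mM", FALSE), 5e5)
  expect_equal(toNanomolar(2, "M", FALSE), 2e9)
  expect_equal(toNanomolar(250, "pM", FALSE), 0.25)
  expect_true(is.na(toNanomolar(1, "furlongs", FALSE)))
  # round trip: nM -> unit -> nM is identity for every supported unit
  for (u in c("M", "mM", "uM", "nM", "pM")) {
    factor <- c(M = 1e9, mM = 1e6, uM = 1e3, nM = 1, pM = 1e-3)[[u]]
    v_nM <- c(0.003, 1, 542.7, 1e6)
    expect_equal(toNanomolar(v_nM / factor, u, FALSE), v_nM, info = u)
  }
  # log form: pIC50 of x nM is 9 - log10(x)
  expect_equal(toNanomolar(9 - log10(37), "pKi", TRUE), 37)
})

test_that("remaining-activity conversion is its own inverse", {
  expect_equal(remainingToInhibition(30), 70)
  expect_equal(remainingToInhibition(100), 0)
  expect_equal(remainingToInhibition(0), 100)
  x <- c(-5, 0, 12.5, 50, 99, 130)
  expect_equal(remainingToInhibition(remainingToInhibition(x)), x)
})

test_that("concentrations are recovered from assay descriptions", {
  expect_equal(complementConcentration("inhibition at 10 uM"), 10)
  expect_equal(complementConcentration("percent block at 300 nM"), 0.3)
  expect_equal(complementConcentration("tested at 1.5 mM"), 1500)
  expect_true(is.na(complementConcentration("no concentration given")))
})

test_that("assay class assignment follows the keyword dictionaries", {
  expect_equal(assignAssayClass("automated patch clamp"), "electrostatic")
  expect_equal(assignAssayClass("IonWorks Quattro PPC"), "electrostatic")
  expect_equal(assignAssayClass("[3H]dofetilide displacement binding"),
               "binding")
  expect_equal(assignAssayClass("hERG assay"), "unknown")
  expect_equal(assignAssayClass(NA), "unknown")
})

test_that("source filters exclude flagged, inconclusive and activator records", {
  rec <- rawRecords(
    record_id = c("a", "b", "c", "d"),
    phenotype = c("activator", "none", "inhibitor", "none"),
    outcome_comment = c(NA, "Inconclusive fit", NA, NA),
    data_validity_comment = c(NA, NA, "Outside typical range", NA))
  out <- applySourceFilters(rec)
  expect_equal(out$exclusion_reason[1], "activator")
  expect_equal(out$exclusion_reason[2], "inconclusive")
  expect_equal(out$exclusion_reason[3], "data validity")
  expect_true(is.na(out$exclusion_reason[4]))
})

test_that("cross-source duplicates collapse to one record", {
  rec <- rawRecords(
    record_id = c("a", "b"),
    source_id = c("chembl", "gostar"),
    reference_id = "same-paper",
    value = 120, unit = "nM")
  out <- applySourceFilters(rec)
  expect_true(is.na(out$exclusion_reason[1]))
  expect_equal(out$exclusion_reason[2], "duplicate")
  # different values from the same reference are genuine repeats, kept
  rec2 <- rawRecords(record_id = c("a", "b"), reference_id = "p",
                     value = c(120, 450))
  expect_true(all(is.na(applySourceFilters(rec2)$exclusion_reason)))
})

test_that("HTS flagging uses a strict distinct-compound threshold", {
  mk <- function(n, sid) {
    rawRecords(record_id = sprintf("%s%04d", sid, seq_len(n)),
               compound_structure = sprintf("mol%04d", seq_len(n)),
               source_id = sid, measure_name = "% inhibition",
               value = 20, unit = "%", test_concentration_uM = 10)
  }
  rec <- rbind(mk(201, "big"), mk(200, "small"))
  h <- harmonizeRecords(rec)
  expect_true(all(h$is_hts_source[h$source_id == "big"]))
  expect_false(any(h$is_hts_source[h$source_id == "small"]))
  # IC50 records from a flagged source are never HTS-flagged
  rec2 <- rbind(mk(250, "big"),
                rawRecords(record_id = "x1", source_id = "big",
                           compound_structure = "mol0001",
                           measure_name = "IC50", value = 5, unit = "uM"))
  h2 <- harmonizeRecords(rec2)
  expect_false(h2$is_hts_source[h2$record_id == "x1"])
})

test_that("every record harmonizes or is excluded with a reason; counts conserve", {
  rec <- rawRecords(
    record_id = sprintf("r%02d", 1:8),
    measure_name = c("IC50", "IC70", "% inhibition", "remaining activity",
                     "QT interval", "Ki", "EC50", "pIC50"),
    relation = c("=", "=", "=", "=", "=", ">", "=", "="),
    value = c(5, 1, 80, 30, 1.2, 100, 2, 7.3),
    unit = c("uM", "uM", "%", "%", "", "nM", "uM", "-log(M)"),
    test_concentration_uM = c(NA, NA, 10, NA, NA, NA, NA, NA),
    assay_description = c(rep("patch clamp", 3), "binding at 10 uM",
                          rep("patch clamp", 4)),
    phenotype = c(rep("none", 6), "activator", "none"))
  h <- harmonizeRecords(rec)
  expect_equal(nrow(h), nrow(rec))
  excluded <- h$value_kind == "excluded"
  expect_true(all(!is.na(h$exclusion_reason[excluded])))
  expect_true(all(is.na(h$exclusion_reason[!excluded])))
  expect_equal(h$exclusion_reason[h$record_id == "r02"], "non-50% threshold")
  expect_equal(h$exclusion_reason[h$record_id == "r07"], "activator")
  # remaining-activity became inhibition with the description concentration
  r4 <- h[h$record_id == "r04", ]
  expect_equal(r4$value_kind, "inhibition_like")
  expect_equal(r4$inhibition_pct, 70)
  expect_equal(r4$test_concentration_uM, 10)
  # exactly one quantity populated per non-excluded quantitative record
  quant <- h$value_kind %in% c("ic50_like", "inhibition_like")
  expect_true(all(xor(is.na(h$potency_nM[quant]),
                      is.na(h$inhibition_pct[quant]))))
  qual <- h$value_kind == "qualitative_negative"
  expect_true(all(is.na(h$potency_nM[qual]) & is.na(h$inhibition_pct[qual])))
})

test_that("harmonization is idempotent through re-serialization", {
  rec <- rawRecords(
    record_id = c("a", "b"),
    measure_name = c("IC50", "% inhibition"),
    value = c(2, 65), unit = c("uM", "%"),
    test_concentration_uM = c(NA, 10))
  h1 <- harmonizeRecords(rec)
  # re-serialize the harmonized values in nM / percent form and re-harmonize
  rec2 <- rec
  rec2$value <- ifelse(!is.na(h1$potency_nM), h1$potency_nM, h1$inhibition_pct)
  rec2$unit <- ifelse(!is.na(h1$potency_nM), "nM", "%")
  rec2$measure_name <- ifelse(!is.na(h1$potency_nM), "IC50", "% inhibition")
  rec2$test_concentration_uM <- h1$test_concentration_uM
  h2 <- harmonizeRecords(rec2)
  expect_equal(h2$potency_nM, h1$potency_nM)
  expect_equal(h2$inhibition_pct, h1$inhibition_pct)
  expect_equal(h2$value_kind, h1$value_kind)
})

test_that("measure-less records with a no-activity comment become qualitative negatives", {
  rec <- rawRecords(record_id = "q1", measure_name = NA, relation = "none",
                    value = NA, unit = NA,
                    outcome_comment = "no activity up to highest dose")
  h <- harmonizeRecords(rec)
  expect_equal(h$value_kind, "qualitative_negative")
})
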