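test_that("IC50 votes honour the inclusive 10 uM threshold and bounds", {
  expect_equal(ic50Vote(5000, "="), "positive")
  expect_equal(ic50Vote(10000, "="), "positive")   # boundary inclusive
  expect_equal(ic50Vote(10001, "="), "negative")
  expect_equal(ic50Vote(30000, ">"), "negative")
  expect_equal(ic50Vote(5000, ">"), "uninformative")
  expect_equal(ic50Vote(8000, "<"), "positive")
  expect_equal(ic50Vote(50000, "<"), "uninformative")
})

test_that("inhibition votes apply standard and strict HTS thresholds", {
  expect_equal(inhibitionVote(60, 10, FALSE), "positive")
  expect_equal(inhibitionVote(50, 10, FALSE), "positive")  # >= 50 inclusive
  expect_equal(inhibitionVote(49.9, 10, FALSE), "negative")
  expect_equal(inhibitionVote(80, 30, FALSE), "uninformative")
  expect_equal(inhibitionVote(20, 1, FALSE), "uninformative")
  expect_equal(inhibitionVote(60, 10, TRUE), "uninformative")
  expect_equal(inhibitionVote(70, 10, TRUE), "uninformative")  # strict > 70
  expect_equal(inhibitionVote(71, 10, TRUE), "positive")
  expect_equal(inhibitionVote(30, 10, TRUE), "uninformative")  # strict < 30
  expect_equal(inhibitionVote(29, 10, TRUE), "negative")
})

test_that("extreme values outside the 1 pM - 1 mM window are dropped", {
  expect_false(extremeValueFilter(0.0005))   # 0.5 pM
  expect_true(extremeValueFilter(1e6))       # exactly 1 mM kept
  expect_true(extremeValueFilter(1e-3))      # exactly 1 pM kept
  expect_false(extremeValueFilter(1.5e6))
  expect_true(extremeValueFilter(100))
  expect_false(extremeValueFilter(NA))
})

test_that("outlier removal uses the geometric mean, single pass", {
  # hand oracle: geometric mean of {100, 120, 90, 5000} is
  # (100*120*90*5000)^(1/4) ~ 271.6 nM; 5000 >= 10*271.6, others inside
  res <- removeOutliers(c(100, 120, 90, 5000))
  expect_equal(res$removed, 4L)
  expect_equal(res$kept, 1:3)
  expect_equal(res$mean_nM, (100 * 120 * 90 * 5000)^(1 / 4))
  # under the arithmetic mean the outlier shields itself (mean 1327.5,
  # 5000 < 13275) and drags the three consistent values below mean/10
  cfg_am <- hergConfig(outlier_mean = "arithmetic")
  expect_equal(removeOutliers(c(100, 120, 90, 5000), cfg_am)$removed, 1:3)
  # fewer than two values: pass-through
  expect_length(removeOutliers(100)$removed, 0L)
  # zero spread: nothing removed
  expect_length(removeOutliers(c(200, 200, 200))$removed, 0L)
  # removal is inclusive at exactly 10-fold from the mean
  res10 <- removeOutliers(c(100, 100, 100, 100))  # mean 100
  expect_length(res10$removed, 0L)
})

test_that("compounds classify through the staged rules", {
  # unanimity
  r <- classifyCompound(harmRecords(potency_nM = c(100, 500, 900, 2000)))
  expect_equal(r$label, "inhibitor")
  expect_equal(r$stage, "ic50_unanimous")
  expect_equal(r$votes_positive, 4L)
  # 3-vs-1 after outlier removal fails: values within 10-fold of the mean,
  # so majority decides on the full set (3/4 >= 2/3)
  r2 <- classifyCompound(harmRecords(potency_nM = c(4000, 6000, 8000, 22000)))
  expect_equal(r2$label, "inhibitor")
  expect_equal(r2$stage, "ic50_majority_after_outlier_removal")
  # a removed 100-fold outlier restores unanimity among the rest
  r3 <- classifyCompound(harmRecords(potency_nM = c(300, 400, 350, 35000)))
  expect_equal(r3$label, "inhibitor")
  expect_equal(r3$removed_outlier_record_ids, "ic004")
  # an even split is inconclusive
  r4 <- classifyCompound(harmRecords(potency_nM = c(5000, 50000)))
  expect_equal(r4$label, "inconclusive")
  # IC50 priority: a negative IC50 beats a positive inhibition record
  rec <- rbind(harmRecords(potency_nM = 50000),
               harmRecords(inhibition_pct = 90, conc_uM = 10))
  r5 <- classifyCompound(rec)
  expect_equal(r5$label, "inactive")
  expect_equal(r5$stage, "ic50_unanimous")
  # inhibition stage when no IC50 exists
  r6 <- classifyCompound(harmRecords(inhibition_pct = c(80, 90), conc_uM = 10))
  expect_equal(r6$label, "inhibitor")
  expect_equal(r6$stage, "inhibition_unanimous")
  # qualitative negatives vote at the inhibition stage
  r7 <- classifyCompound(harmRecords(n_qualitative = 2))
  expect_equal(r7$label, "inactive")
  expect_equal(r7$stage, "qualitative_only")
  # nothing informative: unclassified
  r8 <- classifyCompound(harmRecords(potency_nM = 500, relation = ">"))
  expect_equal(r8$label, "unclassified")
})

test_that("an undecidable IC50 bound falls through to inhibition evidence", {
  rec <- rbind(harmRecords(potency_nM = 500, relation = ">"),
               harmRecords(inhibition_pct = c(85, 90), conc_uM = 10))
  r <- classifyCompound(rec)
  expect_equal(r$label, "inhibitor")
  expect_equal(r$stage, "inhibition_unanimous")
})

test_that("classification is independent of record order", {
  set.seed(11)
  for (trial in 1:20) {
    pot <- 10^stats::runif(sample(2:7, 1), 1, 5.5)
    rec <- harmRecords(potency_nM = pot)
    base <- classifyCompound(rec)
    for (p in 1:3) {
      perm <- rec[sample(nrow(rec)), , drop = FALSE]
      r <- classifyCompound(perm)
      expect_equal(r$label, base$label)
      expect_equal(r$votes_positive, base$votes_positive)
    }
  }
})

test_that("adding a positive vote never flips inhibitor to inactive", {
  # vote-level monotonicity, checked on within-10-fold sets where outlier
  # removal cannot interact
  for (p in 0:5) for (n in 0:5) {
    if (p + n == 0 || p + n > 6) next
    pot <- c(rep(3000, p), rep(30000, n))
    before <- classifyCompound(harmRecords(potency_nM = pot))$label
    after <- classifyCompound(harmRecords(potency_nM = c(pot, 3000)))$label
    if (before == "inhibitor") expect_equal(after, "inhibitor")
    if (after == "inactive") expect_equal(before, "inactive")
  }
})

test_that("classifier agrees with the brute-force oracle on vote multisets up to size 8", {
  # exhaustive over positive/negative counts (potencies chosen within
  # 10-fold so removal cannot fire)
  for (p in 0:8) for (n in 0:(8 - p)) {
    pot <- c(rep(3000, p), rep(30000, n))
    if (!length(pot)) next
    rec <- harmRecords(potency_nM = pot)
    expect_equal(classifyCompound(rec)$label, bruteForceClassify(rec),
                 info = sprintf("p=%d n=%d", p, n))
  }
  # randomized potency multisets spanning outliers, extremes and bounds
  set.seed(4711)
  pool <- c(5, 80, 300, 3000, 9000, 11000, 30000, 300000, 9e5, 2e6, 5e-4)
  for (trial in 1:400) {
    k <- sample(1:8, 1)
    pot <- sample(pool, k, replace = TRUE) * stats::runif(k, 0.8, 1.2)
    rel <- sample(c("=", "=", "=", "<", ">"), k, replace = TRUE)
    rec <- harmRecords(potency_nM = pot, relation = rel)
    expect_equal(classifyCompound(rec)$label, bruteForceClassify(rec),
                 info = paste(round(pot), rel, collapse = " "))
  }
  # mixed stages: IC50 + inhibition + qualitative records
  for (trial in 1:200) {
    # jitter keeps potency pairs off the exact 10-fold-from-mean boundary,
    # where the tie is floating-point ambiguous (covered deterministically
    # in the outlier-removal test)
    kk <- sample(1:3, 1)
    rec <- rbind(
      if (stats::runif(1) < 0.6)
        harmRecords(potency_nM = sample(pool, kk, replace = TRUE) *
                      stats::runif(kk, 0.9, 1.1))
      else harmRecords(),
      harmRecords(inhibition_pct = stats::runif(sample(0:3, 1), -5, 110),
                  conc_uM = sample(c(1, 10, 30), 1),
                  is_hts = stats::runif(1) < 0.3),
      harmRecords(n_qualitative = sample(0:2, 1)))
    expect_equal(classifyCompound(rec)$label, bruteForceClassify(rec))
  }
})

test_that("every merged compound gets exactly one of the four labels", {
  sp <- synthSpec(scale = 0.01, seed = 5)
  g <- generateSynthData(sp)
  out <- runPipeline(g$records, compute_frameworks = FALSE)
  cd <- compoundData(out$result)
  expect_true(all(cd$label %in% c("inhibitor", "inactive", "inconclusive",
                                  "unclassified")))
  expect_equal(anyDuplicated(cd$canonical_key), 0L)
})
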