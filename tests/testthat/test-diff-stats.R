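test_that("internal-standard normalization is a plain mean ratio", {
  expect_equal(normalizeArea(10, c(5, 15)), 1.0)
  expect_equal(normalizeArea(0, c(5, 15)), 0)        # zero propagates
  expect_equal(normalizeArea(3 * 7, 3 * c(5, 15)),   # scale invariance
               normalizeArea(7, c(5, 15)))
  expect_error(normalizeArea(1, numeric()), "at least one")
  expect_error(normalizeArea(1, c(0, 0)), "loading control")
})

test_that("control-relative ratios reproduce the published ratio columns", {
  quant <- table4Fixture()
  r29 <- controlRelativeRatios(quant, "Ser29")
  expect_within(r29$ratio[r29$condition == "control"][1], 0.43, 0.02)
  r504 <- controlRelativeRatios(quant, "Ser504")
  expect_within(r504$ratio[r504$condition == "treated"][1], 8.06, 0.02)
  # identical control values -> control ratios exactly 1
  q <- data.frame(site = "x", experiment = 1:3,
                  condition = "control", normalizedArea = 2.5)
  expect_equal(controlRelativeRatios(q, "x")$ratio, rep(1, 3))
  # zero control mean -> flagged unquantifiable
  q0 <- data.frame(site = "x", experiment = c(1, 1),
                   condition = c("control", "treated"),
                   normalizedArea = c(0, 5))
  rr <- controlRelativeRatios(q0, "x")
  expect_false(attr(rr, "quantifiable"))
  expect_true(all(is.na(rr$ratio)))
})

test_that("fold change and SEM use the n-1 sample standard deviation", {
  fit <- reanalyzeTable(table4Fixture())
  r <- fit$results
  expect_within(r$foldChange[r$site == "Ser504"], 11.67, 0.02)
  expect_within(r$sem[r$site == "Ser504"], 3.33, 0.005)
  expect_within(r$foldChange[r$site == "Ser645/T646"], 2.34, 0.005)
  expect_within(r$sem[r$site == "Ser645/T646"], 0.58, 0.005)
  # independent oracle: direct formula on the treated ratios
  rr <- fit$ratios
  x <- rr$ratio[rr$site == "Ser29" & rr$condition == "treated"]
  expect_equal(r$foldChange[r$site == "Ser29"], mean(x), tolerance = 1e-12)
  expect_equal(r$sem[r$site == "Ser29"],
               sqrt(sum((x - mean(x))^2) / 3) / sqrt(4), tolerance = 1e-12)
  # constant ratios -> SEM 0
  s <- foldChangeSummary(list(control = c(1, 1), treated = c(2, 2, 2)))
  expect_equal(s$foldChange, 2)
  expect_equal(s$sem, 0)
})

test_that("paired t-test matches the closed-form statistic", {
  quant <- table4Fixture()
  ctl <- quant$normalizedArea[quant$site == "Ser504" &
                                quant$condition == "control"]
  trt <- quant$normalizedArea[quant$site == "Ser504" &
                                quant$condition == "treated"]
  tt <- pairedTTest(ctl, trt)
  # direct formula oracle
  d <- trt - ctl
  tOracle <- mean(d) / (sd(d) / sqrt(length(d)))
  pOracle <- 2 * pt(-abs(tOracle), length(d) - 1)
  expect_equal(tt$t, tOracle, tolerance = 1e-12)
  expect_equal(tt$df, 3)
  expect_equal(tt$p, pOracle, tolerance = 1e-12)
  expect_lt(tt$p, 0.05)
  # treated identical to control -> t = 0, p = 1
  same <- pairedTTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(same$flag, "zero-difference")
  # constant non-zero differences -> undefined p, flagged
  const <- pairedTTest(c(1, 2, 3), c(2, 3, 4))
  expect_true(is.na(const$p))
  expect_equal(const$flag, "zero-variance")
  # scale invariance: same p on areas and on ratios
  expect_equal(pairedTTest(ctl / mean(ctl), trt / mean(ctl))$p, tt$p,
               tolerance = 1e-12)
})

test_that("re-analysis table is paired, flagged, and control-centred", {
  fit <- reanalyzeTable(table4Fixture())
  expect_equal(fit$results$controlMean, rep(1, 6), tolerance = 1e-12)
  expect_equal(fit$results$n, rep(4L, 6))
  # an unquantifiable site (all-zero controls) is flagged, not fatal
  q <- rbind(table4Fixture(),
             data.frame(site = "dead", experiment = 1:2,
                        condition = rep(c("control", "treated"), each = 2),
                        normalizedArea = c(0, 0, 1, 2)))
  fit2 <- reanalyzeTable(q)
  dead <- fit2$results[fit2$results$site == "dead", ]
  expect_equal(dead$flag, "unquantifiable")
  expect_true(is.na(dead$foldChange))
  # unpaired input is rejected
  bad <- table4Fixture()
  bad <- bad[!(bad$site == "Ser29" & bad$experiment == 2 &
                 bad$condition == "treated"), ]
  expect_error(reanalyzeTable(bad), "paired")
})

test_that("sequence coverage is a union, not a sum", {
  expect_equal(sequenceCoverage(100, data.frame(start = 1, stop = 100)), 100)
  expect_equal(sequenceCoverage(100, data.frame(start = c(1, 5),
                                                stop = c(10, 14))), 14)
  expect_error(sequenceCoverage(100, data.frame(start = 0, stop = 5)),
               "out of range")
  expect_error(sequenceCoverage(100, data.frame(start = 90, stop = 101)),
               "out of range")
  # panel intervals against the 982-residue protein, checked against a
  # direct residue-enumeration oracle
  co <- do.call(rbind, lapply(panelEntries(ppp1r12bPanel()), function(e) {
    as.data.frame(t(proteinCoords(e$peptide)))
  }))
  oracle <- 100 * length(unique(unlist(Map(seq, co$start, co$stop)))) / 982
  expect_equal(sequenceCoverage(982, co), oracle, tolerance = 1e-12)
})
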