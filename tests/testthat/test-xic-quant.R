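test_that("precursor XIC tolerance window is ppm-exact", {
  mz0 <- 500
  sp <- list(
    spectrum(1L, 1L, 1.0, mz = mz0, intensity = 100),
    spectrum(2L, 1L, 1.1, mz = mz0 * (1 + 11e-6), intensity = 100),
    spectrum(3L, 1L, 1.2, mz = mz0 * (1 + 9e-6), intensity = 50),
    spectrum(4L, 1L, 1.3)
  )
  run <- spectrumRun("tol", sp)
  ch <- precursorXIC(run, mz0, ppmTol = 10)
  expect_equal(rtime(ch), c(1.0, 1.1, 1.2, 1.3))
  # 11 ppm off is outside, 9 ppm inside; empty scans contribute zero
  expect_equal(ch@intensity, c(100, 0, 50, 0))
  # widening the tolerance never decreases a point intensity
  ch2 <- precursorXIC(run, mz0, ppmTol = 20)
  expect_true(all(ch2@intensity >= ch@intensity))
  # empty run -> empty chromatogram, not an error
  expect_equal(length(precursorXIC(spectrumRun("e", list()), mz0)@rt), 0L)
})

test_that("fragment XIC matches precursor by isolation window and fragment by Da", {
  f <- 754.37
  sp <- list(
    spectrum(1L, 2L, 1.0, mz = f + 0.49, intensity = 10,
             precursorMz = 648.78, isolationWidth = 1.5),
    spectrum(2L, 2L, 1.1, mz = f + 0.51, intensity = 10,
             precursorMz = 648.78, isolationWidth = 1.5),
    spectrum(3L, 2L, 1.2, mz = f, intensity = 99,
             precursorMz = 660.00, isolationWidth = 1.5),  # wrong precursor
    spectrum(4L, 2L, 1.3, mz = f, intensity = 33,
             precursorMz = 649.90, isolationWidth = 1.5)   # inside window
  )
  run <- spectrumRun("frag", sp)
  ch <- fragmentXIC(run, precursorMz = 648.78, fragmentMz = f, daTol = 0.5)
  # scan 3 is excluded entirely (no point), +0.51 peak contributes zero
  expect_equal(rtime(ch), c(1.0, 1.1, 1.3))
  expect_equal(ch@intensity, c(10, 0, 33))
})

test_that("trapezoidal integration matches closed forms", {
  # rectangle via trapezoid
  run2 <- spectrumRun("two", list(
    spectrum(1L, 1L, 2.00, mz = 500, intensity = 40),
    spectrum(2L, 1L, 2.05, mz = 500, intensity = 40)))
  pa <- integratePeak(precursorXIC(run2, 500))
  expect_equal(area(pa), 40 * 0.05, tolerance = 1e-12)
  # all-zero trace -> observed zero with zeroFlag
  z <- integratePeak(precursorXIC(spectrumRun("z", list(
    spectrum(1L, 1L, 1, mz = 100, intensity = 5))), 500))
  expect_true(zeroFlag(z))
  expect_identical(area(z), 0)
  # noiseless Gaussian: area within 2% of A * sigma * sqrt(2*pi)
  A <- 1e5; sigma <- 0.1
  ch <- precursorXIC(gaussRun(A = A, sigma = sigma), 500)
  pa <- integratePeak(ch)
  expect_equal(area(pa), A * sigma * sqrt(2 * pi), tolerance = 0.02)
  expect_equal(rtApex(pa), 5, tolerance = 0.02)
})

test_that("apex selection honors expectedRt", {
  # two Gaussian peaks; expectedRt picks the smaller, nearer one
  t <- seq(0, 10, 0.02)
  int <- 1e5 * exp(-(t - 3)^2 / (2 * 0.01)) + 4e4 * exp(-(t - 7)^2 / (2 * 0.01))
  sp <- lapply(seq_along(t), function(i)
    spectrum(i, 1L, t[i], mz = 500, intensity = int[i]))
  ch <- precursorXIC(spectrumRun("two-peaks", sp), 500)
  expect_equal(rtApex(integratePeak(ch)), 3, tolerance = 0.03)
  expect_equal(rtApex(integratePeak(ch, expectedRt = 6.8)), 7,
               tolerance = 0.03)
})

test_that("quantifier areas are additive and linear in intensity", {
  cfg <- simConfig(nPairs = 1L, seed = 11L, sigmaRun = 0, sigmaPep = 0,
                   ppmJitterSd = 0, fragJitterSd = 0, rtJitterSd = 0)
  run <- simulateExperiment(cfg)$runs[["pair1_control"]]
  panel <- ppp1r12bPanel()
  e <- panelEntries(panel)[[1]]  # Ser29, quantifiers y8+y9
  q <- quantifyPeptide(run, e)
  expect_equal(nrow(q$ions), 2L)
  # sum over quantifier ions
  expect_equal(q$area, sum(q$ions$area), tolerance = 1e-12)
  # each single-ion quantification equals its per-ion area
  e1 <- e; e1$quantifiers <- e$quantifiers[1, , drop = FALSE]
  expect_equal(quantifyPeptide(run, e1)$area, q$ions$area[1],
               tolerance = 1e-12)
  # linearity: scaling all intensities scales every area exactly
  q3 <- quantifyPeptide(scaleRun(run, 3), e)
  expect_equal(q3$area, 3 * q$area, tolerance = 1e-12)
  # internal standards are quantified at their listed precursor charges
  is_e <- panelEntries(panel)[[7]]
  qi <- quantifyPeptide(run, is_e)
  expect_equal(qi$ions$ion, c("prec/+3", "prec/+2"))
  expect_equal(qi$area, sum(qi$ions$area), tolerance = 1e-12)
})

test_that("noiseless fragment areas track configured ion weights and abundance", {
  cfg <- simConfig(nPairs = 1L, seed = 5L, sigmaRun = 0, sigmaPep = 0,
                   ppmJitterSd = 0, fragJitterSd = 0, rtJitterSd = 0)
  sim <- simulateExperiment(cfg)
  run <- sim$runs[["pair1_control"]]
  e <- panelEntries(ppp1r12bPanel())[[1]]
  q <- quantifyPeptide(run, e)
  # two quantifier ions share one weight -> equal areas within 3%
  expect_equal(q$ions$area[1], q$ions$area[2], tolerance = 0.03)
  # a doubled-abundance run yields a 2.0 raw-area ratio within 5%
  cfg2 <- simConfig(nPairs = 1L, seed = 5L, sigmaRun = 0, sigmaPep = 0,
                    ppmJitterSd = 0, fragJitterSd = 0, rtJitterSd = 0,
                    foldMap = c("Ser29" = 2.0))
  sim2 <- simulateExperiment(cfg2)
  q2 <- quantifyPeptide(sim2$runs[["pair1_treated"]], e)
  expect_equal(q2$area / q$area, 2.0, tolerance = 0.05)
})
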