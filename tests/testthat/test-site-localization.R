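## spectrum whose peaks are exactly a given m/z list plus decoys
spec_from_mz <- function(mzs, intensity = 100, decoys = numeric(),
                         decoyInt = 10, precursorMz = 650) {
  mz <- c(mzs, decoys)
  int <- c(rep(intensity, length(mzs)), rep(decoyInt, length(decoys)))
  spectrum(1L, 2L, 5.0, mz = mz, intensity = int, precursorMz = precursorMz,
           precursorCharge = 2L, isolationWidth = 1.5)
}

test_that("binomial tail matches direct summation", {
  expect_identical(binomialTail(0, 6, 0.05), 1)
  expect_equal(binomialTail(3, 3, 0.5), 0.125, tolerance = 1e-12)
  expect_equal(binomialTail(4, 6, 0.05), bruteBinomTail(4, 6, 0.05),
               tolerance = 1e-12)
  for (k in c(3, 7, 15)) for (n in 0:k) for (p in c(0.01, 0.1, 0.5))
    expect_equal(binomialTail(n, k, p), bruteBinomTail(n, k, p),
                 tolerance = 1e-10)
  expect_error(binomialTail(4, 3, 0.5), "nMatched")
  expect_error(binomialTail(1, 3, 0), "p must")
})

test_that("complete site-determining evidence gives a confident call", {
  seqs <- "GSLTEQEPAER"
  # all ions of the pos-2 isoform present, none specific to pos 4
  sp <- spec_from_mz(bruteIons(seqs, site = 2))
  loc <- localize(sp, seqs, candidates = c(2L, 4L))
  expect_equal(bestSite(loc), 2L)
  expect_gte(ascore(loc), 13)
  expect_true(isConfident(loc))
})

test_that("symmetric or absent evidence is ambiguous", {
  seqs <- "GSLTEQEPAER"
  shared <- intersect(round(bruteIons(seqs, site = 2), 2),
                      round(bruteIons(seqs, site = 4), 2))
  sp <- spec_from_mz(shared)
  loc <- localize(sp, seqs, candidates = c(2L, 4L))
  expect_equal(ascore(loc), 0)
  expect_false(isConfident(loc))
  # candidate order does not change the magnitude of the score
  loc2 <- localize(sp, seqs, candidates = c(4L, 2L))
  expect_equal(ascore(loc2), ascore(loc))
})

test_that("a single candidate is confident by construction", {
  sp <- spec_from_mz(bruteIons("SLDEEPICHR", site = 1))
  loc <- localize(sp, "SLDEEPICHR", candidates = 1L)
  expect_true(is.infinite(ascore(loc)))
  expect_true(isConfident(loc))
  expect_true(loc@onlyCandidate)
})

test_that("adding matched site-determining ions never decreases the ascore", {
  seqs <- "GSLTEQEPAER"
  p <- modifiedPeptide(seqs, "phospho@2")
  sdi <- siteDeterminingIons(p, 2, 4)$a$mz
  base <- bruteIons(seqs, site = 2)
  nonSD <- setdiff(round(base, 4), round(sdi, 4))
  prev <- -Inf
  for (k in seq_along(sdi)) {
    sp <- spec_from_mz(c(nonSD, sdi[seq_len(k)]))
    a <- ascore(localize(sp, seqs, candidates = c(2L, 4L)))
    expect_gte(a, prev)
    prev <- a
  }
})

test_that("implementation matches the brute-force enumeration exactly", {
  panel <- ppp1r12bPanel()
  sim <- simulateExperiment(simConfig(nPairs = 1L, seed = 13L))
  run <- sim$runs[[1]]
  ms2 <- Filter(function(s) msLevel(s) == 2L, spectra(run))
  # a handful of simulated MS2 spectra of the two-candidate peptide
  e <- panelEntries(panel)[[1]]  # GSLTEQEPAER
  pmz <- protonatedMz(e$peptide, e$precursorCharge)
  hits <- Filter(function(s) abs(precursorMz(s) - pmz) <= 1.5, ms2)
  expect_gt(length(hits), 3)
  for (sp in hits[1:4]) {
    expect_lte(length(sp@mz), 200)
    got <- localize(sp, "GSLTEQEPAER", candidates = c(2L, 4L))
    ref <- bruteLocalize(sp, "GSLTEQEPAER", candidates = c(2L, 4L))
    expect_identical(bestSite(got), ref$bestSite)
    expect_identical(got@peakDepth, as.integer(ref$depth))
    expect_equal(ascore(got), ref$ascore, tolerance = 1e-10)
  }
  # and on dense random spectra, where depth filtering actually bites
  set.seed(99)
  for (rep in 1:3) {
    mz <- sort(runif(180, 150, 1300))
    sp <- spectrum(1L, 2L, 1, mz = mz, intensity = runif(180, 1, 1000),
                   precursorMz = 650)
    got <- localize(sp, "GSLTEQEPAER", candidates = c(2L, 4L))
    ref <- bruteLocalize(sp, "GSLTEQEPAER", candidates = c(2L, 4L))
    expect_equal(ascore(got), ref$ascore, tolerance = 1e-10)
    expect_identical(got@peakDepth, as.integer(ref$depth))
  }
})

test_that("the adjacent-acceptor peptide stays ambiguous end-to-end", {
  # its site-determining ions (b1/y14) are absent from the simulated
  # spectra, so no spectrum can discriminate the two acceptors
  sim <- simulateExperiment(simConfig(nPairs = 1L, seed = 17L))
  loc <- runLocalize(sim$runs[[1]], ppp1r12bPanel())
  amb <- loc[loc$label == "Ser645/T646", ]
  expect_gt(nrow(amb), 0)
  expect_true(all(amb$ascore == 0))
  expect_true(all(!amb$confident))
  # whereas the clean two-candidate peptide localizes confidently
  s29 <- loc[loc$label == "Ser29", ]
  expect_true(all(s29$confident))
  expect_true(all(s29$bestSite == 2L))
})
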