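## Independent oracles and fixture builders. Everything here is written
## naively (plain loops, direct summation) and must stay independent of the
## package's own code paths it is used to check.

## absolute-tolerance comparison (expect_equal's tolerance is relative)
expect_within <- function(object, expected, tol, label = NULL) {
  act <- testthat::quasi_label(rlang::enquo(object), label)
  dev <- max(abs(object - expected))
  testthat::expect(dev <= tol,
                   sprintf("%s deviates by %.4g (> %.4g) from %s", act$lab,
                           dev, tol, paste(format(expected), collapse = ", ")))
  invisible(object)
}

## direct-summation binomial tail: P(X >= n), X ~ Bin(k, p)
bruteBinomTail <- function(n, k, p) {
  if (n == 0) return(1)
  s <- 0
  for (i in n:k) s <- s + choose(k, i) * p^i * (1 - p)^(k - i)
  s
}

## b/y ion masses by direct per-residue summation (charge 1)
bruteIons <- function(sequence, site = NULL, fixed = NULL) {
  rm <- residueMasses()
  mc <- massConstants()
  a <- strsplit(sequence, "")[[1]]
  n <- length(a)
  d <- numeric(n)
  if (!is.null(fixed) && nrow(fixed)) d[fixed$position] <- fixed$delta
  if (!is.null(site)) d[site] <- d[site] + mc[["phospho"]]
  b <- y <- numeric(n - 1)
  for (i in 1:(n - 1)) {
    b[i] <- sum(rm[a[1:i]]) + sum(d[1:i]) + mc[["proton"]]
    y[i] <- sum(rm[a[(n - i + 1):n]]) + sum(d[(n - i + 1):n]) +
      mc[["water"]] + mc[["proton"]]
  }
  c(b, y)
}

## naive Ascore-style localization: explicit loops over windows, depths
## and ions, mirroring the documented procedure step by step
bruteLocalize <- function(spec, sequence, candidates, fixed = NULL,
                          tol = 0.5, maxDepth = 10, windowSize = 100) {
  mz <- peaksMatrix(spec)[, "mz"]
  int <- peaksMatrix(spec)[, "intensity"]
  ions <- lapply(candidates, bruteIons, sequence = sequence, fixed = fixed)
  nTrials <- length(ions[[1]])

  retainAtDepth <- function(d) {
    win <- floor((mz - min(mz)) / windowSize)
    kept <- c()
    for (w in unique(win)) {
      idx <- which(win == w)
      idx <- idx[order(-int[idx], mz[idx])]
      kept <- c(kept, idx[seq_len(min(d, length(idx)))])
    }
    mz[kept]
  }
  countMatch <- function(theo, peaks) {
    m <- 0
    for (t in theo) if (any(abs(peaks - t) <= tol)) m <- m + 1
    m
  }
  score <- matrix(0, maxDepth, length(candidates))
  for (d in 1:maxDepth) {
    peaks <- retainAtDepth(d)
    for (j in seq_along(candidates))
      score[d, j] <- -10 * log10(
        bruteBinomTail(countMatch(ions[[j]], peaks), nTrials, d / windowSize))
  }
  sep <- numeric(maxDepth)
  for (d in 1:maxDepth) {
    o <- sort(score[d, ], decreasing = TRUE)
    sep[d] <- o[1] - o[2]
  }
  dStar <- which.max(sep)
  ord <- order(-score[dStar, ], candidates)
  best <- candidates[ord[1]]
  runner <- candidates[ord[2]]
  ia <- bruteIons(sequence, best, fixed)
  ib <- bruteIons(sequence, runner, fixed)
  sd_idx <- which(abs(ia - ib) > 1e-9)
  peaks <- retainAtDepth(dStar)
  p <- dStar / windowSize
  sA <- -10 * log10(bruteBinomTail(countMatch(ia[sd_idx], peaks),
                                   length(sd_idx), p))
  sB <- -10 * log10(bruteBinomTail(countMatch(ib[sd_idx], peaks),
                                   length(sd_idx), p))
  asc <- sA - sB
  if (asc < 0) {
    tmp <- best; best <- runner; runner <- tmp
    asc <- -asc
  }
  list(bestSite = best, runnerUpSite = runner, ascore = asc, depth = dStar)
}

## one-peptide MS1 run with a Gaussian elution profile
gaussRun <- function(A = 1e5, sigma = 0.1, center = 5, spacing = 0.02,
                     mz = 500, runLength = 10, runId = "gauss") {
  t <- seq(0, runLength, by = spacing)
  sp <- lapply(seq_along(t), function(i) {
    int <- A * exp(-(t[i] - center)^2 / (2 * sigma^2))
    if (int > A * 1e-12)
      spectrum(i, 1L, t[i], mz = mz, intensity = int)
    else spectrum(i, 1L, t[i])
  })
  spectrumRun(runId, sp)
}

## scale every peak intensity in a run by a constant
scaleRun <- function(run, c) {
  sp <- lapply(spectra(run), function(s) {
    pk <- peaksMatrix(s)
    spectrum(scanId(s), msLevel(s), rtime(s), mz = pk[, "mz"],
             intensity = pk[, "intensity"] * c,
             precursorMz = precursorMz(s),
             precursorCharge = precursorCharge(s),
             isolationWidth = s@isolationWidth)
  })
  spectrumRun(runId(run), sp, condition = condition(run),
              replicate = phosquant::replicate(run))
}

## printed per-experiment ratio columns of the published table
## (control then treated, experiments 1-4)
printedRatios <- list(
  "Ser29"       = list(control = c(0.43, 0.46, 1.10, 2.01),
                       treated = c(1.51, 2.65, 2.18, 5.75)),
  "Ser504"      = list(control = c(0.22, 2.66, 1.11, 0.00),
                       treated = c(8.06, 19.45, 14.62, 4.56)),
  "Ser645/T646" = list(control = c(0.52, 1.02, 1.05, 1.41),
                       treated = c(1.05, 2.05, 2.45, 3.82)),
  "Ser711"      = list(control = c(0.56, 0.76, 1.02, 1.66),
                       treated = c(0.58, 0.32, 1.12, 0.88)),
  "Ser760"      = list(control = c(1.00, 1.04, 0.83, 1.13),
                       treated = c(0.62, 0.83, 0.82, 0.60)),
  "Ser839"      = list(control = c(0.16, 0.33, 0.39, 3.12),
                       treated = c(0.20, 0.66, 0.00, 3.24))
)

## published reference m/z values for the quantified peptides
## (precursor table: [M+H]+ and quantified charge states)
publishedPrecursors <- data.frame(
  sequence = c("LGQTPFDVADEGLVEHLELLQK", "LGQTPFDVADEGLVEHLELLQK",
               "IQSGFFK", "IQSGFFK",
               "SSITEQIPAPAQNTFSASSAR", "SSITEQIPAPAQNTFSASSAR",
               "SYISSLAPR", "SYISSLAPR", "ESAVNLVR", "ESAVNLVR",
               "PSLYTSSHLLWTNR", "PSLYTSSHLLWTNR",
               "LESGGSNPTTSDSYGDR", "LKDENGALIR", "LKDENGALIR"),
  charge = c(3L, 2L, 2L, 1L, 3L, 2L, 2L, 1L, 2L, 1L, 3L, 2L, 2L, 2L, 1L),
  mz = c(817.7637, 1226.1419, 413.7265, 826.4458, 721.6941, 1082.0375,
         497.2718, 993.5364, 444.2509, 887.4945, 558.9581, 837.9336,
         871.8768, 564.8222, 1128.6371),
  stringsAsFactors = FALSE
)

publishedMH <- data.frame(
  sequence = c("LGQTPFDVADEGLVEHLELLQK", "IQSGFFK", "SSITEQIPAPAQNTFSASSAR",
               "SYISSLAPR", "ESAVNLVR", "PSLYTSSHLLWTNR",
               "LESGGSNPTTSDSYGDR", "LKDENGALIR"),
  mh = c(2451.2766, 826.4458, 2163.0677, 993.5364, 887.4945, 1674.8598,
         1742.7464, 1128.6371),
  stringsAsFactors = FALSE
)

## published product-ion table for the quantifier fragment ions
publishedFragments <- data.frame(
  label = c(rep("Ser29", 2), rep("Ser504", 2), rep("Ser645/T646", 8),
            rep("Ser711", 3), rep("Ser760", 3), rep("Ser839", 4)),
  ion = c("y8", "y9", "b4", "y7", "b2", "b3", "b4", "b5", "y10", "y11",
          "y12", "y13", "y6", "y7", "y8", "b7", "y12", "y13", "b3", "y12",
          "y13", "y14"),
  mz = c(959.40, 1072.50, 523.23, 821.39, 269.05, 397.11, 454.13, 553.20,
         1175.59, 1274.66, 1331.68, 1459.74, 754.37, 883.41, 998.44,
         842.30, 1241.59, 1370.63, 410.10, 1299.50, 1356.60, 1413.60),
  stringsAsFactors = FALSE
)
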